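#' Three-level food taxonomy
#'
#' Food categories are organized in three levels: a broad hyper-1 category
#' (e.g. "carbohydrates"), a hyper-2 sub-category (e.g. "pasta dishes"), and
#' the fine-grained category itself. Every fine-grained category has exactly
#' one hyper-2 parent and every hyper-2 exactly one hyper-1 parent, so a
#' prediction can always be mapped up the tree — the basis of the
#' hyper-category fallback when a fine-grained food is unknown. The
#' production system carries 319 fine-grained categories; test taxonomies
#' are smaller.
#'
#' The CSV dialect is `fine,hyper2,hyper1,nutrient_key` with a header.
#'
#' @param file path to the taxonomy CSV.
#' @return object of class `mv_taxonomy`: `table` (data.frame), `levels`
#'   (list of category name vectors for fine, hyper2, hyper1).
#' @export
load_taxonomy <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE,
                        colClasses = "character")
  as_taxonomy(df)
}

#' @rdname load_taxonomy
#' @param df data.frame with columns fine, hyper2, hyper1, nutrient_key.
#' @export
as_taxonomy <- function(df) {
  need <- c("fine", "hyper2", "hyper1")
  if (!all(need %in% names(df))) {
    stop("taxonomy needs columns ", paste(need, collapse = ", "))
  }
  if (is.null(df$nutrient_key)) df$nutrient_key <- df$fine
  df <- df[, c("fine", "hyper2", "hyper1", "nutrient_key")]
  for (i in seq_len(nrow(df))) {
    if (any(!nzchar(trimws(unlist(df[i, need]))))) {
      stop("taxonomy row ", i, " ('", df$fine[i],
           "'): empty level name (orphan category)")
    }
  }
  if (anyDuplicated(df$fine)) {
    stop("duplicate fine-grained categories: ",
         paste(unique(df$fine[duplicated(df$fine)]), collapse = ", "))
  }
  # a hyper2 must map to exactly one hyper1
  par <- unique(df[, c("hyper2", "hyper1")])
  bad <- par$hyper2[duplicated(par$hyper2)]
  if (length(bad)) {
    stop("hyper2 category '", bad[1], "' has multiple hyper1 parents")
  }
  lv <- list(fine = df$fine,
             hyper2 = unique(df$hyper2),
             hyper1 = unique(df$hyper1))
  structure(list(table = df, levels = lv), class = "mv_taxonomy")
}

#' @rdname load_taxonomy
#' @param taxonomy an `mv_taxonomy`.
#' @param path output CSV path.
#' @export
write_taxonomy <- function(taxonomy, path) {
  utils::write.csv(taxonomy$table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.mv_taxonomy <- function(x, ...) {
  cat("mv_taxonomy:", length(x$levels$fine), "fine /",
      length(x$levels$hyper2), "hyper2 /", length(x$levels$hyper1),
      "hyper1 categories\n")
  invisible(x)
}

#' Parent chain of a category
#'
#' @param taxonomy an `mv_taxonomy`.
#' @param category a category name at any level.
#' @return character vector of the category and its ancestors, finest first.
#' @export
parent_chain <- function(taxonomy, category) {
  tb <- taxonomy$table
  i <- match(category, tb$fine)
  if (!is.na(i)) return(c(tb$fine[i], tb$hyper2[i], tb$hyper1[i]))
  i <- match(category, tb$hyper2)
  if (!is.na(i)) return(c(tb$hyper2[i], tb$hyper1[i]))
  if (category %in% tb$hyper1) return(category)
  stop("category '", category, "' is not in the taxonomy")
}

# level sizes in head order fine, hyper2, hyper1
taxonomy_sizes <- function(taxonomy) {
  vapply(taxonomy$levels, length, integer(1))
}
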