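# Per-100-ml nutrient accounting: composition table, category resolution
# with hyper-category fallback, and per-meal assembly.

#' Load a nutrient composition table
#'
#' CSV dialect: `key,kcal_per_100ml,cho_g,pro_g,fat_g` — energy and
#' macronutrients per 100 ml of food volume (the system accounts by volume,
#' not mass). Values must be non-negative; duplicate keys are rejected. A
#' record whose energy is wildly inconsistent with its macros
#' (|kcal - (4 CHO + 4 PRO + 9 fat)| > 50% of kcal) triggers a warning but
#' is kept.
#'
#' @param file CSV path.
#' @return object of class `mv_nutrient_table` (data.frame keyed by `key`).
#' @export
load_nutrient_table <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  as_nutrient_table(df)
}

#' @rdname load_nutrient_table
#' @param df data.frame with the table columns.
#' @export
as_nutrient_table <- function(df) {
  need <- c("key", "kcal_per_100ml", "cho_g", "pro_g", "fat_g")
  if (!all(need %in% names(df))) {
    stop("nutrient table needs columns ", paste(need, collapse = ", "))
  }
  df <- df[, need]
  if (anyDuplicated(df$key)) {
    stop("duplicate nutrient keys: ",
         paste(unique(df$key[duplicated(df$key)]), collapse = ", "))
  }
  for (cn in need[-1]) {
    bad <- which(!is.finite(df[[cn]]) | df[[cn]] < 0)
    if (length(bad)) {
      stop("negative or missing value in row ", bad[1], " ('",
           df$key[bad[1]], "'), column ", cn)
    }
  }
  atwater <- 4 * df$cho_g + 4 * df$pro_g + 9 * df$fat_g
  off <- abs(df$kcal_per_100ml - atwater) / pmax(df$kcal_per_100ml, 1) > 0.5
  if (any(off)) {
    warning("kcal inconsistent with macronutrients for: ",
            paste(df$key[off], collapse = ", "))
  }
  structure(df, class = c("mv_nutrient_table", "data.frame"))
}

#' @rdname load_nutrient_table
#' @param table an `mv_nutrient_table`.
#' @param path output CSV path.
#' @export
write_nutrient_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# Resolve a category to a nutrient record, walking up the taxonomy when the
# fine-grained key is absent. Hyper categories without an explicit record
# get the mean of their descendant records (flagged in provenance).
resolve_record <- function(category, table, taxonomy = NULL) {
  lookup <- function(key) {
    i <- match(key, table$key)
    if (is.na(i)) return(NULL)
    list(kcal = table$kcal_per_100ml[i], cho = table$cho_g[i],
         pro = table$pro_g[i], fat = table$fat_g[i])
  }
  chain <- if (is.null(taxonomy)) category else {
    ch <- parent_chain(taxonomy, category)
    # use each level's nutrient key where defined (fine rows may point at a
    # different table key)
    if (!is.null(taxonomy$table$nutrient_key)) {
      i <- match(ch[1], taxonomy$table$fine)
      if (!is.na(i)) ch[1] <- taxonomy$table$nutrient_key[i]
    }
    ch
  }
  for (pos in seq_along(chain)) {
    rec <- lookup(chain[pos])
    if (!is.null(rec)) {
      return(c(rec, list(resolved_key = chain[pos], level_used = pos,
                         derivation = "table")))
    }
    # derived hyper record: mean over descendant fine categories present
    if (!is.null(taxonomy) &&
        (chain[pos] %in% taxonomy$table$hyper2 ||
           chain[pos] %in% taxonomy$table$hyper1)) {
      tb <- taxonomy$table
      kids <- if (chain[pos] %in% tb$hyper2) {
        tb$nutrient_key[tb$hyper2 == chain[pos]]
      } else tb$nutrient_key[tb$hyper1 == chain[pos]]
      hit <- match(kids, table$key)
      hit <- hit[!is.na(hit)]
      if (length(hit)) {
        return(list(kcal = mean(table$kcal_per_100ml[hit]),
                    cho = mean(table$cho_g[hit]),
                    pro = mean(table$pro_g[hit]),
                    fat = mean(table$fat_g[hit]),
                    resolved_key = chain[pos], level_used = pos,
                    derivation = "child_mean"))
      }
    }
  }
  stop("no nutrient record for '", category, "' (tried: ",
       paste(chain, collapse = " -> "), ")")
}

#' Nutrients for a given category and volume
#'
#' Straight linear scaling of the per-100-ml record:
#' `value = volume_ml / 100 * per_100ml`. If the fine-grained key is absent
#' the hyper-category record is used (explicit if present, otherwise the
#' mean of its children), and the provenance is recorded.
#'
#' @param category a taxonomy category (any level) or a bare table key.
#' @param volume_ml non-negative volume.
#' @param table an `mv_nutrient_table`.
#' @param taxonomy optional `mv_taxonomy` enabling the hyper fallback.
#' @return list: `kcal`, `cho_g`, `pro_g`, `fat_g`, `resolved_key`,
#'   `level_used` (1 = as given), `derivation` ("table" or "child_mean").
#' @export
nutrients_for <- function(category, volume_ml, table, taxonomy = NULL) {
  stopifnot(volume_ml >= 0)
  rec <- resolve_record(category, table, taxonomy)
  s <- volume_ml / 100
  list(kcal = s * rec$kcal, cho_g = s * rec$cho, pro_g = s * rec$pro,
       fat_g = s * rec$fat, resolved_key = rec$resolved_key,
       level_used = rec$level_used, derivation = rec$derivation)
}

#' Assemble a meal estimate from recognized items and volumes
#'
#' @param items list of items, each a list with `category` (or an
#'   `mv_recognition` under `recognition`), `volume` (an
#'   `mv_volume_estimate`) and optional `item_id`.
#' @param table an `mv_nutrient_table`.
#' @param taxonomy optional `mv_taxonomy`.
#' @return object of class `mv_meal_estimate`: `items` data.frame and
#'   `totals` (kcal, cho_g, pro_g, fat_g, volume_ml).
#' @export
assemble_meal <- function(items, table, taxonomy = NULL) {
  rows <- lapply(seq_along(items), function(i) {
    it <- items[[i]]
    cat_name <- it$category %||%
      (if (!is.null(it$recognition)) it$recognition$chosen_label)
    if (is.null(cat_name)) stop("item ", i, " has no category")
    vol <- it$volume
    if (inherits(vol, "mv_volume_estimate")) {
      vid <- vol$item_id
      vol_ml <- vol$volume_ml
    } else {
      vid <- it$item_id %||% i
      vol_ml <- as.numeric(vol)
    }
    iid <- it$item_id %||% vid
    if (!is.null(it$item_id) && inherits(it$volume, "mv_volume_estimate") &&
        !identical(as.integer(it$item_id), as.integer(vol$item_id))) {
      stop("item ", i, ": item_id ", it$item_id,
           " does not match volume estimate id ", vol$item_id)
    }
    nut <- nutrients_for(cat_name, vol_ml, table, taxonomy)
    data.frame(item_id = iid, category = cat_name,
               resolved_key = nut$resolved_key, level_used = nut$level_used,
               derivation = nut$derivation,
               volume_ml = vol_ml, kcal = nut$kcal, cho_g = nut$cho_g,
               pro_g = nut$pro_g, fat_g = nut$fat_g,
               stringsAsFactors = FALSE)
  })
  items_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(item_id = integer(0), category = character(0),
               resolved_key = character(0), level_used = integer(0),
               derivation = character(0), volume_ml = numeric(0),
               kcal = numeric(0), cho_g = numeric(0), pro_g = numeric(0),
               fat_g = numeric(0))
  totals <- list(volume_ml = sum(items_df$volume_ml),
                 kcal = sum(items_df$kcal), cho_g = sum(items_df$cho_g),
                 pro_g = sum(items_df$pro_g), fat_g = sum(items_df$fat_g))
  structure(list(items = items_df, totals = totals),
            class = "mv_meal_estimate")
}

#' @export
print.mv_meal_estimate <- function(x, ...) {
  cat("Meal estimate:", nrow(x$items), "item(s)\n")
  if (nrow(x$items)) {
    print(x$items[, c("item_id", "category", "volume_ml", "kcal", "cho_g",
                      "pro_g", "fat_g")], row.names = FALSE)
  }
  cat(sprintf("Totals: %.1f ml, %.1f kcal, CHO %.1f g, PRO %.1f g, fat %.1f g\n",
              x$totals$volume_ml, x$totals$kcal, x$totals$cho_g,
              x$totals$pro_g, x$totals$fat_g))
  invisible(x)
}

#' Serialize a meal estimate to JSON
#' @param meal an `mv_meal_estimate`.
#' @param path optional output path; if `NULL`, the JSON string is returned.
#' @export
meal_to_json <- function(meal, path = NULL) {
  obj <- list(items = meal$items, totals = meal$totals)
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
  }
}
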