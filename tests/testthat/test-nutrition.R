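# Nutrient table, category resolution with hyper fallback, meal assembly.

test_that("nutrient tables load, validate and round-trip", {
  tab <- toy_nutrients()
  expect_equal(nrow(tab), 7)
  path <- tempfile(fileext = ".csv")
  write_nutrient_table(tab, path)
  rt <- load_nutrient_table(path)
  expect_equal(as.data.frame(rt), as.data.frame(tab))
  unlink(path)
  expect_error(as_nutrient_table(data.frame(
    key = c("a", "a"), kcal_per_100ml = 1, cho_g = 0, pro_g = 0,
    fat_g = 0)), "duplicate")
  expect_error(as_nutrient_table(data.frame(
    key = "a", kcal_per_100ml = -5, cho_g = 0, pro_g = 0, fat_g = 0)),
    "row 1.*kcal_per_100ml")
  expect_warning(as_nutrient_table(data.frame(
    key = "weird", kcal_per_100ml = 500, cho_g = 1, pro_g = 1, fat_g = 1)),
    "inconsistent")
})

test_that("nutrients scale linearly with volume", {
  tab <- as_nutrient_table(data.frame(
    key = "soup", kcal_per_100ml = 60, cho_g = 8, pro_g = 3, fat_g = 2))
  n <- nutrients_for("soup", 150, tab)
  expect_equal(n$kcal, 90)
  expect_equal(n$cho_g, 12)
  z <- nutrients_for("soup", 0, tab)
  expect_equal(unlist(z[c("kcal", "cho_g", "pro_g", "fat_g")]),
               c(kcal = 0, cho_g = 0, pro_g = 0, fat_g = 0))
  # additivity: bit-exact on exactly representable volumes, 1e-12 otherwise
  a <- nutrients_for("soup", 25, tab)
  b <- nutrients_for("soup", 50, tab)
  ab <- nutrients_for("soup", 75, tab)
  expect_identical(a$kcal + b$kcal, ab$kcal)
  expect_identical(a$fat_g + b$fat_g, ab$fat_g)
  a2 <- nutrients_for("soup", 37.3, tab)
  b2 <- nutrients_for("soup", 12.9, tab)
  ab2 <- nutrients_for("soup", 37.3 + 12.9, tab)
  expect_equal(a2$kcal + b2$kcal, ab2$kcal, tolerance = 1e-12)
})

test_that("hyper fallback uses explicit record, then child mean, in order", {
  tax <- toy_taxonomy()
  tab <- toy_nutrients()
  # fine key present: no fallback, provenance says table level 1
  direct <- nutrients_for("beef_patty", 100, tab, tax)
  expect_equal(direct$level_used, 1)
  expect_equal(direct$kcal, 220)
  # chicken_breast present too, so 'meat' record must not shadow fine keys
  expect_equal(nutrients_for("chicken_breast", 100, tab, tax)$kcal, 150)
  # fine key absent, hyper2 has an explicit record
  tab2 <- tab; tab2$key[tab2$key == "chicken_breast"] <- "unused"
  fb <- nutrients_for("chicken_breast", 100, as_nutrient_table(tab2), tax)
  expect_equal(fb$resolved_key, "meat")
  expect_equal(fb$level_used, 2)
  expect_equal(fb$derivation, "table")
  expect_equal(fb$kcal, 190)
  # fine key absent and no explicit hyper record: child mean
  cm <- nutrients_for("carrot_sticks", 100, tab, tax)
  expect_equal(cm$resolved_key, "vegetables")
  expect_equal(cm$derivation, "child_mean")
  expect_equal(cm$kcal, 35)  # broccoli is the only tabulated child
  # rice_pilaf is absent but its hyper2 sibling mashed_potato is tabulated,
  # so the starch child-mean record applies
  rp <- nutrients_for("rice_pilaf", 100, tab, tax)
  expect_equal(rp$resolved_key, "starch")
  expect_equal(rp$derivation, "child_mean")
  expect_equal(rp$kcal, 85)
  # absent at every level: error lists the attempted chain
  tax2 <- as_taxonomy(rbind(tax$table,
    data.frame(fine = "mystery_stew", hyper2 = "stews", hyper1 = "mixed",
               nutrient_key = "mystery_stew")))
  expect_error(nutrients_for("mystery_stew", 100, tab, tax2),
               "mystery_stew.*stews.*mixed")
})

test_that("meals assemble additively and permutation-invariantly", {
  tab <- toy_nutrients()
  mk_vol <- function(id, ml) structure(
    list(item_id = id, volume_ml = ml, footprint_area_mm2 = 1,
         grid_resolution_mm = 1), class = "mv_volume_estimate")
  items <- list(
    list(category = "mashed_potato", volume = mk_vol(1, 150)),
    list(category = "beef_patty", volume = mk_vol(2, 50)))
  meal <- assemble_meal(items, tab)
  expect_equal(meal$totals$kcal, 1.5 * 85 + 0.5 * 220)
  expect_equal(meal$totals$kcal, sum(meal$items$kcal), tolerance = 1e-12)
  meal_rev <- assemble_meal(rev(items), tab)
  expect_equal(meal_rev$totals, meal$totals)
  empty <- assemble_meal(list(), tab)
  expect_equal(empty$totals$kcal, 0)
  expect_equal(nrow(empty$items), 0)
  # mismatched explicit ids are rejected
  bad <- list(list(category = "broccoli", volume = mk_vol(2, 10),
                   item_id = 5))
  expect_error(assemble_meal(bad, tab), "does not match")
})

test_that("meal reports serialize to JSON", {
  tab <- toy_nutrients()
  meal <- assemble_meal(list(list(category = "broccoli", volume = 80)), tab)
  js <- jsonlite::fromJSON(meal_to_json(meal))
  expect_equal(js$totals$kcal, 0.8 * 35)
  expect_equal(js$items$category, "broccoli")
})
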