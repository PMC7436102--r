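# Taxonomy, hierarchical model, training, weighted inference, top-k.

test_that("taxonomy loads, validates, and round-trips", {
  tax <- toy_taxonomy()
  expect_equal(length(tax$levels$fine), 8)
  expect_equal(length(tax$levels$hyper2), 4)
  expect_equal(length(tax$levels$hyper1), 3)
  expect_true(length(tax$levels$hyper1) <= length(tax$levels$hyper2))
  path <- tempfile(fileext = ".csv")
  write_taxonomy(tax, path)
  rt <- load_taxonomy(path)
  expect_equal(rt$table, tax$table)
  unlink(path)
  expect_equal(parent_chain(tax, "broccoli"),
               c("broccoli", "vegetables", "veg"))
  expect_equal(parent_chain(tax, "meat"), c("meat", "protein"))
})

test_that("malformed taxonomies are rejected with row context", {
  expect_error(as_taxonomy(data.frame(
    fine = c("a", "a"), hyper2 = c("x", "x"), hyper1 = c("p", "p"))),
    "duplicate")
  expect_error(as_taxonomy(data.frame(
    fine = c("a", "b"), hyper2 = c("x", "y"), hyper1 = c("p", ""))),
    "orphan")
  expect_error(as_taxonomy(data.frame(
    fine = c("a", "b"), hyper2 = c("x", "x"), hyper1 = c("p", "q"))),
    "multiple hyper1")
})

test_that("model heads are sized by the taxonomy and output simplex rows", {
  tax <- as_taxonomy(data.frame(
    fine = c("a", "b", "c", "d"), hyper2 = c("x", "x", "y", "y"),
    hyper1 = c("p", "p", "q", "q")))
  model <- build_model(tax)
  expect_equal(vapply(model$W, ncol, integer(1)),
               c(fine = 4L, hyper2 = 2L, hyper1 = 2L))
  img <- array(0.5, c(16, 16, 3))
  probs <- predict_probs(model, list(img, img))
  for (p in probs) {
    expect_equal(rowSums(p), c(1, 1), tolerance = 1e-9)
  }
  # deterministic forward pass
  expect_identical(predict_probs(model, list(img)),
                   predict_probs(model, list(img)))
})

test_that("lr = 0 leaves weights unchanged; zero head weight drops its loss", {
  tax <- toy_taxonomy()
  set <- cached("clsset", make_classification_set(tax, 25, seed = 7,
                                                  noise_sigma = 0.02))
  model <- build_model(tax)
  m0 <- train_model(model, set, lr = 0, epochs = 1, seed = 1)
  expect_identical(m0$W, model$W)
  # loss with one head's weight 0 equals the sum of the other two heads
  m1 <- train_model(model, set, lr = 0, epochs = 1, seed = 1,
                    level_weights = c(0, 1, 1))
  m2 <- train_model(model, set, lr = 0, epochs = 1, seed = 1,
                    level_weights = c(0, 1, 0))
  m3 <- train_model(model, set, lr = 0, epochs = 1, seed = 1,
                    level_weights = c(0, 0, 1))
  expect_equal(m1$history$loss, m2$history$loss + m3$history$loss,
               tolerance = 1e-9)
})

test_that("labels outside the taxonomy fail before training", {
  tax <- toy_taxonomy()
  set <- make_classification_set(tax, 2, seed = 1)
  set$labels$fine[1] <- "pizza_margherita"
  expect_error(train_model(build_model(tax), set), "outside the taxonomy")
})

test_that("training on the separable set reaches 90% fine accuracy", {
  tax <- toy_taxonomy()
  set <- cached("clsset", make_classification_set(tax, 25, seed = 7,
                                                  noise_sigma = 0.02))
  model <- train_model(build_model(tax), set, seed = 7)
  expect_equal(nrow(model$history), 20)
  expect_gte(model$history$acc_fine[20], 0.9)
  # reproducible under the same seed
  model2 <- train_model(build_model(tax), set, seed = 7)
  expect_identical(model$W, model2$W)
})

test_that("weighted inference: dominant, fallback, and error cases", {
  p <- list(c(0.9, 0.05, 0.05), c(0.6, 0.4), c(0.5, 0.5))
  r <- weighted_inference(p, c(1, 1, 1), fallback_threshold = 0)
  expect_equal(r$chosen_level, "fine")
  expect_equal(r$chosen_confidence, 0.9)
  p2 <- list(c(0.2, 0.2, 0.2, 0.2, 0.2), c(0.8, 0.2), c(0.7, 0.3))
  r2 <- weighted_inference(p2, c(1, 1, 1), fallback_threshold = 0.5)
  expect_equal(r2$chosen_level, "hyper2")
  expect_equal(r2$chosen_confidence, 0.8)
  expect_error(weighted_inference(p, c(0, 0, 0)), "not all zero")
  expect_error(weighted_inference(list(c(0.5, 0.2), c(1, 0), c(1, 0))),
               "sum to 1")
})

test_that("weighted inference equals brute-force enumeration on a 0.05 grid", {
  # oracle: direct enumeration of the decision rule over two-class heads
  brute <- function(pf, p2, p1, w, thr) {
    conf <- w * c(pf, p2, p1)
    allowed <- c(pf >= thr, TRUE, TRUE)
    best <- -Inf; pick <- NA
    for (l in 3:1) {          # walking coarse-to-fine so fine wins ties
      if (allowed[l] && conf[l] >= best) { best <- conf[l]; pick <- l }
    }
    c("fine", "hyper2", "hyper1")[pick]
  }
  grid <- seq(0.5, 1, by = 0.05)  # max prob of a two-class head
  for (w in list(c(1, 1, 1), c(2, 1, 0.5))) {
    for (thr in c(0, 0.5, 0.75)) {
      for (pf in grid) for (p2 in grid) for (p1 in grid) {
        got <- weighted_inference(
          list(c(pf, 1 - pf), c(p2, 1 - p2), c(p1, 1 - p1)),
          w, thr)$chosen_level
        expect_identical(got, brute(pf, p2, p1, w, thr))
      }
    }
  }
})

test_that("weighted inference is scale-invariant in the level weights", {
  p <- list(c(0.45, 0.55), c(0.7, 0.3), c(0.6, 0.4))
  for (thr in c(0, 0.5, 0.6)) {
    a <- weighted_inference(p, c(1, 2, 1), thr)
    b <- weighted_inference(p, 7.3 * c(1, 2, 1), thr)
    expect_identical(a$chosen_level, b$chosen_level)
    expect_identical(a$chosen_index, b$chosen_index)
  }
})

test_that("fine predictions map consistently up the hierarchy", {
  tax <- toy_taxonomy()
  for (f in tax$levels$fine) {
    ch <- parent_chain(tax, f)
    expect_length(ch, 3)
    expect_true(ch[2] %in% tax$levels$hyper2)
    expect_true(ch[3] %in% tax$levels$hyper1)
  }
})

test_that("top-k accuracy: perfect, exhaustive-k and uniform models", {
  tax <- as_taxonomy(data.frame(
    fine = c("a", "b", "c", "d"), hyper2 = c("x", "x", "y", "y"),
    hyper1 = c("p", "p", "q", "q")))
  set <- make_classification_set(tax, 12, seed = 3, noise_sigma = 0.02)
  trained <- train_model(build_model(tax), set, epochs = 20, seed = 3)
  acc <- withr::with_seed(1, topk_accuracy(trained, set, 3))
  expect_gte(acc$top1[1], 0.9)
  # k = number of classes: always a hit
  acc_all <- withr::with_seed(1, topk_accuracy(trained, set, 4))
  expect_equal(acc_all$topk, c(1, 1, 1))
  # untrained model outputs uniform probabilities: top-1 ~ 1/4 on the fine
  # level (binomial tolerance around 0.25 with n = 48)
  acc_unif <- withr::with_seed(42, topk_accuracy(build_model(tax), set, 1))
  expect_gt(acc_unif$top1[1], 0.25 - 3 * sqrt(0.25 * 0.75 / 48))
  expect_lt(acc_unif$top1[1], 0.25 + 3 * sqrt(0.25 * 0.75 / 48))
  expect_error(topk_accuracy(trained, set, 0), "k")
})

test_that("model checkpoints round-trip through JSON", {
  tax <- toy_taxonomy()
  set <- cached("clsset", make_classification_set(tax, 25, seed = 7,
                                                  noise_sigma = 0.02))
  model <- train_model(build_model(tax), set, epochs = 3, seed = 1)
  path <- tempfile(fileext = ".json")
  save_model(model, path)
  rt <- load_model(path)
  expect_equal(rt$W, model$W, tolerance = 1e-12)
  probs_a <- predict_probs(model, set$images[1:3])
  probs_b <- predict_probs(rt, set$images[1:3])
  expect_equal(probs_a, probs_b, tolerance = 1e-12)
  unlink(path)
})
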