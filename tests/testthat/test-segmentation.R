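# Seeded region growing and merging, the automatic fallback, and the
# Fmin/Fsum metric.

test_that("two uniform disks are segmented to within 2% of truth", {
  fx <- two_disk_image()
  seeds <- strokes_from_truth(fx$truth)
  seg <- region_grow_merge(fx$image, seeds)
  for (k in 1:2) {
    disagree <- sum(xor(seg == k, fx$truth == k)) / sum(fx$truth == k)
    expect_lt(disagree, 0.02)
  }
})

test_that("a grown region is a superset of its seed", {
  fx <- two_disk_image()
  stroke <- seed_stroke(1, cbind(16:20, 20))
  seg <- region_grow_merge(fx$image, list(stroke))
  expect_true(all(seg[cbind(20, 16:20)] == 1L))
  expect_gt(sum(seg == 1L), nrow(stroke$pixels))
})

test_that("tau_grow = 0 on a noisy image keeps exactly the seed pixels", {
  fx <- two_disk_image()
  img <- fx$image + withr::with_seed(9,
    array(stats::rnorm(length(fx$image), 0, 0.02), dim(fx$image)))
  img[] <- pmin(1, pmax(0, img))
  seeds <- strokes_from_truth(fx$truth)
  seg <- region_grow_merge(img, seeds, tau_grow = 0)
  for (s in seeds) {
    expect_equal(sum(seg == s$item_id), nrow(s$pixels))
  }
})

test_that("overlapping strokes raise an error naming both items", {
  fx <- two_disk_image()
  seeds <- list(seed_stroke(1, cbind(18:20, 20)),
                seed_stroke(2, cbind(19:21, 20)))
  expect_error(region_grow_merge(fx$image, seeds), "1.*2|2.*1")
})

test_that("segmentation is invariant to stroke order and pixel order", {
  fx <- two_disk_image()
  seeds <- strokes_from_truth(fx$truth)
  seg1 <- region_grow_merge(fx$image, seeds)
  seeds_rev <- list(
    seed_stroke(2, seeds[[2]]$pixels[rev(seq_len(nrow(seeds[[2]]$pixels))), ]),
    seed_stroke(1, seeds[[1]]$pixels[rev(seq_len(nrow(seeds[[1]]$pixels))), ]))
  seg2 <- region_grow_merge(fx$image, seeds_rev)
  # same pixel partition up to relabeling
  expect_equal(unclass(seg1 > 0), unclass(seg2 > 0))
  expect_equal(fscore_min_sum(seg1, relabel_map(seg2)), c(Fmin = 1, Fsum = 1))
})

test_that("adjacent same-color regions merge; distinct colors do not", {
  img <- array(0.3, c(30, 40, 3))
  img[10:20, 5:20, 1] <- 0.8; img[10:20, 5:20, 2] <- 0.2
  img[10:20, 21:35, 1] <- 0.8; img[10:20, 21:35, 2] <- 0.2
  seeds <- list(seed_stroke(1, cbind(8:12, 15)),
                seed_stroke(2, cbind(25:30, 15)))
  seg <- region_grow_merge(img, seeds)
  expect_equal(max(seg), 1L)  # one merged region
  fx <- two_disk_image()
  seg2 <- region_grow_merge(fx$image, strokes_from_truth(fx$truth))
  expect_equal(max(seg2), 2L)
})

test_that("auto_segment fallback recovers the two disks", {
  fx <- two_disk_image()
  seg <- auto_segment(fx$image)
  expect_equal(max(seg), 2L)
  f <- fscore_min_sum(seg, fx$truth)
  expect_gt(f["Fmin"], 0.95)
})

test_that("auto_segment: empty image, backend plumbing, relabeling", {
  img <- array(0.4, c(40, 40, 3))
  expect_equal(max(auto_segment(img)), 0L)
  backend <- function(image) {
    m <- matrix(0L, dim(image)[1], dim(image)[2])
    m[5:10, 5:10] <- 7L  # arbitrary labels get normalized
    m[20:28, 20:28] <- 3L
    m
  }
  seg <- auto_segment(img, backend)
  expect_setequal(unique(as.integer(seg)), c(0L, 1L, 2L))
  bad_backend <- function(image) stop("boom")
  expect_error(auto_segment(img, bad_backend), "bad_backend")
})

test_that("fscore_min_sum reproduces hand-computed cases", {
  truth <- matrix(0L, 20, 20)
  truth[1:10, 1:10] <- 1L   # 100 px
  truth[11:20, 11:20] <- 2L # 100 px
  expect_equal(fscore_min_sum(truth, truth), c(Fmin = 1, Fsum = 1))
  none <- matrix(0L, 20, 20)
  expect_equal(fscore_min_sum(none, truth), c(Fmin = 0, Fsum = 0))
  # perfect on item 1, half of item 2, no false positives:
  # item-2 F = 2*50/(50+100) = 2/3; pooled F = 2*150/(300+50)
  pred <- truth
  pred[11:20, 11:15] <- 0L
  f <- fscore_min_sum(pred, truth)
  expect_equal(unname(f["Fmin"]), 2 / 3)
  expect_equal(unname(f["Fsum"]), 2 * 150 / (2 * 150 + 0 + 50))
  expect_error(fscore_min_sum(matrix(0L, 5, 5), truth), "mismatch")
})

test_that("Fmin <= Fsum over 1000 random mask pairs", {
  # Holds whenever the prediction has no more items than the truth (the
  # seeded segmenter's output space: one region per seed, merges only).
  # A prediction with spurious extra items can push Fmin above Fsum, because
  # unmatched predicted items count against Fsum but define no Fmin term.
  blobs <- function(seed, kmax) {
    withr::with_seed(seed, {
      m <- matrix(0L, 16, 16)
      for (k in 1:sample(1:kmax, 1)) {
        r0 <- sample(1:12, 1); c0 <- sample(1:12, 1)
        m[r0:(r0 + sample(2:4, 1)), c0:(c0 + sample(2:4, 1))] <- k
      }
      m
    })
  }
  for (i in 1:1000) {
    truth <- relabel_map(blobs(2 * i, 3))
    nt <- max(truth)
    if (nt == 0) next
    pred <- relabel_map(blobs(2 * i + 1, nt))
    if (max(pred) > nt) next
    f <- fscore_min_sum(pred, truth)
    expect_lte(f["Fmin"], f["Fsum"] + 1e-12)
  }
  # documented counterexample outside that domain: one truth item, two
  # predicted items, the spurious one purely false-positive
  truth <- matrix(0L, 8, 8); truth[1:4, 1:4] <- 1L
  pred <- truth; pred[7:8, 7:8] <- 2L
  f <- fscore_min_sum(pred, truth)
  expect_gt(f["Fmin"], f["Fsum"])
})

test_that("seed strokes round-trip through JSON", {
  seeds <- list(seed_stroke(1, cbind(5:9, 7)), seed_stroke(3, cbind(2, 2)))
  path <- tempfile(fileext = ".json")
  write_seeds(seeds, path)
  rt <- read_seeds(path)
  expect_equal(rt[[1]]$pixels, seeds[[1]]$pixels)
  expect_equal(rt[[2]]$item_id, 3L)
  unlink(path)
})
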