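test_that("segmentation preprocessing crops, resizes and standardizes", {
  img <- fix_ds$records$PI_0001$image
  x <- preprocess_for_segmentation(img, NULL, 512)
  expect_equal(dim(x), c(512L, 512L, 3L))
  expect_identical(x[, , 1], x[, , 3])
  expect_equal(mean(x[, , 1]), 0, tolerance = 1e-8)
  x2 <- preprocess_for_segmentation(img, c(10, 50, 10, 50), 64)
  expect_equal(dim(x2), c(64L, 64L, 3L))
  expect_error(preprocess_for_segmentation(img, c(10, 10, 1, 5), 64), "degenerate")
})

test_that("region detection respects the exact pixel threshold", {
  truth <- matrix(0, 40, 40); truth[1:20, 1:20] <- 1
  pred100 <- matrix(0, 40, 40); pred100[1:10, 1:10] <- 1          # 100 overlap
  pred99 <- pred100; pred99[10, 10] <- 0                          # 99 overlap
  expect_true(region_detected(pred100, truth, 100))
  expect_false(region_detected(pred99, truth, 100))
  expect_error(region_detected(matrix(0, 2, 2), truth), "shape")
})

test_that("region detection agrees with brute-force intersection counts", {
  set.seed(13)
  for (i in 1:1000) {
    a <- rand_mask(20, 20, runif(1, 0, 0.6))
    b <- rand_mask(20, 20, runif(1, 0, 0.6))
    thr <- sample(0:80, 1)
    expect_identical(region_detected(a, b, thr),
                     length(intersect(which(a > 0), which(b > 0))) >= thr)
  }
})

test_that("snapshot selection is lexicographic in (DR, IoU) with earliest ties", {
  mk <- function(dr, iou) lapply(seq_along(dr), function(i)
    list(epoch = i, dr = dr[i], iou = iou[i], weights = list()))
  expect_equal(select_segmenter(mk(c(0.8, 0.9, 0.9), c(0.5, 0.6, 0.7)))$epoch, 3)
  expect_equal(select_segmenter(mk(0.5, 0.5))$epoch, 1)
  expect_error(select_segmenter(list()), "no snapshots")
  set.seed(14)
  for (i in 1:1000) {
    n <- sample(2:8, 1)
    dr <- round(runif(n), 2); io <- round(runif(n), 2)
    got <- select_segmenter(mk(dr, io))$epoch
    cand <- which(dr == max(dr))
    expect_equal(got, cand[which.max(io[cand])])
  }
})

test_that("one-epoch training on a few phantoms produces finite DR and IoU", {
  recs <- unname(fix_ds$records[c("MI_0001", "MII_0001", "PI_0001",
                                  "MI_0002", "MII_0002", "PI_0002")])
  out <- train_segmenter(recs, NULL,
                         seg_config(input_side = 32, epochs = 1, base_filters = 4,
                                    samples_per_epoch = 6, detect_px = 20, seed = 1))
  s <- out$snapshots[[1]]
  expect_true(is.finite(s$loss))
  expect_true(s$dr >= 0 && s$dr <= 1)
  expect_true(s$iou >= 0 && s$iou <= 1)
  expect_error(train_segmenter(list(), NULL, seg_config()), "empty")
})

test_that("an all-background prediction scores IoU 0 and DR 0 on nonempty targets", {
  truth <- matrix(0, 30, 30); truth[5:20, 5:20] <- 1
  blank <- matrix(0, 30, 30)
  expect_equal(iou(blank, truth), 0)
  expect_false(region_detected(blank, truth, 100))
  expect_equal(detection_ratio(c(FALSE, FALSE)), 0)
  # and a perfect prediction scores both at their maxima
  expect_equal(iou(truth, truth), 1)
  expect_equal(detection_ratio(c(region_detected(truth, truth, 100))), 1)
})

test_that("predicted GV and FPB masks are disjoint and untrained snapshots are rejected", {
  recs <- unname(fix_ds$records[c("PI_0001", "MII_0001", "MI_0001")])
  out <- train_segmenter(recs, NULL,
                         seg_config(input_side = 32, epochs = 1, base_filters = 4,
                                    samples_per_epoch = 3, detect_px = 20, seed = 2))
  snap <- select_segmenter(out)
  pm <- predict_masks(fix_ds$records$PI_0002$image, snap)
  expect_equal(dim(pm$germinal_vesicle), c(64L, 64L))
  expect_true(all(pm$germinal_vesicle * pm$first_polar_body == 0))
  snap$weights <- NULL
  expect_error(predict_masks(fix_ds$records$PI_0002$image, snap), "no trained weights")
})

test_that("mask resized alongside the image keeps its area fraction on convex regions", {
  rec <- generate_phantom("PI", phantom_params(side = 200), 5)
  gv <- rec$masks$germinal_vesicle
  small <- oostage:::resize_nearest(gv, 64, 64)
  frac_src <- mean(gv)
  frac_dst <- mean(small)
  expect_lt(abs(frac_dst - frac_src), 0.01)
})
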