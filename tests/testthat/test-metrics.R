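# Brute-force reference implementations, kept deliberately naive and
# independent of the package internals.

brute_counts <- function(truth, pred, cls) {
  tp <- 0; fp <- 0; fn <- 0; tn <- 0
  for (i in seq_along(truth)) {
    t_is <- truth[i] == cls
    p_is <- pred[i] == cls
    if (t_is && p_is) tp <- tp + 1
    if (!t_is && p_is) fp <- fp + 1
    if (t_is && !p_is) fn <- fn + 1
    if (!t_is && !p_is) tn <- tn + 1
  }
  c(Tp = tp, Fp = fp, Fn = fn, Tn = tn)
}

test_that("tallies match brute-force counting on random label pairs", {
  set.seed(1)
  for (i in 1:200) {
    r <- rand_tally(sample(5:40, 1))
    for (cls in maturity_classes())
      expect_equal(r$tally$counts[cls, ], brute_counts(r$truth, r$pred, cls))
    expect_true(all(rowSums(r$tally$counts) == length(r$truth)))
  }
})

test_that("all-correct and all-one-class tallies have the expected shape", {
  truth <- rep(maturity_classes(), each = 3)
  t1 <- tally_from_predictions(truth, truth)
  for (cls in maturity_classes())
    expect_equal(t1$counts[cls, ], c(Tp = 3, Fp = 0, Fn = 0, Tn = 6))
  t2 <- tally_from_predictions(truth, rep("MII", 9))
  expect_equal(t2$counts["MII", "Tp"], 3)
  expect_equal(t2$counts["MI", "Fn"], 3)
  expect_error(tally_from_predictions(c("MI"), c("XY")), "unknown label")
})

test_that("per-class coefficients equal the defining formulas on random tallies", {
  set.seed(2)
  for (i in 1:1000) {
    r <- rand_tally(sample(4:30, 1))
    m <- per_class_metrics(r$tally)
    for (k in seq_len(3)) {
      cls <- m$class[k]
      ct <- brute_counts(r$truth, r$pred, cls)
      tp <- ct["Tp"]; fp <- ct["Fp"]; fn <- ct["Fn"]; tn <- ct["Tn"]
      expect_equal(m$ACC[k], unname((tp + tn) / (tp + tn + fp + fn)), tolerance = 1e-12)
      if (tp + fn > 0) expect_equal(m$TPR[k], unname(tp / (tp + fn)), tolerance = 1e-12)
      if (tp + fp > 0) {
        expect_equal(m$PPV[k], unname(tp / (tp + fp)), tolerance = 1e-12)
        expect_equal(m$FDR[k], unname(fp / (fp + tp)), tolerance = 1e-12)
        expect_equal(m$PPV[k] + m$FDR[k], 1, tolerance = 1e-12)
      }
      if (m$PPV[k] + m$TPR[k] > 0)
        expect_equal(m$f1[k], 2 * m$PPV[k] * m$TPR[k] / (m$PPV[k] + m$TPR[k]),
                     tolerance = 1e-12)
    }
  }
})

test_that("accuracy conventions: worked example and the literal printed form", {
  truth <- c("MI", "MII", "MII", "PI", "PI", "PI", "MI", "MI", "MII")
  pred <- c("MII", "MII", "MI", "PI", "PI", "MI", "MI", "MI", "MII")
  tl <- tally_from_predictions(truth, pred)
  std <- per_class_metrics(tl, "standard")
  lit <- per_class_metrics(tl, "literal")
  bal <- per_class_metrics(tl, "balanced")
  # MI: Tp=2, Fp=2, Fn=1, Tn=4
  expect_equal(std$ACC[std$class == "MI"], 6 / 9)
  expect_equal(lit$ACC[lit$class == "MI"], 2 / 6)
  expect_equal(bal$ACC[bal$class == "MI"], 2 / 3)
})

test_that("degenerate tallies yield the documented sentinels", {
  tl <- tally_from_predictions(c("MI", "MI"), c("MII", "MII"))
  m <- per_class_metrics(tl)
  pi_row <- m[m$class == "PI", ]
  expect_equal(pi_row$TPR, 0)   # no PI in truth
  expect_true(pi_row$degenerate)
  mi_row <- m[m$class == "MI", ]
  expect_equal(mi_row$PPV, 0)   # Tp + Fp = 0
})

test_that("IoU equals brute-force pixel arithmetic, with the empty-empty convention", {
  set.seed(3)
  for (i in 1:1000) {
    a <- rand_mask(15, 15, runif(1, 0, 0.5))
    b <- rand_mask(15, 15, runif(1, 0, 0.5))
    ai <- which(a > 0); bi <- which(b > 0)
    expected <- if (length(union(ai, bi)) == 0) 1 else
      length(intersect(ai, bi)) / length(union(ai, bi))
    expect_equal(iou(a, b), expected, tolerance = 1e-12)
  }
  m <- matrix(1, 4, 4)
  expect_equal(iou(m, m), 1)
  expect_equal(iou(m * 0, m * 0), 1)
  expect_equal(iou(rbind(c(1, 0), c(0, 0)), rbind(c(0, 1), c(0, 0))), 0)
  expect_error(iou(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("nested SRRS aggregation equals naive class-then-repetition averaging", {
  set.seed(4)
  for (trial in 1:100) {
    n_rep <- sample(2:5, 1)
    tallies <- lapply(seq_len(n_rep), function(r) rand_tally(20, r)$tally)
    rep_means <- sapply(tallies, function(tl) {
      m <- per_class_metrics(tl)
      mean(c(m$ACC[1], m$ACC[2], m$ACC[3]))
    })
    agg <- aggregate_metrics(tallies)
    expect_equal(unname(agg$means[["ACC"]]), mean(rep_means), tolerance = 1e-12)
  }
  # permutation invariance in repetition order
  tl <- lapply(1:3, function(r) rand_tally(15, r)$tally)
  expect_equal(aggregate_metrics(tl)$means, aggregate_metrics(rev(tl))$means)
})

test_that("identical per-class values pass through the nested means unchanged", {
  truth <- rep(maturity_classes(), each = 4)
  tallies <- lapply(1:3, function(r) tally_from_predictions(truth, truth, r))
  agg <- aggregate_metrics(tallies)
  expect_equal(unname(agg$means[c("ACC", "TPR", "PPV", "f1")]), rep(1, 4),
               ignore_attr = TRUE)
  expect_equal(unname(agg$means[["FDR"]]), 0)
})

test_that("detection ratio is the plain fraction of detected regions", {
  expect_equal(detection_ratio(rep(TRUE, 8)), 1)
  expect_equal(detection_ratio(rep(FALSE, 8)), 0)
  expect_equal(detection_ratio(c(rep(TRUE, 7), rep(FALSE, 3))), 0.7)
  expect_error(detection_ratio(logical(0)), "no detection")
})
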