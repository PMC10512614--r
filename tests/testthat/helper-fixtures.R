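# Shared small fixtures, built once per test run.

fix_params64 <- phantom_params(side = 64)
fix_ds <- generate_dataset(c(MI = 12, MII = 12, PI = 12), fix_params64, seed = 77)
fix_selection <- channel_selection(c("first_polar_body", "germinal_vesicle"),
                                   merge_fpb = TRUE)

# random binary mask helper
rand_mask <- function(h, w, p = 0.3) matrix(as.numeric(stats::runif(h * w) < p), h, w)

# random confusion tally from random label vectors
rand_tally <- function(n = 30, srrs_id = 1L) {
  truth <- sample(maturity_classes(), n, replace = TRUE)
  pred <- sample(maturity_classes(), n, replace = TRUE)
  list(truth = truth, pred = pred,
       tally = tally_from_predictions(truth, pred, srrs_id))
}
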