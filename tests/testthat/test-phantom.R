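test_that("class-conditional mask presence holds across many seeds", {
  for (seed in 1:25) {
    for (lab in maturity_classes()) {
      rec <- generate_phantom(lab, fix_params64, seed)
      gv <- sum(rec$masks$germinal_vesicle)
      fpb <- sum(rec$masks$first_polar_body) +
        sum(rec$masks$fragmented_first_polar_body)
      switch(lab,
        PI = { expect_gt(gv, 0); expect_equal(fpb, 0) },
        MII = { expect_gt(fpb, 0); expect_equal(gv, 0) },
        MI = { expect_equal(gv, 0); expect_equal(fpb, 0) })
    }
  }
})

test_that("generation is deterministic and leaves the caller's RNG alone", {
  set.seed(123); before <- .Random.seed
  a <- generate_phantom("MII", fix_params64, 42)
  expect_identical(.Random.seed, before)
  b <- generate_phantom("MII", fix_params64, 42)
  expect_identical(a, b)
  c <- generate_phantom("MII", fix_params64, 43)
  expect_false(identical(a$image, c$image))
})

test_that("masks are binary, image-shaped, and GV/FPB lie inside the oocyte", {
  for (seed in c(3, 9, 27)) for (lab in c("PI", "MII")) {
    rec <- generate_phantom(lab, fix_params64, seed)
    support <- (rec$masks$zona_pellucida + rec$masks$perivitelline_space +
                  rec$masks$clear_cytoplasm) > 0
    # oocyte support is the filled outer ellipse: close holes by adding
    # every structural/interior mask
    for (nm in canonical_regions()) {
      m <- rec$masks[[nm]]
      expect_identical(dim(m), dim(rec$image))
      expect_true(all(m %in% c(0, 1)))
    }
    interior <- (rec$masks$clear_cytoplasm + rec$masks$perivitelline_space +
                   rec$masks$zona_pellucida + rec$masks$germinal_vesicle +
                   rec$masks$first_polar_body +
                   rec$masks$fragmented_first_polar_body +
                   rec$masks$diffuse_cytoplasmic_granularity +
                   rec$masks$cytoplasmic_granular_area + rec$masks$ser_cluster +
                   rec$masks$vacuoles + rec$masks$dark_cytoplasm) > 0
    disc <- (rec$masks$germinal_vesicle + rec$masks$first_polar_body +
               rec$masks$fragmented_first_polar_body) > 0
    expect_true(all(interior[disc]))
  }
})

test_that("MII polar body covers roughly 10-14 % of the oocyte interior", {
  rec <- generate_phantom("MII", phantom_params(), 7)  # default 256 px
  fpb <- sum(rec$masks$first_polar_body) + sum(rec$masks$fragmented_first_polar_body)
  interior <- sum((rec$masks$zona_pellucida + rec$masks$perivitelline_space +
                     rec$masks$clear_cytoplasm + rec$masks$first_polar_body +
                     rec$masks$fragmented_first_polar_body +
                     rec$masks$diffuse_cytoplasmic_granularity +
                     rec$masks$cytoplasmic_granular_area + rec$masks$ser_cluster +
                     rec$masks$vacuoles + rec$masks$dark_cytoplasm) > 0)
  frac <- fpb / interior
  expect_gt(frac, 0.09)
  expect_lt(frac, 0.15)
})

test_that("unknown labels and negative counts are rejected with guidance", {
  expect_error(generate_phantom("MIII", fix_params64, 1), "MI, MII, PI")
  expect_error(generate_dataset(c(MI = -1, MII = 0, PI = 0), fix_params64, 1),
               "non-negative")
  expect_error(generate_dataset(c(XX = 2), fix_params64, 1), "unknown classes")
})

test_that("generate_dataset honours counts, determinism, and zero counts", {
  expect_equal(nrow(fix_ds$manifest), 36)
  expect_equal(unname(table(fix_ds$manifest$label)[maturity_classes()]),
               c(12L, 12L, 12L), ignore_attr = TRUE)
  again <- generate_dataset(c(MI = 12, MII = 12, PI = 12), fix_params64, seed = 77)
  expect_identical(fix_ds$records, again$records)
  empty <- generate_dataset(c(MI = 0, MII = 0, PI = 0), fix_params64, 0)
  expect_length(empty$records, 0)
  expect_equal(nrow(empty$manifest), 0)
  for (rec in fix_ds$records) validate_record(rec)
})

test_that("write/read round trip is pixel-identical and restores empty masks", {
  d <- withr::local_tempdir()
  recs <- fix_ds$records[c("MI_0001", "MII_0001", "PI_0001")]
  write_dataset(recs, d)
  man <- utils::read.csv(file.path(d, "manifest.csv"))
  expect_equal(nrow(man), 3)
  back <- read_dataset(d)
  for (id in names(recs)) {
    expect_identical(back$records[[id]]$image, recs[[id]]$image)
    for (nm in canonical_regions())
      expect_identical(back$records[[id]]$masks[[nm]], recs[[id]]$masks[[nm]])
  }
  # absent regions must not produce files but must be restored as zeros
  mi <- recs$MI_0001
  expect_false(file.exists(file.path(d, "MI_0001_germinal_vesicle.png")))
  expect_equal(sum(back$records$MI_0001$masks$germinal_vesicle), 0)
})
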