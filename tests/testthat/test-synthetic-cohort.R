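# Synthetic multi-site cohort generator.

test_that("cohort_spec validates its fields and names the offender", {
  expect_error(cohort_spec(n_subjects = 3, n_sites = 4), "n_subjects")
  expect_error(cohort_spec(effect_size = -1), "effect_size")
  expect_error(cohort_spec(class_balance = 1), "class_balance")
  expect_error(cohort_spec(n_timepoints = 2), "n_timepoints")
  expect_error(
    cohort_spec(atlas_sizes = c(A = 6),
                effect_pairs = list(list(atlas = 1, pair = c(2, 9)))),
    "out of range")
  expect_error(
    cohort_spec(atlas_sizes = c(A = 6),
                effect_pairs = list(list(atlas = 3, pair = c(1, 2)))),
    "atlas index")
})

test_that("phenotype table has the requested cardinality and ABIDE columns", {
  spec <- cohort_spec(n_subjects = 100, n_sites = 4, atlas_sizes = c(A = 6),
                      seed = 7)
  ph <- generate_phenotypes(spec)
  expect_equal(nrow(ph), 100)
  expect_length(unique(ph$SITE_ID), 4)
  expect_true(all(c("SUB_ID", "SITE_ID", "AGE_AT_SCAN", "SEX", "DX_GROUP",
                    "EYE_STATUS_AT_SCAN", "HANDEDNESS_CATEGORY", "FIQ")
                  %in% names(ph)))
  expect_true(all(ph$DX_GROUP %in% 0:1))
  expect_true(all(ph$AGE_AT_SCAN >= 6 & ph$AGE_AT_SCAN <= 45))
})

test_that("generation is deterministic in the seed and independent of order", {
  spec <- tiny_spec(seed = 11)
  ph1 <- generate_phenotypes(spec)
  ph2 <- generate_phenotypes(spec)
  expect_identical(ph1, ph2)
  # per-subject streams: generating subject 5 alone matches its value inside
  # the full sweep
  full <- generate_cohort(spec)
  solo <- generate_subject_timeseries(ph1[5, ], 1, spec)
  expect_identical(full$series$A[[5]], solo)
})

test_that("case fraction respects class_balance at n = 1000", {
  spec <- cohort_spec(n_subjects = 1000, n_sites = 4, atlas_sizes = c(A = 6),
                      class_balance = 0.5, seed = 1)
  frac <- mean(generate_phenotypes(spec)$DX_GROUP)
  # 99% binomial interval at n = 1000: 0.5 +/- 2.576 * 0.5 / sqrt(1000)
  expect_gt(frac, 0.45)
  expect_lt(frac, 0.55)
})

test_that("time series have the contracted shape and finite entries", {
  spec <- tiny_spec()
  ph <- generate_phenotypes(spec)
  ts <- generate_subject_timeseries(ph[1, ], 1, spec)
  expect_equal(dim(ts), c(spec$n_timepoints, 6))
  expect_true(all(is.finite(ts)))
  expect_error(generate_subject_timeseries(ph[1, ], 2, spec), "atlas")
})

test_that("null cohorts carry no group difference in functional connectivity", {
  # under effect_size = 0 a two-sample t-test on FC(2,5) should accept the
  # null at level 0.01 in at least 95 of 100 seeded replicates
  keep <- vapply(1:100, function(r) {
    spec <- cohort_spec(n_subjects = 24, n_sites = 2, atlas_sizes = c(A = 6),
                        n_timepoints = 40, effect_size = 0, seed = 5000 + r)
    co <- generate_cohort(spec)
    fc <- vapply(co$series$A, function(ts) pearson_fc(ts)$S[2, 5], numeric(1))
    dx <- co$phenotypes$DX_GROUP
    if (length(unique(dx)) < 2) return(TRUE)
    stats::t.test(fc[dx == 1], fc[dx == 0])$p.value > 0.01
  }, logical(1))
  expect_gte(mean(keep), 0.95)
})

test_that("a large planted effect dominates every non-effect pair", {
  spec <- cohort_spec(n_subjects = 200, n_sites = 2, atlas_sizes = c(A = 6),
                      n_timepoints = 120,
                      effect_pairs = list(list(atlas = 1, pair = c(2, 5))),
                      effect_size = 1.5, seed = 42)
  co <- generate_cohort(spec)
  dx <- co$phenotypes$DX_GROUP
  U <- do.call(rbind, lapply(co$series$A, function(ts) pearson_fc(ts)$U))
  contrast <- abs(colMeans(U[dx == 1, ]) - colMeans(U[dx == 0, ]))
  target <- popconn:::pair_index(2, 5, 6)
  expect_equal(which.max(contrast), target)
  expect_true(all(contrast[target] > contrast[-target]))
})

test_that("group FC contrast on the effect pair is monotone in effect size", {
  contrast_at <- function(es) {
    spec <- cohort_spec(n_subjects = 100, n_sites = 2, atlas_sizes = c(A = 6),
                        n_timepoints = 100,
                        effect_pairs = list(list(atlas = 1, pair = c(2, 5))),
                        effect_size = es, seed = 77)
    co <- generate_cohort(spec)
    dx <- co$phenotypes$DX_GROUP
    fc <- vapply(co$series$A, function(ts) pearson_fc(ts)$S[2, 5], numeric(1))
    abs(mean(fc[dx == 1]) - mean(fc[dx == 0]))
  }
  cs <- vapply(c(0, 0.7, 1.4), contrast_at, numeric(1))
  expect_true(all(diff(cs) >= 0))
})

test_that("write_cohort writes one file per subject per atlas plus the CSV", {
  spec <- cohort_spec(n_subjects = 10, n_sites = 2,
                      atlas_sizes = c(A = 4, B = 5, C = 6),
                      n_timepoints = 12, seed = 9)
  co <- generate_cohort(spec)
  dir <- withr::local_tempdir()
  manifest <- write_cohort(co, dir)
  expect_equal(sum(manifest$kind == "timeseries"), 30)
  expect_equal(sum(manifest$kind == "phenotypes"), 1)
  expect_true(all(file.exists(manifest$path)))

  back <- read_cohort(dir)
  expect_equal(back$phenotypes$SUB_ID, co$phenotypes$SUB_ID)
  for (a in names(co$series)) {
    for (i in seq_len(10)) {
      expect_lt(max(abs(back$series[[a]][[i]] -
                          unclass(co$series[[a]][[i]]))), 1e-9)
    }
  }
})

test_that("degenerate cohorts error rather than writing empty manifests", {
  expect_error(write_cohort(tibble::tibble(), withr::local_tempdir()), "empty")
  spec <- tiny_spec(n = 4)
  co <- generate_cohort(spec)
  co$series$A <- co$series$A[1:3]
  expect_error(write_cohort(co, withr::local_tempdir()),
               as.character(co$phenotypes$SUB_ID[4]))
})
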