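test_that("identical seeds give byte-identical datasets", {
  hyp <- hypothesis_wl_incomplete_rtca("CO2")
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    generate_dataset(hyp, params = list(f = 0.2, d_ac = 0.5),
                     noise = noise_model(seed = 1), out_dir = d,
                     analytes = c("Ser", "Asp", "Glu"))
  }
  for (f in c("precursor.csv", "fragments.csv", "ground_truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  d3 <- withr::local_tempdir()
  generate_dataset(hyp, params = list(f = 0.2, d_ac = 0.5),
                   noise = noise_model(seed = 2), out_dir = d3,
                   analytes = c("Ser", "Asp", "Glu"))
  expect_false(identical(readLines(file.path(d1, "precursor.csv")),
                         readLines(file.path(d3, "precursor.csv"))))
})

test_that("the seed is mandatory and noise parameters are guarded", {
  expect_error(noise_model(), "seed")
  expect_error(noise_model(area_cv = -1, seed = 1), "non-negative")
})

test_that("a noise-free unlabeled culture reproduces the natural column", {
  quiet <- noise_model(area_cv = 0, mz_jitter_ppm = 0, mt_jitter_s = 0,
                       baseline_peak_rate = 0, seed = 1)
  ds <- generate_dataset(hypothesis_wl_incomplete_rtca("CO2"),
                         params = list(f = 0, d_ac = 0), noise = quiet,
                         analytes = c("Ser", "Asp", "Glu"))
  specs <- amino_acid_specs(detectable_only = TRUE)
  matches <- match_amino_acids(ds$precursor, specs)
  expected <- list(Ser = c(96.74, 3.23, 0.04, 0.00),
                   Asp = c(95.67, 4.26, 0.07, 0.00, 0.00),
                   Glu = c(94.62, 5.26, 0.12, 0.00, 0.00, 0.00))
  for (code in names(expected)) {
    sp <- specs[specs$code == code, ]
    m <- normalize_mid(extract_isotopologue_areas(
      ds$precursor, matches[matches$analyte == code, ], sp$n_carbons))
    expect_equal(round_half_up(100 * unname(m$fractions)), expected[[code]])
  }
})

test_that("generated analyte peaks stay within the configured m/z jitter", {
  specs <- amino_acid_specs(detectable_only = TRUE)
  ds <- generate_dataset(hypothesis_wl_incomplete_rtca("CO2"),
                         params = list(f = 0.2, d_ac = 0.5),
                         noise = noise_model(seed = 8, baseline_peak_rate = 0))
  matches <- match_amino_acids(ds$precursor, specs)
  expect_true(all(matches$matched))
  expect_lte(max(abs(matches$ppm_error)), 2 + 1e-9)
})

test_that("full-pipeline MID estimates are unbiased at default noise", {
  specs <- amino_acid_specs(detectable_only = TRUE)
  sp <- specs[specs$code == "Glu", ]
  hyp <- hypothesis_wl_incomplete_rtca("CO2")
  ests <- matrix(NA_real_, nrow = 20, ncol = 6)
  truth <- NULL
  for (s in 1:20) {
    ds <- generate_dataset(hyp, params = list(f = 0.2, d_ac = 0.5),
                           noise = noise_model(seed = 200 + s),
                           analytes = "Glu")
    truth <- ds$truth$analytes$Glu$measured_mid
    m <- match_amino_acids(ds$precursor, sp, mt_window = Inf)
    ests[s, ] <- unname(normalize_mid(extract_isotopologue_areas(
      ds$precursor, m, sp$n_carbons))$fractions)
  }
  se <- apply(ests, 2, stats::sd) / sqrt(nrow(ests))
  bias <- abs(colMeans(ests) - truth)
  expect_true(all(bias <= 3 * se + 1e-4))
})

test_that("bundled reference tables are faithful and internally consistent", {
  tab <- reference_mid_table()
  pick <- function(an, k, cond, rep) {
    sel <- tab$analyte == an & tab$n_labels == k & tab$condition == cond &
      (is.na(rep) | tab$replicate %in% rep)
    tab$abundance_percent[sel][1]
  }
  expect_equal(pick("Ser", 0, "natural", NA), 96.74)
  expect_equal(pick("Glu", 2, "13CO2", 1), 6.51)
  expect_true(is.na(pick("Ser", 3, "13CO2", 1))) # N.D. encoded as missing
  sums <- aggregate(abundance_percent ~ analyte + condition + replicate, tab,
                    function(x) sum(x, na.rm = TRUE), na.action = NULL)
  expect_true(all(abs(sums$abundance_percent - 100) <= 0.15))

  pos <- reference_positional_table()
  expect_equal(pos$abundance_percent[pos$analyte == "Ser" & pos$main == 1 &
                                       pos$side == 0 & pos$condition == "natural"], 1.08)
  # positional splits of the labeled conditions sum to the printed MID rows
  m1 <- pos[pos$analyte == "Glu" & pos$condition == "13CO2" & pos$replicate == 1 &
              (pos$main + pos$side) == 1, "abundance_percent"]
  expect_equal(sum(m1), pick("Glu", 1, "13CO2", 1), tolerance = 0.011)
})
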