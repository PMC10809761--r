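specs <- amino_acid_specs(detectable_only = TRUE)

test_that("peak lists round-trip through write and read", {
  ds <- generate_dataset(hypothesis_wl_incomplete_rtca("CO2"),
                         params = list(f = 0.2, d_ac = 0.5),
                         noise = noise_model(seed = 11),
                         analytes = c("Ser", "Asp", "Glu"))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_peaklist(ds$precursor, tmp)
  back <- read_peaklist(tmp, level = "precursor")
  expect_equal(back$mz, ds$precursor$mz, tolerance = 1e-12)
  expect_equal(back$area, ds$precursor$area, tolerance = 1e-12)
  expect_equal(nrow(back), nrow(ds$precursor))
})

test_that("malformed peak lists are rejected with informative messages", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines("sample_id,mz,area,migration_time_s", tmp)
  expect_warning(pl <- read_peaklist(tmp), "header-only")
  expect_equal(nrow(pl), 0L)

  writeLines(c("sample_id,mz,area", "s,100,5"), tmp)
  expect_error(read_peaklist(tmp), "migration_time_s")

  writeLines(c("sample_id,mz,area,migration_time_s",
               "s,100,5,60", "s,oops,5,61"), tmp)
  expect_error(read_peaklist(tmp), "line 2")
  expect_error(read_peaklist("/nonexistent/peaks.csv"), "not found")
})

test_that("accurate-mass matching respects the ppm tolerance", {
  ser_mz <- specs$mz[specs$code == "Ser"]
  pk <- toy_peaklist(list(
    list(mz = ser_mz * (1 + 2e-6), area = 1000, mt = 80),
    list(mz = ser_mz * (1 + 50e-6), area = 5000, mt = 80)
  ))
  m <- match_amino_acids(pk, specs[specs$code == "Ser", ], ppm_tol = 5)
  expect_true(m$matched)
  expect_equal(m$ppm_error, 2, tolerance = 0.01)

  m_far <- match_amino_acids(toy_peaklist(list(
    list(mz = ser_mz * (1 + 50e-6), area = 5000, mt = 80)
  )), specs[specs$code == "Ser", ], ppm_tol = 5)
  expect_false(m_far$matched)
})

test_that("Leu and Ile are disambiguated by migration time alone", {
  leu <- specs[specs$code == "Leu", ]; ile <- specs[specs$code == "Ile", ]
  pk <- toy_peaklist(list(
    list(mz = leu$mz, area = 800, mt = leu$migration_time_s + 1),
    list(mz = ile$mz, area = 900, mt = ile$migration_time_s - 1)
  ))
  m <- match_amino_acids(pk, rbind(leu, ile), ppm_tol = 5, mt_window = 6)
  expect_true(all(m$matched))
  expect_equal(m$migration_time[m$analyte == "Leu"], leu$migration_time_s + 1)
  expect_equal(m$migration_time[m$analyte == "Ile"], ile$migration_time_s - 1)
})

test_that("isotopologue extraction recovers known areas and honours spacing", {
  ser <- specs[specs$code == "Ser", ]
  areas <- c(9674, 323, 4, 0)
  rows <- lapply(0:2, function(k) {
    list(mz = ser$mz + k * 1.003355, area = areas[k + 1], mt = 80)
  })
  pk <- toy_peaklist(rows)
  m <- match_amino_acids(pk, ser, ppm_tol = 5)
  ia <- extract_isotopologue_areas(pk, m, ser$n_carbons, ppm_tol = 5)
  expect_equal(ia$areas, areas)
  expect_false(ia$detected[4])   # absent isotopologue reported, not invented

  # a peak at +1.000 Th (unit spacing) is ~31.6 ppm off the 13C spacing
  pk_wrong <- toy_peaklist(list(
    list(mz = ser$mz, area = 9674, mt = 80),
    list(mz = ser$mz + 1.000, area = 323, mt = 80)
  ))
  m2 <- match_amino_acids(pk_wrong, ser, ppm_tol = 5)
  ia2 <- extract_isotopologue_areas(pk_wrong, m2, ser$n_carbons, ppm_tol = 5)
  expect_equal(ia2$areas, c(9674, 0, 0, 0))
})

test_that("extraction is invariant to input row order", {
  ds <- generate_dataset(hypothesis_wl_incomplete_rtca("CO2"),
                         params = list(f = 0.2, d_ac = 0.5),
                         noise = noise_model(seed = 5),
                         analytes = c("Ser", "Asp", "Glu"))
  pk <- ds$precursor
  set.seed(1)
  shuffled <- as_peaklist(pk[sample(nrow(pk)), ], level = "precursor")
  for (code in c("Ser", "Glu")) {
    sp <- specs[specs$code == code, ]
    m1 <- match_amino_acids(pk, sp)
    m2 <- match_amino_acids(shuffled, sp)
    expect_equal(extract_isotopologue_areas(pk, m1, sp$n_carbons)$areas,
                 extract_isotopologue_areas(shuffled, m2, sp$n_carbons)$areas)
  }
})
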