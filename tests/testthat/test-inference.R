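mk_obs <- function(states, analytes = c("Ser", "Asp", "Glu")) {
  out <- lapply(analytes, function(a) state_to_mid(states[[a]], a))
  names(out) <- analytes
  out
}

test_that("a noiseless self-fit recovers the generating parameters exactly", {
  hyp <- hypothesis_wl_incomplete_rtca("CO2")
  obs <- mk_obs(simulate_isotopomers(hyp$network,
                                     params = list(f = 0.2, d_ac = 0.75, a_ac = 0)))
  fit <- fit_hypothesis(obs, hyp)
  expect_lt(fit$rss, 1e-10)
  expect_equal(fit$parameters$f, 0.2, tolerance = 1e-9)
  expect_equal(fit$parameters$d_ac, 0.75, tolerance = 1e-9)
  expect_equal(fit$n_obs, 4 + 5 + 6)
})

test_that("fitting rejects uncorrected or non-overlapping observations", {
  hyp <- hypothesis_wl_incomplete_rtca("CO2")
  expect_error(fit_hypothesis(list(Ser = natural_mid(3)), hyp), "not.*corrected")
  expect_error(fit_hypothesis(list(Phe = mid(c(1, rep(0, 9)), corrected = TRUE)),
                              hyp), "no overlap")
})

test_that("ranking follows RSS with a parameter-count tie-break", {
  fake_fit <- function(id, rss, n_free, n_obs = 15L) {
    structure(list(id = id, parameters = setNames(as.list(rep(0.5, n_free)),
                                                  paste0("p", seq_len(n_free))),
                   rss = rss, per_analyte_rss = numeric(0),
                   predicted = list(), observed = list(Ser = c(0.9, 0.1)),
                   flags = list(), n_obs = n_obs, n_free = n_free),
              class = "pathway_fit")
  }
  r1 <- compare_hypotheses(list(fake_fit("A", 0.1, 2), fake_fit("B", 0.5, 2)))
  expect_equal(r1$id, c("A", "B"))
  # exact tie: fewer parameters first
  r2 <- compare_hypotheses(list(fake_fit("rich", 0.2, 3), fake_fit("lean", 0.2, 2)))
  expect_equal(r2$id[1], "lean")
  # a decisive improvement lets the richer model through
  r3 <- compare_hypotheses(list(fake_fit("rich", 0.01, 3), fake_fit("lean", 0.5, 2)))
  expect_equal(r3$id[1], "rich")
  # a marginal improvement does not
  r4 <- compare_hypotheses(list(fake_fit("rich", 0.190, 3), fake_fit("lean", 0.2, 2)))
  expect_equal(r4$id[1], "lean")
  bad <- fake_fit("C", 0.3, 2)
  bad$observed <- list(Ser = c(0.8, 0.2))
  expect_error(compare_hypotheses(list(fake_fit("A", 0.1, 2), bad)),
               "different observation sets")
})

test_that("complete-rTCA data rank the complete variant first (symmetric check)", {
  com <- hypothesis_wl_complete_rtca("CO2")
  obs <- mk_obs(simulate_isotopomers(com$network,
                                     params = list(f = 0.2, d_ac = 0.5, a_ac = 0, r = 0.4)))
  fit_i <- fit_hypothesis(obs, hypothesis_wl_incomplete_rtca("CO2"))
  fit_c <- fit_hypothesis(obs, com)
  rk <- compare_hypotheses(list(fit_i, fit_c))
  expect_equal(attr(rk, "best"), "WL_complete_rTCA")
  expect_lt(fit_c$rss, fit_i$rss)
})

test_that("enrichment ordering test reports Glu > Asp > Ser on labeled data", {
  corrected <- lapply(reference_mids("13CO2", 1), correct_mid)
  res <- enrichment_ordering_test(corrected)
  expect_true(res$holds)
  expect_true(res$meaningful)
  expect_equal(res$ordering, c("Glu", "Asp", "Ser"))

  ctrl <- lapply(reference_mids("control", 1), correct_mid)
  res_ctrl <- enrichment_ordering_test(ctrl)
  expect_false(res_ctrl$meaningful) # near-zero enrichment: not interpretable

  uniform <- list(Ser = mid(c(0.5, 0.5, 0, 0), corrected = TRUE),
                  Asp = mid(c(0.5, 0.5, 0, 0, 0), corrected = TRUE),
                  Glu = mid(c(0.5, 0.5, 0, 0, 0, 0), corrected = TRUE))
  expect_false(enrichment_ordering_test(uniform)$holds)
  expect_error(enrichment_ordering_test(corrected[c("Ser", "Asp")]), "Glu")
})

test_that("acetate-tracer fits bound the acetate contribution sensibly", {
  measured <- reference_mids("acetate_2", 1)
  corrected <- lapply(measured, correct_mid)
  hyp <- hypothesis_wl_incomplete_rtca("acetate")
  tr <- tracer_spec("acetate", positions = 2, enrichment = 1)
  fit <- fit_hypothesis(corrected, hyp, tracer = tr)
  expect_gt(fit$parameters$a_ac, 0)
  expect_lt(fit$parameters$a_ac, 0.2) # trace co-feed, not a bulk carbon source
})
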