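test_that("shipped networks parse with the expected carbon counts", {
  net <- load_network("wl_incomplete_rtca")
  expect_equal(unname(net$metabolites[["pyruvate"]]), 3L)
  expect_equal(unname(net$metabolites[["2OG"]]), 5L)
  expect_setequal(net$params, c("f", "d_ac", "a_ac"))
  expect_setequal(load_network("wl_complete_rtca")$params,
                  c("f", "d_ac", "a_ac", "r"))
})

test_that("grammar violations are rejected with line numbers", {
  base <- c("metabolite: A, 1", "metabolite: B, 1", "metabolite: AB, 2",
            "metabolite: D, 2",
            "source: A enrichment=0.5", "source: B enrichment=0",
            "source: D enrichment=0")
  expect_error(parse_network(text = c(base, "AB[aa] <- A[a] + B[a]")),
               "duplicate letter")
  expect_error(parse_network(text = c(base, "AB[ab] <- D[ab] + B[b]")),
               "mapped twice")
  expect_error(parse_network(text = c(base, "AB[ab] <- A[a] + B[c]")),
               "unmapped")
  expect_error(parse_network(text = c(base, "AB[ab] <- A[a] + C[b]")),
               "unknown metabolite")
  expect_error(parse_network(text = c(base, "AB[ab] <- A[ax] + B[b]")),
               "1 carbons")
  expect_error(parse_network(text = c(base[-3], "AB[ab] <- A[a] + B[b]")),
               "unknown metabolite")
  expect_error(parse_network(text = c(base, "metabolite: big, 9")), "at most 8")
  # orphan: C is neither source nor product
  expect_error(parse_network(text = c(base, "metabolite: C, 1",
                                      "AB[ab] <- A[a] + B[b]")),
               "orphan|no source")
})

test_that("serialization round-trips to the same canonical form", {
  for (id in c("wl_only", "wl_incomplete_rtca", "wl_complete_rtca")) {
    net <- load_network(id)
    txt <- serialize_network(net)
    expect_identical(serialize_network(parse_network(text = txt)), txt)
  }
})

test_that("boundary tracers behave as expected", {
  net <- load_network("wl_incomplete_rtca")
  # fully enriched CO2, no dilution: every metabolite fully labeled
  st <- simulate_isotopomers(net, params = list(f = 1, d_ac = 0, a_ac = 0))
  for (m in c("Ser", "Asp", "Glu")) {
    expect_equal(state_enrichment(st[[m]]), 1, tolerance = 1e-12)
  }
  # condensation of independent pools: A (50% labeled) + B (unlabeled)
  toy <- parse_network(text = c(
    "metabolite: A, 1", "metabolite: B, 1", "metabolite: AB, 2",
    "source: A enrichment=0.5", "source: B enrichment=0",
    "AB[ab] <- A[a] + B[b]"))
  stAB <- simulate_isotopomers(toy)
  expect_equal(unname(state_to_mid(stAB$AB)$fractions), c(0.5, 0.5, 0),
               tolerance = 1e-12)
})

test_that("[2-13C1] acetate labels Ser only at the side-chain methyl carbon", {
  net <- load_network("wl_incomplete_rtca")
  tr <- tracer_spec("acetate", positions = 2, enrichment = 1,
                    contribution = 0.3, contribution_param = "a_ac")
  st <- simulate_isotopomers(net, tracer = tr, params = list(f = 0, d_ac = 0))
  ser <- st$Ser
  # acetate C2 -> acetyl methyl -> pyruvate C3 -> Ser C3 (bit 2)
  expect_equal(ser[[1 + 4]], 0.3, tolerance = 1e-12)
  expect_equal(ser[[1]], 0.7, tolerance = 1e-12)
  pos <- state_to_positional(ser, main_indices = 1)
  expect_equal(pos$abundance[1, 2], 0.3, tolerance = 1e-12) # (main 0, side 1)
  expect_equal(unname(positional_marginal_side(pos)), c(0.7, 0.3, 0),
               tolerance = 1e-12)
})

test_that("simulator matches the tree-recursion enumeration oracle", {
  cases <- list(
    # acyclic networks: the tree recursion is exact
    list(id = "wl_only", bind = list(f = 0.3, d_ac = 0.4, a_ac = 0), tol = 1e-10),
    list(id = "wl_incomplete_rtca", bind = list(f = 0.2, d_ac = 0.75, a_ac = 0), tol = 1e-10),
    list(id = "wl_incomplete_rtca", bind = list(f = 0.05, d_ac = 0, a_ac = 0.3), tol = 1e-10),
    # cyclic recycling: oracle truncated at depth 80 (~10 turns of the
    # cycle), residual mass ~ r^10
    list(id = "wl_complete_rtca", bind = list(f = 0.2, d_ac = 0.5, a_ac = 0, r = 0.4), tol = 1e-4)
  )
  for (cs in cases) {
    net <- load_network(cs$id)
    st <- simulate_isotopomers(net, params = cs$bind)
    for (m in intersect(c("Ser", "Asp", "Glu"), names(net$metabolites))) {
      expect_equal(st[[m]], oracle_state(net, m, cs$bind), tolerance = cs$tol,
                   info = paste(cs$id, m))
    }
  }
})

test_that("states conserve probability and respect tracer monotonicity", {
  net <- load_network("wl_incomplete_rtca")
  prev <- NULL
  for (f in c(0.05, 0.2, 0.5, 0.9)) {
    st <- simulate_isotopomers(net, params = list(f = f, d_ac = 0.3, a_ac = 0))
    sums <- vapply(st, sum, numeric(1))
    expect_equal(unname(sums), rep(1, length(sums)), tolerance = 1e-9)
    enr <- vapply(st[c("Ser", "Asp", "Glu")], state_enrichment, numeric(1))
    if (!is.null(prev)) expect_true(all(enr >= prev - 1e-12))
    prev <- enr
  }
})

test_that("mean labels follow the closed form (2a+f)/3, (2a+2f)/4, (2a+3f)/5", {
  net <- load_network("wl_incomplete_rtca")
  for (f in c(0.05, 0.2)) for (a in c(0.02, 0.05)) {
    st <- simulate_isotopomers(net, params = list(f = f, d_ac = 1 - a / f, a_ac = 0))
    expect_equal(state_enrichment(st$Ser), (2 * a + f) / 3, tolerance = 1e-10)
    expect_equal(state_enrichment(st$Asp), (2 * a + 2 * f) / 4, tolerance = 1e-10)
    expect_equal(state_enrichment(st$Glu), (2 * a + 3 * f) / 5, tolerance = 1e-10)
  }
})

test_that("ring closure never lowers Ser/Asp labeling", {
  inc <- load_network("wl_incomplete_rtca")
  com <- load_network("wl_complete_rtca")
  for (f in c(0.1, 0.3)) for (d in c(0.3, 0.8)) {
    p <- list(f = f, d_ac = d, a_ac = 0)
    st_i <- simulate_isotopomers(inc, params = p)
    for (r in c(0, 0.3, 0.7)) {
      st_c <- simulate_isotopomers(com, params = c(p, r = r))
      for (m in c("Ser", "Asp")) {
        expect_gte(state_enrichment(st_c[[m]]) + 1e-12,
                   state_enrichment(st_i[[m]]))
        if (r > 0) expect_gt(state_enrichment(st_c[[m]]),
                             state_enrichment(st_i[[m]]))
      }
    }
  }
})

test_that("amino-acid prediction maps precursor states through the atom maps", {
  net <- load_network("wl_incomplete_rtca")
  st0 <- simulate_isotopomers(net, params = list(f = 0, d_ac = 0, a_ac = 0))
  pred0 <- predict_amino_acid_mids(st0)
  for (p in pred0) expect_equal(unname(p$mid$fractions)[1], 1)
  st1 <- simulate_isotopomers(net, params = list(f = 1, d_ac = 0, a_ac = 0))
  glu <- predict_amino_acid_mids(st1, analytes = "Glu")$Glu
  expect_equal(unname(glu$mid$fractions), c(0, 0, 0, 0, 0, 1), tolerance = 1e-12)
  expect_true(glu$mid$corrected)
  # requesting an analyte the network cannot produce names it
  st_wl <- simulate_isotopomers(load_network("wl_only"),
                                params = list(f = 0.1, d_ac = 0, a_ac = 0))
  expect_error(predict_amino_acid_mids(st_wl, analytes = c("Ser", "Glu")), "Glu")
})

test_that("the 'only' restriction changes nothing but the metabolite set", {
  net <- load_network("wl_complete_rtca")
  p <- list(f = 0.2, d_ac = 0.5, a_ac = 0, r = 0.3)
  full <- simulate_isotopomers(net, params = p)
  part <- simulate_isotopomers(net, params = p, only = c("Ser", "Glu"))
  expect_false("Thr" %in% names(part))
  for (m in c("Ser", "Glu")) expect_equal(part[[m]], full[[m]], tolerance = 1e-12)
})
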