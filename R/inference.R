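# Pathway-hypothesis fitting: deterministic grid + shrinking-grid refinement
# of tracer/dilution parameters against corrected MIDs, and parsimony-aware
# hypothesis ranking.

#' Define a carbon-fixation pathway hypothesis
#'
#' Bundles an atom-transition network with its free parameters (all bounded
#' in `[0, 1]`) and any fixed bindings. Constructors for the three study
#' hypotheses are provided; `pathway_hypothesis()` builds user-defined
#' ones.
#'
#' @param id Hypothesis identifier.
#' @param network An `atom_network`.
#' @param free Character vector of free parameter names (at most 6).
#' @param fixed Named list of fixed parameter values.
#' @return An object of class `"pathway_hypothesis"`.
#' @export
pathway_hypothesis <- function(id, network, free, fixed = list()) {
  stopifnot(length(free) <= 6L)
  unknown <- setdiff(c(free, names(fixed)), network$params)
  if (length(unknown) > 0L) {
    stop(sprintf("parameter(s) not in network: %s", paste(unknown, collapse = ", ")))
  }
  unbound <- setdiff(network$params, c(free, names(fixed)))
  if (length(unbound) > 0L) {
    stop(sprintf("network parameter(s) neither free nor fixed: %s",
                 paste(unbound, collapse = ", ")))
  }
  structure(list(id = id, network = network, free = free, fixed = fixed),
            class = "pathway_hypothesis")
}

#' @rdname pathway_hypothesis
#' @param tracer_substrate `"CO2"` (free CO2 enrichment `f` and acetyl-CoA
#'   dilution `d_ac`; acetate contribution pinned to 0) or `"acetate"`
#'   (CO2 pinned at natural abundance, i.e. zero excess; acetate
#'   contribution `a_ac` free; no extra dilution).
#' @export
hypothesis_wl_incomplete_rtca <- function(tracer_substrate = c("CO2", "acetate")) {
  .study_hypothesis("WL_incomplete_rTCA", "wl_incomplete_rtca",
                    match.arg(tracer_substrate), extra_free = character(0))
}

#' @rdname pathway_hypothesis
#' @export
hypothesis_wl_complete_rtca <- function(tracer_substrate = c("CO2", "acetate")) {
  .study_hypothesis("WL_complete_rTCA", "wl_complete_rtca",
                    match.arg(tracer_substrate), extra_free = "r")
}

#' @rdname pathway_hypothesis
#' @export
hypothesis_wl_only <- function(tracer_substrate = c("CO2", "acetate")) {
  .study_hypothesis("WL_only", "wl_only", match.arg(tracer_substrate),
                    extra_free = character(0))
}

.study_hypothesis <- function(id, network_id, tracer_substrate, extra_free) {
  net <- load_network(network_id)
  if (tracer_substrate == "CO2") {
    free <- c("f", "d_ac", extra_free)
    fixed <- list(a_ac = 0)
  } else {
    free <- c("a_ac", extra_free)
    fixed <- list(f = 0, d_ac = 0)
  }
  pathway_hypothesis(id, net, free = free, fixed = fixed)
}

#' Fit a pathway hypothesis to corrected MIDs
#'
#' Minimizes the residual sum of squares between predicted and
#' observed MID fractions over every analyte present both in the
#' observations and in the hypothesis network. The observed MIDs must be
#' natural-abundance corrected (tracer-only frame). Optimization is fully
#' deterministic: an exhaustive coarse grid over the bounded parameter box
#' `[0, 1]^k`, then box-constrained quasi-Newton (L-BFGS-B) refinement
#' from the best coarse points; the reported RSS never exceeds the best
#' grid value.
#'
#' The default objective uses relative residuals,
#' `sum(((pred - obs) / (obs + w_floor))^2)`: CE-MS peak areas carry
#' multiplicative noise (they span about four orders of magnitude), so
#' after normalization the absolute error of a MID fraction scales with
#' its size and relative residuals are approximately homoscedastic.
#' `weighting = "none"` gives plain unweighted least squares.
#'
#' @param observed Named list of corrected [mid()] objects (names are
#'   analyte codes).
#' @param hypothesis A [pathway_hypothesis()].
#' @param tracer Optional [tracer_spec()] forwarded to the simulator.
#' @param specs Amino-acid reference table.
#' @param grid_step Coarse grid step; default 0.05 for up to two free
#'   parameters, 0.2 otherwise (refinement still reaches ~3e-3
#'   resolution).
#' @param refine_starts Number of best coarse-grid points used as
#'   independent starts for box-constrained local refinement (guards
#'   against multimodal RSS surfaces; the overall best refined point
#'   wins).
#' @param weighting `"relative"` (default) or `"none"`; see Details.
#' @param w_floor Additive floor inside the relative weights, keeping the
#'   weight of zero/near-zero fractions finite.
#' @param flag_threshold Fraction below which an isotopologue is treated as
#'   absent for the qualitative consistency flags.
#' @return An object of class `"pathway_fit"`: hypothesis id, fitted
#'   parameters, `rss`, per-analyte residuals, predicted MIDs, consistency
#'   flags, `n_obs` (number of fitted MID entries) and `n_free`.
#' @export
fit_hypothesis <- function(observed, hypothesis, tracer = NULL,
                           specs = amino_acid_specs(), grid_step = NULL,
                           refine_starts = 3L, flag_threshold = 0.005,
                           weighting = c("relative", "none"), w_floor = 0.01) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(hypothesis, "pathway_hypothesis"))
  net <- hypothesis$network
  analytes <- intersect(names(observed), names(net$metabolites))
  if (length(analytes) == 0L) {
    stop(sprintf("%s: no overlap between observed analytes and network metabolites",
                 hypothesis$id))
  }
  for (a in analytes) {
    if (!isTRUE(observed[[a]]$corrected)) {
      stop(sprintf("observed MID for %s is not natural-abundance corrected", a))
    }
  }
  obs_vec <- unlist(lapply(analytes, function(a) unname(observed[[a]]$fractions)))
  wts <- if (weighting == "relative") 1 / (obs_vec + w_floor)^2 else rep(1, length(obs_vec))
  k <- length(hypothesis$free)
  if (is.null(grid_step)) grid_step <- if (k <= 2L) 0.05 else 0.2

  predict_for <- function(theta) {
    params <- c(as.list(theta), hypothesis$fixed)
    states <- simulate_isotopomers(net, tracer = tracer, params = params,
                                   only = analytes)
    lapply(analytes, function(a) unname(state_to_mid(states[[a]])$fractions))
  }
  memo <- new.env(parent = emptyenv())
  rss_for <- function(theta) {
    key <- paste(signif(theta, 12), collapse = ",")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    pred <- unlist(predict_for(theta))
    val <- sum(wts * (pred - obs_vec)^2)
    memo[[key]] <- val
    val
  }
  eval_grid <- function(grid) {
    apply(grid, 1L, function(row) rss_for(stats::setNames(row, hypothesis$free)))
  }

  if (k == 0L) {
    best <- stats::setNames(numeric(0), character(0))
    best_rss <- rss_for(best)
  } else {
    axes <- rep(list(seq(0, 1, by = grid_step)), k)
    grid <- as.matrix(expand.grid(axes))
    colnames(grid) <- hypothesis$free
    rss_all <- eval_grid(grid)
    starts <- order(rss_all)[seq_len(min(refine_starts, nrow(grid)))]
    best <- stats::setNames(grid[starts[1L], ], hypothesis$free)
    best_rss <- rss_all[starts[1L]]
    for (s in starts) {
      opt <- stats::optim(
        grid[s, ], function(par) rss_for(stats::setNames(par, hypothesis$free)),
        method = "L-BFGS-B", lower = 0, upper = 1,
        control = list(maxit = 200, factr = 1e4))
      if (opt$value < best_rss) {
        best <- stats::setNames(pmin(1, pmax(0, opt$par)), hypothesis$free)
        best_rss <- opt$value
      }
    }
  }

  pred <- predict_for(best)
  names(pred) <- analytes
  per_analyte <- vapply(analytes, function(a) {
    o <- unname(observed[[a]]$fractions)
    w <- if (weighting == "relative") 1 / (o + w_floor)^2 else rep(1, length(o))
    sum(w * (pred[[a]] - o)^2)
  }, numeric(1))
  flags <- lapply(analytes, function(a) {
    p <- pred[[a]]; o <- unname(observed[[a]]$fractions)
    k_idx <- seq_along(p) - 1L
    list(predicted_but_absent = k_idx[p > flag_threshold & o <= flag_threshold],
         absent_but_predicted = k_idx[o > flag_threshold & p <= flag_threshold])
  })
  names(flags) <- analytes
  structure(
    list(id = hypothesis$id, parameters = as.list(best), rss = best_rss,
         per_analyte_rss = per_analyte,
         predicted = lapply(pred, function(p) mid(p, corrected = TRUE, normalize = TRUE)),
         observed = lapply(observed[analytes], function(m) unname(m$fractions)),
         flags = flags, n_obs = length(obs_vec), n_free = k),
    class = "pathway_fit"
  )
}

#' @export
print.pathway_fit <- function(x, ...) {
  cat(sprintf("<pathway_fit> %s: RSS %.4g over %d MID entries\n", x$id, x$rss, x$n_obs))
  if (length(x$parameters) > 0L) {
    cat("  parameters:", paste(sprintf("%s=%.4f", names(x$parameters),
                                       unlist(x$parameters)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Rank fitted pathway hypotheses
#'
#' Fits are ordered by residual sum of squares, with a deterministic
#' parsimony rule for models of unequal size: a fit with more free
#' parameters only outranks a smaller-model fit when its RSS improvement
#' per extra parameter exceeds `parsimony` times its own
#' per-degree-of-freedom residual `RSS / (n_obs - n_free)`. With duplicate
#' measurements and no error model this guards against a nested supermodel
#' (complete rTCA contains the incomplete cycle at recycling fraction 0)
#' winning the ranking by absorbing noise into its extra bounded
#' parameter. Exact RSS ties break in favor of fewer parameters. All fits
#' must be against the same observations.
#'
#' @param fits List of [fit_hypothesis()] results (>= 2).
#' @param parsimony Penalty factor; 0 recovers raw-RSS ordering.
#' @return A `data.frame` ranking with columns `rank`, `id`, `rss`,
#'   `n_free`, `parameters` and qualitative `flags` summaries; attribute
#'   `best` holds the top id.
#' @export
compare_hypotheses <- function(fits, parsimony = 15) {
  stopifnot(length(fits) >= 2L)
  obs0 <- fits[[1L]]$observed
  for (f in fits[-1L]) {
    same <- identical(names(f$observed), names(obs0)) &&
      all(vapply(names(obs0), function(a) {
        isTRUE(all.equal(f$observed[[a]], obs0[[a]], tolerance = 1e-12))
      }, logical(1)))
    if (!same) stop("fits were computed on different observation sets")
  }
  rss <- vapply(fits, `[[`, numeric(1), "rss")
  nfree <- as.integer(vapply(fits, function(f) as.numeric(f$n_free), numeric(1)))
  ord <- order(rss, nfree)
  # parsimony pass: a smaller model bubbles above a richer one unless the
  # richer one's improvement is decisive
  outranks <- function(i_rich, i_small) {
    dp <- nfree[i_rich] - nfree[i_small]
    if (dp <= 0L) return(rss[i_rich] < rss[i_small])
    df <- max(1L, fits[[i_rich]]$n_obs - nfree[i_rich])
    gain <- rss[i_small] - rss[i_rich]
    gain / dp > parsimony * rss[i_rich] / df
  }
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (p in seq_len(length(ord) - 1L)) {
      a <- ord[p]; b <- ord[p + 1L]
      swap <- if (nfree[a] > nfree[b]) !outranks(a, b) else FALSE
      if (swap) { ord[p] <- b; ord[p + 1L] <- a; changed <- TRUE }
    }
  }
  flag_summary <- vapply(fits, function(f) {
    n_bad <- sum(vapply(f$flags, function(fl) {
      length(fl$predicted_but_absent) + length(fl$absent_but_predicted)
    }, numeric(1)))
    sprintf("%d isotopologue presence mismatches", n_bad)
  }, character(1))
  out <- data.frame(
    rank = seq_along(ord),
    id = vapply(fits, `[[`, character(1), "id")[ord],
    rss = rss[ord],
    n_free = nfree[ord],
    parameters = vapply(fits[ord], function(f) {
      if (length(f$parameters) == 0L) return("")
      paste(sprintf("%s=%.4f", names(f$parameters), unlist(f$parameters)), collapse = ", ")
    }, character(1)),
    flags = flag_summary[ord],
    stringsAsFactors = FALSE
  )
  attr(out, "best") <- out$id[1L]
  out
}

#' Test the labeled-carbon enrichment ordering Glu > Asp > Ser
#'
#' Under the Wood-Ljungdahl pathway with an incomplete reductive TCA cycle
#' the 2-oxoglutarate-derived Glu accumulates more label than the
#' oxaloacetate-derived Asp, which in turn exceeds the pyruvate-derived
#' Ser (each step down the chain adds one CO2-derived carbon). A complete
#' reductive cycle would recycle label back into Ser/Asp and erode the
#' ordering.
#'
#' @param observed Named list of corrected [mid()]s containing at least
#'   `Ser`, `Asp`, `Glu`; a missing analyte is an error naming it.
#' @param threshold Enrichment below which the comparison is flagged as not
#'   meaningful (near-zero labeling, e.g. negative controls).
#' @return List with `enrichments` (named, descending), `ordering`
#'   (analyte codes in descending enrichment), `holds` (is the order
#'   exactly Glu > Asp > Ser), and `meaningful` (largest enrichment above
#'   `threshold`).
#' @export
enrichment_ordering_test <- function(observed, threshold = 0.005) {
  needed <- c("Ser", "Asp", "Glu")
  missing <- setdiff(needed, names(observed))
  if (length(missing) > 0L) {
    stop(sprintf("missing analyte(s): %s", paste(missing, collapse = ", ")))
  }
  e <- vapply(observed[needed], enrichment, numeric(1))
  ord <- names(sort(e, decreasing = TRUE))
  list(
    enrichments = sort(e, decreasing = TRUE),
    ordering = ord,
    holds = identical(ord, c("Glu", "Asp", "Ser")) &&
      e[["Glu"]] > e[["Asp"]] && e[["Asp"]] > e[["Ser"]],
    meaningful = max(e) > threshold
  )
}
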