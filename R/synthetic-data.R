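# Seeded synthetic CE-MS datasets with ground truth: pathway-simulated
# isotopomer distributions convolved with natural 13C abundance, scaled to
# peak areas with multiplicative log-normal noise, ppm-scale mass jitter,
# migration-time jitter and low-level baseline peaks.

#' Noise model for the synthetic CE-MS generator
#'
#' Defaults bracket the diagnostics of the real acquisitions the generator
#' emulates: observed mass errors of a few ppm at most, peak areas spanning
#' roughly four orders of magnitude, and sub-minute migration-time
#' reproducibility.
#'
#' @param area_cv Coefficient of variation of the multiplicative
#'   log-normal area noise (0.05 = 5%).
#' @param mz_jitter_ppm Half-width of the uniform m/z jitter, ppm.
#' @param mt_jitter_s Standard deviation of the normal migration-time
#'   jitter, seconds.
#' @param baseline_peak_rate Expected number of spurious background peaks
#'   per spectrum (Poisson); their areas are drawn log-uniform below the
#'   smallest analyte peak.
#' @param area_scale Nominal area of a fully abundant analyte; individual
#'   analytes scatter around it over ~3 orders of magnitude.
#' @param seed Mandatory RNG seed; identical seeds give byte-identical
#'   output files.
#' @return An object of class `"noise_model"`.
#' @export
noise_model <- function(area_cv = 0.05, mz_jitter_ppm = 2, mt_jitter_s = 2,
                        baseline_peak_rate = 20, area_scale = 1e6, seed) {
  if (missing(seed) || !is.numeric(seed)) stop("a numeric RNG seed is mandatory")
  vals <- c(area_cv, mz_jitter_ppm, mt_jitter_s, baseline_peak_rate, area_scale)
  if (any(vals < 0)) stop("noise parameters must be non-negative")
  structure(list(area_cv = area_cv, mz_jitter_ppm = mz_jitter_ppm,
                 mt_jitter_s = mt_jitter_s, baseline_peak_rate = baseline_peak_rate,
                 area_scale = area_scale, seed = as.integer(seed)),
            class = "noise_model")
}

#' Generate a ground-truth-annotated synthetic CE-MS dataset
#'
#' Simulates steady-state labeling under a pathway network and tracer,
#' convolves the tracer-only distributions with natural 13C abundance
#' (per-carbon probability `p13`), scales fractions to peak areas, applies
#' the noise model, and emits precursor and side-chain fragment peak lists
#' in the same CSV dialect [read_peaklist()] consumes, together with the
#' generating ground truth. Analytes in the reference table but absent
#' from the network (aromatics etc.) are emitted unlabeled apart from
#' natural abundance, so the full detectable amino-acid panel is present
#' for annotation tests.
#'
#' @param network An `atom_network` (or a [pathway_hypothesis()], whose
#'   network and fixed parameters are used).
#' @param tracer A [tracer_spec()] or `NULL`.
#' @param params Named list binding the network's free parameters.
#' @param noise A [noise_model()].
#' @param specs Amino-acid reference table.
#' @param analytes Codes to emit; default all detectable analytes.
#' @param p13 Natural 13C abundance used in the forward convolution.
#' @param fragment_yield Fragment ion area relative to its precursor.
#' @param sample_id Sample identifier written into the peak lists.
#' @param out_dir If non-`NULL`, write `precursor.csv`, `fragments.csv`
#'   and `ground_truth.json` there.
#' @return List with `precursor` and `fragments` peak lists, `truth`
#'   (per-analyte tracer-only and measured MIDs, positional joints, scales,
#'   parameters), and `paths` when files were written.
#' @export
generate_dataset <- function(network, tracer = NULL, params = list(),
                             noise, specs = amino_acid_specs(),
                             analytes = NULL, p13 = 0.011,
                             fragment_yield = 0.3, sample_id = "synthetic",
                             out_dir = NULL) {
  stopifnot(inherits(noise, "noise_model"))
  hypothesis_id <- NA_character_
  if (inherits(network, "pathway_hypothesis")) {
    hypothesis_id <- network$id
    params <- c(params, network$fixed[setdiff(names(network$fixed), names(params))])
    network <- network$network
  }
  if (is.null(analytes)) analytes <- specs$code[specs$detectable]
  specs_use <- specs[match(analytes, specs$code), , drop = FALSE]
  if (anyNA(specs_use$code)) stop("unknown analyte code(s) requested")

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(noise$seed)

  states <- simulate_isotopomers(network, tracer = tracer, params = params)

  lognoise <- function(n) {
    if (noise$area_cv <= 0) return(rep(1, n))
    sdlog <- sqrt(log(1 + noise$area_cv^2))
    exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
  }
  jitter_mz <- function(mz) {
    if (noise$mz_jitter_ppm <= 0) return(mz)
    mz * (1 + stats::runif(length(mz), -noise$mz_jitter_ppm, noise$mz_jitter_ppm) * 1e-6)
  }

  prec_rows <- list()
  frag_rows <- list()
  truth <- list()
  min_analyte_area <- Inf
  for (i in seq_len(nrow(specs_use))) {
    sp <- specs_use[i, ]
    n <- sp$n_carbons
    main_idx <- .parse_indices(sp$main_indices)
    n_main <- length(main_idx); n_side <- n - n_main
    if (sp$code %in% names(states)) {
      joint_true <- state_to_positional(states[[sp$code]], main_idx)$abundance
    } else {
      joint_true <- matrix(0, n_main + 1L, n_side + 1L)
      joint_true[1L, 1L] <- 1
    }
    joint_meas <- na_matrix(n_main, p13) %*% joint_true %*% t(na_matrix(n_side, p13))
    true_mid <- .joint_total_margin(joint_true)
    meas_mid <- .joint_total_margin(joint_meas)

    scale <- noise$area_scale * 10^stats::runif(1, -1.5, 1.5)
    mt <- sp$migration_time_s +
      if (noise$mt_jitter_s > 0) stats::rnorm(1, 0, noise$mt_jitter_s) else 0

    keep <- which(meas_mid > 1e-12) - 1L
    areas <- scale * meas_mid[keep + 1L] * lognoise(length(keep))
    min_analyte_area <- min(min_analyte_area, areas)
    prec_rows[[sp$code]] <- data.frame(
      sample_id = sample_id,
      mz = jitter_mz(sp$mz + keep * .c13_spacing),
      area = areas,
      migration_time_s = rep(mt, length(keep)),
      stringsAsFactors = FALSE
    )
    # fragment spectra per isolated precursor isotopologue
    fr <- list()
    for (k in keep) {
      for (ks in 0:min(k, n_side)) {
        km <- k - ks
        if (km > n_main) next
        q <- joint_meas[km + 1L, ks + 1L]
        if (q <= 1e-12) next
        fr[[length(fr) + 1L]] <- data.frame(
          sample_id = sample_id,
          mz = jitter_mz(sp$frag_mz + ks * .c13_spacing),
          area = fragment_yield * scale * q * lognoise(1),
          migration_time_s = mt,
          precursor_name = sp$code,
          precursor_isotopologue = k,
          stringsAsFactors = FALSE
        )
      }
    }
    if (length(fr) > 0L) frag_rows[[sp$code]] <- do.call(rbind, fr)
    truth[[sp$code]] <- list(
      true_mid = unname(true_mid), measured_mid = unname(meas_mid),
      true_joint = unname(joint_true), area_scale = scale
    )
  }

  n_baseline <- if (noise$baseline_peak_rate > 0) stats::rpois(1, noise$baseline_peak_rate) else 0L
  if (n_baseline > 0L) {
    hi <- log10(min_analyte_area)
    prec_rows[["baseline"]] <- data.frame(
      sample_id = sample_id,
      mz = stats::runif(n_baseline, 70, 500),
      area = 10^stats::runif(n_baseline, hi - 3, hi),
      migration_time_s = stats::runif(n_baseline, 30, 180),
      stringsAsFactors = FALSE
    )
  }

  precursor <- as_peaklist(do.call(rbind, c(prec_rows, list(make.row.names = FALSE))),
                           level = "precursor")
  fragments <- as_peaklist(
    if (length(frag_rows) > 0L) {
      do.call(rbind, c(frag_rows, list(make.row.names = FALSE)))
    } else {
      data.frame(sample_id = character(0), mz = numeric(0), area = numeric(0),
                 migration_time_s = numeric(0), precursor_name = character(0),
                 precursor_isotopologue = numeric(0))
    },
    level = "fragment")

  truth_all <- list(hypothesis = hypothesis_id, parameters = params,
                    tracer = if (!is.null(tracer)) unclass(tracer) else NULL,
                    p13 = p13, seed = noise$seed, analytes = truth,
                    n_baseline = n_baseline)
  out <- list(precursor = precursor, fragments = fragments, truth = truth_all)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    paths <- c(precursor = file.path(out_dir, "precursor.csv"),
               fragments = file.path(out_dir, "fragments.csv"),
               truth = file.path(out_dir, "ground_truth.json"))
    write_peaklist(precursor, paths[["precursor"]])
    write_peaklist(fragments, paths[["fragments"]])
    jsonlite::write_json(truth_all, paths[["truth"]], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    out$paths <- paths
  }
  out
}

.joint_total_margin <- function(joint) {
  nm <- nrow(joint) - 1L; ns <- ncol(joint) - 1L
  out <- numeric(nm + ns + 1L)
  for (km in 0:nm) for (ks in 0:ns) {
    out[km + ks + 1L] <- out[km + ks + 1L] + joint[km + 1L, ks + 1L]
  }
  out
}
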