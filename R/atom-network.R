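# Carbon atom-transition networks: a small text grammar for metabolites,
# reactions with per-carbon maps, tracer sources and pool dilution, plus a
# steady-state positional isotopomer simulator over 2^n labeling patterns.

#' Network file grammar
#'
#' One directive or reaction per line; `#` starts a comment. Directives:
#' \preformatted{
#' metabolite: name, nC
#' source: name enrichment=EXPR [positions=i;j]
#' dilute: name fraction=EXPR
#' symmetric: name
#' }
#' Reactions map product carbons from substrate carbons by shared letters,
#' with an optional relative flux weight:
#' \preformatted{
#' product[cabd] <- subA[ab] + subB[cd] @ EXPR
#' }
#' Each product letter must appear in exactly one substrate slot; substrate
#' letters absent from the product are carbons released (e.g. as CO2).
#' `EXPR` is a number, a parameter name, or `1-name`. When several
#' reactions produce the same metabolite, its steady-state pool is the
#' weight-normalized mixture of their outputs. `symmetric` declares a
#' molecule (succinate, fumarate) whose two indistinguishable orientations
#' are averaged 50/50. `dilute` mixes a fraction of the pool from an
#' unlabeled reservoir.
#'
#' @name network_grammar
NULL

.parse_expr <- function(token, where) {
  token <- trimws(token)
  if (grepl("^[0-9.eE+-]+$", token) && !is.na(suppressWarnings(as.numeric(token)))) {
    return(list(kind = "const", value = as.numeric(token)))
  }
  if (grepl("^1-[A-Za-z_][A-Za-z0-9_.]*$", token)) {
    return(list(kind = "one_minus", name = sub("^1-", "", token)))
  }
  if (grepl("^[A-Za-z_][A-Za-z0-9_.]*$", token)) {
    return(list(kind = "param", name = token))
  }
  stop(sprintf("%s: cannot parse expression '%s'", where, token))
}

.expr_params <- function(e) if (e$kind == "const") character(0) else e$name

.eval_expr <- function(e, params, where) {
  if (e$kind == "const") return(e$value)
  if (!e$name %in% names(params)) {
    stop(sprintf("%s: unbound parameter '%s'", where, e$name))
  }
  v <- params[[e$name]]
  if (e$kind == "one_minus") 1 - v else v
}

.deparse_expr <- function(e) {
  switch(e$kind,
         const = format(e$value),
         param = e$name,
         one_minus = paste0("1-", e$name))
}

#' Parse a carbon atom-transition network
#'
#' @param path Path to a network file, or a character vector of lines via
#'   `text`.
#' @param text Optional character vector of lines (overrides `path`).
#' @return An object of class `"atom_network"`: metabolite carbon counts,
#'   source pools, dilution fractions, symmetric metabolites, reactions
#'   with validated atom maps, and the set of free parameter names.
#'   Violations (unmapped or doubly mapped product carbons, unknown
#'   metabolites, inconsistent carbon counts) are reported with line
#'   numbers.
#' @seealso [network_grammar]
#' @export
parse_network <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    if (is.null(path) || !file.exists(path)) stop(sprintf("network file not found: %s", path))
    text <- readLines(path, warn = FALSE)
  }
  lines <- sub("#.*$", "", text)
  metabolites <- integer(0)
  sources <- list()
  dilutions <- list()
  symmetric <- character(0)
  reactions <- list()

  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (!nzchar(line)) next
    where <- sprintf("line %d", ln)
    if (grepl("^metabolite:", line)) {
      body <- trimws(sub("^metabolite:", "", line))
      parts <- trimws(strsplit(body, ",", fixed = TRUE)[[1]])
      if (length(parts) != 2L) stop(sprintf("%s: expected 'metabolite: name, nC'", where))
      nm <- parts[1]; nc <- suppressWarnings(as.integer(parts[2]))
      if (is.na(nc) || nc < 1L) stop(sprintf("%s: invalid carbon count for %s", where, nm))
      if (nc > 8L) stop(sprintf("%s: %s has %d carbons; at most 8 are supported", where, nm, nc))
      if (nm %in% names(metabolites)) stop(sprintf("%s: duplicate metabolite %s", where, nm))
      metabolites[nm] <- nc
    } else if (grepl("^source:", line)) {
      body <- trimws(sub("^source:", "", line))
      toks <- strsplit(body, "\\s+")[[1]]
      nm <- toks[1]
      kv <- .parse_kv(toks[-1], where)
      if (!"enrichment" %in% names(kv)) stop(sprintf("%s: source needs enrichment=", where))
      pos <- if ("positions" %in% names(kv)) as.integer(strsplit(kv[["positions"]], ";")[[1]]) else NULL
      sources[[nm]] <- list(enrichment = .parse_expr(kv[["enrichment"]], where), positions = pos)
    } else if (grepl("^dilute:", line)) {
      body <- trimws(sub("^dilute:", "", line))
      toks <- strsplit(body, "\\s+")[[1]]
      kv <- .parse_kv(toks[-1], where)
      if (!"fraction" %in% names(kv)) stop(sprintf("%s: dilute needs fraction=", where))
      dilutions[[toks[1]]] <- .parse_expr(kv[["fraction"]], where)
    } else if (grepl("^symmetric:", line)) {
      symmetric <- c(symmetric, trimws(sub("^symmetric:", "", line)))
    } else if (grepl("<-", line, fixed = TRUE)) {
      reactions[[length(reactions) + 1L]] <- .parse_reaction(line, ln)
    } else {
      stop(sprintf("%s: cannot parse '%s'", where, line))
    }
  }
  net <- structure(
    list(metabolites = metabolites, sources = sources, dilutions = dilutions,
         symmetric = symmetric, reactions = reactions),
    class = "atom_network"
  )
  .validate_network(net)
  net$params <- .network_params(net)
  net$compiled <- .compile_network(net)
  net
}

.parse_kv <- function(tokens, where) {
  kv <- character(0)
  for (tk in tokens) {
    if (!grepl("=", tk, fixed = TRUE)) stop(sprintf("%s: expected key=value, got '%s'", where, tk))
    parts <- strsplit(tk, "=", fixed = TRUE)[[1]]
    kv[parts[1]] <- parts[2]
  }
  kv
}

.parse_reaction <- function(line, ln) {
  where <- sprintf("line %d", ln)
  weight <- list(kind = "const", value = 1)
  if (grepl("@", line, fixed = TRUE)) {
    parts <- strsplit(line, "@", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop(sprintf("%s: multiple '@' in reaction", where))
    line <- parts[1]
    weight <- .parse_expr(parts[2], where)
  }
  sides <- strsplit(line, "<-", fixed = TRUE)[[1]]
  if (length(sides) != 2L) stop(sprintf("%s: reaction must contain one '<-'", where))
  prod <- .parse_species(sides[1], where)
  subs <- lapply(strsplit(sides[2], "+", fixed = TRUE)[[1]], .parse_species, where = where)
  list(product = prod$name, prod_letters = prod$letters,
       substrates = subs, weight = weight, line = ln)
}

.parse_species <- function(s, where) {
  s <- trimws(s)
  m <- regmatches(s, regexec("^([A-Za-z0-9_.]+)\\[([A-Za-z]+)\\]$", s))[[1]]
  if (length(m) != 3L) stop(sprintf("%s: cannot parse species '%s' (expected name[letters])", where, s))
  list(name = m[2], letters = strsplit(m[3], "")[[1]])
}

.validate_network <- function(net) {
  mets <- net$metabolites
  for (nm in names(net$sources)) {
    if (!nm %in% names(mets)) stop(sprintf("source '%s' is not a declared metabolite", nm))
    pos <- net$sources[[nm]]$positions
    if (!is.null(pos) && any(!(pos %in% seq_len(mets[nm])))) {
      stop(sprintf("source '%s': labeled positions outside 1..%d", nm, mets[nm]))
    }
  }
  for (nm in c(names(net$dilutions), net$symmetric)) {
    if (!nm %in% names(mets)) stop(sprintf("'%s' is not a declared metabolite", nm))
  }
  produced <- character(0)
  for (r in net$reactions) {
    where <- sprintf("line %d (%s)", r$line, r$product)
    if (!r$product %in% names(mets)) stop(sprintf("%s: unknown metabolite '%s'", where, r$product))
    if (length(r$prod_letters) != mets[r$product]) {
      stop(sprintf("%s: product map has %d slots but %s has %d carbons",
                   where, length(r$prod_letters), r$product, mets[r$product]))
    }
    if (anyDuplicated(r$prod_letters)) {
      stop(sprintf("%s: duplicate letter in product map", where))
    }
    sub_letters <- character(0)
    for (s in r$substrates) {
      if (!s$name %in% names(mets)) stop(sprintf("%s: unknown metabolite '%s'", where, s$name))
      if (length(s$letters) != mets[s$name]) {
        stop(sprintf("%s: substrate %s map has %d slots but %d carbons",
                     where, s$name, length(s$letters), mets[s$name]))
      }
      if (anyDuplicated(s$letters)) {
        stop(sprintf("%s: duplicate carbon assignment in substrate %s", where, s$name))
      }
      sub_letters <- c(sub_letters, s$letters)
    }
    counts <- vapply(r$prod_letters, function(l) sum(sub_letters == l), integer(1))
    if (any(counts == 0L)) {
      stop(sprintf("%s: product carbon(s) %s unmapped",
                   where, paste(r$prod_letters[counts == 0L], collapse = ", ")))
    }
    if (any(counts > 1L)) {
      stop(sprintf("%s: product carbon(s) %s mapped twice",
                   where, paste(r$prod_letters[counts > 1L], collapse = ", ")))
    }
    produced <- c(produced, r$product)
  }
  # no orphans: every metabolite must be a source or be produced
  orphan <- setdiff(names(mets), c(produced, names(net$sources)))
  if (length(orphan) > 0L) {
    stop(sprintf("metabolite(s) with no source and no producing reaction: %s",
                 paste(orphan, collapse = ", ")))
  }
  invisible(net)
}

.network_params <- function(net) {
  ps <- character(0)
  for (s in net$sources) ps <- c(ps, .expr_params(s$enrichment))
  for (d in net$dilutions) ps <- c(ps, .expr_params(d))
  for (r in net$reactions) ps <- c(ps, .expr_params(r$weight))
  sort(unique(ps))
}

#' Serialize a network to its canonical text form
#'
#' `parse_network(text = serialize_network(net))` reproduces `net`.
#'
#' @param net An `atom_network`.
#' @return Character vector of lines.
#' @export
serialize_network <- function(net) {
  out <- character(0)
  for (nm in names(net$metabolites)) {
    out <- c(out, sprintf("metabolite: %s, %d", nm, net$metabolites[[nm]]))
  }
  for (nm in names(net$sources)) {
    s <- net$sources[[nm]]
    line <- sprintf("source: %s enrichment=%s", nm, .deparse_expr(s$enrichment))
    if (!is.null(s$positions)) line <- paste0(line, " positions=", paste(s$positions, collapse = ";"))
    out <- c(out, line)
  }
  for (nm in names(net$dilutions)) {
    out <- c(out, sprintf("dilute: %s fraction=%s", nm, .deparse_expr(net$dilutions[[nm]])))
  }
  for (nm in net$symmetric) out <- c(out, sprintf("symmetric: %s", nm))
  for (r in net$reactions) {
    subs <- vapply(r$substrates, function(s) {
      sprintf("%s[%s]", s$name, paste(s$letters, collapse = ""))
    }, character(1))
    line <- sprintf("%s[%s] <- %s", r$product, paste(r$prod_letters, collapse = ""),
                    paste(subs, collapse = " + "))
    if (!(r$weight$kind == "const" && r$weight$value == 1)) {
      line <- paste0(line, " @ ", .deparse_expr(r$weight))
    }
    out <- c(out, line)
  }
  out
}

#' @export
print.atom_network <- function(x, ...) {
  cat(sprintf("<atom_network> %d metabolites, %d reactions, %d source pool(s)\n",
              length(x$metabolites), length(x$reactions), length(x$sources)))
  if (length(x$params) > 0L) cat("free parameters:", paste(x$params, collapse = ", "), "\n")
  invisible(x)
}

#' Load a bundled pathway network
#'
#' Shipped networks encode carbon fixation in a hydrogenotrophic
#' methanogen: the Wood-Ljungdahl (WL) pathway alone (`"wl_only"`), WL plus
#' the incomplete reductive TCA branch from oxaloacetate to 2-oxoglutarate
#' (`"wl_incomplete_rtca"`, the organism lacking aconitase and isocitrate
#' dehydrogenase), and a hypothetical complete reductive cycle with citrate
#' cleavage recycling (`"wl_complete_rtca"`). Each includes the
#' precursor-to-amino-acid maps for Ser, Asp, Glu, Ala, Thr and Pro.
#'
#' @param id One of `"wl_only"`, `"wl_incomplete_rtca"`,
#'   `"wl_complete_rtca"`.
#' @return An `atom_network`.
#' @export
load_network <- function(id = c("wl_incomplete_rtca", "wl_complete_rtca", "wl_only")) {
  id <- match.arg(id)
  parse_network(system.file("extdata", "networks", paste0(id, ".net"),
                            package = "tracemid", mustWork = TRUE))
}

# ---- simulation ------------------------------------------------------------

# Precompute per-reaction transfer matrices: product state vector =
# M %*% (outer product of substrate state vectors, first substrate fastest).
.compile_network <- function(net) {
  mets <- net$metabolites
  compiled <- vector("list", length(net$reactions))
  for (ri in seq_along(net$reactions)) {
    r <- net$reactions[[ri]]
    np <- mets[[r$product]]
    sizes <- vapply(r$substrates, function(s) as.integer(2^mets[[s$name]]), integer(1))
    N <- prod(sizes)
    strides <- cumprod(c(1L, sizes[-length(sizes)]))
    j <- 0:(N - 1L)
    pattern <- integer(N)
    for (c in seq_len(np)) {
      letter <- r$prod_letters[c]
      hit <- NULL
      for (si in seq_along(r$substrates)) {
        pos <- which(r$substrates[[si]]$letters == letter)
        if (length(pos) == 1L) { hit <- c(si, pos); break }
      }
      i_s <- (j %/% strides[hit[1]]) %% sizes[hit[1]]
      bit <- (i_s %/% 2L^(hit[2] - 1L)) %% 2L
      pattern <- pattern + bit * 2L^(c - 1L)
    }
    M <- matrix(0, 2L^np, N)
    M[cbind(pattern + 1L, seq_len(N))] <- 1
    compiled[[ri]] <- list(M = M, substrates = vapply(r$substrates, `[[`, "", "name"))
  }
  # bit-reversal permutations for symmetric metabolites
  sym_perm <- lapply(net$symmetric, function(nm) {
    n <- mets[[nm]]
    p <- 0:(2L^n - 1L)
    rev_p <- vapply(p, function(x) {
      bits <- as.integer(intToBits(x))[seq_len(n)]
      as.integer(sum(rev(bits) * 2^(seq_len(n) - 1)))
    }, integer(1))
    rev_p + 1L
  })
  names(sym_perm) <- net$symmetric
  list(reactions = compiled, sym_perm = sym_perm)
}

.source_state <- function(n, enr_per_carbon) {
  v <- 1
  for (i in seq_len(n)) {
    v <- as.vector(outer(v, c(1 - enr_per_carbon[i], enr_per_carbon[i])))
  }
  # outer(v, new) makes the existing carbons fastest; carbon i is bit i-1
  # only if we build with the new carbon slowest, which outer() does
  v
}

#' Tracer specification
#'
#' Which substrate is labeled, at which carbon positions, to what isotopic
#' enrichment of the pool, and (for co-fed substrates such as acetate) what
#' fraction of the downstream pool it contributes.
#'
#' @param substrate Name of the source metabolite in the network.
#' @param positions Labeled carbon indices; `NULL` labels all carbons
#'   (e.g. a 13CO2 spike).
#' @param enrichment 13C fraction of the substrate pool at the labeled
#'   positions, in `[0, 1]`. For corrected (excess-label) data this is the
#'   enrichment above natural abundance.
#' @param contribution Optional fraction in `[0, 1]` of the downstream pool
#'   drawn from this substrate; bound to the network parameter
#'   `contribution_param` (default `a_<substrate>` in lower case).
#' @param contribution_param Name of the weight parameter to bind.
#' @return An object of class `"tracer_spec"`.
#' @export
tracer_spec <- function(substrate, positions = NULL, enrichment = 1,
                        contribution = NULL, contribution_param = NULL) {
  stopifnot(enrichment >= 0, enrichment <= 1)
  if (!is.null(contribution)) stopifnot(contribution >= 0, contribution <= 1)
  if (is.null(contribution_param)) contribution_param <- paste0("a_", tolower(substrate))
  structure(list(substrate = substrate, positions = positions,
                 enrichment = enrichment, contribution = contribution,
                 contribution_param = contribution_param),
            class = "tracer_spec")
}

#' Simulate steady-state positional isotopomer distributions
#'
#' Computes the fixed point of the pool update rule: each produced
#' metabolite's labeling-state distribution is the weight-normalized
#' mixture over its producing reactions of the atom-mapped product of the
#' (independent) substrate distributions, averaged over orientations for
#' symmetric molecules, then mixed with an unlabeled reservoir according to
#' its dilution fraction. States live on the 2^n binary labeling patterns
#' (bit i set = carbon i+1 is 13C). Acyclic networks converge in a single
#' topological pass; cyclic ones (label recycling) iterate until the
#' largest state change falls below `tol`.
#'
#' @param net An `atom_network`.
#' @param tracer Optional [tracer_spec()]; overrides the source state of
#'   its substrate and binds its contribution parameter.
#' @param params Named list/vector binding the remaining free parameters.
#' @param tol Convergence tolerance on the max absolute state change.
#' @param max_sweeps Sweep limit; non-convergence is an error reporting the
#'   last delta.
#' @param only Optional metabolite names: only these and their ancestors
#'   are simulated (a pure speed restriction; results are unchanged).
#' @return Named list of per-metabolite probability vectors (class
#'   `"isotopomer_states"`), each of length `2^n` and summing to one.
#' @export
simulate_isotopomers <- function(net, tracer = NULL, params = list(),
                                 tol = 1e-12, max_sweeps = 10000L, only = NULL) {
  params <- as.list(params)
  if (!is.null(tracer)) {
    if (!inherits(tracer, "tracer_spec")) stop("tracer must be a tracer_spec")
    if (!tracer$substrate %in% names(net$sources)) {
      stop(sprintf("tracer substrate '%s' is not a source in this network", tracer$substrate))
    }
    if (!is.null(tracer$contribution)) params[[tracer$contribution_param]] <- tracer$contribution
  }
  missing <- setdiff(net$params, c(names(params), if (!is.null(tracer)) {
    # the tracer substrate's enrichment parameter is superseded by the tracer
    .expr_params(net$sources[[tracer$substrate]]$enrichment)
  }))
  if (length(missing) > 0L) {
    stop(sprintf("unbound parameter(s): %s", paste(missing, collapse = ", ")))
  }

  mets <- net$metabolites
  compiled <- if (!is.null(net$compiled)) net$compiled else .compile_network(net)
  states <- vector("list", length(mets))
  names(states) <- names(mets)
  for (nm in names(mets)) {
    n <- mets[[nm]]
    if (nm %in% names(net$sources)) {
      if (!is.null(tracer) && identical(nm, tracer$substrate)) {
        enr <- rep(0, n)
        pos <- if (is.null(tracer$positions)) seq_len(n) else tracer$positions
        if (any(!(pos %in% seq_len(n)))) {
          stop(sprintf("tracer positions outside 1..%d of %s", n, nm))
        }
        enr[pos] <- tracer$enrichment
      } else {
        s <- net$sources[[nm]]
        e <- .eval_expr(s$enrichment, params, sprintf("source %s", nm))
        enr <- rep(0, n)
        enr[if (is.null(s$positions)) seq_len(n) else s$positions] <- e
      }
      states[[nm]] <- .source_state(n, enr)
    } else {
      states[[nm]] <- c(1, numeric(2L^n - 1L))
    }
  }

  products <- vapply(net$reactions, `[[`, "", "product")
  produced <- unique(products)
  if (!is.null(only)) {
    unknown <- setdiff(only, names(mets))
    if (length(unknown) > 0L) {
      stop(sprintf("unknown metabolite(s) in 'only': %s", paste(unknown, collapse = ", ")))
    }
    needed <- only
    repeat {
      subs <- unlist(lapply(net$reactions[products %in% needed], function(r) {
        vapply(r$substrates, `[[`, "", "name")
      }))
      grown <- unique(c(needed, subs))
      if (length(grown) == length(needed)) break
      needed <- grown
    }
    produced <- intersect(produced, needed)
  }
  producers <- lapply(produced, function(nm) which(products == nm))
  names(producers) <- produced
  plan <- .update_plan(net, produced)
  weights <- vapply(net$reactions, function(r) {
    .eval_expr(r$weight, params, sprintf("reaction at line %d", r$line))
  }, numeric(1))
  if (any(weights < -1e-12)) stop("reaction weights must be non-negative")
  dil <- vapply(names(mets), function(nm) {
    if (nm %in% names(net$dilutions)) {
      .eval_expr(net$dilutions[[nm]], params, sprintf("dilute %s", nm))
    } else 0
  }, numeric(1))
  if (any(dil < -1e-12 | dil > 1 + 1e-12)) stop("dilution fractions must lie in [0, 1]")

  update_one <- function(nm) {
    ris <- producers[[nm]]
    w <- weights[ris]
    ws <- sum(w)
    if (ws <= 0) stop(sprintf("reactions producing %s have zero total weight", nm))
    acc <- 0
    for (ri in ris) {
      if (weights[ri] == 0) next
      cp <- compiled$reactions[[ri]]
      joint <- states[[cp$substrates[1L]]]
      for (snm in cp$substrates[-1L]) {
        b <- states[[snm]]
        joint <- joint * rep(b, each = length(joint))  # kron, first substrate fastest
      }
      acc <- acc + (weights[ri] / ws) * as.vector(cp$M %*% joint)
    }
    perm <- compiled$sym_perm[[nm]]
    if (!is.null(perm)) acc <- 0.5 * (acc + acc[perm])
    d <- dil[[nm]]
    if (d > 0) {
      acc <- (1 - d) * acc
      acc[1L] <- acc[1L] + d
    }
    acc / sum(acc)
  }

  # acyclic prefix: one topological pass is exact
  for (nm in plan$prefix) states[[nm]] <- update_one(nm)
  # cyclic core: iterate to the fixed point
  if (length(plan$cyclic) > 0L) {
    delta <- Inf
    for (sweep in seq_len(max_sweeps)) {
      delta <- 0
      for (nm in plan$cyclic) {
        acc <- update_one(nm)
        delta <- max(delta, max(abs(acc - states[[nm]])))
        states[[nm]] <- acc
      }
      if (delta < tol) break
    }
    if (delta >= tol) {
      stop(sprintf("simulation did not converge in %d sweeps (last delta %.3g)",
                   max_sweeps, delta))
    }
  }
  # downstream of the cycle: one topological pass
  for (nm in plan$suffix) states[[nm]] <- update_one(nm)
  if (!is.null(only)) states <- states[intersect(names(states), c(produced, names(net$sources)))]
  structure(states, class = "isotopomer_states",
            n_carbons = mets[names(states)])
}

# Split produced metabolites into an acyclic prefix (computable before any
# cycle), the cyclic core (nodes on a dependency cycle, iterated to a fixed
# point), and a topologically ordered suffix downstream of the cycle.
.update_plan <- function(net, produced) {
  products <- vapply(net$reactions, `[[`, "", "product")
  deps <- lapply(produced, function(nm) {
    subs <- unique(unlist(lapply(net$reactions[products == nm], function(r) {
      vapply(r$substrates, `[[`, "", "name")
    })))
    intersect(subs, produced)
  })
  names(deps) <- produced
  order_nm <- character(0)
  remaining <- produced
  repeat {
    ready <- remaining[vapply(remaining, function(nm) {
      all(deps[[nm]] %in% order_nm)
    }, logical(1))]
    if (length(ready) == 0L) break
    order_nm <- c(order_nm, ready)
    remaining <- setdiff(remaining, ready)
  }
  if (length(remaining) == 0L) {
    return(list(prefix = order_nm, cyclic = character(0), suffix = character(0)))
  }
  # within the unresolved set, nodes reachable from themselves are cyclic;
  # the rest hang downstream of the cycle
  reach <- function(nm) {
    seen <- character(0)
    frontier <- deps[[nm]]
    while (length(frontier) > 0L) {
      seen <- union(seen, frontier)
      frontier <- setdiff(unique(unlist(deps[frontier])), seen)
    }
    seen
  }
  cyclic <- remaining[vapply(remaining, function(nm) nm %in% reach(nm), logical(1))]
  suffix_set <- setdiff(remaining, cyclic)
  # topological order of the suffix treating cyclic nodes as resolved
  suffix <- character(0)
  resolved <- c(order_nm, cyclic)
  while (length(suffix_set) > 0L) {
    ready <- suffix_set[vapply(suffix_set, function(nm) {
      all(deps[[nm]] %in% c(resolved, suffix))
    }, logical(1))]
    if (length(ready) == 0L) { suffix <- c(suffix, suffix_set); break }
    suffix <- c(suffix, ready)
    suffix_set <- setdiff(suffix_set, ready)
  }
  list(prefix = order_nm, cyclic = cyclic, suffix = suffix)
}

# ---- state summaries -------------------------------------------------------

.label_count_cache <- new.env(parent = emptyenv())

.state_label_counts <- function(state) {
  n <- as.integer(round(log2(length(state))))
  key <- as.character(n)
  if (is.null(.label_count_cache[[key]])) {
    .label_count_cache[[key]] <- vapply(
      0:(2^n - 1L),
      function(p) sum(as.integer(intToBits(p))[seq_len(n)]),
      integer(1))
  }
  .label_count_cache[[key]]
}

#' Summaries of a simulated isotopomer state
#'
#' `state_to_mid()` marginalizes a 2^n labeling-pattern distribution over
#' the total label count; `state_to_positional()` marginalizes over a
#' (main-chain, side-chain) carbon bipartition; `state_enrichment()` is the
#' mean fraction of labeled carbons. Simulated states are in the
#' tracer-only frame, so resulting MIDs carry `corrected = TRUE`.
#'
#' @param state A probability vector over `2^n` labeling patterns.
#' @param analyte Analyte name for the returned objects.
#' @return A [mid()], a [positional_table()], or a scalar respectively.
#' @export
state_to_mid <- function(state, analyte = NA_character_) {
  counts <- .state_label_counts(state)
  n <- max(counts)
  f <- vapply(0:n, function(k) sum(state[counts == k]), numeric(1))
  mid(f, analyte = analyte, corrected = TRUE, normalize = TRUE)
}

#' @rdname state_to_mid
#' @param main_indices Carbon indices (1-based) of the main chain.
#' @export
state_to_positional <- function(state, main_indices, analyte = NA_character_) {
  n <- as.integer(round(log2(length(state))))
  side_indices <- setdiff(seq_len(n), main_indices)
  km <- ks <- integer(length(state))
  for (p in 0:(length(state) - 1L)) {
    bits <- as.integer(intToBits(p))[seq_len(n)]
    km[p + 1L] <- sum(bits[main_indices])
    ks[p + 1L] <- sum(bits[side_indices])
  }
  ab <- matrix(0, length(main_indices) + 1L, length(side_indices) + 1L)
  for (i in seq_along(state)) {
    ab[km[i] + 1L, ks[i] + 1L] <- ab[km[i] + 1L, ks[i] + 1L] + state[i]
  }
  positional_table(ab, analyte = analyte, normalize = TRUE)
}

#' @rdname state_to_mid
#' @export
state_enrichment <- function(state) {
  counts <- .state_label_counts(state)
  n <- as.integer(round(log2(length(state))))
  sum(counts * state) / n
}

#' Predict amino-acid MIDs and positional tables from simulated states
#'
#' @param states `isotopomer_states` from [simulate_isotopomers()]; the
#'   network is expected to contain the amino acids as products of their
#'   precursor atom maps.
#' @param specs Amino-acid reference table.
#' @param analytes Codes to predict; defaults to every reference analyte
#'   present in `states`. Requesting an analyte absent from the simulation
#'   is an error naming it.
#' @return Named list per analyte with elements `mid` and `positional`
#'   (both in the tracer-only frame).
#' @export
predict_amino_acid_mids <- function(states, specs = amino_acid_specs(),
                                    analytes = NULL) {
  if (is.null(analytes)) {
    analytes <- intersect(specs$code, names(states))
  }
  missing <- setdiff(analytes, names(states))
  if (length(missing) > 0L) {
    stop(sprintf("precursor state(s) missing from simulation: %s",
                 paste(missing, collapse = ", ")))
  }
  out <- lapply(analytes, function(code) {
    spec <- specs[specs$code == code, , drop = FALSE]
    if (nrow(spec) != 1L) stop(sprintf("unknown analyte code: %s", code))
    st <- states[[code]]
    list(mid = state_to_mid(st, analyte = code),
         positional = state_to_positional(st, .parse_indices(spec$main_indices),
                                          analyte = code))
  })
  names(out) <- analytes
  out
}
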