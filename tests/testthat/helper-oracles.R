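# Independent oracles used across tests. These deliberately avoid the
# package's compiled-matrix code paths: convolution by explicit enumeration
# over per-carbon Bernoulli outcomes, and network labeling by tree
# recursion over molecules with exhaustive joint-substrate enumeration.

rand_simplex <- function(n) {
  x <- stats::rexp(n)
  x / sum(x)
}

# measured MID from a true MID by enumerating all labeling patterns of the
# unlabeled carbons
oracle_convolve <- function(true_mid, p13) {
  n <- length(true_mid) - 1L
  out <- numeric(n + 1L)
  for (j in 0:n) {
    free <- n - j
    if (free == 0L) {
      out[n + 1L] <- out[n + 1L] + true_mid[j + 1L]
      next
    }
    for (pattern in 0:(2^free - 1L)) {
      bits <- as.integer(intToBits(pattern))[seq_len(free)]
      k <- j + sum(bits)
      prob <- prod(ifelse(bits == 1L, p13, 1 - p13))
      out[k + 1L] <- out[k + 1L] + true_mid[j + 1L] * prob
    }
  }
  out
}

# per-molecule labeling distribution by tree recursion; exact for acyclic
# networks, truncation error <= (max recycling weight)^max_depth otherwise
oracle_state <- function(net, met, bindings, source_enr = list(),
                         depth = 0L, max_depth = 80L) {
  n <- net$metabolites[[met]]
  eval_e <- function(e) {
    switch(e$kind,
           const = e$value,
           param = bindings[[e$name]],
           one_minus = 1 - bindings[[e$name]])
  }
  pattern_of <- function(bits) sum(bits * 2^(seq_along(bits) - 1L)) + 1L
  if (met %in% names(net$sources)) {
    enr <- if (met %in% names(source_enr)) {
      source_enr[[met]]
    } else {
      s <- net$sources[[met]]
      e <- eval_e(s$enrichment)
      v <- rep(0, n)
      v[if (is.null(s$positions)) seq_len(n) else s$positions] <- e
      v
    }
    out <- numeric(2^n)
    for (pattern in 0:(2^n - 1L)) {
      bits <- as.integer(intToBits(pattern))[seq_len(n)]
      out[pattern + 1L] <- prod(ifelse(bits == 1L, enr, 1 - enr))
    }
    return(out)
  }
  if (depth > max_depth) {
    return(c(1, numeric(2^n - 1L))) # truncated branch: unlabeled
  }
  products <- vapply(net$reactions, `[[`, "", "product")
  ris <- which(products == met)
  w <- vapply(net$reactions[ris], function(r) eval_e(r$weight), numeric(1))
  w <- w / sum(w)
  dist <- numeric(2^n)
  for (i in seq_along(ris)) {
    if (w[i] == 0) next
    r <- net$reactions[[ris[i]]]
    sub_dists <- lapply(r$substrates, function(s) {
      oracle_state(net, s$name, bindings, source_enr, depth + 1L, max_depth)
    })
    sizes <- vapply(sub_dists, length, integer(1))
    idx_grid <- expand.grid(lapply(sizes, function(sz) 0:(sz - 1L)))
    for (row in seq_len(nrow(idx_grid))) {
      prob <- 1
      sub_bits <- list()
      for (si in seq_along(sub_dists)) {
        p <- idx_grid[row, si]
        prob <- prob * sub_dists[[si]][p + 1L]
        sub_bits[[si]] <- as.integer(intToBits(p))[seq_len(net$metabolites[[r$substrates[[si]]$name]])]
      }
      if (prob == 0) next
      bits <- integer(n)
      for (c in seq_len(n)) {
        letter <- r$prod_letters[c]
        for (si in seq_along(r$substrates)) {
          pos <- which(r$substrates[[si]]$letters == letter)
          if (length(pos) == 1L) bits[c] <- sub_bits[[si]][pos]
        }
      }
      dist[pattern_of(bits)] <- dist[pattern_of(bits)] + w[i] * prob
    }
  }
  if (met %in% net$symmetric) {
    flipped <- numeric(2^n)
    for (pattern in 0:(2^n - 1L)) {
      bits <- as.integer(intToBits(pattern))[seq_len(n)]
      flipped[pattern_of(rev(bits))] <- dist[pattern + 1L]
    }
    dist <- 0.5 * (dist + flipped)
  }
  if (met %in% names(net$dilutions)) {
    d <- eval_e(net$dilutions[[met]])
    dist <- (1 - d) * dist
    dist[1L] <- dist[1L] + d
  }
  dist
}

# tiny synthetic peak list around given analytes, for annotation tests
toy_peaklist <- function(rows) {
  as_peaklist(do.call(rbind, lapply(rows, function(r) {
    data.frame(sample_id = "toy", mz = r$mz, area = r$area,
               migration_time_s = r$mt, stringsAsFactors = FALSE)
  })), level = "precursor")
}
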