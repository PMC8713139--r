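# Independent brute-force oracles used to check the package's fast paths.
# These deliberately avoid the implementation routes they validate.

# Midpoint Riemann sum of f on [0, 1] with n panels.
riemann_integral <- function(f, n = 1e6) {
  h <- 1 / n
  mids <- (seq_len(n) - 0.5) * h
  sum(f(mids)) * h
}

# Root of a monotone function g by two-stage grid scan: coarse step to find
# the sign change, then a fine grid of the given resolution inside it.
grid_scan_root <- function(g, lo, hi, coarse = 0.01, fine = 1e-6) {
  xs <- seq(lo, hi, by = coarse)
  gs <- vapply(xs, g, numeric(1))
  i <- which(diff(sign(gs)) != 0)[1]
  stopifnot(!is.na(i))
  xf <- seq(xs[i], xs[i + 1], by = fine)
  gf <- vapply(xf, g, numeric(1))
  j <- which(diff(sign(gf)) != 0)[1]
  stopifnot(!is.na(j))
  (xf[j] + xf[j + 1]) / 2
}

# Intersection abscissa of two Gaussian densities by dense scan between the
# means at the given resolution.
dense_gaussian_intersection <- function(mu_f, sd_f, mu_r, sd_r, res = 1e-6) {
  lo <- min(mu_f, mu_r); hi <- max(mu_f, mu_r)
  xs <- seq(lo, hi, by = res)
  d <- dnorm(xs, mu_f, sd_f, log = TRUE) - dnorm(xs, mu_r, sd_r, log = TRUE)
  i <- which(diff(sign(d)) != 0)[1]
  stopifnot(!is.na(i))
  (xs[i] + xs[i + 1]) / 2
}

# Spearman rank correlation from first principles: mid-ranks by counting,
# then the Pearson formula on the ranks.
brute_spearman <- function(x, y) {
  midrank <- function(v) {
    vapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2, numeric(1))
  }
  rx <- midrank(x); ry <- midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Minimum-weight perfect matching on an even set of points by exhaustive
# recursion over pairings; returns list of index pairs (each sorted).
brute_min_matching <- function(dmat) {
  n <- nrow(dmat)
  best <- list(weight = Inf, pairs = NULL)
  recurse <- function(remaining, pairs, weight) {
    if (!length(remaining)) {
      if (weight < best$weight) best <<- list(weight = weight, pairs = pairs)
      return()
    }
    i <- remaining[1]
    for (j in remaining[-1]) {
      recurse(setdiff(remaining, c(i, j)),
              c(pairs, list(sort(c(i, j)))), weight + dmat[i, j])
    }
  }
  recurse(seq_len(n), list(), 0)
  best$pairs
}

# All 4-atom paths a-s1-s2-b in a graph given as a two-column edge list of
# qualified names, with s1-s2 the central bond.
brute_dihedral_paths <- function(edges, s1, s2) {
  nbrs <- function(v) {
    hits <- edges$ai == v | edges$aj == v
    setdiff(unique(unlist(edges[hits, c("ai", "aj")])), v)
  }
  out <- list()
  for (a in setdiff(nbrs(s1), s2)) {
    for (b in setdiff(nbrs(s2), s1)) {
      out[[length(out) + 1L]] <- c(a, s1, s2, b)
    }
  }
  out
}

# Convenience: moment-matched samples with exact sample mean/sd.
exact_moment_sample <- function(n, mean, sd, seed = 1) {
  z <- withr::with_seed(seed, rnorm(n))
  z <- (z - mean(z)) / stats::sd(z)
  mean + sd * z
}

# Fixture templates for the hybrid module.
toy_templates <- function() {
  fx <- toy_fixtures()
  list(cysteine = read_residue_template(fx$cysteine),
       cystine = read_residue_template(fx$cystine))
}
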