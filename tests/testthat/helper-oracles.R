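# Independent constructions used as oracles: a hand-rolled scattering
# profile (single-wrap Gaussian lobes, written without the package's
# generator) and an exhaustive-enumeration peak-pairing reference.

# Azimuthal profile of fiber populations `thetas`: one Gaussian lobe at
# theta + 90 and one at theta - 90 per population, on a baseline.
lobe_profile <- function(thetas, amps = 1, width = 15, baseline = 0.1,
                         angles = seq(0, 345, by = 15)) {
  amps <- rep_len(amps, length(thetas))
  p <- rep(baseline, length(angles))
  for (i in seq_along(thetas)) {
    for (ctr in c(thetas[i] + 90, thetas[i] - 90)) {
      d <- (angles - ctr + 180) %% 360 - 180
      p <- p + amps[i] * exp(-d^2 / (2 * width^2))
    }
  }
  p
}

# Exhaustive reference for peak pairing: enumerate every conflict-free
# subset of admissible pairs (up to max_populations pairs), rank pairs by
# (summed prominence desc, positions asc), and return the subset whose
# rank sequence is lexicographically best (prefix ties broken toward the
# larger subset). Independent of the greedy implementation.
brute_force_pairs <- function(peaks, params = profile_params()) {
  pos <- peaks$positions_deg
  prom <- peaks$prominences
  n <- length(pos)
  if (n < 2L) return(NULL)
  pairs <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- abs(pos[i] - pos[j]) %% 360
    d <- min(d, 360 - d)
    if (abs(d - 180) <= params$pairing_tolerance_deg)
      pairs[[length(pairs) + 1L]] <- c(i, j)
  }
  if (!length(pairs)) return(NULL)
  psum <- vapply(pairs, function(p) prom[p[1]] + prom[p[2]], 0)
  lo <- vapply(pairs, function(p) min(pos[p]), 0)
  hi <- vapply(pairs, function(p) max(pos[p]), 0)
  dev180 <- vapply(pairs, function(p) {
    d <- abs(pos[p[1]] - pos[p[2]]) %% 360
    abs(min(d, 360 - d) - 180)
  }, 0)
  rank <- order(order(-psum, dev180, lo, hi))  # rank 1 = best pair

  best <- NULL
  better <- function(a, b) {  # is rank sequence a better than b?
    if (is.null(b)) return(TRUE)
    a <- sort(a); b <- sort(b)
    for (k in seq_len(min(length(a), length(b)))) {
      if (a[k] < b[k]) return(TRUE)
      if (a[k] > b[k]) return(FALSE)
    }
    length(a) > length(b)
  }
  m <- length(pairs)
  for (size in seq_len(min(params$max_populations, m))) {
    for (sel in asplit(utils::combn(m, size), 2)) {
      used <- unlist(pairs[sel])
      if (anyDuplicated(used)) next
      if (better(rank[sel], if (is.null(best)) NULL else rank[best]))
        best <- sel
    }
  }
  if (is.null(best) || !length(best)) return(NULL)
  data.frame(p1 = lo[best], p2 = hi[best],
             prominence = psum[best])[order(-psum[best]), ]
}

# Random smooth scattering profile for oracle comparisons.
random_profile <- function() {
  k <- sample(1:3, 1)
  lobe_profile(stats::runif(k, 0, 180),
               amps = stats::runif(k, 0.3, 1),
               width = stats::runif(1, 10, 25),
               baseline = stats::runif(1, 0, 0.3)) +
    stats::rnorm(24, 0, stats::runif(1, 0, 0.15))
}
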