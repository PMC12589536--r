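#' Parameters of the per-pixel azimuthal profile analysis
#'
#' Controls the pipeline that turns one pixel's intensity-vs-illumination
#' azimuth profile \eqn{I(\phi)} into up to three in-plane fiber
#' orientations: Fourier low-pass filtering, circular peak detection,
#' pairing of peaks ~180 degrees apart, and midline computation.
#'
#' @param fourier_cutoff_fraction low-pass cutoff as a fraction of the
#'   Nyquist harmonic index (default 0.40).
#' @param fourier_window_width relative width of the smooth raised-cosine
#'   roll-off around the cutoff (default 0.225; 0 gives a hard cutoff).
#' @param prominence_fraction minimum peak prominence as a fraction of the
#'   profile range `max - min` (default 0.08).
#' @param pairing_tolerance_deg peaks are paired when their circular
#'   separation is within `180 +/- tolerance` degrees (default 35).
#' @param max_populations maximum number of fiber populations kept per
#'   pixel, 1-3 (default 3).
#' @param background_quantile pixels whose mean scattering signal falls
#'   below this quantile of the average map are masked; 0 disables
#'   quantile masking (zero-signal pixels are always masked).
#' @param filter_mode `"auto"` filters profiles sampled finer than 15
#'   degrees and passes coarser samplings through unfiltered; `"always"` /
#'   `"never"` force the choice.
#' @return A `profile_params` list.
#' @export
profile_params <- function(fourier_cutoff_fraction = 0.40,
                           fourier_window_width = 0.225,
                           prominence_fraction = 0.08,
                           pairing_tolerance_deg = 35,
                           max_populations = 3L,
                           background_quantile = 0,
                           filter_mode = c("auto", "always", "never")) {
  filter_mode <- match.arg(filter_mode)
  stopifnot(fourier_cutoff_fraction > 0, fourier_cutoff_fraction <= 1,
            fourier_window_width >= 0, fourier_window_width < 1,
            prominence_fraction >= 0,
            pairing_tolerance_deg > 0, pairing_tolerance_deg < 90,
            max_populations %in% 1:3,
            background_quantile >= 0, background_quantile < 1)
  structure(
    list(fourier_cutoff_fraction = fourier_cutoff_fraction,
         fourier_window_width = fourier_window_width,
         prominence_fraction = prominence_fraction,
         pairing_tolerance_deg = pairing_tolerance_deg,
         max_populations = as.integer(max_populations),
         background_quantile = background_quantile,
         filter_mode = filter_mode),
    class = "profile_params"
  )
}

#' Fourier low-pass filter of a periodic azimuthal profile
#'
#' Attenuates the discrete spectrum of the length-`A` periodic profile:
#' harmonic indices up to `cutoff - window/2` (in units of the Nyquist
#' index) pass untouched, indices beyond `cutoff + window/2` are zeroed,
#' and the transition follows a raised cosine. The DC component is never
#' touched, so the profile mean is preserved exactly.
#'
#' @param profile numeric vector, one full azimuthal period.
#' @param params a [profile_params] (only the two Fourier fields are used).
#' @return Filtered profile of the same length.
#' @export
fourier_lowpass <- function(profile, params = profile_params()) {
  A <- length(profile)
  stopifnot(A >= 8L)
  H <- lowpass_response(A, params$fourier_cutoff_fraction,
                        params$fourier_window_width)
  Re(stats::fft(stats::fft(profile) * H, inverse = TRUE)) / A
}

# Filter gain per FFT bin; m is the harmonic index folded to [0, A/2].
lowpass_response <- function(A, cutoff, window) {
  k <- 0:(A - 1)
  m <- pmin(k, A - k)
  nyq <- floor(A / 2)
  fc <- cutoff * nyq
  w <- window * nyq
  if (w == 0) return(as.numeric(m <= fc))
  lo <- fc - w / 2
  hi <- fc + w / 2
  H <- numeric(A)
  H[m <= lo] <- 1
  tr <- m > lo & m < hi
  H[tr] <- 0.5 * (1 + cos(pi * (m[tr] - lo) / w))
  H
}

#' Detect scattering peaks on the circular azimuth domain
#'
#' Finds local maxima of the periodic profile, keeps those whose circular
#' prominence reaches `prominence_fraction * (max - min)`, and refines each
#' position to sub-sample precision as the midpoint of the two half-
#' prominence level crossings of the peak lobe (linear interpolation),
#' which is exact for symmetric lobes. Wrap-around peaks are reported once.
#'
#' @param profile numeric vector sampled at `angles`.
#' @param params a [profile_params].
#' @param angles azimuths of the samples in degrees; defaults to a uniform
#'   grid starting at 0.
#' @return A `peak_set`: list with `positions_deg` (strictly increasing,
#'   in `[0, 360)`) and `prominences`.
#' @export
detect_peaks <- function(profile, params = profile_params(),
                         angles = seq(0, 360, length.out = length(profile) + 1L)[-(length(profile) + 1L)]) {
  A <- length(profile)
  rng <- max(profile) - min(profile)
  empty <- structure(list(positions_deg = numeric(0),
                          prominences = numeric(0)), class = "peak_set")
  if (!is.finite(rng) || rng <= 0) return(empty)
  step <- 360 / A
  nxt <- c(2:A, 1L)
  prv <- c(A, 1:(A - 1L))
  cand <- which(profile > profile[nxt] & profile >= profile[prv])
  if (!length(cand)) return(empty)

  prom <- vapply(cand, circular_prominence, 0, profile = profile)
  keep <- prom >= params$prominence_fraction * rng
  cand <- cand[keep]
  prom <- prom[keep]
  if (!length(cand)) return(empty)

  pos <- vapply(seq_along(cand), function(i) {
    refine_peak_position(profile, cand[i], prom[i], angles, step)
  }, 0)
  pos <- pos %% 360
  ord <- order(pos)
  structure(list(positions_deg = pos[ord], prominences = prom[ord]),
            class = "peak_set")
}

# Topographic prominence of profile[i] on the circle: walk each way until a
# strictly higher sample; the key saddle is the higher of the two path minima.
circular_prominence <- function(profile, i) {
  A <- length(profile)
  h <- profile[i]
  walk_min <- function(dir) {
    m <- h
    j <- i
    for (s in seq_len(A - 1L)) {
      j <- ((j - 1L + dir) %% A) + 1L
      if (profile[j] > h) return(m)
      m <- min(m, profile[j])
    }
    m
  }
  h - max(walk_min(1L), walk_min(-1L))
}

# Sub-sample position: midpoint of the two linearly interpolated crossings
# of the half-prominence level around sample index i. The walk never
# leaves the peak's own lobe: it stops where the profile starts rising
# again (the local minimum bounding the lobe), so a tall neighboring peak
# cannot drag the estimate sideways. Works in unwrapped angle coordinates
# relative to the peak, then returns degrees.
refine_peak_position <- function(profile, i, prom, angles, step) {
  A <- length(profile)
  level <- profile[i] - prom / 2
  cross <- function(dir) {
    j <- i
    for (s in seq_len(A)) {
      jn <- ((j - 1L + dir) %% A) + 1L
      if (profile[jn] < level) {
        f <- (profile[j] - level) / (profile[j] - profile[jn])
        return(dir * (s - 1 + f) * step)
      }
      if (profile[jn] > profile[j]) return(dir * (s - 1) * step)
      j <- jn
    }
    dir * 180  # level never crossed (near-flat lobe): use half circle
  }
  angles[i] + (cross(1L) + cross(-1L)) / 2
}

#' Pair scattering peaks separated by ~180 degrees
#'
#' Fibers scatter light predominantly perpendicular to their axis, so each
#' in-plane fiber population produces two peaks ~180 degrees apart in the
#' azimuthal profile. Peaks are matched greedily: all admissible pairs
#' (circular separation within `180 +/- pairing_tolerance_deg`) are ranked
#' by summed prominence, then by closeness of the separation to 180
#' degrees (disambiguates equal-prominence crossing configurations), then
#' by position; each peak is used at most once, and at most
#' `max_populations` pairs are kept. Unpaired peaks are discarded.
#'
#' @param peaks a `peak_set` from [detect_peaks()].
#' @param params a [profile_params].
#' @return Data frame with one row per retained pair: `p1`, `p2` (degrees,
#'   `p1 < p2`), `prom1`, `prom2`, `prominence` (sum), ordered by
#'   decreasing `prominence`.
#' @export
pair_peaks <- function(peaks, params = profile_params()) {
  pos <- peaks$positions_deg
  prom <- peaks$prominences
  n <- length(pos)
  empty <- data.frame(p1 = numeric(0), p2 = numeric(0), prom1 = numeric(0),
                      prom2 = numeric(0), prominence = numeric(0))
  if (n < 2L) return(empty)
  idx <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  sep <- circ_dist360(pos[idx[, 1]], pos[idx[, 2]])
  ok <- abs(sep - 180) <= params$pairing_tolerance_deg
  if (!any(ok)) return(empty)
  i <- idx[ok, 1]; j <- idx[ok, 2]
  psum <- prom[i] + prom[j]
  # rank: prominence first, then closeness to perfect 180-degree
  # antipodality (disambiguates equal-prominence crossing configurations),
  # then position for determinism
  ord <- order(-psum, abs(sep[ok] - 180),
               pmin(pos[i], pos[j]), pmax(pos[i], pos[j]))
  used <- logical(n)
  keep <- integer(0)
  for (r in ord) {
    if (used[i[r]] || used[j[r]]) next
    used[i[r]] <- used[j[r]] <- TRUE
    keep <- c(keep, r)
    if (length(keep) >= params$max_populations) break
  }
  data.frame(p1 = pos[i[keep]], p2 = pos[j[keep]],
             prom1 = prom[i[keep]], prom2 = prom[j[keep]],
             prominence = psum[keep])
}

#' Fiber orientations from peak pairs
#'
#' The in-plane fiber orientation is the midline of a scattering peak pair:
#' the circular midpoint of the two peak azimuths, reduced modulo 180
#' degrees (fibers are axial, not directed).
#'
#' @param pairs data frame from [pair_peaks()].
#' @return Numeric vector of orientations in `[0, 180)`, ordered by pair
#'   prominence (most prominent first).
#' @export
orientations_from_pairs <- function(pairs) {
  if (nrow(pairs) == 0L) return(numeric(0))
  theta <- (pairs$p1 + ((pairs$p2 - pairs$p1) %% 360) / 2) %% 180
  theta[order(-pairs$prominence)]
}

#' Per-pixel fiber orientation analysis of an angular stack
#'
#' Runs the full profile pipeline for every pixel: Fourier low-pass filter
#' (per `filter_mode`; by default only for azimuthal steps finer than 15
#' degrees), circular peak detection, 180-degree pairing, and midline
#' computation. Pixels with zero mean signal, or below the
#' `background_quantile` of the average map, are masked and carry zero
#' populations.
#'
#' @param stack an [angular_stack] (flat-field corrected where applicable).
#' @param params a [profile_params].
#' @return An `orientation_field`: list with `orientations_deg`
#'   (`H x W x 3`, `NA` for unused slots, slot 1 the most prominent
#'   population), `n_populations` (`H x W` integer), `average_map`,
#'   `mask` (TRUE = analyzable pixel), `pixel_size_um`, `params`.
#' @export
analyze_stack <- function(stack, params = profile_params()) {
  stopifnot(inherits(stack, "angular_stack"))
  d <- dim(stack$data)
  H <- d[1]; W <- d[2]; A <- d[3]
  step <- 360 / A
  npix <- H * W
  P <- t(matrix(stack$data, npix, A))  # A x npix profile matrix

  do_filter <- switch(params$filter_mode,
                      always = TRUE, never = FALSE,
                      auto = step < 15 - 1e-9)
  if (do_filter) {
    Hresp <- lowpass_response(A, params$fourier_cutoff_fraction,
                              params$fourier_window_width)
    P <- Re(stats::mvfft(stats::mvfft(P) * Hresp, inverse = TRUE)) / A
  }

  average_map <- matrix(colMeans(P), H, W)
  mask <- average_map > 0
  if (params$background_quantile > 0) {
    thr <- stats::quantile(average_map, params$background_quantile,
                           names = FALSE)
    mask <- mask & (average_map >= thr)
  }

  angles0 <- seq(0, 360 - step, by = step)
  orients <- array(NA_real_, c(H, W, 3L))
  proms <- array(NA_real_, c(H, W, 3L))
  npop <- matrix(0L, H, W)
  for (p in which(mask)) {
    prof <- P[, p]
    pk <- detect_peaks(prof, params, angles0)
    if (length(pk$positions_deg) < 2L) next
    pr <- pair_peaks(pk, params)
    th <- orientations_from_pairs(pr)
    k <- length(th)
    if (k == 0L) next
    r <- ((p - 1L) %% H) + 1L
    cc <- ((p - 1L) %/% H) + 1L
    orients[r, cc, seq_len(k)] <- th
    proms[r, cc, seq_len(k)] <- sort(pr$prominence, decreasing = TRUE)
    npop[r, cc] <- k
  }
  structure(
    list(orientations_deg = orients, prominences = proms,
         n_populations = npop, average_map = average_map, mask = mask,
         pixel_size_um = stack$pixel_size_um, params = params),
    class = "orientation_field"
  )
}

#' Construct an orientation field from known orientations
#'
#' Builds the container [analyze_stack()] produces from explicit per-pixel
#' orientations — useful for ground-truth fields, ROI constructions, and
#' piping externally computed orientations into the muFOD / diffusion
#' stages.
#'
#' @param orientations either an `H x W` matrix (one population per pixel)
#'   or an `H x W x 3` array with `NA` in unused slots, degrees in
#'   `[0, 180)`; slot order is taken as prominence order.
#' @param mask logical `H x W` validity grid; defaults to all `TRUE`.
#' @param pixel_size_um pixel pitch in micrometers.
#' @param average_map optional mean-scattering map (defaults to 1).
#' @return An `orientation_field`.
#' @export
orientation_field <- function(orientations, mask = NULL, pixel_size_um = 1,
                              average_map = NULL) {
  if (is.matrix(orientations)) {
    arr <- array(NA_real_, c(dim(orientations), 3L))
    arr[, , 1] <- orientations
    orientations <- arr
  }
  stopifnot(length(dim(orientations)) == 3L, dim(orientations)[3] == 3L)
  stored <- orientations[!is.na(orientations)]
  if (length(stored) && (any(stored < 0) || any(stored >= 180)))
    stop("orientation_field: orientations must lie in [0, 180)")
  H <- dim(orientations)[1]; W <- dim(orientations)[2]
  npop <- matrix(0L, H, W)
  proms <- array(NA_real_, dim(orientations))
  for (k in 1:3) {
    present <- !is.na(orientations[, , k])
    npop <- npop + present
    proms[, , k][present] <- 4 - k
  }
  if (is.null(mask)) mask <- matrix(TRUE, H, W)
  if (is.null(average_map)) average_map <- matrix(1, H, W)
  structure(
    list(orientations_deg = orientations, prominences = proms,
         n_populations = npop, average_map = average_map, mask = mask,
         pixel_size_um = pixel_size_um, params = NULL),
    class = "orientation_field")
}

#' @export
print.orientation_field <- function(x, ...) {
  d <- dim(x$n_populations)
  tab <- table(factor(x$n_populations[x$mask], levels = 0:3))
  cat(sprintf("orientation_field: %d x %d px (%.4g um/px), %d analyzable\n",
              d[1], d[2], x$pixel_size_um, sum(x$mask)))
  cat("  populations per pixel: ",
      paste(sprintf("%s:%d", names(tab), as.integer(tab)), collapse = "  "),
      "\n", sep = "")
  invisible(x)
}

#' Write an orientation field to per-population TIFF maps plus JSON
#'
#' Serializes the field as 32-bit float TIFFs: one orientation map per
#' population slot (degrees scaled to `[0,1]` by 1/180, background
#' pixels 0 with the valid mask in the count map), an integer population
#' count map, and the average scattering map, plus a JSON sidecar with the
#' analysis parameters.
#'
#' @param field an `orientation_field`.
#' @param prefix output path prefix; files get suffixes
#'   `_theta1..3.tif`, `_npop.tif`, `_avg.tif`, `_params.json`.
#' @return Invisibly, the written paths.
#' @export
write_orientation_field <- function(field, prefix) {
  paths <- character(0)
  for (k in 1:3) {
    th <- field$orientations_deg[, , k]
    th[is.na(th)] <- 0
    f <- paste0(prefix, "_theta", k, ".tif")
    tiff::writeTIFF(th / 180, f, bits.per.sample = 32L, reduce = FALSE)
    paths <- c(paths, f)
  }
  f <- paste0(prefix, "_npop.tif")
  tiff::writeTIFF(field$n_populations / 3, f, bits.per.sample = 32L,
                  reduce = FALSE)
  paths <- c(paths, f)
  f <- paste0(prefix, "_avg.tif")
  avg <- field$average_map
  s <- max(avg); if (s <= 0) s <- 1
  tiff::writeTIFF(avg / s, f, bits.per.sample = 32L, reduce = FALSE)
  paths <- c(paths, f)
  f <- paste0(prefix, "_params.json")
  jsonlite::write_json(
    c(unclass(field$params),
      list(pixel_size_um = field$pixel_size_um, average_scale = s,
           theta_scale_deg = 180)),
    f, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, f))
}
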