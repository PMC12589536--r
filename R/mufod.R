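#' Microstructure-derived fiber orientation distribution (muFOD)
#'
#' Pools every stored orientation of every unmasked pixel in a region into
#' a polar histogram of 20 bins of 9 degrees covering `[0, 180)` (the
#' orientation domain is axial; the polar rendering mirrors it to
#' `[180, 360)`). The total count equals the number of orientation entries
#' in the region, so muFODs of a partition's cells sum to the muFOD of the
#' whole region.
#'
#' @param field an `orientation_field`.
#' @param roi logical `H x W` mask selecting the region, or `NULL` for
#'   the whole image.
#' @param id optional region identifier stored with the histogram.
#' @return A `mufod`: list with `bin_edges_deg` (21 edges 0..180),
#'   `counts` (20 integers), `n_total`, `id`.
#' @export
compute_mufod <- function(field, roi = NULL, id = NULL) {
  H <- dim(field$n_populations)[1]
  W <- dim(field$n_populations)[2]
  if (is.null(roi)) roi <- matrix(TRUE, H, W)
  stopifnot(is.logical(roi), all(dim(roi) == c(H, W)))
  sel <- roi & field$mask
  th <- c(field$orientations_deg[array(sel, c(H, W, 3L))])
  th <- th[!is.na(th)]
  counts <- mufod_bin_counts(th)
  structure(
    list(bin_edges_deg = seq(0, 180, by = 9),
         counts = counts, n_total = sum(counts), id = id),
    class = "mufod"
  )
}

# Half-open 9-degree bins [lo, hi); 180 wraps onto bin 1.
mufod_bin_counts <- function(theta_deg) {
  b <- (floor((theta_deg %% 180) / 9) %% 20) + 1L
  tabulate(b, nbins = 20L)
}

#' @export
print.mufod <- function(x, ...) {
  cat(sprintf("muFOD: %d orientations in 20 bins of 9 deg%s\n", x$n_total,
              if (is.null(x$id)) "" else paste0(" (", x$id, ")")))
  invisible(x)
}

#' muFOD histograms on a kernel grid
#'
#' Partitions the field into non-overlapping `kernel_px` kernels (same
#' tiling rule as [crossing_fraction()]) and computes one muFOD per
#' kernel.
#'
#' @param field an `orientation_field`.
#' @param kernel_px kernel edge in pixels.
#' @return List with `counts` (`n_r x n_c x 20` array), `row_starts`,
#'   `col_starts`, `kernel_px`.
#' @export
mufod_kernels <- function(field, kernel_px) {
  H <- dim(field$n_populations)[1]
  W <- dim(field$n_populations)[2]
  k <- as.integer(kernel_px)
  rs <- tile_starts(H, k)
  cs <- tile_starts(W, k)
  counts <- array(0L, c(length(rs), length(cs), 20L))
  for (i in seq_along(rs)) for (j in seq_along(cs)) {
    roi <- matrix(FALSE, H, W)
    roi[rs[i]:min(rs[i] + k - 1L, H), cs[j]:min(cs[j] + k - 1L, W)] <- TRUE
    counts[i, j, ] <- compute_mufod(field, roi)$counts
  }
  list(counts = counts, row_starts = rs, col_starts = cs, kernel_px = k)
}

#' Periodic spline representation of a muFOD
#'
#' Fits an interpolating periodic cubic spline through the 20 bin
#' mid-points (4.5 + 9k degrees) duplicated onto `[180, 360)`, and
#' evaluates it on a fine grid over the full circle. Because the knot data
#' repeat with period 180 and the periodic interpolant is unique, the
#' spline is automatically mirror-symmetric: `f(phi) = f(phi + 180)`.
#'
#' @param mufod a `mufod`.
#' @param grid_deg evaluation grid spacing in degrees (default 1).
#' @return Data frame with `phi_deg` in `[0, 360)` and `value`; all-zero
#'   histograms give the zero function.
#' @export
spline_mufod <- function(mufod, grid_deg = 1) {
  phi <- seq(0, 360 - grid_deg, by = grid_deg)
  if (all(mufod$counts == 0))
    return(data.frame(phi_deg = phi, value = rep(0, length(phi))))
  mids <- mufod$bin_edges_deg[-21] + 4.5
  x <- c(mids, mids + 180, mids[1] + 360)
  y <- c(mufod$counts, mufod$counts, mufod$counts[1])
  xout <- ifelse(phi < mids[1], phi + 360, phi)
  s <- stats::spline(x, y, method = "periodic", xout = xout)
  data.frame(phi_deg = phi, value = s$y)
}

#' Export a muFOD as CSV (bin mid-point, count)
#'
#' @param mufod a `mufod`.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_mufod_csv <- function(mufod, path) {
  utils::write.csv(
    data.frame(bin_mid_deg = mufod$bin_edges_deg[-21] + 4.5,
               count = mufod$counts),
    path, row.names = FALSE)
  invisible(path)
}

#' Polar plot of a muFOD and its spline
#'
#' @param mufod a `mufod`.
#' @param path output PNG path.
#' @return Invisibly, `path`.
#' @export
plot_mufod_png <- function(mufod, path) {
  s <- spline_mufod(mufod)
  r <- pmax(s$value, 0)
  rmax <- max(r, 1e-9)
  grDevices::png(path, width = 480, height = 480)
  op <- graphics::par(mar = c(1, 1, 2, 1), pty = "s")
  on.exit({ graphics::par(op); grDevices::dev.off() })
  graphics::plot(NA, xlim = c(-1, 1), ylim = c(-1, 1), axes = FALSE,
                 xlab = "", ylab = "", main = "muFOD", asp = 1)
  a <- s$phi_deg * pi / 180
  graphics::polygon(r / rmax * cos(a), r / rmax * sin(a),
                    border = "steelblue", lwd = 2)
  mids <- (mufod$bin_edges_deg[-21] + 4.5) * pi / 180
  rr <- mufod$counts / max(mufod$counts, 1)
  graphics::segments(0, 0, rr * cos(mids), rr * sin(mids), col = "grey40")
  graphics::segments(0, 0, -rr * cos(mids), -rr * sin(mids), col = "grey40")
  invisible(path)
}

#' Orientation difference between two co-registered fields
#'
#' Compares, per pixel, the dominant (most prominent) orientation of each
#' field using the axial circular distance
#' `d(a, b) = min(|a - b|, 180 - |a - b|)` (a metric on the half-circle,
#' bounded by 90 degrees). Background pixels — masked or fiber-free in
#' either field — are excluded. The distribution is summarized by a fine
#' histogram, its median, and the full width at half the modal height
#' (linear interpolation between bin centers).
#'
#' @param fieldA,fieldB co-registered `orientation_field`s of equal shape.
#' @param mode `"dominant"` compares the best-prominence population of
#'   each field; `"matched"` averages, over A's populations, the distance
#'   to the nearest population of B.
#' @param bin_deg histogram bin width in degrees (default 0.3).
#' @return A `difference_result`: `diff_map` (degrees, `NA` on background),
#'   `histogram` (data frame `mid_deg`, `count`), `median_deg`, `fwhm_deg`,
#'   `n_pixels`, `empty` flag.
#' @export
orientation_difference <- function(fieldA, fieldB,
                                   mode = c("dominant", "matched"),
                                   bin_deg = 0.3) {
  mode <- match.arg(mode)
  stopifnot(all(dim(fieldA$n_populations) == dim(fieldB$n_populations)))
  H <- dim(fieldA$n_populations)[1]
  W <- dim(fieldA$n_populations)[2]
  valid <- fieldA$mask & fieldB$mask &
    fieldA$n_populations > 0L & fieldB$n_populations > 0L
  diff_map <- matrix(NA_real_, H, W)
  if (mode == "dominant") {
    a <- fieldA$orientations_deg[, , 1]
    b <- fieldB$orientations_deg[, , 1]
    diff_map[valid] <- orient_dist(a[valid], b[valid])
  } else {
    for (p in which(valid)) {
      r <- ((p - 1L) %% H) + 1L
      cc <- ((p - 1L) %/% H) + 1L
      tha <- fieldA$orientations_deg[r, cc, ]
      thb <- fieldB$orientations_deg[r, cc, ]
      tha <- tha[!is.na(tha)]
      thb <- thb[!is.na(thb)]
      diff_map[r, cc] <- mean(vapply(tha, function(t)
        min(orient_dist(t, thb)), 0))
    }
  }
  d <- diff_map[valid]
  if (!length(d)) {
    warning("orientation_difference: no pixels valid in both fields")
    return(structure(
      list(diff_map = diff_map,
           histogram = data.frame(mid_deg = numeric(0), count = integer(0)),
           median_deg = NA_real_, fwhm_deg = NA_real_, n_pixels = 0L,
           empty = TRUE),
      class = "difference_result"))
  }
  breaks <- seq(0, 90 + bin_deg, by = bin_deg)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE, right = FALSE)
  structure(
    list(diff_map = diff_map,
         histogram = data.frame(mid_deg = h$mids, count = h$counts),
         median_deg = stats::median(d),
         fwhm_deg = histogram_fwhm(h$mids, h$counts),
         n_pixels = length(d), empty = FALSE),
    class = "difference_result"
  )
}

# Full width at half the modal height of a binned histogram, by linear
# interpolation between bin centers; a flank that never drops below half
# height ends at the histogram edge.
histogram_fwhm <- function(mids, counts) {
  im <- which.max(counts)
  half <- counts[im] / 2
  left <- mids[1]
  if (im > 1L) for (i in seq(im, 2L)) {
    if (counts[i - 1L] < half) {
      f <- (counts[i] - half) / (counts[i] - counts[i - 1L])
      left <- mids[i] - f * (mids[i] - mids[i - 1L])
      break
    }
  }
  right <- mids[length(mids)]
  if (im < length(counts)) for (i in seq(im, length(counts) - 1L)) {
    if (counts[i + 1L] < half) {
      f <- (counts[i] - half) / (counts[i] - counts[i + 1L])
      right <- mids[i] + f * (mids[i + 1L] - mids[i])
      break
    }
  }
  right - left
}

#' @export
print.difference_result <- function(x, ...) {
  if (x$empty) {
    cat("difference_result: empty (no jointly valid pixels)\n")
  } else {
    cat(sprintf(
      "difference_result: %d pixels, median %.2f deg, FWHM %.2f deg\n",
      x$n_pixels, x$median_deg, x$fwhm_deg))
  }
  invisible(x)
}
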