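#' Render a fiber orientation map (FOM)
#'
#' Color-encodes per-pixel fiber orientations with a cyclic HSV color
#' wheel: hue = 2 theta, so orientations 0 and 180 degrees share a color
#' and the wheel is traversed once over the half-circle. Every image pixel
#' becomes a 2 x 2 subpixel block in the output; pixels with several
#' populations show a mosaic of the population colors (filled in
#' ascending-theta order: top-left, top-right, bottom-left, bottom-right),
#' masked or fiber-free pixels are black.
#'
#' @param field an `orientation_field`.
#' @return RGB array `2H x 2W x 3` with values in `[0, 1]`.
#' @export
render_fom <- function(field) {
  H <- dim(field$n_populations)[1]
  W <- dim(field$n_populations)[2]
  out <- array(0, c(2L * H, 2L * W, 3L))
  sub <- rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))  # TL TR BL BR
  for (r in seq_len(H)) for (cc in seq_len(W)) {
    k <- field$n_populations[r, cc]
    if (!field$mask[r, cc] || k == 0L) next
    th <- sort(field$orientations_deg[r, cc, seq_len(k)])
    cols <- orientation_rgb(rep_len(th, 4L))
    for (s in 1:4) {
      out[2L * r - 1L + sub[s, 1], 2L * cc - 1L + sub[s, 2], ] <- cols[, s]
    }
  }
  out
}

# Color-wheel mapping: hue(2 theta), full saturation and value.
orientation_rgb <- function(theta_deg) {
  hue <- ((2 * theta_deg) %% 360) / 360
  grDevices::col2rgb(grDevices::hsv(hue, 1, 1)) / 255
}

#' Overlay orientation vectors on a block grid
#'
#' For each `n x n` pixel block, the distinct fiber orientations present
#' in the block are found by circular single-linkage clustering (gap
#' threshold `cluster_gap_deg` on the half-circle) and one line segment
#' per cluster is drawn through the block center at the cluster's mean
#' orientation, colored by the same wheel as [render_fom()]. A pure view:
#' the orientation data are not modified.
#'
#' @param field an `orientation_field`.
#' @param overlay_kernel block edge `n` in pixels (`1` draws one segment
#'   per pixel).
#' @param cluster_gap_deg angular gap separating orientation clusters.
#' @param background `"black"` or `"average"` (dimmed mean scattering map).
#' @return RGB array `H x W x 3`.
#' @export
vector_overlay <- function(field, overlay_kernel = 15L,
                           cluster_gap_deg = 15, background = "black") {
  stopifnot(overlay_kernel >= 1L)
  H <- dim(field$n_populations)[1]
  W <- dim(field$n_populations)[2]
  out <- array(0, c(H, W, 3L))
  if (background == "average") {
    avg <- field$average_map
    s <- max(avg); if (s > 0) avg <- avg / s
    for (ch in 1:3) out[, , ch] <- 0.5 * avg
  }
  n <- as.integer(overlay_kernel)
  for (r0 in seq(1L, H, by = n)) for (c0 in seq(1L, W, by = n)) {
    r1 <- min(r0 + n - 1L, H)
    c1 <- min(c0 + n - 1L, W)
    th <- c(field$orientations_deg[r0:r1, c0:c1, ])
    ok <- c(field$mask[r0:r1, c0:c1])
    th <- th[!is.na(th) & rep_len(ok, length(th))]
    if (!length(th)) next
    centers <- cluster_orientations(th, cluster_gap_deg)
    len <- max(2, 0.8 * (min(r1 - r0, c1 - c0) + 1L))
    for (theta in centers)
      out <- draw_segment(out, (r0 + r1) / 2, (c0 + c1) / 2, theta, len,
                          orientation_rgb(theta)[, 1])
  }
  out
}

# Single-linkage clustering on the half-circle: sort, cut at gaps larger
# than `gap` (including the wrap gap), return up to 3 circular means
# ordered by cluster size.
cluster_orientations <- function(theta, gap) {
  theta <- sort(theta %% 180)
  n <- length(theta)
  if (n == 1L) return(theta)
  d <- c(diff(theta), theta[1] + 180 - theta[n])
  cut <- which(d > gap)
  if (!length(cut)) {  # single cluster spanning the circle
    return(circ_mean180(theta))
  }
  # cluster boundaries: members after cut i up to next cut (wrapping)
  starts <- (cut %% n) + 1L
  groups <- list()
  for (g in seq_along(starts)) {
    from <- starts[g]
    to <- cut[if (g == length(starts)) 1L else g + 1L]
    idx <- if (from <= to) from:to else c(from:n, 1:to)
    groups[[g]] <- theta[idx]
  }
  sizes <- lengths(groups)
  groups <- groups[order(-sizes)][seq_len(min(3L, length(groups)))]
  vapply(groups, circ_mean180, 0)
}

# Mean of axial orientations via the doubled-angle embedding.
circ_mean180 <- function(theta) {
  a <- 2 * theta * pi / 180
  (atan2(mean(sin(a)), mean(cos(a))) * 180 / pi / 2) %% 180
}

# Rasterize a segment centered at (row cy, col cx) at angle theta
# (counterclockwise from +x with the image origin top-left).
draw_segment <- function(img, cy, cx, theta_deg, len, rgb) {
  t <- seq(-len / 2, len / 2, by = 0.4)
  phi <- theta_deg * pi / 180
  rr <- round(cy - t * sin(phi))
  cc <- round(cx + t * cos(phi))
  ok <- rr >= 1 & rr <= dim(img)[1] & cc >= 1 & cc <= dim(img)[2]
  for (ch in 1:3) img[cbind(rr[ok], cc[ok], ch)] <- rgb[ch]
  img
}

#' Kernel-based crossing statistics
#'
#' Tiles the field with non-overlapping `kernel_px x kernel_px` kernels
#' anchored at pixel (1,1); a trailing partial kernel is included when at
#' least half of its extent lies inside the image. Each kernel takes the
#' maximum population count over its unmasked member pixels — a kernel
#' contains a crossing if any microscopic pixel inside it does. Fractions
#' are computed over kernels containing at least one unmasked pixel.
#'
#' @param field an `orientation_field`.
#' @param kernel_px kernel edge in pixels; a kernel larger than the image
#'   acts as a single kernel.
#' @return A `crossing_summary`: `kernel_px`, `resolution_um`,
#'   `fraction_ge2`, `fraction_3`, `map` (per-kernel max count, `NA` where
#'   no unmasked pixel).
#' @export
crossing_fraction <- function(field, kernel_px) {
  stopifnot(kernel_px >= 1L)
  H <- dim(field$n_populations)[1]
  W <- dim(field$n_populations)[2]
  k <- as.integer(kernel_px)  # a kernel larger than the image = one kernel
  rs <- tile_starts(H, k)
  cs <- tile_starts(W, k)
  m <- matrix(NA_real_, length(rs), length(cs))
  for (i in seq_along(rs)) for (j in seq_along(cs)) {
    r <- rs[i]:min(rs[i] + k - 1L, H)
    cc <- cs[j]:min(cs[j] + k - 1L, W)
    np <- field$n_populations[r, cc, drop = FALSE]
    ok <- field$mask[r, cc, drop = FALSE]
    if (any(ok)) m[i, j] <- max(np[ok])
  }
  valid <- !is.na(m)
  structure(
    list(kernel_px = k,
         resolution_um = k * field$pixel_size_um,
         fraction_ge2 = if (any(valid)) mean(m[valid] >= 2) else NA_real_,
         fraction_3 = if (any(valid)) mean(m[valid] >= 3) else NA_real_,
         map = m),
    class = "crossing_summary"
  )
}

# Tile anchors along one axis: full tiles plus a trailing partial tile
# when it covers at least half a kernel.
tile_starts <- function(n, k) {
  s <- seq(1L, n, by = k)
  last <- s[length(s)]
  if (last > 1L && n - last + 1L < k / 2) s <- s[-length(s)]
  s
}

#' Crossing statistics over several kernel sizes
#'
#' @param field an `orientation_field`.
#' @param kernels integer vector of kernel edges.
#' @return Data frame with `kernel_px`, `resolution_um`, `fraction_ge2`,
#'   `fraction_3` — ready for CSV export.
#' @export
crossing_table <- function(field, kernels = c(1L, 7L, 14L, 71L)) {
  rows <- lapply(kernels, function(k) {
    s <- crossing_fraction(field, k)
    data.frame(kernel_px = s$kernel_px, resolution_um = s$resolution_um,
               fraction_ge2 = s$fraction_ge2, fraction_3 = s$fraction_3)
  })
  do.call(rbind, rows)
}

#' Apparent crossings after intensity downsampling
#'
#' Emulates a coarser detector: block-averages the raw intensities of the
#' stack by `factor` per angle (not the orientations), then reruns the
#' per-pixel analysis on the reduced stack. Crossings found this way are
#' "apparent": averaged profiles of adjacent single-fiber domains can show
#' extra peak pairs, but information is also lost, so apparent crossing
#' counts lag behind kernel-based counts at matched resolution.
#'
#' @param stack an [angular_stack].
#' @param factor integer downsampling factor (1 = no reduction).
#' @param params a [profile_params].
#' @return The `orientation_field` of the downsampled stack (pixel size
#'   scaled by `factor`).
#' @export
apparent_crossing_map <- function(stack, factor, params = profile_params()) {
  stopifnot(factor >= 1L)
  factor <- as.integer(factor)
  if (factor == 1L) return(analyze_stack(stack, params))
  d <- dim(stack$data)
  rs <- tile_starts(d[1], factor)
  cs <- tile_starts(d[2], factor)
  red <- array(0, c(length(rs), length(cs), d[3]))
  for (i in seq_along(rs)) for (j in seq_along(cs)) {
    r <- rs[i]:min(rs[i] + factor - 1L, d[1])
    cc <- cs[j]:min(cs[j] + factor - 1L, d[2])
    red[i, j, ] <- apply(stack$data[r, cc, , drop = FALSE], 3, mean)
  }
  small <- angular_stack(red, stack$angles,
                         stack$pixel_size_um * factor,
                         meta = c(stack$meta, list(downsampled_by = factor)))
  analyze_stack(small, params)
}

#' Write an RGB array as PNG
#'
#' @param img `H x W x 3` array in `[0, 1]`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_rgb_png <- function(img, path) {
  png::writePNG(img, path)
  invisible(path)
}
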