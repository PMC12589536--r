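#' Diffuser-based flat-field calibration
#'
#' Scattered-light measurements are preceded by imaging a ground-glass
#' diffuser plate under the same rotating illumination. The diffuser stack
#' captures the uneven illumination across the field of view; dividing each
#' tissue image by the normalized diffuser image of the same azimuth removes
#' that unevenness.
#'
#' `normalize_diffuser()` blurs every diffuser page with a wide Gaussian
#' (standard deviation `blur_sigma_px`, reflect padding) to homogenize dust
#' and sensor defects, then divides all pages by the mean of the per-angle
#' maxima of the blurred pages, so that the correction divisors average to
#' one at the brightest spot and flat-field correction preserves the overall
#' intensity scale.
#'
#' @param diffuser an [angular_stack] of the diffuser plate.
#' @param blur_sigma_px Gaussian standard deviation of the homogenizing
#'   blur, in pixels.
#' @param eps relative threshold: divisors below `eps * max(divisor)` are
#'   masked instead of divided, so sensor-black regions are not amplified.
#' @return A `calibration_field`: list with `normalized` (H x W x A divisor
#'   array), `mask` (TRUE where the divisor is usable), `blur_sigma_px`,
#'   `angles`, `eps`.
#' @export
normalize_diffuser <- function(diffuser, blur_sigma_px = 100, eps = 1e-6) {
  stopifnot(inherits(diffuser, "angular_stack"))
  d <- dim(diffuser$data)
  blurred <- diffuser$data
  for (a in seq_len(d[3]))
    blurred[, , a] <- gaussian_blur(diffuser$data[, , a], blur_sigma_px)
  maxima <- apply(blurred, 3, max)
  mbar <- mean(maxima)
  if (!is.finite(mbar) || mbar <= 0)
    stop("normalize_diffuser: non-positive diffuser intensity after blurring")
  normalized <- blurred / mbar
  mask <- normalized >= eps * max(normalized)
  if (!any(mask))
    stop("normalize_diffuser: calibration field entirely below threshold")
  structure(
    list(normalized = normalized, mask = mask,
         blur_sigma_px = blur_sigma_px, angles = diffuser$angles, eps = eps),
    class = "calibration_field"
  )
}

#' @export
print.calibration_field <- function(x, ...) {
  d <- dim(x$normalized)
  cat(sprintf(
    "calibration_field: %d x %d x %d, blur sigma %g px, %.2f%% pixels usable\n",
    d[1], d[2], d[3], x$blur_sigma_px, 100 * mean(x$mask)))
  invisible(x)
}

#' Apply flat-field correction to a measurement stack
#'
#' Divides each page of `stack` by the calibration divisor of the same
#' azimuth. Pixels masked in the calibration field (divisor below the
#' relative threshold of [normalize_diffuser()]) are set to zero rather
#' than divided. Angles and metadata are preserved; the correction is
#' recorded in `meta$flat_field_corrected`.
#'
#' @param stack an [angular_stack] of tissue images.
#' @param cal a `calibration_field` from [normalize_diffuser()].
#' @return The corrected [angular_stack].
#' @export
flat_field_correct <- function(stack, cal) {
  stopifnot(inherits(stack, "angular_stack"),
            inherits(cal, "calibration_field"))
  if (length(stack$angles) != length(cal$angles) ||
      any(abs(stack$angles - cal$angles) > 1e-6))
    stop("flat_field_correct: stack and calibration angle lists differ")
  if (!all(dim(stack$data) == dim(cal$normalized)))
    stop("flat_field_correct: stack and calibration shapes differ")
  out <- stack$data / cal$normalized
  out[!cal$mask] <- 0
  meta <- stack$meta
  meta$flat_field_corrected <- TRUE
  angular_stack(out, stack$angles, stack$pixel_size_um, meta)
}

#' Gaussian blur of a single image with reflect padding
#'
#' Separable Gaussian convolution truncated at three standard deviations.
#' Reflect (mirror) boundary handling keeps illumination estimates at the
#' image edge unbiased; the reflection is periodic with period `2n - 2`, so
#' any blur radius is valid even on images smaller than the kernel.
#'
#' @param img numeric matrix.
#' @param sigma Gaussian standard deviation in pixels; `0` returns `img`.
#' @return Blurred matrix of the same shape.
#' @export
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  br <- blur_matrix(nrow(img), sigma)
  bc <- blur_matrix(ncol(img), sigma)
  br %*% img %*% t(bc)
}

# Dense n x n one-dimensional Gaussian blur operator with mirror boundary.
blur_matrix <- function(n, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  w <- stats::dnorm(-r:r, sd = sigma)
  w <- w / sum(w)
  B <- matrix(0, n, n)
  idx <- seq_len(n)
  for (k in -r:r) {
    j <- reflect_index(idx + k, n)
    B[cbind(idx, j)] <- B[cbind(idx, j)] + w[k + r + 1L]
  }
  B
}

# Map out-of-range indices into [1, n] by mirror reflection about the edges
# (abcb-style, period 2n - 2).
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- (i - 1L) %% (2L * n - 2L)
  ifelse(p < n, p + 1L, 2L * n - 1L - p)
}
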