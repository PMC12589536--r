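#' Specification of a synthetic scattering phantom
#'
#' Describes a synthetic scene for the azimuthal stack generator: fibers
#' scatter light predominantly perpendicular to their axis, so a fiber
#' population at in-plane orientation `theta` contributes a pair of
#' wrapped-Gaussian lobes centered at `theta + 90` and `theta - 90`
#' degrees to the pixel's azimuthal profile. The phantom is the package's
#' ground-truth fixture: the generator returns both the stack and the true
#' orientation field.
#'
#' @param shape integer `c(H, W)` image size in pixels.
#' @param angles azimuth list in degrees; default 24 steps of 15 degrees,
#'   the acquisition scheme the analysis targets.
#' @param regions list of regions from [phantom_region()]; later regions
#'   overwrite earlier ones where masks overlap.
#' @param peak_width_deg wrapped-Gaussian standard deviation of each
#'   scattering lobe, degrees, in `(0, 45)`.
#' @param baseline background intensity added to every profile.
#' @param noise_sigma additive Gaussian noise standard deviation (applied
#'   after illumination scaling; negative values are clipped at 0).
#' @param illumination `NULL` for flat illumination, a
#'   `list(type = "linear", strength = s)` for a smooth multiplicative
#'   linear gradient whose direction rotates with the illumination
#'   azimuth, or a function `f(row, col, angle_deg)` returning the
#'   multiplicative factor.
#' @param pixel_size_um pixel pitch in micrometers.
#' @param seed RNG seed; fixed seed gives bit-identical stacks.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(64L, 64L),
                         angles = seq(0, 345, by = 15),
                         regions = list(phantom_region(theta = 30)),
                         peak_width_deg = 15,
                         baseline = 0.1,
                         noise_sigma = 0,
                         illumination = NULL,
                         pixel_size_um = 7,
                         seed = 1L) {
  stopifnot(length(shape) == 2L, all(shape >= 1),
            peak_width_deg > 0, peak_width_deg < 45,
            baseline >= 0, noise_sigma >= 0)
  for (r in regions) {
    stopifnot(is.list(r), !is.null(r$theta))
    if (length(r$theta) > 3L)
      stop("phantom_spec: at most 3 fiber populations per region")
    if (any(r$amplitude < 0))
      stop("phantom_spec: amplitudes must be non-negative")
  }
  structure(
    list(shape = as.integer(shape), angles = as.numeric(angles),
         regions = regions, peak_width_deg = peak_width_deg,
         baseline = baseline, noise_sigma = noise_sigma,
         illumination = illumination, pixel_size_um = pixel_size_um,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Define one phantom region
#'
#' @param theta fiber orientations of the region, degrees in `[0, 180)`,
#'   at most three.
#' @param amplitude scattering lobe amplitude per population (recycled).
#' @param mask logical `H x W` matrix selecting the region's pixels, or
#'   `NULL` for the whole image.
#' @return A region descriptor for [phantom_spec()].
#' @export
phantom_region <- function(theta, amplitude = 1, mask = NULL) {
  list(theta = as.numeric(theta) %% 180,
       amplitude = rep_len(as.numeric(amplitude), length(theta)),
       mask = mask)
}

# Wrapped Gaussian lobe on the circle (degrees), unit peak height.
wrapped_gaussian <- function(d, sigma) {
  v <- 0
  for (m in -2:2) v <- v + exp(-((d + 360 * m)^2) / (2 * sigma^2))
  v
}

# Noise-free azimuthal profile of one region (length A).
region_profile <- function(region, angles, sigma, baseline) {
  prof <- rep(baseline, length(angles))
  for (k in seq_along(region$theta)) {
    th <- region$theta[k]
    a <- region$amplitude[k]
    prof <- prof + a * (wrapped_gaussian(angles - (th + 90), sigma) +
                        wrapped_gaussian(angles - (th - 90), sigma))
  }
  prof
}

# Multiplicative illumination factor array H x W x A for a spec.
illumination_field <- function(spec) {
  H <- spec$shape[1]; W <- spec$shape[2]
  A <- length(spec$angles)
  ill <- array(1, c(H, W, A))
  f <- spec$illumination
  if (is.null(f)) return(ill)
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  if (is.function(f)) {
    for (a in seq_len(A)) ill[, , a] <- f(rows, cols, spec$angles[a])
    return(ill)
  }
  if (identical(f$type, "linear")) {
    s <- f$strength
    u <- (cols - (W + 1) / 2) / max(W, 2)
    v <- (rows - (H + 1) / 2) / max(H, 2)
    for (a in seq_len(A)) {
      phi <- spec$angles[a] * pi / 180
      ill[, , a] <- 1 + s * (u * cos(phi) + v * sin(phi))
    }
    return(ill)
  }
  stop("phantom: unknown illumination specification")
}

# Run code with a private, restored RNG stream seeded from `seed`.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic azimuthal stack with known fiber orientations
#'
#' Builds, per pixel, the profile
#' \deqn{I(\phi) = [b + \sum_k A_k (g(\phi - \theta_k - 90) +
#'   g(\phi - \theta_k + 90))] \cdot L(x, y, \phi) + \epsilon}
#' with `g` a wrapped Gaussian of width `peak_width_deg`, `L` the
#' multiplicative illumination, and seeded Gaussian noise clipped at the
#' sensor floor 0.
#'
#' @param spec a [phantom_spec()].
#' @return List with `stack` (the [angular_stack]) and `truth` (an
#'   `orientation_field` carrying each region's orientations, ordered by
#'   amplitude).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  H <- spec$shape[1]; W <- spec$shape[2]
  A <- length(spec$angles)
  data <- array(spec$baseline, c(H, W, A))
  orients <- array(NA_real_, c(H, W, 3L))
  npop <- matrix(0L, H, W)
  for (region in spec$regions) {
    mask <- if (is.null(region$mask)) matrix(TRUE, H, W) else region$mask
    prof <- region_profile(region, spec$angles, spec$peak_width_deg,
                           spec$baseline)
    ord <- order(-region$amplitude, region$theta)
    th <- region$theta[ord]
    for (a in seq_len(A)) {
      page <- data[, , a]
      page[mask] <- prof[a]
      data[, , a] <- page
    }
    for (k in seq_along(th)) {
      slot <- orients[, , k]
      slot[mask] <- th[k]
      orients[, , k] <- slot
    }
    if (length(th) < 3L)
      for (k in (length(th) + 1L):3L) {
        slot <- orients[, , k]
        slot[mask] <- NA_real_
        orients[, , k] <- slot
      }
    npop[mask] <- length(th)
  }
  data <- data * illumination_field(spec)
  if (spec$noise_sigma > 0) {
    noise <- with_seed(spec$seed,
                       array(stats::rnorm(length(data), 0, spec$noise_sigma),
                             dim(data)))
    data <- pmax(data + noise, 0)
  }
  stack <- angular_stack(data, spec$angles, spec$pixel_size_um,
                         meta = list(phantom = TRUE, seed = spec$seed))
  truth <- structure(
    list(orientations_deg = orients, prominences = NULL,
         n_populations = npop,
         average_map = matrix(rowMeans(matrix(data, H * W, A)), H, W),
         mask = matrix(TRUE, H, W),
         pixel_size_um = spec$pixel_size_um, params = NULL),
    class = "orientation_field")
  list(stack = stack, truth = truth)
}

#' Generate the matching diffuser stack for a phantom
#'
#' A smooth per-angle illumination field without any fiber signal: the
#' phantom's multiplicative illumination term on a unit background. Using
#' the same spec guarantees the diffuser captures exactly the illumination
#' applied to the phantom, so flat-field correction can be validated
#' against the gradient-free phantom.
#'
#' @param spec a [phantom_spec()].
#' @return An [angular_stack].
#' @export
generate_diffuser <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  angular_stack(illumination_field(spec), spec$angles, spec$pixel_size_um,
                meta = list(diffuser = TRUE))
}
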