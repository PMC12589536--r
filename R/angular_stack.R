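#' Construct an angular image stack
#'
#' An `angular_stack` holds the per-pixel azimuthal intensity signal
#' \eqn{I(\phi)}: an `H x W x A` array of non-negative intensities together
#' with the `A` illumination azimuths (degrees). It is the raw or calibrated
#' measurement every downstream step consumes.
#'
#' @param data numeric `H x W x A` array of non-negative intensities.
#' @param angles numeric vector of `A` azimuths in degrees, strictly
#'   increasing within `[0, 360)` and equally spaced at `360/A`.
#' @param pixel_size_um physical pixel size in micrometers.
#' @param meta free-form provenance list (source files, bit depth, ...).
#'
#' @return An object of class `angular_stack` with fields `data`, `angles`,
#'   `pixel_size_um` and `meta`.
#' @export
angular_stack <- function(data, angles, pixel_size_um = 1, meta = list()) {
  data <- as_intensity_array(data)
  angles <- as.numeric(angles)
  A <- length(angles)
  if (A < 8L)
    stop("angular_stack: need at least 8 azimuth angles, got ", A)
  if (dim(data)[3] != A)
    stop("angular_stack: data has ", dim(data)[3], " pages but ", A,
         " angles were given")
  if (anyDuplicated(angles))
    stop("angular_stack: duplicate azimuth angles")
  if (any(angles < 0 | angles >= 360))
    stop("angular_stack: angles must lie in [0, 360)")
  if (is.unsorted(angles, strictly = TRUE))
    stop("angular_stack: angles must be strictly increasing")
  step <- 360 / A
  if (any(abs(diff(angles) - step) > 1e-6))
    stop("angular_stack: angles must be equally spaced at 360/A = ",
         format(step), " degrees")
  if (any(data < 0))
    stop("angular_stack: negative intensities")
  structure(
    list(data = data, angles = angles,
         pixel_size_um = as.numeric(pixel_size_um), meta = meta),
    class = "angular_stack"
  )
}

#' @export
print.angular_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "angular_stack: %d x %d pixels, %d azimuths (step %.4g deg), %.4g um/px\n",
    d[1], d[2], d[3], 360 / d[3], x$pixel_size_um))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.angular_stack <- function(x) dim(x$data)

# Promote images to a double H x W x A array; grayscale pages only.
as_intensity_array <- function(data) {
  if (is.list(data)) {
    dims <- lapply(data, dim)
    if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
      stop("image pages differ in shape")
    data <- array(unlist(data, use.names = FALSE),
                  dim = c(dim(data[[1]])[1:2], length(data)))
  }
  if (length(dim(data)) != 3L)
    stop("expected an H x W x A array or list of matrices")
  storage.mode(data) <- "double"
  data
}

#' Read an azimuthal image stack from TIFF
#'
#' Reads either a single multi-page TIFF or one single-page TIFF per angle
#' and assembles an [angular_stack]. Pages may be supplied in any order:
#' they are sorted by their azimuth so that the stored stack always has
#' strictly increasing angles. Intensities are promoted to double; the
#' original bit depth is recorded in `meta$bits_per_sample`. If a JSON
#' sidecar written by [write_angular_stack()] is present, the intensity
#' scale recorded there is re-applied.
#'
#' @param paths character vector: one multi-page TIFF, or one file per angle.
#' @param angles azimuths (degrees) matching the pages of `paths`, in the
#'   supplied page order.
#' @param pixel_size_um pixel pitch in micrometers.
#' @return An [angular_stack].
#' @export
read_angular_stack <- function(paths, angles, pixel_size_um = 1) {
  angles <- as.numeric(angles)
  pages <- list()
  bits <- NA_integer_
  for (p in paths) {
    pg <- tiff::readTIFF(p, all = TRUE, as.is = FALSE, info = TRUE)
    if (!is.null(attr(pg[[1]], "bits.per.sample")))
      bits <- attr(pg[[1]], "bits.per.sample")
    pages <- c(pages, lapply(pg, drop_channels))
  }
  if (length(pages) != length(angles))
    stop("read_angular_stack: ", length(pages), " pages but ",
         length(angles), " angles")
  shapes <- vapply(pages, function(m) paste(dim(m), collapse = "x"), "")
  if (length(unique(shapes)) != 1L)
    stop("read_angular_stack: pages differ in shape (",
         paste(unique(shapes), collapse = " vs "), ")")
  if (anyDuplicated(angles))
    stop("read_angular_stack: duplicate angles")
  ord <- order(angles)
  scale <- 1
  sidecar <- paste0(tools::file_path_sans_ext(paths[1]), ".json")
  if (length(paths) == 1L && file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(side$intensity_scale)) scale <- side$intensity_scale
    if (!is.null(side$pixel_size_um)) pixel_size_um <- side$pixel_size_um
  }
  arr <- as_intensity_array(pages[ord]) * scale
  angular_stack(arr, angles[ord], pixel_size_um,
                meta = list(source = paths, bits_per_sample = bits))
}

# Collapse RGB(A) pages to grayscale by channel mean; pass matrices through.
drop_channels <- function(m) {
  if (length(dim(m)) == 3L) m <- rowMeans(m, dims = 2L)
  m
}

#' Write an angular stack as a multi-page TIFF plus JSON sidecar
#'
#' Stores the stack as 32-bit float pages. TIFF float storage is kept in
#' `[0, 1]`, so intensities are divided by a single scale factor
#' (`max(data)`, or 1 for an all-zero stack) that is recorded, with the
#' angle list and pixel size, in a `.json` sidecar next to the TIFF;
#' [read_angular_stack()] restores the original units from it.
#'
#' @param stack an [angular_stack].
#' @param path output TIFF path.
#' @return Invisibly, the paths written (TIFF and JSON sidecar).
#' @export
write_angular_stack <- function(stack, path) {
  stopifnot(inherits(stack, "angular_stack"))
  scale <- max(stack$data)
  if (scale <= 0) scale <- 1
  pages <- lapply(seq_along(stack$angles),
                  function(a) stack$data[, , a] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  jsonlite::write_json(
    list(angles_deg = stack$angles, intensity_scale = scale,
         pixel_size_um = stack$pixel_size_um),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(tiff = path, json = sidecar))
}

# Circular helpers shared across modules ------------------------------------

# Difference a - b wrapped to (-180, 180].
wrap180 <- function(x) {
  x <- x %% 360
  x - 360 * (x > 180)
}

# Absolute circular distance between azimuths, in [0, 180].
circ_dist360 <- function(a, b) abs(wrap180(a - b))

# Distance between axial orientations (period 180), in [0, 90].
orient_dist <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}
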