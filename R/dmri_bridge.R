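#' Gradient table for the artificial diffusion-MRI dataset
#'
#' Builds the 63-volume diffusion encoding that makes scattered-light
#' orientations consumable by spherical-deconvolution tractography:
#' 3 unweighted (b = 0 ms/um^2) volumes and 60 b = 1 ms/um^2 volumes in
#' three 20-direction sets sharing the 20 muFOD bin azimuths (4.5 + 9k
#' degrees over 180):
#' \itemize{
#'   \item in-plane: the bin azimuths inside the section plane;
#'   \item perpendicular: 20 directions 9 degrees apart in a plane
#'     containing the section normal (spanned by the normal and the
#'     in-plane x-axis);
#'   \item tilted: the in-plane set rotated `tilt_deg` toward the normal,
#'     so `dot(tilted_k, normal) = sin(tilt_deg)` for every k.
#' }
#'
#' @param section_normal unit 3-vector normal to the section plane.
#' @param tilt_deg tilt of the third set off the section plane, degrees.
#' @return A `gradient_table`: `bvals` (63, ms/um^2), `bvecs` (63 x 3 unit
#'   rows, zero rows for b = 0), `set_labels`.
#' @export
build_gradient_table <- function(section_normal = c(0, 0, 1), tilt_deg = 20) {
  n <- as.numeric(section_normal)
  nn <- sqrt(sum(n^2))
  if (!is.finite(nn) || nn < 1e-12)
    stop("build_gradient_table: degenerate section normal")
  n <- n / nn
  # in-plane basis: image x-axis projected off the normal
  e1 <- c(1, 0, 0) - sum(c(1, 0, 0) * n) * n
  if (sqrt(sum(e1^2)) < 1e-9) e1 <- c(0, 1, 0) - sum(c(0, 1, 0) * n) * n
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  az <- (mufod_bin_azimuths()) * pi / 180
  inplane <- t(vapply(az, function(a) cos(a) * e1 + sin(a) * e2,
                      numeric(3)))
  perp <- t(vapply(az, function(a) cos(a) * e1 + sin(a) * n, numeric(3)))
  tr <- tilt_deg * pi / 180
  tilted <- t(apply(inplane, 1, function(v) cos(tr) * v + sin(tr) * n))
  bvecs <- rbind(matrix(0, 3, 3), inplane, perp, tilted)
  structure(
    list(bvals = c(rep(0, 3), rep(1, 60)),
         bvecs = bvecs,
         set_labels = c(rep("b0", 3), rep("inplane", 20),
                        rep("perpendicular", 20), rep("tilted", 20)),
         section_normal = n, tilt_deg = tilt_deg),
    class = "gradient_table"
  )
}

#' muFOD bin mid-point azimuths (degrees)
#'
#' The 20 azimuths 4.5 + 9k covering 0-180 degrees that index both the
#' muFOD histogram bins and the diffusion gradient sets.
#' @return Numeric vector of length 20.
#' @export
mufod_bin_azimuths <- function() 4.5 + 9 * (0:19)

#' Synthesize the artificial diffusion-MRI dataset from an orientation field
#'
#' Converts per-pixel muFODs into diffusion-weighted signals. For each
#' pixel, the muFOD bin counts `n_k` (over a `kernel_px` kernel; 1 uses the
#' pixel's own populations) drive the three gradient sets:
#' \itemize{
#'   \item in-plane set: `S = exp(-n_k / scale)` — more fibers along a bin
#'     azimuth mean stronger attenuation along it;
#'   \item perpendicular set: `S = 1` — no axons leave the section plane;
#'   \item tilted set: `S = 1 - (1 - S_inplane) / 5` — the signal loss 20
#'     degrees off the in-plane axis is exactly 20 percent of the loss
#'     along it, emulating a sharp fiber response.
#' }
#' b = 0 volumes and masked/fiber-free pixels are 1 everywhere.
#'
#' @param field an `orientation_field`.
#' @param kernel_px muFOD kernel edge in pixels (default 1).
#' @param scale attenuation scale constant in `exp(-n/scale)` (default 10).
#' @param gradient_table a [build_gradient_table()] result.
#' @return An `artificial_dwi`: `volumes` (`H x W x 1 x 63`, values in
#'   `(0, 1]`), `gradient_table`, `pixel_size_um`, `attenuation_scale`,
#'   `kernel_px`.
#' @export
synthesize_dwi <- function(field, kernel_px = 1L, scale = 10,
                           gradient_table = build_gradient_table()) {
  stopifnot(inherits(field, "orientation_field"), kernel_px >= 1L,
            scale > 0)
  H <- dim(field$n_populations)[1]
  W <- dim(field$n_populations)[2]
  kernel_px <- as.integer(kernel_px)
  # per-pixel bin counts (H x W x 20)
  counts <- array(0L, c(H, W, 20L))
  if (kernel_px == 1L) {
    for (p in which(field$mask & field$n_populations > 0L)) {
      r <- ((p - 1L) %% H) + 1L
      cc <- ((p - 1L) %/% H) + 1L
      th <- field$orientations_deg[r, cc, ]
      counts[r, cc, ] <- mufod_bin_counts(th[!is.na(th)])
    }
  } else {
    mk <- mufod_kernels(field, kernel_px)
    for (i in seq_along(mk$row_starts)) for (j in seq_along(mk$col_starts)) {
      r <- mk$row_starts[i]:min(mk$row_starts[i] + mk$kernel_px - 1L, H)
      cc <- mk$col_starts[j]:min(mk$col_starts[j] + mk$kernel_px - 1L, W)
      for (b in 1:20) counts[r, cc, b] <- mk$counts[i, j, b]
    }
  }
  vols <- array(1, c(H, W, 1L, 63L))
  s_in <- exp(-counts / scale)
  for (b in 1:20) {
    vols[, , 1L, 3L + b] <- s_in[, , b]             # in-plane set
    vols[, , 1L, 43L + b] <- 1 - (1 - s_in[, , b]) / 5  # tilted set
  }
  bg <- !field$mask
  if (any(bg)) for (v in 1:63) {
    page <- vols[, , 1L, v]
    page[bg] <- 1
    vols[, , 1L, v] <- page
  }
  structure(
    list(volumes = vols, gradient_table = gradient_table,
         pixel_size_um = field$pixel_size_um,
         attenuation_scale = scale, kernel_px = kernel_px),
    class = "artificial_dwi"
  )
}

#' @export
print.artificial_dwi <- function(x, ...) {
  d <- dim(x$volumes)
  cat(sprintf(
    "artificial_dwi: %d x %d x %d x %d volumes, scale %g, kernel %d px\n",
    d[1], d[2], d[3], d[4], x$attenuation_scale, x$kernel_px))
  invisible(x)
}

#' Export the artificial diffusion dataset for tractography tools
#'
#' Writes a 4D NIfTI volume (double precision, voxel size from the pixel
#' pitch, slice thickness equal to the pixel size), FSL-dialect `bval` /
#' `bvec` text files (b in s/mm^2, i.e. 1 ms/um^2 written as 1000; bvecs
#' as three whitespace-separated rows matching the NIfTI axes), and a JSON
#' provenance sidecar. Downstream consumption is intentionally external,
#' e.g. MRtrix3: `dwi2response` (`fa` algorithm, `l_max = 6`), `dwi2fod`
#' (`csd`, `l_max = 6`), `tckgen` (minimum tract length 2 mm).
#'
#' @param dwi an `artificial_dwi`.
#' @param out_prefix output path prefix; writes `<prefix>.nii.gz`,
#'   `<prefix>.bval`, `<prefix>.bvec`, `<prefix>.json`.
#' @return Invisibly, named character vector of written paths.
#' @export
export_dwi <- function(dwi, out_prefix) {
  stopifnot(inherits(dwi, "artificial_dwi"))
  vx <- dwi$pixel_size_um / 1000  # mm
  img <- RNifti::asNifti(dwi$volumes)
  RNifti::pixdim(img) <- c(vx, vx, vx, 1)
  nii <- paste0(out_prefix, ".nii.gz")
  ok <- tryCatch({
    RNifti::writeNifti(img, nii, datatype = "double")
    TRUE
  }, error = function(e) {
    stop("export_dwi: failed writing ", nii, ": ", conditionMessage(e))
  })
  bval <- paste0(out_prefix, ".bval")
  writeLines(paste(format(dwi$gradient_table$bvals * 1000,
                          trim = TRUE, scientific = FALSE),
                   collapse = " "), bval)
  bvec <- paste0(out_prefix, ".bvec")
  writeLines(apply(t(dwi$gradient_table$bvecs), 1, function(r)
    paste(format(r, trim = TRUE, digits = 17), collapse = " ")), bvec)
  json <- paste0(out_prefix, ".json")
  jsonlite::write_json(
    list(b_units = "ms/um^2", bvals_ms_per_um2 = dwi$gradient_table$bvals,
         set_labels = dwi$gradient_table$set_labels,
         attenuation_scale = dwi$attenuation_scale,
         mufod_kernel_px = dwi$kernel_px,
         pixel_size_um = dwi$pixel_size_um,
         tilt_deg = dwi$gradient_table$tilt_deg,
         downstream = paste(
           "dwi2response fa (l_max=6); dwi2fod csd (l_max=6);",
           "tckgen with minimum tract length 2 mm")),
    json, auto_unbox = TRUE, digits = NA)
  invisible(c(nifti = nii, bval = bval, bvec = bvec, json = json))
}

#' Read back an exported artificial diffusion dataset
#'
#' Inverse of [export_dwi()], for round-trip checks and downstream reuse.
#'
#' @param out_prefix the prefix passed to [export_dwi()].
#' @return List with `volumes`, `bvals` (ms/um^2), `bvecs` (63 x 3).
#' @export
read_dwi <- function(out_prefix) {
  img <- RNifti::readNifti(paste0(out_prefix, ".nii.gz"))
  bvals <- scan(paste0(out_prefix, ".bval"), quiet = TRUE) / 1000
  bvecs <- t(as.matrix(utils::read.table(paste0(out_prefix, ".bvec"))))
  list(volumes = array(as.numeric(img), dim(img)), bvals = bvals,
       bvecs = unname(bvecs))
}
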