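# Construct orientation_field objects directly for tests that exercise
# downstream products without running the profile analyzer.

make_field <- function(theta, mask = NULL, pixel_size_um = 7) {
  if (is.matrix(theta)) {
    arr <- array(NA_real_, c(dim(theta), 3L))
    arr[, , 1] <- theta
    theta <- arr
  }
  stopifnot(length(dim(theta)) == 3L, dim(theta)[3] == 3L)
  H <- dim(theta)[1]; W <- dim(theta)[2]
  npop <- matrix(0L, H, W)
  for (k in 1:3) npop <- npop + !is.na(theta[, , k])
  proms <- array(NA_real_, dim(theta))
  for (k in 1:3) proms[, , k][!is.na(theta[, , k])] <- 4 - k
  if (is.null(mask)) mask <- matrix(TRUE, H, W)
  structure(
    list(orientations_deg = theta, prominences = proms,
         n_populations = npop, average_map = matrix(1, H, W),
         mask = mask, pixel_size_um = pixel_size_um, params = NULL),
    class = "orientation_field")
}

# Interleaved 0/90-degree fiber domains with genuinely crossing pixels at
# the domain boundaries (a pixel straddling two domains sees both fiber
# families). Stripes are `width` columns wide with a 2-column crossing
# seam between them.
interleaved_phantom_spec <- function(n = 16L, width = 7L, ...) {
  fam <- (((seq_len(n) - 1L) %/% width) %% 2L)
  seam <- c(diff(fam) != 0L, FALSE) | c(FALSE, diff(fam) != 0L)
  col_class <- ifelse(seam, 2L, fam)  # 0 / 1 pure domains, 2 crossing seam
  cls <- matrix(col_class, n, n, byrow = TRUE)
  phantom_spec(shape = c(n, n), regions = list(
    phantom_region(0, mask = cls == 0L),
    phantom_region(90, mask = cls == 1L),
    phantom_region(c(0, 90), mask = cls == 2L)), ...)
}

# A stack whose azimuth direction is reversed (phi -> 360 - phi).
reverse_stack <- function(stack) {
  A <- length(stack$angles)
  rev_idx <- c(1L, A:2)  # angle a_i maps to (360 - a_i) %% 360
  angular_stack(stack$data[, , rev_idx], stack$angles,
                stack$pixel_size_um, stack$meta)
}
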