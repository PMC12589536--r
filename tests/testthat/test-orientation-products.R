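test_that("crossing fractions match small worked examples", {
  # all single-population: no crossings at any kernel size
  f1 <- make_field(matrix(30, 10, 10))
  for (k in c(1, 3, 7, 20))
    expect_equal(crossing_fraction(f1, k)$fraction_ge2, 0)

  # one crossing pixel, kernel covering the whole image
  th <- array(NA_real_, c(10, 10, 3))
  th[, , 1] <- 30
  th[4, 7, 2] <- 120
  f2 <- make_field(th)
  expect_equal(crossing_fraction(f2, 100)$fraction_ge2, 1)

  # 14 x 14 field, one 2-population pixel, kernel 7: 1 of 4 kernels hit
  th3 <- array(NA_real_, c(14, 14, 3))
  th3[, , 1] <- 10
  th3[3, 3, 2] <- 100
  f3 <- make_field(th3)
  s <- crossing_fraction(f3, 7)
  expect_equal(dim(s$map), c(2, 2))
  expect_equal(s$fraction_ge2, 0.25)
  expect_equal(s$fraction_3, 0)
  expect_equal(s$resolution_um, 7 * f3$pixel_size_um)
})

test_that("kernel map equals direct max-pooling and grows monotonically", {
  set.seed(21)
  th <- array(NA_real_, c(28, 28, 3))
  th[, , 1] <- runif(28 * 28, 0, 180)
  extra <- matrix(runif(28 * 28) < 0.15, 28, 28)
  th[, , 2][extra] <- runif(sum(extra), 0, 180)
  f <- make_field(th)

  # oracle: independent max-pooling over complete kernels
  for (k in c(1, 4, 7, 14)) {
    s <- crossing_fraction(f, k)
    pool <- sapply(seq(1, 28, k), function(c0)
      sapply(seq(1, 28, k), function(r0)
        max(f$n_populations[r0:(r0 + k - 1), c0:(c0 + k - 1)])))
    expect_equal(c(s$map), c(pool), label = sprintf("kernel %d", k))
  }

  # nested tilings: fraction never decreases when kernels merge
  fr <- sapply(c(1, 7, 14, 71), function(k)
    crossing_fraction(f, k)$fraction_ge2)
  expect_true(all(diff(fr[c(1, 2, 3)]) >= 0))  # 1 -> 7 -> 14 nested
  expect_gte(fr[4], fr[1])                     # 1 -> 71 nested
})

test_that("partial trailing kernels follow the half-coverage rule", {
  f <- make_field(matrix(10, 10, 10))
  expect_equal(dim(crossing_fraction(f, 7)$map), c(1, 1))  # 3 < 7/2 dropped
  expect_equal(dim(crossing_fraction(f, 6)$map), c(2, 2))  # 4 >= 3 kept
})

test_that("masked pixels do not contribute crossings", {
  th <- array(NA_real_, c(8, 8, 3))
  th[, , 1] <- 45
  th[1, 1, 2] <- 135
  mask <- matrix(TRUE, 8, 8)
  mask[1, 1] <- FALSE
  f <- make_field(th, mask = mask)
  expect_equal(crossing_fraction(f, 8)$fraction_ge2, 0)
})

test_that("downsampling merges interleaved domains into apparent crossings", {
  # vertical 2-px stripes alternating 0 and 90 degrees
  stripes <- matrix(rep(rep(c(0, 90), each = 2), length.out = 16 * 16),
                    16, 16, byrow = TRUE)
  regions <- list(
    phantom_region(0, mask = stripes == 0),
    phantom_region(90, mask = stripes == 90))
  ph <- generate_phantom(phantom_spec(shape = c(16, 16), regions = regions))

  f_apparent <- apparent_crossing_map(ph$stack, 4)
  expect_equal(f_apparent$pixel_size_um, 4 * ph$stack$pixel_size_um)
  truth_field <- analyze_stack(ph$stack)

  # merged pixels see both stripe families: profiles carry 4 peaks
  expect_true(all(f_apparent$n_populations == 2L))

  # factor 1 is exactly analyze_stack
  f1 <- apparent_crossing_map(ph$stack, 1)
  expect_equal(f1$orientations_deg, truth_field$orientations_deg)

  # with true crossing pixels at domain seams, downsampling can only lose
  # crossing detections relative to the kernel-based rule
  phb <- generate_phantom(interleaved_phantom_spec(n = 28L, width = 7L))
  base <- analyze_stack(phb$stack)
  for (fac in c(4, 7)) {
    apparent <- crossing_fraction(apparent_crossing_map(phb$stack, fac),
                                  1)$fraction_ge2
    expect_lte(apparent, crossing_fraction(base, fac)$fraction_ge2)
  }

  # a uniform single-fiber phantom stays single at any factor
  ph2 <- generate_phantom(phantom_spec(shape = c(16, 16),
                                       regions = list(phantom_region(130))))
  for (fac in c(2, 4, 8))
    expect_true(all(apparent_crossing_map(ph2$stack, fac)$n_populations == 1L))
})

test_that("FOM colors encode orientation as hue(2 theta)", {
  f <- make_field(matrix(0, 3, 3))
  img <- render_fom(f)
  expect_equal(dim(img), c(6, 6, 3))
  expect_true(all(img[, , 1] == 1 & img[, , 2] == 0 & img[, , 3] == 0))

  # theta and theta + 90 sit half a wheel apart (complementary colors)
  f90 <- make_field(matrix(90, 3, 3))
  img90 <- render_fom(f90)
  expect_equal(img90[1, 1, ], c(0, 1, 1))

  # two-population pixel: 2x2 mosaic holds both hues
  th <- array(NA_real_, c(1, 1, 3))
  th[1, 1, 1:2] <- c(0, 90)
  m <- render_fom(make_field(th))
  cols <- unique(apply(matrix(m, 4, 3), 1, paste, collapse = ","))
  expect_setequal(cols, c("1,0,0", "0,1,1"))

  # masked pixels are black
  fm <- make_field(matrix(45, 2, 2), mask = matrix(c(TRUE, FALSE), 2, 2))
  imgm <- render_fom(fm)
  expect_true(all(imgm[3:4, 1:2, ] == 0))
})

test_that("vector overlay draws one segment family per block population", {
  f <- make_field(matrix(0, 30, 30))
  img <- vector_overlay(f, overlay_kernel = 15)
  lit <- which(apply(img, c(1, 2), max) > 0)
  expect_gt(length(lit), 0)
  # uniform field: all drawn pixels share the single orientation color
  cols <- unique(apply(matrix(img, 900, 3)[lit, , drop = FALSE], 1,
                       paste, collapse = ","))
  expect_length(cols, 1)

  # two-population field: both hues appear in the overlay
  th <- array(NA_real_, c(30, 30, 3))
  th[, , 1] <- 0
  th[, , 2] <- 90
  img2 <- vector_overlay(make_field(th), overlay_kernel = 15)
  lit2 <- which(apply(img2, c(1, 2), max) > 0)
  cols2 <- unique(apply(matrix(img2, 900, 3)[lit2, , drop = FALSE], 1,
                        paste, collapse = ","))
  expect_length(cols2, 2)

  # degenerate kernel n = 1 still works
  expect_silent(vector_overlay(make_field(matrix(10, 4, 4)), 1))
})
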