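ang24 <- seq(0, 345, by = 15)
phi24 <- ang24 * pi / 180

test_that("low-pass filter passes low harmonics and kills high ones", {
  expect_equal(fourier_lowpass(rep(3.2, 24)), rep(3.2, 24))

  p2 <- 2 + cos(2 * phi24)
  expect_equal(fourier_lowpass(p2), p2, tolerance = 1e-9)

  p <- p2 + 0.5 * cos(10 * phi24)
  expect_equal(fourier_lowpass(p), p2, tolerance = 1e-9)

  # mean preserved exactly for arbitrary profiles
  set.seed(11)
  for (i in 1:5) {
    r <- runif(24)
    expect_equal(mean(fourier_lowpass(r)), mean(r), tolerance = 1e-12)
  }

  # cutoff 1 / window 0 is the identity
  r <- runif(24)
  expect_equal(fourier_lowpass(r, profile_params(fourier_cutoff_fraction = 1,
                                                 fourier_window_width = 0)),
               r, tolerance = 1e-12)
})

test_that("peak detection finds paired scattering lobes to sub-sample accuracy", {
  expect_length(detect_peaks(rep(1, 24))$positions_deg, 0)

  pk <- detect_peaks(lobe_profile(40))
  expect_length(pk$positions_deg, 2)
  expect_equal(pk$positions_deg, c(130, 310), tolerance = 0.5)

  # wrap-around peak (theta = 0 puts lobes at 90 and 270; theta = 85 puts
  # one lobe at 175 and the paired lobe at 355, crossing the origin)
  pk2 <- detect_peaks(lobe_profile(85))
  expect_length(pk2$positions_deg, 2)
  expect_equal(pk2$positions_deg, c(175, 355), tolerance = 0.5)
})

test_that("prominence threshold gates small bumps at the stated fraction", {
  prof <- rep(0, 24)
  prof[5:7] <- c(0.5, 1, 0.5)   # dominant peak, prominence 1 = range
  prof[15] <- 0.05              # bump of prominence 0.05 * range
  p_default <- detect_peaks(prof, profile_params(prominence_fraction = 0.08))
  p_loose <- detect_peaks(prof, profile_params(prominence_fraction = 0.04))
  expect_length(p_default$positions_deg, 1)
  expect_length(p_loose$positions_deg, 2)
})

test_that("peak pairing matches the worked examples", {
  ps <- function(pos, prom = rep(1, length(pos)))
    structure(list(positions_deg = pos, prominences = prom),
              class = "peak_set")

  p1 <- pair_peaks(ps(c(130, 310)))
  expect_equal(nrow(p1), 1)
  expect_equal(c(p1$p1, p1$p2), c(130, 310))

  p3 <- pair_peaks(ps(c(30, 90, 150, 210, 270, 330)))
  expect_equal(nrow(p3), 3)
  expect_equal(p3[order(p3$p1), c("p1", "p2")],
               data.frame(p1 = c(30, 90, 150), p2 = c(210, 270, 330)),
               ignore_attr = TRUE)

  pu <- pair_peaks(ps(c(10, 100, 190)))
  expect_equal(nrow(pu), 1)
  expect_equal(c(pu$p1, pu$p2), c(10, 190))
})

test_that("pair midlines give fiber orientations in [0, 180)", {
  mk <- function(a, b) data.frame(p1 = a, p2 = b, prominence = 1)
  expect_equal(orientations_from_pairs(mk(130, 310)), 40)
  expect_equal(orientations_from_pairs(mk(350, 170)), 80)
  expect_equal(orientations_from_pairs(mk(0, 180)), 90)
  # orientation independent of which peak comes first
  expect_equal(orientations_from_pairs(mk(170, 350)), 80)
})

test_that("pairing agrees with the exhaustive enumeration oracle", {
  set.seed(42)
  params <- profile_params()
  for (i in 1:150) {
    pk <- detect_peaks(random_profile(), params)
    got <- pair_peaks(pk, params)
    want <- brute_force_pairs(pk, params)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got[order(got$p1), c("p1", "p2")],
                   want[order(want$p1), c("p1", "p2")],
                   ignore_attr = TRUE)
    }
  }
})

test_that("stack analysis recovers phantom truth per pixel", {
  # uniform single fiber
  ph <- generate_phantom(phantom_spec(shape = c(8, 8),
                                      regions = list(phantom_region(30))))
  f <- analyze_stack(ph$stack)
  expect_true(all(f$n_populations == 1L))
  expect_lt(max(abs(f$orientations_deg[, , 1] - 30)), 7.5)

  # two crossing populations: two peak pairs, i.e. four peaks
  ph2 <- generate_phantom(phantom_spec(
    shape = c(6, 6), regions = list(phantom_region(c(0, 90)))))
  f2 <- analyze_stack(ph2$stack)
  expect_true(all(f2$n_populations == 2L))
  err <- apply(f2$orientations_deg[, , 1:2], c(1, 2), function(v) {
    max(vapply(c(0, 90), function(t) {
      d <- abs(v - t) %% 180
      min(pmin(d, 180 - d))
    }, 0))
  })
  expect_lt(max(err), 7.5)

  # all-zero stack is fully masked
  z <- analyze_stack(angular_stack(array(0, c(4, 4, 24)), ang24))
  expect_true(all(!z$mask))
  expect_true(all(z$n_populations == 0L))
})

test_that("analysis is equivariant under grid rotations of the scene", {
  base <- c(20, 75)
  delta <- 15  # one azimuthal step
  f0 <- analyze_stack(generate_phantom(phantom_spec(
    shape = c(4, 4), regions = list(phantom_region(base))))$stack)
  f1 <- analyze_stack(generate_phantom(phantom_spec(
    shape = c(4, 4), regions = list(phantom_region(base + delta))))$stack)
  for (k in 1:2) {
    d <- mapply(function(a, b) min(abs(a - b) %% 180, 180 - abs(a - b) %% 180),
                f0$orientations_deg[, , k] + delta, f1$orientations_deg[, , k])
    expect_lt(max(d), 1e-6)
  }
})

test_that("reversing the azimuth direction mirrors the orientations", {
  ph <- generate_phantom(phantom_spec(shape = c(4, 4),
                                      regions = list(phantom_region(40))))
  f <- analyze_stack(ph$stack)
  fr <- analyze_stack(reverse_stack(ph$stack))
  want <- (180 - f$orientations_deg[, , 1]) %% 180
  d <- abs(fr$orientations_deg[, , 1] - want) %% 180
  expect_lt(max(pmin(d, 180 - d)), 1e-6)
})

test_that("population count is exact for separations of at least 30 degrees", {
  # lobes of width sigma merge below ~4 sigma separation under 15-degree
  # sampling, so the 30-degree-separation regime needs sigma <= 10
  set.seed(5)
  for (npop in 1:3) {
    for (rep in 1:4) {
      repeat {  # rejection-sample orientations pairwise >= 30 deg apart
        th <- sort(runif(npop, 0, 180))
        gaps <- if (npop == 1) 90 else c(diff(th), th[1] + 180 - th[npop])
        if (min(gaps) >= 30) break
      }
      ph <- generate_phantom(phantom_spec(shape = c(3, 3),
                                          regions = list(phantom_region(th)),
                                          peak_width_deg = 10))
      f <- analyze_stack(ph$stack)
      expect_true(all(f$n_populations == npop),
                  label = sprintf("count for thetas %s",
                                  paste(round(th, 1), collapse = "/")))
    }
  }
})

test_that("background quantile masking removes dim pixels", {
  spec <- phantom_spec(shape = c(6, 6), regions = list(
    phantom_region(30, amplitude = 1,
                   mask = matrix(rep(c(TRUE, FALSE), each = 18), 6, 6))))
  ph <- generate_phantom(spec)
  f <- analyze_stack(ph$stack,
                     profile_params(background_quantile = 0.5))
  expect_true(all(!f$mask[, 4:6]))   # baseline-only half masked
  expect_true(all(f$n_populations[, 4:6] == 0L))
  expect_true(all(f$n_populations[, 1:3] == 1L))
})
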