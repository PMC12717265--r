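test_that("SCSF evaluates the two-lobe sech model", {
  expect_equal(scsf(0), 373.08 - 0.8493, tolerance = 1e-9)
  expect_equal(scsf(4.1726), 241.70, tolerance = 0.1)
  expect_lt(scsf(200), 1e-5)
  expect_lt(scsf(400), 1e-9)
  # the peak lies at low frequency, below 3 * f0; with the published
  # parameters the low-frequency lobe (a << psi) leaves it at 0
  f <- seq(0, 20, by = 0.01)
  expect_lt(f[which.max(scsf(f))], 3 * 4.1726)
  # a heavier low-frequency lobe shifts the peak off zero
  p2 <- scsf_params(a = 200)
  expect_gt(f[which.max(scsf(f, p2))], 0)
  expect_error(scsf(-1), ">= 0")
  expect_error(scsf_params(f0 = 1, f1 = 2), "f0 > f1")
})

test_that("age factor is 1 + (age/70)^4", {
  expect_equal(age_factor(0), 1)
  expect_equal(age_factor(70), 2)
  expect_equal(age_factor(35), 1.0625)
  expect_error(age_factor(-5), "age")
})

test_that("MOTF matches hand-evaluated values at zero frequency", {
  # sum form, age 70 (AF = 2): 0.426*(7/9) + 0.574 + 0.123*(7/9) + 0.877
  expect_equal(motf(0, 70, form = "sum"), 1.8780, tolerance = 1e-4)
  # product form, age 0 (AF = 1): (0.426*7/8 + 0.574) * (0.123*7/8 + 0.877)
  expect_equal(motf(0, 0, form = "product"), 0.93219, tolerance = 1e-5)
})

test_that("MOTF decreases in frequency and in age for both forms", {
  f <- seq(0, 60, by = 0.5)
  for (form in c("sum", "product")) {
    v <- motf(f, 45, form)
    expect_true(all(diff(v) <= 0))
    # strictly decreasing wherever the value has not underflowed to zero
    pos <- v > 0
    expect_true(all(diff(v[pos]) < 0))
    for (freq in c(0, 2, 10, 30)) {
      by_age <- sapply(c(0, 30, 50, 65, 80), function(a) motf(freq, a, form))
      expect_true(all(diff(by_age) <= 0))
    }
  }
})

test_that("NTF is SCSF/MOTF and non-negative over the protocol band", {
  expect_equal(ntf(0, 70, form = "sum"), 372.2307 / 1.8780, tolerance = 1e-3)
  f <- seq(0, 60, by = 0.1)
  expect_true(all(ntf(f, 45) >= 0))
  # the product form underflows at high f; the clamp guard warns
  expect_warning(vp <- ntf(f, 45, form = "product"), "clamping")
  expect_true(all(vp >= 0))
  curve <- filter_curve(what = "ntf", age = 45)
  expect_named(curve, c("frequency_cpd", "value"))
  expect_true(all(is.finite(curve$value)))
})

test_that("NTF filtering is DC-normalized, linear, and matches the impulse oracle", {
  set.seed(2)
  m <- matrix(runif(32 * 32), 32, 32)
  img <- optotype_image(m, ppd = 32)
  f <- apply_ntf_filter(img, 45, clip = FALSE)
  expect_equal(mean(f$pixels), mean(m), tolerance = 1e-12)   # DC preserved
  # uniform image passes through unchanged
  u <- apply_ntf_filter(optotype_image(matrix(0.5, 32, 32), 32), 45)
  expect_equal(u$pixels, matrix(0.5, 32, 32), tolerance = 1e-12)
  # linearity before clipping
  f2 <- apply_ntf_filter(optotype_image(0.5 * m, 32), 45, clip = FALSE)
  expect_equal(f2$pixels, 0.5 * f$pixels, tolerance = 1e-10)
  # impulse response equals the shifted inverse transform of the gain map
  d <- matrix(0, 32, 32); d[17, 17] <- 1
  fi <- apply_ntf_filter(optotype_image(d, 32), 45, clip = FALSE)
  gain <- ntf(acuitysim:::freq_grid_cpd(32, 32), 45) / ntf(0, 45)
  ker <- Re(stats::fft(gain, inverse = TRUE)) / 32^2
  expect_equal(fi$pixels, ker[c(17:32, 1:16), c(17:32, 1:16)], tolerance = 1e-6)
  expect_error(apply_ntf_filter(structure(list(pixels = m, ppd = NULL),
                                          class = "optotype_image"), 45),
               "pixels-per-degree")
})

test_that("retinal sampling band-limits to the mosaic Nyquist rate", {
  # rate at or above the canvas rate: identity with a warning
  im <- optotype_image(matrix(runif(16), 4, 4), ppd = 64)
  expect_warning(out <- retinal_sampling(im, 64), "unchanged")
  expect_equal(out$pixels, im$pixels)
  # constant image preserved exactly
  cim <- retinal_sampling(optotype_image(matrix(0.3, 64, 64), 64), 30)
  expect_equal(cim$pixels, matrix(0.3, 64, 64), tolerance = 1e-12)
  # a grating above the retinal Nyquist rate is suppressed below 5% contrast
  ppd <- 128
  x <- (0:127) / ppd
  g <- 0.5 + 0.4 * cos(2 * pi * 45 * outer(x, rep(1, 128)))  # 45 cpd
  gs <- retinal_sampling(optotype_image(g, ppd), 60)         # cutoff 30 cpd
  expect_lt(diff(range(gs$pixels)), 0.05 * diff(range(g)))
})

test_that("Gaussian noise stage has the configured moments and is seeded", {
  base <- optotype_image(matrix(0.5, 224, 224), 224)
  expect_identical(add_gaussian_noise(base, 0)$pixels, base$pixels)
  n1 <- add_gaussian_noise(base, 0.01, seed = 9)
  expect_equal(mean(n1$pixels), 0.5, tolerance = 0.002)
  expect_equal(var(as.numeric(n1$pixels)), 0.01, tolerance = 0.001)
  expect_identical(n1$pixels, add_gaussian_noise(base, 0.01, seed = 9)$pixels)
  expect_true(all(n1$pixels >= 0 & n1$pixels <= 1))
})

test_that("noise variance converges across independent draws", {
  base <- optotype_image(matrix(0.5, 8, 8), 224)
  draws <- sapply(1:1000, function(s)
    as.numeric(add_gaussian_noise(base, 0.01, seed = s)$pixels))
  pixel_var <- apply(draws, 1, var)
  expect_lt(abs(mean(pixel_var) - 0.01), 0.0005)
  expect_true(all(abs(pixel_var - 0.01) < 0.005))
})
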