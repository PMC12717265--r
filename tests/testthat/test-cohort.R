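test_that("cohort generation is seeded and honours the eligibility window", {
  co <- generate_cohort(50, seed = 4, missing_va = 0)
  expect_equal(nrow(co), 100)
  expect_true(all(co$age >= 30 & co$age <= 65))
  se <- spherical_equivalent(co$sphere_d, co$cylinder_d)
  expect_true(all(se >= -7 & se <= 4))
  expect_true(all(co$aa_d >= 0))
  expect_true(all(co$cylinder_d <= 0))
  expect_equal(sum(co$dominant), 50)           # one dominant eye per subject
  expect_true(all(table(co$subject_id) == 2))
  # defocus VA only on dominant eyes
  dcols <- acuitysim:::defocus_colnames()
  expect_true(all(is.na(co[co$dominant == 0, dcols])))
  expect_true(all(!is.na(co[co$dominant == 1, dcols])))
  # reproducible byte-for-byte
  expect_identical(co, generate_cohort(50, seed = 4, missing_va = 0))
  expect_false(identical(co, generate_cohort(50, seed = 5, missing_va = 0)))
})

test_that("the defocus coefficient encodes the eye's spherical equivalent", {
  co <- generate_cohort(20, seed = 8, missing_va = 0)
  se <- spherical_equivalent(co$sphere_d, co$cylinder_d)
  expect_equal(co$z4, diopter_to_z20(se, co$pupil_radius_mm), tolerance = 1e-9)
  # astigmatism magnitude matches the cylinder
  expect_equal(sqrt(co$z3^2 + co$z5^2),
               abs(co$cylinder_d) * co$pupil_radius_mm^2 / (4 * sqrt(6)),
               tolerance = 1e-9)
})

test_that("the blur rule encodes accommodation asymmetry and the acuity floor", {
  # emmetrope, corrected, young: best-acuity floor
  expect_equal(blur_rule_va(0, 0, aa = 6, age = 35), -0.1)
  # accommodation rescues negative defocus when AA covers it
  expect_lt(blur_rule_va(-1.5, 0, aa = 4, age = 40),
            blur_rule_va(+1.5, 0, aa = 4, age = 40))
  expect_equal(blur_rule_va(-1.5, 0, aa = 4, age = 40), -0.1)
  # without reserve, negative blur hurts
  expect_gt(blur_rule_va(-3, 0, aa = 1, age = 40), 0)
  # age penalty beyond 50 and the reporting cap
  expect_gt(blur_rule_va(0, 0, 6, 60), blur_rule_va(0, 0, 6, 49))
  expect_equal(blur_rule_va(10, 2, 0, 65), 1.1)
})

test_that("missing-VA injection blanks exactly the requested cells", {
  co <- generate_cohort(135, seed = 7, missing_va = 11)
  dcols <- acuitysim:::defocus_colnames()
  n_na <- sum(is.na(co$va_uncorrected_logmar)) +
    sum(is.na(co$va_corrected_logmar)) +
    sum(is.na(co[co$dominant == 1, dcols]))
  expect_equal(n_na, 11)
})

test_that("the simulated observer follows its psychometric rule", {
  expect_equal(observer_probability(0.5, 0.5), 0.55)
  expect_gt(observer_probability(1.0, 0.5), 0.99)
  expect_lt(observer_probability(-0.3, 0.5), 0.11)
  # Monte-Carlo agreement at a fixed offset
  set.seed(15)
  p_true <- observer_probability(0.56, 0.5)
  hits <- mean(simulated_observer(rep(0.56, 2000), 0.5))
  expect_lt(abs(hits - p_true), 0.03)
  expect_identical(simulated_observer(0.5, 0.5, seed = 3),
                   simulated_observer(0.5, 0.5, seed = 3))
})

test_that("clipped spherical-equivalent distribution matches its target moments", {
  co <- generate_cohort(5000, seed = 123, missing_va = 0)
  se <- spherical_equivalent(co$sphere_d, co$cylinder_d)
  # clipped-normal oracle for N(-1, 2^2) truncated-by-clipping to [-7, 4]
  mu <- -1; s <- 2; lo <- -7; hi <- 4
  a <- (lo - mu) / s; b <- (hi - mu) / s
  m_clip <- mu + s * (dnorm(a) - dnorm(b)) +
    lo * pnorm(a) + hi * pnorm(-b) - mu * (pnorm(a) + pnorm(-b))
  expect_equal(mean(se), m_clip, tolerance = 0.05 * abs(m_clip) + 0.03)
  expect_equal(sd(se), s, tolerance = 0.05 * s)
})

test_that("protocol VA from the simulated observer tracks the true VA", {
  co <- generate_cohort(10, seed = 31, missing_va = 0)
  set.seed(31)
  scored <- sapply(seq_len(20), function(i) {
    determine_va(function(letter, lm)
      runif(1) < observer_probability(lm, co$va_uncorrected_logmar[i]),
      seed = 100 + i)$final_va
  })
  rho <- cor(scored, co$va_uncorrected_logmar[1:20], method = "spearman")
  expect_gt(rho, 0.7)
})

test_that("the end-to-end fixture chains cohort, images and observations", {
  fx <- end_to_end_fixture(n_subjects = 3, seed = 2)
  expect_equal(nrow(fx$cohort), 6)
  expect_equal(nrow(fx$manifest), 6 * 14 * 5)
  expect_equal(attr(fx$observations, "n_built"), 3 * 4 + 3 * 9)
  expect_true(all(fx$manifest$label %in% c(0, 1)))
  fx2 <- end_to_end_fixture(n_subjects = 3, seed = 2)
  expect_identical(fx$manifest, fx2$manifest)
})
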