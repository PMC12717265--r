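test_that("observation table reproduces the study's row structure", {
  co <- generate_cohort(135, seed = 7, missing_va = 11)
  tab <- build_observation_table(co)
  expect_equal(attr(tab, "n_built"), 1755)     # 270 + 270 + 1215
  expect_equal(attr(tab, "n_dropped"), 11)
  expect_equal(nrow(tab), 1744)
  # defocus block built for every dominant eye at nine levels
  expect_equal(9 * sum(co$dominant), 1215)
  sp <- split_train_test(tab, 0.8, seed = 4)
  expect_equal(nrow(sp$test), 348)
  expect_equal(nrow(sp$train), 1396)
})

test_that("row counts follow 2S + 2S + 9 S_dom minus missing", {
  for (S in c(4, 9)) {
    co <- generate_cohort(S, seed = S, missing_va = 2)
    tab <- build_observation_table(co)
    expect_equal(attr(tab, "n_built"), 2 * S + 2 * S + 9 * S)
    expect_equal(nrow(tab), 4 * S + 9 * S - 2)
  }
  # a subject with no defocus data contributes 4 rows (2 + 2)
  co1 <- generate_cohort(1, seed = 3, missing_va = 0)
  co1[, acuitysim:::defocus_colnames()] <- NA
  tab1 <- build_observation_table(co1)
  expect_equal(nrow(tab1), 4)
  expect_setequal(unique(tab1$condition), c("uncorrected", "corrected"))
})

test_that("accommodation gating follows the sign rules", {
  co <- generate_cohort(10, seed = 2, missing_va = 0)
  tab <- build_observation_table(co)
  d <- tab[tab$condition == "defocus", ]
  aa_of <- co$aa_d[match(paste(d$subject_id, d$eye),
                         paste(co$subject_id, co$eye))]
  expect_equal(d$aa_gated[d$delta_d < 0], aa_of[d$delta_d < 0])
  expect_true(all(d$aa_gated[d$delta_d >= 0] == 0))
  # one defocus row: -1.50 carries AA, +0.50 carries zero
  expect_true(all(d$aa_gated[d$delta_d == -1.5] == aa_of[d$delta_d == -1.5]))
  expect_true(all(d$aa_gated[d$delta_d == 0.5] == 0))
  # corrected rows never carry AA; uncorrected rows gate on SE sign
  expect_true(all(tab$aa_gated[tab$condition == "corrected"] == 0))
  u <- tab[tab$condition == "uncorrected", ]
  se <- spherical_equivalent(u$sphere_d, u$cylinder_d)
  expect_true(all(u$aa_gated[se >= 0] == 0))
  expect_true(all(u$aa_gated[se < 0] > 0 | u$aa_gated[se < 0] ==
                    co$aa_d[match(paste(u$subject_id, u$eye),
                                  paste(co$subject_id, co$eye))][se < 0]))
})

test_that("condition rows carry the coefficient manipulations", {
  co <- generate_cohort(5, seed = 6, missing_va = 0)
  tab <- build_observation_table(co)
  zcols <- paste0("z", 0:35)
  for (i in c(1, 4)) {
    zset <- zernike_set(as.numeric(co[i, zcols]), co$pupil_radius_mm[i])
    key <- paste(tab$subject_id, tab$eye)
    mine <- paste(co$subject_id[i], co$eye[i])
    crow <- tab[tab$condition == "corrected" & key == mine, ]
    expect_equal(as.numeric(crow[, zcols]), apply_correction(zset)$coeffs)
    if (co$dominant[i] == 1) {
      drow <- tab[tab$condition == "defocus" & key == mine & tab$delta_d == -2, ]
      expect_equal(as.numeric(drow[, zcols]),
                   apply_defocus_condition(zset, -2)$coeffs, tolerance = 1e-12)
    }
  }
})

test_that("train/test split is a seeded partition", {
  co <- generate_cohort(8, seed = 1, missing_va = 0)
  tab <- build_observation_table(co)
  sp1 <- split_train_test(tab, 0.8, seed = 9)
  sp2 <- split_train_test(tab, 0.8, seed = 9)
  expect_identical(sp1$test, sp2$test)
  expect_equal(nrow(sp1$train) + nrow(sp1$test), nrow(tab))
  key <- function(d) paste(d$subject_id, d$eye, d$condition, d$delta_d)
  expect_length(intersect(key(sp1$train), key(sp1$test)), 0)
  expect_setequal(c(key(sp1$train), key(sp1$test)), key(tab))
})

test_that("Zernike subsets and feature matrices are assembled correctly", {
  expect_equal(zernike_subset(5), 1:5)
  expect_equal(zernike_subset(9), 1:9)
  expect_equal(zernike_subset(14), 1:14)
  expect_equal(zernike_subset(36), 0:35)
  expect_error(zernike_subset(7), "one of")
  co <- generate_cohort(3, seed = 1, missing_va = 0)
  tab <- build_observation_table(co)
  X <- observation_features(tab, 9, use_aa = TRUE)
  expect_equal(colnames(X), c(paste0("z", 1:9), "age", "aa_gated"))
  X36 <- observation_features(tab, 36, use_aa = FALSE, use_age = FALSE)
  expect_equal(ncol(X36), 36)
})

test_that("stratification uses the clinical bin boundaries", {
  co <- generate_cohort(30, seed = 3, missing_va = 0)
  tab <- build_observation_table(co)
  tab$age[1] <- 44; tab$age[2] <- 45; tab$age[3] <- 40.9
  byage <- stratify(tab, "age_bins")
  expect_named(byage, c("30-40", "41-44", "45-50", "51-55", "56-60", "61-65"))
  expect_true(44 %in% byage[["41-44"]]$age)
  expect_true(45 %in% byage[["45-50"]]$age)
  expect_true(40.9 %in% byage[["30-40"]]$age)
  # SE groups: only uncorrected rows, inclusive emmetropic bounds
  tab$sphere_d[tab$condition == "uncorrected"][1] <- -2
  tab$cylinder_d[tab$condition == "uncorrected"][1] <- -1
  byse <- stratify(tab, "se_groups")
  expect_named(byse, c("myopic", "emmetropic", "hyperopic"))
  expect_true(all(unlist(lapply(byse, function(d) d$condition)) == "uncorrected"))
  u1 <- tab[tab$condition == "uncorrected", ][1, ]
  expect_true(paste(u1$subject_id, u1$eye) %in%
                paste(byse$myopic$subject_id, byse$myopic$eye))
  # boundary: SE = -0.5 exactly is emmetropic
  se <- spherical_equivalent(byse$emmetropic$sphere_d, byse$emmetropic$cylinder_d)
  expect_true(all(se >= -0.5 & se <= 0.5))
})
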