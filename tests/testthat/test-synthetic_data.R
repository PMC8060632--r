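test_that("scene generator hits the target cover exactly and reproducibly", {
  pure_soil <- simulate_canopy_image(scene_config(target_cover = 0, seed = 1))
  expect_false(any(pure_soil$mask))
  all_leaf <- simulate_canopy_image(scene_config(target_cover = 1, seed = 1))
  expect_true(all(all_leaf$mask))

  cfg <- scene_config(target_cover = 0.42, color_noise_sd = 0, seed = 31)
  a <- simulate_canopy_image(cfg)
  b <- simulate_canopy_image(cfg)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  expect_lt(abs(mean(a$mask) - 0.42), 0.01)
  expect_equal(a$true_cover, round(0.42 * length(a$mask)) / length(a$mask))

  expect_error(scene_config(target_cover = 1.2), "target_cover")
  expect_error(scene_config(leaf_color_mean = c(120, 100, 40)), "G - R")
})

test_that("scene generation leaves the caller's RNG state untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_canopy_image(scene_config(seed = 4)))
  expect_identical(.Random.seed, before)
})

test_that("trial table has the full factorial design size", {
  trial <- simulate_trial(trial_config(seed = 1))
  # 2 sites x 2 seasons x 4 cultivars x 5 N rates x 3 reps x 3 stages
  expect_equal(nrow(trial), 720L)
  key <- with(trial, paste(site, season, cultivar, n_rate_kg_ha,
                           replicate, stage))
  expect_equal(anyDuplicated(key), 0L)
  expect_true(all(trial$sdm_t_ha > 0 & trial$lai > 0 &
                    trial$snc_pct > 0 & trial$sna_kg_ha > 0))
})

test_that("noiseless trials satisfy the construction identities", {
  trial <- simulate_trial(trial_config(noise_cv = 0, cc_jitter_sd = 0,
                                       seed = 2))
  # SNA = 10 * SDM * SNC holds exactly
  expect_equal(trial$sna_kg_ha, 10 * trial$sdm_t_ha * trial$snc_pct)
  # power law evaluates exactly at the configured cultivar parameters
  ak <- subset(trial, cultivar == "AK58")
  expect_equal(ak$sdm_t_ha, 4.87 * ak$cc^1.92)
  # CC = 1 would give SDM = a_d; check via the fitted curve instead
  fit <- fit_allometric(ak$cc, ak$sdm_t_ha)
  expect_equal(unname(coef(fit)), c(4.87, 1.92), tolerance = 1e-6)
})

test_that("noiseless round-trip recovers every cultivar's parameters", {
  trial <- simulate_trial(trial_config(noise_cv = 0, seed = 3))
  pars <- ccnni:::default_cultivar_params()
  for (i in seq_len(nrow(pars))) {
    d <- trial[trial$cultivar == pars$cultivar[i], ]
    for (spec in list(c("sdm_t_ha", "a_d", "b_d"),
                      c("lai", "a_l", "b_l"),
                      c("sna_kg_ha", "a_n", "b_n"))) {
      fit <- fit_allometric(d$cc, d[[spec[1]]])
      expect_equal(fit$a, pars[[spec[2]]][i], tolerance = 1e-6)
      expect_equal(fit$b, pars[[spec[3]]][i], tolerance = 1e-6)
      expect_equal(fit$r2, 1, tolerance = 1e-9)
    }
  }
})

test_that("mean CC is ordered across stages and N rates", {
  trial <- simulate_trial(trial_config(seed = 4))
  stages <- c("Feekes 3", "Feekes 5", "Feekes 6")
  for (nr in unique(trial$n_rate_kg_ha)) {
    m <- vapply(stages, function(s)
      mean(trial$cc[trial$n_rate_kg_ha == nr & trial$stage == s]), 0)
    expect_true(all(diff(m) > 0))
  }
  for (s in stages) {
    m <- vapply(sort(unique(trial$n_rate_kg_ha)), function(nr)
      mean(trial$cc[trial$n_rate_kg_ha == nr & trial$stage == s]), 0)
    expect_true(all(diff(m) > 0))
  }
  # generated CC ranges emulate the field conditions: N0 means near
  # 0.18 -> 0.61, N300 near 0.30 -> 0.88
  n0 <- trial[trial$n_rate_kg_ha == 0, ]
  expect_equal(mean(n0$cc[n0$stage == "Feekes 3"]), 0.18, tolerance = 0.05)
  expect_equal(mean(n0$cc[n0$stage == "Feekes 6"]), 0.61, tolerance = 0.05)
  n300 <- trial[trial$n_rate_kg_ha == 300, ]
  expect_equal(mean(n300$cc[n300$stage == "Feekes 3"]), 0.30, tolerance = 0.05)
  expect_equal(mean(n300$cc[n300$stage == "Feekes 6"]), 0.88, tolerance = 0.05)
})

test_that("trial draws are reproducible and config is validated", {
  a <- simulate_trial(trial_config(seed = 17))
  b <- simulate_trial(trial_config(seed = 17))
  expect_identical(a, b)
  expect_false(identical(a, simulate_trial(trial_config(seed = 18))))
  expect_error(trial_config(replicates = 0), "replicates")
  expect_error(trial_config(noise_cv = -0.1), "noise_cv")
  expect_error(trial_config(cc_range_per_n_rate = cbind(0, 1.2)),
               "one \\(min, max\\) row|endpoints")
})
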