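test_that("control trajectory with no noise or drift is the baseline", {
  prof <- variety_profile("X", 0.5, 0.5, baseline = c(70, 120, 55))
  cfg <- sim_config(noise_sd = 0,
                    aging = list(red_per_day = 0, blue_per_day = 0,
                                 green_rise = 0, green_rise_mid = 0.5,
                                 green_rise_width = 0.18))
  tr <- simulate_trajectory(prof, "control", cfg, days = 1:8,
                            duration = 8)
  expect_equal(tr$meanR, rep(70, 8))
  expect_equal(tr$meanG, rep(120, 8))
  expect_equal(tr$meanB, rep(55, 8))
  expect_equal(tr$severity, rep(0, 8))
})

test_that("trajectories are deterministic given a seed", {
  prof <- variety_profile("X", 0.2, 0.4)
  a <- simulate_trajectory(prof, "BPH", sim_config(), days = 1:8,
                           duration = 8, seed = 99)
  b <- simulate_trajectory(prof, "BPH", sim_config(), days = 1:8,
                           duration = 8, seed = 99)
  expect_identical(a, b)
})

test_that("susceptible infested trajectories rise in red and blue", {
  prof <- variety_profile("TN1", 0, 0)
  cfg <- sim_config(noise_sd = 0)
  for (tr_name in c("BPH", "WBPH")) {
    tr <- simulate_trajectory(prof, tr_name, cfg, days = 1:9,
                              duration = 9)
    expect_gt(tr$meanR[9], tr$meanR[1])
    expect_gt(tr$meanB[9], tr$meanB[1])
    expect_true(all(diff(tr$severity) >= 0))
  }
})

test_that("severity maps to 0-9 scores with halves up", {
  expect_equal(severity_to_score(c(0, 1, 0.5)), c(0L, 9L, 5L))
  expect_equal(severity_to_score(1 / 18), 1L)  # 0.5 rounds up
  expect_error(severity_to_score(1.2), class = "hb_domain_error")
  expect_error(severity_to_score(-0.1), class = "hb_domain_error")
})

test_that("experiment observation counts follow the design", {
  cfg <- sim_config(n_check_patches = 1, replicate_rate_sd = 0,
                    noise_sd = 0)
  profs <- default_profiles(5)
  exp <- simulate_experiment(cfg, profs, seed = 3)
  # 5 varieties x 3 arms x 3 replicates x duration days
  expect_equal(nrow(exp$observations),
               5 * 3 * 3 * unique(exp$durations))
  expect_true(all(exp$durations >= 6 & exp$durations <= 10))
  # exactly one observation per (variety, arm, replicate, day)
  key <- with(exp$observations,
              table(variety, treatment, replicate))
  expect_true(all(key == unique(exp$durations)))
})

test_that("experiments are byte-identical under one seed", {
  cfg <- sim_config()
  a <- simulate_experiment(cfg, default_profiles(6), seed = 12)
  b <- simulate_experiment(cfg, default_profiles(6), seed = 12)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c2 <- simulate_experiment(cfg, default_profiles(6), seed = 13)
  expect_false(identical(a$observations$meanR, c2$observations$meanR))
})

test_that("the susceptible check dies in every replicate", {
  exp <- tiny_experiment(6, seed = 4)
  fin <- subset(exp$observations,
                variety == "TN1" & proportionalTime == 1 &
                  treatment != "control")
  expect_true(all(fin$sesScore == 9L))
  expect_error(
    simulate_experiment(sim_config(check = "NOPE"), default_profiles(4)),
    class = "hb_config_error")
})

test_that("final brown-planthopper red exceeds whitebacked red", {
  prof <- variety_profile("TN1", 0, 0)
  cfg <- sim_config(noise_sd = 0)
  b <- simulate_trajectory(prof, "BPH", cfg, days = 1:9, duration = 9)
  w <- simulate_trajectory(prof, "WBPH", cfg, days = 1:9, duration = 9)
  expect_gt(b$meanR[9], w$meanR[9])
})

test_that("whitebacked replicates vary more in hue than brown", {
  set.seed(77)
  prof <- variety_profile("TN1", 0, 0)
  cfg <- sim_config()
  hues <- replicate(200, {
    b <- simulate_trajectory(prof, "BPH", cfg, days = 8, duration = 8)
    w <- simulate_trajectory(prof, "WBPH", cfg, days = 8, duration = 8)
    c(rgb_to_hsb(c(b$meanR, b$meanG, b$meanB))$hue,
      rgb_to_hsb(c(w$meanR, w$meanG, w$meanB))$hue)
  })
  expect_gt(sd(hues[2, ]), sd(hues[1, ]))
})

test_that("dropout removes varieties from replicates but never the check", {
  cfg <- sim_config(dropout_prob = 0.3)
  exp <- suppressWarnings(simulate_experiment(cfg, default_profiles(8),
                                              seed = 21))
  per_rep <- with(exp$observations, tapply(variety, replicate,
                                           function(v) length(unique(v))))
  expect_true(any(per_rep < 8))
  expect_true(all(with(exp$observations,
                       tapply(variety, replicate,
                              function(v) "TN1" %in% v))))
})

test_that("rendered patches have the requested geometry and masks", {
  rp <- render_patch_image(c(62, 108, 48), width = 64, height = 48,
                           seed = 31)
  expect_equal(dim(rp$image), c(48, 64, 3))
  expect_equal(dim(rp$mask), c(48, 64))
  expect_error(render_patch_image(c(62, 108, 48), coverage = 0),
               class = "hb_config_error")
  expect_error(render_patch_image(c(62, 108, 48), width = 16),
               class = "hb_config_error")
})

test_that("renderer noise spec: recovered means stay near the target", {
  set.seed(83)
  dev <- replicate(20, {
    rp <- render_patch_image(c(90, 100, 70))
    cm <- summarize_patch(rp$image, rp$mask)
    max(abs(c(cm$meanR, cm$meanG, cm$meanB) - c(90, 100, 70)))
  })
  expect_gte(mean(dev <= 2), 0.95)
})

test_that("nuisance offsets shift every observation when configured", {
  cfg0 <- sim_config(noise_sd = 0)
  cfg1 <- sim_config(noise_sd = 0,
                     nuisance = list(flash_off = c(-6, -4, 10)),
                     conditions = "flash_off")
  prof <- variety_profile("TN1", 0, 0)
  t0 <- simulate_trajectory(prof, "control", cfg0, days = 1:6,
                            duration = 6)
  t1 <- simulate_trajectory(prof, "control", cfg1, days = 1:6,
                            duration = 6)
  expect_equal(t1$meanR, t0$meanR - 6)
  expect_equal(t1$meanB, t0$meanB + 10)
})
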