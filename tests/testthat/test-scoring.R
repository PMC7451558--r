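test_that("time standardization rounds to the 0.1 grid, halves up", {
  expect_equal(standardize_time(10, 10), 1.0)
  expect_equal(standardize_time(3, 6), 0.5)
  expect_equal(standardize_time(5, 7), 0.7)   # 0.714... -> 0.7
  expect_equal(standardize_time(1, 8), 0.1)   # 0.125 -> 0.1
  expect_equal(standardize_time(1, 10), 0.1)
  expect_equal(standardize_time(3, 8), 0.4)   # 0.375 -> 0.4 (half up)
  expect_error(standardize_time(8, 7), class = "hb_domain_error")
  expect_error(standardize_time(1, 12), class = "hb_domain_error")
})

test_that("a 10-day daily test covers the whole 0.1 grid", {
  expect_equal(standardize_time(1:10, 10), seq(0.1, 1, by = 0.1))
})

test_that("SES banding follows the 0-3 / 4-6 / 7-9 cut-offs", {
  expect_equal(as.character(classify_by_score(c(2, 5, 8))),
               c("resistant", "moderately resistant", "susceptible"))
  expect_equal(as.character(classify_by_score(c(0, 3, 4, 6, 7, 9))),
               c("resistant", "resistant", "moderately resistant",
                 "moderately resistant", "susceptible", "susceptible"))
  expect_error(classify_by_score(10), class = "hb_domain_error")
  expect_error(classify_by_score(-1), class = "hb_domain_error")
})

test_that("final-day table filters, pools controls and averages patches", {
  exp <- tiny_experiment(5, seed = 9)
  ft <- final_day_table(exp, index = "gli")
  expect_true(all(ft$treatment %in% c("control", "BPH", "WBPH")))
  expect_lte(nrow(ft), 5 * 3 * 3)
  # check variety has 7 patches per tray averaged into one row
  expect_equal(unique(ft$nPatches[ft$variety == "TN1"]), 7)
  # manual pooling oracle for one cell
  obs <- exp$observations
  cell <- obs[obs$variety == "TN1" & obs$treatment == "BPH" &
                obs$replicate == 1 & obs$proportionalTime == 1, ]
  want <- mean(compute_index("gli",
                             as.matrix(cell[, c("meanR", "meanG",
                                                "meanB")])))
  expect_equal(ft$value[ft$variety == "TN1" & ft$treatment == "BPH" &
                          ft$replicate == 1], want, tolerance = 1e-12)
  expect_error(final_day_table(obs[obs$proportionalTime < 1, ]),
               class = "hb_domain_error")
})

test_that("split control arms are pooled into one control level", {
  exp <- tiny_experiment(4, seed = 15)
  obs <- exp$observations
  # relabel half the control patches as a second control arm
  ctl <- obs$treatment == "control"
  flip <- ctl & (seq_len(nrow(obs)) %% 2 == 0)
  obs$treatment[flip] <- "control_wbph"
  ft_split <- final_day_table(obs)
  ft_orig <- final_day_table(exp)
  expect_equal(sort(unique(ft_split$treatment)),
               sort(unique(ft_orig$treatment)))
  expect_equal(ft_split$value, ft_orig$value, tolerance = 1e-12)
})

test_that("condition change identities hold", {
  tbl <- data.frame(
    variety = rep(c("A", "CHK"), each = 6),
    treatment = rep(rep(c("BPH", "control"), each = 3), 2),
    replicate = rep(1:3, 4),
    value = c(0.2, 0.21, 0.19, 0.2, 0.21, 0.19,      # A: delta 0
              -0.1, -0.12, -0.08, 0.2, 0.18, 0.22))  # CHK: delta -0.3
  class(tbl) <- c("final_day_table", "data.frame")
  attr(tbl, "index") <- "gli"
  cc <- condition_change(tbl, "A", "BPH", check = "CHK")
  expect_equal(cc$deltaIndex, 0)
  expect_equal(cc$relativeChange, 0)
  expect_true(is.na(cc$foldBetter))

  # variety delta equal to check delta -> relative change 1
  tbl2 <- tbl
  tbl2$value[1:3] <- tbl2$value[4:6] - 0.3
  cc2 <- condition_change(tbl2, "A", "BPH", check = "CHK")
  expect_equal(cc2$relativeChange, 1)
  expect_equal(cc2$foldBetter, 1)

  # -0.01 vs -0.30 -> 1/30 relative, 30-fold better
  tbl3 <- tbl
  tbl3$value[1:3] <- tbl3$value[4:6] - 0.01
  cc3 <- condition_change(tbl3, "A", "BPH", check = "CHK")
  expect_equal(cc3$relativeChange, 1 / 30, tolerance = 1e-9)
  expect_equal(cc3$foldBetter, 30, tolerance = 1e-9)
  expect_equal(cc3$relativeChange * cc3$foldBetter, 1, tolerance = 1e-12)

  # zero check delta -> undefined with warning
  tbl4 <- tbl
  tbl4$value[7:9] <- tbl4$value[10:12]
  expect_warning(cc4 <- condition_change(tbl4, "A", "BPH", check = "CHK"),
                 "check delta")
  expect_true(is.na(cc4$relativeChange))
})

test_that("condition change is affine equivariant", {
  exp <- tiny_experiment(5, seed = 19)
  ft <- final_day_table(exp)
  cc <- condition_change(ft, "V01", "BPH")
  ft_shift <- ft; ft_shift$value <- ft$value + 5
  cc_shift <- condition_change(ft_shift, "V01", "BPH")
  expect_equal(cc_shift$deltaIndex, cc$deltaIndex, tolerance = 1e-12)
  expect_equal(cc_shift$relativeChange, cc$relativeChange,
               tolerance = 1e-12)
  ft_scale <- ft; ft_scale$value <- ft$value * 3
  cc_scale <- condition_change(ft_scale, "V01", "BPH")
  expect_equal(cc_scale$deltaIndex, 3 * cc$deltaIndex, tolerance = 1e-12)
  expect_equal(cc_scale$relativeChange, cc$relativeChange,
               tolerance = 1e-12)
})

test_that("relative change decreases with resistance in noise-free runs", {
  rho <- seq(0, 0.9, by = 0.1)
  profs <- do.call(rbind, lapply(seq_along(rho), function(i)
    variety_profile(if (i == 1) "TN1" else sprintf("P%02d", i),
                    rho[i], rho[i])))
  cfg <- sim_config(noise_sd = 0, replicate_rate_sd = 0,
                    weight_noise_sd = 0)
  exp <- simulate_experiment(cfg, profs, seed = 1)
  ft <- final_day_table(exp)
  cc <- condition_change_table(ft, check = "TN1", treatments = "BPH")
  ord <- match(sprintf("P%02d", 2:10), cc$variety)
  expect_true(all(diff(cc$relativeChange[ord]) < 0))
})

test_that("weight loss equals the brute-force group-mean contrast", {
  tbl <- data.frame(
    variety = rep("A", 6),
    treatment = rep(c("BPH", "control"), each = 3),
    replicate = rep(1:3, 2),
    value = 0,
    dryWeight = c(150, 150, 150, 400, 400, 400))
  expect_equal(weight_loss(tbl, "A", "BPH"), 250)
  tbl$dryWeight <- c(tbl$dryWeight[1:3], tbl$dryWeight[1:3])
  expect_equal(weight_loss(tbl, "A", "BPH"), 0)

  set.seed(23)
  tbl$dryWeight <- runif(6, 100, 400)
  want <- mean(tbl$dryWeight[4:6] - tbl$dryWeight[1:3])
  expect_equal(weight_loss(tbl, "A", "BPH"), want, tolerance = 1e-12)
  expect_warning(wl <- weight_loss(tbl, "B", "BPH"), "missing")
  expect_true(is.na(wl))
})
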