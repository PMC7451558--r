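# Synthetic screening experiments.
#
# The generator emulates the structure a seed-box screen with two
# planthopper species produces: a latent damage severity that rises
# logistically once feeding takes hold (early-flat / late-steep), channel
# means that drift with plant age (slow red and blue rise, a mid-test
# green flush in controls), treatment colour shifts (hopperburn pushes red
# and blue strongly; whitebacked kill retains proportionately more green
# and blue), larger between-replicate noise for the whitebacked species,
# and a test that ends on the day the susceptible check dies (bounded to
# 6-10 days). Parameter values are calibrated only to reproduce these
# qualitative orderings; they are a stated world, not estimates.

#' One variety's simulation profile
#'
#' @param name variety name.
#' @param resistance_bph,resistance_wbph resistance in `[0, 1]` to the
#'   brown and whitebacked planthopper (1 = fully resistant; the latent
#'   severity rate is scaled by `1 - resistance`).
#' @param baseline healthy patch colour, length-3 RGB in 0-255.
#' @return One-row `data.frame`.
#' @export
variety_profile <- function(name, resistance_bph, resistance_wbph,
                            baseline = c(62, 108, 48)) {
  if (any(c(resistance_bph, resistance_wbph) < 0) ||
      any(c(resistance_bph, resistance_wbph) > 1))
    hb_stop("resistance values must lie in [0, 1]",
            class = "hb_domain_error")
  if (any(baseline < 0) || any(baseline > 255))
    hb_stop("baseline colour must lie in [0, 255]",
            class = "hb_domain_error")
  data.frame(name = as.character(name),
             resistance_bph = resistance_bph,
             resistance_wbph = resistance_wbph,
             baseR = baseline[1], baseG = baseline[2], baseB = baseline[3],
             stringsAsFactors = FALSE)
}

#' Default panel of variety profiles
#'
#' A susceptible check (`TN1`, zero resistance), a second susceptible
#' control (`IR22`), and `n - 2` test varieties whose resistance to each
#' species walks a deterministic grid (the two grids are offset so the
#' panel contains brown-resistant, whitebacked-resistant and
#' dual-resistant varieties, as real donor panels do). Baseline colour
#' varies slightly and deterministically between varieties.
#'
#' @param n number of varieties (default 39, including the check).
#' @param check name of the susceptible check (default `"TN1"`).
#' @return `data.frame` of profiles, one row per variety.
#' @export
default_profiles <- function(n = 39, check = "TN1") {
  if (n < 2) hb_stop("need at least 2 varieties", class = "hb_config_error")
  k <- n - 2L
  rb <- if (k > 0) seq(0.05, 0.95, length.out = k) else numeric()
  # rotate the whitebacked grid a third of the way round the panel
  rw <- if (k > 0) rb[((seq_len(k) + k %/% 3 - 1L) %% k) + 1L] else numeric()
  base <- c(62, 108, 48)
  out <- rbind(
    variety_profile(check, 0, 0, base),
    variety_profile("IR22", 0.05, 0.05, base))
  for (i in seq_len(k)) {
    wob <- c(((i * 7) %% 5) - 2, ((i * 3) %% 7) - 3, ((i * 5) %% 5) - 2)
    out <- rbind(out, variety_profile(sprintf("V%02d", i),
                                      rb[i], rw[i], base + wob))
  }
  out
}

#' Simulation configuration
#'
#' Defaults state the emulated screen: 3 replicates; three arms (one
#' shared non-infested control plus the two planthopper infestations);
#' 25 seedlings per patch after thinning, infested at 8 second-instar
#' nymphs per seedling (metadata only); the susceptible check sown on 7
#' patches per tray; tests ending when the check's severity completes,
#' bounded to 6-10 days.
#'
#' @param n_replicates replicates (trays per arm), default 3.
#' @param treatments arm labels; the control arm must be named
#'   `"control"` (or `control_*` for split controls that are pooled at
#'   scoring time).
#' @param shift named list of length-3 colour shifts applied at severity
#'   1: brown planthopper pushes red and blue strongly with a larger
#'   green loss; the whitebacked planthopper is milder on red and retains
#'   relatively more green and blue.
#' @param aging per-day additive drift: slow red and blue rise with plant
#'   age plus a mid-test green flush (Gaussian bump in proportional time)
#'   seen in non-infested controls.
#' @param logistic_rate,logistic_midpoint latent severity is
#'   `plogis(rate * ((1 - rho) * m * t - midpoint))` with `t` in days and
#'   `m` the replicate/treatment rate multiplier; control severity is 0.
#' @param wbph_rate_mult severity rate multiplier for the whitebacked arm
#'   (< 1: its kills run slower, so its tests run longer).
#' @param replicate_rate_sd lognormal sd of the per-replicate rate
#'   multiplier (drives the 6-10 day spread of test durations).
#' @param noise_sd per-channel Gaussian noise sd (intensity units).
#' @param wbph_noise_mult noise multiplier for the whitebacked arm
#'   (between-replicate variability is visibly larger for that species).
#' @param severity_complete severity treated as plant death when choosing
#'   the test duration.
#' @param duration_range allowed test durations in days.
#' @param n_check_patches check patches per tray (7, the corner/centre
#'   layout of a 45-square tray).
#' @param seedlings_per_patch,infestation_density patch density metadata.
#' @param healthy_weight_mg,weight_kappa,weight_noise_sd dry-weight model
#'   `weight = healthy * (1 - kappa * severity) + noise`.
#' @param dead_threshold severity above which seedlings start dying;
#'   dead counts are binomial in the excess severity.
#' @param dropout_prob probability a non-check variety fails to germinate
#'   in a replicate (emulates missing varieties; default 0).
#' @param nuisance optional named list of length-3 RGB offsets for
#'   capture conditions (e.g. flash off, black frame); `conditions` names
#'   the active ones. Offsets are added to every observation.
#' @param conditions character vector of active nuisance conditions.
#' @param check name of the susceptible check variety.
#' @param seed root seed; all stage randomness is derived from it through
#'   named substreams.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_replicates = 3,
                       treatments = c("control", "BPH", "WBPH"),
                       shift = list(BPH = c(70, -40, 55),
                                    WBPH = c(40, -25, 50)),
                       aging = list(red_per_day = 1.2, blue_per_day = 0.8,
                                    green_rise = 8, green_rise_mid = 0.5,
                                    green_rise_width = 0.18),
                       logistic_rate = 1.2, logistic_midpoint = 4,
                       wbph_rate_mult = 0.85, replicate_rate_sd = 0.08,
                       noise_sd = 3, wbph_noise_mult = 2,
                       severity_complete = 0.99, duration_range = c(6, 10),
                       n_check_patches = 7,
                       seedlings_per_patch = 25, infestation_density = 8,
                       healthy_weight_mg = 400, weight_kappa = 0.6,
                       weight_noise_sd = 20, dead_threshold = 0.7,
                       dropout_prob = 0, nuisance = NULL,
                       conditions = character(), check = "TN1", seed = 1) {
  cfg <- list(n_replicates = n_replicates, treatments = treatments,
              shift = shift, aging = aging,
              logistic_rate = logistic_rate,
              logistic_midpoint = logistic_midpoint,
              wbph_rate_mult = wbph_rate_mult,
              replicate_rate_sd = replicate_rate_sd,
              noise_sd = noise_sd, wbph_noise_mult = wbph_noise_mult,
              severity_complete = severity_complete,
              duration_range = duration_range,
              n_check_patches = n_check_patches,
              seedlings_per_patch = seedlings_per_patch,
              infestation_density = infestation_density,
              healthy_weight_mg = healthy_weight_mg,
              weight_kappa = weight_kappa,
              weight_noise_sd = weight_noise_sd,
              dead_threshold = dead_threshold,
              dropout_prob = dropout_prob, nuisance = nuisance,
              conditions = conditions, check = check, seed = seed)
  if (noise_sd < 0 || wbph_noise_mult < 0 || replicate_rate_sd < 0)
    hb_stop("noise parameters must be >= 0", class = "hb_config_error")
  if (!all(duration_range == as.integer(duration_range)) ||
      duration_range[1] < 1 || diff(duration_range) < 0)
    hb_stop("invalid duration range", class = "hb_config_error")
  ctrl <- grepl("^control", treatments)
  if (sum(ctrl) < 1L)
    hb_stop("treatments must include a control arm",
            class = "hb_config_error")
  class(cfg) <- "sim_config"
  cfg
}

# Latent severity in [0, 1]; exactly 0 on the control arm.
#' @keywords internal
#' @noRd
severity_curve <- function(t, rho, treatment, cfg, rate_mult = 1) {
  if (grepl("^control", treatment)) return(rep(0, length(t)))
  tm <- if (treatment == "WBPH") cfg$wbph_rate_mult else 1
  plogis(cfg$logistic_rate *
           ((1 - rho) * tm * rate_mult * t - cfg$logistic_midpoint))
}

# Additive aging drift shared by every arm (control "greening" bump on G)
#' @keywords internal
#' @noRd
aging_drift <- function(t, duration, aging) {
  ptime <- t / duration
  bump <- aging$green_rise *
    exp(-(ptime - aging$green_rise_mid)^2 / (2 * aging$green_rise_width^2))
  cbind(R = aging$red_per_day * t, G = bump, B = aging$blue_per_day * t)
}

#' Simulate one patch colour trajectory
#'
#' Channel means over the test days for one (variety, treatment) patch:
#' `baseline + aging drift + severity * treatment shift + noise`, clamped
#' to `[0, 255]`. Deterministic given `seed`; with `noise_sd = 0` the
#' series is exactly the deterministic skeleton.
#'
#' @param profile one-row profile from [variety_profile()].
#' @param treatment `"control"`, `"BPH"` or `"WBPH"`.
#' @param cfg a [sim_config()].
#' @param days sampling days (default daily to the upper duration bound).
#' @param duration test duration used for proportional-time features.
#' @param rate_mult replicate-level severity rate multiplier.
#' @param seed integer seed for the noise draw (omit for the current RNG
#'   state).
#' @return `data.frame` with `day`, `severity`, `meanR`, `meanG`, `meanB`.
#' @export
simulate_trajectory <- function(profile, treatment, cfg = sim_config(),
                                days = seq_len(cfg$duration_range[2]),
                                duration = max(days), rate_mult = 1,
                                seed = NULL) {
  rho <- switch(treatment, BPH = profile$resistance_bph,
                WBPH = profile$resistance_wbph, 0)
  sev <- severity_curve(days, rho, treatment, cfg, rate_mult)
  base <- matrix(rep(c(profile$baseR, profile$baseG, profile$baseB),
                     each = length(days)), ncol = 3)
  drift <- aging_drift(days, duration, cfg$aging)
  sh <- if (grepl("^control", treatment)) c(0, 0, 0)
        else cfg$shift[[treatment]]
  mu <- base + drift + outer(sev, sh)
  if (length(cfg$conditions))
    for (cond in cfg$conditions)
      mu <- sweep(mu, 2, cfg$nuisance[[cond]], "+")
  sd_t <- cfg$noise_sd * if (treatment == "WBPH") cfg$wbph_noise_mult else 1
  if (!is.null(seed)) set.seed(seed)
  eps <- if (sd_t > 0) matrix(rnorm(length(mu), 0, sd_t), ncol = 3)
         else 0
  ch <- clamp(mu + eps, 0, 255)
  data.frame(day = days, severity = sev, meanR = ch[, 1], meanG = ch[, 2],
             meanB = ch[, 3])
}

#' Map latent severity to a 0-9 damage score
#'
#' `round(9 s)` with halves rounded up: 0 is an undamaged patch, 9 patch
#' death.
#'
#' @param s severity in `[0, 1]`.
#' @return Integer vector in `0:9`.
#' @examples
#' severity_to_score(c(0, 0.5, 1))  # 0 5 9
#' @export
severity_to_score <- function(s) {
  if (anyNA(s) || any(s < 0) || any(s > 1))
    hb_stop("severity must lie in [0, 1]", class = "hb_domain_error")
  as.integer(round_half_up(9 * s))
}

#' Simulate a full screening experiment
#'
#' Lays varieties out on 45-square trays (one tray per arm per
#' replicate, the check on `n_check_patches` squares), simulates every
#' patch trajectory daily until the replicate's test ends — the first day
#' the check's severity completes under the slower of the two
#' infestations, bounded to the configured 6-10 day range — and attaches
#' final-day damage records (0-9 score from latent severity, binomial
#' dead counts above the death threshold, dry weights decreasing in
#' severity).
#'
#' @param cfg a [sim_config()].
#' @param profiles profile table from [default_profiles()] /
#'   [variety_profile()]; must contain the check.
#' @param seed root seed (defaults to `cfg$seed`).
#' @return A list of class `"screening_experiment"` with elements
#'   `config`, `profiles`, `observations` (long per-patch-per-day table)
#'   and `plate_map`.
#' @export
simulate_experiment <- function(cfg = sim_config(),
                                profiles = default_profiles(check = cfg$check),
                                seed = cfg$seed) {
  if (!cfg$check %in% profiles$name)
    hb_stop("susceptible check '", cfg$check,
            "' missing from profiles", class = "hb_config_error")
  set.seed(derive_seed(seed, "design"))
  rep_mult <- exp(rnorm(cfg$n_replicates, 0, cfg$replicate_rate_sd))
  drop_mat <- matrix(runif(nrow(profiles) * cfg$n_replicates) <
                       cfg$dropout_prob,
                     nrow = nrow(profiles))
  drop_mat[profiles$name == cfg$check, ] <- FALSE

  check_prof <- profiles[profiles$name == cfg$check, ]
  infested <- cfg$treatments[!grepl("^control", cfg$treatments)]
  durations <- integer(cfg$n_replicates)
  for (r in seq_len(cfg$n_replicates)) {
    cross <- vapply(infested, function(tr) {
      s <- severity_curve(1:cfg$duration_range[2] + 0, 0, tr, cfg,
                          rep_mult[r])
      # resistance of the check is 0 by definition of a check
      i <- which(s >= cfg$severity_complete)
      if (length(i)) i[1] else cfg$duration_range[2]
    }, numeric(1))
    durations[r] <- as.integer(clamp(max(cross), cfg$duration_range[1],
                                     cfg$duration_range[2]))
  }

  set.seed(derive_seed(seed, "trajectory"))
  obs <- vector("list", 0L)
  plate <- vector("list", 0L)
  for (r in seq_len(cfg$n_replicates)) {
    dur <- durations[r]
    days <- seq_len(dur)
    ptime <- standardize_time(days, dur)
    for (tr in cfg$treatments) {
      tray <- sprintf("R%d_%s", r, tr)
      pos <- 0L
      for (v in seq_len(nrow(profiles))) {
        if (drop_mat[v, r]) next
        prof <- profiles[v, ]
        npatch <- if (prof$name == cfg$check) cfg$n_check_patches else 1L
        for (pp in seq_len(npatch)) {
          pos <- pos + 1L
          pid <- sprintf("%s_P%02d", tray, pos)
          tr_df <- simulate_trajectory(prof, tr, cfg, days = days,
                                       duration = dur,
                                       rate_mult = rep_mult[r])
          obs[[length(obs) + 1L]] <- data.frame(
            patchId = pid, variety = prof$name, treatment = tr,
            replicate = r, tray = tray, day = days,
            proportionalTime = ptime, severity = tr_df$severity,
            meanR = tr_df$meanR, meanG = tr_df$meanG, meanB = tr_df$meanB,
            stringsAsFactors = FALSE)
          plate[[length(plate) + 1L]] <- data.frame(
            patchId = pid, variety = prof$name, tray = tray,
            row = (pos - 1L) %/% 9L, col = (pos - 1L) %% 9L,
            treatment = tr, replicate = r, stringsAsFactors = FALSE)
        }
      }
    }
  }
  observations <- do.call(rbind, obs)
  plate_map <- do.call(rbind, plate)

  # final-day damage records
  set.seed(derive_seed(seed, "damage"))
  observations$sesScore <- NA_integer_
  observations$deadCount <- NA_integer_
  observations$dryWeight <- NA_real_
  fin <- which(observations$proportionalTime == 1)
  sev <- observations$severity[fin]
  observations$sesScore[fin] <- severity_to_score(sev)
  pdead <- clamp((sev - cfg$dead_threshold) / (1 - cfg$dead_threshold), 0, 1)
  observations$deadCount[fin] <- rbinom(length(fin),
                                        cfg$seedlings_per_patch, pdead)
  w <- cfg$healthy_weight_mg * (1 - cfg$weight_kappa * sev) +
    rnorm(length(fin), 0, cfg$weight_noise_sd)
  observations$dryWeight[fin] <- pmax(w, 0)

  structure(list(config = cfg, profiles = profiles,
                 observations = observations, plate_map = plate_map,
                 durations = durations, seed = seed),
            class = "screening_experiment")
}

#' @export
print.screening_experiment <- function(x, ...) {
  cat("screening_experiment:",
      length(unique(x$observations$variety)), "varieties,",
      length(unique(x$observations$treatment)), "arms,",
      max(x$observations$replicate), "replicates,",
      nrow(x$observations), "observations\n")
  cat("  test durations (days):", paste(x$durations, collapse = ", "),
      "| check:", x$config$check, "| seed:", x$seed, "\n")
  invisible(x)
}

#' Render a synthetic patch photograph with ground-truth mask
#'
#' Draws seedling-like sinusoidal strokes over a blue or black frame
#' background; stroke pixels are jittered around the target colour, so
#' the exact foreground mask is known. Used to benchmark segmentation.
#'
#' @param target length-3 RGB (0-255) the foreground should average to.
#' @param width,height image size in pixels (>= 32).
#' @param coverage target foreground fraction, in (0, 1).
#' @param jitter per-channel sd of foreground pixel noise (0 = exact).
#' @param bg_jitter per-channel sd of background noise.
#' @param background `"blue"` or `"black"` frame colour.
#' @param seed integer seed (omit for current RNG state).
#' @return List with `image` (a [patch_image]) and `mask` (logical
#'   ground-truth matrix with coverage attribute).
#' @export
render_patch_image <- function(target, width = 128, height = 128,
                               coverage = 0.35, jitter = 6, bg_jitter = 4,
                               background = c("blue", "black"),
                               seed = NULL) {
  background <- match.arg(background)
  if (width < 32 || height < 32)
    hb_stop("image must be at least 32 x 32", class = "hb_config_error")
  if (coverage <= 0 || coverage >= 1)
    hb_stop("coverage must lie in (0, 1)", class = "hb_config_error")
  if (!is.null(seed)) set.seed(seed)
  bg <- if (background == "blue") c(30, 60, 150) else c(15, 15, 18)
  mask <- matrix(FALSE, height, width)
  y <- seq_len(height)
  guard <- 0L
  while (mean(mask) < coverage && guard < 10000L) {
    guard <- guard + 1L
    x0 <- runif(1, 1, width)
    amp <- runif(1, 1, 4)
    phase <- runif(1, 0, 2 * pi)
    wobble <- runif(1, 1, 3)
    wd <- sample(2:3, 1)
    xc <- round(x0 + amp * sin(2 * pi * wobble * y / height + phase))
    for (o in seq_len(wd) - 1L) {
      xi <- clamp(xc + o, 1, width)
      mask[cbind(y, xi)] <- TRUE
    }
  }
  nfg <- sum(mask)
  px <- array(0, c(height, width, 3))
  for (k in 1:3) {
    ch <- matrix(bg[k], height, width)
    if (bg_jitter > 0)
      ch <- ch + matrix(rnorm(height * width, 0, bg_jitter), height)
    fg <- rep(target[k], nfg)
    if (jitter > 0) fg <- fg + rnorm(nfg, 0, jitter)
    ch[mask] <- fg
    px[, , k] <- clamp(round(ch), 0, 255)
  }
  attr(mask, "coverage") <- mean(mask)
  list(image = patch_image(px), mask = mask)
}
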