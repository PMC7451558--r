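# End-to-end orchestration: configuration, provenance-stamped artifacts,
# and the simulate -> (render) -> extract -> indices -> score -> stats
# pipeline, plus a small command-line front end.

#' Build a run configuration
#'
#' @param out_dir directory for run artifacts.
#' @param root_seed integer root seed; all stage randomness derives from
#'   it and it is recorded in every artifact header.
#' @param index index used by the scoring stage.
#' @param check susceptible check variety name (required whenever scoring
#'   runs).
#' @param table1_literal evaluate literal variant index forms (see
#'   [compute_index()]).
#' @param n_perm,alpha,p_adjust statistics-stage parameters.
#' @param segmentation list: `threshold`, `space`, `coverage_floor`.
#' @param simulation a [sim_config()] for the simulate stage.
#' @param n_varieties panel size for the default profile set.
#' @param render logical: render per-patch images + masks (final day
#'   only) during `run`.
#' @param render_size rendered image edge length in pixels.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(out_dir = tempfile("hb_run_"), root_seed = 1,
                       index = "gli", check = "TN1",
                       table1_literal = FALSE, n_perm = 999, alpha = 0.05,
                       p_adjust = "holm",
                       segmentation = list(threshold = 60, space = "rgb",
                                           coverage_floor = 0.01),
                       simulation = sim_config(check = check,
                                               seed = root_seed),
                       n_varieties = 39, render = FALSE,
                       render_size = 64) {
  cfg <- list(out_dir = out_dir, root_seed = root_seed, index = index,
              check = check, table1_literal = table1_literal,
              n_perm = n_perm, alpha = alpha, p_adjust = p_adjust,
              segmentation = segmentation, simulation = simulation,
              n_varieties = n_varieties, render = render,
              render_size = render_size)
  if (is.null(check) || !nzchar(check))
    hb_stop("a check variety must be named", class = "hb_config_error")
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML or JSON
#'
#' Scalar fields override the defaults of [run_config()]; nested
#' `simulation` entries override [sim_config()] defaults.
#'
#' @param path file ending in `.yaml`/`.yml` or `.json`.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path,
                                                     simplifyVector = TRUE)
         else hb_stop("config must be YAML or JSON: ", path,
                      class = "hb_config_error")
  sim_args <- raw$simulation %||% list()
  raw$simulation <- NULL
  top <- raw[names(raw) %in% names(formals(run_config))]
  cfg <- do.call(run_config, top)
  if (length(sim_args)) {
    known <- sim_args[names(sim_args) %in% names(formals(sim_config))]
    cfg$simulation <- do.call(sim_config, known)
  }
  cfg$simulation$seed <- cfg$root_seed
  cfg
}

# provenance-stamped CSV: comment header lines then standard CSV body
#' @keywords internal
#' @noRd
write_artifact <- function(df, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# hopperburn %s | seed=%s | config=%s",
                     as.character(utils::packageVersion("hopperburn")),
                     cfg$root_seed, run_hash(cfg)), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

# hash of the scientific configuration only: output location must not
# change provenance, or reruns into fresh directories would never match
#' @keywords internal
#' @noRd
run_hash <- function(cfg) {
  x <- unclass(cfg)
  x$out_dir <- NULL
  config_hash(x)
}

#' Read a provenance-stamped artifact CSV
#' @param path CSV written by [run_pipeline()].
#' @return `data.frame`; the header line is available as attribute
#'   `"provenance"`.
#' @export
read_artifact <- function(path) {
  hdr <- readLines(path, n = 1L)
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  attr(df, "provenance") <- sub("^# ", "", hdr)
  df
}

#' @keywords internal
#' @noRd
log_info <- function(stage, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"),
                  stage, paste0(...)))
}

#' Run the full pipeline
#'
#' Executes simulate -> (render -> segment -> summarize) -> indices ->
#' score -> stats as configured and writes provenance-stamped artifacts
#' (`observations.csv`, `plate_map.csv`, `indices.csv`, `scores.csv`,
#' `condition_change.csv`, `stats.csv`, `run_info.json`) under
#' `cfg$out_dir`. When rendering is enabled, final-day patches are also
#' rendered to PNG with their ground-truth masks and re-extracted through
#' the segmentation path; the extracted means are written to
#' `extracted.csv` labelled with the extraction mode.
#'
#' Identical configuration and seed reproduce every artifact
#' byte-for-byte.
#'
#' @param cfg a [run_config()].
#' @return Invisibly, a list with the artifact paths and the in-memory
#'   tables.
#' @export
run_pipeline <- function(cfg = run_config()) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      hb_stop("stage '", name, "' failed: ", conditionMessage(e),
              class = "hb_stage_error"))
  }

  log_info("simulate", "panel of ", cfg$n_varieties, " varieties, seed ",
           cfg$root_seed)
  profiles <- default_profiles(cfg$n_varieties, check = cfg$check)
  exp <- stage("simulate",
               simulate_experiment(cfg$simulation, profiles,
                                   seed = cfg$root_seed))
  paths <- list(
    observations = file.path(cfg$out_dir, "observations.csv"),
    plate_map = file.path(cfg$out_dir, "plate_map.csv"))
  write_artifact(exp$observations, paths$observations, cfg)
  write_artifact(exp$plate_map, paths$plate_map, cfg)

  extracted <- NULL
  if (isTRUE(cfg$render)) {
    log_info("render", "rendering + re-extracting final-day patches")
    extracted <- stage("render", {
      fin <- exp$observations[exp$observations$proportionalTime == 1, ]
      img_dir <- file.path(cfg$out_dir, "images")
      dir.create(img_dir, showWarnings = FALSE)
      rows <- lapply(seq_len(nrow(fin)), function(i) {
        rp <- render_patch_image(
          c(fin$meanR[i], fin$meanG[i], fin$meanB[i]),
          width = cfg$render_size, height = cfg$render_size,
          seed = derive_seed(cfg$root_seed, "render") + i)
        write_patch_image(rp$image,
                          file.path(img_dir,
                                    paste0(fin$patchId[i], ".png")))
        mask <- segment_foreground(
          rp$image, threshold = cfg$segmentation$threshold,
          space = cfg$segmentation$space %||% "rgb",
          coverage_floor = cfg$segmentation$coverage_floor %||% 0.01)
        cm <- summarize_patch(rp$image, mask)
        data.frame(patchId = fin$patchId[i], meanR = cm$meanR,
                   meanG = cm$meanG, meanB = cm$meanB,
                   nPixels = cm$nPixels,
                   coverage = attr(mask, "coverage"),
                   mode = "means-first", stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    })
    paths$extracted <- file.path(cfg$out_dir, "extracted.csv")
    write_artifact(extracted, paths$extracted, cfg)
  }

  log_info("indices", "computing colour indices (",
           if (cfg$table1_literal) "literal" else "canonical", " forms)")
  idx <- stage("indices", {
    cm <- exp$observations[, c("meanR", "meanG", "meanB")]
    cbind(exp$observations[, c("patchId", "variety", "treatment",
                               "replicate", "day", "proportionalTime")],
          compute_indices(as.matrix(cm),
                          literal = cfg$table1_literal)[, -1])
  })
  paths$indices <- file.path(cfg$out_dir, "indices.csv")
  write_artifact(idx, paths$indices, cfg)

  log_info("score", "final-day ", cfg$index, " vs check ", cfg$check)
  ftab <- stage("score", final_day_table(exp, index = cfg$index,
                                         literal = cfg$table1_literal))
  scores <- ftab
  scores$band <- as.character(
    classify_by_score(as.integer(round_half_up(
      ifelse(is.na(scores$sesScore), 0, scores$sesScore)))))
  scores$band[is.na(ftab$sesScore)] <- NA_character_
  cct <- stage("score", condition_change_table(ftab, check = cfg$check))
  cct$weightLoss <- vapply(seq_len(nrow(cct)), function(i)
    suppressWarnings(weight_loss(ftab, cct$variety[i], cct$treatment[i])),
    numeric(1))
  paths$scores <- file.path(cfg$out_dir, "scores.csv")
  paths$condition_change <- file.path(cfg$out_dir, "condition_change.csv")
  write_artifact(scores, paths$scores, cfg)
  write_artifact(cct, paths$condition_change, cfg)

  log_info("stats", "permutation tests, n_perm = ", cfg$n_perm)
  stats_tbl <- stage("stats", {
    pts <- as.matrix(ftab[, c("meanR", "meanG", "meanB")])
    rows <- list()
    pv <- permanova(pts, ftab$treatment, n_perm = cfg$n_perm,
                    seed = derive_seed(cfg$root_seed, "perm"))
    rows[[1]] <- data.frame(test = "permanova", factor = "treatment",
                            statisticKind = "pseudoF",
                            statistic = pv$statistic, pRaw = pv$pValue,
                            pAdjusted = NA_real_,
                            nPermutations = pv$nPermutations,
                            stringsAsFactors = FALSE)
    pw <- pairwise_permanova(pts, ftab$treatment, n_perm = cfg$n_perm,
                             seed = cfg$root_seed,
                             p_adjust = cfg$p_adjust)
    rows[[2]] <- data.frame(
      test = "pairwise", factor = paste(pw$groupA, pw$groupB, sep = ":"),
      statisticKind = "tPairwise", statistic = pw$tPairwise,
      pRaw = pw$pRaw, pAdjusted = pw$pAdjusted,
      nPermutations = pw$nPermutations, stringsAsFactors = FALSE)
    # per-patch values so the check's sub-replicate patches all count
    fin <- idx[idx$proportionalTime == 1, ]
    fin$sesScore <-
      exp$observations$sesScore[exp$observations$proportionalTime == 1]
    for (tr in setdiff(unique(ftab$treatment), "control")) {
      sub <- fin[fin$treatment == tr, ]
      sub$value <- sub[[cfg$index]]
      vals <- split(sub$value, sub$variety)
      m2o <- many_to_one(vals[setdiff(names(vals), cfg$check)],
                         vals[[cfg$check]], n_perm = cfg$n_perm,
                         seed = cfg$root_seed, alpha = cfg$alpha,
                         p_adjust = cfg$p_adjust)
      rows[[length(rows) + 1L]] <- data.frame(
        test = "many_to_one", factor = paste0(tr, ":", m2o$variety),
        statisticKind = "meanDiff", statistic = m2o$meanDiff,
        pRaw = m2o$pRaw, pAdjusted = m2o$pAdjusted,
        nPermutations = m2o$nPermutations, stringsAsFactors = FALSE)
      sc <- sub[!is.na(sub$sesScore), ]
      if (length(unique(sc$variety)) >= 3) {
        agg_v <- tapply(sc$value, sc$variety, mean)
        agg_s <- tapply(sc$sesScore, sc$variety, mean)
        ct <- correlate(agg_v, agg_s, method = "spearman")
        rows[[length(rows) + 1L]] <- data.frame(
          test = "spearman_vs_score", factor = tr,
          statisticKind = "rho", statistic = ct$statistic,
          pRaw = ct$pValue, pAdjusted = NA_real_,
          nPermutations = NA_integer_, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
  paths$stats <- file.path(cfg$out_dir, "stats.csv")
  write_artifact(stats_tbl, paths$stats, cfg)

  info <- list(package = "hopperburn",
               version = as.character(utils::packageVersion("hopperburn")),
               seed = cfg$root_seed,
               configHash = run_hash(cfg),
               durations = exp$durations,
               artifacts = lapply(paths, basename))
  paths$run_info <- file.path(cfg$out_dir, "run_info.json")
  jsonlite::write_json(info, paths$run_info, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(paths = paths, experiment = exp, indices = idx,
                 final_day = ftab, condition_change = cct,
                 stats = stats_tbl, extracted = extracted))
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `run` (full pipeline), `extract` (segment +
#' summarize a directory of images into a summary CSV). Flags:
#' `--config <path>` (YAML/JSON), `--seed <int>`, `--out-dir <dir>`,
#' `--index <name>`, `--check <variety>`, `--table1-literal`,
#' `--n-perm <int>`, `--alpha <x>`, `--images <dir>` (extract).
#'
#' @param args character vector, default `commandArgs(TRUE)`.
#' @return Invisibly, the pipeline result (or extraction table).
#' @export
hb_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1L)
    hb_stop("usage: hopperburn <simulate|run|extract> [--flags]",
            class = "hb_config_error")
  cmd <- args[1]
  flags <- list()
  i <- 2L
  while (i <= length(args)) {
    a <- args[i]
    if (a == "--table1-literal") { flags$table1_literal <- TRUE; i <- i + 1L }
    else if (grepl("^--", a)) {
      if (i + 1L > length(args))
        hb_stop("missing value for ", a, class = "hb_config_error")
      flags[[gsub("-", "_", sub("^--", "", a))]] <- args[i + 1L]
      i <- i + 2L
    } else hb_stop("unexpected argument: ", a, class = "hb_config_error")
  }
  cfg <- if (!is.null(flags$config)) read_run_config(flags$config)
         else run_config()
  if (!is.null(flags$seed)) {
    cfg$root_seed <- as.integer(flags$seed)
    cfg$simulation$seed <- cfg$root_seed
  }
  if (!is.null(flags$out_dir)) cfg$out_dir <- flags$out_dir
  if (!is.null(flags$index)) cfg$index <- tolower(flags$index)
  if (!is.null(flags$check)) cfg$check <- flags$check
  if (isTRUE(flags$table1_literal)) cfg$table1_literal <- TRUE
  if (!is.null(flags$n_perm)) cfg$n_perm <- as.integer(flags$n_perm)
  if (!is.null(flags$alpha)) cfg$alpha <- as.numeric(flags$alpha)

  if (cmd == "simulate") {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    exp <- simulate_experiment(cfg$simulation,
                               default_profiles(cfg$n_varieties,
                                                check = cfg$check),
                               seed = cfg$root_seed)
    write_artifact(exp$observations,
                   file.path(cfg$out_dir, "observations.csv"), cfg)
    write_artifact(exp$plate_map,
                   file.path(cfg$out_dir, "plate_map.csv"), cfg)
    jsonlite::write_json(list(seed = cfg$root_seed,
                              configHash = run_hash(cfg)),
                         file.path(cfg$out_dir, "run_info.json"),
                         auto_unbox = TRUE)
    log_info("simulate", "wrote ", nrow(exp$observations),
             " observations to ", cfg$out_dir)
    return(invisible(exp))
  }
  if (cmd == "run") return(invisible(run_pipeline(cfg)))
  if (cmd == "extract") {
    if (is.null(flags$images))
      hb_stop("extract needs --images <dir>", class = "hb_config_error")
    loaded <- load_patch_images(flags$images)
    rows <- lapply(loaded$images, function(img) {
      mask <- segment_foreground(img,
                                 threshold = cfg$segmentation$threshold)
      cm <- summarize_patch(img, mask)
      data.frame(patchId = cm$patchId, nPixels = cm$nPixels,
                 meanR = cm$meanR, meanG = cm$meanG, meanB = cm$meanB,
                 coverage = attr(mask, "coverage"),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_artifact(out, file.path(cfg$out_dir, "summary.csv"), cfg)
    if (nrow(loaded$errors))
      write_artifact(loaded$errors,
                     file.path(cfg$out_dir, "errors.csv"), cfg)
    return(invisible(out))
  }
  hb_stop("unknown subcommand: ", cmd, class = "hb_config_error")
}
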