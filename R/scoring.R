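# Scoring layer: proportional-time standardization, final-day damage
# tables, delta-index condition change against the susceptible check,
# and resistance banding of 0-9 damage scores.

#' Standardize sampling days to proportional time
#'
#' Test durations vary between replicates (6-10 days), so sampling days
#' are expressed as a proportion of the replicate's total duration,
#' rounded to the nearest 0.1 (halves up). The final day always maps
#' to 1.0.
#'
#' @param days integer sampling days, `1 <= day <= duration`.
#' @param duration total test duration in days (6-10).
#' @return Numeric vector of proportional times on the 0.1 grid.
#' @examples
#' standardize_time(c(3, 5, 7), 7)  # 0.4 0.7 1.0
#' @export
standardize_time <- function(days, duration) {
  if (length(duration) != 1L || duration < 6 || duration > 10 ||
      duration != as.integer(duration))
    hb_stop("duration must be an integer in [6, 10]",
            class = "hb_domain_error")
  if (any(days < 1) || any(days > duration) ||
      any(days != as.integer(days)))
    hb_stop("days must be integers in [1, duration]",
            class = "hb_domain_error")
  round_half_up(days / duration, 1)
}

#' Final-day damage table
#'
#' Relative damage is evaluated only on data from the final day of each
#' replicate (proportional time 1.0), when the susceptible check has
#' died. Control arms (treatments named `control` or `control_*`) are
#' pooled into one `control` level; multiple patches of a variety in a
#' tray (the check's sub-replicates) are averaged.
#'
#' @param exp a `screening_experiment` (or its `observations`
#'   `data.frame`).
#' @param index index name passed to [compute_index()].
#' @param literal see [compute_index()].
#' @return `data.frame` of class `"final_day_table"`, one row per
#'   (variety, treatment, replicate): `value` (the index), `meanR/G/B`,
#'   `sesScore`, `deadCount`, `dryWeight`, `nPatches`. Varieties absent
#'   from a replicate are simply absent, with a warning.
#' @export
final_day_table <- function(exp, index = "gli", literal = FALSE) {
  obs <- if (inherits(exp, "screening_experiment")) exp$observations
         else exp
  fin <- obs[obs$proportionalTime == 1, , drop = FALSE]
  if (nrow(fin) == 0L)
    hb_stop("no final-day (proportional time 1.0) observations",
            class = "hb_domain_error")
  fin$treatment[grepl("^control", fin$treatment)] <- "control"
  fin$value <- compute_index(index, as.matrix(fin[, c("meanR", "meanG",
                                                      "meanB")]),
                             literal = literal)
  agg <- function(d) {
    data.frame(variety = d$variety[1], treatment = d$treatment[1],
               replicate = d$replicate[1], value = mean(d$value),
               meanR = mean(d$meanR), meanG = mean(d$meanG),
               meanB = mean(d$meanB),
               sesScore = if (all(is.na(d$sesScore))) NA_real_
                          else round_half_up(mean(d$sesScore, na.rm = TRUE)),
               deadCount = if (all(is.na(d$deadCount))) NA_real_
                           else mean(d$deadCount, na.rm = TRUE),
               dryWeight = if (all(is.na(d$dryWeight))) NA_real_
                           else mean(d$dryWeight, na.rm = TRUE),
               nPatches = nrow(d), stringsAsFactors = FALSE)
  }
  key <- interaction(fin$variety, fin$treatment, fin$replicate, drop = TRUE)
  out <- do.call(rbind, lapply(split(fin, key), agg))
  rownames(out) <- NULL
  # report varieties that dropped out of some replicate
  reps <- sort(unique(out$replicate))
  tab <- table(out$variety) / length(unique(out$treatment))
  missing <- names(tab)[tab < length(reps)]
  if (length(missing))
    warning("variety absent from some replicate(s): ",
            paste(missing, collapse = ", "), call. = FALSE)
  attr(out, "index") <- tolower(index)
  class(out) <- c("final_day_table", "data.frame")
  out
}

#' Condition change of one variety relative to the susceptible check
#'
#' For each replicate the index delta is infested minus control within
#' that replicate; deltas are then averaged (`deltaIndex`; this is
#' delta-GLI when the index is `gli`). `relativeChange` expresses the
#' variety's averaged delta as a fraction of the check's — the
#' proportional condition change — and `foldBetter` is its reciprocal
#' ("n times better at holding condition than the check"). Both are
#' reported because the ratio reads naturally in either direction.
#'
#' @param tbl a [final_day_table()].
#' @param variety variety to score.
#' @param treatment infested arm to score against the pooled control.
#' @param check susceptible check variety (default `"TN1"`).
#' @return One-row `data.frame`: `variety`, `treatment`, `index`,
#'   `deltaIndex`, `deltaCheck`, `relativeChange`, `foldBetter`,
#'   `nReplicates`. If the check's delta is exactly 0 the ratios are `NA`
#'   with a warning; a zero variety delta gives `relativeChange` 0 and
#'   `foldBetter` `NA`.
#' @export
condition_change <- function(tbl, variety, treatment, check = "TN1") {
  dv <- replicate_deltas(tbl, variety, treatment)
  dc <- replicate_deltas(tbl, check, treatment)
  if (!length(dv) || !length(dc))
    hb_stop("no paired infested/control replicates for ", variety,
            " or ", check, class = "hb_domain_error")
  delta <- mean(dv)
  delta_check <- mean(dc)
  if (delta_check == 0) {
    warning("check delta is exactly 0; relative change undefined",
            call. = FALSE)
    rel <- NA_real_; fold <- NA_real_
  } else if (delta == 0) {
    rel <- 0; fold <- NA_real_
  } else {
    rel <- delta / delta_check
    fold <- delta_check / delta
  }
  data.frame(variety = variety, treatment = treatment,
             index = attr(tbl, "index") %||% NA_character_,
             deltaIndex = delta, deltaCheck = delta_check,
             relativeChange = rel, foldBetter = fold,
             nReplicates = length(dv), stringsAsFactors = FALSE)
}

#' @keywords internal
#' @noRd
replicate_deltas <- function(tbl, variety, treatment) {
  inf <- tbl[tbl$variety == variety & tbl$treatment == treatment, ]
  ctl <- tbl[tbl$variety == variety & tbl$treatment == "control", ]
  reps <- intersect(inf$replicate, ctl$replicate)
  vapply(reps, function(r)
    inf$value[inf$replicate == r] - ctl$value[ctl$replicate == r],
    numeric(1))
}

#' Condition change for every non-check variety
#'
#' @inheritParams condition_change
#' @param treatments infested arms to score (default every non-control
#'   arm in the table).
#' @return `data.frame`, one row per (variety, treatment).
#' @export
condition_change_table <- function(tbl, check = "TN1",
                                   treatments = NULL) {
  treatments <- treatments %||%
    setdiff(unique(tbl$treatment), "control")
  varieties <- setdiff(unique(tbl$variety), check)
  out <- list()
  for (tr in treatments)
    for (v in varieties)
      out[[length(out) + 1L]] <- condition_change(tbl, v, tr, check)
  do.call(rbind, out)
}

#' Resistance band of a 0-9 damage score
#'
#' Standard Evaluation System cut-offs: 0-3 resistant, 4-6 moderately
#' resistant, 7-9 susceptible.
#'
#' @param sesScore integer vector in `0:9`.
#' @return Factor with levels `resistant`, `moderately resistant`,
#'   `susceptible`.
#' @examples
#' classify_by_score(c(2, 5, 8))
#' @export
classify_by_score <- function(sesScore) {
  if (anyNA(sesScore) || any(sesScore < 0) || any(sesScore > 9) ||
      any(sesScore != as.integer(sesScore)))
    hb_stop("damage scores must be integers in [0, 9]",
            class = "hb_domain_error")
  cut(sesScore, breaks = c(-1, 3, 6, 9),
      labels = c("resistant", "moderately resistant", "susceptible"))
}

#' Estimated seedling weight loss for one variety
#'
#' Mean control dry weight minus infested dry weight within each
#' replicate, averaged over replicates (mg).
#'
#' @inheritParams condition_change
#' @return Weight loss in mg; `NA` with a warning when an arm is missing.
#' @export
weight_loss <- function(tbl, variety, treatment) {
  inf <- tbl[tbl$variety == variety & tbl$treatment == treatment, ]
  ctl <- tbl[tbl$variety == variety & tbl$treatment == "control", ]
  reps <- intersect(inf$replicate, ctl$replicate)
  if (!length(reps) || all(is.na(inf$dryWeight)) ||
      all(is.na(ctl$dryWeight))) {
    warning("missing arm or dry weights for ", variety, call. = FALSE)
    return(NA_real_)
  }
  mean(vapply(reps, function(r)
    ctl$dryWeight[ctl$replicate == r] - inf$dryWeight[inf$replicate == r],
    numeric(1)))
}
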