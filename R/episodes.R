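# Episode-aligned NAT trajectories: alignment to the episode-defining BAL,
# window summaries, and de-escalation / cessation detection.

.etiologies <- c("bacterial", "viral", "bacterial_viral",
                 "microbiology_negative", "non_pneumonia_control")

#' Read an adjudicated episode table
#'
#' CSV with header
#' `episode_id,patient_id,bal_day,etiology,resistant,setting,cured_day7,extra_pulmonary_infection`.
#' `etiology` must be one of `bacterial`, `viral`, `bacterial_viral`,
#' `microbiology_negative`, `non_pneumonia_control`; `resistant` is logical and
#' may only be non-missing for bacteria-containing etiologies.
#'
#' @param path CSV file path.
#' @return data.frame, one row per episode, `bal_day` as `Date`.
#' @export
read_episodes <- function(path) {
  if (!file.exists(path)) stop("episode file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  required <- c("episode_id", "patient_id", "bal_day", "etiology", "resistant",
                "setting", "cured_day7", "extra_pulmonary_infection")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("episode table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df$episode_id <- as.character(df$episode_id)
  df$patient_id <- as.character(df$patient_id)
  df$bal_day <- as.Date(df$bal_day)
  bad <- setdiff(unique(df$etiology), .etiologies)
  if (length(bad) > 0) stop("unknown etiology value(s): ",
                            paste(bad, collapse = ", "))
  df$resistant <- as.logical(df$resistant)
  df$cured_day7 <- as.logical(df$cured_day7)
  df$extra_pulmonary_infection <- as.logical(df$extra_pulmonary_infection)
  offenders <- !is.na(df$resistant) &
    !(df$etiology %in% c("bacterial", "bacterial_viral"))
  if (any(offenders)) {
    stop("resistant flag set for non-bacterial episode(s): ",
         paste(df$episode_id[offenders], collapse = ", "))
  }
  if (anyDuplicated(df$episode_id)) stop("duplicate episode_id values")
  for (col in intersect(c("end_of_stay", "admission_day"), names(df))) {
    df[[col]] <- as.Date(df[[col]])
  }
  df
}

#' Align a patient's daily NAT scores to an episode-defining BAL
#'
#' Re-indexes calendar-day NAT scores to days relative to the BAL (day 0 = BAL
#' collection day) over the analysis window (default day −2 to day +7). Days
#' inside the window but absent from `daily_scores` are in-hospital days with
#' no antibiotic administration and score `-2`. Days before admission and days
#' after death or discharge are excluded, so the trajectory covers in-hospital,
#' alive days only.
#'
#' @param daily_scores data.frame with columns `date` and `nat` for one
#'   patient (e.g. a per-patient slice of [score_regimens()] output).
#' @param episode One-row data.frame or list with at least `episode_id` and
#'   `bal_day`.
#' @param end_of_stay Calendar date of death or discharge, or `NULL` if the
#'   stay extends beyond the window.
#' @param admission_day Calendar date of admission, or `NULL` if admission
#'   precedes the window.
#' @param window Integer vector `c(first, last)` of relative days, default
#'   `c(-2, 7)`.
#' @return A `nat_trajectory`: list with `episode_id`, `scores` (integer
#'   vector named by relative day, contiguous) and `end_day` (relative day of
#'   death/discharge if it falls at or before the window end, else `NA`).
#' @export
align_trajectory <- function(daily_scores, episode, end_of_stay = NULL,
                             admission_day = NULL, window = c(-2L, 7L)) {
  stopifnot(length(window) == 2, window[1] <= 0, window[2] >= 0)
  bal_day <- as.Date(episode$bal_day)
  end_of_stay <- if (is.null(end_of_stay) || is.na(end_of_stay)) NULL else
    as.Date(end_of_stay)
  admission_day <- if (is.null(admission_day) || is.na(admission_day)) NULL
    else as.Date(admission_day)
  if (!is.null(end_of_stay) && end_of_stay < bal_day) {
    stop("episode ", episode$episode_id,
         ": end_of_stay precedes the BAL day (day 0 must be in-hospital)")
  }
  if (!is.null(admission_day) && admission_day > bal_day) {
    stop("episode ", episode$episode_id,
         ": admission after the BAL day (day 0 must be in-hospital)")
  }
  rel <- seq.int(window[1], window[2])
  cal <- bal_day + rel
  keep <- rep(TRUE, length(rel))
  if (!is.null(admission_day)) keep <- keep & cal >= admission_day
  if (!is.null(end_of_stay)) keep <- keep & cal <= end_of_stay
  rel <- rel[keep]
  cal <- cal[keep]
  idx <- match(cal, as.Date(daily_scores$date))
  scores <- ifelse(is.na(idx), -2L, as.integer(daily_scores$nat[idx]))
  names(scores) <- rel
  end_day <- NA_integer_
  if (!is.null(end_of_stay)) {
    d <- as.integer(end_of_stay - bal_day)
    if (d <= window[2]) end_day <- d
  }
  structure(list(episode_id = as.character(episode$episode_id),
                 scores = scores, end_day = end_day),
            class = "nat_trajectory")
}

#' @export
print.nat_trajectory <- function(x, ...) {
  cat("<nat_trajectory>", x$episode_id, "\n")
  print(x$scores)
  if (!is.na(x$end_day)) cat("  end of stay at relative day", x$end_day, "\n")
  invisible(x)
}

traj_score <- function(traj, day) {
  s <- traj$scores[as.character(day)]
  if (is.na(names(s)) || is.na(s)) NA_integer_ else as.integer(s)
}

traj_days <- function(traj) as.integer(names(traj$scores))

#' Average NAT score over post-BAL days 1-7
#'
#' Arithmetic mean of the NAT scores on relative days 1 through 7, or through
#' the day of death or discharge, whichever comes first. Day 0 and pre-BAL
#' days are never included.
#'
#' @param traj A `nat_trajectory`.
#' @return Numeric mean, or `NA` (with a warning) when no post-BAL day is
#'   present.
#' @export
average_nat <- function(traj) {
  days <- traj_days(traj)
  use <- days >= 1 & days <= 7
  if (!any(use)) {
    warning("no post-BAL days in trajectory ", traj$episode_id)
    return(NA_real_)
  }
  mean(traj$scores[use])
}

#' Per-day median and IQR of NAT scores across episodes
#'
#' For each group and each relative day, the median and first/third quartiles
#' of the NAT scores of the episodes contributing that day. Quartiles use the
#' linear-interpolation convention (`stats::quantile` type 7).
#'
#' @param trajs List of `nat_trajectory` objects.
#' @param groups Character vector of group labels, one per trajectory
#'   (e.g. etiology); `NULL` pools everything into one group.
#' @return data.frame with columns `group`, `rel_day`, `n`, `q1`, `median`,
#'   `q3`.
#' @export
summarize_by_day <- function(trajs, groups = NULL) {
  if (length(trajs) == 0) stop("no trajectories to summarize")
  if (is.null(groups)) groups <- rep("all", length(trajs))
  stopifnot(length(groups) == length(trajs))
  long <- do.call(rbind, lapply(seq_along(trajs), function(i) {
    data.frame(group = groups[i], rel_day = traj_days(trajs[[i]]),
               nat = as.integer(trajs[[i]]$scores))
  }))
  out <- do.call(rbind, lapply(split(long, list(long$group, long$rel_day),
                                     drop = TRUE), function(d) {
    q <- stats::quantile(d$nat, probs = c(0.25, 0.5, 0.75), type = 7,
                         names = FALSE)
    data.frame(group = d$group[1], rel_day = d$rel_day[1], n = nrow(d),
               q1 = q[1], median = q[2], q3 = q[3])
  }))
  out <- out[order(out$group, out$rel_day), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Did the episode de-escalate by post-BAL day k?
#'
#' De-escalation by day `k` means the running minimum of the post-BAL NAT
#' score over days 1..`k` falls strictly below the day-0 (BAL-day) score.
#'
#' @param traj A `nat_trajectory` whose window covers days 0..`k` (episodes
#'   must last through day `k`; filter eligibility before calling).
#' @param k Relative day, `>= 1`.
#' @return Logical.
#' @export
deescalated_by <- function(traj, k) {
  stopifnot(k >= 1)
  days <- traj_days(traj)
  need <- 0:k
  if (!all(need %in% days)) {
    stop("trajectory ", traj$episode_id, " does not cover days 0..", k,
         " (ineligible for day-", k, " de-escalation analysis)")
  }
  day0 <- traj$scores[as.character(0)]
  min(traj$scores[as.character(1:k)]) < day0
}

#' Complete antibiotic cessation sustained through post-BAL day k
#'
#' `TRUE` when the NAT score reaches `-2` (no antibiotics) on some day in
#' 1..`k` and remains `-2` through day `k` — equivalently, when the day-`k`
#' score is `-2`. A transient stop followed by resumption before day `k` does
#' not count.
#'
#' @inheritParams deescalated_by
#' @return Logical.
#' @export
cessation_by <- function(traj, k) {
  stopifnot(k >= 1)
  days <- traj_days(traj)
  if (!all(1:k %in% days)) {
    stop("trajectory ", traj$episode_id, " does not cover days 1..", k)
  }
  traj$scores[as.character(k)] == -2L
}

#' Cumulative de-escalation timeline
#'
#' For each requested day `k`, the count and percentage of trajectories with
#' de-escalation by day `k`. All trajectories must satisfy the duration
#' eligibility filter (window covering day 0 through `max(days)`).
#'
#' @param trajs List of eligible `nat_trajectory` objects.
#' @param days Integer vector of relative days `k` (default `c(1, 4)`).
#' @return data.frame with columns `day`, `n_deescalated`, `n_total`,
#'   `percent` (one decimal). Counts are non-decreasing in `day`.
#' @export
deescalation_timeline <- function(trajs, days = c(1L, 4L)) {
  if (length(trajs) == 0) stop("no trajectories supplied")
  days <- sort(unique(as.integer(days)))
  out <- do.call(rbind, lapply(days, function(k) {
    hits <- vapply(trajs, deescalated_by, logical(1), k = k)
    data.frame(day = k, n_deescalated = sum(hits), n_total = length(trajs),
               percent = round(100 * mean(hits), 1))
  }))
  rownames(out) <- NULL
  out
}
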