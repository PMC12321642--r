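# End-to-end report assembly: scores the regimen table, aligns trajectories
# to episode-defining BALs, and emits the trajectory summaries, concordance
# summary, de-escalation timelines and outcomes table together with a
# machine-readable manifest.

#' Align NAT trajectories for every episode in a cohort
#'
#' @param daily data.frame of per-patient-day NAT scores
#'   ([score_regimens()] output).
#' @param episodes Episode table; optional `admission_day` and `end_of_stay`
#'   columns bound the in-hospital window.
#' @param window Relative-day window, default `c(-2, 7)`.
#' @return Named list of `nat_trajectory` objects (by `episode_id`).
#' @export
cohort_trajectories <- function(daily, episodes, window = c(-2L, 7L)) {
  by_patient <- split(daily, daily$patient_id)
  trajs <- lapply(seq_len(nrow(episodes)), function(i) {
    epi <- episodes[i, ]
    scores <- by_patient[[epi$patient_id]]
    if (is.null(scores)) {
      scores <- data.frame(date = as.Date(character(0)), nat = integer(0))
    }
    align_trajectory(scores, epi,
                     end_of_stay = epi$end_of_stay %||% NULL,
                     admission_day = epi$admission_day %||% NULL,
                     window = window)
  })
  names(trajs) <- episodes$episode_id
  trajs
}

eligible_through <- function(trajs, k) {
  Filter(function(t) all(0:k %in% traj_days(t)), trajs)
}

#' Run the full stewardship analysis pipeline
#'
#' Composes every stage: NAT scoring of the regimen table, trajectory
#' alignment, per-etiology (and cure-status / extra-pulmonary-infection
#' stratified) day-by-day NAT summaries, average post-BAL NAT per episode,
#' PCR/culture concordance summary and paired-testing rate, de-escalation
#' timelines for susceptible bacterial and microbiology-negative episodes
#' lasting at least four days post BAL, and the clinical outcomes table over
#' patients with exactly one episode. Stratified summaries are re-applications
#' of the same summarizers on episode subsets.
#'
#' @param regimens Regimen table (data.frame) or CSV path.
#' @param episodes Episode table (data.frame) or CSV path.
#' @param bals List of `bal_result` or JSON path.
#' @param outcomes Outcome table (data.frame) or CSV path.
#' @param formulary,panel Scoring formulary and PCR panel definition.
#' @param reference_group Reference etiology for odds ratios.
#' @param window Analysis window in relative days.
#' @param out_dir Optional output directory for the CSV report bundle and the
#'   JSON manifest.
#' @return List with elements `daily_scores`, `trajectories`,
#'   `trajectory_summary`, `stratified_summaries`, `average_nat`,
#'   `concordance`, `paired_testing`, `timelines`, `outcomes_table`,
#'   `manifest`.
#' @export
run_pipeline <- function(regimens, episodes, bals, outcomes,
                         formulary = default_formulary(),
                         panel = default_panel(),
                         reference_group = "microbiology_negative",
                         window = c(-2L, 7L), out_dir = NULL) {
  if (is.character(regimens)) regimens <- read_regimens(regimens)
  if (is.character(episodes)) episodes <- read_episodes(episodes)
  if (is.character(bals)) bals <- read_bal_results(bals)
  if (is.character(outcomes)) outcomes <- read_outcomes(outcomes)
  if (nrow(episodes) == 0) stop("episode table is empty")
  stopifnot(length(window) == 2, window[1] < window[2])

  daily <- score_regimens(regimens, formulary)
  trajs <- cohort_trajectories(daily, episodes, window)

  group <- dynamic_group(episodes$etiology, episodes$resistant)
  traj_summary <- summarize_by_day(trajs, group)

  strata <- list()
  adjudicated <- !is.na(episodes$cured_day7)
  if (any(adjudicated)) {
    strata$by_cure_status <- summarize_by_day(
      trajs[adjudicated],
      paste(group[adjudicated],
            ifelse(episodes$cured_day7[adjudicated], "cured", "uncured"),
            sep = "."))
  }
  strata$by_extra_pulmonary <- summarize_by_day(
    trajs, paste(group,
                 ifelse(episodes$extra_pulmonary_infection,
                        "extra_pulmonary", "no_extra_pulmonary"), sep = "."))

  avg <- data.frame(
    episode_id = episodes$episode_id, group = group,
    average_nat = vapply(trajs, function(t) {
      if (any(traj_days(t) >= 1)) average_nat(t) else NA_real_
    }, numeric(1)))

  paired <- Filter(function(b) isTRUE(b$pcr_performed), bals)
  concordance <- NULL
  if (length(paired) > 0) {
    calls <- lapply(paired, classify_concordance, panel = panel)
    concordance <- summarize_concordance(calls)
  }
  paired_rate <- paired_testing_rate(bals)

  timelines <- list()
  for (g in c("bacterial_susceptible", "microbiology_negative")) {
    elig <- eligible_through(trajs[group == g], 4L)
    if (length(elig) > 0) {
      timelines[[g]] <- deescalation_timeline(elig, days = 1:4)
    }
  }

  one_epi <- names(which(table(episodes$patient_id) == 1))
  epi_one <- episodes[episodes$patient_id %in% one_epi, , drop = FALSE]
  out_one <- outcomes[outcomes$patient_id %in% epi_one$patient_id, ,
                      drop = FALSE]
  out_table <- outcomes_table(out_one, epi_one,
                              reference_group = reference_group)

  manifest <- list(
    package = "balsteward",
    version = as.character(utils::packageVersion("balsteward")),
    formulary_version = formulary$version,
    window = window,
    reference_group = reference_group,
    n_patients = length(unique(episodes$patient_id)),
    n_episodes = nrow(episodes),
    n_bals = length(bals),
    n_outcome_patients = nrow(out_one))

  report <- list(daily_scores = daily, trajectories = trajs,
                 trajectory_summary = traj_summary,
                 stratified_summaries = strata, average_nat = avg,
                 concordance = concordance, paired_testing = paired_rate,
                 timelines = timelines, outcomes_table = out_table,
                 manifest = manifest)
  if (!is.null(out_dir)) write_report(report, out_dir)
  invisible(report)
}

#' Write the pipeline report bundle as CSV + JSON
#'
#' @param report As returned by [run_pipeline()].
#' @param dir Output directory.
#' @return `dir`, invisibly. On failure, partial outputs are removed.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character(0)
  emit <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    written <<- c(written, path)
  }
  tryCatch({
    emit(report$trajectory_summary, "trajectory_summary.csv")
    for (nm in names(report$stratified_summaries)) {
      emit(report$stratified_summaries[[nm]], paste0("summary_", nm, ".csv"))
    }
    emit(report$average_nat, "average_nat.csv")
    if (!is.null(report$concordance)) {
      emit(report$concordance, "concordance_summary.csv")
    }
    for (nm in names(report$timelines)) {
      emit(report$timelines[[nm]], paste0("timeline_", nm, ".csv"))
    }
    out_tab <- report$outcomes_table
    emit(out_tab, "outcomes_table.csv")
    long <- do.call(rbind, lapply(report$trajectories, function(t) {
      data.frame(episode_id = t$episode_id, rel_day = traj_days(t),
                 nat = as.integer(t$scores))
    }))
    emit(long, "trajectories_long.csv")
    manifest <- c(report$manifest,
                  list(paired_testing = report$paired_testing,
                       outputs = basename(written)))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }, error = function(e) {
    unlink(written)
    stop("report assembly failed, partial outputs removed: ",
         conditionMessage(e))
  })
  invisible(dir)
}
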