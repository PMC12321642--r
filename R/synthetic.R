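# Seeded synthetic ICU cohort generator. The defaults encode the study
# conditions the pipeline is designed for: five etiology categories at the
# cohort's reported proportions, empiric-breadth trajectories de-escalating
# after the episode-defining BAL at etiology-specific rates, paired
# PCR/culture results with a configurable concordance mix, and outcome rates
# near the reported table. Exact-count fixtures for the headline proportions
# are built (not sampled) by make_fixture().

.dynamic_groups <- c("bacterial_resistant", "bacterial_susceptible", "viral",
                     "bacterial_viral", "microbiology_negative",
                     "non_pneumonia_control")

#' Configuration for the synthetic cohort generator
#'
#' All arguments have defaults reflecting the cohort the pipeline targets:
#' etiology mix 288/176/198/151/114 over bacterial / viral / mixed /
#' microbiology-negative / control, resistant fraction 104/486 among
#' bacteria-containing episodes, day-0 NAT centred at empiric HAP/VAP breadth
#' (median 2) for bacterial, microbiology-negative and control episodes and at
#' targeted coverage (median 1) for viral and mixed episodes, cessation
#' probability 0.44 for viral episodes by post-BAL day 5, unfavorable-outcome
#' rates from the per-group outcome table, and a paired-testing rate of 0.967.
#' De-escalation hazards are the per-day probability that a non-ceasing
#' episode drops one NAT level; the defaults imply day-1 / day-4 de-escalation
#' proportions near 34%/56% (susceptible bacterial) and 31%/57%
#' (microbiology-negative).
#'
#' @param n_patients Number of patients to simulate.
#' @param seed Integer root seed; every random component derives its stream
#'   from it.
#' @param episode_etiology_weights Named probabilities over the five
#'   etiologies (sum to 1).
#' @param resistant_fraction Probability that a bacteria-containing episode is
#'   resistant.
#' @param day0_score_distribution Named list (per dynamic group) of named
#'   probability vectors over day-0 NAT scores.
#' @param deescalation_hazard Named per-day drop probabilities per dynamic
#'   group (groups: `bacterial_resistant`, `bacterial_susceptible`, `viral`,
#'   `bacterial_viral`, `microbiology_negative`, `non_pneumonia_control`).
#' @param cessation_probability Named per-group probability that antibiotics
#'   stop completely (NAT `-2`) by post-BAL day 5 and stay stopped.
#' @param unfavorable_rate Named per-group probability of the composite
#'   unfavorable outcome.
#' @param duration_distributions List with `icu = c(meanlog, sdlog)` and
#'   `intubation_fraction = c(min, max)` (intubation days as a uniform
#'   fraction of ICU days).
#' @param concordance_weights Probabilities over the four concordance
#'   categories `c(agreement, culture_only, pcr_only, discordant_both)`.
#' @param off_panel_fraction Fraction of culture-only discrepancies caused by
#'   off-panel organisms.
#' @param paired_testing_rate Probability a BAL has the multiplex panel run.
#' @param truncation_fraction Fraction of episode windows ended by death or
#'   discharge before post-BAL day 7 (end day drawn geometrically).
#' @param second_episode_prob Probability a patient has a second adjudicated
#'   episode (such patients are excluded from outcome analysis).
#' @param c_difficile_rate Patient-level C. difficile probability.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(
    n_patients = 500,
    seed = 1L,
    episode_etiology_weights = c(bacterial = 288, viral = 176,
                                 bacterial_viral = 198,
                                 microbiology_negative = 151,
                                 non_pneumonia_control = 114) / 927,
    resistant_fraction = 104 / 486,
    day0_score_distribution = list(
      bacterial_resistant   = c("1" = 0.15, "2" = 0.60, "3" = 0.25),
      bacterial_susceptible = c("1" = 0.15, "2" = 0.60, "3" = 0.25),
      viral                 = c("0" = 0.20, "1" = 0.55, "2" = 0.25),
      bacterial_viral       = c("0" = 0.20, "1" = 0.55, "2" = 0.25),
      microbiology_negative = c("1" = 0.20, "2" = 0.60, "3" = 0.20),
      non_pneumonia_control = c("1" = 0.35, "2" = 0.55, "3" = 0.10)),
    deescalation_hazard = c(bacterial_resistant = 0.02,
                            bacterial_susceptible = 0.129,
                            viral = 0.35, bacterial_viral = 0.30,
                            microbiology_negative = 0.149,
                            non_pneumonia_control = 0.30),
    cessation_probability = c(bacterial_resistant = 0.00,
                              bacterial_susceptible = 0.239,
                              viral = 0.44, bacterial_viral = 0.30,
                              microbiology_negative = 0.188,
                              non_pneumonia_control = 0.30),
    unfavorable_rate = c(bacterial_resistant = 0.463,
                         bacterial_susceptible = 0.407,
                         viral = 0.441, bacterial_viral = 0.461,
                         microbiology_negative = 0.421,
                         non_pneumonia_control = 0.457),
    duration_distributions = list(icu = c(meanlog = log(12), sdlog = 0.65),
                                  intubation_fraction = c(0.5, 0.9)),
    concordance_weights = c(agreement = 390, culture_only = 158,
                            pcr_only = 61, discordant_both = 26) / 635,
    off_panel_fraction = 139 / 158,
    paired_testing_rate = 635 / 657,
    truncation_fraction = 0.15,
    second_episode_prob = 152 / 686,
    c_difficile_rate = 0.02) {
  cfg <- list(n_patients = as.integer(n_patients), seed = as.integer(seed),
              episode_etiology_weights = episode_etiology_weights,
              resistant_fraction = resistant_fraction,
              day0_score_distribution = day0_score_distribution,
              deescalation_hazard = deescalation_hazard,
              cessation_probability = cessation_probability,
              unfavorable_rate = unfavorable_rate,
              duration_distributions = duration_distributions,
              concordance_weights = concordance_weights,
              off_panel_fraction = off_panel_fraction,
              paired_testing_rate = paired_testing_rate,
              truncation_fraction = truncation_fraction,
              second_episode_prob = second_episode_prob,
              c_difficile_rate = c_difficile_rate)
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  problems <- character(0)
  chk_prob_vec <- function(v, what) {
    if (abs(sum(v) - 1) > 1e-9) {
      problems <<- c(problems, paste0(what, " must sum to 1"))
    }
    if (any(v < 0)) problems <<- c(problems, paste0(what, " has negatives"))
  }
  if (cfg$n_patients < 1) problems <- c(problems, "n_patients must be >= 1")
  if (!setequal(names(cfg$episode_etiology_weights), .etiologies)) {
    problems <- c(problems, "etiology weights must cover the five etiologies")
  }
  chk_prob_vec(cfg$episode_etiology_weights, "episode_etiology_weights")
  for (nm in c("deescalation_hazard", "cessation_probability",
               "unfavorable_rate")) {
    v <- cfg[[nm]]
    if (!setequal(names(v), .dynamic_groups)) {
      problems <- c(problems, paste0(nm, " must be keyed by the six groups"))
    } else if (any(v < 0 | v > 1)) {
      problems <- c(problems, paste0(nm, " values must lie in [0, 1]"))
    }
  }
  for (g in names(cfg$day0_score_distribution)) {
    chk_prob_vec(cfg$day0_score_distribution[[g]],
                 paste0("day0_score_distribution$", g))
  }
  chk_prob_vec(cfg$concordance_weights, "concordance_weights")
  for (nm in c("resistant_fraction", "off_panel_fraction",
               "paired_testing_rate", "truncation_fraction",
               "second_episode_prob", "c_difficile_rate")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) {
      problems <- c(problems, paste0(nm, " must lie in [0, 1]"))
    }
  }
  if (length(problems) > 0) {
    stop("invalid cohort config:\n  - ", paste(problems, collapse = "\n  - "))
  }
  cfg
}

dynamic_group <- function(etiology, resistant) {
  ifelse(etiology == "bacterial",
         ifelse(!is.na(resistant) & resistant,
                "bacterial_resistant", "bacterial_susceptible"),
         etiology)
}

# representative regimen realizing each NAT score under the default formulary
.score_regimens <- list(
  `-2` = character(0),
  `-1` = "ampicillin",
  `0`  = c("ceftriaxone", "azithromycin"),
  `1`  = "cefepime",
  `2`  = c("cefepime", "vancomycin"),
  `3`  = c("meropenem", "vancomycin"),
  `4`  = c("meropenem", "vancomycin", "tobramycin"))

# one episode's post-BAL score path: ceasing episodes step down one level per
# day to -2 and stay; others drop one level per day with probability `hazard`,
# floored at -1 (cessation is modelled only through the ceasing flag, so the
# configured cessation probability is identifiable)
simulate_scores <- function(day0, cease, hazard) {
  s <- integer(7)
  cur <- day0
  for (d in 1:7) {
    if (cease) {
      cur <- max(-2L, cur - 1L)
    } else if (cur > -1L && stats::runif(1) < hazard) {
      cur <- cur - 1L
    }
    s[d] <- cur
  }
  s
}

panel_organism_pool <- c("streptococcus pneumoniae", "staphylococcus aureus",
                         "escherichia coli", "klebsiella pneumoniae group",
                         "pseudomonas aeruginosa", "haemophilus influenzae")
off_panel_pool <- c("stenotrophomonas maltophilia", "citrobacter freundii",
                    "corynebacterium striatum")

# build a culture/PCR pair realizing a requested concordance category
build_bal_pair <- function(patient_id, day, category, off_panel, resistant) {
  org <- sample(panel_organism_pool, 1)
  res_pheno <- if (org == "staphylococcus aureus") "MRSA" else "ESBL"
  res_gene <- if (org == "staphylococcus aureus") "mecA/C" else "CTX-M"
  culture <- list(); pcr <- list()
  if (category == "agreement") {
    culture <- list(list(organism = org, quantity = 1e5,
                         phenotypes = if (resistant) res_pheno else
                           character(0)))
    pcr <- list(list(organism = org, detected = TRUE,
                     genes = if (resistant) res_gene else character(0)))
  } else if (category == "culture_only") {
    corg <- if (off_panel) sample(off_panel_pool, 1) else org
    culture <- list(list(organism = corg, quantity = 1e5,
                         phenotypes = if (resistant && !off_panel)
                           res_pheno else character(0)))
  } else if (category == "pcr_only") {
    pcr <- list(list(organism = org, detected = TRUE,
                     genes = if (resistant) res_gene else character(0)))
  } else { # discordant_both
    other <- sample(setdiff(panel_organism_pool, org), 1)
    culture <- list(list(organism = other, quantity = 1e5,
                         phenotypes = if (resistant) "ESBL" else
                           character(0)))
    pcr <- list(list(organism = org, detected = TRUE, genes = character(0)))
  }
  bal_result(patient_id, day, culture = culture, pcr = pcr,
             pcr_performed = TRUE)
}

#' Generate a seeded synthetic ICU cohort
#'
#' Produces the four inputs the pipeline consumes — a long patient-day regimen
#' table, an adjudicated episode table, paired BAL culture/PCR results and a
#' patient outcome table — from a [cohort_config()]. Deterministic for a fixed
#' seed: each random component (episodes, trajectories, microbiology,
#' outcomes) draws from its own stream derived from the root seed, so changing
#' one component does not perturb the others.
#'
#' @param config A `cohort_config`.
#' @param out_dir Optional directory; when given, writes `regimens.csv`,
#'   `episodes.csv`, `bal_results.json` and `outcomes.csv` there.
#' @return List with `regimens`, `episodes`, `outcomes` (data.frames), `bals`
#'   (list of `bal_result`), and the `config`.
#' @export
generate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- validate_cohort_config(config)
  base_day <- as.Date("2020-06-01")

  # --- episode stream -------------------------------------------------------
  set.seed(cfg$seed)
  n <- cfg$n_patients
  patient_id <- sprintf("P%05d", seq_len(n))
  n_episodes <- 1L + stats::rbinom(n, 1L, cfg$second_episode_prob)
  epi_patient <- rep(patient_id, n_episodes)
  epi_index <- sequence(n_episodes)
  n_epi <- length(epi_patient)
  etiology <- sample(names(cfg$episode_etiology_weights), n_epi,
                     replace = TRUE, prob = cfg$episode_etiology_weights)
  resistant <- rep(NA, n_epi)
  bact <- etiology %in% c("bacterial", "bacterial_viral")
  resistant[bact] <- stats::runif(sum(bact)) < cfg$resistant_fraction
  admission <- base_day + sample(0:364, n, replace = TRUE)
  bal_offset <- pmin(9L, stats::rpois(n_epi, 3)) + (epi_index - 1L) * 14L
  bal_day <- admission[match(epi_patient, patient_id)] + bal_offset
  setting <- ifelse(etiology == "non_pneumonia_control", "none",
                    sample(c("CAP", "HAP", "VAP"), n_epi, replace = TRUE,
                           prob = c(150, 257, 406) / 813))
  cured <- rep(NA, n_epi)
  adjudicable <- etiology %in% c("bacterial", "bacterial_viral",
                                 "microbiology_negative")
  cured[adjudicable] <- stats::runif(sum(adjudicable)) < 0.6
  extra_pulm <- stats::runif(n_epi) < 0.3
  episodes <- data.frame(
    episode_id = sprintf("E%05d", seq_len(n_epi)),
    patient_id = epi_patient, bal_day = bal_day, etiology = etiology,
    resistant = resistant, setting = setting, cured_day7 = cured,
    extra_pulmonary_infection = extra_pulm,
    admission_day = admission[match(epi_patient, patient_id)])

  # --- trajectory stream ----------------------------------------------------
  set.seed(cfg$seed + 1000003L)
  group <- dynamic_group(etiology, resistant)
  day0 <- vapply(group, function(g) {
    d <- cfg$day0_score_distribution[[g]]
    as.integer(sample(names(d), 1, prob = d))
  }, integer(1))
  cease <- stats::runif(n_epi) < cfg$cessation_probability[group]
  # geometric end-of-stay: per-day stopping probability chosen so the
  # configured fraction of windows truncates before post-BAL day 7
  p_end <- 1 - (1 - cfg$truncation_fraction)^(1 / 7)
  end_rel <- stats::rgeom(n_epi, p_end) + 1L  # >= day 1 (day 0 in-hospital)
  end_rel[end_rel > 7L] <- NA_integer_
  # only a patient's final episode can end the stay inside its window
  end_rel[epi_index < rep(n_episodes, n_episodes)] <- NA_integer_
  regimen_rows <- vector("list", n_epi)
  scores_post <- matrix(NA_integer_, nrow = n_epi, ncol = 7)
  for (i in seq_len(n_epi)) {
    s_post <- simulate_scores(day0[i], cease[i],
                              cfg$deescalation_hazard[[group[i]]])
    scores_post[i, ] <- s_post
    adm_rel <- as.integer(admission[match(epi_patient[i], patient_id)] -
                            bal_day[i])
    rel <- max(-2L, adm_rel):(if (is.na(end_rel[i])) 7L else end_rel[i])
    sc <- ifelse(rel < 1L, day0[i], s_post[pmax(rel, 1L)])
    agents <- .score_regimens[as.character(sc)]
    n_agents <- lengths(agents)
    if (sum(n_agents) > 0) {
      regimen_rows[[i]] <- data.frame(
        patient_id = epi_patient[i],
        date = rep(bal_day[i] + rel, n_agents),
        agent = unlist(agents, use.names = FALSE))
    }
  }
  regimens <- do.call(rbind, regimen_rows[!vapply(regimen_rows, is.null,
                                                  logical(1))])
  regimens <- regimens[!duplicated(regimens), , drop = FALSE]
  regimens <- regimens[order(regimens$patient_id, regimens$date,
                             regimens$agent), , drop = FALSE]
  rownames(regimens) <- NULL
  episodes$end_of_stay <- bal_day + end_rel  # NA when stay exceeds the window

  # --- microbiology stream --------------------------------------------------
  set.seed(cfg$seed + 2000003L)
  paired <- stats::runif(n_epi) < cfg$paired_testing_rate
  bals <- vector("list", n_epi)
  for (i in seq_len(n_epi)) {
    if (!paired[i]) {
      bals[[i]] <- bal_result(epi_patient[i], bal_day[i],
                              culture = list(), pcr = list(),
                              pcr_performed = FALSE)
      next
    }
    if (bact[i]) {
      cat_i <- sample(names(cfg$concordance_weights), 1,
                      prob = cfg$concordance_weights)
      off <- cat_i == "culture_only" &&
        stats::runif(1) < cfg$off_panel_fraction
      bals[[i]] <- build_bal_pair(epi_patient[i], bal_day[i], cat_i, off,
                                  isTRUE(resistant[i]))
    } else {
      # viral / microbiology-negative / control: no significant bacterial
      # growth and an all-negative panel (doubly negative agreement)
      bals[[i]] <- bal_result(epi_patient[i], bal_day[i], culture = list(),
                              pcr = list(), pcr_performed = TRUE)
    }
  }

  # --- outcome stream -------------------------------------------------------
  set.seed(cfg$seed + 3000003L)
  first_epi <- match(patient_id, epi_patient)
  pat_group <- group[first_epi]
  unf <- stats::runif(n) < cfg$unfavorable_rate[pat_group]
  mode <- sample(c("died", "hospice", "transplant"), n, replace = TRUE,
                 prob = c(0.85, 0.12, 0.03))
  icu <- pmax(1, round(stats::rlnorm(n, cfg$duration_distributions$icu[1],
                                     cfg$duration_distributions$icu[2])))
  fr <- cfg$duration_distributions$intubation_fraction
  intub <- pmax(1, round(icu * stats::runif(n, fr[1], fr[2])))
  outcomes <- data.frame(
    patient_id = patient_id,
    died_in_hospital = unf & mode == "died",
    discharged_to_hospice = unf & mode == "hospice",
    lung_transplant = unf & mode == "transplant",
    icu_days = icu, intubation_days = intub,
    c_difficile = stats::runif(n) < cfg$c_difficile_rate)

  bundle <- list(regimens = regimens, episodes = episodes, bals = bals,
                 outcomes = outcomes, config = cfg)
  if (!is.null(out_dir)) write_cohort(bundle, out_dir)
  bundle
}

#' Write a generated cohort bundle to disk
#'
#' @param bundle As returned by [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(bundle$regimens, file.path(dir, "regimens.csv"),
                   row.names = FALSE)
  epi <- bundle$episodes
  epi$bal_day <- format(epi$bal_day)
  for (col in intersect(c("end_of_stay", "admission_day"), names(epi))) {
    epi[[col]] <- format(epi[[col]])
  }
  utils::write.csv(epi, file.path(dir, "episodes.csv"), row.names = FALSE)
  write_bal_results(bundle$bals, file.path(dir, "bal_results.json"))
  utils::write.csv(bundle$outcomes, file.path(dir, "outcomes.csv"),
                   row.names = FALSE)
  invisible(dir)
}

make_flat_trajectory <- function(id, day0, post) {
  scores <- c(rep(day0, 3), post)
  names(scores) <- -2:7
  structure(list(episode_id = id, scores = scores, end_day = NA_integer_),
            class = "nat_trajectory")
}

#' Exact-count fixtures for the headline proportions
#'
#' Deterministic, constructed (never sampled) datasets reproducing the
#' reported counts exactly:
#' \describe{
#'   \item{`"concordance635"`}{657 BAL records of which 635 are paired, with
#'     concordance category counts 390 / 158 (139 off-panel) / 61 / 26.}
#'   \item{`"timeline205"`}{205 susceptible-bacterial trajectories eligible
#'     through day 4; 69 de-escalate on day 1 and 115 by day 4.}
#'   \item{`"timeline136"`}{136 microbiology-negative trajectories; 42
#'     de-escalate on day 1 and 78 by day 4.}
#'   \item{`"table3"`}{per-patient outcome and episode tables with group sizes
#'     41 / 123 / 93 / 76 / 107 / 94 (resistant, susceptible, viral, mixed,
#'     microbiology-negative, control) and unfavorable counts
#'     19 / 50 / 41 / 35 / 45 / 43.}
#' }
#'
#' @param name Fixture name.
#' @return The fixture: a list of `bal_result` ("concordance635"), a list of
#'   `nat_trajectory` ("timeline205"/"timeline136"), or a list with
#'   `outcomes` and `episodes` data.frames ("table3").
#' @export
make_fixture <- function(name = c("concordance635", "timeline205",
                                  "timeline136", "table3")) {
  name <- match.arg(name)
  day <- as.Date("2021-01-01")
  if (name == "concordance635") {
    mk <- function(i, culture = list(), pcr = list(), performed = TRUE) {
      bal_result(sprintf("P%04d", i), day, culture = culture, pcr = pcr,
                 pcr_performed = performed)
    }
    agree <- lapply(seq_len(390), function(i) mk(i,
      culture = list(list(organism = "streptococcus pneumoniae",
                          quantity = 1e5, phenotypes = character(0))),
      pcr = list(list(organism = "streptococcus pneumoniae", detected = TRUE,
                      genes = character(0)))))
    cul_off <- lapply(390 + seq_len(139), function(i) mk(i,
      culture = list(list(organism = "stenotrophomonas maltophilia",
                          quantity = 1e5, phenotypes = character(0)))))
    cul_on <- lapply(529 + seq_len(19), function(i) mk(i,
      culture = list(list(organism = "escherichia coli", quantity = 1e5,
                          phenotypes = character(0)))))
    pcr_only <- lapply(548 + seq_len(61), function(i) mk(i,
      pcr = list(list(organism = "haemophilus influenzae", detected = TRUE,
                      genes = character(0)))))
    disc <- lapply(609 + seq_len(26), function(i) mk(i,
      culture = list(list(organism = "escherichia coli", quantity = 1e5,
                          phenotypes = character(0))),
      pcr = list(list(organism = "staphylococcus aureus", detected = TRUE,
                      genes = character(0)))))
    unpaired <- lapply(635 + seq_len(22), function(i) mk(i,
      culture = list(list(organism = "streptococcus pneumoniae",
                          quantity = 1e5, phenotypes = character(0))),
      performed = FALSE))
    return(c(agree, cul_off, cul_on, pcr_only, disc, unpaired))
  }
  if (name %in% c("timeline205", "timeline136")) {
    counts <- if (name == "timeline205") c(day1 = 69, day4 = 46, flat = 90)
      else c(day1 = 42, day4 = 36, flat = 58)
    paths <- c(rep(list(c(1L, 1L, 1L, 1L, 1L, 1L, 1L)), counts["day1"]),
               rep(list(c(2L, 2L, 2L, 1L, 1L, 1L, 1L)), counts["day4"]),
               rep(list(rep(2L, 7)), counts["flat"]))
    return(lapply(seq_along(paths), function(i) {
      make_flat_trajectory(sprintf("%s-%03d", name, i), 2L, paths[[i]])
    }))
  }
  # table3
  sizes <- c(bacterial_resistant = 41, bacterial_susceptible = 123,
             viral = 93, bacterial_viral = 76, microbiology_negative = 107,
             non_pneumonia_control = 94)
  unfavorable <- c(bacterial_resistant = 19, bacterial_susceptible = 50,
                   viral = 41, bacterial_viral = 35,
                   microbiology_negative = 45, non_pneumonia_control = 43)
  icu_median <- c(bacterial_resistant = 14, bacterial_susceptible = 10,
                  viral = 15, bacterial_viral = 16.5,
                  microbiology_negative = 11, non_pneumonia_control = 8.5)
  rows_out <- list(); rows_epi <- list(); k <- 0
  for (g in names(sizes)) {
    n <- sizes[[g]]; u <- unfavorable[[g]]
    ids <- sprintf("P%04d", k + seq_len(n)); k <- k + n
    etiology <- if (startsWith(g, "bacterial_") &&
                    g != "bacterial_viral") "bacterial" else g
    resistant <- if (etiology == "bacterial") g == "bacterial_resistant"
      else NA
    rows_out[[g]] <- data.frame(
      patient_id = ids,
      died_in_hospital = seq_len(n) <= u,
      discharged_to_hospice = FALSE, lung_transplant = FALSE,
      icu_days = icu_median[[g]] + ((seq_len(n) %% 7) - 3),
      intubation_days = pmax(1, icu_median[[g]] - 3 + ((seq_len(n) %% 5) - 2)),
      c_difficile = FALSE)
    rows_epi[[g]] <- data.frame(
      episode_id = paste0("E", ids), patient_id = ids, bal_day = day,
      etiology = etiology, resistant = resistant,
      setting = if (etiology == "non_pneumonia_control") "none" else "VAP",
      cured_day7 = NA, extra_pulmonary_infection = FALSE)
  }
  list(outcomes = do.call(rbind, c(rows_out, make.row.names = FALSE)),
       episodes = do.call(rbind, c(rows_epi, make.row.names = FALSE)))
}
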