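# Antibiotic formulary and NAT (Narrow Antibiotic Therapy) scoring.
#
# The NAT score maps the set of antibacterial agents a patient received on one
# calendar day to an integer spectrum score: -2 = no antibiotics, -1 = narrow
# monotherapy, 0 = empiric guideline CAP coverage (the ceftriaxone +
# azithromycin backbone), 1 = targeted broad coverage, 2 = empiric HAP/VAP
# breadth (antipseudomonal beta-lactam plus anti-MRSA agent), with further
# escalation (+1 per feature: carbapenem/MDR agent, additional gram-negative
# agent) capped at +4 by default.

#' Spectrum classes recognized by the NAT scoring engine
#'
#' Every agent in a formulary belongs to exactly one spectrum class. The class
#' drives the tier logic of [score_day()].
#'
#' @return Character vector of the valid `spectrum_class` tokens.
#' @export
spectrum_classes <- function() {
  c("narrow", "cap_core_betalactam", "atypical_coverage", "targeted_broad",
    "antipseudomonal_betalactam", "anti_mrsa", "carbapenem_or_mdr",
    "adjunct_gram_negative")
}

# classes that exceed CAP-level breadth
.broad_classes <- c("targeted_broad", "antipseudomonal_betalactam",
                    "anti_mrsa", "carbapenem_or_mdr", "adjunct_gram_negative")
# gram-negative broad coverage (counted for the "additional gram-negative
# agent" escalation feature)
.gram_negative_classes <- c("targeted_broad", "antipseudomonal_betalactam",
                            "carbapenem_or_mdr", "adjunct_gram_negative")

new_formulary <- function(agents, version = "unversioned") {
  stopifnot(is.data.frame(agents))
  structure(list(agents = agents, version = version), class = "formulary")
}

validate_formulary <- function(fm) {
  agents <- fm$agents
  required <- c("name", "spectrum_class")
  missing_cols <- setdiff(required, names(agents))
  if (length(missing_cols) > 0) {
    stop("formulary is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(agents$name)) {
    dup <- unique(agents$name[duplicated(agents$name)])
    stop("duplicate agent name(s) in formulary: ", paste(dup, collapse = ", "))
  }
  bad <- setdiff(unique(agents$spectrum_class), spectrum_classes())
  if (length(bad) > 0) {
    stop("unknown spectrum_class token(s): ", paste(bad, collapse = ", "))
  }
  anchors <- c(ceftriaxone = "cap_core_betalactam",
               azithromycin = "atypical_coverage")
  for (a in names(anchors)) {
    cls <- agents$spectrum_class[agents$name == a]
    if (length(cls) != 1 || cls != anchors[[a]]) {
      stop("formulary must contain anchor agent '", a,
           "' with spectrum_class '", anchors[[a]], "'")
    }
  }
  fm
}

#' Load an antibiotic formulary
#'
#' Reads a formulary from a CSV file with header `name,spectrum_class,route`
#' (or an equivalent JSON array of objects). Agent names are canonicalized to
#' lowercase. The formulary must contain the two CAP anchor agents,
#' ceftriaxone (`cap_core_betalactam`) and azithromycin (`atypical_coverage`),
#' because they define the zero of the NAT scale.
#'
#' @param path Path to a CSV or JSON formulary file.
#' @return A `formulary` object.
#' @seealso [default_formulary()] for the shipped default, [score_day()].
#' @export
load_formulary <- function(path) {
  if (!file.exists(path)) stop("formulary file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    agents <- jsonlite::fromJSON(path)
    agents <- as.data.frame(agents, stringsAsFactors = FALSE)
  } else {
    agents <- utils::read.csv(path, stringsAsFactors = FALSE,
                              strip.white = TRUE)
  }
  agents$name <- tolower(trimws(agents$name))
  if (is.null(agents$route)) agents$route <- "other"
  validate_formulary(new_formulary(agents, version = basename(path)))
}

#' Default antibiotic formulary
#'
#' The formulary shipped with the package: common ICU antibacterials mapped to
#' spectrum classes. Non-antibacterial antimicrobials (antivirals, antifungals)
#' are deliberately absent; the NAT score measures antibacterial spectrum only.
#'
#' @return A `formulary` object.
#' @export
default_formulary <- function() {
  path <- system.file("extdata", "formulary_default.csv",
                      package = "balsteward", mustWork = TRUE)
  fm <- load_formulary(path)
  fm$version <- "balsteward-default"
  fm
}

#' @export
print.formulary <- function(x, ...) {
  cat("<formulary> version:", x$version, "-", nrow(x$agents), "agents\n")
  tab <- table(factor(x$agents$spectrum_class, levels = spectrum_classes()))
  for (cl in names(tab)) cat(sprintf("  %-28s %d\n", cl, tab[[cl]]))
  invisible(x)
}

agent_classes <- function(agents, formulary) {
  idx <- match(agents, formulary$agents$name)
  if (anyNA(idx)) {
    stop("agent(s) not in formulary: ",
         paste(agents[is.na(idx)], collapse = ", "))
  }
  formulary$agents$spectrum_class[idx]
}

#' NAT score of a single day's antibiotic regimen
#'
#' Deterministic tier logic over the spectrum classes of the agents received:
#' \itemize{
#'   \item `-2` — no antibacterial agents;
#'   \item `-1` — monotherapy with a single narrow-spectrum agent;
#'   \item `0`  — CAP-level breadth: any combination drawn from the CAP core
#'     beta-lactam / atypical-coverage classes (the ceftriaxone + azithromycin
#'     backbone, or either component alone), or two or more narrow agents, with
#'     no broader agent present;
#'   \item `1`  — exactly one axis of broad coverage (a targeted broad,
#'     antipseudomonal beta-lactam, gram-negative adjunct, carbapenem or
#'     anti-MRSA agent);
#'   \item `2`  — empiric HAP/VAP breadth: gram-negative antipseudomonal
#'     coverage combined with an anti-MRSA agent;
#'   \item `+1` per escalation feature on top: a carbapenem/MDR-active agent
#'     given alongside other broad coverage, and each gram-negative agent
#'     beyond the first; capped at `cap` (default `+4`).
#' }
#' Duplicated agent names are ignored; the regimen is a set. Unknown agents
#' are an error rather than silently scored narrow, because silent
#' misclassification would bias trajectories downward.
#'
#' @param agents Character vector of agent names received that day (possibly
#'   empty). Case-insensitive; matched against the formulary.
#' @param formulary A `formulary` object (default: [default_formulary()]).
#' @param cap Upper bound of the scale (default 4).
#' @return Integer NAT score, `>= -2`.
#' @examples
#' score_day(c("ceftriaxone", "azithromycin"))  # 0, empiric CAP
#' score_day(character(0))                      # -2, no antibiotics
#' score_day("ampicillin")                      # -1, narrow monotherapy
#' score_day(c("cefepime", "vancomycin"))       # 2, empiric HAP/VAP
#' @export
score_day <- function(agents, formulary = default_formulary(), cap = 4L) {
  agents <- unique(tolower(trimws(agents)))
  agents <- agents[nzchar(agents)]
  if (length(agents) == 0) return(-2L)
  cls <- agent_classes(agents, formulary)

  if (!any(cls %in% .broad_classes)) {
    # CAP-or-narrower tier
    if (length(agents) == 1 && cls == "narrow") return(-1L)
    return(0L)
  }

  n_gn <- sum(cls %in% .gram_negative_classes)
  has_gn <- n_gn > 0
  has_mrsa <- any(cls == "anti_mrsa")
  has_carb <- any(cls == "carbapenem_or_mdr")

  base <- 1L + as.integer(has_gn && has_mrsa)
  escalation <- as.integer(has_carb && (has_mrsa || n_gn >= 2)) +
    max(0L, n_gn - 1L)
  min(as.integer(cap), base + escalation)
}

#' Read a long-format daily regimen table
#'
#' One row per patient-day-agent: header `patient_id,date,agent`, ISO-8601
#' dates. Days with no antibiotics need no rows; they are scored `-2` when a
#' trajectory window covers them.
#'
#' @param path CSV file path.
#' @return data.frame with columns `patient_id` (character), `date` (Date),
#'   `agent` (character, lowercase).
#' @export
read_regimens <- function(path) {
  if (!file.exists(path)) stop("regimen file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  required <- c("patient_id", "date", "agent")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("regimen table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df$patient_id <- as.character(df$patient_id)
  df$date <- as.Date(df$date)
  if (anyNA(df$date)) stop("regimen table contains unparseable dates")
  df$agent <- tolower(trimws(df$agent))
  df
}

#' Score every patient-day in a regimen table
#'
#' Collapses a long regimen table to one NAT score per patient per calendar
#' day. Only days with at least one administration row appear; absent days are
#' imputed as `-2` later, during trajectory alignment, when they fall inside an
#' in-hospital window.
#'
#' @param regimens data.frame as returned by [read_regimens()].
#' @inheritParams score_day
#' @return data.frame with columns `patient_id`, `date`, `nat`.
#' @export
score_regimens <- function(regimens, formulary = default_formulary(),
                           cap = 4L) {
  stopifnot(all(c("patient_id", "date", "agent") %in% names(regimens)))
  if (nrow(regimens) == 0) {
    return(data.frame(patient_id = character(0), date = as.Date(character(0)),
                      nat = integer(0)))
  }
  # validate all agents once up front for a single, complete error message
  agent_classes(unique(tolower(trimws(regimens$agent))), formulary)
  key <- paste(regimens$patient_id, regimens$date, sep = "\r")
  pieces <- split(seq_len(nrow(regimens)), key)
  firsts <- vapply(pieces, `[[`, integer(1), 1L)
  res <- data.frame(
    patient_id = regimens$patient_id[firsts],
    date = as.Date(regimens$date[firsts]),
    nat = vapply(pieces, function(idx) {
      score_day(regimens$agent[idx], formulary, cap)
    }, integer(1)))
  res <- res[order(res$patient_id, res$date), , drop = FALSE]
  rownames(res) <- NULL
  res
}
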