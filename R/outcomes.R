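# Composite unfavorable outcome and the comparison statistics: sample odds
# ratio, Fisher's exact test (full hypergeometric enumeration) and the
# Mann-Whitney U test (exact U-distribution by counting, or tie-corrected
# normal approximation). The tests are implemented here directly; base R's
# dhyper/pnorm serve only as distribution primitives.

#' Read a patient outcome table
#'
#' CSV with header
#' `patient_id,died_in_hospital,discharged_to_hospice,lung_transplant,icu_days,intubation_days,c_difficile`.
#'
#' @param path CSV file path.
#' @return data.frame, one row per patient.
#' @export
read_outcomes <- function(path) {
  if (!file.exists(path)) stop("outcomes file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  required <- c("patient_id", "died_in_hospital", "discharged_to_hospice",
                "lung_transplant", "icu_days", "intubation_days",
                "c_difficile")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("outcomes table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df$patient_id <- as.character(df$patient_id)
  for (col in c("died_in_hospital", "discharged_to_hospice", "lung_transplant",
                "c_difficile")) {
    df[[col]] <- as.logical(df[[col]])
  }
  if (any(df$icu_days < 0 | df$intubation_days < 0, na.rm = TRUE)) {
    stop("durations must be nonnegative")
  }
  if (anyDuplicated(df$patient_id)) stop("duplicate patient_id values")
  df
}

#' Composite unfavorable outcome
#'
#' In-hospital death, discharge to hospice, or lung transplantation during
#' the admission.
#'
#' @param outcomes data.frame with logical columns `died_in_hospital`,
#'   `discharged_to_hospice`, `lung_transplant` (vectorized over rows).
#' @return Logical vector.
#' @export
unfavorable <- function(outcomes) {
  outcomes$died_in_hospital | outcomes$discharged_to_hospice |
    outcomes$lung_transplant
}

as_contingency2x2 <- function(t) {
  if (is.matrix(t)) {
    stopifnot(all(dim(t) == c(2, 2)))
    t <- c(t[1, 1], t[1, 2], t[2, 1], t[2, 2])
  }
  stopifnot(length(t) == 4, all(t >= 0), all(t == round(t)))
  as.numeric(t)
}

#' Sample (cross-product) odds ratio of a 2x2 table
#'
#' `(a*d)/(b*c)` for the table `(a, b; c, d)` (rows = group, columns =
#' event yes/no). When any cell is zero the Haldane-Anscombe correction adds
#' 0.5 to every cell and the result carries attribute `corrected = TRUE`.
#'
#' @param t Either a length-4 vector `c(a, b, c, d)` or a 2x2 matrix (filled
#'   row-wise as `a, b` / `c, d`).
#' @return The odds ratio, with logical attribute `corrected`.
#' @export
sample_odds_ratio <- function(t) {
  t <- as_contingency2x2(t)
  a <- t[1]; b <- t[2]; cc <- t[3]; d <- t[4]
  if ((a + b) == 0 || (cc + d) == 0) stop("a row sum of the table is zero")
  if ((a + cc) == 0 || (b + d) == 0) stop("a column sum of the table is zero")
  corrected <- any(t == 0)
  if (corrected) {
    a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
  }
  structure((a * d) / (b * cc), corrected = corrected)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Sums the hypergeometric probabilities, conditional on the observed margins,
#' of every table whose probability does not exceed that of the observed table
#' (within relative tolerance `1e-7`, guarding against floating-point
#' near-ties). Degenerate margins (an empty row or column) give `p = 1` with
#' attribute `degenerate = TRUE`.
#'
#' @inheritParams sample_odds_ratio
#' @return Two-sided p-value in `(0, 1]`.
#' @export
fisher_exact <- function(t) {
  t <- as_contingency2x2(t)
  a <- t[1]; b <- t[2]; cc <- t[3]; d <- t[4]
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    return(structure(1, degenerate = TRUE))
  }
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- probs[support == a]
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  structure(min(1, p), degenerate = FALSE)
}

# exact null distribution of the Mann-Whitney U statistic for sample sizes
# m, n without ties: counts[u + 1] = number of arrangements with U = u,
# computed by the classic lattice recursion
# N(m, n, u) = N(m - 1, n, u - n) + N(m, n - 1, u).
mw_count_u <- function(m, n) {
  umax <- m * n
  # prev[[j + 1]] holds counts for (i - 1, j); cur for (i, j)
  prev <- lapply(0:n, function(j) c(1, rep(0, umax)))
  for (i in seq_len(m)) {
    cur <- vector("list", n + 1)
    cur[[1]] <- c(1, rep(0, umax))
    for (j in seq_len(n)) {
      shifted <- c(rep(0, j), prev[[j + 1]][seq_len(umax + 1 - j)])
      cur[[j + 1]] <- shifted + cur[[j]]
    }
    prev <- cur
  }
  prev[[n + 1]]
}

#' Mann-Whitney U test
#'
#' The U statistic is computed from midranks (average ranks for ties). The
#' two-sided p-value comes from the exact null distribution of U — counted by
#' dynamic programming over rank arrangements — whenever there are no ties
#' and `n_x * n_y <= 400`; otherwise from the normal approximation with
#' tie-corrected variance and a 0.5 continuity correction. `method` forces
#' one path (`"exact"` is only available for tie-free samples). The two U
#' statistics always satisfy `U_x + U_y = n_x * n_y`.
#'
#' @param x,y Numeric samples (non-empty).
#' @param method `"auto"` (default), `"exact"` or `"approximate"`.
#' @return List with `U` (the statistic for `x`), `p` (two-sided), and
#'   `method` (`"exact"` or `"normal_approximation"`).
#' @export
mann_whitney <- function(x, y, method = c("auto", "exact", "approximate")) {
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0) stop("samples must be non-empty")
  m <- length(x); n <- length(y); N <- m + n
  r <- rank(c(x, y))
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- table(c(x, y))
  has_ties <- any(ties > 1)
  if (method == "exact" && has_ties) {
    stop("exact Mann-Whitney p requires tie-free samples")
  }
  use_exact <- method == "exact" ||
    (method == "auto" && !has_ties && m * n <= 400)
  if (use_exact) {
    counts <- mw_count_u(m, n)
    total <- choose(N, m)
    dev <- abs(U - m * n / 2)
    u_all <- 0:(m * n)
    p <- sum(counts[abs(u_all - m * n / 2) >= dev - 1e-9]) / total
    return(list(U = U, p = min(1, p), method = "exact"))
  }
  tie_term <- sum(ties^3 - ties)
  sigma2 <- m * n / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal_approximation"))
  z <- max(0, abs(U - m * n / 2) - 0.5) / sqrt(sigma2)
  list(U = U, p = min(1, 2 * stats::pnorm(-z)),
       method = "normal_approximation")
}

.outcome_groups <- c("bacterial", "bacterial_resistant",
                     "bacterial_susceptible", "viral", "bacterial_viral",
                     "microbiology_negative", "non_pneumonia_control")

outcome_group_members <- function(episodes, group) {
  switch(group,
    bacterial = episodes$etiology == "bacterial",
    bacterial_resistant = episodes$etiology == "bacterial" &
      !is.na(episodes$resistant) & episodes$resistant,
    bacterial_susceptible = episodes$etiology == "bacterial" &
      !is.na(episodes$resistant) & !episodes$resistant,
    episodes$etiology == group)
}

#' Clinical outcome comparison table across pneumonia etiologies
#'
#' Restricted to patients with exactly one suspected pneumonia episode (a
#' patient appearing on several episode rows is an error; filter upstream).
#' For each etiology group — bacterial episodes also split into resistant and
#' susceptible — reports n, unfavorable-outcome count and percentage, median
#' and IQR of ICU and intubation days, and C. difficile count, plus the sample
#' odds ratio and two-sided Fisher exact p of the unfavorable outcome versus
#' the reference group and Mann-Whitney p-values for the durations. No
#' multiple-testing correction is applied; p-values are reported raw. A
#' degenerate unfavorable column (all or none) yields `NA` odds ratios with
#' the table still emitted.
#'
#' @param outcomes data.frame as from [read_outcomes()].
#' @param episodes data.frame as from [read_episodes()], one episode per
#'   patient.
#' @param reference_group Group compared against (default
#'   `"microbiology_negative"`); its own OR row is `NA` definitionally.
#' @return data.frame, one row per non-empty group; attribute
#'   `reference_group`.
#' @export
outcomes_table <- function(outcomes, episodes,
                           reference_group = "microbiology_negative") {
  stopifnot(reference_group %in% .outcome_groups)
  if (anyDuplicated(episodes$patient_id)) {
    stop("a patient has more than one episode; ",
         "outcome analysis requires exactly one episode per patient")
  }
  idx <- match(outcomes$patient_id, episodes$patient_id)
  if (anyNA(idx)) stop("outcome rows without a matching episode")
  outcomes$etiology <- episodes$etiology[idx]
  outcomes$resistant <- episodes$resistant[idx]
  outcomes$unfavorable <- unfavorable(outcomes)

  epi <- outcomes  # per-patient frame carrying etiology + resistant
  ref_rows <- epi[outcome_group_members(epi, reference_group), , drop = FALSE]
  if (nrow(ref_rows) == 0) stop("reference group is empty: ", reference_group)

  iqr_chr <- function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    sprintf("%.1f [%.1f, %.1f]", q[2], q[1], q[3])
  }
  rows <- lapply(.outcome_groups, function(g) {
    sel <- epi[outcome_group_members(epi, g), , drop = FALSE]
    if (nrow(sel) == 0) return(NULL)
    n <- nrow(sel)
    unf <- sum(sel$unfavorable)
    or <- NA_real_; fisher_p <- NA_real_
    icu_p <- NA_real_; intub_p <- NA_real_
    if (g != reference_group) {
      tab <- c(unf, n - unf, sum(ref_rows$unfavorable),
               nrow(ref_rows) - sum(ref_rows$unfavorable))
      or <- tryCatch(as.numeric(sample_odds_ratio(tab)),
                     error = function(e) NA_real_)
      fisher_p <- as.numeric(fisher_exact(tab))
      icu_p <- mann_whitney(sel$icu_days, ref_rows$icu_days)$p
      intub_p <- mann_whitney(sel$intubation_days, ref_rows$intubation_days)$p
    }
    data.frame(group = g, n = n, n_unfavorable = unf,
               percent_unfavorable = round(100 * unf / n, 1),
               icu_days = iqr_chr(sel$icu_days),
               intubation_days = iqr_chr(sel$intubation_days),
               n_c_difficile = sum(sel$c_difficile),
               odds_ratio = or, fisher_p = fisher_p,
               icu_mw_p = icu_p, intubation_mw_p = intub_p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reference_group") <- reference_group
  out
}
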