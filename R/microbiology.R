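# Paired quantitative-culture / multiplex-PCR BAL results: resistance
# classification and concordance taxonomy.

#' Resistance genes detected by the multiplex PCR panel
#'
#' The eight-gene vocabulary: mecA/C and MREJ (methicillin resistance in
#' S. aureus), CTX-M (ESBL), and the carbapenemases KPC, NDM, IMP, VIM and
#' OXA-48-like.
#'
#' @return Character vector of gene tokens.
#' @export
resistance_genes <- function() {
  c("mecA/C", "MREJ", "OXA-48-like", "CTX-M", "KPC", "NDM", "IMP", "VIM")
}

#' Resistant-phenotype tokens reportable by quantitative culture
#' @return Character vector of phenotype tokens.
#' @export
resistance_phenotypes <- function() {
  c("MRSA", "ESBL", "CRE", "other_resistant")
}

#' Default multiplex pneumonia panel definition
#'
#' The bacterial (and atypical bacterial) targets of the commercial multiplex
#' pneumonia panel, plus the eight resistance-gene targets. Shipped as an
#' editable JSON config; [load_panel()] reads alternatives.
#'
#' @return A `panel_definition` object: list with `organisms` and `genes`.
#' @export
default_panel <- function() {
  load_panel(system.file("extdata", "panel_default.json",
                         package = "balsteward", mustWork = TRUE))
}

#' Load a panel definition from JSON
#'
#' @param path JSON file with fields `organisms` (array of canonical organism
#'   names) and `genes` (array of resistance-gene tokens).
#' @return A `panel_definition` object.
#' @export
load_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  raw <- jsonlite::fromJSON(path)
  organisms <- tolower(trimws(unlist(raw$organisms)))
  if (length(organisms) == 0) stop("panel must target at least one organism")
  genes <- unlist(raw$genes)
  if (is.null(genes)) genes <- resistance_genes()
  bad <- setdiff(genes, resistance_genes())
  if (length(bad) > 0) stop("unknown resistance gene(s): ",
                            paste(bad, collapse = ", "))
  structure(list(organisms = unique(organisms), genes = genes),
            class = "panel_definition")
}

#' @export
print.panel_definition <- function(x, ...) {
  cat("<panel_definition>", length(x$organisms), "organism targets,",
      length(x$genes), "resistance genes\n")
  invisible(x)
}

#' Construct a single BAL result record
#'
#' Pairs the quantitative-culture findings with the multiplex PCR findings of
#' one BAL sample. A performed PCR panel may be all-negative (`pcr_performed =
#' TRUE` with an empty or all-`detected = FALSE` `pcr` list); non-empty PCR
#' findings imply the panel was performed.
#'
#' @param patient_id Opaque patient identifier.
#' @param collection_day Calendar date of the BAL (coerced with `as.Date`).
#' @param culture List of culture findings, each a list with `organism`
#'   (canonical name), `quantity` (CFU/mL, or `NA` when not quantified) and
#'   `phenotypes` (character vector drawn from [resistance_phenotypes()]).
#' @param pcr List of PCR findings, each a list with `organism`, `detected`
#'   (logical) and `genes` (character vector drawn from [resistance_genes()]).
#' @param pcr_performed Was the multiplex panel run on this sample?
#' @return A `bal_result` object.
#' @export
bal_result <- function(patient_id, collection_day, culture = list(),
                       pcr = list(), pcr_performed = length(pcr) > 0) {
  culture <- lapply(culture, function(f) {
    q <- f$quantity %||% NA_real_
    q <- if (length(q) == 0) NA_real_ else as.numeric(q)
    if (!is.na(q) && q < 0) stop("culture quantity must be nonnegative")
    phen <- as.character(unlist(f$phenotypes) %||% character(0))
    bad <- setdiff(phen, resistance_phenotypes())
    if (length(bad) > 0) stop("unknown resistant phenotype token(s): ",
                              paste(bad, collapse = ", "))
    list(organism = tolower(trimws(f$organism)), quantity = q,
         phenotypes = phen)
  })
  pcr <- lapply(pcr, function(f) {
    genes <- as.character(unlist(f$genes) %||% character(0))
    bad <- setdiff(genes, resistance_genes())
    if (length(bad) > 0) stop("unknown resistance gene token(s): ",
                              paste(bad, collapse = ", "))
    list(organism = tolower(trimws(f$organism)),
         detected = isTRUE(f$detected), genes = genes)
  })
  if (length(pcr) > 0 && !pcr_performed) {
    stop("non-empty PCR findings imply pcr_performed = TRUE")
  }
  structure(list(patient_id = as.character(patient_id),
                 collection_day = as.Date(collection_day),
                 culture = culture, pcr = pcr,
                 pcr_performed = isTRUE(pcr_performed)),
            class = "bal_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read BAL results from JSON
#'
#' One record per BAL: `patient_id`, `collection_day`, `pcr_performed`,
#' `culture` (array of findings) and `pcr` (array of findings), matching the
#' structure documented in [bal_result()].
#'
#' @param path JSON file path.
#' @return List of `bal_result` objects.
#' @export
read_bal_results <- function(path) {
  if (!file.exists(path)) stop("BAL results file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(rec) {
    bal_result(patient_id = rec$patient_id,
               collection_day = rec$collection_day,
               culture = rec$culture %||% list(),
               pcr = rec$pcr %||% list(),
               pcr_performed = isTRUE(rec$pcr_performed))
  })
}

#' Write BAL results to JSON
#'
#' Inverse of [read_bal_results()].
#'
#' @param bals List of `bal_result` objects.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_bal_results <- function(bals, path) {
  recs <- lapply(bals, function(b) {
    list(patient_id = b$patient_id,
         collection_day = format(b$collection_day),
         pcr_performed = b$pcr_performed,
         culture = lapply(b$culture, function(f) {
           rec <- list(organism = f$organism, phenotypes = I(f$phenotypes))
           if (!is.na(f$quantity)) rec$quantity <- f$quantity
           rec
         }),
         pcr = lapply(b$pcr, function(f) {
           list(organism = f$organism, detected = f$detected,
                genes = I(f$genes))
         }))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' Classify an episode as resistant or susceptible
#'
#' An episode is resistant if the causative organism tested positive for any
#' resistance gene on the multiplex panel, or if the quantitative culture
#' indicated a resistant pathogen (e.g. an ESBL-positive organism or MRSA).
#' A BAL with neither marker — including one with no growth and a negative
#' panel — is susceptible.
#'
#' @param bal A `bal_result`.
#' @return `"resistant"` or `"susceptible"`.
#' @export
classify_resistance <- function(bal) {
  stopifnot(inherits(bal, "bal_result"))
  pcr_res <- any(vapply(bal$pcr, function(f) length(f$genes) > 0, logical(1)))
  cul_res <- any(vapply(bal$culture, function(f) length(f$phenotypes) > 0,
                        logical(1)))
  if (pcr_res || cul_res) "resistant" else "susceptible"
}

# gene -> phenotype equivalence used when judging agreement
map_genes_to_phenotypes <- function(organism, genes) {
  if (length(genes) == 0) return(character(0))
  staph <- grepl("staphylococcus", organism)
  out <- character(0)
  if (any(genes %in% c("mecA/C", "MREJ"))) {
    out <- c(out, if (staph) "MRSA" else "other_resistant")
  }
  if ("CTX-M" %in% genes) out <- c(out, "ESBL")
  if (any(genes %in% c("KPC", "NDM", "IMP", "VIM", "OXA-48-like"))) {
    out <- c(out, "CRE")
  }
  unique(out)
}

# organisms excluded from concordance sets (not clinically significant)
.concordance_excluded_organisms <- "candida albicans"

concordance_sets <- function(bal, significance_threshold = 1e4) {
  cul_sig <- Filter(function(f) {
    (is.na(f$quantity) || f$quantity >= significance_threshold) &&
      !(f$organism %in% .concordance_excluded_organisms)
  }, bal$culture)
  c_orgs <- unique(vapply(cul_sig, `[[`, character(1), "organism"))
  c_res <- unique(unlist(lapply(cul_sig, `[[`, "phenotypes")))
  pcr_det <- Filter(function(f) f$detected, bal$pcr)
  p_orgs <- unique(vapply(pcr_det, `[[`, character(1), "organism"))
  p_res <- unique(unlist(lapply(bal$pcr, function(f) {
    map_genes_to_phenotypes(f$organism, f$genes)
  })))
  list(c_orgs = c_orgs, c_res = c_res %||% character(0),
       p_orgs = p_orgs, p_res = p_res %||% character(0))
}

#' Classify PCR/culture concordance for one paired BAL
#'
#' Compares the set of organisms and resistance markers identified by
#' quantitative culture (growth at or above the significance threshold;
#' unquantified growth counts as significant) against those identified by the
#' multiplex PCR (detected organisms, plus resistance genes mapped to their
#' phenotype equivalents). Four mutually exclusive categories:
#' \describe{
#'   \item{agreement}{both sides identify the same organisms and equivalent
#'     resistance (including the doubly negative case);}
#'   \item{culture_only}{culture found organisms/resistance the PCR missed,
#'     and the PCR found nothing extra; `off_panel` is `TRUE` when every
#'     culture-unique organism is outside the panel's target list;}
#'   \item{pcr_only}{the PCR found organisms/resistance the culture missed,
#'     and the culture found nothing extra;}
#'   \item{discordant_both}{each side found something the other missed.}
#' }
#'
#' @param bal A `bal_result` with `pcr_performed = TRUE` (the paired-sample
#'   precondition; unpaired samples are an error).
#' @param panel A `panel_definition` (default [default_panel()]).
#' @param significance_threshold CFU/mL cutoff below which culture growth is
#'   excluded from the comparison (default `1e4`, a conventional BAL cutoff).
#' @return A `concordance_call`: list with `category` and `off_panel`.
#' @export
classify_concordance <- function(bal, panel = default_panel(),
                                 significance_threshold = 1e4) {
  stopifnot(inherits(bal, "bal_result"))
  if (!bal$pcr_performed) {
    stop("unpaired sample: multiplex PCR was not performed on this BAL")
  }
  s <- concordance_sets(bal, significance_threshold)
  c_items <- c(s$c_orgs, s$c_res)
  p_items <- c(s$p_orgs, s$p_res)
  c_extra <- setdiff(c_items, p_items)
  p_extra <- setdiff(p_items, c_items)
  category <- if (length(c_extra) == 0 && length(p_extra) == 0) {
    "agreement"
  } else if (length(p_extra) == 0) {
    "culture_only"
  } else if (length(c_extra) == 0) {
    "pcr_only"
  } else {
    "discordant_both"
  }
  off_panel <- FALSE
  if (category == "culture_only") {
    extra_orgs <- intersect(c_extra, s$c_orgs)
    off_panel <- length(extra_orgs) > 0 &&
      !any(extra_orgs %in% panel$organisms)
  }
  structure(list(category = category, off_panel = off_panel),
            class = "concordance_call")
}

#' Summarize a collection of concordance calls
#'
#' @param calls List of `concordance_call` objects.
#' @return data.frame with one row per category (`agreement`, `culture_only`,
#'   `pcr_only`, `discordant_both`): `n`, `percent` (one decimal), and for
#'   `culture_only` the `n_off_panel` subcount and `percent_off_panel` of the
#'   grand total.
#' @export
summarize_concordance <- function(calls) {
  if (length(calls) == 0) stop("no concordance calls to summarize")
  cats <- vapply(calls, `[[`, character(1), "category")
  off <- vapply(calls, `[[`, logical(1), "off_panel")
  levels <- c("agreement", "culture_only", "pcr_only", "discordant_both")
  bad <- setdiff(unique(cats), levels)
  if (length(bad) > 0) stop("unknown concordance category: ",
                            paste(bad, collapse = ", "))
  n <- as.integer(table(factor(cats, levels = levels)))
  total <- length(calls)
  out <- data.frame(
    category = levels,
    n = n,
    percent = round(100 * n / total, 1),
    n_off_panel = NA_integer_,
    percent_off_panel = NA_real_
  )
  n_off <- sum(off & cats == "culture_only")
  out$n_off_panel[out$category == "culture_only"] <- n_off
  out$percent_off_panel[out$category == "culture_only"] <-
    round(100 * n_off / total, 1)
  attr(out, "total") <- total
  out
}

#' Fraction of BALs with both quantitative culture and multiplex PCR
#'
#' @param bals List of `bal_result` objects.
#' @return List with `n_paired`, `n_total` and `percent` (one decimal). A BAL
#'   counts as paired when the PCR panel was performed; quantitative culture
#'   is assumed routine on every BAL in scope.
#' @export
paired_testing_rate <- function(bals) {
  if (length(bals) == 0) stop("no BAL results supplied")
  paired <- vapply(bals, function(b) isTRUE(b$pcr_performed), logical(1))
  list(n_paired = sum(paired), n_total = length(bals),
       percent = round(100 * mean(paired), 1))
}
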