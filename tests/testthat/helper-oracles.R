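# Independent oracles, coded naively and separately from the package paths
# they check.

# two-sided Fisher p by direct enumeration of all tables sharing the observed
# margins, probabilities from lchoose (the package path uses dhyper)
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1)
  xs <- max(0, c1 - r2):min(r1, c1)
  p <- exp(lchoose(r1, xs) + lchoose(r2, c1 - xs) - lchoose(r1 + r2, c1))
  p_obs <- p[xs == a]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

# two-sided Mann-Whitney p by exhaustive enumeration of all group
# assignments of the pooled sample
oracle_mw_p <- function(x, y) {
  pooled <- c(x, y)
  m <- length(x); N <- length(pooled)
  r <- rank(pooled)
  u_of <- function(ii) sum(r[ii]) - m * (m + 1) / 2
  obs <- u_of(seq_len(m))
  centre <- m * (N - m) / 2
  us <- utils::combn(N, m, u_of)
  mean(abs(us - centre) >= abs(obs - centre) - 1e-9)
}

# linear-interpolation quantile computed by hand from the sorted sample
oracle_quantile <- function(v, p) {
  v <- sort(v); n <- length(v)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  v[lo] + (h - lo) * (v[min(lo + 1, n)] - v[lo])
}

# truth-table concordance oracle: recompute the culture/PCR item sets
# directly from the finding lists and read the category off the two set
# differences
oracle_concordance <- function(bal, panel_orgs, threshold = 1e4) {
  c_orgs <- character(0); c_res <- character(0)
  for (f in bal$culture) {
    if (f$organism == "candida albicans") next
    if (!is.na(f$quantity) && f$quantity < threshold) next
    c_orgs <- c(c_orgs, f$organism)
    c_res <- c(c_res, f$phenotypes)
  }
  p_orgs <- character(0); p_res <- character(0)
  for (f in bal$pcr) {
    if (f$detected) p_orgs <- c(p_orgs, f$organism)
    staph <- grepl("staphylococcus", f$organism)
    for (g in f$genes) {
      p_res <- c(p_res,
                 if (g %in% c("mecA/C", "MREJ")) {
                   if (staph) "MRSA" else "other_resistant"
                 } else if (g == "CTX-M") "ESBL" else "CRE")
    }
  }
  ci <- unique(c(c_orgs, c_res)); pi <- unique(c(p_orgs, p_res))
  cx <- setdiff(ci, pi); px <- setdiff(pi, ci)
  cat <- if (!length(cx) && !length(px)) "agreement"
    else if (!length(px)) "culture_only"
    else if (!length(cx)) "pcr_only"
    else "discordant_both"
  off <- FALSE
  if (cat == "culture_only") {
    xo <- intersect(cx, unique(c_orgs))
    off <- length(xo) > 0 && !any(xo %in% panel_orgs)
  }
  list(category = cat, off_panel = off)
}

# trajectory builder for tests: post = scores on relative days 1..7
make_traj <- function(post, day0 = 2L, pre = c(day0, day0), id = "T1",
                      end_day = NA_integer_) {
  scores <- as.integer(c(pre, day0, post))
  names(scores) <- seq.int(to = 7, length.out = length(scores))
  structure(list(episode_id = id, scores = scores, end_day = end_day),
            class = "nat_trajectory")
}
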