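panel <- default_panel()

cf <- function(org, qty = 1e5, pheno = character(0)) {
  list(organism = org, quantity = qty, phenotypes = pheno)
}
pf <- function(org, detected = TRUE, genes = character(0)) {
  list(organism = org, detected = detected, genes = genes)
}
bal <- function(culture = list(), pcr = list(), performed = TRUE) {
  bal_result("P1", "2021-01-01", culture = culture, pcr = pcr,
             pcr_performed = performed)
}

test_that("resistance classification follows the gene-or-phenotype rule", {
  expect_identical(
    classify_resistance(bal(pcr = list(pf("staphylococcus aureus",
                                          genes = "mecA/C")))),
    "resistant")
  expect_identical(
    classify_resistance(bal(
      culture = list(cf("staphylococcus aureus", pheno = "MRSA")),
      pcr = list(pf("staphylococcus aureus", detected = FALSE)))),
    "resistant")
  expect_identical(
    classify_resistance(bal(
      culture = list(cf("staphylococcus aureus")),
      pcr = list(pf("staphylococcus aureus")))),
    "susceptible")
  # doubly negative BAL is susceptible by vacuity
  expect_identical(classify_resistance(bal()), "susceptible")
})

test_that("adding a resistance marker never flips resistant to susceptible", {
  set.seed(11)
  for (i in 1:50) {
    orgs <- sample(panel$organisms, sample(1:2, 1))
    b <- bal(culture = lapply(orgs, cf), pcr = lapply(orgs, pf))
    before <- classify_resistance(b)
    b$pcr[[1]]$genes <- sample(resistance_genes(), 1)
    expect_identical(classify_resistance(b), "resistant")
    expect_false(before == "resistant" &&
                   classify_resistance(b) == "susceptible")
  }
})

test_that("unknown gene and phenotype tokens are rejected", {
  expect_error(bal(pcr = list(pf("escherichia coli", genes = "blaZ"))),
               "unknown resistance gene")
  expect_error(bal(culture = list(cf("escherichia coli", pheno = "VRE"))),
               "unknown resistant phenotype")
})

test_that("the four concordance categories come out as specified", {
  # culture-only, off panel
  call <- classify_concordance(
    bal(culture = list(cf("stenotrophomonas maltophilia"))), panel)
  expect_identical(call$category, "culture_only")
  expect_true(call$off_panel)
  # culture-only, on panel
  call <- classify_concordance(bal(culture = list(cf("escherichia coli"))),
                               panel)
  expect_identical(call$category, "culture_only")
  expect_false(call$off_panel)
  # agreement
  call <- classify_concordance(
    bal(culture = list(cf("streptococcus pneumoniae")),
        pcr = list(pf("streptococcus pneumoniae"))), panel)
  expect_identical(call$category, "agreement")
  expect_false(call$off_panel)
  # pcr-only
  call <- classify_concordance(
    bal(pcr = list(pf("haemophilus influenzae"))), panel)
  expect_identical(call$category, "pcr_only")
  # discordant
  call <- classify_concordance(
    bal(culture = list(cf("escherichia coli")),
        pcr = list(pf("staphylococcus aureus"))), panel)
  expect_identical(call$category, "discordant_both")
})

test_that("gene-phenotype equivalence makes MRSA calls agree across methods", {
  b <- bal(culture = list(cf("staphylococcus aureus", pheno = "MRSA")),
           pcr = list(pf("staphylococcus aureus", genes = c("mecA/C",
                                                            "MREJ"))))
  expect_identical(classify_concordance(b, panel)$category, "agreement")
  # ESBL phenotype vs CTX-M gene
  b <- bal(culture = list(cf("escherichia coli", pheno = "ESBL")),
           pcr = list(pf("escherichia coli", genes = "CTX-M")))
  expect_identical(classify_concordance(b, panel)$category, "agreement")
  # resistance seen by culture only is a culture_only discrepancy, on panel
  b <- bal(culture = list(cf("escherichia coli", pheno = "ESBL")),
           pcr = list(pf("escherichia coli")))
  call <- classify_concordance(b, panel)
  expect_identical(call$category, "culture_only")
  expect_false(call$off_panel)
})

test_that("below-threshold growth and Candida albicans are excluded", {
  b <- bal(culture = list(cf("escherichia coli", qty = 1e3)),
           pcr = list())
  expect_identical(classify_concordance(b, panel)$category, "agreement")
  # unquantified growth counts as significant
  b <- bal(culture = list(cf("escherichia coli", qty = NA)))
  expect_identical(classify_concordance(b, panel)$category, "culture_only")
  b <- bal(culture = list(cf("candida albicans")))
  expect_identical(classify_concordance(b, panel)$category, "agreement")
})

test_that("unpaired samples are rejected by the concordance classifier", {
  b <- bal(culture = list(cf("escherichia coli")), performed = FALSE)
  expect_error(classify_concordance(b, panel), "unpaired")
})

test_that("concordance matches an exhaustive truth-table oracle", {
  set.seed(23)
  pool <- c("staphylococcus aureus", "escherichia coli",
            "stenotrophomonas maltophilia")
  for (i in 1:300) {
    cul_orgs <- sample(pool, sample(0:3, 1))
    pcr_orgs <- sample(setdiff(pool, "stenotrophomonas maltophilia"),
                       sample(0:2, 1))
    culture <- lapply(cul_orgs, function(o) {
      cf(o, qty = sample(c(1e3, 1e5, NA), 1),
         pheno = sample(c("MRSA", "ESBL"), sample(0:1, 1)))
    })
    pcr <- lapply(pcr_orgs, function(o) {
      pf(o, genes = sample(c("mecA/C", "CTX-M"), sample(0:2, 1)))
    })
    b <- bal(culture = culture, pcr = pcr)
    got <- classify_concordance(b, panel)
    want <- oracle_concordance(b, panel$organisms)
    expect_identical(got$category, want$category)
    expect_identical(got$off_panel, want$off_panel)
  }
})

test_that("concordance is invariant under bijective organism relabelling", {
  # swap two on-panel organisms throughout a paired result
  swap <- c("escherichia coli" = "klebsiella pneumoniae group",
            "klebsiella pneumoniae group" = "escherichia coli")
  b1 <- bal(culture = list(cf("escherichia coli")),
            pcr = list(pf("klebsiella pneumoniae group")))
  b2 <- bal(culture = list(cf(unname(swap["escherichia coli"]))),
            pcr = list(pf(unname(swap["klebsiella pneumoniae group"]))))
  expect_identical(classify_concordance(b1, panel)$category,
                   classify_concordance(b2, panel)$category)
})

test_that("concordance summary counts are exhaustive and percentages exact", {
  calls <- c(
    rep(list(structure(list(category = "agreement", off_panel = FALSE),
                       class = "concordance_call")), 390),
    rep(list(structure(list(category = "culture_only", off_panel = TRUE),
                       class = "concordance_call")), 139),
    rep(list(structure(list(category = "culture_only", off_panel = FALSE),
                       class = "concordance_call")), 19),
    rep(list(structure(list(category = "pcr_only", off_panel = FALSE),
                       class = "concordance_call")), 61),
    rep(list(structure(list(category = "discordant_both", off_panel = FALSE),
                       class = "concordance_call")), 26))
  s <- summarize_concordance(calls)
  expect_identical(sum(s$n), 635L)
  expect_identical(s$percent, c(61.4, 24.9, 9.6, 4.1))
  expect_identical(s$n_off_panel[s$category == "culture_only"], 139L)
  # symmetry and single-category edge cases
  one <- summarize_concordance(calls[1:10])
  expect_identical(one$percent, c(100, 0, 0, 0))
  four <- summarize_concordance(calls[c(1, 391, 549, 610)])
  expect_identical(four$percent, rep(25, 4))
  expect_error(summarize_concordance(list()), "no concordance calls")
})

test_that("paired testing rate counts PCR-performed BALs", {
  bals <- c(rep(list(bal()), 3), list(bal(performed = FALSE)))
  r <- paired_testing_rate(bals)
  expect_identical(r$n_paired, 3L)
  expect_identical(r$percent, 75)
  expect_identical(paired_testing_rate(rep(list(bal()), 2))$percent, 100)
  expect_identical(
    paired_testing_rate(rep(list(bal(performed = FALSE)), 2))$percent, 0)
  expect_error(paired_testing_rate(list()), "no BAL")
})

test_that("BAL JSON round-trips without loss", {
  bals <- list(
    bal(culture = list(cf("escherichia coli", pheno = "ESBL"),
                       cf("candida albicans", qty = NA)),
        pcr = list(pf("escherichia coli", genes = "CTX-M"))),
    bal(performed = FALSE))
  path <- tempfile(fileext = ".json")
  write_bal_results(bals, path)
  back <- expect_no_warning(read_bal_results(path))
  expect_identical(back, bals)
})
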