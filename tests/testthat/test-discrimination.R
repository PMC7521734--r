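# Four-level pair classification, panel summaries, identification.

test_that("classify_pair reproduces the published pair calls", {
  fps <- fixture_panel()
  # three bands vs a single band: distinct patterns
  expect_equal(classify_pair(fps[["Basel1"]], fps[["Basel2"]], "ms-c25145"), 1L)
  # amplification in one strain only
  expect_equal(classify_pair(fps[["Hm-105"]], fps[["reg-16"]], "ms-c25145"), 2L)
  # identical two-band patterns
  expect_equal(classify_pair(fps[["AEP1"]], fps[["AEP2"]], "ms-DMTF1"), 3L)
  # absent from both
  expect_equal(classify_pair(fps[["reg-16"]], fps[["Nicolet"]], "ms-c25145"), 4L)
})

test_that("a missing locus is missing data, not level 4", {
  fps <- fixture_panel()
  partial <- structure(list(strain_name = "q",
                            patterns = fps[["AEP1"]]$patterns["ms-AIP"]),
                       class = "strain_fingerprint")
  expect_error(classify_pair(partial, fps[["AEP2"]], "ms-c25145"),
               class = "msb_missing_data_error")
})

test_that("summarize_discrimination reproduces the printed panel statistics", {
  fps <- fixture_panel()
  s <- summarize_discrimination(fps, "ms-c25145")
  expect_equal(s$n_pairs, 36L)
  expect_equal(unname(s$counts), c(15L, 14L, 6L, 1L))
  expect_equal(s$positive, 29L)
  expect_equal(round(s$positive_pct_of_all, 1), 80.6)
  expect_equal(round(unname(s$pct_of_all[c("1", "2")]), 1), c(41.7, 38.9))

  s2 <- summarize_discrimination(fps, "ms-AIP")
  expect_equal(unname(s2$counts), c(12L, 18L, 3L, 3L))
  expect_equal(s2$positive, 30L)
  expect_equal(round(unname(s2$pct_of_positive), 1), c(40, 60))
})

test_that("an all-identical panel has zero positive discrimination", {
  fps <- fixture_panel()
  clones <- list(a = fps[["AEP1"]], b = fps[["AEP1"]], c = fps[["AEP1"]])
  for (n in names(clones)) clones[[n]]$strain_name <- n
  s <- summarize_discrimination(clones, "ms-AIP")
  expect_equal(unname(s$counts), c(0L, 0L, 3L, 0L))
  expect_equal(s$positive, 0L)
  expect_true(is.na(s$pct_of_positive[["1"]]))
})

test_that("combined_matrix derives the best level per pair", {
  fps <- fixture_panel()
  cm <- combined_matrix(fps)
  aep <- cm[cm$strain_a == "AEP1" & cm$strain_b == "AEP2", ]
  expect_equal(aep[["ms-AIP"]], 1L)
  expect_equal(aep[["ms-c25145"]], 3L)
  expect_equal(aep[["ms-DMTF1"]], 3L)
  expect_equal(aep$best, 1L)
  expect_true(aep$resolved)

  ho <- cm[cm$strain_a %in% c("Ho_CS", "Ho_CR") &
             cm$strain_b %in% c("Ho_CS", "Ho_CR"), ]
  expect_equal(ho$best, 3L)
  expect_false(ho$resolved)

  # single-locus combination collapses to the per-locus classification
  cm1 <- combined_matrix(fps, loci = "ms-AIP")
  expect_equal(cm1$best, cm1[["ms-AIP"]])
})

test_that("level counts partition all pairs and are symmetric", {
  fps <- fixture_panel()
  panel_cfg <- read_panel_config(system.file("extdata",
                                             "paper_like_panel.yaml",
                                             package = "msbarcode"))
  sim <- simulate_panel(panel_cfg, seed = 99L)
  sim_fps <- fingerprints_from_table(sim$band_table,
                                     strains = names(panel_cfg$strains))
  for (panel in list(fps, sim_fps)) {
    n <- length(panel)
    for (locus in names(panel[[1L]]$patterns)) {
      s <- summarize_discrimination(panel, locus)
      expect_equal(sum(s$counts), choose(n, 2L))
      expect_equal(s$positive + s$counts[["3"]] + s$counts[["4"]],
                   choose(n, 2L))
      # symmetry on a sample of pairs
      prs <- utils::combn(names(panel), 2L)
      for (j in sample(ncol(prs), 10L)) {
        a <- panel[[prs[1L, j]]]
        b <- panel[[prs[2L, j]]]
        expect_equal(classify_pair(a, b, locus), classify_pair(b, a, locus))
      }
    }
  }
})

test_that("removing a strain leaves remaining pair classifications unchanged", {
  fps <- fixture_panel()
  cm_full <- combined_matrix(fps)
  drop <- "Hm-105"
  cm_sub <- combined_matrix(fps[setdiff(names(fps), drop)])
  merged <- merge(cm_sub, cm_full, by = c("strain_a", "strain_b"),
                  suffixes = c(".sub", ".full"))
  expect_equal(nrow(merged), nrow(cm_sub))
  for (l in names(fps[[1L]]$patterns)) {
    expect_equal(merged[[paste0(l, ".sub")]], merged[[paste0(l, ".full")]])
  }
})

test_that("identify_strain ranks by exact per-locus identity", {
  fps <- fixture_panel()
  hits <- identify_strain(fps[["Basel2"]], fps)
  expect_identical(hits$strain[1L], "Basel2")
  expect_equal(hits$score[1L], 1.0)

  # a query typed at ms-c25145 only ties across the 218 bp class
  q <- structure(list(strain_name = "query",
                      patterns = fps[["AEP1"]]$patterns["ms-c25145"]),
                 class = "strain_fingerprint")
  hits2 <- identify_strain(q, fps)
  top <- hits2[hits2$score == 1, "strain"]
  expect_setequal(top, c("AEP1", "AEP2", "Ho_CS", "Ho_CR"))
  expect_identical(top, sort(top))  # alphabetical tie-break

  # disjoint loci: no evidence at all
  refs <- lapply(fps, function(f) {
    f$patterns <- f$patterns["ms-AIP"]
    f
  })
  expect_error(identify_strain(q, refs), class = "msb_no_evidence_error")
})

test_that("a simulated one-allele mutant identifies its parent below 1", {
  panel_cfg <- read_panel_config(system.file("extdata",
                                             "paper_like_panel.yaml",
                                             package = "msbarcode"))
  sim <- simulate_panel(panel_cfg, stutter = stutter_model(0, 0, 1000, 0),
                        seed = 5L)
  refs <- fingerprints_from_table(sim$band_table,
                                  strains = names(panel_cfg$strains))
  mutant <- refs[["Basel1"]]
  mutant$strain_name <- "mutant"
  # shift one ms-c25145 allele by two repeat units
  mutant$patterns[["ms-c25145"]]$band_classes <-
    mutant$patterns[["ms-c25145"]]$band_classes + c(0L, 4L)
  hits <- identify_strain(mutant, refs)
  expect_identical(hits$strain[1L], "Basel1")
  expect_lt(hits$score[1L], 1.0)
  expect_equal(hits$score[1L], 2 / 3)
})
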