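# Synthetic panel generator: templates, stutter, mosaicism, reproducibility.

synth_fixture_spec <- function(motif = "AT", alleles = list(c(11L, 13L)),
                               intact = TRUE, insert = NULL,
                               apply_deletion = FALSE) {
  pair <- primer_pair("ms-test", "CGAGACAGCGTTTTCAAG", "CCACTCTTCCATTCTAACCA")
  left <- paste0(pair$forward,
                 if (!is.null(insert)) insert else "",
                 "CCATGGTTCAGAGCTACCATGGTTCAGAGC")
  right <- paste0("GCCATGGTTCAGAGCTACCATGG", revcomp(pair$reverse))
  synthetic_locus("ms-test", motif, pair, left, right, alleles,
                  primer_site_intact = intact,
                  fixed_flank_deletion = if (apply_deletion) insert)
}

test_that("build_templates plants the exact ground-truth tracts", {
  spec <- synth_fixture_spec(alleles = list(c(11L, 13L)))
  built <- build_templates(spec, seed = 1L)
  expect_length(built$templates, 2L)
  for (j in seq_len(nrow(built$tracts))) {
    truth <- built$tracts[j, ]
    got <- find_repeats(built$templates[[truth$sequence_id]],
                        truth$sequence_id)
    expect_equal(got, built$tracts[j, ], ignore_attr = TRUE)
  }
  expect_setequal(built$tracts$unit_count, c(11L, 13L))
})

test_that("a duplicated locus yields one template per copy per allele", {
  spec <- synth_fixture_spec(motif = "TG",
                             alleles = list(c(6L, 13L), c(17L, 17L)))
  built <- build_templates(spec, seed = 1L)
  expect_length(built$templates, 4L)
  # three distinct product sizes: 6, 13 and twice 17 units
  expect_length(unique(unname(built$true_sizes)), 3L)
  amp <- amplify_templates(built$templates, spec$primers)
  expect_equal(nrow(amp), 4L)
  expect_setequal(amp$length_bp, unname(built$true_sizes))
})

test_that("a fixed flank deletion shortens every product by its length", {
  del <- "TAGTCAAAGTAGTACA"
  with_del <- build_templates(
    synth_fixture_spec(insert = del, apply_deletion = TRUE), seed = 1L)
  without <- build_templates(synth_fixture_spec(insert = del), seed = 1L)
  expect_equal(unname(without$true_sizes) - unname(with_del$true_sizes),
               rep(nchar(del), 2L))
  expect_error(
    synthetic_locus("x", "AT",
                    primer_pair("x", "CGAGACAGCGTTTTCAAG",
                                "CCACTCTTCCATTCTAACCA"),
                    paste0("CGAGACAGCGTTTTCAAG", "CCATGGTTCC"),
                    paste0("GCCATG", revcomp("CCACTCTTCCATTCTAACCA")),
                    list(10L), fixed_flank_deletion = "TAGTCAAAGTAGTACA"),
    class = "msb_spec_error")
})

test_that("disrupted primer sites abolish amplification", {
  spec <- synth_fixture_spec(intact = FALSE)
  built <- build_templates(spec, seed = 3L)
  amp <- amplify_templates(built$templates, spec$primers)
  expect_equal(nrow(amp), 0L)
})

test_that("zero stutter gives exactly one full-intensity band per size", {
  spec <- synth_fixture_spec(alleles = list(c(13L, 13L)))
  built <- build_templates(spec, seed = 1L)
  b <- simulate_bands(built$templates, spec$primers, spec$motif,
                      stutter_model(0, 0, 1000, 0), seed = 1L)
  expect_equal(nrow(b), 1L)
  expect_equal(b$size_bp, unname(built$true_sizes)[1L])
  expect_equal(b$intensity, 1)
})

test_that("stutter produces minor satellite bands one unit away", {
  spec <- synth_fixture_spec(motif = "TG", alleles = list(c(14L, 14L)))
  built <- build_templates(spec, seed = 1L)
  true_size <- unname(built$true_sizes)[1L]
  b <- simulate_bands(built$templates, spec$primers, spec$motif,
                      stutter_model(0.1, 0.05, 1000, 0), seed = 7L)
  expect_equal(b$size_bp[which.max(b$intensity)], true_size)
  minor <- b[b$size_bp != true_size, ]
  expect_true(all(minor$size_bp %in% (true_size + c(-2L, 2L))))
  expect_true(all(minor$intensity < 0.2))
  # binomial expectation: the n-1 band carries ~10% of molecules
  n_minus <- minor[minor$size_bp == true_size - 2L, ]
  expect_equal(nrow(n_minus), 1L)
  expect_gt(n_minus$intensity, 0.05)
})

test_that("every stuttered size differs from a true size by whole units", {
  spec <- synth_fixture_spec(motif = "TG",
                             alleles = list(c(6L, 13L), c(17L, 17L)))
  built <- build_templates(spec, seed = 2L)
  for (seed in 1:5) {
    b <- simulate_bands(built$templates, spec$primers, spec$motif,
                        stutter_model(0.15, 0.1, 500, 0), seed = seed)
    diffs <- outer(b$size_bp, unname(built$true_sizes), "-")
    expect_true(all(apply(diffs %% 2L == 0L, 1L, any)))
    expect_true(all(apply(abs(diffs) <= 4L, 1L, any)))
  }
})

test_that("a forced mosaic allele appears as one faint extra band", {
  spec <- synth_fixture_spec(alleles = list(c(13L, 13L)))
  built <- build_templates(spec, seed = 1L)
  b <- simulate_bands(built$templates, spec$primers, spec$motif,
                      stutter_model(0, 0, 1000, mosaic_allele_rate = 1),
                      seed = 11L)
  faint <- b[b$flags == "faint", ]
  expect_equal(nrow(faint), 1L)
  expect_true(faint$size_bp %in% (unname(built$true_sizes)[1L] + c(-4L, 4L)))
  expect_lte(faint$intensity, 0.2)
})

test_that("simulate_panel is byte-identical under a fixed seed", {
  panel <- read_panel_config(system.file("extdata", "paper_like_panel.yaml",
                                         package = "msbarcode"))
  sim1 <- simulate_panel(panel, seed = 17L)
  sim2 <- simulate_panel(panel, seed = 17L)
  expect_identical(sim1, sim2)
  f1 <- tempfile(); f2 <- tempfile()
  write_band_table(sim1$band_table, f1)
  write_band_table(sim2$band_table, f2)
  expect_identical(readLines(f1), readLines(f2))
  sim3 <- simulate_panel(panel, seed = 18L)
  expect_false(identical(sim1$band_table, sim3$band_table))
})

test_that("with zero stutter the pipeline recovers the ground truth exactly", {
  panel <- read_panel_config(system.file("extdata", "paper_like_panel.yaml",
                                         package = "msbarcode"))
  sim <- simulate_panel(panel, stutter = stutter_model(0, 0, 1000, 0),
                        seed = 23L)
  fps <- fingerprints_from_table(sim$band_table,
                                 strains = names(panel$strains))
  for (s in names(fps)) {
    for (l in names(panel$primers)) {
      expect_true(patterns_equal(fps[[s]]$patterns[[l]],
                                 sim$truth[[s]]$patterns[[l]]),
                  info = paste(s, l))
    }
  }
})

test_that("modal recovery degrades monotonically with total stutter", {
  panel <- read_panel_config(system.file("extdata", "paper_like_panel.yaml",
                                         package = "msbarcode"))
  recovery <- function(p_total, seed) {
    st <- stutter_model(p_total * 2 / 3, p_total / 3, 60L, 0)
    sim <- simulate_panel(panel, stutter = st, seed = seed)
    fps <- fingerprints_from_table(sim$band_table,
                                   strains = names(panel$strains))
    ts <- sim$true_sizes
    hits <- vapply(seq_len(nrow(ts)), function(j) {
      pat <- fps[[ts$strain[j]]]$patterns[[ts$locus[j]]]
      pat$state == "amplified" && ts$size_bp[j] %in% pat$band_classes
    }, logical(1))
    mean(hits)
  }
  # averaged over seeds, more stutter can only hurt modal-band recovery
  rates <- vapply(c(0, 0.3, 0.6), function(p) {
    mean(vapply(1:4, function(s) recovery(p, s), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(rates) <= 0.02 + 1e-9))
  expect_equal(rates[1L], 1)
})
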