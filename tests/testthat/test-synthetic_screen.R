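test_that("default spectra reflect the mutagens' chemistry", {
  ems <- default_spectrum("EMS")
  expect_identical(names(which.max(ems)), "G:C>A:T")
  enu <- default_spectrum("ENU")
  expect_gt(enu[["A:T>T:A"]], 0)
  expect_gt(enu[["A:T>G:C"]], 0)
  expect_identical(names(which.max(enu)), "A:T>T:A")
  for (m in c("EMS", "ENU", "EMS+ENU"))
    expect_equal(sum(default_spectrum(m)), 1, tolerance = 1e-12)
  expect_error(default_spectrum("UV"), "unknown mutagen")
  # config override replaces the weights wholesale
  w <- setNames(c(1, 0, 0, 0, 0, 0), SUBSTITUTION_CLASSES)
  expect_equal(as.numeric(default_spectrum("EMS", weights = w)),
               as.numeric(w))
  expect_error(mutagen_spectrum(setNames(rep(0.2, 6),
                                         SUBSTITUTION_CLASSES)),
               "sum to 1")
})

test_that("simulated genomes are seed-deterministic with binomial GC", {
  a <- simulate_genome(c(x = 1000), 0.36, seed = 7)
  b <- simulate_genome(c(x = 1000), 0.36, seed = 7)
  expect_identical(unclass(a), unclass(b))
  g <- simulate_genome(c(x = 100000), 0.36, seed = 2)
  gc <- sum(strsplit(unclass(g)[["x"]], "")[[1]] %in% c("G", "C"))
  sd3 <- 3 * sqrt(100000 * 0.36 * 0.64)
  expect_lt(abs(gc - 36000), sd3)
  expect_error(simulate_genome(c(x = 0), 0.36), ">= 1")
  expect_error(simulate_genome(c(x = 10), 1.2), "inside \\(0, 1\\)")
})

test_that("the fixture satisfies every documented genomic/cDNA pair", {
  f <- fx()
  pairs <- rbind(
    c(5650846, 937), c(5650847, 938), c(5650939, 947), c(5650947, 955),
    c(5650948, 956), c(5651073, 1081), c(5651146, 1154),
    c(5651219, 1227), c(5651252, 1260), c(5651254, 1262),
    c(5653611, 1597))
  for (i in seq_len(nrow(pairs))) {
    cc <- genomic_to_cdna(f$transcript, pairs[i, 1])
    expect_identical(cc$kind, "CODING")
    expect_identical(cc$coding_position, as.integer(pairs[i, 2]))
  }
  expect_identical(genomic_to_cdna(f$transcript, 5649770)$coding_position,
                   -4L)
  expect_identical(genomic_to_cdna(f$transcript, 5649756)$coding_position,
                   -18L)
  # c.1 sits at g5,649,774 and the primary lesion at c.1325 (codon 442)
  expect_identical(genomic_to_cdna(f$transcript, 5649774)$coding_position,
                   1L)
  cc <- genomic_to_cdna(f$transcript, f$primary$position)
  expect_identical(cc$coding_position, 1325L)
  expect_identical(codon_arithmetic(1325)$codon_index, 442L)
  expect_identical(genome_base(f$genome, "II", f$primary$position), "C")
})

test_that("strain simulation honours truth labels and the plan", {
  f <- fx()
  txs <- list(f$transcript)
  si <- build_site_index(txs, f$genome)
  sp <- default_spectrum("ENU")
  plan0 <- screen_plan(mutation_load_mean = 0, seed = 3)
  st <- simulate_strain(f$genome, txs, f$primary, sp, plan0,
                        "EXTRAGENIC_SUPPRESSOR", "Z1", site_index = si)
  expect_identical(nrow(st$calls), 1L)
  expect_identical(st$calls$position, f$primary$position)
  expect_identical(st$calls$alt_base, f$primary$mutant_base)

  plan <- screen_plan(mutation_load_mean = 40, seed = 3)
  cont <- simulate_strain(f$genome, txs, f$primary, sp, plan,
                          "CONTAMINATION", "Z2", site_index = si)
  expect_false(any(cont$calls$position == f$primary$position &
                     cont$calls$alt_base == f$primary$mutant_base))
  expect_lte(nrow(cont$calls), 3L)

  rev <- simulate_strain(f$genome, txs, f$primary, sp, plan,
                         "REVERTANT", "Z3", site_index = si)
  expect_false(any(rev$calls$position == f$primary$position))
  expect_gt(nrow(rev$calls), 10)

  intra <- simulate_strain(f$genome, txs, f$primary, sp, plan,
                           "INTRAGENIC_SUPPRESSOR", "Z4", site_index = si)
  span <- c(min(f$transcript$exons), max(f$transcript$exons))
  pv <- intra$planted_variant
  expect_false(is.null(pv))
  expect_true(pv$position >= span[1] && pv$position <= span[2])
  expect_true(any(intra$calls$position == f$primary$position))
  # depth/AF emulate a homozygous call profile
  expect_true(all(intra$calls$read_depth >= 1))
  expect_gt(mean(intra$calls$allele_fraction), 0.9)
})

test_that("identical plan and seed give identical emitted VCFs", {
  f <- fx()
  txs <- list(f$transcript)
  si <- build_site_index(txs, f$genome)
  plan <- screen_plan(mutation_load_mean = 30, seed = 12)
  sp <- default_spectrum("EMS")
  p1 <- withr::local_tempfile(fileext = ".vcf")
  p2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(simulate_strain(f$genome, txs, f$primary, sp, plan,
                            "REVERTANT", "R", site_index = si)$calls, p1)
  write_vcf(simulate_strain(f$genome, txs, f$primary, sp, plan,
                            "REVERTANT", "R", site_index = si)$calls, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("sampled substitution classes follow the configured spectrum", {
  sp <- default_spectrum("ENU")
  cls <- withr::with_seed(91, draw_substitution_classes(sp, 20000))
  obs <- table(factor(cls, levels = SUBSTITUTION_CLASSES))
  expected <- as.numeric(sp) * 20000
  chisq <- sum((obs - expected)^2 / expected)
  p <- pchisq(chisq, df = 5, lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("placed background substitutions match the spectrum too", {
  f <- fx()
  si <- build_site_index(list(f$transcript), f$genome)
  plan <- screen_plan(mutation_load_mean = 400, seed = 5)
  sp <- default_spectrum("ENU")
  st <- simulate_strain(f$genome, list(f$transcript), f$primary, sp, plan,
                        "REVERTANT", "SPEC", site_index = si)
  gof <- spectrum_consistency(st$calls, sp)
  expect_identical(gof$consistent_fraction, 1)
  expect_gt(gof$p_value, 0.01)
})

test_that("phenotype simulation respects degenerate suppression strengths", {
  ph1 <- simulate_phenotype(1, n_plates = 4, seed = 2, strain_id = "full")
  rates <- vapply(split(ph1$hatch, ph1$hatch$plate_id), hatching_rate,
                  numeric(1))
  expect_true(all(rates == 100))

  ph0 <- simulate_phenotype(0, n_plates = 4, seed = 2, strain_id = "none")
  ev <- do.call(rbind, lapply(split(ph0$population, ph0$population$plate_id),
                              population_events))
  expect_true(all(ev$observed[ev$metric == "death"]))
  expect_false(any(ev$observed[ev$metric == "reach_viable"]))
  expect_false(any(ev$observed[ev$metric == "reach_l4"]))
  expect_error(simulate_phenotype(1.4, 2), "\\[0, 1\\]")
})

test_that("mean hatching rate converges to the suppression strength", {
  ph <- simulate_phenotype(0.6, n_plates = 200, seed = 8, strain_id = "mid")
  pooled <- sum(ph$hatch$hatched) / sum(ph$hatch$eggs_laid)
  n_eggs <- sum(ph$hatch$eggs_laid)
  half <- qnorm(0.995) * sqrt(0.6 * 0.4 / n_eggs)
  expect_lt(abs(pooled - 0.6), half)
})

test_that("decoy transcripts are valid and seed-stable", {
  g <- simulate_genome(c(I = 60000), 0.36, seed = 5)
  a <- simulate_transcripts(g, n_genes = 10, seed = 2)
  b <- simulate_transcripts(g, n_genes = 10, seed = 2)
  expect_identical(a, b)
  expect_gt(length(a), 0)
  for (tx in a) expect_s3_class(tx, "TranscriptModel")
  expect_true(any(vapply(a, `[[`, "", "strand") == "-"))
})
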