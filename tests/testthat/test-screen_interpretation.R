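test_that("substitutions classify into transition/transversion and class", {
  cs <- classify_substitution("C", "T")
  expect_identical(cs$type, "transition")
  expect_identical(cs$class, "G:C>A:T")
  tv <- classify_substitution("T", "G")
  expect_identical(tv$type, "transversion")
  expect_identical(tv$class, "A:T>C:G")
  tr <- classify_substitution("A", "G")
  expect_identical(tr$type, "transition")
  expect_identical(tr$class, "A:T>G:C")
  expect_error(classify_substitution("A", "A"), "identical")
})

test_that("complementary substitutions always share a collapsed class", {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (ref in c("A", "C", "G", "T")) {
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      a <- classify_substitution(ref, alt)
      b <- classify_substitution(unname(comp[ref]), unname(comp[alt]))
      expect_identical(a$class, b$class, info = paste(ref, alt))
      expect_identical(a$type, b$type)
    }
  }
})

test_that("spectrum consistency separates matching and impossible calls", {
  one <- mutagen_spectrum(setNames(c(1, 0, 0, 0, 0, 0),
                                   SUBSTITUTION_CLASSES))
  gc_at <- variant_calls(rep("S", 4), rep("I", 4), 1:4,
                         c("C", "G", "C", "G"), c("T", "A", "T", "A"),
                         30, 1)
  r <- spectrum_consistency(gc_at, one)
  expect_identical(r$consistent_fraction, 1)
  # calls entirely in a zero-weight class
  at_ta <- variant_calls(rep("S", 3), rep("I", 3), 1:3,
                         c("A", "T", "A"), c("T", "A", "T"), 30, 1)
  r0 <- spectrum_consistency(at_ta, one)
  expect_identical(r0$consistent_fraction, 0)
  expect_identical(r0$p_value, 0)
  expect_error(spectrum_consistency(variant_calls(), one),
               "at least one call")
})

test_that("simulated spectrum-drawn calls are not rejected by the fit", {
  f <- fx()
  sp <- default_spectrum("ENU")
  si <- build_site_index(list(f$transcript), f$genome)
  plan <- screen_plan(mutation_load_mean = 1000, seed = 6)
  st <- simulate_strain(f$genome, list(f$transcript), f$primary, sp, plan,
                        "REVERTANT", "GOF", site_index = si)
  r <- spectrum_consistency(st$calls, sp)
  expect_identical(r$consistent_fraction, 1)
  expect_gt(r$p_value, 0.01)
})

test_that("revertant validation applies both thresholds", {
  f <- fx()
  txs <- list(f$transcript)
  si <- build_site_index(txs, f$genome)
  cfg <- filter_config()
  sp <- default_spectrum("EMS+ENU")

  # ~70 spectrum-drawn background variants: a true revertant
  plan <- screen_plan(mutation_load_mean = 70, seed = 8,
                      depth_mean = 40, af_homozygous_concentration = 200)
  st <- simulate_strain(f$genome, txs, f$primary, sp, plan, "REVERTANT",
                        "RV", site_index = si)
  fr <- apply_filters(st$calls, variant_calls(), txs, cfg, f$primary)
  v <- validate_revertant(fr, f$primary, sp)
  expect_identical(v$status, "TRUE_REVERTANT")
  expect_gte(v$background_load, 20)
  expect_identical(v$spectrum_consistent_fraction, 1)

  # reverted with no background at all: suspected contamination
  empty <- apply_filters(variant_calls(), variant_calls(), txs, cfg,
                         f$primary)
  expect_identical(empty$retention_status, "REVERTED")
  v0 <- validate_revertant(empty, f$primary, sp)
  expect_identical(v0$status, "SUSPECTED_CONTAMINATION")

  # ample load but half the calls in a zero-weight class: ambiguous
  one <- mutagen_spectrum(setNames(c(1, 0, 0, 0, 0, 0),
                                   SUBSTITUTION_CLASSES))
  n <- 70
  mixed <- variant_calls(rep("S", n), rep("II", n),
                         seq(5650450, by = 2, length.out = n),
                         rep(c("C", "A"), n / 2), rep(c("T", "T"), n / 2),
                         30, 1)
  fr_mixed <- structure(list(passing = mixed, retention_status = "REVERTED"),
                        class = "FilterResult")
  vm <- validate_revertant(fr_mixed, f$primary, one)
  expect_identical(vm$status, "AMBIGUOUS")
  expect_equal(vm$spectrum_consistent_fraction, 0.5)

  # calling it on a retained strain is a usage error
  retained <- structure(list(passing = mixed,
                             retention_status = "RETAINED"),
                        class = "FilterResult")
  expect_error(validate_revertant(retained, f$primary, sp), "REVERTED")
})

test_that("revertant verdict is monotone in load and fraction", {
  f <- fx()
  one <- mutagen_spectrum(setNames(c(1, 0, 0, 0, 0, 0),
                                   SUBSTITUTION_CLASSES))
  mk <- function(n_match, n_off) {
    n <- n_match + n_off
    if (n == 0) return(variant_calls())
    variant_calls(rep("S", n), rep("II", n),
                  seq(5650450, by = 2, length.out = n),
                  c(rep("C", n_match), rep("A", n_off)),
                  rep("T", n), 30, 1)
  }
  status_rank <- c(SUSPECTED_CONTAMINATION = 0, AMBIGUOUS = 1,
                   TRUE_REVERTANT = 2)
  prev <- -1
  for (load in c(0, 10, 25, 60)) {
    frl <- structure(list(passing = mk(load, 0),
                          retention_status = "REVERTED"),
                     class = "FilterResult")
    v <- validate_revertant(frl, f$primary, one)
    expect_gte(status_rank[[v$status]], prev)
    prev <- status_rank[[v$status]]
  }
})

test_that("recurrence grouping matches the documented intragenic set", {
  ann <- golden_annotations()
  rec <- recurrence_report(ann)
  expect_setequal(rec$by_position[["II:5651146:C:T"]],
                  c("MTG57", "MTG309", "MTG406"))
  expect_setequal(rec$by_position[["II:5651254:G:A"]],
                  c("MTG308", "MTG355"))
  # two positions hit by >= 2 strains
  expect_identical(rec$multi_hit_positions, 2L)
  # codon 313 carries two distinct changes from two strains
  d313 <- rec$by_codon[["zyg-1-like:313"]]
  expect_setequal(d313, c("MTG354:D313A", "MTG437:D313N"))
  # multi-strain codons: 313 (D313A/N), 319 (S319A/F), 385, 421
  expect_identical(rec$multi_hit_codons, 4L)
})

test_that("recurrence grouping equals brute-force pairwise comparison", {
  ann <- golden_annotations()
  rec <- recurrence_report(ann)
  key <- paste(ann$chromosome, ann$position, ann$ref_base, ann$alt_base,
               sep = ":")
  # brute force: for every pair of rows sharing a key, both strains must
  # be listed under that key
  for (i in seq_along(key)) {
    for (j in seq_along(key)) {
      if (i < j && key[i] == key[j]) {
        expect_true(all(c(ann$strain_id[i], ann$strain_id[j]) %in%
                          rec$by_position[[key[i]]]))
      }
    }
  }
  n_multi <- sum(vapply(split(ann$strain_id, key),
                        function(s) length(unique(s)) >= 2, logical(1)))
  expect_identical(rec$multi_hit_positions, n_multi)
  single <- recurrence_report(ann[ann$strain_id == "MTG57", ])
  expect_identical(single$multi_hit_positions, 0L)
})

test_that("prior-screen overlap counts shared position keys", {
  ann <- golden_annotations()
  prior <- data.frame(position_key = c("II:5651146:C:T", "II:1:A:T"),
                      label = c("known", "elsewhere"),
                      stringsAsFactors = FALSE)
  rec <- recurrence_report(ann, prior_sites = prior)
  expect_identical(rec$prior_overlap, 1L)
})

test_that("saturation signals summarise recurrence and reversion", {
  ann <- golden_annotations()
  s <- saturation_signals(recurrence_report(ann),
                          revertant_observed = TRUE)
  expect_true(s$revertant_observed)
  expect_true(s$position_recurrence)
  expect_true(s$codon_recurrence)
  expect_match(s$summary, "3/3")

  none <- saturation_signals(recurrence_report(ann[0, ]))
  expect_false(none$revertant_observed)
  expect_false(none$position_recurrence)
  expect_false(none$codon_recurrence)

  # codon-level recurrence only: same codon, different positions
  f <- fx()
  a <- rbind(
    annotate_variant(f$transcript, f$genome,
                     variant_calls("A1", "II", 5650846, "G", "A", 30, 1)),
    annotate_variant(f$transcript, f$genome,
                     variant_calls("A2", "II", 5650847, "A", "C", 30, 1)))
  s2 <- saturation_signals(recurrence_report(a))
  expect_false(s2$position_recurrence)
  expect_true(s2$codon_recurrence)
})
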