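test_that("genomic/cDNA mapping handles all coordinate kinds", {
  f <- fx()
  tx <- f$transcript
  expect_identical(genomic_to_cdna(tx, 5651146)$coding_position, 1154L)
  expect_identical(genomic_to_cdna(tx, 5649756)$coding_position, -18L)
  u <- genomic_to_cdna(tx, 5649756)
  expect_identical(u$kind, "UTR5")
  # intronic: 3 nt into the 83-nt intron after c.942
  ic <- genomic_to_cdna(tx, 5650854)
  expect_identical(ic$kind, "INTRONIC")
  expect_identical(ic$intron_anchor$anchor, 942L)
  expect_identical(ic$intron_anchor$offset, 3L)
  # near the acceptor: negative offset from the next exonic base
  ia <- genomic_to_cdna(tx, 5650933)
  expect_identical(ia$intron_anchor$anchor, 943L)
  expect_identical(ia$intron_anchor$offset, -2L)
  expect_identical(genomic_to_cdna(tx, 5654285)$kind, "UTR3")
  expect_error(genomic_to_cdna(tx, 5649600), "off transcript")
})

test_that("cDNA mapping round-trips on random exonic positions", {
  g <- simulate_genome(c(I = 50000), 0.4, seed = 14)
  txs <- c(simulate_transcripts(g, n_genes = 8, seed = 15),
           list(fx()$transcript))
  withr::with_seed(16, {
    for (tx in txs) {
      exonic <- unlist(lapply(seq_len(nrow(tx$exons)), function(i)
        seq.int(tx$exons[i, 1], tx$exons[i, 2])))
      for (g_pos in sample(exonic, 40)) {
        cc <- genomic_to_cdna(tx, g_pos)
        expect_identical(cdna_to_genomic(tx, cc), g_pos,
                         info = paste(tx$transcript_id, g_pos))
      }
    }
  })
})

test_that("codon arithmetic is ceiling-based with offsets in 1..3", {
  expect_identical(codon_arithmetic(1154),
                   data.frame(codon_index = 385L, codon_offset = 2L))
  expect_identical(codon_arithmetic(1597)$codon_index, 533L)
  expect_identical(codon_arithmetic(1262)$codon_index, 421L)
  expect_identical(codon_arithmetic(1)$codon_index, 1L)
  expect_identical(codon_arithmetic(1)$codon_offset, 1L)
  expect_identical(codon_arithmetic(3)$codon_index, 1L)
  expect_identical(codon_arithmetic(3)$codon_offset, 3L)
  ca <- codon_arithmetic(1:300)
  expect_true(all(ca$codon_offset %in% 1:3))
  expect_identical(ca$codon_index, as.integer(ceiling((1:300) / 3)))
  expect_error(codon_arithmetic(0), "positive")
})

test_that("the golden substitution suite reproduces every printed string", {
  f <- fx()
  gv <- golden_variants()
  for (i in seq_len(nrow(gv))) {
    v <- variant_calls(gv$strain[i], "II", gv$position[i], gv$ref[i],
                       gv$alt[i], 30L, 1)
    ann <- annotate_variant(f$transcript, f$genome, v)
    expect_identical(ann$c_hgvs, gv$c_expected[i],
                     info = paste(gv$strain[i], gv$position[i]))
    if (gv$p_expected[i] != ".")
      expect_identical(ann$p_hgvs, gv$p_expected[i],
                       info = paste(gv$strain[i], gv$position[i]))
    else
      expect_identical(ann$effect_class, "UTR5_VARIANT")
  }
})

test_that("annotation rejects calls disagreeing with the reference", {
  f <- fx()
  v <- variant_calls("BAD1", "II", 5651146, "A", "G", 30, 1)
  expect_error(annotate_variant(f$transcript, f$genome, v),
               "BAD1.*II:5651146")
})

test_that("codon-local annotation equals whole-CDS retranslation", {
  g <- simulate_genome(c(I = 80000), 0.42, seed = 8)
  txs <- simulate_transcripts(g, n_genes = 12, seed = 9)
  withr::with_seed(31, {
    for (rep in 1:400) {
      tx <- txs[[sample.int(length(txs), 1)]]
      b <- modscreen:::cds_spliced_bounds(tx)
      cp <- sample.int(b[["end"]] - b[["start"]] + 1L, 1)
      gpos <- cdna_to_genomic(tx, cp, "CODING")
      ref <- genome_base(g, tx$chromosome, gpos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      v <- variant_calls("S", tx$chromosome, gpos, ref, alt, 30, 1)
      ann <- annotate_variant(tx, g, v)
      oracle <- oracle_coding_effect(tx, g, gpos, alt)
      expect_identical(ann$coding_position, cp)
      if (oracle$synonymous) {
        expect_identical(ann$effect_class, "SYNONYMOUS")
      } else {
        expect_identical(ann$codon_index, oracle$codon)
        expect_identical(ann$ref_aa, oracle$ref_aa)
        expect_identical(ann$alt_aa, oracle$alt_aa)
      }
    }
  })
})

test_that("mirrored minus-strand transcripts annotate identically", {
  g <- simulate_genome(c(M = 2000), 0.45, seed = 33)
  L <- 2000L
  tx <- TranscriptModel("mir", "mir.t1", "M", "+",
                        exons = rbind(c(101L, 400L), c(501L, 800L)),
                        cds_start_g = 151L, cds_end_g = 751L)
  # reverse-complement the chromosome and mirror all coordinates
  seq_rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(unclass(g)[["M"]])))
  g_rc <- Genome(c(M = seq_rc))
  mirror <- function(p) L - p + 1L
  tx_rc <- TranscriptModel("mir", "mir.t1rc", "M", "-",
                           exons = rbind(c(mirror(800L), mirror(501L)),
                                         c(mirror(400L), mirror(101L))),
                           cds_start_g = mirror(751L),
                           cds_end_g = mirror(151L))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  withr::with_seed(34, {
    exonic <- c(151:400, 501:751)
    for (gpos in sample(exonic, 60)) {
      ref <- genome_base(g, "M", gpos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      a_plus <- annotate_variant(tx, g, variant_calls("S", "M", gpos,
                                                      ref, alt, 30, 1))
      a_minus <- annotate_variant(
        tx_rc, g_rc,
        variant_calls("S", "M", mirror(gpos), unname(comp[ref]),
                      unname(comp[alt]), 30, 1))
      expect_identical(a_minus$coding_position, a_plus$coding_position)
      expect_identical(a_minus$p_hgvs, a_plus$p_hgvs)
      expect_identical(a_minus$c_hgvs, a_plus$c_hgvs)
      expect_identical(a_minus$effect_class, a_plus$effect_class)
    }
  })
})

test_that("complex alleles join protein tokens sorted by codon", {
  f <- fx()
  mk <- function(strain, positions, refs, alts) {
    do.call(rbind, lapply(seq_along(positions), function(i)
      annotate_variant(f$transcript, f$genome,
                       variant_calls(strain, "II", positions[i], refs[i],
                                     alts[i], 30, 1))))
  }
  two <- mk("MTG192", c(5650939, 5650947), c("C", "T"), c("A", "G"))
  expect_identical(unname(group_complex_alleles(two)["zyg-1-like"]),
                   "P316H;S319A")
  one <- mk("MTG57", 5651146, "C", "T")
  expect_identical(unname(group_complex_alleles(one)["zyg-1-like"]),
                   "A385V")
  # sorted by codon even when given in reverse order
  rev2 <- mk("MTG320", c(5651252, 5651219), c("T", "T"), c("A", "C"))
  expect_identical(unname(group_complex_alleles(rev2)["zyg-1-like"]),
                   "H409=;N420K")
  expect_length(group_complex_alleles(annotate_variant(
    f$transcript, f$genome,
    variant_calls("X", "II", 5651146, "C", "T", 30, 1))[0, ]), 0)
})

test_that("burden percentages round half-up to two decimals", {
  b <- burden_percentages(188, 5, 4)
  expect_identical(b$pct_nonsense, 2.66)
  expect_identical(b$pct_splice, 2.13)
  b2 <- burden_percentages(70, 1, 2)
  expect_identical(b2$pct_nonsense, 1.43)
  expect_identical(b2$pct_splice, 2.86)
  b0 <- burden_percentages(0, 0, 0)
  expect_true(is.na(b0$pct_nonsense))
  expect_identical(b0$n_total, 0L)
})

test_that("burden summary counts effect classes from annotations", {
  f <- fx()
  # force a nonsense change: codon 533 is AAA (K); c.1597 A>T gives TAA
  v <- variant_calls("B", "II", 5653611, "A", "T", 30, 1)
  ann <- rbind(annotate_variant(f$transcript, f$genome, v),
               annotate_variant(f$transcript, f$genome,
                                variant_calls("B", "II", 5651146, "C",
                                              "T", 30, 1)))
  expect_identical(ann$effect_class[1], "NONSENSE")
  expect_identical(ann$p_hgvs[1], "p.K533*")
  b <- burden_summary(ann)
  expect_identical(b$n_total, 2L)
  expect_identical(b$n_nonsense, 1L)
  expect_identical(b$pct_nonsense, 50)
})
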