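# Shared fixtures and independent oracles.  The oracles deliberately
# re-derive results through a different route than the implementation
# (interval enumeration, whole-CDS retranslation, explicit risk sets).

.fixture_cache <- new.env(parent = emptyenv())

# memoised zyg-1-like fixture (deterministic, so sharing is safe)
fx <- function() {
  if (is.null(.fixture_cache$fx))
    .fixture_cache$fx <- build_fixture_transcript()
  .fixture_cache$fx
}

# small plus-strand toy transcript: exon 101-160, CDS 111-140 (30 nt)
toy_transcript <- function() {
  TranscriptModel("toyg", "toyg.t1", "chrT", "+",
                  exons = rbind(c(101L, 160L)),
                  cds_start_g = 111L, cds_end_g = 140L)
}

# two-exon toy with an intron 131-210 and CDS split across exons
toy_two_exon <- function() {
  TranscriptModel("toy2", "toy2.t1", "chrT", "+",
                  exons = rbind(c(101L, 130L), c(211L, 250L)),
                  cds_start_g = 111L, cds_end_g = 241L)
}

# the documented intragenic substitution set: 16 substitutions across
# 14 strains (two strains carry two variants each), with the expected
# whitespace-normalised c./p. strings
golden_variants <- function() {
  read.table(header = TRUE, stringsAsFactors = FALSE, text = "
strain    position ref alt c_expected  p_expected
MTG57    5651146  C   T   c.1154C>T   p.A385V
MTG192   5650939  C   A   c.947C>A    p.P316H
MTG192   5650947  T   G   c.955T>G    p.S319A
MTG308   5651254  G   A   c.1262G>A   p.G421E
MTG309   5651146  C   T   c.1154C>T   p.A385V
MTG315   5649756  G   A   c.-18G>A    .
MTG320   5651219  T   C   c.1227T>C   p.H409=
MTG320   5651252  T   A   c.1260T>A   p.N420K
MTG329   5653611  A   G   c.1597A>G   p.K533E
MTG354   5650847  A   C   c.938A>C    p.D313A
MTG355   5651254  G   A   c.1262G>A   p.G421E
MTG398   5649770  T   A   c.-4T>A     .
MTG406   5651146  C   T   c.1154C>T   p.A385V
MTG423   5651073  G   A   c.1081G>A   p.E361K
MTG426   5650948  C   T   c.956C>T    p.S319F
MTG437   5650846  G   A   c.937G>A    p.D313N
")
}

# annotate the golden set against the fixture, one row per substitution
golden_annotations <- function() {
  f <- fx()
  g <- golden_variants()
  do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
    v <- variant_calls(g$strain[i], "II", g$position[i], g$ref[i],
                       g$alt[i], 30L, 1)
    annotate_variant(f$transcript, f$genome, v)
  }))
}

# ---------------------------------------------------------------------
# independent region classification by interval enumeration

oracle_region <- function(transcripts, chrom, pos, w = 10L) {
  pr <- c(CODING = 1, SPLICE_PROX = 2, UTR5 = 3, UTR3 = 4,
          INTRONIC = 5, INTERGENIC = 6)
  best <- "INTERGENIC"
  for (tx in transcripts) {
    if (tx$chromosome != chrom) next
    ex <- tx$exons
    if (pos < min(ex) || pos > max(ex)) next
    exonic <- any(pos >= ex[, 1] & pos <= ex[, 2])
    coding <- exonic && pos >= tx$cds_start_g && pos <= tx$cds_end_g
    near <- FALSE
    if (nrow(ex) > 1 && w > 0) {
      for (k in seq_len(nrow(ex) - 1)) {
        is <- ex[k, 2] + 1L; ie <- ex[k + 1, 1] - 1L
        win <- c(seq.int(is - w, is + w - 1L), seq.int(ie - w + 1L, ie + w))
        if (pos %in% win) near <- TRUE
      }
    }
    cls <- if (coding) "CODING"
    else if (near) "SPLICE_PROX"
    else if (exonic) {
      if (tx$strand == "+") {
        if (pos < tx$cds_start_g) "UTR5" else "UTR3"
      } else {
        if (pos > tx$cds_end_g) "UTR5" else "UTR3"
      }
    } else "INTRONIC"
    if (pr[cls] < pr[best]) best <- cls
  }
  best
}

# independent filter: direct conjunction of the four predicates with
# first-fail tallying
oracle_filter <- function(calls, parental, transcripts, cfg) {
  pk <- if (nrow(parental))
    paste(parental$chromosome, parental$position, parental$ref_base,
          parental$alt_base)
  else character(0)
  ok_regions <- c("CODING", "SPLICE_PROX",
                  if (cfg$include_utr) c("UTR5", "UTR3"))
  tally <- c(depth = 0L, allele_fraction = 0L, region = 0L, de_novo = 0L)
  keep <- logical(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    reg <- oracle_region(transcripts, calls$chromosome[i],
                         calls$position[i], cfg$splice_window_nt)
    if (!(calls$read_depth[i] > cfg$min_depth_exclusive))
      tally["depth"] <- tally["depth"] + 1L
    else if (!(calls$allele_fraction[i] > cfg$min_af_exclusive))
      tally["allele_fraction"] <- tally["allele_fraction"] + 1L
    else if (!reg %in% ok_regions)
      tally["region"] <- tally["region"] + 1L
    else if (cfg$require_de_novo &&
             paste(calls$chromosome[i], calls$position[i],
                   calls$ref_base[i], calls$alt_base[i]) %in% pk)
      tally["de_novo"] <- tally["de_novo"] + 1L
    else keep[i] <- TRUE
  }
  list(keep = keep, tally = tally)
}

# random call sets over a transcript neighbourhood (for filter tests)
random_calls <- function(n, transcripts, strain = "R1") {
  tx <- transcripts[[sample.int(length(transcripts), 1)]]
  span <- c(min(tx$exons) - 50L, max(tx$exons) + 50L)
  pos <- sample(seq.int(span[1], span[2]), n, replace = TRUE)
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
  variant_calls(rep(strain, n), rep(tx$chromosome, n), pos, ref, alt,
                read_depth = rpois(n, 8),
                allele_fraction = ifelse(runif(n) < 0.7,
                                         runif(n, 0.91, 1),
                                         runif(n, 0, 0.91)))
}

# ---------------------------------------------------------------------
# whole-CDS retranslation oracle for annotation

# per-transcript cache of the spliced CDS string and the genomic
# position of each CDS base
.cds_cache <- new.env(parent = emptyenv())

oracle_cds_map <- function(tx, genome) {
  # key must distinguish same-named transcripts from different simulated
  # genomes
  key <- paste(tx$transcript_id, tx$chromosome, tx$cds_start_g,
               tx$cds_end_g, genome_length(genome, tx$chromosome))
  if (!is.null(.cds_cache[[key]])) return(.cds_cache[[key]])
  b <- modscreen:::cds_spliced_bounds(tx)
  gpos <- vapply(seq.int(b[["start"]], b[["end"]]), function(sp)
    modscreen:::genomic_position(tx, sp), integer(1))
  bases <- genome_base(genome, tx$chromosome, gpos)
  if (tx$strand == "-") bases <- modscreen:::complement_base(bases)
  out <- list(gpos = gpos, cds = paste(bases, collapse = ""))
  .cds_cache[[key]] <- out
  out
}

# expected (codon_index, ref_aa, alt_aa, effect) by editing the full
# CDS and diffing the translated proteins
oracle_coding_effect <- function(tx, genome, gpos, alt) {
  m <- oracle_cds_map(tx, genome)
  idx <- match(gpos, m$gpos)
  stopifnot(!is.na(idx))
  alt_t <- if (tx$strand == "-") modscreen:::complement_base(alt) else alt
  mut <- m$cds
  substr(mut, idx, idx) <- alt_t
  p0 <- as.character(Biostrings::translate(Biostrings::DNAString(m$cds),
                                           no.init.codon = TRUE))
  p1 <- as.character(Biostrings::translate(Biostrings::DNAString(mut),
                                           no.init.codon = TRUE))
  d <- which(strsplit(p0, "")[[1]] != strsplit(p1, "")[[1]])
  if (length(d) == 0)
    list(codon = (idx + 2L) %/% 3L, ref_aa = NA, alt_aa = NA,
         synonymous = TRUE)
  else
    list(codon = d, ref_aa = substr(p0, d, d), alt_aa = substr(p1, d, d),
         synonymous = FALSE)
}

# ---------------------------------------------------------------------
# explicit risk-set product-limit computation

oracle_km <- function(day, observed) {
  ts <- sort(unique(day[observed]))
  s <- 1
  surv <- numeric(length(ts))
  for (k in seq_along(ts)) {
    n_at_risk <- sum(day >= ts[k])   # events precede censorings at ties
    d <- sum(day == ts[k] & observed)
    s <- s * (1 - d / n_at_risk)
    surv[k] <- s
  }
  list(times = ts, surv = surv)
}
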