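# Coding-effect annotation from first principles: genomic <-> cDNA
# coordinate mapping, codon arithmetic under the standard genetic code,
# and the simplified one-letter HGVS c./p. rendering used in worm
# genetics reports ("c.1154C>T; p.A385V", "p.H409=" for synonymous).

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

complement_base <- function(b) unname(COMPLEMENT[b])

#' Map a genomic position to cDNA coordinates
#'
#' Exonic positions map to cumulative spliced offsets from the CDS start
#' (strand-aware); exonic positions 5' of the start codon get negative
#' numbering counting back from `-1` (no position 0, HGVS convention);
#' intronic positions return the nearest exonic anchor with a signed
#' offset in transcript orientation (the `c.938+3` style).
#'
#' @param transcript a [TranscriptModel()].
#' @param position 1-based genomic position on the transcript's
#'   chromosome; positions off the transcript span are a domain error.
#' @return object of class `CdnaCoordinate`: list with `kind`
#'   (`CODING`, `UTR5`, `UTR3`, `INTRONIC`), `coding_position` (>= 1 for
#'   CODING, <= -1 for UTR5, distance past the stop for UTR3, `NA` for
#'   INTRONIC) and, for INTRONIC, `intron_anchor = list(anchor, offset)`.
#' @examples
#' fx <- build_fixture_transcript()
#' genomic_to_cdna(fx$transcript, 5651146)  # CODING 1154
#' @export
genomic_to_cdna <- function(transcript, position) {
  span <- transcript_span(transcript)
  if (position < span[1] || position > span[2])
    stop_domain("position ", position, " is off transcript ",
                transcript$transcript_id, " (", span[1], "-", span[2], ")")
  s <- spliced_position(transcript, position)
  if (is.na(s)) {
    introns <- transcript_introns(transcript)
    hit <- which(position >= introns[, 1] & position <= introns[, 2])
    i5 <- introns[hit, 1] - 1L      # exonic base on the lower side
    i3 <- introns[hit, 2] + 1L      # exonic base on the upper side
    d_lo <- position - introns[hit, 1] + 1L
    d_hi <- introns[hit, 2] - position + 1L
    plus <- transcript$strand == "+"
    # nearer flank wins; ties go to the 5' (donor) side
    donor_g <- if (plus) i5 else i3
    accep_g <- if (plus) i3 else i5
    d_donor <- if (plus) d_lo else d_hi
    d_accep <- if (plus) d_hi else d_lo
    if (d_donor <= d_accep) {
      anchor <- cdna_number(transcript, donor_g)
      off <- d_donor
    } else {
      anchor <- cdna_number(transcript, accep_g)
      off <- -d_accep
    }
    return(structure(list(kind = "INTRONIC", coding_position = NA_integer_,
                          intron_anchor = list(anchor = anchor,
                                               offset = as.integer(off))),
                     class = "CdnaCoordinate"))
  }
  b <- cds_spliced_bounds(transcript)
  if (s < b["start"]) {
    structure(list(kind = "UTR5",
                   coding_position = as.integer(s - b["start"]),
                   intron_anchor = NULL), class = "CdnaCoordinate")
  } else if (s > b["end"]) {
    structure(list(kind = "UTR3",
                   coding_position = as.integer(s - b["end"]),
                   intron_anchor = NULL), class = "CdnaCoordinate")
  } else {
    structure(list(kind = "CODING",
                   coding_position = as.integer(s - b["start"] + 1L),
                   intron_anchor = NULL), class = "CdnaCoordinate")
  }
}

# signed cDNA number of an *exonic* genomic position (negative = UTR5)
cdna_number <- function(transcript, position) {
  cc <- genomic_to_cdna(transcript, position)
  cc$coding_position
}

#' @export
print.CdnaCoordinate <- function(x, ...) {
  lab <- switch(x$kind,
                CODING = paste0("c.", x$coding_position),
                UTR5 = paste0("c.", x$coding_position),
                UTR3 = paste0("c.*", x$coding_position),
                INTRONIC = paste0("c.", x$intron_anchor$anchor,
                                  ifelse(x$intron_anchor$offset >= 0, "+", ""),
                                  x$intron_anchor$offset))
  cat("<CdnaCoordinate> ", x$kind, " ", lab, "\n", sep = "")
  invisible(x)
}

#' Map a cDNA coordinate back to the genome
#'
#' Inverse of [genomic_to_cdna()] for exonic coordinates;
#' `cdna_to_genomic(tx, genomic_to_cdna(tx, g))` is the identity for any
#' exonic `g`.
#'
#' @param transcript a [TranscriptModel()].
#' @param coding_position integer cDNA number (`>= 1` coding, `<= -1`
#'   5'UTR) or a `CdnaCoordinate` of kind CODING/UTR5/UTR3.
#' @param kind coordinate kind when `coding_position` is an integer.
#' @return 1-based genomic position.
#' @export
cdna_to_genomic <- function(transcript, coding_position, kind = NULL) {
  if (inherits(coding_position, "CdnaCoordinate")) {
    kind <- coding_position$kind
    coding_position <- coding_position$coding_position
  }
  if (is.null(kind))
    kind <- if (coding_position >= 1) "CODING" else "UTR5"
  b <- cds_spliced_bounds(transcript)
  s <- switch(kind,
              CODING = {
                if (coding_position < 1)
                  stop_domain("coding position must be >= 1")
                b["start"] + coding_position - 1L
              },
              UTR5 = {
                if (coding_position > -1)
                  stop_domain("5'UTR positions are <= -1")
                b["start"] + coding_position
              },
              UTR3 = b["end"] + coding_position,
              stop_domain("cannot invert an intronic coordinate"))
  genomic_position(transcript, as.integer(s))
}

#' Codon index and within-codon offset of a coding position
#'
#' @param coding_position integer vector of cDNA positions (>= 1).
#' @return data.frame with `codon_index = ceiling(coding_position / 3)`
#'   and `codon_offset` in `{1, 2, 3}`.
#' @examples
#' codon_arithmetic(1154)  # codon 385, offset 2
#' @export
codon_arithmetic <- function(coding_position) {
  if (any(coding_position < 1) || any(coding_position != trunc(coding_position)))
    stop_domain("coding positions must be positive integers")
  ci <- as.integer(ceiling(coding_position / 3))
  data.frame(codon_index = ci,
             codon_offset = as.integer(coding_position - 3L * (ci - 1L)))
}

# reference codon (transcript strand) covering codon_index
reference_codon <- function(transcript, genome, codon_index) {
  cps <- (codon_index - 1L) * 3L + 1:3
  g <- vapply(cps, function(cp) cdna_to_genomic(transcript, cp, "CODING"),
              integer(1))
  bases <- genome_base(genome, transcript$chromosome, g)
  if (transcript$strand == "-") bases <- complement_base(bases)
  paste(bases, collapse = "")
}

translate_codon <- function(codon) {
  if (grepl("N", codon)) return(NA_character_)
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Annotate the coding effect of one substitution
#'
#' Classifies a single-nucleotide substitution against one transcript and
#' renders the simplified HGVS strings.  Coding effects are computed by
#' editing the affected codon under the standard genetic code, with
#' strand-aware complementation for minus-strand transcripts.  The
#' variant's `ref_base` must match the genome (data-integrity check).
#'
#' @param transcript a [TranscriptModel()].
#' @param genome a [Genome()] containing the transcript's chromosome.
#' @param variant one-row [variant_calls()] table (or a list with the
#'   same fields).
#' @param splice_window_nt intronic positions within this many nt of a
#'   splice junction are classed `SPLICE_PROX` (default 10).
#' @return one-row data.frame with columns `strain_id`, `gene_id`,
#'   `transcript_id`, `chromosome`, `position`, `ref_base`, `alt_base`,
#'   `region` (coordinate kind), `coding_position`, `codon_index`,
#'   `codon_offset`, `ref_aa`, `alt_aa`, `effect_class`, `c_hgvs`,
#'   `p_hgvs`, `protein_change`.
#' @examples
#' fx <- build_fixture_transcript()
#' v <- variant_calls("S1", "II", 5650846, "G", "A", 30, 1)
#' annotate_variant(fx$transcript, fx$genome, v)  # p.D313N
#' @export
annotate_variant <- function(transcript, genome, variant,
                             splice_window_nt = 10L) {
  v <- as.list(as.data.frame(variant)[1, ])
  gbase <- genome_base(genome, v$chromosome, v$position)
  if (gbase != v$ref_base)
    stop_domain("reference mismatch for strain ", v$strain_id, " at ",
                v$chromosome, ":", v$position, " (call says ", v$ref_base,
                ", genome has ", gbase, ")")
  cc <- genomic_to_cdna(transcript, v$position)
  plus <- transcript$strand == "+"
  ref_t <- if (plus) v$ref_base else complement_base(v$ref_base)
  alt_t <- if (plus) v$alt_base else complement_base(v$alt_base)

  ci <- NA_integer_; co <- NA_integer_
  ref_aa <- NA_character_; alt_aa <- NA_character_
  p_hgvs <- ""; protein_change <- ""
  if (cc$kind == "CODING") {
    ca <- codon_arithmetic(cc$coding_position)
    ci <- ca$codon_index; co <- ca$codon_offset
    codon <- reference_codon(transcript, genome, ci)
    if (substr(codon, co, co) != ref_t)
      stop_domain("internal codon/reference disagreement at ",
                  v$chromosome, ":", v$position)
    mut <- codon
    substr(mut, co, co) <- alt_t
    ref_aa <- translate_codon(codon)
    alt_aa <- translate_codon(mut)
    effect <- if (ref_aa == alt_aa) "SYNONYMOUS"
    else if (ref_aa == "*") "STOP_LOSS"
    else if (alt_aa == "*") "NONSENSE"
    else if (ci == 1L && ref_aa == "M") "START_LOSS"
    else "MISSENSE"
    p_hgvs <- if (effect == "SYNONYMOUS") paste0("p.", ref_aa, ci, "=")
    else paste0("p.", ref_aa, ci, alt_aa)
    protein_change <- sub("^p\\.", "", p_hgvs)
    c_hgvs <- paste0("c.", cc$coding_position, ref_t, ">", alt_t)
  } else if (cc$kind == "UTR5") {
    effect <- "UTR5_VARIANT"
    c_hgvs <- paste0("c.", cc$coding_position, ref_t, ">", alt_t)
  } else if (cc$kind == "UTR3") {
    effect <- "UTR3_VARIANT"
    c_hgvs <- paste0("c.*", cc$coding_position, ref_t, ">", alt_t)
  } else {
    off <- cc$intron_anchor$offset
    effect <- if (abs(off) <= splice_window_nt) "SPLICE_PROX" else "INTRONIC"
    c_hgvs <- paste0("c.", cc$intron_anchor$anchor,
                     ifelse(off >= 0, "+", ""), off, ref_t, ">", alt_t)
  }
  data.frame(strain_id = v$strain_id, gene_id = transcript$gene_id,
             transcript_id = transcript$transcript_id,
             chromosome = v$chromosome, position = v$position,
             ref_base = v$ref_base, alt_base = v$alt_base,
             region = cc$kind,
             coding_position = cc$coding_position,
             codon_index = ci, codon_offset = co,
             ref_aa = ref_aa, alt_aa = alt_aa, effect_class = effect,
             c_hgvs = c_hgvs, p_hgvs = p_hgvs,
             protein_change = protein_change,
             stringsAsFactors = FALSE)
}

#' Annotate a call table against a set of transcripts
#'
#' Each call is annotated against every transcript whose span covers it;
#' calls hitting no transcript are dropped (they are intergenic).
#'
#' @param transcripts list of [TranscriptModel()].
#' @param genome a [Genome()].
#' @param calls a [variant_calls()] table.
#' @param splice_window_nt splice-proximity window, nt.
#' @return data.frame of annotations (see [annotate_variant()]), zero
#'   rows if nothing overlaps.
#' @export
annotate_calls <- function(transcripts, genome, calls,
                           splice_window_nt = 10L) {
  rows <- list()
  tx_chrom <- vapply(transcripts, `[[`, "", "chromosome")
  tx_start <- vapply(transcripts, function(t) min(t$exons), 0)
  tx_end <- vapply(transcripts, function(t) max(t$exons), 0)
  for (i in seq_len(nrow(calls))) {
    hit <- which(tx_chrom == calls$chromosome[i] &
                   tx_start <= calls$position[i] &
                   tx_end >= calls$position[i])
    for (j in hit) {
      rows[[length(rows) + 1L]] <-
        annotate_variant(transcripts[[j]], genome,
                         calls[i, , drop = FALSE],
                         splice_window_nt = splice_window_nt)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    annotate_empty()
}

annotate_empty <- function() {
  data.frame(strain_id = character(), gene_id = character(),
             transcript_id = character(), chromosome = character(),
             position = integer(), ref_base = character(),
             alt_base = character(), region = character(),
             coding_position = integer(), codon_index = integer(),
             codon_offset = integer(), ref_aa = character(),
             alt_aa = character(), effect_class = character(),
             c_hgvs = character(), p_hgvs = character(),
             protein_change = character(), stringsAsFactors = FALSE)
}

#' Group in-gene variants of one strain into complex-allele labels
#'
#' Two or more variants in the same gene within one strain form a complex
#' allele; its label joins the protein-change tokens sorted by codon
#' index (non-coding variants sort before codon 1 by their cDNA number
#' and contribute their `c.` string).
#'
#' @param annotations annotation data.frame for one strain.
#' @return named character vector, gene id -> allele label.
#' @examples
#' # {P316H, S319A} in one gene -> "P316H;S319A"
#' @export
group_complex_alleles <- function(annotations) {
  if (nrow(annotations) == 0) return(setNames(character(0), character(0)))
  if (length(unique(annotations$strain_id)) > 1)
    stop_domain("complex-allele grouping expects a single strain")
  out <- character(0)
  for (g in unique(annotations$gene_id)) {
    a <- annotations[annotations$gene_id == g, , drop = FALSE]
    token <- ifelse(nzchar(a$protein_change), a$protein_change, a$c_hgvs)
    key <- ifelse(is.na(a$codon_index),
                  ifelse(is.na(a$coding_position), 0, a$coding_position) / 1e6,
                  a$codon_index)
    out[g] <- paste(token[order(key)], collapse = ";")
  }
  out
}

#' Nonsense and splice burden of a filtered variant set
#'
#' @param annotations annotation data.frame (one row per variant; pass
#'   one annotation per variant, e.g. the highest-priority transcript).
#' @return list with `n_total`, `n_nonsense`, `n_splice`,
#'   `pct_nonsense`, `pct_splice` (percentages rounded half-up to two
#'   decimals; `NA` when `n_total` is zero).
#' @export
burden_summary <- function(annotations) {
  n <- nrow(annotations)
  n_non <- sum(annotations$effect_class == "NONSENSE")
  n_spl <- sum(annotations$effect_class == "SPLICE_PROX")
  burden_percentages(n, n_non, n_spl)
}

#' Burden percentages from explicit counts
#'
#' @param n_total total filtered variants.
#' @param n_nonsense nonsense count.
#' @param n_splice splice-affecting count.
#' @return list as in [burden_summary()].
#' @examples
#' burden_percentages(188, 5, 4)  # 2.66% nonsense, 2.13% splicing
#' @export
burden_percentages <- function(n_total, n_nonsense, n_splice) {
  pct <- function(k) if (n_total == 0) NA_real_ else
    round_half_up(100 * k / n_total, 2)
  list(n_total = as.integer(n_total),
       n_nonsense = as.integer(n_nonsense),
       n_splice = as.integer(n_splice),
       pct_nonsense = pct(n_nonsense),
       pct_splice = pct(n_splice))
}
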