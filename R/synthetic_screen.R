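# Synthetic EMS/ENU suppressor-screen generator.  Emulates the study
# conditions of a temperature-sensitive lethality suppressor screen:
# strand-collapsed mutagen substitution spectra, homozygous-mutant call
# profiles (high allele fraction, moderate depth), planted intragenic
# suppressors, revertants, wildtype contamination, and plate-level
# phenotype assays.  Every downstream module can therefore be exercised
# against known ground truth.

#' The six strand-collapsed substitution classes
#'
#' A substitution and its complement (e.g. C>T and G>A) belong to the
#' same class because alkylating-mutagen chemistry is strand-symmetric.
#' @export
SUBSTITUTION_CLASSES <- c("G:C>A:T", "A:T>G:C", "G:C>T:A",
                          "G:C>C:G", "A:T>T:A", "A:T>C:G")

# per class, the two (ref, alt) substitutions it collapses
CLASS_SUBSTITUTIONS <- list(
  "G:C>A:T" = list(c("G", "A"), c("C", "T")),
  "A:T>G:C" = list(c("A", "G"), c("T", "C")),
  "G:C>T:A" = list(c("G", "T"), c("C", "A")),
  "G:C>C:G" = list(c("G", "C"), c("C", "G")),
  "A:T>T:A" = list(c("A", "T"), c("T", "A")),
  "A:T>C:G" = list(c("A", "C"), c("T", "G")))

#' Construct a mutagen substitution spectrum
#'
#' @param weights named numeric over the six classes in
#'   [SUBSTITUTION_CLASSES]; non-negative, summing to 1 within `1e-9`.
#' @return object of class `MutagenSpectrum` (a named numeric vector).
#' @export
mutagen_spectrum <- function(weights) {
  if (is.null(names(weights)) ||
      !setequal(names(weights), SUBSTITUTION_CLASSES))
    stop_config("spectrum weights must be named by the six substitution ",
                "classes")
  weights <- weights[SUBSTITUTION_CLASSES]
  if (any(weights < 0)) stop_config("spectrum weights must be >= 0")
  if (abs(sum(weights) - 1) > 1e-9)
    stop_config("spectrum weights must sum to 1 (got ", sum(weights), ")")
  structure(as.numeric(weights), names = SUBSTITUTION_CLASSES,
            class = "MutagenSpectrum")
}

#' Default mutagen spectra
#'
#' EMS overwhelmingly produces G:C>A:T transitions; ENU produces A:T
#' transversions (chiefly A:T>T:A) alongside transitions.  The paperless
#' reality of these chemistries is qualitative, so the numeric defaults
#' here are package conventions and fully overridable.
#'
#' @param mutagen_name `"EMS"`, `"ENU"` or `"EMS+ENU"` (equal mixture).
#' @param weights optional full replacement weights (named over the six
#'   classes); when given, `mutagen_name` is only a label.
#' @return a [mutagen_spectrum()].
#' @export
default_spectrum <- function(mutagen_name, weights = NULL) {
  if (!is.null(weights)) return(mutagen_spectrum(weights))
  ems <- c("G:C>A:T" = 0.85, "A:T>G:C" = 0.03, "G:C>T:A" = 0.03,
           "G:C>C:G" = 0.03, "A:T>T:A" = 0.03, "A:T>C:G" = 0.03)
  enu <- c("A:T>T:A" = 0.30, "A:T>G:C" = 0.25, "G:C>A:T" = 0.25,
           "G:C>T:A" = 0.20 / 3, "G:C>C:G" = 0.20 / 3,
           "A:T>C:G" = 0.20 / 3)
  w <- switch(mutagen_name,
              "EMS" = ems,
              "ENU" = enu,
              "EMS+ENU" = (ems[SUBSTITUTION_CLASSES] +
                             enu[SUBSTITUTION_CLASSES]) / 2,
              stop_config("unknown mutagen '", mutagen_name,
                          "' (expected EMS, ENU or EMS+ENU)"))
  mutagen_spectrum(w)
}

#' Draw substitution classes from a spectrum
#'
#' Multinomial sampling of strand-collapsed classes; uses the session
#' RNG (seed at the call site for reproducibility).
#'
#' @param spectrum a [mutagen_spectrum()].
#' @param n number of draws.
#' @return character vector of class labels.
#' @export
draw_substitution_classes <- function(spectrum, n) {
  sample(SUBSTITUTION_CLASSES, n, replace = TRUE, prob = as.numeric(spectrum))
}

#' Simulate a random genome
#'
#' I.i.d. bases with `P(G) + P(C) = gc_fraction`; reproducible for a
#' fixed seed.
#'
#' @param chrom_lengths named integer vector of chromosome lengths
#'   (>= 1).
#' @param gc_fraction GC content in (0, 1).
#' @param seed integer seed.
#' @return a [Genome()].
#' @export
simulate_genome <- function(chrom_lengths, gc_fraction = 0.36, seed = 1) {
  if (gc_fraction <= 0 || gc_fraction >= 1)
    stop_config("gc_fraction must lie strictly inside (0, 1)")
  if (length(chrom_lengths) == 0 || any(chrom_lengths < 1))
    stop_config("chromosome lengths must be >= 1")
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  with_seed(seed, {
    seqs <- vapply(chrom_lengths, function(len) {
      paste(sample(DNA_BASES, len, replace = TRUE, prob = p), collapse = "")
    }, "")
  })
  Genome(seqs)
}

# ---------------------------------------------------------------------
# Fixture transcript

# codons pinned so the documented substitutions force the documented
# amino-acid changes (e.g. GCT codon 385 + c.1154C>T -> A385V)
FIXTURE_CODONS <- c("1" = "ATG", "313" = "GAC", "316" = "CCC",
                    "319" = "TCC", "361" = "GAA", "385" = "GCT",
                    "409" = "CAT", "420" = "AAT", "421" = "GGA",
                    "442" = "CCA", "533" = "AAA", "707" = "TAA")

#' Build the zyg-1-like fixture transcript
#'
#' A fully deterministic plus-strand transcript on a synthetic
#' chromosome `II`, laid out so that the genomic/cDNA coordinate pairs
#' of the documented intragenic suppressor set hold exactly: `c.1` at
#' g5,649,774; 5'UTR pairs `c.-4` = g5,649,770 and `c.-18` = g5,649,756;
#' offsets `g - c` of 5,649,909 for `c.937-938`, 5,649,992 for
#' `c.947-1262` and 5,652,014 for `c.1291` onward (hence the primary
#' lesion g5,653,339 = `c.1325`, codon 442).  Intron lengths are 136, 83
#' and 2,022 nt.  Reference codons are pinned so each documented base
#' change forces the documented amino-acid change (A385V, H409=, K533E,
#' ...); all unconstrained bases are generated from a fixed internal
#' seed.  The chromosome is padded with `N` outside the gene
#' neighbourhood so that 1-based positions match.
#'
#' @return list with `transcript` (a [TranscriptModel()]), `genome` (a
#'   [Genome()] with chromosome `II`), and `primary` (the
#'   [primary_allele()]: C>T at II:5,653,339, P442L).
#' @export
build_fixture_transcript <- function() {
  exons <- rbind(c(5649744L, 5650313L),   # 5'UTR (-30..-1) + c.1..540
                 c(5650450L, 5650851L),   # c.541..942
                 c(5650935L, 5651282L),   # c.943..1290
                 c(5653305L, 5654285L))   # c.1291..2121 + 150 nt 3'UTR
  cds_start_g <- 5649774L                 # c.1
  cds_end_g <- 5654135L                   # c.2121 (stop included)

  with_seed(104729, {
    sense <- setdiff(names(Biostrings::GENETIC_CODE),
                     c("TAA", "TAG", "TGA"))
    codons <- sample(sense, 707, replace = TRUE)
    codons[as.integer(names(FIXTURE_CODONS))] <- FIXTURE_CODONS
    cds <- paste(codons, collapse = "")
    rnd <- function(n) paste(sample(DNA_BASES, n, replace = TRUE),
                             collapse = "")
    utr5 <- rnd(30)
    substr(utr5, 13, 13) <- "G"           # c.-18
    substr(utr5, 27, 27) <- "T"           # c.-4
    utr3 <- rnd(150)
    intron <- function(n) paste0("GT", rnd(n - 4), "AG")
    introns <- list(intron(136), intron(83), intron(2022))
    flank5 <- rnd(150)
    flank3 <- rnd(100)
  })

  spliced <- paste0(utr5, cds, utr3)      # 30 + 2121 + 150 = 2301 nt
  # interleave exons and introns on the genomic axis
  widths <- exons[, 2] - exons[, 1] + 1L
  pieces <- character(0)
  at <- 1L
  for (i in seq_len(nrow(exons))) {
    pieces <- c(pieces, substr(spliced, at, at + widths[i] - 1L))
    at <- at + widths[i]
    if (i < nrow(exons)) pieces <- c(pieces, introns[[i]])
  }
  region <- paste(pieces, collapse = "")
  region_start <- exons[1, 1] - nchar(flank5)
  chrII <- paste0(strrep("N", region_start - 1L), flank5, region, flank3)

  tx <- TranscriptModel(gene_id = "zyg-1-like",
                        transcript_id = "zyg-1-like.t1",
                        chromosome = "II", strand = "+", exons = exons,
                        cds_start_g = cds_start_g, cds_end_g = cds_end_g)
  list(transcript = tx,
       genome = Genome(c(II = chrII)),
       primary = primary_allele("zyg-1-like", "II", 5653339L, "C", "T",
                                protein_change = "P442L"))
}

# ---------------------------------------------------------------------
# Screen plan and strain simulation

#' Parameterise a synthetic screen
#'
#' Defaults encode the emulated study conditions: per-strain filtered
#' mutation loads in the observed 47-188 range (mean 110), roughly 12%
#' of suppressor strains intragenic, rare revertants and contamination,
#' moderate depth and near-1 homozygous allele fractions.
#'
#' @param n_strains number of suppressor strains.
#' @param mutation_load_mean expected surviving (coding/splice/UTR)
#'   mutations per strain.
#' @param fraction_intragenic,fraction_revertant,fraction_contamination
#'   label fractions; the remainder is extragenic suppressors.  Must sum
#'   to at most 1.
#' @param depth_mean mean read depth (negative-binomial, size 10).
#' @param af_homozygous_concentration Beta(`c`, 1) concentration of the
#'   homozygous allele fraction near 1.
#' @param seed integer master seed.
#' @return object of class `ScreenPlan`.
#' @export
screen_plan <- function(n_strains = 50, mutation_load_mean = 110,
                        fraction_intragenic = 0.12,
                        fraction_revertant = 0.01,
                        fraction_contamination = 0.01,
                        depth_mean = 30, af_homozygous_concentration = 60,
                        seed = 1) {
  if (n_strains < 1) stop_config("n_strains must be positive")
  if (mutation_load_mean < 0) stop_config("mutation_load_mean must be >= 0")
  fr <- c(fraction_intragenic, fraction_revertant, fraction_contamination)
  if (any(fr < 0 | fr > 1) || sum(fr) > 1)
    stop_config("label fractions must lie in [0,1] and sum to at most 1")
  if (depth_mean <= 0 || af_homozygous_concentration <= 0)
    stop_config("depth_mean and af_homozygous_concentration must be > 0")
  structure(list(n_strains = as.integer(n_strains),
                 mutation_load_mean = mutation_load_mean,
                 fraction_intragenic = fraction_intragenic,
                 fraction_revertant = fraction_revertant,
                 fraction_contamination = fraction_contamination,
                 depth_mean = depth_mean,
                 af_homozygous_concentration = af_homozygous_concentration,
                 seed = as.integer(seed)),
            class = "ScreenPlan")
}

# deterministic small-integer seed from the plan seed and a strain label
strain_seed <- function(seed, strain_id) {
  h <- 0
  for (k in utf8ToInt(strain_id)) h <- (h * 31 + k) %% 1000003
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483629)
}

#' Index the mutable sites of a transcript set
#'
#' All exonic positions plus `splice_window_nt` of intronic flank for
#' every transcript, with their reference bases -- the regions in which
#' mutagen background is placed by default (matching what a
#' coding/splice/UTR filter would retain).
#'
#' @param transcripts list of [TranscriptModel()].
#' @param genome a [Genome()].
#' @param splice_window_nt intronic flank width.
#' @return data.frame with `chromosome`, `position`, `base`.
#' @export
build_site_index <- function(transcripts, genome, splice_window_nt = 10L) {
  rows <- list()
  for (tx in transcripts) {
    pos <- integer(0)
    for (i in seq_len(nrow(tx$exons)))
      pos <- c(pos, seq.int(tx$exons[i, 1], tx$exons[i, 2]))
    introns <- transcript_introns(tx)
    for (i in seq_len(nrow(introns))) {
      w <- min(splice_window_nt, introns[i, 2] - introns[i, 1] + 1L)
      pos <- c(pos, seq.int(introns[i, 1], introns[i, 1] + w - 1L),
               seq.int(introns[i, 2] - w + 1L, introns[i, 2]))
    }
    pos <- sort(unique(pos))
    base <- genome_base(genome, tx$chromosome, pos)
    keep <- base %in% DNA_BASES
    rows[[length(rows) + 1L]] <- data.frame(
      chromosome = tx$chromosome, position = pos[keep], base = base[keep],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out[!duplicated(out[c("chromosome", "position")]), , drop = FALSE]
}

# Sample an unused site compatible with a collapsed class, uniformly
# over the compatible sites, via precomputed per-base row pools
# (rejection sampling; collisions are rare at realistic loads).
place_class <- function(class, site_index, pools, used) {
  subs <- CLASS_SUBSTITUTIONS[[class]]
  refs <- vapply(subs, `[`, "", 1)
  sizes <- vapply(refs, function(b) length(pools[[b]]), 0L)
  if (sum(sizes) == 0) return(NULL)
  i <- NA_integer_
  for (try in seq_len(50)) {
    b <- if (length(refs) > 1) refs[sample.int(2L, 1, prob = sizes)]
    else refs
    cand <- pools[[b]][sample.int(length(pools[[b]]), 1)]
    if (!used[cand]) { i <- cand; break }
  }
  if (is.na(i)) {   # nearly saturated pools: exhaustive fallback
    cand <- setdiff(unlist(pools[refs], use.names = FALSE), which(used))
    if (length(cand) == 0) return(NULL)
    i <- cand[sample.int(length(cand), 1)]
  }
  ref <- site_index$base[i]
  alt <- subs[[match(ref, refs)]][2]
  list(row = i, chromosome = site_index$chromosome[i],
       position = site_index$position[i], ref = ref, alt = alt)
}

#' Simulate one screened strain
#'
#' Draws a mutagen background around the plan's mutation load, placing
#' each drawn substitution class on a compatible reference base within
#' the mutable-site index; adds the primary mutant allele unless the
#' strain is a revertant or contamination; plants one in-gene coding
#' variant for intragenic suppressors.  Depths are negative-binomial
#' around `depth_mean` and allele fractions Beta-concentrated near 1.
#' Output is deterministic given the plan seed and strain id.
#'
#' @param genome a [Genome()].
#' @param transcripts list of [TranscriptModel()]; the first transcript
#'   whose gene matches `primary$gene_id` is the planting target.
#' @param primary the [primary_allele()].
#' @param spectrum a [mutagen_spectrum()].
#' @param plan a [screen_plan()].
#' @param truth_label one of `INTRAGENIC_SUPPRESSOR`,
#'   `EXTRAGENIC_SUPPRESSOR`, `REVERTANT`, `CONTAMINATION`.
#' @param strain_id strain label.
#' @param mutagen mutagen label stored with the strain.
#' @param site_index optional precomputed [build_site_index()] result.
#' @param stray_call_max maximum stray calls in a contamination strain.
#' @return object of class `SimulatedStrain`: list with `strain_id`,
#'   `truth_label`, `mutagen`, `planted_variant` (one-row
#'   [variant_calls()] or `NULL`) and `calls`.
#' @export
simulate_strain <- function(genome, transcripts, primary, spectrum, plan,
                            truth_label, strain_id, mutagen = "EMS+ENU",
                            site_index = NULL, stray_call_max = 3L) {
  labels <- c("INTRAGENIC_SUPPRESSOR", "EXTRAGENIC_SUPPRESSOR",
              "REVERTANT", "CONTAMINATION")
  if (!truth_label %in% labels)
    stop_config("unknown truth label '", truth_label, "'")
  if (genome_base(genome, primary$chromosome, primary$position) !=
      primary$wildtype_base)
    stop_domain("primary allele wildtype base does not match the genome")
  if (is.null(site_index))
    site_index <- build_site_index(transcripts, genome)
  target <- NULL
  for (tx in transcripts)
    if (tx$gene_id == primary$gene_id) { target <- tx; break }

  pools <- split(seq_len(nrow(site_index)), site_index$base)
  for (b in DNA_BASES) if (is.null(pools[[b]])) pools[[b]] <- integer(0)

  with_seed(strain_seed(plan$seed, strain_id), {
    used <- rep(FALSE, nrow(site_index))
    # never mutate the primary site as background
    used[site_index$chromosome == primary$chromosome &
           site_index$position == primary$position] <- TRUE

    rows <- list()
    add_call <- function(chromosome, position, ref, alt) {
      rows[[length(rows) + 1L]] <<- data.frame(
        strain_id = strain_id, chromosome = chromosome,
        position = as.integer(position), ref_base = ref, alt_base = alt,
        read_depth = max(1L, rnbinom(1, size = 10, mu = plan$depth_mean)),
        allele_fraction = rbeta(1, plan$af_homozygous_concentration, 1),
        stringsAsFactors = FALSE)
    }

    if (truth_label != "CONTAMINATION") {
      n_bg <- rpois(1, plan$mutation_load_mean)
      if (n_bg > 0) {
        classes <- draw_substitution_classes(spectrum, n_bg)
        for (cl in classes) {
          hit <- place_class(cl, site_index, pools, used)
          if (is.null(hit))
            stop_domain("spectrum class ", cl, " cannot be placed: no ",
                        "compatible reference base left in the site index")
          used[hit$row] <- TRUE
          add_call(hit$chromosome, hit$position, hit$ref, hit$alt)
        }
      }
    } else {
      n_stray <- min(rpois(1, 1), stray_call_max)
      if (n_stray > 0) {
        for (k in seq_len(n_stray)) {
          i <- which(!used)[sample.int(sum(!used), 1)]
          used[i] <- TRUE
          alt <- sample(setdiff(DNA_BASES, site_index$base[i]), 1)
          add_call(site_index$chromosome[i], site_index$position[i],
                   site_index$base[i], alt)
        }
      }
    }

    planted <- NULL
    if (truth_label == "INTRAGENIC_SUPPRESSOR") {
      if (is.null(target))
        stop_config("no transcript matches the primary allele's gene")
      in_target <- site_index$chromosome == target$chromosome &
        site_index$position >= transcript_span(target)[1] &
        site_index$position <= transcript_span(target)[2] & !used
      if (!any(in_target))
        stop_domain("no free site left in the target gene for planting")
      # conditional class choice given the site's reference base
      i <- which(in_target)[sample.int(sum(in_target), 1)]
      ref <- site_index$base[i]
      compat <- vapply(SUBSTITUTION_CLASSES, function(cl) {
        any(vapply(CLASS_SUBSTITUTIONS[[cl]],
                   function(s) s[1] == ref, logical(1)))
      }, logical(1))
      w <- as.numeric(spectrum) * compat
      cl <- if (sum(w) > 0)
        sample(SUBSTITUTION_CLASSES, 1, prob = w)
      else sample(SUBSTITUTION_CLASSES[compat], 1)
      subs <- CLASS_SUBSTITUTIONS[[cl]]
      alt <- subs[[match(ref, vapply(subs, `[`, "", 1))]][2]
      used[i] <- TRUE
      add_call(site_index$chromosome[i], site_index$position[i], ref, alt)
      planted <- rows[[length(rows)]]
    }

    if (truth_label %in% c("INTRAGENIC_SUPPRESSOR",
                           "EXTRAGENIC_SUPPRESSOR")) {
      add_call(primary$chromosome, primary$position,
               primary$wildtype_base, primary$mutant_base)
    }
  })

  calls <- if (length(rows)) validate_variant_calls(do.call(rbind, rows))
  else variant_calls()
  ord <- order(calls$chromosome, calls$position)
  calls <- calls[ord, , drop = FALSE]
  rownames(calls) <- NULL
  structure(list(strain_id = strain_id, truth_label = truth_label,
                 mutagen = mutagen,
                 planted_variant = planted, calls = calls),
            class = "SimulatedStrain")
}

#' @export
print.SimulatedStrain <- function(x, ...) {
  cat("<SimulatedStrain> ", x$strain_id, " [", x$truth_label, ", ",
      x$mutagen, "] ", nrow(x$calls), " call(s)",
      if (!is.null(x$planted_variant))
        paste0("; planted ", x$planted_variant$chromosome, ":",
               x$planted_variant$position, " ",
               x$planted_variant$ref_base, ">",
               x$planted_variant$alt_base), "\n", sep = "")
  invisible(x)
}

#' Simulate random decoy transcripts on a genome
#'
#' Lays non-overlapping multi-exon genes along the given chromosomes so
#' mutagen background can be distributed genome-wide over many genes,
#' as in a real screen.  Gene structures (exon counts, intron and UTR
#' lengths, strand) are drawn randomly but reproducibly.
#'
#' @param genome a [Genome()].
#' @param n_genes number of genes to place.
#' @param chromosomes chromosomes to use (default all).
#' @param seed integer seed.
#' @return list of [TranscriptModel()].
#' @export
simulate_transcripts <- function(genome, n_genes = 80,
                                 chromosomes = names(genome), seed = 1) {
  with_seed(seed, {
    out <- list()
    per_chrom <- table(sample(chromosomes, n_genes, replace = TRUE))
    for (chrom in names(per_chrom)) {
      len <- genome_length(genome, chrom)
      cursor <- 200L
      for (k in seq_len(per_chrom[[chrom]])) {
        u5 <- sample(20:80, 1)
        u3 <- sample(20:80, 1)
        n_codons <- sample(100:400, 1)
        cds_len <- 3L * n_codons
        s_len <- u5 + cds_len + u3
        n_intron <- sample(0:3, 1)
        cuts <- if (n_intron > 0)
          sort(sample(seq_len(s_len - 1L), n_intron)) else integer(0)
        ilens <- if (n_intron > 0) sample(45:300, n_intron, replace = TRUE)
        else integer(0)
        g_len <- s_len + sum(ilens)
        if (cursor + g_len + 200L > len) break
        start <- cursor
        bounds <- c(0L, cuts, s_len)
        exons <- matrix(0L, nrow = n_intron + 1L, ncol = 2)
        at <- start
        for (e in seq_len(n_intron + 1L)) {
          w <- bounds[e + 1L] - bounds[e]
          exons[e, ] <- c(at, at + w - 1L)
          at <- at + w + (if (e <= n_intron) ilens[e] else 0L)
        }
        strand <- sample(c("+", "-"), 1)
        # spliced CDS interval is u5+1 .. u5+cds_len on the coding strand
        sp <- if (strand == "+") c(u5 + 1L, u5 + cds_len)
        else c(u3 + 1L, u3 + cds_len)   # minus strand: 5'UTR at high end
        tx_like <- list(exons = exons, strand = "+",
                        transcript_id = "tmp")
        cds_g <- sort(c(genomic_position(tx_like, sp[1]),
                        genomic_position(tx_like, sp[2])))
        id <- paste0("g", chrom, "_", k)
        out[[length(out) + 1L]] <- TranscriptModel(
          gene_id = id, transcript_id = paste0(id, ".t1"),
          chromosome = chrom, strand = strand, exons = exons,
          cds_start_g = cds_g[1], cds_end_g = cds_g[2])
        cursor <- at + sample(300:1500, 1)
      }
    }
  })
  out
}

# ---------------------------------------------------------------------
# Phenotype simulation

#' Simulate hatching and population plate assays
#'
#' Hatch assay: eggs laid daily around a brood mean over 4 days, each
#' egg hatching with probability `suppression_strength`.  Population
#' assay: a single founder seeds a daily branching process -- adults
#' lay for four days, eggs hatch after one day with probability
#' `suppression_strength`, hatched worms are themselves fertile with
#' the same probability (suppression rescues viability *and*
#' fertility), worms mature at 2 days and die at 12.  Weak suppression
#' therefore gives a subcritical process whose plates die out, as
#' unsuppressed temperature-sensitive strains do.  Population death is
#' recorded when no worm remains viable; observation stops at the
#' `horizon` (default 30 days).
#'
#' @param suppression_strength hatching success probability in `[0, 1]`.
#' @param n_plates number of plates (>= 1).
#' @param seed integer seed.
#' @param strain_id strain label.
#' @param truth_label optional metadata label stored with the plates.
#' @param brood_mean expected eggs per mother over the 4-day lay.
#' @param horizon censoring day for the population assay.
#' @return list with `hatch` (columns `strain_id, plate_id, day,
#'   eggs_laid, hatched`) and `population` (columns `strain_id,
#'   plate_id, day, viable, l4plus, dead_flag`).
#' @export
simulate_phenotype <- function(suppression_strength, n_plates, seed = 1,
                               strain_id = "strain", truth_label = NA,
                               brood_mean = 200, horizon = 30L) {
  if (suppression_strength < 0 || suppression_strength > 1)
    stop_config("suppression_strength must lie in [0, 1]")
  if (n_plates < 1) stop_config("n_plates must be >= 1")
  lay_daily <- brood_mean / 4
  maturity <- 2L    # days post-hatch to L4
  lay_ages <- maturity + 0:3
  lifespan <- 12L
  cap <- 500L       # population bound; growth beyond it is established

  hatch <- list()
  pop <- list()
  with_seed(seed, {
    for (p in seq_len(n_plates)) {
      plate_id <- sprintf("%s_p%02d", strain_id, p)
      eggs <- rpois(4, lay_daily)
      hat <- rbinom(4, eggs, suppression_strength)
      hatch[[p]] <- data.frame(strain_id = strain_id, plate_id = plate_id,
                               day = 1:4, eggs_laid = eggs, hatched = hat,
                               stringsAsFactors = FALSE)
      ages <- maturity          # the plated L4 founder
      fertile <- TRUE
      pending <- 0L             # eggs laid today hatch tomorrow
      rows <- list()
      for (d in seq_len(horizon)) {
        hatched_today <- if (pending > 0)
          rbinom(1, pending, suppression_strength) else 0L
        ages <- ages + 1L
        alive <- ages <= lifespan
        ages <- ages[alive]; fertile <- fertile[alive]
        room <- max(cap - length(ages), 0L)
        add <- min(hatched_today, room)
        if (add > 0) {
          ages <- c(ages, rep(0L, add))
          fertile <- c(fertile, runif(add) < suppression_strength)
        }
        layers <- sum(fertile & ages %in% lay_ages)
        pending <- if (layers > 0) rpois(1, layers * lay_daily) else 0L
        viable <- length(ages)
        l4plus <- sum(ages >= maturity)
        rows[[d]] <- data.frame(strain_id = strain_id, plate_id = plate_id,
                                day = d, viable = viable,
                                l4plus = l4plus,
                                dead_flag = as.integer(viable == 0L),
                                stringsAsFactors = FALSE)
        if (viable == 0L) break
        # an abundant, reproducing population is established: stop
        # simulating individuals (the count metrics are long crossed and
        # such plates do not die out within the assay horizon)
        if (viable >= 200L && l4plus >= 100L && layers > 0L) break
      }
      pop[[p]] <- do.call(rbind, rows)
    }
  })
  list(hatch = do.call(rbind, hatch), population = do.call(rbind, pop))
}
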