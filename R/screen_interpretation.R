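# Post-annotation inference: does a strain's background match its
# mutagen's substitution spectrum (revertant vs contamination), and do
# recurrent positions/codons indicate the screen is nearing saturation?

TRANSITIONS <- c("A>G", "G>A", "C>T", "T>C")

#' Classify a substitution
#'
#' @param ref_base,alt_base distinct single bases.
#' @return list with `type` (`"transition"` or `"transversion"`) and
#'   `class` (one of [SUBSTITUTION_CLASSES]; complementary substitutions
#'   such as C>T and G>A share a class).
#' @examples
#' classify_substitution("C", "T")  # transition, G:C>A:T
#' @export
classify_substitution <- function(ref_base, alt_base) {
  ref_base <- toupper(ref_base); alt_base <- toupper(alt_base)
  if (!ref_base %in% DNA_BASES || !alt_base %in% DNA_BASES)
    stop_domain("bases must be one of A,C,G,T")
  if (ref_base == alt_base)
    stop_domain("ref and alt base are identical")
  cls <- NULL
  for (cl in SUBSTITUTION_CLASSES) {
    for (s in CLASS_SUBSTITUTIONS[[cl]])
      if (s[1] == ref_base && s[2] == alt_base) cls <- cl
  }
  list(type = if (paste0(ref_base, ">", alt_base) %in% TRANSITIONS)
    "transition" else "transversion",
    class = cls)
}

collapsed_classes <- function(calls) {
  vapply(seq_len(nrow(calls)), function(i)
    classify_substitution(calls$ref_base[i], calls$alt_base[i])$class, "")
}

#' Spectrum consistency of a call set
#'
#' `consistent_fraction` is the share of calls whose collapsed class has
#' spectrum weight above `weight_floor`; the goodness-of-fit statistic
#' is the multinomial chi-square of observed class counts against the
#' spectrum, with degrees of freedom = (classes with nonzero weight) - 1.
#'
#' @param calls non-empty [variant_calls()] table.
#' @param spectrum a [mutagen_spectrum()].
#' @param weight_floor classes with weight above this count as
#'   spectrum-consistent (default 0).
#' @return list with `consistent_fraction`, `chisq`, `df`, `p_value`.
#' @export
spectrum_consistency <- function(calls, spectrum, weight_floor = 0) {
  if (nrow(calls) == 0)
    stop_domain("spectrum consistency needs at least one call")
  cls <- collapsed_classes(calls)
  w <- as.numeric(spectrum)
  names(w) <- SUBSTITUTION_CLASSES
  consistent <- mean(w[cls] > weight_floor)
  nz <- w > 0
  obs <- table(factor(cls, levels = SUBSTITUTION_CLASSES))
  exp <- w * nrow(calls)
  # a zero-weight class observed at all is an impossible outcome
  chisq <- if (any(obs[!nz] > 0)) Inf
  else sum((obs[nz] - exp[nz])^2 / exp[nz])
  df <- sum(nz) - 1L
  list(consistent_fraction = consistent, chisq = as.numeric(chisq),
       df = df,
       p_value = if (is.finite(chisq)) pchisq(chisq, df, lower.tail = FALSE)
       else 0)
}

#' Validate a reverted strain against its mutagen background
#'
#' A strain whose primary site has reverted to wildtype is a *true
#' revertant* only if it still carries a genome-wide mutagen background:
#' enough filtered variants, matching the mutagen's substitution
#' spectrum.  A reverted strain with (almost) no background is suspected
#' wildtype contamination.
#'
#' @param filter_result a [apply_filters()] result with
#'   `retention_status == "REVERTED"`.
#' @param primary the [primary_allele()].
#' @param spectrum the strain's [mutagen_spectrum()].
#' @param min_load minimum background load (passing filtered variants
#'   excluding the primary site) for a true revertant (default 20).
#' @param min_fraction minimum spectrum-consistent fraction (default
#'   0.9).
#' @param weight_floor see [spectrum_consistency()].
#' @return object of class `RevertantVerdict`: list with `status`
#'   (`TRUE_REVERTANT`, `SUSPECTED_CONTAMINATION`, `AMBIGUOUS`),
#'   `background_load`, `spectrum_consistent_fraction`.
#' @export
validate_revertant <- function(filter_result, primary, spectrum,
                               min_load = 20L, min_fraction = 0.9,
                               weight_floor = 0) {
  if (!identical(filter_result$retention_status, "REVERTED"))
    stop_domain("validate_revertant expects a strain with retention ",
                "status REVERTED (got ", filter_result$retention_status, ")")
  bg <- filter_result$passing
  bg <- bg[!(bg$chromosome == primary$chromosome &
               bg$position == primary$position), , drop = FALSE]
  load <- nrow(bg)
  frac <- if (load > 0)
    spectrum_consistency(bg, spectrum, weight_floor)$consistent_fraction
  else 0
  status <- if (load >= min_load && frac >= min_fraction) "TRUE_REVERTANT"
  else if (load < min_load) "SUSPECTED_CONTAMINATION"
  else "AMBIGUOUS"
  structure(list(status = status, background_load = load,
                 spectrum_consistent_fraction = frac),
            class = "RevertantVerdict")
}

#' @export
print.RevertantVerdict <- function(x, ...) {
  cat("<RevertantVerdict> ", x$status, " (background load ",
      x$background_load, ", spectrum-consistent fraction ",
      formatC(x$spectrum_consistent_fraction, digits = 3, format = "f"),
      ")\n", sep = "")
  invisible(x)
}

#' Recurrence of in-gene variants across strains
#'
#' Groups target-gene annotations by exact variant key
#' `(chromosome, position, ref, alt)` and by `(gene, codon)`, counting
#' keys hit by two or more strains -- the raw material of the
#' saturation argument.
#'
#' @param annotations annotation data.frame across strains (restricted
#'   to the target gene by the caller), carrying `strain_id`.
#' @param prior_sites optional data.frame of previously known sites with
#'   columns `position_key` (`"chrom:pos:ref:alt"`) and `label`;
#'   `prior_overlap` counts current position keys present there.
#' @return object of class `RecurrenceReport`: list with `by_position`
#'   (named list of strain-id vectors), `by_codon` (named list of
#'   `strain:protein_change` vectors), `multi_hit_positions`,
#'   `multi_hit_codons`, `prior_overlap`.
#' @export
recurrence_report <- function(annotations, prior_sites = NULL) {
  by_position <- list()
  by_codon <- list()
  if (nrow(annotations)) {
    pkey <- paste(annotations$chromosome, annotations$position,
                  annotations$ref_base, annotations$alt_base, sep = ":")
    for (k in unique(pkey))
      by_position[[k]] <-
        unique(annotations$strain_id[pkey == k])
    coding <- !is.na(annotations$codon_index)
    ckey <- paste(annotations$gene_id[coding],
                  annotations$codon_index[coding], sep = ":")
    for (k in unique(ckey)) {
      rows <- which(coding)[ckey == k]
      by_codon[[k]] <- unique(paste(annotations$strain_id[rows],
                                    annotations$protein_change[rows],
                                    sep = ":"))
    }
  }
  n_strains_pos <- vapply(by_position, length, 0L)
  n_strains_codon <- vapply(by_codon, function(v)
    length(unique(sub(":.*$", "", v))), 0L)
  prior_overlap <- 0L
  if (!is.null(prior_sites) && length(by_position))
    prior_overlap <- sum(names(by_position) %in% prior_sites$position_key)
  structure(list(by_position = by_position, by_codon = by_codon,
                 multi_hit_positions = sum(n_strains_pos >= 2),
                 multi_hit_codons = sum(n_strains_codon >= 2),
                 prior_overlap = prior_overlap),
            class = "RecurrenceReport")
}

#' Qualitative saturation signals of a screen
#'
#' A screen nearing saturation mostly re-isolates known lesions; the
#' recognised signals are a rare reversion event, at least one genomic
#' position hit by multiple strains, and at least one codon hit by
#' multiple strains (plus overlap with previously published sites).  No
#' formal saturation probability is computed.
#'
#' @param report a [recurrence_report()].
#' @param revertant_observed was a reverted strain validated as a true
#'   revertant?
#' @return list with logical `revertant_observed`,
#'   `position_recurrence`, `codon_recurrence`, integer `prior_overlap`,
#'   and a one-line `summary` string.
#' @export
saturation_signals <- function(report, revertant_observed = FALSE) {
  pos <- report$multi_hit_positions >= 1
  cod <- report$multi_hit_codons >= 1
  n_signals <- sum(revertant_observed, pos, cod)
  summary <- paste0(
    n_signals, "/3 saturation signals: ",
    "revertant ", if (revertant_observed) "observed" else "not observed",
    "; ", report$multi_hit_positions, " position(s) hit multiple times",
    "; ", report$multi_hit_codons, " codon(s) hit multiple times",
    "; overlap with prior screen sites: ", report$prior_overlap)
  list(revertant_observed = isTRUE(revertant_observed),
       position_recurrence = pos, codon_recurrence = cod,
       prior_overlap = report$prior_overlap, summary = summary)
}
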