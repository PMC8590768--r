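# Homozygous-variant filtering of per-strain WGS call sets: strict
# depth (> 5) and allele-fraction (> 0.9) thresholds, gene-context
# restriction (coding region or +/- 10 nt of a splice junction, with
# UTRs includable), and de novo status against the parental strain.

REGION_PRIORITY <- c("CODING", "SPLICE_PROX", "UTR5", "UTR3",
                     "INTRONIC", "INTERGENIC")

#' Filtering configuration
#'
#' The depth and allele-fraction thresholds are *strict* inequalities
#' (depth 5 fails, AF 0.9 fails).  `include_utr = TRUE` lets UTR
#' variants within transcript bounds pass the region criterion, which is
#' how upstream suppressor variants (e.g. `c.-4`, `c.-18`) survive; set
#' it `FALSE` for the strict coding/splice-window reading.
#'
#' @param min_depth_exclusive calls need `read_depth >` this (default 5).
#' @param min_af_exclusive calls need `allele_fraction >` this (default
#'   0.9, selecting homozygotes).
#' @param splice_window_nt splice-junction window, nt (default 10).
#' @param include_utr admit UTR5/UTR3 regions (default `TRUE`).
#' @param require_de_novo reject calls also present in the parental
#'   strain (default `TRUE`).
#' @return object of class `FilterConfig`.
#' @export
filter_config <- function(min_depth_exclusive = 5L,
                          min_af_exclusive = 0.9,
                          splice_window_nt = 10L,
                          include_utr = TRUE,
                          require_de_novo = TRUE) {
  if (splice_window_nt < 0) stop_config("splice_window_nt must be >= 0")
  if (min_af_exclusive < 0 || min_af_exclusive >= 1)
    stop_config("min_af_exclusive must lie in [0, 1)")
  structure(list(min_depth_exclusive = as.integer(min_depth_exclusive),
                 min_af_exclusive = min_af_exclusive,
                 splice_window_nt = as.integer(splice_window_nt),
                 include_utr = isTRUE(include_utr),
                 require_de_novo = isTRUE(require_de_novo)),
            class = "FilterConfig")
}

#' Classify the gene context of a genomic position
#'
#' `SPLICE_PROX` means within `splice_window_nt` of an exon-intron
#' junction (on either side) without being coding; `CODING` takes
#' precedence.  UTR classes are strand-aware.  When several transcripts
#' overlap the position, the highest-priority class is returned
#' (`CODING > SPLICE_PROX > UTR5 > UTR3 > INTRONIC > INTERGENIC`).
#'
#' @param transcripts list of [TranscriptModel()].
#' @param chromosome chromosome identifier (verbatim).
#' @param position 1-based genomic position.
#' @param splice_window_nt junction window, nt.
#' @return one of the six region classes.
#' @export
classify_region <- function(transcripts, chromosome, position,
                            splice_window_nt = 10L) {
  if (position < 1) stop_domain("position must be >= 1")
  best <- "INTERGENIC"
  for (tx in transcripts) {
    if (tx$chromosome != chromosome) next
    span <- transcript_span(tx)
    if (position < span[1] || position > span[2]) next
    introns <- transcript_introns(tx)
    near_junction <- FALSE
    if (nrow(introns) > 0 && splice_window_nt > 0) {
      # 1-based distance into the intron from its nearer end, or into
      # the exon from the junction, respectively
      d_in <- pmin(position - introns[, 1] + 1L, introns[, 2] - position + 1L)
      d_ex <- pmin(introns[, 1] - position, position - introns[, 2])
      inside <- position >= introns[, 1] & position <= introns[, 2]
      near_junction <- any(inside & d_in <= splice_window_nt) ||
        any(!inside & d_ex >= 1 & d_ex <= splice_window_nt)
    }
    s <- spliced_position(tx, position)
    cls <- if (is.na(s)) {
      if (near_junction) "SPLICE_PROX" else "INTRONIC"
    } else {
      b <- cds_spliced_bounds(tx)
      if (s >= b["start"] && s <= b["end"]) "CODING"
      else if (near_junction) "SPLICE_PROX"
      else if (s < b["start"]) "UTR5"
      else "UTR3"
    }
    if (match(cls, REGION_PRIORITY) < match(best, REGION_PRIORITY))
      best <- cls
  }
  best
}

#' Filter one strain's calls and check primary-allele retention
#'
#' A call passes iff `read_depth > min_depth_exclusive` AND
#' `allele_fraction > min_af_exclusive` (both strict) AND its region is
#' `CODING`/`SPLICE_PROX` (plus UTRs when `include_utr`) AND, when
#' `require_de_novo`, no parental call matches on the full
#' `(chromosome, position, ref, alt)` tuple.  Rejected calls are tallied
#' under the *first* failed criterion in the fixed order depth ->
#' allele fraction -> region -> de novo, so tallies are deterministic.
#'
#' Retention of the primary lesion is assessed on the *raw* calls:
#' `RETAINED` when the exact primary substitution is present; since
#' calls are made against the wildtype-like reference, absence of any
#' call at the primary site means the strain carries the wildtype base,
#' i.e. `REVERTED`; a different substitution at the site gives
#' `NOT_OBSERVED`.
#'
#' @param calls [variant_calls()] of one strain.
#' @param parental_calls [variant_calls()] of the parental strain (may
#'   be empty).
#' @param transcripts list of [TranscriptModel()].
#' @param config a [filter_config()].
#' @param primary the [primary_allele()], or `NULL` to skip the
#'   retention check.
#' @return object of class `FilterResult`: list with `passing` (the
#'   surviving calls with a `region` column), `rejection_tally` (named
#'   integer: depth, allele_fraction, region, de_novo), `n_input`, and
#'   `retention_status`.
#' @export
apply_filters <- function(calls, parental_calls, transcripts, config,
                          primary = NULL) {
  calls <- validate_variant_calls(as.data.frame(calls))
  if (length(transcripts) == 0)
    stop_config("region filtering needs at least one transcript model")
  if (nrow(calls) && length(unique(calls$strain_id)) > 1)
    stop_domain("apply_filters expects calls from a single strain")

  tally <- c(depth = 0L, allele_fraction = 0L, region = 0L, de_novo = 0L)
  keep <- logical(nrow(calls))
  region <- character(nrow(calls))
  tx_chrom <- vapply(transcripts, `[[`, "", "chromosome")
  tx_start <- vapply(transcripts, function(t) min(t$exons), 0)
  tx_end <- vapply(transcripts, function(t) max(t$exons), 0)
  ok_regions <- c("CODING", "SPLICE_PROX",
                  if (config$include_utr) c("UTR5", "UTR3"))
  parental_keys <- if (!is.null(parental_calls) && nrow(parental_calls))
    paste(parental_calls$chromosome, parental_calls$position,
          parental_calls$ref_base, parental_calls$alt_base)
  else character(0)

  for (i in seq_len(nrow(calls))) {
    hit <- tx_chrom == calls$chromosome[i] &
      tx_start <= calls$position[i] & tx_end >= calls$position[i]
    region[i] <- classify_region(transcripts[hit], calls$chromosome[i],
                                 calls$position[i],
                                 config$splice_window_nt)
    if (calls$read_depth[i] <= config$min_depth_exclusive) {
      tally["depth"] <- tally["depth"] + 1L
    } else if (calls$allele_fraction[i] <= config$min_af_exclusive) {
      tally["allele_fraction"] <- tally["allele_fraction"] + 1L
    } else if (!region[i] %in% ok_regions) {
      tally["region"] <- tally["region"] + 1L
    } else if (config$require_de_novo &&
               paste(calls$chromosome[i], calls$position[i],
                     calls$ref_base[i], calls$alt_base[i]) %in%
               parental_keys) {
      tally["de_novo"] <- tally["de_novo"] + 1L
    } else {
      keep[i] <- TRUE
    }
  }

  retention <- NA_character_
  if (!is.null(primary)) {
    at_site <- calls$chromosome == primary$chromosome &
      calls$position == primary$position
    exact <- at_site & calls$ref_base == primary$wildtype_base &
      calls$alt_base == primary$mutant_base
    retention <- if (any(exact)) "RETAINED"
    else if (any(at_site)) "NOT_OBSERVED"
    else "REVERTED"
  }

  passing <- calls[keep, , drop = FALSE]
  passing$region <- region[keep]
  rownames(passing) <- NULL
  structure(list(passing = passing, rejection_tally = tally,
                 n_input = nrow(calls), retention_status = retention),
            class = "FilterResult")
}

#' @export
print.FilterResult <- function(x, ...) {
  cat("<FilterResult> ", nrow(x$passing), "/", x$n_input,
      " call(s) pass; rejected: ",
      paste(names(x$rejection_tally), x$rejection_tally, sep = "=",
            collapse = ", "),
      "; primary allele: ", x$retention_status, "\n", sep = "")
  invisible(x)
}
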