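# Domain types and format I/O shared by every stage of the pipeline.
# Coordinates are 1-based inclusive at every interface (VCF/GFF3
# convention); chromosome names are taken verbatim from the inputs.

DNA_BASES <- c("A", "C", "G", "T")

#' Construct a genome object
#'
#' A genome is a named set of uppercase DNA sequences (alphabet
#' `A,C,G,T,N`), one per chromosome.  Chromosome names are kept verbatim;
#' no `chr` prefix normalisation is performed.
#'
#' @param sequences named character vector of DNA strings.
#' @return an object of class `Genome`.
#' @examples
#' g <- Genome(c(chrI = "ACGT"))
#' genome_length(g, "chrI")
#' @export
Genome <- function(sequences) {
  if (!is.character(sequences) || length(sequences) == 0)
    stop_format("a Genome needs at least one sequence")
  nm <- names(sequences)
  if (is.null(nm) || any(!nzchar(nm)))
    stop_format("every chromosome needs a non-empty identifier")
  if (anyDuplicated(nm))
    stop_format("duplicate chromosome identifier: ",
                nm[duplicated(nm)][1])
  sequences <- toupper(sequences)
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad))
    stop_format("non-DNA characters in record '", nm[bad][1], "'")
  structure(sequences, class = "Genome")
}

#' @export
print.Genome <- function(x, ...) {
  cat("<Genome> ", length(x), " chromosome(s)\n", sep = "")
  for (nm in names(x))
    cat("  ", nm, ": ", nchar(x[[nm]]), " bp\n", sep = "")
  invisible(x)
}

#' Chromosome length
#' @param genome a [Genome()] object.
#' @param chromosome chromosome identifier.
#' @return integer length in bp.
#' @export
genome_length <- function(genome, chromosome) {
  if (!chromosome %in% names(genome))
    stop_domain("unknown chromosome '", chromosome, "'")
  nchar(genome[[chromosome]])
}

#' Fetch reference bases
#'
#' @param genome a [Genome()] object.
#' @param chromosome chromosome identifier.
#' @param positions 1-based positions.
#' @return character vector of single bases.
#' @export
genome_base <- function(genome, chromosome, positions) {
  len <- genome_length(genome, chromosome)
  if (any(positions < 1 | positions > len))
    stop_domain("position outside chromosome '", chromosome, "'")
  vapply(positions, function(p) substr(genome[[chromosome]], p, p), "")
}

#' Construct a transcript model
#'
#' The coordinate backbone for all annotation: exon structure, strand and
#' CDS bounds of one mRNA.  Exons are 1-based inclusive genomic intervals
#' sorted in ascending genomic order regardless of strand.
#'
#' @param gene_id,transcript_id identifiers.
#' @param chromosome chromosome identifier (verbatim).
#' @param strand `"+"` or `"-"`.
#' @param exons two-column matrix (start, end) of 1-based inclusive
#'   intervals, rows sorted ascending and non-overlapping.
#' @param cds_start_g,cds_end_g genomic positions of the first and last
#'   coding bases (genomic order, i.e. `cds_start_g <= cds_end_g`).
#' @return an object of class `TranscriptModel`.
#' @export
TranscriptModel <- function(gene_id, transcript_id, chromosome, strand,
                            exons, cds_start_g, cds_end_g) {
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (!strand %in% c("+", "-"))
    stop_format("transcript ", transcript_id, ": strand must be + or -")
  if (any(exons[, 1] > exons[, 2]))
    stop_format("transcript ", transcript_id, ": exon start > end")
  if (nrow(exons) > 1) {
    o <- order(exons[, 1])
    if (any(o != seq_len(nrow(exons))))
      stop_format("transcript ", transcript_id, ": exons not sorted")
    if (any(exons[-1, 1] <= exons[-nrow(exons), 2]))
      stop_format("transcript ", transcript_id, ": overlapping exons")
  }
  tx <- structure(list(gene_id = gene_id, transcript_id = transcript_id,
                       chromosome = chromosome, strand = strand,
                       exons = exons,
                       cds_start_g = as.integer(cds_start_g),
                       cds_end_g = as.integer(cds_end_g)),
                  class = "TranscriptModel")
  if (!position_in_exons(tx, cds_start_g) ||
      !position_in_exons(tx, cds_end_g))
    stop_format("transcript ", transcript_id,
                ": CDS bounds outside the exon union")
  clen <- coding_length(tx)
  if (clen <= 0 || clen %% 3L != 0L)
    stop_format("transcript ", transcript_id, ": spliced CDS length ",
                clen, " is not a positive multiple of 3")
  tx
}

#' @export
print.TranscriptModel <- function(x, ...) {
  cat("<TranscriptModel> ", x$transcript_id, " (", x$gene_id, ") ",
      x$chromosome, ":", min(x$exons), "-", max(x$exons), " (", x$strand,
      "), ", nrow(x$exons), " exon(s), CDS ", x$cds_start_g, "-",
      x$cds_end_g, " (", coding_length(x), " nt)\n", sep = "")
  invisible(x)
}

position_in_exons <- function(tx, position) {
  any(position >= tx$exons[, 1] & position <= tx$exons[, 2])
}

transcript_span <- function(tx) c(min(tx$exons), max(tx$exons))

# introns as a (start, end) matrix in genomic order; zero rows if
# single-exon
transcript_introns <- function(tx) {
  n <- nrow(tx$exons)
  if (n < 2) return(matrix(integer(0), ncol = 2,
                           dimnames = list(NULL, c("start", "end"))))
  cbind(start = tx$exons[-n, 2] + 1L, end = tx$exons[-1, 1] - 1L)
}

# 1-based position within the spliced transcript (5' to 3' on the coding
# strand); NA for intronic/off-transcript positions
spliced_position <- function(tx, position) {
  hit <- which(position >= tx$exons[, 1] & position <= tx$exons[, 2])
  if (length(hit) == 0) return(NA_integer_)
  widths <- tx$exons[, 2] - tx$exons[, 1] + 1L
  if (tx$strand == "+") {
    before <- if (hit > 1) sum(widths[seq_len(hit - 1)]) else 0L
    as.integer(before + position - tx$exons[hit, 1] + 1L)
  } else {
    after <- if (hit < nrow(tx$exons))
      sum(widths[seq(hit + 1, nrow(tx$exons))]) else 0L
    as.integer(after + tx$exons[hit, 2] - position + 1L)
  }
}

# inverse of spliced_position for exonic coordinates
genomic_position <- function(tx, spliced) {
  spliced <- unname(spliced)
  widths <- tx$exons[, 2] - tx$exons[, 1] + 1L
  total <- sum(widths)
  if (spliced < 1 || spliced > total)
    stop_domain("spliced position ", spliced, " outside transcript ",
                tx$transcript_id)
  ord <- if (tx$strand == "+") seq_len(nrow(tx$exons)) else
    rev(seq_len(nrow(tx$exons)))
  rem <- spliced
  for (i in ord) {
    if (rem <= widths[i]) {
      return(as.integer(if (tx$strand == "+") tx$exons[i, 1] + rem - 1L
                        else tx$exons[i, 2] - rem + 1L))
    }
    rem <- rem - widths[i]
  }
}

# spliced coordinates of the first/last coding base on the coding strand
cds_spliced_bounds <- function(tx) {
  g1 <- if (tx$strand == "+") tx$cds_start_g else tx$cds_end_g
  g2 <- if (tx$strand == "+") tx$cds_end_g else tx$cds_start_g
  c(start = spliced_position(tx, g1), end = spliced_position(tx, g2))
}

coding_length <- function(tx) {
  b <- cds_spliced_bounds(tx)
  as.integer(b["end"] - b["start"] + 1L)
}

#' Construct a table of variant calls
#'
#' One row per called single-nucleotide substitution in one strain, with
#' the read depth and allele fraction that the homozygosity filter
#' consumes.
#'
#' @param strain_id,chromosome character vectors (recycled).
#' @param position 1-based genomic positions.
#' @param ref_base,alt_base single bases in `A,C,G,T`; `ref_base !=
#'   alt_base` row-wise.
#' @param read_depth non-negative integer depths.
#' @param allele_fraction alternate allele fractions in `[0, 1]`.
#' @return a `data.frame` of class `variant_calls`.
#' @export
variant_calls <- function(strain_id = character(), chromosome = character(),
                          position = integer(), ref_base = character(),
                          alt_base = character(), read_depth = integer(),
                          allele_fraction = numeric()) {
  df <- data.frame(strain_id = as.character(strain_id),
                   chromosome = as.character(chromosome),
                   position = as.integer(position),
                   ref_base = toupper(as.character(ref_base)),
                   alt_base = toupper(as.character(alt_base)),
                   read_depth = as.integer(read_depth),
                   allele_fraction = as.numeric(allele_fraction),
                   stringsAsFactors = FALSE)
  validate_variant_calls(df)
}

#' Validate a variant-call table
#' @param df a data.frame with the `variant_calls` columns.
#' @return `df` with class `variant_calls` prepended.
#' @export
validate_variant_calls <- function(df) {
  need <- c("strain_id", "chromosome", "position", "ref_base", "alt_base",
            "read_depth", "allele_fraction")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_format("variant calls lack column(s): ",
                paste(miss, collapse = ", "))
  if (nrow(df)) {
    if (any(!df$ref_base %in% DNA_BASES) || any(!df$alt_base %in% DNA_BASES))
      stop_format("ref/alt bases must be one of A,C,G,T")
    if (any(df$ref_base == df$alt_base))
      stop_format("ref_base equals alt_base at row ",
                  which(df$ref_base == df$alt_base)[1])
    if (any(df$position < 1))
      stop_format("positions must be >= 1")
    if (any(df$read_depth < 0))
      stop_format("read depth must be non-negative")
    if (any(df$allele_fraction < 0 | df$allele_fraction > 1))
      stop_format("allele fraction must lie in [0, 1]")
  }
  if (!inherits(df, "variant_calls"))
    class(df) <- c("variant_calls", class(df))
  df
}

#' Describe the primary phenotype-causing allele
#'
#' The screen's primary lesion, e.g. a temperature-sensitive missense
#' allele; every strain is checked for its retention or reversion.
#'
#' @param gene_id,chromosome identifiers.
#' @param position 1-based genomic position.
#' @param wildtype_base,mutant_base single distinct bases.
#' @param protein_change display label, e.g. `"P442L"`.
#' @return object of class `PrimaryAllele`.
#' @export
primary_allele <- function(gene_id, chromosome, position, wildtype_base,
                           mutant_base, protein_change = "") {
  wildtype_base <- toupper(wildtype_base)
  mutant_base <- toupper(mutant_base)
  if (wildtype_base == mutant_base)
    stop_format("primary allele: wildtype and mutant base are identical")
  if (!wildtype_base %in% DNA_BASES || !mutant_base %in% DNA_BASES)
    stop_format("primary allele: bases must be one of A,C,G,T")
  structure(list(gene_id = gene_id, chromosome = chromosome,
                 position = as.integer(position),
                 wildtype_base = wildtype_base, mutant_base = mutant_base,
                 protein_change = protein_change),
            class = "PrimaryAllele")
}

# ---------------------------------------------------------------------
# FASTA

#' Read a genome from FASTA
#'
#' @param path FASTA file.
#' @return a [Genome()] with one entry per record, record order
#'   preserved, sequences uppercased.  Record names are truncated at the
#'   first whitespace.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_format("no such file: ", path)
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop_format("not FASTA: ", path,
                                                  " (", conditionMessage(e),
                                                  ")"))
  if (length(set) == 0) stop_format("FASTA file has zero records: ", path)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  Genome(seqs)
}

#' Write a genome to FASTA
#' @param genome a [Genome()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  set <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(set, filepath = path, width = 70L)
  invisible(path)
}

# ---------------------------------------------------------------------
# GFF3

#' Read transcript models from GFF3
#'
#' Expects `gene`/`mRNA`/`exon`/`CDS` features with 1-based inclusive
#' coordinates.  One [TranscriptModel()] is returned per mRNA; CDS bounds
#' are derived from the CDS features and all TranscriptModel invariants
#' are enforced (a CDS whose spliced length is not a multiple of 3 is a
#' model error naming the transcript).
#'
#' @param path GFF3 file.
#' @return list of [TranscriptModel()] in file order.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop_format("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  body <- !grepl("^\\s*(#|$)", lines)
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield != 9L)) {
    lineno <- which(body)[which(nfield != 9L)[1]]
    stop_format("malformed GFF3 line ", lineno, " in ", path, ": expected 9",
                " tab-separated columns, found ", nfield[nfield != 9L][1])
  }
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  mrna <- which(type %in% c("mRNA", "transcript"))
  if (length(mrna) == 0)
    stop_format("no mRNA features in ", path)
  parent1 <- vapply(gr$Parent, function(p)
    if (length(p)) p[1] else NA_character_, "")
  out <- vector("list", length(mrna))
  for (k in seq_along(mrna)) {
    i <- mrna[k]
    tid <- gr$ID[i] %||% paste0("transcript_", k)
    gene <- if (!is.na(parent1[i])) parent1[i] else tid
    kids <- which(!is.na(parent1) & parent1 == tid)
    ex <- kids[type[kids] == "exon"]
    cds <- kids[type[kids] == "CDS"]
    if (length(cds) == 0)
      stop_format("transcript ", tid, " has no CDS features")
    exm <- if (length(ex)) {
      m <- cbind(GenomicRanges::start(gr)[ex], GenomicRanges::end(gr)[ex])
      m[order(m[, 1]), , drop = FALSE]
    } else {
      m <- cbind(GenomicRanges::start(gr)[cds], GenomicRanges::end(gr)[cds])
      m[order(m[, 1]), , drop = FALSE]
    }
    cds_len <- sum(GenomicRanges::end(gr)[cds] -
                     GenomicRanges::start(gr)[cds] + 1L)
    if (cds_len %% 3L != 0L)
      stop_format("transcript ", tid, ": CDS length ", cds_len,
                  " is not a multiple of 3")
    out[[k]] <- TranscriptModel(
      gene_id = gene, transcript_id = tid,
      chromosome = as.character(GenomicRanges::seqnames(gr))[i],
      strand = as.character(GenomicRanges::strand(gr))[i],
      exons = exm,
      cds_start_g = min(GenomicRanges::start(gr)[cds]),
      cds_end_g = max(GenomicRanges::end(gr)[cds]))
  }
  out
}

#' Write transcript models to GFF3
#' @param transcripts list of [TranscriptModel()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(transcripts, path) {
  rows <- list()
  for (tx in transcripts) {
    span <- transcript_span(tx)
    rows[[length(rows) + 1L]] <- data.frame(
      seqnames = tx$chromosome, start = span[1], end = span[2],
      strand = tx$strand, type = "gene", ID = tx$gene_id, Parent = NA)
    rows[[length(rows) + 1L]] <- data.frame(
      seqnames = tx$chromosome, start = span[1], end = span[2],
      strand = tx$strand, type = "mRNA", ID = tx$transcript_id,
      Parent = tx$gene_id)
    for (i in seq_len(nrow(tx$exons)))
      rows[[length(rows) + 1L]] <- data.frame(
        seqnames = tx$chromosome, start = tx$exons[i, 1],
        end = tx$exons[i, 2], strand = tx$strand, type = "exon",
        ID = NA, Parent = tx$transcript_id)
    # CDS features: exon pieces clipped to the CDS bounds
    for (i in seq_len(nrow(tx$exons))) {
      s <- max(tx$exons[i, 1], tx$cds_start_g)
      e <- min(tx$exons[i, 2], tx$cds_end_g)
      if (s <= e)
        rows[[length(rows) + 1L]] <- data.frame(
          seqnames = tx$chromosome, start = s, end = e,
          strand = tx$strand, type = "CDS", ID = NA,
          Parent = tx$transcript_id)
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqnames,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand)
  gr$type <- df$type
  gr$ID <- ifelse(is.na(df$ID), NA_character_, df$ID)
  gr$Parent <- ifelse(is.na(df$Parent), NA_character_, df$Parent)
  # CDS phase is derivable from the model; rtracklayer warns when it is
  # not supplied, which is expected here
  suppressWarnings(rtracklayer::export(gr, path, format = "gff3"))
  invisible(path)
}

# ---------------------------------------------------------------------
# VCF

#' Read single-nucleotide substitutions from a VCF
#'
#' VCF v4.2; only single-base substitutions are retained.  Depth and
#' allele fraction come from `DP` and `AF`, read from either the INFO
#' column or the first sample's FORMAT fields; FORMAT wins when both are
#' present.  Multi-allelic records are split into one call per ALT.
#' Indels and symbolic alleles are skipped with a count; records lacking
#' DP or AF are rejected with a count, never fatally.
#'
#' @param path VCF file (plain or bgzipped).
#' @param strain_id strain label for the calls; defaults to the first
#'   sample name, falling back to the file stem.
#' @return object of class `vcf_calls`: a list with elements `calls` (a
#'   [variant_calls()] table in file order), `n_indels_skipped`, and
#'   `n_rejected` (records lacking DP/AF).
#' @export
read_vcf <- function(path, strain_id = NULL) {
  if (!file.exists(path)) stop_format("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  has_gt <- ncol(v@gt) >= 2
  sample_name <- if (has_gt) colnames(v@gt)[2] else NULL
  if (is.null(strain_id))
    strain_id <- sample_name %||% sub("\\.vcf(\\.gz)?$", "", basename(path))

  info_field <- function(info, key) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]+)"), info))[[1]]
    if (length(m) < 2) NA_character_ else m[2]
  }
  fmt_field <- function(fmt, smp, key) {
    keys <- strsplit(fmt, ":", fixed = TRUE)[[1]]
    vals <- strsplit(smp, ":", fixed = TRUE)[[1]]
    i <- match(key, keys)
    if (is.na(i) || i > length(vals)) NA_character_ else vals[i]
  }

  rows <- vector("list", n)
  n_indel <- 0L
  n_rej <- 0L
  for (i in seq_len(n)) {
    ref <- toupper(fix[i, "REF"])
    alts <- strsplit(toupper(fix[i, "ALT"]), ",", fixed = TRUE)[[1]]
    dp_raw <- NA_character_
    af_raw <- NA_character_
    info <- fix[i, "INFO"]
    if (!is.na(info)) {
      dp_raw <- info_field(info, "DP")
      af_raw <- info_field(info, "AF")
    }
    if (has_gt && !is.na(v@gt[i, 1]) && !is.na(v@gt[i, 2])) {
      dp_fmt <- fmt_field(v@gt[i, 1], v@gt[i, 2], "DP")
      af_fmt <- fmt_field(v@gt[i, 1], v@gt[i, 2], "AF")
      if (!is.na(dp_fmt)) dp_raw <- dp_fmt   # FORMAT wins over INFO
      if (!is.na(af_fmt)) af_raw <- af_fmt
    }
    afs <- if (is.na(af_raw)) NA_character_ else
      strsplit(af_raw, ",", fixed = TRUE)[[1]]
    for (j in seq_along(alts)) {
      alt <- alts[j]
      if (nchar(ref) != 1 || nchar(alt) != 1 ||
          !ref %in% DNA_BASES || !alt %in% DNA_BASES) {
        n_indel <- n_indel + 1L
        next
      }
      af_j <- if (length(afs) >= j) afs[j] else afs[1]
      dp_num <- suppressWarnings(as.numeric(dp_raw))
      af_num <- suppressWarnings(as.numeric(af_j))
      if (is.na(dp_num) || is.na(af_num)) {
        n_rej <- n_rej + 1L
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        strain_id = strain_id, chromosome = fix[i, "CHROM"],
        position = as.integer(fix[i, "POS"]), ref_base = ref,
        alt_base = alt, read_depth = as.integer(dp_num),
        allele_fraction = af_num, stringsAsFactors = FALSE)
    }
  }
  rows <- Filter(Negate(is.null), rows)
  calls <- if (length(rows)) validate_variant_calls(do.call(rbind, rows))
  else variant_calls()
  rownames(calls) <- NULL
  structure(list(calls = calls, n_indels_skipped = n_indel,
                 n_rejected = n_rej),
            class = "vcf_calls")
}

#' @export
print.vcf_calls <- function(x, ...) {
  cat("<vcf_calls> ", nrow(x$calls), " substitution call(s); ",
      x$n_indels_skipped, " indel(s) skipped; ", x$n_rejected,
      " record(s) rejected (missing DP/AF)\n", sep = "")
  invisible(x)
}

#' Write substitution calls as a VCF
#'
#' Emits a minimal single-sample VCF v4.2 with `DP` in INFO and
#' `GT:DP:AF` in FORMAT, the dialect [read_vcf()] prefers.
#'
#' @param calls a [variant_calls()] table for one strain.
#' @param path output path.
#' @param sample_id sample column name; defaults to the strain id.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, sample_id = NULL) {
  calls <- validate_variant_calls(as.data.frame(calls))
  if (nrow(calls) && length(unique(calls$strain_id)) > 1)
    stop_format("write_vcf expects calls from a single strain")
  if (is.null(sample_id))
    sample_id <- if (nrow(calls)) calls$strain_id[1] else "SAMPLE"
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=modscreen",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("##FORMAT=<ID=AF,Number=A,Type=Float,Description=",
           "\"Allele fraction\">"),
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_id, sep = "\t"))
  body <- if (nrow(calls)) {
    ord <- order(calls$chromosome, calls$position)
    calls <- calls[ord, , drop = FALSE]
    paste(calls$chromosome, calls$position, ".", calls$ref_base,
          calls$alt_base, ".", "PASS",
          paste0("DP=", calls$read_depth),
          "GT:DP:AF",
          paste0("1/1:", calls$read_depth, ":",
                 formatC(calls$allele_fraction, format = "g", digits = 6)),
          sep = "\t")
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

# ---------------------------------------------------------------------
# Strain manifest

#' Read a strain manifest
#'
#' Tab-separated table with columns `strain_id`, `mutagen`
#' (`EMS|ENU|EMS+ENU|none`), `vcf_path` and `role`
#' (`suppressor|parental|control`).  Relative `vcf_path`s are resolved
#' against the manifest's directory.
#'
#' @param path TSV file.
#' @return data.frame of class `screen_manifest`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_format("no such file: ", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   comment.char = "#")
  need <- c("strain_id", "mutagen", "vcf_path", "role")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_format("manifest lacks column(s): ", paste(miss, collapse = ", "))
  bad <- !df$mutagen %in% c("EMS", "ENU", "EMS+ENU", "none")
  if (any(bad))
    stop_format("manifest: unknown mutagen '", df$mutagen[bad][1],
                "' for strain ", df$strain_id[bad][1])
  bad <- !df$role %in% c("suppressor", "parental", "control")
  if (any(bad))
    stop_format("manifest: unknown role '", df$role[bad][1],
                "' for strain ", df$strain_id[bad][1])
  rel <- !grepl("^(/|[A-Za-z]:)", df$vcf_path) & nzchar(df$vcf_path)
  df$vcf_path[rel] <- file.path(dirname(path), df$vcf_path[rel])
  class(df) <- c("screen_manifest", class(df))
  df
}
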