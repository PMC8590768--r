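# Orchestration: YAML configuration, the simulate / analyze / phenotype
# / cost stages, and report files.  Every report carries the seed and a
# config hash in comment-style header lines so runs are attributable
# and byte-reproducible.

default_config <- function() {
  list(seed = 1L,
       outdir = "modscreen_out",
       paths = list(genome = NULL, gff3 = NULL, manifest = NULL,
                    hatch = NULL, population = NULL, prior_sites = NULL),
       filter = list(min_depth_exclusive = 5, min_af_exclusive = 0.9,
                     splice_window_nt = 10, include_utr = TRUE,
                     require_de_novo = TRUE),
       spectra = list(),
       revertant = list(min_load = 20, min_fraction = 0.9),
       phenotype = list(threshold = 50, horizon = 30, brood_mean = 200,
                        n_plates = 10),
       plan = list(n_strains = 50, mutation_load_mean = 110,
                   fraction_intragenic = 0.12, fraction_revertant = 0.01,
                   fraction_contamination = 0.01, depth_mean = 30,
                   af_homozygous_concentration = 60),
       decoys = list(n_genes = 300, chrom_length = 2000000,
                     gc_fraction = 0.36),
       primary = list(gene_id = "zyg-1-like", chromosome = "II",
                      position = 5653339, wildtype_base = "C",
                      mutant_base = "T", protein_change = "P442L"),
       cost = list(n_strains = 100))
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Load a run configuration
#'
#' Reads a YAML file (or takes a list), merges it over the package
#' defaults, and stamps it with an md5 of its canonical YAML rendering.
#' Recognised blocks: `seed`, `outdir`, `paths` (genome, gff3,
#' manifest, hatch, population, prior_sites), `filter` (the
#' [filter_config()] fields), `spectra` (per-mutagen weight overrides),
#' `revertant` (min_load, min_fraction), `phenotype` (threshold,
#' horizon, brood_mean, n_plates), `plan` (the [screen_plan()] fields),
#' `decoys`, `primary`, `cost`.
#'
#' @param config path to a YAML file, or a list of overrides, or `NULL`
#'   for pure defaults.
#' @param seed optional seed override.
#' @return object of class `RunConfig`.
#' @export
run_config <- function(config = NULL, seed = NULL) {
  override <- if (is.null(config)) list()
  else if (is.character(config)) {
    if (!file.exists(config)) stop_config("no such config file: ", config)
    yaml::read_yaml(config) %||% list()
  } else if (is.list(config)) config
  else stop_config("config must be a YAML path or a list")
  cfg <- merge_config(default_config(), override)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  # hash the scientific configuration; the output location does not
  # change what is computed
  hashable <- cfg
  hashable$outdir <- NULL
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(hashable, tf)
  cfg$md5 <- unname(tools::md5sum(tf))
  structure(cfg, class = "RunConfig")
}

report_header <- function(config) {
  c(paste0("# modscreen seed=", config$seed),
    paste0("# config_md5=", config$md5))
}

write_report_tsv <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(report_header(config), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_report_tsv <- function(path) {
  read.delim(path, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE)
}

config_spectrum <- function(config, mutagen) {
  ov <- config$spectra[[mutagen]]
  default_spectrum(mutagen,
                   weights = if (!is.null(ov)) unlist(ov) else NULL)
}

config_filter <- function(config) {
  do.call(filter_config, config$filter)
}

config_primary <- function(config) {
  do.call(primary_allele, config$primary)
}

#' Read a prior-screen site table
#'
#' Two-column TSV: `position_key` (`chrom:pos:ref:alt`) and `label`.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_prior_sites <- function(path) {
  df <- read.delim(path, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  if (!all(c("position_key", "label") %in% names(df)))
    stop_format("prior-site table needs columns position_key, label")
  df
}

#' Generate a synthetic screen bundle on disk
#'
#' Builds the target-gene fixture plus a decoy chromosome carrying many
#' random genes, simulates every strain of the plan (labels allocated
#' by the plan fractions, mutagens cycling EMS / ENU / EMS+ENU), and
#' writes: `genome.fasta`, `transcripts.gff3`, per-strain VCFs under
#' `vcf/`, a parental-strain VCF (primary lesion only), `manifest.tsv`,
#' `truth.tsv` and phenotype tables `hatch.tsv` / `population.tsv`.
#' Deterministic for a fixed config seed.
#'
#' @param config a [run_config()] (or anything it accepts).
#' @param outdir output directory (default from config).
#' @return invisibly, a list with the in-memory `genome`,
#'   `transcripts`, `primary`, `strains` and `truth` table.
#' @export
cmd_simulate <- function(config = NULL, outdir = NULL) {
  config <- if (inherits(config, "RunConfig")) config else run_config(config)
  outdir <- outdir %||% config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(outdir, 2) != 0)
    stop_config("output directory not writable: ", outdir)
  dir.create(file.path(outdir, "vcf"), showWarnings = FALSE)

  fx <- build_fixture_transcript()
  decoy_genome <- simulate_genome(
    c(I = config$decoys$chrom_length),
    gc_fraction = config$decoys$gc_fraction, seed = config$seed)
  genome <- Genome(c(unclass(decoy_genome), unclass(fx$genome)))
  decoys <- simulate_transcripts(decoy_genome,
                                 n_genes = config$decoys$n_genes,
                                 seed = config$seed + 1L)
  transcripts <- c(list(fx$transcript), decoys)
  primary <- config_primary(config)
  plan <- do.call(screen_plan, c(config$plan, list(seed = config$seed)))
  site_index <- build_site_index(transcripts, genome,
                                 config$filter$splice_window_nt)

  n <- plan$n_strains
  n_intra <- round(plan$fraction_intragenic * n)
  n_rev <- round(plan$fraction_revertant * n)
  n_cont <- round(plan$fraction_contamination * n)
  labels <- c(rep("INTRAGENIC_SUPPRESSOR", n_intra),
              rep("REVERTANT", n_rev),
              rep("CONTAMINATION", n_cont),
              rep("EXTRAGENIC_SUPPRESSOR", n - n_intra - n_rev - n_cont))
  labels <- with_seed(plan$seed, sample(labels))
  mutagens <- rep(c("EMS", "ENU", "EMS+ENU"), length.out = n)

  strains <- vector("list", n)
  truth_rows <- vector("list", n)
  hatch_all <- list()
  pop_all <- list()
  for (i in seq_len(n)) {
    sid <- sprintf("SIM%03d", i)
    spectrum <- config_spectrum(config, mutagens[i])
    st <- simulate_strain(genome, transcripts, primary, spectrum, plan,
                          truth_label = labels[i], strain_id = sid,
                          mutagen = mutagens[i], site_index = site_index)
    strains[[i]] <- st
    write_vcf(st$calls, file.path(outdir, "vcf", paste0(sid, ".vcf")),
              sample_id = sid)
    strength <- with_seed(strain_seed(plan$seed, paste0(sid, "_pheno")),
                          switch(labels[i],
                                 REVERTANT = 0.99,
                                 CONTAMINATION = runif(1, 0.85, 0.98),
                                 runif(1, 0.1, 0.95)))
    ph <- simulate_phenotype(strength,
                             n_plates = config$phenotype$n_plates,
                             seed = strain_seed(plan$seed,
                                                paste0(sid, "_plates")),
                             strain_id = sid,
                             brood_mean = config$phenotype$brood_mean,
                             horizon = config$phenotype$horizon)
    hatch_all[[i]] <- ph$hatch
    pop_all[[i]] <- ph$population
    pv <- st$planted_variant
    truth_rows[[i]] <- data.frame(
      strain_id = sid, truth_label = labels[i], mutagen = mutagens[i],
      planted_chromosome = if (is.null(pv)) NA else pv$chromosome,
      planted_position = if (is.null(pv)) NA else pv$position,
      planted_ref = if (is.null(pv)) NA else pv$ref_base,
      planted_alt = if (is.null(pv)) NA else pv$alt_base,
      suppression_strength = strength, stringsAsFactors = FALSE)
  }

  # parental strain: carries the primary lesion only
  parental_calls <- variant_calls("PARENTAL", primary$chromosome,
                                  primary$position, primary$wildtype_base,
                                  primary$mutant_base, 40L, 0.99)
  write_vcf(parental_calls, file.path(outdir, "vcf", "PARENTAL.vcf"),
            sample_id = "PARENTAL")

  write_fasta(genome, file.path(outdir, "genome.fasta"))
  write_gff3(transcripts, file.path(outdir, "transcripts.gff3"))
  truth <- do.call(rbind, truth_rows)
  write_report_tsv(truth, file.path(outdir, "truth.tsv"), config)
  manifest <- data.frame(
    strain_id = c(vapply(strains, `[[`, "", "strain_id"), "PARENTAL"),
    mutagen = c(mutagens, "none"),
    vcf_path = file.path("vcf", c(paste0(vapply(strains, `[[`, "",
                                                "strain_id"), ".vcf"),
                                  "PARENTAL.vcf")),
    role = c(rep("suppressor", n), "parental"), stringsAsFactors = FALSE)
  write_report_tsv(manifest, file.path(outdir, "manifest.tsv"), config)
  write_report_tsv(do.call(rbind, hatch_all),
                   file.path(outdir, "hatch.tsv"), config)
  write_report_tsv(do.call(rbind, pop_all),
                   file.path(outdir, "population.tsv"), config)
  invisible(list(genome = genome, transcripts = transcripts,
                 primary = primary, strains = strains, truth = truth))
}

#' Analyze a screen: filter, annotate, interpret
#'
#' Consumes a genome, gene models and a strain manifest (either from a
#' [cmd_simulate()] bundle or user-supplied), runs the filter ->
#' annotate -> interpret chain for every suppressor strain, and writes
#' a candidate table in the per-strain layout of a screen overview
#' (strain, mutagen, filtered-variant count, position, ref/alt,
#' effects), a `recurrence.tsv`, and a `summary.json` holding rejection
#' tallies, retention statuses, revertant verdicts and saturation
#' signals.
#'
#' @param config a [run_config()]; `paths$genome`, `paths$gff3` and
#'   `paths$manifest` must resolve (they default to a bundle under
#'   `outdir`).
#' @param outdir report directory (default from config).
#' @return invisibly, a list with `per_strain` (list), `candidates`
#'   (data.frame), `recurrence`, `signals`, `n_strains`.
#' @export
cmd_analyze <- function(config = NULL, outdir = NULL) {
  config <- if (inherits(config, "RunConfig")) config else run_config(config)
  outdir <- outdir %||% config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  genome_path <- config$paths$genome %||% file.path(outdir, "genome.fasta")
  gff3_path <- config$paths$gff3 %||% file.path(outdir, "transcripts.gff3")
  manifest_path <- config$paths$manifest %||%
    file.path(outdir, "manifest.tsv")
  for (p in c(genome_path, gff3_path, manifest_path))
    if (!file.exists(p)) stop_config("missing input: ", p)

  genome <- read_fasta(genome_path)
  transcripts <- read_gff3(gff3_path)
  manifest <- read_manifest(manifest_path)
  fcfg <- config_filter(config)
  primary <- config_primary(config)
  prior <- if (!is.null(config$paths$prior_sites))
    read_prior_sites(config$paths$prior_sites) else NULL

  suppressors <- manifest[manifest$role == "suppressor", , drop = FALSE]
  parental_rows <- manifest[manifest$role == "parental", , drop = FALSE]
  parental_calls <- if (nrow(parental_rows)) {
    if (!file.exists(parental_rows$vcf_path[1]))
      stop_config("parental strain ", parental_rows$strain_id[1],
                  " has no VCF at ", parental_rows$vcf_path[1])
    read_vcf(parental_rows$vcf_path[1],
             strain_id = parental_rows$strain_id[1])$calls
  } else variant_calls()

  if (nrow(suppressors) == 0)
    warning("manifest lists no suppressor strains; reports will be empty")

  per_strain <- list()
  cand_rows <- list()
  gene_annotations <- list()
  revertant_validated <- FALSE
  for (i in seq_len(nrow(suppressors))) {
    sid <- suppressors$strain_id[i]
    vcf_path <- suppressors$vcf_path[i]
    if (!file.exists(vcf_path))
      stop_config("strain ", sid, " has no VCF at ", vcf_path)
    vc <- read_vcf(vcf_path, strain_id = sid)
    fr <- apply_filters(vc$calls, parental_calls, transcripts, fcfg,
                        primary)
    ann <- annotate_calls(transcripts, genome, fr$passing,
                          splice_window_nt = fcfg$splice_window_nt)
    in_gene <- ann[ann$gene_id == primary$gene_id, , drop = FALSE]
    spectrum <- config_spectrum(
      config, if (suppressors$mutagen[i] == "none") "EMS+ENU"
      else suppressors$mutagen[i])
    verdict <- NULL
    if (identical(fr$retention_status, "REVERTED")) {
      verdict <- validate_revertant(
        fr, primary, spectrum,
        min_load = config$revertant$min_load,
        min_fraction = config$revertant$min_fraction)
      if (verdict$status == "TRUE_REVERTANT") revertant_validated <- TRUE
    }
    complex_label <- if (nrow(in_gene) >= 1)
      group_complex_alleles(in_gene)[[primary$gene_id]] else NA_character_
    per_strain[[sid]] <- list(
      strain_id = sid, mutagen = suppressors$mutagen[i],
      n_input = fr$n_input, n_passing = nrow(fr$passing),
      rejection_tally = as.list(fr$rejection_tally),
      n_indels_skipped = vc$n_indels_skipped,
      n_rejected_missing_fields = vc$n_rejected,
      retention_status = fr$retention_status,
      revertant_verdict = if (is.null(verdict)) NULL else
        list(status = verdict$status,
             background_load = verdict$background_load,
             spectrum_consistent_fraction =
               verdict$spectrum_consistent_fraction),
      burden = burden_summary(ann),
      complex_allele = complex_label,
      n_intragenic_candidates = nrow(in_gene))
    if (nrow(in_gene)) {
      gene_annotations[[sid]] <- in_gene
      cand_rows[[sid]] <- data.frame(
        strain_id = sid, mutagen = suppressors$mutagen[i],
        n_filtered = nrow(fr$passing),
        chromosome = in_gene$chromosome, position = in_gene$position,
        ref_alt = paste0(in_gene$ref_base, "/", in_gene$alt_base),
        effect = ifelse(nzchar(in_gene$p_hgvs),
                        paste0(in_gene$c_hgvs, "; ", in_gene$p_hgvs),
                        in_gene$c_hgvs),
        retention_status = fr$retention_status,
        flag = if (is.null(verdict)) "" else verdict$status,
        stringsAsFactors = FALSE)
    } else if (identical(fr$retention_status, "REVERTED")) {
      cand_rows[[sid]] <- data.frame(
        strain_id = sid, mutagen = suppressors$mutagen[i],
        n_filtered = nrow(fr$passing), chromosome = primary$chromosome,
        position = primary$position,
        ref_alt = paste0(primary$mutant_base, "/",
                         primary$wildtype_base),
        effect = "Revertant", retention_status = fr$retention_status,
        flag = if (is.null(verdict)) "" else verdict$status,
        stringsAsFactors = FALSE)
    }
  }

  candidates <- if (length(cand_rows)) do.call(rbind, cand_rows)
  else data.frame(strain_id = character(), mutagen = character(),
                  n_filtered = integer(), chromosome = character(),
                  position = integer(), ref_alt = character(),
                  effect = character(), retention_status = character(),
                  flag = character(), stringsAsFactors = FALSE)
  rownames(candidates) <- NULL
  all_gene_ann <- if (length(gene_annotations))
    do.call(rbind, gene_annotations) else annotate_empty()
  recur <- recurrence_report(all_gene_ann, prior_sites = prior)
  signals <- saturation_signals(recur, revertant_validated)

  write_report_tsv(candidates, file.path(outdir, "candidates.tsv"),
                   config)
  recur_df <- data.frame(
    position_key = names(recur$by_position),
    n_strains = vapply(recur$by_position, length, 0L),
    strains = vapply(recur$by_position, paste, "", collapse = ","),
    stringsAsFactors = FALSE)
  write_report_tsv(recur_df, file.path(outdir, "recurrence.tsv"), config)
  jsonlite::write_json(
    list(seed = config$seed, config_md5 = config$md5,
         n_strains = nrow(suppressors), per_strain = per_strain,
         recurrence = list(multi_hit_positions = recur$multi_hit_positions,
                           multi_hit_codons = recur$multi_hit_codons,
                           prior_overlap = recur$prior_overlap),
         saturation = signals),
    file.path(outdir, "summary.json"), auto_unbox = TRUE, pretty = TRUE,
    null = "null")
  invisible(list(per_strain = per_strain, candidates = candidates,
                 recurrence = recur, signals = signals,
                 n_strains = nrow(suppressors)))
}

#' Summarise phenotype assays and emit survival curves
#'
#' Reads the hatch and population tables, writes a per-strain summary
#' TSV (mean eggs laid, pooled hatching rate, percent of plates
#' reaching each metric, percent died, N) and one curve TSV per
#' population metric (day, at-risk, events, censored, survival) pooled
#' per strain.
#'
#' @param config a [run_config()]; `paths$hatch` / `paths$population`
#'   default to the bundle under `outdir`.
#' @param outdir report directory.
#' @return invisibly, list with `summary` and `curves` (nested list
#'   strain -> metric -> [km_curve()]).
#' @export
cmd_phenotype <- function(config = NULL, outdir = NULL) {
  config <- if (inherits(config, "RunConfig")) config else run_config(config)
  outdir <- outdir %||% config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hatch_path <- config$paths$hatch %||% file.path(outdir, "hatch.tsv")
  pop_path <- config$paths$population %||%
    file.path(outdir, "population.tsv")
  for (p in c(hatch_path, pop_path))
    if (!file.exists(p)) stop_config("missing input: ", p)
  hatch <- read_report_tsv(hatch_path)
  population <- read_report_tsv(pop_path)

  summary <- strain_summary(hatch, population,
                            threshold = config$phenotype$threshold,
                            horizon = config$phenotype$horizon)
  write_report_tsv(summary, file.path(outdir, "phenotype_summary.tsv"),
                   config)

  curves <- list()
  curve_rows <- list()
  for (s in unique(population$strain_id)) {
    p <- population[population$strain_id == s, , drop = FALSE]
    ev <- do.call(rbind, lapply(split(p, p$plate_id), population_events,
                                threshold = config$phenotype$threshold,
                                horizon = config$phenotype$horizon))
    for (m in unique(ev$metric)) {
      cv <- km_curve(ev[ev$metric == m, , drop = FALSE])
      curves[[s]][[m]] <- cv
      curve_rows[[paste(s, m)]] <- data.frame(
        strain_id = s, metric = m, day = cv$event_times,
        at_risk = cv$n_risk, events = cv$n_events,
        censored = cv$n_censored, survival = cv$estimates,
        stringsAsFactors = FALSE)
    }
  }
  write_report_tsv(do.call(rbind, curve_rows),
                   file.path(outdir, "population_curves.tsv"), config)
  invisible(list(summary = summary, curves = curves))
}

#' Write the Sanger-vs-WGS cost comparison
#'
#' @param config a [run_config()]; `cost$n_strains` sets the screen
#'   size, `cost$sanger` / `cost$wgs` may override component costs.
#' @param outdir report directory.
#' @return invisibly, the [compare_costs()] result.
#' @export
cmd_cost <- function(config = NULL, outdir = NULL) {
  config <- if (inherits(config, "RunConfig")) config else run_config(config)
  outdir <- outdir %||% config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  n <- config$cost$n_strains
  sg <- if (!is.null(config$cost$sanger))
    cost_profile("SANGER", unlist(config$cost$sanger),
                 hands_on_hours = config$cost$sanger_hours %||% 60,
                 n_strains = n)
  else sanger_profile(n)
  wg <- if (!is.null(config$cost$wgs))
    cost_profile("WGS", unlist(config$cost$wgs),
                 hands_on_hours = config$cost$wgs_hours %||% 7,
                 n_strains = n)
  else wgs_profile(n)
  cmp <- compare_costs(sg, wg)
  df <- data.frame(method = cmp$methods,
                   n_strains = cmp$n_strains,
                   per_strain = as.numeric(cmp$per_strain),
                   total = as.numeric(cmp$totals),
                   hands_on_hours = as.numeric(cmp$hands_on_hours),
                   stringsAsFactors = FALSE)
  write_report_tsv(df, file.path(outdir, "cost_report.tsv"), config)
  invisible(cmp)
}
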