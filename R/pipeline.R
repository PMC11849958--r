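# Pipeline assembly: config handling, stage runners over files on disk,
# reporting arithmetic, and manifests. Each stage reads the previous
# stage's outputs, so the whole analysis is reproducible from a single
# config.

#' Round-half-up percentage
#'
#' Whole-percent reporting: `100 * num / den`, rounded half-up (0.5 always
#' rounds away from zero towards the larger percent), the convention used
#' in summary tables of this kind.
#'
#' @param num,den numerator and denominator (den > 0), or `num` may be a
#'   pre-computed percentage when `den` is omitted.
#' @return integer percent.
#' @export
report_percent <- function(num, den = 100) {
  if (any(den <= 0)) stop("denominator must be > 0")
  as.integer(floor(100 * num / den + 0.5))
}

#' Read a pipeline configuration
#'
#' YAML key-value file; unknown keys are an error (they usually mean a
#' typo). See [default_pipeline_config()] for the schema and defaults.
#'
#' @param path YAML file path.
#' @return a `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_pipeline_config()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("invalid config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(user)] <- user
  structure(cfg, class = "pipeline_config")
}

#' Default pipeline configuration
#'
#' @return a `pipeline_config` list of all recognized keys: input paths
#'   (defaulting to the files [run_simulate()] writes under `data_dir`),
#'   analysis parameters (bin size, pseudocounts, thresholds, promoter
#'   window, RNA fold threshold, minimum nuclear expression), the output
#'   directory and the simulation seed.
#' @export
default_pipeline_config <- function() {
  structure(list(
    data_dir = "nad_data",
    out_dir = "nad_out",
    chrom_sizes = NULL, gtf = NULL, bin_counts = NULL,
    expression = NULL, samples = NULL,
    peaks_atac = NULL, peaks_h3k4me3 = NULL, peaks_pol2 = NULL,
    repeats = NULL,
    cell_line = "synthetic",
    bin_size = 1e5,
    pseudocount = 0.5,
    background = "median",
    nad_threshold = 2,
    max_gap_bins = 0,
    min_overlap = 1,
    promoter_upstream = 2000,
    promoter_downstream = 500,
    rna_fold = 2,
    rna_pseudocount = 0.5,
    min_expr = 1,
    seed = 42), class = "pipeline_config")
}

# resolve an input path: explicit config key, else the simulate output
cfg_path <- function(cfg, key, default_file) {
  p <- cfg[[key]]
  if (is.null(p)) p <- file.path(cfg$data_dir, default_file)
  if (!file.exists(p))
    stop("missing input for '", key, "': ", p,
         " (produce it with run_simulate() or point the config at it)")
  p
}

# short hash of the config, recorded in every stage manifest
config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(names(cfg),
                   vapply(cfg, function(v) paste(format(v), collapse = ","),
                          ""), sep = "="), tmp)
  unname(tools::md5sum(tmp))
}

write_stage_manifest <- function(cfg, stage, files) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(cfg$out_dir, paste0(stage, "_manifest.json"))
  jsonlite::write_json(list(stage = stage, config_hash = config_hash(cfg),
                            files = as.list(files)),
                       path, auto_unbox = TRUE, pretty = TRUE)
  path
}

#' Pipeline stage: simulate
#'
#' Writes the default synthetic study (at the config's seed) under
#' `data_dir`.
#'
#' @param cfg a `pipeline_config` (or path to a YAML config).
#' @return the written file paths, invisibly.
#' @export
run_simulate <- function(cfg = default_pipeline_config()) {
  cfg <- as_pipeline_config(cfg)
  sim <- simulate_nad_study(nad_sim_config(seed = cfg$seed,
                                           bin_size = cfg$bin_size),
                            dir = cfg$data_dir)
  invisible(sim$files)
}

as_pipeline_config <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  cfg
}

#' Pipeline stage: call NADs
#'
#' Reads the bin-count table, fits the NAD segmentation and writes the
#' segment BED, log2-ratio bedGraph, per-chromosome table and a JSON
#' summary.
#'
#' @param cfg a `pipeline_config` (or YAML path).
#' @return the `nad_call`, invisibly.
#' @export
run_call_nads <- function(cfg = default_pipeline_config()) {
  cfg <- as_pipeline_config(cfg)
  assembly <- read_chrom_sizes(cfg_path(cfg, "chrom_sizes",
                                        "genome.chrom.sizes"))
  grid <- make_bins(assembly, cfg$bin_size)
  counts <- read_bin_counts(cfg_path(cfg, "bin_counts", "bin_counts.tsv"),
                            grid)
  nads <- call_nads(counts, threshold = cfg$nad_threshold,
                    max_gap_bins = cfg$max_gap_bins,
                    pseudocount = cfg$pseudocount,
                    background = cfg$background)
  files <- write_nad_results(nads, cfg$out_dir)
  sm <- file.path(cfg$out_dir, "nads_summary.json")
  jsonlite::write_json(list(
    threshold = nads$threshold,
    n_segments = nrow(nads$segments),
    n_positive_bins = sum(nads$bin_positive),
    genome_fraction_pct = nads$genome_fraction),
    sm, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files["summary"] <- sm
  write_stage_manifest(cfg, "call_nads", files)
  invisible(nads)
}

#' Pipeline stage: annotate NAGs
#'
#' @param cfg a `pipeline_config` (or YAML path).
#' @param nads optional `nad_call` (recomputed from the config otherwise).
#' @return the `nag_set`, invisibly.
#' @export
run_annotate <- function(cfg = default_pipeline_config(), nads = NULL) {
  cfg <- as_pipeline_config(cfg)
  if (is.null(nads)) nads <- run_call_nads(cfg)
  genes <- read_gtf_genes(cfg_path(cfg, "gtf", "genes.gtf"))
  nags <- annotate_nags(nads, genes, min_overlap = cfg$min_overlap,
                        cell_line = cfg$cell_line)
  tsv <- file.path(cfg$out_dir, "nags.tsv")
  write_nag_table(nags, tsv)
  comp <- biotype_composition(nags)
  cj <- file.path(cfg$out_dir, "nag_biotypes.json")
  jsonlite::write_json(list(n = comp$n,
                            coding_fraction = comp$coding_fraction,
                            by_class = comp$by_class),
                       cj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_stage_manifest(cfg, "annotate", c(nags = tsv, biotypes = cj))
  invisible(nags)
}

#' Pipeline stage: integrate activity assays
#'
#' @param cfg a `pipeline_config` (or YAML path).
#' @param nags optional `nag_set` (recomputed otherwise).
#' @return the `nag_activity`, invisibly.
#' @export
run_integrate <- function(cfg = default_pipeline_config(), nags = NULL) {
  cfg <- as_pipeline_config(cfg)
  if (is.null(nags)) nags <- run_annotate(cfg)
  genes <- read_gtf_genes(cfg_path(cfg, "gtf", "genes.gtf"))
  atac <- read_bed(cfg_path(cfg, "peaks_atac", "peaks_ATAC.bed"))
  h3k4 <- read_bed(cfg_path(cfg, "peaks_h3k4me3", "peaks_H3K4me3.bed"))
  pol2 <- read_bed(cfg_path(cfg, "peaks_pol2", "peaks_POL2.bed"))
  act <- classify_active_nags(nags, genes, atac = atac, h3k4me3 = h3k4,
                              pol2 = pol2,
                              upstream = cfg$promoter_upstream,
                              downstream = cfg$promoter_downstream)
  tsv <- file.path(cfg$out_dir, "nag_activity.tsv")
  write.table(as.data.frame(act), tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  sj <- file.path(cfg$out_dir, "summary_row.json")
  jsonlite::write_json(unclass(attr(act, "summary")), sj,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_stage_manifest(cfg, "integrate", c(activity = tsv, summary = sj))
  invisible(act)
}

#' Pipeline stage: RNA enrichment
#'
#' @param cfg a `pipeline_config` (or YAML path).
#' @param nags optional `nag_set` (recomputed otherwise).
#' @return list of `calls` (`enrichment_call`) and `partition`
#'   (`nag_partition`), invisibly.
#' @export
run_rna <- function(cfg = default_pipeline_config(), nags = NULL) {
  cfg <- as_pipeline_config(cfg)
  if (is.null(nags)) nags <- run_annotate(cfg)
  genes <- read_gtf_genes(cfg_path(cfg, "gtf", "genes.gtf"))
  expr <- read.table(cfg_path(cfg, "expression", "expression.tsv"),
                     sep = "\t", header = TRUE, check.names = FALSE,
                     stringsAsFactors = FALSE)
  counts <- as.matrix(expr[, -1, drop = FALSE])
  rownames(counts) <- expr[[1]]
  samples <- read.table(cfg_path(cfg, "samples", "samples.tsv"),
                        sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  tab <- normalize_expression(expression_table(counts, samples))
  calls <- call_nucleolar_enriched(tab, fold = cfg$rna_fold,
                                   pseudocount = cfg$rna_pseudocount,
                                   genes = genes)
  part <- nag_transcription_partition(nags, calls, tab,
                                      min_expr = cfg$min_expr)
  ct <- file.path(cfg$out_dir, "rna_enrichment.tsv")
  write.table(as.data.frame(calls), ct, sep = "\t", quote = FALSE,
              row.names = FALSE)
  pt <- file.path(cfg$out_dir, "nag_partition.tsv")
  write.table(data.frame(class = names(part$counts),
                         n = as.integer(part$counts)),
              pt, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(enrichment = ct, partition = pt)
  if (sum(calls$enriched) > 0) {
    comp <- nucleolar_transcriptome_composition(calls)
    cj <- file.path(cfg$out_dir, "nucleolar_composition.json")
    jsonlite::write_json(list(n = comp$n,
                              coding_fraction = comp$coding_fraction,
                              by_class = comp$by_class),
                         cj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files["composition"] <- cj
  }
  write_stage_manifest(cfg, "rna", files)
  invisible(list(calls = calls, partition = part))
}

#' Pipeline stage: assembled report
#'
#' Runs the full pipeline and writes the report bundle: the per-cell-line
#' summary row (with transcript-compartment counts merged in), the
#' genome-fraction figure data, the per-chromosome contribution table and
#' the per-bin track, all listed in a manifest carrying the config hash.
#'
#' @param cfg a `pipeline_config` (or YAML path).
#' @return the report list, invisibly.
#' @export
run_report <- function(cfg = default_pipeline_config()) {
  cfg <- as_pipeline_config(cfg)
  nads <- run_call_nads(cfg)
  nags <- run_annotate(cfg, nads)
  act <- run_integrate(cfg, nags)
  rna <- run_rna(cfg, nags)
  base_sr <- attr(act, "summary")
  cls <- rna$partition$classes
  bt <- nags$biotype[match(cls$gene_id, nags$gene_id)]
  split_of <- function(which) c(
    protein_coding = sum(cls$class == which & bt == "protein_coding"),
    non_coding = sum(cls$class == which & bt != "protein_coding"))
  sr <- summary_row(
    cell_line = base_sr$cell_line, n_nad = base_sr$n_nad,
    n_nag = base_sr$n_nag,
    n_nag_accessible = base_sr$n_nag_accessible,
    n_nag_promoter_accessible = base_sr$n_nag_promoter_accessible,
    n_nag_h3k4me3 = base_sr$n_nag_h3k4me3,
    n_nag_pol2 = base_sr$n_nag_pol2,
    n_double = base_sr$n_double,
    triple_marked = if (is.null(base_sr$triple_split)) base_sr$n_triple
      else unlist(base_sr$triple_split),
    nuclear_transcripts = split_of("nuclear_only"),
    nucleolar_transcripts = split_of("nucleolar"))
  report <- list(
    summary_row = sr,
    genome_fraction_pct = report_percent(nads$genome_fraction),
    pct_nags_active = if (!is.na(sr$n_triple))
      report_percent(sr$n_triple, sr$n_nag) else NA,
    per_chromosome = chromosome_contribution(nads))
  st <- file.path(cfg$out_dir, "report_summary.tsv")
  write.table(as.data.frame(sr), st, sep = "\t", quote = FALSE,
              row.names = FALSE)
  rj <- file.path(cfg$out_dir, "report.json")
  jsonlite::write_json(list(
    summary_row = unclass(sr),
    genome_fraction_pct = report$genome_fraction_pct,
    pct_nags_active = report$pct_nags_active),
    rj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_stage_manifest(cfg, "report", c(summary = st, report = rj))
  invisible(report)
}
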