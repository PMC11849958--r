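# Seeded synthetic-data generator: genome + gene models, planted NADs,
# negative-binomial two-library bin counts, promoter peak sets, and
# compartmentalized expression, with serialized ground truth. Every stage of
# the pipeline is testable against the planted truth without any download.

#' Simulation configuration
#'
#' All knobs of the synthetic NAD study, validated and frozen together with
#' the seed. Defaults describe a desk-scale study: 3 chromosomes x 20 Mb in
#' 100-kb bins (600 bins), 1000 non-overlapping genes, a quarter of the
#' genome nucleolus-associated with 4-fold mean enrichment over a 1x
#' background, sequencing depth 100 reads per bin per library with
#' negative-binomial dispersion (size) 10, and the triplicate library
#' design typical of indexed DNA library preparation.
#'
#' @param seed integer RNG seed (every stage derives its stream from it).
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param bin_size bin width in bp.
#' @param n_genes number of genes to place.
#' @param gene_length_range uniform range of gene lengths (bp).
#' @param min_gene_gap minimum gap between adjacent genes (bp). The default
#'   (4000, i.e. twice the default promoter upstream extent) guarantees the
#'   promoter windows of neighbouring genes are disjoint, so a planted
#'   promoter peak identifies exactly one gene.
#' @param nad_fraction target NAD fraction of the genome, in (0, 1).
#' @param nad_enrichment mean No/N ratio inside planted NADs (> 0).
#' @param background_enrichment mean No/N ratio outside NADs (> 0).
#' @param depth mean reads per bin per library replicate.
#' @param dispersion negative-binomial size parameter (Poisson as
#'   `dispersion -> Inf`).
#' @param n_replicates replicate libraries per compartment (DNA).
#' @param chrom_weights per-chromosome NAD allocation weights (emulating
#'   the concentration of NADs on particular small chromosomes).
#' @param mean_nad_bins mean planted segment length in bins (>= 2).
#' @param frac_coding probability a gene is protein_coding.
#' @param frac_nags_active fraction of NAGs planted as transcriptionally
#'   active.
#' @param peak_fpr,peak_fnr per-assay false-positive / false-negative peak
#'   probabilities.
#' @param frac_active_retained fraction of active NAGs whose transcript is
#'   nucleolar-retained (the rest are exported).
#' @param frac_nonnag_expressed fraction of non-NAG genes expressed.
#' @param frac_nonnag_retained fraction of expressed non-NAG genes with
#'   nucleolar-enriched transcripts (the nucleolar RNA pool is largely of
#'   non-NAD origin).
#' @param expr_meanlog,expr_sdlog log-normal parameters of baseline
#'   expression.
#' @param retained_multiplier nucleolar/total abundance ratio for retained
#'   transcripts (>= 2).
#' @param exported_multiplier nucleolar/total ratio for exported
#'   transcripts (<= 0.5).
#' @param n_rna_replicates RNA samples per compartment.
#' @param expr_count_noise Poisson-sample the expression counts (`FALSE`
#'   gives noise-free expected counts).
#' @param promoter_upstream,promoter_downstream promoter window (bp).
#' @return A validated `nad_sim_config` list.
#' @export
nad_sim_config <- function(seed = 42,
                           chrom_lengths = c(chr1 = 2e7, chr2 = 2e7,
                                             chr3 = 2e7),
                           bin_size = 1e5,
                           n_genes = 1000,
                           gene_length_range = c(5e3, 2e4),
                           min_gene_gap = 4000,
                           nad_fraction = 0.25,
                           nad_enrichment = 4,
                           background_enrichment = 1,
                           depth = 100,
                           dispersion = 10,
                           n_replicates = 3,
                           chrom_weights = c(1, 1, 3),
                           mean_nad_bins = 6,
                           frac_coding = 0.87,
                           frac_nags_active = 0.13,
                           peak_fpr = 0.02,
                           peak_fnr = 0.05,
                           frac_active_retained = 0.1,
                           frac_nonnag_expressed = 0.5,
                           frac_nonnag_retained = 0.05,
                           expr_meanlog = 4,
                           expr_sdlog = 1,
                           retained_multiplier = 4,
                           exported_multiplier = 0.25,
                           n_rna_replicates = 2,
                           expr_count_noise = TRUE,
                           promoter_upstream = 2000,
                           promoter_downstream = 500) {
  cfg <- as.list(environment())
  if (is.null(names(cfg$chrom_lengths)))
    names(cfg$chrom_lengths) <- paste0("chr", seq_along(cfg$chrom_lengths))
  probs <- c(frac_coding, frac_nags_active, peak_fpr, peak_fnr,
             frac_active_retained, frac_nonnag_expressed,
             frac_nonnag_retained)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (!(nad_fraction > 0 && nad_fraction < 1))
    stop("nad_fraction must lie in (0, 1)")
  if (nad_enrichment <= 0 || background_enrichment <= 0)
    stop("enrichment factors must be > 0")
  if (depth <= 0) stop("depth must be > 0")
  if (dispersion <= 0) stop("dispersion must be > 0")
  if (mean_nad_bins < 2) stop("mean_nad_bins must be >= 2")
  if (length(cfg$chrom_weights) == 1L)
    cfg$chrom_weights <- rep(cfg$chrom_weights, length(cfg$chrom_lengths))
  if (length(cfg$chrom_weights) != length(cfg$chrom_lengths))
    stop("chrom_weights must cover every chromosome")
  if (any(cfg$chrom_weights < 0) || sum(cfg$chrom_weights) == 0)
    stop("chrom_weights must be non-negative and not all zero")
  if (retained_multiplier < 2)
    stop("retained_multiplier must be >= 2 (the enrichment threshold)")
  if (exported_multiplier > 0.5)
    stop("exported_multiplier must be <= 0.5")
  seed <- as.integer(seed)
  if (is.na(seed) || abs(seed) > .Machine$integer.max - 10L)
    stop("seed must be a (not too large) integer")
  cfg$seed <- seed
  structure(cfg, class = "nad_sim_config")
}

#' Simulate a genome and its gene models
#'
#' Genes are placed uniformly by rejection sampling, non-overlapping and
#' separated by at least `min_gene_gap` bp, with lengths uniform in
#' `gene_length_range`, random strands, and biotypes protein_coding with
#' probability `frac_coding` (non-coding genes draw a subclass among
#' snoRNA, miRNA, lincRNA, antisense, rRNA).
#'
#' @param config a [nad_sim_config()].
#' @return list with `assembly` (a [genome_assembly()]) and `genes`
#'   (gene-model data.frame, sorted by position).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "nad_sim_config"))
  set.seed(config$seed + 1L)
  assembly <- genome_assembly(names(config$chrom_lengths),
                              config$chrom_lengths)
  n <- config$n_genes
  lens <- round(runif(n, config$gene_length_range[1],
                      config$gene_length_range[2]))
  placed <- vector("list", nrow(assembly))
  chrom_idx <- integer(n); starts <- numeric(n)
  max_tries <- 200L * n
  tries <- 0L
  for (g in seq_len(n)) {
    repeat {
      tries <- tries + 1L
      if (tries > max_tries)
        stop("cannot place ", n, " non-overlapping genes in this genome")
      ci <- sample.int(nrow(assembly), 1L,
                       prob = assembly$length / sum(assembly$length))
      limit <- assembly$length[ci] - lens[g]
      if (limit < 1) next
      s <- floor(runif(1, 0, limit))
      e <- s + lens[g]
      prev <- placed[[ci]]
      gap <- config$min_gene_gap
      if (!is.null(prev) &&
          any(s < prev$end + gap & e + gap > prev$start)) next
      placed[[ci]] <- rbind(prev, data.frame(start = s, end = e))
      chrom_idx[g] <- ci; starts[g] <- s
      break
    }
  }
  genes <- data.frame(chrom = assembly$chrom[chrom_idx], start = starts,
                      end = starts + lens, stringsAsFactors = FALSE)
  genes <- genes[order(match(genes$chrom, assembly$chrom), genes$start), ]
  genes$gene_id <- sprintf("G%04d", seq_len(n))
  genes$gene_name <- sprintf("GENE%04d", seq_len(n))
  genes$strand <- sample(c("+", "-"), n, replace = TRUE)
  coding <- runif(n) < config$frac_coding
  noncoding_classes <- c("snoRNA", "miRNA", "lincRNA", "antisense", "rRNA")
  genes$biotype <- ifelse(coding, "protein_coding",
                          sample(noncoding_classes, n, replace = TRUE,
                                 prob = c(0.3, 0.2, 0.3, 0.15, 0.05)))
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  rownames(genes) <- NULL
  genes <- genes[, c("gene_id", "gene_name", "chrom", "start", "end",
                     "strand", "biotype", "tss")]
  list(assembly = assembly, genes = genes)
}

#' Plant NAD segments
#'
#' Selects `round(nad_fraction * n_bins)` bins, allocated across
#' chromosomes proportionally to `chrom_weights` (capped at chromosome
#' capacity), and arranges them into runs with mean length
#' `mean_nad_bins` (minimum 2 bins). Planted coverage therefore matches
#' the target fraction up to rounding.
#'
#' @param config a [nad_sim_config()].
#' @param assembly a [genome_assembly()] (normally from
#'   [simulate_genome()]).
#' @return list with `segments` (truth NAD intervals, merged bin runs),
#'   `bin_mask` (logical per grid bin) and `grid`.
#' @export
plant_nads <- function(config, assembly) {
  stopifnot(inherits(config, "nad_sim_config"))
  set.seed(config$seed + 2L)
  grid <- make_bins(assembly, config$bin_size)
  nb <- nrow(grid)
  k <- round(config$nad_fraction * nb)
  if (k < 1) stop("target NAD fraction unreachable: rounds to 0 bins")
  bins_per_chrom <- vapply(assembly$chrom,
                           function(ch) sum(grid$chrom == ch), 1L)
  w <- config$chrom_weights / sum(config$chrom_weights)
  alloc <- floor(k * w)
  # largest-remainder top-up, then push overflow to chromosomes with room
  rem <- k * w - alloc
  while (sum(alloc) < k) {
    i <- which.max(ifelse(alloc < bins_per_chrom, rem, -Inf))
    alloc[i] <- alloc[i] + 1L; rem[i] <- -1
  }
  overflow <- sum(pmax(alloc - bins_per_chrom, 0))
  alloc <- pmin(alloc, bins_per_chrom)
  while (overflow > 0) {
    room <- bins_per_chrom - alloc
    if (all(room == 0)) stop("target NAD fraction exceeds genome capacity")
    i <- which.max(room)
    take <- min(overflow, room[i])
    alloc[i] <- alloc[i] + take
    overflow <- overflow - take
  }
  mask <- logical(nb)
  p_run <- 1 / (config$mean_nad_bins - 1)
  for (ci in seq_len(nrow(assembly))) {
    rows <- which(grid$chrom == assembly$chrom[ci])
    need <- alloc[ci]
    if (need == 0) next
    local <- logical(length(rows))
    tries <- 0L
    while (sum(local) < need) {
      tries <- tries + 1L
      remaining <- need - sum(local)
      len <- if (tries > 1000L) 1L else
        min(2L + stats::rgeom(1L, p_run), remaining, length(rows))
      free <- which(!local)
      if (len == 1L) {
        local[free[sample.int(length(free), 1L)]] <- TRUE
        next
      }
      s <- sample.int(length(rows) - len + 1L, 1L)
      if (any(local[s:(s + len - 1L)])) next
      local[s:(s + len - 1L)] <- TRUE
    }
    mask[rows] <- local
  }
  segments <- mask_to_segments(mask, grid)
  list(segments = segments, bin_mask = mask, grid = grid)
}

# collapse a per-bin logical mask into merged segment intervals
mask_to_segments <- function(mask, grid) {
  segs <- list()
  for (ch in unique(grid$chrom)) {
    rows <- which(grid$chrom == ch)
    r <- rle(mask[rows])
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (i in which(r$values)) {
      span <- rows[starts[i]:ends[i]]
      segs[[length(segs) + 1L]] <-
        data.frame(chrom = ch, start = grid$start[span[1]],
                   end = grid$end[span[length(span)]],
                   stringsAsFactors = FALSE)
    }
  }
  if (length(segs)) {
    out <- do.call(rbind, segs); rownames(out) <- NULL; out
  } else data.frame(chrom = character(), start = numeric(), end = numeric())
}

#' Simulate two-library binned counts
#'
#' Genomic counts are NB(mean = depth, size = dispersion) in every bin;
#' nucleolar counts are NB(mean = depth x factor, size = dispersion) with
#' factor = `nad_enrichment` inside planted NADs and
#' `background_enrichment` elsewhere, independently per replicate library.
#'
#' @param truth result of [plant_nads()] (or a full `nad_sim_truth`).
#' @param config a [nad_sim_config()].
#' @return A [bin_counts()] table with `n_replicates` columns per library.
#' @export
simulate_bin_counts <- function(truth, config) {
  stopifnot(inherits(config, "nad_sim_config"))
  set.seed(config$seed + 3L)
  grid <- truth$grid; mask <- truth$bin_mask
  nb <- nrow(grid)
  mu_no <- config$depth * ifelse(mask, config$nad_enrichment,
                                 config$background_enrichment)
  reps <- config$n_replicates
  no <- sapply(seq_len(reps), function(j)
    rnbinom(nb, mu = mu_no, size = config$dispersion))
  n <- sapply(seq_len(reps), function(j)
    rnbinom(nb, mu = config$depth, size = config$dispersion))
  bin_counts(grid, matrix(no, nrow = nb), matrix(n, nrow = nb))
}

#' Simulate promoter peak sets
#'
#' For each assay (ATAC, H3K4me3, POL2) every planted-active gene receives
#' one promoter-window peak with probability `1 - peak_fnr`, and every
#' other gene with probability `peak_fpr`; peak positions are jittered
#' inside the promoter window.
#'
#' @param truth a `nad_sim_truth` (needs `active_ids`).
#' @param genes gene-model data.frame.
#' @param config a [nad_sim_config()].
#' @return named list of interval data.frames: `ATAC`, `H3K4me3`, `POL2`.
#' @export
simulate_peaks <- function(truth, genes, config) {
  stopifnot(inherits(config, "nad_sim_config"))
  set.seed(config$seed + 4L)
  active <- genes$gene_id %in% truth$active_ids
  prom <- promoter_windows(genes, config$promoter_upstream,
                           config$promoter_downstream)
  out <- list()
  for (assay in c("ATAC", "H3K4me3", "POL2")) {
    p_peak <- ifelse(active, 1 - config$peak_fnr, config$peak_fpr)
    has <- runif(nrow(genes)) < p_peak
    idx <- which(has)
    if (length(idx)) {
      wwidth <- prom$end[idx] - prom$start[idx]
      pw <- pmin(round(runif(length(idx), 200, 800)), wwidth)
      off <- floor(runif(length(idx), 0, wwidth - pw + 1))
      peaks <- data.frame(chrom = prom$chrom[idx],
                          start = prom$start[idx] + off,
                          end = prom$start[idx] + off + pw,
                          name = paste0(assay, "_", genes$gene_id[idx]),
                          score = round(runif(length(idx), 10, 1000), 1),
                          strand = ".", stringsAsFactors = FALSE)
    } else {
      peaks <- data.frame(chrom = character(), start = numeric(),
                          end = numeric(), name = character(),
                          score = numeric(), strand = character())
    }
    out[[assay]] <- peaks[order(peaks$chrom, peaks$start), , drop = FALSE]
    rownames(out[[assay]]) <- NULL
  }
  out
}

#' Simulate compartmentalized expression
#'
#' Expressed genes (active NAGs plus a fraction of non-NAG genes) draw a
#' log-normal baseline; total and nuclear samples observe the baseline,
#' nucleolar samples observe baseline x `retained_multiplier` for
#' nucleolar-retained transcripts and x `exported_multiplier` for exported
#' ones. Counts are Poisson around the expectation unless
#' `expr_count_noise = FALSE` (exact expectations, for noise-free truth
#' recovery).
#'
#' @param truth a `nad_sim_truth` (needs `active_ids`, `retained_ids`,
#'   `nonnag_expressed_ids`, `nonnag_retained_ids`).
#' @param genes gene-model data.frame.
#' @param config a [nad_sim_config()].
#' @return An [expression_table()] (raw counts) with `n_rna_replicates`
#'   samples per compartment.
#' @export
simulate_expression <- function(truth, genes, config) {
  stopifnot(inherits(config, "nad_sim_config"))
  set.seed(config$seed + 5L)
  n <- nrow(genes)
  expressed_ids <- c(truth$active_ids, truth$nonnag_expressed_ids)
  retained_ids <- c(truth$retained_ids, truth$nonnag_retained_ids)
  expressed <- genes$gene_id %in% expressed_ids
  retained <- genes$gene_id %in% retained_ids
  base <- ifelse(expressed,
                 rlnorm(n, config$expr_meanlog, config$expr_sdlog), 0)
  mult <- ifelse(retained, config$retained_multiplier,
                 config$exported_multiplier)
  mu <- list(total = base, nuclear = base, nucleolar = base * mult)
  reps <- config$n_rna_replicates
  cols <- list(); manifest <- list()
  for (comp in names(mu)) {
    for (j in seq_len(reps)) {
      nm <- paste0(comp, "_", j)
      x <- if (config$expr_count_noise) stats::rpois(n, mu[[comp]]) else
        mu[[comp]]
      cols[[nm]] <- x
      manifest[[nm]] <- data.frame(sample = nm, compartment = comp,
                                   replicate = j, stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- genes$gene_id
  expression_table(counts, do.call(rbind, manifest))
}

#' Simulate a complete synthetic NAD study
#'
#' Runs every generator stage under one seed and assembles the ground
#' truth: planted NAD segments, the NAG set they imply, the planted active
#' and nucleolar-retained gene sets, and the full configuration. With
#' `dir` set, writes the complete dataset as plain-text files
#' (chrom.sizes, GTF, truth BED, bin-count TSV, per-assay peak BEDs,
#' expression TSV + sample manifest, truth JSON) plus a manifest.
#'
#' @param config a [nad_sim_config()].
#' @param dir optional output directory.
#' @return A `nad_sim` object: `truth` (`nad_sim_truth`), `counts`,
#'   `peaks`, `expression`, and `files` (when written).
#' @export
simulate_nad_study <- function(config = nad_sim_config(), dir = NULL) {
  stopifnot(inherits(config, "nad_sim_config"))
  gen <- simulate_genome(config)
  planted <- plant_nads(config, gen$assembly)
  # NAGs implied by the planted segments (any-overlap, >= 1 bp)
  hits <- find_interval_overlaps(gen$genes, planted$segments)
  nag_ids <- gen$genes$gene_id[sort(unique(hits$a_idx))]
  set.seed(config$seed + 6L)
  active_ids <- sort(sample(nag_ids,
                            round(config$frac_nags_active *
                                    length(nag_ids))))
  retained_ids <- sort(sample(active_ids,
                              round(config$frac_active_retained *
                                      length(active_ids))))
  non_nags <- setdiff(gen$genes$gene_id, nag_ids)
  nonnag_expressed <- sort(sample(non_nags,
                                  round(config$frac_nonnag_expressed *
                                          length(non_nags))))
  nonnag_retained <- sort(sample(nonnag_expressed,
                                 round(config$frac_nonnag_retained *
                                         length(nonnag_expressed))))
  truth <- structure(list(config = config, assembly = gen$assembly,
                          genes = gen$genes, grid = planted$grid,
                          nad_segments = planted$segments,
                          bin_mask = planted$bin_mask,
                          nag_ids = nag_ids, active_ids = active_ids,
                          retained_ids = retained_ids,
                          nonnag_expressed_ids = nonnag_expressed,
                          nonnag_retained_ids = nonnag_retained),
                     class = "nad_sim_truth")
  counts <- simulate_bin_counts(truth, config)
  peaks <- simulate_peaks(truth, gen$genes, config)
  expression <- simulate_expression(truth, gen$genes, config)
  out <- structure(list(truth = truth, counts = counts, peaks = peaks,
                        expression = expression), class = "nad_sim")
  if (!is.null(dir)) out$files <- write_nad_study(out, dir)
  out
}

#' @export
print.nad_sim <- function(x, ...) {
  t <- x$truth
  cat("Synthetic NAD study (seed", t$config$seed, ")\n")
  cat("  genome:", nrow(t$assembly), "chromosomes,",
      format(assembly_size(t$assembly), big.mark = ","), "bp;",
      nrow(t$genes), "genes\n")
  cat("  planted:", nrow(t$nad_segments), "NAD segments (",
      sprintf("%.1f%%", 100 * sum(t$bin_mask) / length(t$bin_mask)),
      "of bins);", length(t$nag_ids), "NAGs;", length(t$active_ids),
      "active;", length(t$retained_ids), "nucleolar-retained\n")
  invisible(x)
}

#' Write a synthetic study to plain-text files
#'
#' @param sim a `nad_sim` from [simulate_nad_study()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_nad_study <- function(sim, dir) {
  stopifnot(inherits(sim, "nad_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  t <- sim$truth
  files <- c(chrom_sizes = file.path(dir, "genome.chrom.sizes"),
             gtf = file.path(dir, "genes.gtf"),
             truth_nads = file.path(dir, "truth_nads.bed"),
             bin_counts = file.path(dir, "bin_counts.tsv"),
             expression = file.path(dir, "expression.tsv"),
             samples = file.path(dir, "samples.tsv"),
             truth = file.path(dir, "truth.json"))
  write_chrom_sizes(t$assembly, files["chrom_sizes"])
  write_gtf_genes(t$genes, files["gtf"])
  write_bed(t$nad_segments, files["truth_nads"])
  write_bin_counts(sim$counts, files["bin_counts"])
  expr <- data.frame(gene_id = rownames(sim$expression$counts),
                     sim$expression$counts, check.names = FALSE,
                     stringsAsFactors = FALSE)
  write.table(expr, files["expression"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$expression$samples, files["samples"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (assay in names(sim$peaks)) {
    p <- file.path(dir, paste0("peaks_", assay, ".bed"))
    files[paste0("peaks_", assay)] <- p
    write_bed(sim$peaks[[assay]], p)
  }
  truth_json <- list(
    config = unclass(t$config),
    nag_ids = t$nag_ids, active_ids = t$active_ids,
    retained_ids = t$retained_ids,
    nonnag_expressed_ids = t$nonnag_expressed_ids,
    nonnag_retained_ids = t$nonnag_retained_ids,
    n_nad_segments = nrow(t$nad_segments),
    nad_bin_fraction = sum(t$bin_mask) / length(t$bin_mask))
  jsonlite::write_json(truth_json, files["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(files = as.list(files)), manifest,
                       auto_unbox = TRUE, pretty = TRUE)
  files["manifest"] <- manifest
  invisible(files)
}
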