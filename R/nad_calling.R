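# NAD calling: normalized nucleolar/genomic (No/N) enrichment per bin and
# two-fold segmentation into nucleolus-associated domains.

#' Assemble a binned count table
#'
#' Pairs a bin grid with nucleolar (No) and whole-cell/genomic (N) read
#' counts. Each library may be a single vector or a bins-by-replicates
#' matrix (sequencing libraries are commonly prepared in triplicate;
#' replicate ratios are combined by [compute_enrichment()]).
#'
#' @param grid a `bin_grid` from [make_bins()].
#' @param no,n non-negative counts: vectors of length `nrow(grid)` or
#'   matrices with that many rows.
#' @return A `bin_counts` object (list of `grid`, `no`, `n`).
#' @export
bin_counts <- function(grid, no, n) {
  stopifnot(is(grid, "bin_grid"))
  no <- as.matrix(no); n <- as.matrix(n)
  if (nrow(no) != nrow(grid) || nrow(n) != nrow(grid))
    stop("counts must have one row per grid bin")
  if (any(no < 0) || any(n < 0)) stop("counts must be non-negative")
  structure(list(grid = grid, no = no, n = n), class = "bin_counts")
}

#' @export
print.bin_counts <- function(x, ...) {
  cat("Binned No/N count table:", nrow(x$grid), "bins,",
      ncol(x$no), "nucleolar and", ncol(x$n), "genomic replicate(s)\n")
  cat("  library totals: No =", paste(colSums(x$no), collapse = ", "),
      "| N =", paste(colSums(x$n), collapse = ", "), "\n")
  invisible(x)
}

#' Count read placements into bins
#'
#' Each placement is assigned to exactly one bin by its midpoint
#' (`floor((start + end) / 2)`), so totals are conserved: the bin counts sum
#' to the number of (retained) placements.
#'
#' @param reads interval data.frame of read placements (e.g. from
#'   [read_bed()]).
#' @param grid a `bin_grid`.
#' @param on_unknown what to do with placements on chromosomes absent from
#'   the grid: `"error"` (default) or `"skip"` (drop with a warning).
#' @return integer vector of counts, one per grid bin.
#' @export
count_reads_in_bins <- function(reads, grid, on_unknown = c("error", "skip")) {
  on_unknown <- match.arg(on_unknown)
  stopifnot(is(grid, "bin_grid"))
  validate_intervals(reads, what = "reads")
  assembly <- attr(grid, "assembly")
  unknown <- !reads$chrom %in% assembly$chrom
  if (any(unknown)) {
    msg <- paste0(sum(unknown), " placement(s) on chromosomes absent from ",
                  "the grid (e.g. ", reads$chrom[which(unknown)[1]], ")")
    if (on_unknown == "error") stop(msg)
    warning(msg, "; skipped")
    reads <- reads[!unknown, , drop = FALSE]
  }
  counts <- integer(nrow(grid))
  if (nrow(reads) == 0L) return(counts)
  bin_size <- attr(grid, "bin_size")
  # bins are laid out chromosome by chromosome in assembly order
  n_bins_chrom <- ceiling(assembly$length / bin_size)
  offset <- c(0, cumsum(n_bins_chrom))[match(reads$chrom, assembly$chrom)]
  mid <- floor((reads$start + reads$end) / 2)
  idx <- offset + floor(mid / bin_size) + 1L
  tab <- tabulate(idx, nbins = nrow(grid))
  counts + tab
}

#' Per-bin normalized nucleolar enrichment
#'
#' For each bin i and replicate pair j the enrichment ratio is
#' \deqn{r_{ij} = \frac{(no_{ij} + \alpha) / No_j}{(n_{ij} + \alpha) / N_j}}
#' where `No_j`, `N_j` are the library totals: library-size normalization
#' with a pseudocount guaranteeing finite positive ratios. Replicates are
#' combined by the geometric mean (mean log-ratio). With
#' `background = "median"` the combined ratios are additionally divided by
#' their genome-wide median, re-centering the unenriched background at 1 —
#' the correction that makes an absolute two-fold cutoff meaningful when a
#' large genome fraction is nucleolus-associated (an enriched compartment
#' inflates the nucleolar library total and would otherwise deflate every
#' ratio).
#'
#' @param counts a [bin_counts()] table.
#' @param pseudocount additive pseudocount \eqn{\alpha > 0} (default 0.5).
#'   `pseudocount = 0` reproduces the plain ratio of library-normalized
#'   counts (bins with zero genomic count then yield infinite ratios).
#' @param background `"none"` (plain library-size normalization) or
#'   `"median"` (additionally re-center the genome-wide median ratio at 1).
#' @return An `enrichment_track` data.frame: grid columns plus `ratio` and
#'   `log2_ratio`.
#' @export
compute_enrichment <- function(counts, pseudocount = 0.5,
                               background = c("none", "median")) {
  background <- match.arg(background)
  stopifnot(is(counts, "bin_counts"))
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  no <- counts$no; n <- counts$n
  if (ncol(no) != ncol(n))
    stop("nucleolar and genomic libraries must have equal replicate number")
  no_tot <- colSums(no); n_tot <- colSums(n)
  if (any(no_tot == 0) || any(n_tot == 0))
    stop("empty library: a replicate has total count 0")
  logr <- sapply(seq_len(ncol(no)), function(j)
    log((no[, j] + pseudocount) / no_tot[j]) -
      log((n[, j] + pseudocount) / n_tot[j]))
  ratio <- exp(rowMeans(as.matrix(logr)))
  bg_factor <- 1
  if (background == "median") {
    bg_factor <- median(ratio)
    if (!is.finite(bg_factor) || bg_factor <= 0)
      stop("cannot median-correct: non-positive median ratio")
    ratio <- ratio / bg_factor
  }
  grid <- counts$grid
  out <- cbind(as.data.frame(grid), ratio = ratio, log2_ratio = log2(ratio))
  structure(out, class = c("enrichment_track", "data.frame"),
            bin_size = attr(grid, "bin_size"),
            assembly = attr(grid, "assembly"),
            pseudocount = pseudocount, background = background,
            background_factor = bg_factor,
            n_replicates = ncol(no))
}

#' Call nucleolus-associated domains
#'
#' The package's central estimator. A bin is NAD-positive iff its normalized
#' No/N enrichment ratio is `>= threshold` (inclusive: "two-fold or
#' greater"). Runs of positive bins separated by at most `max_gap_bins`
#' negative bins are merged into segments whose boundaries coincide with bin
#' boundaries.
#'
#' `call_nads()` is generic: applied to a [bin_counts()] table it first
#' computes the enrichment track (by default with median background
#' correction, see [compute_enrichment()]); applied to an existing
#' `enrichment_track` it thresholds that track as-is.
#'
#' @param x a `bin_counts` table or an `enrichment_track`.
#' @param threshold enrichment cutoff on the linear ratio scale (default 2).
#' @param max_gap_bins negative-bin gap tolerated inside a segment
#'   (default 0).
#' @param ... passed between methods.
#' @return A `nad_call` object: `segments` (data.frame of merged segments
#'   with `n_bins`, `mean_ratio`, `max_ratio`, `mean_log2`), `bin_positive`
#'   (per-bin logical calls), the input `track`, `threshold`,
#'   `genome_fraction` (percent of assembly bp in segments) and the
#'   assembly/grid. Methods: `print`, `summary`, `plot`.
#' @seealso [nad_genome_fraction()], [chromosome_contribution()],
#'   [shared_nad_fraction()], [annotate_nags()]
#' @export
call_nads <- function(x, threshold = 2, max_gap_bins = 0, ...) {
  UseMethod("call_nads")
}

#' @rdname call_nads
#' @param pseudocount,background forwarded to [compute_enrichment()] (the
#'   bin-counts method defaults to median background correction).
#' @export
call_nads.bin_counts <- function(x, threshold = 2, max_gap_bins = 0,
                                 pseudocount = 0.5, background = "median",
                                 ...) {
  track <- compute_enrichment(x, pseudocount = pseudocount,
                              background = background)
  call_nads(track, threshold = threshold, max_gap_bins = max_gap_bins)
}

#' @rdname call_nads
#' @export
call_nads.enrichment_track <- function(x, threshold = 2, max_gap_bins = 0,
                                       ...) {
  if (!is.numeric(threshold) || threshold <= 0)
    stop("threshold must be > 0")
  if (max_gap_bins < 0) stop("max_gap_bins must be >= 0")
  assembly <- attr(x, "assembly")
  positive <- x$ratio >= threshold
  seg_list <- list()
  for (ch in unique(x$chrom)) {
    rows <- which(x$chrom == ch)
    r <- rle(positive[rows])
    if (max_gap_bins > 0 && length(r$values) > 2) {
      inner <- which(!r$values & r$lengths <= max_gap_bins)
      inner <- inner[inner > 1 & inner < length(r$values)]
      if (length(inner)) {
        r$values[inner] <- TRUE
        r <- rle(inverse.rle(r))
      }
    }
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      span <- rows[starts[k]:ends[k]]
      seg_list[[length(seg_list) + 1L]] <- data.frame(
        chrom = ch, start = x$start[span[1]], end = x$end[span[length(span)]],
        n_bins = length(span),
        mean_ratio = mean(x$ratio[span]), max_ratio = max(x$ratio[span]),
        mean_log2 = mean(x$log2_ratio[span]), stringsAsFactors = FALSE)
    }
  }
  segments <- if (length(seg_list)) do.call(rbind, seg_list) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               n_bins = integer(), mean_ratio = numeric(),
               max_ratio = numeric(), mean_log2 = numeric())
  rownames(segments) <- NULL
  res <- structure(list(segments = segments, bin_positive = positive,
                        track = x, threshold = threshold,
                        max_gap_bins = max_gap_bins, assembly = assembly),
                   class = "nad_call")
  res$genome_fraction <- nad_genome_fraction(res)
  res
}

#' NAD genome fraction
#'
#' Percent of the assembly covered by NAD segments:
#' sum of segment lengths / assembly length x 100.
#'
#' @param result a `nad_call`.
#' @param assembly optional assembly to use instead of the one bound to the
#'   result.
#' @return percent (numeric scalar).
#' @export
nad_genome_fraction <- function(result, assembly = NULL) {
  stopifnot(inherits(result, "nad_call"))
  if (is.null(assembly)) assembly <- result$assembly
  segs <- result$segments
  100 * sum(segs$end - segs$start) / assembly_size(assembly)
}

#' Per-chromosome NAD contribution
#'
#' Fraction of the total NAD complement contributed by each chromosome,
#' reported both as share of segment count and share of covered bp (sums to
#' 1 each). Also tabulates raw counts and bp.
#'
#' @param result a `nad_call` with at least one segment.
#' @return data.frame with one row per assembly chromosome: `chrom`,
#'   `n_segments`, `nad_bp`, `share_segments`, `share_bp`.
#' @export
chromosome_contribution <- function(result) {
  stopifnot(inherits(result, "nad_call"))
  segs <- result$segments
  if (nrow(segs) == 0L) stop("no NAD segments: contribution undefined")
  chroms <- result$assembly$chrom
  n_seg <- vapply(chroms, function(ch) sum(segs$chrom == ch), 1L)
  bp <- vapply(chroms, function(ch)
    sum((segs$end - segs$start)[segs$chrom == ch]), 1)
  data.frame(chrom = chroms, n_segments = as.integer(n_seg), nad_bp = bp,
             share_segments = n_seg / sum(n_seg), share_bp = bp / sum(bp),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fraction of one line's NAD bp shared with another
#'
#' Directional: the fraction of `a`'s NAD base pairs that fall inside `b`'s
#' NAD segments. `shared_nad_fraction(a, a)` is 1; the measure is not
#' symmetric when the two NAD complements differ in size.
#'
#' @param a,b `nad_call` objects on the same assembly.
#' @return numeric in [0, 1].
#' @export
shared_nad_fraction <- function(a, b) {
  stopifnot(inherits(a, "nad_call"), inherits(b, "nad_call"))
  if (!identical(a$assembly, b$assembly))
    stop("NAD calls are on different assemblies")
  if (nrow(a$segments) == 0L)
    stop("'a' has no NAD segments: shared fraction undefined")
  gra <- GenomicRanges::reduce(as_gr(a$segments))
  if (nrow(b$segments) == 0L) return(0)
  grb <- GenomicRanges::reduce(as_gr(b$segments))
  # common coordinate frame so disjoint chromosome sets intersect cleanly
  GenomeInfoDb::seqlevels(gra) <- a$assembly$chrom
  GenomeInfoDb::seqlevels(grb) <- a$assembly$chrom
  ov <- GenomicRanges::intersect(gra, grb)
  sum(as.numeric(BiocGenerics::width(ov))) /
    sum(as.numeric(BiocGenerics::width(gra)))
}

#' @export
print.nad_call <- function(x, ...) {
  cat("NAD call (No/N >=", x$threshold, ", gap", x$max_gap_bins, "bins)\n")
  cat("  ", nrow(x$segments), "segments over",
      sum(x$bin_positive), "positive of", length(x$bin_positive), "bins;",
      sprintf("%.1f%%", x$genome_fraction), "of the genome\n")
  invisible(x)
}

#' @export
summary.nad_call <- function(object, ...) {
  segs <- object$segments
  out <- list(
    threshold = object$threshold,
    n_segments = nrow(segs),
    n_positive_bins = sum(object$bin_positive),
    n_bins = length(object$bin_positive),
    nad_bp = sum(segs$end - segs$start),
    genome_fraction = object$genome_fraction,
    per_chromosome = if (nrow(segs)) chromosome_contribution(object) else NULL)
  class(out) <- "summary.nad_call"
  out
}

#' @export
print.summary.nad_call <- function(x, ...) {
  cat("NAD segmentation summary\n")
  cat(sprintf("  threshold %.2f | %d segments | %d/%d positive bins | %s bp | %.1f%% of genome\n",
              x$threshold, x$n_segments, x$n_positive_bins, x$n_bins,
              format(x$nad_bp, big.mark = ","), x$genome_fraction))
  if (!is.null(x$per_chromosome)) {
    cat("  per-chromosome contribution:\n")
    print.data.frame(x$per_chromosome, digits = 3)
  }
  invisible(x)
}

#' @param y unused.
#' @rdname call_nads
#' @export
plot.nad_call <- function(x, y, ...) {
  tr <- x$track
  assembly <- x$assembly
  offs <- c(0, cumsum(assembly$length))[match(tr$chrom, assembly$chrom)]
  pos <- offs + (tr$start + tr$end) / 2
  col <- ifelse(x$bin_positive, "firebrick", "grey60")
  graphics::plot(pos / 1e6, tr$log2_ratio, pch = 16, cex = 0.5, col = col,
                 xlab = "genome position (Mb, chromosomes concatenated)",
                 ylab = "log2 No/N enrichment", ...)
  graphics::abline(h = log2(x$threshold), lty = 2)
  bnd <- cumsum(assembly$length) / 1e6
  graphics::abline(v = bnd[-length(bnd)], col = "grey85")
  invisible(x)
}

#' Export NAD-call results
#'
#' Writes the merged segments as BED6 (score = mean log2 ratio), the per-bin
#' track as bedGraph (log2 ratio), and the per-chromosome contribution table
#' as TSV.
#'
#' @param result a `nad_call`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return named character vector of the written paths, invisibly.
#' @export
write_nad_results <- function(result, dir, prefix = "nads") {
  stopifnot(inherits(result, "nad_call"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  segs <- result$segments
  bed <- file.path(dir, paste0(prefix, "_segments.bed"))
  write_bed(data.frame(chrom = segs$chrom, start = segs$start, end = segs$end,
                       name = if (nrow(segs)) paste0("NAD", seq_len(nrow(segs))) else character(),
                       score = round(segs$mean_log2, 4), strand = "."), bed)
  bg <- file.path(dir, paste0(prefix, "_log2_ratio.bedgraph"))
  tr <- result$track
  writeLines(paste(tr$chrom,
                   format(tr$start, scientific = FALSE, trim = TRUE),
                   format(tr$end, scientific = FALSE, trim = TRUE),
                   round(tr$log2_ratio, 4), sep = "\t"), bg)
  tsv <- file.path(dir, paste0(prefix, "_per_chromosome.tsv"))
  tab <- if (nrow(segs)) chromosome_contribution(result) else
    data.frame(chrom = result$assembly$chrom, n_segments = 0L, nad_bp = 0,
               share_segments = NA, share_bp = NA)
  write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(segments = bed, track = bg, per_chromosome = tsv))
}

#' Read or write a binned No/N count TSV
#'
#' The TSV layout is `bin`, `chrom`, `start`, `end`, then one or more
#' `no_count*` columns and the matching `n_count*` columns.
#'
#' @param path TSV path.
#' @param counts a `bin_counts` object (for writing).
#' @param grid optional `bin_grid` to validate against; if omitted a grid is
#'   reconstructed from the file (requires complete tiling rows).
#' @return `read_bin_counts()`: a `bin_counts` object. `write_bin_counts()`:
#'   `path`, invisibly.
#' @export
read_bin_counts <- function(path, grid = NULL) {
  x <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("bin", "chrom", "start", "end")
  if (!all(need %in% names(x)))
    stop("bin-count TSV must have columns bin, chrom, start, end")
  no_cols <- grep("^no_count", names(x), value = TRUE)
  n_cols <- grep("^n_count", names(x), value = TRUE)
  if (!length(no_cols) || !length(n_cols))
    stop("bin-count TSV must have no_count* and n_count* columns")
  if (is.null(grid)) {
    chroms <- unique(x$chrom)
    lens <- vapply(chroms, function(ch) max(x$end[x$chrom == ch]), 1)
    grid <- make_bins(genome_assembly(chroms, lens),
                      bin_size = max(x$end - x$start))
  }
  if (nrow(grid) != nrow(x)) stop("bin-count TSV does not match the grid")
  bin_counts(grid, as.matrix(x[no_cols]), as.matrix(x[n_cols]))
}

#' @rdname read_bin_counts
#' @export
write_bin_counts <- function(counts, path) {
  stopifnot(is(counts, "bin_counts"))
  no <- counts$no; n <- counts$n
  colnames(no) <- if (ncol(no) == 1L) "no_count" else
    paste0("no_count_", seq_len(ncol(no)))
  colnames(n) <- if (ncol(n) == 1L) "n_count" else
    paste0("n_count_", seq_len(ncol(n)))
  out <- cbind(as.data.frame(counts$grid), no, n)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
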