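# Integration of ATAC / H3K4me3 / RNA Pol II peak sets with NAGs: merged
# regions across samples, peak-to-gene annotation, TSS metaprofiles, and the
# triple-mark transcriptional-activity classification.

#' Build Merged Regions from several peak sets
#'
#' Overlapping peaks across samples are grouped into connected components
#' (transitive closure of the pairwise half-open overlap relation). Each
#' Merged Region spans from the start of its most upstream member to the end
#' of its most downstream member, and carries per-sample presence flags.
#' Touching-but-not-overlapping peaks (end == start) stay in separate
#' regions.
#'
#' @param peaksets named list of interval data.frames, one per sample.
#' @return A `merged_regions` object: `regions` (data.frame `region`,
#'   `chrom`, `start`, `end`, `n_peaks`), `presence` (regions x samples
#'   logical matrix), `members` (data.frame `region`, `sample`, `peak_idx`).
#' @export
build_merged_regions <- function(peaksets) {
  if (is.null(names(peaksets)) || any(!nzchar(names(peaksets))))
    stop("peaksets must be a named list (one element per sample)")
  if (length(peaksets) < 1L) stop("need at least one peak set")
  for (nm in names(peaksets))
    validate_intervals(peaksets[[nm]], what = paste0("peaks[", nm, "]"))
  all <- do.call(rbind, lapply(names(peaksets), function(nm) {
    p <- peaksets[[nm]]
    if (nrow(p) == 0L) return(NULL)
    data.frame(chrom = p$chrom, start = p$start, end = p$end,
               sample = nm, peak_idx = seq_len(nrow(p)),
               stringsAsFactors = FALSE)
  }))
  if (is.null(all) || nrow(all) == 0L)
    return(structure(list(
      regions = data.frame(region = integer(), chrom = character(),
                           start = numeric(), end = numeric(),
                           n_peaks = integer()),
      presence = matrix(FALSE, 0, length(peaksets),
                        dimnames = list(NULL, names(peaksets))),
      members = data.frame(region = integer(), sample = character(),
                           peak_idx = integer())),
      class = "merged_regions"))
  ord <- order(all$chrom, all$start, all$end)
  all <- all[ord, , drop = FALSE]
  region <- integer(nrow(all))
  rid <- 0L; cur_chrom <- ""; cur_end <- -Inf
  for (i in seq_len(nrow(all))) {
    # sweep: a peak starting before the running max end overlaps the
    # current component (strict <: half-open coordinates)
    if (all$chrom[i] != cur_chrom || all$start[i] >= cur_end) {
      rid <- rid + 1L
      cur_chrom <- all$chrom[i]
      cur_end <- all$end[i]
    } else cur_end <- max(cur_end, all$end[i])
    region[i] <- rid
  }
  fr <- factor(region, levels = seq_len(rid))
  regions <- data.frame(
    region = seq_len(rid),
    chrom = as.character(tapply(all$chrom, fr, `[`, 1L)),
    start = as.numeric(tapply(all$start, fr, min)),
    end = as.numeric(tapply(all$end, fr, max)),
    n_peaks = as.integer(table(fr)),
    stringsAsFactors = FALSE, row.names = NULL)
  presence <- matrix(FALSE, rid, length(peaksets),
                     dimnames = list(NULL, names(peaksets)))
  presence[cbind(region, match(all$sample, names(peaksets)))] <- TRUE
  members <- data.frame(region = region, sample = all$sample,
                        peak_idx = all$peak_idx, stringsAsFactors = FALSE,
                        row.names = NULL)
  structure(list(regions = regions, presence = presence, members = members),
            class = "merged_regions")
}

#' @export
print.merged_regions <- function(x, ...) {
  cat("Merged Regions:", nrow(x$regions), "regions from",
      nrow(x$members), "peaks across", ncol(x$presence), "sample(s)\n")
  invisible(x)
}

#' Fraction of one sample's peaks co-occurring with another's
#'
#' Computed through Merged Regions: the fraction of `a`'s peaks whose
#' Merged Region also contains at least one peak of `b`.
#'
#' @param a,b interval data.frames of peaks.
#' @return numeric in [0, 1].
#' @export
peak_overlap_fraction <- function(a, b) {
  validate_intervals(a, what = "a"); validate_intervals(b, what = "b")
  if (nrow(a) == 0L) stop("'a' has no peaks: overlap fraction undefined")
  mr <- build_merged_regions(list(a = a, b = b))
  am <- mr$members[mr$members$sample == "a", , drop = FALSE]
  shared <- mr$presence[, "a"] & mr$presence[, "b"]
  mean(shared[am$region])
}

#' Promoter windows around gene TSSs
#'
#' Strand-aware window of `upstream` bp before and `downstream` bp after the
#' TSS (first transcribed base), in 0-based half-open coordinates, clipped
#' at position 0 (and at chromosome ends when an assembly is supplied).
#'
#' @param genes gene-model data.frame.
#' @param upstream,downstream window extent in bp (defaults 2000 / 500).
#' @param assembly optional `genome_assembly` for right-end clipping.
#' @return interval data.frame with `gene_id` and the window coordinates.
#' @export
promoter_windows <- function(genes, upstream = 2000, downstream = 500,
                             assembly = NULL) {
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - upstream, genes$tss - downstream + 1)
  end <- ifelse(plus, genes$tss + downstream, genes$tss + upstream + 1)
  start <- pmax(start, 0)
  if (!is.null(assembly)) {
    lim <- assembly$length[match(genes$chrom, assembly$chrom)]
    end <- pmin(end, lim)
  }
  data.frame(chrom = genes$chrom, start = start, end = end,
             gene_id = genes$gene_id, strand = genes$strand,
             stringsAsFactors = FALSE)
}

#' Annotate peaks relative to gene models
#'
#' Category priority is promoter > gene_body > intergenic. A peak
#' overlapping any promoter window is a promoter peak; otherwise a peak
#' overlapping a gene body is a gene-body peak; anything else is
#' intergenic. The target gene is the candidate with the nearest TSS
#' (distance from peak midpoint), ties broken by the lexicographically
#' smallest `gene_id`. `distance_to_tss` is always the distance to the
#' nearest TSS of any gene.
#'
#' @param peaks interval data.frame of peaks.
#' @param genes gene-model data.frame.
#' @param upstream,downstream promoter window extents (see
#'   [promoter_windows()]).
#' @return A `peak_annotation` data.frame: peak coordinates plus
#'   `category`, `gene_id`, `distance_to_tss`.
#' @export
annotate_peaks <- function(peaks, genes, upstream = 2000, downstream = 500) {
  validate_intervals(peaks, what = "peaks")
  if (nrow(genes) == 0L) stop("need at least one gene model")
  mid <- floor((peaks$start + peaks$end) / 2)
  category <- rep("intergenic", nrow(peaks))
  gene_id <- rep(NA_character_, nrow(peaks))

  pick_target <- function(hits) {
    # hits: data.frame(a_idx = peak, b_idx = gene); choose nearest TSS,
    # ties -> smallest gene_id
    d <- abs(mid[hits$a_idx] - genes$tss[hits$b_idx])
    ord <- order(hits$a_idx, d, genes$gene_id[hits$b_idx])
    h <- hits[ord, , drop = FALSE]
    first <- !duplicated(h$a_idx)
    list(peak = h$a_idx[first], gene = h$b_idx[first])
  }

  prom <- promoter_windows(genes, upstream, downstream)
  ph <- find_interval_overlaps(peaks, prom)
  if (nrow(ph)) {
    t <- pick_target(ph)
    category[t$peak] <- "promoter"
    gene_id[t$peak] <- genes$gene_id[t$gene]
  }
  remaining <- which(category == "intergenic")
  if (length(remaining)) {
    bh <- find_interval_overlaps(peaks[remaining, , drop = FALSE], genes)
    if (nrow(bh)) {
      bh$a_idx <- remaining[bh$a_idx]
      t <- pick_target(bh)
      category[t$peak] <- "gene_body"
      gene_id[t$peak] <- genes$gene_id[t$gene]
    }
  }
  dist_all <- vapply(seq_len(nrow(peaks)), function(i) {
    same <- genes$chrom == peaks$chrom[i]
    if (!any(same)) return(NA_real_)
    min(abs(mid[i] - genes$tss[same]))
  }, 1)
  out <- data.frame(chrom = peaks$chrom, start = peaks$start,
                    end = peaks$end, category = category, gene_id = gene_id,
                    distance_to_tss = dist_all, stringsAsFactors = FALSE)
  structure(out, class = c("peak_annotation", "data.frame"),
            upstream = upstream, downstream = downstream)
}

#' TSS-centered occupancy metaprofile
#'
#' Mean binary peak occupancy in a +/- `window` bp frame around gene TSSs,
#' averaged over genes and aggregated into `n_bins` equal offset bins.
#' Minus-strand genes are orientation-flipped before averaging, so the
#' profile reads upstream -> downstream.
#'
#' @param peaks interval data.frame of peaks (binarized occupancy).
#' @param genes gene-model data.frame (>= 1 gene).
#' @param window half-width of the frame in bp (default 2000).
#' @param n_bins number of offset bins; `2 * window` must be divisible by
#'   `n_bins`.
#' @return data.frame `offset` (bin center relative to TSS, bp) and
#'   `occupancy` (mean fraction of covered bp).
#' @export
tss_profile <- function(peaks, genes, window = 2000, n_bins = 40) {
  if (nrow(genes) == 0L) stop("need at least one gene")
  if ((2 * window) %% n_bins != 0)
    stop("2 * window must be divisible by n_bins")
  validate_intervals(peaks, what = "peaks")
  width <- 2L * window
  acc <- numeric(width)
  for (g in seq_len(nrow(genes))) {
    tss <- genes$tss[g]
    plus <- genes$strand[g] == "+"
    # frame covering offsets -window .. window-1 relative to the TSS,
    # reading in transcription direction
    lo <- if (plus) tss - window else tss - window + 1
    hi <- lo + width
    cov <- logical(width)
    p <- peaks[peaks$chrom == genes$chrom[g] &
                 peaks$end > lo & peaks$start < hi, , drop = FALSE]
    if (nrow(p)) {
      s <- pmax(p$start, lo) - lo + 1
      e <- pmin(p$end, hi) - lo
      for (k in seq_len(nrow(p))) cov[s[k]:e[k]] <- TRUE
    }
    if (!plus) cov <- rev(cov)
    acc <- acc + cov
  }
  occ <- acc / nrow(genes)
  bw <- width / n_bins
  occupancy <- vapply(seq_len(n_bins), function(b)
    mean(occ[((b - 1) * bw + 1):(b * bw)]), 1)
  offset <- (seq_len(n_bins) - 0.5) * bw - window
  data.frame(offset = offset, occupancy = occupancy)
}

#' Triple-mark activity classification of NAGs
#'
#' Applies the transcriptional-activity criteria at NAG promoters: ATAC
#' accessibility, H3K4me3, and RNA Pol II, each scored as >= 1 peak of that
#' assay overlapping the gene's promoter window (applied uniformly across
#' assays). `active` is the conjunction of the three promoter flags;
#' `double` flags genes with both H3K4me3 and Pol II. `atac_gene`
#' additionally records accessibility anywhere in the gene body or
#' promoter. A missing assay (`NULL`) leaves its flag `NA` and is excluded
#' from the conjunction, with a warning.
#'
#' @param nags a `nag_set` from [annotate_nags()].
#' @param genes gene-model data.frame covering at least the NAG genes.
#' @param atac,h3k4me3,pol2 interval data.frames of assay peaks (any may be
#'   `NULL`).
#' @param upstream,downstream promoter window extents (defaults 2000 / 500).
#' @param n_nad optional NAD segment count carried into the summary row.
#' @return A `nag_activity` data.frame (one row per NAG: flags
#'   `atac_gene`, `atac_promoter`, `h3k4me3`, `pol2`, `double`, `active`)
#'   with a [summary_row()] in `attr(, "summary")`.
#' @export
classify_active_nags <- function(nags, genes, atac = NULL, h3k4me3 = NULL,
                                 pol2 = NULL, upstream = 2000,
                                 downstream = 500, n_nad = NULL) {
  stopifnot(inherits(nags, "nag_set"))
  if (nrow(nags) == 0L) stop("NAG set is empty")
  gm <- genes[match(nags$gene_id, genes$gene_id), , drop = FALSE]
  if (anyNA(gm$gene_id))
    stop("gene models missing for some NAG ids (e.g. ",
         nags$gene_id[which(is.na(gm$gene_id))[1]], ")")
  prom <- promoter_windows(gm, upstream, downstream)
  flag_overlap <- function(peaks, targets) {
    if (is.null(peaks)) return(rep(NA, nrow(targets)))
    hits <- find_interval_overlaps(targets, peaks)
    seq_len(nrow(targets)) %in% hits$a_idx
  }
  atac_promoter <- flag_overlap(atac, prom)
  h3k4 <- flag_overlap(h3k4me3, prom)
  p2 <- flag_overlap(pol2, prom)
  atac_gene <- if (is.null(atac)) rep(NA, nrow(gm)) else
    flag_overlap(atac, gm) | atac_promoter
  missing_assays <- c(ATAC = is.null(atac), H3K4me3 = is.null(h3k4me3),
                      POL2 = is.null(pol2))
  if (any(missing_assays))
    warning("assay(s) missing and excluded from the 'active' call: ",
            paste(names(missing_assays)[missing_assays], collapse = ", "))
  conj <- cbind(atac_promoter, h3k4, p2)[, !missing_assays, drop = FALSE]
  active <- if (ncol(conj)) rowSums(!conj) == 0L else
    rep(NA, nrow(gm))
  dbl <- if (!is.null(h3k4me3) && !is.null(pol2)) h3k4 & p2 else
    rep(NA, nrow(gm))
  out <- data.frame(gene_id = nags$gene_id, gene_name = nags$gene_name,
                    biotype = nags$biotype, atac_gene = atac_gene,
                    atac_promoter = atac_promoter, h3k4me3 = h3k4,
                    pol2 = p2, double = dbl, active = active,
                    stringsAsFactors = FALSE, row.names = NULL)
  n_or_na <- function(v) if (all(is.na(v))) NA_integer_ else sum(v, na.rm = TRUE)
  sr <- summary_row(
    cell_line = attr(nags, "cell_line"),
    n_nad = if (is.null(n_nad)) attr(nags, "n_nad_segments") else n_nad,
    n_nag = nrow(nags),
    n_nag_accessible = n_or_na(atac_gene),
    n_nag_promoter_accessible = n_or_na(atac_promoter),
    n_nag_h3k4me3 = n_or_na(h3k4),
    n_nag_pol2 = n_or_na(p2),
    n_double = n_or_na(dbl),
    triple_marked = if (all(is.na(active))) NULL else c(
      protein_coding = sum(active & out$biotype == "protein_coding",
                           na.rm = TRUE),
      non_coding = sum(active & out$biotype != "protein_coding",
                       na.rm = TRUE)))
  structure(out, class = c("nag_activity", "data.frame"),
            summary = sr, missing_assays = names(missing_assays)[missing_assays])
}

#' @export
print.nag_activity <- function(x, ...) {
  cat("NAG activity profile:", nrow(x), "genes;",
      sum(x$active, na.rm = TRUE), "triple-marked active\n")
  print(attr(x, "summary"))
  invisible(x)
}

#' Assemble a per-cell-line summary row
#'
#' The tabular summary of a cell line's NAD/NAG census: NAD segments, NAGs,
#' accessibility, histone-mark and Pol II counts, the triple-marked active
#' count, and transcript counts by compartment. Counts supplied as
#' protein-coding / non-coding splits (named vectors) are summed into their
#' totals; stated totals are checked against the splits. Invariants are
#' enforced: every count <= `n_nag` and
#' `n_triple <= min(promoter-accessible, H3K4me3, Pol II)`.
#'
#' @param cell_line label.
#' @param n_nad,n_nag,n_nag_accessible,n_nag_promoter_accessible counts.
#' @param n_nag_h3k4me3,n_nag_pol2,n_double counts (NA when unmeasured).
#' @param triple_marked scalar count or named vector
#'   `c(protein_coding =, non_coding =)`.
#' @param nuclear_transcripts,nucleolar_transcripts scalar counts or named
#'   protein-coding / non-coding split vectors.
#' @return A `summary_row` (named list with derived totals and splits).
#' @export
summary_row <- function(cell_line = NA, n_nad = NA, n_nag = NA,
                        n_nag_accessible = NA,
                        n_nag_promoter_accessible = NA,
                        n_nag_h3k4me3 = NA, n_nag_pol2 = NA, n_double = NA,
                        triple_marked = NULL, nuclear_transcripts = NULL,
                        nucleolar_transcripts = NULL) {
  split_total <- function(x) {
    if (is.null(x)) return(list(total = NA_integer_, split = NULL))
    if (length(x) == 1L && is.null(names(x)))
      return(list(total = as.integer(x), split = NULL))
    if (!all(c("protein_coding", "non_coding") %in% names(x)))
      stop("splits must be named c(protein_coding =, non_coding =)")
    list(total = as.integer(sum(x)),
         split = as.list(setNames(as.integer(x), names(x))))
  }
  tm <- split_total(triple_marked)
  nuc <- split_total(nuclear_transcripts)
  nol <- split_total(nucleolar_transcripts)
  row <- list(cell_line = cell_line, n_nad = n_nad, n_nag = n_nag,
              n_nag_accessible = n_nag_accessible,
              n_nag_promoter_accessible = n_nag_promoter_accessible,
              n_nag_h3k4me3 = n_nag_h3k4me3, n_nag_pol2 = n_nag_pol2,
              n_double = n_double,
              n_triple = tm$total, triple_split = tm$split,
              n_nuclear_transcript = nuc$total, nuclear_split = nuc$split,
              n_nucleolar_transcript = nol$total, nucleolar_split = nol$split)
  chk <- function(v) !is.na(v)
  if (chk(row$n_triple)) {
    lims <- c(row$n_nag_promoter_accessible, row$n_nag_h3k4me3,
              row$n_nag_pol2)
    if (any(chk(lims) & row$n_triple > lims))
      stop("invariant violated: n_triple exceeds a constituent mark count")
  }
  if (chk(row$n_nag)) {
    counts <- unlist(row[c("n_nag_accessible", "n_nag_promoter_accessible",
                           "n_nag_h3k4me3", "n_nag_pol2", "n_triple")])
    if (any(chk(counts) & counts > row$n_nag))
      stop("invariant violated: a per-assay count exceeds n_nag")
  }
  structure(row, class = "summary_row")
}

#' @export
print.summary_row <- function(x, ...) {
  cat("Summary row [", if (is.na(x$cell_line)) "?" else x$cell_line, "]\n",
      sep = "")
  flat <- x[!vapply(x, function(v) is.list(v) || is.null(v), TRUE)]
  for (nm in names(flat)[-1])
    cat(sprintf("  %-26s %s\n", nm, format(flat[[nm]])))
  invisible(x)
}

#' @export
as.data.frame.summary_row <- function(x, ...) {
  flat <- x[!vapply(x, function(v) is.list(v) || is.null(v), TRUE)]
  as.data.frame(flat, stringsAsFactors = FALSE)
}
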