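# Nucleolar RNA enrichment: CPM normalization, the two-fold nucleolar/total
# enrichment call, transcriptome composition, the NAG transcription
# partition, and repeat (SINE/LINE) association.

#' Construct an expression table
#'
#' A genes-by-samples abundance matrix with a per-sample compartment label
#' (`nucleolar`, `total`, or `nuclear`).
#'
#' @param counts non-negative numeric matrix, genes in rows (rownames =
#'   gene ids), samples in columns.
#' @param samples data.frame with columns `sample` (matching the matrix
#'   column names) and `compartment`.
#' @param normalized logical; `FALSE` for raw counts.
#' @return An `expression_table` object.
#' @export
expression_table <- function(counts, samples, normalized = FALSE) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have gene ids as rownames")
  if (any(counts < 0)) stop("negative abundances are not allowed")
  if (!all(c("sample", "compartment") %in% names(samples)))
    stop("samples must have columns 'sample' and 'compartment'")
  if (!setequal(colnames(counts), samples$sample) ||
      ncol(counts) != nrow(samples))
    stop("sample manifest does not match count matrix columns")
  bad <- !samples$compartment %in% c("nucleolar", "total", "nuclear")
  if (any(bad))
    stop("unknown compartment label: ", samples$compartment[which(bad)[1]])
  samples <- samples[match(colnames(counts), samples$sample), , drop = FALSE]
  structure(list(counts = counts, samples = samples,
                 normalized = isTRUE(normalized)),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat("Expression table:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples (", if (x$normalized) "normalized" else "raw counts", ")\n")
  print(table(x$samples$compartment))
  invisible(x)
}

#' Counts-per-million normalization
#'
#' Scales every sample so its column sums to 1e6. Applying it to an
#' already-normalized table is an error by default (`if_normalized =
#' "noop"` passes the table through instead; CPM is idempotent up to
#' floating point).
#'
#' @param x an [expression_table()].
#' @param if_normalized `"error"` or `"noop"`.
#' @return A normalized `expression_table`.
#' @export
normalize_expression <- function(x, if_normalized = c("error", "noop")) {
  if_normalized <- match.arg(if_normalized)
  stopifnot(inherits(x, "expression_table"))
  if (x$normalized) {
    if (if_normalized == "error")
      stop("table is already normalized (use if_normalized = \"noop\")")
    return(x)
  }
  tot <- colSums(x$counts)
  if (any(tot == 0))
    stop("all-zero sample: ", colnames(x$counts)[which(tot == 0)[1]])
  x$counts <- sweep(x$counts, 2L, tot, "/") * 1e6
  x$normalized <- TRUE
  x
}

# mean abundance per gene over the samples of one compartment
compartment_mean <- function(x, compartment) {
  cols <- x$samples$sample[x$samples$compartment == compartment]
  if (length(cols) == 0L) return(NULL)
  rowMeans(x$counts[, cols, drop = FALSE])
}

#' Call nucleolar-enriched transcripts
#'
#' Per gene, the fold change is
#' `(mean nucleolar CPM + alpha) / (mean total CPM + alpha)`; a gene is
#' enriched iff `fold_change >= fold` (inclusive: "two-fold or more").
#'
#' @param x a normalized [expression_table()] with at least one `nucleolar`
#'   and one `total` sample.
#' @param fold enrichment threshold (default 2).
#' @param pseudocount additive pseudocount alpha (default 0.5, on the CPM
#'   scale).
#' @param genes optional gene-model data.frame used to attach biotypes.
#' @return An `enrichment_call` data.frame: `gene_id`, `nucleolar_cpm`,
#'   `total_cpm`, `fold_change`, `enriched` (+ `biotype` when available).
#' @export
call_nucleolar_enriched <- function(x, fold = 2, pseudocount = 0.5,
                                    genes = NULL) {
  stopifnot(inherits(x, "expression_table"))
  if (!x$normalized)
    stop("expression table must be normalized first (normalize_expression)")
  if (fold <= 0) stop("fold threshold must be > 0")
  mn <- compartment_mean(x, "nucleolar")
  mt <- compartment_mean(x, "total")
  if (is.null(mn) || is.null(mt))
    stop("need >= 1 nucleolar and >= 1 total sample")
  fc <- (mn + pseudocount) / (mt + pseudocount)
  out <- data.frame(gene_id = rownames(x$counts), nucleolar_cpm = mn,
                    total_cpm = mt, fold_change = fc,
                    enriched = fc >= fold, stringsAsFactors = FALSE,
                    row.names = NULL)
  if (!is.null(genes))
    out$biotype <- genes$biotype[match(out$gene_id, genes$gene_id)]
  structure(out, class = c("enrichment_call", "data.frame"),
            fold = fold, pseudocount = pseudocount)
}

#' @export
print.enrichment_call <- function(x, ...) {
  cat("Nucleolar enrichment call (fold >=", attr(x, "fold"), "):",
      sum(x$enriched), "of", nrow(x), "genes enriched\n")
  invisible(x)
}

#' Biotype composition of the nucleolar-enriched transcriptome
#'
#' Fractions over the enriched gene set (they sum to 1), with the
#' protein-coding vs non-coding rollup.
#'
#' @param calls an `enrichment_call` with a `biotype` column (see
#'   [call_nucleolar_enriched()]).
#' @return As [biotype_composition()].
#' @export
nucleolar_transcriptome_composition <- function(calls) {
  stopifnot(inherits(calls, "enrichment_call"))
  if (is.null(calls$biotype))
    stop("enrichment call lacks biotypes; pass genes= when calling")
  enriched <- calls[calls$enriched, , drop = FALSE]
  if (nrow(enriched) == 0L) stop("no enriched genes: composition undefined")
  biotype_composition(enriched$biotype)
}

#' Partition NAGs by transcriptional compartment
#'
#' Disjoint and exhaustive three-way partition of a NAG set:
#' `nucleolar` (nucleolar-enriched per `calls`), `nuclear_only`
#' (not enriched but nuclear abundance >= `min_expr` CPM), and `silent`
#' (neither). NAG ids absent from the expression data are reported with a
#' warning and classified `silent`.
#'
#' @param nags a `nag_set` (or character vector of gene ids).
#' @param calls an `enrichment_call`.
#' @param nuclear a normalized [expression_table()] containing `nuclear`
#'   samples (may be the same table used for the enrichment call).
#' @param min_expr detection threshold in CPM for "transcribed in the
#'   nucleus" (default 1).
#' @return A `nag_partition`: list with `counts` (named integer vector
#'   `nucleolar`, `nuclear_only`, `silent`) and `classes` (per-gene
#'   data.frame).
#' @export
nag_transcription_partition <- function(nags, calls, nuclear,
                                        min_expr = 1) {
  ids <- if (is.character(nags)) unique(nags) else nags$gene_id
  stopifnot(inherits(calls, "enrichment_call"))
  stopifnot(inherits(nuclear, "expression_table"))
  if (!nuclear$normalized) stop("nuclear expression table must be normalized")
  mnuc <- compartment_mean(nuclear, "nuclear")
  if (is.null(mnuc)) stop("expression table has no nuclear samples")
  missing <- setdiff(ids, union(calls$gene_id, names(mnuc)))
  if (length(missing))
    warning(length(missing), " NAG id(s) absent from expression data ",
            "(classified silent), e.g. ", missing[1])
  enriched <- ids %in% calls$gene_id[calls$enriched]
  nuc_cpm <- mnuc[match(ids, names(mnuc))]
  nuc_cpm[is.na(nuc_cpm)] <- 0
  cls <- ifelse(enriched, "nucleolar",
                ifelse(nuc_cpm >= min_expr, "nuclear_only", "silent"))
  counts <- c(nucleolar = sum(cls == "nucleolar"),
              nuclear_only = sum(cls == "nuclear_only"),
              silent = sum(cls == "silent"))
  structure(list(counts = counts,
                 classes = data.frame(gene_id = ids, class = cls,
                                      nuclear_cpm = as.numeric(nuc_cpm),
                                      stringsAsFactors = FALSE,
                                      row.names = NULL),
                 min_expr = min_expr),
            class = "nag_partition")
}

#' @export
print.nag_partition <- function(x, ...) {
  cat("NAG transcription partition (min nuclear expression",
      x$min_expr, "CPM):\n")
  print(x$counts)
  invisible(x)
}

#' Repeat-class association of a gene set
#'
#' Fraction of genes whose body overlaps at least one repeat element of
#' each class (`SINE`, `LINE`, `other`); a gene counts once per class no
#' matter how many elements it overlaps. Unknown class labels are grouped
#' as `other`.
#'
#' @param gene_ids character vector of gene ids.
#' @param genes gene-model data.frame providing coordinates.
#' @param repeats interval data.frame of repeat elements whose `name`
#'   column is the repeat class.
#' @return named numeric vector of per-class fractions in [0, 1].
#' @export
repeat_association <- function(gene_ids, genes, repeats) {
  gm <- genes[match(unique(gene_ids), genes$gene_id), , drop = FALSE]
  if (anyNA(gm$gene_id)) stop("gene models missing for some gene ids")
  classes <- c("SINE", "LINE", "other")
  if (nrow(gm) == 0L) return(setNames(rep(NA_real_, 3), classes))
  if (nrow(repeats) == 0L) return(setNames(rep(0, 3), classes))
  validate_intervals(repeats, what = "repeats")
  cls <- ifelse(repeats$name %in% c("SINE", "LINE"), repeats$name, "other")
  hits <- find_interval_overlaps(gm, repeats)
  out <- vapply(classes, function(cl) {
    touched <- unique(hits$a_idx[cls[hits$b_idx] == cl])
    length(touched) / nrow(gm)
  }, 1)
  out
}
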