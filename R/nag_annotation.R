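# Nucleolus-associated genes: which genes overlap NAD segments, their
# biotype make-up, and multi-cell-line set comparison (Venn region counts).

#' Annotate nucleolus-associated genes (NAGs)
#'
#' A gene is a NAG iff its body `[start, end)` overlaps any NAD segment by
#' at least `min_overlap` bp (half-open: a gene merely adjacent to a segment
#' is excluded). Overlap statistics are aggregated over all segments, which
#' are disjoint by construction.
#'
#' @param nads a `nad_call` from [call_nads()].
#' @param genes gene-model data.frame (see [read_gtf_genes()]).
#' @param min_overlap minimum overlap in bp (default 1).
#' @param cell_line optional label carried in the result.
#' @return A `nag_set` data.frame: `gene_id`, `gene_name`, `biotype`,
#'   `chrom`, `gene_bp`, `overlap_bp`, `fraction_in_nad`; attributes
#'   `cell_line`, `min_overlap`, `n_nad_segments`.
#' @export
annotate_nags <- function(nads, genes, min_overlap = 1, cell_line = NA) {
  stopifnot(inherits(nads, "nad_call"))
  if (min_overlap < 1) stop("min_overlap must be >= 1 bp")
  validate_intervals(genes, what = "gene models")
  segs <- nads$segments
  hits <- find_interval_overlaps(genes, segs, min_overlap = 1)
  ov_by_gene <- numeric(nrow(genes))
  if (nrow(hits)) {
    agg <- tapply(hits$overlap_bp, hits$a_idx, sum)
    ov_by_gene[as.integer(names(agg))] <- agg
  }
  keep <- ov_by_gene >= min_overlap
  out <- data.frame(gene_id = genes$gene_id[keep],
                    gene_name = genes$gene_name[keep],
                    biotype = genes$biotype[keep],
                    chrom = genes$chrom[keep],
                    gene_bp = (genes$end - genes$start)[keep],
                    overlap_bp = ov_by_gene[keep],
                    stringsAsFactors = FALSE, row.names = NULL)
  out$fraction_in_nad <- out$overlap_bp / out$gene_bp
  structure(out, class = c("nag_set", "data.frame"),
            cell_line = cell_line, min_overlap = min_overlap,
            n_nad_segments = nrow(segs))
}

#' @export
print.nag_set <- function(x, ...) {
  cl <- attr(x, "cell_line")
  cat("NAG set", if (!is.na(cl)) paste0("[", cl, "]") else "", ":",
      nrow(x), "genes overlapping", attr(x, "n_nad_segments"),
      "NAD segments (min overlap", attr(x, "min_overlap"), "bp)\n")
  print.data.frame(head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...", nrow(x) - 6, "more genes\n")
  invisible(x)
}

#' Biotype composition of a gene set
#'
#' Fractions per biotype class, plus the protein-coding vs non-coding
#' rollup. Fractions sum to 1 over the set.
#'
#' @param x a `nag_set`, or any data.frame with a `biotype` column, or a
#'   character vector of biotypes.
#' @return list with `by_class` (data.frame `biotype`, `n`, `fraction`),
#'   `coding_fraction`, `non_coding_fraction`, `n`.
#' @export
biotype_composition <- function(x) {
  biotype <- if (is.character(x)) x else x$biotype
  if (is.null(biotype) || length(biotype) == 0L)
    stop("empty set: biotype composition undefined")
  tab <- sort(table(biotype), decreasing = TRUE)
  by_class <- data.frame(biotype = names(tab), n = as.integer(tab),
                         fraction = as.numeric(tab) / length(biotype),
                         stringsAsFactors = FALSE, row.names = NULL)
  coding <- mean(biotype == "protein_coding")
  list(by_class = by_class, coding_fraction = coding,
       non_coding_fraction = 1 - coding, n = length(biotype))
}

#' Multi-way set comparison (Venn region counts)
#'
#' Exact counts of every non-empty membership pattern over 2-6 named sets
#' (more are computed but flagged with a warning, as the 2^k table becomes
#' unwieldy). Region counts sum to the union size.
#'
#' @param sets named list of character vectors (gene ids).
#' @return A `set_comparison`: list with `labels`, `region_counts` (named
#'   integer vector, names like `"A&B"`), `union_size`, and `members`
#'   (list of ids per pattern).
#' @export
compare_sets <- function(sets) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be a named list")
  if (length(sets) < 2L) stop("need at least 2 sets")
  if (length(sets) > 6L)
    warning("more than 6 sets: full 2^k membership table computed anyway")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  universe <- unique(unlist(sets, use.names = FALSE))
  memb <- vapply(sets, function(s) universe %in% s,
                 logical(length(universe)))
  memb <- matrix(memb, nrow = length(universe),
                 dimnames = list(NULL, names(sets)))
  pattern <- apply(memb, 1L, function(row)
    paste(names(sets)[row], collapse = "&"))
  counts <- table(pattern)
  members <- split(universe, pattern)
  structure(list(labels = names(sets),
                 region_counts = setNames(as.integer(counts), names(counts)),
                 union_size = length(universe),
                 members = members),
            class = "set_comparison")
}

#' Region count for one membership pattern
#'
#' Convenience accessor: the number of elements belonging to exactly the
#' given labels (and to no other set in the comparison).
#'
#' @param comparison a `set_comparison`.
#' @param labels character vector of set labels.
#' @return integer count (0 if the pattern is empty).
#' @export
region_count <- function(comparison, labels) {
  stopifnot(inherits(comparison, "set_comparison"))
  if (!all(labels %in% comparison$labels))
    stop("unknown label(s): ",
         paste(setdiff(labels, comparison$labels), collapse = ", "))
  key <- paste(comparison$labels[comparison$labels %in% labels],
               collapse = "&")
  n <- comparison$region_counts[key]
  if (is.na(n)) 0L else as.integer(n)
}

#' @export
print.set_comparison <- function(x, ...) {
  cat("Set comparison over", length(x$labels), "sets (",
      paste(x$labels, collapse = ", "), "); union", x$union_size, "\n")
  df <- data.frame(pattern = names(x$region_counts),
                   n = as.integer(x$region_counts), row.names = NULL)
  print.data.frame(df[order(-df$n), ], row.names = FALSE)
  invisible(x)
}

#' Write a NAG table as TSV
#' @param nags a `nag_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_nag_table <- function(nags, path) {
  write.table(as.data.frame(nags), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
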