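# Fixture builders and independent brute-force oracles. The oracles
# re-derive each quantity by direct enumeration (per-pair, per-bp,
# per-element), never through the package's own interval machinery.

toy_assembly <- function(lengths = c(chrA = 3e5, chrB = 2e5)) {
  genome_assembly(names(lengths), lengths)
}

random_intervals <- function(n, assembly, max_len = 5e3) {
  ci <- sample.int(nrow(assembly), n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  lim <- assembly$length[ci] - len
  start <- floor(runif(n, 0, pmax(lim, 1)))
  data.frame(chrom = assembly$chrom[ci], start = start, end = start + len,
             name = paste0("iv", seq_len(n)),
             score = round(runif(n, 0, 100), 2),
             strand = sample(c("+", "-", "."), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

toy_genes <- function(df) {
  # df: chrom, start, end, strand [, biotype]
  n <- nrow(df)
  df$gene_id <- sprintf("G%03d", seq_len(n))
  df$gene_name <- df$gene_id
  if (is.null(df$biotype)) df$biotype <- "protein_coding"
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1)
  df[, c("gene_id", "gene_name", "chrom", "start", "end", "strand",
         "biotype", "tss")]
}

# all-pairs quadratic overlap oracle
brute_overlaps <- function(a, b) {
  out <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
    if (ov > 0)
      out[[length(out) + 1L]] <- data.frame(a_idx = i, b_idx = j,
                                            overlap_bp = ov)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(a_idx = integer(), b_idx = integer(), overlap_bp = numeric())
}

# connected components of the pairwise-overlap graph by union-find
brute_components <- function(peaks) {
  n <- nrow(peaks)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j || peaks$chrom[i] != peaks$chrom[j]) next
    if (max(peaks$start[i], peaks$start[j]) <
        min(peaks$end[i], peaks$end[j]))
      parent[find(i)] <- find(j)
  }
  vapply(seq_len(n), find, 1L)
}

# power-set membership enumeration
brute_venn <- function(sets) {
  universe <- unique(unlist(sets))
  patterns <- vapply(universe, function(el) {
    inset <- vapply(sets, function(s) el %in% s, TRUE)
    paste(names(sets)[inset], collapse = "&")
  }, "")
  table(patterns)
}

# per-bp occupancy vector over a toy assembly
bp_mask <- function(segs, assembly) {
  offs <- c(0, cumsum(assembly$length))
  mask <- logical(sum(assembly$length))
  for (i in seq_len(nrow(segs))) {
    o <- offs[match(segs$chrom[i], assembly$chrom)]
    if (segs$end[i] > segs$start[i])
      mask[(o + segs$start[i] + 1):(o + segs$end[i])] <- TRUE
  }
  mask
}

# wrap a segments data.frame as a minimal nad_call for the set operations
fake_nad_call <- function(segs, assembly) {
  structure(list(segments = segs, assembly = assembly,
                 bin_positive = logical(), threshold = 2, max_gap_bins = 0),
            class = "nad_call")
}

random_segments <- function(assembly, n_seg = 5, bin = 1e4) {
  segs <- list()
  for (i in seq_len(n_seg)) {
    ci <- sample.int(nrow(assembly), 1)
    nb <- assembly$length[ci] %/% bin
    s <- (sample.int(nb, 1) - 1) * bin
    len <- sample.int(3, 1) * bin
    segs[[i]] <- data.frame(chrom = assembly$chrom[ci], start = s,
                            end = min(s + len, assembly$length[ci]),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, segs)
  # drop duplicates/contained rows to keep the fixture simple; overlap is
  # still possible and intended
  out[!duplicated(out), , drop = FALSE]
}

bin_f1 <- function(called, truth) {
  tp <- sum(called & truth)
  2 * tp / (2 * tp + sum(called & !truth) + sum(!called & truth))
}
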