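#' @importFrom stats median rnbinom rlnorm rgeom runif setNames quantile
#' @importFrom utils read.table write.table head tail
#' @importFrom methods is
NULL

# Coordinates are 0-based half-open [start, end) everywhere inside the
# package; BED is native, GTF is converted on read, GRanges (1-based closed)
# only inside helper calls.

#' Construct a genome assembly
#'
#' An assembly is an ordered table of chromosome names and lengths, the
#' coordinate frame for every interval, bin grid and track in the package.
#'
#' @param chrom character vector of chromosome names (unique).
#' @param length integer-like vector of chromosome lengths in bp (>= 1).
#' @return A `genome_assembly` data.frame with columns `chrom` and `length`.
#' @export
genome_assembly <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (base::length(chrom) != base::length(length))
    stop("chrom and length must have equal length")
  if (base::length(chrom) == 0L) stop("assembly must have >= 1 chromosome")
  if (anyDuplicated(chrom))
    stop("duplicate chromosome name: ",
         paste(unique(chrom[duplicated(chrom)]), collapse = ", "))
  if (any(!is.finite(length)) || any(length < 1) || any(length != floor(length)))
    stop("chromosome lengths must be positive integers")
  structure(data.frame(chrom = chrom, length = length,
                       stringsAsFactors = FALSE),
            class = c("genome_assembly", "data.frame"))
}

#' Total assembly size in bp
#' @param assembly a `genome_assembly`.
#' @return numeric, sum of chromosome lengths.
#' @export
assembly_size <- function(assembly) sum(assembly$length)

#' @export
print.genome_assembly <- function(x, ...) {
  cat("Genome assembly:", nrow(x), "chromosomes,",
      format(assembly_size(x), big.mark = ","), "bp\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Read a chrom.sizes file
#'
#' Two whitespace-separated columns: chromosome name, length in bp. File
#' order is preserved.
#'
#' @param path path to a chrom.sizes file.
#' @return A [genome_assembly()].
#' @export
read_chrom_sizes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty chrom.sizes file: ", path)
  parts <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(vapply(parts, length, 1L) != 2L)
  if (length(bad))
    stop("malformed chrom.sizes line ", bad[1], ": ", lines[bad[1]])
  len <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  if (anyNA(len))
    stop("non-numeric length in chrom.sizes: ",
         lines[which(is.na(len))[1]])
  genome_assembly(vapply(parts, `[`, "", 1L), len)
}

#' Write a chrom.sizes file
#' @param assembly a `genome_assembly`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(assembly, path) {
  writeLines(paste(assembly$chrom, format(assembly$length, scientific = FALSE,
                                          trim = TRUE)), path)
  invisible(path)
}

#' Tile an assembly into fixed-size bins
#'
#' Every chromosome is tiled completely by adjacent, non-overlapping bins of
#' `bin_size` bp; only the last bin of a chromosome may be shorter. Bins at
#' chromosome ends are truncated, never dropped, so bin lengths always sum to
#' the assembly size.
#'
#' @param assembly a [genome_assembly()].
#' @param bin_size bin width in bp (default 100 kb, the standard NAD-mapping
#'   resolution).
#' @return A `bin_grid` data.frame with columns `bin`, `chrom`, `start`,
#'   `end`; attributes `bin_size` and `assembly`.
#' @export
make_bins <- function(assembly, bin_size = 1e5) {
  stopifnot(is(assembly, "genome_assembly"))
  if (!is.numeric(bin_size) || length(bin_size) != 1L || bin_size < 1)
    stop("bin_size must be a single integer >= 1")
  bin_size <- floor(bin_size)
  pieces <- lapply(seq_len(nrow(assembly)), function(i) {
    len <- assembly$length[i]
    n <- ceiling(len / bin_size)
    start <- (seq_len(n) - 1) * bin_size
    data.frame(chrom = assembly$chrom[i], start = start,
               end = pmin(start + bin_size, len), stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, pieces)
  grid <- cbind(bin = seq_len(nrow(grid)), grid)
  rownames(grid) <- NULL
  structure(grid, class = c("bin_grid", "data.frame"),
            bin_size = bin_size, assembly = assembly)
}

#' @export
print.bin_grid <- function(x, ...) {
  cat("Bin grid:", nrow(x), "bins of", format(attr(x, "bin_size"),
      big.mark = ","), "bp over", nrow(attr(x, "assembly")), "chromosomes\n")
  print.data.frame(head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("...", nrow(x) - 6, "more bins\n")
  invisible(x)
}

# validate an interval data.frame (chrom/start/end [+ name/score/strand])
validate_intervals <- function(x, assembly = NULL, what = "intervals") {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(x)))
    stop(what, " must have columns chrom, start, end")
  if (nrow(x) == 0L) return(invisible(x))
  if (any(x$start < 0)) stop(what, ": negative start coordinate")
  if (any(x$start >= x$end))
    stop(what, ": start must be < end (0-based half-open); first offender row ",
         which(x$start >= x$end)[1])
  if (!is.null(assembly)) {
    m <- match(x$chrom, assembly$chrom)
    if (anyNA(m))
      stop(what, ": unknown chromosome ", x$chrom[which(is.na(m))[1]])
    if (any(x$end > assembly$length[m]))
      stop(what, ": interval beyond chromosome end at row ",
           which(x$end > assembly$length[m])[1])
  }
  invisible(x)
}

#' Read a BED3/BED6 file
#'
#' Coordinates are kept 0-based half-open, BED's native convention. Columns
#' beyond the sixth are ignored; missing name/score/strand fields become
#' `NA`/`NA`/`"."`.
#'
#' @param path path to a BED file.
#' @param assembly optional [genome_assembly()] to validate against.
#' @return data.frame with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @export
read_bed <- function(path, assembly = NULL) {
  x <- read.table(path, sep = "\t", header = FALSE, quote = "",
                  comment.char = "#", stringsAsFactors = FALSE,
                  colClasses = "character", fill = TRUE)
  if (ncol(x) < 3L) stop("BED file must have >= 3 columns: ", path)
  out <- data.frame(chrom = x[[1]],
                    start = as.numeric(x[[2]]),
                    end = as.numeric(x[[3]]),
                    stringsAsFactors = FALSE)
  out$name <- if (ncol(x) >= 4L) ifelse(x[[4]] == ".", NA, x[[4]]) else NA_character_
  out$score <- if (ncol(x) >= 5L)
    suppressWarnings(ifelse(x[[5]] == ".", NA, as.numeric(x[[5]]))) else NA_real_
  out$strand <- if (ncol(x) >= 6L) x[[6]] else "."
  if (anyNA(out$start) || anyNA(out$end))
    stop("non-numeric BED coordinates in ", path)
  bad_strand <- !out$strand %in% c("+", "-", ".")
  if (any(bad_strand))
    stop("unknown strand symbol in BED: ", out$strand[which(bad_strand)[1]])
  validate_intervals(out, assembly, what = basename(path))
  out
}

#' Write intervals as BED
#'
#' Writes BED6 (or BED3 when name/score/strand are absent). Round-trips
#' exactly with [read_bed()] for canonical records.
#'
#' @param x interval data.frame (`chrom`, `start`, `end`, optional `name`,
#'   `score`, `strand`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  fmt_num <- function(v) format(v, scientific = FALSE, trim = TRUE)
  cols <- list(x$chrom, fmt_num(x$start), fmt_num(x$end))
  if (!is.null(x$name) || !is.null(x$score) || !is.null(x$strand)) {
    name <- if (is.null(x$name)) rep(".", nrow(x)) else ifelse(is.na(x$name), ".", x$name)
    score <- if (is.null(x$score)) rep(".", nrow(x)) else
      ifelse(is.na(x$score), ".", fmt_num(x$score))
    strand <- if (is.null(x$strand)) rep(".", nrow(x)) else x$strand
    cols <- c(cols, list(name, score, strand))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Read gene models from a GTF file
#'
#' Extracts `gene` feature rows and converts the GTF 1-based closed
#' coordinates to the package's 0-based half-open convention. The TSS is the
#' first transcribed base: `start` for `+` genes, `end - 1` for `-` genes.
#' Attribute keys follow the Ensembl dialect but are configurable.
#'
#' @param path path to a GTF file.
#' @param feature_type feature column value identifying gene rows.
#' @param id_attr,name_attr,biotype_attr attribute keys for gene id, gene name
#'   and biotype. `id_attr` is mandatory in the file; missing names fall back
#'   to the id, missing biotypes to `NA`.
#' @return data.frame of gene models: `gene_id`, `gene_name`, `chrom`,
#'   `start`, `end`, `strand`, `biotype`, `tss`.
#' @export
read_gtf_genes <- function(path, feature_type = "gene", id_attr = "gene_id",
                           name_attr = "gene_name",
                           biotype_attr = "gene_biotype") {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[as.character(gr$type) == feature_type]
  if (length(gr) == 0L) stop("no '", feature_type, "' features in ", path)
  mc <- as.data.frame(S4Vectors::mcols(gr))
  if (!id_attr %in% names(mc) || anyNA(mc[[id_attr]]))
    stop("GTF gene feature lacking mandatory attribute '", id_attr, "'")
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(strand == "*"))
    stop("unknown strand symbol in GTF gene feature (strand must be + or -)")
  start0 <- BiocGenerics::start(gr) - 1L   # to 0-based half-open
  end0 <- BiocGenerics::end(gr)
  genes <- data.frame(
    gene_id = as.character(mc[[id_attr]]),
    gene_name = if (name_attr %in% names(mc))
      ifelse(is.na(mc[[name_attr]]), as.character(mc[[id_attr]]),
             as.character(mc[[name_attr]]))
    else as.character(mc[[id_attr]]),
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = start0, end = end0, strand = strand,
    biotype = if (biotype_attr %in% names(mc))
      as.character(mc[[biotype_attr]]) else NA_character_,
    stringsAsFactors = FALSE)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  validate_intervals(genes, what = "gene models")
  genes
}

#' Write gene models as GTF
#'
#' Inverse of [read_gtf_genes()] for the fields this package uses (gene
#' feature rows only, Ensembl attribute keys).
#'
#' @param genes gene-model data.frame as returned by [read_gtf_genes()].
#' @param path output path.
#' @param source source column value.
#' @return `path`, invisibly.
#' @export
write_gtf_genes <- function(genes, path, source = "nadcall") {
  attrs <- sprintf('gene_id "%s"; gene_name "%s"; gene_biotype "%s";',
                   genes$gene_id, genes$gene_name, genes$biotype)
  lines <- paste(genes$chrom, source, "gene",
                 format(genes$start + 1, scientific = FALSE, trim = TRUE),
                 format(genes$end, scientific = FALSE, trim = TRUE),
                 ".", genes$strand, ".", attrs, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

# internal: intervals -> GRanges (1-based closed)
as_gr <- function(x) {
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start + 1, end = x$end))
}

#' Overlapping pairs between two interval sets
#'
#' Reports every pair (i, j) with `a[i]` and `b[j]` on the same chromosome
#' and `max(starts) < min(ends)` (half-open overlap), with the overlap width.
#'
#' @param a,b interval data.frames.
#' @param min_overlap minimum overlap in bp for a pair to be reported.
#' @return data.frame `a_idx`, `b_idx`, `overlap_bp`.
#' @export
find_interval_overlaps <- function(a, b, min_overlap = 1) {
  validate_intervals(a, what = "a"); validate_intervals(b, what = "b")
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(data.frame(a_idx = integer(), b_idx = integer(),
                      overlap_bp = numeric()))
  hits <- GenomicRanges::findOverlaps(as_gr(a), as_gr(b),
                                      minoverlap = min_overlap)
  ai <- S4Vectors::queryHits(hits); bi <- S4Vectors::subjectHits(hits)
  ov <- pmin(a$end[ai], b$end[bi]) - pmax(a$start[ai], b$start[bi])
  data.frame(a_idx = ai, b_idx = bi, overlap_bp = ov)
}
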