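# Core genomic containers and readers/writers.
#
# Coordinate convention: everywhere in memory and on disk (BED, bedGraph,
# gene table) intervals are 0-based, half-open [start, end). Conversion to
# the 1-based closed convention of IRanges happens only inside as_granges().

#' Read a two-column chromosome sizes file
#'
#' @param path TSV with columns chrom, length (no header).
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  if (anyDuplicated(df$chrom))
    stop("duplicate chromosome in ", path)
  if (any(df$length <= 0))
    stop("non-positive chromosome length in ", path)
  stats::setNames(df$length, df$chrom)
}

#' @noRd
write_chrom_sizes <- function(chrom_sizes, path) {
  utils::write.table(
    data.frame(chrom = names(chrom_sizes), length = unname(chrom_sizes)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Validate an interval data frame
#'
#' Intervals are data frames with columns `chrom`, `start`, `end` and
#' optionally `name` and `score`, 0-based half-open.
#'
#' @param x data.frame of intervals.
#' @param chrom_sizes optional named vector; when given, intervals must lie
#'   within the named chromosomes.
#' @param what label used in error messages.
#' @return `x`, invisibly, after validation.
#' @export
validate_intervals <- function(x, chrom_sizes = NULL, what = "interval") {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad))
    stop(sprintf("malformed %s at record %d: start=%s end=%s",
                 what, bad[1], x$start[bad[1]], x$end[bad[1]]))
  if (!is.null(chrom_sizes)) {
    unk <- setdiff(unique(x$chrom), names(chrom_sizes))
    if (length(unk))
      stop("unknown chromosome: ", paste(unk, collapse = ", "))
    over <- which(x$end > chrom_sizes[x$chrom])
    if (length(over))
      stop(sprintf("%s at record %d extends beyond chromosome end",
                   what, over[1]))
  }
  invisible(x)
}

#' @noRd
sort_intervals <- function(x) {
  x[order(x$chrom, x$start, x$end), , drop = FALSE]
}

#' Convert 0-based half-open intervals to GRanges
#' @param x interval data.frame.
#' @param chrom_sizes optional seqlengths.
#' @return A [GenomicRanges::GRanges] object.
#' @export
as_granges <- function(x, chrom_sizes = NULL) {
  if (!is.null(chrom_sizes)) validate_intervals(x, chrom_sizes)
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end))
}

#' Read a BED3/BED6 file
#'
#' @param path BED file, tab-separated, no header.
#' @param chrom_sizes optional named vector for bounds checking.
#' @return data.frame with columns chrom, start, end, name, score.
#' @export
read_bed <- function(path, chrom_sizes = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), name = character(),
                      score = numeric()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("BED record with < 3 fields at line ", which(nf < 3)[1])
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  if (anyNA(start) || anyNA(end))
    stop("non-numeric BED coordinate at line ",
         which(is.na(start) | is.na(end))[1])
  bad <- which(start >= end | start < 0)
  if (length(bad))
    stop(sprintf("malformed BED interval at line %d: start=%s end=%s",
                 bad[1], start[bad[1]], end[bad[1]]))
  name <- ifelse(nf >= 4, vapply(fields, function(f) f[min(4, length(f))], ""),
                 paste0("iv", seq_along(fields)))
  score <- ifelse(nf >= 5,
                  suppressWarnings(as.numeric(
                    vapply(fields, function(f) f[min(5, length(f))], ""))),
                  0)
  out <- data.frame(chrom = chrom, start = start, end = end,
                    name = name, score = score)
  validate_intervals(out, chrom_sizes, what = "BED interval")
  out
}

#' Write intervals as BED
#'
#' Records are sorted by (chrom, start) on write; name and score columns are
#' emitted when present (BED4/BED5), otherwise BED3.
#'
#' @param x interval data.frame.
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  x <- sort_intervals(x)
  cols <- list(x$chrom, format_coord(x$start), format_coord(x$end))
  if (!is.null(x$name)) {
    cols <- c(cols, list(x$name))
    if (!is.null(x$score)) cols <- c(cols, list(x$score))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

# integer-formatted coordinates even when stored as doubles
format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Construct a binned coverage track
#'
#' A BinnedTrack stores one numeric value per fixed-width bin per chromosome;
#' the last bin of a chromosome is truncated at the chromosome end, never
#' dropped.
#'
#' @param values named list, chromosome -> numeric vector of bin values.
#' @param bin_size bin width in bases.
#' @param chrom_sizes named vector of chromosome lengths.
#' @param sample_id sample identifier.
#' @param role one of "flag", "h2a", "atac".
#' @return A `BinnedTrack` object.
#' @export
binned_track <- function(values, bin_size, chrom_sizes, sample_id = "sample",
                         role = c("flag", "h2a", "atac")) {
  role <- match.arg(role)
  stopifnot(is.list(values), bin_size >= 1)
  if (!setequal(names(values), names(chrom_sizes)))
    stop("track chromosomes do not match chrom_sizes")
  for (chr in names(chrom_sizes)) {
    nb <- n_bins(chrom_sizes[[chr]], bin_size)
    if (length(values[[chr]]) != nb)
      stop(sprintf("chromosome %s: expected %d bins, got %d",
                   chr, nb, length(values[[chr]])))
  }
  structure(list(values = values[names(chrom_sizes)], bin_size = bin_size,
                 chrom_sizes = chrom_sizes, sample_id = sample_id,
                 role = role),
            class = "BinnedTrack")
}

#' Number of bins covering a chromosome
#' @param length chromosome length in bases.
#' @param bin_size bin width in bases.
#' @return ceiling(length / bin_size).
#' @export
n_bins <- function(length, bin_size) as.integer(ceiling(length / bin_size))

#' @export
print.BinnedTrack <- function(x, ...) {
  cat(sprintf("BinnedTrack '%s' (%s): %d chromosome(s), bin_size=%d, %d bins\n",
              x$sample_id, x$role, length(x$values), as.integer(x$bin_size),
              sum(lengths(x$values))))
  invisible(x)
}

#' Read a bedGraph file onto a fixed bin grid
#'
#' Records must be sorted and non-overlapping within chromosomes. Values are
#' resampled onto the bin grid by coverage-weighted mean: a record
#' contributes value * overlap-width to each bin it touches, and each bin's
#' value is the accumulated mass divided by the bin width (uncovered bases
#' count as zero).
#'
#' @param path bedGraph file.
#' @param chrom_sizes named vector of chromosome lengths.
#' @param bin_size target bin width.
#' @param sample_id,role stored on the returned track.
#' @return A [binned_track()] object.
#' @export
read_bedgraph <- function(path, chrom_sizes, bin_size, sample_id = "sample",
                          role = "flag") {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "value"),
                          colClasses = c("character", "numeric", "numeric",
                                         "numeric"))
  if (nrow(df)) validate_intervals(df, chrom_sizes, what = "bedGraph record")
  values <- lapply(names(chrom_sizes), function(chr) {
    L <- chrom_sizes[[chr]]
    nb <- n_bins(L, bin_size)
    mass <- numeric(nb)
    sub <- df[df$chrom == chr, , drop = FALSE]
    if (nrow(sub)) {
      sub <- sub[order(sub$start), , drop = FALSE]
      if (nrow(sub) > 1 && any(sub$start[-1] < sub$end[-nrow(sub)]))
        stop("overlapping bedGraph records on ", chr)
      b0 <- sub$start %/% bin_size
      b1 <- (sub$end - 1) %/% bin_size
      span <- b1 - b0 + 1
      idx <- rep.int(seq_len(nrow(sub)), span)
      bins <- b0[idx] + (sequence(span) - 1)
      lo <- pmax(sub$start[idx], bins * bin_size)
      hi <- pmin(sub$end[idx], (bins + 1) * bin_size)
      acc <- rowsum(sub$value[idx] * (hi - lo), bins)
      mass[as.numeric(rownames(acc)) + 1] <- acc[, 1]
    }
    widths <- pmin((seq_len(nb)) * bin_size, L) - (seq_len(nb) - 1) * bin_size
    mass / widths
  })
  names(values) <- names(chrom_sizes)
  binned_track(values, bin_size, chrom_sizes, sample_id, role)
}

#' Write a binned track as bedGraph
#'
#' Adjacent bins with equal values are merged into single run-length records;
#' zero-valued runs are omitted.
#'
#' @param track a [binned_track()] object.
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chr in names(track$values)) {
    v <- track$values[[chr]]
    if (!length(v)) next
    L <- track$chrom_sizes[[chr]]
    r <- rle(v)
    ends_bin <- cumsum(r$lengths)
    starts <- c(0, ends_bin[-length(ends_bin)]) * track$bin_size
    ends <- pmin(ends_bin * track$bin_size, L)
    keep <- r$values != 0
    if (any(keep))
      writeLines(paste(chr, format_coord(starts[keep]),
                       format_coord(ends[keep]),
                       format(r$values[keep], scientific = FALSE, trim = TRUE),
                       sep = "\t"), con)
  }
  invisible(path)
}

#' Construct a genome annotation
#'
#' Derives the transcription start and end site of each gene from its strand:
#' on the plus strand TSS = start and TES = end - 1; on the minus strand
#' TSS = end - 1 and TES = start ("upstream" of a minus-strand gene moves
#' toward larger coordinates).
#'
#' @param genes data.frame with columns chrom, start, end, strand, gene_id.
#' @param chrom_sizes named vector of chromosome lengths.
#' @return A `GenomeAnnotation` object: list(chrom_sizes, genes) where genes
#'   gains tss and tes columns.
#' @export
genome_annotation <- function(genes, chrom_sizes) {
  stopifnot(all(c("chrom", "start", "end", "strand", "gene_id") %in%
                  names(genes)))
  if (nrow(genes)) {
    validate_intervals(genes, chrom_sizes, what = "gene")
    if (!all(genes$strand %in% c("+", "-")))
      stop("unknown strand symbol: ",
           paste(setdiff(unique(genes$strand), c("+", "-")), collapse = ","))
    if (anyDuplicated(genes$gene_id))
      stop("duplicate gene_id: ", genes$gene_id[duplicated(genes$gene_id)][1])
  }
  genes <- sort_intervals(genes)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  genes$tes <- ifelse(genes$strand == "+", genes$end - 1, genes$start)
  rownames(genes) <- NULL
  structure(list(chrom_sizes = chrom_sizes, genes = genes),
            class = "GenomeAnnotation")
}

#' @export
print.GenomeAnnotation <- function(x, ...) {
  cat(sprintf("GenomeAnnotation: %d gene(s) on %d chromosome(s) (%s bp)\n",
              nrow(x$genes), length(x$chrom_sizes),
              format(sum(x$chrom_sizes), big.mark = ",")))
  invisible(x)
}

#' Read a gene table
#'
#' @param path TSV with header chrom, start, end, strand, gene_id
#'   (0-based half-open).
#' @param chrom_sizes named vector of chromosome lengths.
#' @return A [genome_annotation()] object.
#' @export
read_gene_table <- function(path, chrom_sizes) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c(chrom = "character",
                                         start = "numeric", end = "numeric",
                                         strand = "character",
                                         gene_id = "character"))
  genome_annotation(df, chrom_sizes)
}

#' Write a gene table
#' @param annotation a [genome_annotation()] object.
#' @param path output TSV path.
#' @export
write_gene_table <- function(annotation, path) {
  utils::write.table(
    annotation$genes[, c("chrom", "start", "end", "strand", "gene_id")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a count matrix
#'
#' @param counts integer matrix, genes x samples, with dimnames.
#' @param groups named character vector mapping sample id to "WT" or "MUT".
#' @return A `CountMatrix` object.
#' @export
count_matrix <- function(counts, groups) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("invalid count at gene '%s', sample '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  if (!all(colnames(counts) %in% names(groups)))
    stop("missing group label for sample: ",
         setdiff(colnames(counts), names(groups))[1])
  groups <- groups[colnames(counts)]
  if (!all(groups %in% c("WT", "MUT")))
    stop("group labels must be WT or MUT")
  structure(list(counts = counts, gene_ids = rownames(counts),
                 sample_ids = colnames(counts), groups = groups),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d genes x %d samples (%d WT, %d MUT)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$groups == "WT"), sum(x$groups == "MUT")))
  invisible(x)
}

#' Read a counts table
#'
#' @param path TSV; first column gene_id, remaining columns one per sample
#'   with a header row of sample ids.
#' @param groups named character vector mapping sample id to WT/MUT. When
#'   NULL, labels are inferred from sample ids starting with "WT"/"MUT".
#' @return A [count_matrix()] object.
#' @export
read_counts <- function(path, groups = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "numeric"
  if (is.null(groups)) {
    ids <- colnames(m)
    groups <- stats::setNames(ifelse(grepl("^WT", ids), "WT",
                                     ifelse(grepl("^MUT", ids), "MUT", NA)),
                              ids)
    if (anyNA(groups))
      stop("cannot infer WT/MUT group for sample: ", ids[is.na(groups)][1])
  }
  count_matrix(m, groups)
}

#' Write a counts table
#' @param cm a [count_matrix()] object.
#' @param path output TSV path.
#' @export
write_counts <- function(cm, path) {
  df <- data.frame(gene_id = cm$gene_ids, cm$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Strand-aware locus windows (1 kb upstream of TSS to TES)
#'
#' The locus window of a gene runs from `upstream` bases upstream of its TSS
#' to its TES; on the minus strand "upstream" extends toward larger
#' coordinates. Windows are clipped at chromosome boundaries and flagged.
#'
#' @param annotation a [genome_annotation()] object.
#' @param upstream bases upstream of the TSS (default 1000).
#' @return data.frame gene_id, chrom, start, end, clipped.
#' @export
locus_windows <- function(annotation, upstream = 1000) {
  g <- annotation$genes
  L <- annotation$chrom_sizes[g$chrom]
  start <- ifelse(g$strand == "+", g$start - upstream, g$start)
  end <- ifelse(g$strand == "+", g$end, g$end + upstream)
  clipped <- start < 0 | end > L
  data.frame(gene_id = g$gene_id, chrom = g$chrom,
             start = pmax(start, 0), end = pmin(end, L),
             clipped = clipped, row.names = NULL)
}

#' Strand-aware promoter windows around the TSS
#'
#' @param annotation a [genome_annotation()] object.
#' @param promoter_up,promoter_down bases upstream/downstream of the TSS
#'   (strand-aware; defaults 1000 each).
#' @return data.frame gene_id, chrom, start, end (clipped at chromosome
#'   boundaries).
#' @export
promoter_windows <- function(annotation, promoter_up = 1000,
                             promoter_down = 1000) {
  g <- annotation$genes
  L <- annotation$chrom_sizes[g$chrom]
  # plus strand: [TSS - up, TSS + down); minus: mirrored about the TSS base
  start <- ifelse(g$strand == "+", g$tss - promoter_up,
                  g$tss - promoter_down + 1)
  end <- ifelse(g$strand == "+", g$tss + promoter_down,
                g$tss + promoter_up + 1)
  data.frame(gene_id = g$gene_id, chrom = g$chrom,
             start = pmax(start, 0), end = pmin(end, L), row.names = NULL)
}
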