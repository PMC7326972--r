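# Genomic classification of peaks (promoter / gene body / intergenic), a
# length-preserving shuffled-peak null for the category distribution tested
# by chi-square, and co-localization with ATAC open-chromatin peaks.

PEAK_CATEGORIES <- c("promoter", "gene_body", "intergenic")

#' Assign each peak to a genomic category
#'
#' A peak overlapping (>= 1 bp) any strand-aware promoter window
#' `[TSS - promoter_up, TSS + promoter_down)` is "promoter"; otherwise a
#' peak overlapping any gene body is "gene_body"; otherwise "intergenic".
#' The precedence makes the categories mutually exclusive.
#'
#' @param peaks interval data.frame (chrom, start, end).
#' @param annotation a [genome_annotation()] object.
#' @param promoter_up,promoter_down promoter window extent around the TSS
#'   (strand-aware; defaults 1000 bp each side).
#' @return Factor of categories, one per peak, levels
#'   promoter/gene_body/intergenic.
#' @export
assign_category <- function(peaks, annotation, promoter_up = 1000,
                            promoter_down = 1000) {
  if (!nrow(peaks))
    return(factor(character(), levels = PEAK_CATEGORIES))
  validate_intervals(peaks, annotation$chrom_sizes, what = "peak")
  pk <- as_granges(peaks)
  cat <- rep("intergenic", nrow(peaks))
  if (nrow(annotation$genes)) {
    prom <- promoter_windows(annotation, promoter_up, promoter_down)
    hit_g <- unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(
      pk, as_granges(annotation$genes))))
    cat[hit_g] <- "gene_body"
    hit_p <- unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(
      pk, as_granges(prom))))
    cat[hit_p] <- "promoter"
  }
  factor(cat, levels = PEAK_CATEGORIES)
}

#' Shuffle peaks preserving lengths and chromosome composition
#'
#' Each shuffle keeps every peak on its original chromosome with its
#' original length and draws the start uniformly over valid positions.
#' Shuffled peaks may overlap one another (pure uniform null) unless
#' `allow_overlap = FALSE`, in which case each shuffle is redrawn by
#' rejection sampling until its peaks are disjoint.
#'
#' @param peaks interval data.frame.
#' @param chrom_sizes named vector of chromosome lengths.
#' @param n_shuffles number of shuffled sets.
#' @param seed integer seed (deterministic per seed).
#' @param allow_overlap allow shuffled peaks to overlap (default TRUE).
#' @return One data.frame with columns chrom, start, end, shuffle
#'   (1..n_shuffles).
#' @export
shuffle_peaks <- function(peaks, chrom_sizes, n_shuffles, seed = 1,
                          allow_overlap = TRUE) {
  validate_intervals(peaks, what = "peak")
  unk <- setdiff(unique(peaks$chrom), names(chrom_sizes))
  if (length(unk)) stop("unknown chromosome: ", unk[1])
  len <- peaks$end - peaks$start
  maxstart <- chrom_sizes[peaks$chrom] - len
  if (any(maxstart < 0))
    stop("peak longer than its chromosome")
  n <- nrow(peaks)
  .with_seed(seed, {
    if (allow_overlap) {
      st <- floor(stats::runif(n * n_shuffles, 0, rep(maxstart + 1,
                                                      n_shuffles)))
      out <- data.frame(chrom = rep(peaks$chrom, n_shuffles), start = st,
                        end = st + rep(len, n_shuffles),
                        shuffle = rep(seq_len(n_shuffles), each = n))
    } else {
      draw_one <- function() {
        repeat {
          st <- floor(stats::runif(n, 0, maxstart + 1))
          df <- data.frame(chrom = peaks$chrom, start = st, end = st + len)
          srt <- sort_intervals(df)
          ovl <- any(unlist(lapply(split(srt, srt$chrom), function(s)
            if (nrow(s) > 1) s$start[-1] < s$end[-nrow(s)] else FALSE)))
          if (!ovl) return(df)
        }
      }
      out <- do.call(rbind, lapply(seq_len(n_shuffles), function(i) {
        df <- draw_one()
        df$shuffle <- i
        df
      }))
    }
    rownames(out) <- NULL
    out
  })
}

#' Chi-square statistic from observed and expected category counts
#'
#' Expected counts are rescaled to the observed total; chi2 =
#' sum((O - E)^2 / E) with df = k - 1 and an upper-tail p-value.
#'
#' @param observed,expected numeric vectors over the same categories.
#' @return list(chi2, df, p, observed, expected).
#' @export
chi_square_from_counts <- function(observed, expected) {
  stopifnot(length(observed) == length(expected))
  if (any(expected <= 0))
    stop("zero expected category count: use more shuffles or merge ",
         "categories")
  expected <- expected * sum(observed) / sum(expected)
  chi2 <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df = df, lower.tail = FALSE),
       observed = observed, expected = expected)
}

#' Test the genomic distribution of peaks against a shuffled null
#'
#' Categorizes the observed peaks, generates `n_shuffles` length- and
#' chromosome-preserving shuffled peak sets, takes the mean category counts
#' over shuffles as the expected distribution, and compares with a
#' chi-square test (df = categories - 1).
#'
#' @param peaks interval data.frame.
#' @param annotation a [genome_annotation()] object.
#' @param n_shuffles number of shuffles (default 1000).
#' @param seed integer seed.
#' @param promoter_up,promoter_down promoter window extent (bp).
#' @param allow_overlap passed to [shuffle_peaks()].
#' @return An `AnnotationEnrichment` list: categories, observed, expected,
#'   chi2, df, p, n_shuffles, peak_categories (per-peak factor).
#' @export
annotation_enrichment <- function(peaks, annotation, n_shuffles = 1000,
                                  seed = 1, promoter_up = 1000,
                                  promoter_down = 1000,
                                  allow_overlap = TRUE) {
  obs_cat <- assign_category(peaks, annotation, promoter_up, promoter_down)
  observed <- table(obs_cat)
  sh <- shuffle_peaks(peaks, annotation$chrom_sizes, n_shuffles, seed,
                      allow_overlap)
  sh_cat <- assign_category(sh, annotation, promoter_up, promoter_down)
  expected <- table(sh_cat) / n_shuffles
  res <- chi_square_from_counts(as.numeric(observed), as.numeric(expected))
  structure(list(categories = PEAK_CATEGORIES,
                 observed = stats::setNames(as.numeric(observed),
                                            PEAK_CATEGORIES),
                 expected = stats::setNames(res$expected, PEAK_CATEGORIES),
                 chi2 = res$chi2, df = res$df, p = res$p,
                 n_shuffles = n_shuffles, peak_categories = obs_cat),
            class = "AnnotationEnrichment")
}

#' @export
print.AnnotationEnrichment <- function(x, ...) {
  cat("Peak genomic distribution vs shuffled null\n")
  print(rbind(observed = x$observed, expected = round(x$expected, 1)))
  cat(sprintf("chi2 = %.3f, df = %d, p = %.3g (%d shuffles)\n",
              x$chi2, x$df, x$p, x$n_shuffles))
  invisible(x)
}

#' Co-localization of peaks with ATAC open-chromatin peaks
#'
#' A peak is co-localized when it overlaps an ATAC peak by >= 1 bp;
#' computed overall and stratified by genomic category when given.
#'
#' @param peaks interval data.frame.
#' @param atac ATAC interval data.frame.
#' @param categories optional per-peak factor from [assign_category()].
#' @return list(n_peaks, n_colocalized, fraction, by_category,
#'   colocalized = logical per peak).
#' @export
atac_colocalization <- function(peaks, atac, categories = NULL) {
  n <- nrow(peaks)
  hit <- logical(n)
  if (n && nrow(atac)) {
    ov <- GenomicRanges::findOverlaps(as_granges(peaks), as_granges(atac))
    hit[unique(S4Vectors::queryHits(ov))] <- TRUE
  }
  by_cat <- NULL
  if (!is.null(categories)) {
    stopifnot(length(categories) == n)
    by_cat <- do.call(rbind, lapply(levels(categories), function(lv) {
      sel <- categories == lv
      data.frame(category = lv, n_peaks = sum(sel),
                 n_colocalized = sum(hit[sel]),
                 fraction = if (sum(sel)) sum(hit[sel]) / sum(sel) else NA)
    }))
  }
  list(n_peaks = n, n_colocalized = sum(hit),
       fraction = if (n) sum(hit) / n else NA,
       by_category = by_cat, colocalized = hit)
}

#' Cross-tabulate promoter-peak genes with upregulated genes
#'
#' Finds genes whose promoter window overlaps at least one peak and
#' intersects them with a set of upregulated genes.
#'
#' @param peaks interval data.frame (typically the mutant-specific peaks).
#' @param annotation a [genome_annotation()] object.
#' @param up_genes character vector of upregulated gene ids.
#' @param promoter_up,promoter_down promoter window extent (bp).
#' @return list(n_promoter_genes, n_also_up, promoter_genes, up_overlap).
#' @export
promoter_expression_crosstab <- function(peaks, annotation, up_genes,
                                         promoter_up = 1000,
                                         promoter_down = 1000) {
  prom <- promoter_windows(annotation, promoter_up, promoter_down)
  genes <- character()
  if (nrow(peaks) && nrow(prom)) {
    ov <- GenomicRanges::findOverlaps(as_granges(peaks), as_granges(prom))
    genes <- sort(unique(prom$gene_id[S4Vectors::subjectHits(ov)]))
  }
  also_up <- intersect(genes, up_genes)
  list(n_promoter_genes = length(genes), n_also_up = length(also_up),
       promoter_genes = genes, up_overlap = also_up)
}
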