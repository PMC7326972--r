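# Integration of RNA-seq and PRO-seq differential results: fold-change
# correlation, quadrant classification of joint differential status,
# intersection with locus-wide FLAG-enriched genes, and hypergeometric
# over-representation of user-supplied gene sets.

#' Pearson correlation of paired fold changes
#'
#' Sample Pearson r with a two-sided p-value from the t transform with
#' n - 2 degrees of freedom (via [stats::cor.test()]).
#'
#' @param x,y paired numeric vectors (n >= 3, both non-constant).
#' @return list(r, p, n).
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Quadrant classification of joint RNA-seq / PRO-seq differential status
#'
#' Genes are classified over the shared universe (intersection of the two
#' tables' genes) by each table's `call` field: both_up = up in both,
#' rna_only_up = up in RNA and ns in PRO, pro_only_up = ns in RNA and up in
#' PRO, symmetrically for down, discordant buckets for opposite calls, and
#' neither for ns in both. The sets are pairwise disjoint and partition the
#' universe. Also reports the Pearson correlation of the shared log2 fold
#' changes.
#'
#' @param rna,pro differential result data.frames (gene_id, log2fc, call).
#' @return A `ConcordanceResult` list: pearson_r, p_r, n_shared,
#'   dropped_genes, and the quadrant sets.
#' @export
quadrant_classify <- function(rna, pro) {
  shared <- intersect(rna$gene_id, pro$gene_id)
  dropped <- union(setdiff(rna$gene_id, shared), setdiff(pro$gene_id, shared))
  r_ <- rna[match(shared, rna$gene_id), ]
  p_ <- pro[match(shared, pro$gene_id), ]
  cr <- pearson_correlation(r_$log2fc, p_$log2fc)
  bucket <- function(rc, pc) sort(shared[r_$call == rc & p_$call == pc])
  structure(list(
    pearson_r = cr$r, p_r = cr$p, n_shared = length(shared),
    dropped_genes = sort(dropped),
    both_up = bucket("up", "up"),
    both_down = bucket("down", "down"),
    rna_only_up = bucket("up", "ns"),
    rna_only_down = bucket("down", "ns"),
    pro_only_up = bucket("ns", "up"),
    pro_only_down = bucket("ns", "down"),
    discordant_up_down = bucket("up", "down"),
    discordant_down_up = bucket("down", "up"),
    neither = bucket("ns", "ns")), class = "ConcordanceResult")
}

#' @export
print.ConcordanceResult <- function(x, ...) {
  cat(sprintf("RNA-seq / PRO-seq concordance over %d shared genes\n",
              x$n_shared))
  cat(sprintf("Pearson r = %.3f (p = %.3g)\n", x$pearson_r, x$p_r))
  sizes <- vapply(x[c("both_up", "both_down", "rna_only_up", "rna_only_down",
                      "pro_only_up", "pro_only_down", "discordant_up_down",
                      "discordant_down_up", "neither")], length, 0L)
  print(sizes)
  invisible(x)
}

#' Intersect concordantly upregulated genes with FLAG-enriched genes
#'
#' @param both_up character vector of concordantly upregulated gene ids.
#' @param flag_enriched character vector of locus-wide FLAG-enriched gene
#'   ids.
#' @param rna,pro optional differential tables used to annotate the
#'   intersection with per-gene fold changes.
#' @param locus_table optional locus-score table from [locus_scores()].
#' @return list(genes, table) where table has one row per intersected gene.
#' @export
intersect_with_flag <- function(both_up, flag_enriched, rna = NULL,
                                pro = NULL, locus_table = NULL) {
  genes <- sort(intersect(both_up, flag_enriched))
  tab <- data.frame(gene_id = genes)
  if (!is.null(rna))
    tab$log2fc_rna <- rna$log2fc[match(genes, rna$gene_id)]
  if (!is.null(pro))
    tab$log2fc_pro <- pro$log2fc[match(genes, pro$gene_id)]
  if (!is.null(locus_table))
    tab$locus_score <- locus_table$score[match(genes, locus_table$gene_id)]
  list(genes = genes, table = tab)
}

#' Hypergeometric over-representation of gene sets
#'
#' For each gene set, the upper-tail hypergeometric probability of drawing
#' at least the observed overlap when sampling |hit_genes| genes from the
#' universe without replacement; BH adjustment across sets.
#'
#' @param hit_genes character vector (subset of `universe`).
#' @param gene_sets named list of character vectors (each a subset of
#'   `universe`).
#' @param universe character vector of all testable gene ids.
#' @return data.frame set, set_size, n_hits, overlap, p, q.
#' @export
hypergeometric_overrepresentation <- function(hit_genes, gene_sets,
                                              universe) {
  if (!length(universe)) stop("empty universe")
  if (!is.list(gene_sets)) gene_sets <- list(gene_set = gene_sets)
  hit_genes <- intersect(hit_genes, universe)
  rows <- lapply(names(gene_sets), function(nm) {
    gs <- intersect(gene_sets[[nm]], universe)
    ov <- length(intersect(hit_genes, gs))
    p <- stats::phyper(ov - 1, length(gs), length(universe) - length(gs),
                       length(hit_genes), lower.tail = FALSE)
    data.frame(set = nm, set_size = length(gs),
               n_hits = length(hit_genes), overlap = ov, p = p)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out
}
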