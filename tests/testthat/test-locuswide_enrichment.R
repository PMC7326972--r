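cs1 <- c(chr1 = 2000)

# two WT tracks at baseline and two MUT tracks with an additive offset field
offset_tracks <- function(base, offs) {
  list(
    make_ratio_track(list(chr1 = base), 100, cs1, "w1", "WT"),
    make_ratio_track(list(chr1 = base), 100, cs1, "w2", "WT"),
    make_ratio_track(list(chr1 = base + offs), 100, cs1, "m1", "MUT"),
    make_ratio_track(list(chr1 = base + offs), 100, cs1, "m2", "MUT"))
}

test_that("locus scores average the ratio field over the locus window", {
  ann <- genome_annotation(
    data.frame(chrom = "chr1", start = 1100, end = 1500, strand = "+",
               gene_id = "g1"), cs1)
  # constant offset c over the genome -> score = c exactly
  tr <- offset_tracks(rep(0.3, 20), rep(1.7, 20))
  ls <- locus_scores(ann, tr, upstream = 1000)
  expect_equal(ls$table$score, 1.7)
  expect_equal(ls$table$start, 100)
  expect_equal(ls$table$end, 1500)

  # two equal-width bins with delta 1 and 3 -> score 2
  ann2 <- genome_annotation(
    data.frame(chrom = "chr1", start = 1000, end = 1200, strand = "+",
               gene_id = "g1"), cs1)
  offs <- rep(0, 20); offs[11] <- 1; offs[12] <- 3
  ls2 <- locus_scores(ann2, offset_tracks(rep(0, 20), offs), upstream = 0)
  expect_equal(ls2$table$score, 2)

  # partial bin overlap is width-weighted: window [1000, 1150) covers
  # 100 bp of bin 11 (delta 1) and 50 bp of bin 12 (delta 3)
  ann3 <- genome_annotation(
    data.frame(chrom = "chr1", start = 1000, end = 1150, strand = "+",
               gene_id = "g1"), cs1)
  ls3 <- locus_scores(ann3, offset_tracks(rep(0, 20), offs), upstream = 0)
  expect_equal(ls3$table$score, (100 * 1 + 50 * 3) / 150)
})

test_that("mirror-image genomes give identical locus scores", {
  L <- 2000
  set.seed(17)
  base <- rnorm(20)
  offs <- c(rep(0, 8), rep(2, 6), rep(0, 6))
  fwd_ann <- genome_annotation(
    data.frame(chrom = "chr1", start = 900, end = 1400, strand = "+",
               gene_id = "g"), cs1)
  # reflect gene and fields about the chromosome midpoint
  rev_ann <- genome_annotation(
    data.frame(chrom = "chr1", start = L - 1400, end = L - 900,
               strand = "-", gene_id = "g"), cs1)
  fwd <- locus_scores(fwd_ann, offset_tracks(base, offs), upstream = 100)
  rev_ <- locus_scores(rev_ann, offset_tracks(rev(base), rev(offs)),
                       upstream = 100)
  expect_equal(rev_$table$score, fwd$table$score)
})

test_that("ranking is descending with documented lexicographic ties", {
  tab <- data.frame(gene_id = c("gb", "ga", "gc"), score = c(2, 5, -1))
  expect_equal(rank_by_enrichment(tab), c("ga", "gb", "gc"))
  ties <- data.frame(gene_id = c("gc", "ga", "gb"), score = c(1, 1, 1))
  expect_equal(rank_by_enrichment(ties), c("ga", "gb", "gc"))
  shuffled <- tab[c(3, 1, 2), ]
  expect_equal(rank_by_enrichment(shuffled), rank_by_enrichment(tab))
})

test_that("running sum walks match hand-computed cases", {
  ids <- paste0("g", 1:5)
  sc <- c(5, 4, 3, 2, 1)
  # singleton top-ranked set, w = 0 -> ES = 1 at rank 1
  top <- gsea_running_sum(ids, sc, "g1", weight = 0)
  expect_equal(top$es, 1)
  expect_equal(top$es_rank, 1)
  # singleton bottom set of N = 5, w = 0: walk -0.25 ... -1.0 then back
  bot <- gsea_running_sum(ids, sc, "g5", weight = 0)
  expect_equal(bot$running_sum, c(-0.25, -0.5, -0.75, -1, 0))
  expect_equal(bot$es, -1)
  # w = 0 walks always terminate at zero
  set.seed(18)
  for (i in 1:20) {
    N <- sample(5:30, 1)
    ids <- sprintf("x%02d", 1:N)
    set <- sample(ids, sample(1:(N - 1), 1))
    rs <- gsea_running_sum(ids, rnorm(N), set, weight = 0)$running_sum
    expect_equal(rs[N], 0)
  }
  ids5 <- paste0("g", 1:5)
  expect_error(gsea_running_sum(ids5, sc, character()), "no ranked gene")
  expect_error(gsea_running_sum(ids5, sc, ids5), "whole ranked universe")
  expect_error(gsea_running_sum(ids5, sc, c("g1", "zz")), "absent")
})

test_that("ES equals an independent brute-force walk on random instances", {
  set.seed(19)
  for (i in 1:100) {
    N <- sample(8:50, 1)
    ids <- sprintf("x%02d", 1:N)
    sc <- sort(rnorm(N), decreasing = TRUE)
    set <- sample(ids, sample(1:(N - 1), 1))
    w <- sample(c(0, 1), 1)
    got <- gsea_running_sum(ids, sc, set, weight = w)
    want <- bf_gsea(ids, sc, set, w)
    expect_equal(got$running_sum, want$rs, tolerance = 1e-12)
    expect_equal(abs(got$es), abs(want$es), tolerance = 1e-12)
    tied <- sum(abs(abs(want$rs) - abs(want$es)) < 1e-9) > 1
    if (!tied) expect_equal(got$es, want$es, tolerance = 1e-12)
    # the O(set)-sized scorer agrees with the full walk
    expect_equal(abs(oncohist:::.es_fast(which(ids %in% set),
                                         abs(sc)^w, N)),
                 abs(want$es), tolerance = 1e-12)
  }
})

test_that("ES agrees with the fgsea reference implementation", {
  set.seed(20)
  for (i in 1:20) {
    N <- sample(10:50, 1)
    ids <- sprintf("x%02d", 1:N)
    sc <- sort(rnorm(N), decreasing = TRUE)
    set <- sample(ids, sample(2:6, 1))
    expect_equal(gsea_running_sum(ids, sc, set, weight = 1)$es,
                 fgsea::calcGseaStat(stats::setNames(sc, ids),
                                     which(ids %in% set), gseaParam = 1),
                 tolerance = 1e-12)
  }
})

test_that("permutation p is deterministic, bounded and extreme-capable", {
  N <- 60
  ids <- sprintf("x%02d", 1:N)
  sc <- c(100, 99, 98, sort(abs(rnorm(N - 3, 0, 0.01)),
                            decreasing = TRUE))
  set <- ids[1:3]  # carries nearly all the weight: ES ~ 1
  r1 <- permutation_p(ids, sc, set, weight = 1, n_perm = 99, seed = 2)
  r2 <- permutation_p(ids, sc, set, weight = 1, n_perm = 99, seed = 2)
  expect_identical(r1$p_perm, r2$p_perm)
  expect_equal(r1$p_perm, 1 / 100)  # exceeds every permuted ES
  expect_gte(r1$p_perm, 1 / (r1$n_perm + 1))
  expect_error(permutation_p(ids, sc, set, n_perm = 0), "n_perm")
})

test_that("locus-wide enriched set: null empty, monotone in alpha", {
  set.seed(22)
  base <- rnorm(20, 0, 0.2)
  g <- data.frame(chrom = "chr1", start = c(200, 1100),
                  end = c(700, 1600), strand = "+",
                  gene_id = c("g1", "g2"))
  ann <- genome_annotation(g, cs1)
  # identical groups -> empty set
  same <- list(
    make_ratio_track(list(chr1 = base), 100, cs1, "w1", "WT"),
    make_ratio_track(list(chr1 = base + 0.01), 100, cs1, "w2", "WT"),
    make_ratio_track(list(chr1 = base), 100, cs1, "m1", "MUT"),
    make_ratio_track(list(chr1 = base + 0.01), 100, cs1, "m2", "MUT"))
  ls0 <- locus_scores(ann, same, upstream = 100)
  expect_length(locuswide_enriched_genes(ls0)$genes, 0)

  # planted offset at g2's window only
  offs <- c(rep(0, 10), rep(3, 10))
  ls1 <- locus_scores(ann, offset_tracks(base, offs), upstream = 100)
  sel <- locuswide_enriched_genes(ls1, alpha = 0.05)
  expect_equal(sel$genes, "g2")
  # monotone: enlarging alpha never shrinks the set
  prev <- character()
  for (a in c(1e-6, 1e-3, 0.05, 0.5, 1)) {
    cur <- locuswide_enriched_genes(ls1, alpha = a)$genes
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})
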