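make_cm <- function(m, groups = NULL) {
  if (is.null(groups))
    groups <- stats::setNames(ifelse(grepl("^WT", colnames(m)), "WT", "MUT"),
                              colnames(m))
  count_matrix(m, groups)
}

test_that("size factors follow the median-of-ratios definition", {
  # identical columns -> all factors 1
  m <- matrix(rep(c(5L, 9L, 2L), 3), 3, 3,
              dimnames = list(paste0("g", 1:3),
                              c("WT1", "WT2", "MUT1")))
  expect_equal(unname(size_factors(make_cm(m))), rep(1, 3))

  # hand case: [[10,20],[30,60]] -> (1/sqrt(2), sqrt(2))
  m2 <- matrix(c(10L, 30L, 20L, 60L), 2, 2,
               dimnames = list(c("g1", "g2"), c("WT1", "MUT1")))
  expect_equal(unname(size_factors(make_cm(m2))),
               c(0.7071, 1.4142), tolerance = 1e-4)

  # single sample: geometric mean of one -> factor 1
  m3 <- matrix(c(4L, 7L), 2, 1, dimnames = list(c("g1", "g2"), "WT1"))
  expect_equal(unname(size_factors(make_cm(m3, c(WT1 = "WT")))), 1)

  # no gene positive everywhere
  m4 <- matrix(c(0L, 3L, 5L, 0L), 2, 2,
               dimnames = list(c("g1", "g2"), c("WT1", "MUT1")))
  expect_error(size_factors(make_cm(m4)), "positive")

  # doubling one library doubles its factor relative to the rest
  m5 <- matrix(rpois(40, 50) + 1L, 10, 4,
               dimnames = list(paste0("g", 1:10),
                               c("WT1", "WT2", "MUT1", "MUT2")))
  m5b <- m5; m5b[, 3] <- m5b[, 3] * 2L
  f <- size_factors(make_cm(m5b))
  f0 <- size_factors(make_cm(m5))
  expect_equal(unname(f[3] / f0[3]), 2 * unname(f[1] / f0[1]),
               tolerance = 1e-12)
})

test_that("size factors agree with the DESeq2 reference implementation", {
  set.seed(21)
  m <- matrix(rpois(400, 60) + 1L, 100, 4,
              dimnames = list(sprintf("g%03d", 1:100),
                              c("WT1", "WT2", "MUT1", "MUT2")))
  expect_equal(unname(size_factors(make_cm(m))),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-12)
})

test_that("moment dispersion matches the formula and flags degenerate genes", {
  m <- matrix(c(85L, 115L, 90L, 110L,   # hand-checkable gene
                0L, 0L, 0L, 0L),        # all-zero gene
              2, 4, byrow = TRUE,
              dimnames = list(c("g1", "g2"),
                              c("WT1", "WT2", "MUT1", "MUT2")))
  cm <- make_cm(m)
  f <- stats::setNames(rep(1, 4), colnames(m))
  d <- estimate_dispersion(cm, f, pool = "none")
  # pooled within-group var = (450 + 200) / 2 = 325, mean = 100
  expect_equal(unname(d$dispersion["g1"]), (325 - 100) / 100^2)
  expect_equal(unname(d$dispersion["g2"]), 1e-8)
  expect_equal(unname(d$flagged), c(FALSE, TRUE))

  # Poisson-like gene (var <= mean) floors at the minimum
  mp <- matrix(c(99L, 101L, 99L, 101L), 1, 4,
               dimnames = list("g1", colnames(m)))
  dp <- estimate_dispersion(make_cm(mp), f, pool = "none")
  expect_equal(unname(dp$dispersion), 1e-8)
})

test_that("the NB Wald test is null-centered and antisymmetric", {
  m <- matrix(c(10L, 20L, 10L, 20L), 2, 2,
              dimnames = list(c("g1", "g2"), c("WT1", "MUT1")))
  grp <- c(WT1 = "WT", MUT1 = "MUT")
  f <- stats::setNames(rep(1, 2), colnames(m))
  disp <- stats::setNames(rep(0.05, 2), rownames(m))
  r <- nb_wald_test(count_matrix(m, grp), f, disp)
  expect_equal(r$log2fc, c(0, 0))
  expect_equal(r$p, c(1, 1))

  set.seed(8)
  m2 <- matrix(rpois(80, 60), 20, 4,
               dimnames = list(sprintf("g%02d", 1:20),
                               c("WT1", "WT2", "MUT1", "MUT2")))
  grp2 <- stats::setNames(c("WT", "WT", "MUT", "MUT"), colnames(m2))
  swap <- stats::setNames(c("MUT", "MUT", "WT", "WT"), colnames(m2))
  f2 <- size_factors(count_matrix(m2, grp2))
  d2 <- estimate_dispersion(count_matrix(m2, grp2), f2)$dispersion
  a <- nb_wald_test(count_matrix(m2, grp2), f2, d2)
  b <- nb_wald_test(count_matrix(m2, swap), f2, d2)
  expect_equal(b$log2fc, -a$log2fc)
  expect_equal(b$p, a$p)
})

test_that("BH adjustment equals the textbook step-up rule", {
  expect_equal(bh_adjust(0.02), 0.02)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(9)
  for (i in 1:50) {
    m <- sample(1:6, 1)
    p <- round(stats::runif(m), 3)
    q <- bh_adjust(p)
    expect_true(all(q >= p - 1e-12))
    expect_true(all(q <= 1))
    # q is non-decreasing in sorted p
    expect_true(!is.unsorted(q[order(p)]))
  }
})

test_that("BH rejections coincide with the step-up oracle exactly", {
  set.seed(10)
  for (i in 1:50) {
    p <- stats::runif(sample(2:8, 1))
    for (alpha in c(0.05, 0.25)) {
      expect_identical(bh_adjust(p) <= alpha, bf_bh_reject(p, alpha))
    }
  }
})

test_that("differential calls partition by q and fold-change thresholds", {
  res <- data.frame(gene_id = c("a", "b", "c", "d"),
                    log2fc = c(1.5, 0.5, -2, -1.2),
                    q = c(0.04, 0.04, 0.2, 0.01))
  out <- call_differential(res, alpha = 0.05, min_abs_log2fc = 1)
  expect_equal(out$call, c("up", "ns", "ns", "down"))
})

test_that("planted effects are recovered with high sensitivity", {
  cfg <- sim_config(n_chromosomes = 2, chromosome_length = 3e6,
                    n_genes = 500, frac_up = 0.1, frac_down = 0.1,
                    effect_log2fc = 2, nb_dispersion = 0.05, seed = 12)
  ann <- generate_genome(cfg)
  truth <- plant_truth(ann, cfg)
  pro <- simulate_counts(ann, truth, cfg, "pro")  # 2 vs 2, no repeats
  res <- differential_analysis(pro)
  up <- res$gene_id[res$call == "up"]
  down <- res$gene_id[res$call == "down"]
  expect_gte(mean(truth$up_genes %in% up), 0.9)
  expect_gte(mean(truth$down_genes %in% down), 0.9)
  # and the false calls stay controlled
  null_genes <- setdiff(res$gene_id, c(truth$up_genes, truth$down_genes))
  expect_lte(mean(null_genes %in% c(up, down)), 0.05)
})
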