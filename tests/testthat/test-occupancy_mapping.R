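cs2 <- c(chr1 = 1000, chr2 = 500)

test_that("internal-control normalization: identity, hand value, depth", {
  # flag = h2a everywhere at equal depth -> r = 0 in every bin
  fl <- flat_track(8, 100, cs2, "s", "flag")
  h2 <- flat_track(8, 100, cs2, "s", "h2a")
  rt <- normalize_internal_control(fl, h2)
  expect_equal(unique(unlist(rt$r)), 0)

  # hand case: one bin 30 vs 10, equal library totals, pseudocount of one
  # raw count (pc in CPM units = 1e6 / total) -> r = log2(31 / 11)
  fv <- list(chr1 = c(30, rep(2, 9)), chr2 = rep(2, 5))
  hv <- list(chr1 = c(10, rep(2, 9)), chr2 = rep(6, 5))
  stopifnot(sum(unlist(fv)) == sum(unlist(hv)))
  total <- sum(unlist(fv))
  tr <- normalize_internal_control(
    binned_track(fv, 100, cs2, "s", "flag"),
    binned_track(hv, 100, cs2, "s", "h2a"),
    pc = 1e6 / total)
  expect_equal(tr$r$chr1[1], log2(31 / 11), tolerance = 1e-12)
  expect_equal(tr$r$chr1[1], 1.4948, tolerance = 1e-4)

  # multiplying a sample's FLAG and H2A by a common constant leaves r
  # unchanged exactly
  fv3 <- lapply(fv, `*`, 7); hv3 <- lapply(hv, `*`, 7)
  tr3 <- normalize_internal_control(
    binned_track(fv3, 100, cs2, "s", "flag"),
    binned_track(hv3, 100, cs2, "s", "h2a"),
    pc = 1e6 / total)
  expect_equal(tr3$r, tr$r)

  expect_error(normalize_internal_control(
    flat_track(1, 100, cs2, "s"), flat_track(1, 50, cs2, "s", "h2a")),
    "bin grids")
})

test_that("differential windows: null, antisymmetry and planted signal", {
  set.seed(13)
  mk <- function(id, grp, bump = NULL) {
    v <- list(chr1 = rpois(10, 20) + 1, chr2 = rpois(5, 20) + 1)
    if (!is.null(bump)) v$chr1[bump] <- v$chr1[bump] * 8
    make_ratio_track(lapply(v, log2), 100, cs2, id, grp)
  }
  wt <- list(mk("w1", "WT"), mk("w2", "WT"))
  # identical groups -> delta 0 everywhere, nothing significant
  mut_same <- list(
    make_ratio_track(wt[[1]]$r, 100, cs2, "m1", "MUT"),
    make_ratio_track(wt[[2]]$r, 100, cs2, "m2", "MUT"))
  win0 <- differential_windows(mut_same, wt)
  expect_equal(win0$delta, rep(0, 15))
  expect_false(any(win0$q < 0.05))

  mut <- list(mk("m1", "MUT", 3:5), mk("m2", "MUT", 3:5))
  win <- differential_windows(mut, wt)
  swapped <- differential_windows(wt, mut)
  expect_equal(swapped$delta, -win$delta)
  expect_equal(swapped$p, win$p)
  expect_error(differential_windows(mut[1], wt), ">= 2")
})

test_that("a planted enriched region reaches per-bin significance", {
  s <- small_sim()
  rt <- lapply(names(s$tracks$flag), function(cl)
    normalize_internal_control(s$tracks$flag[[cl]], s$tracks$h2a[[cl]],
                               group = s$tracks$groups[[cl]]))
  names(rt) <- names(s$tracks$flag)
  win <- differential_windows(rt[c("MUT1", "MUT2")], rt[c("WT1", "WT2")])
  pk <- s$truth$planted_peaks
  inside <- rep(FALSE, nrow(win))
  for (i in seq_len(nrow(pk)))
    inside <- inside | (win$chrom == pk$chrom[i] &
                          win$start >= pk$start[i] & win$end <= pk$end[i])
  expect_gte(mean(win$q[inside] < 0.05), 0.95)
  # and the genome-wide background stays quiet
  expect_lte(mean(win$q[!inside] < 0.05), 0.01)
})

test_that("peak assembly follows the gap and minimum-run rules", {
  mk_win <- function(sig, bs = 100) {
    n <- length(sig)
    data.frame(chrom = "chr1", start = (seq_len(n) - 1) * bs,
               end = seq_len(n) * bs,
               delta = ifelse(sig, 2, 0),
               p = ifelse(sig, 1e-6, 0.9),
               q = ifelse(sig, 1e-4, 0.95))
  }
  # two adjacent significant bins, max_gap = 0 -> one peak [0, 200)
  p1 <- merge_windows(mk_win(c(TRUE, TRUE, FALSE)), max_gap = 0,
                      min_bins = 1)
  expect_equal(nrow(p1), 1)
  expect_equal(c(p1$start, p1$end), c(0, 200))

  # significant bins separated by 3 non-significant bins, max_gap = 1 ->
  # two peaks (min_bins = 1 so singletons survive)
  p2 <- merge_windows(mk_win(c(TRUE, FALSE, FALSE, FALSE, TRUE)),
                      max_gap = 1, min_bins = 1)
  expect_equal(nrow(p2), 2)

  # a gap of exactly max_gap bins is bridged
  p3 <- merge_windows(mk_win(c(TRUE, FALSE, TRUE)), max_gap = 1,
                      min_bins = 2)
  expect_equal(nrow(p3), 1)
  expect_equal(c(p3$start, p3$end), c(0, 300))
  expect_equal(p3$n_bins, 2)

  # runs with fewer than min_bins significant members are dropped
  p4 <- merge_windows(mk_win(c(TRUE, FALSE, FALSE, TRUE, TRUE)),
                      max_gap = 0, min_bins = 2)
  expect_equal(nrow(p4), 1)
  expect_equal(c(p4$start, p4$end), c(300, 500))
})

test_that("peak assembly equals a brute-force run-length scan", {
  set.seed(14)
  for (i in 1:30) {
    n <- 100
    sig <- stats::runif(n) < 0.2
    max_gap <- sample(0:2, 1)
    min_bins <- sample(1:3, 1)
    win <- data.frame(chrom = "chr1", start = (seq_len(n) - 1) * 50,
                      end = seq_len(n) * 50, delta = stats::rnorm(n),
                      p = ifelse(sig, 1e-5, 0.5),
                      q = ifelse(sig, 0.01, 0.6))
    got <- merge_windows(win, alpha = 0.05, max_gap = max_gap,
                         min_bins = min_bins)
    want <- bf_merge_mask(sig, max_gap, min_bins)
    expect_equal(nrow(got), length(want))
    if (length(want)) {
      expect_equal(got$start, vapply(want, function(r) (r[1] - 1) * 50, 0))
      expect_equal(got$end, vapply(want, function(r) r[2] * 50, 0))
    }
  }
})

test_that("mutant-specific filtering respects direction and threshold", {
  pk <- data.frame(chrom = "chr1", start = c(0, 100, 200),
                   end = c(50, 150, 250), name = c("a", "b", "c"),
                   n_bins = 2, delta = c(2, -1, 1),
                   p = c(1e-5, 1e-5, 0.2), q = c(1e-4, 1e-4, 0.3),
                   score = 1)
  expect_equal(g53d_specific_peaks(pk)$name, "a")
  neg <- pk; neg$delta <- -abs(neg$delta)
  expect_equal(nrow(g53d_specific_peaks(neg)), 0)
  expect_equal(g53d_specific_peaks(pk, alpha = 1)$name, c("a", "c"))
  expect_equal(g53d_specific_peaks(pk, alpha = 1, direction = "-")$name,
               "b")
})
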