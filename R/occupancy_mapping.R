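# CUT&RUN differential occupancy: FLAG coverage normalized against the H2A
# internal-control track, moderated per-bin differential testing between
# mutant and wild-type clones, and assembly of significant bins into
# mutant-specific peaks.

#' Normalize FLAG coverage against the H2A internal control
#'
#' Both tracks are depth-normalized to counts per million of their own
#' library total, then the per-bin log2 ratio
#' r = log2((cpm_flag + pc) / (cpm_h2a + pc)) is taken. Because the
#' pseudocount lives in depth-normalized (CPM) units, multiplying a
#' sample's FLAG and H2A tracks by any common constant leaves r unchanged
#' exactly; equal signal at equal depth gives r = 0.
#'
#' @param flag,h2a [binned_track()] objects on the same bin grid and
#'   chromosome set.
#' @param pc pseudocount in CPM units (default 0.5).
#' @param group genotype label stored on the result ("WT" or "MUT").
#' @return A `NormalizedRatioTrack`: list(r = per-chromosome log2-ratio
#'   vectors, coverage = per-chromosome raw flag+h2a counts, bin_size,
#'   chrom_sizes, sample_id, group).
#' @export
normalize_internal_control <- function(flag, h2a, pc = 0.5, group = NA) {
  if (!identical(flag$bin_size, h2a$bin_size) ||
      !identical(names(flag$values), names(h2a$values)) ||
      !identical(lengths(flag$values), lengths(h2a$values)))
    stop("FLAG and H2A tracks are on different bin grids")
  total_f <- sum(unlist(flag$values, use.names = FALSE))
  total_h <- sum(unlist(h2a$values, use.names = FALSE))
  if (total_f <= 0 || total_h <= 0)
    stop("cannot normalize an all-zero track")
  r <- lapply(names(flag$values), function(chr) {
    cf <- flag$values[[chr]] * 1e6 / total_f
    ch <- h2a$values[[chr]] * 1e6 / total_h
    log2((cf + pc) / (ch + pc))
  })
  names(r) <- names(flag$values)
  coverage <- lapply(names(flag$values), function(chr)
    flag$values[[chr]] + h2a$values[[chr]])
  names(coverage) <- names(flag$values)
  structure(list(r = r, coverage = coverage, bin_size = flag$bin_size,
                 chrom_sizes = flag$chrom_sizes,
                 sample_id = flag$sample_id, group = group),
            class = "NormalizedRatioTrack")
}

#' @export
print.NormalizedRatioTrack <- function(x, ...) {
  cat(sprintf("NormalizedRatioTrack '%s' (%s): %d bins, bin_size=%d\n",
              x$sample_id, x$group, sum(lengths(x$r)),
              as.integer(x$bin_size)))
  invisible(x)
}

# stack per-sample ratio tracks into one matrix per chromosome
.stack_tracks <- function(tracks) {
  ref <- tracks[[1]]
  for (t in tracks[-1])
    if (!identical(lengths(t$r), lengths(ref$r)))
      stop("ratio tracks are on different bin grids")
  lapply(names(ref$r), function(chr)
    do.call(cbind, lapply(tracks, function(t) t$r[[chr]])))
}

#' Per-bin differential occupancy between mutant and wild-type tracks
#'
#' For every bin, delta = mean_MUT(r) - mean_WT(r). Because a per-bin
#' variance over 2 + 2 samples is hopeless, the pooled within-group
#' variance is averaged across all bins falling in the same decile of mean
#' raw coverage, and the z statistic
#' delta / sqrt(s2_decile * (1/n_MUT + 1/n_WT)) is referred to the normal
#' distribution; q is BH across bins.
#'
#' @param mut,wt lists of `NormalizedRatioTrack` (>= 2 each).
#' @param n_deciles number of coverage strata for variance pooling.
#' @return data.frame chrom, start, end, delta, p, q (one row per bin).
#' @export
differential_windows <- function(mut, wt, n_deciles = 10) {
  if (length(mut) < 2 || length(wt) < 2)
    stop("need >= 2 tracks per group")
  all_m <- .stack_tracks(c(mut, wt))  # also checks grid compatibility
  M <- lapply(all_m, function(m) m[, seq_along(mut), drop = FALSE])
  W <- lapply(all_m, function(m) m[, length(mut) + seq_along(wt),
                                   drop = FALSE])
  ref <- mut[[1]]
  chroms <- names(ref$r)
  nM <- length(mut); nW <- length(wt)
  mM <- unlist(lapply(M, rowMeans), use.names = FALSE)
  mW <- unlist(lapply(W, rowMeans), use.names = FALSE)
  ssM <- unlist(lapply(M, function(m) rowSums((m - rowMeans(m))^2)),
                use.names = FALSE)
  ssW <- unlist(lapply(W, function(m) rowSums((m - rowMeans(m))^2)),
                use.names = FALSE)
  s2 <- (ssM + ssW) / (nM + nW - 2)
  cov_all <- rowMeans(do.call(
    cbind, lapply(c(mut, wt), function(t)
      unlist(t$coverage, use.names = FALSE))))
  dec <- cut(rank(cov_all, ties.method = "first"),
             min(n_deciles, length(cov_all)), labels = FALSE)
  s2p <- stats::ave(s2, dec, FUN = mean)
  delta <- mM - mW
  z <- delta / sqrt(pmax(s2p, 1e-300) * (1 / nM + 1 / nW))
  p <- 2 * stats::pnorm(-abs(z))
  bs <- ref$bin_size
  bins <- lapply(chroms, function(chr) {
    nb <- length(ref$r[[chr]])
    data.frame(chrom = chr, start = (seq_len(nb) - 1) * bs,
               end = pmin(seq_len(nb) * bs, ref$chrom_sizes[[chr]]))
  })
  out <- do.call(rbind, bins)
  out$delta <- delta
  out$p <- p
  out$q <- bh_adjust(p)
  rownames(out) <- NULL
  out
}

#' Merge significant bins into peaks
#'
#' Consecutive significant bins separated by gaps of at most `max_gap`
#' non-significant bins are merged into one peak spanning from the first to
#' the last significant bin; merged runs containing fewer than `min_bins`
#' significant bins are dropped. Per-peak delta is the width-weighted mean
#' over member (significant) bins, per-peak p is the Fisher combination of
#' member-bin p-values, and q is BH across peaks.
#'
#' @param windows data.frame from [differential_windows()].
#' @param alpha per-bin FDR threshold defining significance (default 0.05).
#' @param max_gap maximum gap in bins inside one peak (default 1).
#' @param min_bins minimum number of significant bins per peak (default 2).
#' @return PeakSet data.frame: chrom, start, end, name, n_bins, delta, p, q,
#'   score (-10 log10 q), sorted and non-overlapping.
#' @export
merge_windows <- function(windows, alpha = 0.05, max_gap = 1, min_bins = 2) {
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), name = character(),
                      n_bins = integer(), delta = numeric(), p = numeric(),
                      q = numeric(), score = numeric())
  sig <- windows[windows$q < alpha, , drop = FALSE]
  if (!nrow(sig)) return(empty)
  peaks <- lapply(split(sig, sig$chrom), function(s) {
    s <- s[order(s$start), , drop = FALSE]
    bs <- s$end - s$start
    # gap in bins between consecutive significant bins
    gap <- (s$start[-1] - s$end[-nrow(s)]) / stats::median(bs)
    grp <- cumsum(c(0, gap > max_gap))
    do.call(rbind, lapply(split(s, grp), function(run) {
      if (nrow(run) < min_bins) return(NULL)
      w <- run$end - run$start
      chi <- -2 * sum(log(pmax(run$p, 1e-300)))
      data.frame(chrom = run$chrom[1], start = min(run$start),
                 end = max(run$end), n_bins = nrow(run),
                 delta = sum(run$delta * w) / sum(w),
                 p = stats::pchisq(chi, df = 2 * nrow(run),
                                   lower.tail = FALSE))
    }))
  })
  out <- do.call(rbind, peaks)
  if (is.null(out) || !nrow(out)) return(empty)
  out <- sort_intervals(out)
  out$name <- sprintf("peak%04d", seq_len(nrow(out)))
  out$q <- bh_adjust(out$p)
  out$score <- -10 * log10(pmax(out$q, 1e-30))
  rownames(out) <- NULL
  out[, c("chrom", "start", "end", "name", "n_bins", "delta", "p", "q",
          "score")]
}

#' Retain mutant-specific peaks
#'
#' Mutant-specific ("G53D-specific") peaks are those with positive delta
#' (higher normalized FLAG in mutants) and q below `alpha`.
#'
#' @param peaks PeakSet data.frame from [merge_windows()].
#' @param alpha peak-level FDR threshold (default 0.05).
#' @param direction "+" keeps mutant-elevated peaks (default);
#'   "-" keeps mutant-depleted peaks.
#' @return Filtered, sorted PeakSet data.frame.
#' @export
g53d_specific_peaks <- function(peaks, alpha = 0.05, direction = "+") {
  keep <- if (direction == "+") peaks$delta > 0 else peaks$delta < 0
  out <- peaks[keep & peaks$q < alpha, , drop = FALSE]
  out <- sort_intervals(out)
  rownames(out) <- NULL
  out
}

#' Call mutant-specific occupancy peaks from raw tracks
#'
#' Convenience wrapper: normalizes every FLAG track against its matched H2A
#' track, runs [differential_windows()], [merge_windows()] and
#' [g53d_specific_peaks()].
#'
#' @param flag_tracks,h2a_tracks named lists of [binned_track()] per clone.
#' @param groups named WT/MUT vector over clone names.
#' @param pc CPM pseudocount (default 0.5).
#' @param alpha FDR threshold for bins and peaks (default 0.05).
#' @param max_gap,min_bins peak assembly parameters (defaults 1 and 2).
#' @return list(ratio_tracks, windows, peaks, specific).
#' @export
call_occupancy_peaks <- function(flag_tracks, h2a_tracks, groups, pc = 0.5,
                                 alpha = 0.05, max_gap = 1, min_bins = 2) {
  stopifnot(identical(names(flag_tracks), names(h2a_tracks)))
  rt <- lapply(names(flag_tracks), function(cl)
    normalize_internal_control(flag_tracks[[cl]], h2a_tracks[[cl]],
                               pc = pc, group = groups[[cl]]))
  names(rt) <- names(flag_tracks)
  win <- differential_windows(rt[groups[names(rt)] == "MUT"],
                              rt[groups[names(rt)] == "WT"])
  peaks <- merge_windows(win, alpha = alpha, max_gap = max_gap,
                         min_bins = min_bins)
  list(ratio_tracks = rt, windows = win,
       peaks = peaks, specific = g53d_specific_peaks(peaks, alpha = alpha))
}
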