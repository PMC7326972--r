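# Differential analysis of RNA-seq / PRO-seq count matrices:
# median-of-ratios normalization, moment dispersion estimation, and a
# negative-binomial Wald test on group means.

#' Median-of-ratios size factors
#'
#' factor_s = median over genes (positive in every sample) of
#' count_gs / geometric-mean_g. Identical columns get equal factors; a
#' single-sample matrix gets factor 1.
#'
#' @param cm a [count_matrix()] object.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(cm) {
  m <- cm$counts
  keep <- rowSums(m > 0) == ncol(m)
  if (!any(keep))
    stop("no gene has positive counts in all samples")
  lg <- log(m[keep, , drop = FALSE])
  geo <- rowMeans(lg)
  stats::setNames(exp(apply(lg - geo, 2, stats::median)), colnames(m))
}

#' Per-gene method-of-moments dispersion
#'
#' On size-factor-normalized counts, alpha_g =
#' max((var_g - mean_g) / mean_g^2, floor), with the variance pooled within
#' groups (sum of within-group squared deviations over n - K degrees of
#' freedom) and the mean taken over all samples. With `pool = "decile"`
#' (the default used by [differential_analysis()]) the raw moment estimate
#' is averaged within deciles of the mean before flooring: with only two
#' samples per group the per-gene estimate is far too noisy for a
#' calibrated Wald test, and pooling across genes of similar expression
#' stabilizes it the same way the occupancy module pools bin variances
#' within coverage deciles.
#'
#' @param cm a [count_matrix()] object (>= 2 samples per group).
#' @param factors size factors from [size_factors()].
#' @param floor lower bound for the dispersion (default 1e-8).
#' @param pool "decile" (mean-decile pooled, default) or "none" (per gene).
#' @return list(dispersion = named vector, flagged = logical vector marking
#'   all-zero genes whose dispersion is the floor by convention).
#' @export
estimate_dispersion <- function(cm, factors, floor = 1e-8,
                                pool = c("decile", "none")) {
  pool <- match.arg(pool)
  if (any(table(cm$groups) < 2))
    stop("need >= 2 samples per group to estimate dispersion")
  x <- sweep(cm$counts, 2, factors[cm$sample_ids], "/")
  mean_g <- rowMeans(x)
  groups <- unique(cm$groups)
  ss <- 0
  for (g in groups) {
    xg <- x[, cm$groups == g, drop = FALSE]
    ss <- ss + rowSums((xg - rowMeans(xg))^2)
  }
  var_g <- ss / (ncol(x) - length(groups))
  flagged <- mean_g == 0
  raw <- ifelse(flagged, floor, (var_g - mean_g) / pmax(mean_g, 1e-300)^2)
  if (pool == "decile" && sum(!flagged) >= 10) {
    ok <- !flagged
    dec <- cut(rank(mean_g[ok], ties.method = "first"), 10, labels = FALSE)
    raw[ok] <- stats::ave(raw[ok], dec, FUN = mean)
  }
  disp <- pmax(raw, floor)
  list(dispersion = stats::setNames(disp, cm$gene_ids), flagged = flagged)
}

#' Negative-binomial Wald test on group means
#'
#' log2 fold change is computed from pseudocounted normalized group means,
#' log2((mean_MUT + pc) / (mean_WT + pc)); its standard error comes from the
#' negative-binomial delta-method variance of the log mean difference,
#' se^2 = sum_k (m_k + alpha m_k^2) / (n_k (m_k + pc)^2 log(2)^2); the
#' two-sided p-value uses the normal reference. Swapping group labels flips
#' the sign of log2fc and leaves p unchanged.
#'
#' @param cm a [count_matrix()] object with both groups present.
#' @param factors size factors.
#' @param dispersions per-gene dispersion vector (e.g. from
#'   [estimate_dispersion()]).
#' @param pseudocount pseudocount on normalized group means (default 0.5).
#' @return data.frame gene_id, base_mean, log2fc, se, p.
#' @export
nb_wald_test <- function(cm, factors, dispersions, pseudocount = 0.5) {
  if (!all(c("WT", "MUT") %in% cm$groups))
    stop("both WT and MUT groups are required")
  x <- sweep(cm$counts, 2, factors[cm$sample_ids], "/")
  a <- unname(dispersions[cm$gene_ids])
  pc <- pseudocount
  mW <- rowMeans(x[, cm$groups == "WT", drop = FALSE])
  mM <- rowMeans(x[, cm$groups == "MUT", drop = FALSE])
  nW <- sum(cm$groups == "WT"); nM <- sum(cm$groups == "MUT")
  log2fc <- log2((mM + pc) / (mW + pc))
  se2 <- ((mW + a * mW^2) / (nW * (mW + pc)^2) +
            (mM + a * mM^2) / (nM * (mM + pc)^2)) / log(2)^2
  se <- sqrt(se2)
  z <- ifelse(se > 0, log2fc / se, 0)
  p <- ifelse(se > 0, 2 * stats::pnorm(-abs(z)), 1)
  data.frame(gene_id = cm$gene_ids, base_mean = rowMeans(x),
             log2fc = log2fc, se = se, p = p, row.names = NULL)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH via [stats::p.adjust()], after validating that the inputs are
#' probabilities.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order; q >= p elementwise.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call up/down/ns from a differential result
#'
#' call = "up" when q < alpha and log2fc >= min_abs_log2fc (and > 0),
#' "down" symmetrically, otherwise "ns".
#'
#' @param results data.frame with log2fc and q columns.
#' @param alpha FDR threshold (default 0.05).
#' @param min_abs_log2fc minimum absolute log2 fold change (default 1).
#' @return `results` with a `call` column added.
#' @export
call_differential <- function(results, alpha = 0.05, min_abs_log2fc = 1) {
  call <- rep("ns", nrow(results))
  sig <- results$q < alpha & abs(results$log2fc) >= min_abs_log2fc
  call[sig & results$log2fc > 0] <- "up"
  call[sig & results$log2fc < 0] <- "down"
  results$call <- call
  results
}

#' Full differential analysis of a count matrix
#'
#' Runs [size_factors()], [estimate_dispersion()], [nb_wald_test()],
#' [bh_adjust()] and [call_differential()] in sequence.
#'
#' @param cm a [count_matrix()] object.
#' @param alpha FDR threshold (default 0.05).
#' @param min_abs_log2fc minimum absolute log2 fold change (default 1).
#' @param dispersion_floor lower dispersion bound (default 1e-8).
#' @param pseudocount pseudocount on normalized means (default 0.5).
#' @param dispersion_pool "decile" or "none" (see [estimate_dispersion()]).
#' @return data.frame gene_id, base_mean, log2fc, se, p, q, call.
#' @export
differential_analysis <- function(cm, alpha = 0.05, min_abs_log2fc = 1,
                                  dispersion_floor = 1e-8, pseudocount = 0.5,
                                  dispersion_pool = "decile") {
  f <- size_factors(cm)
  d <- estimate_dispersion(cm, f, floor = dispersion_floor,
                           pool = dispersion_pool)
  res <- nb_wald_test(cm, f, d$dispersion, pseudocount = pseudocount)
  res$q <- bh_adjust(res$p)
  call_differential(res, alpha = alpha, min_abs_log2fc = min_abs_log2fc)
}
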