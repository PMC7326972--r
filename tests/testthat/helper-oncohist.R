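# Shared fixtures (built in code, memoized) and independent brute-force
# oracles used across test files.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# small simulation shared by several files: 200 genes on 2 x 1 Mb
small_config <- function(...) {
  args <- list(n_chromosomes = 2, chromosome_length = 1e6, n_genes = 200,
               gene_length_range = c(1000, 4000), min_gene_gap = 2500,
               seed = 11)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

small_sim <- function() memo("small_sim", {
  cfg <- small_config()
  ann <- generate_genome(cfg)
  truth <- plant_truth(ann, cfg)
  list(cfg = cfg, ann = ann, truth = truth,
       tracks = simulate_tracks(ann, truth, cfg))
})

# hand-built annotation on one 100 kb chromosome: 10 plus-strand genes of
# length 3 kb starting every 10 kb; with promoter_up = promoter_down = 1000
# the promoter windows cover exactly 20% of the genome
grid_annotation <- function() {
  starts <- seq(5000, 95000, by = 10000)
  genome_annotation(
    data.frame(chrom = "chr1", start = starts, end = starts + 3000,
               strand = "+", gene_id = sprintf("g%02d", seq_along(starts))),
    c(chr1 = 1e5))
}

# constant-valued ratio track without going through count normalization
make_ratio_track <- function(values, bin_size, chrom_sizes, sample_id,
                             group) {
  structure(list(r = values,
                 coverage = lapply(values, function(v) rep(1, length(v))),
                 bin_size = bin_size, chrom_sizes = chrom_sizes,
                 sample_id = sample_id, group = group),
            class = "NormalizedRatioTrack")
}

# uniform binned track with every bin equal to `value`
flat_track <- function(value, bin_size, chrom_sizes, sample_id = "s",
                       role = "flag") {
  vals <- lapply(chrom_sizes, function(L)
    rep(value, n_bins(L, bin_size)))
  names(vals) <- names(chrom_sizes)
  binned_track(vals, bin_size, chrom_sizes, sample_id, role)
}

# --- independent oracles -------------------------------------------------

# explicit step-by-step GSEA running-sum walk
bf_gsea <- function(ranked_ids, scores, gene_set, weight) {
  N <- length(ranked_ids)
  nh <- sum(ranked_ids %in% gene_set)
  denom <- sum(abs(scores[ranked_ids %in% gene_set])^weight)
  rs <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    cur <- if (ranked_ids[i] %in% gene_set)
      cur + abs(scores[i])^weight / denom
    else cur - 1 / (N - nh)
    rs[i] <- cur
  }
  best <- 1
  for (i in seq_len(N)) if (abs(rs[i]) > abs(rs[best])) best <- i
  list(es = rs[best], rs = rs)
}

# all-pairs interval overlap (0-based half-open)
bf_overlaps_any <- function(iv, others) {
  vapply(seq_len(nrow(iv)), function(i) {
    any(iv$chrom[i] == others$chrom &
          iv$start[i] < others$end & others$start < iv$end[i])
  }, TRUE)
}

# brute-force category assignment by explicit overlap sets with precedence
bf_category <- function(peaks, annotation, promoter_up = 1000,
                        promoter_down = 1000) {
  prom <- promoter_windows(annotation, promoter_up, promoter_down)
  body <- annotation$genes
  ifelse(bf_overlaps_any(peaks, prom), "promoter",
         ifelse(bf_overlaps_any(peaks, body), "gene_body", "intergenic"))
}

# textbook BH step-up rejection set at level alpha
bf_bh_reject <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  k <- 0
  for (i in seq_len(m)) if (p[o[i]] <= i / m * alpha) k <- i
  rej <- rep(FALSE, m)
  if (k > 0) rej[o[seq_len(k)]] <- TRUE
  rej
}

# run-length interpretation of a significance mask over consecutive bins:
# merge significant bins with gaps <= max_gap, drop runs with < min_bins
# significant members; returns list of c(first_sig_bin, last_sig_bin)
bf_merge_mask <- function(mask, max_gap, min_bins) {
  idx <- which(mask)
  if (!length(idx)) return(list())
  runs <- list()
  cur <- c(idx[1], idx[1])
  members <- 1
  for (i in idx[-1]) {
    if (i - cur[2] - 1 <= max_gap) {
      cur[2] <- i
      members <- members + 1
    } else {
      if (members >= min_bins) runs[[length(runs) + 1]] <- cur
      cur <- c(i, i)
      members <- 1
    }
  }
  if (members >= min_bins) runs[[length(runs) + 1]] <- cur
  runs
}

# per-planted-interval Jaccard against the union of overlapping called peaks
jaccard_vs_truth <- function(truth_iv, called) {
  vapply(seq_len(nrow(truth_iv)), function(i) {
    t1 <- truth_iv[i, ]
    ov <- called[called$chrom == t1$chrom & called$start < t1$end &
                   t1$start < called$end, , drop = FALSE]
    if (!nrow(ov)) return(0)
    inter <- sum(pmin(ov$end, t1$end) - pmax(ov$start, t1$start))
    uni <- max(c(t1$end, ov$end)) - min(c(t1$start, ov$start))
    inter / uni
  }, 0)
}
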