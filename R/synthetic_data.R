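# Synthetic fixture generator: toy genome, planted differential genes and
# planted locus-wide FLAG enrichment, emulating a 2 wild-type + 2 mutant
# clone design with RNA-seq in duplicate.

# run code under a fixed RNG state without disturbing the caller's stream
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

#' Simulation configuration
#'
#' Defaults describe the emulated study design: two wild-type and two mutant
#' clones, RNA-seq in duplicate, 2,000 genes on a 20 Mb toy genome, 5%
#' planted up- and down-regulated genes with a 2 log2-unit effect, and
#' locus-wide FLAG enrichment of 3 log2 units planted at 40% of the
#' up-regulated genes.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chromosome_length length of each chromosome (bases).
#' @param n_genes number of genes to place.
#' @param gene_length_range min/max gene length (bases).
#' @param min_gene_gap minimum intergenic distance enforced at placement
#'   (bases). The default (2500) exceeds the worst-case 2 kb of facing
#'   locus-window extensions, so no gene's locus window can overlap a
#'   neighbor's planted enrichment region and planted ground truth stays
#'   identifiable.
#' @param n_samples_per_group clones per genotype (default 2).
#' @param rna_repeats RNA-seq technical repeats per clone (default 2).
#' @param nb_mean_range min/max baseline expected count (sampled
#'   log-uniformly per gene).
#' @param nb_dispersion shared negative-binomial dispersion (> 0).
#' @param frac_up,frac_down fractions of genes planted up/down in mutants.
#' @param effect_log2fc planted expression effect (log2 units).
#' @param frac_flag_enriched_of_up fraction of planted up-genes that also
#'   receive locus-wide FLAG enrichment.
#' @param flag_enrichment_log2 planted track effect (log2 units).
#' @param bin_size coverage track bin width (bases).
#' @param flag_mean,h2a_mean baseline expected counts per bin for the FLAG
#'   and H2A tracks.
#' @param clone_sigma sd of the per-clone log-normal scaling factor.
#' @param depth_factors optional named per-sample depth multipliers
#'   (default all 1).
#' @param atac_halfwidth half-width of promoter ATAC peaks (bases).
#' @param n_atac_background number of background ATAC peaks.
#' @param upstream_bp locus-window upstream extent used for planting
#'   FLAG enrichment.
#' @param seed integer seed; every generator output is a pure function of
#'   (config, seed).
#' @return A validated `sim_config` object (list).
#' @export
sim_config <- function(n_chromosomes = 4,
                       chromosome_length = 5e6,
                       n_genes = 2000,
                       gene_length_range = c(2000, 8000),
                       min_gene_gap = 2500,
                       n_samples_per_group = 2,
                       rna_repeats = 2,
                       nb_mean_range = c(20, 200),
                       nb_dispersion = 0.05,
                       frac_up = 0.05,
                       frac_down = 0.05,
                       effect_log2fc = 2,
                       frac_flag_enriched_of_up = 0.4,
                       flag_enrichment_log2 = 3,
                       bin_size = 100,
                       flag_mean = 20,
                       h2a_mean = 20,
                       clone_sigma = 0.1,
                       depth_factors = NULL,
                       atac_halfwidth = 300,
                       n_atac_background = 200,
                       upstream_bp = 1000,
                       seed = 1) {
  cfg <- as.list(environment())
  stopifnot(n_chromosomes >= 1, chromosome_length >= 1, n_genes >= 0,
            length(gene_length_range) == 2,
            gene_length_range[1] >= 1,
            gene_length_range[1] <= gene_length_range[2],
            gene_length_range[2] < chromosome_length,
            min_gene_gap >= 0,
            n_samples_per_group >= 1, rna_repeats >= 1,
            length(nb_mean_range) == 2, all(nb_mean_range > 0),
            nb_dispersion > 0,
            frac_up >= 0, frac_up <= 1, frac_down >= 0, frac_down <= 1,
            frac_up + frac_down <= 1,
            frac_flag_enriched_of_up >= 0, frac_flag_enriched_of_up <= 1,
            bin_size >= 1, flag_mean > 0, h2a_mean > 0, clone_sigma >= 0,
            atac_halfwidth >= 1, n_atac_background >= 0, upstream_bp >= 0)
  structure(cfg, class = "sim_config")
}

#' @noRd
clone_ids <- function(config) {
  n <- config$n_samples_per_group
  c(paste0("WT", seq_len(n)), paste0("MUT", seq_len(n)))
}

#' @noRd
clone_groups <- function(config) {
  ids <- clone_ids(config)
  stats::setNames(ifelse(grepl("^WT", ids), "WT", "MUT"), ids)
}

#' Generate a toy genome annotation
#'
#' Places `n_genes` non-overlapping, strand-assigned genes uniformly at
#' random. Genes are distributed over chromosomes proportionally to
#' chromosome length; within a chromosome, positions are drawn by uniform
#' placement of the inter-gene gaps, so no rejection loop over gene pairs is
#' needed. Placement fails (after bounded retries of the chromosome
#' assignment) only when the genes cannot fit.
#'
#' @param config a [sim_config()] object.
#' @return A [genome_annotation()] object; deterministic for a fixed seed.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  chrom_sizes <- stats::setNames(rep(config$chromosome_length,
                                     config$n_chromosomes),
                                 paste0("chr", seq_len(config$n_chromosomes)))
  if (config$n_genes == 0)
    return(genome_annotation(
      data.frame(chrom = character(), start = numeric(), end = numeric(),
                 strand = character(), gene_id = character()),
      chrom_sizes))
  .with_seed(config$seed, {
    len <- sample(seq(config$gene_length_range[1],
                      config$gene_length_range[2]),
                  config$n_genes, replace = TRUE)
    assign_chr <- NULL
    for (try in seq_len(100)) {
      cand <- sample(names(chrom_sizes), config$n_genes, replace = TRUE,
                     prob = chrom_sizes / sum(chrom_sizes))
      fc <- factor(cand, levels = names(chrom_sizes))
      load <- tapply(len, fc, sum)
      load[is.na(load)] <- 0
      load <- load + pmax(table(fc) - 1, 0) * config$min_gene_gap
      if (all(load <= chrom_sizes)) { assign_chr <- cand; break }
    }
    if (is.null(assign_chr))
      stop("gene placement failed: requested genes do not fit ",
           "without overlap")
    rows <- lapply(names(chrom_sizes), function(chr) {
      l <- len[assign_chr == chr]
      k <- length(l)
      if (!k) return(NULL)
      free <- chrom_sizes[[chr]] - sum(l) - (k - 1) * config$min_gene_gap
      gaps <- floor(sort(stats::runif(k, 0, free + 1)))
      starts <- gaps + c(0, cumsum(l[-k] + config$min_gene_gap))
      data.frame(chrom = chr, start = starts, end = starts + l,
                 strand = sample(c("+", "-"), k, replace = TRUE))
    })
    genes <- do.call(rbind, rows)
    genes <- genes[order(genes$chrom, genes$start), ]
    genes$gene_id <- sprintf("g%05d", seq_len(nrow(genes)))
    genome_annotation(genes, chrom_sizes)
  })
}

#' Plant ground truth onto an annotation
#'
#' Samples disjoint up- and down-regulated gene sets and a subset of the
#' up-genes as locus-wide FLAG-enrichment targets; the planted peak
#' intervals are those targets' locus windows (TSS - upstream_bp to TES).
#'
#' @param annotation a [genome_annotation()] object.
#' @param config a [sim_config()] object.
#' @return A `GroundTruth` object: list(up_genes, down_genes, flag_genes,
#'   planted_peaks).
#' @export
plant_truth <- function(annotation, config) {
  ids <- annotation$genes$gene_id
  n_up <- round(config$frac_up * length(ids))
  n_down <- round(config$frac_down * length(ids))
  .with_seed(config$seed + 1, {
    up <- sort(sample(ids, n_up))
    down <- sort(sample(setdiff(ids, up), n_down))
    flag <- sort(sample(up, round(config$frac_flag_enriched_of_up * n_up)))
    lw <- locus_windows(annotation, config$upstream_bp)
    pk <- lw[lw$gene_id %in% flag, c("chrom", "start", "end", "gene_id")]
    names(pk)[4] <- "name"
    pk <- sort_intervals(pk)
    rownames(pk) <- NULL
    structure(list(up_genes = up, down_genes = down, flag_genes = flag,
                   planted_peaks = pk),
              class = "GroundTruth")
  })
}

#' Simulate a count matrix with planted effects
#'
#' Counts are negative-binomial with a single shared dispersion. The
#' expected count of gene g in sample s is
#' baseline_g x clone_factor x depth_factor x 2^(+/- effect) where the
#' effect applies only to planted genes in mutant clones. The RNA assay has
#' `rna_repeats` columns per clone (labels encode clone and repeat, e.g.
#' "WT1_r2"); the PRO assay has one column per clone.
#'
#' @param annotation a [genome_annotation()] object.
#' @param truth a [plant_truth()] object (gene ids must be a subset of the
#'   annotation's).
#' @param config a [sim_config()] object.
#' @param assay "rna" or "pro".
#' @return A [count_matrix()] object; deterministic for a fixed seed.
#' @export
simulate_counts <- function(annotation, truth, config,
                            assay = c("rna", "pro")) {
  assay <- match.arg(assay)
  stopifnot(inherits(truth, "GroundTruth"))
  ids <- annotation$genes$gene_id
  if (!all(c(truth$up_genes, truth$down_genes) %in% ids))
    stop("ground-truth gene ids not in annotation")
  if (config$nb_dispersion <= 0) stop("dispersion must be > 0")
  clones <- clone_ids(config)
  reps <- if (assay == "rna") config$rna_repeats else 1L
  samples <- if (reps > 1)
    as.vector(vapply(clones, function(cl) paste0(cl, "_r", seq_len(reps)),
                     character(reps)))
  else clones
  groups <- stats::setNames(ifelse(grepl("^WT", samples), "WT", "MUT"),
                            samples)
  depth <- rep(1, length(samples))
  if (!is.null(config$depth_factors))
    depth <- unname(config$depth_factors[samples])
  seed <- config$seed + if (assay == "rna") 2 else 3
  .with_seed(seed, {
    base <- exp(stats::runif(length(ids), log(config$nb_mean_range[1]),
                             log(config$nb_mean_range[2])))
    cfac <- stats::setNames(
      stats::rlnorm(length(clones), 0, config$clone_sigma), clones)
    eff <- rep(1, length(ids))
    eff[ids %in% truth$up_genes] <- 2^config$effect_log2fc
    eff[ids %in% truth$down_genes] <- 2^(-config$effect_log2fc)
    m <- matrix(0L, length(ids), length(samples),
                dimnames = list(ids, samples))
    for (j in seq_along(samples)) {
      cl <- sub("_r[0-9]+$", "", samples[j])
      mu <- base * cfac[[cl]] * depth[j]
      if (groups[[j]] == "MUT") mu <- mu * eff
      m[, j] <- stats::rnbinom(length(ids), mu = mu,
                               size = 1 / config$nb_dispersion)
    }
    count_matrix(m, groups)
  })
}

#' Simulate FLAG/H2A coverage tracks and ATAC peaks
#'
#' H2A tracks are baseline Poisson noise everywhere. FLAG tracks equal the
#' baseline except over the locus windows (TSS - upstream_bp to TES) of the
#' planted flag-genes in mutant clones, where the expected count is
#' multiplied by 2^flag_enrichment_log2 (bins partially covered by a window
#' are scaled proportionally to their covered fraction). ATAC peaks are
#' placed at every gene promoter plus a configurable random background set.
#' The last, truncated bin of a chromosome has its expectation scaled by its
#' width.
#'
#' @param annotation a [genome_annotation()] object.
#' @param truth a [plant_truth()] object.
#' @param config a [sim_config()] object.
#' @return list(flag = named list of [binned_track()] per clone,
#'   h2a = likewise, atac = interval data.frame, groups = named WT/MUT
#'   vector); deterministic for a fixed seed.
#' @export
simulate_tracks <- function(annotation, truth, config) {
  stopifnot(inherits(truth, "GroundTruth"))
  chrom_sizes <- annotation$chrom_sizes
  bs <- config$bin_size
  clones <- clone_ids(config)
  groups <- clone_groups(config)
  # per-chromosome fraction of each bin covered by a planted window
  cover <- lapply(names(chrom_sizes), function(chr) {
    nb <- n_bins(chrom_sizes[[chr]], bs)
    cov <- numeric(nb)
    pk <- truth$planted_peaks
    pk <- pk[pk$chrom == chr, , drop = FALSE]
    if (nrow(pk)) {
      b0 <- pk$start %/% bs
      b1 <- (pk$end - 1) %/% bs
      span <- b1 - b0 + 1
      idx <- rep.int(seq_len(nrow(pk)), span)
      bins <- b0[idx] + (sequence(span) - 1)
      lo <- pmax(pk$start[idx], bins * bs)
      hi <- pmin(pk$end[idx], (bins + 1) * bs)
      acc <- rowsum(hi - lo, bins)
      cov[as.numeric(rownames(acc)) + 1] <- acc[, 1]
    }
    widths <- pmin(seq_len(nb) * bs, chrom_sizes[[chr]]) -
      (seq_len(nb) - 1) * bs
    list(frac = pmin(cov / widths, 1), wfrac = widths / bs)
  })
  names(cover) <- names(chrom_sizes)
  .with_seed(config$seed + 4, {
    cfac_flag <- stats::rlnorm(length(clones), 0, config$clone_sigma)
    cfac_h2a <- stats::rlnorm(length(clones), 0, config$clone_sigma)
    mult <- 2^config$flag_enrichment_log2
    flag <- h2a <- stats::setNames(vector("list", length(clones)), clones)
    for (j in seq_along(clones)) {
      fv <- lapply(names(chrom_sizes), function(chr) {
        cv <- cover[[chr]]
        lam <- config$flag_mean * cfac_flag[j] * cv$wfrac
        if (groups[[clones[j]]] == "MUT")
          lam <- lam * (1 + (mult - 1) * cv$frac)
        as.numeric(stats::rpois(length(lam), lam))
      })
      names(fv) <- names(chrom_sizes)
      hv <- lapply(names(chrom_sizes), function(chr) {
        cv <- cover[[chr]]
        as.numeric(stats::rpois(length(cv$wfrac),
                                config$h2a_mean * cfac_h2a[j] * cv$wfrac))
      })
      names(hv) <- names(chrom_sizes)
      flag[[j]] <- binned_track(fv, bs, chrom_sizes, clones[j], "flag")
      h2a[[j]] <- binned_track(hv, bs, chrom_sizes, clones[j], "h2a")
    }
    pw <- annotation$genes
    atac_prom <- data.frame(
      chrom = pw$chrom,
      start = pmax(pw$tss - config$atac_halfwidth, 0),
      end = pmin(pw$tss + config$atac_halfwidth,
                 chrom_sizes[pw$chrom]),
      name = paste0("atac_", pw$gene_id))
    atac_bg <- NULL
    if (config$n_atac_background > 0) {
      w <- 2 * config$atac_halfwidth
      chr <- sample(names(chrom_sizes), config$n_atac_background,
                    replace = TRUE,
                    prob = chrom_sizes / sum(chrom_sizes))
      st <- floor(stats::runif(config$n_atac_background, 0,
                               chrom_sizes[chr] - w))
      atac_bg <- data.frame(chrom = chr, start = st, end = st + w,
                            name = paste0("atac_bg",
                                          seq_len(config$n_atac_background)))
    }
    atac <- sort_intervals(rbind(atac_prom, atac_bg))
    rownames(atac) <- NULL
    list(flag = flag, h2a = h2a, atac = atac, groups = groups)
  })
}

#' Write a complete synthetic fixture to disk
#'
#' Emits the gene table, chromosome sizes, RNA and PRO count tables,
#' per-clone FLAG and H2A bedGraph tracks, the ATAC peak BED, the ground
#' truth (gene sets as TSV, planted intervals as BED), and a JSON manifest
#' listing every file with its MD5 checksum.
#'
#' @param config a [sim_config()] object.
#' @param out_dir output directory (created if absent).
#' @return The manifest, invisibly: list(files = named md5 vector,
#'   dir, config).
#' @export
write_fixture <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  annotation <- generate_genome(config)
  truth <- plant_truth(annotation, config)
  rna <- simulate_counts(annotation, truth, config, "rna")
  pro <- simulate_counts(annotation, truth, config, "pro")
  tracks <- simulate_tracks(annotation, truth, config)
  p <- function(f) file.path(out_dir, f)
  write_chrom_sizes(annotation$chrom_sizes, p("chrom_sizes.tsv"))
  write_gene_table(annotation, p("genes.tsv"))
  write_counts(rna, p("counts_rna.tsv"))
  write_counts(pro, p("counts_pro.tsv"))
  for (cl in names(tracks$flag)) {
    write_bedgraph(tracks$flag[[cl]], p(sprintf("flag_%s.bedgraph", cl)))
    write_bedgraph(tracks$h2a[[cl]], p(sprintf("h2a_%s.bedgraph", cl)))
  }
  write_bed(tracks$atac, p("atac_peaks.bed"))
  gt <- rbind(
    data.frame(set = "up", gene_id = truth$up_genes),
    data.frame(set = "down", gene_id = truth$down_genes),
    data.frame(set = "flag", gene_id = truth$flag_genes))
  utils::write.table(gt, p("ground_truth.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_bed(truth$planted_peaks, p("planted_peaks.bed"))
  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    files = as.list(tools::md5sum(file.path(out_dir, files))),
    dir = out_dir,
    config = unclass(config))
  names(manifest$files) <- files
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a ground-truth fixture back from disk
#'
#' @param dir fixture directory written by [write_fixture()].
#' @return A `GroundTruth` object equal to the one that was written.
#' @export
read_ground_truth <- function(dir) {
  gt <- utils::read.table(file.path(dir, "ground_truth.tsv"), sep = "\t",
                          header = TRUE, colClasses = "character")
  pk <- read_bed(file.path(dir, "planted_peaks.bed"))
  structure(list(up_genes = sort(gt$gene_id[gt$set == "up"]),
                 down_genes = sort(gt$gene_id[gt$set == "down"]),
                 flag_genes = sort(gt$gene_id[gt$set == "flag"]),
                 planted_peaks = pk[, c("chrom", "start", "end", "name")]),
            class = "GroundTruth")
}
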