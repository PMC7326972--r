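# End-to-end orchestration over an on-disk fixture: differential counts for
# both assays, occupancy peak calling, peak annotation, locus scores + GSEA,
# and concordance, each stage persisting its outputs so stages can be rerun
# individually and reproduce the full run bit for bit.

#' Pipeline configuration
#'
#' @param alpha FDR threshold shared by all differential calls.
#' @param min_abs_log2fc minimum |log2FC| for an up/down expression call.
#' @param bin_size coverage bin width (bp) used to read bedGraph tracks.
#' @param pc CPM pseudocount for the FLAG/H2A ratio.
#' @param max_gap,min_bins peak assembly parameters.
#' @param promoter_up,promoter_down promoter window extent (bp).
#' @param n_shuffles shuffled peak sets for the chi-square null.
#' @param upstream_bp locus-window upstream extent (bp).
#' @param weight_exponent GSEA weight exponent.
#' @param n_perm GSEA permutations.
#' @param seed master seed for shuffling and permutation.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(alpha = 0.05, min_abs_log2fc = 1, bin_size = 100,
                            pc = 0.5, max_gap = 1, min_bins = 2,
                            promoter_up = 1000, promoter_down = 1000,
                            n_shuffles = 1000, upstream_bp = 1000,
                            weight_exponent = 1, n_perm = 10000, seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

.fixture_paths <- function(fixture_dir) {
  cs <- file.path(fixture_dir, "chrom_sizes.tsv")
  req <- c(cs, file.path(fixture_dir, c("genes.tsv", "counts_rna.tsv",
                                        "counts_pro.tsv", "atac_peaks.bed")))
  missing <- req[!file.exists(req)]
  if (length(missing)) stop("missing input file: ", missing[1])
  flag <- sort(list.files(fixture_dir, "^flag_.*\\.bedgraph$",
                          full.names = TRUE))
  h2a <- sort(list.files(fixture_dir, "^h2a_.*\\.bedgraph$",
                         full.names = TRUE))
  if (!length(flag) || length(flag) != length(h2a))
    stop("FLAG/H2A bedGraph tracks missing or unpaired in ", fixture_dir)
  list(chrom_sizes = cs, genes = req[2], rna = req[3], pro = req[4],
       atac = req[5], flag = flag, h2a = h2a)
}

.read_tracks <- function(paths, config) {
  chrom_sizes <- read_chrom_sizes(paths$chrom_sizes)
  clones <- sub("^flag_(.*)\\.bedgraph$", "\\1", basename(paths$flag))
  flag <- stats::setNames(lapply(seq_along(paths$flag), function(i)
    read_bedgraph(paths$flag[i], chrom_sizes, config$bin_size,
                  clones[i], "flag")), clones)
  h2a <- stats::setNames(lapply(seq_along(paths$h2a), function(i)
    read_bedgraph(paths$h2a[i], chrom_sizes, config$bin_size,
                  clones[i], "h2a")), clones)
  groups <- stats::setNames(ifelse(grepl("^WT", clones), "WT", "MUT"),
                            clones)
  list(flag = flag, h2a = h2a, groups = groups, chrom_sizes = chrom_sizes)
}

.ratio_tracks <- function(tr, config) {
  rt <- lapply(names(tr$flag), function(cl)
    normalize_internal_control(tr$flag[[cl]], tr$h2a[[cl]], pc = config$pc,
                               group = tr$groups[[cl]]))
  stats::setNames(rt, names(tr$flag))
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = NA, check.names = FALSE)
}

#' Differential-counts stage
#'
#' Runs [differential_analysis()] on the RNA-seq and PRO-seq count tables
#' and persists `diff_rna.tsv` / `diff_pro.tsv`.
#'
#' @param fixture_dir directory holding the pipeline inputs (layout of
#'   [write_fixture()]).
#' @param out_dir output directory (created if absent).
#' @param config a [pipeline_config()].
#' @return list(rna, pro) differential tables, invisibly.
#' @export
stage_diff <- function(fixture_dir, out_dir, config = pipeline_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- .fixture_paths(fixture_dir)
  res <- lapply(list(rna = paths$rna, pro = paths$pro), function(p)
    differential_analysis(read_counts(p), alpha = config$alpha,
                          min_abs_log2fc = config$min_abs_log2fc))
  .write_tsv(res$rna, file.path(out_dir, "diff_rna.tsv"))
  .write_tsv(res$pro, file.path(out_dir, "diff_pro.tsv"))
  invisible(res)
}

#' Occupancy peak-calling stage
#'
#' Normalizes FLAG against H2A per clone, tests bins, assembles peaks, and
#' persists `peaks.tsv`, `specific_peaks.tsv` and `specific_peaks.bed`
#' (name = peak id, score = -10 log10 q).
#'
#' @inheritParams stage_diff
#' @return list(peaks, specific), invisibly.
#' @export
stage_peaks <- function(fixture_dir, out_dir, config = pipeline_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- .fixture_paths(fixture_dir)
  tr <- .read_tracks(paths, config)
  occ <- call_occupancy_peaks(tr$flag, tr$h2a, tr$groups, pc = config$pc,
                              alpha = config$alpha, max_gap = config$max_gap,
                              min_bins = config$min_bins)
  .write_tsv(occ$peaks, file.path(out_dir, "peaks.tsv"))
  .write_tsv(occ$specific, file.path(out_dir, "specific_peaks.tsv"))
  bed <- occ$specific[, c("chrom", "start", "end", "name", "score")]
  write_bed(bed, file.path(out_dir, "specific_peaks.bed"))
  invisible(occ[c("peaks", "specific")])
}

#' Peak-annotation stage
#'
#' Categorizes the mutant-specific peaks, runs the shuffled-null chi-square
#' test, the ATAC co-localization, and the promoter/expression crosstab;
#' persists `peak_categories.tsv`, `annotation_enrichment.json` and
#' `promoter_crosstab.json`. Requires `stage_peaks` and `stage_diff`
#' outputs in `out_dir`.
#'
#' @inheritParams stage_diff
#' @return list(enrichment, colocalization, crosstab), invisibly.
#' @export
stage_annotate <- function(fixture_dir, out_dir,
                           config = pipeline_config()) {
  paths <- .fixture_paths(fixture_dir)
  chrom_sizes <- read_chrom_sizes(paths$chrom_sizes)
  annotation <- read_gene_table(paths$genes, chrom_sizes)
  peaks <- .read_tsv(file.path(out_dir, "specific_peaks.tsv"))
  atac <- read_bed(paths$atac, chrom_sizes)
  enr <- annotation_enrichment(peaks, annotation,
                               n_shuffles = config$n_shuffles,
                               seed = config$seed,
                               promoter_up = config$promoter_up,
                               promoter_down = config$promoter_down)
  col <- atac_colocalization(peaks, atac, enr$peak_categories)
  rna <- .read_tsv(file.path(out_dir, "diff_rna.tsv"))
  ct <- promoter_expression_crosstab(peaks, annotation,
                                     rna$gene_id[rna$call == "up"],
                                     config$promoter_up,
                                     config$promoter_down)
  .write_tsv(cbind(peaks[, c("chrom", "start", "end", "name")],
                   category = as.character(enr$peak_categories),
                   atac_colocalized = col$colocalized),
             file.path(out_dir, "peak_categories.tsv"))
  jsonlite::write_json(
    list(observed = as.list(enr$observed),
         expected = as.list(enr$expected), chi2 = enr$chi2, df = enr$df,
         p = enr$p, n_shuffles = enr$n_shuffles,
         colocalization = list(n_peaks = col$n_peaks,
                               n_colocalized = col$n_colocalized,
                               fraction = col$fraction)),
    file.path(out_dir, "annotation_enrichment.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(
    list(n_promoter_genes = ct$n_promoter_genes, n_also_up = ct$n_also_up,
         promoter_genes = ct$promoter_genes, up_overlap = ct$up_overlap),
    file.path(out_dir, "promoter_crosstab.json"),
    auto_unbox = TRUE, pretty = TRUE)
  invisible(list(enrichment = enr, colocalization = col, crosstab = ct))
}

#' Locus-score and GSEA stage
#'
#' Computes per-gene locus-wide scores, the significant flag-enriched gene
#' set, and the GSEA running-sum enrichment of the concordantly
#' upregulated genes; persists `locus_scores.tsv`, `flag_genes.txt`,
#' `gsea.json` and `running_sum.tsv`. Requires `stage_diff` outputs.
#'
#' @inheritParams stage_diff
#' @return list(locus, flag_enriched, gsea), invisibly.
#' @export
stage_gsea <- function(fixture_dir, out_dir, config = pipeline_config()) {
  paths <- .fixture_paths(fixture_dir)
  chrom_sizes <- read_chrom_sizes(paths$chrom_sizes)
  annotation <- read_gene_table(paths$genes, chrom_sizes)
  tr <- .read_tracks(paths, config)
  rt <- .ratio_tracks(tr, config)
  ls <- locus_scores(annotation, rt, upstream = config$upstream_bp)
  fe <- locuswide_enriched_genes(ls, alpha = config$alpha)
  rna <- .read_tsv(file.path(out_dir, "diff_rna.tsv"))
  pro <- .read_tsv(file.path(out_dir, "diff_pro.tsv"))
  qc <- quadrant_classify(rna, pro)
  gsea <- NULL
  if (length(qc$both_up) > 0 &&
      length(qc$both_up) < nrow(ls$table)) {
    gsea <- gsea_enrichment(ls$table, qc$both_up,
                            weight = config$weight_exponent,
                            n_perm = config$n_perm, seed = config$seed)
  }
  .write_tsv(ls$table, file.path(out_dir, "locus_scores.tsv"))
  writeLines(fe$genes, file.path(out_dir, "flag_genes.txt"))
  if (!is.null(gsea)) {
    jsonlite::write_json(
      list(es = gsea$es, es_rank = gsea$es_rank, p_perm = gsea$p_perm,
           n_perm = gsea$n_perm, seed = gsea$seed,
           gene_set_size = length(intersect(qc$both_up, ls$table$gene_id))),
      file.path(out_dir, "gsea.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    .write_tsv(data.frame(rank = seq_along(gsea$running_sum),
                          gene_id = gsea$ranked_ids,
                          running_sum = gsea$running_sum),
               file.path(out_dir, "running_sum.tsv"))
  }
  invisible(list(locus = ls, flag_enriched = fe$genes, gsea = gsea))
}

#' Concordance stage
#'
#' Quadrant-classifies the two differential tables, intersects the
#' concordantly upregulated genes with the locus-wide FLAG-enriched set,
#' and persists `concordance.json` and `intersection.tsv`. Requires
#' `stage_diff` and `stage_gsea` outputs.
#'
#' @inheritParams stage_diff
#' @return list(concordance, intersection), invisibly.
#' @export
stage_concord <- function(fixture_dir, out_dir,
                          config = pipeline_config()) {
  rna <- .read_tsv(file.path(out_dir, "diff_rna.tsv"))
  pro <- .read_tsv(file.path(out_dir, "diff_pro.tsv"))
  flag_genes <- readLines(file.path(out_dir, "flag_genes.txt"))
  locus <- .read_tsv(file.path(out_dir, "locus_scores.tsv"))
  qc <- quadrant_classify(rna, pro)
  ix <- intersect_with_flag(qc$both_up, flag_genes, rna, pro, locus)
  sets <- c("both_up", "both_down", "rna_only_up", "rna_only_down",
            "pro_only_up", "pro_only_down", "discordant_up_down",
            "discordant_down_up", "neither")
  jsonlite::write_json(
    c(list(pearson_r = qc$pearson_r, p_r = qc$p_r,
           n_shared = qc$n_shared),
      stats::setNames(lapply(sets, function(s) length(qc[[s]])),
                      paste0("n_", sets)),
      list(n_intersection = length(ix$genes))),
    file.path(out_dir, "concordance.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  .write_tsv(ix$table, file.path(out_dir, "intersection.tsv"))
  invisible(list(concordance = qc, intersection = ix))
}

#' Run the full pipeline
#'
#' Executes the stages in dependency order (differential counts for both
#' assays, occupancy peaks, peak annotation, locus scores + GSEA,
#' concordance), persisting every intermediate in `out_dir`, and writes a
#' machine-readable `summary.json`. The run is a pure function of (inputs,
#' config): re-running with the same inputs and seeds reproduces every
#' output.
#'
#' @inheritParams stage_diff
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(fixture_dir, out_dir,
                         config = pipeline_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    message(sprintf("[oncohist] stage %s ...", name))
    force(expr)
  }
  diff <- stage("diff", stage_diff(fixture_dir, out_dir, config))
  pk <- stage("peaks", stage_peaks(fixture_dir, out_dir, config))
  ann <- stage("annotate", stage_annotate(fixture_dir, out_dir, config))
  gs <- stage("gsea", stage_gsea(fixture_dir, out_dir, config))
  cc <- stage("concord", stage_concord(fixture_dir, out_dir, config))
  paths <- .fixture_paths(fixture_dir)
  inputs <- unlist(paths, use.names = FALSE)
  summary <- list(
    package_version = as.character(utils::packageVersion("oncohist")),
    config = unclass(config),
    input_checksums = as.list(tools::md5sum(inputs)),
    n_up_rna = sum(diff$rna$call == "up"),
    n_down_rna = sum(diff$rna$call == "down"),
    n_up_pro = sum(diff$pro$call == "up"),
    n_down_pro = sum(diff$pro$call == "down"),
    n_peaks = nrow(pk$peaks),
    n_specific_peaks = nrow(pk$specific),
    peak_categories = as.list(ann$enrichment$observed),
    chi2 = ann$enrichment$chi2,
    chi2_p = ann$enrichment$p,
    atac_colocalization_fraction = ann$colocalization$fraction,
    n_promoter_genes = ann$crosstab$n_promoter_genes,
    n_promoter_genes_up = ann$crosstab$n_also_up,
    pearson_r = cc$concordance$pearson_r,
    pearson_p = cc$concordance$p_r,
    n_both_up = length(cc$concordance$both_up),
    n_rna_only_up = length(cc$concordance$rna_only_up),
    n_pro_only_up = length(cc$concordance$pro_only_up),
    n_flag_enriched = length(gs$flag_enriched),
    n_intersection = length(cc$intersection$genes),
    gsea_es = if (is.null(gs$gsea)) NA else gs$gsea$es,
    gsea_p_perm = if (is.null(gs$gsea)) NA else gs$gsea$p_perm,
    elapsed_sec = proc.time()[["elapsed"]] - t0)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
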