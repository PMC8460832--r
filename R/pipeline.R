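#' Cohort bookkeeping summary
#'
#' Totals and per-category percentages for a table of sample or core counts.
#' Percentages are `100 * count / total`, rounded half away from zero to one
#' decimal (the usual clinical reporting convention).
#'
#' @param counts Named non-negative numeric vector of category counts.
#' @return Data frame `category`, `count`, `percent`, with the total in
#'   attribute `total`.
#' @examples
#' cohort_bookkeeping(c(primary = 48, metastatic = 48, control = 10))
#' @export
cohort_bookkeeping <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total == 0) stop("zero total: percentages undefined")
  out <- data.frame(
    category = if (is.null(names(counts))) as.character(seq_along(counts))
               else names(counts),
    count = as.numeric(counts),
    percent = round_half_up(100 * counts / total, 1),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "total") <- total
  out
}

#' Configuration for a full pipeline run
#'
#' Bundles the analysis constants of the workflow: reference sample,
#' top-variance count (500), protein cluster count (4), permutation count
#' (500) with its stability percentile, CV-filter options, the cleavage
#' assay and the enzyme. Input is either a synthetic-cohort [sim_config()]
#' or paths to an abundance matrix, metadata and peptide table on disk.
#'
#' @param sim A [sim_config()] for synthetic input, or `NULL`.
#' @param matrix_path,metadata_path,peptides_path Input files (used when
#'   `sim` is `NULL`; all three must exist).
#' @param reference Reference run id for normalization (default `"AG1"`).
#' @param top_k Number of top-variance proteins for clustering (default 500;
#'   capped at the number available).
#' @param n_clusters Flat protein cluster count (default 4).
#' @param n_permutations Label permutations for the stability test
#'   (default 500).
#' @param percentile Stability percentile (default 5).
#' @param cv_scale Passed to [cv_filter()].
#' @param assay Cleavage assay (default [npy_dpp4_assay()]).
#' @param seed Integer seed governing every stochastic stage.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            matrix_path = NULL, metadata_path = NULL,
                            peptides_path = NULL,
                            reference = "AG1", top_k = 500, n_clusters = 4,
                            n_permutations = 500, percentile = 5,
                            cv_scale = "linear",
                            assay = npy_dpp4_assay(), seed = 1L) {
  cfg <- structure(list(
    sim = sim, matrix_path = matrix_path, metadata_path = metadata_path,
    peptides_path = peptides_path, reference = reference,
    top_k = as.integer(top_k), n_clusters = as.integer(n_clusters),
    n_permutations = as.integer(n_permutations), percentile = percentile,
    cv_scale = cv_scale, assay = assay, seed = as.integer(seed)
  ), class = "pipeline_config")
  if (is.null(cfg$sim)) {
    for (f in c("matrix_path", "metadata_path", "peptides_path")) {
      if (is.null(cfg[[f]]) || !file.exists(cfg[[f]])) {
        stop("pipeline_config field '", f, "' must point to an existing file ",
             "when no simulation config is given")
      }
    }
  } else {
    validate_sim_config(cfg$sim)
  }
  if (is.null(cfg$reference) || !nzchar(cfg$reference)) {
    stop("pipeline_config field 'reference' is required")
  }
  for (f in c("top_k", "n_clusters", "n_permutations")) {
    if (cfg[[f]] < 1) stop("pipeline_config field '", f, "' must be >= 1")
  }
  if (length(cfg$seed) != 1 || is.na(cfg$seed)) {
    stop("pipeline_config field 'seed' is required")
  }
  validate_assay(cfg$assay)
  cfg
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  path
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — simulate/load, normalize to the reference,
#' replicate correlation, CV filter, structure (top-variance Z-scores,
#' Ward/Euclidean clustering, PCA), differential expression (both regimes),
#' permutation rank-stability, protease activity — and writes each stage's
#' output as plain TSV/JSON into `out_dir`, together with a provenance
#' manifest (package version, seed, MD5 of every input and output). All
#' randomness derives from `config$seed`, so a rerun with an identical
#' config reproduces identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(...) file.path(out_dir, ...)
  written <- character(0)
  emit <- function(df, name) {
    written[[length(written) + 1]] <<- .write_tsv(df, pth(name))
  }

  # --- stage: input ---------------------------------------------------
  if (!is.null(config$sim)) {
    cohort <- simulate_cohort(config$sim)
    x <- cohort$abundance; metadata <- cohort$metadata
    peptides <- simulate_peptides(config$sim, metadata, cohort$truth)
    write_abundance(x, pth("abundance.tsv"))
    write_metadata(metadata, pth("metadata.tsv"))
    write_peptides(peptides, pth("peptides.tsv"))
    jsonlite::write_json(
      list(effects = cohort$truth$effects,
           protease_panel = cohort$truth$protease_panel,
           dpp4 = as.list(cohort$truth$dpp4),
           replicated_samples = cohort$truth$replicated_samples),
      pth("ground_truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <- c(written, pth(c("abundance.tsv", "metadata.tsv",
                                "peptides.tsv", "ground_truth.json")))
  } else {
    x <- read_abundance(config$matrix_path)
    metadata <- read_metadata(config$metadata_path)
    peptides <- read_peptides(config$peptides_path)
  }
  validate_metadata(metadata, x)
  if (!config$reference %in% colnames(x)) {
    stop("pipeline aborted at stage 'normalize': reference run '",
         config$reference, "' (field 'reference') is not a column of the matrix")
  }

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline aborted at stage '", stage, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- normalize ------------------------------------------------------
  norm <- run_stage("normalize", normalize_to_reference(x, config$reference))
  norm_s <- average_replicates(norm, metadata)
  emit(data.frame(protein_id = rownames(norm_s$log2), norm_s$log2,
                  check.names = FALSE), "normalized_log2.tsv")

  repcor <- run_stage("replicate_correlation",
                      tryCatch(replicate_correlation(norm, metadata),
                               error = function(e) NULL))

  # --- cv filter ------------------------------------------------------
  cvrec <- run_stage("cvfilter",
                     cv_filter(norm, metadata, cv_scale = config$cv_scale))
  emit(cvrec, "cv_records.tsv")
  filt <- apply_cv_filter(norm_s, cvrec)

  # --- structure ------------------------------------------------------
  k <- min(config$top_k, sum(!is.na(.row_vars(filt$log2))))
  top <- run_stage("structure", select_top_variance(filt, k))
  z <- suppressWarnings(zscore_rows(filt$log2[top, , drop = FALSE]))
  clus <- run_stage("structure", hierarchical_structure(z, config$n_clusters))
  pca <- run_stage("structure", pca_samples(z))
  emit(data.frame(protein_id = names(clus$protein_clusters),
                  cluster = clus$protein_clusters), "protein_clusters.tsv")
  info <- .sample_info(metadata)
  emit(data.frame(sample_id = rownames(pca$scores),
                  group = info$group[match(rownames(pca$scores), info$sample_id)],
                  pca$scores[, seq_len(min(5, ncol(pca$scores))), drop = FALSE],
                  check.names = FALSE), "pca_scores.tsv")

  # --- differential ---------------------------------------------------
  de_tumor <- run_stage("differential",
                        differential_expression(filt, metadata, "tumor_vs_control"))
  de_sub <- run_stage("differential",
                      differential_expression(filt, metadata, "ag_vs_nag"))
  de_tumor$neg_log10_p <- -log10(de_tumor$p_value)
  de_sub$neg_log10_p <- -log10(de_sub$p_value)
  emit(de_tumor, "differential_tumor_vs_control.tsv")
  emit(de_sub, "differential_ag_vs_nag.tsv")

  # --- stability ------------------------------------------------------
  stab <- run_stage("stability",
                    permutation_stability(filt, metadata,
                                          n_permutations = config$n_permutations,
                                          percentile = config$percentile,
                                          seed = config$seed))
  emit(stab$results, "stability.tsv")
  emit(stab$curve, "stability_curve.tsv")

  # --- activity -------------------------------------------------------
  act <- run_stage("activity", compute_ratios(peptides, config$assay, metadata))
  emit(as.data.frame(act), "activity_ratios.tsv")
  # enzyme expression taken from the normalized sample matrix; if the enzyme
  # has no ratio to the reference run (not quantified there), fall back to
  # its replicate-averaged raw log2 abundance
  enzyme <- config$assay$enzyme_protein_id
  enz_mat <- norm_s
  usable <- enzyme %in% rownames(norm_s$log2) &&
    sum(!is.na(norm_s$log2[enzyme, act$sample_id])) >= 3
  if (!usable) {
    message("enzyme '", enzyme, "' has no normalized ratios; ",
            "correlating against raw log2 abundance")
    enz_mat <- average_replicates(log2(x), metadata)
  }
  assoc <- run_stage("activity", list(
    correlation = correlate_with_enzyme(act, enz_mat, enzyme),
    ag_vs_nag = compare_ratio_groups(act, "AG", "NAG")
  ))
  jsonlite::write_json(assoc, pth("activity_association.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  written <- c(written, pth("activity_association.json"))

  # --- manifest -------------------------------------------------------
  manifest <- list(
    package = "swathpipe",
    version = as.character(utils::packageVersion("swathpipe")),
    seed = config$seed,
    reference = config$reference,
    parameters = list(top_k = config$top_k, n_clusters = config$n_clusters,
                      n_permutations = config$n_permutations,
                      percentile = config$percentile,
                      cv_scale = config$cv_scale),
    files = {
      md5 <- tools::md5sum(sort(unique(written)))
      names(md5) <- basename(names(md5))
      as.list(md5)
    }
  )
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(normalized = norm_s, replicate_correlation = repcor,
                 cv_records = cvrec, filtered = filt, top_proteins = top,
                 clustering = clus, pca = pca,
                 differential_tumor = de_tumor, differential_subtype = de_sub,
                 stability = stab, activity = act, association = assoc,
                 manifest = manifest))
}
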