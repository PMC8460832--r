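#' Cohort designs of the study being emulated
#'
#' Group sizes of the discovery cohort (10 C, 10 NAG, 9 AG, 10 Nmet, 10 M),
#' the validation cohort (19 NAG, 10 AG, 28 M) and their combination
#' (106 tissue samples in total).
#'
#' @param which One of `"discovery"`, `"validation"`, `"combined"`.
#' @return Named integer vector of biological sample counts per group.
#' @examples
#' cohort_design("discovery")
#' sum(cohort_design("combined"))  # 106
#' @export
cohort_design <- function(which = c("discovery", "validation", "combined")) {
  which <- match.arg(which)
  switch(which,
    discovery  = c(C = 10L, NAG = 10L, AG = 9L, Nmet = 10L, M = 10L),
    validation = c(NAG = 19L, AG = 10L, M = 28L),
    combined   = c(C = 10L, NAG = 29L, AG = 19L, Nmet = 10L, M = 38L)
  )
}

#' Configuration for the synthetic SWATH cohort generator
#'
#' Defines the statistical model behind [simulate_cohort()] and
#' [simulate_peptides()]. Protein log2 abundances are Gaussian per protein
#' (baseline drawn across proteins, biological variation across samples,
#' group-level planted shifts); duplicate runs of a sample resample only
#' technical noise; missingness follows a logistic function of abundance; and
#' the cleaved/intact substrate peptide log-ratio is linearly linked to the
#' planted DPP4 level.
#'
#' @param group_sizes Named vector of biological sample counts per tissue
#'   group (names from [TISSUE_GROUPS]); default the discovery design.
#' @param n_proteins Number of proteins (default 4415).
#' @param n_replicated_samples Number of biological samples run in duplicate
#'   (default 48, capped at the cohort size); the subset is drawn at random.
#' @param baseline_log2_mean,baseline_log2_sd Across-protein distribution of
#'   baseline log2 intensities (defaults 20 and 2).
#' @param biological_log2_sd Between-sample biological SD on the log2 scale
#'   (default 0.6).
#' @param technical_cv Technical coefficient of variation of replicate runs
#'   on the linear scale; a scalar or a named per-group vector (default 0.15).
#' @param planted_effects `NULL` or a data frame with columns `protein_id`,
#'   `group`, `log2_shift` of additional planted differential effects.
#' @param protease_panel Protein identifiers of the planted protease panel,
#'   down-shifted in the AG, Nmet and M groups (default DPP4, KLK3, CMA1,
#'   CPE, ITGB1, ANPEP). May be `character(0)` for a null cohort.
#' @param protease_log2_shift Log2 shift applied to the panel in AG/Nmet/M
#'   (default -1.5).
#' @param miss_intercept,miss_slope Logistic model of missingness,
#'   `P(missing) = plogis(miss_intercept + miss_slope * log2_abundance)`;
#'   defaults 7 and -0.5 (about 5% missing at the mean abundance, rising
#'   steeply for faint proteins). `miss_slope` must be <= 0 so that
#'   missingness never increases with abundance.
#' @param dpp4_ratio_slope Slope linking the centered true DPP4 log2 level to
#'   the log2 cleaved/intact NPY peptide ratio (default 1).
#' @param dpp4_ratio_noise SD of the Gaussian noise on the log2
#'   cleaved/intact ratio (default 1.87, which places the population Pearson
#'   correlation between DPP4 level and log-ratio at 0.45 under the combined
#'   106-sample design; see the methods vignette for the derivation).
#' @param npy_log2_mean,npy_log2_sd Distribution of the total NPY substrate
#'   log2 intensity per sample (defaults 18 and 0.5).
#' @param npy_ag_log2_shift Additional log2 shift of total NPY in the AG
#'   group (default 1, emulating substrate accumulation where the protease is
#'   lost).
#' @param reference_noise_log2_sd Log2-scale noise of the C-terminal
#'   (total-substrate) reference peptide around intact + cleaved
#'   (default 0.1).
#' @param cohort Cohort label written into the metadata (default
#'   "discovery").
#' @param seed Integer seed; the same seed and config give byte-identical
#'   output.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_cohort()], [simulate_peptides()]
#' @export
sim_config <- function(group_sizes = cohort_design("discovery"),
                       n_proteins = 4415,
                       n_replicated_samples = 48,
                       baseline_log2_mean = 20,
                       baseline_log2_sd = 2,
                       biological_log2_sd = 0.6,
                       technical_cv = 0.15,
                       planted_effects = NULL,
                       protease_panel = c("DPP4", "KLK3", "CMA1", "CPE",
                                          "ITGB1", "ANPEP"),
                       protease_log2_shift = -1.5,
                       miss_intercept = 7,
                       miss_slope = -0.5,
                       dpp4_ratio_slope = 1,
                       dpp4_ratio_noise = 1.87,
                       npy_log2_mean = 18,
                       npy_log2_sd = 0.5,
                       npy_ag_log2_shift = 1,
                       reference_noise_log2_sd = 0.1,
                       cohort = "discovery",
                       seed = 1L) {
  cfg <- list(
    group_sizes = group_sizes, n_proteins = as.integer(n_proteins),
    n_replicated_samples = as.integer(n_replicated_samples),
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    biological_log2_sd = biological_log2_sd,
    technical_cv = technical_cv,
    planted_effects = planted_effects,
    protease_panel = as.character(protease_panel),
    protease_log2_shift = protease_log2_shift,
    miss_intercept = miss_intercept, miss_slope = miss_slope,
    dpp4_ratio_slope = dpp4_ratio_slope,
    dpp4_ratio_noise = dpp4_ratio_noise,
    npy_log2_mean = npy_log2_mean, npy_log2_sd = npy_log2_sd,
    npy_ag_log2_shift = npy_ag_log2_shift,
    reference_noise_log2_sd = reference_noise_log2_sd,
    cohort = cohort, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' Validate a simulation configuration
#'
#' @param cfg A `sim_config` object.
#' @return The validated config, invisibly unchanged.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  gs <- cfg$group_sizes
  if (is.null(names(gs)) || !all(names(gs) %in% TISSUE_GROUPS)) {
    stop("group_sizes must be named with labels among: ",
         paste(TISSUE_GROUPS, collapse = ", "))
  }
  if (anyDuplicated(names(gs))) stop("duplicated group labels in group_sizes")
  if (any(gs < 1)) stop("all group sizes must be >= 1")
  if (cfg$n_proteins < 1) stop("n_proteins must be >= 1")
  if (cfg$n_proteins < length(cfg$protease_panel)) {
    stop("n_proteins smaller than the protease panel")
  }
  if (cfg$n_replicated_samples < 0) stop("n_replicated_samples must be >= 0")
  if (any(cfg$technical_cv < 0)) stop("technical_cv must be >= 0")
  if (length(cfg$technical_cv) > 1 &&
      !all(names(gs) %in% names(cfg$technical_cv))) {
    stop("per-group technical_cv must name every group")
  }
  if (cfg$biological_log2_sd < 0 || cfg$baseline_log2_sd < 0) {
    stop("standard deviations must be >= 0")
  }
  if (cfg$miss_slope > 0) {
    stop("miss_slope must be <= 0 (missingness cannot increase with abundance)")
  }
  if (cfg$dpp4_ratio_noise < 0) stop("dpp4_ratio_noise must be >= 0")
  pe <- cfg$planted_effects
  if (!is.null(pe)) {
    if (!all(c("protein_id", "group", "log2_shift") %in% names(pe))) {
      stop("planted_effects needs columns protein_id, group, log2_shift")
    }
    if (!all(pe$group %in% names(gs))) {
      bad <- setdiff(pe$group, names(gs))
      stop("planted effect in group(s) absent from the design: ",
           paste(bad, collapse = ", "))
    }
  }
  if (length(cfg$seed) != 1 || is.na(cfg$seed)) stop("seed must be a single integer")
  invisible(cfg)
}

#' Read / write a simulation configuration as YAML
#'
#' Scalar fields are stored as-is; `planted_effects` as a list of records.
#'
#' @param path File path.
#' @param cfg A `sim_config` object.
#' @return `read_sim_config()` returns a validated `sim_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$planted_effects)) {
    raw$planted_effects <- do.call(rbind, lapply(raw$planted_effects, as.data.frame))
  }
  raw$group_sizes <- unlist(raw$group_sizes)
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(cfg, path) {
  validate_sim_config(cfg)
  out <- unclass(cfg)
  out$group_sizes <- as.list(out$group_sizes)
  if (!is.null(out$planted_effects)) {
    pe <- out$planted_effects
    out$planted_effects <- lapply(seq_len(nrow(pe)), function(i) as.list(pe[i, ]))
  }
  yaml::write_yaml(out, path)
  invisible(path)
}
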