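# linear-scale technical CV -> log2-scale SD of the lognormal run noise
.tech_sd_log2 <- function(cv) sqrt(log(1 + cv^2)) / log(2)

#' Generate a synthetic SWATH cohort
#'
#' Draws a proteins-by-runs intensity matrix with the statistical structure
#' the downstream analysis assumes: per-protein Gaussian log2 abundances with
#' group-level planted shifts, duplicate runs for a random subset of samples
#' that resample only technical noise, and abundance-dependent missingness
#' (logistic in the run-level log2 intensity). Missing entries are `NA`,
#' never zero. The protease panel in `config` is down-shifted in the AG,
#' Nmet and M groups, emulating the loss of DPP4-like proteases in
#' aggressive and metastatic tumors.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `sim_cohort` with elements
#'   \describe{
#'     \item{abundance}{numeric matrix (proteins x runs), linear intensities,
#'       `NA` = missing.}
#'     \item{metadata}{data frame with `run_id`, `sample_id`, `group`,
#'       `cohort`, `replicate`.}
#'     \item{truth}{ground-truth record (class `sim_truth`): planted
#'       `effects`, `protease_panel`, per-sample true `dpp4` log2 level,
#'       per-protein `baseline_log2`, `replicated_samples`, and the config.}
#'   }
#' @examples
#' cohort <- simulate_cohort(sim_config(n_proteins = 50, seed = 7))
#' dim(cohort$abundance)
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  withr::with_seed(config$seed, .simulate_cohort_impl(config))
}

.simulate_cohort_impl <- function(config) {
  gs <- config$group_sizes
  groups <- rep(names(gs), gs)
  sample_ids <- unlist(lapply(names(gs), function(g) paste0(g, seq_len(gs[[g]]))),
                       use.names = FALSE)
  n_s <- length(sample_ids)
  np <- config$n_proteins

  panel <- config$protease_panel
  protein_ids <- c(panel,
                   sprintf("PROT%05d", seq_len(np - length(panel))))

  # group-level effect matrix (proteins x groups)
  eff <- matrix(0, np, length(gs), dimnames = list(protein_ids, names(gs)))
  planted <- NULL
  if (length(panel)) {
    shifted_groups <- intersect(c("AG", "Nmet", "M"), names(gs))
    for (g in shifted_groups) eff[panel, g] <- config$protease_log2_shift
    planted <- expand.grid(protein_id = panel, group = shifted_groups,
                           stringsAsFactors = FALSE)
    planted$log2_shift <- config$protease_log2_shift
  }
  if (!is.null(config$planted_effects)) {
    pe <- config$planted_effects
    if (!all(pe$protein_id %in% protein_ids)) {
      stop("planted_effects references unknown protein id(s): ",
           paste(setdiff(pe$protein_id, protein_ids), collapse = ", "))
    }
    for (i in seq_len(nrow(pe))) {
      eff[pe$protein_id[i], pe$group[i]] <-
        eff[pe$protein_id[i], pe$group[i]] + pe$log2_shift[i]
    }
    planted <- rbind(planted, pe[, c("protein_id", "group", "log2_shift")])
  }

  baseline <- stats::rnorm(np, config$baseline_log2_mean, config$baseline_log2_sd)
  names(baseline) <- protein_ids

  # true per-sample log2 levels (biological, before technical noise)
  L <- baseline + eff[, groups, drop = FALSE] +
    matrix(stats::rnorm(np * n_s, 0, config$biological_log2_sd), np, n_s)
  colnames(L) <- sample_ids

  # duplicate runs for a random subset of biological samples
  n_rep <- min(config$n_replicated_samples, n_s)
  replicated <- sort(sample(sample_ids, n_rep))
  run_sample <- c(sample_ids, replicated)
  run_rep <- c(rep(1L, n_s), rep(2L, n_rep))
  run_ids <- ifelse(run_rep == 1L, run_sample, paste0(run_sample, "_rep2"))
  ord <- order(match(run_sample, sample_ids), run_rep)
  run_sample <- run_sample[ord]; run_rep <- run_rep[ord]; run_ids <- run_ids[ord]

  cv <- config$technical_cv
  run_groups <- groups[match(run_sample, sample_ids)]
  run_cv <- if (length(cv) > 1) unname(cv[run_groups]) else rep(cv, length(run_ids))

  eps <- matrix(stats::rnorm(np * length(run_ids)), np, length(run_ids))
  eps <- sweep(eps, 2, .tech_sd_log2(run_cv), `*`)
  log2_run <- L[, run_sample, drop = FALSE] + eps
  x <- 2^log2_run
  colnames(x) <- run_ids

  # abundance-dependent missingness on the run-level log2 intensity
  pmiss <- stats::plogis(config$miss_intercept + config$miss_slope * log2_run)
  x[stats::runif(length(x)) < pmiss] <- NA_real_

  metadata <- data.frame(
    run_id = run_ids, sample_id = run_sample, group = run_groups,
    cohort = config$cohort, replicate = run_rep,
    stringsAsFactors = FALSE
  )

  truth <- structure(list(
    effects = planted,
    protease_panel = panel,
    dpp4 = if ("DPP4" %in% protein_ids) stats::setNames(L["DPP4", ], sample_ids),
    baseline_log2 = baseline,
    replicated_samples = replicated,
    config = config
  ), class = "sim_truth")

  structure(list(abundance = x, metadata = metadata, truth = truth),
            class = "sim_cohort")
}

#' Generate a synthetic NPY substrate peptide table
#'
#' For every run of the cohort, draws intensities of the three neuropeptide-Y
#' surrogate peptides: intact NPY(1-36) (`YPSKPDNPGEDAPAEDMAR`), the
#' DPP4-cleaved NPY(3-36) (`SKPDNPGEDAPAEDMAR`, the intact sequence minus its
#' N-terminal dipeptide) and the shared C-terminal peptide (`HYINLITRQR`)
#' tracking total substrate. The log2 cleaved/intact ratio of a sample is
#' `dpp4_ratio_slope * (true DPP4 log2 level - cohort mean) + noise`, and the
#' C-terminal peptide equals intact + cleaved up to lognormal noise. Total
#' NPY is shifted up in AG samples by `npy_ag_log2_shift`.
#'
#' @param config A [sim_config()] object (the one used for the cohort).
#' @param metadata Run-level metadata from [simulate_cohort()].
#' @param truth Ground truth from [simulate_cohort()]; must contain the
#'   per-sample `dpp4` levels (i.e. "DPP4" must be in the protease panel).
#' @return Data frame with columns `peptide_sequence`, `protein_id`,
#'   `run_id`, `intensity`.
#' @export
simulate_peptides <- function(config, metadata, truth) {
  validate_sim_config(config)
  if (is.null(truth$dpp4)) {
    stop("ground truth carries no DPP4 level; include 'DPP4' in the protease panel")
  }
  withr::with_seed(config$seed + 99991L,
                   .simulate_peptides_impl(config, metadata, truth))
}

.simulate_peptides_impl <- function(config, metadata, truth) {
  info <- .sample_info(metadata)
  dpp4 <- truth$dpp4[info$sample_id]
  n <- nrow(info)

  total_log2 <- stats::rnorm(n, config$npy_log2_mean, config$npy_log2_sd) +
    ifelse(info$group == "AG", config$npy_ag_log2_shift, 0)
  ratio_log2 <- config$dpp4_ratio_slope * (dpp4 - mean(dpp4)) +
    stats::rnorm(n, 0, config$dpp4_ratio_noise)

  total <- 2^total_log2
  r <- 2^ratio_log2
  intact <- total / (1 + r)
  cleaved <- total * r / (1 + r)
  reference <- (intact + cleaved) *
    2^stats::rnorm(n, 0, config$reference_noise_log2_sd)

  base <- rbind(
    data.frame(peptide_sequence = NPY_INTACT, sample = info$sample_id,
               value = intact),
    data.frame(peptide_sequence = NPY_CLEAVED, sample = info$sample_id,
               value = cleaved),
    data.frame(peptide_sequence = NPY_CTERM, sample = info$sample_id,
               value = reference)
  )

  # one row per run; replicate runs resample technical noise only
  idx <- match(metadata$sample_id, info$sample_id)
  cv <- config$technical_cv
  run_cv <- if (length(cv) > 1) unname(cv[metadata$group]) else rep(cv, nrow(metadata))
  out <- do.call(rbind, lapply(seq_len(nrow(metadata)), function(i) {
    v <- base$value[base$sample == metadata$sample_id[i]]
    s <- base$peptide_sequence[base$sample == metadata$sample_id[i]]
    data.frame(peptide_sequence = s, protein_id = "NPY",
               run_id = metadata$run_id[i],
               intensity = v * 2^stats::rnorm(length(v), 0, .tech_sd_log2(run_cv[i])),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  validate_peptides(out)
}
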