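#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data generator.  Defaults mirror
#' the study conditions the pipeline targets: an 18-control healthy
#' reference panel sequenced to roughly 100,000 on-target reads per sample,
#' moderate between-control overdispersion, and longitudinal cohorts whose
#' survival depends on the baseline genome-wide z-score group.
#'
#' @param n_controls Controls in the healthy reference panel (default 18).
#' @param read_depth Reads per sample (default 100000; must be >= 1000).
#' @param theta Dirichlet-multinomial concentration governing
#'   between-sample variability of arm fractions; the Dirichlet fraction
#'   variance is `w(1-w)/(theta+1)`, so the default 40000 gives a per-arm
#'   fraction CV of roughly 3% at the median arm weight.
#' @param bin_noise_sd Gaussian noise sd of binned log2 ratios (default 0.05).
#' @param n_bins_per_arm Bins per arm in simulated log2-ratio tracks
#'   (default 25).
#' @param cohort_size Patients per simulated cohort (default 29).
#' @param hazard_ratio Multiplicative hazard of the baseline z-score >= 3
#'   group relative to the rest (default 3).
#' @param os_median_low,pfs_median_low Median OS / PFS (months) of the
#'   low z-score group under the exponential hazard model.
#' @param censor_horizon Administrative censoring horizon in months;
#'   censoring times are uniform on `[0, censor_horizon]`.
#' @param p_zero_tf Probability a patient's baseline tumor fraction is
#'   near zero (ctDNA-negative).
#' @param responder_prob Probability a patient responds to treatment.
#' @param responder_range,nonresponder_range,progression_range Uniform
#'   ranges for the treatment / progression tumor-fraction multipliers.
#' @param altered_arm_range Range (min, max) of altered arms per tumor
#'   profile.
#' @param rank_targets Named Spearman targets coupling true tumor fraction
#'   and the co-biomarkers (Gaussian-copula calibration); defaults follow
#'   the correlation structure reported for this assay class.
#' @param seed Master seed recorded in all outputs (`NULL` = leave RNG
#'   untouched).
#' @return Object of class `sim_config` (a list).
#' @export
sim_config <- function(n_controls = 18L,
                       read_depth = 100000L,
                       theta = 40000,
                       bin_noise_sd = 0.05,
                       n_bins_per_arm = 25L,
                       cohort_size = 29L,
                       hazard_ratio = 3,
                       os_median_low = 30,
                       pfs_median_low = 14,
                       censor_horizon = 120,
                       p_zero_tf = 0.45,
                       responder_prob = 0.5,
                       responder_range = c(0.05, 0.3),
                       nonresponder_range = c(0.8, 1.5),
                       progression_range = c(1.2, 3.0),
                       altered_arm_range = c(8L, 16L),
                       rank_targets = c(tf_ctc = 0.02, tf_cea = 0.26,
                                        tf_ca153 = 0.25, ctc_cea = 0.01,
                                        ctc_ca153 = 0.30, cea_ca153 = 0.41),
                       seed = NULL) {
  cfg <- list(n_controls = as.integer(n_controls),
              read_depth = as.integer(read_depth),
              theta = theta, bin_noise_sd = bin_noise_sd,
              n_bins_per_arm = as.integer(n_bins_per_arm),
              cohort_size = as.integer(cohort_size),
              hazard_ratio = hazard_ratio,
              os_median_low = os_median_low,
              pfs_median_low = pfs_median_low,
              censor_horizon = censor_horizon,
              p_zero_tf = p_zero_tf,
              responder_prob = responder_prob,
              responder_range = responder_range,
              nonresponder_range = nonresponder_range,
              progression_range = progression_range,
              altered_arm_range = as.integer(altered_arm_range),
              rank_targets = rank_targets,
              seed = seed)
  if (cfg$read_depth < 1000L) stop("read_depth must be >= 1000")
  if (cfg$theta <= 0) stop("theta must be > 0")
  if (cfg$n_controls < 3L) stop("n_controls must be >= 3")
  probs <- c(cfg$p_zero_tf, cfg$responder_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$bin_noise_sd < 0) stop("bin_noise_sd must be >= 0")
  class(cfg) <- "sim_config"
  cfg
}

# Dirichlet draw via normalized gammas; shape = theta * weights.
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

dm_counts_row <- function(weights, depth, theta) {
  p <- if (is.finite(theta) && theta < 1e8) rdirichlet1(theta * weights) else weights
  as.integer(stats::rmultinom(1L, size = depth, prob = p))
}

#' Simulate a healthy control panel's arm read counts
#'
#' Draws `n_controls` samples of Dirichlet-multinomial arm counts so that
#' arm fractions vary realistically between controls; every row sums to
#' the configured read depth exactly.
#'
#' @param catalog Arm catalog.
#' @param cfg [sim_config()].
#' @param seed Optional seed (defaults to `cfg$seed`).
#' @return Integer matrix (controls x arms) with dimnames; rows sum to
#'   `cfg$read_depth`.
#' @export
simulate_control_counts <- function(catalog, cfg = sim_config(),
                                    seed = cfg$seed) {
  if (!is.null(seed)) set.seed(seed)
  m <- t(vapply(seq_len(cfg$n_controls), function(i)
    dm_counts_row(catalog$weight, cfg$read_depth, cfg$theta),
    integer(nrow(catalog))))
  dimnames(m) <- list(sprintf("ctrl%02d", seq_len(cfg$n_controls)),
                      catalog$arm)
  m
}

#' Simulate a tumor sample's arm read counts
#'
#' Arm counts of a diploid/tumor mixture at tumor fraction `tf`: expected
#' fractions follow [expected_arm_fractions()], counts are
#' Dirichlet-multinomial at the configured depth.
#'
#' @param catalog Arm catalog.
#' @param profile `scna_profile`.
#' @param tf Tumor fraction in `[0, 1)`.
#' @param cfg [sim_config()].
#' @param seed Optional seed.
#' @return Named integer vector of arm counts summing to `cfg$read_depth`.
#' @export
simulate_tumor_counts <- function(catalog, profile, tf, cfg = sim_config(),
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- expected_arm_fractions(catalog, profile, tf)
  stats::setNames(dm_counts_row(p, cfg$read_depth, cfg$theta), catalog$arm)
}

#' Simulate binned log2 copy-number ratios
#'
#' Stand-in for shallow whole-genome copy-number profiling: each arm is
#' tiled with `cfg$n_bins_per_arm` bins whose expected log2 ratio is
#' `log2(((1 - tf) * 2 + tf * cn) / 2)` plus Gaussian noise.
#'
#' @inheritParams simulate_tumor_counts
#' @param noise_sd Bin noise sd; defaults to `cfg$bin_noise_sd`.
#' @return A `bin_series` data frame with columns `arm`, `start`, `end`
#'   (0-based half-open, 1 Mb bins) and `log2ratio`.
#' @export
simulate_bin_logratios <- function(catalog, profile, tf, cfg = sim_config(),
                                   noise_sd = cfg$bin_noise_sd, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (cfg$n_bins_per_arm < 1L) stop("n_bins_per_arm must be >= 1")
  nb <- cfg$n_bins_per_arm
  mu <- log2(((1 - tf) * 2 + tf * profile$copy_number) / 2)
  n <- nrow(catalog) * nb
  starts <- rep(seq_len(nb) - 1L, times = nrow(catalog)) * 1e6
  out <- data.frame(
    arm = rep(catalog$arm, each = nb),
    start = starts,
    end = starts + 1e6,
    log2ratio = rep(mu, each = nb) + stats::rnorm(n, 0, noise_sd),
    stringsAsFactors = FALSE)
  class(out) <- c("bin_series", "data.frame")
  out
}

#' Simulate a longitudinal metastatic cohort
#'
#' Generates, with full ground truth, everything the downstream pipeline
#' consumes: a healthy control panel, per-sample tumor arm counts and
#' (optionally) binned log2 ratios, a patient table with survival, and a
#' sample table with timepoint categories and true tumor fractions.
#'
#' Each patient receives a baseline tumor fraction (near zero with
#' probability `p_zero_tf`, otherwise Beta-distributed), a random
#' copy-number profile, and responder status; treatment and progression
#' samples scale the baseline fraction by the configured multipliers so
#' that on average progression > baseline >= treatment.  Overall and
#' progression-free survival are exponential with a multiplicative hazard
#' for the baseline genome-wide z-score >= 3 group (the z-score is measured
#' by scoring the simulated baseline counts against the simulated panel),
#' with uniform administrative censoring; OS >= PFS entry-wise by
#' construction.
#'
#' @param cfg [sim_config()].
#' @param seed Master seed (defaults to `cfg$seed`).
#' @param make_bins Also simulate a log2-ratio track per sample
#'   (default TRUE).
#' @return List of class `cohort_sim` with elements `patients`, `samples`,
#'   `controls` (count matrix), `counts` (sample count matrix), `bins`
#'   (named list of `bin_series` or NULL), `panel` (the fitted
#'   [build_reference_panel()]), `catalog`, `profiles`, `config`, `seed`.
#' @export
simulate_longitudinal_cohort <- function(cfg = sim_config(), seed = cfg$seed,
                                         make_bins = TRUE) {
  if (cfg$cohort_size < 2L) stop("cohort_size must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  catalog <- make_arm_catalog()
  controls <- simulate_control_counts(catalog, cfg, seed = NULL)
  panel <- build_reference_panel(controls)

  npat <- cfg$cohort_size
  pat_id <- sprintf("P%03d", seq_len(npat))
  subtype <- sample(c("HR+/HER2-", "HR-/HER2-", "HER2+"), npat,
                    replace = TRUE, prob = c(0.62, 0.10, 0.28))
  mets <- data.frame(bone_met = stats::rbinom(npat, 1, 0.69),
                     liver_met = stats::rbinom(npat, 1, 0.345),
                     lung_met = stats::rbinom(npat, 1, 0.448))
  # three-component baseline tumor-fraction mixture: a ctDNA-negative
  # spike, a main component centred near the tumor fraction whose
  # genome-wide z-score sits at the clinical cutoff (most treated
  # metastatic patients carry low ctDNA levels), and a minority high-burden
  # tail; together they put cohort baseline positivity near the one-third
  # reported for metastatic breast cancer while retaining extreme scores
  u <- stats::runif(npat)
  baseline_tf <- ifelse(
    u < cfg$p_zero_tf, stats::runif(npat, 0, 0.005),
    ifelse(u < cfg$p_zero_tf + (1 - cfg$p_zero_tf) * 0.85,
           pmin(0.8, stats::rlnorm(npat, log(0.115), 0.25)),
           stats::runif(npat, 0.25, 0.7)))
  responder <- stats::runif(npat) < cfg$responder_prob
  treat_mult <- ifelse(responder,
                       stats::runif(npat, cfg$responder_range[1], cfg$responder_range[2]),
                       stats::runif(npat, cfg$nonresponder_range[1], cfg$nonresponder_range[2]))
  prog_mult <- stats::runif(npat, cfg$progression_range[1], cfg$progression_range[2])
  n_alt <- sample(seq(cfg$altered_arm_range[1], cfg$altered_arm_range[2]),
                  npat, replace = TRUE)

  profiles <- lapply(seq_len(npat), function(i)
    random_scna_profile(catalog, n_alt[i], label = pat_id[i]))
  names(profiles) <- pat_id

  samples <- list(); counts <- list(); bins <- list()
  for (i in seq_len(npat)) {
    n_treat <- sample(1:3, 1L)
    tfs <- c(baseline_tf[i],
             pmin(0.9, baseline_tf[i] * treat_mult[i] *
                    stats::runif(n_treat, 0.8, 1.2)),
             pmin(0.9, baseline_tf[i] * prog_mult[i]))
    cats <- c("baseline", rep("treatment", n_treat), "progression")
    weeks <- c(0, sort(stats::runif(n_treat, 3, 20)),
               stats::runif(1, 22, 40))
    for (j in seq_along(tfs)) {
      sid <- sprintf("%s_S%d", pat_id[i], j)
      counts[[sid]] <- simulate_tumor_counts(catalog, profiles[[i]], tfs[j], cfg)
      if (make_bins)
        bins[[sid]] <- simulate_bin_logratios(catalog, profiles[[i]], tfs[j], cfg)
      samples[[sid]] <- data.frame(
        patient = pat_id[i], sample = sid, week = round(weeks[j], 1),
        category = cats[j], true_tf = tfs[j], stringsAsFactors = FALSE)
    }
  }
  count_mat <- do.call(rbind, counts)
  samples <- do.call(rbind, samples)
  rownames(samples) <- NULL

  # baseline z-score group drives the hazard
  base_ids <- samples$sample[samples$category == "baseline"]
  base_scores <- score_samples(count_mat[base_ids, , drop = FALSE], panel)
  zgroup <- base_scores$Z >= 3

  h_os <- log(2) / cfg$os_median_low
  h_pfs <- log(2) / cfg$pfs_median_low
  hr <- ifelse(zgroup, cfg$hazard_ratio, 1)
  t_pfs <- stats::rexp(npat, rate = h_pfs * hr)
  t_os <- t_pfs + stats::rexp(npat, rate = h_os * hr)
  cens <- stats::runif(npat, 0, cfg$censor_horizon)
  patients <- data.frame(
    patient = pat_id, subtype = subtype, mets,
    baseline_tf = baseline_tf, baseline_z = base_scores$Z,
    zgroup = zgroup, responder = responder,
    os_months = round(pmin(t_os, cens), 2),
    os_event = as.integer(t_os <= cens),
    pfs_months = round(pmin(t_pfs, cens), 2),
    pfs_event = as.integer(t_pfs <= cens),
    stringsAsFactors = FALSE)

  samples <- simulate_biomarkers(samples, cfg$rank_targets)

  out <- list(patients = patients, samples = samples, controls = controls,
              counts = count_mat,
              bins = if (make_bins) bins else NULL,
              panel = panel, catalog = catalog, profiles = profiles,
              config = cfg, seed = seed)
  class(out) <- "cohort_sim"
  out
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf(
    "Simulated cohort: %d patients, %d samples (seed %s)\n",
    nrow(x$patients), nrow(x$samples),
    if (is.null(x$seed)) "unset" else x$seed))
  invisible(x)
}

# Spearman target -> Pearson correlation of the Gaussian copula
spearman_to_pearson <- function(rho) 2 * sin(pi * rho / 6)

#' Attach co-biomarkers coupled to true tumor fraction
#'
#' Adds CTC counts (zero-inflated negative binomial), CEA and CA15-3
#' (lognormal) to a sample table via a Gaussian copula whose latent
#' correlations are calibrated so the requested Spearman rank correlations
#' with true tumor fraction are achieved asymptotically.
#'
#' @param samples Sample table with a `true_tf` column.
#' @param rank_targets Named vector with entries `tf_ctc`, `tf_cea`,
#'   `tf_ca153`, `ctc_cea`, `ctc_ca153`, `cea_ca153`.
#' @return `samples` with columns `ctc`, `cea`, `ca153` appended.
#' @export
simulate_biomarkers <- function(samples,
                                rank_targets = sim_config()$rank_targets) {
  rt <- rank_targets
  need <- c("tf_ctc", "tf_cea", "tf_ca153", "ctc_cea", "ctc_ca153", "cea_ca153")
  if (!all(need %in% names(rt)))
    stop("rank_targets must name: ", paste(need, collapse = ", "))
  R <- diag(4)
  R[1, 2] <- R[2, 1] <- spearman_to_pearson(rt["tf_ctc"])
  R[1, 3] <- R[3, 1] <- spearman_to_pearson(rt["tf_cea"])
  R[1, 4] <- R[4, 1] <- spearman_to_pearson(rt["tf_ca153"])
  R[2, 3] <- R[3, 2] <- spearman_to_pearson(rt["ctc_cea"])
  R[2, 4] <- R[4, 2] <- spearman_to_pearson(rt["ctc_ca153"])
  R[3, 4] <- R[4, 3] <- spearman_to_pearson(rt["cea_ca153"])
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop(sprintf("infeasible correlation matrix: smallest eigenvalue %.4g",
                 min(ev)))
  n <- nrow(samples)
  L <- chol(R + diag(1e-12, 4))
  Zlat <- matrix(stats::rnorm(n * 4), n, 4) %*% L
  # couple first latent coordinate to existing true tf by rank matching
  Zlat <- Zlat[order(Zlat[, 1]), , drop = FALSE][rank(samples$true_tf,
                                                      ties.method = "first"), ]
  u <- stats::pnorm(Zlat)
  pi0 <- 0.45  # zero-inflation of CTC counts
  q_ctc <- pmin(1 - 1e-12, pmax(0, (u[, 2] - pi0) / (1 - pi0)))
  samples$ctc <- ifelse(u[, 2] < pi0, 0L,
                        stats::qnbinom(q_ctc, size = 0.8, mu = 6))
  samples$cea <- round(stats::qlnorm(u[, 3], meanlog = log(4), sdlog = 1.1), 2)
  samples$ca153 <- round(stats::qlnorm(u[, 4], meanlog = log(35), sdlog = 0.9), 1)
  samples
}
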