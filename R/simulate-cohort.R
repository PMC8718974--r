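#' Simulation configuration
#'
#' Ground-truth parameters for the synthetic cohort, PET and expression
#' generators.  Defaults mirror the study conditions the pipeline is
#' meant for: a 51 / 25 two-group TSPO PET cohort, a choroid-plexus
#' volume group effect of about half a standard deviation, a planted
#' partial correlation of 0.34 between log10 CP volume and regional DVR,
#' a 6 mm scanner point-spread function, and a desk-scale transcriptome
#' (34 regions, 1500 genes).
#'
#' @param seed integer seed.
#' @param n_depressed,n_control group sizes.
#' @param cp_volume_effect standardized mean difference of log10 CP
#'   volume (depressed minus control), in SD units.
#' @param partial_r_cp_dvr target ICV- and group-adjusted partial
#'   correlation between log10 CP volume and regional DVR, |r| < 1.
#' @param kinetic_truth data frame `label, region, R1, k2, BPnd` of
#'   per-region reference-tissue parameters.
#' @param psf_fwhm scanner point-spread FWHM (mm).
#' @param noise_cov fractional TAC noise.
#' @param n_regions,n_genes,n_signal_genes transcriptome dimensions.
#' @param autocorr_length spatial correlation length of background gene
#'   expression (mm).
#' @param beta_signal loading of signal genes on the target map, in
#'   background-SD units.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_depressed = 51L, n_control = 25L,
                              cp_volume_effect = 0.46,
                              partial_r_cp_dvr = 0.34,
                              kinetic_truth = default_kinetic_truth(),
                              psf_fwhm = 6, noise_cov = 0.05,
                              n_regions = 34L, n_genes = 1500L,
                              n_signal_genes = 50L,
                              autocorr_length = 20,
                              beta_signal = 1) {
  cfg <- list(seed = as.integer(seed), n_depressed = as.integer(n_depressed),
              n_control = as.integer(n_control),
              cp_volume_effect = cp_volume_effect,
              partial_r_cp_dvr = partial_r_cp_dvr,
              kinetic_truth = kinetic_truth, psf_fwhm = psf_fwhm,
              noise_cov = noise_cov, n_regions = as.integer(n_regions),
              n_genes = as.integer(n_genes),
              n_signal_genes = as.integer(n_signal_genes),
              autocorr_length = autocorr_length, beta_signal = beta_signal)
  with(cfg, {
    if (n_depressed <= 0 || n_control <= 0 || n_regions <= 0 || n_genes <= 0)
      stop("config error: counts must be positive")
    if (abs(partial_r_cp_dvr) >= 1)
      stop("config error: |partial_r_cp_dvr| must be < 1")
    if (psf_fwhm < 0) stop("config error: psf_fwhm must be >= 0")
    if (n_signal_genes > n_genes)
      stop("config error: n_signal_genes > n_genes")
  })
  structure(cfg, class = "simulation_config")
}

#' Default per-region kinetic ground truth
#'
#' Plausible [11C]PK11195 reference-tissue parameters for the regions the
#' pipeline reads out (anterior cingulate, prefrontal cortex, insula,
#' choroid plexus, plus a reference-like grey parcel).
#'
#' @return Data frame `label, region, R1, k2, BPnd`.
#' @export
default_kinetic_truth <- function() {
  data.frame(
    label = 1:5,
    region = c("GM_ref", "ACC", "PFC", "INS", "CP"),
    R1 = c(1.0, 1.05, 1.0, 1.1, 0.9),
    k2 = c(0.10, 0.11, 0.10, 0.12, 0.09),
    BPnd = c(0.0, 0.25, 0.20, 0.30, 0.50))
}

#' Simulate a two-group cohort table with planted effects
#'
#' Generates a per-subject table shaped like a case-control
#' neuroimaging cohort.  Log10 choroid-plexus volume gets a linear
#' intracranial-volume dependence plus a group mean shift of
#' `cp_volume_effect` SDs; regional DVRs are built from the CP-volume
#' residual (after ICV and group) so that their ICV- and group-adjusted
#' partial correlation with log10 CP volume equals `partial_r_cp_dvr` in
#' expectation.  Lateral-ventricle exchange indices (SUVR, 30-60 min
#' AUC) carry a planted negative partial correlation of the same
#' construction; clinical scores and blood markers are group-shifted
#' noise of realistic location and spread.
#'
#' @param config a `simulation_config`.
#' @param partial_r_cp_exchange planted partial correlation between
#'   log10 CP volume and the exchange indices (default -0.25).
#' @return List of class `cohort_sim`: `table` (data frame) and `truth`
#'   (planted parameters and the latent CP-volume residual).
#' @export
simulate_cohort <- function(config = simulation_config(),
                            partial_r_cp_exchange = -0.25) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_depressed + config$n_control
  group <- factor(rep(c("depressed", "control"),
                      c(config$n_depressed, config$n_control)),
                  levels = c("control", "depressed"))
  g <- as.numeric(group == "depressed")

  icv <- stats::rnorm(n, 1.55e6, 1.55e5)
  z_icv <- as.numeric(scale(icv))

  # log10 CP volume: marginal SD sigma, ICV share rho_icv, group shift in
  # SD units, residual e kept as the latent driver of the planted
  # partial correlations.
  sigma <- 0.11; rho_icv <- 0.25; mu <- log10(1600)
  e <- stats::rnorm(n)
  l10cp <- mu + sigma * (rho_icv * z_icv + sqrt(1 - rho_icv^2) * e) +
    config$cp_volume_effect * sigma * g

  plant <- function(r, mean_, sd_) {
    mean_ + sd_ * (r * e + sqrt(1 - r^2) * stats::rnorm(n))
  }
  kt <- config$kinetic_truth
  dvr <- sapply(c("ACC", "PFC", "INS", "CP"), function(rg) {
    plant(config$partial_r_cp_dvr, 1 + kt$BPnd[kt$region == rg], 0.10)
  })
  colnames(dvr) <- paste0("dvr_", colnames(dvr))

  tab <- data.frame(
    id = sprintf("sub-%03d", seq_len(n)), group = group,
    age = round(stats::rnorm(n, 36.5, 7.5), 1),
    sex = sample(c("M", "F"), n, replace = TRUE, prob = c(0.34, 0.66)),
    bmi = round(stats::rnorm(n, 26.2 + 1.5 * g, 4.3), 1),
    icv = icv, cp_volume = 10^l10cp, log10_cp_volume = l10cp, dvr,
    lv_suvr = plant(partial_r_cp_exchange, 0.9, 0.12),
    auc_30_60 = plant(partial_r_cp_exchange, 250, 40),
    hdrs = pmax(0, round(stats::rnorm(n, 0.6 + 17.9 * g, 0.9 + 2.8 * g), 0)),
    ctq = pmax(25, round(stats::rnorm(n, 38 + 16 * g, 5.4 + 8.6 * g), 0)),
    pss = pmax(0, round(stats::rnorm(n, 10 + 16.7 * g, 5.9 - 1.6 * g), 0)),
    crp = pmax(0.05, stats::rnorm(n, 1.1 + 1.8 * g, 0.9 + 1.9 * g)),
    vegf = pmax(5, stats::rnorm(n, 136 - 54 * g, 48 + 7 * g)),
    albumin = stats::rnorm(n, 45, 2.5))
  structure(list(table = tab,
                 truth = list(config = config, e = e,
                              partial_r_cp_exchange = partial_r_cp_exchange,
                              sigma_log10cp = sigma, rho_icv = rho_icv)),
            class = "cohort_sim")
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf("cohort_sim: %d subjects (%s)\n", nrow(x$table),
              paste(levels(x$table$group), table(x$table$group),
                    sep = " = ", collapse = ", ")))
  invisible(x)
}
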