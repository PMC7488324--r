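# Desk-scale synthetic cohorts with planted structure: differentially
# altered driver genes, co-occurring pairs driven by a shared latent
# factor, genotype-linked exponential tumor growth, and genotype-linked
# progression-free survival. Every stage of the pipeline is testable on
# these cohorts without external data.

#' Configuration of a synthetic cohort
#'
#' Defaults describe the desk-scale study condition used throughout the
#' package: 40 responders vs 40 non-responders, 120 candidate driver
#' genes with background alteration rates drawn from `Beta(2, 23)`
#' (mean 8%, the typical frequency range of recurrent drivers), three
#' planted differential genes altered in 60% of responders vs 5% of
#' non-responders, and two planted responder-specific co-occurring pairs
#' whose latent co-alteration factor fires in 35% of responders vs 2% of
#' non-responders.
#'
#' @param n_resp,n_nonresp Samples per response group.
#' @param n_genes Total genes (background + planted).
#' @param background_shape1,background_shape2 Beta parameters of the
#'   background per-gene alteration-rate distribution.
#' @param planted_genes Number of planted differential genes.
#' @param rate_resp,rate_nonresp Alteration rates of planted genes per
#'   group.
#' @param planted_pairs Number of planted co-occurring pairs.
#' @param pair_factor_resp,pair_factor_nonresp Latent-factor firing
#'   probability per group; when the factor fires, both pair genes are
#'   altered (on top of independent background at `pair_background`).
#' @param pair_background Independent background rate of pair genes.
#' @param v0 Baseline tumor volume (mm^3).
#' @param growth_rate Per-day exponential growth rate of untreated
#'   tumors.
#' @param treatment_effect Reduction of the growth rate in
#'   genotype-responders (values above `growth_rate` shrink tumors).
#' @param observation_days Measurement days; day 0 is baseline.
#' @param volume_noise_sd Lognormal measurement noise SD (log scale).
#' @param pfs_scale Weibull scale (months) of the non-responder
#'   survival time.
#' @param pfs_shape Weibull shape.
#' @param pfs_hr Hazard ratio of genotype non-responders over
#'   responders.
#' @param censor_rate Fraction of patients with independently censored
#'   follow-up.
#' @param seed Mandatory integer seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_resp = 40, n_nonresp = 40, n_genes = 120,
                          background_shape1 = 2, background_shape2 = 23,
                          planted_genes = 3, rate_resp = 0.6,
                          rate_nonresp = 0.05, planted_pairs = 2,
                          pair_factor_resp = 0.35,
                          pair_factor_nonresp = 0.02,
                          pair_background = 0.03,
                          v0 = 150, growth_rate = 0.06,
                          treatment_effect = 0.12,
                          observation_days = seq(0, 28, by = 4),
                          volume_noise_sd = 0.05,
                          pfs_scale = 6, pfs_shape = 1.2, pfs_hr = 2.5,
                          censor_rate = 0.15, seed) {
  if (missing(seed)) {
    stop_dconet("`seed` is mandatory in a cohort configuration",
                "dconet_input_error")
  }
  rates <- c(rate_resp, rate_nonresp, pair_factor_resp, pair_factor_nonresp,
             pair_background, censor_rate)
  if (any(rates < 0 | rates > 1)) {
    stop_dconet("all rates must lie in [0, 1]", "dconet_input_error")
  }
  if (n_genes < planted_genes + 2 * planted_pairs) {
    stop_dconet("n_genes too small for the planted structure",
                "dconet_input_error")
  }
  structure(as.list(environment()), class = "cohort_config")
}

#' Simulate a driver-alteration matrix with planted structure
#'
#' Background genes are independent Bernoulli with gene-specific rates
#' drawn once from the configured beta distribution. Planted
#' differential genes are Bernoulli at group-specific rates. Each
#' planted pair gets a shared latent Bernoulli factor per sample (fired
#' with the group's factor probability); both genes are altered whenever
#' the factor fires, plus independent background alterations, so the
#' pair co-occurs above independence in the designated group while the
#' marginals stay configurable.
#'
#' @param config A [cohort_config()].
#' @return A list with `matrix` (an [alteration_matrix()]), `response`
#'   (tibble `sample_id`, `response` of the genotype-defined groups) and
#'   `truth` (planted gene and pair identities plus all background
#'   rates).
#' @export
simulate_alterations <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_resp + config$n_nonresp
  samples <- sprintf("S%03d", seq_len(n))
  is_resp <- c(rep(TRUE, config$n_resp), rep(FALSE, config$n_nonresp))
  genes <- sprintf("G%03d", seq_len(config$n_genes))
  planted <- genes[seq_len(config$planted_genes)]
  pair_genes <- genes[config$planted_genes +
                        seq_len(2 * config$planted_pairs)]
  pairs <- matrix(pair_genes, ncol = 2, byrow = TRUE)
  background <- setdiff(genes, c(planted, pair_genes))

  m <- matrix(0L, n, config$n_genes, dimnames = list(samples, genes))
  bg_rates <- rbeta(length(background), config$background_shape1,
                    config$background_shape2)
  for (i in seq_along(background)) {
    m[, background[i]] <- rbinom(n, 1, bg_rates[i])
  }
  for (g in planted) {
    m[, g] <- rbinom(n, 1, ifelse(is_resp, config$rate_resp,
                                  config$rate_nonresp))
  }
  for (p in seq_len(nrow(pairs))) {
    factor_p <- ifelse(is_resp, config$pair_factor_resp,
                       config$pair_factor_nonresp)
    fired <- rbinom(n, 1, factor_p)
    for (g in pairs[p, ]) {
      m[, g] <- pmin(1L, fired + rbinom(n, 1, config$pair_background))
    }
  }
  list(
    matrix = alteration_matrix(m),
    response = tibble::tibble(
      sample_id = samples,
      response = ifelse(is_resp, "responder", "non-responder")
    ),
    truth = list(planted_genes = planted,
                 planted_pairs = pairs,
                 background_genes = background,
                 background_rates = setNames(bg_rates, background))
  )
}

#' Simulate tumor-volume trajectories linked to genotype
#'
#' Each sample's tumor grows as
#' `V(t) = v0 * exp((g - e * responder) * t)` with multiplicative
#' lognormal measurement noise, where `responder` is the genotype label
#' from [simulate_alterations()]. With the default effect size,
#' genotype-responders shrink or stall (SD/PR/CR) and the rest progress
#' (PD).
#'
#' @param sim Output of [simulate_alterations()].
#' @param config The same [cohort_config()].
#' @param treatment_id Treatment identifier stamped on the series.
#' @return A tibble of observations: `model_id`, `treatment_id`, `day`,
#'   `volume_mm3`.
#' @export
simulate_volumes <- function(sim, config, treatment_id = "T1") {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed + 1L)
  resp <- sim$response$response == "responder"
  days <- config$observation_days
  purrr::map_dfr(seq_along(sim$response$sample_id), function(i) {
    rate <- config$growth_rate - config$treatment_effect * resp[i]
    noise <- if (config$volume_noise_sd > 0) {
      rlnorm(length(days), 0, config$volume_noise_sd)
    } else {
      rep(1, length(days))
    }
    noise[1] <- 1 # baseline measured exactly
    tibble::tibble(
      model_id = sim$response$sample_id[i],
      treatment_id = treatment_id,
      day = days,
      volume_mm3 = config$v0 * exp(rate * days) * noise
    )
  })
}

#' Simulate progression-free survival linked to genotype
#'
#' Event times are Weibull with the configured shape; genotype
#' non-responders carry the configured hazard ratio relative to
#' responders. Censoring is independent uniform over the follow-up
#' window at the configured rate.
#'
#' @inheritParams simulate_volumes
#' @return A tibble: `patient_id`, `duration_months`, `event`.
#' @export
simulate_pfs <- function(sim, config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed + 2L)
  n <- nrow(sim$response)
  resp <- sim$response$response == "responder"
  # Weibull PH: scale multiplies by hr^(-1/shape) for the high-risk group.
  scale <- config$pfs_scale *
    ifelse(resp, 1, config$pfs_hr^(-1 / config$pfs_shape))
  t_event <- rweibull(n, shape = config$pfs_shape, scale = scale)
  censored <- rbinom(n, 1, config$censor_rate) == 1
  t_cens <- runif(n, 0, pmax(t_event, 1e-6))
  duration <- ifelse(censored, t_cens, t_event)
  tibble::tibble(
    patient_id = sim$response$sample_id,
    duration_months = pmax(duration, 1e-3),
    event = as.integer(!censored)
  )
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper running [simulate_alterations()],
#' [simulate_volumes()] and [simulate_pfs()] under one configuration.
#'
#' @inheritParams simulate_alterations
#' @param treatment_id Treatment identifier for the volume series.
#' @return A list with `matrix`, `response`, `truth`, `volumes`,
#'   `outcomes`, and the `config`.
#' @export
simulate_cohort <- function(config, treatment_id = "T1") {
  sim <- simulate_alterations(config)
  sim$volumes <- simulate_volumes(sim, config, treatment_id)
  sim$outcomes <- simulate_pfs(sim, config)
  sim$config <- config
  sim
}
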