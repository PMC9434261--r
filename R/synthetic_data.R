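# Seeded generators that emulate the two instruments behind the study:
# a negative-ion TOF producing peak lists with ppm-scale error, sodium
# adduct envelopes and decoy peaks, and a UV/Vis spectrophotometer
# producing coupled-assay traces and rate tables under Michaelis-Menten,
# substrate-inhibition or diprotic-pH truth. Every generator takes a
# mandatory seed, runs in an isolated RNG scope, and attaches the full
# generating parameters as a `truth` attribute so the same dataset can
# be regenerated bit-identically.

.sim_truth <- function(seed, ...) {
  c(list(seed = seed), list(...))
}

#' Simulate a TOF peak list with known truth
#'
#' For each ladder species, each ion in the configured (z, k) grid is
#' retained independently with probability `ion_prob` (the base
#' deprotonated ion of each species is always kept, so every simulated
#' species is in principle recoverable). Observed m/z values are the
#' theoretical values scaled by `1 + (bias + N(0, sd)) * 1e-6`, i.e.
#' multiplicative, instrument-like ppm error. Decoy peaks are drawn
#' uniformly over the m/z range while avoiding a +/- 3 sd ppm window
#' around every true ion.
#'
#' @param species A `precursor_ladder` of species present in the sample.
#' @param seed Integer seed (mandatory).
#' @param ppm_bias Systematic calibration offset in ppm (default 15,
#'   matching the magnitude of observed-vs-expected offsets in practice).
#' @param ppm_sd Random ppm error standard deviation (default 5).
#' @param ion_prob Probability of retaining each non-base ion.
#' @param n_decoys Number of uniform decoy peaks to add.
#' @param cfg A [match_config()] giving the (z, k) grid to sample from.
#' @return A data frame of peaks (`mz`, plus true `species`, `z`, `k`,
#'   `decoy` columns for assessment) with the generating parameters in
#'   `attr(, "truth")`.
#' @export
simulate_peaklist <- function(species, seed, ppm_bias = 15, ppm_sd = 5,
                              ion_prob = 0.8, n_decoys = 0,
                              cfg = match_config()) {
  stopifnot(ppm_sd >= 0, ion_prob >= 0, ion_prob <= 1, n_decoys >= 0)
  withr::local_seed(seed)
  ions <- enumerate_ions(species, cfg)
  keep <- stats::runif(nrow(ions)) < ion_prob | ions$k == 0 & ions$z == 1
  ions <- ions[keep, , drop = FALSE]
  err <- ppm_bias + stats::rnorm(nrow(ions), 0, ppm_sd)
  peaks <- data.frame(mz = ions$mz * (1 + err * 1e-6),
                      species = ions$species, z = ions$z, k = ions$k,
                      decoy = FALSE)
  if (n_decoys > 0) {
    lo <- min(ions$mz) * 0.9; hi <- max(ions$mz) * 1.1
    guard <- 3 * max(ppm_sd, 1) * 1e-6
    draw <- function() {
      repeat {
        x <- stats::runif(1, lo, hi)
        if (all(abs(x - ions$mz) / ions$mz > guard)) return(x)
      }
    }
    peaks <- rbind(peaks, data.frame(
      mz = vapply(seq_len(n_decoys), function(i) draw(), numeric(1)),
      species = NA_character_, z = NA_integer_, k = NA_integer_,
      decoy = TRUE))
  }
  peaks <- peaks[order(peaks$mz), , drop = FALSE]
  rownames(peaks) <- NULL
  attr(peaks, "truth") <- .sim_truth(seed, species = species$species,
                                     ppm_bias = ppm_bias, ppm_sd = ppm_sd,
                                     ion_prob = ion_prob, n_decoys = n_decoys)
  peaks
}

.kinetic_model_v <- function(model, S, vmax, km, ki = NULL) {
  switch(model,
         MM = vmax * S / (km + S),
         SI = vmax * S / (km + S * (1 + S / ki)),
         stop("unknown model: ", model))
}

#' Simulate an initial-rate series
#'
#' `v = model(S) + N(0, (sigma * Vmax)^2)`, i.i.d. per replicate:
#' additive Gaussian noise scaled to the maximal rate, the usual error
#' structure for replicate initial-rate determinations.
#'
#' @param model `"MM"` or `"SI"`.
#' @param vmax,km,ki True parameters (ki only for `"SI"`).
#' @param S Substrate concentration grid (uM).
#' @param sigma Noise standard deviation as a fraction of `vmax`.
#' @param replicates Replicates per concentration.
#' @param seed Integer seed (mandatory).
#' @return Data frame `S`, `v`, `replicate`, with `attr(, "truth")`.
#' @export
simulate_rate_series <- function(model = c("MM", "SI"), vmax, km, ki = NULL,
                                 S, sigma = 0.05, replicates = 1, seed) {
  model <- match.arg(model)
  stopifnot(sigma >= 0, length(S) > 0, replicates >= 1)
  if (model == "SI" && is.null(ki)) stop("SI model needs ki")
  withr::local_seed(seed)
  grid <- expand.grid(S = S, replicate = seq_len(replicates),
                      KEEP.OUT.ATTRS = FALSE)
  mu <- .kinetic_model_v(model, grid$S, vmax, km, ki)
  out <- data.frame(S = grid$S,
                    v = mu + stats::rnorm(nrow(grid), 0, sigma * vmax),
                    replicate = grid$replicate)
  attr(out, "truth") <- .sim_truth(seed, model = model, vmax = vmax, km = km,
                                   ki = ki, S = S, sigma = sigma,
                                   replicates = replicates)
  out
}

#' Simulate a coupled-assay absorbance trace
#'
#' `A340(t) = A0 - v0 * [E] * epsilon * l * t + drift * t + N(0, sigma_A^2)`,
#' truncated at zero: a linear NADH-consumption time course with
#' additive detector noise and optional baseline drift.
#'
#' @param v0 True per-enzyme rate (ADP/s).
#' @param config An [assay_config()].
#' @param seed Integer seed (mandatory).
#' @param duration Trace length (s).
#' @param dt Sampling interval (s).
#' @param sigma_A Absorbance noise standard deviation.
#' @param drift Linear baseline drift (A/s).
#' @param A0 Starting absorbance.
#' @return Data frame `time`, `a340`, with `attr(, "truth")`.
#' @export
simulate_trace <- function(v0, config, seed, duration = 60, dt = 1,
                           sigma_A = 0, drift = 0, A0 = 1.0) {
  stopifnot(duration > 0, dt > 0, sigma_A >= 0)
  withr::local_seed(seed)
  t <- seq(0, duration, by = dt)
  a <- A0 - v0 * config$enzyme_conc * config$epsilon * config$path_length * t +
    drift * t + stats::rnorm(length(t), 0, sigma_A)
  out <- data.frame(time = t, a340 = pmax(a, 0))
  attr(out, "truth") <- .sim_truth(seed, v0 = v0, duration = duration,
                                   dt = dt, sigma_A = sigma_A, drift = drift,
                                   A0 = A0, epsilon = config$epsilon,
                                   path_length = config$path_length,
                                   enzyme_conc = config$enzyme_conc)
  out
}

#' Simulate a pH-rate profile
#'
#' Diprotic bell-model rates plus additive Gaussian noise scaled to the
#' optimum rate.
#'
#' @param vopt,pka1,pka2 True parameters (`pka1 < pka2`).
#' @param seed Integer seed (mandatory).
#' @param pH pH grid (default 5.7 to 9.7 in 0.5 steps, the span a bench
#'   buffer series covers).
#' @param sigma Noise standard deviation as a fraction of `vopt`.
#' @return Data frame `pH`, `v`, with `attr(, "truth")`.
#' @export
simulate_ph_profile <- function(vopt, pka1, pka2, seed,
                                pH = seq(5.7, 9.7, by = 0.5), sigma = 0.05) {
  stopifnot(pka1 < pka2, sigma >= 0)
  withr::local_seed(seed)
  mu <- vopt / (1 + 10^(pka1 - pH) + 10^(pH - pka2))
  out <- data.frame(pH = pH, v = mu + stats::rnorm(length(pH), 0, sigma * vopt))
  attr(out, "truth") <- .sim_truth(seed, vopt = vopt, pka1 = pka1,
                                   pka2 = pka2, pH = pH, sigma = sigma)
  out
}
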