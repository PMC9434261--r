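# Mur-ligase enzymology for the coupled ADP-release assay.
#
# Ligase-catalysed ADP release is coupled through pyruvate kinase and
# lactate dehydrogenase to stoichiometric NADH oxidation, read as a fall
# in A340. Rates are therefore expressed per enzyme: mol ADP . mol
# ligase^-1 . s^-1 ("ADP/s"), which makes Vmax and kcat numerically
# identical. All fitted constants are "apparent": they are obtained at
# fixed concentrations of the co-substrates (ATP, UDP-MurNAc-dipeptide).

#' Coupled-assay configuration
#'
#' @param epsilon NADH molar extinction coefficient at 340 nm
#'   (M^-1 cm^-1). Default 6220, the standard literature value.
#' @param path_length Cuvette path length (cm), default 1.
#' @param volume Assay volume (L), default 2e-4 (0.2 mL).
#' @param enzyme_conc Ligase concentration in the assay (M).
#' @return A list of class `assay_config`.
#' @export
assay_config <- function(epsilon = 6220, path_length = 1,
                         volume = 2e-4, enzyme_conc) {
  stopifnot(epsilon > 0, path_length > 0, volume > 0, enzyme_conc > 0)
  structure(list(epsilon = epsilon, path_length = path_length,
                 volume = volume, enzyme_conc = enzyme_conc),
            class = "assay_config")
}

#' Initial rate from an absorbance trace
#'
#' Fits a least-squares line to A340 versus time over the requested
#' window (the linear range of the time course) and converts the slope
#' to a per-enzyme rate: `v0 = (-slope) / (epsilon * l) / [E]` in mol
#' ADP . mol ligase^-1 . s^-1. A negative computed rate (absorbance
#' rising) is reported as-is and flagged, never clamped.
#'
#' @param trace Data frame with columns `time` (s, strictly increasing)
#'   and `a340`.
#' @param config An [assay_config()].
#' @param window Length-2 numeric, time span to fit; must lie within the
#'   trace and contain at least 3 points. Defaults to the whole trace.
#' @return A list of class `initial_rate`: `v0` (ADP/s), `slope` (A/s),
#'   `r_squared`, `n_points`, `window`, `negative_rate` flag.
#' @export
initial_rate <- function(trace, config, window = range(trace$time)) {
  stopifnot(is.data.frame(trace), all(c("time", "a340") %in% names(trace)))
  if (any(diff(trace$time) <= 0)) stop("trace time must be strictly increasing")
  if (length(window) != 2 || window[1] >= window[2])
    stop("window must be an increasing length-2 time span")
  if (window[1] < min(trace$time) || window[2] > max(trace$time))
    stop("window lies outside the trace")
  sel <- trace$time >= window[1] & trace$time <= window[2]
  if (sum(sel) < 3) stop("window must contain at least 3 points")
  fit <- stats::lm(a340 ~ time, data = trace[sel, ])
  slope <- unname(stats::coef(fit)[["time"]])
  sst <- sum((trace$a340[sel] - mean(trace$a340[sel]))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  v0 <- (-slope) / (config$epsilon * config$path_length) / config$enzyme_conc
  structure(list(v0 = v0, slope = slope, r_squared = r2,
                 n_points = sum(sel), window = window,
                 negative_rate = v0 < 0),
            class = "initial_rate")
}

.rate_df <- function(data) {
  if (is.list(data) && !is.data.frame(data)) data <- as.data.frame(data)
  stopifnot(is.data.frame(data), all(c("S", "v") %in% names(data)))
  stopifnot(all(data$S >= 0), all(is.finite(data$v)))
  data
}

.kfit <- function(model, data, fit, param_names) {
  n <- nrow(data)
  if (is.null(fit)) {
    return(structure(list(model = model, converged = FALSE, data = data,
                          diagnostics = "nonlinear least squares failed",
                          apparent = TRUE),
                     class = "kinetic_fit"))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e)
                   stats::setNames(rep(NA_real_, length(cf)), names(cf)))
  rss <- sum(stats::residuals(fit)^2)
  sst <- sum((data$v - mean(data$v))^2)
  r2 <- if (sst > 0) 1 - rss / sst else NA_real_
  out <- list(model = model, converged = TRUE,
              vmax = unname(cf[["Vmax"]]), km = unname(cf[["KM"]]),
              ki = if ("Ki" %in% names(cf)) unname(cf[["Ki"]]) else NULL,
              se = se, r_squared = r2, rss = rss, n = n,
              kcat = unname(cf[["Vmax"]]),          # per-enzyme rate units
              efficiency = unname(cf[["Vmax"]] / cf[["KM"]]),  # uM^-1 s^-1
              apparent = TRUE, data = data, fit = fit)
  structure(out, class = "kinetic_fit")
}

.nls_lm <- function(formula, data, start, lower) {
  # Levenberg-Marquardt first; if its post-fit model construction fails
  # (typically at a parameter boundary such as vanishing inhibition),
  # fall back to the bounded trust-region nl2sol ("port") solver.
  fit <- tryCatch(
    minpack.lm::nlsLM(formula, data = data, start = start, lower = lower,
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) NULL)
  if (!is.null(fit)) return(fit)
  tryCatch(
    stats::nls(formula, data = data, start = start, lower = lower,
               algorithm = "port",
               control = stats::nls.control(maxiter = 500, tol = 1e-10,
                                            warnOnly = FALSE)),
    error = function(e) NULL)
}

# Deterministic multi-start: try each start, keep the converged fit with
# the smallest residual sum of squares.
.nls_multistart <- function(formula, data, starts, lower) {
  best <- NULL
  for (st in starts) {
    f <- .nls_lm(formula, data, st, lower)
    if (!is.null(f) && (is.null(best) ||
        sum(stats::residuals(f)^2) < sum(stats::residuals(best)^2)))
      best <- f
  }
  best
}

# KM starting values: half-max crossing on the rising limb (robust to a
# substrate-inhibited declining arm), backed by substrate quantiles.
.km_starts <- function(data) {
  i_max <- which.max(data$v)
  rising <- data[data$S <= data$S[i_max], , drop = FALSE]
  half <- rising$S[which.min(abs(rising$v - max(data$v) / 2))]
  pos <- data$S[data$S > 0]
  out <- unique(c(half, stats::quantile(pos, c(0.1, 0.25, 0.5),
                                        names = FALSE)))
  out[out > 0]
}

#' Fit Michaelis-Menten kinetics
#'
#' Nonlinear least squares (Levenberg-Marquardt) of
#' `v = Vmax * S / (KM + S)`. Starting values are `Vmax0 = max(v)` and
#' `KM0 =` the substrate concentration nearest half-maximal rate.
#'
#' @param data Data frame with columns `S` (substrate, uM) and `v`
#'   (initial rate, ADP/s); at least 3 distinct `S` values.
#' @return A `kinetic_fit` with Vmax, KM, standard errors, R^2, kcat
#'   (= Vmax in per-enzyme units) and kcat/KM. A fit that fails to
#'   converge is returned flagged (`converged = FALSE`) with
#'   diagnostics, never silently defaulted.
#' @export
fit_michaelis_menten <- function(data) {
  data <- .rate_df(data)
  if (length(unique(data$S)) < 3)
    stop("Michaelis-Menten fit needs >= 3 distinct substrate concentrations")
  vmax0 <- max(data$v)
  starts <- lapply(.km_starts(data),
                   function(km0) list(Vmax = vmax0, KM = km0))
  fit <- .nls_multistart(v ~ Vmax * S / (KM + S), data, starts,
                         lower = c(Vmax = 1e-12, KM = 1e-12))
  .kfit("MM", data, fit, c("Vmax", "KM"))
}

#' Fit substrate-inhibition kinetics
#'
#' Nonlinear least squares of `v = Vmax * S / (KM + S * (1 + S/Ki))`,
#' the standard uncompetitive substrate-inhibition form. The fitted
#' curve has its maximum at `S* = sqrt(KM * Ki)`; as `Ki -> Inf` the
#' model reduces to Michaelis-Menten. Starting values as for
#' [fit_michaelis_menten()] plus `Ki0 = max(S)`.
#'
#' @param data Data frame with columns `S` and `v`; at least 4 distinct
#'   `S` values.
#' @return A `kinetic_fit` with Vmax, KM, Ki and the same reporting
#'   contract as [fit_michaelis_menten()].
#' @export
fit_substrate_inhibition <- function(data) {
  data <- .rate_df(data)
  if (length(unique(data$S)) < 4)
    stop("substrate-inhibition fit needs >= 4 distinct substrate concentrations")
  vmax0 <- max(data$v)
  # Fitted in terms of the inverse inhibition constant beta = 1/Ki, which
  # keeps the gradient well-conditioned as inhibition vanishes (beta -> 0,
  # the Michaelis-Menten limit); Ki and its standard error are recovered
  # by the delta method.
  starts <- list()
  for (km0 in .km_starts(data))
    for (b0 in c(1 / max(data$S), 0.1 / max(data$S)))
      starts <- c(starts, list(list(Vmax = vmax0, KM = km0, beta = b0)))
  fit <- .nls_multistart(v ~ Vmax * S / (KM + S * (1 + S * beta)), data,
                         starts,
                         lower = c(Vmax = 1e-12, KM = 1e-12, beta = 0))
  out <- .kfit("SI", data, fit, c("Vmax", "KM"))
  if (out$converged) {
    beta <- unname(stats::coef(fit)[["beta"]])
    out$ki <- if (beta > 0) 1 / beta else Inf
    se <- out$se
    i <- match("beta", names(se))
    names(se)[i] <- "Ki"
    se[i] <- if (beta > 0) se[i] / beta^2 else NA_real_
    out$se <- se
  }
  out
}

.aicc <- function(fit) {
  # Gaussian AICc from RSS; p counts the variance as a parameter.
  p <- length(stats::coef(fit$fit)) + 1
  n <- fit$n
  aic <- n * log(fit$rss / n) + 2 * p
  if (n - p - 1 > 0) aic + 2 * p * (p + 1) / (n - p - 1) else Inf
}

#' Compare Michaelis-Menten and substrate-inhibition fits
#'
#' Reports both coefficients of determination and selects the model with
#' the larger R^2 (the criterion used when comparing the two fits on a
#' shared data set); small-sample corrected AICc, which penalises the
#' extra Ki parameter, is reported as advisory.
#'
#' @param mm,si `kinetic_fit` objects fitted to the same data.
#' @return A list of class `model_comparison`: `selected` (`"MM"`,
#'   `"SI"` or `"tie"`), `r_squared`, `delta_r_squared`, `aicc`,
#'   `aicc_preferred`.
#' @export
compare_models <- function(mm, si) {
  stopifnot(inherits(mm, "kinetic_fit"), inherits(si, "kinetic_fit"),
            mm$model == "MM", si$model == "SI")
  if (!isTRUE(mm$converged) || !isTRUE(si$converged))
    stop("both fits must have converged")
  if (!isTRUE(all.equal(mm$data$v, si$data$v)))
    stop("fits must be on the same data")
  r2 <- c(MM = mm$r_squared, SI = si$r_squared)
  d <- r2[["SI"]] - r2[["MM"]]
  selected <- if (abs(d) < 1e-12) "tie" else if (d > 0) "SI" else "MM"
  aicc <- c(MM = .aicc(mm), SI = .aicc(si))
  structure(list(selected = selected, r_squared = r2,
                 delta_r_squared = d, aicc = aicc,
                 aicc_preferred = names(aicc)[which.min(aicc)]),
            class = "model_comparison")
}

#' Catalytic efficiency from a converged fit
#'
#' In per-enzyme rate units, `kcat = Vmax` (ADP/s is already s^-1 per
#' ligase), so efficiency is `kcat / KM`.
#'
#' @param fit A converged `kinetic_fit`.
#' @return A list with `kcat` (s^-1), `efficiency_uM` (uM^-1 s^-1) and
#'   `efficiency_M` (M^-1 s^-1, = 1e6 * the former).
#' @export
catalytic_efficiency <- function(fit) {
  stopifnot(inherits(fit, "kinetic_fit"), isTRUE(fit$converged))
  if (fit$km <= 0) stop("KM must be positive")
  list(kcat = fit$vmax, efficiency_uM = fit$vmax / fit$km,
       efficiency_M = fit$vmax / fit$km * 1e6)
}

#' Fit a diprotic bell-shaped pH-rate profile
#'
#' Fits `v(pH) = vopt / (1 + 10^(pKa1 - pH) + 10^(pH - pKa2))`, the
#' two-ionisation model in which activity requires one group
#' deprotonated and a second protonated. The optimum pH is the midpoint
#' `(pKa1 + pKa2)/2`, where the fitted curve is maximal. Data must cover
#' both flanks of the bell: a profile whose maximum sits at the edge of
#' the pH grid leaves one pKa unidentifiable and is rejected.
#'
#' @param profile Data frame with columns `pH` and `v` (>= 5 points).
#' @return A list of class `ph_bell_fit`: `vopt`, `pka1`, `pka2`,
#'   `optimum`, `r_squared`, `se`, plus the underlying `nls` fit.
#' @export
fit_ph_bell <- function(profile) {
  stopifnot(is.data.frame(profile), all(c("pH", "v") %in% names(profile)))
  profile <- profile[order(profile$pH), , drop = FALSE]
  if (nrow(profile) < 5) stop("pH-bell fit needs >= 5 pH points")
  mean_v <- tapply(profile$v, profile$pH, mean)
  peak <- which.max(mean_v)
  if (peak == 1L || peak == length(mean_v))
    stop("unidentifiable pH profile: maximum lies at the edge of the pH grid ",
         "(one-sided data cannot constrain both pKa values)")
  ph_opt <- as.numeric(names(mean_v)[peak])
  starts <- list(
    list(vopt = max(profile$v), pKa1 = ph_opt - 1, pKa2 = ph_opt + 1),
    list(vopt = max(profile$v), pKa1 = ph_opt - 0.5, pKa2 = ph_opt + 0.5),
    list(vopt = max(profile$v), pKa1 = ph_opt - 2, pKa2 = ph_opt + 2)
  )
  best <- NULL
  for (st in starts) {
    f <- .nls_lm(v ~ vopt / (1 + 10^(pKa1 - pH) + 10^(pH - pKa2)),
                 profile, start = st,
                 lower = c(vopt = 1e-12, pKa1 = 0, pKa2 = 0))
    if (!is.null(f) &&
        (is.null(best) || sum(stats::residuals(f)^2) <
           sum(stats::residuals(best)^2))) best <- f
  }
  if (is.null(best)) stop("pH-bell fit did not converge")
  cf <- stats::coef(best)
  if (cf[["pKa1"]] >= cf[["pKa2"]])
    stop("unidentifiable pH profile: fitted pKa1 >= pKa2")
  rss <- sum(stats::residuals(best)^2)
  sst <- sum((profile$v - mean(profile$v))^2)
  se <- tryCatch(summary(best)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  structure(list(vopt = unname(cf[["vopt"]]), pka1 = unname(cf[["pKa1"]]),
                 pka2 = unname(cf[["pKa2"]]),
                 optimum = unname((cf[["pKa1"]] + cf[["pKa2"]]) / 2),
                 r_squared = if (sst > 0) 1 - rss / sst else NA_real_,
                 se = se, fit = best),
            class = "ph_bell_fit")
}

#' Coupling-enzyme independence check
#'
#' The ADP-release assay is only valid if the measured ligase rate does
#' not depend on the concentration of the coupling enzymes. Given paired
#' rates at 1x and 2x coupling enzyme, this computes the per-pair rate
#' ratios, their mean and 95% confidence interval, and a two-tailed
#' one-sample t test of the ratio against 1. The verdict is
#' "independent" when the confidence interval contains 1.
#'
#' @param rates_1x,rates_2x Numeric vectors of paired rates (same
#'   conditions, 1x and 2x coupling enzymes).
#' @param conf_level Confidence level, default 0.95.
#' @return A list of class `coupling_check`: `mean_ratio`, `conf_int`,
#'   `t_statistic`, `p_value`, `independent`.
#' @export
coupling_control_check <- function(rates_1x, rates_2x, conf_level = 0.95) {
  if (length(rates_1x) != length(rates_2x))
    stop("rate series must be paired (equal lengths)")
  if (length(rates_1x) < 2) stop("need at least 2 paired rates")
  if (any(rates_1x == 0)) stop("zero rate in the 1x series: ratio undefined")
  ratio <- rates_2x / rates_1x
  if (stats::sd(ratio) <= 1e-12 * max(abs(ratio))) {
    ci <- rep(mean(ratio), 2)
    res <- list(statistic = if (mean(ratio) == 1) 0 else Inf,
                p.value = if (mean(ratio) == 1) 1 else 0)
  } else {
    tt <- stats::t.test(ratio, mu = 1, conf.level = conf_level)
    ci <- as.numeric(tt$conf.int)
    res <- list(statistic = unname(tt$statistic), p.value = tt$p.value)
  }
  structure(list(mean_ratio = mean(ratio), conf_int = ci,
                 t_statistic = res$statistic, p_value = res$p.value,
                 independent = ci[1] <= 1 && 1 <= ci[2]),
            class = "coupling_check")
}

#' Amino-acid specificity panel statistics
#'
#' Summarises replicate initial rates per amino-acid substrate (mean and
#' 95% t-distribution confidence interval) and tests each substrate
#' against the reference substrate with an unpaired two-tailed t test
#' (Welch unequal-variance form by default; the classic equal-variance
#' Student form is available by flag), plus a one-sample two-tailed test
#' of each group mean against zero. P values are reported unadjusted by
#' default, with optional Holm adjustment.
#'
#' @param panel Data frame with columns `substrate` and `v0` (replicate
#'   rates, ADP/s).
#' @param reference Substrate name serving as the reference (e.g.
#'   `"DL-DAP"`).
#' @param var_equal Use the classic Student test instead of Welch.
#' @param adjust Apply Holm adjustment to the pairwise p values.
#' @param conf_level Confidence level for the group CIs.
#' @return A data frame of class `specificity_panel`: one row per
#'   substrate with `n`, `mean`, `ci_lo`, `ci_hi`, `t_vs_ref`,
#'   `p_vs_ref`, `p_vs_zero`. Groups with fewer than 2 replicates are
#'   dropped with a warning.
#' @export
specificity_test <- function(panel, reference, var_equal = FALSE,
                             adjust = FALSE, conf_level = 0.95) {
  stopifnot(is.data.frame(panel), all(c("substrate", "v0") %in% names(panel)))
  counts <- table(panel$substrate)
  small <- names(counts)[counts < 2]
  if (length(small)) {
    warning("excluding groups with < 2 replicates: ",
            paste(small, collapse = ", "))
    panel <- panel[!panel$substrate %in% small, , drop = FALSE]
  }
  if (!reference %in% panel$substrate)
    stop("reference substrate '", reference, "' not in panel")
  ref_v <- panel$v0[panel$substrate == reference]
  groups <- unique(panel$substrate)
  rows <- lapply(groups, function(g) {
    v <- panel$v0[panel$substrate == g]
    m <- mean(v); s <- stats::sd(v); n <- length(v)
    half <- stats::qt(1 - (1 - conf_level) / 2, n - 1) * s / sqrt(n)
    if (g == reference) {
      tst <- 0; p <- 1
    } else if (s == 0 && stats::sd(ref_v) == 0) {
      tst <- if (m == mean(ref_v)) 0 else Inf
      p <- if (m == mean(ref_v)) 1 else 0
    } else {
      tt <- stats::t.test(v, ref_v, var.equal = var_equal)
      tst <- unname(tt$statistic); p <- tt$p.value
    }
    p0 <- if (s == 0) as.numeric(m != 0) * 0 + as.numeric(m == 0) else
      stats::t.test(v, mu = 0)$p.value
    data.frame(substrate = g, n = n, mean = m,
               ci_lo = m - half, ci_hi = m + half,
               t_vs_ref = tst, p_vs_ref = p, p_vs_zero = p0)
  })
  out <- do.call(rbind, rows)
  if (adjust) out$p_vs_ref <- stats::p.adjust(out$p_vs_ref, method = "holm")
  rownames(out) <- NULL
  attr(out, "reference") <- reference
  attr(out, "test") <- if (var_equal) "Student" else "Welch"
  class(out) <- c("specificity_panel", "data.frame")
  out
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("<kinetic fit:", if (x$model == "MM") "Michaelis-Menten"
      else "substrate inhibition", ">\n")
  if (!x$converged) {
    cat("  NOT CONVERGED:", x$diagnostics, "\n")
    return(invisible(x))
  }
  cat(sprintf("  Vmax (apparent): %.4g ADP/s   KM (apparent): %.4g uM\n",
              x$vmax, x$km))
  if (!is.null(x$ki)) cat(sprintf("  Ki (apparent): %.4g uM\n", x$ki))
  cat(sprintf("  kcat: %.4g s^-1   kcat/KM: %.4g uM^-1 s^-1   R^2: %.4f\n",
              x$kcat, x$efficiency, x$r_squared))
  invisible(x)
}
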