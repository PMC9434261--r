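# Coupled-assay rates, saturation-kinetics fitting and panel statistics.

mm_data <- function(vmax, km, S) data.frame(S = S, v = vmax * S / (km + S))
si_data <- function(vmax, km, ki, S)
  data.frame(S = S, v = vmax * S / (km + S * (1 + S / ki)))

test_that("initial_rate converts an A340 slope to a per-enzyme rate", {
  cfgA <- assay_config(epsilon = 6220, path_length = 1, enzyme_conc = 100e-9)
  t <- 0:60
  trace <- data.frame(time = t, a340 = 1 - 0.00622 * t)
  ir <- initial_rate(trace, cfgA)
  # 0.00622 A/s / 6220 = 1 uM NADH/s; over 0.1 uM enzyme -> 10 ADP/s
  expect_equal(ir$v0, 10, tolerance = 1e-9)
  expect_false(ir$negative_rate)
  flat <- initial_rate(data.frame(time = t, a340 = rep(0.9, 61)), cfgA)
  expect_equal(flat$v0, 0)
})

test_that("initial_rate validates its window and time axis", {
  cfgA <- assay_config(enzyme_conc = 1e-7)
  trace <- data.frame(time = 0:10, a340 = seq(1, 0.9, length.out = 11))
  expect_error(initial_rate(trace, cfgA, window = c(5, 20)), "outside")
  expect_error(initial_rate(trace, cfgA, window = c(3, 3.5)), "3 points")
  bad <- data.frame(time = c(0, 2, 1), a340 = c(1, 0.9, 0.95))
  expect_error(initial_rate(bad, cfgA), "increasing")
  rising <- data.frame(time = 0:10, a340 = seq(0.5, 0.6, length.out = 11))
  expect_true(initial_rate(rising, cfgA)$negative_rate)
})

test_that("initial_rate recovers a known rate from a noisy simulated trace", {
  cfgA <- assay_config(enzyme_conc = 100e-9)
  trace <- simulate_trace(2.5, cfgA, seed = 5, duration = 60, dt = 0.5,
                          sigma_A = 0.001)
  expect_equal(initial_rate(trace, cfgA)$v0, 2.5, tolerance = 0.05 * 2.5)
})

test_that("a noiseless trace is recovered essentially exactly", {
  cfgA <- assay_config(enzyme_conc = 100e-9)
  trace <- simulate_trace(3.2, cfgA, seed = 1, sigma_A = 0, drift = 0)
  expect_equal(initial_rate(trace, cfgA)$v0, 3.2, tolerance = 1e-9)
})

test_that("Michaelis-Menten fit recovers noiseless truth to < 1e-6 relative", {
  d <- mm_data(2, 50, c(5, 10, 25, 50, 100, 250, 500))
  f <- fit_michaelis_menten(d)
  expect_true(f$converged)
  expect_equal(f$vmax, 2, tolerance = 1e-6)
  expect_equal(f$km, 50, tolerance = 1e-6)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
  # analytic half-saturation property of the fitted curve
  expect_equal(f$vmax * f$km / (f$km + f$km), f$vmax / 2)
  expect_error(fit_michaelis_menten(mm_data(2, 50, c(10, 10, 20))), "distinct")
})

test_that("substrate-inhibition fit recovers noiseless truth and its optimum", {
  d <- si_data(3, 20, 400, c(2, 5, 10, 20, 50, 100, 200, 400, 800))
  f <- fit_substrate_inhibition(d)
  expect_equal(f$vmax, 3, tolerance = 1e-6)
  expect_equal(f$km, 20, tolerance = 1e-6)
  expect_equal(f$ki, 400, tolerance = 1e-6)
  # curve maximum at S* = sqrt(KM * Ki)
  s_star <- sqrt(f$km * f$ki)
  v_of <- function(S) f$vmax * S / (f$km + S * (1 + S / f$ki))
  expect_gt(v_of(s_star), v_of(s_star * 1.01))
  expect_gt(v_of(s_star), v_of(s_star * 0.99))
})

test_that("with enormous Ki the SI fit is indistinguishable from MM on MM data", {
  d <- mm_data(2, 50, c(5, 10, 25, 50, 100, 250, 500))
  mm <- fit_michaelis_menten(d)
  si <- fit_substrate_inhibition(d)
  expect_lt(abs(si$r_squared - mm$r_squared), 1e-6)
  expect_equal(si$vmax, mm$vmax, tolerance = 1e-3)
})

test_that("KM estimation bias is small over noisy simulations", {
  km_hat <- vapply(1:200, function(i) {
    d <- simulate_rate_series("MM", vmax = 2, km = 50,
                              S = c(5, 10, 25, 50, 100, 200, 350, 500),
                              sigma = 0.05, seed = 1000 + i)
    fit_michaelis_menten(d)$km
  }, numeric(1))
  expect_lt(abs(stats::median(km_hat) / 50 - 1), 0.10)
})

test_that("model comparison reports both R^2 and selects sensibly", {
  d_si <- simulate_rate_series("SI", vmax = 2, km = 50, ki = 250,
                               S = c(5, 10, 25, 50, 100, 200, 400, 600, 800, 1000),
                               sigma = 0.03, seed = 42)
  cmp <- compare_models(fit_michaelis_menten(d_si), fit_substrate_inhibition(d_si))
  expect_equal(cmp$selected, "SI")
  d_mm <- simulate_rate_series("MM", vmax = 2, km = 50,
                               S = c(5, 10, 25, 50, 100, 200, 400, 600, 800, 1000),
                               sigma = 0.03, seed = 43)
  cmp2 <- compare_models(fit_michaelis_menten(d_mm), fit_substrate_inhibition(d_mm))
  expect_lt(abs(cmp2$delta_r_squared), 0.03)  # below the noise floor
  expect_equal(cmp2$aicc_preferred, "MM")
  mm <- fit_michaelis_menten(mm_data(2, 50, c(5, 25, 50, 100, 500)))
  expect_equal(compare_models(mm, {
    si <- fit_substrate_inhibition(mm_data(2, 50, c(5, 25, 50, 100, 500)))
    si$r_squared <- mm$r_squared; si
  })$selected, "tie")
})

test_that("catalytic efficiency is Vmax/KM in per-enzyme units", {
  f <- fit_michaelis_menten(mm_data(2, 50, c(5, 10, 25, 50, 100, 250, 500)))
  eff <- catalytic_efficiency(f)
  expect_equal(eff$kcat, 2, tolerance = 1e-6)
  expect_equal(eff$efficiency_uM, 0.04, tolerance = 1e-6)
  expect_equal(eff$efficiency_M, eff$efficiency_uM * 1e6)
})

test_that("pH bell fit recovers a noiseless diprotic profile", {
  prof <- simulate_ph_profile(1, 6.5, 8.5, seed = 3, sigma = 0)
  f <- fit_ph_bell(prof)
  expect_equal(f$vopt, 1, tolerance = 1e-6)
  expect_equal(f$pka1, 6.5, tolerance = 1e-6)
  expect_equal(f$pka2, 8.5, tolerance = 1e-6)
  expect_equal(f$optimum, 7.5, tolerance = 1e-6)
  # the fitted curve's argmax equals the pKa midpoint
  grid <- seq(5, 10, by = 1e-3)
  pred <- f$vopt / (1 + 10^(f$pka1 - grid) + 10^(grid - f$pka2))
  expect_equal(grid[which.max(pred)], f$optimum, tolerance = 2e-3)
})

test_that("pH optimum is recovered within 0.2 units under 5% noise", {
  opts <- vapply(1:100, function(i)
    fit_ph_bell(simulate_ph_profile(1, 6.5, 8.5, seed = 2000 + i,
                                    sigma = 0.05))$optimum, numeric(1))
  expect_lt(stats::median(abs(opts - 7.5)), 0.2)
  expect_gt(mean(abs(opts - 7.5) <= 0.2), 0.9)
})

test_that("one-sided pH data is flagged unidentifiable", {
  prof <- simulate_ph_profile(1, 6.5, 8.5, seed = 4, pH = seq(3, 5.5, 0.5),
                              sigma = 0)
  expect_error(fit_ph_bell(prof), "unidentifiable")
})

test_that("coupling-enzyme independence verdicts follow the ratio CI", {
  r <- c(1.0, 1.1, 0.9, 1.05, 0.95)
  same <- coupling_control_check(r, r)
  expect_equal(same$mean_ratio, 1)
  expect_true(same$independent)
  shifted <- coupling_control_check(r, r * 1.5)
  expect_false(shifted$independent)
  expect_lt(shifted$p_value, 0.01)
  expect_error(coupling_control_check(r, r[-1]), "paired")
})

test_that("equal-mean noisy coupling series test as independent most of the time", {
  verdicts <- vapply(1:200, function(i) {
    withr::with_seed(3000 + i, {
      a <- rnorm(6, 2, 0.1); b <- rnorm(6, 2, 0.1)
      coupling_control_check(a, b)$independent
    })
  }, logical(1))
  expect_gte(mean(verdicts), 0.9)
})

test_that("specificity panel statistics behave on degenerate and clear cases", {
  panel <- data.frame(substrate = rep(c("DL-DAP", "L-Lys"), each = 3),
                      v0 = c(5, 5, 5, 5, 5, 5))
  out <- specificity_test(panel, reference = "DL-DAP")
  expect_equal(out$t_vs_ref[out$substrate == "L-Lys"], 0)
  expect_equal(out$p_vs_ref[out$substrate == "L-Lys"], 1)
  withr::with_seed(9, {
    strong <- data.frame(
      substrate = rep(c("DL-DAP", "L-Lys"), each = 5),
      v0 = c(rnorm(5, 10, 0.5), rnorm(5, 0.1, 0.5)))
    res <- specificity_test(strong, reference = "DL-DAP")
    expect_lte(res$p_vs_ref[res$substrate == "L-Lys"], 0.01)
    expect_true(all(res$ci_lo <= res$mean & res$mean <= res$ci_hi))
  })
})

test_that("specificity CI width shrinks like 1/sqrt(n)", {
  withr::with_seed(10, {
    v <- rnorm(64, 5, 1)
    w <- function(n) {
      p <- data.frame(substrate = c(rep("A", n), "B", "B"),
                      v0 = c(v[1:n], 1, 1.1))
      r <- specificity_test(p, reference = "A")
      r$ci_hi[r$substrate == "A"] - r$ci_lo[r$substrate == "A"]
    }
    expect_equal(w(16) / w(64), 2, tolerance = 0.6)
  })
})

test_that("groups with fewer than 2 replicates are excluded with a warning", {
  panel <- data.frame(substrate = c("DL-DAP", "DL-DAP", "DD-DAP"),
                      v0 = c(4, 5, 0.2))
  expect_warning(out <- specificity_test(panel, reference = "DL-DAP"),
                 "DD-DAP")
  expect_false("DD-DAP" %in% out$substrate)
})
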