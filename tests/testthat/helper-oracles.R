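# Independent oracles, kept deliberately separate from the package code
# paths they check.

# Per-atom brute-force mass: expands a formula string into individual
# atoms and sums an independently typed mass table (fewer digits than the
# package constants; agreement is asserted to 1e-6 Da).
oracle_atomic <- c(C = 12.0, H = 1.00782503, N = 14.00307401,
                   O = 15.99491462, P = 30.97376163)

oracle_mass_from_formula <- function(formula) {
  if (formula == "") return(0)
  m <- gregexpr("([CHNOP])([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([CHNOP])([0-9]*)", formula))[[1]]
  total <- 0
  for (p in parts) {
    el <- substr(p, 1, 1)
    n <- if (nchar(p) > 1) as.integer(substr(p, 2, nchar(p))) else 1L
    # one term per atom, not count * mass, to stay a genuine enumeration
    for (i in seq_len(n)) total <- total + oracle_atomic[[el]]
  }
  total
}

# All-pairs brute-force matcher: for every peak scan every ion, keep the
# in-tolerance ion with smallest |ppm| (ties: lower z then lower k).
oracle_match <- function(peak_mz, ions, tol_ppm) {
  out <- integer(length(peak_mz))
  for (i in seq_along(peak_mz)) {
    best <- NA_integer_
    for (j in seq_len(nrow(ions))) {
      ppm <- (peak_mz[i] - ions$mz[j]) / ions$mz[j] * 1e6
      if (abs(ppm) > tol_ppm) next
      if (is.na(best)) { best <- j; next }
      bppm <- abs((peak_mz[i] - ions$mz[best]) / ions$mz[best] * 1e6)
      if (abs(ppm) < bppm ||
          (abs(ppm) == bppm && (ions$z[j] < ions$z[best] ||
            (ions$z[j] == ions$z[best] && ions$k[j] < ions$k[best]))))
        best <- j
    }
    out[i] <- best
  }
  out
}
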