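# Independent oracles, written with explicit element-by-element loops so they
# share no code path with the package's vectorized implementations.

# Woolf allelic odds ratio by direct 2x2 arithmetic.
oracle_woolf <- function(case, control, orientation = "minor") {
  a_minor <- case$n_het + 2 * case$n_minor_hom
  a_major <- 2 * case$n_major_hom + case$n_het
  c_minor <- control$n_het + 2 * control$n_minor_hom
  c_major <- 2 * control$n_major_hom + control$n_het
  if (orientation == "minor") {
    a <- a_minor; b <- a_major; cc <- c_minor; d <- c_major
  } else {
    a <- a_major; b <- a_minor; cc <- c_major; d <- c_minor
  }
  list(log_or = log(a) + log(d) - log(b) - log(cc),
       se = sqrt(1 / a + 1 / b + 1 / cc + 1 / d))
}

# Cochran Q, I2 and DL tau2 by direct summation loops.
oracle_q_tau <- function(theta, se) {
  k <- length(theta)
  sw <- 0; swt <- 0; sw2 <- 0
  for (i in seq_len(k)) {
    w <- 1 / se[i]^2
    sw <- sw + w
    swt <- swt + w * theta[i]
    sw2 <- sw2 + w^2
  }
  mu <- swt / sw
  q <- 0
  for (i in seq_len(k)) q <- q + (theta[i] - mu)^2 / se[i]^2
  df <- k - 1
  tau2 <- (q - df) / (sw - sw2 / sw)
  if (tau2 < 0) tau2 <- 0
  i2 <- if (q > 0) max(0, (q - df) / q) * 100 else 0
  list(q = q, df = df, i_squared = i2, tau2 = tau2, mu = mu)
}

# Egger intercept by the closed-form simple-regression formulas.
oracle_egger_intercept <- function(theta, se) {
  x <- 1 / se
  y <- theta / se
  n <- length(x)
  sx <- 0; sy <- 0; sxy <- 0; sxx <- 0
  for (i in seq_len(n)) {
    sx <- sx + x[i]; sy <- sy + y[i]
    sxy <- sxy + x[i] * y[i]; sxx <- sxx + x[i]^2
  }
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  (sy - slope * sx) / n
}

# FPRP in log space: a different evaluation path from the direct ratio.
oracle_fprp_log <- function(alpha, power, prior) {
  1 / (1 + exp(log(power) - log(alpha) + log(prior) - log1p(-prior)))
}

# FPRP values computed with exact rational arithmetic (arbitrary-precision
# oracle), frozen.
fprp_exact_cases <- list(
  list(alpha = 0.05, power = 1, prior = 0.5, fprp = 0.047619047619047616),
  list(alpha = 1e-06, power = 0.9, prior = 0.0001, fprp = 0.010987924162554025),
  list(alpha = 0.001, power = 0.8, prior = 0.01, fprp = 0.11012235817575083),
  list(alpha = 0.0491, power = 0.63, prior = 0.25, fprp = 0.1895021227325357),
  list(alpha = 1e-08, power = 0.999, prior = 1e-05, fprp = 0.0009999900099999),
  list(alpha = 0.3, power = 0.2, prior = 0.9, fprp = 0.14285714285714285),
  list(alpha = 0.0007, power = 0.85, prior = 0.001, fprp = 0.45136513264054734),
  list(alpha = 0.04, power = 0.05, prior = 0.1, fprp = 0.8780487804878049),
  list(alpha = 1, power = 0.5, prior = 0.5, fprp = 0.6666666666666666),
  list(alpha = 1e-15, power = 0.95, prior = 0.0001, fprp = 1.0525263157783956e-11),
  list(alpha = 0.02, power = 0.4, prior = 0.3, fprp = 0.1044776119402985),
  list(alpha = 0.5, power = 0.7, prior = 0.02, fprp = 0.9722222222222222)
)

# Quick builders for synthetic effects and outcomes.
make_effect <- function(or, lo, hi, label = NA_character_) {
  effect_from_ci(or, lo, hi, label = label)
}

make_ci_outcome <- function(study, snp, or, lo, hi, n_ca = 500, n_co = 500) {
  study_outcome(study_id = study, year = 2010L, country = "X",
                ancestry = "European", snp = snp, design = "case_control",
                reported_or = or, ci_low = lo, ci_high = hi,
                n_cases = n_ca, n_controls = n_co)
}
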