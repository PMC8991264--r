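# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the discrepancy is a literal double loop over
# the defining sum, and raw-data reconstruction lets stats::aov cross-check
# the summary-statistic ANOVA.

# centered L2 discrepancy, straight from the defining double sum
cd2_slow <- function(x) {
  n <- nrow(x)
  s <- ncol(x)
  t1 <- (13 / 12)^s
  t2 <- 0
  for (i in seq_len(n)) {
    prod1 <- 1
    for (j in seq_len(s)) {
      d <- abs(x[i, j] - 0.5)
      prod1 <- prod1 * (1 + d / 2 - d^2 / 2)
    }
    t2 <- t2 + prod1
  }
  t3 <- 0
  for (i in seq_len(n)) {
    for (k in seq_len(n)) {
      prod2 <- 1
      for (j in seq_len(s)) {
        di <- abs(x[i, j] - 0.5)
        dk <- abs(x[k, j] - 0.5)
        prod2 <- prod2 * (1 + di / 2 + dk / 2 - abs(x[i, j] - x[k, j]) / 2)
      }
      t3 <- t3 + prod2
    }
  }
  sqrt(t1 - 2 * t2 / n + t3 / n^2)
}

# good-lattice columns written independently of the package internals;
# coprimality by checking every common divisor explicitly
glp_cols_oracle <- function(n, modulus) {
  coprime <- function(h) {
    divisors <- seq_len(modulus)
    common <- divisors[h %% divisors == 0 & modulus %% divisors == 0]
    identical(common, 1L) || identical(common, 1)
  }
  hs <- Filter(coprime, seq_len(modulus - 1L))
  cols <- sapply(hs, function(h) {
    u <- (seq_len(n) * h) %% modulus
    u[u == 0] <- modulus
    u
  })
  colnames(cols) <- hs
  cols
}

ten_level_factors <- function(s) {
  lapply(paste0("f", seq_len(s)), design_factor, levels = seq_len(10))
}

# raw replicate vectors reproducing a given mean and SE exactly
raw_from_summary <- function(mean, se, n) {
  base <- scale(seq_len(n))[, 1]          # mean 0, sd 1
  mean + base * se * sqrt(n)
}

# random valid kinetic parameter sets, one draw per call
random_params <- function(kind) {
  p <- list(
    mumax = runif(1, 0.02, 0.15),
    ks = runif(1, 2, 25),
    Yb = runif(1, 0.2, 0.6),
    Yp = runif(1, 5, 30),
    C0 = runif(1, 20, 45),
    X0 = runif(1, 0.2, 2)
  )
  if (kind == "contois") p$ks <- runif(1, 1, 10)
  if (kind == "andrews") p$ki <- runif(1, 40, 400)
  if (kind == "aibe") p$kp <- runif(1, 30, 300)
  do.call(kinetic_params, p)
}
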