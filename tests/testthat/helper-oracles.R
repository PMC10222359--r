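# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Numeric ODE integration of the two-compartment mass-balance system
# (gut amount, central amount) with a stiff solver; returns concentrations
# in ug/L and the amounts for mass-balance checks.
ode_profile <- function(times, ka, v, ke, f, dose) {
  rhs <- function(t, y, p) {
    with(as.list(c(y, p)), {
      list(c(-ka * agi, ka * agi - ke * a1, ke * a1))
    })
  }
  y0 <- c(agi = f * dose, a1 = 0, elim = 0)
  out <- deSolve::lsoda(y0, times, rhs, c(ka = ka, ke = ke),
                        rtol = 1e-10, atol = 1e-12)
  list(conc = out[, "a1"] / v * 1000,
       agi = out[, "agi"], a1 = out[, "a1"], elim = out[, "elim"])
}

# Dense design-matrix least squares for the crossover ANOVA, built
# column-by-column and solved via the normal equations. Returns the
# treatment contrast (T - R), its SE, the residual mean square and df.
lsq_crossover_oracle <- function(data) {
  data <- data[order(data$subject_id, data$period), ]
  subj <- sort(unique(data$subject_id))
  X <- cbind(1,
             as.numeric(data$sequence == "RT"),
             as.numeric(data$period == 2),
             as.numeric(data$treatment == "T"))
  for (s in subj[-1]) X <- cbind(X, as.numeric(data$subject_id == s))
  y <- data$ln_cmax
  # drop aliased columns (sequence is a linear combination of subjects)
  keep <- qr(X)$pivot[seq_len(qr(X)$rank)]
  Xk <- X[, sort(keep), drop = FALSE]
  tcol <- which(sort(keep) == 4)
  XtX <- crossprod(Xk)
  beta <- solve(XtX, crossprod(Xk, y))
  res <- y - Xk %*% beta
  df <- nrow(Xk) - ncol(Xk)
  mse <- sum(res^2) / df
  se <- sqrt(mse * solve(XtX)[tcol, tcol])
  list(lsm_diff = beta[tcol], se_diff = se, mse = mse, df = df)
}

# Second, independently written f2 evaluation.
f2_oracle <- function(r, t) {
  n <- length(r)
  ssd <- sum((r - t)^2)
  50 * log10(100 * (1 + ssd / n)^(-0.5))
}

# Monte-Carlo TOST power from the normal model on the log scale.
mc_tost_power <- function(cv, n, gmr, alpha = 0.05, nsim = 20000,
                          seed = 99) {
  set.seed(seed)
  sw <- sqrt(log(1 + (cv / 100)^2))
  df <- n - 2
  se_true <- sw * sqrt(2 / n)
  tcrit <- qt(1 - alpha, df)
  d <- rnorm(nsim, log(gmr), se_true)
  s2 <- sw^2 * rchisq(nsim, df) / df
  se_hat <- sqrt(s2 * 2 / n)
  lo <- d - tcrit * se_hat
  hi <- d + tcrit * se_hat
  mean(lo >= log(0.8) & hi <= log(1.25))
}

# Small complete balanced ln(Cmax) table for ANOVA tests.
make_nca_table <- function(n = 12, seed = 1, shift = 0, noise = 0.1) {
  set.seed(seed)
  asg <- rep(c("TR", "RT"), each = n / 2)
  rows <- lapply(seq_len(n), function(i) {
    base <- rnorm(1, log(600), 0.3)
    data.frame(subject_id = i, sequence = asg[i], period = 1:2,
               treatment = ifelse(substring(asg[i], 1:2, 1:2) == "T",
                                  "T", "R"))
  })
  tbl <- do.call(rbind, rows)
  subj_eff <- rnorm(n, log(600), 0.3)
  tbl$ln_cmax <- subj_eff[tbl$subject_id] +
    ifelse(tbl$treatment == "T", shift, 0) +
    rnorm(nrow(tbl), 0, noise)
  tibble::as_tibble(tbl)
}

table1_model <- function(...) pilotbe::pk_model(...)
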