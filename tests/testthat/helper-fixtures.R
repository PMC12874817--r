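# Shared fixtures and independent oracles, all built in code.

# Minimal two-covariate cure config used by recovery-style tests:
# one binary covariate, Weibull(1.2, 3) latency baseline.
toy_cure_config <- function(n, seed, b0 = 0.5, b1 = 1.0, beta1 = 0.7,
                            horizon = 12, dropout = 0.05) {
  cohort_config(
    n_subjects = n,
    covariates = list(list(name = "grp", levels = c("a", "b"),
                           probs = c(0.5, 0.5))),
    incidence = c(intercept = b0, grp_b = b1),
    latency = c(grp_b = beta1),
    baseline = list(shape = 1.2, scale = 3),
    censoring = list(horizon = horizon, dropout_rate = dropout),
    switching = list(p_transplant_short = 0, p_transplant_long = 0,
                     p_modality_switch = 0),
    seed = seed)
}

# The toy config has no modality covariate, so give subjects one for
# cohort-format completeness when needed.
toy_cohort <- function(n, seed, ...) {
  g <- generate_cohort(toy_cure_config(n, seed, ...))
  g$cohort$grp <- factor(g$cohort$grp, levels = c("a", "b"))
  g
}

# Brute-force product-limit estimator: recompute every risk set directly.
km_brute_force <- function(time, event, t_eval) {
  et <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(t_eval))
  for (i in seq_along(t_eval)) {
    s <- 1
    for (tt in et[et <= t_eval[i]]) {
      n_risk <- sum(time >= tt)
      d <- sum(time == tt & event == 1)
      s <- s * (1 - d / n_risk)
    }
    out[i] <- s
  }
  out
}

# Direct counting-process Breslow partial log-likelihood: expand nothing,
# just loop over event times and rows. theta is the full coefficient
# vector in fit_cox_counting order; X is the baseline covariate matrix.
cox_cp_loglik_direct <- function(ep, X, theta, mods, interaction,
                                 reference = "hemodialysis") {
  p <- ncol(X)
  bmod <- stats::setNames(c(0, theta[p + seq_along(mods)]), c(reference, mods))
  gmod <- stats::setNames(
    c(0, if (interaction) theta[p + length(mods) + seq_along(mods)]
      else numeric(length(mods))),
    c(reference, mods))
  lp0 <- if (p) unname(drop(X %*% theta[seq_len(p)])) else numeric(nrow(ep))
  taus <- sort(unique(ep$stop[ep$event == 1]))
  ll <- 0
  for (t in taus) {
    at_risk <- ep$start < t & t <= ep$stop
    risk <- exp(lp0[at_risk] + bmod[ep$modality[at_risk]] +
                  gmod[ep$modality[at_risk]] * t)
    ev <- which(ep$event == 1 & ep$stop == t)
    for (j in ev)
      ll <- ll + lp0[j] + bmod[ep$modality[j]] + gmod[ep$modality[j]] * t
    ll <- ll - length(ev) * log(sum(risk))
  }
  unname(ll)
}

# Iteratively refined grid search: maximizes f over a box by coordinate
# grids, shrinking the box each round; independent of any gradient code.
grid_maximize <- function(f, lower, upper, final_step) {
  centre <- (lower + upper) / 2
  width <- (upper - lower) / 2
  repeat {
    grids <- lapply(seq_along(centre), function(i)
      seq(centre[i] - width[i], centre[i] + width[i], length.out = 11))
    pts <- as.matrix(expand.grid(grids))
    vals <- apply(pts, 1, f)
    centre <- pts[which.max(vals), ]
    if (all(width / 5 <= final_step)) return(centre)
    width <- width / 4
  }
}

published_path <- function(file) {
  system.file("extdata", file, package = "cureterm", mustWork = TRUE)
}
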