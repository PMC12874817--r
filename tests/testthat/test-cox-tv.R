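test_that("episode splitting produces contiguous half-open spells", {
  ep <- episode_split(time = 5, event = 1, baseline_modality = "hemodialysis",
                      switches = data.frame(time = 2, modality = "transplant"))
  expect_equal(ep$start, c(0, 2))
  expect_equal(ep$stop, c(2, 5))
  expect_equal(ep$modality, c("hemodialysis", "transplant"))
  expect_equal(ep$event, c(0L, 1L))

  ep <- episode_split(time = 4, event = 0, baseline_modality = "peritoneal")
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$stop, 4)
  expect_equal(ep$event, 0L)

  expect_message(
    ep <- episode_split(time = 5, event = 0, baseline_modality = "hemodialysis",
                        switches = data.frame(time = 6, modality = "transplant")),
    "dropped 1 switch")
  expect_equal(nrow(ep), 1L)

  expect_error(
    episode_split(time = 5, event = 1, baseline_modality = "hemodialysis",
                  switches = data.frame(time = c(3, 2),
                                        modality = c("peritoneal", "transplant"))),
    "strictly increasing")
})

# small switching episode set used by several blocks below
toy_episodes <- function() {
  mk <- function(id, time, event, base, st = NULL, sm = NULL) {
    sw <- if (is.null(st)) data.frame(time = numeric(0), modality = character(0))
          else data.frame(time = st, modality = sm)
    cbind(id = id, episode_split(time, event, base, sw))
  }
  rbind(mk(1, 5.0, 1, "hemodialysis", 2.0, "transplant"),
        mk(2, 3.2, 1, "hemodialysis"),
        mk(3, 4.1, 0, "peritoneal", 1.5, "hemodialysis"),
        mk(4, 6.0, 1, "peritoneal"),
        mk(5, 2.5, 1, "hemodialysis", 1.0, "peritoneal"),
        mk(6, 7.0, 0, "hemodialysis", 3.0, "transplant"))
}

test_that("null log partial likelihood equals -sum log risk-set size", {
  ep <- toy_episodes()
  ep$x <- c(0.5, -1, 0.2, 1, 0.3, -0.5)[ep$id]
  # the null value of the partial likelihood does not depend on the terms
  fit <- fit_cox_counting(ep, covariates = "x", interaction = FALSE)
  taus <- sort(unique(ep$stop[ep$event == 1]))
  ll0 <- -sum(vapply(taus, function(t) {
    sum(ep$event == 1 & ep$stop == t) *
      log(sum(ep$start < t & t <= ep$stop))
  }, numeric(1)))
  expect_equal(unname(fit$loglik["null"]), ll0, tolerance = 1e-12)
})

test_that("counting-process estimates match a refined grid-search oracle", {
  ep <- toy_episodes()
  # 2 coefficients: one continuous covariate + peritoneal main effect,
  # transplant rows relabelled to keep the parameter space 2-D
  ep$modality[ep$modality == "transplant"] <- "hemodialysis"
  ep$x <- c(0.7, -0.4, 0.1, 1.1, -0.9, 0.3)[ep$id]
  fit <- fit_cox_counting(ep, covariates = "x", interaction = FALSE)
  oracle <- grid_maximize(function(th)
    cox_cp_loglik_direct(ep, as.matrix(ep[, "x", drop = FALSE]), th,
                         mods = "peritoneal", interaction = FALSE),
    lower = c(-4, -4), upper = c(4, 4), final_step = 1e-3)
  expect_equal(unname(fit$coefficients), unname(oracle), tolerance = 5e-3)
})

test_that("fitter agrees with coxph on episode data expanded at event times", {
  cfg <- default_cohort_config(n_subjects = 400, seed = 5)
  g <- generate_cohort(cfg)
  coh <- as_cohort_factors(g$cohort, cfg)
  ep <- merge_episode_covariates(g$episodes, coh, c("sex", "comorbidity"))
  fit <- fit_cox_counting(ep, covariates = c("sex", "comorbidity"),
                          interaction = TRUE)

  ee <- cureterm:::expand_at_event_times(
    ep[, c("id", "start", "stop", "event", "modality", "sex", "comorbidity")])
  for (m in c("peritoneal", "transplant")) {
    ee[[m]] <- as.numeric(ee$modality == m)
    ee[[paste0(m, "_time")]] <- ee[[m]] * ee$stop
  }
  ref <- survival::coxph(
    survival::Surv(start, stop, event) ~ sex + comorbidity + peritoneal +
      transplant + peritoneal_time + transplant_time,
    data = ee, cluster = id, ties = "breslow", robust = TRUE)
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-7)
  expect_equal(unname(fit$var_model), unname(ref$naive.var), tolerance = 1e-6)
  expect_equal(unname(fit$var_robust), unname(ref$var), tolerance = 1e-6)
  expect_equal(unname(fit$loglik["fitted"]), unname(ref$loglik[2]),
               tolerance = 1e-9)
})

test_that("without switches or interactions the fit reduces to standard Cox", {
  set.seed(12)
  n <- 200
  d <- data.frame(id = seq_len(n), start = 0,
                  stop = rexp(n, 0.4), modality = "hemodialysis",
                  x1 = rnorm(n), x2 = rbinom(n, 1, 0.5))
  d$event <- rbinom(n, 1, 0.7)
  d$event[which.max(d$stop)] <- 1L
  fit <- fit_cox_counting(d, covariates = c("x1", "x2"), interaction = FALSE)
  ref <- survival::coxph(survival::Surv(stop, event) ~ x1 + x2, data = d,
                         ties = "breslow")
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-8)
})

test_that("robust variance equals the explicit score-residual sandwich", {
  cfg <- default_cohort_config(n_subjects = 60, seed = 8)
  g <- generate_cohort(cfg)
  ep <- merge_episode_covariates(g$episodes, g$cohort, "comorbidity")
  names(ep)[names(ep) == "comorbidity"] <- "x"
  fit <- fit_cox_counting(ep, covariates = "x", interaction = FALSE)

  # direct residual algebra: loop over event times and rows
  theta <- fit$coefficients
  X <- as.matrix(ep[, "x", drop = FALSE])
  mods <- fit$modalities[-1]
  uvec <- function(j, t) {
    m <- ep$modality[j]
    c(X[j, ], as.numeric(mods == m))
  }
  risk <- function(j, t) exp(sum(uvec(j, t) * theta))
  taus <- sort(unique(ep$stop[ep$event == 1]))
  P <- length(theta)
  R <- matrix(0, nrow(ep), P)
  info <- matrix(0, P, P)
  for (t in taus) {
    at <- which(ep$start < t & t <= ep$stop)
    rr <- vapply(at, risk, numeric(1), t = t)
    U <- t(vapply(at, uvec, numeric(P), t = t))
    S0 <- sum(rr)
    ubar <- colSums(rr * U) / S0
    d_t <- sum(ep$event == 1 & ep$stop == t)
    S2 <- t(U) %*% (rr * U) / S0
    info <- info + d_t * (S2 - tcrossprod(ubar))
    for (i in seq_along(at)) {
      j <- at[i]
      isev <- ep$event[j] == 1 && ep$stop[j] == t
      R[j, ] <- R[j, ] + isev * (U[i, ] - ubar) -
        (d_t * rr[i] / S0) * (U[i, ] - ubar)
    }
  }
  Ui <- rowsum(R, ep$id)
  V <- solve(info)
  expect_equal(unname(fit$var_robust), unname(V %*% crossprod(Ui) %*% V),
               tolerance = 1e-8)

  # single subject: no between-cluster variation
  one <- ep[ep$id == ep$id[which(ep$event == 1)[1]], ]
  expect_error(fit_cox_counting(one, covariates = character()),
               "at least 2 subjects")
})

test_that("robust and model-based SEs agree on correctly specified data", {
  # plain PH data, no cure structure, one episode per subject
  set.seed(101)
  n <- 20000
  x <- rbinom(n, 1, 0.5)
  tt <- rexp(n, 0.3 * exp(0.6 * x))
  cens <- runif(n, 0, 10)
  d <- data.frame(id = seq_len(n), start = 0, stop = pmin(tt, cens),
                  event = as.integer(tt <= cens),
                  modality = sample(c("hemodialysis", "peritoneal"), n, TRUE),
                  x = x)
  fit <- fit_cox_counting(d, covariates = "x", interaction = FALSE)
  se_m <- sqrt(diag(fit$var_model))
  se_r <- sqrt(diag(robust_variance(fit)))
  expect_true(all(abs(se_r / se_m - 1) < 0.1))
})

test_that("coefficients recover truth on simulated switching PH data", {
  # exposure switches hemodialysis -> peritoneal at S ~ Exp(0.3);
  # piecewise-exponential event times with hazard 0.25 e^{0.5 x - 0.3 pd(t)}
  set.seed(202)
  n <- 20000
  x <- rbinom(n, 1, 0.5)
  sw <- rexp(n, 0.3)
  lam1 <- 0.25 * exp(0.5 * x)
  lam2 <- lam1 * exp(-0.3)
  u <- -log(runif(n))
  tt <- ifelse(u <= lam1 * sw, u / lam1, sw + (u - lam1 * sw) / lam2)
  horizon <- 10
  time <- pmin(tt, horizon)
  event <- as.integer(tt <= horizon)
  has_sw <- sw < time
  ep <- rbind(
    data.frame(id = seq_len(n), start = 0, stop = pmin(sw, time),
               modality = "hemodialysis",
               event = ifelse(has_sw, 0L, event), x = x),
    data.frame(id = which(has_sw), start = sw[has_sw], stop = time[has_sw],
               modality = "peritoneal", event = event[has_sw],
               x = x[has_sw]))
  ep <- ep[order(ep$id, ep$start), ]
  fit <- fit_cox_counting(ep, covariates = "x", interaction = FALSE)
  se <- sqrt(diag(robust_variance(fit)))
  truth <- c(x = 0.5, peritoneal = -0.3)
  expect_true(all(abs(fit$coefficients - truth) < 3 * se))
})

test_that("time-dependent hazard ratios reproduce the published narrative", {
  pub <- read.csv(published_path("published_cox_estimates.csv"))
  rows <- c("peritoneal", "peritoneal_time", "transplant", "transplant_time")
  coefs <- setNames(pub$coef[match(rows, pub$term)], rows)
  ses <- setNames(pub$se[match(rows, pub$term)], rows)
  fit <- cox_tv_from_estimates(coefs, se = ses)

  # hemodialysis vs peritoneal at the end of year one: 1.28
  expect_equal(round(time_dependent_hr(fit, "hemodialysis", "peritoneal", 1)$hr,
                     2), 1.28)
  # peritoneal vs hemodialysis at the end of year nine: 1.27
  expect_equal(round(time_dependent_hr(fit, "peritoneal", "hemodialysis", 9)$hr,
                     2), 1.27)
  # hemodialysis vs transplant at the end of year five: 4.62
  expect_equal(round(time_dependent_hr(fit, "hemodialysis", "transplant", 5)$hr,
                     2), 4.62)
  # the peritoneal/hemodialysis log-HR crosses zero near five years
  t_cross <- 0.3107 / 0.0607
  expect_equal(time_dependent_hr(fit, "peritoneal", "hemodialysis",
                                 t_cross)$hr, 1, tolerance = 1e-10)
  expect_equal(round(t_cross, 2), 5.12)

  expect_error(time_dependent_hr(fit, "nocturnal", "hemodialysis", 1),
               "unknown modality")
})

test_that("hazard-ratio inversion is an exact reciprocal", {
  cfg <- default_cohort_config(n_subjects = 300, seed = 15)
  g <- generate_cohort(cfg)
  ep <- merge_episode_covariates(g$episodes, g$cohort, "comorbidity")
  fit <- fit_cox_counting(ep, covariates = "comorbidity", interaction = TRUE)
  for (t in c(0.5, 2, 7)) {
    ab <- time_dependent_hr(fit, "peritoneal", "hemodialysis", t)$hr
    ba <- time_dependent_hr(fit, "hemodialysis", "peritoneal", t)$hr
    expect_equal(ab * ba, 1, tolerance = 1e-12)
  }
})
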