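test_that("config validation rejects malformed specifications", {
  expect_error(toy_cure_config(0, 1), "n_subjects")
  expect_error(
    cohort_config(10,
                  covariates = list(list(name = "sex", levels = c("m", "f"),
                                         probs = c(0.7, 0.4))),
                  incidence = c(intercept = 0), latency = c()),
    "sum to 1")
  expect_error(
    cohort_config(10,
                  covariates = list(list(name = "sex", levels = c("m", "f"),
                                         probs = c(0.5, 0.5))),
                  incidence = c(intercept = 0, nope_x = 1), latency = c()),
    "unknown incidence")
  cfg <- toy_cure_config(10, 1)
  cfg$censoring$horizon <- -1
  expect_error(do.call(cohort_config, unclass(cfg)[setdiff(names(unclass(cfg)),
                                                           "schema_version")]),
               "horizon")
})

test_that("covariate sampling matches its stated distribution", {
  cfg <- cohort_config(10,
                       covariates = list(list(name = "sex", levels = c("m", "f"),
                                              probs = c(1, 0))),
                       incidence = c(intercept = 0), latency = c())
  expect_true(all(sample_covariates(cfg, seed = 1)$sex == "m"))

  n <- 100000
  probs <- c(0.659, 0.279, 0.037, 0.011, 0.010, 0.004)
  cfg <- cohort_config(n,
                       covariates = list(list(
                         name = "race",
                         levels = c("white", "black", "asian", "ai", "nhpi", "other"),
                         probs = probs)),
                       incidence = c(intercept = 0), latency = c())
  tab <- sample_covariates(cfg, seed = 42)
  freq <- as.numeric(table(factor(tab$race, levels = cfg$covariates[[1]]$levels))) / n
  se <- sqrt(probs * (1 - probs) / n)
  expect_true(all(abs(freq - probs) < 3 * se))

  expect_identical(sample_covariates(cfg, seed = 7),
                   sample_covariates(cfg, seed = 7))
})

test_that("latent class assignment follows the logistic incidence model", {
  z <- cbind(intercept = rep(1, 100))
  expect_true(all(assign_latent_class(-50, z, seed = 1) == "long_term"))
  expect_error(assign_latent_class(Inf, z, seed = 1), "non-finite")

  n <- 50000
  z <- cbind(intercept = rep(1, n))
  frac <- mean(assign_latent_class(0, z, seed = 3) == "short_term")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n))

  # at the published all-reference incidence intercept the long-term
  # fraction is 1 - plogis(1.5854) = 0.1701
  p_long <- 1 - plogis(1.5854)
  frac_long <- mean(assign_latent_class(1.5854, z, seed = 4) == "long_term")
  expect_lt(abs(frac_long - p_long), 3 * sqrt(p_long * (1 - p_long) / n))
})

test_that("event-time sampling follows the PH Weibull model", {
  n <- 100000
  x <- matrix(0, n, 1)
  cls <- rep("short_term", n)
  tt <- sample_event_times(0, list(shape = 1, scale = 2), x, cls, seed = 5)
  # Weibull(1, 2) is exponential with mean 2
  expect_lt(abs(mean(tt) - 2), 3 * 2 / sqrt(n))

  tt2 <- sample_event_times(log(2), list(shape = 1, scale = 2),
                            matrix(1, n, 1), cls, seed = 6)
  expect_lt(abs(mean(tt2) - 1), 3 * 1 / sqrt(n))

  expect_identical(sample_event_times(0, list(shape = 1, scale = 2),
                                      x[1:4, , drop = FALSE],
                                      rep("long_term", 4), seed = 1),
                   rep(Inf, 4))
})

test_that("censoring takes the minimum of event, dropout and horizon", {
  out <- apply_censoring(c(3, Inf), list(horizon = 5, dropout_rate = 0),
                         seed = 1)
  expect_equal(out$time, c(3, 5))
  expect_equal(out$event, c(1L, 0L))

  # all-cured cohort: censoring times follow min(Exp(0.1), 21)
  n <- 50000
  out <- apply_censoring(rep(Inf, n), list(horizon = 21, dropout_rate = 0.1),
                         seed = 2)
  expect_true(all(out$event == 0))
  for (q in c(3, 8, 15)) {
    p_true <- 1 - exp(-0.1 * q)
    p_emp <- mean(out$time <= q)
    expect_lt(abs(p_emp - p_true), 3 * sqrt(p_true * (1 - p_true) / n))
  }
  expect_lt(abs(mean(out$time == 21) - exp(-0.1 * 21)), 0.01)
})

test_that("modality histories respect class enrichment and follow-up bounds", {
  g <- toy_cohort(500, seed = 9)
  subj <- data.frame(id = g$cohort$id, time = g$cohort$time,
                     event = g$cohort$event, latent_class = g$latent_class,
                     modality = rep("hemodialysis", 500))
  cfg0 <- toy_cure_config(500, 9)

  cfg0$switching <- list(p_transplant_short = 0, p_transplant_long = 0,
                         p_modality_switch = 0)
  h <- simulate_modality_history(cfg0, subj, seed = 1)
  expect_true(all(is.na(h$transplant_time)))
  expect_equal(nrow(h$episodes), 500)

  cfg0$switching <- list(p_transplant_short = 0, p_transplant_long = 1,
                         p_modality_switch = 0)
  h <- simulate_modality_history(cfg0, subj, seed = 2)
  expect_identical(!is.na(h$transplant_time), g$latent_class == "long_term")
  tx <- h$transplant_time[!is.na(h$transplant_time)]
  tj <- subj$time[!is.na(h$transplant_time)]
  expect_true(all(tx > 0 & tx < tj))
})

test_that("default config yields the registry-like 11% transplant fraction", {
  cfg <- default_cohort_config(n_subjects = 100000, seed = 21)
  g <- generate_cohort(cfg)
  frac <- mean(g$cohort$transplant)
  expect_lt(abs(frac - 0.11), 3 * sqrt(0.11 * 0.89 / 100000) + 0.005)
})

test_that("generated cohorts satisfy the latent-structure invariants", {
  g <- generate_cohort(default_cohort_config(n_subjects = 20000, seed = 13))
  # long-term subjects are never events
  expect_equal(sum(g$cohort$event[g$latent_class == "long_term"]), 0)
  # observed time respects censoring construction
  expect_true(all(g$cohort$time > 0 & g$cohort$time <= 21))
  expect_true(!anyNA(g$cohort))
  # episode table conserves follow-up and events
  ep <- g$episodes
  idf <- factor(ep$id, levels = g$cohort$id)
  expect_equal(as.numeric(tapply(ep$stop, idf, max)), g$cohort$time)
  expect_equal(unname(as.integer(tapply(ep$event, idf, sum))), g$cohort$event)

  # with no dropout and a huge horizon every short-term subject is an event
  cfg <- toy_cure_config(2000, 31, horizon = 1e6, dropout = 0)
  g2 <- generate_cohort(cfg)
  expect_true(all(g2$cohort$event[g2$latent_class == "short_term"] == 1))
})

test_that("cohort files round-trip exactly and are seed-deterministic", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  cfg <- default_cohort_config(n_subjects = 500, seed = 17)
  g1 <- generate_cohort(cfg, out_dir = dir1)
  g2 <- generate_cohort(cfg, out_dir = dir2)
  expect_identical(unname(tools::md5sum(file.path(dir1, "cohort.csv"))),
                   unname(tools::md5sum(file.path(dir2, "cohort.csv"))))
  expect_identical(unname(tools::md5sum(file.path(dir1, "episodes.csv"))),
                   unname(tools::md5sum(file.path(dir2, "episodes.csv"))))

  back <- read_cohort(file.path(dir1, "cohort.csv"))
  expect_equal(back, g1$cohort)
  back_ep <- read_episodes(file.path(dir1, "episodes.csv"))
  rownames(back_ep) <- NULL
  expect_equal(back_ep, g1$episodes)
})

test_that("observed event proportion matches the analytic generative value", {
  # categorical-only config so the covariate space is a finite product
  cfg <- cohort_config(
    n_subjects = 40000,
    covariates = list(list(name = "grp", levels = c("a", "b"),
                           probs = c(0.6, 0.4))),
    incidence = c(intercept = 0.5, grp_b = 0.8),
    latency = c(grp_b = 0.3),
    baseline = list(shape = 1.2, scale = 3),
    censoring = list(horizon = 8, dropout_rate = 0.05),
    switching = list(p_transplant_short = 0, p_transplant_long = 0,
                     p_modality_switch = 0),
    seed = 23)
  g <- generate_cohort(cfg)

  # oracle: numerical integration of P(T <= min(C, H)) per profile
  p_event_profile <- function(eta_inc, eta_lat) {
    k <- 1.2; lam <- 3; rho <- 0.05; H <- 8
    f <- function(t) {
      haz <- exp(eta_lat) * (k / lam) * (t / lam)^(k - 1)
      surv <- exp(-(t / lam)^k * exp(eta_lat))
      haz * surv * exp(-rho * t)
    }
    plogis(eta_inc) * stats::integrate(f, 0, H, rel.tol = 1e-10)$value
  }
  p_true <- 0.6 * p_event_profile(0.5, 0) + 0.4 * p_event_profile(1.3, 0.3)
  expect_lt(abs(mean(g$cohort$event) - p_true),
            3 * sqrt(p_true * (1 - p_true) / 40000))
})

test_that("config YAML round-trips through its versioned schema", {
  path <- withr::local_tempfile(fileext = ".yaml")
  cfg <- default_cohort_config(n_subjects = 100, seed = 3)
  write_cohort_config(cfg, path)
  back <- read_cohort_config(path)
  expect_equal(back$incidence, cfg$incidence)
  expect_equal(back$latency, cfg$latency)
  expect_equal(back$n_subjects, cfg$n_subjects)
  expect_error(read_cohort_config(withr::local_tempfile(lines = "a: 1",
                                                        fileext = ".yaml")),
               "schema_version")
})
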