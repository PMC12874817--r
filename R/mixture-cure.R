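#' Susceptibility (short-term class) probability
#'
#' Logistic incidence submodel: `pi(z) = exp(b'z) / (1 + exp(b'z))`,
#' evaluated overflow-safely. `1 - pi(z)` is the probability of belonging
#' to the long-term survivor class.
#'
#' @param b incidence coefficients (intercept first).
#' @param z incidence design vector or matrix with leading intercept column.
#' @return probabilities in (0, 1).
#' @export
susceptibility_probability <- function(b, z) {
  if (any(!is.finite(b)) || any(!is.finite(z)))
    stop("non-finite inputs to susceptibility_probability()")
  if (is.matrix(z)) logistic(drop(z %*% b)) else logistic(sum(b * z))
}

#' Population (mixture) survival
#'
#' `S(t) = pi * S_u(t) + 1 - pi`: the short-term class follows the proper
#' survival `S_u`, the long-term class never fails, so the population curve
#' plateaus at `1 - pi`.
#'
#' @param pi susceptibility probability in \[0, 1\].
#' @param s_u conditional (short-term) survival in \[0, 1\].
#' @return mixture survival in \[0, 1\].
#' @export
population_survival <- function(pi, s_u) {
  if (any(pi < 0 | pi > 1, na.rm = TRUE)) stop("pi must lie in [0, 1]")
  if (any(s_u < 0 | s_u > 1, na.rm = TRUE)) stop("s_u must lie in [0, 1]")
  pi * s_u + 1 - pi
}

#' E-step posterior weights
#'
#' Posterior probability that a subject belongs to the short-term class
#' given the current parameters: events are short-term by construction
#' (`w = 1`); a censored subject gets
#' `w = pi S_u(t) / (pi S_u(t) + 1 - pi)`. Under the zero-tail constraint a
#' subject censored beyond the last event time has `S_u = 0`, hence `w = 0`
#' whenever `pi < 1`.
#'
#' @param delta event indicators (0/1).
#' @param pi susceptibility probabilities.
#' @param s_u conditional survival evaluated at each subject's time.
#' @return weights in \[0, 1\], 1 for every event.
#' @export
e_step <- function(delta, pi, s_u) {
  num <- pi * s_u
  den <- num + 1 - pi
  w <- ifelse(delta == 1, 1, ifelse(den <= 0, 1, num / den))
  if (any(den <= 0 & delta == 0))
    message("e_step: pi = 1 with S_u = 0 for some subject(s); w set to 1")
  pmin(pmax(w, 0), 1)
}

# Weighted Bernoulli log-likelihood with fractional responses, stable form.
incidence_loglik <- function(eta, w) {
  sum(w * stats::plogis(eta, log.p = TRUE) +
        (1 - w) * stats::plogis(-eta, log.p = TRUE))
}

#' Weighted logistic (incidence) M-step
#'
#' Maximizes the weighted Bernoulli log-likelihood
#' `sum_j w_j log pi_j + (1 - w_j) log(1 - pi_j)` with fractional responses
#' by damped Newton iteration; converges when the gradient sup-norm falls
#' below `tol`.
#'
#' @param z design matrix with leading intercept column.
#' @param w responses in \[0, 1\].
#' @param start optional starting coefficients.
#' @param tol gradient sup-norm tolerance.
#' @param max_iter maximum Newton iterations.
#' @return list with `coef` (named), `loglik`, `iterations`.
#' @export
fit_incidence_weighted <- function(z, w, start = NULL, tol = 1e-8,
                                   max_iter = 100) {
  z <- as.matrix(z)
  if (any(w < 0 | w > 1)) stop("weights must lie in [0, 1]")
  if (qr(z)$rank < ncol(z)) stop("incidence design matrix is rank deficient")
  p <- ncol(z)
  b <- start %||% numeric(p)
  ll <- incidence_loglik(drop(z %*% b), w)
  for (it in seq_len(max_iter)) {
    eta <- drop(z %*% b)
    mu <- stats::plogis(eta)
    grad <- drop(crossprod(z, w - mu))
    if (max(abs(grad)) < tol) break
    info <- crossprod(z * (mu * (1 - mu)), z)
    step <- tryCatch(solve(info, grad),
                     error = function(e) stop("singular information in weighted logistic fit"))
    # Newton decrement: attainable log-likelihood gain of this step
    dec <- sum(step * grad) / 2
    # damped update: halve until the log-likelihood does not decrease
    fac <- 1
    repeat {
      b_new <- b + fac * step
      ll_new <- incidence_loglik(drop(z %*% b_new), w)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      fac <- fac / 2
      if (fac < 1e-8) stop("weighted logistic fit failed to make progress")
    }
    b <- b_new
    ll <- ll_new
    if (dec < 1e-12) break
    if (any(abs(b) > 20)) {
      worst <- colnames(z)[which.max(abs(b))] %||% which.max(abs(b))
      stop("separation in incidence fit: coefficient for '", worst,
           "' diverged beyond 20")
    }
  }
  names(b) <- colnames(z)
  list(coef = b, loglik = ll, iterations = it)
}

# --- weighted Cox machinery (latency M-step) --------------------------------

# Structures that depend only on (time, event, x): sorted copies, distinct
# event times, tie-block starts and event counts. Hoisted out of both the
# Newton loop and the EM loop.
latency_prep <- function(time, event, x) {
  ord <- order(time)
  tt <- time[ord]
  dd <- event[ord]
  xx <- as.matrix(x)[ord, , drop = FALSE]
  et <- unique(tt[dd == 1])
  ei <- match(et, tt)                  # block start of each tied time
  d <- as.numeric(tabulate(match(tt[dd == 1], et), nbins = length(et)))
  p <- ncol(xx)
  xev_sum <- if (p > 0) colSums(xx[dd == 1, , drop = FALSE]) else numeric(0)
  list(ord = ord, tt = tt, dd = dd, xx = xx, et = et, ei = ei, d = d,
       xev_sum = xev_sum, p = p, n = length(tt))
}

# Weighted partial likelihood, score and information at beta (Breslow).
latency_eval <- function(prep, ww, beta) {
  p <- prep$p
  lp <- if (p) drop(prep$xx %*% beta) else numeric(prep$n)
  r <- ww * exp(lp)
  S0 <- revcumsum(r)[prep$ei]
  ll <- sum(lp[prep$dd == 1]) - sum(prep$d * log(S0))
  if (p == 0) return(list(loglik = ll, grad = numeric(0),
                          info = matrix(0, 0, 0), S0 = S0))
  S1 <- matrix(0, length(prep$et), p)
  for (j in seq_len(p)) S1[, j] <- revcumsum(r * prep$xx[, j])[prep$ei]
  m <- S1 / S0
  grad <- prep$xev_sum - colSums(prep$d * m)
  info <- matrix(0, p, p)
  for (j in seq_len(p)) for (k in seq_len(j)) {
    S2jk <- revcumsum(r * prep$xx[, j] * prep$xx[, k])[prep$ei]
    v <- sum(prep$d * (S2jk / S0 - m[, j] * m[, k]))
    info[j, k] <- v
    info[k, j] <- v
  }
  list(loglik = ll, grad = grad, info = info, S0 = S0)
}

# Damped Newton on the weighted partial likelihood. Convergence when the
# score sup-norm drops below tol or the Newton decrement g'H^{-1}g/2 —
# the expected remaining log-likelihood gain, which stays meaningful when
# score entries are sums of many large terms — falls below 1e-10.
latency_fit_core <- function(prep, ww, start = NULL, tol = 1e-8,
                             max_iter = 100) {
  p <- prep$p
  beta <- start %||% numeric(p)
  cur <- latency_eval(prep, ww, beta)
  if (p > 0) {
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      if (max(abs(cur$grad)) < tol) { converged <- TRUE; break }
      step <- tryCatch(solve(cur$info, cur$grad),
                       error = function(e) stop("singular information in weighted Cox fit"))
      dec <- sum(step * cur$grad) / 2
      fac <- 1
      repeat {
        beta_new <- beta + fac * step
        nxt <- latency_eval(prep, ww, beta_new)
        if (is.finite(nxt$loglik) && nxt$loglik >= cur$loglik - 1e-12) break
        fac <- fac / 2
        if (fac < 1e-8) stop("weighted Cox fit failed to make progress")
      }
      beta <- beta_new
      cur <- nxt
      if (dec < 1e-12) { converged <- TRUE; break }
      if (any(abs(beta) > 20))
        stop("monotone partial likelihood: coefficient '",
             (colnames(prep$xx)[which.max(abs(beta))] %||% which.max(abs(beta))),
             "' diverged beyond 20; data cannot identify the latency model")
    }
    if (!converged)
      warning("weighted Cox Newton did not reach convergence tolerance")
  }
  hazard <- prep$d / cur$S0
  cumhaz <- cumsum(hazard)
  basehaz <- data.frame(time = prep$et, hazard = hazard, cumhaz = cumhaz,
                        s0 = exp(-cumhaz))
  names(beta) <- colnames(prep$xx)
  structure(list(beta = beta, basehaz = basehaz, tmax = max(prep$et),
                 loglik = cur$loglik, dist = "semiparametric"),
            class = "latency_model")
}

#' Weighted Cox (latency) M-step with Breslow baseline
#'
#' Maximizes the weighted partial likelihood in which subject `k`
#' contributes `w_k exp(beta'x_k)` to every risk set (Breslow tie handling;
#' events must carry weight 1), then sets the baseline hazard increment at
#' each event time to `d_i / sum_{at risk} w_k exp(beta'x_k)` and the
#' baseline survival to `exp(-cumulative hazard)`, forced to zero beyond the
#' largest event time (the zero-tail constraint that identifies the cure
#' fraction).
#'
#' @param time follow-up times (> 0).
#' @param event event indicators (0/1); at least one event required.
#' @param x latency design matrix (no intercept); may have zero columns.
#' @param w weights in \[0, 1\]; must be 1 wherever `event == 1`.
#' @param start optional starting coefficients.
#' @param tol gradient sup-norm tolerance.
#' @param max_iter maximum Newton iterations.
#' @return object of class `latency_model`: `beta`, `basehaz`
#'   (data.frame `time,hazard,cumhaz,s0` over distinct event times),
#'   `tmax` (largest event time), `loglik` (weighted partial likelihood),
#'   `dist = "semiparametric"`.
#' @export
fit_latency_weighted <- function(time, event, x, w, start = NULL,
                                 tol = 1e-8, max_iter = 100) {
  if (!any(event == 1)) stop("no events: latency submodel cannot be fitted")
  if (any(w[event == 1] < 1 - 1e-8))
    stop("all events must carry weight 1 in the latency M-step")
  prep <- latency_prep(time, event, x)
  latency_fit_core(prep, w[prep$ord], start = start, tol = tol,
                   max_iter = max_iter)
}

# Parametric Weibull latency M-step behind the same interface: weighted
# Weibull PH fit via survreg's AFT parameterization (k = 1/scale,
# lambda = exp(intercept), beta_PH = -beta_AFT / scale).
fit_latency_weibull <- function(time, event, x, w, ...) {
  x <- as.matrix(x)
  if (!any(event == 1)) stop("no events: latency submodel cannot be fitted")
  keep <- w > 1e-10
  df <- data.frame(.time = time[keep], .event = event[keep])
  p <- ncol(x)
  fml <- if (p > 0) {
    df <- cbind(df, as.data.frame(x[keep, , drop = FALSE]))
    stats::reformulate(colnames(x), response = quote(survival::Surv(.time, .event)))
  } else survival::Surv(.time, .event) ~ 1
  sr <- survival::survreg(fml, data = df, weights = w[keep], dist = "weibull")
  shape <- 1 / sr$scale
  scale <- exp(stats::coef(sr)[1])
  beta <- if (p > 0) -stats::coef(sr)[-1] / sr$scale else numeric(0)
  names(beta) <- colnames(x)
  structure(list(beta = beta, shape = unname(shape), scale = unname(scale),
                 loglik = sr$loglik[2], dist = "weibull"),
            class = "latency_model")
}

#' Baseline survival of a latency model
#'
#' For the semiparametric model this is the Breslow step function with the
#' zero-tail constraint (`s0(t) = 0` beyond the largest event time); for the
#' Weibull variant the closed form `exp(-(t/scale)^shape)`.
#'
#' @param latency a `latency_model`.
#' @param times evaluation times (>= 0).
#' @return baseline survival values.
#' @export
baseline_survival <- function(latency, times) {
  if (latency$dist == "weibull")
    return(exp(-(times / latency$scale)^latency$shape))
  idx <- findInterval(times, latency$basehaz$time)
  s0 <- c(1, latency$basehaz$s0)[idx + 1L]
  s0[times > latency$tmax] <- 0
  s0
}

# Conditional (short-term) survival S_u(t; x) = s0(t)^exp(beta'x).
latency_survival <- function(latency, times, eta) {
  baseline_survival(latency, times)^exp(eta)
}

# Observed-data log-likelihood of the mixture under the discrete-hazard
# (Breslow) or Weibull latency parameterization.
observed_loglik <- function(delta, time, pi, latency, eta_x) {
  s_u <- latency_survival(latency, time, eta_x)
  ll_cens <- log(pmax(pi * s_u + 1 - pi, 1e-300))
  if (latency$dist == "weibull") {
    log_h0 <- log(latency$shape / latency$scale) +
      (latency$shape - 1) * log(pmax(time, 1e-300) / latency$scale)
  } else {
    hz <- latency$basehaz$hazard[match(time, latency$basehaz$time)]
    log_h0 <- log(pmax(hz, 1e-300))
  }
  ll_ev <- log(pmax(pi, 1e-300)) + log_h0 + eta_x + log(pmax(s_u, 1e-300))
  sum(ifelse(delta == 1, ll_ev, ll_cens))
}

# EM driver on prepared matrices; shared by fit_mixture_cure and the
# bootstrap so resamples avoid re-parsing formulas.
em_mixture_cure <- function(time, event, x, z, latency_dist = "semiparametric",
                            eps = 1e-7, max_iter = 200,
                            init_b = NULL, init_beta = NULL) {
  n <- length(time)
  semi <- latency_dist == "semiparametric"
  if (!semi && latency_dist != "weibull")
    stop("unknown latency_dist: ", latency_dist)
  prep <- if (semi) latency_prep(time, event, x) else NULL
  fit_lat <- function(w, start = NULL) {
    if (semi) latency_fit_core(prep, w[prep$ord], start = start)
    else fit_latency_weibull(time, event, x, w)
  }
  b <- init_b %||% tryCatch(fit_incidence_weighted(z, event)$coef,
                            error = function(e) {
                              out <- numeric(ncol(z))
                              names(out) <- colnames(z)
                              out
                            })
  latency <- fit_lat(rep(1, n), start = init_beta)
  trace <- numeric(0)
  converged <- FALSE
  ll_prev <- -Inf
  for (it in seq_len(max_iter)) {
    pi <- logistic(drop(z %*% b))
    eta_x <- if (length(latency$beta)) drop(x %*% latency$beta) else numeric(n)
    w <- e_step(event, pi, latency_survival(latency, time, eta_x))
    b <- fit_incidence_weighted(z, w, start = b)$coef
    latency <- fit_lat(w, start = latency$beta)
    eta_x <- if (length(latency$beta)) drop(x %*% latency$beta) else numeric(n)
    ll <- observed_loglik(event, time, logistic(drop(z %*% b)), latency, eta_x)
    trace <- c(trace, ll)
    if (is.finite(ll_prev) &&
        abs(ll - ll_prev) < eps * (abs(ll_prev) + 0.1)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
  }
  list(b = b, latency = latency, loglik = ll, loglik_trace = trace,
       iterations = it, converged = converged)
}

#' Fit a proportional-hazards mixture cure model by EM
#'
#' Population survival is modelled as
#' `S(t; x, z) = pi(z) S_u(t; x) + 1 - pi(z)` with logistic incidence
#' `pi(z)` and proportional-hazards latency
#' `S_u(t; x) = s0(t)^exp(beta'x)`. Estimation alternates an E-step
#' (posterior short-term weights) with weighted-logistic and weighted-Cox
#' M-steps until the observed-data log-likelihood stabilizes. The
#' semiparametric latency uses a weighted Breslow baseline with the
#' zero-tail constraint; a parametric Weibull latency is available behind
#' the same interface for cross-checking.
#'
#' @param formula latency model formula, `Surv(time, event) ~ covariates`.
#' @param cureform one-sided formula for the incidence (cure) submodel,
#'   e.g. `~ age + sex`; an intercept is always included.
#' @param data data.frame holding all variables.
#' @param latency_dist `"semiparametric"` (default) or `"weibull"`.
#' @param eps relative observed-log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @return object of class `mixture_cure_fit` with elements `incidence`
#'   (`coef`), `latency` (a `latency_model`), `loglik`, `loglik_trace`,
#'   `iterations`, `converged`, plus the internal design matrices used for
#'   bootstrapping and prediction.
#' @examples
#' cfg <- default_cohort_config(n_subjects = 800, seed = 7)
#' coh <- generate_cohort(cfg)$cohort
#' fit <- fit_mixture_cure(survival::Surv(time, event) ~ sex + comorbidity,
#'                         cureform = ~ sex + comorbidity, data = coh)
#' fit
#' @export
fit_mixture_cure <- function(formula, cureform, data,
                             latency_dist = c("semiparametric", "weibull"),
                             eps = 1e-7, max_iter = 200) {
  latency_dist <- match.arg(latency_dist)
  if (nrow(data) < 2) stop("need at least 2 records")
  data <- droplevels(data)        # unused factor levels carry no information
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (!survival::is.Surv(y)) stop("formula response must be a survival::Surv object")
  time <- unname(y[, 1]); event <- unname(y[, 2])
  if (any(!is.finite(time)) || any(time <= 0)) stop("times must be finite and > 0")
  if (!all(event %in% c(0, 1))) stop("event indicator must be 0/1")
  if (!any(event == 1) || !any(event == 0))
    stop("both events and censored subjects are required to fit a cure model")
  if (mean(event == 0) < 0.01)
    warning("censoring fraction below 1%: the cure fraction is barely identifiable")
  lat_terms <- stats::delete.response(stats::terms(formula, data = data))
  x <- stats::model.matrix(lat_terms, data)
  x_assign <- attr(x, "assign")
  x <- x[, x_assign != 0, drop = FALSE]
  cure_terms <- stats::terms(cureform, data = data)
  z <- stats::model.matrix(cure_terms, data)
  colnames(z)[1] <- "intercept"
  em <- em_mixture_cure(time, event, x, z, latency_dist, eps, max_iter)
  if (!em$converged)
    warning("EM did not converge in ", max_iter, " iterations")
  structure(list(incidence = list(coef = em$b),
                 latency = em$latency,
                 loglik = em$loglik,
                 loglik_trace = em$loglik_trace,
                 iterations = em$iterations,
                 converged = em$converged,
                 n = length(time), n_events = sum(event),
                 time = time, event = event, x = x, z = z,
                 lat_terms = lat_terms, cure_terms = cure_terms,
                 xlevels = stats::.getXlevels(stats::terms(formula, data = data), mf),
                 latency_dist = latency_dist,
                 eps = eps, max_iter = max_iter,
                 call = match.call()),
            class = "mixture_cure_fit")
}

#' @export
print.mixture_cure_fit <- function(x, ...) {
  cat("Mixture cure model (", x$latency_dist, " latency), EM ",
      x$iterations, " iterations, ",
      if (x$converged) "converged" else "NOT converged", "\n", sep = "")
  cat("  n =", x$n, " events =", x$n_events,
      " log-likelihood =", format(x$loglik), "\n")
  cat("Incidence (long-term) coefficients b:\n")
  print(round(x$incidence$coef, 4))
  cat("Latency (short-term) coefficients beta:\n")
  print(round(x$latency$beta, 4))
  invisible(x)
}

#' Predicted population survival from a mixture cure fit
#'
#' Evaluates `pi(z) s0(t)^exp(beta'x) + 1 - pi(z)` for each profile in
#' `newdata` at the requested times. The curve is non-increasing and
#' plateaus at exactly `1 - pi(z)` beyond the last event time.
#'
#' @param fit a `mixture_cure_fit`.
#' @param newdata data.frame of covariate profiles (one row per profile).
#' @param times non-decreasing evaluation times (>= 0).
#' @return data.frame with columns `profile`, `time`, `survival`.
#' @export
predict_survival <- function(fit, newdata, times) {
  if (is.unsorted(times) || any(times < 0))
    stop("'times' must be sorted and non-negative")
  x <- tryCatch(stats::model.matrix(fit$lat_terms, newdata,
                                    xlev = fit$xlevels),
                error = function(e) stop("cannot build latency design for newdata: ",
                                         conditionMessage(e)))
  x <- x[, colnames(fit$x), drop = FALSE]
  z <- stats::model.matrix(fit$cure_terms, newdata)
  colnames(z)[1] <- "intercept"
  z <- z[, colnames(fit$z), drop = FALSE]
  pi <- susceptibility_probability(fit$incidence$coef, z)
  out <- vector("list", nrow(newdata))
  for (i in seq_len(nrow(newdata))) {
    eta <- if (length(fit$latency$beta)) sum(x[i, ] * fit$latency$beta) else 0
    s_u <- latency_survival(fit$latency, times, eta)
    out[[i]] <- data.frame(profile = i, time = times,
                           survival = population_survival(pi[i], s_u))
  }
  do.call(rbind, out)
}

#' Nonparametric bootstrap variance for a mixture cure fit
#'
#' Resamples subjects with replacement `B` times, refits the EM on each
#' resample, and reports resample standard deviations and percentile
#' confidence intervals for the incidence and latency coefficients.
#'
#' @param fit a `mixture_cure_fit`.
#' @param B number of bootstrap resamples (>= 50).
#' @param seed integer seed (resampling is deterministic given it).
#' @param level confidence level for percentile intervals.
#' @return list of class `cure_bootstrap` with `se`, `ci` (matrix with
#'   columns `lo`, `hi`), `cov`, `estimates` (B x p matrix), `n_failed`.
#' @export
bootstrap_variance <- function(fit, B = 100, seed = 1, level = 0.95) {
  stopifnot(inherits(fit, "mixture_cure_fit"))
  if (B < 50) stop("B must be at least 50 for bootstrap variance estimation")
  set.seed(seed)
  n <- fit$n
  nm <- c(paste0("incidence.", names(fit$incidence$coef)),
          if (length(fit$latency$beta))
            paste0("latency.", names(fit$latency$beta)))
  est <- matrix(NA_real_, B, length(nm), dimnames = list(NULL, nm))
  n_failed <- 0L
  for (bidx in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    res <- tryCatch(
      em_mixture_cure(fit$time[idx], fit$event[idx],
                      fit$x[idx, , drop = FALSE], fit$z[idx, , drop = FALSE],
                      fit$latency_dist, fit$eps, fit$max_iter,
                      init_b = fit$incidence$coef,
                      init_beta = fit$latency$beta),
      error = function(e) NULL)
    if (is.null(res) || !res$converged) {
      n_failed <- n_failed + 1L
    } else {
      est[bidx, ] <- c(res$b, res$latency$beta)
    }
  }
  if (n_failed > 0.2 * B)
    stop("more than 20% of bootstrap resamples failed to converge (",
         n_failed, "/", B, ")")
  ok <- stats::complete.cases(est)
  alpha <- (1 - level) / 2
  ci <- t(apply(est[ok, , drop = FALSE], 2, stats::quantile,
                probs = c(alpha, 1 - alpha), names = FALSE))
  colnames(ci) <- c("lo", "hi")
  structure(list(se = apply(est[ok, , drop = FALSE], 2, stats::sd),
                 ci = ci,
                 cov = stats::cov(est[ok, , drop = FALSE]),
                 estimates = est, B = B, n_failed = n_failed, level = level),
            class = "cure_bootstrap")
}

#' @export
print.cure_bootstrap <- function(x, ...) {
  cat("Bootstrap (B = ", x$B, ", failed = ", x$n_failed, ")\n", sep = "")
  print(round(cbind(se = x$se, x$ci), 4))
  invisible(x)
}
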