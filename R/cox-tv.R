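#' Split one subject's history into counting-process episodes
#'
#' Produces one `(start, stop]` row per modality spell. The event flag is
#' set on the final row only; covariates are carried by the caller. A
#' switch recorded at or after the follow-up time cannot be in force during
#' observation and is dropped with a logged note; switch times that are not
#' strictly increasing are an error.
#'
#' @param time follow-up time (> 0).
#' @param event event indicator (0/1).
#' @param baseline_modality modality in force from time 0.
#' @param switches data.frame with columns `time` and `modality`, the state
#'   entered at each switch (may have zero rows).
#' @return data.frame `start,stop,modality,event`.
#' @export
episode_split <- function(time, event, baseline_modality,
                          switches = data.frame(time = numeric(0),
                                                modality = character(0))) {
  stopifnot(length(time) == 1L, time > 0, event %in% c(0, 1))
  if (nrow(switches) > 1 && any(diff(switches$time) <= 0))
    stop("switch times must be strictly increasing")
  if (any(switches$time <= 0))
    stop("switch times must be strictly positive")
  late <- switches$time >= time
  if (any(late)) {
    message("episode_split: dropped ", sum(late),
            " switch(es) at or beyond follow-up time ", format(time))
    switches <- switches[!late, , drop = FALSE]
  }
  bounds <- c(0, switches$time, time)
  k <- length(bounds) - 1L
  data.frame(start = bounds[-length(bounds)],
             stop = bounds[-1L],
             modality = c(baseline_modality, switches$modality),
             event = c(rep(0L, k - 1L), as.integer(event)),
             stringsAsFactors = FALSE)
}

#' Attach baseline covariates to an episode table
#'
#' @param episodes episode data.frame (`id,start,stop,modality,event`).
#' @param cohort cohort data.frame with `id` and the requested columns.
#' @param covariates character vector of cohort column names to carry.
#' @return episodes with the covariate columns merged on, original order.
#' @export
merge_episode_covariates <- function(episodes, cohort, covariates) {
  miss <- setdiff(covariates, names(cohort))
  if (length(miss)) stop("cohort lacks covariate column(s): ",
                         paste(miss, collapse = ", "))
  idx <- match(episodes$id, cohort$id)
  if (anyNA(idx)) stop("episode ids missing from the cohort table")
  cbind(episodes, cohort[idx, covariates, drop = FALSE], row.names = NULL)
}

# Split episodes at every event time so that each at-risk row at an event
# time t ends exactly at t; the modality-by-time covariate is then the
# modality indicator times the row's stop. Used by small-scale test oracles
# (the fitter itself handles the time interaction analytically).
expand_at_event_times <- function(ep) {
  cut <- sort(unique(ep$stop[ep$event == 1]))
  # survSplit wants a literal Surv() call on the LHS
  env <- new.env(parent = baseenv())
  env$Surv <- survival::Surv
  fml <- stats::as.formula("Surv(start, stop, event) ~ .", env = env)
  survival::survSplit(fml, data = ep, cut = cut)
}

# Prepared inputs for the compiled partial-likelihood sweep.
cox_cp_prepare <- function(ep, X, state, nstate, interaction) {
  n <- nrow(ep)
  p <- ncol(X)
  nb <- nstate - 1L
  ng <- if (interaction) nb else 0L
  P <- p + nb + ng
  tau <- sort(unique(ep$stop[ep$event == 1]))
  K <- length(tau)
  ev <- which(ep$event == 1)
  ev_k <- match(ep$stop[ev], tau)
  d <- as.numeric(tabulate(ev_k, nbins = K))
  # per-event-time sums of the full covariate vector over events; every
  # tau holds at least one event, so rowsum's groups are exactly 1..K
  u_ev <- matrix(0, K, P)
  if (p > 0)
    u_ev[, seq_len(p)] <- as.matrix(rowsum(X[ev, , drop = FALSE], ev_k,
                                           reorder = TRUE))
  nev_state <- matrix(0, K, nb)
  for (s in seq_len(nb))
    nev_state[, s] <- tabulate(ev_k[state[ev] == s + 1L], nbins = K)
  if (nb > 0) {
    u_ev[, p + seq_len(nb)] <- nev_state
    if (ng > 0) u_ev[, p + nb + seq_len(ng)] <- nev_state * tau
  }
  list(tau = tau, d = d, ev = ev, ev_k = ev_k, nev_state = nev_state,
       u_ev = u_ev, n = n, p = p, nb = nb, ng = ng, P = P,
       ord_start = order(ep$start) - 1L, ord_stop = order(ep$stop) - 1L)
}

cox_cp_eval <- function(prep, ep, X, state, theta) {
  p <- prep$p; nb <- prep$nb; ng <- prep$ng
  bx <- theta[seq_len(p)]
  bmod <- theta[p + seq_len(nb)]
  gmod <- if (ng) theta[p + nb + seq_len(ng)] else numeric(0)
  lp0 <- if (p) drop(X %*% bx) else numeric(prep$n)
  # sum over events of the full linear predictor at the event time
  ev_lp <- lp0[prep$ev]
  s_ev <- state[prep$ev]
  if (nb) {
    bm <- c(0, bmod)
    gm <- c(0, if (ng) gmod else numeric(nb))
    ev_lp <- ev_lp + bm[s_ev] + gm[s_ev] * prep$tau[prep$ev_k]
  }
  ev_lp_sum <- as.numeric(rowsum(ev_lp, prep$ev_k, reorder = TRUE))
  sweep <- cox_cp_sweep(prep$tau, prep$d, ep$start, ep$stop,
                        as.integer(state), as.integer(nb + 1L),
                        X, exp(lp0), bmod, gmod,
                        prep$ord_start, prep$ord_stop,
                        ev_lp_sum, prep$u_ev)
  sweep$lp0 <- lp0
  sweep
}

#' Cox model on counting-process episodes with time-varying modality
#'
#' Fits the proportional-hazards partial likelihood (Breslow ties) on
#' `(start, stop]` episodes; a row is at risk at event time `t` iff
#' `start < t <= stop`. With `interaction = TRUE` each non-reference
#' modality also gets a modality-by-time term whose value at every event
#' time is the modality indicator times that event time (in years), giving
#' a log-linear time-dependent hazard ratio. The interaction covariate is
#' evaluated at each event time for every at-risk row; because the
#' time-varying part is shared by all rows in a modality state, risk-set
#' sums factor into per-state aggregates and no episode expansion is
#' needed. Estimation is Newton-Raphson with step halving; model-based
#' (inverse information) and robust (sandwich, clustered by subject)
#' covariances are both computed.
#'
#' @param episodes episode data.frame with `id,start,stop,modality,event`
#'   plus any baseline covariate columns (see
#'   [merge_episode_covariates()]).
#' @param covariates character vector of baseline covariate column names to
#'   adjust for (may be empty).
#' @param interaction logical: include modality-by-time interactions.
#' @param reference reference modality level (default `"hemodialysis"`).
#' @param tol gradient sup-norm convergence tolerance.
#' @param max_iter maximum Newton-Raphson iterations.
#' @return object of class `cox_tv_fit`: `coefficients`, `var_model`
#'   (inverse observed information), `var_robust` (clustered sandwich),
#'   `loglik` (named vector: null, fitted), `modalities`, `reference`,
#'   `interaction`, `n_subjects`, `n_events`.
#' @export
fit_cox_counting <- function(episodes, covariates = character(),
                             interaction = TRUE,
                             reference = "hemodialysis",
                             tol = 1e-8, max_iter = 100) {
  req <- c("id", "start", "stop", "modality", "event")
  miss <- setdiff(req, names(episodes))
  if (length(miss)) stop("episodes lack column(s): ", paste(miss, collapse = ", "))
  if (any(episodes$start < 0) || any(episodes$stop <= episodes$start))
    stop("episodes must satisfy 0 <= start < stop")
  if (!any(episodes$event == 1)) stop("no events in the episode table")
  if (length(unique(episodes$id)) < 2)
    stop("robust clustered variance needs at least 2 subjects")
  ep <- droplevels(episodes)      # unused factor levels carry no information
  mods <- setdiff(sort(unique(ep$modality)), reference)
  interaction <- interaction && length(mods) > 0
  state <- match(ep$modality, c(reference, mods))
  X <- if (length(covariates)) {
    mm <- stats::model.matrix(stats::reformulate(covariates), data = ep)
    mm[, -1, drop = FALSE]
  } else matrix(0, nrow(ep), 0)
  if (ncol(X) && qr(X)$rank < ncol(X))
    stop("baseline covariate design is rank deficient")
  prep <- cox_cp_prepare(ep, X, state, length(mods) + 1L, interaction)
  if (prep$P == 0) stop("model has no covariates")
  nm <- c(colnames(X), mods, if (interaction) paste0(mods, "_time"))
  theta <- numeric(prep$P)
  cur <- cox_cp_eval(prep, ep, X, state, theta)
  ll_null <- cur$loglik
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    if (max(abs(cur$grad)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(cur$info, cur$grad),
                     error = function(e)
                       stop("singular information: design is rank deficient within risk sets"))
    # Newton decrement: attainable partial-log-likelihood gain of this step
    dec <- sum(step * cur$grad) / 2
    fac <- 1
    repeat {
      cand <- theta + fac * step
      nxt <- cox_cp_eval(prep, ep, X, state, cand)
      if (is.finite(nxt$loglik) && nxt$loglik >= cur$loglik - 1e-12) break
      fac <- fac / 2
      if (fac < 1e-8) stop("partial-likelihood maximization failed to make progress")
    }
    theta <- cand
    cur <- nxt
    if (dec < 1e-12) { converged <- TRUE; break }
    if (any(abs(theta) > 20))
      stop("monotone partial likelihood / separation: coefficient '",
           nm[which.max(abs(theta))], "' diverged beyond 20")
  }
  if (!converged)
    stop("Newton-Raphson did not converge in ", max_iter, " iterations")
  var_model <- solve(cur$info)
  U <- cox_score_residuals(prep, ep, X, state, theta, cur)
  var_robust <- var_model %*% crossprod(U) %*% var_model
  names(theta) <- nm
  dimnames(var_model) <- dimnames(var_robust) <- list(nm, nm)
  structure(list(coefficients = theta,
                 var_model = var_model,
                 var_robust = var_robust,
                 loglik = c(null = ll_null, fitted = cur$loglik),
                 iterations = it,
                 modalities = c(reference, mods),
                 reference = reference,
                 interaction = interaction,
                 n_subjects = length(unique(episodes$id)),
                 n_events = sum(episodes$event)),
            class = "cox_tv_fit")
}

# Per-subject sums of score residuals at the fitted parameters, computed
# without episode expansion: the at-risk integral of each row factors into
# per-state cumulative sums over event times because the row's risk is
# exp(lp0 + b_s) * exp(g_s t) and its covariate vector is a_k + t c_k.
cox_score_residuals <- function(prep, ep, X, state, theta, cur) {
  p <- prep$p; nb <- prep$nb; ng <- prep$ng; P <- prep$P
  tau <- prep$tau; K <- length(tau); n <- nrow(ep)
  nstate <- nb + 1L
  q <- prep$d / cur$S0
  ubar <- matrix(cur$ubar, nrow = K)
  bm <- c(0, theta[p + seq_len(nb)])
  gm <- c(0, if (ng) theta[p + nb + seq_len(ng)] else numeric(nb))
  P0 <- P1 <- matrix(0, K, nstate)
  Pbar <- array(0, c(K, P, nstate))
  for (s in seq_len(nstate)) {
    w <- q * exp(gm[s] * tau)
    P0[, s] <- cumsum(w)
    P1[, s] <- cumsum(w * tau)
    Pbar[, , s] <- apply(w * ubar, 2, cumsum)
  }
  hi <- findInterval(ep$stop, tau)
  lo <- findInterval(ep$start, tau)
  at <- function(M, idx) ifelse(idx >= 1, M[cbind(pmax(idx, 1L), state)], 0)
  d0 <- at(P0, hi) - at(P0, lo)
  d1 <- at(P1, hi) - at(P1, lo)
  dPbar <- matrix(0, n, P)
  for (s in seq_len(nstate)) {
    rows <- which(state == s)
    if (!length(rows)) next
    Ms <- matrix(Pbar[, , s], nrow = K)
    block <- matrix(0, length(rows), P)
    ok <- hi[rows] >= 1
    block[ok, ] <- Ms[hi[rows][ok], , drop = FALSE]
    ok <- lo[rows] >= 1
    block[ok, ] <- block[ok, , drop = FALSE] - Ms[lo[rows][ok], , drop = FALSE]
    dPbar[rows, ] <- block
  }
  A <- matrix(0, n, P)
  if (p) A[, seq_len(p)] <- X
  Cc <- matrix(0, n, P)
  for (s in seq_len(nb)) {
    rows <- state == s + 1L
    A[rows, p + s] <- 1
    if (ng) Cc[rows, p + nb + s] <- 1
  }
  E <- exp(cur$lp0 + bm[state])
  R <- -E * (d0 * A + d1 * Cc - dPbar)
  ev <- prep$ev; k_ev <- prep$ev_k
  u_ev <- A[ev, , drop = FALSE] + tau[k_ev] * Cc[ev, , drop = FALSE]
  R[ev, ] <- R[ev, , drop = FALSE] + u_ev - ubar[k_ev, , drop = FALSE]
  rowsum(R, ep$id)
}

#' Construct a `cox_tv_fit` from published coefficient estimates
#'
#' Allows downstream operations (notably [time_dependent_hr()]) to run on
#' externally reported coefficients, e.g. a printed regression table.
#' Modality main effects must be named by modality level (e.g.
#' `"peritoneal"`, `"transplant"`) and interactions `"<level>_time"`.
#'
#' @param coef named numeric vector of coefficients.
#' @param se optional named standard errors (used to build a diagonal
#'   covariance when `vcov` is absent; covariances between terms are then
#'   taken as zero).
#' @param vcov optional full covariance matrix.
#' @param reference reference modality level.
#' @return a `cox_tv_fit` (estimates only; no fit diagnostics).
#' @export
cox_tv_from_estimates <- function(coef, se = NULL, vcov = NULL,
                                  reference = "hemodialysis") {
  stopifnot(!is.null(names(coef)))
  if (is.null(vcov) && !is.null(se)) {
    vcov <- diag(se[names(coef)]^2, nrow = length(coef))
    dimnames(vcov) <- list(names(coef), names(coef))
  }
  mods <- grep("_time$", names(coef), value = TRUE)
  mains <- sub("_time$", "", mods)
  structure(list(coefficients = coef,
                 var_model = vcov, var_robust = vcov,
                 loglik = NULL,
                 modalities = c(reference, union(mains,
                   setdiff(names(coef), c(mods, mains)))),
                 reference = reference,
                 interaction = length(mods) > 0,
                 n_subjects = NA_integer_, n_events = NA_integer_),
            class = "cox_tv_fit")
}

#' Robust (sandwich) covariance of a counting-process Cox fit
#'
#' The working-independence sandwich `I^-1 (sum_i u_i u_i') I^-1`, with
#' `u_i` the per-subject sum of score residuals and `I` the observed
#' information, as computed when the fit was clustered by subject.
#'
#' @param fit a `cox_tv_fit`.
#' @return covariance matrix.
#' @export
robust_variance <- function(fit) {
  stopifnot(inherits(fit, "cox_tv_fit"))
  if (is.null(fit$var_robust)) stop("fit carries no robust covariance")
  if (!is.na(fit$n_subjects) && fit$n_subjects < 2)
    stop("robust variance undefined with a single subject")
  fit$var_robust
}

# Contrast vector selecting a modality's main effect (+ t * interaction).
modality_contrast <- function(fit, modality, t) {
  cc <- numeric(length(fit$coefficients))
  names(cc) <- names(fit$coefficients)
  if (!modality %in% fit$modalities)
    stop("unknown modality label: '", modality, "'")
  if (modality != fit$reference) {
    if (!modality %in% names(cc))
      stop("modality '", modality, "' has no coefficient in this fit")
    cc[modality] <- 1
    it <- paste0(modality, "_time")
    if (it %in% names(cc)) cc[it] <- t
  }
  cc
}

#' Time-dependent hazard ratio between two modalities
#'
#' `HR(t) = exp(c(t)' theta)` where the contrast `c(t)` selects the main
#' effect plus `t` times the modality-by-time interaction of the numerator
#' minus that of the denominator, holding all other covariates fixed.
#' Pointwise confidence intervals use the robust covariance:
#' `exp(c' theta +/- z sqrt(c' Sigma c))`.
#'
#' @param fit a `cox_tv_fit`.
#' @param numerator,denominator modality labels.
#' @param t time(s) in years (>= 0); vectorized.
#' @param level confidence level (default 0.95).
#' @return data.frame `t,hr,lo,hi`.
#' @export
time_dependent_hr <- function(fit, numerator, denominator, t, level = 0.95) {
  stopifnot(inherits(fit, "cox_tv_fit"))
  if (any(t < 0)) stop("t must be non-negative")
  z <- stats::qnorm(1 - (1 - level) / 2)
  V <- fit$var_robust
  out <- lapply(t, function(ti) {
    cc <- modality_contrast(fit, numerator, ti) -
      modality_contrast(fit, denominator, ti)
    est <- sum(cc * fit$coefficients)
    se <- if (is.null(V)) NA_real_ else sqrt(drop(cc %*% V %*% cc))
    data.frame(t = ti, hr = exp(est),
               lo = exp(est - z * se), hi = exp(est + z * se))
  })
  do.call(rbind, out)
}

#' @export
print.cox_tv_fit <- function(x, ...) {
  cat("Counting-process Cox fit (Breslow ties",
      if (x$interaction) ", modality-by-time interactions", ")\n", sep = "")
  if (!is.na(x$n_subjects))
    cat("  subjects:", x$n_subjects, " events:", x$n_events, "\n")
  se <- if (!is.null(x$var_robust)) sqrt(diag(x$var_robust)) else NA
  print(round(cbind(coef = x$coefficients, `robust se` = se,
                    hr = exp(x$coefficients)), 4))
  invisible(x)
}
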