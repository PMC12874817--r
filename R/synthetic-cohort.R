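#' Draw baseline covariates for a synthetic cohort
#'
#' Each categorical covariate is drawn independently from its stated level
#' probabilities; continuous covariates are normal with the stated mean and
#' standard deviation.
#'
#' @param config a [cohort_config()].
#' @param seed optional integer; when given, `set.seed(seed)` is called
#'   first. Leave `NULL` inside [generate_cohort()], which manages one
#'   global stream.
#' @return data.frame with column `id` and one column per covariate
#'   (character for categorical, numeric for continuous).
#' @export
sample_covariates <- function(config, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_subjects
  out <- data.frame(id = seq_len(n))
  for (cv in config$covariates) {
    out[[cv$name]] <- if (is.null(cv$levels)) {
      stats::rnorm(n, cv$mean, cv$sd)
    } else {
      sample(cv$levels, n, replace = TRUE, prob = cv$probs)
    }
  }
  out
}

#' Assign latent short-term / long-term class
#'
#' Each subject is short-term (susceptible) with probability
#' `pi = plogis(b'z)` and long-term otherwise. The long-term class plays the
#' role of the subpopulation whose survival is flat at 1 — in the target
#' application, patients headed for a successful transplant.
#'
#' @param b incidence coefficient vector (intercept first).
#' @param z incidence design matrix with leading intercept column.
#' @param seed optional integer seed.
#' @return character vector, `"short_term"` or `"long_term"` per subject.
#' @export
assign_latent_class <- function(b, z, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  eta <- drop(z %*% b)
  p <- logistic(eta)
  ifelse(stats::runif(length(p)) < p, "short_term", "long_term")
}

#' Sample latent event times
#'
#' Short-term subjects get a proportional-hazards Weibull time by inverse
#' transform: if `S0(t) = exp(-(t/scale)^shape)`, the subject's survival is
#' `S0(t)^exp(beta'x)` and `T = scale * (-log(U) * exp(-beta'x))^(1/shape)`.
#' Long-term subjects never experience the event and get `Inf`.
#'
#' @param beta latency coefficient vector.
#' @param baseline `list(shape, scale)` of the Weibull baseline.
#' @param x latency design matrix.
#' @param latent_class character vector from [assign_latent_class()].
#' @param seed optional integer seed.
#' @return numeric vector of event times in years (`Inf` for long-term).
#' @export
sample_event_times <- function(beta, baseline, x, latent_class, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (baseline$shape <= 0 || baseline$scale <= 0)
    stop("Weibull shape and scale must be positive")
  n <- length(latent_class)
  eta <- if (length(beta)) drop(x %*% beta) else rep(0, n)
  u <- stats::runif(n)
  tt <- baseline$scale * (-log(u) * exp(-eta))^(1 / baseline$shape)
  tt[latent_class == "long_term"] <- Inf
  tt
}

#' Apply right censoring
#'
#' Censoring time is the minimum of the administrative horizon and an
#' exponential dropout time; the observed time is `min(T, C)` with event
#' indicator 1 exactly when the latent event time is the minimum. Long-term
#' subjects (infinite latent time) are always censored.
#'
#' @param true_times latent event times (years; `Inf` allowed).
#' @param censoring `list(horizon, dropout_rate)`.
#' @param seed optional integer seed.
#' @return data.frame with columns `time` and `event`.
#' @export
apply_censoring <- function(true_times, censoring, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (censoring$horizon <= 0) stop("censoring horizon must be > 0")
  n <- length(true_times)
  dropout <- if (censoring$dropout_rate > 0)
    stats::rexp(n, censoring$dropout_rate) else rep(Inf, n)
  cens <- pmin(dropout, censoring$horizon)
  time <- pmin(true_times, cens)
  event <- as.integer(true_times <= cens)
  stopifnot(all(time > 0), all(is.finite(time)))
  data.frame(time = time, event = event)
}

#' Simulate transplant and modality-switch histories
#'
#' Transplantation is drawn per subject with a class-specific probability
#' (enriched in the long-term class, making ever-transplant the observable
#' proxy for that class); the transplant time is uniform strictly inside
#' (0, follow-up). A dialysis-to-dialysis switch (hemodialysis <->
#' peritoneal) may additionally occur before the transplant. Per-subject
#' episode boundaries are emitted in counting-process form.
#'
#' @param config a [cohort_config()].
#' @param subjects data.frame with columns `id`, `time`, `event`,
#'   `latent_class` and the baseline `modality` column.
#' @param seed optional integer seed.
#' @return list with `transplant_time` (numeric, `NA` when none) and
#'   `episodes` (data.frame `id,start,stop,modality,event`).
#' @export
simulate_modality_history <- function(config, subjects, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sw <- config$switching
  n <- nrow(subjects)
  p_tx <- ifelse(subjects$latent_class == "long_term",
                 sw$p_transplant_long, sw$p_transplant_short)
  # fixed-length draws keep the stream layout independent of outcomes
  has_tx <- stats::runif(n) < p_tx
  tx_frac <- stats::runif(n)
  has_switch <- stats::runif(n) < (sw$p_modality_switch %||% 0)
  switch_frac <- stats::runif(n)

  tx_time <- ifelse(has_tx, tx_frac * subjects$time, NA_real_)
  switch_cap <- ifelse(has_tx, tx_time, subjects$time)
  sw_time <- ifelse(has_switch, switch_frac * switch_cap, NA_real_)

  time <- subjects$time
  valid_tx <- !is.na(tx_time) & tx_time > 0 & tx_time < time
  tx_time[!valid_tx] <- NA_real_
  valid_sw <- !is.na(sw_time) & sw_time > 0 &
    sw_time < ifelse(valid_tx, tx_time, time)
  other <- c(hemodialysis = "peritoneal", peritoneal = "hemodialysis")

  # vectorized counting-process rows: baseline spell, optional
  # dialysis-switch spell, optional transplant spell
  r1 <- data.frame(id = subjects$id, start = 0,
                   stop = ifelse(valid_sw, sw_time,
                                 ifelse(valid_tx, tx_time, time)),
                   modality = subjects$modality,
                   event = ifelse(valid_sw | valid_tx, 0L, subjects$event),
                   stringsAsFactors = FALSE)
  r2 <- data.frame(id = subjects$id[valid_sw], start = sw_time[valid_sw],
                   stop = ifelse(valid_tx[valid_sw], tx_time[valid_sw],
                                 time[valid_sw]),
                   modality = unname(other[subjects$modality[valid_sw]]),
                   event = ifelse(valid_tx[valid_sw], 0L,
                                  subjects$event[valid_sw]),
                   stringsAsFactors = FALSE)
  r3 <- data.frame(id = subjects$id[valid_tx], start = tx_time[valid_tx],
                   stop = time[valid_tx],
                   modality = rep("transplant", sum(valid_tx)),
                   event = subjects$event[valid_tx],
                   stringsAsFactors = FALSE)
  eps <- rbind(r1, r2, r3)
  eps <- eps[order(eps$id, eps$start), , drop = FALSE]
  rownames(eps) <- NULL
  list(transplant_time = tx_time, episodes = eps)
}

#' Generate a complete synthetic cohort
#'
#' Runs the full generative chain under one seeded stream, in this order:
#' baseline covariates, latent class assignment, latent event times,
#' censoring, and modality/transplant histories. The result is a
#' complete-case subject table (no missing values) and a companion episode
#' table in counting-process form; when `out_dir` is given both are written
#' as CSV (see [write_cohort()]).
#'
#' @param config a [cohort_config()].
#' @param out_dir optional directory to write `cohort.csv` and
#'   `episodes.csv` into.
#' @return list of class `synthetic_cohort` with elements `cohort`,
#'   `episodes`, `latent_class`, `true_times` and `config`.
#' @export
generate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  covs <- sample_covariates(config)
  z <- build_design(covs, config$covariates,
                    setdiff(names(config$incidence), "intercept"),
                    intercept = TRUE)
  cls <- assign_latent_class(config$incidence[c("intercept",
                                               colnames(z)[-1L])], z)
  x <- build_design(covs, config$covariates, names(config$latency))
  true_t <- sample_event_times(config$latency, config$baseline, x, cls)
  obs <- apply_censoring(true_t, config$censoring)
  # configs without a modality covariate default everyone to hemodialysis
  if (!"modality" %in% names(covs)) covs$modality <- "hemodialysis"
  subj <- cbind(covs[, "id", drop = FALSE], obs,
                latent_class = cls,
                covs[, setdiff(names(covs), "id"), drop = FALSE])
  hist <- simulate_modality_history(config, subj)
  cohort <- data.frame(id = subj$id,
                       time = subj$time,
                       event = subj$event,
                       transplant = as.integer(!is.na(hist$transplant_time)),
                       modality = subj$modality,
                       stringsAsFactors = FALSE)
  extra <- setdiff(names(covs), c("id", "modality"))
  cohort[extra] <- covs[extra]
  stopifnot(!anyNA(cohort))
  out <- structure(list(cohort = cohort,
                        episodes = hist$episodes,
                        latent_class = cls,
                        true_times = true_t,
                        transplant_time = hist$transplant_time,
                        config = config),
                   class = "synthetic_cohort")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cohort(cohort, file.path(out_dir, "cohort.csv"))
    write_episodes(hist$episodes, file.path(out_dir, "episodes.csv"))
  }
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic KRT cohort:", nrow(x$cohort), "subjects,",
      sum(x$cohort$event), "events,",
      sum(x$cohort$transplant), "transplanted\n")
  cat("  long-term fraction:",
      round(mean(x$latent_class == "long_term"), 4), "\n")
  invisible(x)
}

# %.17g round-trips IEEE doubles exactly through text.
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  int <- is.finite(x) & x == floor(x) & abs(x) < 1e15
  out[int] <- sprintf("%.0f", x[int])
  out
}

#' Read and write cohort and episode tables
#'
#' Cohort files are CSV with header `id,time,event,transplant,modality,...`;
#' episode files are CSV `id,start,stop,modality,event` with half-open
#' `(start, stop]` intervals whose last `stop` equals the subject's
#' follow-up time. Numeric columns are written with full precision so that
#' `read_cohort(write_cohort(x))` reproduces `x` exactly.
#'
#' @param cohort,episodes data.frames as produced by [generate_cohort()].
#' @param path file path.
#' @return the data.frame (readers) or `path`, invisibly (writers).
#' @export
write_cohort <- function(cohort, path) {
  df <- cohort
  for (nm in names(df)) if (is.numeric(df[[nm]])) df[[nm]] <- fmt_num(df[[nm]])
  tryCatch(utils::write.csv(df, path, row.names = FALSE, quote = FALSE),
           error = function(e) stop("failed to write cohort file ", path,
                                    ": ", conditionMessage(e)))
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("id", "time", "event", "transplant", "modality")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("cohort file ", path, " lacks column(s): ",
                         paste(miss, collapse = ", "))
  df$id <- as.integer(df$id)
  df$event <- as.integer(df$event)
  df$transplant <- as.integer(df$transplant)
  df
}

#' @rdname write_cohort
#' @export
write_episodes <- function(episodes, path) {
  df <- episodes
  for (nm in c("start", "stop")) df[[nm]] <- fmt_num(df[[nm]])
  tryCatch(utils::write.csv(df, path, row.names = FALSE, quote = FALSE),
           error = function(e) stop("failed to write episode file ", path,
                                    ": ", conditionMessage(e)))
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_episodes <- function(path) {
  if (!file.exists(path)) stop("episode file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("id", "start", "stop", "modality", "event")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("episode file ", path, " lacks column(s): ",
                         paste(miss, collapse = ", "))
  df$id <- as.integer(df$id)
  df$event <- as.integer(df$event)
  df
}
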