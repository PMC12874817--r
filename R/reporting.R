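# 97.5% normal quantile used throughout the reporting layer; rounding
# happens only at presentation.
Z975 <- stats::qnorm(0.975)

#' Wald ratio table
#'
#' Turns coefficient/standard-error pairs into ratio-scale summaries:
#' `ratio = exp(coef)`, `CI = exp(coef +/- z se)` and a two-sided normal
#' p-value. The returned columns are full precision; use
#' [format_ratio_table()] for printed output.
#'
#' @param term character vector of term labels.
#' @param coef,se numeric vectors (se > 0), one entry per term.
#' @param submodel label: `"cox"`, `"msm-long-term"` or `"msm-short-term"`.
#' @param level confidence level.
#' @return data.frame `term,submodel,coef,se,ratio,ci_lo,ci_hi,p`.
#' @export
wald_ratio_table <- function(term, coef, se, submodel = "cox", level = 0.95) {
  if (length(term) != length(coef) || length(coef) != length(se))
    stop("term, coef and se must have equal length")
  if (any(!is.na(se) & se <= 0)) stop("standard errors must be positive")
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(term = term, submodel = submodel, coef = coef, se = se,
             ratio = exp(coef),
             ci_lo = exp(coef - z * se),
             ci_hi = exp(coef + z * se),
             p = wald_p(coef / se))
}

#' Format a Wald ratio table for printing
#'
#' Ratio and CI rounded to the requested number of decimals (journal tables
#' print 2, occasionally 3 for the CI); p-values below 0.001 print as
#' `"< 0.001"`.
#'
#' @param tbl output of [wald_ratio_table()].
#' @param digits decimals for the ratio.
#' @param ci_digits decimals for the CI bounds (default `digits`).
#' @return `tbl` with added character columns `pretty` and `p_pretty`.
#' @export
format_ratio_table <- function(tbl, digits = 2, ci_digits = digits) {
  fmt <- function(x, d) formatC(round(x, d), format = "f", digits = d)
  tbl$pretty <- sprintf("%s (%s-%s)",
                        fmt(tbl$ratio, digits),
                        fmt(tbl$ci_lo, ci_digits),
                        fmt(tbl$ci_hi, ci_digits))
  tbl$p_pretty <- ifelse(tbl$p < 0.001, "< 0.001",
                         formatC(round(tbl$p, 3), format = "f", digits = 3))
  tbl
}

#' Long-format forest-plot data
#'
#' Aligns several ratio tables (e.g. Cox HRs, mixture-model short-term HRs
#' and long-term ORs) term by term for forest plotting. All tables must
#' share exactly the same set of terms. Confidence limits beyond the
#' display bounds are flagged so a renderer can draw arrows.
#'
#' @param tables non-empty list of [wald_ratio_table()] outputs.
#' @param display_bounds optional `c(lo, hi)` display limits on the ratio
#'   scale.
#' @return row-bound table with an added logical `out_of_bounds` column.
#' @export
forest_data <- function(tables, display_bounds = NULL) {
  if (!length(tables)) stop("empty table list")
  ref <- sort(tables[[1]]$term)
  for (i in seq_along(tables)) {
    bad <- c(setdiff(tables[[i]]$term, ref), setdiff(ref, tables[[i]]$term))
    if (length(bad))
      stop("term mismatch across tables: ", paste(unique(bad), collapse = ", "))
  }
  out <- do.call(rbind, c(tables, list(make.row.names = FALSE)))
  out$out_of_bounds <- if (is.null(display_bounds)) FALSE else
    out$ci_lo < display_bounds[1] | out$ci_hi > display_bounds[2]
  out
}

#' Convert cohort covariate columns to factors with config-defined levels
#'
#' Character covariate columns (as read from a cohort CSV) become factors
#' whose level order follows the generating configuration, so the reference
#' level of every model term is the config's first level.
#'
#' @param cohort cohort data.frame.
#' @param config the [cohort_config()] that generated it.
#' @return the cohort with factor covariate columns.
#' @export
as_cohort_factors <- function(cohort, config) {
  for (cv in config$covariates) {
    if (!is.null(cv$levels) && cv$name %in% names(cohort))
      cohort[[cv$name]] <- factor(cohort[[cv$name]], levels = cv$levels)
  }
  cohort
}

#' Run the full simulate-fit-report pipeline
#'
#' Generates a synthetic cohort, fits the mixture cure model and the
#' counting-process Cox comparator, produces descriptive and ratio tables
#' plus a time-dependent hazard-ratio curve, and writes everything as CSV
#' with a plain-text manifest. Deterministic given the config's seed.
#'
#' @param config a [cohort_config()].
#' @param out_dir output directory (created if needed).
#' @param covariates baseline covariate names to adjust for; default all
#'   config covariates except `modality` (which enters the Cox model as the
#'   time-varying state, and the mixture model as its baseline value).
#' @param bootstrap_B bootstrap resamples for mixture-model standard errors
#'   (0 = skip; otherwise >= 50).
#' @param hr_grid time grid (years) for the hazard-ratio curve.
#' @return invisibly, a list with the fitted objects and file paths.
#' @export
run_study <- function(config, out_dir, covariates = NULL, bootstrap_B = 0,
                      hr_grid = seq(0.25, 10, by = 0.25)) {
  stopifnot(inherits(config, "cohort_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("run_study failed at stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }
  gen <- stage("simulate", generate_cohort(config, out_dir))
  cohort <- as_cohort_factors(gen$cohort, config)
  covs <- covariates %||%
    setdiff(vapply(config$covariates, `[[`, "", "name"), "modality")

  msm <- stage("fit-msm", {
    fml <- stats::reformulate(c(covs, "modality", "transplant"),
                              response = quote(survival::Surv(time, event)))
    cure <- stats::reformulate(c(covs, "modality", "transplant"))
    fit_mixture_cure(fml, cureform = cure, data = cohort)
  })
  boot <- NULL
  if (bootstrap_B > 0)
    boot <- stage("bootstrap", bootstrap_variance(msm, B = bootstrap_B,
                                                  seed = config$seed))
  cox <- stage("fit-cox", {
    ep <- merge_episode_covariates(gen$episodes, cohort, covs)
    fit_cox_counting(ep, covariates = covs, interaction = TRUE)
  })
  km <- stage("describe", kaplan_meier(cohort$time, cohort$event,
                                       group = cohort$transplant))
  tab1 <- stage("describe", descriptive_table(cohort, group_by = "transplant"))

  # --- ratio tables ---------------------------------------------------------
  nb <- length(msm$incidence$coef)
  msm_se_b <- msm_se_beta <- NULL
  if (!is.null(boot)) {
    msm_se_b <- boot$se[seq_len(nb)]
    msm_se_beta <- boot$se[-seq_len(nb)]
  }
  tbl_long <- wald_ratio_table(names(msm$incidence$coef), msm$incidence$coef,
                               msm_se_b %||% rep(NA_real_, nb),
                               submodel = "msm-long-term")
  tbl_short <- wald_ratio_table(names(msm$latency$beta), msm$latency$beta,
                                msm_se_beta %||%
                                  rep(NA_real_, length(msm$latency$beta)),
                                submodel = "msm-short-term")
  tbl_cox <- wald_ratio_table(names(cox$coefficients), cox$coefficients,
                              sqrt(diag(robust_variance(cox))),
                              submodel = "cox")
  hr <- stage("report", time_dependent_hr(cox, "peritoneal", "hemodialysis",
                                          hr_grid))

  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    p
  }
  files <- c(file.path(out_dir, c("cohort.csv", "episodes.csv")),
             wr(rbind(tbl_long, tbl_short), "msm_coefficients.csv"),
             wr(tbl_cox, "cox_coefficients.csv"),
             wr(msm$latency$basehaz[, c("time", "s0")], "baseline_survival.csv"),
             wr(hr, "hr_curve.csv"),
             wr(km, "km_by_transplant.csv"),
             wr(tab1, "table1.csv"))

  cfg_path <- file.path(out_dir, "config.yaml")
  write_cohort_config(config, cfg_path)
  manifest <- c("cureterm run manifest",
                paste0("package_version: ",
                       as.character(utils::packageVersion("cureterm"))),
                paste0("seed: ", config$seed),
                paste0("config_md5: ", unname(tools::md5sum(cfg_path))),
                paste0("em_iterations: ", msm$iterations),
                paste0("em_converged: ", msm$converged),
                "outputs:",
                paste0("  ", basename(files), " md5=",
                       unname(tools::md5sum(files))))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(list(cohort = gen, msm = msm, cox = cox, bootstrap = boot,
                 km = km, table1 = tab1, hr_curve = hr,
                 files = c(files, cfg_path,
                           file.path(out_dir, "manifest.txt"))))
}
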