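default_covariates <- c("bmi", "smoking", "physical_activity", "education",
                        "energy_kcal", "alcohol")

# assemble the analysis frame: exposure joined to cohort, alcohol covariate
# categorized at the sex-specific non-zero median, factors coded with first
# level as reference
risk_frame <- function(cohort, exposure, covariates) {
  if (is.data.frame(exposure)) {
    stopifnot(ncol(exposure) == 2L)
    names(exposure) <- c("participant_id", ".exposure")
    df <- merge(cohort, exposure, by = "participant_id", sort = FALSE)
    df <- df[order(match(df$participant_id, cohort$participant_id)), ]
  } else {
    stopifnot(length(exposure) == nrow(cohort))
    df <- cohort
    df$.exposure <- exposure
  }
  if ("alcohol" %in% covariates && !("alcohol" %in% names(df)))
    df$alcohol <- categorize_alcohol(df$alcohol_g, df$sex)
  for (v in intersect(c("smoking", "physical_activity", "education"),
                      covariates)) {
    if (!is.factor(df[[v]])) df[[v]] <- factor(df[[v]])
  }
  df
}

#' Conditional logistic regression for matched pairs, per 1-SD exposure
#'
#' Estimates the association between a dietary exposure and case status in
#' individually matched 1:1 case-control pairs by maximizing the conditional
#' likelihood (via `survival::clogit`), with the exposure standardized to
#' unit SD so the odds ratio is per 1-SD increase. Pairs with a missing
#' exposure or covariate in either member are dropped. When the exposure is
#' itself alcohol, the categorical alcohol covariate is excluded.
#'
#' @param cohort Cohort table (`participant_id`, `pair_id`, `case`, `sex`,
#'   covariate columns; `alcohol_g` is categorized on the fly when `alcohol`
#'   is among the covariates).
#' @param exposure Numeric vector aligned with `cohort` rows, or a two-column
#'   data frame (`participant_id`, value).
#' @param covariates Character vector of adjustment variables (default: BMI,
#'   smoking, physical activity, education, total energy, alcohol category).
#' @param exposure_name Label for the output row.
#' @param exclude_alcohol Drop the alcohol covariate; defaults to `TRUE`
#'   when `exposure_name` contains "alcohol".
#' @param sd_scope Standardize by the SD over all analyzed participants
#'   (default) or over controls only.
#' @param stratum Stratum label recorded in the output.
#' @param standardize Standardize the exposure to unit SD before fitting
#'   (default `TRUE`; set `FALSE` for ORs on the raw exposure scale, e.g. a
#'   binary exposure).
#' @param min_pairs Minimum complete pairs required (default 10); below it
#'   the estimate is flagged `unstable` (and an error is raised when no
#'   pairs contribute at all). Optimizer non-convergence also sets the
#'   `unstable` flag.
#' @return A one-row `RiskEstimate` data frame: `exposure`, `stratum`,
#'   `n_pairs`, `or`, `ci_low`, `ci_high`, `p`, `beta`, `se`, `unstable`.
#' @export
fit_clogit <- function(cohort, exposure, covariates = default_covariates,
                       exposure_name = "exposure", exclude_alcohol = NULL,
                       sd_scope = c("all", "controls"), stratum = "all",
                       min_pairs = 10, standardize = TRUE) {
  sd_scope <- match.arg(sd_scope)
  if (is.null(exclude_alcohol))
    exclude_alcohol <- grepl("alcohol", exposure_name, ignore.case = TRUE)
  if (exclude_alcohol) covariates <- setdiff(covariates, "alcohol")
  df <- risk_frame(cohort, exposure, covariates)

  used <- c(".exposure", covariates)
  complete <- stats::complete.cases(df[, used, drop = FALSE])
  # pair-wise deletion: both members must be complete
  ok_pairs <- names(which(tapply(complete, df$pair_id, all)))
  df <- df[complete & df$pair_id %in% ok_pairs, , drop = FALSE]
  n_pairs <- length(unique(df$pair_id))
  if (n_pairs < 2L) stop("fewer than 2 complete pairs")

  if (standardize) {
    sd_base <- if (sd_scope == "all") df$.exposure else
      df$.exposure[df$case == 0]
    s <- stats::sd(sd_base)
    if (!is.finite(s) || s == 0) stop("exposure SD is zero; cannot standardize")
    df$.exposure_sd <- (df$.exposure - mean(df$.exposure)) / s
  } else {
    if (stats::sd(df$.exposure) == 0) stop("exposure has zero variance")
    df$.exposure_sd <- df$.exposure
  }

  # exposure constant within every pair: no within-pair contrast, the
  # conditional likelihood is flat and the estimate is exactly null
  diffs <- tapply(df$.exposure_sd * ifelse(df$case == 1L, 1, -1),
                  df$pair_id, sum)
  if (all(abs(diffs) < 1e-12))
    return(data.frame(exposure = exposure_name, stratum = stratum,
                      n_pairs = n_pairs, or = 1, ci_low = 0, ci_high = Inf,
                      p = 1, beta = 0, se = Inf, unstable = TRUE,
                      stringsAsFactors = FALSE))

  # drop covariates that are constant after pair filtering (degenerate design)
  keep <- covariates[vapply(covariates, function(v)
    length(unique(df[[v]])) > 1L, TRUE)]
  rhs <- paste(c(".exposure_sd", keep, "strata(pair_id)"), collapse = " + ")
  # capture optimizer non-convergence warnings (small strata) into the
  # unstable flag instead of letting them propagate
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::clogit(stats::as.formula(paste("case ~", rhs)), data = df),
    warning = function(w) {
      if (grepl(paste0("did not converge|loglik may be infinite|",
                       "out of iterations|beta may be infinite"),
                conditionMessage(w), ignore.case = TRUE)) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    })
  beta <- unname(stats::coef(fit)[".exposure_sd"])
  se <- sqrt(diag(fit$var))[which(names(stats::coef(fit)) == ".exposure_sd")]
  if (!is.finite(beta) || !is.finite(se) || abs(beta) > 15 || se > 50)
    stop("conditional logistic fit is degenerate (possible complete ",
         "separation): beta = ", signif(beta, 3), ", se = ", signif(se, 3))
  data.frame(exposure = exposure_name, stratum = stratum, n_pairs = n_pairs,
             or = exp(beta), ci_low = exp(beta - 1.96 * se),
             ci_high = exp(beta + 1.96 * se),
             p = 2 * stats::pnorm(-abs(beta / se)), beta = beta, se = se,
             unstable = n_pairs < min_pairs || !converged,
             stringsAsFactors = FALSE)
}

#' Sex- and tumor-site-stratified conditional logistic analyses
#'
#' Sex strata keep whole pairs (pairs are sex-matched); tumor-site strata
#' keep the pairs whose case has that site, excluding unknown-site pairs.
#' Strata with fewer than `min_pairs` complete pairs are flagged unstable
#' but still returned.
#'
#' @inheritParams fit_clogit
#' @param strata Any of `"sex"`, `"site"`.
#' @param sites Site labels analyzed (default proximal, distal, rectum).
#' @return A `RiskEstimate` data frame with one row per stratum.
#' @export
stratified_analysis <- function(cohort, exposure,
                                covariates = default_covariates,
                                exposure_name = "exposure",
                                strata = c("sex", "site"),
                                sites = c("proximal", "distal", "rectum"),
                                ...) {
  strata <- match.arg(strata, several.ok = TRUE)
  if (is.data.frame(exposure)) {
    expo_of <- function(keep) exposure[exposure$participant_id %in%
                                         keep$participant_id, , drop = FALSE]
  } else {
    expo_of <- function(keep) exposure[match(keep$participant_id,
                                             cohort$participant_id)]
  }
  na_row <- function(lab, n) data.frame(
    exposure = exposure_name, stratum = lab, n_pairs = n, or = NA_real_,
    ci_low = NA_real_, ci_high = NA_real_, p = NA_real_, beta = NA_real_,
    se = NA_real_, unstable = TRUE, stringsAsFactors = FALSE)
  try_fit <- function(sub, lab) {
    tryCatch(fit_clogit(sub, expo_of(sub), covariates, exposure_name,
                        stratum = lab, ...),
             error = function(e) na_row(lab, length(unique(sub$pair_id))))
  }
  out <- list()
  if ("sex" %in% strata) {
    for (s in sort(unique(cohort$sex))) {
      sub <- cohort[cohort$sex == s, , drop = FALSE]
      out[[length(out) + 1L]] <- try_fit(sub, paste0("sex:", s))
    }
  }
  if ("site" %in% strata) {
    case_site <- cohort$tumor_site[cohort$case == 1L]
    names(case_site) <- cohort$pair_id[cohort$case == 1L]
    for (st in sites) {
      keep_pairs <- names(case_site)[!is.na(case_site) & case_site == st]
      sub <- cohort[cohort$pair_id %in% keep_pairs, , drop = FALSE]
      out[[length(out) + 1L]] <- try_fit(sub, paste0("site:", st))
    }
  }
  do.call(rbind, out)
}
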