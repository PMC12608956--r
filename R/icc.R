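#' Condition-level intraclass correlation from a random-effect model
#'
#' Fits the intercept-only model \eqn{y_{cj} = \mu + b_c + e_{cj}} with the
#' walking conditions as random intercepts (\eqn{b_c \sim N(0,
#' \sigma_{cond}^2)}, \eqn{e_{cj} \sim N(0, \sigma_{res}^2)}) by restricted
#' maximum likelihood, and reports
#' \deqn{ICC = \sigma_{cond}^2 / (\sigma_{cond}^2 + \sigma_{res}^2),}
#' the share of ratio variance explained by systematic between-condition
#' differences. Reporting is suppressed when the estimated random-effect SD
#' is below `suppress_sd` (default 0.1: no meaningful condition signal to
#' reproduce).
#'
#' For perfectly balanced designs (equal group sizes) the REML solution has
#' a closed form via the one-way ANOVA mean squares
#' (\eqn{\hat\sigma^2_{res} = MS_W}, \eqn{\hat\sigma^2_{cond} = \max(0,
#' (MS_B - MS_W)/k)}), which `method = "auto"` uses directly; unbalanced
#' data go through [lme4::lmer()]. Both routes agree to numerical precision
#' on balanced data; the closed form is also the fallback when the
#' iterative fit fails.
#'
#' @param values Numeric step-count ratios.
#' @param groups Condition code (or other grouping factor) per value.
#' @param suppress_sd Random-effect SD below which reporting is suppressed.
#' @param method `"auto"` (closed form when balanced, REML otherwise),
#'   `"reml"` (always [lme4::lmer()]) or `"anova"` (always closed form;
#'   balanced designs only).
#' @return An `icc_result` list: `sigma_condition`, `sigma_residual`,
#'   `icc`, `suppressed`, `reason`, `n_obs`, `n_groups`, `method_used`.
#' @examples
#' fit_condition_icc(c(0, 0.05, 1, 0.95, 0.5, 0.55),
#'                   rep(c("S-25", "S-100", "Z-40"), each = 2))
#' @export
fit_condition_icc <- function(values, groups, suppress_sd = 0.1,
                              method = c("auto", "reml", "anova")) {
  method <- match.arg(method)
  stopifnot(length(values) == length(groups))
  ok <- !is.na(values)
  values <- values[ok]
  groups <- factor(groups[ok])
  groups <- droplevels(groups)
  res <- list(sigma_condition = NA_real_, sigma_residual = NA_real_,
              icc = NA_real_, suppressed = TRUE, reason = NA_character_,
              n_obs = length(values), n_groups = nlevels(groups),
              method_used = NA_character_)
  class(res) <- "icc_result"
  if (nlevels(groups) < 2 || length(values) < nlevels(groups) + 1) {
    res$reason <- "insufficient data (need >= 2 groups and replication)"
    return(res)
  }
  sizes <- table(groups)
  balanced <- length(unique(sizes)) == 1 && sizes[1] >= 2

  vc <- NULL
  if (method == "anova" || (method == "auto" && balanced)) {
    if (!balanced) stop("closed-form ANOVA estimator needs balanced data",
                        call. = FALSE)
    vc <- .anova_components(values, groups)
    res$method_used <- "anova_closed_form"
  } else {
    fit <- tryCatch(
      suppressWarnings(suppressMessages(
        lme4::lmer(values ~ 1 + (1 | groups),
                   data = data.frame(values = values, groups = groups),
                   REML = TRUE,
                   control = lme4::lmerControl(
                     check.conv.singular = "ignore",
                     calc.derivs = FALSE,
                     optimizer = "bobyqa",
                     optCtrl = list(rhobeg = 0.2, rhoend = 2e-9))))),
      error = function(e) e)
    if (inherits(fit, "error")) {
      if (balanced) {
        vc <- .anova_components(values, groups)
        res$method_used <- "anova_fallback"
      } else {
        res$reason <- paste("REML fit failed:",
                            conditionMessage(fit))
        return(res)
      }
    } else {
      v <- as.data.frame(lme4::VarCorr(fit))
      vc <- list(sigma2_b = v$vcov[v$grp == "groups"],
                 sigma2_w = v$vcov[v$grp == "Residual"])
      res$method_used <- "reml"
    }
  }
  res$sigma_condition <- sqrt(max(0, vc$sigma2_b))
  res$sigma_residual <- sqrt(vc$sigma2_w)
  denom <- vc$sigma2_b + vc$sigma2_w
  res$icc <- if (denom > 0) vc$sigma2_b / denom else NA_real_
  if (res$sigma_condition < suppress_sd) {
    res$suppressed <- TRUE
    res$reason <- sprintf(
      "random-effect SD %.4f below suppression threshold %.2f",
      res$sigma_condition, suppress_sd)
  } else {
    res$suppressed <- FALSE
  }
  res
}

# Balanced one-way random-effects variance components from ANOVA mean
# squares; equals the REML estimator for balanced data. When MSB <= MSW the
# REML maximum sits on the boundary (sigma2_b = 0), where the residual REML
# estimate is the pooled variance SS_total/(n-1), not MSW.
.anova_components <- function(values, groups) {
  k <- as.integer(table(groups)[1])
  g <- nlevels(groups)
  gm <- tapply(values, groups, mean)
  msb <- k * sum((gm - mean(values))^2) / (g - 1)
  msw <- sum((values - gm[groups])^2) / (g * (k - 1))
  if (msb <= msw) {
    list(sigma2_b = 0,
         sigma2_w = sum((values - mean(values))^2) / (g * k - 1))
  } else {
    list(sigma2_b = (msb - msw) / k, sigma2_w = msw)
  }
}

#' @export
print.icc_result <- function(x, ...) {
  if (is.na(x$icc)) {
    cat("ICC: undefined (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf(
      "ICC = %.3f (sigma_cond = %.3f, sigma_res = %.3f, n = %d, %s)%s\n",
      x$icc, x$sigma_condition, x$sigma_residual, x$n_obs, x$method_used,
      if (x$suppressed) paste0(" [suppressed: ", x$reason, "]") else ""))
  }
  invisible(x)
}

#' Intra-rater ICC for one participant and tracker
#'
#' Fits [fit_condition_icc()] on the participant's round-1 and round-2
#' ratios grouped by condition (two observations per condition for complete
#' data): high ICC means the participant reproduced the between-condition
#' differences on the second run.
#'
#' @inheritParams intra_hcp_pairs
#' @inheritParams fit_condition_icc
#' @return An `icc_result`.
#' @export
intra_hcp_icc <- function(data, participant, pat, suppress_sd = 0.1,
                          method = "auto") {
  pairs <- intra_hcp_pairs(data, participant, pat)
  if (nrow(pairs) == 0) {
    res <- fit_condition_icc(numeric(0), character(0), suppress_sd)
    res$reason <- "no condition observed in both rounds"
    return(res)
  }
  fit_condition_icc(c(pairs$ratio_a, pairs$ratio_b),
                    rep(pairs$condition, 2), suppress_sd, method)
}

#' Inter-rater ICC for one tracker
#'
#' For each unordered participant pair and round combination, the two
#' participants' condition-matched ratios are fit with
#' [fit_condition_icc()]; the headline ICC is the unweighted mean over the
#' non-suppressed fits (suppressed fits are excluded, not imputed as zero,
#' and counted in `n_suppressed`). `pooled = TRUE` instead fits one model
#' to all participants' data at once (alternative reading of the averaging
#' design).
#'
#' @inheritParams inter_hcp_kappa
#' @inheritParams fit_condition_icc
#' @param pooled Fit a single pooled model instead of averaging per-pair
#'   fits.
#' @return A list with `icc`, `n_combinations`, `n_suppressed`,
#'   `suppressed`, `breakdown`.
#' @export
inter_hcp_icc <- function(data, pat, suppress_sd = 0.1, method = "auto",
                          round_combos = c("all", "cross"),
                          pooled = FALSE) {
  round_combos <- match.arg(round_combos)
  d <- .pat_slice(data, pat)
  if (pooled) {
    fit <- fit_condition_icc(d$ratio, d$condition, suppress_sd, method)
    return(list(icc = fit$icc, n_combinations = 1L,
                n_suppressed = as.integer(fit$suppressed),
                suppressed = fit$suppressed,
                breakdown = data.frame(icc = fit$icc,
                                       suppressed = fit$suppressed)))
  }
  ids <- sort(unique(d$participant_id))
  if (length(ids) < 2) stop("need at least 2 participants", call. = FALSE)
  combos <- if (round_combos == "all") {
    cbind(a = c(1, 1, 2, 2), b = c(1, 2, 1, 2))
  } else {
    cbind(a = c(1, 2), b = c(2, 1))
  }
  rows <- list()
  for (i in seq_along(ids)[-length(ids)]) {
    for (j in seq((i + 1), length(ids))) {
      for (k in seq_len(nrow(combos))) {
        pairs <- inter_hcp_pairs(d, ids[i], ids[j],
                                 combos[k, "a"], combos[k, "b"], pat)
        fit <- if (nrow(pairs) >= 2) {
          fit_condition_icc(c(pairs$ratio_a, pairs$ratio_b),
                            rep(pairs$condition, 2), suppress_sd, method)
        } else NULL
        rows[[length(rows) + 1L]] <- data.frame(
          participant_a = ids[i], participant_b = ids[j],
          round_a = combos[k, "a"], round_b = combos[k, "b"],
          sigma_condition = if (is.null(fit)) NA_real_
                            else fit$sigma_condition,
          icc = if (is.null(fit)) NA_real_ else fit$icc,
          suppressed = if (is.null(fit)) TRUE else fit$suppressed,
          reason = if (is.null(fit)) "insufficient overlap"
                   else ifelse(is.na(fit$reason), "", fit$reason),
          stringsAsFactors = FALSE)
      }
    }
  }
  breakdown <- do.call(rbind, rows)
  usable <- !breakdown$suppressed & !is.na(breakdown$icc)
  list(
    icc = if (any(usable)) mean(breakdown$icc[usable]) else NA_real_,
    n_combinations = nrow(breakdown),
    n_suppressed = sum(!usable),
    suppressed = !any(usable),
    breakdown = breakdown
  )
}
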