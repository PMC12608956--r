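#' Zero-inflated negative binomial condition-effect model
#'
#' Models a tracker's step counts as a two-part process that mirrors how
#' detection limits act: a condition may push the device below its
#' detection limit (a structural zero, probability \eqn{\pi_c} on the logit
#' scale) and, when steps are detected, the count is negative binomial
#' (NB2) with mean proportional to the true number of steps,
#' \deqn{\log \mu_{ic} = \log(\mathrm{true\ steps}_{i}) + \beta_0 +
#'   \beta_c, \qquad
#'   \mathrm{logit}\, \pi_{c} = \gamma_0 + \gamma_c,}
#' with the walking condition as the only covariate, the true step count as
#' exposure (fixed unit coefficient), and NB overdispersion \eqn{\theta}
#' absorbing participant heterogeneity in counts. Repeated measures within
#' a participant are handled by replacing the maximum-likelihood covariance
#' with a cluster-robust Huber-White sandwich over participants (with the
#' usual G/(G-1) small-sample factor).
#'
#' When the data contain no zeros the inflation component is not
#' identifiable and the fit falls back to a plain negative binomial
#' (`nb_fallback = TRUE`, \eqn{\pi = 0}). When the full-factor inflation
#' model fails to converge, an intercept-only inflation component is tried
#' (`inflation_fallback = TRUE`).
#'
#' @param trials Trial records for one tracker (columns `participant_id`,
#'   `condition`, `true_steps`, `counted_steps`); rows with missing counts
#'   are dropped.
#' @param inflation `"condition"` (default: condition factor in the
#'   inflation component) or `"intercept"`.
#' @param ref Reference condition for both factors (default `"S-100"` when
#'   present, else the first condition in protocol order).
#' @param maxit Maximum optimizer iterations.
#' @return A `zinb_fit` object with elements `coefficients` (named vector:
#'   count-model `count_*`, inflation `zero_*`, and `log_theta`), `theta`,
#'   `vcov` (cluster-robust), `vcov_naive` (inverse observed information),
#'   `conditions`, `ref`, `n_obs`, `n_clusters`, `converged`, `loglik`,
#'   `nb_fallback`, `inflation_fallback`.
#' @export
fit_zinb <- function(trials, inflation = c("condition", "intercept"),
                     ref = NULL, maxit = 1000L) {
  inflation <- match.arg(inflation)
  trials <- trials[!is.na(trials$counted_steps), , drop = FALSE]
  if (nrow(trials) == 0) stop("no usable trial records", call. = FALSE)
  conds <- intersect(protocol_codes(), unique(trials$condition))
  if (length(conds) < 2) {
    stop("need data from at least 2 conditions", call. = FALSE)
  }
  if (is.null(ref)) ref <- if ("S-100" %in% conds) "S-100" else conds[1]
  conds <- c(ref, setdiff(conds, ref))
  f <- factor(trials$condition, levels = conds)
  X <- stats::model.matrix(~f)
  colnames(X) <- c("(Intercept)", paste0("cond", conds[-1]))
  y <- as.integer(trials$counted_steps)
  off <- log(trials$true_steps)
  cluster <- trials$participant_id

  has_zeros <- any(y == 0)
  Z <- if (!has_zeros) NULL
       else if (inflation == "condition") X else X[, 1, drop = FALSE]

  fit <- .zinb_ml(y, X, Z, off, maxit = maxit)
  inflation_fallback <- FALSE
  if (!fit$converged && has_zeros && inflation == "condition") {
    fit2 <- .zinb_ml(y, X, X[, 1, drop = FALSE], off, maxit = maxit)
    if (fit2$converged) {
      fit <- fit2
      Z <- X[, 1, drop = FALSE]
      inflation_fallback <- TRUE
    }
  }

  # cluster-robust sandwich: A^{-1} B A^{-1} with A the observed
  # information and B the outer product of per-participant score sums
  A <- stats::optimHess(fit$par, .zinb_nll, y = y, X = X, Z = Z, off = off)
  scores <- .cluster_scores(fit$par, y, X, Z, off, cluster)
  G <- nrow(scores)
  B <- crossprod(scores) * G / (G - 1)
  Ainv <- tryCatch(solve(A), error = function(e) .pseudo_inverse(A))
  vcov_naive <- Ainv
  vcov_cl <- Ainv %*% B %*% Ainv
  vcov_cl <- (vcov_cl + t(vcov_cl)) / 2

  p <- ncol(X)
  q <- if (is.null(Z)) 0L else ncol(Z)
  nm_count <- paste0("count_", colnames(X))
  nm_zero <- if (q) paste0("zero_", colnames(Z)) else character()
  names(fit$par) <- c(nm_count, nm_zero, "log_theta")
  dimnames(vcov_cl) <- dimnames(vcov_naive) <-
    list(names(fit$par), names(fit$par))

  structure(list(
    coefficients = fit$par,
    theta = exp(fit$par[["log_theta"]]),
    vcov = vcov_cl,
    vcov_naive = vcov_naive,
    conditions = conds,
    ref = ref,
    inflation = if (is.null(Z)) "none"
                else if (ncol(Z) == 1) "intercept" else "condition",
    n_obs = length(y),
    n_clusters = G,
    converged = fit$converged,
    loglik = -fit$value,
    nb_fallback = !has_zeros,
    inflation_fallback = inflation_fallback,
    p_count = p, q_zero = q
  ), class = "zinb_fit")
}

# negative log-likelihood of the ZINB (Z = NULL: plain NB)
.zinb_nll <- function(par, y, X, Z, off) {
  p <- ncol(X)
  beta <- par[seq_len(p)]
  theta <- exp(par[length(par)])
  log_mu <- off + drop(X %*% beta)
  mu <- exp(log_mu)
  ll_nb <- stats::dnbinom(y, size = theta, mu = mu, log = TRUE)
  if (is.null(Z)) return(-sum(ll_nb))
  q <- ncol(Z)
  eta <- drop(Z %*% par[p + seq_len(q)])
  log_pi <- stats::plogis(eta, log.p = TRUE)
  log_1mpi <- stats::plogis(-eta, log.p = TRUE)
  ll <- numeric(length(y))
  z0 <- y == 0
  if (any(z0)) {
    # log(pi + (1-pi) * P(NB = 0)) via log-sum-exp
    a <- log_pi[z0]
    b <- log_1mpi[z0] + ll_nb[z0]
    m <- pmax(a, b)
    ll[z0] <- m + log(exp(a - m) + exp(b - m))
  }
  ll[!z0] <- log_1mpi[!z0] + ll_nb[!z0]
  -sum(ll)
}

.zinb_ml <- function(y, X, Z, off, maxit = 1000L) {
  p <- ncol(X)
  q <- if (is.null(Z)) 0L else ncol(Z)
  # empirical starting values: log mean ratio among positives for the
  # count part, logit zero fraction for the inflation part
  pos <- y > 0
  start_int <- log(max(mean(y[pos] / exp(off[pos])), 1e-3))
  beta0 <- c(start_int, rep(0, p - 1))
  gamma0 <- if (q) c(stats::qlogis(min(max(mean(y == 0), 0.02), 0.98)),
                     rep(0, q - 1)) else numeric()
  start <- c(beta0, gamma0, log(5))
  lower <- c(rep(-15, p + q), -5)
  upper <- c(rep(15, p + q), 10)
  opt <- stats::optim(start, .zinb_nll, y = y, X = X, Z = Z, off = off,
                      method = "L-BFGS-B", lower = lower, upper = upper,
                      control = list(maxit = maxit, factr = 1e4))
  # polish with BFGS from the box solution (interior refinement)
  opt2 <- tryCatch(
    stats::optim(opt$par, .zinb_nll, y = y, X = X, Z = Z, off = off,
                 method = "BFGS",
                 control = list(maxit = maxit, reltol = 1e-12)),
    error = function(e) opt)
  if (!inherits(opt2, "error") && opt2$value <= opt$value) opt <- opt2
  list(par = opt$par, value = opt$value, converged = opt$convergence == 0)
}

# per-cluster score vectors (central finite differences of the cluster
# log-likelihood at the MLE)
.cluster_scores <- function(par, y, X, Z, off, cluster) {
  ids <- unique(cluster)
  k <- length(par)
  h <- 1e-6 * pmax(1, abs(par))
  scores <- matrix(0, nrow = length(ids), ncol = k)
  for (ci in seq_along(ids)) {
    sel <- cluster == ids[ci]
    Zc <- if (is.null(Z)) NULL else Z[sel, , drop = FALSE]
    for (j in seq_len(k)) {
      pp <- pm <- par
      pp[j] <- pp[j] + h[j]
      pm[j] <- pm[j] - h[j]
      scores[ci, j] <-
        (.zinb_nll(pm, y[sel], X[sel, , drop = FALSE], Zc, off[sel]) -
         .zinb_nll(pp, y[sel], X[sel, , drop = FALSE], Zc, off[sel])) /
        (2 * h[j])
    }
  }
  scores
}

# Moore-Penrose pseudoinverse (eigen based); used only when the observed
# information is numerically singular
.pseudo_inverse <- function(A, tol = 1e-10) {
  e <- eigen(A, symmetric = TRUE)
  keep <- abs(e$values) > tol * max(abs(e$values))
  e$vectors[, keep, drop = FALSE] %*%
    diag(1 / e$values[keep], sum(keep)) %*%
    t(e$vectors[, keep, drop = FALSE])
}

#' @export
print.zinb_fit <- function(x, ...) {
  cat("Zero-inflated negative binomial condition-effect fit\n")
  cat(sprintf("  %d observations, %d participant clusters, theta = %.2f\n",
              x$n_obs, x$n_clusters, x$theta))
  cat(sprintf("  inflation component: %s%s%s\n", x$inflation,
              if (x$nb_fallback) " (no zeros: plain NB fallback)" else "",
              if (x$inflation_fallback)
                " (condition factor inestimable: intercept fallback)"
              else ""))
  mm <- marginal_means(x)
  cat("  marginal mean counts at 20 true steps:\n")
  print(round(stats::setNames(mm$estimate, mm$condition), 2))
  invisible(x)
}

#' Inflation probabilities of a ZINB fit
#' @param fit A `zinb_fit`.
#' @return Named vector of structural-zero probabilities per condition.
#' @export
zero_probabilities <- function(fit) {
  stopifnot(inherits(fit, "zinb_fit"))
  if (fit$q_zero == 0) {
    return(stats::setNames(rep(0, length(fit$conditions)), fit$conditions))
  }
  Zc <- .condition_design(fit, "zero")
  stats::setNames(as.numeric(stats::plogis(
    Zc %*% fit$coefficients[fit$p_count + seq_len(fit$q_zero)])),
    fit$conditions)
}

# design rows per condition for the count ("count") or inflation ("zero")
# component
.condition_design <- function(fit, part = c("count", "zero")) {
  part <- match.arg(part)
  k <- length(fit$conditions)
  if (part == "zero" && fit$q_zero == 1) {
    return(matrix(1, nrow = k, ncol = 1))
  }
  D <- cbind(1, rbind(0, diag(k - 1)))
  rownames(D) <- fit$conditions
  D
}

# Jacobian of the marginal means with respect to the full parameter vector
.marginal_jacobian <- function(fit, true_steps) {
  k <- length(fit$conditions)
  Xc <- .condition_design(fit, "count")
  beta <- fit$coefficients[seq_len(fit$p_count)]
  mu <- true_steps * exp(drop(Xc %*% beta))
  if (fit$q_zero > 0) {
    Zc <- .condition_design(fit, "zero")
    gamma <- fit$coefficients[fit$p_count + seq_len(fit$q_zero)]
    pi <- as.numeric(stats::plogis(drop(Zc %*% gamma)))
  } else {
    Zc <- NULL
    pi <- rep(0, k)
  }
  m <- (1 - pi) * mu
  J <- matrix(0, nrow = k, ncol = length(fit$coefficients))
  J[, seq_len(fit$p_count)] <- (1 - pi) * mu * Xc
  if (fit$q_zero > 0) {
    J[, fit$p_count + seq_len(fit$q_zero)] <- -pi * (1 - pi) * mu * Zc
  }
  list(m = m, J = J)
}

#' Marginal mean counted steps per condition
#'
#' The expected device count for a walk of `true_steps` true steps under
#' each condition, \eqn{(1 - \pi_c)\,\mu_c}, combining the detection
#' failure probability and the conditional count mean. Standard errors are
#' delta-method transforms of the cluster-robust covariance.
#'
#' @param fit A `zinb_fit`.
#' @param true_steps Exposure at which means are evaluated (default 20, the
#'   protocol's walk length).
#' @return Data frame with `condition`, `estimate`, `std_error`,
#'   `zero_prob`, `count_mean`.
#' @export
marginal_means <- function(fit, true_steps = 20) {
  stopifnot(inherits(fit, "zinb_fit"))
  mj <- .marginal_jacobian(fit, true_steps)
  se <- sqrt(pmax(0, diag(mj$J %*% fit$vcov %*% t(mj$J))))
  data.frame(
    condition = fit$conditions,
    estimate = mj$m,
    std_error = se,
    zero_prob = as.numeric(zero_probabilities(fit)),
    count_mean = mj$m / (1 - as.numeric(zero_probabilities(fit))),
    stringsAsFactors = FALSE
  )
}

# Wald chi-square test of L %*% m = 0 on the marginal-mean scale
.wald_marginal <- function(fit, L, true_steps = 20) {
  mj <- .marginal_jacobian(fit, true_steps)
  est <- drop(L %*% mj$m)
  V <- L %*% mj$J %*% fit$vcov %*% t(mj$J) %*% t(L)
  V <- (V + t(V)) / 2
  Vinv <- tryCatch(solve(V), error = function(e) .pseudo_inverse(V))
  stat <- drop(t(est) %*% Vinv %*% est)
  df <- qr(V)$rank
  list(est = est, se = sqrt(pmax(0, diag(as.matrix(V)))),
       statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Marginal-mean contrasts between protocol conditions
#'
#' Evaluates, on the marginal-mean scale at `true_steps` true steps:
#' \itemize{
#'   \item the effect of step size within each category (pairwise
#'     differences between that category's step-size levels, plus a joint
#'     Wald test of equality across all its levels);
#'   \item the difference between each non-straight category (T, Z, C, W,
#'     L) and the straight-line category S, averaged over the step sizes
#'     present in both;
#'   \item the global Wald test of no difference between any conditions.
#' }
#' All estimates are in counted steps; inference uses the cluster-robust
#' covariance through the delta method with a large-sample normal /
#' chi-square reference.
#'
#' @inheritParams marginal_means
#' @return A list with `contrasts` (data frame: `label`, `type`,
#'   `estimate`, `std_error`, `statistic`, `df`, `p_value`) and
#'   `global_p_value`.
#' @export
contrast_tests <- function(fit, true_steps = 20) {
  stopifnot(inherits(fit, "zinb_fit"))
  conds <- fit$conditions
  k <- length(conds)
  cats <- condition_category(conds)
  sizes <- condition_step_size(conds)
  unit <- function(cond) as.numeric(conds == cond)
  rows <- list()
  add <- function(label, type, w) {
    res <- .wald_marginal(fit, matrix(w, nrow = 1), true_steps)
    rows[[length(rows) + 1L]] <<- data.frame(
      label = label, type = type, estimate = res$est, std_error = res$se,
      statistic = res$statistic, df = res$df, p_value = res$p_value,
      stringsAsFactors = FALSE)
  }

  for (cc in intersect(c("S", "T", "Z", "C", "W", "L"), unique(cats))) {
    lv <- conds[cats == cc]
    lv <- lv[order(-condition_step_size(lv))]
    if (length(lv) < 2) next
    for (i in seq_len(length(lv) - 1)) {
      add(paste0(lv[i], " - ", lv[i + 1]), "step_size_within_category",
          unit(lv[i]) - unit(lv[i + 1]))
    }
    if (length(lv) > 2) {
      L <- t(vapply(seq_len(length(lv) - 1),
                    function(i) unit(lv[i]) - unit(lv[i + 1]),
                    numeric(k)))
      res <- .wald_marginal(fit, L, true_steps)
      rows[[length(rows) + 1L]] <- data.frame(
        label = paste0("step size within ", cc, " (joint)"),
        type = "step_size_joint", estimate = NA_real_,
        std_error = NA_real_, statistic = res$statistic, df = res$df,
        p_value = res$p_value, stringsAsFactors = FALSE)
    }
  }

  s_sizes <- sizes[cats == "S"]
  for (cc in intersect(c("T", "Z", "C", "W", "L"), unique(cats))) {
    shared <- intersect(sizes[cats == cc], s_sizes)
    if (!length(shared)) next
    w <- rep(0, k)
    for (s in shared) {
      w <- w + (unit(paste0(cc, "-", s)) - unit(paste0("S-", s))) /
        length(shared)
    }
    add(paste0(cc, " - S (avg over ",
               paste(sort(shared, decreasing = TRUE), collapse = "/"),
               "%)"), "category_vs_S", w)
  }

  Lg <- t(vapply(seq_len(k - 1), function(i) unit(conds[i + 1]) -
                   unit(conds[1]), numeric(k)))
  glob <- .wald_marginal(fit, Lg, true_steps)
  contrasts <- do.call(rbind, rows)
  list(contrasts = contrasts,
       global_statistic = glob$statistic,
       global_df = glob$df,
       global_p_value = glob$p_value)
}
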