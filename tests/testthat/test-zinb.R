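sim_zinb_trials <- function(zero_probs, mean_ratios, n_participants = 60,
                            dispersion = 10, effect_sd = 0,
                            seed = 1, n_rounds = 2) {
  conds <- names(zero_probs)
  prof <- lapply(conds, function(cc) {
    zp <- zero_probs[[cc]]
    detection_scenario(
      label = if (zp <= 0.05) "detectable"
              else if (zp >= 0.9) "undetectable" else "near_limit",
      zero_prob = zp, mean_ratio = mean_ratios[[cc]],
      dispersion = dispersion)
  })
  names(prof) <- conds
  cfg <- synthetic_config(n_participants,
                          pat_profiles = list(dev = prof),
                          participant_effect_sd = effect_sd,
                          true_step_jitter = c("20" = 1),
                          conditions = conds, n_rounds = n_rounds)
  simulate_dataset(cfg, seed = seed)
}

test_that("error-free counts trigger the NB fallback with marginal means near 20", {
  tr <- sim_zinb_trials(c("S-100" = 0, "S-75" = 0),
                        c("S-100" = 1, "S-75" = 1),
                        n_participants = 30, dispersion = 200, seed = 2)
  fit <- fit_zinb(tr)
  expect_true(fit$nb_fallback)
  expect_identical(fit$inflation, "none")
  mm <- marginal_means(fit)
  expect_true(all(abs(mm$estimate - 20) < 1))
  expect_equal(as.numeric(zero_probabilities(fit)), c(0, 0))
})

test_that("the exposure enters with a fixed unit coefficient", {
  tr <- sim_zinb_trials(c("S-100" = 0.1, "S-40" = 0.4),
                        c("S-100" = 0.9, "S-40" = 0.6), seed = 3)
  fit <- fit_zinb(tr)
  m20 <- marginal_means(fit, true_steps = 20)
  m40 <- marginal_means(fit, true_steps = 40)
  expect_equal(m40$estimate, 2 * m20$estimate, tolerance = 1e-12)
})

test_that("a condition with inflation 0.5 and full detection has marginal mean near 10", {
  tr <- sim_zinb_trials(c("S-100" = 0.02, "S-40" = 0.5),
                        c("S-100" = 1, "S-40" = 1),
                        n_participants = 150, dispersion = 30, seed = 4)
  fit <- fit_zinb(tr)
  mm <- marginal_means(fit)
  expect_lt(abs(mm$estimate[mm$condition == "S-40"] - 10), 1)
  expect_lt(abs(mm$zero_prob[mm$condition == "S-40"] - 0.5), 0.1)
})

test_that("marginal mean decreases as the inflation probability rises", {
  tr <- sim_zinb_trials(c("S-100" = 0.1, "S-75" = 0.3),
                        c("S-100" = 0.9, "S-75" = 0.8), seed = 5)
  fit <- fit_zinb(tr)
  base <- marginal_means(fit)$estimate
  # raise the inflation intercept, holding the count component fixed
  fit2 <- fit
  fit2$coefficients["zero_(Intercept)"] <-
    fit2$coefficients["zero_(Intercept)"] + 1
  expect_true(all(marginal_means(fit2)$estimate < base))
})

test_that("the fit agrees with an independent ZINB implementation", {
  tr <- sim_zinb_trials(c("S-100" = 0.1, "S-75" = 0.35, "S-40" = 0.6),
                        c("S-100" = 0.95, "S-75" = 0.8, "S-40" = 0.6),
                        n_participants = 80, seed = 6)
  fit <- fit_zinb(tr)
  tmb <- glmmTMB::glmmTMB(
    counted_steps ~ cond + offset(log(true_steps)),
    ziformula = ~cond,
    family = glmmTMB::nbinom2(),
    data = transform(tr, cond = factor(condition,
                                       levels = fit$conditions)))
  tmb_fix <- glmmTMB::fixef(tmb)
  expect_lt(max(abs(fit$coefficients[1:3] - tmb_fix$cond)), 5e-3)
  expect_lt(max(abs(fit$coefficients[4:6] - tmb_fix$zi)), 5e-2)
  expect_lt(abs(fit$theta - glmmTMB::sigma(tmb)) / fit$theta, 1e-2)
  expect_lt(abs(fit$loglik - as.numeric(stats::logLik(tmb))), 1e-3)
})

test_that("without structural zeros, ZINB marginal means match a plain NB fit", {
  # strong overdispersion: sampling zeros but no structural inflation
  tr <- sim_zinb_trials(c("S-100" = 0, "S-40" = 0),
                        c("S-100" = 0.9, "S-40" = 0.85),
                        n_participants = 120, dispersion = 0.4, seed = 7)
  expect_true(any(tr$counted_steps == 0))
  fit <- fit_zinb(tr)
  nb <- MASS::glm.nb(counted_steps ~ cond + offset(log(true_steps)),
                     data = transform(tr, cond = factor(condition,
                                                        levels = fit$conditions)))
  nb_means <- 20 * exp(cumsum(stats::coef(nb)))
  expect_lt(max(abs(marginal_means(fit)$estimate - nb_means)), 0.5)
})

test_that("cluster-robust standard errors exceed naive ones under clustering", {
  # strong participant effects induce positive within-cluster correlation
  bigger <- 0
  n_rep <- 12
  for (s in seq_len(n_rep)) {
    tr <- sim_zinb_trials(c("S-100" = 0.1, "S-40" = 0.4),
                          c("S-100" = 0.9, "S-40" = 0.6),
                          n_participants = 40, effect_sd = 0.4,
                          seed = 100 + s)
    fit <- fit_zinb(tr)
    i <- "count_(Intercept)"
    if (fit$vcov[i, i] > fit$vcov_naive[i, i]) bigger <- bigger + 1
  }
  expect_gte(bigger / n_rep, 0.9)
})

test_that("contrasts cover step size, category-vs-S and a global test", {
  tr <- sim_zinb_trials(
    c("S-75" = 0.1, "S-40" = 0.3, "W-75" = 0.6, "W-40" = 0.8),
    c("S-75" = 0.9, "S-40" = 0.75, "W-75" = 0.5, "W-40" = 0.4),
    n_participants = 80, seed = 8)
  fit <- fit_zinb(tr)
  ct <- contrast_tests(fit)
  expect_true("S-75 - S-40" %in% ct$contrasts$label)
  expect_true("W-75 - W-40" %in% ct$contrasts$label)
  wS <- ct$contrasts[ct$contrasts$type == "category_vs_S", ]
  expect_equal(nrow(wS), 1L)
  # generator truth: W sits far below S; the contrast must detect it
  expect_lt(wS$estimate, 0)
  expect_lt(wS$p_value, 0.01)
  expect_lt(ct$global_p_value, 1e-4)
  # hand-check the averaged contrast against the marginal means
  mm <- marginal_means(fit)
  m <- stats::setNames(mm$estimate, mm$condition)
  expect_equal(wS$estimate,
               unname(((m["W-75"] - m["S-75"]) + (m["W-40"] - m["S-40"])) / 2),
               tolerance = 1e-8)
})

test_that("inputs without enough conditions are rejected", {
  tr <- sim_zinb_trials(c("S-100" = 0.1), c("S-100" = 0.9),
                        n_participants = 10, seed = 9)
  expect_error(fit_zinb(tr), "at least 2 conditions")
})
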