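sim_grouped <- function(sigma_cond, sigma_res, n_groups = 12, k = 6) {
  b <- rnorm(n_groups, 0, sigma_cond)
  data.frame(group = rep(seq_len(n_groups), each = k),
             value = rep(b, each = k) + rnorm(n_groups * k, 0, sigma_res))
}

test_that("between-dominated variance gives ICC near 1", {
  values <- c(rep(0, 6) + rnorm(6, 0, 0.01), rep(1, 6) + rnorm(6, 0, 0.01))
  res <- fit_condition_icc(values, rep(c("A", "B"), each = 6))
  expect_gte(res$icc, 0.95)
  expect_false(res$suppressed)
})

test_that("no between-group signal triggers the suppression rule", {
  res <- fit_condition_icc(rep(0.7, 12), rep(letters[1:6], each = 2))
  expect_true(res$suppressed)
  expect_match(res$reason, "below suppression threshold")
  expect_equal(res$sigma_condition, 0)
})

test_that("closed-form balanced estimator matches iterative REML to 1e-6", {
  set.seed(202)
  for (i in 1:20) {
    d <- sim_grouped(sigma_cond = runif(1, 0.05, 0.5),
                     sigma_res = runif(1, 0.05, 0.5),
                     n_groups = 12, k = sample(2:4, 1))
    a <- fit_condition_icc(d$value, d$group, method = "anova")
    r <- fit_condition_icc(d$value, d$group, method = "reml")
    expect_equal(a$sigma_condition, r$sigma_condition, tolerance = 1e-6)
    expect_equal(a$sigma_residual, r$sigma_residual, tolerance = 1e-6)
  }
})

test_that("unbalanced data fall back to the iterative REML route", {
  set.seed(9)
  d <- sim_grouped(0.4, 0.2)
  d <- d[-(1:3), ] # unbalance the first group
  res <- fit_condition_icc(d$value, d$group)
  expect_equal(res$method_used, "reml")
  expect_false(res$suppressed)
})

test_that("ICC is invariant to location shifts and positive scaling", {
  set.seed(17)
  d <- sim_grouped(0.3, 0.3)
  base <- fit_condition_icc(d$value, d$group)
  shifted <- fit_condition_icc(d$value + 5, d$group)
  scaled <- fit_condition_icc(d$value * 3, d$group)
  expect_equal(base$icc, shifted$icc, tolerance = 1e-8)
  expect_equal(base$icc, scaled$icc, tolerance = 1e-8)
})

test_that("degenerate inputs are reported, not errored", {
  res <- fit_condition_icc(c(1, 2), c("a", "a"))
  expect_true(res$suppressed)
  expect_match(res$reason, "insufficient")
})

test_that("intra-rater ICC reflects test-retest reproduction", {
  d <- clean_dataset(simulate_dataset(toy_config(4), seed = 21),
                     provenance = "synthetic")
  # perfect test-retest: copy round 1 into round 2
  dd <- d[d$pat == "limit" & d$participant_id == 1, ]
  r1 <- dd[dd$round == 1, ]
  r2 <- r1
  r2$round <- 2L
  perfect <- rbind(r1, r2)
  res <- intra_hcp_icc(perfect, 1, "limit")
  expect_gt(res$icc, 0.99)

  # balanced 2-per-group design equals the closed-form hand computation
  res_real <- intra_hcp_icc(d, 2, "limit")
  pairs <- intra_hcp_pairs(d, 2, "limit")
  v <- c(pairs$ratio_a, pairs$ratio_b)
  gr <- factor(rep(pairs$condition, 2))
  gm <- tapply(v, gr, mean)
  msb <- 2 * sum((gm - mean(v))^2) / (nlevels(gr) - 1)
  msw <- sum((v - gm[gr])^2) / nlevels(gr)
  s2b <- max(0, (msb - msw) / 2)
  expect_equal(res_real$icc, s2b / (s2b + msw), tolerance = 1e-8)

  # missing round: undefined with reason
  d1 <- d[!(d$participant_id == 3 & d$round == 2), ]
  res3 <- suppressMessages(intra_hcp_icc(d1, 3, "limit"))
  expect_true(is.na(res3$icc))
  expect_match(res3$reason, "no condition")
})

test_that("inter-rater ICC is near 1 for identical participants and averages fits", {
  d <- clean_dataset(simulate_dataset(toy_config(4), seed = 33),
                     provenance = "synthetic")
  r1 <- d[d$participant_id == 1 & d$pat == "limit" & d$round == 1, ]
  r2 <- r1
  r2$round <- 2L
  base <- rbind(r1, r2)
  twin <- base
  twin$participant_id <- 2L
  res_id <- inter_hcp_icc(rbind(base, twin), "limit")
  expect_gt(res_id$icc, 0.99)

  res <- inter_hcp_icc(d, "limit")
  expect_equal(res$n_combinations, choose(4, 2) * 4)
  usable <- !res$breakdown$suppressed & !is.na(res$breakdown$icc)
  expect_equal(res$icc, mean(res$breakdown$icc[usable]))

  pooled <- inter_hcp_icc(d, "limit", pooled = TRUE)
  expect_true(is.finite(pooled$icc))
})

test_that("participants with no shared condition structure give low or suppressed ICC", {
  set.seed(44)
  g <- expand.grid(participant_id = 1:6, round = 1:2,
                   condition = analysis_codes(), stringsAsFactors = FALSE)
  g$pat <- "dev"
  g$ratio <- runif(nrow(g)) # no condition effect at all
  res <- inter_hcp_icc(g, "dev")
  expect_true(res$suppressed || res$icc < 0.35)
})
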