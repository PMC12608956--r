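test_that("band_of partitions the ratio axis with the stated boundaries", {
  expect_equal(as.character(band_of(c(0, 0.19, 0.2, 0.49, 0.5, 0.8,
                                      0.801, 0.95, 1.55))),
               c("low", "low", "mid_low", "mid_low", "mid_high",
                 "mid_high", "high", "high", "high"))
  expect_error(band_of(-0.1), "nonnegative")
  # every nonnegative ratio lands in exactly one band
  expect_false(anyNA(band_of(seq(0, 3, by = 0.01))))
})

test_that("the weight table matches the verbal clauses on all 16 band pairs", {
  w <- weight_table()
  expect_equal(dim(w), c(4L, 4L))
  for (a in names(band_rep)) {
    for (b in names(band_rep)) {
      expect_equal(w[a, b],
                   naive_pair_weight(band_rep[[a]], band_rep[[b]]),
                   info = paste(a, b))
    }
  }
  expect_identical(w, t(w)) # symmetry
})

test_that("pair_weight reproduces the clause examples and self-agreement", {
  expect_equal(pair_weight(0.95, 0.05), 0.0)
  expect_equal(pair_weight(0.65, 0.10), 0.5)
  expect_equal(pair_weight(0.30, 0.95), 0.5)
  for (x in c(band_rep, 0, 0.2, 0.5, 0.8, 1.55)) {
    expect_equal(pair_weight(x, x), 1.0)
  }
  expect_error(pair_weight(-1, 0.5), "nonnegative")
})

test_that("agreement_rate is the mean pair weight; empty sets are undefined", {
  pairs <- data.frame(ratio_a = c(0.95, 0.95), ratio_b = c(0.05, 0.95))
  expect_equal(agreement_rate(pairs), 0.5)
  expect_equal(agreement_rate(data.frame(ratio_a = 0.3, ratio_b = 0.3)), 1)
  expect_warning(res <- agreement_rate(data.frame(ratio_a = numeric(),
                                                  ratio_b = numeric())),
                 "empty")
  expect_true(is.na(res))
})

test_that("weighted kappa is 1 under perfect agreement with band diversity", {
  pairs <- data.frame(ratio_a = c(rep(0.05, 5), rep(0.95, 5)),
                      ratio_b = c(rep(0.05, 5), rep(0.95, 5)))
  res <- weighted_kappa(pairs)
  expect_false(res$suppressed)
  expect_equal(res$observed_agreement, 1)
  expect_lt(res$chance_agreement, 1)
  expect_equal(res$kappa, 1)
})

test_that("kappa is suppressed when all ratios are above 0.5 or marginals degenerate", {
  pairs <- data.frame(ratio_a = c(0.95, 0.7), ratio_b = c(0.9, 0.99))
  res <- weighted_kappa(pairs)
  expect_true(res$suppressed)
  expect_match(res$reason, "above 0.5")
  # all ratios in one band but not all above 0.5: chance agreement is 1
  pairs2 <- data.frame(ratio_a = rep(0.3, 4), ratio_b = rep(0.4, 4))
  res2 <- weighted_kappa(pairs2)
  expect_true(res2$suppressed)
  expect_match(res2$reason, "degenerate")
})

test_that("kappa is chance-level under independent band assignments", {
  set.seed(421)
  n <- 10000
  pairs <- data.frame(ratio_a = band_rep[sample(4, n, replace = TRUE)],
                      ratio_b = band_rep[sample(4, n, replace = TRUE)])
  res <- weighted_kappa(pairs)
  expect_false(res$suppressed)
  expect_lt(abs(res$kappa), 0.05)
  # pooled-marginals policy gives the same answer for exchangeable members
  res_pooled <- weighted_kappa(pairs, chance_marginals = "pooled")
  expect_lt(abs(res_pooled$kappa - res$kappa), 0.02)
})

test_that("kappa never exceeds 1 and equals 1 only at perfect agreement", {
  set.seed(77)
  for (i in 1:50) {
    pairs <- data.frame(ratio_a = random_ratios(20),
                        ratio_b = random_ratios(20))
    res <- weighted_kappa(pairs)
    if (!res$suppressed) {
      expect_lte(res$kappa, 1)
      if (res$kappa == 1) expect_equal(res$observed_agreement, 1)
    }
  }
})

test_that("intra-rater pairs join round 1 and round 2 per condition", {
  d <- clean_dataset(simulate_dataset(toy_config(4), seed = 3),
                     provenance = "synthetic")
  pairs <- intra_hcp_pairs(d, 2, "limit")
  expect_equal(nrow(pairs), 12L)
  # member A is round 1, member B is round 2 (brute-force join oracle)
  for (i in seq_len(nrow(pairs))) {
    a <- d$ratio[d$participant_id == 2 & d$pat == "limit" &
                   d$round == 1 & d$condition == pairs$condition[i]]
    b <- d$ratio[d$participant_id == 2 & d$pat == "limit" &
                   d$round == 2 & d$condition == pairs$condition[i]]
    expect_equal(pairs$ratio_a[i], a)
    expect_equal(pairs$ratio_b[i], b)
  }
  # a participant with no round-1 data yields an empty pair set
  d1 <- d[!(d$participant_id == 3 & d$round == 1), ]
  expect_message(p3 <- intra_hcp_pairs(d1, 3, "limit"), "no condition")
  expect_equal(nrow(p3), 0L)
})

test_that("inter-rater kappa averages over participant pairs and round combos", {
  d <- clean_dataset(simulate_dataset(toy_config(5), seed = 8),
                     provenance = "synthetic")
  res <- inter_hcp_kappa(d, "limit")
  expect_equal(res$n_combinations, choose(5, 2) * 4)
  expect_equal(res$kappa,
               mean(res$breakdown$kappa[!res$breakdown$suppressed]))
  res_cross <- inter_hcp_kappa(d, "limit", round_combos = "cross")
  expect_equal(res_cross$n_combinations, choose(5, 2) * 2)

  # two identical participants (same ratios everywhere, both rounds) with
  # band diversity agree perfectly
  r1 <- d[d$participant_id == 1 & d$pat == "limit" & d$round == 1, ]
  r2 <- r1
  r2$round <- 2L
  base <- rbind(r1, r2)
  twin <- base
  twin$participant_id <- 2L
  dd <- rbind(base, twin)
  res_id <- inter_hcp_kappa(dd, "limit")
  expect_equal(res_id$kappa, 1)
})

test_that("inter-rater kappa is chance-level for independent participants", {
  # many pseudo-participants with independent band draws per condition
  set.seed(31)
  n_p <- 40
  g <- expand.grid(participant_id = seq_len(n_p), round = 1:2,
                   condition = analysis_codes(),
                   stringsAsFactors = FALSE)
  g$pat <- "dev"
  g$ratio <- band_rep[sample(4, nrow(g), replace = TRUE)]
  res <- inter_hcp_kappa(g, "dev")
  expect_lt(abs(res$kappa), 0.05)
})

test_that("Landis-Koch labels follow the published cut-offs", {
  expect_equal(landis_koch_label(c(-0.2, 0, 0.1, 0.38, 0.5, 0.62, 0.9, 1)),
               c("poor", "poor", "slight", "fair", "moderate",
                 "substantial", "almost perfect", "almost perfect"))
  expect_true(is.na(landis_koch_label(NA_real_)))
})
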