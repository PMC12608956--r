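# Independent oracles for the agreement statistics: a direct, naive
# translation of the verbal weight clauses (kept deliberately separate from
# the package's band/table implementation).

naive_pair_weight <- function(a, b) {
  below_02  <- function(x) x < 0.2
  bet_02_05 <- function(x) x >= 0.2 && x < 0.5
  bet_05_08 <- function(x) x >= 0.5 && x <= 0.8
  above_08  <- function(x) x > 0.8
  bet_02_08 <- function(x) x >= 0.2 && x <= 0.8
  above_05  <- function(x) x >= 0.5
  below_05  <- function(x) x < 0.5

  either <- function(f, g) (f(a) && g(b)) || (f(b) && g(a))
  if (either(above_08, below_02)) return(0.0)
  if (either(bet_05_08, below_02) || either(bet_02_05, above_08)) {
    return(0.5)
  }
  if ((bet_02_08(a) && bet_02_08(b)) ||
      either(above_08, above_05) ||
      either(below_02, below_05)) {
    return(1.0)
  }
  stop("no clause matched for (", a, ", ", b, ")")
}

naive_agreement_rate <- function(ratio_a, ratio_b) {
  total <- 0
  for (i in seq_along(ratio_a)) {
    total <- total + naive_pair_weight(ratio_a[i], ratio_b[i])
  }
  total / length(ratio_a)
}

# representative ratio inside each band
band_rep <- c(low = 0.1, mid_low = 0.3, mid_high = 0.65, high = 0.95)

# random ratios resembling counts over ~20 true steps, mixed with
# continuous values
random_ratios <- function(n) {
  ifelse(stats::runif(n) < 0.7,
         sample(0:40, n, replace = TRUE) / 20,
         stats::runif(n, 0, 2))
}

# simple two-tracker config used across tests: one device near its
# detection limit (informative bands), one essentially perfect
toy_config <- function(n_participants = 6, seed_free = FALSE) {
  synthetic_config(
    n_participants = n_participants,
    pat_profiles = list(
      limit = list(
        "S-100" = detection_scenario("detectable", 0.0, 0.95, 15),
        "S-75"  = detection_scenario("near_limit", 0.3, 0.8, 10),
        "S-40"  = detection_scenario("near_limit", 0.6, 0.6, 10),
        "S-25"  = detection_scenario("undetectable", 0.95, 0.3, 10),
        ".default" = detection_scenario("near_limit", 0.45, 0.7, 10)),
      perfect = list(.default = detection_scenario("detectable", 0, 1, Inf))
    ),
    participant_effect_sd = c(limit = 0.1),
    true_step_jitter = c("20" = 1)
  )
}
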