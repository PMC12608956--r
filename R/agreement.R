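#' Ratio bands for the weighted agreement scheme
#'
#' The step-count-ratio axis is partitioned at 0.2, 0.5 and 0.8 into four
#' bands. The outer thresholds (0.2, 0.8) acknowledge that even truly
#' perfect (ratio 1) or truly blind (ratio 0) detection carries some noise;
#' 0.5 splits the unstable middle. Boundary convention: "below 0.2" is
#' \eqn{[0, 0.2)}, "between 0.2 and 0.5" is \eqn{[0.2, 0.5)}, "between 0.5
#' and 0.8" is \eqn{[0.5, 0.8]}, "above 0.8" is \eqn{(0.8, \infty)}. This
#' makes the four weight clauses a gapless partition; the boundary values
#' 0.5 and 0.8 land in the mid-high band so that 0.8 still counts as
#' "between 0.2 and 0.8" (the full-weight clause).
#'
#' @param ratio Nonnegative step-count ratios.
#' @return Factor with levels `low`, `mid_low`, `mid_high`, `high`.
#' @examples
#' band_of(c(0, 0.2, 0.5, 0.8, 0.95))
#' @export
band_of <- function(ratio) {
  if (any(is.na(ratio)) || any(ratio < 0)) {
    stop("ratios must be nonnegative and non-missing", call. = FALSE)
  }
  b <- ifelse(ratio < 0.2, "low",
       ifelse(ratio < 0.5, "mid_low",
       ifelse(ratio <= 0.8, "mid_high", "high")))
  factor(b, levels = band_levels())
}

band_levels <- function() c("low", "mid_low", "mid_high", "high")

#' Band-pair agreement weight table
#'
#' The 4x4 symmetric weight matrix realizing the clauses: weight 0 when one
#' ratio is above 0.8 and the other below 0.2; weight 0.5 when one is
#' between 0.5 and 0.8 and the other below 0.2, or one between 0.2 and 0.5
#' and the other above 0.8; weight 1 otherwise (both between 0.2 and 0.8,
#' both on the same side of 0.5, or adjacent bands).
#'
#' @return A 4x4 numeric matrix with band names on both dimensions.
#' @export
weight_table <- function() {
  lv <- band_levels()
  w <- matrix(c(
    # low  mid_low mid_high high
      1.0, 1.0,    0.5,     0.0,   # low
      1.0, 1.0,    1.0,     0.5,   # mid_low
      0.5, 1.0,    1.0,     1.0,   # mid_high
      0.0, 0.5,    1.0,     1.0),  # high
    nrow = 4, byrow = TRUE, dimnames = list(lv, lv))
  w
}

#' Agreement weight of a pair of step-count ratios
#'
#' @param ratio_a,ratio_b Nonnegative ratios (vectorized).
#' @return Numeric vector of weights in \{0, 0.5, 1\}.
#' @examples
#' pair_weight(0.95, 0.05) # 0: full disagreement
#' pair_weight(0.65, 0.10) # 0.5: partial
#' pair_weight(0.30, 0.40) # 1: agreement
#' @export
pair_weight <- function(ratio_a, ratio_b) {
  w <- weight_table()
  w[cbind(as.integer(band_of(ratio_a)), as.integer(band_of(ratio_b)))]
}

#' Weighted agreement rate of a set of ratio pairs
#'
#' The mean pair weight over all pairs: 1 is perfect banded agreement, 0
#' complete disagreement.
#'
#' @param pairs Data frame with columns `ratio_a`, `ratio_b` (one row per
#'   condition-matched pair).
#' @return The mean weight, or `NA_real_` (with a warning) for an empty
#'   pair set.
#' @export
agreement_rate <- function(pairs) {
  if (is.null(pairs) || nrow(pairs) == 0) {
    warning("empty pair set: agreement rate undefined")
    return(NA_real_)
  }
  mean(pair_weight(pairs$ratio_a, pairs$ratio_b))
}

#' Chance-corrected weighted agreement (kappa)
#'
#' Transforms the weighted agreement rate into a kappa value following
#' Cohen's chance-correction principle: \eqn{\kappa = (P_o - P_e)/(1 -
#' P_e)}, with the chance agreement \eqn{P_e = \sum_{a,b} p_A(a) p_B(b)
#' w(a,b)} computed from marginal band distributions. With
#' `chance_marginals = "pair"` (default) \eqn{p_A} and \eqn{p_B} are the
#' empirical band distributions of the first and second pair members
#' (Cohen's asymmetric-marginals convention); `"pooled"` uses the single
#' distribution of all ratios on both margins. Reporting is suppressed when
#' every ratio in the pair set is above 0.5 (no informative variation: the
#' device detected steps throughout) or when the marginals are degenerate
#' (\eqn{P_e = 1}).
#'
#' @param pairs Data frame with columns `ratio_a`, `ratio_b`.
#' @param chance_marginals `"pair"` or `"pooled"` chance-agreement policy.
#' @return An `agreement_result` list: `observed_agreement`,
#'   `chance_agreement`, `kappa`, `n_pairs`, `suppressed`, `reason`.
#' @export
weighted_kappa <- function(pairs, chance_marginals = c("pair", "pooled")) {
  chance_marginals <- match.arg(chance_marginals)
  res <- list(observed_agreement = NA_real_, chance_agreement = NA_real_,
              kappa = NA_real_, n_pairs = 0L, suppressed = TRUE,
              reason = "empty pair set",
              chance_marginals = chance_marginals)
  class(res) <- "agreement_result"
  if (is.null(pairs) || nrow(pairs) == 0) return(res)

  res$n_pairs <- nrow(pairs)
  res$observed_agreement <- mean(pair_weight(pairs$ratio_a, pairs$ratio_b))
  all_ratios <- c(pairs$ratio_a, pairs$ratio_b)
  if (all(all_ratios > 0.5)) {
    res$reason <- "all step count ratios above 0.5"
    return(res)
  }
  w <- weight_table()
  if (chance_marginals == "pair") {
    p_a <- prop.table(table(band_of(pairs$ratio_a)))
    p_b <- prop.table(table(band_of(pairs$ratio_b)))
  } else {
    p_a <- p_b <- prop.table(table(band_of(all_ratios)))
  }
  p_e <- as.numeric(t(as.numeric(p_a)) %*% w %*% as.numeric(p_b))
  res$chance_agreement <- p_e
  if (p_e >= 1 - 1e-12) {
    res$reason <- "degenerate marginals (chance agreement = 1)"
    return(res)
  }
  res$kappa <- (res$observed_agreement - p_e) / (1 - p_e)
  res$suppressed <- FALSE
  res$reason <- NA_character_
  res
}

#' @export
print.agreement_result <- function(x, ...) {
  if (x$suppressed) {
    cat(sprintf("weighted kappa: suppressed (%s), n_pairs = %d\n",
                x$reason, x$n_pairs))
  } else {
    cat(sprintf(
      "weighted kappa = %.3f (%s); P_o = %.3f, P_e = %.3f, n_pairs = %d\n",
      x$kappa, landis_koch_label(x$kappa), x$observed_agreement,
      x$chance_agreement, x$n_pairs))
  }
  invisible(x)
}

#' Verbal label for a kappa value (Landis-Koch scale)
#'
#' Cut-offs 0.2, 0.4, 0.6 and 0.8: poor (at or below 0), slight (up to
#' 0.2], fair (0.2, 0.4], moderate (0.4, 0.6], substantial (0.6, 0.8],
#' almost perfect (0.8, 1].
#'
#' @param kappa Numeric kappa values.
#' @return Character vector of labels (`NA` for `NA` input).
#' @export
landis_koch_label <- function(kappa) {
  vapply(kappa, function(k) {
    if (is.na(k)) return(NA_character_)
    if (k <= 0) "poor"
    else if (k <= 0.2) "slight"
    else if (k <= 0.4) "fair"
    else if (k <= 0.6) "moderate"
    else if (k <= 0.8) "substantial"
    else "almost perfect"
  }, character(1))
}

.pat_slice <- function(data, pat) {
  stopifnot(pat %in% data$pat)
  data[data$pat == pat, , drop = FALSE]
}

#' Test-retest (intra-rater) ratio pairs for one participant
#'
#' One pair per condition present in both protocol rounds: member A is the
#' round-1 ratio, member B the round-2 ratio. With the full 12-condition
#' analysis set in both rounds, this yields 12 pairs.
#'
#' @param data A `ratio_dataset`.
#' @param participant Participant id.
#' @param pat Tracker name.
#' @return Data frame with columns `condition`, `ratio_a`, `ratio_b` (empty,
#'   with a message, when the participant lacks overlapping conditions).
#' @export
intra_hcp_pairs <- function(data, participant, pat) {
  d <- .pat_slice(data, pat)
  d <- d[d$participant_id == participant, , drop = FALSE]
  r1 <- d[d$round == 1L, c("condition", "ratio")]
  r2 <- d[d$round == 2L, c("condition", "ratio")]
  pairs <- merge(r1, r2, by = "condition", suffixes = c("_a", "_b"))
  names(pairs) <- c("condition", "ratio_a", "ratio_b")
  if (nrow(pairs) == 0) {
    message("participant ", participant, ", tracker '", pat,
            "': no condition observed in both rounds")
  }
  pairs
}

#' Condition-matched ratio pairs between two participants
#'
#' @param data A `ratio_dataset`.
#' @param participant_a,participant_b Participant ids.
#' @param round_a,round_b Protocol round to take each participant's ratios
#'   from.
#' @param pat Tracker name.
#' @return Data frame with columns `condition`, `ratio_a`, `ratio_b`.
#' @export
inter_hcp_pairs <- function(data, participant_a, participant_b,
                            round_a, round_b, pat) {
  d <- .pat_slice(data, pat)
  a <- d[d$participant_id == participant_a & d$round == round_a,
         c("condition", "ratio")]
  b <- d[d$participant_id == participant_b & d$round == round_b,
         c("condition", "ratio")]
  pairs <- merge(a, b, by = "condition", suffixes = c("_a", "_b"))
  names(pairs) <- c("condition", "ratio_a", "ratio_b")
  pairs
}

#' Intra-rater weighted kappa for one participant and tracker
#'
#' @inheritParams intra_hcp_pairs
#' @inheritParams weighted_kappa
#' @return An `agreement_result`.
#' @export
intra_hcp_kappa <- function(data, participant, pat,
                            chance_marginals = c("pair", "pooled")) {
  weighted_kappa(intra_hcp_pairs(data, participant, pat),
                 chance_marginals = match.arg(chance_marginals))
}

#' Inter-rater weighted kappa for one tracker
#'
#' For every unordered pair of participants and every combination of
#' protocol rounds, condition-matched ratio pairs are formed and a weighted
#' kappa computed; the headline statistic is the unweighted mean of the
#' non-suppressed per-combination kappas. With `round_combos = "all"`
#' (default) all four round combinations (1,1), (1,2), (2,1), (2,2) enter;
#' `"cross"` restricts to the two cross-round combinations.
#'
#' @param data A `ratio_dataset`.
#' @param pat Tracker name.
#' @param chance_marginals Chance-agreement policy, see [weighted_kappa()].
#' @param round_combos `"all"` or `"cross"`.
#' @return A list with `kappa` (mean over non-suppressed combinations),
#'   `n_combinations`, `n_suppressed`, `suppressed` (logical: no
#'   combination usable), `breakdown` (one row per participant-pair x
#'   round-combination).
#' @export
inter_hcp_kappa <- function(data, pat,
                            chance_marginals = c("pair", "pooled"),
                            round_combos = c("all", "cross")) {
  chance_marginals <- match.arg(chance_marginals)
  round_combos <- match.arg(round_combos)
  d <- .pat_slice(data, pat)
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
        res <- weighted_kappa(pairs, chance_marginals = chance_marginals)
        rows[[length(rows) + 1L]] <- data.frame(
          participant_a = ids[i], participant_b = ids[j],
          round_a = combos[k, "a"], round_b = combos[k, "b"],
          n_pairs = res$n_pairs,
          observed_agreement = res$observed_agreement,
          kappa = res$kappa, suppressed = res$suppressed,
          reason = ifelse(is.na(res$reason), "", res$reason),
          stringsAsFactors = FALSE)
      }
    }
  }
  breakdown <- do.call(rbind, rows)
  usable <- !breakdown$suppressed
  list(
    kappa = if (any(usable)) mean(breakdown$kappa[usable]) else NA_real_,
    agreement_rate = mean(breakdown$observed_agreement[breakdown$n_pairs > 0]),
    n_combinations = nrow(breakdown),
    n_suppressed = sum(!usable),
    suppressed = !any(usable),
    breakdown = breakdown
  )
}
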