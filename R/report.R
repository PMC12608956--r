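#' Run the full reproducibility analysis
#'
#' Executes the whole pipeline on a set of trial records:
#' \enumerate{
#'   \item cleaning ([clean_dataset()]: slipper conditions and missing
#'     counts dropped, with a log);
#'   \item per-tracker ratio variation screen: trackers whose ratios show
#'     very limited variation (at least `variation_quantile` of ratios
#'     inside `variation_band`) detect essentially every step, so banded
#'     agreement statistics are uninformative for them; they are excluded
#'     from the reproducibility quantification with a logged note;
#'   \item intra-rater weighted kappa and ICC per participant and tracker;
#'   \item inter-rater weighted kappa and ICC per tracker (averaged over
#'     participant pairs and round combinations);
#'   \item zero-inflated negative binomial condition-effect model with
#'     marginal-mean contrasts for each analysed tracker.
#' }
#'
#' @param trials Trial records ([read_trials()] or [simulate_dataset()]).
#' @param variation_band Ratio interval regarded as "essentially correct
#'   detection" for the variation screen (default `c(0.9, 1.1)`).
#' @param variation_quantile Minimum fraction of ratios inside
#'   `variation_band` for a tracker to be screened out (default 0.95).
#' @param chance_marginals Chance-agreement policy, see [weighted_kappa()].
#' @param round_combos Round combinations for the inter-rater averaging,
#'   see [inter_hcp_kappa()].
#' @param provenance Passed to [clean_dataset()].
#' @return A `study_report` list: `data` (the cleaned `ratio_dataset`),
#'   `excluded_pats` (with per-tracker in-band fractions), `intra`
#'   (per-participant table), `inter` (per-tracker table),
#'   `condition_effects` (per-tracker list: `fit`, `marginal_means`,
#'   `contrasts`, `global_p_value`), `cleaning_log`, `settings`.
#' @export
run_analysis <- function(trials,
                         variation_band = c(0.9, 1.1),
                         variation_quantile = 0.95,
                         chance_marginals = c("pair", "pooled"),
                         round_combos = c("all", "cross"),
                         provenance = c("observed", "synthetic")) {
  chance_marginals <- match.arg(chance_marginals)
  round_combos <- match.arg(round_combos)
  if (is.null(trials) || nrow(trials) == 0) {
    stop("empty input: no trial records to analyse", call. = FALSE)
  }
  data <- clean_dataset(trials, provenance = match.arg(provenance))

  pats <- sort(unique(data$pat))
  in_band <- vapply(pats, function(p) {
    r <- data$ratio[data$pat == p]
    mean(r >= variation_band[1] & r <= variation_band[2])
  }, numeric(1))
  excluded <- pats[in_band >= variation_quantile]
  analysed <- setdiff(pats, excluded)
  if (length(excluded)) {
    message("excluded from reproducibility quantification (ratio ",
            "variation too limited): ", paste(excluded, collapse = ", "))
  }

  intra_rows <- list()
  inter_rows <- list()
  cond_effects <- list()
  for (p in analysed) {
    ids <- sort(unique(data$participant_id[data$pat == p]))
    for (id in ids) {
      pairs <- suppressMessages(intra_hcp_pairs(data, id, p))
      if (nrow(pairs) == 0) {
        intra_rows[[length(intra_rows) + 1L]] <- data.frame(
          participant_id = id, pat = p, n_pairs = 0L,
          agreement_rate = NA_real_, kappa = NA_real_,
          kappa_label = NA_character_, kappa_suppressed = TRUE,
          kappa_reason = "no condition observed in both rounds",
          icc = NA_real_, icc_suppressed = TRUE,
          icc_reason = "no condition observed in both rounds",
          stringsAsFactors = FALSE)
        next
      }
      kap <- weighted_kappa(pairs, chance_marginals = chance_marginals)
      icc <- intra_hcp_icc(data, id, p)
      intra_rows[[length(intra_rows) + 1L]] <- data.frame(
        participant_id = id, pat = p, n_pairs = kap$n_pairs,
        agreement_rate = kap$observed_agreement,
        kappa = kap$kappa,
        kappa_label = landis_koch_label(kap$kappa),
        kappa_suppressed = kap$suppressed,
        kappa_reason = ifelse(is.na(kap$reason), "", kap$reason),
        icc = icc$icc, icc_suppressed = icc$suppressed,
        icc_reason = ifelse(is.na(icc$reason), "", icc$reason),
        stringsAsFactors = FALSE)
    }
    ik <- inter_hcp_kappa(data, p, chance_marginals = chance_marginals,
                          round_combos = round_combos)
    ii <- inter_hcp_icc(data, p, round_combos = round_combos)
    this_intra <- do.call(rbind, intra_rows)
    this_intra <- this_intra[this_intra$pat == p, , drop = FALSE]
    inter_rows[[length(inter_rows) + 1L]] <- data.frame(
      pat = p,
      intra_mean_kappa = mean(
        this_intra$kappa[!this_intra$kappa_suppressed], na.rm = TRUE),
      intra_mean_icc = mean(
        this_intra$icc[!this_intra$icc_suppressed], na.rm = TRUE),
      inter_kappa = ik$kappa,
      inter_kappa_label = landis_koch_label(ik$kappa),
      inter_kappa_suppressed = ik$suppressed,
      inter_icc = ii$icc,
      inter_icc_suppressed = ii$suppressed,
      n_combinations = ik$n_combinations,
      n_kappa_suppressed = ik$n_suppressed,
      n_icc_suppressed = ii$n_suppressed,
      stringsAsFactors = FALSE)

    fit <- tryCatch(fit_zinb(data[data$pat == p, , drop = FALSE]),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      cond_effects[[p]] <- list(error = conditionMessage(fit))
    } else if (!fit$converged) {
      cond_effects[[p]] <- list(fit = fit,
                                error = "model did not converge")
    } else {
      ct <- contrast_tests(fit)
      cond_effects[[p]] <- list(
        fit = fit,
        marginal_means = marginal_means(fit),
        contrasts = ct$contrasts,
        global_p_value = ct$global_p_value)
    }
  }

  structure(list(
    data = data,
    pats = pats,
    analysed_pats = analysed,
    excluded_pats = data.frame(pat = pats, in_band_fraction = in_band,
                               excluded = pats %in% excluded,
                               stringsAsFactors = FALSE),
    intra = if (length(intra_rows)) do.call(rbind, intra_rows) else NULL,
    inter = if (length(inter_rows)) do.call(rbind, inter_rows) else NULL,
    condition_effects = cond_effects,
    cleaning_log = cleaning_log(data),
    settings = list(variation_band = variation_band,
                    variation_quantile = variation_quantile,
                    chance_marginals = chance_marginals,
                    round_combos = round_combos)
  ), class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("Step-count reproducibility study report\n")
  cat("  trackers:", paste(x$pats, collapse = ", "), "\n")
  cat("  analysed for reproducibility:",
      paste(x$analysed_pats, collapse = ", "), "\n")
  excl <- x$excluded_pats$pat[x$excluded_pats$excluded]
  if (length(excl)) {
    cat("  excluded (limited ratio variation):",
        paste(excl, collapse = ", "), "\n")
  }
  if (!is.null(x$inter)) {
    cat("  inter-rater reproducibility:\n")
    print(x$inter[, c("pat", "inter_kappa", "inter_kappa_label",
                      "inter_icc")], row.names = FALSE)
  }
  for (p in names(x$condition_effects)) {
    ce <- x$condition_effects[[p]]
    if (!is.null(ce$global_p_value)) {
      cat(sprintf(
        "  %s: global test of condition differences p = %.2g\n",
        p, ce$global_p_value))
    }
  }
  invisible(x)
}

#' Write a study report to CSV tables
#'
#' Writes `intra_rater.csv` (per participant x tracker), `inter_rater.csv`
#' (per tracker), `cleaning_log.csv`, `pat_screen.csv`, and per-tracker
#' `marginal_means_<pat>.csv` / `contrasts_<pat>.csv`. The tables are plain
#' CSV and reload losslessly with [utils::read.csv()].
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  wr <- function(df, name) {
    if (is.null(df)) return()
    path <- file.path(dir, name)
    utils::write.csv(df, path, row.names = FALSE, na = "")
    paths <<- c(paths, path)
  }
  wr(report$intra, "intra_rater.csv")
  wr(report$inter, "inter_rater.csv")
  wr(report$cleaning_log, "cleaning_log.csv")
  wr(report$excluded_pats, "pat_screen.csv")
  for (p in names(report$condition_effects)) {
    ce <- report$condition_effects[[p]]
    if (!is.null(ce$marginal_means)) {
      wr(ce$marginal_means, paste0("marginal_means_", p, ".csv"))
      ct <- ce$contrasts
      ct <- rbind(ct, data.frame(
        label = "all conditions equal (global)", type = "global",
        estimate = NA_real_, std_error = NA_real_,
        statistic = NA_real_, df = NA_real_,
        p_value = ce$global_p_value, stringsAsFactors = FALSE))
      wr(ct, paste0("contrasts_", p, ".csv"))
    }
  }
  invisible(paths)
}
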