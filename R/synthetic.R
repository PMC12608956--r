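#' Detection scenario for one tracker under one condition
#'
#' A tracker facing a specific walking condition is in one of three regimes:
#' it detects the steps (ratio close to 1), it cannot detect them (count 0),
#' or the condition sits near its detection limit, where counts are unstable
#' and the step-count ratio covers a wide range. The generator encodes a
#' regime as a zero-inflated count law: with probability `zero_prob` the
#' device registers nothing; otherwise the count is negative binomial with
#' mean `true_steps * mean_ratio` (times a participant effect) and
#' overdispersion `dispersion` (NB size; `Inf` means a deterministic
#' `round()` of the mean, for near-perfect devices). Occasional overcounting
#' bursts (probability `overcount_prob`, additive Poisson extra counts with
#' mean `overcount_scale * true_steps`) let ratios exceed 1.5.
#'
#' @param label One of `"detectable"`, `"undetectable"`, `"near_limit"`.
#' @param zero_prob Probability that no steps are registered.
#' @param mean_ratio Expected counted/true ratio when steps are registered.
#' @param dispersion Negative-binomial size parameter (`Inf` = no count
#'   noise).
#' @param overcount_prob Probability of an overcounting burst.
#' @param overcount_scale Mean extra counts per true step in a burst.
#' @return A `detection_scenario` list.
#' @export
detection_scenario <- function(label = c("detectable", "undetectable",
                                         "near_limit"),
                               zero_prob, mean_ratio, dispersion = 10,
                               overcount_prob = 0, overcount_scale = 0.5) {
  label <- match.arg(label)
  if (!is.numeric(zero_prob) || zero_prob < 0 || zero_prob > 1) {
    stop("zero_prob must be a probability in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(mean_ratio) || mean_ratio < 0) {
    stop("mean_ratio must be nonnegative", call. = FALSE)
  }
  if (!is.numeric(dispersion) || dispersion <= 0) {
    stop("dispersion must be positive", call. = FALSE)
  }
  if (overcount_prob < 0 || overcount_prob > 1) {
    stop("overcount_prob must be a probability in [0, 1]", call. = FALSE)
  }
  if (overcount_scale <= 0 && overcount_prob > 0) {
    stop("overcount_scale must be positive", call. = FALSE)
  }
  ok <- switch(label,
    detectable   = zero_prob <= 0.05 && mean_ratio >= 0.85 &&
                   mean_ratio <= 1.05,
    undetectable = zero_prob >= 0.90,
    near_limit   = zero_prob > 0.05 && zero_prob < 0.90
  )
  if (!ok) {
    stop("scenario label '", label, "' is inconsistent with zero_prob = ",
         zero_prob, ", mean_ratio = ", mean_ratio, call. = FALSE)
  }
  structure(list(label = label, zero_prob = zero_prob,
                 mean_ratio = mean_ratio, dispersion = dispersion,
                 overcount_prob = overcount_prob,
                 overcount_scale = overcount_scale),
            class = "detection_scenario")
}

#' Configuration for the synthetic trial generator
#'
#' @param n_participants Number of simulated raters.
#' @param pat_profiles Named list (one element per tracker) of named lists
#'   mapping condition codes to [detection_scenario()] objects. A profile may
#'   carry a single scenario under the name `".default"` applying to all
#'   conditions not listed explicitly.
#' @param participant_effect_sd SD of the log-normal participant effect
#'   multiplying the count mean (drawn once per participant x tracker,
#'   shared across conditions). Either a single value for all trackers or a
#'   named vector with one entry per tracker (missing trackers get 0).
#' @param true_step_jitter Named numeric vector of probabilities over the
#'   realised true step counts; the default puts 0.9 on 20 steps and 0.05 on
#'   each of 19 and 21 (small execution errors around the intended 20).
#' @param off_by_one Character vector of tracker names that systematically
#'   drop one step (half steps at the start and end of the walk); their
#'   counts are `max(0, draw - 1)`.
#' @param missing_participants Named list mapping a tracker name to the
#'   participant ids whose data are entirely missing for that tracker
#'   (device/app failure).
#' @param unrecorded Data frame with columns `participant_id`, `round`
#'   listing participant-rounds that were not recorded at all.
#' @param repeat_prob Probability that a trial is flagged as having been
#'   repeated on the instructor's request (annotation only; the stored trial
#'   is the final one).
#' @param conditions Condition codes to simulate (default: the full
#'   14-condition protocol).
#' @param n_rounds Number of protocol rounds per participant.
#' @return A `synthetic_config` list, validated.
#' @seealso [simulate_dataset()], [preset_study_like()]
#' @export
synthetic_config <- function(n_participants,
                             pat_profiles,
                             participant_effect_sd = 0,
                             true_step_jitter = c("19" = 0.05, "20" = 0.90,
                                                  "21" = 0.05),
                             off_by_one = character(),
                             missing_participants = list(),
                             unrecorded = NULL,
                             repeat_prob = 0,
                             conditions = protocol_codes(),
                             n_rounds = 2L) {
  stopifnot(n_participants >= 1, n_rounds >= 1)
  if (!is.list(pat_profiles) || is.null(names(pat_profiles))) {
    stop("pat_profiles must be a named list of tracker profiles",
         call. = FALSE)
  }
  if (!is.numeric(participant_effect_sd) || any(participant_effect_sd < 0)) {
    stop("participant_effect_sd must be nonnegative", call. = FALSE)
  }
  if (length(participant_effect_sd) > 1 &&
      is.null(names(participant_effect_sd))) {
    stop("a vector participant_effect_sd must be named by tracker",
         call. = FALSE)
  }
  if (abs(sum(true_step_jitter) - 1) > 1e-8 || any(true_step_jitter < 0)) {
    stop("true_step_jitter must be a probability distribution",
         call. = FALSE)
  }
  valid <- vapply(protocol_codes(), identity, "")
  for (pat in names(pat_profiles)) {
    prof <- pat_profiles[[pat]]
    if (!is.list(prof) || is.null(names(prof))) {
      stop("profile for tracker '", pat, "' must be a named list",
           call. = FALSE)
    }
    for (code in names(prof)) {
      if (code != ".default" && !code %in% valid) {
        stop("profile for tracker '", pat, "' names unknown condition '",
             code, "'", call. = FALSE)
      }
      if (!inherits(prof[[code]], "detection_scenario")) {
        stop("profile entry ", pat, "/", code,
             " is not a detection_scenario", call. = FALSE)
      }
    }
    missing_codes <- setdiff(conditions, names(prof))
    if (length(missing_codes) && !".default" %in% names(prof)) {
      stop("profile for tracker '", pat, "' lacks conditions ",
           paste(missing_codes, collapse = ", "),
           " and has no '.default' scenario", call. = FALSE)
    }
  }
  bad <- setdiff(off_by_one, names(pat_profiles))
  if (length(bad)) {
    stop("off_by_one names unknown tracker(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(n_participants = as.integer(n_participants),
                 pat_profiles = pat_profiles,
                 participant_effect_sd = participant_effect_sd,
                 true_step_jitter = true_step_jitter,
                 off_by_one = off_by_one,
                 missing_participants = missing_participants,
                 unrecorded = unrecorded,
                 repeat_prob = repeat_prob,
                 conditions = conditions,
                 n_rounds = as.integer(n_rounds)),
            class = "synthetic_config")
}

.scenario_for <- function(profile, code) {
  if (!is.null(profile[[code]])) profile[[code]] else profile[[".default"]]
}

#' Simulate a trial dataset
#'
#' Generates one trial record per participant x round x condition x tracker
#' under the zero-inflated count law of each tracker's profile (see
#' [detection_scenario()]). Fixing `seed` reproduces the dataset exactly.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed for all randomness.
#' @return A data frame of trial records with columns `participant_id`,
#'   `round`, `condition`, `pat`, `true_steps`, `counted_steps` (NA where
#'   the device failed or the round was not recorded), `repeated`.
#' @examples
#' cfg <- synthetic_config(
#'   n_participants = 2,
#'   pat_profiles = list(toy = list(
#'     .default = detection_scenario("detectable", 0, 1, Inf))))
#' simulate_dataset(cfg, seed = 1)
#' @export
simulate_dataset <- function(config, seed = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(as.integer(seed))
  pats <- names(config$pat_profiles)
  grid <- expand.grid(participant_id = seq_len(config$n_participants),
                      round = seq_len(config$n_rounds),
                      condition = config$conditions,
                      pat = pats,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # participant effects: one multiplicative log-normal factor per
  # participant x tracker, shared across conditions and rounds
  sd_for <- function(pat) {
    s <- config$participant_effect_sd
    if (length(s) == 1 && is.null(names(s))) return(s)
    if (pat %in% names(s)) s[[pat]] else 0
  }
  eff <- vapply(pats, function(pat) {
    exp(stats::rnorm(config$n_participants, 0, sd_for(pat)))
  }, numeric(config$n_participants))
  eff <- matrix(eff, nrow = config$n_participants,
                dimnames = list(NULL, pats))

  n <- nrow(grid)
  # true steps per physical walk: the four trackers are worn simultaneously,
  # so the realised true count is shared across trackers within one
  # participant x round x condition walk
  walks <- unique(grid[c("participant_id", "round", "condition")])
  jit <- config$true_step_jitter
  walks$true_steps <- as.integer(sample(names(jit), nrow(walks),
                                        replace = TRUE, prob = jit))
  walks$repeated <- stats::runif(nrow(walks)) < config$repeat_prob
  grid <- merge(grid, walks, by = c("participant_id", "round", "condition"),
                sort = FALSE)

  counted <- integer(n)
  for (i in seq_len(n)) {
    sc <- .scenario_for(config$pat_profiles[[grid$pat[i]]],
                        grid$condition[i])
    if (stats::runif(1) < sc$zero_prob) {
      y <- 0L
    } else {
      mu <- grid$true_steps[i] * sc$mean_ratio *
        eff[grid$participant_id[i], grid$pat[i]]
      y <- if (is.infinite(sc$dispersion)) as.integer(round(mu))
           else stats::rnbinom(1, size = sc$dispersion, mu = mu)
      if (sc$overcount_prob > 0 && stats::runif(1) < sc$overcount_prob) {
        y <- y + stats::rpois(1, sc$overcount_scale * grid$true_steps[i])
      }
    }
    if (grid$pat[i] %in% config$off_by_one) y <- max(0L, y - 1L)
    counted[i] <- y
  }
  grid$counted_steps <- counted

  # device/app failures: whole-tracker missingness for listed participants
  for (pat in names(config$missing_participants)) {
    sel <- grid$pat == pat &
      grid$participant_id %in% config$missing_participants[[pat]]
    grid$counted_steps[sel] <- NA_integer_
  }
  # unrecorded participant-rounds (all trackers)
  if (!is.null(config$unrecorded) && nrow(config$unrecorded) > 0) {
    for (k in seq_len(nrow(config$unrecorded))) {
      sel <- grid$participant_id == config$unrecorded$participant_id[k] &
        grid$round == config$unrecorded$round[k]
      grid$counted_steps[sel] <- NA_integer_
    }
  }
  ord <- order(grid$pat, grid$participant_id, grid$round,
               match(grid$condition, protocol_codes()))
  grid <- grid[ord, c("participant_id", "round", "condition", "pat",
                      "true_steps", "counted_steps", "repeated")]
  rownames(grid) <- NULL
  grid
}

#' Study-like generator configuration
#'
#' A configuration emulating the structure observed in a four-tracker
#' evaluation of the protocol with 14 raters:
#' \itemize{
#'   \item \strong{sole}: a shoe-sole force sensor that detects essentially
#'     every step under every condition but consistently drops one step per
#'     walk (half steps at the start and end), so its ratios sit at 19/20.
#'   \item \strong{knee}: a knee-worn sensor, also near-perfect, but whose
#'     companion app fails for 9 of the 14 raters, leaving no data.
#'   \item \strong{trouser}: a pocket sensor with a clear, step-size
#'     dependent detection limit — reliable at full step size, near its
#'     limit at 75\%, mostly blind at 25\% — and markedly worse with
#'     crutches (an average decrease of about eight counted steps at 20
#'     true steps across the crutch conditions).
#'   \item \strong{wrist}: a consumer wrist tracker with mild condition
#'     effects but strong participant heterogeneity: some raters see ratios
#'     near 1 throughout, others wide, poorly reproducible variation from 0
#'     to above 1.5.
#' }
#' Round 1 of participant 1 is unrecorded (the instructor's decision after
#' failed step-size targets), and about 5\% of walks are flagged repeated.
#' All distributional values are illustrative: they encode the qualitative
#' regimes above, not measured device parameters.
#'
#' @param n_participants Number of raters (default 14).
#' @return A [synthetic_config()].
#' @export
preset_study_like <- function(n_participants = 14L) {
  det <- function(zp, mr, disp = 10, op = 0, os = 0.5)
    detection_scenario(
      label = if (zp <= 0.05) "detectable"
              else if (zp >= 0.90) "undetectable" else "near_limit",
      zero_prob = zp, mean_ratio = mr, dispersion = disp,
      overcount_prob = op, overcount_scale = os)

  perfect <- detection_scenario("detectable", 0, 1, Inf)
  trouser <- list(
    "S-100" = det(0.02, 0.95, 15),
    "S-75"  = det(0.15, 0.80, 12),
    "S-40"  = det(0.50, 0.60, 10),
    "S-25"  = det(0.92, 0.30, 8),
    "T-75"  = det(0.20, 0.75, 12),
    "Z-75"  = det(0.45, 0.65, 10),
    "C-75"  = det(0.30, 0.70, 10),
    "T-40"  = det(0.55, 0.55, 10),
    "Z-40"  = det(0.75, 0.50, 8),
    "C-40"  = det(0.60, 0.55, 8),
    "W-75"  = det(0.70, 0.50, 8),
    "W-40"  = det(0.90, 0.40, 8),
    "L-75"  = det(0.15, 0.80, 12),
    "L-40"  = det(0.50, 0.60, 10)
  )
  trouser <- lapply(trouser, function(s) {
    s$overcount_prob <- 0.03; s$overcount_scale <- 0.6; s
  })
  wrist <- list(
    "S-100" = det(0.02, 0.95, 8, 0.05, 0.8),
    "S-75"  = det(0.10, 0.90, 8, 0.05, 0.8),
    "S-40"  = det(0.25, 0.80, 8, 0.05, 0.8),
    "S-25"  = det(0.40, 0.70, 8, 0.05, 0.8),
    "T-75"  = det(0.10, 0.90, 8, 0.05, 0.8),
    "Z-75"  = det(0.12, 0.88, 8, 0.05, 0.8),
    "C-75"  = det(0.12, 0.88, 8, 0.05, 0.8),
    "T-40"  = det(0.25, 0.80, 8, 0.05, 0.8),
    "Z-40"  = det(0.28, 0.78, 8, 0.05, 0.8),
    "C-40"  = det(0.28, 0.78, 8, 0.05, 0.8),
    "W-75"  = det(0.10, 0.90, 8, 0.05, 0.8),
    "W-40"  = det(0.25, 0.80, 8, 0.05, 0.8),
    "L-75"  = det(0.10, 0.90, 8, 0.05, 0.8),
    "L-40"  = det(0.25, 0.80, 8, 0.05, 0.8)
  )
  synthetic_config(
    n_participants = n_participants,
    pat_profiles = list(
      sole    = list(.default = perfect),
      knee    = list(.default = perfect),
      trouser = trouser,
      wrist   = wrist
    ),
    participant_effect_sd = c(sole = 0, knee = 0,
                              trouser = 0.15, wrist = 0.50),
    off_by_one = "sole",
    missing_participants = list(
      knee = seq_len(min(9L, n_participants))),
    unrecorded = data.frame(participant_id = 1L, round = 1L),
    repeat_prob = 19 / 350
  )
}
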