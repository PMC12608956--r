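#' Read trial records from delimited text
#'
#' Reads a trial table with one row per walk x tracker. The expected header
#' is `participant_id, round, condition, pat, true_steps, counted_steps,
#' repeated`; both comma- and semicolon-separated files are accepted (the
#' delimiter is sniffed from the header line). An empty `counted_steps`
#' field means the device produced no reading (failure); a `0` is a real
#' measurement (the device registered no steps). The optional `repeated`
#' column marks walks that were redone on the instructor's request; absent,
#' it defaults to `FALSE`.
#'
#' @param path Path to a CSV file.
#' @return A data frame of trial records.
#' @seealso [write_trials()], [clean_dataset()]
#' @export
read_trials <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr(";", header))) >
             lengths(regmatches(header, gregexpr(",", header)))) ";" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  required <- c("participant_id", "round", "condition", "pat",
                "true_steps", "counted_steps")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("trial file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"repeated" %in% names(df)) df$repeated <- FALSE
  df$participant_id <- as.integer(df$participant_id)
  df$round <- as.integer(df$round)
  df$true_steps <- as.integer(df$true_steps)
  df$counted_steps <- as.integer(df$counted_steps)
  df$repeated <- as.logical(df$repeated)
  validate_trials(df)
  df[, c(required, "repeated")]
}

#' @rdname read_trials
#' @param trials A trial-record data frame.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, na = "")
  invisible(path)
}

validate_trials <- function(trials) {
  if (nrow(trials) == 0) stop("no trial records", call. = FALSE)
  bad <- setdiff(unique(trials$condition), protocol_codes())
  if (length(bad)) {
    stop("unknown condition code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(trials$participant_id < 1, na.rm = TRUE)) {
    stop("participant_id must be >= 1", call. = FALSE)
  }
  if (!all(trials$round %in% c(1L, 2L))) {
    stop("round must be 1 or 2", call. = FALSE)
  }
  if (any(trials$true_steps <= 0, na.rm = TRUE)) {
    stop("true_steps must be positive", call. = FALSE)
  }
  if (any(trials$counted_steps < 0, na.rm = TRUE)) {
    stop("counted_steps must be nonnegative", call. = FALSE)
  }
  key <- with(trials, paste(participant_id, round, condition, pat))
  if (anyDuplicated(key)) {
    stop("duplicate (participant, round, condition, pat) records",
         call. = FALSE)
  }
  invisible(trials)
}

#' Step-count ratio of one or more trials
#'
#' The ratio of the count shown by the device to the true (assistant
#' counted) number of steps. A ratio near 1 means the device detects the
#' walk's steps; 0 means it registers nothing; values above 1 (occasionally
#' above 1.5) are overcounts and are retained.
#'
#' @param counted_steps Nonnegative device counts.
#' @param true_steps Positive true step counts.
#' @return Numeric vector of ratios.
#' @examples
#' compute_ratio(19, 20)  # 0.95
#' @export
compute_ratio <- function(counted_steps, true_steps) {
  if (any(true_steps <= 0, na.rm = TRUE)) {
    stop("true_steps must be positive", call. = FALSE)
  }
  if (any(counted_steps < 0, na.rm = TRUE)) {
    stop("counted_steps must be nonnegative", call. = FALSE)
  }
  counted_steps / true_steps
}

#' Apply the study's exclusion rules and compute ratios
#'
#' Cleaning drops, in order and with per-rule bookkeeping:
#' \enumerate{
#'   \item slipper conditions (L-75, L-40) — omitted from all analyses;
#'   \item records with a missing device count (device/app failure or
#'     unrecorded round).
#' }
#' Ratios above `ratio_cap` are flagged (`capped` column) but retained;
#' overcounting is data. Cleaning is idempotent: running it on its own
#' output changes nothing.
#'
#' @param trials Trial records (from [read_trials()] or
#'   [simulate_dataset()]).
#' @param ratio_cap Sanity threshold above which ratios are flagged.
#' @param provenance `"observed"` or `"synthetic"`, recorded on the output.
#' @return A `ratio_dataset`: a data frame with `ratio` and `capped` added
#'   and the slipper/missing rows removed; attribute `cleaning_log` holds a
#'   data frame of per-rule drop counts.
#' @export
clean_dataset <- function(trials, ratio_cap = 3.0,
                          provenance = c("observed", "synthetic")) {
  provenance <- match.arg(provenance)
  validate_trials(trials)
  n_in <- nrow(trials)

  slipper <- trials$condition %in% c("L-75", "L-40")
  kept <- trials[!slipper, , drop = FALSE]
  n_slipper <- sum(slipper)

  miss <- is.na(kept$counted_steps)
  miss_by_pat <- table(kept$pat[miss])
  kept <- kept[!miss, , drop = FALSE]
  n_missing <- sum(miss)

  kept$ratio <- compute_ratio(kept$counted_steps, kept$true_steps)
  kept$capped <- kept$ratio > ratio_cap
  kept$provenance <- provenance
  rownames(kept) <- NULL

  log <- data.frame(
    rule = c("slipper_condition", "missing_count", "retained"),
    n = c(n_slipper, n_missing, nrow(kept)),
    detail = c("conditions L-75, L-40 omitted from all analyses",
               if (n_missing > 0)
                 paste("missing device counts:",
                       paste(names(miss_by_pat), as.integer(miss_by_pat),
                             sep = "=", collapse = ", "))
               else "no missing device counts",
               paste("of", n_in, "input records")),
    stringsAsFactors = FALSE
  )
  structure(kept, cleaning_log = log, class = c("ratio_dataset",
                                                class(kept)))
}

#' @export
print.ratio_dataset <- function(x, ...) {
  log <- attr(x, "cleaning_log")
  cat("Step-count ratio dataset:", nrow(x), "trials,",
      length(unique(x$participant_id)), "participants,",
      length(unique(x$condition)), "conditions,",
      length(unique(x$pat)), "tracker(s)\n")
  if (!is.null(log)) {
    dropped <- log[log$rule != "retained", , drop = FALSE]
    for (i in seq_len(nrow(dropped))) {
      cat(sprintf("  dropped %d (%s)\n", dropped$n[i], dropped$rule[i]))
    }
  }
  if (nrow(x) > 10) {
    print(utils::head(as.data.frame(x), 10))
    cat("... and", nrow(x) - 10, "more rows\n")
  } else {
    print(as.data.frame(x))
  }
  invisible(x)
}

#' Cleaning log of a ratio dataset
#' @param data A `ratio_dataset`.
#' @return The per-rule cleaning log data frame.
#' @export
cleaning_log <- function(data) attr(data, "cleaning_log")
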