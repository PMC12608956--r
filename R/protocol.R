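#' The 14-condition low-impact gait protocol
#'
#' The protocol asks a rater to walk 20 steps under each of 14 conditions,
#' formed as an incomplete factorial of four factors: intended step size
#' (25/40/75/100% of normal), walking direction (straight line, 90-degree
#' turn after 10 steps, zigzag with turns after 5/10/15 steps, full
#' 360-degree circle), use of forearm crutches, and footwear (street shoes
#' vs. home slippers). Condition codes combine a category letter with the
#' step-size percentage:
#'
#' \describe{
#'   \item{S}{straight line, no aid, street shoes (the core conditions)}
#'   \item{T}{90-degree right turn after 10 steps}
#'   \item{Z}{zigzag, starting with a left turn}
#'   \item{C}{360-degree circle, clockwise}
#'   \item{W}{straight line with walking aid (forearm crutches)}
#'   \item{L}{straight line in home slippers}
#' }
#'
#' The letter-code expansion is inferred from the factor-level ordering of
#' the protocol description (the codes are never expanded explicitly in the
#' source protocol); S-75 and S-40 are the two core conditions that the
#' remaining factors vary around.
#'
#' @return A data frame with one row per condition in protocol order and
#'   columns `code`, `category`, `step_size_pct`, `direction`,
#'   `walking_aid`, `footwear`, `sequence_index`, `standard`.
#' @examples
#' build_protocol()
#' @export
build_protocol <- function() {
  codes <- c("S-100", "S-75", "S-40", "S-25",
             "T-75", "Z-75", "C-75",
             "T-40", "Z-40", "C-40",
             "W-75", "W-40", "L-75", "L-40")
  out <- do.call(rbind, lapply(codes, condition_spec))
  out$sequence_index <- seq_len(nrow(out))
  out
}

#' @rdname build_protocol
#' @export
protocol_codes <- function() build_protocol()$code

.category_table <- function() {
  data.frame(
    category    = c("S", "T", "Z", "C", "W", "L"),
    direction   = c("straight", "turn90", "zigzag", "circle360",
                    "straight", "straight"),
    walking_aid = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    footwear    = c("street", "street", "street", "street",
                    "street", "slipper"),
    stringsAsFactors = FALSE
  )
}

#' Construct a condition specification from category and step size
#'
#' `condition_spec()` is the permissive constructor: any category letter in
#' S/T/Z/C/W/L combined with any step-size percentage in 25/40/75/100 is
#' accepted, so user-defined protocol extensions can be represented; codes
#' outside the standard 14 are flagged with `standard = FALSE`.
#' [parse_condition()] accepts only the 14 standard protocol codes.
#'
#' @param code Condition code such as `"S-75"` (category letter, dash,
#'   step-size percent).
#' @return A one-row data frame with the condition's factor levels.
#' @examples
#' condition_spec("S-75")
#' condition_spec("T-100") # valid but non-standard
#' @export
condition_spec <- function(code) {
  stopifnot(is.character(code), length(code) == 1L)
  m <- regmatches(code, regexec("^([A-Za-z])-([0-9]+)$", code))[[1]]
  if (length(m) != 3L) {
    stop("malformed condition code: '", code,
         "' (expected letter-dash-number, e.g. 'S-75')", call. = FALSE)
  }
  cat_tab <- .category_table()
  idx <- match(m[2], cat_tab$category)
  if (is.na(idx)) {
    stop("unknown condition category '", m[2], "' in code '", code,
         "' (known: ", paste(cat_tab$category, collapse = ", "), ")",
         call. = FALSE)
  }
  pct <- as.integer(m[3])
  if (!pct %in% c(25L, 40L, 75L, 100L)) {
    stop("unknown step size ", pct, "% in code '", code,
         "' (known: 25, 40, 75, 100)", call. = FALSE)
  }
  data.frame(
    code = code,
    category = cat_tab$category[idx],
    step_size_pct = pct,
    direction = cat_tab$direction[idx],
    walking_aid = cat_tab$walking_aid[idx],
    footwear = cat_tab$footwear[idx],
    sequence_index = NA_integer_,
    standard = code %in% c("S-100", "S-75", "S-40", "S-25",
                           "T-75", "Z-75", "C-75",
                           "T-40", "Z-40", "C-40",
                           "W-75", "W-40", "L-75", "L-40"),
    stringsAsFactors = FALSE
  )
}

#' Parse one of the 14 standard protocol condition codes
#'
#' @param code Condition code, e.g. `"Z-40"`.
#' @return A one-row data frame as in [build_protocol()], including the
#'   protocol `sequence_index`.
#' @examples
#' parse_condition("Z-40")
#' @export
parse_condition <- function(code) {
  prot <- build_protocol()
  idx <- match(code, prot$code)
  if (is.na(idx)) {
    # reuse condition_spec for a precise malformed-code message
    spec <- condition_spec(code)
    stop("'", code, "' is not one of the 14 standard protocol conditions",
         call. = FALSE)
  }
  prot[idx, , drop = FALSE]
}

#' Category letter of a condition code
#' @param code Character vector of condition codes.
#' @return Character vector of category letters (S, T, Z, C, W or L).
#' @export
condition_category <- function(code) {
  cat <- sub("-.*$", "", code)
  bad <- !cat %in% .category_table()$category
  if (any(bad)) {
    stop("unknown condition category in code(s): ",
         paste(unique(code[bad]), collapse = ", "), call. = FALSE)
  }
  cat
}

#' Step-size percentage of a condition code
#' @param code Character vector of condition codes.
#' @return Integer vector of step sizes (25, 40, 75 or 100).
#' @export
condition_step_size <- function(code) {
  as.integer(sub("^[A-Za-z]-", "", code))
}

#' Conditions retained in the analyses
#'
#' Slipper conditions (L-75, L-40) are excluded from all analyses because
#' too few raters bring suitable footwear; the remaining 12 codes are the
#' analysis set.
#' @return Character vector of the 12 analysed condition codes.
#' @export
analysis_codes <- function() {
  setdiff(protocol_codes(), c("L-75", "L-40"))
}
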