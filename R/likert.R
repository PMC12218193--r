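#' Likert coding scheme
#'
#' Describes how ordinal survey codes map onto the continuous opinion
#' interval \eqn{[0, 1]}. The default 5-point scheme maps codes 1..5 to
#' 0, 0.25, 0.5, 0.75, 1 (equal spacing); the first mapped value must be 0
#' and the last 1, and values must be strictly increasing. Codes listed in
#' `missing` are treated as invalid answers (to be excluded listwise
#' downstream), not as errors.
#'
#' @param levels Ordered integer vector of admissible codes.
#' @param values Numeric vector of the same length with the mapped values.
#' @param missing Integer vector of codes representing invalid/missing
#'   answers.
#' @return An object of class `likert_scheme`.
#' @examples
#' likert_scheme() # the default 5-point scheme
#' likert_scheme(1:7, missing = c(77L, 88L, 99L))
#' @export
likert_scheme <- function(levels = 1:5,
                          values = seq(0, 1, length.out = length(levels)),
                          missing = integer()) {
  levels <- as.integer(levels)
  values <- as.numeric(values)
  if (length(levels) != length(values)) {
    stop("`levels` and `values` must have equal length", call. = FALSE)
  }
  if (length(levels) < 2L) stop("need at least two levels", call. = FALSE)
  if (any(duplicated(levels))) stop("duplicated codes in `levels`", call. = FALSE)
  if (any(diff(values) <= 0)) {
    stop("`values` must be strictly increasing", call. = FALSE)
  }
  if (values[1] != 0 || values[length(values)] != 1) {
    stop("`values` must start at 0 and end at 1", call. = FALSE)
  }
  missing <- as.integer(missing)
  if (any(missing %in% levels)) {
    stop("missing codes overlap admissible levels", call. = FALSE)
  }
  structure(list(levels = levels, values = values, missing = missing),
            class = "likert_scheme")
}

#' @export
print.likert_scheme <- function(x, ...) {
  cat("<likert_scheme> ", length(x$levels), " levels: ",
      paste0(x$levels, "->", signif(x$values, 3), collapse = ", "), sep = "")
  if (length(x$missing)) cat("; missing codes:", paste(x$missing, collapse = ", "))
  cat("\n")
  invisible(x)
}

#' Map ordinal Likert codes to the unit interval
#'
#' Maps each admissible code to its scheme value in \eqn{[0, 1]}. Cells with
#' a declared missing code become `NA` and the affected rows are flagged for
#' listwise exclusion downstream (attribute `flagged`). A code that is
#' neither admissible nor declared missing is a hard error naming the row,
#' column and code.
#'
#' @param responses A data frame or matrix of ordinal codes.
#' @param scheme A [likert_scheme()].
#' @return A tibble of the same shape with values in \eqn{[0, 1]} (or `NA`),
#'   with attribute `flagged` giving the row indices containing any missing
#'   code.
#' @examples
#' map_likert_to_unit(data.frame(q = c(1L, 3L, 5L)), likert_scheme())
#' @export
map_likert_to_unit <- function(responses, scheme = likert_scheme()) {
  stopifnot(inherits(scheme, "likert_scheme"))
  responses <- tibble::as_tibble(as.data.frame(responses))
  out <- responses
  for (j in seq_along(responses)) {
    codes <- as.integer(responses[[j]])
    pos <- match(codes, scheme$levels)
    is_missing <- codes %in% scheme$missing | is.na(codes)
    unknown <- which(is.na(pos) & !is_missing)
    if (length(unknown) > 0L) {
      i <- unknown[1]
      stop("unknown code ", codes[i], " at row ", i, ", column '",
           names(responses)[j], "' (not admissible, not declared missing)",
           call. = FALSE)
    }
    out[[j]] <- scheme$values[pos]
  }
  flagged <- which(!stats::complete.cases(out))
  attr(out, "flagged") <- flagged
  out
}

#' Map unit-interval values back to their nearest Likert codes
#'
#' The inverse lookup of [map_likert_to_unit()]: each value snaps to the
#' admissible code whose mapped value is nearest (ties resolve to the lower
#' code). Exactly recovers the codes for values produced by the forward
#' mapping.
#'
#' @param values A data frame or matrix of values in \eqn{[0, 1]}.
#' @inheritParams map_likert_to_unit
#' @return A tibble of integer codes of the same shape.
#' @export
unit_to_likert <- function(values, scheme = likert_scheme()) {
  stopifnot(inherits(scheme, "likert_scheme"))
  values <- tibble::as_tibble(as.data.frame(values))
  out <- values
  for (j in seq_along(values)) {
    v <- as.numeric(values[[j]])
    idx <- vapply(v, function(x) {
      if (is.na(x)) return(NA_integer_)
      which.min(abs(scheme$values - x))
    }, integer(1))
    out[[j]] <- scheme$levels[idx]
  }
  out
}
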