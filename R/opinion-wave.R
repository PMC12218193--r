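#' Construct an opinion wave
#'
#' An opinion wave is one cross-sectional survey round: a tibble with one row
#' per respondent, a group identity column, a positive analysis weight column,
#' and one column per opinion item, each coordinate lying in the unit interval
#' \eqn{[0, 1]}. The reserved identity label `"None"` marks nonpartisans,
#' whose in-group is the whole sample.
#'
#' @param data A data frame with one row per respondent.
#' @param items Character vector naming the opinion item columns. Defaults to
#'   every column other than the group and weight columns.
#' @param wave Single string labelling the wave (e.g. `"2016"`). Defaults to
#'   the unique value of a `wave` column if present, else `"wave"`.
#' @param group Name of the identity column (default `"group"`).
#' @param weight Name of the weight column; if absent, all weights default
#'   to 1.
#'
#' @return A tibble of class `opinion_wave` with columns `group`, `weight`
#'   and the item columns, and attributes `wave_label` and `items`.
#'
#' @examples
#' d <- tibble::tibble(
#'   group = c("A", "A", "B", "B"),
#'   econ = c(0.1, 0.2, 0.8, 0.9),
#'   green = c(0.2, 0.3, 0.7, 0.6)
#' )
#' w <- opinion_wave(d, wave = "t1")
#' wave_label(w)
#' @export
opinion_wave <- function(data, items = NULL, wave = NULL,
                         group = "group", weight = "weight") {
  stopifnot(is.data.frame(data))
  data <- tibble::as_tibble(data)
  if (!group %in% names(data)) {
    stop("column '", group, "' (group identity) not found", call. = FALSE)
  }
  if (is.null(wave)) {
    wave <- if ("wave" %in% names(data)) {
      u <- unique(data[["wave"]])
      if (length(u) != 1L) {
        stop("data contains ", length(u),
             " distinct wave labels; pass `wave` explicitly", call. = FALSE)
      }
      as.character(u)
    } else "wave"
  }
  w <- if (weight %in% names(data)) as.numeric(data[[weight]]) else rep(1, nrow(data))
  reserved <- unique(c(group, weight, "wave"))
  if (is.null(items)) items <- setdiff(names(data), reserved)
  if (length(items) < 1L) stop("at least one opinion item is required", call. = FALSE)
  missing_items <- setdiff(items, names(data))
  if (length(missing_items) > 0L) {
    stop("item column(s) not found: ", paste(missing_items, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(
    group = as.character(data[[group]]),
    weight = w
  )
  for (it in items) out[[it]] <- as.numeric(data[[it]])
  out <- new_opinion_wave(out, wave_label = wave, items = items)
  viol <- validate_wave(out)
  if (nrow(viol) > 0L) {
    stop("invalid opinion wave (", nrow(viol), " violation(s)); first: ",
         viol$invariant[1], " at row ", viol$row[1],
         " (value ", format(viol$value[1]), "). Run validate_wave() for all.",
         call. = FALSE)
  }
  out
}

new_opinion_wave <- function(tbl, wave_label, items) {
  structure(
    tbl,
    wave_label = wave_label,
    items = items,
    class = c("opinion_wave", class(tibble::tibble()))
  )
}

#' @rdname opinion_wave
#' @param x An `opinion_wave`.
#' @export
wave_label <- function(x) attr(x, "wave_label")

#' @rdname opinion_wave
#' @export
wave_items <- function(x) attr(x, "items")

#' @rdname opinion_wave
#' @export
opinion_matrix <- function(x) {
  stopifnot(inherits(x, "opinion_wave"))
  m <- as.matrix(as.data.frame(x)[, wave_items(x), drop = FALSE])
  rownames(m) <- NULL
  m
}

#' @export
print.opinion_wave <- function(x, ...) {
  cat("<opinion_wave> wave '", wave_label(x), "': ", nrow(x),
      " respondents, ", length(wave_items(x)), " item(s), ",
      length(unique(x$group)), " group(s)\n", sep = "")
  NextMethod()
}

#' Validate an opinion wave
#'
#' Checks the wave invariants: opinion coordinates in \eqn{[0, 1]}, strictly
#' positive finite weights, at least two respondents and one item. Diagnostic:
#' it reports rather than throws.
#'
#' @param wave An `opinion_wave` (or a tibble shaped like one).
#' @return A tibble with columns `invariant`, `row`, `column`, `value`; zero
#'   rows iff every invariant holds.
#' @examples
#' w <- opinion_wave(tibble::tibble(group = c("A", "B"), x = c(0, 1)))
#' validate_wave(w) # zero rows
#' @export
validate_wave <- function(wave) {
  items <- attr(wave, "items")
  if (is.null(items)) items <- setdiff(names(wave), c("group", "weight"))
  viol <- list()
  add <- function(invariant, row, column, value) {
    viol[[length(viol) + 1L]] <<- tibble::tibble(
      invariant = invariant, row = as.integer(row),
      column = as.character(column), value = as.numeric(value)
    )
  }
  if (nrow(wave) < 2L) add("n >= 2", NA_integer_, NA_character_, nrow(wave))
  if (length(items) < 1L) add("m >= 1", NA_integer_, NA_character_, length(items))
  w <- wave$weight
  bad_w <- which(!is.finite(w) | w <= 0)
  for (i in bad_w) add("weight > 0 and finite", i, "weight", w[i])
  for (it in items) {
    v <- wave[[it]]
    bad <- which(!is.finite(v) | v < 0 | v > 1)
    for (i in bad) add("opinion in [0, 1]", i, it, v[i])
  }
  if (length(viol) == 0L) {
    tibble::tibble(invariant = character(), row = integer(),
                   column = character(), value = numeric())
  } else {
    dplyr::bind_rows(viol)
  }
}
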