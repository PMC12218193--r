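#' Read a delimited survey table
#'
#' Reads a comma-, semicolon- or tab-delimited text file with a header row
#' and checks that every column named in the configuration is present. No
#' filtering happens here; the raw table is returned as typed columns.
#'
#' @param path File path.
#' @param config A run configuration (see [read_run_config()]) or a list
#'   with at least `columns` (roles `wave`, `weight`, `party`, `closeness`,
#'   `group`, `items`; all optional except `items`).
#' @param delim Field delimiter; `NULL` (default) autodetects among
#'   `","`, `";"` and tab from the header line.
#' @return A tibble.
#' @export
read_survey_table <- function(path, config = list(), delim = NULL) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    counts <- c(`,` = lengths(regmatches(header, gregexpr(",", header))),
                `;` = lengths(regmatches(header, gregexpr(";", header))),
                `\t` = lengths(regmatches(header, gregexpr("\t", header))))
    delim <- names(counts)[which.max(counts)]
  }
  tbl <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  cols <- config$columns
  needed <- c(cols$wave, cols$weight, cols$party, cols$closeness,
              cols$group, unlist(cols$items))
  absent <- setdiff(needed, names(tbl))
  if (length(absent) > 0L) {
    stop("configured column(s) missing from ", basename(path), ": ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  tbl
}

#' Apply respondent exclusion rules
#'
#' Applies the configured exclusion rules in their declared order, each
#' counted against the survivors of the previous rule, and returns the
#' filtered table together with an auditable [filter ledger][filter_ledger].
#' Supported rules (any subset, in this fixed order):
#'
#' * `invalid_item_response` — drop respondents with a missing/invalid code
#'   (from the Likert scheme's missing codes, or `NA`) on any opinion item;
#' * `disqualifying_answer` — drop respondents giving a configured
#'   disqualifying code on a configured item (e.g. denying that the
#'   phenomenon under study exists at all);
#' * `other_party` — drop respondents affiliated with a party outside the
#'   configured party map (no-preference and refusal codes are not
#'   "other");
#' * `party_refusal` — drop respondents who refused the party question.
#'
#' @param table A raw survey table.
#' @param config Run configuration: uses `columns`, `likert`, `party_map`,
#'   `closeness` and the `filters` list naming the active rules.
#' @return A list with elements `table` (filtered) and `ledger`
#'   (a `filter_ledger`).
#' @export
apply_filters <- function(table, config) {
  cols <- config$columns
  filters <- config$filters
  if (is.null(filters)) filters <- list()
  known <- c("invalid_item_response", "disqualifying_answer", "other_party",
             "party_refusal")
  unknown <- setdiff(names(filters), known)
  if (length(unknown) > 0L) {
    stop("unknown filter rule(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  n_input <- nrow(table)
  steps <- tibble::tibble(rule = character(), n_excluded = integer())
  record <- function(rule, keep) {
    steps <<- dplyr::bind_rows(steps, tibble::tibble(
      rule = rule, n_excluded = sum(!keep)))
    table[keep, , drop = FALSE]
  }

  if (isTRUE(filters$invalid_item_response)) {
    miss <- as.integer(config$likert$missing %||% integer())
    items <- unlist(cols$items)
    bad <- rep(FALSE, nrow(table))
    for (it in items) {
      v <- table[[it]]
      bad <- bad | is.na(v) | (as.integer(v) %in% miss)
    }
    table <- record("invalid_item_response", !bad)
  }
  dq <- filters$disqualifying_answer
  if (!is.null(dq) && !isFALSE(dq)) {
    v <- table[[dq$item]]
    table <- record("disqualifying_answer",
                    !(as.integer(v) %in% as.integer(dq$codes)))
  }
  if (isTRUE(filters$other_party)) {
    v <- as.character(table[[cols$party]])
    ok_codes <- c(names(config$party_map),
                  as.character(config$closeness$no_preference_codes %||% character()),
                  as.character(config$closeness$refusal_codes %||% character()))
    table <- record("other_party", is.na(v) | v %in% ok_codes)
  }
  if (isTRUE(filters$party_refusal)) {
    v <- as.character(table[[cols$party]])
    refusal <- as.character(config$closeness$refusal_codes %||% character())
    table <- record("party_refusal", !(v %in% refusal))
  }

  ledger <- new_filter_ledger(steps, n_input = n_input,
                              n_retained = nrow(table))
  list(table = table, ledger = ledger)
}

new_filter_ledger <- function(steps, n_input, n_retained) {
  structure(steps, n_input = as.integer(n_input),
            n_retained = as.integer(n_retained),
            class = c("filter_ledger", class(tibble::tibble())))
}

#' @rdname apply_filters
#' @param ledger A `filter_ledger`.
#' @export
ledger_counts <- function(ledger) {
  list(n_input = attr(ledger, "n_input"),
       n_retained = attr(ledger, "n_retained"),
       n_excluded = sum(ledger$n_excluded))
}

#' @export
print.filter_ledger <- function(x, ...) {
  cat("<filter_ledger> ", attr(x, "n_input"), " in, ",
      attr(x, "n_retained"), " retained\n", sep = "")
  NextMethod()
}

#' Assign identity labels from party preference
#'
#' Maps each respondent's party code to its group label. Respondents with
#' no party preference, or who said they feel "not at all" close to their
#' preferred party (the configured closeness codes), become nonpartisans
#' with the reserved identity `"None"`.
#'
#' @param table A filtered survey table.
#' @param party_map Named list/vector: party code (as character) -> group
#'   label.
#' @param config Run configuration providing `columns` (`party`,
#'   `closeness`) and `closeness` (codes for `no_preference_codes` on the
#'   party item and `not_close_codes` on the closeness item).
#' @return Character vector of group labels.
#' @export
assign_identities <- function(table, party_map, config) {
  cols <- config$columns
  party <- as.character(table[[cols$party]])
  nopref <- as.character(config$closeness$no_preference_codes %||% character())
  labels <- rep("None", nrow(table))
  mapped <- party %in% names(party_map)
  labels[mapped] <- unlist(party_map)[party[mapped]]
  labels[is.na(party) | party %in% nopref] <- "None"
  unmapped <- !is.na(party) & !mapped & !(party %in% nopref)
  if (any(unmapped)) {
    stop("unmapped party code(s) survive the filters: ",
         paste(unique(party[unmapped]), collapse = ", "), call. = FALSE)
  }
  if (!is.null(cols$closeness) && cols$closeness %in% names(table)) {
    close <- as.character(table[[cols$closeness]])
    not_close <- as.character(config$closeness$not_close_codes %||% character())
    labels[close %in% not_close] <- "None"
  }
  labels
}

#' Build opinion waves from a filtered survey table
#'
#' Maps Likert codes to the unit interval (when a scheme is configured),
#' assigns identities (from the party map when configured, else from a
#' `group` column), attaches weights (1 when no weight column is
#' configured), and splits the table into one [opinion_wave()] per wave
#' label.
#'
#' @inheritParams apply_filters
#' @param identities Optional precomputed identity labels (overrides the
#'   configured assignment).
#' @return Named list of [opinion_wave()]s, ordered by wave label.
#' @export
survey_to_waves <- function(table, config, identities = NULL) {
  cols <- config$columns
  items <- unlist(cols$items)
  if (is.null(items)) stop("config$columns$items is required", call. = FALSE)

  if (!is.null(config$likert)) {
    scheme <- as_likert_scheme(config$likert)
    mapped <- map_likert_to_unit(table[, items, drop = FALSE], scheme)
    if (length(attr(mapped, "flagged")) > 0L) {
      stop(length(attr(mapped, "flagged")), " respondent(s) still carry ",
           "missing item codes; apply the 'invalid_item_response' filter ",
           "first", call. = FALSE)
    }
  } else {
    mapped <- tibble::as_tibble(lapply(table[, items, drop = FALSE],
                                       as.numeric))
  }

  if (is.null(identities)) {
    identities <- if (!is.null(cols$party) && !is.null(config$party_map)) {
      assign_identities(table, config$party_map, config)
    } else if (!is.null(cols$group)) {
      as.character(table[[cols$group]])
    } else if ("group" %in% names(table)) {
      as.character(table$group)
    } else {
      stop("no identity source: configure columns$party + party_map, or ",
           "columns$group", call. = FALSE)
    }
  }
  weights <- if (!is.null(cols$weight)) {
    as.numeric(table[[cols$weight]])
  } else {
    rep(1, nrow(table))
  }
  wave_col <- cols$wave %||% "wave"
  wave_vals <- if (wave_col %in% names(table)) {
    as.character(table[[wave_col]])
  } else {
    rep("wave", nrow(table))
  }

  body <- dplyr::bind_cols(
    tibble::tibble(group = identities, weight = weights, wave = wave_vals),
    mapped
  )
  labs <- unique(wave_vals)
  waves <- purrr::map(labs, function(lb) {
    part <- dplyr::select(dplyr::filter(body, .data$wave == lb), -"wave")
    opinion_wave(part, items = items, wave = lb)
  })
  names(waves) <- labs
  waves[order(labs)]
}

as_likert_scheme <- function(cfg) {
  if (inherits(cfg, "likert_scheme")) return(cfg)
  levels <- as.integer(cfg$levels %||% 1:5)
  values <- as.numeric(cfg$values %||% seq(0, 1, length.out = length(levels)))
  likert_scheme(levels, values, missing = as.integer(cfg$missing %||% integer()))
}

#' Write and re-read an opinion wave as delimited text
#'
#' The layout is one header row with `wave`, `group`, `weight` and the item
#' columns; numbers are written at full round-trip precision, so
#' `read_opinion_wave(write_opinion_wave(w, f))` reproduces `w` exactly.
#'
#' @param wave An [opinion_wave()].
#' @param path Output CSV path.
#' @return `path` (write) / an [opinion_wave()] (read).
#' @export
write_opinion_wave <- function(wave, path) {
  stopifnot(inherits(wave, "opinion_wave"))
  lab <- wave_label(wave)
  out <- dplyr::bind_cols(tibble::tibble(wave = lab),
                          tibble::as_tibble(as.data.frame(wave)))
  # full binary precision so the round-trip is lossless
  for (j in which(vapply(out, is.double, logical(1)))) {
    out[[j]] <- sprintf("%.17g", out[[j]])
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_opinion_wave
#' @export
read_opinion_wave <- function(path) {
  # base reader: correctly rounded strtod, so %.17g text is bit-exact
  tbl <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  opinion_wave(tbl, items = setdiff(names(tbl), c("wave", "group", "weight")))
}

#' Read a run configuration file
#'
#' A single YAML file holding column roles, the Likert scheme, the party
#' map, filter rules, lens settings and (optionally) a synthetic scenario.
#' See the shipped example:
#' `system.file("extdata", "ess_german_climate.yaml", package = "lenspol")`.
#'
#' @param path YAML file path.
#' @return A list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = c("run_config", "list"))
}

#' @importFrom rlang %||% .data
NULL
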