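#' Specify one synthetic identity group
#'
#' Describes a group of respondents whose opinions are drawn from a
#' truncated Gaussian on the unit opinion cube: a mean vector in
#' \eqn{[0, 1]^m}, an m x m PSD covariance, a group size and a weight rule.
#'
#' @param label Group identity label (use `"None"` for nonpartisans).
#' @param n Number of respondents (>= 3 for a lens-bearing group).
#' @param mean Length-m numeric mean in \eqn{[0, 1]}.
#' @param covariance m x m PSD matrix, or a single number for an isotropic
#'   diagonal.
#' @param weight Either a single positive constant weight or a function
#'   `function(n)` returning n positive weights.
#' @return A `group_spec` list.
#' @examples
#' group_spec("red", 100, c(0.7, 0.7), 0.005)
#' @export
group_spec <- function(label, n, mean, covariance, weight = 1) {
  mean <- as.numeric(mean)
  m <- length(mean)
  if (is.numeric(covariance) && length(covariance) == 1L) {
    covariance <- diag(rep(covariance, m), m)
  }
  covariance <- as.matrix(covariance)
  stopifnot(nrow(covariance) == m, ncol(covariance) == m, n >= 1)
  if (max(abs(covariance - t(covariance))) > 1e-10) {
    stop("covariance must be symmetric", call. = FALSE)
  }
  if (min(eigen(covariance, symmetric = TRUE, only.values = TRUE)$values) <
      -1e-10) {
    stop("covariance must be positive semidefinite", call. = FALSE)
  }
  if (any(mean < 0 | mean > 1)) {
    stop("group mean must lie in [0, 1]^m", call. = FALSE)
  }
  structure(list(label = label, n = as.integer(n), mean = mean,
                 covariance = covariance, weight = weight),
            class = "group_spec")
}

#' Generate one synthetic opinion wave
#'
#' Draws each group's opinions from its Gaussian, truncated to the unit
#' cube by rejection (resample-until-inside), which avoids the boundary
#' atoms that clipping would create. Reproducible: the same specs and seed
#' give bitwise-identical waves.
#'
#' @param specs List of [group_spec()]s.
#' @param seed Integer seed for the draw.
#' @param wave_label Label for the generated wave.
#' @param truncation `"resample"` (default; rejection sampling) or
#'   `"clip"` (clamp to the cube; distorts covariances, mainly for
#'   degenerate tests).
#' @param max_retries Rejection budget per point before erroring.
#' @return An [opinion_wave()] with items `item_1 ... item_m`.
#' @examples
#' w <- generate_wave(list(group_spec("A", 10, 0.5, 0.01)), seed = 1)
#' @export
generate_wave <- function(specs, seed, wave_label = "wave",
                          truncation = c("resample", "clip"),
                          max_retries = 1000) {
  truncation <- match.arg(truncation)
  if (inherits(specs, "group_spec")) specs <- list(specs)
  m <- length(specs[[1]]$mean)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()),
          add = TRUE)
  set.seed(as.integer(seed))

  parts <- purrr::map(specs, function(sp) {
    if (length(sp$mean) != m) {
      stop("all groups must share the same opinion dimension", call. = FALSE)
    }
    x <- draw_truncated(sp$n, sp$mean, sp$covariance, truncation, max_retries,
                        sp$label)
    w <- if (is.function(sp$weight)) sp$weight(sp$n) else rep(sp$weight, sp$n)
    if (any(w <= 0)) stop("weights must be positive", call. = FALSE)
    tib <- tibble::as_tibble(as.data.frame(x), .name_repair = "minimal")
    names(tib) <- paste0("item_", seq_len(m))
    dplyr::bind_cols(tibble::tibble(group = sp$label, weight = w), tib)
  })
  opinion_wave(dplyr::bind_rows(parts), wave = wave_label)
}

draw_truncated <- function(n, mu, sigma, truncation, max_retries, label) {
  m <- length(mu)
  if (all(sigma == 0)) {
    return(matrix(rep(mu, each = n), nrow = n))
  }
  x <- MASS::mvrnorm(n, mu, sigma)
  if (m == 1L) x <- matrix(x, ncol = 1L)
  if (truncation == "clip") {
    return(pmin(pmax(x, 0), 1))
  }
  for (attempt in seq_len(max_retries)) {
    bad <- which(apply(x, 1, function(r) any(r < 0 | r > 1)))
    if (length(bad) == 0L) return(x)
    redraw <- MASS::mvrnorm(length(bad), mu, sigma)
    if (m == 1L || length(bad) == 1L) redraw <- matrix(redraw, ncol = m)
    x[bad, ] <- redraw
  }
  stop("truncation infeasible for group '", label, "': points still outside ",
       "[0, 1]^m after ", max_retries, " rejection rounds", call. = FALSE)
}

#' Specify a multi-wave synthetic scenario
#'
#' @param waves Named list: wave label -> list of [group_spec()]s. All waves
#'   must share group labels and opinion dimension.
#' @param seed Integer base seed; wave k is drawn with `seed + k - 1`.
#' @param discretize Optional [likert_scheme()]: generated tables snap to
#'   the grid when exported via [cmd_simulate()].
#' @param truncation Passed to [generate_wave()].
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(waves, seed = 1, discretize = NULL,
                          truncation = "resample") {
  stopifnot(is.list(waves), length(waves) >= 1)
  if (is.null(names(waves)) || any(names(waves) == "")) {
    names(waves) <- paste0("t", seq_along(waves))
  }
  labels <- purrr::map(waves, function(ws) sort(purrr::map_chr(ws, "label")))
  for (k in seq_along(labels)[-1]) {
    if (!identical(labels[[k]], labels[[1]])) {
      diff <- c(setdiff(labels[[k]], labels[[1]]),
                setdiff(labels[[1]], labels[[k]]))
      stop("wave '", names(waves)[k], "' has mismatched group label(s): ",
           paste(diff, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(waves = waves, seed = as.integer(seed),
                 discretize = discretize, truncation = truncation),
            class = "scenario_spec")
}

#' Generate all waves of a scenario
#'
#' @param scenario A [scenario_spec()].
#' @return Named list of [opinion_wave()]s.
#' @export
generate_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "scenario_spec"))
  purrr::imap(scenario$waves, function(specs, lab) {
    k <- match(lab, names(scenario$waves))
    generate_wave(specs, seed = scenario$seed + k - 1L, wave_label = lab,
                  truncation = scenario$truncation)
  })
}

#' Two-wave contraction scenario
#'
#' Takes a one-wave base scenario and builds the canonical two-wave
#' construction in which nothing changes except that one group's opinion
#' covariance is multiplied by `factor^2` (its spread contracts by
#' `factor`), with the mean held fixed. Opinion positions elsewhere are
#' statistically unchanged, so pure polarization is approximately zero
#' while the contracted group's narrowed lens makes its perceived distances
#' grow — lens-specific polarization without opinion divergence.
#'
#' @param base A [scenario_spec()] with at least one wave (its first wave
#'   is used as the baseline).
#' @param group_label The group whose covariance contracts.
#' @param factor Spread multiplier in (0, 1].
#' @return A two-wave [scenario_spec()].
#' @examples
#' contraction_scenario(two_lenses_spec(), "red", 0.5)
#' @export
contraction_scenario <- function(base, group_label, factor) {
  stopifnot(inherits(base, "scenario_spec"))
  if (!(is.numeric(factor) && length(factor) == 1L && factor > 0 &&
        factor <= 1)) {
    stop("`factor` must lie in (0, 1]", call. = FALSE)
  }
  w1 <- base$waves[[1]]
  labels <- purrr::map_chr(w1, "label")
  if (!group_label %in% labels) {
    stop("group '", group_label, "' is not in the base scenario",
         call. = FALSE)
  }
  w2 <- purrr::map(w1, function(sp) {
    if (sp$label == group_label) {
      sp$covariance <- sp$covariance * factor^2
    }
    sp
  })
  nm1 <- names(base$waves)[1]
  if (is.null(nm1) || nm1 == "") nm1 <- "t1"
  waves <- list(w1, w2)
  names(waves) <- c(nm1, paste0(nm1, "_contracted"))
  scenario_spec(waves, seed = base$seed, discretize = base$discretize,
                truncation = base$truncation)
}

#' The default asymmetric two-group fixture
#'
#' A "red" group with a small isotropic opinion covariance and a "blue"
#' group with a larger, anisotropic one, on a 2-D opinion space. Because
#' red's lens is narrow, red perceives the opinion gap to blue as large
#' while blue perceives the same gap as modest — the canonical asymmetric
#' perception construction.
#'
#' @param n Respondents per group.
#' @param seed Scenario seed.
#' @return A one-wave [scenario_spec()].
#' @export
two_lenses_spec <- function(n = 400, seed = 1) {
  red <- group_spec("red", n, c(0.75, 0.75),
                    diag(c(0.004, 0.004)))
  blue <- group_spec("blue", n, c(0.35, 0.4),
                     matrix(c(0.030, 0.012, 0.012, 0.020), 2))
  scenario_spec(list(t1 = list(red, blue)), seed = seed)
}

#' Discretize a continuous wave to a Likert survey table
#'
#' Snaps every opinion coordinate to the nearest scheme value and emits the
#' corresponding ordinal codes in the delimited survey-table layout
#' (columns `wave`, `group`, `weight`, then one integer column per item),
#' so synthetic data can be pushed through the full survey-reading
#' pipeline. Each coordinate moves by at most half the level spacing.
#'
#' @param wave An [opinion_wave()].
#' @param scheme A [likert_scheme()].
#' @return A tibble of ordinal codes in survey layout.
#' @export
discretize_to_likert <- function(wave, scheme = likert_scheme()) {
  stopifnot(inherits(wave, "opinion_wave"))
  codes <- unit_to_likert(as.data.frame(wave)[, wave_items(wave),
                                              drop = FALSE], scheme)
  lab <- wave_label(wave)
  grp <- wave$group
  wt <- wave$weight
  meta <- tibble::tibble(wave = lab, group = grp, weight = wt)
  dplyr::bind_cols(meta, codes)
}
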