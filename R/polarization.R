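#' Mean perceived disagreement in a wave
#'
#' Averages, over ordered respondent pairs \eqn{(i, j)}, \eqn{i \neq j}, the
#' distance perceiver i measures to j through the lens of i's identity
#' group, with pair weight \eqn{w_i w_j} normalized over the included
#' pairs. The objective counterpart (identity lens for everyone, i.e. plain
#' Euclidean distance) is reported alongside. Perceivers whose group has no
#' lens in the set fall back to the set's `"None"` (full-sample) lens; each
#' fallback is recorded.
#'
#' @param opinions An [opinion_wave()].
#' @param lenses A [build_lens_set()] (possibly fitted on another wave).
#' @param perceiver_filter Optional group label: restrict the perceiving
#'   side i to that group while j still ranges over the whole wave.
#' @param block_size Perceiver rows per internal block (memory knob; the
#'   result does not depend on it).
#' @param subsample_pairs Optional integer: estimate the averages from this
#'   many uniformly sampled ordered pairs instead of all \eqn{n(n-1)};
#'   default `NULL` computes exactly.
#' @param seed Seed for the pair subsample (ignored when exact).
#' @return An object of class `disagreement_report` with fields
#'   `population_mean`, `population_mean_sq` (same average of squared
#'   distances), `per_group` (per perceiver group), `objective_mean`,
#'   `n_pairs_effective`, plus wave/lens labels.
#' @examples
#' w <- generate_wave(list(
#'   group_spec("A", 40, 0.3, 0.01),
#'   group_spec("B", 40, 0.7, 0.04)
#' ), seed = 7)
#' mean_disagreement(w, build_lens_set(w))
#' @export
mean_disagreement <- function(opinions, lenses, perceiver_filter = NULL,
                              block_size = 1024, subsample_pairs = NULL,
                              seed = NULL) {
  stopifnot(inherits(opinions, "opinion_wave"), inherits(lenses, "lens_set"))
  x <- opinion_matrix(opinions)
  m <- ncol(x)
  any_lens <- lenses$lenses[[1]]
  if (nrow(any_lens$metric) != m) {
    stop("wave has ", m, " item(s) but the lens set is ",
         nrow(any_lens$metric), "-dimensional", call. = FALSE)
  }
  w <- opinions$weight
  groups <- opinions$group
  perceiver_groups <- unique(groups)
  if (!is.null(perceiver_filter)) {
    if (!perceiver_filter %in% perceiver_groups) {
      stop("perceiver_filter '", perceiver_filter,
           "' is not a group in wave '", wave_label(opinions), "'",
           call. = FALSE)
    }
    perceiver_groups <- perceiver_filter
  }

  fallbacks <- character()
  lens_for <- function(g) {
    if (!is.null(lenses$lenses[[g]])) return(lenses$lenses[[g]])
    fallbacks <<- c(fallbacks, g)
    lenses$lenses[["None"]]
  }

  if (!is.null(subsample_pairs)) {
    return(disagreement_subsampled(opinions, lenses, perceiver_groups,
                                   lens_for, subsample_pairs, seed,
                                   fallbacks_env = environment()))
  }

  w_tot <- sum(w)
  per <- purrr::map(perceiver_groups, function(g) {
    idx <- which(groups == g)
    tr <- lens_whitener(lens_for(g))
    s <- pair_sums(x, w, idx, tr, block_size)
    tibble::tibble(group = g, mean = s$num_d / s$mass,
                   mean_sq = s$num_d2 / s$mass, mass = s$mass)
  })
  per <- dplyr::bind_rows(per)
  mass_tot <- sum(per$mass)

  obj_idx <- which(groups %in% perceiver_groups)
  s_obj <- pair_sums(x, w, obj_idx, diag(m), block_size)

  new_disagreement_report(
    opinions_wave = wave_label(opinions),
    lenses_wave = lenses$fitted_on,
    population_mean = sum(per$mean * per$mass) / mass_tot,
    population_mean_sq = sum(per$mean_sq * per$mass) / mass_tot,
    per_group = per,
    objective_mean = s_obj$num_d / s_obj$mass,
    n_pairs_effective = mass_tot,
    items = wave_items(opinions),
    fallbacks = unique(fallbacks)
  )
}

# blockwise weighted sums of d and d^2 from perceivers `idx` to all rows
pair_sums <- function(x, w, idx, transform, block_size) {
  y <- x %*% transform
  rs <- rowSums(y * y)
  n <- nrow(y)
  num_d <- 0
  num_d2 <- 0
  starts <- seq(1L, length(idx), by = block_size)
  for (s in starts) {
    blk <- idx[s:min(s + block_size - 1L, length(idx))]
    g <- y[blk, , drop = FALSE] %*% t(y)
    sq <- outer(rs[blk], rs, "+") - 2 * g
    sq[sq < 0] <- 0
    sq[cbind(seq_along(blk), blk)] <- 0 # exclude self-pairs exactly
    d <- sqrt(sq)
    num_d <- num_d + sum(w[blk] * drop(d %*% w))
    num_d2 <- num_d2 + sum(w[blk] * drop(sq %*% w))
  }
  mass <- sum(w[idx] * (sum(w) - w[idx]))
  list(num_d = num_d, num_d2 = num_d2, mass = mass)
}

# seeded uniform ordered-pair subsample estimate
disagreement_subsampled <- function(opinions, lenses, perceiver_groups,
                                    lens_for, n_pairs, seed, fallbacks_env) {
  x <- opinion_matrix(opinions)
  w <- opinions$weight
  groups <- opinions$group
  keep <- which(groups %in% perceiver_groups)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  i <- sample(keep, n_pairs, replace = TRUE)
  j <- sample(nrow(x), n_pairs, replace = TRUE)
  ok <- i != j
  i <- i[ok]; j <- j[ok]
  tr <- lapply(unique(groups[i]), function(g) lens_whitener(lens_for(g)))
  names(tr) <- unique(groups[i])
  delta <- x[i, , drop = FALSE] - x[j, , drop = FALSE]
  d2 <- numeric(length(i))
  for (g in names(tr)) {
    rows <- which(groups[i] == g)
    z <- delta[rows, , drop = FALSE] %*% tr[[g]]
    d2[rows] <- rowSums(z * z)
  }
  pw <- w[i] * w[j]
  per <- tibble::tibble(group = groups[i], d = sqrt(d2), d2 = d2, pw = pw) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(mean = sum(.data$d * .data$pw) / sum(.data$pw),
                     mean_sq = sum(.data$d2 * .data$pw) / sum(.data$pw),
                     mass = sum(.data$pw), .groups = "drop")
  ze <- x[i, , drop = FALSE] - x[j, , drop = FALSE]
  d_obj <- sqrt(rowSums(ze * ze))
  new_disagreement_report(
    opinions_wave = wave_label(opinions),
    lenses_wave = lenses$fitted_on,
    population_mean = sum(sqrt(d2) * pw) / sum(pw),
    population_mean_sq = sum(d2 * pw) / sum(pw),
    per_group = per,
    objective_mean = sum(d_obj * pw) / sum(pw),
    n_pairs_effective = sum(pw),
    items = wave_items(opinions),
    fallbacks = unique(get("fallbacks", fallbacks_env))
  )
}

new_disagreement_report <- function(...) {
  structure(list(...), class = "disagreement_report")
}

#' @export
print.disagreement_report <- function(x, ...) {
  cat("<disagreement_report> opinions '", x$opinions_wave,
      "' through lenses of '", x$lenses_wave, "'\n", sep = "")
  cat("  perceived mean: ", signif(x$population_mean, 6),
      "   objective (Euclidean) mean: ", signif(x$objective_mean, 6), "\n",
      sep = "")
  print(x$per_group)
  if (length(x$fallbacks)) {
    cat("  lens fallbacks to 'None':", paste(x$fallbacks, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Perceived polarization between two disagreement reports
#'
#' The change in mean perceived disagreement,
#' \eqn{P(t_1, t_2) = \bar d(t_2) - \bar d(t_1)}. Positive values mean the
#' population perceives opinions diverging; negative, converging.
#'
#' @param d1,d2 [mean_disagreement()] reports computed on the same item set.
#' @return A single number.
#' @export
perceived_polarization <- function(d1, d2) {
  stopifnot(inherits(d1, "disagreement_report"),
            inherits(d2, "disagreement_report"))
  if (!identical(d1$items, d2$items)) {
    stop("reports were computed on different item sets: ",
         paste(d1$items, collapse = ","), " vs ",
         paste(d2$items, collapse = ","), call. = FALSE)
  }
  d2$population_mean - d1$population_mean
}

#' Decompose perceived polarization into pure and lens-specific parts
#'
#' Between waves \eqn{t_1} and \eqn{t_2}, perceived polarization
#' \eqn{P = \bar d(X_{t_2}, L_{t_2}) - \bar d(X_{t_1}, L_{t_1})} splits
#' exactly into pure polarization
#' \eqn{P_1 = \bar d(X_{t_2}, L_{t_1}) - \bar d(X_{t_1}, L_{t_1})}
#' (opinion change seen through the old lenses) and lens-specific
#' polarization
#' \eqn{P_2 = \bar d(X_{t_2}, L_{t_2}) - \bar d(X_{t_2}, L_{t_1})}
#' (the effect of updating the lenses on the new opinions). When the lenses
#' are held fixed (`lenses2 = NULL`), \eqn{P_2 = 0} and \eqn{P = P_1}.
#'
#' @param wave1,wave2 Two [opinion_wave()]s sharing the same items.
#' @param lenses1 Lens set for \eqn{t_1} (typically fitted on `wave1`).
#' @param lenses2 Lens set for \eqn{t_2}; `NULL` keeps `lenses1` fixed.
#' @param mode Label stored on the result; inferred when `NULL`
#'   (`"fixed"` without `lenses2`, else `"custom"`).
#' @param ... Passed to [mean_disagreement()] (e.g. `block_size`).
#' @return An object of class `polarization_decomposition`: population
#'   `P`, `P1`, `P2`, per-group triples (perceiver-side restriction),
#'   values relative to the baseline disagreement, the three underlying
#'   reports, and the objective (Euclidean) polarization.
#' @examples
#' sc <- contraction_scenario(two_lenses_spec(n = 60), "red", 0.5)
#' waves <- generate_scenario(sc)
#' decompose_instantaneous(waves[[1]], waves[[2]])
#' @export
decompose <- function(wave1, wave2, lenses1, lenses2 = NULL, mode = NULL,
                      ...) {
  stopifnot(inherits(wave1, "opinion_wave"), inherits(wave2, "opinion_wave"),
            inherits(lenses1, "lens_set"))
  if (!identical(wave_items(wave1), wave_items(wave2))) {
    stop("waves measure different item sets", call. = FALSE)
  }
  if (is.null(mode)) mode <- if (is.null(lenses2)) "fixed" else "custom"
  r11 <- mean_disagreement(wave1, lenses1, ...)
  r21 <- mean_disagreement(wave2, lenses1, ...)
  r22 <- if (is.null(lenses2)) r21 else mean_disagreement(wave2, lenses2, ...)

  p1 <- r21$population_mean - r11$population_mean
  p2 <- r22$population_mean - r21$population_mean
  p <- p1 + p2

  per <- dplyr::full_join(
    dplyr::select(r11$per_group, "group", baseline = "mean"),
    dplyr::select(r21$per_group, "group", old_lens = "mean"),
    by = "group"
  )
  per <- dplyr::full_join(
    per,
    dplyr::select(r22$per_group, "group", new_lens = "mean"),
    by = "group"
  )
  per <- dplyr::mutate(
    per,
    P1 = .data$old_lens - .data$baseline,
    P2 = .data$new_lens - .data$old_lens,
    P = .data$P1 + .data$P2,
    rel_P = .data$P / .data$baseline,
    rel_P1 = .data$P1 / .data$baseline,
    rel_P2 = .data$P2 / .data$baseline
  )
  per <- dplyr::select(per, "group", "baseline", "P", "P1", "P2",
                       "rel_P", "rel_P1", "rel_P2")

  structure(
    list(
      t1 = wave_label(wave1), t2 = wave_label(wave2),
      P = p, P1 = p1, P2 = p2, mode = mode,
      baseline = r11$population_mean,
      relative = list(P = p / r11$population_mean,
                      P1 = p1 / r11$population_mean,
                      P2 = p2 / r11$population_mean),
      per_group = per,
      objective = list(
        d1 = r11$objective_mean, d2 = r21$objective_mean,
        P_obj = r21$objective_mean - r11$objective_mean
      ),
      reports = list(baseline = r11, old_lens = r21, new_lens = r22)
    ),
    class = "polarization_decomposition"
  )
}

#' @rdname decompose
#' @param ridge_epsilon,min_group_size Passed to [build_lens_set()] for the
#'   internal fits.
#' @details `decompose_instantaneous()` models perfectly informed
#'   perceivers (zero lens-updating delay): it fits one lens set on each
#'   wave internally and the `P2` field then carries the instantaneous
#'   lens-specific polarization \eqn{P_2^*}.
#' @export
decompose_instantaneous <- function(wave1, wave2, ridge_epsilon = 1e-6,
                                    min_group_size = 3, ...) {
  l1 <- build_lens_set(wave1, ridge_epsilon = ridge_epsilon,
                       min_group_size = min_group_size, quiet = TRUE)
  l2 <- build_lens_set(wave2, ridge_epsilon = ridge_epsilon,
                       min_group_size = min_group_size, quiet = TRUE)
  decompose(wave1, wave2, l1, l2, mode = "instantaneous", ...)
}

#' @export
print.polarization_decomposition <- function(x, ...) {
  cat("<polarization_decomposition> '", x$t1, "' -> '", x$t2, "' (",
      x$mode, " lenses)\n", sep = "")
  cat(sprintf("  P = %+.5f   P1 (pure) = %+.5f   P2 (lens) = %+.5f\n",
              x$P, x$P1, x$P2))
  cat(sprintf("  relative to baseline %.5f: P %+.2f%%, P1 %+.2f%%, P2 %+.2f%%\n",
              x$baseline, 100 * x$relative$P, 100 * x$relative$P1,
              100 * x$relative$P2))
  cat(sprintf("  objective polarization (Euclidean): %+.5f\n",
              x$objective$P_obj))
  print(x$per_group)
  invisible(x)
}
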