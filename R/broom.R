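#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a disagreement report
#'
#' One row per perceiver group with its mean perceived distance, mean
#' squared distance, and weighted pair mass, plus a `"(all)"` population
#' row.
#'
#' @param x A [mean_disagreement()] report.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy disagreement_report
#' @export
tidy.disagreement_report <- function(x, ...) {
  dplyr::bind_rows(
    x$per_group,
    tibble::tibble(group = "(all)", mean = x$population_mean,
                   mean_sq = x$population_mean_sq,
                   mass = x$n_pairs_effective)
  )
}

#' @rdname tidy.disagreement_report
#' @method glance disagreement_report
#' @export
glance.disagreement_report <- function(x, ...) {
  tibble::tibble(
    opinions_wave = x$opinions_wave, lenses_wave = x$lenses_wave,
    population_mean = x$population_mean,
    population_mean_sq = x$population_mean_sq,
    objective_mean = x$objective_mean,
    n_pairs_effective = x$n_pairs_effective,
    n_groups = nrow(x$per_group)
  )
}

#' Tidy a polarization decomposition
#'
#' One row per perceiver group (plus `"(all)"`) with the baseline
#' disagreement, the decomposition `P = P1 + P2`, and the same quantities
#' relative to the baseline.
#'
#' @param x A [decompose()] result.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy polarization_decomposition
#' @export
tidy.polarization_decomposition <- function(x, ...) {
  dplyr::bind_rows(
    x$per_group,
    tibble::tibble(group = "(all)", baseline = x$baseline,
                   P = x$P, P1 = x$P1, P2 = x$P2,
                   rel_P = x$relative$P, rel_P1 = x$relative$P1,
                   rel_P2 = x$relative$P2)
  )
}

#' @rdname tidy.polarization_decomposition
#' @method glance polarization_decomposition
#' @export
glance.polarization_decomposition <- function(x, ...) {
  tibble::tibble(
    t1 = x$t1, t2 = x$t2, mode = x$mode, baseline = x$baseline,
    P = x$P, P1 = x$P1, P2 = x$P2,
    rel_P = x$relative$P, rel_P1 = x$relative$P1, rel_P2 = x$relative$P2,
    P_objective = x$objective$P_obj
  )
}

#' Plot a polarization decomposition
#'
#' Stacked per-group bars of the pure (`P1`) and lens-specific (`P2`)
#' components, with a point marking total perceived polarization `P`.
#'
#' @param object A [decompose()] result.
#' @param relative Plot quantities relative to the baseline disagreement.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot polarization_decomposition
#' @export
autoplot.polarization_decomposition <- function(object, relative = FALSE,
                                                ...) {
  tb <- tidy(object)
  if (relative) {
    tb <- dplyr::transmute(tb, group = .data$group, P = .data$rel_P,
                           P1 = .data$rel_P1, P2 = .data$rel_P2)
  }
  long <- tidyr::pivot_longer(
    dplyr::select(tb, "group", "P1", "P2"),
    c("P1", "P2"), names_to = "component", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$value,
                                     fill = .data$component)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::geom_point(
      data = dplyr::select(tb, "group", "P"),
      mapping = ggplot2::aes(x = .data$group, y = .data$P),
      inherit.aes = FALSE, shape = 18, size = 3
    ) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(
      x = "perceiver group",
      y = if (relative) "polarization (relative to baseline)" else "polarization",
      fill = NULL,
      title = sprintf("Perceived polarization %s → %s (%s lenses)",
                      object$t1, object$t2, object$mode)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a disagreement report
#'
#' Per-group mean perceived distances with dashed lines at the population
#' perceived and objective (Euclidean) means.
#'
#' @param object A [mean_disagreement()] report.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot disagreement_report
#' @export
autoplot.disagreement_report <- function(object, ...) {
  ggplot2::ggplot(object$per_group,
                  ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_hline(yintercept = object$population_mean,
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = object$objective_mean,
                        linetype = "dotted") +
    ggplot2::labs(
      x = "perceiver group", y = "mean perceived distance",
      title = sprintf("Disagreement: opinions '%s' through lenses of '%s'",
                      object$opinions_wave, object$lenses_wave),
      subtitle = "dashed: population perceived mean; dotted: objective mean"
    ) +
    ggplot2::theme_minimal()
}
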