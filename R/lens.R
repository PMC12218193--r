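#' Weighted in-group opinion covariance
#'
#' The covariance of the opinion vectors of the respondents sharing one
#' identity label, using the survey analysis weights as frequency weights:
#' weights are normalized to sum to the in-group size \eqn{n_g} and the
#' unbiased \eqn{n_g - 1} denominator is used, so the estimate is invariant
#' to rescaling all weights and reduces to the ordinary unbiased sample
#' covariance under equal weights. For the reserved nonpartisan label
#' `"None"` the in-group is the entire sample.
#'
#' @param wave An [opinion_wave()].
#' @param group_label Identity label; `"None"` selects all respondents.
#' @return An m x m symmetric positive semidefinite matrix.
#' @examples
#' w <- opinion_wave(tibble::tibble(group = c("A", "A", "A"),
#'                                  x = c(0, 0.5, 1)))
#' weighted_group_covariance(w, "A")
#' @export
weighted_group_covariance <- function(wave, group_label) {
  stopifnot(inherits(wave, "opinion_wave"))
  idx <- if (identical(group_label, "None")) {
    seq_len(nrow(wave))
  } else {
    which(wave$group == group_label)
  }
  if (length(idx) == 0L) {
    stop("group '", group_label, "' not present in wave '",
         wave_label(wave), "'", call. = FALSE)
  }
  if (length(idx) < 3L) {
    stop("group '", group_label, "' has only ", length(idx),
         " member(s); at least 3 are required to fit a covariance",
         call. = FALSE)
  }
  x <- opinion_matrix(wave)[idx, , drop = FALSE]
  w <- wave$weight[idx]
  n <- length(idx)
  w <- w * (n / sum(w)) # normalize to the in-group count
  mu <- colSums(x * w) / n
  xc <- sweep(x, 2, mu)
  s <- crossprod(xc * sqrt(w)) / (n - 1)
  s <- (s + t(s)) / 2
  dimnames(s) <- NULL
  s
}

#' Build a group lens from a covariance matrix
#'
#' Eigendecomposes the in-group covariance; the lens basis columns are the
#' principal axes scaled by the square roots of their eigenvalues, and the
#' induced subjective metric is the inverse of the (ridge-regularized)
#' covariance, so the squared subjective distance is the Mahalanobis
#' quadratic form \eqn{\Delta^T \Sigma^{-1} \Delta}. A ridge
#' \eqn{\epsilon \cdot \mathrm{tr}(\Sigma)/m \cdot I} keeps the metric finite
#' when a group is (near-)unanimous; such a group perceives very large but
#' finite distances.
#'
#' @param covariance Symmetric PSD m x m matrix.
#' @param group_label Identity label the lens belongs to.
#' @param ridge_epsilon Nonnegative relative ridge (default `1e-6`). With a
#'   zero ridge an all-zero covariance is an error (singular lens).
#' @param fitted_on Wave label the covariance was estimated from.
#' @return An object of class `lens` with fields `group`, `fitted_on`,
#'   `basis` (columns \eqn{\sqrt{\lambda_k} v_k}), `metric` (the inverse
#'   regularized covariance), `eigenvalues` (nonincreasing), and `ridge`
#'   (the absolute ridge added to each eigenvalue).
#' @examples
#' build_lens(diag(c(0.25, 1)), "A") # metric diag(4, 1) up to the ridge
#' @export
build_lens <- function(covariance, group_label, ridge_epsilon = 1e-6,
                       fitted_on = NA_character_) {
  covariance <- as.matrix(covariance)
  m <- nrow(covariance)
  if (ncol(covariance) != m) stop("covariance must be square", call. = FALSE)
  asym <- max(abs(covariance - t(covariance)))
  if (asym > 1e-8 * max(1, max(abs(covariance)))) {
    stop("covariance is not symmetric (max asymmetry ", format(asym), ")",
         call. = FALSE)
  }
  if (ridge_epsilon < 0) stop("ridge_epsilon must be nonnegative", call. = FALSE)
  covariance <- (covariance + t(covariance)) / 2
  eig <- eigen(covariance, symmetric = TRUE)
  lambda <- eig$values
  if (min(lambda) < -1e-8 * max(1, max(abs(lambda)))) {
    stop("covariance is not positive semidefinite (eigenvalue ",
         format(min(lambda)), ")", call. = FALSE)
  }
  lambda <- pmax(lambda, 0)
  scale <- mean(diag(covariance))
  if (scale <= 0) scale <- 1 # unanimous group: ridge on the unit scale
  ridge <- ridge_epsilon * scale
  lam_reg <- lambda + ridge
  if (any(lam_reg <= 0)) {
    stop("singular lens for group '", group_label,
         "': covariance is rank-deficient and the ridge is 0", call. = FALSE)
  }
  v <- eig$vectors
  basis <- v %*% diag(sqrt(lambda), m)
  metric <- v %*% diag(1 / lam_reg, m) %*% t(v)
  metric <- (metric + t(metric)) / 2
  structure(
    list(group = group_label, fitted_on = fitted_on, basis = basis,
         metric = metric, eigenvalues = lambda, ridge = ridge),
    class = "lens"
  )
}

#' @export
print.lens <- function(x, ...) {
  cat("<lens> group '", x$group, "' fitted on '", x$fitted_on, "': ",
      length(x$eigenvalues), "D, eigenvalues ",
      paste(signif(x$eigenvalues, 4), collapse = ", "),
      if (x$ridge > 0) paste0(" (ridge ", signif(x$ridge, 3), ")") else "",
      "\n", sep = "")
  invisible(x)
}

# identity lens: the objective (Euclidean) viewpoint
identity_lens <- function(m, group_label = "objective") {
  structure(
    list(group = group_label, fitted_on = NA_character_,
         basis = diag(m), metric = diag(m),
         eigenvalues = rep(1, m), ridge = 0),
    class = "lens"
  )
}

#' Fit one lens per identity group in a wave
#'
#' Fits the `"None"` lens on the full sample and a group lens on each
#' identity's in-group. Groups smaller than `min_group_size` cannot support
#' a covariance of their own; they fall back to the full-sample (`"None"`)
#' lens and the fallback is recorded in the returned set's `fallbacks`
#' tibble (and messaged).
#'
#' @inheritParams weighted_group_covariance
#' @inheritParams build_lens
#' @param min_group_size Smallest group fitted on its own (default 3).
#' @param quiet Suppress fallback messages.
#' @return An object of class `lens_set`: fields `fitted_on`, `lenses`
#'   (named list including `"None"`), and `fallbacks`.
#' @examples
#' w <- generate_wave(list(
#'   group_spec("A", 50, 0.3, 0.01),
#'   group_spec("B", 50, 0.7, 0.04)
#' ), seed = 1)
#' build_lens_set(w)
#' @export
build_lens_set <- function(wave, ridge_epsilon = 1e-6, min_group_size = 3,
                           quiet = FALSE) {
  stopifnot(inherits(wave, "opinion_wave"))
  wl <- wave_label(wave)
  none_lens <- build_lens(weighted_group_covariance(wave, "None"), "None",
                          ridge_epsilon = ridge_epsilon, fitted_on = wl)
  groups <- setdiff(unique(wave$group), "None")
  lenses <- list(None = none_lens)
  fallbacks <- tibble::tibble(group = character(), n = integer())
  for (g in groups) {
    n_g <- sum(wave$group == g)
    if (n_g < max(3L, min_group_size)) {
      lens_g <- none_lens
      lens_g$group <- g
      fallbacks <- dplyr::bind_rows(fallbacks,
                                    tibble::tibble(group = g, n = n_g))
      if (!quiet) {
        message("group '", g, "' has ", n_g, " member(s) < min_group_size ",
                min_group_size, "; using the full-sample lens")
      }
    } else {
      lens_g <- build_lens(weighted_group_covariance(wave, g), g,
                           ridge_epsilon = ridge_epsilon, fitted_on = wl)
    }
    lenses[[g]] <- lens_g
  }
  structure(list(fitted_on = wl, lenses = lenses, fallbacks = fallbacks),
            class = "lens_set")
}

#' @export
print.lens_set <- function(x, ...) {
  cat("<lens_set> fitted on wave '", x$fitted_on, "': ",
      length(x$lenses), " lens(es) [",
      paste(names(x$lenses), collapse = ", "), "]\n", sep = "")
  if (nrow(x$fallbacks) > 0L) {
    cat("  fallbacks to the full-sample lens:",
        paste0(x$fallbacks$group, " (n=", x$fallbacks$n, ")", collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Subjective distance between two opinions through a lens
#'
#' \eqn{d(x_i, x_j | L) = \sqrt{(x_i - x_j)^T M (x_i - x_j)}} with `M` the
#' lens metric (the inverse in-group covariance). With an identity lens this
#' is the Euclidean distance; in one dimension it is \eqn{|\Delta|/\sigma},
#' the opinion difference normalized by the in-group standard deviation.
#' Symmetric in `x_i` and `x_j` for a fixed lens, but different lenses
#' yield different distances for the same pair.
#'
#' @param x_i,x_j Numeric opinion vectors of length m.
#' @param lens A [build_lens()] object.
#' @return Nonnegative scalar.
#' @examples
#' l <- build_lens(diag(2), "obj", ridge_epsilon = 0)
#' subjective_distance(c(0, 0), c(0.3, 0.4), l) # Euclidean: 0.5
#' @export
subjective_distance <- function(x_i, x_j, lens) {
  stopifnot(inherits(lens, "lens"))
  m <- nrow(lens$metric)
  if (length(x_i) != m || length(x_j) != m) {
    stop("opinion vectors of length ", length(x_i), "/", length(x_j),
         " do not match the ", m, "-dimensional lens", call. = FALSE)
  }
  d <- as.numeric(x_i) - as.numeric(x_j)
  sqrt(max(0, drop(crossprod(d, lens$metric %*% d))))
}

# whitening transform W with d(x, y)^2 = |(x - y) W|^2 for row vectors
lens_whitener <- function(lens) {
  e <- eigen(lens$metric, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), length(e$values)) %*% t(e$vectors)
}

#' Serialize a lens set to JSON
#'
#' Writes group labels, the fitted wave, bases, metrics, eigenvalues and
#' ridge values at full floating-point precision, so
#' [read_lens_set()] reproduces the set exactly.
#'
#' @param lens_set A [build_lens_set()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lens_set <- function(lens_set, path) {
  stopifnot(inherits(lens_set, "lens_set"))
  payload <- list(
    fitted_on = lens_set$fitted_on,
    fallbacks = lens_set$fallbacks,
    lenses = purrr::map(lens_set$lenses, function(l) {
      list(group = l$group, fitted_on = l$fitted_on,
           basis = l$basis, metric = l$metric,
           eigenvalues = l$eigenvalues, ridge = l$ridge)
    })
  )
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_lens_set
#' @export
read_lens_set <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  lenses <- purrr::map(payload$lenses, function(l) {
    structure(
      list(group = l$group, fitted_on = l$fitted_on,
           basis = as.matrix(l$basis), metric = as.matrix(l$metric),
           eigenvalues = as.numeric(l$eigenvalues),
           ridge = as.numeric(l$ridge)),
      class = "lens"
    )
  })
  fallbacks <- tibble::as_tibble(payload$fallbacks)
  if (nrow(fallbacks) == 0L) {
    fallbacks <- tibble::tibble(group = character(), n = integer())
  }
  structure(list(fitted_on = payload$fitted_on, lenses = lenses,
                 fallbacks = fallbacks),
            class = "lens_set")
}
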