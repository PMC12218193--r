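# shared test utilities: oracles are deliberately independent of the
# package's eigendecomposition path (direct solve() / quadratic forms)

random_psd <- function(m) {
  a <- matrix(stats::rnorm(m * m), m)
  crossprod(a) / m + 0.05 * diag(m)
}

# brute-force Mahalanobis oracle: invert the covariance directly
oracle_distance <- function(x, y, sigma) {
  d <- as.numeric(x) - as.numeric(y)
  sqrt(drop(t(d) %*% solve(sigma) %*% d))
}

# a lens set in which every group (and "None") uses the identity lens
identity_lens_set <- function(wave) {
  m <- length(wave_items(wave))
  groups <- unique(c("None", wave$group))
  lenses <- lapply(groups, function(g) build_lens(diag(m), g,
                                                  ridge_epsilon = 0,
                                                  fitted_on = wave_label(wave)))
  names(lenses) <- groups
  structure(list(fitted_on = wave_label(wave), lenses = lenses,
                 fallbacks = tibble::tibble(group = character(),
                                            n = integer())),
            class = "lens_set")
}

# small random multi-group wave for property tests
random_wave <- function(n_per_group = 25, m = 2, n_groups = 2, seed = 1,
                        wave_label = "w") {
  set.seed(seed)
  specs <- lapply(seq_len(n_groups), function(k) {
    group_spec(LETTERS[k], n_per_group,
               mean = stats::runif(m, 0.3, 0.7),
               covariance = random_psd(m) * 0.01)
  })
  generate_wave(specs, seed = seed + 1000L, wave_label = wave_label)
}

# deterministic contraction of a wave's opinions toward each group's mean
contract_wave <- function(wave, factor, groups = unique(wave$group),
                          label = paste0(wave_label(wave), "_c")) {
  x <- opinion_matrix(wave)
  for (g in groups) {
    idx <- which(wave$group == g)
    mu <- colMeans(x[idx, , drop = FALSE])
    centered <- sweep(x[idx, , drop = FALSE], 2, mu)
    x[idx, ] <- sweep(centered * factor, 2, mu, `+`)
  }
  tbl <- tibble::tibble(group = wave$group, weight = wave$weight)
  for (j in seq_along(wave_items(wave))) tbl[[wave_items(wave)[j]]] <- x[, j]
  opinion_wave(tbl, items = wave_items(wave), wave = label)
}

# the shipped synthetic ESS-style fixture and its configuration
fixture_path <- function(name) {
  system.file("extdata", name, package = "lenspol")
}
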