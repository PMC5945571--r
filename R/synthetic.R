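#' Simulate grouped probit bioassays
#'
#' Emulates the WHO-style larvicidal bioassay design behind the experimental
#' LC50 table: groups of larvae exposed to a log-spaced dose grid, deaths
#' drawn as `Binomial(n, Phi(slope * (log10 d - log10 lc50)))`. Defaults
#' mirror the reported design: 5 dose groups of 20 larvae. Reproducible per
#' seed and isolated from the global RNG state.
#'
#' @param lc50 true median lethal concentration (µg/mL)
#' @param slope probit slope per log10 dose unit (> 0)
#' @param doses dose grid (default 5 log-spaced doses spanning lc50)
#' @param n_per_group larvae per group (default 20)
#' @param replicates number of independent datasets
#' @param seed integer seed
#' @return a [dose_response()] dataset, or a list of them when
#'   `replicates > 1`
#' @export
gen_bioassay <- function(lc50 = 50, slope = 2.5,
                         doses = lc50 * 10^seq(-0.8, 0.8, length.out = 5),
                         n_per_group = 20, replicates = 1, seed = 1) {
  stopifnot(lc50 > 0, slope > 0, n_per_group >= 1, all(doses > 0))
  p <- stats::pnorm(slope * (log10(doses) - log10(lc50)))
  out <- withr_seed(seed, {
    lapply(seq_len(replicates), function(r) {
      dead <- stats::rbinom(length(doses), n_per_group, p)
      dose_response(doses, rep(n_per_group, length(doses)), dead)
    })
  })
  if (replicates == 1) out[[1]] else out
}

# evaluate expr under a local RNG seed, restoring global state afterwards
withr_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Simulate a descriptor/activity matrix with a planted linear model
#'
#' Descriptors are drawn from an equicorrelated multivariate normal;
#' the response is a linear combination of a planted descriptor subset plus
#' Gaussian noise. The returned truth record carries the planted subset,
#' coefficients and the realised in-sample R2, supporting recovery tests of
#' the GA subset search. Defaults mirror the published modelling scale:
#' 50 compounds, 20 candidate descriptors, a small planted subset, noise
#' tuned so the realised R2 is about 0.85.
#'
#' @param n_compounds rows
#' @param n_descriptors columns
#' @param planted indices of the true descriptors
#' @param coefficients planted coefficients (same length as `planted`)
#' @param intercept planted intercept
#' @param noise_sd Gaussian noise SD (>= 0)
#' @param correlation equicorrelation of the descriptor block, in [0, 1)
#' @param seed integer seed
#' @return list with `X` (matrix, columns d1..dm), `y`, and `truth`
#' @export
gen_qsar <- function(n_compounds = 50, n_descriptors = 20,
                     planted = c(3, 7, 12),
                     coefficients = c(1, -0.8, 0.6),
                     intercept = 0, noise_sd = 0.45,
                     correlation = 0.2, seed = 1) {
  stopifnot(length(planted) == length(coefficients),
            all(planted >= 1), all(planted <= n_descriptors),
            noise_sd >= 0)
  if (correlation < 0 || correlation >= 1)
    stop("equicorrelation must lie in [0, 1) for a positive-definite matrix")
  withr_seed(seed, {
    # equicorrelated normals: sqrt(rho) * shared + sqrt(1-rho) * idiosyncratic
    shared <- stats::rnorm(n_compounds)
    X <- sqrt(correlation) * matrix(shared, n_compounds, n_descriptors) +
      sqrt(1 - correlation) * matrix(stats::rnorm(n_compounds * n_descriptors),
                                     n_compounds, n_descriptors)
    colnames(X) <- paste0("d", seq_len(n_descriptors))
    signal <- intercept + drop(X[, planted, drop = FALSE] %*% coefficients)
    y <- signal + stats::rnorm(n_compounds, 0, noise_sd)
    r2 <- if (stats::var(y) > 0) 1 - sum((y - signal)^2) / sum((y - mean(y))^2) else NA
    list(X = X, y = y,
         truth = list(planted = planted, coefficients = coefficients,
                      intercept = intercept, noise_sd = noise_sd,
                      realized_r2 = r2, seed = seed))
  })
}
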