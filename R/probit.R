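#' Dose-response dataset constructor
#'
#' Grouped binomial mortality counts at positive doses, with an optional
#' control group at dose 0 (used only by [abbott_correct()]).
#'
#' @param dose concentrations (µg/mL); a single 0 entry marks the control
#' @param n number of organisms exposed per group
#' @param dead number dead per group
#' @return data.frame of class `dose_response`
#' @export
dose_response <- function(dose, n, dead) {
  stopifnot(length(dose) == length(n), length(n) == length(dead))
  if (any(dead < 0 | dead > n)) stop("dead counts must lie in [0, n]")
  if (any(dose < 0)) stop("doses must be non-negative")
  if (sum(dose == 0) > 1) stop("at most one control (dose 0) group")
  if (length(unique(dose[dose > 0])) < 2)
    stop("need at least 2 distinct positive doses")
  structure(data.frame(dose = dose, n = n, dead = dead),
            class = c("dose_response", "data.frame"))
}

#' Abbott's correction for control mortality
#'
#' Rescales treated mortality by the control rate: `p' = (p - c)/(1 - c)`,
#' clipped to `[0, 1]`, then rounds `p' * n` back to counts. A no-op when
#' control mortality is zero (the reference bioassays reported fully active
#' negative controls, so this exists for generality).
#'
#' @param ds a [dose_response()] dataset containing a control group
#' @return corrected dataset without the control group
#' @export
abbott_correct <- function(ds) {
  ctrl <- ds$dose == 0
  if (!any(ctrl)) stop("no control (dose 0) group present")
  c0 <- ds$dead[ctrl] / ds$n[ctrl]
  if (c0 >= 1) stop("control mortality of 100% cannot be corrected")
  out <- ds[!ctrl, , drop = FALSE]
  if (c0 > 0) {
    p <- out$dead / out$n
    p2 <- pmin(1, pmax(0, (p - c0) / (1 - c0)))
    out$dead <- round(p2 * out$n)
  }
  rownames(out) <- NULL
  structure(out, class = c("dose_response", "data.frame"))
}

probit_loglik <- function(par, ld, n, dead) {
  p <- stats::pnorm(par[1] + par[2] * ld)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(dead * log(p) + (n - dead) * log(1 - p))
}

probit_score_hess <- function(par, ld, n, dead) {
  eta <- par[1] + par[2] * ld
  p <- stats::pnorm(eta); phi <- stats::dnorm(eta)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  w <- (dead - n * p) * phi / (p * (1 - p))
  grad <- c(sum(w), sum(w * ld))
  # expected information (Fisher scoring)
  wi <- n * phi^2 / (p * (1 - p))
  info <- matrix(c(sum(wi), sum(wi * ld), sum(wi * ld), sum(wi * ld^2)), 2, 2)
  list(grad = grad, info = info)
}

#' Maximum-likelihood probit fit of a dose-response dataset
#'
#' Fits `P(death) = Phi(alpha + beta * log10(dose))` to grouped binomial
#' mortality by Fisher scoring, started from the least-squares line through
#' the empirical probits of the non-extreme groups. The median lethal
#' concentration is `LC50 = 10^(-alpha/beta)` with a Fieller 95% interval
#' (delta-method fallback when Fieller's g >= 1, flagged). Overdispersion is
#' handled as in the classical bioassay packages: when Pearson X²/df exceeds
#' 1 the covariance is inflated by the heterogeneity factor and the critical
#' value switches to the t distribution.
#'
#' @param ds a [dose_response()] dataset (control group, if present, is
#'   removed via [abbott_correct()])
#' @param level confidence level (default 0.95)
#' @param max_iter Fisher-scoring iteration cap
#' @param tol convergence tolerance on the gradient norm
#' @return object of class `probit_fit`: alpha, beta, lc50 with CI, loglik,
#'   vcov, heterogeneity factor and flags
#' @export
fit_probit <- function(ds, level = 0.95, max_iter = 100, tol = 1e-8) {
  if (any(ds$dose == 0)) ds <- abbott_correct(ds)
  ld <- log10(ds$dose); n <- ds$n; dead <- ds$dead
  p_emp <- dead / n
  if (all(dead == 0) || all(dead == n))
    stop("non-convergence: all-extreme mortality carries no dose information")
  # start values: empirical probits of non-extreme groups
  mid <- p_emp > 0 & p_emp < 1
  if (sum(mid) >= 2) {
    sl <- stats::lm(stats::qnorm(p_emp[mid]) ~ ld[mid])
    par <- c(stats::coef(sl)[[1]], max(stats::coef(sl)[[2]], 1e-3))
  } else {
    par <- c(-mean(ld), 1)
  }
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    sh <- probit_score_hess(par, ld, n, dead)
    step <- tryCatch(solve(sh$info, sh$grad), error = function(e) NULL)
    if (is.null(step)) break
    # step halving to keep the likelihood moving uphill
    ll0 <- probit_loglik(par, ld, n, dead)
    lam <- 1
    repeat {
      cand <- par + lam * step
      if (probit_loglik(cand, ld, n, dead) >= ll0 - 1e-12 || lam < 1e-4) break
      lam <- lam / 2
    }
    par <- par + lam * step
    if (sqrt(sum(sh$grad^2)) < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    sh <- probit_score_hess(par, ld, n, dead)
    if (sqrt(sum(sh$grad^2)) < sqrt(tol)) converged <- TRUE
    else stop("non-convergence: probit likelihood did not stabilise ",
              "(possible complete separation; gradient norm ",
              format(sqrt(sum(sh$grad^2)), digits = 3), ")")
  }
  alpha <- par[1]; beta <- par[2]
  info <- probit_score_hess(par, ld, n, dead)$info
  vcov <- solve(info)
  # heterogeneity factor (Pearson X^2 / df), classical Proc-Probit style
  phat <- stats::pnorm(alpha + beta * ld)
  phat <- pmin(pmax(phat, 1e-12), 1 - 1e-12)
  X2 <- sum((dead - n * phat)^2 / (n * phat * (1 - phat)))
  df <- max(length(ld) - 2, 1)
  h <- max(1, X2 / df)
  crit <- if (X2 / df > 1) stats::qt(1 - (1 - level) / 2, df)
          else stats::qnorm(1 - (1 - level) / 2)
  vcov_adj <- vcov * h
  ci <- fieller_ci(alpha, beta, vcov_adj, crit)
  fit <- structure(list(
    alpha = alpha, beta = beta,
    lc50 = 10^(-alpha / beta),
    lc50_ci = 10^(ci$interval),
    ci_method = ci$method,
    loglik = probit_loglik(par, ld, n, dead),
    vcov = vcov_adj,
    heterogeneity = h,
    converged = converged,
    beta_nonpositive = beta <= 0,
    level = level,
    data = ds
  ), class = "probit_fit")
  if (beta <= 0) warning("fitted slope is non-positive; LC50 unreliable",
                         call. = FALSE)
  fit
}

# Fieller interval for the ratio -alpha/beta (log10 LC50); delta fallback.
fieller_ci <- function(alpha, beta, V, crit, p_shift = 0) {
  m <- (p_shift - alpha) / beta   # log10 LC_p with probit quantile shift
  v11 <- V[1, 1]; v12 <- V[1, 2]; v22 <- V[2, 2]
  g <- crit^2 * v22 / beta^2
  if (g < 1) {
    mstar <- (m + g * v12 / v22) / (1 - g)
    half <- crit / (abs(beta) * (1 - g)) *
      sqrt(v11 + 2 * m * v12 + m^2 * v22 - g * (v11 - v12^2 / v22))
    list(interval = c(mstar - half, mstar + half), method = "fieller")
  } else {
    se <- sqrt(v11 + 2 * m * v12 + m^2 * v22) / abs(beta)
    list(interval = c(m - crit * se, m + crit * se), method = "delta")
  }
}

#' Lethal-concentration quantile from a probit fit
#'
#' `LC_p = 10^((qnorm(p) - alpha)/beta)` with a Fieller (or flagged
#' delta-method) confidence interval; `p = 0.5` recovers the fit's LC50.
#'
#' @param fit a [fit_probit()] result
#' @param p mortality proportion in (0, 1)
#' @return list with `estimate`, `ci`, `ci_method`
#' @export
lc_quantile <- function(fit, p) {
  if (!is.numeric(p) || length(p) != 1 || p <= 0 || p >= 1)
    stop("p must be a single proportion strictly inside (0, 1)")
  if (!fit$converged) stop("cannot compute quantiles from a non-converged fit")
  z <- stats::qnorm(p)
  crit <- stats::qnorm(1 - (1 - fit$level) / 2)
  ci <- fieller_ci(fit$alpha, fit$beta, fit$vcov, crit, p_shift = z)
  list(estimate = 10^((z - fit$alpha) / fit$beta),
       ci = 10^(ci$interval), ci_method = ci$method)
}

#' @export
print.probit_fit <- function(x, ...) {
  cat(sprintf("Probit fit: alpha = %.4f, beta = %.4f (on log10 dose)\n",
              x$alpha, x$beta))
  cat(sprintf("LC50 = %.4g  [%.4g, %.4g]  (%s, %g%%)\n",
              x$lc50, x$lc50_ci[1], x$lc50_ci[2], x$ci_method, 100 * x$level))
  cat(sprintf("logLik = %.3f, heterogeneity = %.2f%s\n", x$loglik,
              x$heterogeneity,
              if (x$beta_nonpositive) "  [WARNING: non-positive slope]" else ""))
  invisible(x)
}
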