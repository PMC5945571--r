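test_that("build_activity transforms and subsets correctly", {
  lib <- compound_library(validate = FALSE)
  act <- build_activity(lib, "iv", "all")
  expect_equal(nrow(act), 50)
  expect_equal(act$y[act$id == 4], log10(1 / 7.7), tolerance = 1e-12)
  act47 <- build_activity(lib, "iv", "no-sesquiterpenes")
  expect_equal(nrow(act47), 47)
  expect_false(any(c(9, 21, 22) %in% act47$id))
  act39 <- build_activity(lib, "iv", "cyclic")
  expect_equal(nrow(act39), 39)
  # censored pupae values drop with a warning
  expect_warning(actp <- build_activity(lib, "pupae", "all"), "censored")
  expect_equal(nrow(actp), 48)
  expect_error(build_activity(lib, "iv", subset = c(1, 999)), "unknown compound")
})

test_that("fit_ols statistics against trivial cases", {
  set.seed(1)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  beta <- c(2, -1, 0.5)
  y <- drop(X %*% beta) + 3
  m <- fit_ols(X, y)
  expect_equal(m$r2, 1, tolerance = 1e-12)
  expect_equal(m$s, 0, tolerance = 1e-8)
  expect_equal(unname(m$coefficients), beta, tolerance = 1e-10)
  expect_equal(m$intercept, 3, tolerance = 1e-10)
  # intercept-only model
  m0 <- fit_ols(NULL, y)
  expect_equal(m0$r2, 0)
  # rank deficiency errors with the offending columns named
  Xbad <- cbind(X, d = X[, "a"] * 2)
  expect_error(fit_ols(Xbad, y), "collinear")
})

test_that("hat-matrix Q2 equals the explicit refit oracle to 1e-10", {
  for (seed in c(2, 5, 9)) {
    set.seed(seed)
    n <- 18 + seed
    X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("d", 1:4)))
    y <- X[, 1] - 0.5 * X[, 3] + rnorm(n, 0, 0.6)
    expect_equal(loo_q2(X, y), loo_press_oracle(X, y), tolerance = 1e-10)
  }
})

test_that("Q2 < R2 and random-response Q2 collapses", {
  set.seed(42)
  X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("d", 1:4)))
  y_noise <- rnorm(50)
  m <- fit_ols(X, y_noise)
  expect_lt(m$q2, m$r2)
  expect_lt(m$q2, 0.2)
  y_sig <- X[, 2] + rnorm(50, 0, 0.3)
  ms <- fit_ols(X, y_sig)
  expect_lt(ms$q2, ms$r2)
})

test_that("R2 and Q2 are invariant under affine transforms of y", {
  set.seed(7)
  X <- matrix(rnorm(120), 30, 4, dimnames = list(NULL, paste0("d", 1:4)))
  y <- X[, 1] - X[, 2] + rnorm(30, 0, 0.5)
  m <- fit_ols(X, y)
  for (tr in list(c(2.5, 1), c(-1, 0.3), c(0.01, -4))) {
    mt <- fit_ols(X, tr[1] * y + tr[2])
    expect_equal(mt$r2, m$r2, tolerance = 1e-12)
    expect_equal(mt$q2, m$q2, tolerance = 1e-12)
  }
})

test_that("GA equals exhaustive search on a small pool", {
  sim <- gen_qsar(n_compounds = 40, n_descriptors = 5, planted = c(1, 4),
                  coefficients = c(1, -1), noise_sd = 0.5, seed = 3)
  oracle <- exhaustive_best_subset(sim$X, sim$y, cap = 5)
  ga <- ga_search(sim$X, sim$y, max_size = 5, pop_size = 30, generations = 30,
                  seed = 3, n_best = 1)
  got <- sort(match(ga[[1]]$descriptors, colnames(sim$X)))
  expect_equal(as.integer(got), as.integer(oracle$subset))
  expect_equal(attr(ga, "fitness")[1], oracle$q2, tolerance = 1e-12)
})

test_that("GA contract: determinism, zero generations, elitism monotonicity", {
  sim <- gen_qsar(seed = 13)
  a <- ga_search(sim$X, sim$y, max_size = 3, pop_size = 25, generations = 12,
                 seed = 8, n_best = 3)
  b <- ga_search(sim$X, sim$y, max_size = 3, pop_size = 25, generations = 12,
                 seed = 8, n_best = 3)
  expect_identical(lapply(a, `[[`, "descriptors"),
                   lapply(b, `[[`, "descriptors"))
  expect_identical(attr(a, "fitness"), attr(b, "fitness"))
  # zero generations: evaluated random initial population only
  z <- ga_search(sim$X, sim$y, max_size = 3, pop_size = 25, generations = 0,
                 seed = 8, n_best = 3)
  expect_true(all(is.finite(attr(z, "fitness"))))
  # more generations never hurt the best fitness (elitism + archive)
  long <- ga_search(sim$X, sim$y, max_size = 3, pop_size = 25, generations = 24,
                    seed = 8, n_best = 1)
  expect_gte(attr(long, "fitness")[1], attr(a, "fitness")[1])
  expect_error(ga_search(sim$X[1:5, ], sim$y[1:5], max_size = 5),
               "infeasible")
})

test_that("published-model refits report printed and recomputed side by side", {
  ev <- evaluate_published_model("QSAR", 1)
  expect_equal(ev$n, 50)
  expect_equal(ev$refit$descriptors, c("nCt", "nCconj", "nRCO", "nROR"))
  expect_equal(ev$printed$r2, 0.828)
  expect_true(is.finite(ev$refit$r2) && ev$refit$r2 > 0 && ev$refit$r2 < 1)
  expect_lte(ev$refit$q2, ev$refit$r2)
  ev3 <- evaluate_published_model("QSAR", 3)
  expect_equal(ev3$n, 47)
  evq <- evaluate_published_model("QPAR", 1)
  expect_equal(evq$refit$descriptors, c("J", "MlogP", "TIE", "AMR"))
  # garbled printed cells carry the suspect flag
  ev2 <- evaluate_published_model("QSAR", 2)
  expect_true(ev2$printed$r2_suspect && ev2$printed$q2_suspect)
  # underdetermined n=39 subset is flagged
  ev5 <- evaluate_published_model("QSAR", 5)
  expect_true(ev5$flagged_subset)
  expect_equal(ev5$n, 39)
  expect_error(evaluate_published_model("QSAR", 9), "unknown model")
})

test_that("descriptor fixture matrix has full provenance and no gaps", {
  X <- descriptor_fixture_matrix()
  expect_equal(nrow(X), 50)
  expect_false(anyNA(X))
  prov <- attr(X, "provenance")
  expect_setequal(names(prov), colnames(X))
  expect_equal(unname(prov["nROR"]), "computed")
  expect_equal(unname(prov["J"]), "printed-table-7")
  # the ether count that the printed tables omit
  expect_equal(sum(X$nROR), 3)  # anisole, eucalyptol, epoxide
})
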