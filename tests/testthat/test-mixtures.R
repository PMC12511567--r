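test_that("single-component EM reduces to the sample mean", {
  x <- contact_series(c(0, 1, 2, 3, 4, 5, 10, 2, 1, 0, 3, 4))
  fit <- fit_poisson_mixture_em(x, K = 1, restarts = 1, seed = 1)
  expect_equal(fit$means, mean(x))
  expect_equal(fit$weights, 1)
  expect_true(fit$converged)
  # BIC for K = 1 has a single free parameter
  expect_equal(fit$bic,
               -2 * sum(dpois(unclass(x), mean(x), log = TRUE)) +
                 log(length(x)))
})

test_that("EM log-likelihood is monotone and responsibilities normalize", {
  x <- simulate_contact_counts(5000, seed = 17)
  fit <- fit_poisson_mixture_em(x, K = 4, restarts = 5, seed = 2)
  expect_true(all(diff(fit$loglik_path) >= -1e-8))
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  expect_equal(fit$means, sort(fit$means))
  gamma <- posterior_responsibilities(fit, unclass(x)[1:100])
  expect_equal(rowSums(gamma), rep(1, 100), tolerance = 1e-12)
})

test_that("EM recovers two well-separated components", {
  x <- simulate_contact_counts(10000, means = c(2, 40),
                               weights = c(0.5, 0.5), seed = 5)
  fit <- fit_poisson_mixture_em(x, K = 2, restarts = 10, seed = 1)
  expect_equal(fit$means[1], 2, tolerance = 0.05)
  expect_equal(fit$means[2], 40, tolerance = 0.05)
  expect_equal(fit$weights, c(0.5, 0.5), tolerance = 0.05)
})

test_that("EM recovers the four-component contact mixture", {
  means <- c(0.2, 8, 30, 50)
  weights <- c(0.40, 0.10, 0.35, 0.15)
  x <- simulate_contact_counts(50000, means = means, weights = weights,
                               seed = 9)
  fit <- fit_poisson_mixture_em(x, K = 4, restarts = 20, seed = 1)
  # the three bound components are recovered within 5%
  for (k in 2:4)
    expect_equal(fit$means[k], means[k], tolerance = 0.05)
  expect_equal(fit$weights, weights, tolerance = 0.1)
  # replicated recovery: median absolute error below 5% of truth
  errs <- sapply(1:20, function(s) {
    xi <- simulate_contact_counts(50000, means = means, weights = weights,
                                  seed = 1000 + s)
    fi <- fit_poisson_mixture_em(xi, K = 4, restarts = 8, seed = s)
    abs(fi$means - means) / pmax(means, 1e-6)
  })
  expect_true(all(apply(errs[2:4, ], 1, stats::median) < 0.05))
})

test_that("fit is invariant to initial component order after sorting", {
  x <- simulate_contact_counts(20000, seed = 21)
  f1 <- fit_poisson_mixture_em(x, K = 4, restarts = 10, seed = 1)
  f2 <- fit_poisson_mixture_em(x, K = 4, restarts = 10, seed = 77)
  expect_equal(f1$means, f2$means, tolerance = 1e-3)
  expect_equal(f1$weights, f2$weights, tolerance = 1e-3)
})

test_that("BIC selects the generating component count", {
  single <- withr::with_seed(4, contact_series(rpois(2000, 7)))
  sel1 <- select_component_count(single, K_max = 3, restarts = 5, seed = 1)
  expect_equal(sel1$K_star, 1L)

  x <- simulate_contact_counts(50000, seed = 13)
  sel4 <- select_component_count(x, K_max = 6, restarts = 5, seed = 1)
  expect_equal(sel4$K_star, 4L)
  expect_equal(nrow(sel4$table), 6L)

  # replicated: the four-component truth wins in >= 18 of 20 seeded runs
  wins <- sum(sapply(1:20, function(s) {
    xi <- simulate_contact_counts(50000, seed = 2000 + s)
    select_component_count(xi, K_max = 6, restarts = 4,
                           seed = s)$K_star == 4L
  }))
  expect_gte(wins, 18)

  tiny <- contact_series(rep(c(0, 5), 15))
  expect_warning(sel <- select_component_count(tiny, K_max = 5,
                                               restarts = 2, seed = 1),
                 "reduced")
  expect_lte(max(sel$table$K), 3)
})

test_that("bound fraction follows the stated classification policies", {
  x <- simulate_contact_counts(50000, seed = 9)
  fit <- fit_poisson_mixture_em(x, K = 4, restarts = 10, seed = 1)
  # generating weights 0.40/0.10/0.35/0.15: threshold policy counts the
  # two tight components (0.50), the other policy adds the loose one (0.60)
  expect_equal(as.numeric(bound_fraction(fit)), 0.50, tolerance = 0.02)
  expect_equal(as.numeric(bound_fraction(fit, "all_but_unbound")), 0.60,
               tolerance = 0.02)
  all_bound <- fit_poisson_mixture_em(
    simulate_contact_counts(2000, means = c(30, 50), weights = c(.6, .4),
                            seed = 2),
    K = 2, restarts = 5, seed = 1)
  expect_equal(as.numeric(bound_fraction(all_bound)), 1)
})

test_that("per-residue contact frequency averages the indicator over frames", {
  all_on <- matrix(TRUE, nrow = 10, ncol = 5)
  expect_equal(unname(residue_contact_frequency(all_on)), rep(1, 5))
  # alternating contact / no-contact frames give frequency 1/2
  alt <- matrix(rep(c(TRUE, FALSE), 10), ncol = 2)
  expect_equal(unname(residue_contact_frequency(alt)), c(0.5, 0.5))
  # Bernoulli recovery within binomial error
  rates <- c(0.1, 0.5, 0.9)
  m <- withr::with_seed(8, {
    vapply(rates, function(p) runif(4000) < p, logical(4000))
  })
  freq <- residue_contact_frequency(m)
  se <- sqrt(rates * (1 - rates) / 4000)
  expect_true(all(abs(freq - rates) < 4 * se))
  # count matrices are thresholded at > 0
  cm <- matrix(c(0L, 2L, 1L, 0L), nrow = 2)
  expect_equal(unname(residue_contact_frequency(cm)), c(0.5, 0.5))
  expect_error(residue_contact_frequency(matrix(numeric(0), 0, 0)),
               "non-empty")
})
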