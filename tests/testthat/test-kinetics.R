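test_that("equilibrium initial state follows B0/A0 = k1/k2", {
  eq <- equilibrium_initial_state(kinetic_params(1, 1, 5))
  expect_equal(unname(eq), c(0.375, 0.375))
  eq2 <- equilibrium_initial_state(kinetic_params(3, 1, 5))
  expect_equal(unname(eq2), c(0.1875, 0.5625))
  eq3 <- equilibrium_initial_state(kinetic_params(0, 1, 5))
  expect_equal(unname(eq3), c(0.75, 0))
  expect_error(equilibrium_initial_state(kinetic_params(0, 0, 5)),
               "degenerate")
})

test_that("relaxation eigenvalues satisfy the characteristic quadratic", {
  ev <- rate_eigenvalues(kinetic_params(0, 2, 5))
  expect_equal(unname(ev), c(-2, -5), ignore_attr = TRUE)
  # k1 = k2 = k3 = 1: roots of r^2 + 3r + 1
  ev2 <- rate_eigenvalues(kinetic_params(1, 1, 1))
  expect_equal(unname(ev2), c((-3 + sqrt(5)) / 2, (-3 - sqrt(5)) / 2),
               ignore_attr = TRUE)
  ev3 <- rate_eigenvalues(kinetic_params(2, 3, 0))
  expect_equal(unname(ev3)[1], 0)
  # Vieta: r1*r2 = k2*k3, r1 + r2 = -(k1+k2+k3), both roots <= 0
  set.seed(101)
  for (i in 1:50) {
    p <- random_kinetic_params()
    ev <- rate_eigenvalues(p)
    expect_equal(unname(prod(ev)), p$k2 * p$k3, tolerance = 1e-9)
    expect_equal(unname(sum(ev)), -(p$k1 + p$k2 + p$k3), tolerance = 1e-9)
    expect_true(all(ev <= 1e-12))
  }
})

test_that("closed-form loaded fraction obeys its analytic limits", {
  p <- kinetic_params(1, 0.5, 10)
  expect_equal(loaded_fraction(p, 0)$C, 0)
  # k1 = 0 reduces to single-exponential loading
  p0 <- kinetic_params(0, 1, 5)
  expect_equal(loaded_fraction(p0, 0.2)$C, 0.75 * (1 - exp(-1)),
               tolerance = 1e-12)
  tt <- c(0.01, 0.1, 1, 10)
  expect_equal(loaded_fraction(p0, tt)$C, 0.75 * (1 - exp(-5 * tt)),
               tolerance = 1e-12)
  # long-time limit is the loadable fraction
  ev <- rate_eigenvalues(p)
  t_inf <- 100 / min(abs(ev[abs(ev) > 0]))
  expect_equal(loaded_fraction(p, t_inf)$C, 0.75, tolerance = 1e-6)
  expect_error(loaded_fraction(p, -1), "non-negative")
})

test_that("closed form agrees with the ODE oracle across random parameters", {
  set.seed(202)
  tt <- c(0.001, 0.01, 0.1, 1, 10, 100, 600)
  for (i in 1:100) {
    p <- random_kinetic_params()
    cf <- loaded_fraction(p, tt)
    od <- integrate_two_state_ode(p, tt)
    expect_lt(max(abs(cf$C - od$C)), 1e-8)
    # conservation and monotonicity
    expect_equal(od$A + od$B + od$C, rep(p$total, length(tt)),
                 tolerance = 1e-8)
    expect_true(all(diff(cf$C) >= -1e-12))
    expect_true(all(cf$C <= p$total + 1e-12))
  }
})

test_that("degenerate repeated eigenvalues use the confluent branch smoothly", {
  # k1 = 0, k2 = k3 makes the two relaxation rates coincide
  p_eq <- kinetic_params(0, 2, 2)
  p_near <- kinetic_params(0, 2, 2 * (1 + 1e-12))
  tt <- c(0.01, 0.1, 1, 5)
  expect_true(attr(rate_eigenvalues(p_eq), "degenerate"))
  expect_equal(loaded_fraction(p_eq, tt)$C, loaded_fraction(p_near, tt)$C,
               tolerance = 1e-8)
  expect_equal(loaded_fraction(p_eq, tt)$C,
               integrate_two_state_ode(p_eq, tt)$C, tolerance = 1e-8)
})

test_that("dataset assembly windows manual records inclusively", {
  manual <- data.frame(condition = "a", time_s = c(10, 30, 120, 600, 1200),
                       fraction_loaded = seq(0.1, 0.5, by = 0.1))
  qf <- data.frame(condition = "a", time_s = c(0.01, 0.1),
                   fraction_loaded = c(0.2, 0.4))
  merged <- assemble_loading_dataset(qf, manual)
  expect_equal(merged$time_s[merged$source == "manual"], c(30, 120, 600))
  expect_equal(nrow(merged), 5L)
  only_manual <- assemble_loading_dataset(NULL, manual)
  expect_true(all(only_manual$source == "manual"))
  all_in <- assemble_loading_dataset(qf, manual, manual_window = c(0, Inf))
  expect_equal(nrow(all_in), 7L)
  expect_error(
    assemble_loading_dataset(NULL, manual, manual_window = c(2000, 3000)),
    "empty")
})

test_that("global fit recovers rates exactly from noise-free data", {
  truth <- list(lo = kinetic_params(5, 0.02, 30),
                hi = kinetic_params(0.5, 2, 30))
  sim <- simulate_loading_timecourse(conditions = truth, noise_sd = 0,
                                     replicates = 1, seed = 1)
  fit <- fit_global_two_state(sim, n_starts = 4, seed = 1)
  expect_true(fit$converged)
  expect_equal(fit$k3, 30, tolerance = 1e-4)
  got <- fit$conditions
  expect_equal(got$k1[got$condition == "lo"], 5, tolerance = 1e-4)
  expect_equal(got$k2[got$condition == "lo"], 0.02, tolerance = 1e-4)
  expect_equal(got$k1[got$condition == "hi"], 0.5, tolerance = 1e-4)
  expect_equal(got$k2[got$condition == "hi"], 2, tolerance = 1e-4)
  expect_lt(fit$rss, 1e-10)
  expect_equal(nrow(fit$fitted), 40L)
})

test_that("global fit enforces its preconditions", {
  one_cond <- data.frame(condition = "a", time_s = c(1, 10),
                         fraction_loaded = c(0.1, 0.2))
  expect_error(fit_global_two_state(one_cond), ">= 2 conditions")
  narrow <- data.frame(
    condition = rep(c("a", "b"), each = 4),
    time_s = rep(c(1, 2, 3, 4), 2),
    fraction_loaded = rep(0.2, 8))
  expect_error(fit_global_two_state(narrow), "decade")
})

test_that("noisy global fits recover the shared loading rate", {
  # seeded parameter-recovery sweep at the study noise level
  rel_err <- function(est, truth) abs(est - truth) / truth
  errs_k3 <- numeric(0)
  errs_rates <- numeric(0)
  truth <- list("10% SFA" = kinetic_params(5, 0.02, 30),
                "60% SFA" = kinetic_params(0.5, 2, 30))
  for (s in 1:10) {
    sim <- simulate_loading_timecourse(conditions = truth, noise_sd = 0.02,
                                       replicates = 10, seed = 100 + s)
    fit <- fit_global_two_state(sim, n_starts = 4, seed = s)
    errs_k3 <- c(errs_k3, rel_err(fit$k3, 30))
    tab <- fit$conditions
    errs_rates <- c(
      errs_rates,
      rel_err(tab$k1[tab$condition == "10% SFA"], 5),
      rel_err(tab$k2[tab$condition == "10% SFA"], 0.02),
      rel_err(tab$k1[tab$condition == "60% SFA"], 0.5),
      rel_err(tab$k2[tab$condition == "60% SFA"], 2),
      rel_err(fit$k3, 30))
  }
  expect_lt(stats::median(errs_k3), 0.10)
  expect_lt(stats::median(errs_rates), 0.15)
})

test_that("exponential discharge fit recovers the decay rate", {
  t <- seq(0, 600, by = 30)
  exact <- data.frame(time_s = t, fraction_loaded = 0.6 * exp(-0.01 * t))
  fit <- fit_exponential_discharge(exact)
  expect_equal(fit$kd, 0.01, tolerance = 1e-6)
  expect_equal(fit$C0, 0.6, tolerance = 1e-6)
  expect_false(fit$increasing_warning)

  flat <- data.frame(time_s = t, fraction_loaded = rep(0.5, length(t)))
  expect_equal(fit_exponential_discharge(flat)$kd, 0)

  noisy <- withr::with_seed(33, {
    data.frame(time_s = t,
               fraction_loaded = pmax(0.6 * exp(-0.01 * t) +
                                        rnorm(length(t), sd = 0.02), 0))
  })
  expect_equal(fit_exponential_discharge(noisy)$kd, 0.01, tolerance = 0.15)

  rising <- data.frame(time_s = t, fraction_loaded = seq(0, 1, length.out = length(t)))
  expect_true(fit_exponential_discharge(rising)$increasing_warning)
})

test_that("steady-state cycling fraction matches its closed form and oracle", {
  expect_equal(steady_state_loaded_fraction(cycling_params(1, 2, 5, 0)), 1)
  expect_equal(steady_state_loaded_fraction(cycling_params(0, 1, 0.2, 0.2)),
               0.5)
  expect_error(steady_state_loaded_fraction(cycling_params(1, 0, 1, 1)),
               "k2")
  expect_error(steady_state_loaded_fraction(cycling_params(1, 1, 0, 0)),
               "undefined")
  set.seed(303)
  for (i in 1:10) {
    p <- cycling_params(k1 = 10^runif(1, -2, 1), k2 = 10^runif(1, -2, 1),
                        k3 = 10^runif(1, -2, 1), kd = 10^runif(1, -2, 1))
    expect_equal(steady_state_loaded_fraction(p), cycle_steady_state_ode(p),
                 tolerance = 1e-6)
  }
})

test_that("conformational equilibrium matters only under frequent cycling", {
  # loaded fraction decreases in k1/k2 and in kd
  ss <- function(k1, kd) steady_state_loaded_fraction(
    cycling_params(k1, 1, 0.5, kd))
  kds <- 10^seq(-4, 2, length.out = 13)
  ratios <- vapply(kds, function(kd) ss(0.2, kd) / ss(5, kd), numeric(1))
  # sensitivity to the equilibrium grows monotonically with cycling rate
  expect_true(all(diff(ratios) > 0))
  expect_equal(ratios[1], 1, tolerance = 0.01)
  expect_equal(ratios[length(ratios)], (1 + 5) / (1 + 0.2),
               tolerance = 0.02)
  k1s <- c(0.1, 0.5, 1, 5, 10)
  for (kd in c(0.01, 1)) {
    vals <- vapply(k1s, function(k1) ss(k1, kd), numeric(1))
    expect_true(all(diff(vals) < 0))
  }
})
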