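#' Two-state loading model parameters
#'
#' The model: a membrane-anchored E2 interconverts between an active
#' conformation A and an inactive conformation B with rates `k1` (A -> B)
#' and `k2` (B -> A); only A is loaded with ubiquitin by the E1, at rate
#' `k3`, giving the loaded species C:
#' \deqn{dA/dt = -k_3 A - k_1 A + k_2 B,\quad dB/dt = k_1 A - k_2 B,\quad
#'       dC/dt = k_3 A.}
#' The system starts from the conformational equilibrium `B0/A0 = k1/k2`
#' with `A0 + B0 = total`, the loadable fraction of the enzyme (the
#' remainder never loads and is outside the model). Discharge of C is
#' neglected here; it enters only the cycling model
#' ([steady_state_loaded_fraction()]).
#'
#' @param k1 Inactivation rate A -> B, per second (>= 0).
#' @param k2 Activation rate B -> A, per second (>= 0).
#' @param k3 Loading rate of the active state, per second (>= 0).
#' @param total Total loadable fraction `T` in (0, 1]; 0.75 by default, the
#'   value fixed in the global fit.
#' @return An object of class `kinetic_params`.
#' @examples
#' kinetic_params(k1 = 1, k2 = 0.5, k3 = 10)
#' @export
kinetic_params <- function(k1, k2, k3, total = 0.75) {
  stopifnot(is.numeric(k1), is.numeric(k2), is.numeric(k3),
            is.numeric(total), length(total) == 1L)
  if (k1 < 0 || k2 < 0 || k3 < 0)
    stop("rates must be non-negative", call. = FALSE)
  if (total <= 0 || total > 1)
    stop("total loadable fraction must lie in (0, 1]", call. = FALSE)
  structure(list(k1 = k1, k2 = k2, k3 = k3, total = total),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf(
    "<kinetic_params> k1 = %g /s, k2 = %g /s, k3 = %g /s, total = %g\n",
    x$k1, x$k2, x$k3, x$total))
  invisible(x)
}

#' Equilibrium initial state of the two-state model
#'
#' Before E1 addition the enzyme equilibrates between conformations, so
#' `B0/A0 = k1/k2`: `A0 = total * k2/(k1+k2)`, `B0 = total * k1/(k1+k2)`.
#'
#' @param p A [kinetic_params].
#' @return Named numeric `c(A0, B0)` with `A0 + B0 = total`.
#' @export
equilibrium_initial_state <- function(p) {
  stopifnot(inherits(p, "kinetic_params"))
  if (p$k1 + p$k2 <= 0)
    stop("degenerate equilibrium: k1 = k2 = 0", call. = FALSE)
  c(A0 = p$total * p$k2 / (p$k1 + p$k2),
    B0 = p$total * p$k1 / (p$k1 + p$k2))
}

#' Relaxation eigenvalues of the two-state loading model
#'
#' The (A, B) subsystem relaxes with rates given by the roots of
#' \deqn{r^2 + (k_1+k_2+k_3) r + k_2 k_3 = 0,}
#' i.e. `r = (-(k1+k2+k3) +/- sqrt((k1+k2+k3)^2 - 4 k2 k3)) / 2`. The
#' discriminant is always >= (k2-k3)^2 >= 0, so both roots are real and
#' non-positive. The slow root is computed from the Vieta product
#' `r1*r2 = k2*k3` to avoid cancellation when the roots are far apart.
#'
#' @param p A [kinetic_params].
#' @return Named numeric `c(r1, r2)` with `0 >= r1 >= r2`, plus attribute
#'   `degenerate` flagging a (near-)repeated root.
#' @examples
#' rate_eigenvalues(kinetic_params(0, 2, 5))  # -2, -5
#' @export
rate_eigenvalues <- function(p) {
  stopifnot(inherits(p, "kinetic_params"))
  s <- p$k1 + p$k2 + p$k3
  disc <- s^2 - 4 * p$k2 * p$k3
  sq <- sqrt(max(disc, 0))
  r2 <- (-s - sq) / 2
  r1 <- if (r2 < 0) (p$k2 * p$k3) / r2 else (-s + sq) / 2
  degen <- abs(r1 - r2) < 1e-10 * max(1, abs(r1 + r2))
  structure(c(r1 = r1, r2 = r2), degenerate = degen)
}

# exp(r*t) integrals with safe r -> 0 limits:
#   int_0^t e^{r s} ds      = (e^{rt} - 1)/r          -> t
#   int_0^t s e^{r s} ds    = (e^{rt}(rt - 1) + 1)/r^2 -> t^2/2
exp_int1 <- function(r, t) {
  if (abs(r) < 1e-14) return(t)
  expm1(r * t) / r
}
exp_int2 <- function(r, t) {
  if (abs(r) < 1e-14) return(t^2 / 2)
  (exp(r * t) * (r * t - 1) + 1) / r^2
}

#' Closed-form solution of the two-state loading model
#'
#' Solves the linear system from the equilibrium initial condition
#' (`A(0) = A0`, `B(0) = B0`, `C(0) = 0`) by eigen-decomposition of the
#' (A, B) subsystem: `A(t) = a1 e^{r1 t} + a2 e^{r2 t}` with coefficients
#' fixed by `A(0)` and `A'(0)`, and `C(t) = k3 * \int_0^t A(s) ds`. A
#' (near-)repeated eigenvalue is handled by the confluent `t e^{rt}` branch.
#' The solution satisfies `C(0) = 0`, `C` non-decreasing, `C(t) -> total` as
#' `t -> Inf` (when all rates are positive), and reduces to
#' `total * (1 - exp(-k3 t))` when `k1 = 0`.
#'
#' Note: some published closed forms of this model contain typographical
#' errors (failing the `k1 = 0` reduction and the mass-conservation limit
#' `C(Inf) = total`); this implementation is derived directly from the
#' eigen-decomposition and is validated against numerical integration
#' ([integrate_two_state_ode()]).
#'
#' @param p A [kinetic_params].
#' @param times Non-negative times in seconds.
#' @return A `two_state_solution`: data frame with columns `time_s`, `A`,
#'   `B`, `C` and attributes `r1`, `r2`, `params`.
#' @examples
#' sol <- loaded_fraction(kinetic_params(1, 0.5, 10), c(0, 0.1, 1, 10))
#' sol$C
#' @export
loaded_fraction <- function(p, times) {
  stopifnot(inherits(p, "kinetic_params"), is.numeric(times))
  if (any(times < 0)) stop("times must be non-negative", call. = FALSE)
  init <- equilibrium_initial_state(p)
  A0 <- init[["A0"]]; B0 <- init[["B0"]]
  ev <- rate_eigenvalues(p)
  r1 <- ev[["r1"]]; r2 <- ev[["r2"]]
  dA0 <- -(p$k1 + p$k3) * A0 + p$k2 * B0

  if (attr(ev, "degenerate")) {
    # A(t) = (A0 + c2 t) e^{rt}; C = k3 [A0 I1(r,t) + c2 I2(r,t)]
    r <- (r1 + r2) / 2
    c2 <- dA0 - r * A0
    A <- vapply(times, function(t) (A0 + c2 * t) * exp(r * t), numeric(1))
    C <- vapply(times, function(t)
      p$k3 * (A0 * exp_int1(r, t) + c2 * exp_int2(r, t)), numeric(1))
  } else {
    a1 <- (dA0 - r2 * A0) / (r1 - r2)
    a2 <- A0 - a1
    A <- vapply(times, function(t)
      a1 * exp(r1 * t) + a2 * exp(r2 * t), numeric(1))
    C <- vapply(times, function(t)
      p$k3 * (a1 * exp_int1(r1, t) + a2 * exp_int1(r2, t)), numeric(1))
  }
  C <- pmin(pmax(C, 0), p$total)
  A <- pmax(A, 0)
  B <- pmax(p$total - C - A, 0)
  structure(
    data.frame(time_s = times, A = A, B = B, C = C),
    r1 = r1, r2 = r2, params = p,
    class = c("two_state_solution", "data.frame"))
}

#' Numerical integration of the two-state loading model
#'
#' Integrates the loading ODE system with a stiff-safe solver (lsoda) from
#' the same equilibrium initial conditions as [loaded_fraction()]. Serves as
#' the independent numerical cross-check of the closed-form solution.
#'
#' @param p A [kinetic_params].
#' @param times Non-negative, increasing times in seconds.
#' @param rtol,atol Solver tolerances.
#' @return A `two_state_solution` (same shape as [loaded_fraction()]).
#' @export
integrate_two_state_ode <- function(p, times, rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(p, "kinetic_params"), is.numeric(times))
  if (any(times < 0)) stop("times must be non-negative", call. = FALSE)
  init <- equilibrium_initial_state(p)
  t_out <- sort(unique(c(0, times)))
  rhs <- function(t, y, parms) {
    A <- y[1]; B <- y[2]
    list(c(-parms$k3 * A - parms$k1 * A + parms$k2 * B,
           parms$k1 * A - parms$k2 * B,
           parms$k3 * A))
  }
  out <- deSolve::ode(y = c(A = init[["A0"]], B = init[["B0"]], C = 0),
                      times = t_out, func = rhs, parms = p,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (!is.null(attr(out, "istate")) && attr(out, "istate")[1] < 0)
    stop("ODE solver failed: istate = ", attr(out, "istate")[1],
         call. = FALSE)
  out <- as.data.frame(out)
  idx <- match(times, out$time)
  ev <- rate_eigenvalues(p)
  structure(
    data.frame(time_s = times, A = out$A[idx], B = out$B[idx],
               C = out$C[idx]),
    r1 = ev[["r1"]], r2 = ev[["r2"]], params = p,
    class = c("two_state_solution", "data.frame"))
}

#' Assemble a loading dataset from quenched-flow and manual time courses
#'
#' Quenched-flow data resolve the millisecond regime; manual sampling covers
#' later times. The merged fit target keeps all quenched-flow records and
#' the manual records inside a closed time window, by default 30 s to
#' 600 s (10 min). Provenance is preserved in the `source` column.
#'
#' @param quenched_flow,manual Data frames with columns `condition`,
#'   `time_s`, `fraction_loaded` and optionally `replicate`; either may be
#'   empty (zero rows) or `NULL`.
#' @param manual_window Closed window `c(t_min, t_max)` in seconds applied
#'   to the manual records.
#' @return A loading dataset: data frame with columns `condition`, `time_s`,
#'   `fraction_loaded`, `replicate`, `source`.
#' @export
assemble_loading_dataset <- function(quenched_flow, manual,
                                     manual_window = c(30, 600)) {
  stopifnot(length(manual_window) == 2L, manual_window[1] <= manual_window[2])
  norm <- function(d, src) {
    if (is.null(d) || nrow(d) == 0L)
      return(data.frame(condition = character(), time_s = numeric(),
                        fraction_loaded = numeric(), replicate = integer(),
                        source = character()))
    need <- c("condition", "time_s", "fraction_loaded")
    if (!all(need %in% names(d)))
      stop("dataset must have columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    if (any(d$time_s < 0) || any(d$fraction_loaded < 0) ||
        any(d$fraction_loaded > 1))
      stop("times must be >= 0 and fractions in [0, 1]", call. = FALSE)
    data.frame(condition = as.character(d$condition), time_s = d$time_s,
               fraction_loaded = d$fraction_loaded,
               replicate = if ("replicate" %in% names(d)) d$replicate else 1L,
               source = src)
  }
  qf <- norm(quenched_flow, "quenched_flow")
  mn <- norm(manual, "manual")
  mn <- mn[mn$time_s >= manual_window[1] & mn$time_s <= manual_window[2], ,
           drop = FALSE]
  out <- rbind(qf, mn)
  if (nrow(out) == 0L)
    stop("assembled dataset is empty", call. = FALSE)
  rownames(out) <- NULL
  out
}

# parameter packing for the global fit: per-condition (log k1, log k2),
# then shared log k3
unpack_theta <- function(theta, conditions, total) {
  nc <- length(conditions)
  k3 <- exp(theta[2 * nc + 1])
  lapply(seq_len(nc), function(i)
    kinetic_params(exp(theta[2 * i - 1]), exp(theta[2 * i]), k3,
                   total = total))
}

#' Global fit of the two-state model across conditions
#'
#' Fits the loading time courses of all conditions jointly by nonlinear
#' least squares (Levenberg-Marquardt, \code{minpack.lm::nls.lm}): each
#' condition gets its own conformational rates (k1, k2), the loading rate
#' k3 is shared across conditions (the reactivity of the active state does
#' not depend on the membrane), and the loadable fraction is fixed at
#' `total`. Replicates enter as individual unweighted residuals. Rates are
#' fitted on the log scale inside `bounds`; the optimizer is restarted from
#' `n_starts` seeded log-uniform starting points and the best solution by
#' residual sum of squares is kept.
#'
#' @param data Loading dataset (see [assemble_loading_dataset()]); needs at
#'   least 2 conditions, each with >= 4 distinct positive times spanning at
#'   least a decade.
#' @param total Fixed loadable fraction (default 0.75).
#' @param bounds Rate bounds in per-second, default `c(1e-6, 1e4)`.
#' @param n_starts Number of multi-start restarts (default 8).
#' @param seed Integer seed making the restarts deterministic.
#' @param start Optional named list of starting rates
#'   (`k1`, `k2` per condition as vectors, scalar `k3`); used as the first
#'   start.
#' @param weights Optional per-record weights (1/sigma); default unweighted.
#' @return A `global_fit` object: list with `conditions` (per-condition
#'   data frame of k1, k2 and standard errors), `k3`, `k3_se`, `total`,
#'   `rss`, `converged`, `fitted` (data frame of fitted curves at the
#'   observed times) and the per-start RSS trace.
#' @examples
#' sim <- simulate_loading_timecourse(
#'   conditions = list(lo = kinetic_params(5, 0.02, 30),
#'                     hi = kinetic_params(0.5, 2, 30)),
#'   noise_sd = 0, replicates = 1, seed = 1)
#' fit <- fit_global_two_state(sim, n_starts = 2, seed = 1)
#' fit$k3
#' @export
fit_global_two_state <- function(data, total = 0.75, bounds = c(1e-6, 1e4),
                                 n_starts = 8, seed = 1, start = NULL,
                                 weights = NULL) {
  stopifnot(is.data.frame(data),
            all(c("condition", "time_s", "fraction_loaded") %in% names(data)))
  conditions <- unique(as.character(data$condition))
  if (length(conditions) < 2L)
    stop("global fit needs >= 2 conditions (k3 is shared)", call. = FALSE)
  for (cond in conditions) {
    t_pos <- unique(data$time_s[data$condition == cond & data$time_s > 0])
    if (length(t_pos) < 4L || max(t_pos) / min(t_pos) < 10)
      stop("condition '", cond, "' needs >= 4 distinct positive times ",
           "spanning at least one decade", call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, nrow(data))
  stopifnot(length(weights) == nrow(data))
  idx_by_cond <- split(seq_len(nrow(data)), as.character(data$condition))
  lb <- log(bounds[1]); ub <- log(bounds[2])
  n_par <- 2L * length(conditions) + 1L

  resid_fn <- function(theta) {
    pars <- unpack_theta(theta, conditions, total)
    r <- numeric(nrow(data))
    for (i in seq_along(conditions)) {
      idx <- idx_by_cond[[conditions[i]]]
      pred <- loaded_fraction(pars[[i]], data$time_s[idx])$C
      r[idx] <- (pred - data$fraction_loaded[idx]) * weights[idx]
    }
    r
  }

  starts <- withr::with_seed(seed, {
    # heuristic start box: rates between 1e-2 and 1e2 /s (inside bounds)
    lapply(seq_len(n_starts), function(i)
      stats::runif(n_par, log(1e-2), log(1e2)))
  })
  if (!is.null(start)) {
    theta0 <- log(c(rbind(start$k1, start$k2), start$k3))
    starts[[1]] <- pmin(pmax(theta0, lb), ub)
  }

  best <- NULL
  rss_trace <- numeric(0)
  for (th0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = th0, lower = rep(lb, n_par),
                         upper = rep(ub, n_par), fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    rss_trace <- c(rss_trace, rss)
    if (is.null(best) || rss < best$rss)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("global fit failed from every starting point", call. = FALSE)
  converged <- best$fit$info %in% 1:4
  if (!converged)
    warning("optimizer did not report convergence (info = ",
            best$fit$info, "); returning best solution found")

  theta <- best$fit$par
  pars <- unpack_theta(theta, conditions, total)
  # delta-method SEs: se(rate) = rate * se(log rate)
  se_log <- rep(NA_real_, n_par)
  dof <- nrow(data) - n_par
  if (dof > 0) {
    h <- try(solve(best$fit$hessian) * best$rss / dof, silent = TRUE)
    if (!inherits(h, "try-error")) {
      dg <- diag(h)
      se_log[dg >= 0] <- sqrt(dg[dg >= 0])
    }
  }
  rates <- exp(theta)
  se <- rates * se_log
  cond_tab <- data.frame(
    condition = conditions,
    k1 = vapply(pars, function(p) p$k1, numeric(1)),
    k2 = vapply(pars, function(p) p$k2, numeric(1)),
    k1_se = se[seq(1, 2 * length(conditions), by = 2)],
    k2_se = se[seq(2, 2 * length(conditions), by = 2)])

  fitted <- do.call(rbind, lapply(seq_along(conditions), function(i) {
    t_u <- sort(unique(data$time_s[data$condition == conditions[i]]))
    data.frame(condition = conditions[i], time_s = t_u,
               fitted = loaded_fraction(pars[[i]], t_u)$C)
  }))
  rownames(fitted) <- NULL

  structure(list(conditions = cond_tab, k3 = rates[n_par],
                 k3_se = se[n_par], total = total, rss = best$rss,
                 converged = converged, n_obs = nrow(data),
                 fitted = fitted, rss_trace = rss_trace,
                 bounds = bounds, seed = seed),
            class = "global_fit")
}

#' @export
print.global_fit <- function(x, ...) {
  cat("Global two-state loading fit\n")
  cat(sprintf("  shared k3 = %.4g /s (se %.3g), total fixed at %g\n",
              x$k3, x$k3_se, x$total))
  cat(sprintf("  RSS = %.4g over %d observations; converged: %s\n",
              x$rss, x$n_obs, x$converged))
  print(x$conditions, row.names = FALSE)
  invisible(x)
}

#' Single-exponential discharge fit
#'
#' Discharge of the loaded enzyme (thioester hydrolysis after quenching the
#' loading reaction) is modelled as `C(t) = C0 * exp(-kd * t)` with
#' `kd >= 0`. `C0` is profiled out analytically for each candidate `kd` and
#' the decay rate is found by 1-D minimization of the residual sum of
#' squares. Data whose trend is increasing are fitted anyway but flagged.
#'
#' @param data Data frame with columns `time_s` and `fraction_loaded`.
#' @return List with `kd` (per second), `C0`, `rss`, and
#'   `increasing_warning` (logical).
#' @export
fit_exponential_discharge <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("time_s", "fraction_loaded") %in% names(data)))
  t <- data$time_s; y <- data$fraction_loaded
  if (length(t) < 2L) stop("need at least 2 points", call. = FALSE)
  rss_of <- function(kd) {
    e <- exp(-kd * t)
    c0 <- sum(y * e) / sum(e^2)
    sum((y - c0 * e)^2)
  }
  increasing <- stats::coef(stats::lm(y ~ t))[2] > 0
  t_pos <- t[t > 0]
  kd_hi <- if (length(t_pos) > 0) 50 / min(t_pos) else 1
  opt <- stats::optimize(rss_of, interval = c(0, kd_hi), tol = 1e-12)
  kd <- opt$minimum
  # prefer kd = 0 when decay gives no real improvement (constant data)
  if (rss_of(0) <= opt$objective * (1 + 1e-8) + 1e-15) kd <- 0
  e <- exp(-kd * t)
  c0 <- sum(y * e) / sum(e^2)
  list(kd = kd, C0 = c0, rss = rss_of(kd),
       increasing_warning = unname(increasing))
}

#' Cycling model parameters
#'
#' Extends the two-state loading model with continuous re-loading: the
#' loaded enzyme C discharges back to the active state A at rate `kd`,
#' giving the cycle A <-> B (k1, k2), A -> C (k3), C -> A (kd). This is the
#' setting of a cell, where E1 is always present and the enzyme cycles
#' between loaded and discharged states.
#'
#' @param k1,k2,k3 As in [kinetic_params()].
#' @param kd Discharge rate C -> A, per second (>= 0).
#' @return An object of class `cycling_params`.
#' @export
cycling_params <- function(k1, k2, k3, kd) {
  if (any(c(k1, k2, k3, kd) < 0))
    stop("rates must be non-negative", call. = FALSE)
  structure(list(k1 = k1, k2 = k2, k3 = k3, kd = kd),
            class = "cycling_params")
}

#' Steady-state loaded fraction under continuous cycling
#'
#' At steady state of the cycle A <-> B, A -> C, C -> A the loaded fraction
#' is
#' \deqn{C^\ast = \frac{k_3/k_d}{1 + k_1/k_2 + k_3/k_d}.}
#' With `kd = 0` the loaded state absorbs everything (fraction 1). The
#' fraction decreases in the inactivation ratio `k1/k2` and in `kd`; the
#' conformational equilibrium matters most when loading/discharge cycling is
#' fast relative to conformational interconversion (large `kd`), which is
#' how membrane composition can gate steady-state ubiquitination capacity
#' in vivo even though it only shifts the A/B equilibrium.
#'
#' @param p A [cycling_params] with `k2 > 0` and not both `k3` and `kd`
#'   zero.
#' @return Steady-state loaded fraction in `[0, 1]`.
#' @examples
#' steady_state_loaded_fraction(cycling_params(0, 1, 0.1, 0.1))  # 0.5
#' @export
steady_state_loaded_fraction <- function(p) {
  stopifnot(inherits(p, "cycling_params"))
  if (p$k2 <= 0)
    stop("k2 must be positive (otherwise everything sinks into B)",
         call. = FALSE)
  if (p$k3 == 0 && p$kd == 0)
    stop("k3 = kd = 0: no loading or discharge, steady state undefined",
         call. = FALSE)
  if (p$kd == 0) return(1)
  x <- p$k3 / p$kd
  x / (1 + p$k1 / p$k2 + x)
}
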