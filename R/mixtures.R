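#' Contact-count series
#'
#' Per-frame counts of contacts between a protein domain and the membrane,
#' extracted from a simulation trajectory. Plain non-negative integers with
#' optional metadata (condition label, frame stride, region definition; the
#' default region is the catalytic UBC domain, residues 1-168).
#'
#' @param counts Non-negative integer vector, one entry per frame.
#' @param condition Optional condition label.
#' @param stride Optional frame stride.
#' @param region Region definition string.
#' @return Integer vector of class `contact_series` with metadata
#'   attributes.
#' @export
contact_series <- function(counts, condition = NA_character_, stride = 1L,
                           region = "UBC domain, residues 1-168") {
  counts <- as.integer(round(counts))
  if (length(counts) < 1L || any(counts < 0) || anyNA(counts))
    stop("counts must be a non-empty vector of non-negative integers",
         call. = FALSE)
  structure(counts, condition = condition, stride = stride, region = region,
            class = "contact_series")
}

logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

# one EM run on tabulated counts (x = unique values, w = frequencies)
em_run <- function(x, w, n, lambda, pi, tol, max_iter, zero_inflated) {
  K <- length(lambda)
  loglik_path <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    ld <- vapply(seq_len(K), function(k) {
      if (zero_inflated && k == 1L) {
        ifelse(x == 0L, 0, -Inf) + log(pi[k])
      } else {
        stats::dpois(x, lambda[k], log = TRUE) + log(pi[k])
      }
    }, numeric(length(x)))
    ld <- matrix(ld, nrow = length(x))
    lse <- logsumexp_rows(ld)
    ll <- sum(w * lse)
    loglik_path <- c(loglik_path, ll)
    gamma <- exp(ld - lse)
    nk <- colSums(w * gamma)
    pi <- nk / n
    lam_new <- colSums(w * gamma * x) / nk
    lam_new[!is.finite(lam_new)] <- 1e-6
    lambda_upd <- pmax(lam_new, 1e-6)
    if (zero_inflated) lambda_upd[1] <- 0
    lambda <- lambda_upd
    if (is.finite(ll_prev) && abs(ll - ll_prev) <= tol * (1 + abs(ll))) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_prev <- ll
  }
  list(lambda = lambda, pi = pi, loglik = ll, loglik_path = loglik_path,
       converged = converged, n_iterations = iter)
}

#' Fit a Poisson mixture to contact counts by EM
#'
#' Models the per-frame contact-count distribution as a K-component Poisson
#' mixture, the components being interpreted as conformational states
#' (unbound near zero contacts, loosely bound, tightly bound). Expectation-
#' maximization with closed-form M-step (`lambda_k` = responsibility-
#' weighted mean, `pi_k` = mean responsibility); the best of `restarts`
#' seeded initializations is returned, components sorted by ascending mean.
#' Component means are floored at 1e-6 so the "unbound" zero-contact peak
#' stays a proper Poisson; `zero_inflated = TRUE` instead replaces the
#' first component by a structural point mass at zero.
#'
#' Internally the counts are tabulated to their unique values, which makes
#' each EM sweep exact and cheap regardless of trajectory length.
#'
#' @param counts Integer vector (or [contact_series]) of contact counts;
#'   length must be at least `10 * K`.
#' @param K Number of mixture components (>= 1).
#' @param restarts Number of seeded initializations (default 20). The first
#'   uses k-quantile means and uniform weights; the rest are randomized.
#' @param seed Integer seed.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations per restart.
#' @param zero_inflated Replace the lowest component by a point mass at 0.
#' @return A `poisson_mixture_fit`: list with `K`, `weights`, `means`
#'   (ascending), `log_likelihood`, `bic`, `converged`, `n_iterations`,
#'   `loglik_path` (best restart), `n`, `degenerate` (any weight < 1e-6),
#'   `zero_inflated`.
#' @examples
#' x <- simulate_contact_counts(2000, means = c(1, 20), weights = c(.5, .5),
#'                              seed = 1)
#' fit_poisson_mixture_em(x, K = 2, restarts = 5, seed = 1)$means
#' @export
fit_poisson_mixture_em <- function(counts, K, restarts = 20, seed = 1,
                                   tol = 1e-8, max_iter = 500,
                                   zero_inflated = FALSE) {
  counts <- as.integer(round(unclass(counts)))
  stopifnot(K >= 1, all(counts >= 0))
  n <- length(counts)
  if (n < 10 * K)
    stop("need at least 10*K observations (have ", n, ", K = ", K, ")",
         call. = FALSE)
  tab <- table(counts)
  x <- as.numeric(names(tab))
  w <- as.numeric(tab)

  quant_means <- stats::quantile(counts, probs = (2 * seq_len(K) - 1) / (2 * K),
                                 names = FALSE)
  inits <- withr::with_seed(seed, {
    lapply(seq_len(restarts), function(r) {
      if (r == 1L) {
        list(lambda = pmax(quant_means, 1e-6), pi = rep(1 / K, K))
      } else {
        lam <- sort(stats::quantile(counts, probs = sort(stats::runif(K)),
                                    names = FALSE))
        g <- stats::rgamma(K, shape = 2)
        list(lambda = pmax(lam + stats::runif(K, 0, 1), 1e-6),
             pi = g / sum(g))
      }
    })
  })

  best <- NULL
  for (init in inits) {
    lam0 <- init$lambda
    if (zero_inflated) lam0[1] <- 0
    run <- em_run(x, w, n, lam0, init$pi, tol, max_iter, zero_inflated)
    if (is.null(best) || run$loglik > best$loglik) best <- run
  }

  ord <- order(best$lambda)
  means <- best$lambda[ord]
  weights <- best$pi[ord]
  p <- if (zero_inflated) 2 * K - 2 else 2 * K - 1
  structure(list(K = K, weights = weights, means = means,
                 log_likelihood = best$loglik,
                 bic = -2 * best$loglik + p * log(n),
                 converged = best$converged,
                 n_iterations = best$n_iterations,
                 loglik_path = best$loglik_path, n = n,
                 degenerate = any(weights < 1e-6),
                 zero_inflated = zero_inflated),
            class = "poisson_mixture_fit")
}

#' @export
print.poisson_mixture_fit <- function(x, ...) {
  cat(sprintf("Poisson mixture fit: K = %d, n = %d, logL = %.2f, BIC = %.2f\n",
              x$K, x$n, x$log_likelihood, x$bic))
  tab <- data.frame(component = seq_len(x$K),
                    mean = signif(x$means, 4),
                    weight = signif(x$weights, 4))
  print(tab, row.names = FALSE)
  if (!x$converged) cat("  (EM did not converge)\n")
  if (x$degenerate) cat("  (degenerate component: weight < 1e-6)\n")
  invisible(x)
}

#' Posterior responsibilities of a Poisson mixture fit
#'
#' @param fit A `poisson_mixture_fit`.
#' @param counts Counts to score (default: any non-negative integers).
#' @return Matrix `length(counts) x K`; rows sum to 1.
#' @export
posterior_responsibilities <- function(fit, counts) {
  stopifnot(inherits(fit, "poisson_mixture_fit"))
  counts <- as.numeric(unclass(counts))
  ld <- vapply(seq_len(fit$K), function(k) {
    if (fit$zero_inflated && k == 1L) {
      ifelse(counts == 0, 0, -Inf) + log(fit$weights[k])
    } else {
      stats::dpois(counts, fit$means[k], log = TRUE) + log(fit$weights[k])
    }
  }, numeric(length(counts)))
  ld <- matrix(ld, nrow = length(counts))
  exp(ld - logsumexp_rows(ld))
}

#' Choose the number of mixture components
#'
#' Fits K = 1..K_max mixtures and selects the K minimizing an information
#' criterion, by default BIC = -2 logL + p log n with p = 2K - 1 free
#' parameters (K means + K-1 weights). Values of K for which the data are
#' too few (n < 10 K) are dropped from the scan with a warning.
#'
#' @inheritParams fit_poisson_mixture_em
#' @param K_max Largest component count scanned (>= 2).
#' @param criterion `"bic"` or `"aic"`.
#' @return List with `K_star`, `fits` (one per scanned K), and `table`
#'   (K, log-likelihood, criterion value).
#' @export
select_component_count <- function(counts, K_max = 6, criterion = c("bic", "aic"),
                                   restarts = 20, seed = 1, tol = 1e-8,
                                   max_iter = 500) {
  criterion <- match.arg(criterion)
  stopifnot(K_max >= 2)
  counts <- as.integer(round(unclass(counts)))
  n <- length(counts)
  ks <- seq_len(K_max)
  feasible <- ks[n >= 10 * ks]
  if (length(feasible) < length(ks))
    warning("only ", n, " observations: scan reduced to K <= ",
            max(feasible))
  fits <- lapply(feasible, function(k)
    fit_poisson_mixture_em(counts, K = k, restarts = restarts,
                           seed = seed + k, tol = tol, max_iter = max_iter))
  crit <- vapply(fits, function(f) {
    p <- 2 * f$K - 1
    if (criterion == "bic") f$bic else -2 * f$log_likelihood + 2 * p
  }, numeric(1))
  tab <- data.frame(K = feasible,
                    log_likelihood = vapply(fits, `[[`, numeric(1),
                                            "log_likelihood"),
                    criterion = crit)
  names(tab)[3] <- criterion
  list(K_star = feasible[which.min(crit)],
       fits = stats::setNames(fits, paste0("K", feasible)),
       table = tab)
}

#' Membrane-bound population of a mixture fit
#'
#' Sums the weights of the components classified as membrane-bound.
#' Policies: `"threshold"` (default) counts components whose mean contact
#' number exceeds `threshold` (default 15 contacts, separating the unbound/
#' loosely-bound peaks from the tightly bound ones); `"all_but_unbound"`
#' counts every component except the smallest-mean one. Whether the loosely
#' bound population belongs to the "bound" state is a reporting choice, so
#' the policy is always recorded with the number.
#'
#' @param fit A `poisson_mixture_fit`.
#' @param policy `"threshold"` or `"all_but_unbound"`.
#' @param threshold Contact-count threshold for the default policy.
#' @return Fraction in `[0, 1]` with attribute `policy`.
#' @export
bound_fraction <- function(fit, policy = c("threshold", "all_but_unbound"),
                           threshold = 15) {
  stopifnot(inherits(fit, "poisson_mixture_fit"))
  policy <- match.arg(policy)
  sel <- if (policy == "threshold") fit$means > threshold
         else seq_len(fit$K) != 1L
  structure(sum(fit$weights[sel]), policy = policy)
}

#' Per-residue contact frequency
#'
#' Given a frames x residues contact matrix (logical, or counts which are
#' treated as contact when positive), returns for each residue the fraction
#' of frames in which it touches the membrane.
#'
#' @param mat Matrix with one row per frame and one column per residue;
#'   column names (1-based residue indices) are preserved.
#' @return Named numeric vector of frequencies in `[0, 1]`.
#' @export
residue_contact_frequency <- function(mat) {
  if (!is.matrix(mat) || nrow(mat) < 1L || ncol(mat) < 1L)
    stop("mat must be a non-empty frames x residues matrix", call. = FALSE)
  if (is.logical(mat)) {
    freq <- colMeans(mat)
  } else {
    if (any(mat < 0)) stop("contact counts must be non-negative",
                           call. = FALSE)
    freq <- colMeans(mat > 0)
  }
  if (is.null(names(freq))) names(freq) <- as.character(seq_along(freq))
  freq
}

#' Read a contact-count series from CSV
#'
#' Single-column format: one `count` column (header required). Long format:
#' columns `condition`, `frame`, `count`; use `condition` to pick one.
#'
#' @param path CSV file path.
#' @param condition Condition label for long-format files.
#' @return A [contact_series].
#' @export
read_contact_series_csv <- function(path, condition = NULL) {
  tab <- utils::read.csv(path, check.names = FALSE)
  if (!"count" %in% names(tab))
    stop("contact CSV must have a 'count' column", call. = FALSE)
  if ("condition" %in% names(tab)) {
    if (is.null(condition)) {
      conds <- unique(tab$condition)
      if (length(conds) > 1L)
        stop("file holds several conditions (",
             paste(conds, collapse = ", "), "); pick one with condition=",
             call. = FALSE)
      condition <- conds
    }
    tab <- tab[tab$condition == condition, , drop = FALSE]
    if ("frame" %in% names(tab)) tab <- tab[order(tab$frame), , drop = FALSE]
  }
  contact_series(tab$count,
                 condition = if (is.null(condition)) NA_character_
                             else as.character(condition))
}
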