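#' Simulate multi-condition ubiquitin-loading time courses
#'
#' Forward-simulates the two-state loading model ([loaded_fraction()]) for
#' each condition on a common time grid and adds i.i.d. Gaussian noise to
#' the loaded fraction, clipped to `[0, 1]`. The defaults emulate the
#' biphasic loading seen in reconstituted membranes: a
#' tightly packed membrane condition in which most enzyme loads within tens
#' of milliseconds, and a loosely packed condition where the fast pool is
#' nearly absent and loading proceeds on the minute timescale. Records with
#' times below 30 s are labelled `quenched_flow` and the rest `manual`,
#' mirroring how such data are collected.
#'
#' @param conditions Named list of [kinetic_params], one per condition.
#'   Default: a loosely packed, mostly inactive condition
#'   (`k1 = 5, k2 = 0.02`) and a tightly packed, mostly active one
#'   (`k1 = 0.5, k2 = 2`), both with shared `k3 = 30` per second. These are
#'   synthetic magnitudes chosen for realism, not measured values.
#' @param times Time grid in seconds; default 20 points log-spaced from
#'   5 ms to 600 s (quenched-flow plus manual sampling range).
#' @param noise_sd Gaussian noise SD on the fraction scale (default 0.02).
#' @param replicates Number of replicates per condition (default 3).
#' @param seed Integer seed; the output is deterministic given the seed.
#' @return Loading dataset: data frame with columns `condition`, `time_s`,
#'   `fraction_loaded`, `replicate`, `source`, with the generating
#'   parameters and seed stored in attributes.
#' @examples
#' sim <- simulate_loading_timecourse(seed = 7)
#' head(sim)
#' @export
simulate_loading_timecourse <- function(
    conditions = list(
      "10% SFA" = kinetic_params(k1 = 5, k2 = 0.02, k3 = 30),
      "60% SFA" = kinetic_params(k1 = 0.5, k2 = 2, k3 = 30)),
    times = exp(seq(log(0.005), log(600), length.out = 20)),
    noise_sd = 0.02, replicates = 3, seed = 1) {
  stopifnot(is.list(conditions), length(conditions) >= 1L,
            !is.null(names(conditions)), all(nzchar(names(conditions))),
            noise_sd >= 0, replicates >= 1, all(times > 0))
  out <- withr::with_seed(seed, {
    rows <- lapply(names(conditions), function(cond) {
      clean <- loaded_fraction(conditions[[cond]], times)$C
      do.call(rbind, lapply(seq_len(replicates), function(rep) {
        y <- clean + stats::rnorm(length(times), sd = noise_sd)
        data.frame(condition = cond, time_s = times,
                   fraction_loaded = pmin(pmax(y, 0), 1),
                   replicate = rep,
                   source = ifelse(times < 30, "quenched_flow", "manual"))
      }))
    })
    do.call(rbind, rows)
  })
  rownames(out) <- NULL
  structure(out, params = conditions, noise_sd = noise_sd, seed = seed)
}

#' Simulate a protein-membrane contact-count series
#'
#' Draws per-frame contact counts from a Poisson mixture. In `iid` mode the
#' component of each frame is independent; in `markov` mode a hidden state
#' chain with the given mean dwell time (in frames) and stationary
#' distribution equal to `weights` selects the component, emulating
#' reversible association of the domain with the membrane while keeping the
#' same marginal distribution. Defaults are a four-component mixture with
#' means 0.2, 8, 30 and 50 contacts (unbound, loosely bound, bound, tightly
#' bound) and weights 0.40/0.10/0.35/0.15.
#'
#' @param n_frames Number of frames to draw.
#' @param means Component Poisson means (contacts).
#' @param weights Component probabilities (sum to 1).
#' @param mode `"iid"` or `"markov"`.
#' @param mean_dwell Mean dwell in frames for `markov` mode. The chain
#'   redraws its state from `weights` with probability `1/mean_dwell` per
#'   frame, so dwell times are geometric.
#' @param seed Integer seed.
#' @param condition Condition label stored in the series metadata.
#' @return A [contact_series] with the generating spec in attributes.
#' @examples
#' x <- simulate_contact_counts(1000, seed = 1)
#' mean(x)  # close to sum(weights * means) = 15.8
#' @export
simulate_contact_counts <- function(n_frames,
                                    means = c(0.2, 8, 30, 50),
                                    weights = c(0.40, 0.10, 0.35, 0.15),
                                    mode = c("iid", "markov"),
                                    mean_dwell = 50, seed = 1,
                                    condition = NA_character_) {
  mode <- match.arg(mode)
  stopifnot(n_frames >= 1, length(means) == length(weights),
            all(means >= 0), all(weights >= 0), mean_dwell >= 1)
  if (abs(sum(weights) - 1) > 1e-9)
    stop("weights must sum to 1", call. = FALSE)
  K <- length(means)
  out <- withr::with_seed(seed, {
    if (mode == "iid") {
      states <- sample.int(K, n_frames, replace = TRUE, prob = weights)
    } else {
      states <- integer(n_frames)
      states[1] <- sample.int(K, 1, prob = weights)
      jump <- stats::runif(n_frames) < 1 / mean_dwell
      redraw <- sample.int(K, n_frames, replace = TRUE, prob = weights)
      for (i in seq_len(n_frames)[-1])
        states[i] <- if (jump[i]) redraw[i] else states[i - 1]
    }
    stats::rpois(n_frames, means[states])
  })
  cs <- contact_series(out, condition = condition)
  attr(cs, "spec") <- list(means = means, weights = weights, mode = mode,
                           mean_dwell = mean_dwell, seed = seed)
  cs
}

#' Simulate a two-band emission spectrum
#'
#' Sum of Gaussian emission bands evaluated on a wavelength grid, plus
#' optional Gaussian noise, floored at zero.
#'
#' @param bands Data frame with columns `center_nm`, `width_nm` (Gaussian
#'   sigma) and `height`.
#' @param grid Wavelength grid in nm (default 400-600 nm, 2 nm step).
#' @param noise_sd Noise SD in intensity units (default 0).
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @return An [emission_spectrum].
#' @examples
#' bands <- data.frame(center_nm = c(430, 500), width_nm = c(10, 10),
#'                     height = c(3, 1))
#' generalized_polarization(simulate_emission_spectrum(bands))
#' @export
simulate_emission_spectrum <- function(bands, grid = seq(400, 600, by = 2),
                                       noise_sd = 0, seed = 1) {
  stopifnot(is.data.frame(bands),
            all(c("center_nm", "width_nm", "height") %in% names(bands)),
            all(diff(grid) > 0), noise_sd >= 0)
  clean <- rowSums(vapply(seq_len(nrow(bands)), function(i)
    bands$height[i] * exp(-(grid - bands$center_nm[i])^2 /
                            (2 * bands$width_nm[i]^2)),
    numeric(length(grid))))
  y <- if (noise_sd > 0) {
    withr::with_seed(seed, clean + stats::rnorm(length(grid), sd = noise_sd))
  } else clean
  emission_spectrum(grid, pmax(y, 0),
                    metadata = list(bands = bands, noise_sd = noise_sd,
                                    seed = seed))
}

#' Write a complete synthetic fixture set
#'
#' Generates one file per pipeline input under `dir`: a loading time-course
#' CSV, a contact-count CSV (iid and markov), an emission-spectrum CSV, and
#' the built-in liposome composition table. A `manifest.json` records every
#' generator spec and seed so the set is reproducible.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer master seed; sub-generators use fixed offsets.
#' @return Invisibly, the manifest list.
#' @export
write_fixture_set <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  loading <- simulate_loading_timecourse(seed = seed)
  utils::write.csv(loading, file.path(dir, "loading_timecourse.csv"),
                   row.names = FALSE)
  iid <- simulate_contact_counts(50000, seed = seed + 1,
                                 condition = "ER-like")
  utils::write.csv(data.frame(condition = attr(iid, "condition"),
                              frame = seq_along(iid),
                              count = as.integer(iid)),
                   file.path(dir, "contact_counts_iid.csv"),
                   row.names = FALSE)
  mk <- simulate_contact_counts(50000, mode = "markov", seed = seed + 2,
                                condition = "ER-like")
  utils::write.csv(data.frame(condition = attr(mk, "condition"),
                              frame = seq_along(mk),
                              count = as.integer(mk)),
                   file.path(dir, "contact_counts_markov.csv"),
                   row.names = FALSE)
  bands <- data.frame(center_nm = c(430, 500), width_nm = c(12, 12),
                      height = c(2, 1))
  spec <- simulate_emission_spectrum(bands, noise_sd = 0.005,
                                     seed = seed + 3)
  utils::write.csv(as.data.frame(spec),
                   file.path(dir, "emission_spectrum.csv"),
                   row.names = FALSE)
  file.copy(system.file("extdata", "liposome_compositions.csv",
                        package = "lipkin", mustWork = TRUE),
            file.path(dir, "liposome_compositions.csv"), overwrite = TRUE)
  manifest <- list(
    seed = seed,
    loading = list(seed = seed, noise_sd = attr(loading, "noise_sd")),
    contacts_iid = attr(iid, "spec"),
    contacts_markov = attr(mk, "spec"),
    spectrum = list(bands = bands, noise_sd = 0.005, seed = seed + 3))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
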