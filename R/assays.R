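#' Emission spectrum container
#'
#' An ordered wavelength/intensity table, as recorded by a plate reader
#' (typically 400-600 nm in 2 nm steps for C-Laurdan work).
#'
#' @param wavelength_nm Strictly increasing wavelengths in nm.
#' @param intensity Non-negative intensities (arbitrary units).
#' @param metadata Optional named list of free-form labels.
#' @return An object of class `emission_spectrum`.
#' @export
emission_spectrum <- function(wavelength_nm, intensity, metadata = list()) {
  stopifnot(is.numeric(wavelength_nm), is.numeric(intensity),
            length(wavelength_nm) == length(intensity),
            length(wavelength_nm) >= 1L)
  if (any(diff(wavelength_nm) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (any(intensity < 0))
    stop("intensities must be non-negative", call. = FALSE)
  structure(
    data.frame(wavelength_nm = wavelength_nm, intensity = intensity),
    metadata = metadata,
    class = c("emission_spectrum", "data.frame"))
}

#' Band definition for generalized polarization
#'
#' Two non-overlapping wavelength windows. The defaults are the C-Laurdan
#' bands: the ordered (gel-like) band p1 = 402-460 nm and the disordered
#' band p2 = 470-530 nm. Band sums include samples on the closed interval
#' boundaries.
#'
#' @param p1_range,p2_range Length-2 numeric `c(low, high)` in nm.
#' @return An object of class `band_definition`.
#' @export
band_definition <- function(p1_range = c(402, 460), p2_range = c(470, 530)) {
  for (r in list(p1_range, p2_range))
    if (length(r) != 2L || r[1] >= r[2])
      stop("each band range must be c(low, high) with low < high",
           call. = FALSE)
  lo <- max(p1_range[1], p2_range[1]); hi <- min(p1_range[2], p2_range[2])
  if (lo <= hi)
    stop("band ranges must not overlap", call. = FALSE)
  structure(list(p1_range = p1_range, p2_range = p2_range),
            class = "band_definition")
}

band_sum <- function(spec, range, method) {
  inside <- spec$wavelength_nm >= range[1] & spec$wavelength_nm <= range[2]
  if (!any(inside)) return(0)
  if (method == "sum") {
    sum(spec$intensity[inside])
  } else {
    w <- spec$wavelength_nm[inside]; y <- spec$intensity[inside]
    if (length(w) < 2L) return(0)
    sum(diff(w) * (y[-1] + y[-length(y)]) / 2)
  }
}

#' Generalized polarization of an emission spectrum
#'
#' GP = (Ip1 - Ip2) / (Ip1 + Ip2), where Ip1 and Ip2 are the summed
#' intensities over the two band windows. GP lies in (-1, 1) and reports
#' lipid packing: tightly packed (more saturated) bilayers shift C-Laurdan
#' emission toward the p1 band and give higher GP. By default the band
#' intensities are raw sums over the recorded samples; `method =
#' "trapezoid"` integrates instead (useful for non-uniform grids).
#'
#' @param spec An [emission_spectrum].
#' @param bands A [band_definition].
#' @param method `"sum"` (default) or `"trapezoid"`.
#' @return GP value in `[-1, 1]` (the closed boundary is attained when one
#'   band holds all intensity).
#' @examples
#' s <- emission_spectrum(seq(400, 600, 2), dnorm(seq(400, 600, 2), 440, 10))
#' generalized_polarization(s)
#' @export
generalized_polarization <- function(spec, bands = band_definition(),
                                     method = c("sum", "trapezoid")) {
  stopifnot(inherits(spec, "emission_spectrum"),
            inherits(bands, "band_definition"))
  method <- match.arg(method)
  ip1 <- band_sum(spec, bands$p1_range, method)
  ip2 <- band_sum(spec, bands$p2_range, method)
  if (ip1 + ip2 <= 0)
    stop("total band intensity is zero; GP undefined", call. = FALSE)
  (ip1 - ip2) / (ip1 + ip2)
}

#' FRET acceptor/donor emission ratio
#'
#' Ratio of the emission intensity at the acceptor wavelength to that at the
#' donor wavelength, each read from the nearest recorded sample (plate
#' readers report discrete wavelength steps; no interpolation by default).
#' Defaults correspond to an Alexa 488 donor / Alexa 594 acceptor pair
#' (I614/I516).
#'
#' @param spec An [emission_spectrum].
#' @param acceptor_nm,donor_nm Wavelengths in nm; must lie within the
#'   recorded range.
#' @return Non-negative intensity ratio.
#' @export
fret_ratio <- function(spec, acceptor_nm = 614, donor_nm = 516) {
  stopifnot(inherits(spec, "emission_spectrum"))
  rng <- range(spec$wavelength_nm)
  for (wl in c(acceptor_nm, donor_nm))
    if (wl < rng[1] || wl > rng[2])
      stop(sprintf("wavelength %g nm outside recorded range [%g, %g]",
                   wl, rng[1], rng[2]), call. = FALSE)
  nearest <- function(wl) spec$intensity[which.min(abs(spec$wavelength_nm - wl))]
  i_d <- nearest(donor_nm)
  if (i_d <= 0)
    stop("donor intensity is zero; FRET ratio undefined", call. = FALSE)
  nearest(acceptor_nm) / i_d
}

#' Gel lane profile
#'
#' Labelled band intensities from a densitometry trace plus the total lane
#' intensity; each band must not exceed the total.
#'
#' @param labels Character vector of band labels.
#' @param intensities Non-negative band intensities.
#' @param total_intensity Total lane intensity (> 0). Defaults to the sum of
#'   the band intensities (bands partition the lane).
#' @return An object of class `lane_profile`.
#' @export
lane_profile <- function(labels, intensities,
                         total_intensity = sum(intensities)) {
  stopifnot(is.character(labels), is.numeric(intensities),
            length(labels) == length(intensities))
  if (anyDuplicated(labels))
    stop("duplicate band labels", call. = FALSE)
  if (any(intensities < 0) || total_intensity <= 0)
    stop("band intensities must be >= 0 and total > 0", call. = FALSE)
  if (any(intensities > total_intensity))
    stop("band intensity exceeds total lane intensity", call. = FALSE)
  structure(list(labels = labels, intensities = intensities,
                 total_intensity = total_intensity),
            class = "lane_profile")
}

#' Fraction of modified protein in a gel lane
#'
#' Normalizes the summed intensity of the selected (modified) bands to the
#' total lane intensity, the standard quantification for ubiquitin-loading
#' and ubiquitination gels.
#'
#' @param lane A [lane_profile].
#' @param modified_labels Character vector of band labels counted as
#'   modified; may be empty (fraction 0).
#' @return Fraction in `[0, 1]`.
#' @examples
#' lane <- lane_profile(c("unmod", "mod"), c(75, 25), total_intensity = 100)
#' lane_modified_fraction(lane, "mod")  # 0.25
#' @export
lane_modified_fraction <- function(lane, modified_labels) {
  stopifnot(inherits(lane, "lane_profile"))
  modified_labels <- as.character(modified_labels)
  unknown <- setdiff(modified_labels, lane$labels)
  if (length(unknown) > 0L)
    stop("unknown band label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (length(modified_labels) == 0L) return(0)
  sum(lane$intensities[lane$labels %in% modified_labels]) /
    lane$total_intensity
}

#' Read an emission spectrum from CSV
#'
#' Wide format: columns `wavelength_nm`, `intensity`. Long format (several
#' spectra per file): additionally a `spectrum_id` column; use `id` to pick
#' one.
#'
#' @param path CSV file path.
#' @param id Spectrum id for long-format files.
#' @return An [emission_spectrum].
#' @export
read_spectrum_csv <- function(path, id = NULL) {
  tab <- utils::read.csv(path, check.names = FALSE)
  need <- c("wavelength_nm", "intensity")
  if (!all(need %in% names(tab)))
    stop("spectrum CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if ("spectrum_id" %in% names(tab)) {
    if (is.null(id)) {
      ids <- unique(tab$spectrum_id)
      if (length(ids) > 1L)
        stop("file holds several spectra (", paste(ids, collapse = ", "),
             "); pick one with id=", call. = FALSE)
      id <- ids
    }
    tab <- tab[tab$spectrum_id == id, , drop = FALSE]
    if (nrow(tab) == 0L)
      stop("no spectrum with id '", id, "'", call. = FALSE)
  }
  tab <- tab[order(tab$wavelength_nm), , drop = FALSE]
  emission_spectrum(tab$wavelength_nm, tab$intensity,
                    metadata = if (is.null(id)) list() else list(id = id))
}
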