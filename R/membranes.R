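#' Define a lipid species
#'
#' A lipid species is described by its acyl chains, each given as
#' `c(carbons, double_bonds)`. A chain is saturated when it has zero double
#' bonds. Sterols (e.g. cholesterol) carry no acyl chains and are excluded
#' from all chain arithmetic.
#'
#' @param name Short identifier, e.g. `"POPC"`.
#' @param chains List of length-2 integer vectors `c(carbons, double_bonds)`.
#'   Non-sterol phospholipids must have exactly two chains.
#' @param is_sterol Logical; sterols have no chains.
#' @return An object of class `lipid_species`.
#' @examples
#' lipid_species("POPC", list(c(16, 0), c(18, 1)))
#' lipid_species("cholesterol", is_sterol = TRUE)
#' @export
lipid_species <- function(name, chains = list(), is_sterol = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (is_sterol) {
    if (length(chains) > 0L)
      stop("a sterol species has no acyl chains", call. = FALSE)
  } else {
    if (length(chains) != 2L)
      stop("a non-sterol species must have exactly 2 acyl chains, got ",
           length(chains), call. = FALSE)
  }
  for (ch in chains) {
    if (length(ch) != 2L || ch[1] <= 0 || ch[2] < 0)
      stop("each chain must be c(carbons > 0, double_bonds >= 0)",
           call. = FALSE)
  }
  structure(list(name = name, chains = chains, is_sterol = is_sterol),
            class = "lipid_species")
}

#' @export
print.lipid_species <- function(x, ...) {
  if (x$is_sterol) {
    cat("<lipid_species>", x$name, "(sterol)\n")
  } else {
    ch <- vapply(x$chains, function(c) paste0(c[1], ":", c[2]), "")
    cat("<lipid_species>", x$name, paste(ch, collapse = "/"), "\n")
  }
  invisible(x)
}

n_saturated_chains <- function(sp) {
  if (sp$is_sterol) return(0L)
  sum(vapply(sp$chains, function(ch) ch[2] == 0, logical(1)))
}

n_chains <- function(sp) if (sp$is_sterol) 0L else length(sp$chains)

#' Built-in lipid species annotations
#'
#' Chain annotations for the common synthetic lipids used in reconstitution
#' work: POPC/POPE carry one palmitoyl (16:0) and one oleoyl (18:1) chain,
#' DOPC/DOPE/DOPS two oleoyl chains, DPPC two palmitoyl chains, the 16:1
#' ("palmitoleoyl") PC/PE species two mono-unsaturated 16-carbon chains, and
#' cholesterol is a sterol.
#'
#' @return Named list of [lipid_species] objects.
#' @export
builtin_species_db <- function() {
  po <- list(c(16, 0), c(18, 1))
  do <- list(c(18, 1), c(18, 1))
  dp <- list(c(16, 0), c(16, 0))
  hx <- list(c(16, 1), c(16, 1))
  list(
    POPC        = lipid_species("POPC", po),
    POPE        = lipid_species("POPE", po),
    DOPC        = lipid_species("DOPC", do),
    DOPE        = lipid_species("DOPE", do),
    DOPS        = lipid_species("DOPS", do),
    DPPC        = lipid_species("DPPC", dp),
    `16:1 PC`   = lipid_species("16:1 PC", hx),
    `16:1 PE`   = lipid_species("16:1 PE", hx),
    cholesterol = lipid_species("cholesterol", is_sterol = TRUE)
  )
}

#' Build a membrane composition
#'
#' A composition is a set of lipid species with their mole percentages.
#' Species named in [builtin_species_db()] need no annotation; other species
#' must be supplied through `species_db`.
#'
#' @param species Character vector of species names.
#' @param mol_percent Numeric vector of mole percentages (same length).
#' @param species_db Named list of [lipid_species] used to resolve names;
#'   defaults to the built-in annotations.
#' @param validate Validate invariants immediately (default `TRUE`).
#' @param tol Tolerance on the mol-percent sum, passed to
#'   [validate_composition()].
#' @return An object of class `membrane_composition`: a data frame with
#'   columns `species` and `mol_percent` plus resolved species annotations.
#' @examples
#' er_like <- membrane_composition(
#'   c("POPC", "DOPE", "DOPS", "cholesterol"), c(60, 20, 10, 10))
#' sfa_chain_fraction(er_like)
#' @export
membrane_composition <- function(species, mol_percent,
                                 species_db = builtin_species_db(),
                                 validate = TRUE, tol = 0.5) {
  stopifnot(is.character(species), is.numeric(mol_percent),
            length(species) == length(mol_percent))
  if (length(species) == 0L)
    stop("composition must contain at least one species", call. = FALSE)
  resolved <- lapply(species, function(nm) {
    sp <- species_db[[nm]]
    if (is.null(sp))
      stop("unknown lipid species '", nm,
           "': add an annotation via species_db", call. = FALSE)
    sp
  })
  comp <- structure(
    data.frame(species = species, mol_percent = as.numeric(mol_percent),
               stringsAsFactors = FALSE),
    species_db = stats::setNames(resolved, species),
    class = c("membrane_composition", "data.frame"))
  if (validate) validate_composition(comp, tol = tol) else comp
}

#' Validate a membrane composition
#'
#' Checks that mole percentages are non-negative and sum to 100 within `tol`
#' (the default +/-0.5 accommodates tables rounded to one decimal, e.g.
#' 66.7 + 16.7 + 6.7 + 10 = 100.1), and that no species is listed twice.
#'
#' @param comp A [membrane_composition].
#' @param tol Allowed deviation of the mol-percent sum from 100.
#' @return `comp`, unchanged, if valid; otherwise an error.
#' @export
validate_composition <- function(comp, tol = 0.5) {
  stopifnot(inherits(comp, "membrane_composition"))
  if (nrow(comp) == 0L)
    stop("composition must contain at least one species", call. = FALSE)
  if (any(comp$mol_percent < 0))
    stop("mol_percent values must be non-negative", call. = FALSE)
  if (anyDuplicated(comp$species))
    stop("duplicate species in composition: ",
         paste(unique(comp$species[duplicated(comp$species)]),
               collapse = ", "), call. = FALSE)
  s <- sum(comp$mol_percent)
  if (abs(s - 100) > tol)
    stop(sprintf("mol_percent values sum to %g, not 100 (tolerance %g)",
                 s, tol), call. = FALSE)
  comp
}

#' Saturated-acyl-chain fraction of a membrane
#'
#' The SFA content of a composition is the percentage of phospholipid acyl
#' chains that are fully saturated (zero double bonds):
#' `100 * sum(mol% * saturated chains) / sum(mol% * total chains)`,
#' with sterols excluded from both numerator and denominator. This is the
#' quantity that labels liposome mixes as e.g. "33% SFA (ER-like)".
#'
#' @param comp A validated [membrane_composition] containing at least one
#'   non-sterol species.
#' @return SFA chain percentage in `[0, 100]`.
#' @examples
#' comp <- membrane_composition(
#'   c("POPC", "DOPE", "DOPS", "cholesterol"), c(60, 20, 10, 10))
#' sfa_chain_fraction(comp)  # 33.3: 60 saturated chains of 180
#' @export
sfa_chain_fraction <- function(comp) {
  stopifnot(inherits(comp, "membrane_composition"))
  db <- attr(comp, "species_db")
  sat <- vapply(comp$species, function(nm) n_saturated_chains(db[[nm]]),
                numeric(1))
  tot <- vapply(comp$species, function(nm) n_chains(db[[nm]]), numeric(1))
  denom <- sum(comp$mol_percent * tot)
  if (denom <= 0)
    stop("SFA fraction is undefined for a sterol-only composition",
         call. = FALSE)
  100 * sum(comp$mol_percent * sat) / denom
}

#' Built-in liposome compositions
#'
#' The eleven liposome mixes used across the reconstitution experiments,
#' keyed by their SFA-content label. The label records the saturated-chain
#' percentage of the phospholipid mixture; the "+cholesterol" variants keep
#' the label of their parent phospholipid mix (the label is metadata, not
#' recomputed after cholesterol addition). Shipped as a plain CSV under
#' `extdata/liposome_compositions.csv`.
#'
#' @return Named list of [membrane_composition] objects.
#' @examples
#' builtin_compositions()[["50% SFA"]]
#' @export
builtin_compositions <- function() {
  path <- system.file("extdata", "liposome_compositions.csv",
                      package = "lipkin", mustWork = TRUE)
  tab <- utils::read.csv(path, check.names = FALSE)
  out <- lapply(split(tab, factor(tab$label, levels = unique(tab$label))),
                function(d) membrane_composition(d$species, d$mol_percent))
  out
}

#' Look up a built-in composition by label
#'
#' @param label Composition label, e.g. `"50% SFA"`.
#' @return A [membrane_composition].
#' @export
composition_by_label <- function(label) {
  comps <- builtin_compositions()
  if (!label %in% names(comps))
    stop("no built-in composition labelled '", label, "'; available: ",
         paste(names(comps), collapse = "; "), call. = FALSE)
  comps[[label]]
}

#' Read / write a composition as CSV or JSON
#'
#' CSV files carry columns `species` and `mol_percent`, one composition per
#' file; JSON files carry an object mapping species name to mol percent.
#'
#' @param path File path.
#' @param species_db Species annotations, as in [membrane_composition()].
#' @return A [membrane_composition] (readers) or `path`, invisibly (writer).
#' @export
read_composition_csv <- function(path, species_db = builtin_species_db()) {
  tab <- utils::read.csv(path, check.names = FALSE)
  need <- c("species", "mol_percent")
  if (!all(need %in% names(tab)))
    stop("composition CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  membrane_composition(tab$species, tab$mol_percent, species_db = species_db)
}

#' @rdname read_composition_csv
#' @export
read_composition_json <- function(path, species_db = builtin_species_db()) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  membrane_composition(names(obj), unlist(obj), species_db = species_db)
}

#' @rdname read_composition_csv
#' @param comp Composition to write.
#' @export
write_composition_csv <- function(comp, path) {
  stopifnot(inherits(comp, "membrane_composition"))
  utils::write.csv(as.data.frame(comp)[, c("species", "mol_percent")],
                   path, row.names = FALSE)
  invisible(path)
}
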