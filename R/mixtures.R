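#' Construct an osmolyte mixture
#'
#' @param molarities Named numeric vector, mol/L per species. Zero entries
#'   are dropped (the species is absent).
#' @param pH Solution pH.
#' @param ratio_string Optional ratio annotation such as \code{"5:12:3"}.
#' @param name Optional mixture label.
#' @return An object of class \code{mixture}.
#' @export
#' @examples
#' mixture(c(KCl = 0.25, `D-Glc` = 0.60, `L-Gln` = 0.15))
mixture <- function(molarities, pH = 7.0, ratio_string = NULL, name = NULL) {
  if (length(molarities) && is.null(names(molarities)))
    stop("molarities must be a named vector")
  if (any(!is.finite(molarities)) || any(molarities < 0))
    stop("molarities must be finite and >= 0")
  molarities <- molarities[molarities > 0]
  structure(list(species_molarity = molarities,
                 total_molarity = sum(molarities),
                 pH = pH,
                 ratio_string = ratio_string,
                 name = name),
            class = "mixture")
}

#' @export
print.mixture <- function(x, ...) {
  nm <- if (is.null(x$name)) "mixture" else x$name
  cat(sprintf("<%s> total %.4g M, pH %.3g\n", nm, x$total_molarity, x$pH))
  for (s in names(x$species_molarity))
    cat(sprintf("  %-6s %.4g mol/L\n", s, x$species_molarity[[s]]))
  invisible(x)
}

#' Build a mixture from a composition ratio string
#'
#' The model cytosols are defined by integer ratio strings such as
#' \code{"5:12:3"} ([KCl]:[D-Glc]:[L-Gln]) together with a total molarity:
#' species k gets \code{total_molarity * ratio_k / sum(ratios)} mol/L. A
#' zero ratio means the species is absent.
#'
#' @param ratio_string Colon-separated non-negative numbers, one per entry
#'   of \code{species}.
#' @param total_molarity Total molarity, mol/L (> 0).
#' @param pH Solution pH.
#' @param species Character vector naming the species the ratio positions
#'   refer to.
#' @param name Optional mixture label.
#' @return A \code{mixture}.
#' @export
#' @examples
#' mixture_from_ratio("5:12:3", 1.00)  # KCl 0.25, D-Glc 0.60, L-Gln 0.15
mixture_from_ratio <- function(ratio_string, total_molarity, pH = 7.0,
                               species = c("KCl", "D-Glc", "L-Gln"),
                               name = NULL) {
  stopifnot(is.character(ratio_string), length(ratio_string) == 1)
  if (!is.finite(total_molarity) || total_molarity <= 0)
    stop("total_molarity must be > 0")
  parts <- strsplit(trimws(ratio_string), ":", fixed = TRUE)[[1]]
  r <- suppressWarnings(as.numeric(parts))
  if (length(r) == 0 || any(is.na(r)))
    stop("unparseable ratio string: ", ratio_string)
  if (any(r < 0)) stop("ratios must be non-negative")
  if (sum(r) == 0) stop("all-zero ratio string")
  if (length(r) != length(species))
    stop(sprintf("ratio string has %d entries but %d species were given",
                 length(r), length(species)))
  m <- total_molarity * r / sum(r)
  names(m) <- species
  mixture(m, pH = pH, ratio_string = ratio_string, name = name)
}

#' Recover the integer ratio annotation of a mixture
#'
#' Inverse of \code{\link{mixture_from_ratio}} over the given species order:
#' scales molarities to the smallest integer vector (within tolerance).
#'
#' @param mix A \code{mixture}.
#' @param species Species order for the ratio positions.
#' @return Ratio string such as \code{"5:12:3"}.
#' @export
mixture_ratio_string <- function(mix, species = c("KCl", "D-Glc", "L-Gln")) {
  stopifnot(inherits(mix, "mixture"))
  m <- vapply(species, function(s) {
    v <- mix$species_molarity[s]
    if (is.na(v)) 0 else unname(v)
  }, numeric(1))
  pos <- m[m > 0]
  scale <- min(pos)
  r <- m / scale
  # search a small multiplier that makes all entries near-integer
  for (k in 1:1000) {
    if (all(abs(r * k - round(r * k)) < 1e-6 * k)) {
      return(paste(round(r * k), collapse = ":"))
    }
  }
  stop("molarities are not commensurable at tolerance 1e-6")
}

#' Estimate the osmotic potential of a mixture (modified Van 't Hoff)
#'
#' Sums the per-species contributions gamma_k * M_k * R * T with molarity
#' converted to mol m^-3 internally; the result is returned in MPa.
#' Additive over species and exactly linear in molarity (the gamma factors
#' are concentration-independent in this model).
#'
#' @param mix A \code{mixture}.
#' @param params An \code{osmo_params}.
#' @param species_db Named list of \code{osmolyte_species}; defaults to
#'   \code{default_species()}.
#' @return Estimated osmotic potential, MPa.
#' @export
#' @examples
#' estimate_osmotic_potential(mixture(c(KCl = 1.5)))  # 6.7377... MPa
estimate_osmotic_potential <- function(mix,
                                       params = osmotic_model_params(),
                                       species_db = default_species()) {
  stopifnot(inherits(mix, "mixture"), inherits(params, "osmo_params"))
  if (params$T <= 0) stop("temperature must be > 0")
  if (length(mix$species_molarity) == 0) return(0)
  pa <- 0
  for (s in names(mix$species_molarity)) {
    if (!s %in% names(species_db))
      stop("species not in registry: ", s)
    g <- gamma_factor(species_db[[s]], params)
    # mol/L -> mol/m^3 is the factor 1000
    pa <- pa + g * mix$species_molarity[[s]] * 1000 * params$R * params$T
  }
  pa / 1e6
}

#' Osmotic potential ratio
#'
#' Ratio between a measured (cryo-osmometric) and an estimated osmotic
#' potential. Values below 1 signal that fewer osmotically active particles
#' are present than the sum-of-contributions estimate assumes, i.e.
#' osmolyte association.
#'
#' @param measured Measured potential, MPa (>= 0).
#' @param estimated Estimated potential, MPa (> 0).
#' @param digits If non-NULL, round (half-up) to this many decimals --
#'   the tabulated display convention is 2.
#' @return Dimensionless ratio.
#' @export
osmotic_potential_ratio <- function(measured, estimated, digits = NULL) {
  if (any(!is.finite(estimated)) || any(estimated <= 0))
    stop("estimated potential must be > 0")
  if (any(!is.finite(measured)) || any(measured < 0))
    stop("measured potential must be >= 0")
  r <- measured / estimated
  if (!is.null(digits)) r <- round_half_up(r, digits)
  r
}

#' Osmolyte association degree from the osmotic potential ratio
#'
#' Fraction (in percent) of osmolytes bound into supramolecular complexes,
#' reconstructed from the osmotic deficit 1 - ratio. The ratio is first
#' rounded to two decimals (the tabulated convention), then scaled by
#' \code{multiplier} (3/2 by default, the value consistent with all
#' tabulated degrees; see the methods vignette for the tension with the
#' four-member complex reading) and floored at zero, so a mixture whose
#' rounded ratio is >= 1 has degree 0.
#'
#' @param ratio Osmotic potential ratio (> 0).
#' @param multiplier Deficit multiplier (default 3/2).
#' @return Association degree, percent.
#' @export
#' @examples
#' association_degree(0.87)  # 19.5
association_degree <- function(ratio, multiplier = 3 / 2) {
  if (any(!is.finite(ratio)) || any(ratio <= 0))
    stop("ratio must be > 0")
  r2 <- round_half_up(ratio, 2)
  pmax(0, 100 * multiplier * (1 - r2))
}

#' Anomer fractions from NMR peak intensities
#'
#' Converts the anomeric-carbon peak intensities of alpha- and
#' beta-D-glucose into percentages (the mutarotation equilibrium of the
#' pure sugar sits at 36:64).
#'
#' @param intensity_alpha,intensity_beta Peak intensities, arbitrary units,
#'   each >= 0 and not both zero.
#' @return Named numeric vector \code{c(alpha =, beta =)} summing to 100.
#' @export
anomer_fractions <- function(intensity_alpha, intensity_beta) {
  if (!is.finite(intensity_alpha) || !is.finite(intensity_beta) ||
      intensity_alpha < 0 || intensity_beta < 0)
    stop("intensities must be finite and >= 0")
  tot <- intensity_alpha + intensity_beta
  if (tot == 0) stop("both intensities are zero")
  c(alpha = 100 * intensity_alpha / tot, beta = 100 * intensity_beta / tot)
}

#' Assemble the derived mixture table
#'
#' For each mixture: total molarity, estimated osmotic potential, the
#' measured/estimated ratio and the association degree. The degree is only
#' reported for three-component mixtures (association is proposed for
#' those); other rows get \code{NA}.
#'
#' @param mixtures Named list of \code{mixture} objects.
#' @param measured Named numeric vector of measured potentials, MPa,
#'   matched to \code{mixtures} by name; \code{NA} allowed (ratio columns
#'   left blank).
#' @param params An \code{osmo_params}.
#' @param species_db Species registry.
#' @return \code{data.frame} with columns \code{name, total_M,
#'   measured_MPa, estimated_MPa, ratio, assoc_degree_pct} (unrounded; see
#'   \code{\link{format_table1}} for display rounding).
#' @export
table1_report <- function(mixtures, measured,
                          params = osmotic_model_params(),
                          species_db = default_species()) {
  if (length(mixtures) == 0) stop("empty mixture list")
  if (is.null(names(mixtures)))
    names(mixtures) <- vapply(mixtures, function(m)
      if (is.null(m$name)) "" else m$name, character(1))
  rows <- lapply(names(mixtures), function(nm) {
    mx <- mixtures[[nm]]
    est <- estimate_osmotic_potential(mx, params, species_db)
    mea <- if (nm %in% names(measured)) unname(measured[[nm]]) else NA_real_
    ratio <- if (is.finite(mea) && est > 0)
      osmotic_potential_ratio(mea, est) else NA_real_
    three <- length(mx$species_molarity) == 3
    deg <- if (three && is.finite(ratio)) association_degree(ratio)
           else NA_real_
    data.frame(name = nm, total_M = mx$total_molarity,
               measured_MPa = mea, estimated_MPa = est,
               ratio = ratio, assoc_degree_pct = deg,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Apply the display rounding convention to a derived table
#'
#' MPa and ratio columns to 2 decimals (half-up), degrees to 1 decimal.
#'
#' @param tab Output of \code{\link{table1_report}}.
#' @return The table with rounded numeric columns.
#' @export
format_table1 <- function(tab) {
  tab$measured_MPa <- round_half_up(tab$measured_MPa, 2)
  tab$estimated_MPa <- round_half_up(tab$estimated_MPa, 2)
  tab$ratio <- round_half_up(tab$ratio, 2)
  tab$assoc_degree_pct <- round_half_up(tab$assoc_degree_pct, 1)
  tab
}

# Round half away from zero (printed-table convention), unlike base
# round()'s banker's rounding.
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}
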