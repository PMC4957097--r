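#' Osmotic model parameters
#'
#' Bundle of physical constants and non-ideality settings used by the
#' modified Van 't Hoff estimator. The temperature default (300.15 K) is the
#' value under which the single-solute KCl reference and the two-component
#' KCl/D-Glc mixture reproduce their tabulated osmotic potentials at two
#' decimals; it is exposed so users can re-estimate at other temperatures.
#'
#' @param R Universal gas constant, J K^-1 mol^-1.
#' @param T Absolute temperature, K.
#' @param pK1,pK2 First and second ionisation constants of L-glutamine
#'   (carboxyl and amino groups). Carried for a future closed-form
#'   zwitterion correction; the default glutamine factor is a calibrated
#'   constant (see \code{gamma_gln}).
#' @param pH Solution pH (the model cytosols sit at 7.0 +/- 0.1).
#' @param gamma_gln Calibrated non-ideality factor for L-glutamine
#'   (dimensionless). The default 1.96 is back-derived from the
#'   two-component D-Glc + L-Gln mixture: (Pi_est/(R T) - [Glc])/[Gln].
#' @return An object of class \code{osmo_params}.
#' @export
#' @examples
#' p <- osmotic_model_params()
#' p$T
osmotic_model_params <- function(R = 8.314, T = 300.15,
                                 pK1 = 2.17, pK2 = 9.13, pH = 7.0,
                                 gamma_gln = 1.96) {
  stopifnot(R > 0, T > 0, pK1 < pK2, gamma_gln > 0)
  structure(list(R = R, T = T, pK1 = pK1, pK2 = pK2, pH = pH,
                 gamma_gln = gamma_gln),
            class = "osmo_params")
}

#' Define an osmolyte species
#'
#' @param name Species identifier, e.g. \code{"KCl"}.
#' @param vant_hoff_i Dissociation count (2 for a 1:1 salt, 1 otherwise).
#' @param phi Osmotic coefficient, dimensionless in (0, 1.2].
#' @param gamma_mode One of \code{"ideal"}, \code{"electrolyte"},
#'   \code{"amino_acid"}, \code{"constant"}. Determines how the
#'   non-ideality factor gamma is obtained (see \code{\link{gamma_factor}}).
#' @param gamma_constant Stored gamma for \code{gamma_mode = "constant"}.
#' @param rejection_sigma Membrane reflection coefficient in [0, 1]
#'   (1 = fully retained).
#' @param stokes_radius_nm Optional annotation, nm.
#' @return An object of class \code{osmolyte_species}.
#' @export
osmolyte_species <- function(name, vant_hoff_i = 1, phi = 1,
                             gamma_mode = c("ideal", "electrolyte",
                                            "amino_acid", "constant"),
                             gamma_constant = NA_real_,
                             rejection_sigma = 1,
                             stokes_radius_nm = NA_real_) {
  gamma_mode <- match.arg(gamma_mode)
  stopifnot(is.character(name), nzchar(name),
            vant_hoff_i >= 1, phi > 0, phi <= 1.2,
            rejection_sigma >= 0, rejection_sigma <= 1)
  if (gamma_mode == "constant" && !is.finite(gamma_constant))
    stop("gamma_mode = 'constant' requires a finite gamma_constant")
  structure(list(name = name, vant_hoff_i = vant_hoff_i, phi = phi,
                 gamma_mode = gamma_mode, gamma_constant = gamma_constant,
                 rejection_sigma = rejection_sigma,
                 stokes_radius_nm = stokes_radius_nm),
            class = "osmolyte_species")
}

#' Default osmolyte registry for the model cytosols
#'
#' KCl is treated as an electrolyte (i = 2, phi = 0.90, so gamma = 1.8);
#' D-glucose as ideal (gamma = 1); L-glutamine through the calibrated
#' amino-acid factor. Reflection coefficients come from the known rejection
#' coefficients of the cellulose-triacetate forward-osmosis membrane:
#' 50-70\% for KCl (upper end adopted, see the methods vignette), 99\% for
#' D-Glc, ~100\% for L-Gln.
#'
#' @return Named list of \code{osmolyte_species}.
#' @export
default_species <- function() {
  list(
    "KCl" = osmolyte_species("KCl", vant_hoff_i = 2, phi = 0.90,
                             gamma_mode = "electrolyte",
                             rejection_sigma = 0.70,
                             stokes_radius_nm = 0.13),
    "D-Glc" = osmolyte_species("D-Glc", gamma_mode = "ideal",
                               rejection_sigma = 0.99,
                               stokes_radius_nm = 0.36),
    "L-Gln" = osmolyte_species("L-Gln", gamma_mode = "amino_acid",
                               rejection_sigma = 1.0,
                               stokes_radius_nm = 0.31)
  )
}

#' Non-ideality factor gamma for one species
#'
#' Maps the species' \code{gamma_mode} to its effective Van 't Hoff
#' correction: \code{ideal} gives exactly 1, \code{electrolyte} gives
#' \code{phi * i}, \code{amino_acid} returns the pluggable glutamine factor
#' from \code{params} (a calibrated constant by default; a closed-form
#' pK1/pK2/pH expression can be swapped in through
#' \code{params$gamma_gln}), and \code{constant} returns the stored value.
#'
#' @param species An \code{osmolyte_species} or the name of one in
#'   \code{default_species()}.
#' @param params An \code{osmo_params} object.
#' @return Dimensionless gamma.
#' @export
#' @examples
#' gamma_factor("KCl")   # 1.8
#' gamma_factor("D-Glc") # 1
gamma_factor <- function(species, params = osmotic_model_params()) {
  if (is.character(species)) {
    db <- default_species()
    if (!species %in% names(db))
      stop("unknown species: ", species)
    species <- db[[species]]
  }
  stopifnot(inherits(species, "osmolyte_species"),
            inherits(params, "osmo_params"))
  switch(species$gamma_mode,
    ideal       = 1,
    electrolyte = species$phi * species$vant_hoff_i,
    amino_acid  = params$gamma_gln,
    constant    = species$gamma_constant,
    stop("unknown gamma_mode: ", species$gamma_mode))
}
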