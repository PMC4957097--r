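#' Four-member supramolecular complex model
#'
#' One thermodynamic complex species of stoichiometry 1:1:1:1 over
#' (K+, Cl-, D-Glc, L-Gln); the geometric isomers proposed for the
#' potassium coordination are equally probable and are treated as a single
#' species. Association follows ideal mass action with activity =
#' concentration.
#'
#' @param K_assoc Association constant, (L/mol)^3, >= 0.
#' @param members Ordered member names.
#' @return Object of class \code{complex_model}.
#' @export
complex_model <- function(K_assoc,
                          members = c("K+", "Cl-", "D-Glc", "L-Gln")) {
  if (!is.finite(K_assoc) || K_assoc < 0)
    stop("K_assoc must be finite and >= 0")
  stopifnot(length(members) == 4)
  structure(list(members = members, K_assoc = K_assoc, n_members = 4L),
            class = "complex_model")
}

#' Member totals (mol/L) implied by a mixture
#'
#' KCl supplies K+ and Cl- at its molarity each; absent species get 0.
#'
#' @param mix A \code{mixture}.
#' @return Named numeric vector over (K+, Cl-, D-Glc, L-Gln).
#' @export
member_totals <- function(mix) {
  stopifnot(inherits(mix, "mixture"))
  m <- mix$species_molarity
  kcl <- if ("KCl" %in% names(m)) m[["KCl"]] else 0
  c("K+" = kcl, "Cl-" = kcl,
    "D-Glc" = if ("D-Glc" %in% names(m)) m[["D-Glc"]] else 0,
    "L-Gln" = if ("L-Gln" %in% names(m)) m[["L-Gln"]] else 0)
}

#' Solve the mass-action speciation of the complex
#'
#' Finds the association extent x in [0, min(member totals)] satisfying
#' x = K_assoc * prod(total_m - x). On that interval the left side is
#' increasing and the right side strictly decreasing, so the root exists
#' and is unique; it is bracketed by bisection to 1e-12 relative
#' tolerance.
#'
#' @param totals Named numeric vector of member totals, mol/L (or a
#'   \code{mixture}, in which case \code{\link{member_totals}} is applied).
#' @param model A \code{complex_model}.
#' @param params An \code{osmo_params} (for the effective-particle
#'   gamma weighting: phi per free ion, calibrated factor for L-Gln).
#' @return Object of class \code{speciation}: \code{free} (mol/L per
#'   member), \code{complex_concentration}, \code{fraction_associated}
#'   (bound members / total members), and
#'   \code{effective_particle_molarity} (gamma-weighted free particles + 1
#'   per complex; mol/L).
#' @export
#' @examples
#' sp <- speciate(c(`K+` = .25, `Cl-` = .25, `D-Glc` = .6, `L-Gln` = .15),
#'                complex_model(K_assoc = 5))
#' sp$fraction_associated
speciate <- function(totals, model, params = osmotic_model_params()) {
  if (inherits(totals, "mixture")) totals <- member_totals(totals)
  stopifnot(inherits(model, "complex_model"))
  if (any(!is.finite(totals)) || any(totals < 0))
    stop("totals must be finite and >= 0")
  totals <- totals[model$members]
  names(totals) <- model$members
  x <- solve_extent(unname(totals), model$K_assoc)
  free <- totals - x
  tot_members <- sum(totals)
  structure(list(
    totals = totals,
    free = free,
    complex_concentration = x,
    fraction_associated = if (tot_members > 0) 4 * x / tot_members else 0,
    effective_particle_molarity = sum(member_gammas(params) * free) + x
  ), class = "speciation")
}

# Bisection for x = K * prod(totals - x) on [0, min(totals)].
solve_extent <- function(totals, K, rel_tol = 1e-12) {
  if (!is.finite(K)) stop("non-finite K_assoc")
  hi <- min(totals)
  if (K == 0 || hi == 0) return(0)
  f <- function(x) x - K * prod(totals - x)
  lo <- 0
  # f(0) <= 0, f(hi) = hi > 0
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if ((hi - lo) <= rel_tol * max(hi, .Machine$double.eps)) break
  }
  (lo + hi) / 2
}

# gamma weights of the free members: each ion of the dissociated salt
# carries the osmotic coefficient phi, the sugar is ideal, glutamine uses
# the calibrated factor. Keeps K_assoc = 0 consistent with the mixture
# estimator.
member_gammas <- function(params = osmotic_model_params(),
                          species_db = default_species()) {
  kcl <- species_db[["KCl"]]
  c("K+" = kcl$phi, "Cl-" = kcl$phi,
    "D-Glc" = gamma_factor(species_db[["D-Glc"]], params),
    "L-Gln" = gamma_factor(species_db[["L-Gln"]], params))
}

#' Calibrate the association constant to a target association degree
#'
#' Monotone bisection on log10(K) such that
#' \code{speciate(mix)$fraction_associated} equals \code{target_degree}/100
#' within 1e-6 absolute. The degree cannot exceed the limiting-reagent
#' ceiling 4 * min(totals) / sum(totals) (reached as K -> Inf); targets at
#' or above the ceiling raise an error.
#'
#' @param mix A \code{mixture} containing all four members (i.e. KCl,
#'   D-Glc and L-Gln all present).
#' @param target_degree Target association degree, percent in [0, 100).
#' @param log10K_bracket Search bracket for log10(K_assoc).
#' @param tol Absolute tolerance on the fraction associated.
#' @return A \code{complex_model} with the calibrated \code{K_assoc}.
#' @export
#' @examples
#' m2 <- mixture_from_ratio("15:12:3", 1.5)
#' cm <- calibrate_K(m2, 18.0)
#' speciate(m2, cm)$fraction_associated  # 0.180
calibrate_K <- function(mix, target_degree,
                        log10K_bracket = c(-6, 12), tol = 1e-6) {
  if (!is.finite(target_degree) || target_degree < 0 || target_degree >= 100)
    stop("target_degree must be in [0, 100)")
  totals <- member_totals(mix)
  if (any(totals == 0))
    stop("mixture must contain all four complex members (KCl, D-Glc, L-Gln)")
  if (target_degree == 0) return(complex_model(K_assoc = 0))
  ceiling_pct <- 100 * 4 * min(totals) / sum(totals)
  if (target_degree >= ceiling_pct - 100 * tol)
    stop(sprintf(
      "target degree %.3g%% unreachable: limiting-reagent ceiling is %.3g%%",
      target_degree, ceiling_pct))
  target <- target_degree / 100
  frac <- function(lk)
    speciate(totals, complex_model(10^lk))$fraction_associated
  lo <- log10K_bracket[1]; hi <- log10K_bracket[2]
  if (frac(lo) > target) stop("bracket lower bound too high")
  if (frac(hi) < target)
    stop("target degree unreachable within log10K bracket")
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    fm <- frac(mid)
    if (abs(fm - target) < tol / 10) break
    if (fm > target) hi <- mid else lo <- mid
  }
  complex_model(K_assoc = 10^mid)
}

#' Effective osmotic potential of a speciated mixture
#'
#' Pi_eff = R T (gamma-weighted free particles + one particle per
#' complex). With K_assoc = 0 this equals
#' \code{\link{estimate_osmotic_potential}} exactly.
#'
#' @param spec A \code{speciation}.
#' @param params An \code{osmo_params}.
#' @return MPa.
#' @export
effective_osmotic_potential <- function(spec,
                                        params = osmotic_model_params()) {
  stopifnot(inherits(spec, "speciation"))
  spec$effective_particle_molarity * 1000 * params$R * params$T / 1e6
}

#' Effective osmotic potential along a dilution series
#'
#' Dilutes all totals by each factor, re-speciates, and reports the
#' effective potential. For an associating mixture the normalized product
#' Pi_eff(lambda) * lambda increases with lambda: complex disassembly on
#' dilution releases osmolytes and buffers the potential (the cooperative
#' effect).
#'
#' @param mix A \code{mixture}.
#' @param model A \code{complex_model}.
#' @param dilution_factors Numeric vector of factors >= 1.
#' @param params An \code{osmo_params}.
#' @return \code{data.frame} with columns \code{factor, complex_M,
#'   fraction_assoc, pi_eff_MPa}.
#' @export
dilution_curve <- function(mix, model, dilution_factors,
                           params = osmotic_model_params()) {
  if (any(!is.finite(dilution_factors)) || any(dilution_factors < 1))
    stop("dilution factors must be >= 1")
  totals <- member_totals(mix)
  rows <- lapply(dilution_factors, function(lam) {
    sp <- speciate(totals / lam, model, params)
    data.frame(factor = lam,
               complex_M = sp$complex_concentration,
               fraction_assoc = sp$fraction_associated,
               pi_eff_MPa = effective_osmotic_potential(sp, params))
  })
  do.call(rbind, rows)
}
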