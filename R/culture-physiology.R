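#' Henry-constant and acid-dissociation constants for fermentation gases
#'
#' Solubility constants at 25 degrees C (M/atm) with the acid dissociation
#' constants driving pH-dependent speciation of the acid gases. Values are
#' standard-compilation figures and fully user-overridable; an optional
#' van 't Hoff correction to another temperature uses tabulated solution
#' enthalpies (-d ln(H)/d(1/T), in K).
#'
#' @param temperature_C Temperature for the van 't Hoff correction; the
#'   default 25 returns the tabulated constants unchanged.
#' @return Named list per species (`CO2`, `H2`, `CH4`, `H2S`) with entries
#'   `hcp` (M/atm), `pka1`, `pka2` (NA where not applicable) and `dlnH_dinvT`.
#' @export
henry_constants <- function(temperature_C = 25) {
  constants <- list(
    CO2 = list(hcp = 3.3e-2, pka1 = 6.35, pka2 = 10.33, dlnH_dinvT = 2400),
    H2  = list(hcp = 7.8e-4, pka1 = NA_real_, pka2 = NA_real_, dlnH_dinvT = 500),
    CH4 = list(hcp = 1.4e-3, pka1 = NA_real_, pka2 = NA_real_, dlnH_dinvT = 1900),
    H2S = list(hcp = 0.1,    pka1 = 7.0,      pka2 = NA_real_, dlnH_dinvT = 2100)
  )
  if (temperature_C != 25) {
    t0 <- 298.15
    t1 <- temperature_C + 273.15
    for (sp in names(constants)) {
      constants[[sp]]$hcp <- constants[[sp]]$hcp *
        exp(constants[[sp]]$dlnH_dinvT * (1 / t1 - 1 / t0))
    }
  }
  constants
}

#' Integrate calorimeter heat flow into accumulated heat
#'
#' Trapezoidal integration of the heat-flow channel with unit conversion
#' (uW x h -> J, factor 3.6e-3), returning the full Q(t) curve.
#'
#' @param series Tibble with columns `time_h` (strictly increasing) and
#'   `heatflow_uW`, e.g. from [simulate_calorimetry_series()].
#' @return The input with an added `Q_J` column (accumulated heat).
#' @export
integrate_heat <- function(series) {
  stopifnot(all(c("time_h", "heatflow_uW") %in% names(series)),
            nrow(series) >= 2L)
  if (any(diff(series$time_h) <= 0)) {
    stop("time points must be strictly increasing", call. = FALSE)
  }
  q_uwh <- pracma::cumtrapz(series$time_h, series$heatflow_uW)[, 1L]
  series$Q_J <- q_uwh * 3.6e-3
  series
}

#' Biomass dry weight from accumulated heat
#'
#' Anaerobic fermentations release roughly 4000 J of heat per gram of dry
#' biomass formed; dry weight is the accumulated heat divided by that
#' yield.
#'
#' @param Q Accumulated heat in joules (scalar or vector, >= 0).
#' @param heat_yield Heat per gram of biomass (J/g, default 4000).
#' @param working_volume_L Culture volume for the volumetric estimate
#'   (default 2 mL).
#' @return Tibble `Q_J`, `dw_g`, `dw_g_per_L`.
#' @export
biomass_from_heat <- function(Q, heat_yield = 4000, working_volume_L = 2e-3) {
  if (heat_yield <= 0) stop("`heat_yield` must be > 0", call. = FALSE)
  if (any(Q < 0)) stop("`Q` must be >= 0", call. = FALSE)
  dw <- Q / heat_yield
  tibble::tibble(Q_J = Q, dw_g = dw, dw_g_per_L = dw / working_volume_L)
}

#' Dissolved gas concentration by Henry's law
#'
#' `c = Hcp*(pH) x p`, where the effective Henry constant of an acid gas
#' grows with pH through aqueous speciation: for CO2,
#' `Hcp* = Hcp (1 + Ka1/[H+] + Ka1 Ka2/[H+]^2)` (bicarbonate and
#' carbonate); for H2S analogously with its first dissociation only. H2 and
#' CH4 are pH-independent.
#'
#' @param species One of `"CO2"`, `"H2"`, `"CH4"`, `"H2S"` (vectorized).
#' @param p_atm Partial pressure in atm (>= 0).
#' @param pH pH of the medium, in [0, 14].
#' @param constants Constant set from [henry_constants()].
#' @return Tibble `species`, `p_atm`, `pH`, `hcp_eff_M_per_atm`, `conc_M`.
#' @export
dissolved_gas_concentration <- function(species, p_atm, pH,
                                        constants = henry_constants()) {
  n <- max(length(species), length(p_atm), length(pH))
  species <- rep_len(species, n)
  p_atm <- rep_len(p_atm, n)
  pH <- rep_len(pH, n)
  bad <- setdiff(unique(species), names(constants))
  if (length(bad) > 0L) {
    stop("unknown gas species: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(p_atm < 0)) stop("partial pressures must be >= 0", call. = FALSE)
  if (any(pH < 0 | pH > 14)) stop("pH must be in [0, 14]", call. = FALSE)

  h <- 10^(-pH)
  hcp_eff <- numeric(n)
  for (sp in unique(species)) {
    k <- constants[[sp]]
    i <- species == sp
    fac <- 1
    if (!is.na(k$pka1)) {
      ka1 <- 10^(-k$pka1)
      fac <- 1 + ka1 / h[i]
      if (!is.na(k$pka2)) {
        ka2 <- 10^(-k$pka2)
        fac <- fac + ka1 * ka2 / h[i]^2
      }
    }
    hcp_eff[i] <- k$hcp * fac
  }
  tibble::tibble(species = species, p_atm = p_atm, pH = pH,
                 hcp_eff_M_per_atm = hcp_eff, conc_M = hcp_eff * p_atm)
}

#' Normalize a metabolite concentration to culture dry weight
#'
#' mmol per gram dry weight: concentration (mM) times working volume (L)
#' divided by dry weight (g).
#'
#' @param conc_mM Concentration in mM (>= 0, vectorized).
#' @param dw_g Dry weight in grams.
#' @param working_volume_L Culture volume (default 2 mL).
#' @return Numeric vector, mmol/gDW. Entries with `dw_g = 0` are returned
#'   as `NA` with a warning (undefined, not infinite).
#' @export
normalize_to_dry_weight <- function(conc_mM, dw_g, working_volume_L = 2e-3) {
  if (any(conc_mM < 0)) stop("concentrations must be >= 0", call. = FALSE)
  if (any(dw_g < 0)) stop("dry weight must be >= 0", call. = FALSE)
  n <- max(length(conc_mM), length(dw_g))
  conc_mM <- rep_len(conc_mM, n)
  dw_g <- rep_len(dw_g, n)
  out <- conc_mM * working_volume_L / dw_g
  if (any(dw_g == 0)) {
    warning("zero dry weight: normalized value undefined, returned NA",
            call. = FALSE)
    out[dw_g == 0] <- NA_real_
  }
  out
}

#' Stoichiometric upper bound on propionate from mucin proline
#'
#' Mucin protein backbones are proline-rich; released proline can be
#' fermented via glutamate, GABA and succinate to propionate at up to one
#' mole per mole. The bound is
#' `1000 x (protein g/L / mean residue mass) x proline mole fraction x yield`,
#' in mM.
#'
#' @param protein_g_per_L Protein-equivalent mucin concentration (g/L).
#' @param proline_mole_fraction Mole fraction of proline among residues,
#'   in (0, 1].
#' @param mean_residue_mass Mean residue mass (g/mol, default 105 — typical
#'   for a Pro/Thr/Ser-rich backbone).
#' @param yield_mol_per_mol Moles propionate per mole proline (default 1,
#'   the Pro -> Glu -> GABA -> succinate -> propionate route).
#' @return Upper-bound propionate concentration in mM.
#' @examples
#' mucin_propionate_bound(0.5, 0.10)  # ~0.48 mM, i.e. 0.5 mM to one decimal
#' @export
mucin_propionate_bound <- function(protein_g_per_L, proline_mole_fraction,
                                   mean_residue_mass = 105,
                                   yield_mol_per_mol = 1) {
  if (protein_g_per_L <= 0 || mean_residue_mass <= 0 ||
      yield_mol_per_mol <= 0) {
    stop("all inputs must be > 0", call. = FALSE)
  }
  if (proline_mole_fraction <= 0 || proline_mole_fraction > 1) {
    stop("`proline_mole_fraction` must be in (0, 1]", call. = FALSE)
  }
  1000 * (protein_g_per_L / mean_residue_mass) * proline_mole_fraction *
    yield_mol_per_mol
}
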