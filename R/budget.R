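#' SST regime classification
#'
#' Four sea-surface-temperature regimes stand in for season in the
#' subtropical study region: below 24, 24-26, 26-28, and above 28 deg C.
#' Bins are half-open with the lower edge inclusive: (-Inf,24), [24,26),
#' [26,28), [28,Inf).
#'
#' @param sst SST value(s), deg C; NA/NaN is an error.
#' @return factor with levels `"SST<24"`, `"24-26"`, `"26-28"`, `"SST>28"`.
#' @export
classify_sst_regime <- function(sst) {
  if (any(!is.finite(sst))) stop("classify_sst_regime: non-finite SST")
  cut(sst, breaks = c(-Inf, 24, 26, 28, Inf), right = FALSE,
      labels = sst_regime_levels())
}

#' @rdname classify_sst_regime
#' @export
sst_regime_levels <- function() c("SST<24", "24-26", "26-28", "SST>28")

#' Regime climatology from a monthly SST series
#'
#' Counts the months of a 12-value monthly-mean SST series falling in each
#' regime and converts month counts to days at a uniform 365/12 days per
#' month, so days always sum to 365.
#'
#' @param monthly_sst numeric vector of exactly 12 monthly mean SSTs, deg C.
#' @return list of class `"regime_climatology"`: `months` and `days`,
#'   both named by regime.
#' @export
regime_days <- function(monthly_sst) {
  if (length(monthly_sst) != 12L)
    stop("regime_days: need exactly 12 monthly values")
  reg <- classify_sst_regime(monthly_sst)
  months <- table(factor(reg, levels = sst_regime_levels()))
  months <- stats::setNames(as.numeric(months), names(months))
  structure(list(months = months, days = months * 365 / 12),
            class = "regime_climatology")
}

#' @export
print.regime_climatology <- function(x, ...) {
  cat("<regime_climatology> months:",
      paste(names(x$months), x$months, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Atmospheric-side forcing rates
#'
#' Scalar atmospheric and marine-fixation inputs to the annual budget:
#' per-regime monthly air-sea CO2 flux (positive into the ocean), and
#' daily rates of marine N2 fixation, atmospheric bioavailable-N
#' deposition, and atmospheric P deposition, each with a 95 % CI.
#' Defaults are observed subtropical North Pacific climatological rates.
#'
#' @param co2_flux_monthly named numeric, mol C m^-2 month^-1 per regime
#'   (may be negative in the warm outgassing regime).
#' @param n2_fixation [uncertain()], mol N m^-2 d^-1.
#' @param n_deposition [uncertain()], mol N m^-2 d^-1.
#' @param p_deposition [uncertain()], mol P m^-2 d^-1.
#' @return list of class `"atmospheric_forcing"`.
#' @export
atmospheric_forcing <- function(
    co2_flux_monthly = c("SST<24" = 0.10, "24-26" = 0.07,
                         "26-28" = 0.04, "SST>28" = -0.01),
    n2_fixation = uncertain(2.2e-4, 6.4e-5),
    n_deposition = uncertain(2.7e-5, 5.7e-6),
    p_deposition = uncertain(8.4e-8, 5.4e-8)) {
  n2_fixation <- as_uncertain(n2_fixation)
  n_deposition <- as_uncertain(n_deposition)
  p_deposition <- as_uncertain(p_deposition)
  for (r in list(n2_fixation, n_deposition, p_deposition)) {
    if (r$m < 0) stop("atmospheric_forcing: rates must be >= 0")
  }
  if (!all(sst_regime_levels() %in% names(co2_flux_monthly)))
    stop("atmospheric_forcing: co2_flux_monthly must name all four regimes")
  structure(list(co2_flux_monthly = co2_flux_monthly,
                 n2_fixation = n2_fixation,
                 n_deposition = n_deposition,
                 p_deposition = p_deposition),
            class = "atmospheric_forcing")
}

#' Microbial C:N and C:P stoichiometry ranges
#'
#' Molar elemental ratio ranges of subtropical picoplankton and
#' nanoplankton used to convert the carbon NCP requirement into N and P
#' microbial demand: C:N 6-11 and C:P 107-243 by default.
#'
#' @param cn,cp length-2 numeric intervals (lower, upper), > 0.
#' @return list of class `"stoichiometry_range"`.
#' @export
stoichiometry_range <- function(cn = c(6, 11), cp = c(107, 243)) {
  stopifnot(length(cn) == 2L, length(cp) == 2L)
  if (any(c(cn, cp) <= 0) || cn[1] > cn[2] || cp[1] > cp[2])
    stop("stoichiometry_range: intervals must be positive and ordered")
  structure(list(cn = cn, cp = cp), class = "stoichiometry_range")
}

#' Annual upward influx from regime layer-mean fluxes
#'
#' Scales each regime's mean daily 100-200 m upward flux by the number of
#' days that regime occupies in the climatological year, and sums over
#' regimes. CIs scale with the days inside each regime and combine in
#' quadrature across regimes. Regimes with days but no flux data
#' contribute zero and raise a warning.
#'
#' @param regime_flux named list mapping regime label to an [uncertain()]
#'   mean daily flux (mol m^-2 d^-1); omit regimes without data.
#' @param clim a [regime_climatology()][regime_days()].
#' @return [uncertain()], mol m^-2 y^-1.
#' @export
annual_upward_influx <- function(regime_flux, clim) {
  total <- uncertain(0, 0)
  any_data <- FALSE
  for (reg in sst_regime_levels()) {
    d <- clim$days[[reg]]
    if (d == 0) next
    uv <- regime_flux[[reg]]
    if (is.null(uv) || is.na(as_uncertain(uv)$m)) {
      warning("annual_upward_influx: regime '", reg,
              "' has ", round(d, 1), " days but no flux data; contributes 0")
      next
    }
    any_data <- TRUE
    total <- propagate("sum", total, uv_scale(as_uncertain(uv), d))
  }
  if (!any_data) stop("annual_upward_influx: no regime has flux data")
  total
}

#' Annual atmospheric-side influx for one element
#'
#' C: sum over regimes of monthly air-sea CO2 flux times months in
#' regime. N: (N2 fixation + N deposition) x 365. P: P deposition x 365.
#' CIs propagate by exact scaling and quadrature sums.
#'
#' @param element `"C"`, `"N"` or `"P"`.
#' @param forcing an [atmospheric_forcing()].
#' @param clim a regime climatology from [regime_days()] (required for C).
#' @return [uncertain()], mol m^-2 y^-1.
#' @export
annual_atmospheric_influx <- function(element = c("C", "N", "P"),
                                      forcing, clim = NULL) {
  element <- match.arg(element)
  if (element == "C") {
    if (is.null(clim)) stop("annual_atmospheric_influx: C needs a climatology")
    total <- sum(forcing$co2_flux_monthly[sst_regime_levels()] *
                   clim$months[sst_regime_levels()])
    return(uncertain(total, 0))
  }
  if (element == "N") {
    daily <- propagate("sum", forcing$n2_fixation, forcing$n_deposition)
    return(uv_scale(daily, 365))
  }
  uv_scale(forcing$p_deposition, 365)
}

#' NCP requirement: budget closure for one element
#'
#' Under annual steady state the net community production requirement of
#' element Y equals the total influx: NCP-Y = Fup_Y + Fat_Y. The sum's CI
#' combines the two half-widths in quadrature. Closure is exact by
#' construction: `ncp$m - fup$m - fat$m == 0`.
#'
#' @param fup annual upward influx, [uncertain()], mol m^-2 y^-1.
#' @param fat annual atmospheric-side influx, same units.
#' @return [uncertain()], mol m^-2 y^-1.
#' @export
ncp_requirement <- function(fup, fat) propagate("sum", fup, fat)

#' C:N:P ratio normalized to P = 1
#'
#' Divides the C and N values by the P value, propagating CIs through each
#' quotient; the P component is 1 by construction and the ratio is
#' invariant under common rescaling of all three inputs.
#'
#' @param c_val,n_val,p_val [uncertain()] values in common units.
#' @param quotient_form passed to [propagate()].
#' @return list: `c`, `n` ([uncertain()] quotients), `p` (exactly 1).
#' @export
stoichiometric_ratio <- function(c_val, n_val, p_val,
                                 quotient_form = "printed") {
  p_val <- as_uncertain(p_val)
  if (p_val$m <= 0) stop("stoichiometric_ratio: P value must be > 0")
  list(c = propagate("quotient", c_val, p_val, quotient_form = quotient_form),
       n = propagate("quotient", n_val, p_val, quotient_form = quotient_form),
       p = 1)
}

#' Microbial N and P demand implied by the carbon NCP
#'
#' Converts the annual carbon requirement into the N and P the microbial
#' community must acquire, via the molar stoichiometry ranges: MD-N =
#' NCP-C / C:N and MD-P = NCP-C / C:P, each an interval (dividing by the
#' upper ratio gives the lower demand bound). Full-precision bounds are
#' returned alongside 2-significant-figure reporting values.
#'
#' @param ncp_c annual carbon NCP requirement, mol C m^-2 y^-1 (mean of an
#'   [uncertain()] or a bare number), > 0.
#' @param stoich a [stoichiometry_range()].
#' @return list: `md_n`, `md_p` (length-2 intervals, mol m^-2 y^-1),
#'   `md_n_2sf`, `md_p_2sf`.
#' @export
microbial_demand <- function(ncp_c, stoich = stoichiometry_range()) {
  m <- if (inherits(ncp_c, "uncertain")) ncp_c$m else as.numeric(ncp_c)
  if (m <= 0) stop("microbial_demand: NCP-C must be > 0")
  md_n <- c(m / stoich$cn[2], m / stoich$cn[1])
  md_p <- c(m / stoich$cp[2], m / stoich$cp[1])
  list(md_n = md_n, md_p = md_p,
       md_n_2sf = signif2(md_n), md_p_2sf = signif2(md_p))
}

#' Recycling factor: microbial demand over in-situ NCP
#'
#' RF = MD / NCP (dimensionless): how many times an element must be
#' recycled within the euphotic zone for total supply plus reuse to meet
#' microbial demand. An interval because MD is one.
#'
#' @param md length-2 demand interval, mol m^-2 y^-1.
#' @param ncp in-situ NCP of the same element ([uncertain()] or number), > 0.
#' @return list: `rf` (full precision interval), `rf_2sf`.
#' @export
recycling_factor <- function(md, ncp) {
  m <- if (inherits(ncp, "uncertain")) ncp$m else as.numeric(ncp)
  if (m <= 0) stop("recycling_factor: NCP must be > 0")
  rf <- sort(md / m)
  list(rf = rf, rf_2sf = signif2(rf))
}

#' Assemble the full annual element budget
#'
#' Runs the closure chain for C, N and P: annual upward influxes from the
#' per-regime 100-200 m layer fluxes, atmospheric-side influxes from the
#' forcing, NCP requirements, NCP and upward stoichiometric ratios,
#' microbial demand from NCP-C, and N and P recycling factors.
#'
#' @param regime_flux named list: per element (`dic`, `nn`, `po4`) a named
#'   list of regime [uncertain()] mean daily fluxes, mol m^-2 d^-1.
#' @param clim a regime climatology from [regime_days()].
#' @param forcing an [atmospheric_forcing()].
#' @param stoich a [stoichiometry_range()].
#' @return list of class `"budget_result"` with per-element `fup`, `fat`,
#'   `ncp`, plus `ncp_ratio`, `fup_ratio`, `md`, `rf_n`, `rf_p`.
#' @export
compute_budget <- function(regime_flux, clim, forcing = atmospheric_forcing(),
                           stoich = stoichiometry_range()) {
  elements <- c(C = "dic", N = "nn", P = "po4")
  fup <- fat <- ncp <- list()
  for (el in names(elements)) {
    fup[[el]] <- annual_upward_influx(regime_flux[[elements[[el]]]], clim)
    fat[[el]] <- annual_atmospheric_influx(el, forcing, clim)
    ncp[[el]] <- ncp_requirement(fup[[el]], fat[[el]])
  }
  md <- microbial_demand(ncp$C, stoich)
  structure(list(
    fup = fup, fat = fat, ncp = ncp,
    ncp_ratio = stoichiometric_ratio(ncp$C, ncp$N, ncp$P),
    fup_ratio = stoichiometric_ratio(fup$C, fup$N, fup$P),
    md = md,
    rf_n = recycling_factor(md$md_n, ncp$N),
    rf_p = recycling_factor(md$md_p, ncp$P)),
    class = "budget_result")
}

#' @export
print.budget_result <- function(x, ...) {
  cat("<budget_result> annual element budget (mol m-2 y-1, 2 s.f.)\n")
  for (el in c("C", "N", "P")) {
    cat(sprintf("  %s: Fup %s + Fat %s = NCP %s\n", el,
                format(x$fup[[el]]), format(x$fat[[el]]),
                format(x$ncp[[el]])))
  }
  cat(sprintf("  NCP C:N:P = %.0f:%.0f:1,  upward = %.0f:%.0f:1\n",
              x$ncp_ratio$c$m, x$ncp_ratio$n$m,
              x$fup_ratio$c$m, x$fup_ratio$n$m))
  cat(sprintf("  MD-N [%g, %g], MD-P [%g, %g]\n",
              x$md$md_n_2sf[1], x$md$md_n_2sf[2],
              x$md$md_p_2sf[1], x$md$md_p_2sf[2]))
  cat(sprintf("  RF-N [%g, %g], RF-P [%g, %g]\n",
              x$rf_n$rf_2sf[1], x$rf_n$rf_2sf[2],
              x$rf_p$rf_2sf[1], x$rf_p$rf_2sf[2]))
  invisible(x)
}
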