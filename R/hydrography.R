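#' A single station visit: depth-resolved hydrography and chemistry
#'
#' Bundles one bottle/CTD cast: depths (m, positive downward, strictly
#' increasing), potential temperature (deg C), practical salinity,
#' optionally PAR, and constituent concentrations in mol m^-3. Typical
#' constituents are `dic`, `nn` (nitrate + nitrite), `po4`, `dop`, `tdp`,
#' `tpp`. SST is taken as the 10-m temperature when not given.
#'
#' @param station station label.
#' @param date cast date (`Date` or coercible).
#' @param depth numeric depths, m, strictly increasing, >= 0.
#' @param temperature potential temperature, deg C, same length as depth.
#' @param salinity practical salinity, > 0, same length as depth.
#' @param par optional photon flux profile (any consistent units).
#' @param conc named list of concentration vectors, mol m^-3.
#' @param sst optional sea-surface temperature, deg C; defaults to the
#'   temperature interpolated at 10 m.
#' @return object of class `"cast"`.
#' @export
cast <- function(station, date, depth, temperature, salinity,
                 par = NULL, conc = list(), sst = NULL) {
  depth <- as.numeric(depth)
  if (length(depth) < 1L || any(diff(depth) <= 0))
    stop("cast: depths must be strictly increasing")
  if (any(depth < 0)) stop("cast: depths must be >= 0")
  stopifnot(length(temperature) == length(depth),
            length(salinity) == length(depth))
  if (any(salinity <= 0, na.rm = TRUE)) stop("cast: salinity must be > 0")
  if (!is.null(par)) stopifnot(length(par) == length(depth))
  for (nm in names(conc)) {
    if (length(conc[[nm]]) != length(depth))
      stop("cast: concentration '", nm, "' length mismatch")
  }
  if (is.null(sst)) {
    sst <- if (max(depth) >= 10 && min(depth) <= 10)
      stats::approx(depth, temperature, xout = 10)$y else temperature[1]
  }
  structure(list(station = station, date = as.Date(date), sst = sst,
                 depth = depth, temperature = as.numeric(temperature),
                 salinity = as.numeric(salinity),
                 par = if (is.null(par)) NULL else as.numeric(par),
                 conc = conc),
            class = "cast")
}

#' @export
print.cast <- function(x, ...) {
  cat(sprintf("<cast> station %s, %s, SST %.2f degC, %d depths (%g-%g m)\n",
              x$station, format(x$date), x$sst, length(x$depth),
              min(x$depth), max(x$depth)))
  cat("  constituents:", paste(names(x$conc), collapse = ", "), "\n")
  invisible(x)
}

#' Mixed layer depth by the 0.2 degC potential-temperature criterion
#'
#' The MLD is the shallowest depth at which potential temperature falls
#' 0.2 degC below its 10-m value, with linear interpolation in theta-z
#' between sampled levels. If the criterion is never met the deepest
#' sampled depth is returned with `mld_not_reached = TRUE`.
#'
#' @param cast a [cast()].
#' @param delta_theta threshold drop below the 10-m temperature, deg C.
#' @return list: `mld` (m), `mld_not_reached` (flag).
#' @export
compute_mld <- function(cast, delta_theta = 0.2) {
  z <- cast$depth; th <- cast$temperature
  if (max(z) < 10) stop("compute_mld: no data at or below 10 m")
  th10 <- stats::approx(z, th, xout = 10)$y
  target <- th10 - delta_theta
  keep <- z >= 10
  z <- z[keep]; th <- th[keep]
  below <- which(th <= target)
  if (length(below) == 0L)
    return(list(mld = max(cast$depth), mld_not_reached = TRUE))
  i <- below[1]
  if (th[i] == target || i == 1L)
    return(list(mld = z[i], mld_not_reached = FALSE))
  # linear crossing between levels i-1 and i
  f <- (th[i - 1] - target) / (th[i - 1] - th[i])
  list(mld = z[i - 1] + f * (z[i] - z[i - 1]), mld_not_reached = FALSE)
}

#' Euphotic zone depth: 1 % of surface PAR
#'
#' EZD is the shallowest depth where PAR drops to 1 % of its surface
#' (shallowest-sample) value. Because PAR decays approximately
#' exponentially, interpolation between samples is log-linear in PAR.
#'
#' @param cast a [cast()] with a `par` profile.
#' @param fraction light fraction defining the euphotic floor (default 0.01).
#' @return list: `ezd` (m), `ezd_not_reached` (flag).
#' @export
compute_ezd <- function(cast, fraction = 0.01) {
  if (is.null(cast$par)) stop("compute_ezd: cast has no PAR profile")
  z <- cast$depth; par <- cast$par
  keep <- !is.na(par)
  z <- z[keep]; par <- par[keep]
  if (length(z) < 1L || par[1] <= 0)
    stop("compute_ezd: nonpositive or missing surface PAR")
  target <- fraction * par[1]
  below <- which(par <= target)
  if (length(below) == 0L)
    return(list(ezd = max(cast$depth), ezd_not_reached = TRUE))
  i <- below[1]
  if (par[i] == target || i == 1L)
    return(list(ezd = z[i], ezd_not_reached = FALSE))
  lp <- log(par)
  f <- (lp[i - 1] - log(target)) / (lp[i - 1] - lp[i])
  list(ezd = z[i - 1] + f * (z[i] - z[i - 1]), ezd_not_reached = FALSE)
}

#' Configuration for normalization and detection-limit handling
#'
#' @param reference_salinity practical salinity used to normalize
#'   concentrations for evaporation/precipitation (default 34.91).
#' @param detection_limits named vector, nM: concentrations at or below
#'   which a value counts as below detection (N+N 3, PO4 3).
#' @param detection_substitution named vector, nM: value substituted for
#'   below-detection measurements (N+N 5, PO4 3).
#' @return list of class `"normalization_config"`.
#' @export
normalization_config <- function(reference_salinity = 34.91,
                                 detection_limits = c(nn = 3, po4 = 3),
                                 detection_substitution = c(nn = 5, po4 = 3)) {
  if (reference_salinity <= 0) stop("reference_salinity must be > 0")
  structure(list(reference_salinity = reference_salinity,
                 detection_limits = detection_limits,
                 detection_substitution = detection_substitution),
            class = "normalization_config")
}

#' Substitute below-detection nutrient values
#'
#' Nanomolar analyses cannot resolve concentrations below their detection
#' limits; values at or below the limit are replaced by fixed nominal
#' values (N+N -> 5 nM, PO4 -> 3 nM by default) before fluxes, inventories
#' and ratios are computed. The operation is idempotent.
#'
#' @param cast a [cast()] with concentrations in mol m^-3.
#' @param config a [normalization_config()].
#' @return the cast with substituted concentrations; the number of
#'   substitutions per constituent is attached as attribute
#'   `"n_substituted"`.
#' @export
substitute_below_detection <- function(cast, config = normalization_config()) {
  n_sub <- integer(0)
  for (nm in names(config$detection_limits)) {
    if (is.null(cast$conc[[nm]])) next
    limit <- config$detection_limits[[nm]] * 1e-6      # nM -> mol m^-3
    subst <- config$detection_substitution[[nm]] * 1e-6
    x <- cast$conc[[nm]]
    low <- !is.na(x) & x < limit
    x[low] <- subst
    cast$conc[[nm]] <- x
    n_sub[nm] <- sum(low)
  }
  attr(cast, "n_substituted") <- n_sub
  cast
}

#' Normalize a concentration to a reference salinity
#'
#' Removes the dilution/concentration effect of precipitation and
#' evaporation by scaling with reference salinity over observed salinity:
#' `x * s_ref / s`. Identity at `s == s_ref`; linear in `x`.
#'
#' @param x concentration(s), mol m^-3.
#' @param s observed salinity(ies), > 0.
#' @param config a [normalization_config()] providing `reference_salinity`.
#' @return normalized concentration(s).
#' @export
normalize_salinity <- function(x, s, config = normalization_config()) {
  if (any(s <= 0, na.rm = TRUE)) stop("normalize_salinity: salinity must be > 0")
  x * config$reference_salinity / s
}

#' Seawater density at atmospheric pressure (EOS-80)
#'
#' One-atmosphere International Equation of State of Seawater (Millero &
#' Poisson 1981): density as a polynomial in temperature and practical
#' salinity at 0 dbar. With potential temperature as input this is the
#' surface-referenced potential density.
#'
#' @param salinity practical salinity.
#' @param temperature (potential) temperature, deg C.
#' @return density, kg m^-3.
#' @export
seawater_density <- function(salinity, temperature) {
  t <- temperature; s <- salinity
  rho_w <- 999.842594 + 6.793952e-2 * t - 9.095290e-3 * t^2 +
    1.001685e-4 * t^3 - 1.120083e-6 * t^4 + 6.536332e-9 * t^5
  a <- 0.824493 - 4.0899e-3 * t + 7.6438e-5 * t^2 -
    8.2467e-7 * t^3 + 5.3875e-9 * t^4
  b <- -5.72466e-3 + 1.0227e-4 * t - 1.6546e-6 * t^2
  c0 <- 4.8314e-4
  rho_w + a * s + b * s^1.5 + c0 * s^2
}

#' Squared buoyancy frequency from a potential-density profile
#'
#' N^2 = (g / rho0) * d(rho_theta)/dz with depth z positive downward, by
#' centered differences on a profile already interpolated to a regular
#' grid (one-sided at the ends).
#'
#' @param depth depths, m, regularly spaced, increasing.
#' @param rho potential density, kg m^-3, same length.
#' @param g gravitational acceleration, m s^-2.
#' @param rho0 reference density, kg m^-3.
#' @return N^2, s^-2, same length as `depth`.
#' @export
n_sq_from_density <- function(depth, rho, g = 9.81, rho0 = 1025) {
  if (length(depth) < 2L) stop("n_sq_from_density: need >= 2 levels")
  n <- length(depth)
  drho <- numeric(n)
  drho[1] <- (rho[2] - rho[1]) / (depth[2] - depth[1])
  drho[n] <- (rho[n] - rho[n - 1]) / (depth[n] - depth[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    drho[i] <- (rho[i + 1] - rho[i - 1]) / (depth[i + 1] - depth[i - 1])
  }
  (g / rho0) * drho
}

#' Buoyancy frequency squared on a 5-m grid from a cast
#'
#' Interpolates temperature and salinity to a regular grid (default 5 m)
#' between the shallowest and deepest samples, evaluates surface-referenced
#' potential density via [seawater_density()], and differentiates by
#' centered differences.
#'
#' @param cast a [cast()] with T and S at >= 2 depths.
#' @param dz grid spacing, m.
#' @return data.frame with `depth` (m) and `n_sq` (s^-2).
#' @export
buoyancy_frequency_sq <- function(cast, dz = 5) {
  z <- cast$depth
  if (length(z) < 2L) stop("buoyancy_frequency_sq: need >= 2 levels")
  grid <- seq(ceiling(min(z) / dz) * dz, floor(max(z) / dz) * dz, by = dz)
  tg <- stats::approx(z, cast$temperature, xout = grid)$y
  sg <- stats::approx(z, cast$salinity, xout = grid)$y
  rho <- seawater_density(sg, tg)
  data.frame(depth = grid, n_sq = n_sq_from_density(grid, rho))
}

#' Trapezoidal depth integration of a profile
#'
#' Water-column inventory of a constituent over `[z0, z1]` by the
#' trapezoidal rule on the piecewise-linear interpolant of the sampled
#' profile. Endpoints inside the sampled range are obtained by linear
#' interpolation; endpoints outside it use nearest-sample (constant)
#' extension.
#'
#' @param depth sampled depths, m, increasing.
#' @param values concentration at each depth, mol m^-3.
#' @param z0,z1 integration bounds, m, `z0 < z1`.
#' @return inventory, mol m^-2.
#' @export
depth_integrate <- function(depth, values, z0, z1) {
  keep <- !is.na(values)
  depth <- depth[keep]; values <- values[keep]
  if (length(depth) == 0L) stop("depth_integrate: empty profile")
  if (z0 >= z1) stop("depth_integrate: need z0 < z1")
  at <- function(z) {
    if (z <= depth[1]) return(values[1])
    if (z >= depth[length(depth)]) return(values[length(values)])
    stats::approx(depth, values, xout = z)$y
  }
  inner <- depth[depth > z0 & depth < z1]
  zz <- c(z0, inner, z1)
  vv <- c(at(z0), values[depth > z0 & depth < z1], at(z1))
  sum(diff(zz) * (utils::head(vv, -1) + utils::tail(vv, -1)) / 2)
}

#' Inventory difference between two SST regimes
#'
#' Mean inventory in regime `a` minus mean inventory in regime `b`
#' (e.g. winter-summer seasonal drawdown), with 95 % CIs propagated in
#' quadrature through the difference.
#'
#' @param inventories numeric per-cast inventories, mol m^-2.
#' @param regimes regime label per cast (see [classify_sst_regime()]).
#' @param regime_a,regime_b labels to difference (`a - b`).
#' @return [uncertain()], mol m^-2.
#' @export
regime_inventory_difference <- function(inventories, regimes,
                                        regime_a, regime_b) {
  ia <- inventories[regimes == regime_a]
  ib <- inventories[regimes == regime_b]
  if (length(ia) < 2L || length(ib) < 2L)
    stop("regime_inventory_difference: need >= 2 casts per regime")
  propagate("difference", mean_ci(ia), mean_ci(ib))
}
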