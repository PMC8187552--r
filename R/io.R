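#' Write a cruise dataset to the pipeline's CSV formats
#'
#' `casts.csv` holds one row per bottle depth with columns station, date,
#' depth_m, temp_C, sal, par, dic_mol_m3, nn_nM, po4_nM, dop_nM, tdp_nM,
#' tpp_nM (nutrients in nM, DIC in mol m^-3, matching shipboard
#' reporting conventions). `turbulence.csv` holds station, date, depth_m,
#' epsilon_W_kg, n_sq_s2 on the 5-m grid. `forcing.yaml` carries the
#' atmospheric-side rates with their CIs.
#'
#' @param data a `cruise_dataset` from [generate_cruise_dataset()].
#' @param dir output directory (created if needed).
#' @param forcing optional [atmospheric_forcing()] to write alongside.
#' @return invisibly, the paths written.
#' @export
write_cruise_csv <- function(data, dir, forcing = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cast_rows <- lapply(data$casts, function(cs) {
    data.frame(station = cs$station, date = format(cs$date),
               depth_m = cs$depth, temp_C = cs$temperature,
               sal = cs$salinity,
               par = if (is.null(cs$par)) NA_real_ else cs$par,
               dic_mol_m3 = cs$conc$dic,
               nn_nM = cs$conc$nn / 1e-6, po4_nM = cs$conc$po4 / 1e-6,
               dop_nM = cs$conc$dop / 1e-6, tdp_nM = cs$conc$tdp / 1e-6,
               tpp_nM = cs$conc$tpp / 1e-6)
  })
  casts_path <- file.path(dir, "casts.csv")
  utils::write.csv(do.call(rbind, cast_rows), casts_path, row.names = FALSE)

  turb_rows <- Map(function(cs, tb) {
    data.frame(station = cs$station, date = format(cs$date),
               depth_m = tb$depth, epsilon_W_kg = tb$epsilon,
               n_sq_s2 = tb$n_sq)
  }, data$casts, data$turbulence)
  turb_path <- file.path(dir, "turbulence.csv")
  utils::write.csv(do.call(rbind, turb_rows), turb_path, row.names = FALSE)

  paths <- c(casts = casts_path, turbulence = turb_path)
  if (!is.null(forcing)) {
    forcing_path <- file.path(dir, "forcing.yaml")
    yaml::write_yaml(list(
      co2_flux_monthly = as.list(forcing$co2_flux_monthly),
      n2_fixation = list(m = forcing$n2_fixation$m, e = forcing$n2_fixation$e),
      n_deposition = list(m = forcing$n_deposition$m,
                          e = forcing$n_deposition$e),
      p_deposition = list(m = forcing$p_deposition$m,
                          e = forcing$p_deposition$e)),
      forcing_path)
    paths["forcing"] <- forcing_path
  }
  invisible(paths)
}

#' Read casts from the pipeline CSV format
#'
#' Nutrient columns arrive in nM and are converted to mol m^-3 on load
#' (1 nM = 1e-6 mol m^-3); the conversion is logged once per file.
#'
#' @param path path to a `casts.csv`.
#' @param quiet suppress the unit-conversion message.
#' @return list of [cast()] objects, one per station-date.
#' @export
read_casts_csv <- function(path, quiet = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!quiet)
    message("read_casts_csv: converting nn/po4/dop/tdp/tpp from nM to mol m-3 (x 1e-6)")
  key <- interaction(df$station, df$date, drop = TRUE)
  lapply(split(df, key), function(d) {
    d <- d[order(d$depth_m), ]
    cast(station = d$station[1], date = d$date[1], depth = d$depth_m,
         temperature = d$temp_C, salinity = d$sal,
         par = if (all(is.na(d$par))) NULL else d$par,
         conc = list(dic = d$dic_mol_m3, nn = d$nn_nM * 1e-6,
                     po4 = d$po4_nM * 1e-6, dop = d$dop_nM * 1e-6,
                     tdp = d$tdp_nM * 1e-6, tpp = d$tpp_nM * 1e-6))
  })
}

#' Read turbulence profiles from the pipeline CSV format
#'
#' @param path path to a `turbulence.csv` (station, date, depth_m,
#'   epsilon_W_kg, n_sq_s2).
#' @return named list of [turbulence_profile()] keyed `station.date`.
#' @export
read_turbulence_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  key <- interaction(df$station, df$date, drop = TRUE)
  lapply(split(df, key), function(d) {
    d <- d[order(d$depth_m), ]
    turbulence_profile(d$depth_m, d$epsilon_W_kg, d$n_sq_s2)
  })
}

#' Read atmospheric forcing from YAML
#'
#' @param path path to a `forcing.yaml` as written by [write_cruise_csv()].
#' @return an [atmospheric_forcing()].
#' @export
read_forcing_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  atmospheric_forcing(
    co2_flux_monthly = unlist(y$co2_flux_monthly),
    n2_fixation = uncertain(y$n2_fixation$m, y$n2_fixation$e),
    n_deposition = uncertain(y$n_deposition$m, y$n_deposition$e),
    p_deposition = uncertain(y$p_deposition$m, y$p_deposition$e))
}
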