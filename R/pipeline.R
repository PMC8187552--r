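#' Run the full annual C-N-P budget pipeline
#'
#' Orchestrates the whole chain: casts -> detection-limit substitution ->
#' MLD -> Osborn diffusivity and diffusive flux profiles -> 100-200 m
#' layer means -> SST-regime climatology -> annual upward and atmospheric
#' influxes -> NCP requirements, stoichiometric ratios, microbial demand
#' and recycling factors -> salinity-normalized seasonal DIC drawdown and
#' regime hypothesis tests.
#'
#' @param config a [scenario_config()] (synthetic run), or the path to a
#'   YAML file with either a `scenario:` block of [scenario_config()]
#'   parameters or an `inputs:` block naming `casts` / `turbulence` /
#'   `forcing` files and a 12-value `monthly_sst` list.
#' @param forcing an [atmospheric_forcing()]; defaults to
#'   [generate_forcing()] unless the config supplies one.
#' @param report_path optional path; when given, the report is written as
#'   JSON (deterministic for a fixed seed).
#' @return list of class `"budget_report"`: `budget` (a
#'   [compute_budget()] result), `regime_flux`, `climatology`,
#'   `drawdown_ndic` ([uncertain()], mol m^-2), `ndic_kw`
#'   (a [kruskal_dunn()] comparison of 0-100 m nDIC inventories across
#'   regimes), `shares` (N2-fixation share of NCP-N and upward share of
#'   NCP-P, percent), `log` (substitution and masking bookkeeping),
#'   `manifest`.
#' @export
run_full_budget <- function(config = scenario_config(), forcing = NULL,
                            report_path = NULL) {
  monthly_sst <- NULL
  if (is.character(config)) {
    y <- yaml::read_yaml(config)
    if (!is.null(y$scenario)) {
      config <- do.call(scenario_config, y$scenario)
    } else if (!is.null(y$inputs)) {
      casts <- read_casts_csv(y$inputs$casts, quiet = TRUE)
      if (length(casts) == 0L)
        stop("run_full_budget [stage: load casts]: empty cast file")
      turbulence <- read_turbulence_csv(y$inputs$turbulence)
      if (!is.null(y$inputs$forcing))
        forcing <- read_forcing_yaml(y$inputs$forcing)
      monthly_sst <- as.numeric(unlist(y$inputs$monthly_sst))
      config <- NULL
    } else stop("run_full_budget [stage: config]: need 'scenario' or 'inputs'")
  }
  if (!is.null(config) && inherits(config, "scenario_config")) {
    data <- generate_cruise_dataset(config)
    casts <- data$casts
    turbulence <- data$turbulence
    monthly_sst <- generate_monthly_sst(config)
  }
  if (length(casts) == 0L)
    stop("run_full_budget [stage: load casts]: no casts")
  if (is.null(forcing)) forcing <- generate_forcing()
  if (is.null(monthly_sst) || length(monthly_sst) != 12L)
    stop("run_full_budget [stage: climatology]: need a 12-value monthly SST series")

  clim <- regime_days(monthly_sst)
  norm_cfg <- normalization_config()
  constituents <- c("dic", "nn", "po4")

  n_sub_total <- c(nn = 0L, po4 = 0L)
  per_cast <- vector("list", length(casts))
  masked <- numeric(length(casts))
  for (i in seq_along(casts)) {
    cs <- substitute_below_detection(casts[[i]], norm_cfg)
    ns <- attr(cs, "n_substituted")
    n_sub_total[names(ns)] <- n_sub_total[names(ns)] + ns
    fx <- cast_fluxes(cs, turbulence[[i]], constituents)
    masked[i] <- attr(osborn_diffusivity(turbulence[[i]]), "masked_fraction")
    ndic <- normalize_salinity(cs$conc$dic, cs$salinity, norm_cfg)
    per_cast[[i]] <- list(
      sst = cs$sst, regime = as.character(classify_sst_regime(cs$sst)),
      mld = fx$mld,
      flux_100_200 = vapply(constituents,
                            function(cn) fx[[cn]]$l100_200$value$m, 0),
      ndic_0_100 = depth_integrate(cs$depth, ndic, 0, 100))
  }
  regimes <- vapply(per_cast, `[[`, "", "regime")

  # regime-mean daily fluxes (100-200 m) per constituent
  regime_flux <- list()
  for (cn in constituents) {
    vals <- vapply(per_cast, function(p) p$flux_100_200[[cn]], 0)
    regime_flux[[cn]] <- list()
    for (reg in sst_regime_levels()) {
      v <- vals[regimes == reg & !is.na(vals)]
      if (length(v) > 0) regime_flux[[cn]][[reg]] <- mean_ci(v)
    }
  }

  budget <- compute_budget(regime_flux, clim, forcing)

  inv <- vapply(per_cast, `[[`, 0, "ndic_0_100")
  drawdown <- regime_inventory_difference(inv, regimes, "SST<24", "SST>28")
  ndic_kw <- kruskal_dunn(inv, regimes)

  shares <- c(
    n2_fixation_share_ncp_n = 100 * uv_scale(forcing$n2_fixation, 365)$m /
      budget$ncp$N$m,
    upward_share_ncp_p = 100 * budget$fup$P$m / budget$ncp$P$m)

  report <- structure(list(
    budget = budget, regime_flux = regime_flux, climatology = clim,
    drawdown_ndic = drawdown, ndic_kw = ndic_kw, shares = shares,
    log = list(n_below_detection = n_sub_total,
               mean_masked_kz_fraction = mean(masked),
               regimes_without_data = setdiff(
                 sst_regime_levels()[clim$days > 0], unique(regimes))),
    manifest = list(
      n_casts = length(casts),
      seed = if (!is.null(config)) config$seed else NA,
      package_version = as.character(utils::packageVersion("ncpbudget")))),
    class = "budget_report")
  if (!is.null(report_path)) write_budget_report(report, report_path)
  report
}

#' @export
print.budget_report <- function(x, ...) {
  cat(sprintf("<budget_report> %d casts; regime days: %s\n",
              x$manifest$n_casts,
              paste(names(x$climatology$days),
                    round(x$climatology$days, 1), sep = "=", collapse = ", ")))
  print(x$budget)
  cat("  nDIC 0-100 m drawdown (cool - warm):",
      format(x$drawdown_ndic), "mol m-2\n")
  cat(sprintf("  N2-fixation share of NCP-N: %.0f %%; upward share of NCP-P: %.0f %%\n",
              x$shares[["n2_fixation_share_ncp_n"]],
              x$shares[["upward_share_ncp_p"]]))
  invisible(x)
}

uv_json <- function(x) list(m = x$m, e = x$e)

#' Serialize a budget report to JSON
#'
#' All Fig.-4-style quantities (influxes, NCP, ratios, MD, RF) with their
#' CIs, plus the drawdown, hypothesis test and run log. Byte-identical
#' for identical inputs.
#'
#' @param report a `budget_report`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_budget_report <- function(report, path) {
  b <- report$budget
  obj <- list(
    fup = lapply(b$fup, uv_json), fat = lapply(b$fat, uv_json),
    ncp = lapply(b$ncp, uv_json),
    ncp_ratio = list(c = uv_json(b$ncp_ratio$c), n = uv_json(b$ncp_ratio$n),
                     p = 1),
    fup_ratio = list(c = uv_json(b$fup_ratio$c), n = uv_json(b$fup_ratio$n),
                     p = 1),
    md = list(n = b$md$md_n, p = b$md$md_p,
              n_2sf = b$md$md_n_2sf, p_2sf = b$md$md_p_2sf),
    rf = list(n = b$rf_n$rf_2sf, p = b$rf_p$rf_2sf),
    drawdown_ndic = uv_json(report$drawdown_ndic),
    ndic_kw = list(h = report$ndic_kw$h_statistic, p = report$ndic_kw$p_value),
    shares_pct = as.list(report$shares),
    climatology = list(months = as.list(report$climatology$months),
                       days = as.list(report$climatology$days)),
    log = list(
      n_below_detection = as.list(report$log$n_below_detection),
      mean_masked_kz_fraction = report$log$mean_masked_kz_fraction,
      regimes_without_data = report$log$regimes_without_data),
    manifest = report$manifest)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write fixture datasets for a named scenario
#'
#' `"paper-defaults"`: the default 13-cruise, 5-station synthetic
#' time-series with forcing. `"linear-gradient-analytic"`: a single cast
#' with exactly linear concentration profiles and a constant-epsilon,
#' constant-N^2 turbulence profile, for closed-form flux recovery checks.
#'
#' @param scenario scenario name.
#' @param seed RNG seed.
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
make_fixtures <- function(scenario = c("paper-defaults",
                                       "linear-gradient-analytic"),
                          seed = 1L, dir = ".") {
  scenario <- tryCatch(match.arg(scenario), error = function(e)
    stop("make_fixtures: unknown scenario; available: ",
         "paper-defaults, linear-gradient-analytic"))
  if (scenario == "paper-defaults") {
    cfg <- scenario_config(seed = seed)
    data <- generate_cruise_dataset(cfg)
    return(write_cruise_csv(data, dir, forcing = generate_forcing(cfg)))
  }
  data <- linear_gradient_dataset()
  write_cruise_csv(data, dir)
}

#' Analytic single-cast dataset with linear tracer profiles
#'
#' Concentrations are exactly linear in depth (DIC slope 5e-4, N+N 3e-5,
#' PO4 2.4e-6 mol m^-4), epsilon is constant at 2e-9 W kg^-1 and N^2
#' constant at 1e-4 s^-2, so every layer-mean flux has the closed form
#' 0.2 * (epsilon/N^2) * slope * 86400.
#'
#' @return a `cruise_dataset` with one cast.
#' @export
linear_gradient_dataset <- function() {
  z <- c(0, 10, 25, 50, 75, 100, 125, 150, 200)
  cs <- cast("StA", "2017-01-15", z,
             temperature = 25 - 0.02 * z, salinity = rep(34.91, length(z)),
             par = 2000 * exp(-0.046 * z),
             conc = list(dic = 1.95 + 5e-4 * z, nn = 1e-5 + 3e-5 * z,
                         po4 = 1e-6 + 2.4e-6 * z,
                         dop = 1e-4 - 2e-7 * z,
                         tdp = 1.01e-4 + 2.2e-6 * z,
                         tpp = 1e-5 - 4e-8 * z))
  tgrid <- seq(0, 200, by = 5)
  tb <- turbulence_profile(tgrid, rep(2e-9, length(tgrid)),
                           rep(1e-4, length(tgrid)))
  structure(list(casts = list(cs), turbulence = list(tb),
                 config = NULL),
            class = "cruise_dataset")
}
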