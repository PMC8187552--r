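#' Chemical composition proportions of total particulate phosphorus
#'
#' TPP fractionates into orthophosphate, sugar P, nucleotide P, nucleic
#' acid P, lipid P, acid-soluble poly P, acid-insoluble poly P and
#' residual P. Each fraction is expressed as a proportion of the fraction
#' sum, so proportions sum to one.
#'
#' An optional triplicate QC check flags fractions whose replicate CV
#' exceeds 10 % of the TPP concentration; flagged fractions are reported,
#' not removed.
#'
#' @param fractions named nonnegative numeric vector, mol P m^-3.
#' @param replicates optional matrix (replicates x fractions) for the QC
#'   flag.
#' @return named proportions summing to 1; attribute `"qc_flagged"` when
#'   replicates are given.
#' @export
tpp_proportions <- function(fractions, replicates = NULL) {
  if (any(fractions < 0, na.rm = TRUE))
    stop("tpp_proportions: fractions must be >= 0")
  total <- sum(fractions, na.rm = TRUE)
  if (total <= 0) stop("tpp_proportions: all fractions zero")
  out <- fractions / total
  if (!is.null(replicates)) {
    cv <- apply(replicates, 2, stats::sd) / total
    attr(out, "qc_flagged") <- cv > 0.10
  }
  out
}

#' Published cellular carbon quotas of subtropical picoplankton groups
#'
#' @param prochlorococcus,synechococcus,eukaryotes mol C cell^-1, > 0.
#' @return named numeric vector.
#' @export
cell_quota_table <- function(prochlorococcus = 5.2e-15,
                             synechococcus = 3.0e-14,
                             eukaryotes = 3.9e-13) {
  q <- c(prochlorococcus = prochlorococcus,
         synechococcus = synechococcus,
         eukaryotes = eukaryotes)
  if (any(q <= 0)) stop("cell_quota_table: quotas must be > 0")
  q
}

#' Flow-cytometry carbon biomass by microbial group
#'
#' Biomass is cell abundance times the published cellular carbon quota;
#' group shares are each group's biomass over the total.
#'
#' @param counts named cell abundances, cells L^-1, >= 0; names must match
#'   the quota table.
#' @param quotas a [cell_quota_table()].
#' @return list: `biomass` (mol C L^-1 by group), `shares` (sum to 1, or
#'   all NA with `shares_undefined = TRUE` when total biomass is zero).
#' @export
fcm_carbon_biomass <- function(counts, quotas = cell_quota_table()) {
  if (any(counts < 0)) stop("fcm_carbon_biomass: counts must be >= 0")
  if (!all(names(counts) %in% names(quotas)))
    stop("fcm_carbon_biomass: unknown group in counts")
  biomass <- counts * quotas[names(counts)]
  total <- sum(biomass)
  if (total == 0) {
    return(list(biomass = biomass,
                shares = stats::setNames(rep(NA_real_, length(biomass)),
                                         names(biomass)),
                shares_undefined = TRUE))
  }
  list(biomass = biomass, shares = biomass / total, shares_undefined = FALSE)
}
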