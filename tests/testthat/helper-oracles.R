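# Independent oracles used across test files.

# Kruskal-Wallis H from first principles: squared deviations of group mean
# ranks, with the standard tie correction on the pooled ranks.
brute_force_kw_h <- function(values, groups) {
  groups <- factor(groups)
  n <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ng <- tapply(r, groups, length)
  h <- 12 / (n * (n + 1)) * sum(ng * (rbar - (n + 1) / 2)^2)
  tt <- table(r)
  h / (1 - sum(tt^3 - tt) / (n^3 - n))
}

# Adaptive-quadrature inventory oracle: integrate the piecewise-linear
# interpolant segment by segment with stats::integrate.
quadrature_inventory <- function(depth, values, z0, z1) {
  f <- stats::approxfun(depth, values, rule = 2)
  knots <- sort(unique(c(z0, z1, depth[depth > z0 & depth < z1])))
  total <- 0
  for (i in seq_len(length(knots) - 1)) {
    total <- total + stats::integrate(f, knots[i], knots[i + 1],
                                      rel.tol = 1e-13)$value
  }
  total
}

# A simple stratified test cast on the standard 9-depth bottle grid.
make_test_cast <- function(conc = list(), par = NULL,
                           temperature = NULL, salinity = NULL) {
  z <- c(0, 10, 25, 50, 75, 100, 125, 150, 200)
  if (is.null(temperature)) temperature <- 28 - 0.05 * z
  if (is.null(salinity)) salinity <- rep(34.91, length(z))
  cast("TST", "2017-06-15", z, temperature, salinity,
       par = par, conc = conc)
}
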