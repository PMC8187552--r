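#' Uncertain value: mean with 95 % confidence half-width
#'
#' All reported quantities in the budget pipeline carry a mean `m` and a
#' 95 % confidence-interval half-width `e` (same units as `m`). This light
#' S3 container keeps the two together through arithmetic so that error
#' propagation is never applied to a bare number by accident.
#'
#' @param m mean (any units).
#' @param e 95 % CI half-width, same units as `m`; must be >= 0. `NA` marks
#'   an undefined CI (e.g. a single observation).
#' @param n optional sample count behind the mean.
#' @return An object of class `"uncertain"`.
#' @examples
#' uncertain(7.5e-1, 1.5e-1)
#' @export
uncertain <- function(m, e = NA_real_, n = NA_integer_) {
  stopifnot(length(m) == 1L, length(e) == 1L, is.numeric(m))
  if (!is.na(e) && e < 0) stop("CI half-width 'e' must be >= 0")
  structure(list(m = as.numeric(m), e = as.numeric(e), n = as.integer(n)),
            class = "uncertain")
}

#' @export
print.uncertain <- function(x, ...) {
  e <- if (is.na(x$e)) "CI undefined" else paste0("± ", signif(x$e, 3))
  cat(signif(x$m, 4), e,
      if (!is.na(x$n)) paste0("(n = ", x$n, ")") else "", "\n")
  invisible(x)
}

#' @export
format.uncertain <- function(x, digits = 2, ...) {
  paste0(signif(x$m, digits), " ± ",
         if (is.na(x$e)) "NA" else signif(x$e, digits))
}

as_uncertain <- function(x) {
  if (inherits(x, "uncertain")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(uncertain(x, 0))
  if (is.numeric(x) && length(x) == 2L) return(uncertain(x[1], x[2]))
  stop("cannot interpret input as an uncertain value")
}

#' Sample mean with t-based 95 % confidence interval
#'
#' The workhorse behind every regime mean in the pipeline. CIs are
#' Student-t based (`qt(0.975, n - 1) * s / sqrt(n)`) because regime sample
#' sizes are small (typically 3-10 casts); a normal 1.96-SE interval is
#' available via `method = "normal"`.
#'
#' @param values numeric sample, NAs dropped.
#' @param method `"t"` (default) or `"normal"`.
#' @return [uncertain()] with `n` set. For `n == 1` the mean is returned
#'   with an `NA` half-width (flagged undefined CI); `n == 0` is an error.
#' @export
mean_ci <- function(values, method = c("t", "normal")) {
  method <- match.arg(method)
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0L) stop("mean_ci: empty sample")
  if (n == 1L) return(uncertain(values, NA_real_, 1L))
  se <- stats::sd(values) / sqrt(n)
  k <- if (method == "t") stats::qt(0.975, df = n - 1L) else stats::qnorm(0.975)
  uncertain(mean(values), k * se, n)
}

#' Error propagation for sums, differences and quotients
#'
#' Propagates 95 % CI half-widths through the three operations used by the
#' budget: sums and differences combine half-widths in quadrature,
#' `sqrt(E1^2 + E2^2)`. For quotients two conventions are supported. The
#' default (`quotient_form = "printed"`) divides both half-widths by the
#' denominator mean: `(M1/M2) * sqrt((E1/M2)^2 + (E2/M2)^2)`. The standard
#' relative-error form `(M1/M2) * sqrt((E1/M1)^2 + (E2/M2)^2)` is selectable;
#' when the two differ by more than 1 % a message is logged once per call.
#'
#' @param op one of `"sum"`, `"difference"`, `"quotient"`.
#' @param a,b [uncertain()] values (bare numerics are promoted with e = 0).
#' @param quotient_form `"printed"` (default) or `"standard"`.
#' @return [uncertain()].
#' @examples
#' propagate("sum", uncertain(3, 4), uncertain(4, 3))        # 7 +/- 5
#' propagate("quotient", uncertain(6, 0.6), uncertain(3, 0.3))
#' @export
propagate <- function(op = c("sum", "difference", "quotient"), a, b,
                      quotient_form = c("printed", "standard")) {
  op <- match.arg(op)
  quotient_form <- match.arg(quotient_form)
  a <- as_uncertain(a); b <- as_uncertain(b)
  e1 <- ifelse(is.na(a$e), 0, a$e)
  e2 <- ifelse(is.na(b$e), 0, b$e)
  if (op == "sum") {
    return(uncertain(a$m + b$m, sqrt(e1^2 + e2^2)))
  }
  if (op == "difference") {
    return(uncertain(a$m - b$m, sqrt(e1^2 + e2^2)))
  }
  if (b$m == 0) stop("propagate: quotient with zero denominator mean")
  q <- a$m / b$m
  e_printed <- abs(q) * sqrt((e1 / b$m)^2 + (e2 / b$m)^2)
  e_standard <- if (a$m == 0) abs(e1 / b$m) else
    abs(q) * sqrt((e1 / a$m)^2 + (e2 / b$m)^2)
  if (e_printed > 0 && abs(e_printed - e_standard) / e_printed > 0.01) {
    message(sprintf(
      "propagate: quotient CI differs between conventions (printed %.3g, standard %.3g)",
      e_printed, e_standard))
  }
  uncertain(q, if (quotient_form == "printed") e_printed else e_standard)
}

#' Scale an uncertain value by an exact constant
#'
#' Mean and half-width both scale by `|k|`; used for day/year conversions
#' where the multiplier carries no uncertainty.
#'
#' @param x [uncertain()].
#' @param k exact numeric scalar.
#' @return [uncertain()].
#' @export
uv_scale <- function(x, k) {
  x <- as_uncertain(x)
  uncertain(x$m * k, if (is.na(x$e)) NA_real_ else abs(k) * x$e, x$n)
}

#' Kruskal-Wallis regime comparison with Dunn's post-hoc procedure
#'
#' Omnibus comparison of a biogeochemical quantity across SST regimes
#' (or any grouping) by the two-sided Kruskal-Wallis rank-sum test,
#' followed by Dunn's pairwise z-tests on mean ranks with tie correction.
#' Pairwise significance is assessed against a Bonferroni-corrected
#' threshold of 0.05 divided by the number of pairs: 0.05/6 = 0.0083 for
#' four groups.
#'
#' @param values numeric vector of observations.
#' @param groups grouping factor/vector, same length as `values`.
#' @return list of class `"group_comparison"`: `h_statistic`, `p_value`,
#'   `pairwise` (data.frame with group pair, z, unadjusted p, significance
#'   at the Bonferroni threshold), `alpha_pairwise`, `significant` (omnibus
#'   at 0.05).
#' @export
kruskal_dunn <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  groups <- droplevels(groups)
  if (nlevels(groups) < 2L) stop("kruskal_dunn: need >= 2 nonempty groups")
  n <- length(values)

  if (length(unique(values)) == 1L) {
    # all observations identical: no rank information at all
    h <- 0; p <- 1
  } else {
    kw <- stats::kruskal.test(values, groups)
    h <- unname(kw$statistic)
    p <- kw$p.value
  }

  # Dunn's z-tests on mean ranks, pooled-rank tie correction
  r <- rank(values)
  tie_tab <- table(r)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (n - 1))
  lev <- levels(groups)
  mean_rank <- tapply(r, groups, mean)
  n_g <- tapply(r, groups, length)
  pairs <- utils::combn(lev, 2)
  alpha_pair <- 0.05 / ncol(pairs)
  pw <- data.frame(
    group_a = pairs[1, ], group_b = pairs[2, ],
    z = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    ga <- pairs[1, i]; gb <- pairs[2, i]
    sigma <- sqrt((n * (n + 1) / 12 - tie_term) *
                    (1 / n_g[[ga]] + 1 / n_g[[gb]]))
    z <- if (sigma == 0) 0 else (mean_rank[[ga]] - mean_rank[[gb]]) / sigma
    pw$z[i] <- z
    pw$p[i] <- 2 * stats::pnorm(-abs(z))
  }
  pw$significant <- pw$p < alpha_pair
  structure(list(h_statistic = h, p_value = p, pairwise = pw,
                 alpha_pairwise = alpha_pair, significant = p < 0.05),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis H = %.4g, p = %.4g%s\n", x$h_statistic,
              x$p_value, if (x$significant) " *" else ""))
  cat(sprintf("Dunn pairwise (threshold p < %.4f):\n", x$alpha_pairwise))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

# round to the 2-significant-figure reporting style used for budget outputs
signif2 <- function(x) signif(x, 2)
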