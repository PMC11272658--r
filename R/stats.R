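# Statistical contracts of the study: group comparison, viscosity
# regression, orientation-distribution tests, summary reporting.

#' Group summary (mean, SD, SEM)
#'
#' @param x numeric vector.
#' @param label optional group label.
#' @return One-row tibble with `group`, `n`, `mean`, `sd`, `sem`
#'   (sem = sd/sqrt(n)).
#' @export
group_summary <- function(x, label = NA_character_) {
  if (length(x) == 0) stop("empty sample", call. = FALSE)
  tibble::tibble(group = label, n = length(x), mean = mean(x),
                 sd = stats::sd(x),
                 sem = stats::sd(x) / sqrt(length(x)))
}

#' Compare two groups with the Mann-Whitney test
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test, the non-parametric
#' comparison used for male-vs-female contrasts. Exact p-values for small
#' tie-free samples (both n <= 25), normal approximation with continuity
#' correction otherwise.
#'
#' @param x,y numeric samples (each n >= 1).
#' @param alpha significance level for the `significant` flag.
#' @return A list with `statistic` (U), `p_value`, `significant`.
#' @export
compare_groups <- function(x, y, alpha = 0.05) {
  if (length(x) < 1 || length(y) < 1) stop("empty sample", call. = FALSE)
  exact <- length(x) <= 25 && length(y) <= 25 &&
    !any(duplicated(c(x, y)))
  res <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  )
  list(statistic = unname(res$statistic), p_value = res$p.value,
       significant = res$p.value < alpha)
}

#' Fit the hematocrit-viscosity regression
#'
#' Ordinary least squares of total blood viscosity on hematocrit.
#' Performed with hematocrit as a fraction and viscosity in Pa·s (the
#' package's canonical coefficient scale); the same coefficients are also
#' reported in cP per hematocrit fraction.
#'
#' @param hematocrit hematocrit fractions, n >= 3, not all equal.
#' @param eta_b_cP total blood viscosities, cP.
#' @return A list with `slope`, `intercept` (Pa·s scale), `slope_cP`,
#'   `intercept_cP`, `r_squared`, and the underlying `fit`.
#' @export
#' @examples
#' ht <- c(0.38, 0.42, 0.46)
#' fit_viscosity_regression(ht, (0.01258 * ht - 0.001443) * 1e3)
fit_viscosity_regression <- function(hematocrit, eta_b_cP) {
  if (length(hematocrit) < 3) stop("need n >= 3", call. = FALSE)
  if (stats::sd(hematocrit) == 0) {
    stop("`hematocrit` is constant; slope undefined", call. = FALSE)
  }
  eta_pas <- cp_to_pas(eta_b_cP)
  fit <- stats::lm(eta_pas ~ hematocrit)
  co <- stats::coef(fit)
  list(slope = unname(co[2]), intercept = unname(co[1]),
       slope_cP = unname(co[2]) * 1e3, intercept_cP = unname(co[1]) * 1e3,
       r_squared = summary(fit)$r.squared, fit = fit)
}

#' Test orientation classes against the no-orientation null
#'
#' Chi-square goodness-of-fit of the three orientation-class counts
#' against the equiprobable null (one third per class, df = 2), or, given
#' two count vectors, a two-sample contingency chi-square (e.g.
#' male vs female).
#'
#' @param counts integer vector of 3 class counts (dromic, lateral,
#'   antidromic).
#' @param counts2 optional second group's counts for the contingency test.
#' @param alpha significance level.
#' @return A list with `statistic`, `df`, `p_value`, `significant`.
#' @export
#' @examples
#' test_orientation_uniformity(c(20, 20, 191))
test_orientation_uniformity <- function(counts, counts2 = NULL,
                                        alpha = 0.05) {
  if (sum(counts) == 0) stop("zero total count", call. = FALSE)
  res <- if (is.null(counts2)) {
    stats::chisq.test(counts, p = rep(1 / 3, 3))
  } else {
    if (sum(counts2) == 0) stop("zero total count", call. = FALSE)
    suppressWarnings(stats::chisq.test(rbind(counts, counts2)))
  }
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value, significant = res$p.value < alpha)
}

# exact one-sample signed-rank p by sign-flip enumeration (handles tied
# absolute differences, which the stats::wilcox.test exact path refuses)
.signed_rank_exact_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  mu <- sum(r) / 2
  min(1, sum(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9) / length(w_all))
}

#' Test nucleus elongation against 1
#'
#' Two-sided one-sample Wilcoxon signed-rank test of the elongation index
#' against the circular-nucleus null value 1. For n <= 15 the p-value is
#' computed by exact sign-flip enumeration (valid under ties); larger
#' samples use the normal approximation with continuity correction.
#' Values exactly equal to 1 carry no information and are dropped (the
#' usual signed-rank convention); if all values equal 1 the statistic is
#' undefined and the result is reported non-significant with a warning.
#'
#' @param elongations elongation indices (major/minor >= 1), n >= 1.
#' @param mu null value, default 1.
#' @param alpha significance level.
#' @return A list with `n_effective`, `p_value`, `significant`.
#' @export
#' @examples
#' test_elongation(rep(1.5, 7))$p_value  # 2/2^7
test_elongation <- function(elongations, mu = 1, alpha = 0.05) {
  if (length(elongations) < 1) stop("empty sample", call. = FALSE)
  d <- elongations - mu
  d <- d[d != 0]
  if (length(d) == 0) {
    warning("all values equal the null value; statistic undefined",
            call. = FALSE)
    return(list(n_effective = 0L, p_value = 1, significant = FALSE))
  }
  p <- if (length(d) == 1) {
    1  # a single informative value cannot reject
  } else if (length(d) <= 15) {
    .signed_rank_exact_p(d)
  } else {
    suppressWarnings(
      stats::wilcox.test(d, mu = 0, exact = FALSE, correct = TRUE)$p.value
    )
  }
  list(n_effective = length(d), p_value = p, significant = p < alpha)
}
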