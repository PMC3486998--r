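#' Paired between-visit differences
#'
#' Baseline minus repeat: \eqn{\Delta = CT1 - CT2}.
#'
#' @param ct1,ct2 numeric vectors of equal length, same subject order.
#' @return Vector of differences.
#' @export
#' @examples
#' paired_differences(10.8, 11.7) # -0.9
paired_differences <- function(ct1, ct2) {
  if (length(ct1) != length(ct2))
    stop("baseline and repeat series must have equal length")
  if (anyNA(ct1) || anyNA(ct2)) stop("missing values are not allowed")
  ct1 - ct2
}

#' Bland-Altman limits of agreement
#'
#' Mean difference plus limits at \eqn{\pm 1.96} times the sample standard
#' deviation (n-1 denominator) of the differences.
#'
#' @param diffs per-subject between-visit differences (at least 3).
#' @param pair_means optional per-subject means of the two visits, retained as
#'   plotting coordinates.
#' @return Object of class `bland_altman`: `mean_diff`, `sd_diff`, `loa_low`,
#'   `loa_high`, `n`, and a `points` data frame if `pair_means` was given.
#'   The limits always straddle the mean difference symmetrically:
#'   `(loa_low + loa_high)/2 == mean_diff`.
#' @export
#' @examples
#' bland_altman(c(-1, 0, 1)) # LoA -1.96 to 1.96
bland_altman <- function(diffs, pair_means = NULL) {
  if (length(diffs) < 3) stop("at least 3 paired differences are required")
  if (anyNA(diffs)) stop("missing values are not allowed")
  m <- mean(diffs)
  s <- stats::sd(diffs)
  out <- list(mean_diff = m, sd_diff = s,
              loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
              n = length(diffs))
  if (!is.null(pair_means)) {
    stopifnot(length(pair_means) == length(diffs))
    out$points <- data.frame(mean = pair_means, diff = diffs)
  }
  structure(out, class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): mean difference %.3f, LoA %.3f to %.3f\n",
              x$n, x$mean_diff, x$loa_low, x$loa_high))
  invisible(x)
}

#' Lin's concordance correlation coefficient
#'
#' Agreement index combining correlation with deviation from the identity
#' line: \eqn{\rho_c = 2 s_{xy} / (s_x^2 + s_y^2 + (\bar x - \bar y)^2)} with
#' n-denominator moments (the original definition; no bias correction). It
#' equals 1 iff the two series are identical elementwise, and is symmetric in
#' its arguments.
#'
#' @param x,y numeric vectors of equal length `>= 3`, neither constant.
#' @return Coefficient in `[-1, 1]`.
#' @export
#' @examples
#' concordance_correlation(c(1, 2, 3), c(2, 3, 4)) # 4/7
concordance_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("at least 3 pairs are required")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2)
  sy2 <- mean((y - my)^2)
  if (sx2 == 0 || sy2 == 0)
    stop("undefined: concordance requires non-constant inputs")
  sxy <- mean((x - mx) * (y - my))
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

# All permutations of 1..n (n small), rows = permutations.
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Sandvik-Olsson paired-dispersion test
#'
#' Tests whether two conditions measured on the same subjects have equal
#' dispersion. Each series is centred at its own mean; the rank (Spearman)
#' correlation between the within-pair sums and differences of the centred
#' series is the statistic — a nearly distribution-free analogue of the
#' Pitman-Morgan test, since \eqn{cov(a+b, a-b) = var(a) - var(b)}. A
#' positive statistic signals larger dispersion in the first condition.
#'
#' @param d1,d2 values under conditions A and B for the same subjects, equal
#'   lengths `>= 4`.
#' @return List with `rho` (rank statistic), `p` (two-sided; exact
#'   permutation for `n <= 8`, t-approximation with `n - 2` df otherwise),
#'   `n`, and `method`. Identical dispersion patterns (all within-pair
#'   differences of the centred series zero) return `rho = 0`, `p = 1`.
#' @export
sandvik_olsson <- function(d1, d2) {
  if (length(d1) != length(d2)) stop("d1 and d2 must have equal length")
  n <- length(d1)
  if (n < 4) stop("at least 4 pairs are required")
  if (anyNA(d1) || anyNA(d2)) stop("missing values are not allowed")
  a <- d1 - mean(d1)
  b <- d2 - mean(d2)
  s <- a + b
  t <- a - b
  if (all(t == 0) || stats::var(t) == 0 || stats::var(s) == 0)
    return(list(rho = 0, p = 1, n = n, method = "degenerate"))
  rs <- rank(s); rt <- rank(t)
  rho <- stats::cor(rs, rt)
  if (n <= 8) {
    perms <- all_perms(n)
    rho_perm <- apply(perms, 1, function(pp) stats::cor(rs, rt[pp]))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p = p, n = n, method = method)
}

#' Levene's test for equal variances between two groups
#'
#' Classic (mean-centred) Levene: one-way ANOVA F on the absolute deviations
#' of each observation from its group mean, referred to an
#' \eqn{F(1, n_A + n_B - 2)} distribution. A median-centred variant
#' (Brown-Forsythe) is available via `center`.
#'
#' @param group_a,group_b numeric vectors, each of length `>= 3`.
#' @param center `"mean"` (classic) or `"median"` (Brown-Forsythe).
#' @return List with `statistic` (F), `p`, `df` and `center`.
#' @export
#' @examples
#' levene_test(c(-1, 0, 1), c(-2, 0, 2)) # F = 0.8
levene_test <- function(group_a, group_b, center = c("mean", "median")) {
  center <- match.arg(center)
  if (length(group_a) < 3 || length(group_b) < 3)
    stop("each group needs at least 3 observations")
  cfun <- if (center == "mean") mean else stats::median
  dev <- c(abs(group_a - cfun(group_a)), abs(group_b - cfun(group_b)))
  g <- factor(rep(c("A", "B"), c(length(group_a), length(group_b))))
  if (all(tapply(dev, g, stats::var) == 0))
    stop("degenerate: zero within-group deviation variance")
  fit <- stats::anova(stats::lm(dev ~ g))
  list(statistic = fit[1, "F value"], p = fit[1, "Pr(>F)"],
       df = c(fit[1, "Df"], fit[2, "Df"]), center = center)
}

#' Breath-hold reproducibility subgroups
#'
#' Ranks the signed per-subject between-visit volume differences and labels
#' the \eqn{\lfloor n/4 \rfloor} lowest plus \eqn{\lfloor n/4 \rfloor}
#' highest (the outer quartiles Q1 and Q4) as `"inferior"` breath-hold
#' reproducibility, the interquartile remainder as `"superior"`. Rank tails
#' are used rather than percentile cut-offs: the split is deterministic under
#' ties (broken by input order) and gives groups of 22 and 23 at n = 45.
#'
#' @param delta_volumes signed between-visit volume differences, one per
#'   subject.
#' @param min_n smallest cohort for which quartile tails are meaningful
#'   (default 8).
#' @return Factor of labels `"inferior"` / `"superior"`, same order as the
#'   input; inferior count is `2 * floor(n/4)`.
#' @export
#' @examples
#' table(breath_hold_subgroups(rnorm(45))) # 22 inferior, 23 superior
breath_hold_subgroups <- function(delta_volumes, min_n = 8) {
  n <- length(delta_volumes)
  if (n < min_n)
    stop(sprintf("at least %d subjects are required for quartile subgrouping",
                 min_n))
  if (anyNA(delta_volumes)) stop("missing values are not allowed")
  m <- n %/% 4L
  r <- rank(delta_volumes, ties.method = "first")
  lab <- ifelse(r <= m | r > n - m, "inferior", "superior")
  factor(lab, levels = c("inferior", "superior"))
}
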