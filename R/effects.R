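rb_estimate <- function(a, b) {
  n1 <- length(a)
  n2 <- length(b)
  r <- rank(c(a, b))
  u_a <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2  # pairs favorable to a (+ half-ties)
  u_b <- n1 * n2 - u_a
  list(estimate = 1 - 2 * u_b / (n1 * n2), u_a = u_a, u_b = u_b,
       n1 = n1, n2 = n2)
}

#' Rank-biserial correlation between two groups
#'
#' The nonparametric effect size for a two-group comparison:
#' `r_rb = 1 - 2U / (n1 * n2)`, where `U` is the Mann-Whitney count of
#' pairs favorable to the second group, with ties counted as one half. The
#' estimate is positive when `group_a` is stochastically larger; its
#' absolute value (`magnitude`) matches the unsigned ranges conventionally
#' reported.
#'
#' @param group_a,group_b Numeric vectors of scores.
#' @return An object of class `effect_size` with `estimate`, `magnitude`,
#'   `u_a`, `u_b`, `n1`, `n2`.
#' @export
#' @examples
#' rank_biserial(c(5, 6, 7), c(1, 2, 3))$estimate  # 1: complete separation
rank_biserial <- function(group_a, group_b) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop_navcog("both groups must be non-empty",
                class = "navcog_validation_error")
  }
  est <- rb_estimate(group_a, group_b)
  structure(
    list(kind = "rank_biserial", estimate = est$estimate,
         magnitude = abs(est$estimate), u_a = est$u_a, u_b = est$u_b,
         n1 = est$n1, n2 = est$n2),
    class = "effect_size"
  )
}

#' Confidence interval for the rank-biserial correlation
#'
#' The default is a seeded percentile bootstrap resampling within each
#' group. The `"normal"` method instead uses the large-sample standard
#' error of the rank-biserial statistic,
#' `sqrt((n1 + n2 + 1) / (3 * n1 * n2))`, around the point estimate.
#'
#' @inheritParams rank_biserial
#' @param confidence Confidence level.
#' @param method `"bootstrap"` (percentile) or `"normal"`.
#' @param n_boot Bootstrap replicates; fewer than 100 triggers a warning.
#' @param seed Integer seed for the bootstrap (same seed, same interval).
#' @return Named numeric vector `c(lower, upper)`. For the percentile
#'   bootstrap the interval is not guaranteed to bracket the point
#'   estimate; if it does not, attribute `estimate_outside` is set.
#' @export
rank_biserial_ci <- function(group_a, group_b, confidence = 0.95,
                             method = c("bootstrap", "normal"),
                             n_boot = 2000L, seed = NULL) {
  method <- match.arg(method)
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  est <- rb_estimate(group_a, group_b)
  alpha <- 1 - confidence
  if (method == "normal") {
    se <- sqrt((est$n1 + est$n2 + 1) / (3 * est$n1 * est$n2))
    z <- stats::qnorm(1 - alpha / 2)
    return(c(lower = max(-1, est$estimate - z * se),
             upper = min(1, est$estimate + z * se)))
  }
  n_boot <- assert_count(n_boot, "n_boot", lower = 1L)
  if (n_boot < 100L) {
    warning("n_boot < 100 gives unstable percentile intervals")
  }
  n1 <- est$n1
  n2 <- est$n2
  stats_boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      a <- group_a[sample.int(n1, n1, replace = TRUE)]
      b <- group_b[sample.int(n2, n2, replace = TRUE)]
      rb_estimate(a, b)$estimate
    }, numeric(1))
  })
  ci <- stats::quantile(stats_boot, c(alpha / 2, 1 - alpha / 2),
                        names = FALSE, type = 7)
  out <- c(lower = ci[1], upper = ci[2])
  if (est$estimate < out[1] || est$estimate > out[2]) {
    attr(out, "estimate_outside") <- TRUE
  }
  out
}

#' Cramer's V association for a contingency table
#'
#' `V = sqrt(chi2 / (N * min(r - 1, c - 1)))` with the Pearson chi-square
#' statistic (no continuity correction). Rows or columns with zero margins
#' are dropped with a warning before computation.
#'
#' @param table Matrix of non-negative integer counts, at least 2x2 after
#'   dropping empty margins.
#' @return An object of class `effect_size` with `estimate`, `chi2`, `df`,
#'   `N`, and the table dimensions used.
#' @export
cramers_v <- function(table) {
  m <- as.matrix(table)
  if (any(m < 0) || any(m != round(m))) {
    stop_navcog("contingency table must hold non-negative integer counts",
                class = "navcog_validation_error")
  }
  keep_r <- rowSums(m) > 0
  keep_c <- colSums(m) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warning("dropping zero-margin rows/columns from the contingency table")
    m <- m[keep_r, keep_c, drop = FALSE]
  }
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop_navcog("table must be at least 2x2 after dropping empty margins",
                class = "navcog_validation_error")
  }
  chi2 <- suppressWarnings(stats::chisq.test(m, correct = FALSE))$statistic
  chi2 <- unname(chi2)
  N <- sum(m)
  min_dim <- min(nrow(m) - 1L, ncol(m) - 1L)
  structure(
    list(kind = "cramers_v",
         estimate = sqrt(chi2 / (N * min_dim)),
         chi2 = chi2, df = (nrow(m) - 1L) * (ncol(m) - 1L),
         N = N, n_rows = nrow(m), n_cols = ncol(m), min_dim = min_dim),
    class = "effect_size"
  )
}

#' Confidence interval for Cramer's V via noncentral chi-square inversion
#'
#' Inverts the noncentral chi-square distribution on the noncentrality
#' parameter: the bounds are the `lambda` values at which the observed
#' statistic sits at the `alpha/2` tail probabilities, transformed to the V
#' scale by `V = sqrt(lambda / (N * min_dim))`. The lower bound is floored
#' at 0 and the upper bound capped at 1.
#'
#' @param chi2 Observed Pearson chi-square statistic.
#' @param df Degrees of freedom of the table.
#' @param N Total count.
#' @param min_dim `min(r - 1, c - 1)` of the table.
#' @param confidence Confidence level.
#' @return Named numeric vector `c(lower, upper)`. If the numeric inversion
#'   fails an error of class `navcog_nonconvergence_error` is thrown rather
#'   than returning NaN.
#' @export
cramers_v_ci <- function(chi2, df, N, min_dim, confidence = 0.95) {
  assert_scalar_number(chi2, "chi2", lower = 0)
  df <- assert_count(df, "df", lower = 1L)
  N <- assert_count(N, "N", lower = 1L)
  min_dim <- assert_count(min_dim, "min_dim", lower = 1L)
  alpha <- 1 - confidence
  solve_ncp <- function(target_p) {
    # find lambda with pchisq(chi2, df, ncp = lambda) == target_p;
    # pchisq is decreasing in lambda
    f <- function(l) stats::pchisq(chi2, df, ncp = l) - target_p
    if (f(0) <= 0) return(0)
    hi <- max(chi2, 1)
    it <- 0
    while (f(hi) > 0 && it < 60) {
      hi <- hi * 2
      it <- it + 1
    }
    if (f(hi) > 0) {
      stop_navcog("noncentrality inversion did not converge",
                  class = "navcog_nonconvergence_error")
    }
    stats::uniroot(f, c(0, hi), tol = 1e-10)$root
  }
  lam_lower <- solve_ncp(1 - alpha / 2)
  lam_upper <- solve_ncp(alpha / 2)
  c(lower = max(0, sqrt(lam_lower / (N * min_dim))),
    upper = min(1, sqrt(lam_upper / (N * min_dim))))
}

#' @export
print.effect_size <- function(x, ...) {
  if (x$kind == "rank_biserial") {
    cat(sprintf("rank-biserial r = %.3f (|r| = %.3f), U = %.1f, n = %d vs %d\n",
                x$estimate, x$magnitude, x$u_b, x$n1, x$n2))
  } else {
    cat(sprintf("Cramer's V = %.3f (chi2 = %.2f, df = %d, N = %d)\n",
                x$estimate, x$chi2, x$df, x$N))
  }
  invisible(x)
}

#' Compare two Delphi consultation rounds
#'
#' Per criterion (column), compares the paired scores of the same raters
#' across rounds with a Wilcoxon signed-rank test (normal approximation
#' with continuity correction, appropriate for tied ordinal data) and a
#' matched-pairs rank-biserial effect size
#' `(T+ - T-) / (T+ + T-)` over the nonzero differences. Criteria with no
#' changed ratings get effect 0 and p-value 1. The returned table is
#' suitable for the anonymized feedback report circulated between rounds.
#'
#' @param round1,round2 [rating_matrix()] objects with identical rater and
#'   item sets.
#' @param alpha Decision level for the `decision` label.
#' @param adjust Multiplicity adjustment passed to [stats::p.adjust()]
#'   (default `"none"`; the battery is small).
#' @return An object of class `delphi_comparison`: a data frame with one
#'   row per criterion (`criterion`, `median_diff`, `statistic`, `p_value`,
#'   `effect_rb`, `decision`).
#' @export
compare_delphi_rounds <- function(round1, round2, alpha = 0.05,
                                  adjust = "none") {
  if (!identical(dim(round1), dim(round2))) {
    stop_navcog("rounds must share the same raters and items",
                class = "navcog_validation_error")
  }
  if (!is.null(rownames(round1)) && !is.null(rownames(round2)) &&
      !identical(rownames(round1), rownames(round2))) {
    stop_navcog("rater sets differ between rounds",
                class = "navcog_validation_error")
  }
  items <- colnames(round1) %||% paste0("criterion_", seq_len(ncol(round1)))
  rows <- lapply(seq_len(ncol(round1)), function(j) {
    d <- as.numeric(round2[, j]) - as.numeric(round1[, j])
    nz <- d[d != 0]
    if (length(nz) == 0L) {
      eff <- 0
      p <- 1
      stat <- NA_real_
    } else {
      rk <- rank(abs(nz))
      t_plus <- sum(rk[nz > 0])
      t_minus <- sum(rk[nz < 0])
      eff <- (t_plus - t_minus) / (t_plus + t_minus)
      wt <- suppressWarnings(
        stats::wilcox.test(as.numeric(round2[, j]), as.numeric(round1[, j]),
                           paired = TRUE, exact = FALSE, correct = TRUE)
      )
      p <- wt$p.value
      stat <- unname(wt$statistic)
    }
    data.frame(criterion = items[j],
               median_diff = stats::median(d),
               statistic = stat, p_value = p, effect_rb = eff,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = adjust)
  out$decision <- ifelse(out$p_adjusted < alpha, "changed", "no_difference")
  class(out) <- c("delphi_comparison", "data.frame")
  out
}

#' @export
print.delphi_comparison <- function(x, ...) {
  cat("Delphi round comparison (paired signed-rank, matched rank-biserial)\n")
  disp <- data.frame(criterion = x$criterion,
                     median_diff = x$median_diff,
                     p = signif(x$p_value, 3),
                     r_rb = sprintf("%.2f", x$effect_rb),
                     decision = x$decision)
  print(disp, row.names = FALSE)
  invisible(x)
}
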