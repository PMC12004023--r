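#' Expert rating matrix
#'
#' A raters-by-items grid of ordinal ratings on a declared category scale,
#' tagged with the dimension being judged (relevance, representativeness, or
#' ergonomics) and the consultation round.
#'
#' @param ratings Integer matrix or data frame, raters in rows, items in
#'   columns.
#' @param n_categories Number of ordinal categories `c`.
#' @param category_floor Lowest category value (ratings live in
#'   `floor .. floor + c - 1`).
#' @param dimension One of `"relevance"`, `"representativeness"`,
#'   `"ergonomics"`.
#' @param round Consultation round label (integer).
#' @return An object of class `rating_matrix`.
#' @export
rating_matrix <- function(ratings, n_categories = 4L, category_floor = 1L,
                          dimension = c("relevance", "representativeness",
                                        "ergonomics"),
                          round = 1L) {
  dimension <- match.arg(dimension)
  m <- as.matrix(ratings)
  storage.mode(m) <- "integer"
  n_categories <- assert_count(n_categories, "n_categories", lower = 2L)
  category_floor <- assert_count(category_floor, "category_floor",
                                 lower = 0L)
  if (nrow(m) < 2L) {
    stop_navcog("at least 2 raters are required",
                class = "navcog_validation_error")
  }
  lo <- category_floor
  hi <- category_floor + n_categories - 1L
  bad <- !is.na(m) & (m < lo | m > hi)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop_navcog(sprintf("rating %d at rater %d, item %d outside scale %d..%d",
                        m[bad][1], idx[1], idx[2], lo, hi),
                class = "navcog_validation_error")
  }
  structure(m, n_categories = n_categories, category_floor = category_floor,
            dimension = dimension, round = as.integer(round),
            class = c("rating_matrix", "matrix"))
}

#' Item-level content validity index
#'
#' The I-CVI is the proportion of experts judging an item relevant, where a
#' rating at or above `relevance_cut` on the ordinal scale counts as
#' relevant.
#'
#' @param ratings Integer vector: one item's column of ratings.
#' @param relevance_cut Lowest rating counted as "relevant" (default 3 on a
#'   1-4 scale, the conventional dichotomization).
#' @return A list with `A` (number judging relevant), `N` (raters), and
#'   `i_cvi = A / N`.
#' @export
item_cvi <- function(ratings, relevance_cut = 3L) {
  ratings <- ratings[!is.na(ratings)]
  N <- length(ratings)
  if (N < 2L) {
    stop_navcog("I-CVI needs at least 2 raters",
                class = "navcog_validation_error")
  }
  A <- sum(ratings >= relevance_cut)
  list(A = A, N = N, i_cvi = A / N)
}

#' Probability of chance agreement among experts
#'
#' Under a binomial model in which each expert independently judges
#' relevant/not-relevant with probability one half, the probability that
#' exactly `A` of `N` experts agree on relevance is
#' `choose(N, A) * 0.5^N`. This is the chance term used to correct the
#' I-CVI into the modified kappa.
#'
#' @param N Number of raters.
#' @param A Number judging the item relevant.
#' @return The chance-agreement probability.
#' @export
#' @examples
#' chance_agreement_pc(8, 8)  # 0.5^8
chance_agreement_pc <- function(N, A) {
  N <- assert_count(N, "N", lower = 1L)
  A <- assert_count(A, "A", lower = 0L)
  if (A > N) {
    stop_navcog("A cannot exceed N", class = "navcog_validation_error")
  }
  choose(N, A) * 0.5^N
}

#' Modified kappa (chance-corrected content validity)
#'
#' Corrects the item content validity index for chance agreement:
#' `kappa = (i_cvi - p_c) / (1 - p_c)`. Interpretation bands: values above
#' 0.88 indicate excellent agreement, values above 0.72 good agreement
#' (band edges exclusive).
#'
#' @param i_cvi Item content validity index in \[0, 1\].
#' @param p_c Chance-agreement probability from [chance_agreement_pc()].
#' @return A list with `kappa_star` and `label` (`"excellent"`, `"good"`,
#'   or `"below_good"`).
#' @export
modified_kappa <- function(i_cvi, p_c) {
  assert_scalar_number(i_cvi, "i_cvi", lower = 0, upper = 1)
  assert_scalar_number(p_c, "p_c", lower = 0, upper = 1)
  if (p_c >= 1) {
    stop_navcog("chance agreement of 1 leaves the kappa undefined",
                class = "navcog_degenerate_error")
  }
  k <- (i_cvi - p_c) / (1 - p_c)
  label <- if (k > 0.88) "excellent" else if (k > 0.72) "good" else "below_good"
  list(kappa_star = k, label = label)
}

#' Aiken's V agreement coefficient
#'
#' `V = sum(r_i - floor) / (n * (c - 1))`: the mean rating expressed as a
#' proportion of the maximum possible elevation above the scale floor.
#' Unlike the I-CVI it uses the full ordinal scale, which makes it
#' informative for small expert panels.
#'
#' @inheritParams item_cvi
#' @param n_categories Number of ordinal categories.
#' @param category_floor Lowest category value.
#' @return V in \[0, 1\] at full precision (round for display).
#' @export
#' @examples
#' aiken_v(c(4, 4, 4, 4, 4, 4, 4, 3))  # 23/24
aiken_v <- function(ratings, n_categories = 4L, category_floor = 1L) {
  ratings <- ratings[!is.na(ratings)]
  n_categories <- assert_count(n_categories, "n_categories", lower = 2L)
  n <- length(ratings)
  if (n < 1L) {
    stop_navcog("no ratings supplied", class = "navcog_validation_error")
  }
  if (any(ratings < category_floor |
          ratings > category_floor + n_categories - 1L)) {
    stop_navcog("ratings outside the declared scale",
                class = "navcog_validation_error")
  }
  sum(ratings - category_floor) / (n * (n_categories - 1L))
}

#' Score-type confidence interval for Aiken's V
#'
#' Treats the rating sum as `k = n * (c - 1)` Bernoulli-like units and
#' inverts the normal score test, the same construction as the Wilson
#' interval for a binomial proportion:
#' `L, U = (2kV + z^2 -/+ z * sqrt(4kV(1 - V) + z^2)) / (2(k + z^2))`.
#' A Wald interval (`V -/+ z * sqrt(V(1-V)/k)`, clipped to \[0, 1\]) is
#' available for comparison.
#'
#' @param v Aiken's V estimate.
#' @param n Number of raters.
#' @param n_categories Number of ordinal categories.
#' @param confidence Confidence level in (0, 1).
#' @param method `"score"` (default) or `"wald"`.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
aiken_v_ci <- function(v, n, n_categories = 4L, confidence = 0.95,
                       method = c("score", "wald")) {
  method <- match.arg(method)
  assert_scalar_number(v, "v", lower = 0, upper = 1)
  n <- assert_count(n, "n", lower = 1L)
  n_categories <- assert_count(n_categories, "n_categories", lower = 2L)
  if (!is.numeric(confidence) || confidence <= 0 || confidence >= 1) {
    stop_navcog("confidence must lie strictly between 0 and 1",
                class = "navcog_validation_error")
  }
  k <- n * (n_categories - 1L)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  if (method == "score") {
    half <- z * sqrt(4 * k * v * (1 - v) + z^2)
    lower <- (2 * k * v + z^2 - half) / (2 * (k + z^2))
    upper <- (2 * k * v + z^2 + half) / (2 * (k + z^2))
  } else {
    half <- z * sqrt(v * (1 - v) / k)
    lower <- max(0, v - half)
    upper <- min(1, v + half)
  }
  c(lower = lower, upper = upper)
}

#' Content validity report for an expert rating matrix
#'
#' Computes, per item: the I-CVI, binomial chance agreement, modified kappa
#' with its interpretation label, and Aiken's V with a score-type confidence
#' interval.
#'
#' @param ratings A [rating_matrix()].
#' @param relevance_cut Dichotomization cut for the I-CVI.
#' @param confidence Confidence level for the V interval.
#' @return An object of class `content_validity_report`: a data frame with
#'   one row per item (columns `item`, `A`, `N`, `i_cvi`, `p_c`,
#'   `kappa_star`, `kappa_label`, `aiken_v`, `v_lower`, `v_upper`).
#' @export
content_validity <- function(ratings, relevance_cut = 3L, confidence = 0.95) {
  stopifnot(inherits(ratings, "rating_matrix"))
  c_cat <- attr(ratings, "n_categories")
  floor_ <- attr(ratings, "category_floor")
  items <- colnames(ratings) %||% paste0("item_", seq_len(ncol(ratings)))
  rows <- lapply(seq_len(ncol(ratings)), function(j) {
    col <- ratings[, j]
    cvi <- item_cvi(col, relevance_cut)
    pc <- chance_agreement_pc(cvi$N, cvi$A)
    kap <- modified_kappa(cvi$i_cvi, pc)
    v <- aiken_v(col, c_cat, floor_)
    ci <- aiken_v_ci(v, cvi$N, c_cat, confidence)
    data.frame(item = items[j], A = cvi$A, N = cvi$N, i_cvi = cvi$i_cvi,
               p_c = pc, kappa_star = kap$kappa_star,
               kappa_label = kap$label, aiken_v = v,
               v_lower = ci[["lower"]], v_upper = ci[["upper"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "dimension") <- attr(ratings, "dimension")
  attr(out, "confidence") <- confidence
  class(out) <- c("content_validity_report", "data.frame")
  out
}

#' @export
print.content_validity_report <- function(x, digits = 2, ...) {
  cat("Content validity (", attr(x, "dimension"), ", ",
      format(100 * attr(x, "confidence")), "% CI)\n", sep = "")
  disp <- data.frame(
    item = x$item,
    kappa = sprintf("%.2f", round_half_up(x$kappa_star, digits)),
    `Aiken V (CI)` = sprintf("%.2f (%.2f-%.2f)",
                             round_half_up(x$aiken_v, digits),
                             round_half_up(x$v_lower, digits),
                             round_half_up(x$v_upper, digits)),
    agreement = x$kappa_label,
    check.names = FALSE
  )
  print(disp, row.names = FALSE)
  invisible(x)
}
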