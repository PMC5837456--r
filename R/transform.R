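# Numerical transforms on the continuous pathway: inverse rank-normal
# transformation (IRNT), dominance check for heavily tied distributions, and
# equal-mass binning into ordered categories for the variables IRNT cannot
# serve.

#' Inverse rank-normal transformation
#'
#' Replaces each non-missing value by the normal quantile of its rank:
#' \eqn{\Phi^{-1}((r - 0.5)/n)} with 1-based rank \eqn{r} among the \eqn{n}
#' non-missing values. The half offset keeps quantiles off 0 and 1 and makes
#' the output antisymmetric about zero. Tied values receive ranks uniformly at
#' random under the given seed — acceptable when ties are rare, which is why
#' heavily tied variables are routed to [bin_to_ordered()] instead.
#'
#' @param values Numeric vector; `NA` = missing and stays missing.
#' @param seed Integer seed governing tie breaking.
#' @return Numeric vector of the same length, marginally standard normal.
#' @export
inverse_rank_normal <- function(values, seed = 1234L) {
  obs <- !is.na(values)
  x <- values[obs]
  phs_assert(length(unique(x)) >= 2L, "degenerate_distribution",
             "inverse rank-normal transform needs >=2 distinct values")
  r <- with_local_seed(seed, rank(x, ties.method = "random"))
  out <- values
  out[obs] <- stats::qnorm((r - 0.5) / length(x))
  out
}

#' Does a continuous-pathway variable need binning instead of IRNT?
#'
#' When a large share of participants hold one identical value (e.g. zero
#' alcohol intake), rank-normalising would assign random ranks within that
#' mass and inject pure noise. Such variables are binned into ordered
#' categories instead. The rule: the single most frequent value's share of
#' non-missing observations strictly exceeds `threshold`.
#'
#' @param values Numeric vector with >=2 distinct non-missing values.
#' @param threshold Dominance share above which binning is used (default 0.2).
#' @return `TRUE` if the variable should be binned.
#' @export
needs_binning <- function(values, threshold = 0.2) {
  x <- values[!is.na(values)]
  max(tabulate(match(x, unique(x)))) / length(x) > threshold
}

#' Bin a heavily tied variable into k ordered categories of near-equal mass
#'
#' Split points are placed strictly between distinct observed values, chosen
#' to minimise the maximum absolute deviation of category counts from `n/k`
#' (ties broken towards the lowest split values). Category labels `1..k`
#' preserve the value order. With fewer than `k` (but more than 2) distinct
#' values, each distinct value becomes its own category.
#'
#' @param values Numeric vector (NA = missing).
#' @param k Number of categories (default 3).
#' @return List with `labels` (integer categories, NA preserved), `splits`
#'   (numeric split points) and `counts` (per-category counts).
#' @export
bin_to_ordered <- function(values, k = 3L) {
  obs <- which(!is.na(values))
  x <- values[obs]
  dv <- sort(unique(x))
  d <- length(dv)
  phs_assert(d > 2L, "degenerate_distribution",
             "binning needs more than 2 distinct values (2 distinct routes to BINARY)")
  out <- rep(NA_integer_, length(values))
  if (d <= k) {
    out[obs] <- match(x, dv)
    return(list(labels = out, splits = utils::head(dv, -1) + diff(dv) / 2,
                counts = tabulate(out[obs], d)))
  }
  counts <- tabulate(match(x, dv), d)
  cum <- cumsum(counts)
  n <- length(x)
  target <- n / k
  # enumerate all (k-1)-subsets of the d-1 gaps between distinct values;
  # k = 3 vectorised, general k via combn
  if (k == 3L) {
    ij <- which(upper.tri(matrix(0, d - 1, d - 1)), arr.ind = TRUE)  # i < j
    s1 <- cum[ij[, 1]]
    s2 <- cum[ij[, 2]] - cum[ij[, 1]]
    s3 <- n - cum[ij[, 2]]
    score <- pmax(abs(s1 - target), abs(s2 - target), abs(s3 - target))
    # tie-break to lowest split values: among minimal scores, smallest (i, j)
    cand <- which(score == min(score))
    cand <- cand[order(ij[cand, 1], ij[cand, 2])][1]
    gaps <- c(ij[cand, 1], ij[cand, 2])
  } else {
    combos <- utils::combn(d - 1L, k - 1L)
    score <- apply(combos, 2L, function(g) {
      sizes <- diff(c(0, cum[g], n))
      max(abs(sizes - target))
    })
    cand <- which(score == min(score))[1]  # combn enumerates lexicographically
    gaps <- combos[, cand]
  }
  splits <- dv[gaps] + diff(dv)[gaps] / 2
  out[obs] <- findInterval(x, splits) + 1L
  list(labels = out, splits = splits, counts = tabulate(out[obs], k))
}

#' Route an integer field by its number of distinct values
#'
#' Integer fields with few distinct values behave like categories: 2 distinct
#' values are binary, 3–20 are ordered categorical in natural numeric order,
#' and more than 20 are treated exactly like continuous variables (IRNT or
#' binning).
#'
#' @param values Numeric vector after recoding.
#' @return `"BINARY"`, `"ORDERED"` or `"CONTINUOUS_PATH"`.
#' @export
classify_integer <- function(values) {
  d <- n_distinct_nonmissing(values)
  phs_assert(d >= 2L, "degenerate_distribution",
             "integer field has <2 distinct non-missing values")
  if (d == 2L) "BINARY" else if (d <= 20L) "ORDERED" else "CONTINUOUS_PATH"
}
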