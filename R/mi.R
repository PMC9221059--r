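# Mutual information estimation by adaptive partitioning on
# copula-transformed (rank) data. The compute kernel lives in src/apmi.cpp.

#' Copula (rank) transform of an expression matrix
#'
#' Maps every protein's values to rank/N in (0, 1], making marginals
#' uniform so mutual information can be estimated on the copula. Ties are
#' broken by a small seeded jitter applied before ranking, so constant or
#' tied rows still yield a valid permutation of ranks and the result is
#' reproducible under the same seed.
#'
#' @param m an [expression_matrix()] (complete) or a numeric matrix with
#'   rows = proteins.
#' @param seed integer seed for tie-breaking jitter.
#' @return numeric matrix of the same shape; every row is a permutation of
#'   `(1/N, 2/N, ..., 1)`. Carries attribute `ranked = TRUE`.
#' @export
copula_rank_transform <- function(m, seed = 1) {
  vals <- if (inherits(m, "expr_matrix")) m$values else m
  if (!is.matrix(vals) || !is.numeric(vals)) stop("'m' must be numeric")
  if (anyNA(vals)) stop("matrix has missing values; filter/impute first")
  n <- ncol(vals)
  if (n < 8) stop("need at least 8 samples for rank-based MI")
  out <- with_seed(seed, {
    t(apply(vals, 1, function(x) {
      if (anyDuplicated(x)) {
        if (max(x) == min(x)) {
          warning("constant row; ranks assigned at random")
          x <- x + runif(n)
        } else {
          gaps <- diff(sort(unique(x)))
          x <- x + runif(n, 0, min(gaps) / 2)
        }
      }
      rank(x) / n
    }))
  })
  dimnames(out) <- dimnames(vals)
  attr(out, "ranked") <- TRUE
  out
}

#' Adaptive-partitioning mutual information of two ranked vectors
#'
#' Recursively splits the copula unit square at cell midpoints into four
#' quadrants; a cell with n points is split while the chi-square statistic
#' of the quadrant counts against local uniformity,
#' \eqn{X^2 = \sum (obs - n/4)^2 / (n/4)}, exceeds `chi2_crit` and
#' n >= `min_points`. Each leaf cell contributes
#' \eqn{(n/N) \log[(n/N) / \mathrm{area}]}; the sum (floored at 0) is the
#' MI estimate in nats.
#'
#' @param x,y numeric vectors of equal length N >= 8 with values in
#'   (0, 1] (rows of [copula_rank_transform()]).
#' @param chi2_crit chi-square splitting threshold; the default 7.815 is
#'   the 95% point at 3 degrees of freedom.
#' @param min_points smallest cell size eligible for splitting.
#' @return mutual information in nats (>= 0).
#' @export
apmi <- function(x, y, chi2_crit = 7.815, min_points = 8) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (length(x) < 8) stop("need at least 8 points")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  apmi_cpp(as.numeric(x), as.numeric(y), chi2_crit, as.integer(min_points))
}

#' Mutual information for all protein pairs
#'
#' @param ranked matrix from [copula_rank_transform()].
#' @inheritParams apmi
#' @return data.frame with columns `a`, `b` (protein pair, `a` < `b`
#'   lexicographically) and `mi` (nats), covering all n(n-1)/2 pairs.
#' @export
allpairs_mi <- function(ranked, chi2_crit = 7.815, min_points = 8) {
  n <- nrow(ranked)
  if (n < 2) stop("need at least two proteins")
  mi <- allpairs_mi_cpp(ranked, chi2_crit, as.integer(min_points))
  ids <- rownames(ranked)
  i <- rep(seq_len(n - 1), times = (n - 1):1)
  j <- sequence((n - 1):1) + i
  a <- ids[i]; b <- ids[j]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  data.frame(a = a, b = b, mi = mi, stringsAsFactors = FALSE)
}
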