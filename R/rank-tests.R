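#' @importFrom stats wilcox.test kruskal.test pnorm pchisq rnbinom rlnorm
NULL

#' Two-sample Wilcoxon rank-sum test
#'
#' Midranks for ties; two-sided p. Uses exact enumeration when the pooled
#' sample size is at most 12 and there are no ties, otherwise the normal
#' approximation with tie-corrected variance and continuity correction.
#' Degenerate input with every observation tied returns p = 1.
#'
#' @param x,y Non-empty numeric vectors.
#' @return List with `statistic` (Mann-Whitney U of `x`), `p.value`
#'   (two-sided) and `exact` (logical, branch taken).
#' @export
#' @examples
#' wilcoxonRankSum(c(5, 6, 7), c(1, 2, 3))$p.value  # 0.1, exact
wilcoxonRankSum <- function(x, y) {
  if (length(x) < 1L || length(y) < 1L) stop("both groups must be non-empty")
  if (length(unique(c(x, y))) == 1L)
    return(list(statistic = length(x) * length(y) / 2, p.value = 1,
                exact = FALSE))
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && (length(x) + length(y) <= 12L)
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  p <- wt$p.value
  if (is.na(p)) p <- 1
  list(statistic = unname(wt$statistic), p.value = min(1, p), exact = exact)
}

#' Kruskal-Wallis rank test
#'
#' H statistic with midrank tie correction; p from the chi-square
#' distribution with k - 1 degrees of freedom. All observations tied across
#' groups returns H = 0, p = 1.
#'
#' @param groups List of at least two non-empty numeric vectors (total
#'   n >= 3).
#' @return List with `statistic` (H), `p.value` and `df`.
#' @export
#' @examples
#' kruskalWallis(list(c(1, 2), c(3, 4), c(5, 6)))  # H = 4.5714, p = 0.1017
kruskalWallis <- function(groups) {
  if (length(groups) < 2L) stop("need at least two groups")
  sizes <- lengths(groups)
  if (any(sizes == 0L)) {
    nm <- names(groups)
    bad <- if (is.null(nm)) which(sizes == 0L) else nm[sizes == 0L]
    stop("empty group(s): ", paste(bad, collapse = ", "))
  }
  v <- unlist(groups, use.names = FALSE)
  if (length(v) < 3L) stop("need total n >= 3")
  if (length(unique(v)) == 1L)
    return(list(statistic = 0, p.value = 1, df = length(groups) - 1L))
  g <- factor(rep(seq_along(groups), sizes))
  kt <- stats::kruskal.test(v, g)
  list(statistic = unname(kt$statistic), p.value = unname(kt$p.value),
       df = unname(kt$parameter))
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)` with an explicit test count `m`, which may exceed
#' the number of p values supplied (e.g. when some contrasts were screened
#' out after testing).
#'
#' @param p Numeric vector of p values.
#' @param m Number of tests, `m >= length(p)`.
#' @return Adjusted p values, capped at 1.
#' @export
#' @examples
#' bonferroniAdjust(c(0.004, 0.2), m = 10)
bonferroniAdjust <- function(p, m = length(p)) {
  if (m < length(p)) stop("m must be >= number of p values")
  pmin(1, m * p)
}

# ---- vectorized row-wise implementations used by the DEG/marker callers ----
# Same math as the scalar ops (midranks, tie-corrected variance); validated
# against stats::kruskal.test / stats::wilcox.test in the test suite.

# mat: genes x cells (dense), g: factor of group membership.
# Returns data.frame(H, p) per row. Rows that are all-tied get p = 1.
.rowKruskal <- function(mat, g) {
  g <- droplevels(as.factor(g))
  k <- nlevels(g)
  n <- length(g)
  stopifnot(ncol(mat) == n, k >= 2L)
  idx <- split(seq_len(n), g)
  sizes <- lengths(idx)
  H <- p <- numeric(nrow(mat))
  for (i in seq_len(nrow(mat))) {
    v <- mat[i, ]
    r <- rank(v)
    S <- vapply(idx, function(j) sum(r[j]), numeric(1))
    h <- 12 / (n * (n + 1)) * sum(S^2 / sizes) - 3 * (n + 1)
    u <- match(v, v)
    tj <- tabulate(u)[unique(u)]
    tie <- 1 - sum(tj^3 - tj) / (n^3 - n)
    if (tie <= 0) { H[i] <- 0; p[i] <- 1; next }
    H[i] <- h / tie
    p[i] <- stats::pchisq(H[i], k - 1L, lower.tail = FALSE)
  }
  data.frame(H = H, p = p)
}

# One-vs-rest Wilcoxon per row, normal approximation with tie-corrected
# variance and continuity correction (the large-n branch of the scalar op).
# idx1: column indices of the target group. Returns W, p, delta (mean of
# target minus mean of rest).
.rowWilcoxon <- function(mat, idx1) {
  n <- ncol(mat)
  m1 <- length(idx1)
  m2 <- n - m1
  stopifnot(m1 >= 1L, m2 >= 1L)
  W <- p <- delta <- numeric(nrow(mat))
  for (i in seq_len(nrow(mat))) {
    v <- mat[i, ]
    r <- rank(v)
    w <- sum(r[idx1]) - m1 * (m1 + 1) / 2
    W[i] <- w
    delta[i] <- mean(v[idx1]) - mean(v[-idx1])
    u <- match(v, v)
    tj <- tabulate(u)[unique(u)]
    sigma2 <- (m1 * m2 / 12) * ((n + 1) - sum(tj^3 - tj) / (n * (n - 1)))
    if (sigma2 <= 0) { p[i] <- 1; next }
    z <- w - m1 * m2 / 2
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p[i] <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  data.frame(W = W, p = p, delta = delta)
}
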