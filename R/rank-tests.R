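# Exact small-sample rank tests.
#
# The study designs behind this package are tiny (n = 4 mice per group,
# n = 9 regions), where printed p-values come from full enumeration of the
# rank statistic's null distribution.  These implementations take the exact
# path whenever the design is small enough and fall back to the usual
# asymptotic approximations (flagged `exact = FALSE`) otherwise.

# all permutations of 1..n as an (n!, n) integer matrix
perms_all <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sp <- perms_all(n - 1L)
  k <- nrow(sp)
  out <- matrix(0L, n * k, n)
  for (pos in seq_len(n)) {
    rows <- ((pos - 1L) * k + 1L):(pos * k)
    if (pos == 1L) out[rows, ] <- cbind(n, sp)
    else if (pos == n) out[rows, ] <- cbind(sp, n)
    else out[rows, ] <- cbind(sp[, 1:(pos - 1L), drop = FALSE], n,
                              sp[, pos:(n - 1L), drop = FALSE])
  }
  out
}

#' Mann-Whitney (Wilcoxon rank-sum) test with exact enumeration
#'
#' Two-sided exact p-values by full enumeration of the U distribution over
#' all `choose(n_x + n_y, n_x)` rank assignments when the combined sample has
#' at most 20 observations and no ties.  With ties or larger samples, the
#' mid-rank statistic with a tie-corrected normal approximation is used and
#' flagged `exact = FALSE`.
#'
#' @param x,y numeric vectors (both nonempty).
#' @param alternative `"two-sided"`, `"less"` or `"greater"` (of x relative
#'   to y).
#' @return a [cm_test] object; `statistic` is U for the first sample.
#' @examples
#' # complete separation with n = 4 per group: exact p = 2/70 = 0.0286
#' mann_whitney_exact(c(1, 2, 3, 4), c(5, 6, 7, 8))
#' @export
mann_whitney_exact <- function(x, y, alternative = "two-sided") {
  alternative <- match.arg(alternative, c("two-sided", "less", "greater"))
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  nx <- length(x); ny <- length(y)
  if (nx == 0L || ny == 0L) stopf("both groups must be nonempty")
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  if (!ties && nx + ny <= 20L) {
    sets <- utils::combn(nx + ny, nx)
    u_all <- colSums(matrix(seq_len(nx + ny)[sets], nrow = nx)) -
      nx * (nx + 1) / 2
    tol <- 1e-9
    p_le <- mean(u_all <= u_obs + tol)
    p_ge <- mean(u_all >= u_obs - tol)
    p <- switch(alternative,
                "two-sided" = min(1, 2 * min(p_le, p_ge)),
                "less" = p_le,
                "greater" = p_ge)
    return(cm_test(statistic = u_obs, p_value = p,
                   method = "Mann-Whitney U test (exact enumeration)",
                   n = c(nx, ny), exact = TRUE))
  }
  # tie-corrected normal approximation
  n <- nx + ny
  mu <- nx * ny / 2
  tie_tab <- table(pooled)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  sigma <- sqrt(nx * ny / 12 * ((n + 1) - tie_corr))
  z <- (u_obs - mu) / sigma
  p <- switch(alternative,
              "two-sided" = 2 * stats::pnorm(-abs(z)),
              "less" = stats::pnorm(z),
              "greater" = stats::pnorm(z, lower.tail = FALSE))
  cm_test(statistic = u_obs, p_value = min(1, p),
          method = "Mann-Whitney U test (normal approximation, mid-ranks)",
          n = c(nx, ny), exact = FALSE)
}

# enumerate all partitions of indices 1..N into groups of the given sizes;
# returns an integer matrix (N rows, one column per partition) of group labels
enum_partitions <- function(sizes) {
  N <- sum(sizes)
  k <- length(sizes)
  recurse <- function(avail, gi) {
    if (gi == k) {
      lab <- integer(N); lab[avail] <- k
      return(matrix(lab, ncol = 1))
    }
    picks <- utils::combn(length(avail), sizes[gi])
    cols <- lapply(seq_len(ncol(picks)), function(j) {
      chosen <- avail[picks[, j]]
      rest <- avail[-picks[, j]]
      sub <- recurse(rest, gi + 1L)
      sub[chosen, ] <- gi
      sub
    })
    do.call(cbind, cols)
  }
  recurse(seq_len(N), 1L)
}

# tie-corrected Kruskal-Wallis H from pooled ranks and group labels
kw_h <- function(r, lab, sizes) {
  N <- length(r)
  ssq <- vapply(seq_along(sizes), function(g) sum(r[lab == g])^2 / sizes[g],
                numeric(1))
  h <- 12 / (N * (N + 1)) * sum(ssq) - 3 * (N + 1)
  tie_tab <- table(r)
  corr <- 1 - sum(tie_tab^3 - tie_tab) / (N^3 - N)
  if (corr > 0) h / corr else 0
}

#' Kruskal-Wallis test with exact permutation p-value for small designs
#'
#' Computes the tie-corrected H statistic.  When the pooled sample has at
#' most 12 observations the p-value is obtained by enumerating every
#' assignment of the pooled ranks to the groups; otherwise the chi-square
#' approximation is used and flagged `exact = FALSE`.
#'
#' @param groups list of numeric vectors (>= 3 nonempty groups).
#' @return a [cm_test] object.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 3L) stopf("need at least 3 groups")
  groups <- lapply(groups, function(g) g[is.finite(g)])
  if (any(lengths(groups) == 0L)) stopf("all groups must be nonempty")
  sizes <- lengths(groups)
  pooled <- unlist(groups)
  N <- length(pooled)
  lab <- rep(seq_along(groups), sizes)
  r <- rank(pooled)
  if (stats::var(pooled) == 0)
    return(cm_test(statistic = 0, p_value = 1,
                   method = "Kruskal-Wallis test (degenerate: all values equal)",
                   n = sizes, exact = TRUE))
  h_obs <- kw_h(r, lab, sizes)
  if (N <= 12L) {
    labs <- enum_partitions(sizes)
    h_all <- vapply(seq_len(ncol(labs)), function(j) kw_h(r, labs[, j], sizes),
                    numeric(1))
    p <- mean(h_all >= h_obs - 1e-9)
    return(cm_test(statistic = h_obs, p_value = p,
                   method = "Kruskal-Wallis test (exact enumeration)",
                   n = sizes, exact = TRUE))
  }
  p <- stats::pchisq(h_obs, df = length(groups) - 1L, lower.tail = FALSE)
  cm_test(statistic = h_obs, p_value = p,
          method = "Kruskal-Wallis test (chi-square approximation)",
          n = sizes, exact = FALSE)
}

#' Spearman rank correlation with exact permutation p-value
#'
#' Spearman's rho from mid-ranks.  For `n <= 9` the two-sided p-value is
#' exact, from full enumeration of all `n!` permutations of one variable's
#' ranks; for larger n the t approximation on `n - 2` degrees of freedom is
#' used and flagged `exact = FALSE`.
#'
#' @param x,y paired numeric vectors, `n >= 4`.
#' @return a [cm_test] object (statistic = rho).
#' @export
spearman <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stopf("need at least 4 complete pairs, got %d", n)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stopf("Spearman correlation undefined for constant input")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 9L) {
    P <- perms_all(n)
    RY <- matrix(ry[P], nrow(P), n)
    s <- as.vector(RY %*% rx)
    mx <- mean(rx); my <- mean(ry)
    denom <- sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
    rho_all <- (s - n * mx * my) / denom
    p <- mean(abs(rho_all) >= abs(rho) - 1e-9)
    return(cm_test(statistic = rho, p_value = p,
                   method = "Spearman rank correlation (exact enumeration)",
                   n = n, exact = TRUE))
  }
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  cm_test(statistic = rho, p_value = min(1, p),
          method = "Spearman rank correlation (t approximation)",
          n = n, exact = FALSE)
}
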