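#' Circular correlation between paired angle samples
#'
#' Computes the circular correlation coefficient of Jammalamadaka and
#' SenGupta,
#' \deqn{\rho_c = \frac{\sum \sin(a_i-\bar a)\sin(b_i-\bar b)}
#'   {\sqrt{\sum \sin^2(a_i-\bar a)\sum \sin^2(b_i-\bar b)}},}
#' with \eqn{\bar a,\bar b} the circular means, together with its asymptotic
#' normal p-value.  Axial data (angles defined modulo pi, such as fiber axes)
#' are doubled before applying the directional formula.
#'
#' @param angles_a,angles_b paired numeric vectors of angles in radians.
#' @param axial logical; TRUE when the angles are axial (pi-periodic).
#' @return a [cm_test] object (statistic = rho_c).
#' @export
angular_correlation <- function(angles_a, angles_b, axial = FALSE) {
  ok <- is.finite(angles_a) & is.finite(angles_b)
  a <- angles_a[ok]; b <- angles_b[ok]
  n <- length(a)
  if (n < 5L) stopf("need at least 5 valid angle pairs, got %d", n)
  if (axial) { a <- 2 * a; b <- 2 * b }
  sa <- sin(a - circ_mean(a))
  sb <- sin(b - circ_mean(b))
  ssa <- sum(sa^2); ssb <- sum(sb^2)
  if (ssa < 1e-12 || ssb < 1e-12)
    stopf("circular correlation undefined: zero circular variance in a sample")
  rho <- sum(sa * sb) / sqrt(ssa * ssb)
  l20 <- mean(sa^2); l02 <- mean(sb^2); l22 <- mean(sa^2 * sb^2)
  z <- sqrt(n * l20 * l02 / l22) * rho
  p <- 2 * stats::pnorm(-abs(z))
  p <- min(max(p, .Machine$double.xmin), 1)
  cm_test(statistic = rho, p_value = p,
          method = "Circular correlation (Jammalamadaka-SenGupta)",
          n = n, exact = FALSE,
          extra = list(z = z, axial = axial))
}

#' Mantel-style permutation test of association between two angle matrices
#'
#' Tests whether two spatial angle maps co-vary, using the circular
#' correlation coefficient over jointly valid entries as the statistic.  The
#' null distribution is built by applying one random permutation per
#' iteration simultaneously to the rows and columns of `matrix_b` (the joint
#' row/column scheme of matrix-similarity Mantel tests), which preserves the
#' within-map spatial structure while breaking the cross-map pairing.  The
#' p-value is the one-sided permutation estimate
#' `(1 + #(null >= observed)) / (1 + n_perm)`.
#'
#' @param matrix_a,matrix_b square numeric matrices of angles (radians), or
#'   [map_matrix] objects; non-finite entries are treated as invalid.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed; the global RNG state is untouched.
#' @param axial logical; double angles before correlating (axial data).
#' @return a [cm_test] object (statistic = observed rho_c).
#' @export
mantel_matrix_test <- function(matrix_a, matrix_b, n_perm = 1000, seed = 1,
                               axial = FALSE) {
  va <- if (inherits(matrix_a, "map_matrix")) matrix_a$values else matrix_a
  vb <- if (inherits(matrix_b, "map_matrix")) matrix_b$values else matrix_b
  if (!identical(dim(va), dim(vb))) stopf("matrices must have the same shape")
  if (nrow(va) != ncol(va))
    stopf("joint row/column permutation requires square matrices")
  if (n_perm < 99) stopf("n_perm must be at least 99")
  maska <- is.finite(va); maskb <- is.finite(vb)
  both <- maska & maskb
  if (sum(both) < 25L) stopf("too few jointly valid entries (%d < 25)", sum(both))
  obs <- angular_correlation(va[both], vb[both], axial = axial)$statistic
  n <- nrow(va)

  full <- all(maska) && all(maskb)
  null_stat <- numeric(n_perm)
  if (full) {
    # joint permutation preserves the entry multiset, so the circular means
    # (and hence the sin-residuals) can be computed once
    a <- as.vector(va); b <- vb
    if (axial) { a <- 2 * a; b <- 2 * b }
    sa <- sin(a - circ_mean(a))
    sb <- sin(b - circ_mean(as.vector(b)))
    denom <- sqrt(sum(sa^2) * sum(sb^2))
    null_stat <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        p <- sample.int(n)
        sum(sa * as.vector(sb[p, p])) / denom
      }, numeric(1))
    })
  } else {
    null_stat <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        p <- sample.int(n)
        vbp <- vb[p, p]
        ok <- maska & is.finite(vbp)
        if (sum(ok) < 25L) return(NA_real_)
        angular_correlation(va[ok], vbp[ok], axial = axial)$statistic
      }, numeric(1))
    })
    null_stat <- null_stat[is.finite(null_stat)]
  }
  pval <- (1 + sum(null_stat >= obs - 1e-12)) / (1 + length(null_stat))
  cm_test(statistic = obs, p_value = pval,
          method = "Mantel matrix permutation test (circular correlation)",
          n = sum(both), exact = FALSE, seed = seed,
          extra = list(n_perm = length(null_stat), axial = axial))
}
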