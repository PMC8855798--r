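#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a test result
#'
#' @param x a [cm_test].
#' @param ... unused.
#' @return one-row tibble with `method`, `statistic`, `p_value`, `n`,
#'   `exact`.
#' @export
tidy.cm_test <- function(x, ...) {
  tibble::tibble(method = x$method, statistic = x$statistic,
                 p_value = x$p_value, n = paste(x$n, collapse = ","),
                 exact = isTRUE(x$exact))
}

#' @rdname tidy.cm_test
#' @export
glance.cm_test <- function(x, ...) tidy(x)

#' Tidy a fitted homography
#'
#' @param x a `cm_homography`.
#' @param ... unused.
#' @return per-point residual tibble (`point`, `residual_px`, `inlier`,
#'   `label`).
#' @export
tidy.cm_homography <- function(x, ...) x$residuals

#' @rdname tidy.cm_homography
#' @export
glance.cm_homography <- function(x, ...) {
  tibble::tibble(n = x$n, n_inliers = sum(x$residuals$inlier),
                 rmse_px = x$rmse, det = det(x$H))
}

#' Tidy a traced fiber graph
#'
#' @param x a `fiber_graph`.
#' @param ... unused.
#' @return the segment table of [fiber_segments()] without the path column.
#' @export
tidy.fiber_graph <- function(x, ...) {
  s <- fiber_segments(x)
  s$path <- NULL
  s
}

#' @rdname tidy.fiber_graph
#' @export
glance.fiber_graph <- function(x, ...) {
  s <- fiber_segments(x)
  tibble::tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
                 n_segments = nrow(s), total_length_um = sum(s$length_um))
}
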