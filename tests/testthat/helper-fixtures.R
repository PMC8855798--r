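# Shared fixtures, built in code at test time.

# single synthetic optical AP trace on a ms grid
sigmoid_trace <- function(t, t_act = 5, apd = 50, tau = 1) {
  up <- 1 / (1 + exp(-(t - t_act) / tau))
  s <- pmax(t - t_act, 0)
  up * exp(-log(5) * (s / apd)^3)
}

# straight-line fiber spec for the nerve renderer
tube_spec <- function(fiber, x0, y0, x1, y1, diameter_um, n = 20) {
  tibble::tibble(fiber = fiber,
                 x_um = seq(x0, x1, length.out = n),
                 y_um = seq(y0, y1, length.out = n),
                 diameter_um = diameter_um)
}

# hand-built fiber graph: two near-horizontal fibers plus an optional bridge
two_fiber_graph <- function(slope = 0.0875, bridge = TRUE, radius_um = 1.5) {
  n1 <- tibble::tibble(node = 1:21, x = as.numeric(0:20),
                       y = 5 + slope * (0:20), radius_um = radius_um)
  n2 <- tibble::tibble(node = 22:42, x = as.numeric(0:20),
                       y = 10 - slope * (0:20), radius_um = radius_um)
  nodes <- dplyr::bind_rows(n1, n2)
  edges <- tibble::tibble(from = c(1:20, 22:41), to = c(2:21, 23:42))
  if (bridge)
    edges <- dplyr::bind_rows(edges, tibble::tibble(from = 11, to = 32))
  cardiomapr:::fiber_graph(nodes, edges, 1)
}

# well-spread random correspondences under a known homography
random_fiducials <- function(H, n = 8, seed = 1, jitter = 0) {
  set.seed(seed)
  src <- cbind(stats::runif(n, 5, 90), stats::runif(n, 5, 90))
  dst <- project_points(H, src)
  if (jitter > 0) {
    src <- src + stats::rnorm(2 * n, 0, jitter)
    dst <- dst + stats::rnorm(2 * n, 0, jitter)
  }
  tibble::tibble(x_optical = dst[, 1], y_optical = dst[, 2],
                 x_structural = src[, 1], y_structural = src[, 2])
}

H_example <- matrix(c(1.05, 0.02, 4, -0.03, 0.98, -3, 5e-5, -4e-5, 1),
                    3, 3, byrow = TRUE)
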