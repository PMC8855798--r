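# Regional composite analyses: per-ROI metric tables, the myofiber
# anisotropy vs tissue-activation-time composite that localises infarct
# border zones, and regional delta-APD comparisons.

#' Per-ROI metric table
#'
#' Computes, for every non-scar ROI of a segmentation, the metrics that are
#' available from the supplied inputs: myofiber anisotropy index, normalised
#' tissue activation time, median delta-APD80, and per-bin nerve-fiber
#' prevalence.  Dense scar is always excluded (no surviving myocytes).
#'
#' @param rois a `roi_set` from [segment_rois()].
#' @param orientation an [orientation_field] aligned to the ROI grid.
#' @param activation an activation-time [map_matrix].
#' @param delta_apd a delta-APD [map_matrix].
#' @param nerve_graph a `fiber_graph` in the same frame.
#' @param min_roi_px ROIs with fewer valid pixels are dropped with a warning.
#' @return tibble with one row per ROI: `roi`, `n_pixels`, and whichever of
#'   `anisotropy_index`, `tissue_activation_time`, `delta_apd80_median`,
#'   `prev_small`, `prev_medium`, `prev_large` could be computed.
#' @export
region_table <- function(rois, orientation = NULL, activation = NULL,
                         delta_apd = NULL, nerve_graph = NULL,
                         min_roi_px = 20) {
  stopifnot(inherits(rois, "roi_set"))
  labels <- roi_labels(rois, include_scar = FALSE)
  whole <- NULL
  if (!is.null(nerve_graph)) whole <- bin_lengths(nerve_graph)
  rows <- lapply(labels, function(lb) {
    m <- roi_mask(rois, lb)
    out <- tibble::tibble(roi = lb, n_pixels = sum(m))
    if (!is.null(orientation)) {
      out$anisotropy_index <- tryCatch(
        anisotropy_index(orientation, m)$index, error = function(e) NA_real_)
    }
    if (!is.null(activation)) {
      out$tissue_activation_time <- tryCatch(
        tissue_activation_time(activation, m), error = function(e) NA_real_)
    }
    if (!is.null(delta_apd)) {
      v <- delta_apd$values[m & delta_apd$valid_mask]
      out$delta_apd80_median <- if (length(v)) stats::median(v, na.rm = TRUE)
      else NA_real_
    }
    if (!is.null(nerve_graph)) {
      prev <- prevalence_index(bin_lengths(nerve_graph, roi_mask = m), whole)
      out$prev_small <- prev$prevalence[prev$bin == "small"]
      out$prev_medium <- prev$prevalence[prev$bin == "medium"]
      out$prev_large <- prev$prevalence[prev$bin == "large"]
    }
    out
  })
  out <- dplyr::bind_rows(rows)
  small <- out$n_pixels < min_roi_px
  if (any(small)) {
    warnf("dropping %d ROI(s) with fewer than %d pixels", sum(small), min_roi_px)
    out <- out[!small, , drop = FALSE]
  }
  out
}

#' Anisotropy vs activation-time composite
#'
#' The structure-function composite that localises infarct border zones:
#' each ROI contributes a point (anisotropy index, normalised tissue
#' activation time); within each group the association is tested by exact
#' Spearman correlation.  In infarcted hearts the BZ is expected in the
#' high-anisotropy, slow-activation corner and the group correlation is
#' positive; in sham hearts the points cluster low/fast with negligible
#' correlation.
#'
#' @param region_table tibble with columns `roi`, `anisotropy_index`,
#'   `tissue_activation_time`, and optionally `group` (one test per group)
#'   and `heart`.
#' @return list with `data` (rows used, BZ flagged) and `tests` (tibble of
#'   per-group Spearman results: `group`, `rho`, `p_value`, `n`, `exact`).
#' @export
bz_composite <- function(region_table) {
  need <- c("roi", "anisotropy_index", "tissue_activation_time")
  stopifnot(all(need %in% names(region_table)))
  d <- region_table
  keep <- stats::complete.cases(d[, c("anisotropy_index",
                                      "tissue_activation_time")])
  if (any(!keep)) warnf("dropping %d ROI row(s) with missing metrics",
                        sum(!keep))
  d <- d[keep, , drop = FALSE]
  if (nrow(d) < 3L) stopf("need at least 3 regions with complete metrics")
  if (!"group" %in% names(d)) d$group <- "all"
  d$is_bz <- d$roi == "BZ"
  tests <- lapply(split(d, d$group), function(g) {
    if (nrow(g) < 4L) {
      warnf("group '%s' has fewer than 4 regions; correlation not tested",
            g$group[1])
      return(tibble::tibble(group = g$group[1], rho = NA_real_,
                            p_value = NA_real_, n = nrow(g), exact = NA))
    }
    ts <- spearman(g$anisotropy_index, g$tissue_activation_time)
    tibble::tibble(group = g$group[1], rho = ts$statistic,
                   p_value = ts$p_value, n = nrow(g), exact = ts$exact)
  })
  list(data = tibble::as_tibble(d), tests = dplyr::bind_rows(tests))
}

#' Regional delta-APD analysis
#'
#' Median delta-APD80 per ROI, a Kruskal-Wallis test of regional variation
#' (pixel values grouped by ROI), and - when per-ROI small-fiber prevalence
#' is supplied - Spearman correlations of regional delta-APD against
#' small-fiber prevalence computed with and without the BZ rows (nerve
#' sprouts at the BZ need not be functionally coupled, so the BZ can mask an
#' otherwise positive relationship).
#'
#' @param delta_map delta-APD [map_matrix], aligned to the ROI grid.
#' @param rois a `roi_set`; scar is excluded.
#' @param small_prevalence optional tibble with columns `roi`, `prev_small`
#'   (or per-heart rows `roi`, `prev_small`, `delta_apd80_median` given via
#'   `table` instead of `delta_map`/`rois`).
#' @param max_pixels_per_roi subsample cap on pixels per ROI for the
#'   Kruskal-Wallis test (keeps the test well-posed on large maps);
#'   deterministic thinning.
#' @param pooled_rows optional tibble of additional hearts' rows (`roi`,
#'   `delta_apd80_median`, `prev_small`) pooled into the correlations,
#'   mirroring a regions-from-several-hearts design.
#' @return list with `table` (per-ROI medians), `kruskal` ([cm_test]),
#'   `spearman_with_bz`, `spearman_without_bz` (NULL when prevalence is
#'   absent or too few regions remain).
#' @export
regional_delta_apd <- function(delta_map, rois, small_prevalence = NULL,
                               max_pixels_per_roi = 2000,
                               pooled_rows = NULL) {
  stopifnot(inherits(delta_map, "map_matrix"), inherits(rois, "roi_set"))
  labels <- roi_labels(rois, include_scar = FALSE)
  vals <- list(); med <- numeric(0); used <- character(0)
  for (lb in labels) {
    v <- delta_map$values[roi_mask(rois, lb) & delta_map$valid_mask]
    v <- v[is.finite(v)]
    if (length(v) == 0L) { warnf("empty ROI %s dropped", lb); next }
    if (length(v) > max_pixels_per_roi) {
      v <- v[round(seq(1, length(v), length.out = max_pixels_per_roi))]
    }
    vals[[lb]] <- v
    med <- c(med, stats::median(v)); used <- c(used, lb)
  }
  tab <- tibble::tibble(roi = used, delta_apd80_median = med,
                        n_pixels = lengths(vals)[used])
  kw <- if (length(vals) >= 3L) kruskal_wallis(vals) else NULL
  sp_with <- sp_without <- NULL
  if (!is.null(small_prevalence)) {
    j <- dplyr::inner_join(tab, small_prevalence, by = "roi")
    j <- j[, c("roi", "delta_apd80_median", "prev_small")]
    if (!is.null(pooled_rows))
      j <- dplyr::bind_rows(j, pooled_rows[, names(j)])
    if (nrow(j) >= 4L)
      sp_with <- spearman(j$prev_small, j$delta_apd80_median)
    jn <- j[j$roi != "BZ", , drop = FALSE]
    if (nrow(jn) >= 4L)
      sp_without <- spearman(jn$prev_small, jn$delta_apd80_median)
  }
  list(table = tab, kruskal = kw,
       spearman_with_bz = sp_with, spearman_without_bz = sp_without)
}
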