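# Anatomical region segmentation: dense scar and border zone from muscle
# autofluorescence intensity, LV base / LV apex / RV from user-supplied
# anatomical landmark lines.

.roi_levels <- c("LV_base", "LV_apex", "RV", "BZ", "scar", "excluded")

# signed side of the directed line a -> b for points (x, y): > 0 is left
.line_side <- function(a, b, x, y) {
  (b[1] - a[1]) * (y - a[2]) - (b[2] - a[2]) * (x - a[1])
}

#' Segment a heart image into anatomical ROIs
#'
#' Dense scar is detected as connected tissue whose autofluorescence falls
#' below `scar_frac` of the remote tissue median (surviving myocytes are
#' autofluorescent; scar is signal-void); the border zone (BZ) is the
#' non-scar tissue within `bz_width_um` of the scar.  The remaining tissue
#' is split by two user-supplied landmark lines: `lv_rv` (directed line with
#' the RV on its left) and `base_apex` (directed line with the base on its
#' left), mirroring segmentation by anatomical landmarks.
#'
#' @param autofluorescence intensity [map_matrix].
#' @param landmarks list with elements `lv_rv` and `base_apex`, each a 2x2
#'   matrix of `(x, y)` endpoints defining a directed line.
#' @param tissue_mask logical matrix; defaults to pixels above 20% of the
#'   remote median.
#' @param scar_frac scar intensity threshold as a fraction of the remote
#'   tissue median (default 0.3).
#' @param bz_width_um border-zone band width in micrometres (default 300).
#' @param min_scar_px smallest connected component accepted as scar.
#' @return an object of class `roi_set`: `label_map` (integer matrix, 0 =
#'   excluded), `legend` (named codes), `provenance` tibble.
#' @export
segment_rois <- function(autofluorescence, landmarks, tissue_mask = NULL,
                         scar_frac = 0.3, bz_width_um = 300,
                         min_scar_px = 20) {
  stopifnot(inherits(autofluorescence, "map_matrix"))
  stopifnot(all(c("lv_rv", "base_apex") %in% names(landmarks)))
  af <- autofluorescence$values
  h <- nrow(af); w <- ncol(af)
  pitch <- autofluorescence$pixel_pitch
  med_all <- stats::median(af[autofluorescence$valid_mask], na.rm = TRUE)
  tissue_mask <- tissue_mask %||% (af > 0.2 * med_all & autofluorescence$valid_mask)
  remote_med <- stats::median(af[tissue_mask], na.rm = TRUE)

  scar_cand <- tissue_mask & af < scar_frac * remote_med
  scar <- matrix(FALSE, h, w)
  if (any(scar_cand)) {
    lab <- EBImage::bwlabel(scar_cand)
    sizes <- table(lab[lab > 0])
    keep <- as.integer(names(sizes)[sizes >= min_scar_px])
    scar <- matrix(lab %in% keep, h, w)
  }
  bz <- matrix(FALSE, h, w)
  if (any(scar)) {
    dist_px <- EBImage::distmap((!scar) * 1)    # distance to nearest scar px
    bz <- tissue_mask & !scar & dist_px <= bz_width_um / pitch
  } else if (bz_width_um > 0) {
    warnf("no scar found; returning ROI set without scar/BZ")
  }

  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), times = w), h, w)
  lm1 <- as.matrix(landmarks$lv_rv); lm2 <- as.matrix(landmarks$base_apex)
  rv_side <- .line_side(lm1[1, ], lm1[2, ], xs, ys) > 0
  base_side <- .line_side(lm2[1, ], lm2[2, ], xs, ys) > 0

  label <- matrix(0L, h, w)
  rest <- tissue_mask & !scar & !bz
  label[rest & rv_side] <- 3L                       # RV
  label[rest & !rv_side & base_side] <- 1L          # LV_base
  label[rest & !rv_side & !base_side] <- 2L         # LV_apex
  label[bz] <- 4L
  label[scar] <- 5L

  legend <- stats::setNames(c(1L, 2L, 3L, 4L, 5L, 0L), .roi_levels)
  prov <- tibble::tibble(
    label = .roi_levels,
    provenance = c("anatomical landmark", "anatomical landmark",
                   "anatomical landmark", "autofluorescence intensity",
                   "autofluorescence intensity", "outside tissue")
  )
  structure(list(label_map = label, legend = legend, provenance = prov,
                 pixel_pitch = pitch),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat("<roi_set>\n")
  tab <- table(factor(x$label_map[x$label_map > 0],
                      levels = x$legend[.roi_levels[1:5]],
                      labels = .roi_levels[1:5]))
  print(tab)
  invisible(x)
}

#' Logical mask of one ROI
#'
#' @param rois a `roi_set`.
#' @param label ROI name (`"LV_base"`, `"LV_apex"`, `"RV"`, `"BZ"`,
#'   `"scar"`).
#' @return logical matrix.
#' @export
roi_mask <- function(rois, label) {
  stopifnot(inherits(rois, "roi_set"))
  code <- rois$legend[[label]]
  rois$label_map == code
}

#' ROI labels present in a segmentation
#'
#' @param rois a `roi_set`.
#' @param include_scar include the scar label (excluded from quantitative
#'   analyses by default, since dense scar has no surviving myocytes).
#' @return character vector.
#' @export
roi_labels <- function(rois, include_scar = FALSE) {
  present <- .roi_levels[rois$legend[.roi_levels] %in% unique(as.vector(rois$label_map))]
  present <- setdiff(present, "excluded")
  if (!include_scar) present <- setdiff(present, "scar")
  present
}
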