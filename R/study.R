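# End-to-end phantom "study": one synthetic heart processed exactly like a
# mapped heart, and families of hearts for the structure-function composite.

#' Build and analyse one phantom heart end-to-end
#'
#' Generates a phantom under an infarcted (`"mi"`) or control (`"sham"`)
#' condition, simulates anisotropic activation from an LV pacing site,
#' segments ROIs from the autofluorescence image and landmark lines, and
#' assembles the per-ROI metric table.  Per-heart variation (fiber-field
#' phase, pacing location, conduction speed, landmark placement) is drawn
#' deterministically from `seed`, so hearts differ from one another the way
#' biological replicates do while remaining reproducible.
#'
#' Conditions: MI hearts use disorder level 0.7, a 2 mm scar and a 600 um
#' border zone; sham hearts disorder 0.15 and no scar.  Frame 64 x 64 px at
#' 220 um/px (a desk-scale stand-in for 256 x 256 at 55 um); conduction
#' speeds 0.45-0.6 mm/ms along fibers with anisotropy ratio 2.5.
#'
#' @param seed integer seed.
#' @param condition `"mi"` or `"sham"`.
#' @param size frame size in px.
#' @param pixel_pitch micrometres per pixel.
#' @return list with `phantom`, `orientation` ([orientation_field]),
#'   `activation` ([map_matrix]), `rois` (`roi_set`), and `table` (per-ROI
#'   metrics with a `heart` column).
#' @export
phantom_heart_study <- function(seed, condition = c("mi", "sham"),
                                size = 64, pixel_pitch = 220) {
  condition <- match.arg(condition)
  mi <- condition == "mi"
  p <- make_phantom(size, size, pixel_pitch = pixel_pitch,
                    disorder_level = if (mi) 0.7 else 0.15,
                    scar_radius_um = if (mi) 9 * pixel_pitch else 0,
                    bz_width_um = 2.7 * pixel_pitch, seed = seed)
  of <- orientation_field(p$fiber_angle, pixel_pitch = pixel_pitch)
  s <- size / 64
  prm <- with_seed(seed + 10L, list(
    pacing = c(sample(round(30 * s):round(44 * s), 1),
               sample(round(14 * s):round(28 * s), 1)),
    v_along = stats::runif(1, 0.45, 0.6),
    x_lv_rv = sample(round(24 * s):round(28 * s), 1),
    y_base = sample(round(30 * s):round(36 * s), 1)
  ))
  act <- simulate_activation(p, prm$v_along, 0.4 * prm$v_along, prm$pacing)
  lms <- list(lv_rv = rbind(c(prm$x_lv_rv, 1), c(prm$x_lv_rv, size)),
              base_apex = rbind(c(size, prm$y_base), c(prm$x_lv_rv, prm$y_base)))
  rs <- suppressWarnings(segment_rois(p$autofluorescence, lms,
                                      tissue_mask = p$tissue_mask,
                                      bz_width_um = 2.7 * pixel_pitch))
  rt <- suppressWarnings(region_table(rs, orientation = of, activation = act))
  rt$heart <- seed
  rt$condition <- condition
  list(phantom = p, orientation = of, activation = act, rois = rs, table = rt)
}

#' Region table for a family of phantom hearts
#'
#' Runs [phantom_heart_study()] for `n_hearts` seeds and stacks the per-ROI
#' tables.  For MI hearts the regions entering the composite are LV base, RV
#' and BZ (the LV apex is largely scar); sham hearts contribute LV base, LV
#' apex and RV — three regions per heart either way, mirroring a
#' 9-regions-from-3-hearts design.
#'
#' @param seed integer seed; heart seeds are `seed, seed + 1, ...`.
#' @param condition `"mi"` or `"sham"`.
#' @param n_hearts number of hearts.
#' @return tibble of per-ROI metrics.
#' @export
phantom_family_table <- function(seed, condition = c("mi", "sham"),
                                 n_hearts = 3) {
  condition <- match.arg(condition)
  tabs <- lapply(seq_len(n_hearts) - 1L, function(k)
    phantom_heart_study(seed + k, condition)$table)
  out <- dplyr::bind_rows(tabs)
  keep <- if (condition == "mi") c("LV_base", "RV", "BZ")
  else c("LV_base", "LV_apex", "RV")
  out[out$roi %in% keep, , drop = FALSE]
}
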