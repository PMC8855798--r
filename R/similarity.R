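#' Cosine similarity between conduction and fiber-orientation maps
#'
#' Per-pixel cosine of the angular difference between the functional
#' (conduction-velocity direction) and structural (myofiber axis) maps.
#' Two conventions are offered because conduction direction is a full
#' angle (0-360 degrees) while a fiber axis is axial (0-180):
#' `"literal"` lifts the fiber axis into the hemicircle around the
#' conduction angle and takes the plain cosine (so a 90-degree offset gives
#' 0); `"axial"` uses the double-angle cosine `cos(2 * delta)` of the axial
#' difference (a 90-degree offset gives -1).  Values lie in `[-1, 1]`.
#'
#' @param orientation_field an [orientation_field] (structural).
#' @param vector_field a [vector_field] (functional), same shape, aligned.
#' @param mode `"axial"` or `"literal"`.
#' @return a dimensionless [map_matrix].
#' @export
cosine_similarity_map <- function(orientation_field, vector_field,
                                  mode = c("axial", "literal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(orientation_field, "orientation_field"),
            inherits(vector_field, "vector_field"))
  if (!identical(dim(orientation_field$theta), dim(vector_field$angle)))
    stopf("maps must have the same shape")
  th_f <- orientation_field$theta
  th_cv <- vector_field$angle
  mask <- orientation_field$valid_mask & vector_field$valid_mask
  d <- th_cv - th_f
  vals <- if (mode == "axial") cos(2 * (th_cv %% pi - th_f)) else abs(cos(d))
  vals[!mask] <- NA_real_
  map_matrix(vals, "dimensionless", vector_field$pixel_pitch,
             valid_mask = mask & is.finite(vals))
}
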