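#' Classify cartilage boundary voxels into inner and outer surfaces
#'
#' Boundary voxels of the cartilage mask (cartilage voxels with at least
#' one face-adjacent non-cartilage neighbour, 6-connectivity) are split
#' into the inner surface, facing the bone (bone-cartilage interface), and
#' the outer surface, facing away (articular surface). The classifier is
#' the sign of the dot product of the gradients of the two signed distance
#' fields: the bone field's gradient always points away from the bone, and
#' the cartilage field's gradient at a boundary voxel points out of the
#' cartilage -- towards the bone on the inner surface (negative dot
#' product) and away from it on the outer surface (positive dot product).
#'
#' Exact zero dot products are broken deterministically: a tied voxel goes
#' to the outer set if any face-adjacent neighbour is background (neither
#' cartilage nor bone), otherwise to the inner set.
#'
#' @param bone_sdf,cart_sdf `signed_distance_field`s of the bone and its
#'   cartilage, on the same grid.
#' @param cart_mask the cartilage [label_mask()] the cartilage field was
#'   computed from.
#' @param bone_mask optional bone [label_mask()]; used only by the
#'   zero-dot-product tie rule to identify background neighbours. When
#'   omitted, bone voxels are taken as those with `bone_sdf$values <= 0`.
#' @param smooth passed to [gradient()].
#' @return object of class `boundary_points`: list with `inner` and
#'   `outer` (integer matrices of voxel indices, one row per point, columns
#'   i,j,k), `inner_mm`/`outer_mm` (physical coordinates), `thickness_mm`
#'   (`NA` until [thickness_at_inner_points()] fills it), `spacing_mm`.
#' @export
classify_boundary <- function(bone_sdf, cart_sdf, cart_mask,
                              bone_mask = NULL, smooth = TRUE) {
  stopifnot(inherits(bone_sdf, "signed_distance_field"),
            inherits(cart_sdf, "signed_distance_field"),
            inherits(cart_mask, "label_mask"))
  if (!identical(dim(bone_sdf$values), dim(cart_sdf$values)))
    stop("bone and cartilage fields are on different grids")
  if (!identical(dim(cart_sdf$values), dim(cart_mask$voxels)))
    stop("cartilage mask does not match the cartilage field grid")
  vox <- cart_mask$voxels
  bnd <- boundary_voxels(vox)
  if (!any(bnd)) stop("cartilage mask has no boundary voxels")

  gb <- gradient(bone_sdf, smooth = smooth)
  gc <- gradient(cart_sdf, smooth = smooth)
  dot <- gb$gx * gc$gx + gb$gy * gc$gy + gb$gz * gc$gz

  bone_vox <- if (is.null(bone_mask)) bone_sdf$values <= 0 else bone_mask$voxels
  # face-adjacent background neighbour (not cartilage, not bone)
  bg <- !(vox | bone_vox)
  has_bg_neigh <- boundary_voxels(!bg) & !bg
  # has_bg_neigh marks non-background voxels adjacent to background

  idx <- which(bnd)
  s <- sign(dot[idx])
  tie_outer <- s == 0 & has_bg_neigh[idx]
  inner_sel <- s < 0 | (s == 0 & !has_bg_neigh[idx])
  outer_sel <- s > 0 | tie_outer

  d <- dim(vox)
  inner <- arrayInd(idx[inner_sel], d)
  outer <- arrayInd(idx[outer_sel], d)
  structure(list(
    inner = inner, outer = outer,
    inner_mm = voxel_to_mm(inner, cart_mask$spacing_mm),
    outer_mm = voxel_to_mm(outer, cart_mask$spacing_mm),
    thickness_mm = rep(NA_real_, nrow(inner)),
    spacing_mm = cart_mask$spacing_mm,
    dim = d), class = "boundary_points")
}

#' @export
print.boundary_points <- function(x, ...) {
  cat("<boundary_points> ", nrow(x$inner), " inner, ", nrow(x$outer),
      " outer voxels", sep = "")
  if (!anyNA(x$thickness_mm) && length(x$thickness_mm))
    cat("; mean thickness ",
        format(mean(x$thickness_mm), digits = 4), " mm", sep = "")
  cat("\n")
  invisible(x)
}

#' Cartilage thickness at the inner boundary points
#'
#' Thickness at each inner (bone-facing) boundary point is its Euclidean
#' distance in mm to the nearest outer (articular-surface) boundary point,
#' read from a distance map seeded at the outer point set -- the final step
#' of the distance-map thickness algorithm.
#'
#' @param points a `boundary_points` object from [classify_boundary()].
#' @return the same object with `thickness_mm` filled (one value per inner
#'   point, non-negative mm).
#' @export
thickness_at_inner_points <- function(points) {
  stopifnot(inherits(points, "boundary_points"))
  if (nrow(points$outer) == 0)
    stop("outer boundary point set is empty: degenerate cartilage")
  d <- points$dim
  seed <- array(FALSE, d)
  seed[points$outer] <- TRUE
  dmap <- sqrt(.edt_sq(as.logical(seed), as.integer(d),
                       as.numeric(points$spacing_mm)))
  points$thickness_mm <- array(dmap, d)[points$inner]
  points
}

#' Average thickness per region
#'
#' Arithmetic mean of the per-point thickness over the inner boundary
#' points assigned to each of the 14 regions. Regions with no points are
#' reported as `NA` (missing), never as zero.
#'
#' @param points a `boundary_points` object with thickness filled.
#' @param region_assignment character (or factor) vector, one region code
#'   per inner point; `NA` marks unassigned points.
#' @param regions the full region code set defining the output columns.
#' @return named numeric vector of length `length(regions)`, mm.
#' @export
per_region_thickness <- function(points, region_assignment,
                                 regions = worms_regions) {
  stopifnot(inherits(points, "boundary_points"))
  if (anyNA(points$thickness_mm))
    stop("thickness not yet computed; run thickness_at_inner_points()")
  if (length(region_assignment) != nrow(points$inner))
    stop("one region assignment per inner point required")
  if (all(is.na(region_assignment)))
    stop("all inner points are unassigned")
  f <- factor(as.character(region_assignment), levels = regions)
  out <- tapply(points$thickness_mm, f, mean)
  setNames(as.numeric(out), regions)
}

#' Per-point cartilage thickness for one bone-cartilage pair
#'
#' Convenience wrapper running the full per-structure chain: signed
#' distance fields of bone and cartilage, gradient dot-product boundary
#' classification, and the outer-boundary distance map.
#'
#' @param volume a [label_volume()] containing the pair.
#' @param bone,cartilage structure names in `volume$codes`.
#' @param mode thickness dimensionality, `"3d"` (default) or `"2d"`
#'   (slice-wise distance transforms).
#' @param smooth smooth fields before gradient evaluation (default TRUE).
#' @return a `boundary_points` object with `thickness_mm` filled.
#' @examples
#' ph <- annulus_phantom(10, 3)
#' bp <- cartilage_thickness(ph$volume, "femur", "femoral_cartilage")
#' mean(bp$thickness_mm)   # ~3 mm
#' @export
cartilage_thickness <- function(volume, bone, cartilage,
                                mode = c("3d", "2d"), smooth = TRUE) {
  mode <- match.arg(mode)
  bone_m <- label_mask(volume, bone)
  cart_m <- label_mask(volume, cartilage)
  bone_sdf <- signed_distance(bone_m, mode = mode)
  cart_sdf <- signed_distance(cart_m, mode = mode)
  bp <- classify_boundary(bone_sdf, cart_sdf, cart_m, bone_mask = bone_m,
                          smooth = smooth)
  thickness_at_inner_points(bp)
}
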