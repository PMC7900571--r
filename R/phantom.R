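#' Cylindrical-shell calibration phantom with known cartilage thickness
#'
#' Builds a "bone" cylinder (axis along the slice direction, i.e. the third,
#' coarsely sampled axis) wrapped in a cartilage annulus of known radial
#' thickness. The thickness may vary with the in-plane polar angle via
#' `profile`, which emulates region-wise thickness differences; the true
#' thickness at every cartilage position is therefore known analytically,
#' which is what makes the phantom usable as a calibration target for the
#' distance-map thickness estimator.
#'
#' Voxelization: surfaces are placed symmetrically with respect to voxel
#' centres -- a voxel belongs to the cartilage if its centre lies within
#' half a voxel (measured along the local radial direction) of the
#' continuum shell `[inner_radius, inner_radius + thickness(theta)]`, and
#' to the bone if its centre is radially inside the inner surface. Voxel
#' centres of the first (last) cartilage layer then straddle the true
#' inner (outer) surface, so centre-to-centre distances across the shell
#' estimate the continuum thickness without a systematic half-voxel loss
#' at each surface; residual error is bounded by about one in-plane voxel.
#'
#' @param inner_radius bone cylinder radius in mm.
#' @param thickness_mm cartilage shell thickness in mm; either a single
#'   number or a function of the polar angle (radians, in `(-pi, pi]`)
#'   returning the local true thickness (>= 0; 0 removes the shell there).
#' @param spacing_mm voxel size in mm, default `c(0.5, 0.5, 3)` (sub-mm
#'   in-plane with 3 mm slices, as in routine knee MR).
#' @param margin_mm empty margin around the shell, in mm.
#' @param n_slices number of axial slices.
#' @param codes named codes for the two structures written into the volume.
#' @return list with `volume` (a [label_volume()] with bone and cartilage),
#'   `truth` (3-D numeric array: true thickness in mm at cartilage voxels,
#'   `NA` elsewhere), and `center_vox` (in-plane centre, voxel units).
#' @examples
#' ph <- annulus_phantom(10, 3)
#' range(ph$truth, na.rm = TRUE)
#' @export
annulus_phantom <- function(inner_radius, thickness_mm,
                            spacing_mm = c(0.5, 0.5, 3),
                            margin_mm = 2, n_slices = 8,
                            codes = c(femur = 1L, femoral_cartilage = 4L)) {
  stopifnot(inner_radius > 0, length(spacing_mm) == 3, all(spacing_mm > 0))
  prof <- if (is.function(thickness_mm)) thickness_mm else function(theta) {
    rep_len(thickness_mm, length(theta))
  }
  tmax <- if (is.function(thickness_mm)) {
    max(prof(seq(-pi, pi, length.out = 721)))
  } else thickness_mm
  if (tmax < 0) stop("cartilage thickness must be >= 0")
  if (tmax > 0 && tmax < max(spacing_mm[1:2]))
    warning("cartilage profile thinner than one in-plane voxel; ",
            "quantization will dominate the recovered thickness")
  half <- inner_radius + tmax + margin_mm
  nx <- 2L * ceiling(half / spacing_mm[1]) + 1L
  ny <- 2L * ceiling(half / spacing_mm[2]) + 1L
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  xmm <- (seq_len(nx) - cx) * spacing_mm[1]
  ymm <- (seq_len(ny) - cy) * spacing_mm[2]
  r <- sqrt(outer(xmm^2, ymm^2, `+`))
  theta <- atan2(rep(ymm, each = nx), rep(xmm, ny))
  tloc <- matrix(prof(theta), nx, ny)
  if (any(tloc < 0)) stop("cartilage thickness must be >= 0")
  # half-voxel extent along the local radial direction (voxel centres of
  # the first/last cartilage layer straddle the continuum surfaces)
  e <- matrix((abs(cos(theta)) * spacing_mm[1] +
                 abs(sin(theta)) * spacing_mm[2]) / 2, nx, ny)
  bone2d <- r < inner_radius - e
  cart2d <- tloc > 0 & r >= inner_radius - e & r < inner_radius + tloc + e
  arr <- array(0L, c(nx, ny, n_slices))
  truth <- array(NA_real_, c(nx, ny, n_slices))
  lab2d <- matrix(0L, nx, ny)
  lab2d[bone2d] <- codes[[1]]
  lab2d[cart2d] <- codes[[2]]
  t2d <- matrix(NA_real_, nx, ny)
  t2d[cart2d] <- tloc[cart2d]
  for (z in seq_len(n_slices)) {
    arr[, , z] <- lab2d
    truth[, , z] <- t2d
  }
  list(volume = label_volume(arr, spacing_mm, codes),
       truth = truth, center_vox = c(cx, cy))
}

#' Three-bone knee phantom covering all 14 cartilage regions
#'
#' A geometric stand-in for a segmented knee: the femur is a cylinder with
#' its axis along the medial-lateral (first) axis wearing a cartilage shell
#' on its inferior half; the tibia is a slab below the femur carrying a flat
#' cartilage plate of uniform thickness on its superior surface; the patella
#' is a small block anterior to the femur with a cartilage plate on its
#' posterior face. Every cartilage voxel has an analytically known true
#' thickness. The anatomy is schematic -- its purpose is to exercise the
#' full pipeline (boundary classification, thickness, atlas partition) with
#' known answers, not to look like a knee.
#'
#' Axis convention: axis 1 = medial-lateral (medial at low index), axis 2 =
#' anterior-posterior (anterior at low index), axis 3 = inferior-superior.
#'
#' @param femoral_mm,tibial_mm,patellar_mm cartilage thicknesses in mm;
#'   `femoral_mm` may be a function of the in-plane angle as in
#'   [annulus_phantom()] (angle 0 = anterior, pi/2 = inferior).
#' @param spacing_mm voxel size in mm.
#' @param drop character vector of structures to omit, e.g. `"patella"`
#'   (omitting a bone also omits its cartilage).
#' @param codes named integer codes for the six structures.
#' @return list with `volume` (a [label_volume()]), `truth` (true thickness
#'   in mm at cartilage voxels, `NA` elsewhere).
#' @export
knee_phantom <- function(femoral_mm = 2.0, tibial_mm = 1.6, patellar_mm = 2.2,
                         spacing_mm = c(0.5, 0.5, 1.0),
                         drop = character(), codes = knee_codes) {
  stopifnot(all(spacing_mm > 0))
  fem_prof <- if (is.function(femoral_mm)) femoral_mm else function(theta) {
    rep_len(femoral_mm, length(theta))
  }
  fmax <- max(fem_prof(seq(-pi, pi, length.out = 721)))
  ext_mm <- c(40, 46, 42)  # physical extent of the grid
  n <- ceiling(ext_mm / spacing_mm)
  arr <- array(0L, n)
  truth <- array(NA_real_, n)
  # voxel-centre coordinates in mm
  xs <- (seq_len(n[1]) - 1) * spacing_mm[1]
  ys <- (seq_len(n[2]) - 1) * spacing_mm[2]
  zs <- (seq_len(n[3]) - 1) * spacing_mm[3]
  X <- array(rep(xs, times = n[2] * n[3]), n)
  Y <- array(rep(rep(ys, each = n[1]), times = n[3]), n)
  Z <- array(rep(zs, each = n[1] * n[2]), n)

  # femur: cylinder along x, centred posterior-superior
  fc <- c(y = 24, z = 28); fr <- 9
  ry <- Y - fc["y"]; rz <- Z - fc["z"]
  rad <- sqrt(ry^2 + rz^2)
  # angle 0 = anterior (-y), pi/2 = inferior (-z)
  ang <- atan2(-rz, -ry)
  # half-voxel extent along the local radial direction (see annulus_phantom)
  ef <- (abs(cos(ang)) * spacing_mm[2] + abs(sin(ang)) * spacing_mm[3]) / 2
  if (!"femur" %in% drop) {
    femur <- rad < fr - ef
    arr[femur] <- codes[["femur"]]
    if (!"femoral_cartilage" %in% drop) {
      tloc <- array(fem_prof(ang), n)
      # shell on the inferior half plus the anterior/posterior flanks,
      # leaving the superior (shaft) aspect bare
      fcart <- tloc > 0 & rad >= fr - ef & rad < fr + tloc + ef &
        !(rz > 0 & abs(ry) <= 0.6 * fr)
      arr[fcart & arr == 0L] <- codes[["femoral_cartilage"]]
      idx <- arr == codes[["femoral_cartilage"]]
      truth[idx] <- tloc[idx]
    }
  }

  # tibia: slab below the femur, flat top; cartilage plate on top
  tib_top <- fc["z"] - fr - fmax - 3  # leave a joint-space gap
  ez <- spacing_mm[3] / 2             # plate normal is the z axis
  if (!"tibia" %in% drop) {
    tibia <- Z < tib_top - tibial_mm - ez & Z > tib_top - tibial_mm - 8 &
      Y > 10 & Y < 38
    arr[tibia] <- codes[["tibia"]]
    if (!"tibial_cartilage" %in% drop) {
      tcart <- Z >= tib_top - tibial_mm - ez & Z < tib_top + ez &
        Y > 10 & Y < 38
      arr[tcart & arr == 0L] <- codes[["tibial_cartilage"]]
      truth[arr == codes[["tibial_cartilage"]]] <- tibial_mm
    }
  }

  # patella: block anterior to the femur; cartilage on its posterior face
  ey <- spacing_mm[2] / 2             # patellar plate normal is the y axis
  if (!"patella" %in% drop) {
    # plate spans the full medial-lateral extent (the grid edge is not a
    # boundary) so rim effects are confined to the superior/inferior edges
    pat <- Y < 8 - ey & Y > 2 & abs(Z - fc["z"]) < 10
    arr[pat] <- codes[["patella"]]
    if (!"patellar_cartilage" %in% drop) {
      pcart <- Y >= 8 - ey & Y < 8 + patellar_mm + ey &
        abs(Z - fc["z"]) < 10
      arr[pcart & arr == 0L] <- codes[["patellar_cartilage"]]
      truth[arr == codes[["patellar_cartilage"]]] <- patellar_mm
    }
  }

  list(volume = label_volume(arr, spacing_mm, codes), truth = truth)
}

#' Morphologically perturb a mask for segmentation-metric fixtures
#'
#' Randomly flips boundary-adjacent voxels (erosion and dilation flips in
#' equal expectation). The Dice similarity against the unperturbed mask
#' decreases monotonically in `severity` in expectation: `severity` is the
#' probability that any boundary-layer voxel flips. At `severity = 0` the
#' mask is returned unchanged; at `severity = 1` every boundary-layer voxel
#' flips, and repeated application inside small masks drives Dice to 0.
#'
#' @param mask a [label_mask()] (or logical array with `spacing_mm` attr
#'   via [as_label_mask()]).
#' @param severity flip probability in `[0, 1]`.
#' @param seed integer RNG seed.
#' @param layers how many boundary peel layers are eligible to flip;
#'   more layers make severity bite harder on small masks.
#' @return a perturbed [label_mask()].
#' @export
perturb_mask <- function(mask, severity, seed = 1L, layers = 2L) {
  stopifnot(inherits(mask, "label_mask"))
  if (!is.numeric(severity) || length(severity) != 1 ||
      is.na(severity) || severity < 0 || severity > 1)
    stop("'severity' must be a single number in [0, 1]")
  if (severity == 0) return(mask)
  vox <- mask$voxels
  set.seed(as.integer(seed))
  for (l in seq_len(layers)) {
    inner_b <- boundary_voxels(vox)            # mask-side boundary layer
    outer_b <- boundary_voxels(!vox)           # background-side layer
    cand <- inner_b | outer_b
    flip <- cand & array(stats::runif(length(vox)) < severity, dim(vox))
    vox <- xor(vox, flip)
  }
  as_label_mask(vox, mask$spacing_mm, mask$structure)
}
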