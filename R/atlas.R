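#' Build a geometric 14-region atlas from a segmented knee volume
#'
#' Rule-based parcellation of the three cartilage plates into the 14
#' anatomical regions. Conventions (axis 1 = medial-lateral with medial at
#' low index, axis 2 = anterior-posterior with anterior at low index):
#'
#' * medial/lateral split: a parasagittal plane through the tibial centroid
#'   (for femoral and tibial cartilage) or the patellar centroid (for
#'   patellar cartilage);
#' * anterior/central/posterior split (femur and tibia only): the
#'   anteroposterior extent of each bone's cartilage is divided at
#'   `acp_fractions` of its span (equal thirds by default);
#' * the patella is split medial/lateral only (PM, PL).
#'
#' The anatomical boundary of the load-bearing "central" region has no
#' universally quantified definition; the equal-thirds default is a
#' reproducible convention and can be overridden.
#'
#' @param volume a [label_volume()] containing femur, tibia, patella and
#'   the three cartilages.
#' @param acp_fractions two increasing numbers in (0,1): cut points of the
#'   anterior/central and central/posterior boundaries along the
#'   anteroposterior cartilage extent.
#' @return object of class `region_atlas`: list with `labels` (3-D integer
#'   array, codes 1-14 over cartilage voxels, 0 elsewhere), `region_codes`
#'   (named integer vector, names from [worms_regions]), `spacing_mm`,
#'   `provenance = "builtin_geometric"`.
#' @examples
#' ph <- knee_phantom()
#' at <- build_geometric_atlas(ph$volume)
#' length(unique(at$labels[at$labels > 0]))  # 14
#' @export
build_geometric_atlas <- function(volume, acp_fractions = c(1 / 3, 2 / 3)) {
  stopifnot(inherits(volume, "label_volume"))
  stopifnot(length(acp_fractions) == 2, acp_fractions[1] < acp_fractions[2],
            all(acp_fractions > 0), all(acp_fractions < 1))
  for (b in c("femur", "tibia", "patella")) {
    if (!b %in% names(volume$codes) || !any(volume$data == volume$codes[[b]]))
      stop("missing bone: ", b)
  }
  d <- dim(volume$data)
  codes <- volume$codes
  region_codes <- setNames(seq_along(worms_regions), worms_regions)
  labels <- array(0L, d)

  centroid_x <- function(structure) {
    idx <- which(volume$data == codes[[structure]])
    mean(arrayInd(idx, d)[, 1])
  }
  tib_cx <- centroid_x("tibia")
  pat_cx <- centroid_x("patella")

  assign_bone <- function(cart_structure, prefix, split_x) {
    cidx <- which(volume$data == codes[[cart_structure]])
    if (length(cidx) == 0) return(invisible(NULL))
    ci <- arrayInd(cidx, d)
    medial <- ci[, 1] < split_x
    if (prefix == "P") {
      lab <- ifelse(medial, region_codes[["PM"]], region_codes[["PL"]])
    } else {
      yr <- range(ci[, 2])
      span <- diff(yr)
      cut1 <- yr[1] + acp_fractions[1] * span
      cut2 <- yr[1] + acp_fractions[2] * span
      acp <- ifelse(ci[, 2] <= cut1, "A", ifelse(ci[, 2] <= cut2, "C", "P"))
      ml <- ifelse(medial, "M", "L")
      lab <- region_codes[paste0(prefix, ml, acp)]
    }
    labels[cidx] <<- as.integer(lab)
    invisible(NULL)
  }
  assign_bone("femoral_cartilage", "F", tib_cx)
  assign_bone("tibial_cartilage", "T", tib_cx)
  assign_bone("patellar_cartilage", "P", pat_cx)

  structure(list(labels = labels, region_codes = region_codes,
                 spacing_mm = volume$spacing_mm,
                 provenance = "builtin_geometric"),
            class = "region_atlas")
}

#' @export
print.region_atlas <- function(x, ...) {
  present <- sort(unique(x$labels[x$labels > 0L]))
  cat("<region_atlas> (", x$provenance, ") ",
      paste(dim(x$labels), collapse = " x "), " voxels, ",
      length(present), " regions present\n", sep = "")
  invisible(x)
}

#' Alignment transforms for atlas-to-subject registration
#'
#' The pipeline replaces full deformable registration with a pluggable
#' transform hook. A transform maps subject world coordinates (mm) to
#' atlas world coordinates; the atlas is resampled onto the subject grid
#' by nearest-label lookup. `identity_transform()` is a no-op;
#' `affine_transform(A)` applies a 4x4 affine in world (mm) coordinates
#' (the matrix maps subject points into atlas space).
#'
#' @param A 4x4 numeric affine matrix acting on homogeneous world
#'   coordinates (mm).
#' @return a function `f(xyz_mm) -> xyz_mm` (n x 3 matrices).
#' @export
identity_transform <- function() {
  function(xyz) xyz
}

#' @rdname identity_transform
#' @export
affine_transform <- function(A) {
  stopifnot(is.matrix(A), all(dim(A) == c(4, 4)))
  function(xyz) {
    h <- cbind(xyz, 1) %*% t(A)
    h[, 1:3, drop = FALSE] / h[, 4]
  }
}

#' Read a 4x4 world-coordinate affine from a whitespace-delimited text file
#'
#' @param path text file with 4 rows of 4 numbers.
#' @return 4x4 numeric matrix.
#' @export
read_affine <- function(path) {
  m <- as.matrix(read.table(path))
  dimnames(m) <- NULL
  if (!all(dim(m) == c(4, 4))) stop("expected a 4x4 matrix in ", path)
  m
}

#' Resample an atlas into a subject grid through a transform hook
#'
#' Every voxel of the subject grid is mapped through `transform` into atlas
#' world coordinates and takes the nearest atlas voxel's region label
#' (nearest-label interpolation; no averaging across codes). Points mapping
#' outside the atlas grid become unassigned (code 0); the count is
#' reported via a message when nonzero.
#'
#' @param atlas a `region_atlas`.
#' @param subject a [label_volume()] defining the target grid.
#' @param transform function mapping subject world mm coordinates to atlas
#'   world mm coordinates, e.g. [identity_transform()].
#' @return a `region_atlas` on the subject grid.
#' @export
align_atlas <- function(atlas, subject, transform = identity_transform()) {
  stopifnot(inherits(atlas, "region_atlas"), inherits(subject, "label_volume"))
  ds <- dim(subject$data)
  da <- dim(atlas$labels)
  idx <- arrayInd(seq_len(prod(ds)), ds)
  mm <- voxel_to_mm(idx, subject$spacing_mm)
  amm <- transform(mm)
  av <- sweep(amm, 2, atlas$spacing_mm, `/`) + 1  # fractional atlas voxel
  av <- round(av)
  inside <- av[, 1] >= 1 & av[, 1] <= da[1] &
    av[, 2] >= 1 & av[, 2] <= da[2] &
    av[, 3] >= 1 & av[, 3] <= da[3]
  lab <- integer(prod(ds))
  ii <- which(inside)
  lab[ii] <- atlas$labels[cbind(av[ii, 1], av[ii, 2], av[ii, 3])]
  if (any(!inside))
    message(sum(!inside), " subject voxels map outside the atlas grid; ",
            "left unassigned")
  structure(list(labels = array(lab, ds), region_codes = atlas$region_codes,
                 spacing_mm = subject$spacing_mm,
                 provenance = atlas$provenance,
                 n_unmapped = sum(!inside)),
            class = "region_atlas")
}

#' Assign inner boundary points to atlas regions
#'
#' Each inner point takes the region code of the atlas voxel it occupies;
#' code 0 yields `NA` (unassigned -- a valid, reported outcome).
#'
#' @param points a `boundary_points` object.
#' @param atlas a `region_atlas` on the same grid as the points.
#' @return character vector of region names (`NA` for unassigned), one per
#'   inner point.
#' @export
assign_points <- function(points, atlas) {
  stopifnot(inherits(points, "boundary_points"),
            inherits(atlas, "region_atlas"))
  if (!identical(points$dim, dim(atlas$labels)))
    stop("atlas is not in subject space (grid mismatch)")
  code <- atlas$labels[points$inner]
  nm <- names(atlas$region_codes)[match(code, atlas$region_codes)]
  nm
}

#' Write / read a region atlas as NIfTI plus a JSON code table
#'
#' @param atlas a `region_atlas`.
#' @param path `.nii` / `.nii.gz` path; JSON sidecar at `<path>.json`.
#' @return `read_region_atlas()` returns a `region_atlas`.
#' @export
write_region_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "region_atlas"))
  lab <- atlas$labels
  storage.mode(lab) <- "integer"
  write_nifti(lab, path, atlas$spacing_mm, datatype = "int16")
  jsonlite::write_json(as.list(atlas$region_codes), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_region_atlas
#' @export
read_region_atlas <- function(path) {
  v <- read_nifti(path)
  lst <- jsonlite::read_json(paste0(path, ".json"))
  lab <- v$data
  storage.mode(lab) <- "integer"
  structure(list(labels = lab,
                 region_codes = setNames(as.integer(unlist(lst)), names(lst)),
                 spacing_mm = v$spacing_mm, provenance = "user_supplied"),
            class = "region_atlas")
}
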