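#' Label volumes and binary structure masks
#'
#' A `label_volume` is a 3-D integer array of structure codes together with
#' the physical voxel spacing in mm and a named code table mapping structure
#' names to integer labels. A `label_mask` is one structure extracted as a
#' logical array, keeping the spacing and the structure name. These are the
#' containers every stage of the thickness pipeline consumes.
#'
#' @param data 3-D integer array of label codes (0 = background).
#' @param spacing_mm numeric length-3, physical voxel size per axis in mm.
#' @param codes named integer vector mapping structure names to label codes.
#' @return `label_volume()` returns an object of class `label_volume`:
#'   a list with elements `data`, `spacing_mm`, `codes`.
#' @examples
#' arr <- array(0L, c(4, 4, 2))
#' arr[2:3, 2:3, ] <- 1L
#' vol <- label_volume(arr, c(0.5, 0.5, 3), c(femur = 1L))
#' m <- label_mask(vol, "femur")
#' sum(m$voxels)
#' @export
label_volume <- function(data, spacing_mm, codes = knee_codes) {
  stopifnot(length(dim(data)) == 3, length(spacing_mm) == 3)
  if (any(spacing_mm <= 0)) stop("all voxel spacings must be > 0")
  if (is.null(names(codes)) || any(!nzchar(names(codes))))
    stop("'codes' must be a fully named integer vector")
  storage.mode(data) <- "integer"
  structure(list(data = data, spacing_mm = as.numeric(spacing_mm),
                 codes = setNames(as.integer(codes), names(codes))),
            class = "label_volume")
}

#' @rdname label_volume
#' @param volume a `label_volume`.
#' @param structure structure name (must be present in `volume$codes`).
#' @return `label_mask()` returns an object of class `label_mask`: a list
#'   with elements `voxels` (logical 3-D array), `structure`, `spacing_mm`.
#' @export
label_mask <- function(volume, structure) {
  stopifnot(inherits(volume, "label_volume"))
  if (!structure %in% names(volume$codes))
    stop("unknown structure '", structure, "'")
  structure(list(voxels = volume$data == volume$codes[[structure]],
                 structure = structure,
                 spacing_mm = volume$spacing_mm),
            class = "label_mask")
}

#' @rdname label_volume
#' @param voxels logical 3-D array.
#' @export
as_label_mask <- function(voxels, spacing_mm, structure = "mask") {
  stopifnot(is.logical(voxels), length(dim(voxels)) == 3,
            length(spacing_mm) == 3, all(spacing_mm > 0))
  structure(list(voxels = voxels, structure = structure,
                 spacing_mm = as.numeric(spacing_mm)),
            class = "label_mask")
}

#' @export
print.label_volume <- function(x, ...) {
  cat("<label_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(format(x$spacing_mm), collapse = " x "),
      " mm\n", sep = "")
  tab <- table(factor(x$data[x$data != 0L], levels = x$codes,
                      labels = names(x$codes)))
  for (nm in names(tab))
    cat(sprintf("  %-20s %d voxels\n", nm, tab[[nm]]))
  invisible(x)
}

#' @export
print.label_mask <- function(x, ...) {
  cat("<label_mask> '", x$structure, "': ", sum(x$voxels), " of ",
      length(x$voxels), " voxels\n", sep = "")
  invisible(x)
}

# voxel centre -> physical coordinate (mm), 1-based index convention:
# voxel i sits at (i - 1) * spacing.
voxel_to_mm <- function(idx, spacing_mm) {
  sweep(idx - 1, 2, spacing_mm, `*`)
}

# Logical array of mask voxels with >= 1 face-adjacent (6-connectivity)
# voxel outside the mask. Out-of-grid neighbours count as *inside*: the
# grid edge is unobserved, not background, so a structure cut by the field
# of view does not grow a spurious boundary on the cut plane.
boundary_voxels <- function(voxels) {
  d <- dim(voxels)
  inner <- array(TRUE, d)
  neighbour_inside <- function(ax, by) {
    # TRUE at voxel p iff voxel p + by along axis `ax` lies inside the mask;
    # out-of-grid neighbours replicate the edge voxel itself.
    out <- voxels
    src <- seq_len(d[ax] - 1L)
    ix <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    ixd <- ix; ixd[[ax]] <- if (by > 0) src else src + 1L
    ixs <- ix; ixs[[ax]] <- if (by > 0) src + 1L else src
    out[ixd[[1]], ixd[[2]], ixd[[3]]] <- voxels[ixs[[1]], ixs[[2]], ixs[[3]]]
    out
  }
  for (ax in 1:3) for (by in c(-1L, 1L))
    inner <- inner & neighbour_inside(ax, by)
  voxels & !inner
}
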