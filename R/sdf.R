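#' Signed Euclidean distance field of a structure mask
#'
#' Computes the exact Euclidean distance transform of the mask with
#' anisotropic physical spacing and assembles the signed field: negative
#' inside the structure, positive outside, magnitude equal to the distance
#' (in mm) from the voxel centre to the nearest voxel centre of the
#' opposite phase. Voxels on either side of the interface therefore carry
#' magnitudes no larger than the largest voxel spacing.
#'
#' @param mask a [label_mask()]; must be nonempty.
#' @param mode `"3d"` (default) for a fully 3-D transform, `"2d"` to
#'   compute each axial slice independently with in-plane spacing only
#'   (sensitivity-analysis mode; out-of-plane structure is ignored).
#' @return object of class `signed_distance_field`: list with `values`
#'   (3-D numeric array, mm), `source_mask` (structure name), `spacing_mm`.
#' @examples
#' arr <- array(FALSE, c(9, 9, 3)); arr[5, 5, 2] <- TRUE
#' f <- signed_distance(as_label_mask(arr, c(1, 1, 1)))
#' f$values[5, 5, 2]   # -1: one voxel to the nearest background voxel
#' @export
signed_distance <- function(mask, mode = c("3d", "2d")) {
  stopifnot(inherits(mask, "label_mask"))
  mode <- match.arg(mode)
  vox <- mask$voxels
  if (!any(vox)) stop("empty mask: no boundary exists")
  d <- dim(vox)
  if (mode == "3d") {
    d_out <- sqrt(.edt_sq(as.logical(vox), as.integer(d),
                          as.numeric(mask$spacing_mm)))
    d_in <- sqrt(.edt_sq(as.logical(!vox), as.integer(d),
                         as.numeric(mask$spacing_mm)))
  } else {
    sp2 <- c(mask$spacing_mm[1:2], 1)
    d_out <- d_in <- numeric(length(vox))
    np <- d[1] * d[2]
    for (z in seq_len(d[3])) {
      sl <- vox[, , z]
      ix <- (z - 1L) * np + seq_len(np)
      d_out[ix] <- sqrt(.edt_sq(as.logical(sl), c(d[1:2], 1L), sp2))
      d_in[ix] <- sqrt(.edt_sq(as.logical(!sl), c(d[1:2], 1L), sp2))
    }
  }
  vals <- array(ifelse(as.logical(vox), -d_in, d_out), d)
  structure(list(values = vals, source_mask = mask$structure,
                 spacing_mm = mask$spacing_mm, mode = mode),
            class = "signed_distance_field")
}

#' @export
print.signed_distance_field <- function(x, ...) {
  cat("<signed_distance_field> from '", x$source_mask, "', ",
      paste(dim(x$values), collapse = " x "), " voxels, range [",
      paste(format(range(x$values), digits = 4), collapse = ", "),
      "] mm\n", sep = "")
  invisible(x)
}

# Separable Gaussian smoothing, sigma in voxels per axis, kernel truncated
# at 3 sigma, edge-replicated (kernel renormalized at edges by padding).
smooth_field <- function(values, sigma_vox = c(1, 1, 1)) {
  d <- dim(values)
  out <- values
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0 || d[ax] < 2) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-(seq(-r, r))^2 / (2 * s^2))
    k <- k / sum(k)
    out <- convolve_axis(out, k, ax)
  }
  out
}

# 1-D convolution along one axis with edge replication, vectorized as a
# sum of shifted arrays.
convolve_axis <- function(a, k, ax) {
  d <- dim(a)
  r <- (length(k) - 1L) / 2L
  acc <- array(0, d)
  n <- d[ax]
  ix <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  for (j in seq_along(k)) {
    off <- j - r - 1L  # offset of source sample relative to centre
    src <- pmin(pmax(seq_len(n) + off, 1L), n)  # replicate edges
    ixs <- ix; ixs[[ax]] <- src
    acc <- acc + k[j] * a[ixs[[1]], ixs[[2]], ixs[[3]], drop = FALSE]
  }
  acc
}

#' First-order gradient of a signed distance field
#'
#' Central differences in the grid interior and one-sided differences at
#' the grid edges, each axis divided by its physical spacing, so the
#' gradient is the dimensionless direction of steepest ascent of the
#' signed distance (near-unit magnitude away from the medial axis).
#'
#' @param field a `signed_distance_field` (or any list with `values` and
#'   `spacing_mm`).
#' @param smooth logical; smooth the field with a Gaussian of one voxel
#'   sigma per axis before differencing (default `TRUE`). Raw
#'   distance-transform gradients are noisy at the voxel scale; only the
#'   gradient direction is consumed downstream, so smoothing is safe.
#' @return object of class `gradient_field`: list with `gx`, `gy`, `gz`
#'   (3-D arrays, per-mm differences) and `source`.
#' @export
gradient <- function(field, smooth = TRUE) {
  vals <- field$values
  d <- dim(vals)
  if (smooth) vals <- smooth_field(vals, sigma_vox = c(1, 1, 1))
  g <- vector("list", 3)
  for (ax in 1:3) {
    n <- d[ax]
    if (n < 2) {
      warning("axis ", ax, " has size 1; gradient component set to 0")
      g[[ax]] <- array(0, d)
      next
    }
    ix <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    fwd <- ix; fwd[[ax]] <- pmin(seq_len(n) + 1L, n)
    bwd <- ix; bwd[[ax]] <- pmax(seq_len(n) - 1L, 1L)
    num <- vals[fwd[[1]], fwd[[2]], fwd[[3]], drop = FALSE] -
      vals[bwd[[1]], bwd[[2]], bwd[[3]], drop = FALSE]
    # interior divisor 2h, one-sided h at the two grid edges
    den <- rep(2, n); den[1] <- 1; den[n] <- 1
    den_full <- rep(den, each = prod(d[seq_len(ax - 1L)]))  # column-major
    g[[ax]] <- array(num, d) / array(den_full, d) / field$spacing_mm[ax]
  }
  structure(list(gx = g[[1]], gy = g[[2]], gz = g[[3]],
                 source = field$source_mask),
            class = "gradient_field")
}
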