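#' Dice similarity coefficient between two segmentation masks
#'
#' `DSC(A, B) = 2|A intersect B| / (|A| + |B|)`, computed volumetrically
#' over the whole 3-D masks. Ranges over \[0, 1\]; higher is better
#' agreement. When both masks are empty the coefficient is defined as 1
#' (perfect agreement on absence; avoids 0/0).
#'
#' @param reference,candidate [label_mask()]s on the same grid with the
#'   same structure code (reference = manual labelling, candidate =
#'   automatic segmentation, by convention).
#' @return a number in \[0, 1\].
#' @examples
#' a <- array(FALSE, c(4, 4, 1)); a[1:2, 1, 1] <- TRUE
#' b <- array(FALSE, c(4, 4, 1)); b[2:3, 1, 1] <- TRUE
#' dice(as_label_mask(a, c(1, 1, 1)), as_label_mask(b, c(1, 1, 1)))  # 0.5
#' @export
dice <- function(reference, candidate) {
  stopifnot(inherits(reference, "label_mask"),
            inherits(candidate, "label_mask"))
  if (!identical(dim(reference$voxels), dim(candidate$voxels)))
    stop("mask grids differ in shape")
  if (!identical(reference$structure, candidate$structure))
    stop("masks are for different structures ('", reference$structure,
         "' vs '", candidate$structure, "')")
  na <- sum(reference$voxels)
  nb <- sum(candidate$voxels)
  if (na + nb == 0L) return(1)
  2 * sum(reference$voxels & candidate$voxels) / (na + nb)
}

#' Per-structure Dice report (mean and SD over subjects)
#'
#' Computes the Dice coefficient for each reference/candidate pair and
#' summarizes per structure with the subject-level mean and sample SD,
#' the layout of a per-structure segmentation-accuracy table.
#'
#' @param pairs list of `list(reference =, candidate =)` pairs of
#'   [label_mask()]s; the structure is read from each pair.
#' @param digits decimals used in the formatted column (default 4).
#' @return data.frame with columns `structure`, `n`, `mean`, `sd`,
#'   `formatted` ("mean +/- sd" at `digits` decimals).
#' @export
dice_report <- function(pairs, digits = 4) {
  if (length(pairs) == 0) stop("no mask pairs supplied")
  d <- vapply(pairs, function(p) dice(p$reference, p$candidate), numeric(1))
  s <- vapply(pairs, function(p) p$reference$structure, character(1))
  out <- do.call(rbind, lapply(split(d, s), function(v) {
    data.frame(n = length(v), mean = mean(v),
               sd = if (length(v) > 1) sd(v) else NA_real_)
  }))
  out <- data.frame(structure = rownames(out), out, row.names = NULL)
  out$formatted <- sprintf(paste0("%.", digits, "f ± %.", digits, "f"),
                           out$mean, ifelse(is.na(out$sd), 0, out$sd))
  out
}
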