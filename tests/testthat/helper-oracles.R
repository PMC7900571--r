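# Independent oracles kept deliberately naive: brute force beats clever.

# Brute-force signed distance: for every voxel, the minimum physical
# distance to any voxel of the opposite phase, negative inside.
brute_signed_distance <- function(vox, spacing) {
  d <- dim(vox)
  idx <- arrayInd(seq_len(prod(d)), d)
  mm <- sweep(idx - 1, 2, spacing, `*`)
  out <- numeric(prod(d))
  for (i in seq_len(prod(d))) {
    opp <- which(as.logical(vox) != vox[i])
    dmin <- sqrt(min(colSums((t(mm[opp, , drop = FALSE]) - mm[i, ])^2)))
    out[i] <- if (vox[i]) -dmin else dmin
  }
  array(out, d)
}

# Brute-force nearest-point distances from each inner point to the outer
# point set (physical units).
brute_nearest_outer <- function(inner, outer, spacing) {
  im <- sweep(inner - 1, 2, spacing, `*`)
  om <- sweep(outer - 1, 2, spacing, `*`)
  vapply(seq_len(nrow(im)), function(i) {
    sqrt(min(colSums((t(om) - im[i, ])^2)))
  }, numeric(1))
}

# Small all-purpose cohort for statistics tests.
tiny_cohort <- function(n = 60, seed = 11) {
  set.seed(seed)
  d <- data.frame(subject_id = sprintf("S%03d", 1:n),
                  age = runif(n, 16, 63),
                  sex = rep(c("M", "F"), length.out = n),
                  side = rep(c("L", "L", "R"), length.out = n))
  for (r in worms_regions) d[[r]] <- rnorm(n, 2, 0.2)
  class(d) <- c("region_thickness_table", "data.frame")
  d
}
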