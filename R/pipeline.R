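#' Pipeline configuration
#'
#' Bundles the knobs of the end-to-end run: the structure code table, an
#' optional spacing override, the thickness mode, gradient smoothing, the
#' atlas source, the statistics options and the seed. Validated once here
#' so every stage can trust it.
#'
#' @param codes named integer code table for the six structures.
#' @param spacing_override optional numeric length-3 spacing in mm
#'   replacing the header spacing.
#' @param mode `"3d"` or `"2d"` thickness computation.
#' @param smooth smooth distance fields before gradients.
#' @param atlas `"geometric"` or a path to a NIfTI atlas (+ JSON sidecar).
#' @param transform_path optional path to a 4x4 world affine text file
#'   used when resampling a user atlas.
#' @param alpha significance level in (0,1).
#' @param factors condition factors for the regressions.
#' @param seed integer seed.
#' @param out_dir output directory for written tables.
#' @return object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(codes = knee_codes, spacing_override = NULL,
                            mode = c("3d", "2d"), smooth = TRUE,
                            atlas = "geometric", transform_path = NULL,
                            alpha = 0.05, factors = c("sex", "side"),
                            seed = 1L, out_dir = ".") {
  mode <- match.arg(mode)
  if (!(is.numeric(alpha) && length(alpha) == 1 && alpha > 0 && alpha < 1))
    stop("alpha must be in (0, 1)")
  if (!is.null(spacing_override))
    stopifnot(length(spacing_override) == 3, all(spacing_override > 0))
  structure(list(codes = codes, spacing_override = spacing_override,
                 mode = mode, smooth = isTRUE(smooth), atlas = atlas,
                 transform_path = transform_path, alpha = alpha,
                 factors = factors, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Any field of [pipeline_config()] may appear in the file; missing fields
#' keep their defaults. `codes` is given as a name-to-integer mapping.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configs")
  raw <- yaml::read_yaml(path)
  args <- list()
  for (nm in intersect(names(raw), c("spacing_override", "mode", "smooth",
                                     "atlas", "transform_path", "alpha",
                                     "factors", "seed", "out_dir")))
    args[[nm]] <- raw[[nm]]
  if (!is.null(raw$codes))
    args$codes <- setNames(as.integer(unlist(raw$codes)), names(raw$codes))
  do.call(pipeline_config, args)
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(config[setdiff(names(config), "out_dir")],
                              auto_unbox = TRUE, force = TRUE), f)
  unname(tools::md5sum(f))
}

table_header <- function(config) {
  sprintf("# carthick %s | config %s", as.character(packageVersion("carthick")),
          config_hash(config))
}

write_output_table <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(table_header(config), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the thickness pipeline on one subject volume
#'
#' Full per-subject chain: extract masks, signed distance fields, gradient
#' dot-product boundary classification, outer-boundary distance map,
#' atlas partition, per-region averaging. Produces the subject's 14-region
#' thickness record; regions whose cartilage is absent come back `NA` and
#' are listed in a message. Per-stage counts go to `message()` so silent
#' data loss is visible.
#'
#' @param volume a [label_volume()] or a path to a NIfTI label volume.
#' @param config a [pipeline_config()].
#' @return named numeric vector of 14 region thickness means (mm), with
#'   attributes `n_inner`, `n_outer`, `n_unassigned`.
#' @examples
#' rec <- run_subject(knee_phantom()$volume)
#' sum(!is.na(rec))  # 14
#' @export
run_subject <- function(volume, config = pipeline_config()) {
  if (is.character(volume))
    volume <- read_label_volume(volume, codes = config$codes)
  stopifnot(inherits(volume, "label_volume"))
  if (!is.null(config$spacing_override))
    volume$spacing_mm <- as.numeric(config$spacing_override)
  need <- c("femur", "tibia", "patella")
  missing_b <- need[!vapply(need, function(b)
    b %in% names(volume$codes) && any(volume$data == volume$codes[[b]]),
    logical(1))]
  if (length(missing_b) == 3)
    stop("missing structure codes: ", paste(missing_b, collapse = ", "))

  atlas <- if (identical(config$atlas, "geometric")) {
    if (length(missing_b))
      stop("geometric atlas needs all three bones; missing: ",
           paste(missing_b, collapse = ", "))
    build_geometric_atlas(volume)
  } else {
    at <- read_region_atlas(config$atlas)
    tr <- if (is.null(config$transform_path)) identity_transform()
          else affine_transform(read_affine(config$transform_path))
    align_atlas(at, volume, tr)
  }

  pairs <- list(femur = "femoral_cartilage", tibia = "tibial_cartilage",
                patella = "patellar_cartilage")
  rec <- setNames(rep(NA_real_, length(worms_regions)), worms_regions)
  n_inner <- n_outer <- n_unassigned <- 0L
  for (bone in names(pairs)) {
    cart <- pairs[[bone]]
    has <- any(volume$data == volume$codes[[cart]]) &&
      any(volume$data == volume$codes[[bone]])
    if (!has) next
    bp <- cartilage_thickness(volume, bone, cart, mode = config$mode,
                              smooth = config$smooth)
    asg <- assign_points(bp, atlas)
    n_inner <- n_inner + nrow(bp$inner)
    n_outer <- n_outer + nrow(bp$outer)
    n_unassigned <- n_unassigned + sum(is.na(asg))
    ok <- !is.na(asg)
    if (!any(ok)) next
    means <- tapply(bp$thickness_mm[ok],
                    factor(asg[ok], levels = worms_regions), mean)
    got <- !is.na(means)
    rec[names(means)[got]] <- as.numeric(means[got])
  }
  message("run_subject: ", n_inner, " inner / ", n_outer,
          " outer boundary points; ", n_unassigned, " unassigned; ",
          sum(is.na(rec)), " regions missing")
  if (all(is.na(rec))) stop("no cartilage structure produced any thickness")
  attr(rec, "n_inner") <- n_inner
  attr(rec, "n_outer") <- n_outer
  attr(rec, "n_unassigned") <- n_unassigned
  rec
}

#' Run the cohort statistics stage
#'
#' Consumes a cohort thickness table (path or data.frame) and emits every
#' table needed for the standard cohort figures: overall and per-factor
#' region means, the all-region Tukey comparison table, per-region Tukey
#' comparisons for each condition factor, interaction regressions per
#' region and factor, and the 95% confidence bands over an age grid.
#' A factor whose two levels are not both present is skipped with a
#' warning (partial-failure contract: remaining outputs still run).
#'
#' @param cohort a `region_thickness_table` or CSV path.
#' @param config a [pipeline_config()].
#' @param write write CSVs into `config$out_dir` (each with a
#'   version+config-hash header comment).
#' @return (invisibly) a list with `group_means`, `means_by_factor`,
#'   `tukey_regions`, `tukey_by_factor`, `regressions`, `bands`.
#' @export
run_cohort <- function(cohort, config = pipeline_config(), write = FALSE) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  res <- list()
  res$group_means <- summarize_group_means(cohort)
  res$tukey_regions <- tukey_pairwise(cohort, "region")
  res$means_by_factor <- list()
  res$tukey_by_factor <- list()
  res$regressions <- list()
  res$bands <- list()
  age_grid <- seq(ceiling(min(cohort$age)), floor(max(cohort$age)), by = 1)
  for (f in config$factors) {
    if (length(unique(cohort[[f]])) < 2) {
      warning("factor '", f, "' has a single level; its comparisons and ",
              "regressions are skipped")
      next
    }
    res$means_by_factor[[f]] <- summarize_group_means(cohort, f)
    tk <- lapply(worms_regions, function(r)
      cbind(region = r, tukey_pairwise(cohort, f, response = r)))
    res$tukey_by_factor[[f]] <- do.call(rbind, tk)
    fits <- lapply(worms_regions, function(r)
      fit_interaction_model(cohort, r, f, alpha = config$alpha))
    names(fits) <- worms_regions
    res$regressions[[f]] <- do.call(rbind, lapply(worms_regions, function(r)
      cbind(region = r, fits[[r]]$coefficients,
            consistent = fits[[r]]$consistent)))
    res$bands[[f]] <- do.call(rbind, lapply(worms_regions, function(r)
      cbind(region = r, ci_band(fits[[r]], age_grid))))
  }
  if (write) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(df, name)
      write_output_table(df, file.path(config$out_dir, name), config)
    wt(res$group_means, "group_means.csv")
    wt(as.data.frame(res$tukey_regions), "tukey_regions.csv")
    for (f in names(res$means_by_factor)) {
      wt(res$means_by_factor[[f]], paste0("means_by_", f, ".csv"))
      wt(as.data.frame(res$tukey_by_factor[[f]]),
         paste0("tukey_by_", f, ".csv"))
      wt(res$regressions[[f]], paste0("regression_", f, ".csv"))
      wt(res$bands[[f]], paste0("bands_", f, ".csv"))
    }
  }
  invisible(res)
}
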