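#' Default per-region thickness calibration
#'
#' Baseline mean and SD (mm) for each of the 14 regions, plus per-region
#' age slope (mm/year), sex offset (mm, added for males) and side offset
#' (mm, added for left knees). Thirteen of the baselines are calibrated to
#' published cohort means from 2,481 radiographically normal knees; PL has
#' no published value and its default (PM minus 0.1 mm, SD 0.30) is a
#' placeholder -- it is flagged `calibrated = FALSE` and must not be read
#' as truth. Slopes and offsets default to 0: published results give the
#' signs and significance of age effects but not their magnitudes, so
#' magnitudes are free parameters a study configures explicitly.
#'
#' @param sex_calibrated if `TRUE`, FMC and FMP are parameterized from the
#'   published sex-stratified means instead of the pooled ones: baseline =
#'   female mean, `sex_offset` = male minus female difference (FMC
#'   1.70 + 0.10, SD 0.11; FMP 1.54 + 0.09, SD 0.155 pooled across the
#'   published per-sex SDs).
#' @return data.frame with one row per region: `region`, `mean`, `sd`,
#'   `age_slope`, `sex_offset`, `side_offset`, `calibrated`.
#' @export
default_region_params <- function(sex_calibrated = FALSE) {
  p <- data.frame(
    region = worms_regions,
    mean = c(2.06, 1.75, 1.59, 2.15, 1.77, 1.61,
             1.48, 1.60, 1.44, 1.51, 1.66, 1.40,
             2.18, 2.08),
    sd = c(0.20, 0.12, 0.16, 0.24, 0.13, 0.22,
           0.10, 0.12, 0.08, 0.11, 0.13, 0.11,
           0.32, 0.30),
    age_slope = 0,
    sex_offset = 0,
    side_offset = 0,
    calibrated = c(rep(TRUE, 13), FALSE)
  )
  if (sex_calibrated) {
    p[p$region == "FMC", c("mean", "sd", "sex_offset")] <-
      list(1.70, 0.11, 0.10)
    p[p$region == "FMP", c("mean", "sd", "sex_offset")] <-
      list(1.54, 0.155, 0.09)
  }
  p
}

#' Cohort specification for the synthetic thickness table
#'
#' Describes a cohort with the structure of a large knee-MR study
#' population: 2,481 subjects aged 15-64 (truncated normal, mean 35,
#' SD 10), 1,355 male / 1,126 female, 1,228 left / 1,253 right knees, and
#' per-region thickness distributions. Region thickness for subject i is
#' drawn as
#' `Normal(mean + age_slope * (age_i - 35) + sex_offset * I(male) +
#' side_offset * I(left), sd)`, truncated at 0 by redrawing.
#'
#' @param n_subjects cohort size.
#' @param age_mean,age_sd,age_range parameters of the truncated normal age
#'   distribution (years).
#' @param n_male,n_left exact stratum counts (the remaining subjects are
#'   female / right); counts are exact, not sampled.
#' @param region_params data.frame as from [default_region_params()].
#' @param seed integer RNG seed.
#' @return object of class `cohort_spec` (validated list).
#' @export
cohort_spec <- function(n_subjects = 2481L,
                        age_mean = 35, age_sd = 10, age_range = c(15, 64),
                        n_male = 1355L, n_left = 1228L,
                        region_params = default_region_params(),
                        seed = 20210209L) {
  stopifnot(n_subjects > 0, age_sd > 0, age_range[1] < age_range[2])
  if (n_male < 0 || n_male > n_subjects)
    stop("sex counts must sum to n_subjects (0 <= n_male <= n)")
  if (n_left < 0 || n_left > n_subjects)
    stop("side counts must sum to n_subjects (0 <= n_left <= n)")
  req <- c("region", "mean", "sd", "age_slope", "sex_offset", "side_offset")
  if (!all(req %in% names(region_params)))
    stop("region_params must have columns ", paste(req, collapse = ", "))
  if (!setequal(region_params$region, worms_regions))
    stop("region_params must cover exactly the 14 region codes")
  if (any(region_params$sd <= 0)) stop("all region SDs must be > 0")
  structure(list(n_subjects = as.integer(n_subjects),
                 age_mean = age_mean, age_sd = age_sd, age_range = age_range,
                 n_male = as.integer(n_male), n_left = as.integer(n_left),
                 region_params = region_params, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort thickness table
#'
#' One row per subject with `subject_id`, `age` (years), `sex` (`"M"`/
#' `"F"`), `side` (`"L"`/`"R"`) and the 14 per-region mean thicknesses in
#' mm. Ages are truncated-normal; sex and side strata have exact counts in
#' randomized order; thickness draws follow the linear model in
#' [cohort_spec()]. Negative draws are redrawn (truncation at zero keeps
#' the SD approximately honest, unlike clipping); the redraw count is
#' attached as attribute `n_redraws`. Fully reproducible for a fixed spec.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame of class `region_thickness_table`.
#' @examples
#' tab <- make_cohort(cohort_spec(n_subjects = 50, n_male = 30, n_left = 25))
#' dim(tab)
#' @export
make_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects
  age <- truncnorm::rtruncnorm(n, a = spec$age_range[1], b = spec$age_range[2],
                               mean = spec$age_mean, sd = spec$age_sd)
  sex <- sample(rep(c("M", "F"), c(spec$n_male, n - spec$n_male)))
  side <- sample(rep(c("L", "R"), c(spec$n_left, n - spec$n_left)))
  out <- data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                    age = age, sex = sex, side = side,
                    stringsAsFactors = FALSE)
  rp <- spec$region_params
  n_redraws <- 0L
  for (r in worms_regions) {
    p <- rp[rp$region == r, ]
    mu <- p$mean + p$age_slope * (age - spec$age_mean) +
      p$sex_offset * (sex == "M") + p$side_offset * (side == "L")
    x <- rnorm(n, mu, p$sd)
    bad <- which(x < 0)
    while (length(bad)) {
      n_redraws <- n_redraws + length(bad)
      x[bad] <- rnorm(length(bad), mu[bad], p$sd)
      bad <- bad[x[bad] < 0]
    }
    out[[r]] <- x
  }
  attr(out, "n_redraws") <- n_redraws
  attr(out, "spec") <- spec
  class(out) <- c("region_thickness_table", "data.frame")
  out
}

#' Read / write a cohort thickness table as CSV
#'
#' Columns: `subject_id, age, sex, side`, then the 14 region columns (mm).
#'
#' @param table a `region_thickness_table` (or compatible data.frame).
#' @param path CSV path.
#' @return `read_cohort()` returns a `region_thickness_table`.
#' @export
write_cohort <- function(table, path) {
  write.csv(as.data.frame(table)[, c("subject_id", "age", "sex", "side",
                                     worms_regions)],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "age", "sex", "side", worms_regions)
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("cohort CSV missing columns: ",
                         paste(miss, collapse = ", "))
  bad <- which(!complete.cases(tab[, c("age", worms_regions)]) |
                 !tab$sex %in% c("M", "F") | !tab$side %in% c("L", "R"))
  if (length(bad)) stop("malformed cohort rows: ",
                        paste(head(bad, 5), collapse = ", "),
                        if (length(bad) > 5) " ...")
  class(tab) <- c("region_thickness_table", "data.frame")
  tab
}
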