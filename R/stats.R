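#' Tukey simultaneous pairwise comparisons
#'
#' All-pairwise differences between factor-level means with simultaneous
#' 95% confidence intervals from the studentized-range distribution at the
#' one-way ANOVA residual degrees of freedom, controlling the family-wise
#' error rate (Tukey-Kramer for unequal group sizes). A pair is declared
#' significantly different iff its interval excludes zero; alpha is fixed
#' at 0.05, two-tailed. The difference estimates are exactly the plain
#' group-mean differences.
#'
#' With `grouping = "region"` the 14 region columns are stacked into a
#' single response with region as the factor (each subject contributes one
#' observation per region). With `grouping = "sex"` or `"side"`,
#' `response` names the single region column to compare between the two
#' strata.
#'
#' @param table a `region_thickness_table`.
#' @param grouping `"region"` (stacks the 14 region columns) or the name
#'   of any factor-like column of `table`, e.g. `"sex"` or `"side"`.
#' @param response region column name, required unless
#'   `grouping = "region"`.
#' @param conf_level family confidence level (default 0.95).
#' @param var_equal classic pooled-variance Tukey (default `TRUE`);
#'   `FALSE` gives the Games-Howell unequal-variance variant with
#'   Welch-Satterthwaite per-pair degrees of freedom.
#' @return object of class `tukey_comparisons`: data.frame with columns
#'   `group1`, `group2`, `diff` (mean(group1) - mean(group2)), `se`,
#'   `lwr`, `upr`, `significant`.
#' @examples
#' tab <- make_cohort(cohort_spec(n_subjects = 200, n_male = 100,
#'                                n_left = 100))
#' head(tukey_pairwise(tab, "region"))
#' @export
tukey_pairwise <- function(table, grouping = "region",
                           response = NULL, conf_level = 0.95,
                           var_equal = TRUE) {
  if (!identical(grouping, "region") && !grouping %in% names(table))
    stop("no grouping column '", grouping, "'")
  if (grouping == "region") {
    y <- unlist(lapply(worms_regions, function(r) table[[r]]),
                use.names = FALSE)
    g <- factor(rep(worms_regions, each = nrow(table)),
                levels = worms_regions)
  } else {
    if (is.null(response)) stop("'response' is required for grouping = '",
                                grouping, "'")
    if (!response %in% names(table)) stop("no column '", response, "'")
    y <- table[[response]]
    g <- factor(table[[grouping]])
  }
  ns <- tapply(y, g, length)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(is.na(ns)) || any(ns < 2))
    stop("every group needs at least 2 observations")
  means <- tapply(y, g, mean)
  vars <- tapply(y, g, var)
  k <- nlevels(g)
  N <- length(y)
  mse <- sum((ns - 1) * vars) / (N - k)
  if (mse <= 0) stop("zero residual variance: intervals undefined")
  df <- N - k
  # for k = 2 the studentized range is exactly sqrt(2) * t, so use the
  # closed form rather than qtukey's numerics
  qrange <- function(k, df) {
    if (k == 2) sqrt(2) * qt((1 + conf_level) / 2, df)
    else qtukey(conf_level, k, df)
  }
  pairs <- utils::combn(levels(g), 2)
  res <- apply(pairs, 2, function(p) {
    i <- p[1]; j <- p[2]
    dm <- means[[i]] - means[[j]]
    if (var_equal) {
      se <- sqrt(mse * (1 / ns[[i]] + 1 / ns[[j]]))
      qc <- qrange(k, df)
    } else {
      vi <- vars[[i]] / ns[[i]]; vj <- vars[[j]] / ns[[j]]
      se <- sqrt(vi + vj)
      dfw <- (vi + vj)^2 / (vi^2 / (ns[[i]] - 1) + vj^2 / (ns[[j]] - 1))
      qc <- qrange(k, dfw)
    }
    # pooled: q/sqrt(2) * sqrt(mse*(1/ni+1/nj)); Games-Howell:
    # q_{k,df'} * sqrt((vi+vj)/2) -- both are qc * se / sqrt(2)
    half <- qc * se / sqrt(2)
    c(diff = dm, se = se, lwr = dm - half, upr = dm + half)
  })
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    t(res), row.names = NULL)
  out$significant <- out$lwr > 0 | out$upr < 0
  attr(out, "conf_level") <- conf_level
  attr(out, "grouping") <- grouping
  attr(out, "response") <- response
  class(out) <- c("tukey_comparisons", "data.frame")
  out
}

#' @export
print.tukey_comparisons <- function(x, ...) {
  cat("Tukey simultaneous ", 100 * attr(x, "conf_level"),
      "% comparisons (", attr(x, "grouping"),
      if (!is.null(attr(x, "response"))) paste0(", ", attr(x, "response")),
      "): ", nrow(x), " pairs, ", sum(x$significant), " significant\n",
      sep = "")
  print.data.frame(cbind(x[, c("group1", "group2")],
                         round(x[, c("diff", "se", "lwr", "upr")], 4),
                         significant = x$significant), ...)
  invisible(x)
}

#' Age-by-condition interaction regression of region thickness
#'
#' Ordinary least squares of one region's thickness on age (continuous),
#' a two-level condition (sex or side; main effect) and their interaction.
#' The interaction coefficient equals the difference between the
#' condition-specific age slopes, so its two-tailed p-value tests whether
#' thickness changes with age consistently across the two strata
#' ("inconsistent between conditions" iff p < alpha). Age is centred at
#' the cohort mean for the fit; coefficients are reported on the
#' uncentred scale.
#'
#' @param table a `region_thickness_table`.
#' @param response region column name.
#' @param condition `"sex"` or `"side"`.
#' @param alpha significance level (two-tailed), default 0.05.
#' @return object of class `interaction_fit` with coefficient table
#'   (estimate, SE, t, p, 95% CI per term), stratified slopes, the
#'   consistency verdict, and the underlying `lm` fit.
#' @examples
#' tab <- make_cohort(cohort_spec(n_subjects = 400, n_male = 200,
#'                                n_left = 200))
#' fit <- fit_interaction_model(tab, "FMC", "sex")
#' coef(fit)
#' @export
fit_interaction_model <- function(table, response,
                                  condition = c("sex", "side"),
                                  alpha = 0.05) {
  condition <- match.arg(condition)
  if (!response %in% names(table)) stop("no column '", response, "'")
  y <- table[[response]]
  cond <- factor(table[[condition]],
                 levels = if (condition == "sex") c("F", "M") else c("R", "L"))
  if (nlevels(droplevels(cond)) < 2)
    stop("both ", condition, " levels must be present")
  age <- table$age
  if (length(unique(age)) < 4) stop("need >= 4 distinct ages")
  abar <- mean(age)
  ac <- age - abar
  ind <- as.numeric(cond == levels(cond)[2])
  fit <- lm(y ~ ac * ind)
  if (fit$df.residual < 1 || any(is.na(coef(fit))))
    stop("rank-deficient design (e.g. a single age value)")
  # map centred coefficients (a0, a1, a2, a3) back to the uncentred scale:
  # b0 = a0 - a1*abar, b1 = a1, b2 = a2 - a3*abar, b3 = a3
  Tm <- diag(4)
  Tm[1, 2] <- -abar
  Tm[3, 4] <- -abar
  b <- drop(Tm %*% coef(fit))
  V <- Tm %*% vcov(fit) %*% t(Tm)
  se <- sqrt(diag(V))
  dfres <- fit$df.residual
  tval <- b / se
  pval <- 2 * pt(-abs(tval), dfres)
  tcrit <- qt(1 - alpha / 2, dfres)
  terms <- c("(Intercept)", "age", paste0(condition, levels(cond)[2]),
             paste0("age:", condition, levels(cond)[2]))
  coefs <- data.frame(term = terms, estimate = b, se = se, t = tval,
                      p = pval, lwr = b - tcrit * se, upr = b + tcrit * se,
                      row.names = NULL)
  slopes <- setNames(c(b[2], b[2] + b[4]), levels(cond))
  structure(list(coefficients = coefs, response = response,
                 condition = condition, levels = levels(cond),
                 slopes = slopes, alpha = alpha,
                 consistent = pval[4] >= alpha,
                 age_mean = abar, age_range = range(age),
                 lm = fit, n = length(y)),
            class = "interaction_fit")
}

#' @export
coef.interaction_fit <- function(object, ...) {
  setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
print.interaction_fit <- function(x, ...) {
  cat("Age x ", x$condition, " regression of ", x$response, " (n = ", x$n,
      ")\n", sep = "")
  print(cbind(x$coefficients[, "term", drop = FALSE],
              round(x$coefficients[, -1], 5)), row.names = FALSE)
  cat("Age slopes (mm/year): ",
      paste(sprintf("%s = %.5f", names(x$slopes), x$slopes),
            collapse = ", "), "\n", sep = "")
  cat("Verdict: thickness change with age is ",
      if (x$consistent) "consistent" else "inconsistent",
      " between ", x$condition, " levels (interaction p = ",
      format.pval(x$coefficients$p[4], digits = 3), ")\n", sep = "")
  invisible(x)
}

#' @export
summary.interaction_fit <- function(object, ...) {
  print(object)
  invisible(object$coefficients)
}

#' @export
predict.interaction_fit <- function(object, age, level = NULL,
                                    interval = c("confidence", "none"), ...) {
  interval <- match.arg(interval)
  if (is.null(level)) level <- object$levels
  grids <- lapply(level, function(lv) {
    nd <- data.frame(ac = age - object$age_mean,
                     ind = as.numeric(lv == object$levels[2]))
    pr <- predict(object$lm, newdata = nd,
                  interval = if (interval == "confidence") "confidence" else "none",
                  level = 0.95)
    pr <- as.data.frame(pr)
    if (interval == "none") names(pr) <- "fit"
    cbind(data.frame(age = age, condition = lv), pr)
  })
  do.call(rbind, grids)
}

#' @export
residuals.interaction_fit <- function(object, ...) residuals(object$lm)

#' Pointwise 95% confidence band of the conditional mean over an age grid
#'
#' @param fit an `interaction_fit`.
#' @param age_grid ages (years) at which to evaluate the band; values
#'   outside the fitted cohort's age support trigger an extrapolation
#'   warning.
#' @return data.frame with `age`, `condition`, `fit`, `lwr`, `upr` (mm).
#' @export
ci_band <- function(fit, age_grid = seq(15, 64, by = 1)) {
  stopifnot(inherits(fit, "interaction_fit"))
  if (any(age_grid < fit$age_range[1] - 1e-9 |
            age_grid > fit$age_range[2] + 1e-9))
    warning("age grid extends outside the fitted age range [",
            round(fit$age_range[1], 1), ", ", round(fit$age_range[2], 1),
            "]: extrapolating")
  predict(fit, age = age_grid, interval = "confidence")
}

#' @export
plot.interaction_fit <- function(x, age_grid = seq(15, 64, by = 1), ...) {
  band <- suppressWarnings(ci_band(x, age_grid))
  cols <- c("#1b6ca8", "#c0392b")
  plot(NA, xlim = range(age_grid), ylim = range(band$lwr, band$upr),
       xlab = "age (years)", ylab = paste(x$response, "thickness (mm)"),
       main = paste0(x$response, ": age x ", x$condition), ...)
  for (i in seq_along(x$levels)) {
    b <- band[band$condition == x$levels[i], ]
    graphics::polygon(c(b$age, rev(b$age)), c(b$lwr, rev(b$upr)),
                      col = grDevices::adjustcolor(cols[i], 0.25),
                      border = NA)
    graphics::lines(b$age, b$fit, col = cols[i], lwd = 2)
  }
  graphics::legend("topright", legend = x$levels, col = cols, lwd = 2,
                   bty = "n")
  invisible(x)
}

#' Per-group region means and SDs
#'
#' Arithmetic mean and sample SD of every region column, overall or per
#' level of a grouping factor; for `sex` and `side` the male-minus-female
#' (respectively left-minus-right) difference columns are appended. A
#' single-observation group reports `NA` SD (undefined, not zero).
#'
#' @param table a `region_thickness_table`.
#' @param grouping `NULL` (overall), `"sex"` or `"side"`.
#' @return data.frame with one row per region: `region`, then
#'   `mean`/`sd` (overall) or per-level mean/sd columns plus `diff`
#'   (M - F, or L - R).
#' @export
summarize_group_means <- function(table, grouping = NULL) {
  if (nrow(table) == 0) stop("empty cohort table")
  sd_or_na <- function(v) if (length(v) > 1) sd(v) else NA_real_
  if (is.null(grouping)) {
    return(data.frame(region = worms_regions,
                      mean = vapply(worms_regions,
                                    function(r) mean(table[[r]]), 0),
                      sd = vapply(worms_regions,
                                  function(r) sd_or_na(table[[r]]), 0),
                      row.names = NULL))
  }
  grouping <- match.arg(grouping, c("sex", "side"))
  lv <- if (grouping == "sex") c("M", "F") else c("L", "R")
  g <- factor(table[[grouping]], levels = lv)
  out <- data.frame(region = worms_regions, row.names = NULL)
  for (l in lv) {
    sub <- table[g == l, , drop = FALSE]
    out[[paste0("mean_", l)]] <- vapply(worms_regions,
                                        function(r) mean(sub[[r]]), 0)
    out[[paste0("sd_", l)]] <- vapply(worms_regions,
                                      function(r) sd_or_na(sub[[r]]), 0)
  }
  out$diff <- out[[paste0("mean_", lv[1])]] - out[[paste0("mean_", lv[2])]]
  attr(out, "diff_is") <- paste(lv[1], "-", lv[2])
  out
}
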