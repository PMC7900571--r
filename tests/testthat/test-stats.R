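test_that("tukey: identical groups give zero difference, not significant", {
  d <- tiny_cohort()
  # sexes alternate M,F,M,F...; a period-4 value pattern hands both sexes
  # the identical multiset {1.9, 2.1, ...}
  d$FMA <- rep(c(1.9, 1.9, 2.1, 2.1), nrow(d) / 4)
  tk <- tukey_pairwise(d, "sex", response = "FMA")
  expect_equal(tk$diff, 0)
  expect_false(tk$significant)
  expect_lte(tk$lwr, 0); expect_gte(tk$upr, 0)
})

test_that("k=2 Tukey interval equals the pooled two-sample t interval", {
  d <- tiny_cohort(n = 50, seed = 4)
  tk <- tukey_pairwise(d, "sex", response = "FMC")
  tt <- t.test(FMC ~ sex, data = d, var.equal = TRUE)
  # t.test orders F then M, as does the factor in tukey_pairwise
  expect_equal(tk$lwr, tt$conf.int[1], tolerance = 1e-10)
  expect_equal(tk$upr, tt$conf.int[2], tolerance = 1e-10)
  expect_equal(tk$diff, unname(diff(rev(tt$estimate))), tolerance = 1e-12)
})

test_that("tukey difference estimates equal plain group-mean differences; cross-check TukeyHSD", {
  d <- tiny_cohort(n = 90, seed = 12)
  tk <- tukey_pairwise(d, "region")
  long <- data.frame(
    y = unlist(d[worms_regions], use.names = FALSE),
    g = factor(rep(worms_regions, each = nrow(d)), levels = worms_regions))
  means <- tapply(long$y, long$g, mean)
  for (i in sample(nrow(tk), 10)) {
    expect_equal(tk$diff[i],
                 unname(means[tk$group1[i]] - means[tk$group2[i]]),
                 tolerance = 1e-12)
  }
  # independent route: stats::TukeyHSD on the same one-way layout
  hs <- TukeyHSD(aov(y ~ g, data = long))$g
  key <- paste(tk$group2, tk$group1, sep = "-")  # TukeyHSD uses later-earlier
  expect_equal(-tk$diff, unname(hs[key, "diff"]), tolerance = 1e-10)
  expect_equal(-tk$upr, unname(hs[key, "lwr"]), tolerance = 1e-8)
  expect_equal(-tk$lwr, unname(hs[key, "upr"]), tolerance = 1e-8)
})

test_that("tukey error contracts", {
  d <- tiny_cohort(n = 8)
  d$sex <- c("M", rep("F", 7))
  expect_error(tukey_pairwise(d, "sex", response = "FMA"),
               "at least 2 observations")
  d2 <- tiny_cohort(n = 8)
  d2$FMA <- rep(1, 8)
  expect_error(tukey_pairwise(d2, "sex", response = "FMA"),
               "zero residual variance")
})

test_that("family error rate under the global null stays controlled", {
  # 5,000 simulated null datasets, k = 4 groups of 8; count families with
  # any significant pair
  set.seed(2026)
  k <- 4; n <- 8; reps <- 5000
  hits <- 0L
  d <- data.frame(grp = rep(letters[1:k], each = n), y = numeric(k * n))
  for (b in seq_len(reps)) {
    d$y <- rnorm(k * n)
    tk <- tukey_pairwise(d, "grp", response = "y")
    if (any(tk$significant)) hits <- hits + 1L
  }
  rate <- hits / reps
  mc_se <- sqrt(0.05 * 0.95 / reps)
  expect_lte(rate, 0.05 + 2 * mc_se)
})

test_that("interaction coefficient equals the stratified slope difference", {
  set.seed(5)
  for (rep in 1:5) {
    d <- tiny_cohort(n = 120, seed = rep)
    d$FMA <- 2 - 0.01 * d$age + 0.004 * d$age * (d$sex == "M") +
      rnorm(120, 0, 0.15)
    fit <- fit_interaction_model(d, "FMA", "sex")
    sM <- coef(lm(FMA ~ age, d[d$sex == "M", ]))["age"]
    sF <- coef(lm(FMA ~ age, d[d$sex == "F", ]))["age"]
    expect_equal(unname(coef(fit)["age:sexM"]), unname(sM - sF),
                 tolerance = 1e-8)
    expect_equal(unname(fit$slopes["M"] - fit$slopes["F"]),
                 unname(sM - sF), tolerance = 1e-8)
  }
})

test_that("uncentred coefficients match a direct uncentred lm fit", {
  d <- tiny_cohort(n = 80, seed = 21)
  fit <- fit_interaction_model(d, "TLC", "side")
  ref <- lm(TLC ~ age * ind, data = transform(d, ind = as.numeric(side == "L")))
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-9)
  expect_equal(fit$coefficients$se, unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-9)
})

test_that("null interaction is rarely significant; configured slope difference is recovered", {
  # equal slopes in both sexes -> interaction null
  spec <- cohort_spec(seed = 17L)
  tab <- make_cohort(spec)
  fit <- fit_interaction_model(tab, "FMA", "sex")
  expect_gt(fit$coefficients$p[4], 0.05)
  expect_true(fit$consistent)
  # male slope -0.010, female -0.002 -> interaction -0.008
  rp <- default_region_params()
  rp$age_slope[rp$region == "FMC"] <- -0.002        # female baseline slope
  spec2 <- cohort_spec(region_params = rp, seed = 23L)
  tab2 <- make_cohort(spec2)
  tab2$FMC <- tab2$FMC + (-0.008) * (tab2$age - 35) * (tab2$sex == "M")
  fit2 <- fit_interaction_model(tab2, "FMC", "sex")
  est <- fit2$coefficients[4, ]
  expect_lt(abs(est$estimate - (-0.008)), 3 * est$se)
})

test_that("confidence band is narrowest near the age centroid and widens outward", {
  d <- tiny_cohort(n = 200, seed = 3)
  fit <- fit_interaction_model(d, "FMA", "sex")
  grid <- seq(17, 62, by = 0.5)
  band <- ci_band(fit, grid)
  bM <- band[band$condition == "M", ]
  w <- bM$upr - bM$lwr
  i0 <- which.min(abs(bM$age - mean(d$age[d$sex == "M"])))
  expect_lt(abs(which.min(w) - i0), 6)
  # widths increase monotonically away from the minimum (leverage)
  expect_true(all(diff(w[seq(which.min(w), length(w))]) > -1e-12))
  expect_true(all(diff(w[seq(which.min(w), 1)]) > -1e-12))
  expect_warning(ci_band(fit, c(10, 30)), "extrapolat")
})

test_that("quadrupling n halves the band width", {
  mk <- function(n, seed) {
    set.seed(seed)
    d <- data.frame(age = runif(n, 16, 63),
                    sex = rep(c("M", "F"), length.out = n),
                    side = rep(c("L", "R"), length.out = n))
    d$FMA <- 2 - 0.005 * d$age + rnorm(n, 0, 0.2)
    for (r in setdiff(worms_regions, "FMA")) d[[r]] <- rnorm(n, 2, 0.2)
    class(d) <- c("region_thickness_table", "data.frame")
    d
  }
  f1 <- fit_interaction_model(mk(400, 8), "FMA", "sex")
  f4 <- fit_interaction_model(mk(1600, 8), "FMA", "sex")
  w1 <- with(ci_band(f1, 40), mean(upr - lwr))
  w4 <- with(ci_band(f4, 40), mean(upr - lwr))
  expect_lt(abs(w4 / w1 - 0.5), 0.15)
})

test_that("summarize_group_means: overall, by sex, single-subject SD missing", {
  tab <- make_cohort(cohort_spec(n_subjects = 300L, n_male = 150L,
                                 n_left = 150L, seed = 9L))
  gm <- summarize_group_means(tab)
  expect_equal(gm$mean[gm$region == "FMA"], mean(tab$FMA))
  sm <- summarize_group_means(tab, "sex")
  expect_equal(sm$diff, sm$mean_M - sm$mean_F)
  # offsets are zero by default, so sex differences are sampling noise
  expect_lt(max(abs(sm$diff)), 4 * 0.32 * sqrt(2 / 150))
  one <- tab[1, , drop = FALSE]
  g1 <- summarize_group_means(one)
  expect_true(all(is.na(g1$sd)))
})

test_that("generator slopes and offsets are recovered across seeded replicates", {
  # 100 replicates at modest n: the average estimate must sit within 3
  # standard errors of the configured truth
  rp <- default_region_params()
  rp$age_slope[rp$region == "TMA"] <- -0.004
  rp$sex_offset[rp$region == "TMA"] <- 0.05
  ests <- matrix(NA_real_, 100, 2)
  for (s in 1:100) {
    spec <- cohort_spec(n_subjects = 400L, n_male = 200L, n_left = 200L,
                        region_params = rp, seed = 1000L + s)
    tab <- make_cohort(spec)
    fit <- lm(TMA ~ age + I(sex == "M"), data = tab)
    ests[s, ] <- coef(fit)[2:3]
  }
  expect_lt(abs(mean(ests[, 1]) - (-0.004)), 3 * sd(ests[, 1]) / 10)
  expect_lt(abs(mean(ests[, 2]) - 0.05), 3 * sd(ests[, 2]) / 10)
})
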