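test_that("one-way ANOVA matches the textbook decomposition on a hand fixture", {
  groups <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5))
  # brute-force oracle evaluated in place
  y <- unlist(groups); gm <- mean(y)
  means <- vapply(groups, mean, numeric(1))
  ss_b <- sum(3 * (means - gm)^2)
  ss_w <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  an <- one_way_anova(groups)
  expect_equal(an$ss_between, ss_b)
  expect_equal(an$ss_within, ss_w)
  expect_equal(an$df_between, 2)
  expect_equal(an$df_within, 6)
  expect_equal(an$f, (ss_b / 2) / (ss_w / 6))
  expect_equal(an$p, 1 - pf(an$f, 2, 6))
  # total sum of squares decomposes exactly
  expect_equal(an$ss_between + an$ss_within, sum((y - gm)^2))
})

test_that("ANOVA handles identical groups and bad input", {
  an <- one_way_anova(list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3)))
  expect_equal(an$f, 0)
  expect_equal(an$p, 1)
  expect_message(
    an0 <- one_way_anova(list(a = rep(2, 4), b = rep(2, 5))),
    "zero total variance")
  expect_equal(an0$p, 1)
  expect_error(one_way_anova(list(a = 1, b = c(1, 2))), "n >= 2")
  expect_error(one_way_anova(list(a = c(1, 2))), "2 groups")
})

test_that("ANOVA F is invariant under affine transformation of the data", {
  set.seed(77)
  groups <- lapply(1:3, function(i) rnorm(10, i * 0.3))
  names(groups) <- letters[1:3]
  f1 <- one_way_anova(groups)$f
  f2 <- one_way_anova(lapply(groups, function(g) 3.2 * g - 5))$f
  expect_equal(f1, f2)
})

test_that("studentized range CDF is a valid, monotone distribution", {
  expect_equal(studentized_range_cdf(0, 3, 10), 0)
  q <- seq(0.5, 6, by = 0.5)
  p <- studentized_range_cdf(q, 4, 20)
  expect_true(all(diff(p) > 0))
  expect_true(all(p >= 0 & p <= 1))
  # k = 2, large df: range of two normals ~ |N(0,2)|
  q0 <- 2.2
  expect_equal(studentized_range_cdf(q0, 2, 1e6),
               2 * pnorm(q0 / sqrt(2)) - 1, tolerance = 1e-4)
  expect_error(studentized_range_cdf(-1, 3, 10), ">= 0")
  expect_error(studentized_range_cdf(1, 1, 10), ">= 2")
})

test_that("studentized range CDF matches a Monte-Carlo oracle", {
  set.seed(99)
  nrep <- 200000
  k <- 3; df <- 10; q0 <- 3.5
  z <- matrix(rnorm(nrep * k), ncol = k)
  s <- sqrt(rchisq(nrep, df) / df)
  Q <- (apply(z, 1, max) - apply(z, 1, min)) / s
  mc <- mean(Q <= q0)
  mcse <- sqrt(mc * (1 - mc) / nrep)
  expect_lt(abs(studentized_range_cdf(q0, k, df) - mc), 3 * mcse)
})

test_that("Tukey HSD reduces to the pooled t-test for two groups", {
  set.seed(12)
  g <- list(a = rnorm(12), b = rnorm(15, 0.6))
  tk <- tukey_hsd(g)
  tt <- t.test(g$b, g$a, var.equal = TRUE)
  expect_equal(tk$p_adj, tt$p.value, tolerance = 1e-10)
  expect_equal(tk$diff, unname(tt$estimate[1] - tt$estimate[2]),
               tolerance = 1e-10)
})

test_that("Tukey HSD agrees with the reference implementation on three groups", {
  set.seed(13)
  g <- list(`25` = rnorm(30, 2.5, 0.4), `34` = rnorm(30, 2.7, 0.4),
            `44` = rnorm(30, 3.0, 0.4))
  tk <- tukey_hsd(g)
  y <- unlist(g); f <- factor(rep(names(g), lengths(g)), levels = names(g))
  ref <- TukeyHSD(aov(y ~ f))$f
  expect_equal(tk$diff, unname(ref[, "diff"]), tolerance = 1e-10)
  expect_equal(tk$lwr, unname(ref[, "lwr"]), tolerance = 1e-10)
  expect_equal(tk$upr, unname(ref[, "upr"]), tolerance = 1e-10)
  expect_equal(tk$p_adj, unname(ref[, "p adj"]), tolerance = 1e-8)
  # intervals bracket the differences; adjusted p not below the unadjusted
  # pairwise p computed from the same pooled variance
  expect_true(all(tk$lwr <= tk$diff & tk$diff <= tk$upr))
  an <- attr(tk, "anova")
  for (r in 1:3) {
    tstat <- abs(tk$diff[r]) / sqrt(an$ms_within * (2 / 30))
    praw <- 2 * pt(-tstat, an$df_within)
    expect_gte(tk$p_adj[r], praw - 1e-10)
  }
})

test_that("Tukey HSD on identical groups returns zero differences and p = 1", {
  g <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(1, 2, 3, 4))
  tk <- tukey_hsd(g)
  expect_equal(tk$diff, rep(0, 3))
  expect_equal(tk$p_adj, rep(1, 3))
})

test_that("OLS matches the normal equations on a 5-point fixture", {
  x <- c(1, 2, 3, 5, 8); y <- c(2.1, 2.9, 4.2, 6.1, 9.8)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  reg <- linear_regression(x, y)
  expect_equal(reg$intercept, beta[1])
  expect_equal(reg$slope, beta[2])
  expect_equal(sum(reg$residuals), 0, tolerance = 1e-12)
  # collinear data
  r2 <- linear_regression(1:5, 2 * (1:5) + 3)
  expect_equal(r2$r2, 1)
  expect_equal(max(abs(r2$residuals)), 0, tolerance = 1e-12)
  # constant response
  r3 <- linear_regression(1:5, rep(4, 5))
  expect_equal(r3$slope, 0)
  expect_equal(r3$r2, 0)
  expect_error(linear_regression(rep(1, 5), 1:5), "constant")
  expect_error(linear_regression(1:2, 1:2), "3 observations")
})

test_that("global assumption statistic is the exact sum of its four components", {
  set.seed(21)
  x <- runif(40, 1, 5); y <- 1 + x + rnorm(40, 0, 0.3)
  rep_ <- validate_assumptions(linear_regression(x, y), refit = FALSE)
  expect_equal(rep_$global_stat, sum(rep_$components$statistic))
  expect_equal(rep_$global_p, 1 - pchisq(rep_$global_stat, 4))
  expect_match(rep_$independence, "assumed")
})

test_that("heteroscedastic data trips the heteroscedasticity component", {
  set.seed(22)
  hits <- 0
  for (r in 1:30) {
    x <- runif(100, 1, 5)
    y <- 2 + x + rnorm(100, 0, 0.25 * x)
    rep_ <- validate_assumptions(linear_regression(x, y), refit = FALSE)
    het <- rep_$components$p[rep_$components$component ==
                               "heteroscedasticity"]
    hits <- hits + (het < 0.05)
  }
  expect_gt(hits / 30, 0.8)
})

test_that("log-linear data with multiplicative noise triggers the log-transform policy", {
  set.seed(9)
  x <- runif(30, 1, 6); y <- 0.5 * x^2.5 * exp(rnorm(30, 0, 0.25))
  rep_ <- validate_assumptions(linear_regression(x, y))
  expect_equal(rep_$decision, "log-transform")
  expect_false(is.null(rep_$transformed))
  expect_equal(rep_$transformed$transform, "log-log")
  rep2 <- validate_assumptions(rep_$transformed, refit = FALSE)
  expect_gte(rep2$global_p, 0.05)
})

test_that("small samples skip the asymptotic assumption tests with a warning", {
  expect_warning(
    rep_ <- validate_assumptions(linear_regression(1:5, c(1, 3, 2, 5, 4))),
    "n < 8")
  expect_true(is.na(rep_$global_p))
  expect_equal(rep_$decision, "keep")
})

test_that("influence diagnostics flag injected outliers and stay near nominal level", {
  set.seed(30)
  x <- runif(50, 0, 10); y <- 1 + x + rnorm(50, 0, 0.5)
  y[17] <- y[17] + 10 * 0.5
  reg <- linear_regression(x, y)
  expect_true(17 %in% influential_points(reg))
  # clean data: flagged fraction stays at or below the pointwise level
  # (the envelope is conservative for regression residuals because the
  # fitted constraints remove the location mode of QQ excursions)
  set.seed(31)
  fr <- replicate(150, {
    x <- runif(200); y <- x + rnorm(200)
    length(influential_points(linear_regression(x, y))) / 200
  })
  expect_lt(mean(fr), 0.06)
  # a milder 5-sigma outlier is still caught most of the time
  set.seed(32)
  hits <- mean(replicate(50, {
    x <- runif(60, 0, 10); y <- 1 + x + rnorm(60, 0, 0.5)
    y[8] <- y[8] + 5 * 0.5
    8 %in% influential_points(linear_regression(x, y))
  }))
  expect_gt(hits, 0.6)
  # perfect tiny fit: nothing to flag
  expect_length(influential_points(linear_regression(1:3, c(2, 4, 6))),
                0)
})

test_that("resolvability requires twice the standard uncertainty", {
  expect_false(resolvable_difference(0.3, 0.2))
  expect_true(resolvable_difference(0.4, 0.2))
  expect_true(resolvable_difference(-0.5, 0.2))
  expect_false(resolvable_difference(0, 0.2))
  expect_error(resolvable_difference(0.3, -0.1), ">= 0")
})

test_that("analyze_study reproduces the decoupled-thickness salinity pattern", {
  design <- make_mini_design(coupling = "decoupled", beta = 0.037)
  study <- simulate_study(design, seed = 55, mode = "table")
  report <- analyze_study(study_tables(study))
  an <- report$anova
  expect_equal(nrow(an), 6) # 2 strains x 3 metrics
  len <- an[an$metric == "length", ]
  thk <- an[an$metric == "thickness", ]
  expect_true(all(len$significant))
  expect_false(any(thk$significant))
  # regressions computed for every sample x response
  expect_equal(nrow(report$regressions), 6 * 4)
  # resolvability flags only differences exceeding twice the uncertainty
  if (!is.null(report$tukey)) {
    expect_true(all(report$tukey$resolved ==
                      (report$tukey$significant &
                         abs(report$tukey$diff) >=
                           2 * report$tukey$uncertainty)))
  }
})

test_that("isometric studies couple length and thickness significantly", {
  design <- make_mini_design(coupling = "isometric", beta = 0.037)
  study <- simulate_study(design, seed = 56, mode = "table")
  report <- analyze_study(study_tables(study))
  an <- report$anova
  expect_true(all(an[an$metric == "length", "significant"]))
  expect_true(all(an[an$metric == "thickness", "significant"]))
  regs <- report$regressions
  thick_regs <- regs[regs$response == "thickness", ]
  expect_gt(mean(thick_regs$significant), 0.8)
})

test_that("strains with a single salinity level are skipped with a warning", {
  pop <- population_spec(n = 10)
  design <- list(list(strain = "solo", species = NA, salinity = 34,
                      pop = pop))
  study <- simulate_study(design, seed = 57, mode = "table")
  expect_warning(report <- analyze_study(study_tables(study)),
                 "skipped")
  expect_equal(report$skipped, "solo")
})
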