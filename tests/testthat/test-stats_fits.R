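# Brute-force normal-equations oracle, independent of lm.fit.
solve_ls <- function(X, y) as.numeric(solve(t(X) %*% X, t(X) %*% y))

test_that("linear fit is exact on lines and matches the oracle", {
  x <- c(1, 2, 3, 5, 8)
  f <- fit_linear(x, 2 * x + 1)
  expect_equal(unname(f$coefficients["slope"]), 2, tolerance = 1e-12)
  expect_equal(unname(f$coefficients["intercept"]), 1, tolerance = 1e-12)
  expect_equal(f$correlation, 1)
  expect_equal(f$p_value, 0)
  expect_equal(fit_linear(x, -x)$correlation, -1)

  set.seed(5)
  y <- 3 * x - 2 + rnorm(5)
  f2 <- fit_linear(x, y)
  oracle <- solve_ls(cbind(1, x), y)
  expect_equal(unname(f2$coefficients[c("intercept", "slope")]), oracle,
               tolerance = 1e-10)
  expect_error(fit_linear(rep(2, 5), y), "degenerate")
  expect_error(fit_linear(1:2, 1:2), "at least 3")
})

test_that("power fit recovers exponents in log-log space", {
  x <- c(80, 100, 120, 150, 180)
  f <- fit_power(x, 2 * x^1.5)
  expect_equal(unname(f$coefficients["exponent"]), 1.5, tolerance = 1e-10)
  expect_equal(unname(f$coefficients["amplitude"]), 2, tolerance = 1e-10)
  expect_equal(f$correlation, 1)
  expect_equal(unname(fit_power(x, rep(4, 5))$coefficients["exponent"]), 0,
               tolerance = 1e-12)
  expect_error(fit_power(c(-1, 2, 3), c(1, 2, 3)), "positive")

  # oracle in the linearized space
  set.seed(9)
  y <- 0.5 * x^1.3 * exp(rnorm(5, 0, 0.05))
  f2 <- fit_power(x, y)
  oracle <- solve_ls(cbind(1, log(x)), log(y))
  expect_equal(unname(f2$coefficients["exponent"]), oracle[2],
               tolerance = 1e-10)
  expect_equal(unname(f2$coefficients["amplitude"]), exp(oracle[1]),
               tolerance = 1e-10)
})

test_that("exponential fit reports signed correlation and Y-intercept", {
  x <- c(0.64, 0.96, 1.92, 3.84, 5.76)
  f <- fit_exponential(x, 7.54 * exp(-0.3 * x))
  expect_equal(unname(f$coefficients["y_intercept"]), 7.54,
               tolerance = 1e-10)
  expect_equal(unname(f$coefficients["rate"]), 0.3, tolerance = 1e-10)
  expect_equal(f$correlation, -1)
  expect_equal(unname(fit_exponential(x, rep(3, 5))$coefficients["rate"]),
               0, tolerance = 1e-12)
  expect_error(fit_exponential(x, c(1, 2, 0, 4, 5)), "positive")
})

test_that("power and exponential fits are equivariant under y rescaling", {
  x <- c(1, 2, 4, 7, 11)
  set.seed(13)
  y <- 2 * x^1.2 * exp(rnorm(5, 0, 0.1))
  for (s in c(0.1, 3, 50)) {
    fp <- fit_power(x, s * y)
    expect_equal(unname(fp$coefficients["exponent"]),
                 unname(fit_power(x, y)$coefficients["exponent"]),
                 tolerance = 1e-10)
    expect_equal(unname(fp$coefficients["amplitude"]),
                 s * unname(fit_power(x, y)$coefficients["amplitude"]),
                 tolerance = 1e-8)
    fe <- fit_exponential(x, s * y)
    expect_equal(unname(fe$coefficients["rate"]),
                 unname(fit_exponential(x, y)$coefficients["rate"]),
                 tolerance = 1e-10)
  }
})

test_that("quadratic fit is exact, nests the linear case, matches oracle", {
  x <- c(-2, -1, 0, 1, 2, 3)
  f <- fit_quadratic(x, x^2)
  expect_equal(unname(f$coefficients), c(1, 0, 0), tolerance = 1e-10)
  expect_equal(f$correlation, 1)
  f2 <- fit_quadratic(x, 3 * x + 1)
  expect_equal(unname(f2$coefficients["quadratic"]), 0, tolerance = 1e-10)

  set.seed(17)
  y <- 1 + 0.5 * x - 0.2 * x^2 + rnorm(6, 0, 0.1)
  f3 <- fit_quadratic(x, y)
  oracle <- solve_ls(cbind(1, x, x^2), y)
  expect_equal(unname(f3$coefficients[c("constant", "linear", "quadratic")]),
               oracle, tolerance = 1e-9)
  expect_error(fit_quadratic(c(1, 1, 1, 1), 1:4), "degenerate")
  expect_error(fit_quadratic(1:3, 1:3), "at least 4")
})

test_that("one-way ANOVA matches aov/TukeyHSD and handles degeneracy", {
  set.seed(19)
  groups <- list(a = rnorm(5, 10), b = rnorm(5, 11), c = rnorm(5, 13))
  res <- one_way_anova_tukey(groups)

  df <- data.frame(y = unlist(groups),
                   g = rep(names(groups), each = 5))
  fit <- stats::aov(y ~ g, data = df)
  expect_equal(res$f_statistic, summary(fit)[[1]]$`F value`[1],
               tolerance = 1e-10)
  expect_equal(res$p_value, summary(fit)[[1]]$`Pr(>F)`[1],
               tolerance = 1e-10)
  hsd <- stats::TukeyHSD(fit)$g
  expect_equal(nrow(res$tukey_pairs), choose(3, 2))
  for (i in seq_len(nrow(res$tukey_pairs))) {
    key <- paste0(res$tukey_pairs$group2[i], "-", res$tukey_pairs$group1[i])
    expect_equal(res$tukey_pairs$p_adj[i], hsd[key, "p adj"],
                 tolerance = 1e-8)
  }

  # all groups identical constants
  flat <- one_way_anova_tukey(list(a = rep(2, 4), b = rep(2, 4)))
  expect_equal(flat$f_statistic, 0)
  expect_equal(flat$p_value, 1)
  expect_true(flat$degenerate)

  # well-separated groups land in the strongest band
  sep <- one_way_anova_tukey(list(lo = rnorm(5, 0, 1), hi = rnorm(5, 100, 1)))
  expect_lt(sep$p_value, 1e-3)
  expect_equal(sep$tukey_pairs$band, "<0.001")
  expect_error(one_way_anova_tukey(list(a = 1:3)), "2 groups")
  expect_error(one_way_anova_tukey(list(a = 1, b = 2)), "at least 2")
})

test_that("ANOVA F agrees with a permutation oracle at n = 5", {
  set.seed(23)
  groups <- list(a = rnorm(5, 0), b = rnorm(5, 1.4), c = rnorm(5, 2.2))
  res <- one_way_anova_tukey(groups)
  y <- unlist(groups)
  g <- rep(1:3, each = 5)
  f_of <- function(yy) {
    m <- tapply(yy, g, mean); n <- tapply(yy, g, length)
    ssb <- sum(n * (m - mean(yy))^2)
    ssw <- sum((yy - m[g])^2)
    (ssb / 2) / (ssw / 12)
  }
  expect_equal(res$f_statistic, f_of(y), tolerance = 1e-12)
  perm <- vapply(1:2000, function(i) f_of(sample(y)), numeric(1))
  p_perm <- mean(perm >= res$f_statistic)
  expect_lt(abs(p_perm - res$p_value), 0.05)
})

test_that("ANOVA is shift-invariant and Tukey bands are order-symmetric", {
  set.seed(29)
  vals <- rnorm(15, 5)
  g <- rep(c("x", "y", "z"), each = 5)
  a <- one_way_anova_tukey(vals, g)
  b <- one_way_anova_tukey(vals + 123.4, g)
  expect_equal(a$f_statistic, b$f_statistic, tolerance = 1e-9)
  rev_order <- one_way_anova_tukey(rev(vals), rev(g))
  expect_equal(sort(a$tukey_pairs$p_adj), sort(rev_order$tukey_pairs$p_adj),
               tolerance = 1e-9)
})
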