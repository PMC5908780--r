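# Statistical layer: first-order, power, exponential and second-order
# least-squares fits with signed correlation + p-value, and one-way ANOVA
# with Tukey's HSD. Curvilinear families are linearized (log transforms)
# so coefficients are closed-form; correlation is reported in the
# linearized space, which is the only convention that can produce the
# negative R conventionally printed for decaying exponentials.

fit_result <- function(family, coefficients, correlation, p_value, n) {
  structure(list(family = family, coefficients = coefficients,
                 correlation = correlation, p_value = p_value, n = n),
            class = "fit_result")
}

# p-value of a Pearson correlation via the t transform, df = n - 2.
cor_p_value <- function(r, n) {
  if (abs(r) >= 1) return(0)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tstat), df = n - 2)
}

check_xy <- function(x, y, min_n) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length", call. = FALSE)
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < min_n) {
    stop("need at least ", min_n, " finite (x, y) pairs; got ",
         length(x), call. = FALSE)
  }
  list(x = x, y = y)
}

#' First-order (linear) least-squares fit
#'
#' Ordinary least squares `y = intercept + slope * x`, with the Pearson
#' correlation of (x, y) and its t-transform p-value.
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @return A `fit_result` with coefficients `slope`, `intercept`.
#' @export
fit_linear <- function(x, y) {
  d <- check_xy(x, y, 3L)
  if (stats::var(d$x) == 0) {
    stop("`x` is degenerate (zero variance)", call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, d$x), d$y)
  r <- if (stats::var(d$y) == 0) 0 else stats::cor(d$x, d$y)
  fit_result("linear",
             c(slope = unname(fit$coefficients[2L]),
               intercept = unname(fit$coefficients[1L])),
             r, cor_p_value(r, length(d$x)), length(d$x))
}

#' Power-law fit, y = a * x^b
#'
#' Least squares on (ln x, ln y); the exponent is the log-log slope and
#' the correlation is the Pearson r in log-log space.
#'
#' @param x,y Positive numeric vectors of equal length, n >= 3.
#' @return A `fit_result` with coefficients `amplitude` (a) and
#'   `exponent` (b).
#' @export
fit_power <- function(x, y) {
  d <- check_xy(x, y, 3L)
  if (any(d$x <= 0) || any(d$y <= 0)) {
    stop("power fit requires strictly positive x and y", call. = FALSE)
  }
  lx <- log(d$x); ly <- log(d$y)
  if (stats::var(lx) == 0) {
    stop("`x` is degenerate (zero variance on the log scale)",
         call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, lx), ly)
  r <- if (stats::var(ly) == 0) 0 else stats::cor(lx, ly)
  fit_result("power",
             c(amplitude = exp(unname(fit$coefficients[1L])),
               exponent = unname(fit$coefficients[2L])),
             r, cor_p_value(r, length(lx)), length(lx))
}

#' Exponential fit, y = Y0 * exp(-k * x)
#'
#' Least squares on (x, ln y). The reported correlation is the signed
#' Pearson r of (x, ln y): negative for decaying data. The Y-intercept
#' Y0 = exp(intercept) is the fit's x -> 0 extrapolation.
#'
#' @param x Numeric vector; `y` strictly positive; n >= 3.
#' @param y Numeric vector, positive.
#' @return A `fit_result` with coefficients `y_intercept` (Y0) and
#'   `rate` (k, positive for decay).
#' @export
fit_exponential <- function(x, y) {
  d <- check_xy(x, y, 3L)
  if (any(d$y <= 0)) {
    stop("exponential fit requires strictly positive y", call. = FALSE)
  }
  if (stats::var(d$x) == 0) {
    stop("`x` is degenerate (zero variance)", call. = FALSE)
  }
  ly <- log(d$y)
  fit <- stats::lm.fit(cbind(1, d$x), ly)
  r <- if (stats::var(ly) == 0) 0 else stats::cor(d$x, ly)
  fit_result("exponential",
             c(y_intercept = exp(unname(fit$coefficients[1L])),
               rate = -unname(fit$coefficients[2L])),
             r, cor_p_value(r, length(d$x)), length(d$x))
}

#' Second-order polynomial fit
#'
#' Degree-2 least squares `y = c0 + c1 x + c2 x^2`; the correlation is
#' the Pearson r between fitted and observed y.
#'
#' @param x,y Numeric vectors of equal length, n >= 4.
#' @return A `fit_result` with coefficients `quadratic`, `linear`,
#'   `constant`.
#' @export
fit_quadratic <- function(x, y) {
  d <- check_xy(x, y, 4L)
  X <- cbind(1, d$x, d$x^2)
  if (qr(X)$rank < 3L) {
    stop("degenerate design: x values do not support a quadratic fit",
         call. = FALSE)
  }
  fit <- stats::lm.fit(X, d$y)
  yhat <- X %*% fit$coefficients
  r <- if (stats::var(d$y) == 0 || stats::var(as.numeric(yhat)) == 0) {
    0
  } else {
    stats::cor(as.numeric(yhat), d$y)
  }
  fit_result("quadratic",
             c(quadratic = unname(fit$coefficients[3L]),
               linear = unname(fit$coefficients[2L]),
               constant = unname(fit$coefficients[1L])),
             r, cor_p_value(r, length(d$x)), length(d$x))
}

#' One-way ANOVA with Tukey's HSD
#'
#' Classical one-way analysis of variance followed by all pairwise
#' comparisons via the studentized-range distribution (Tukey's honestly
#' significant difference), with significance bands at 0.05 / 0.01 /
#' 0.001 as conventionally printed in figure legends.
#'
#' @param values Numeric vector of observations, or a named list of
#'   per-group numeric vectors (in which case `groups` is ignored).
#' @param groups Group labels aligned with `values`.
#' @return An object of class `anova_result`: `f_statistic`, `p_value`,
#'   `df` (between, within), `group_labels`, `group_means`, and
#'   `tukey_pairs`, a data.frame with one row per unordered pair
#'   (`group1`, `group2`, `diff`, `q`, `p_adj`, `band`).
#' @export
one_way_anova_tukey <- function(values, groups = NULL) {
  if (is.list(values)) {
    groups <- rep(names(values) %||% as.character(seq_along(values)),
                  lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  if (length(values) != length(groups)) {
    stop("`values` and `groups` must have equal length", call. = FALSE)
  }
  g <- factor(groups)
  k <- nlevels(g)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  ns <- tapply(values, g, length)
  if (any(ns < 2L)) {
    stop("every group needs at least 2 observations", call. = FALSE)
  }
  means <- tapply(values, g, mean)
  grand <- mean(values)
  n_tot <- length(values)
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((values - means[g])^2)
  df1 <- k - 1L
  df2 <- n_tot - k
  mse <- ssw / df2
  degenerate <- ssw == 0 && ssb == 0
  if (degenerate) {
    f_stat <- 0
    p <- 1
  } else if (ssw == 0) {
    f_stat <- Inf
    p <- 0
  } else {
    f_stat <- (ssb / df1) / mse
    p <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)
  }

  pairs <- utils::combn(levels(g), 2L)
  band_of <- function(p) {
    if (is.na(p) || p >= 0.05) "ns"
    else if (p >= 0.01) "<0.05"
    else if (p >= 0.001) "<0.01"
    else "<0.001"
  }
  tukey <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                      diff = NA_real_, q = NA_real_, p_adj = NA_real_,
                      band = NA_character_, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    diff <- means[[b]] - means[[a]]
    if (degenerate) {
      q <- 0; p_adj <- 1
    } else if (mse == 0) {
      q <- if (diff == 0) 0 else Inf
      p_adj <- if (diff == 0) 1 else 0
    } else {
      # Tukey-Kramer standard error; reduces to sqrt(MSE/n) when balanced
      se <- sqrt(mse / 2 * (1 / ns[[a]] + 1 / ns[[b]]))
      q <- abs(diff) / se
      p_adj <- stats::ptukey(q, nmeans = k, df = df2, lower.tail = FALSE)
    }
    tukey$diff[j] <- diff
    tukey$q[j] <- q
    tukey$p_adj[j] <- p_adj
    tukey$band[j] <- band_of(p_adj)
  }
  structure(
    list(f_statistic = f_stat, p_value = p, df = c(df1, df2),
         group_labels = levels(g), group_means = as.numeric(means),
         degenerate = degenerate, tukey_pairs = tukey),
    class = "anova_result")
}

#' @export
print.fit_result <- function(x, ...) {
  co <- paste(sprintf("%s = %.4g", names(x$coefficients), x$coefficients),
              collapse = ", ")
  cat(sprintf("%s fit (n = %d): %s; R = %.4f, p = %.3g\n",
              x$family, x$n, co, x$correlation, x$p_value))
  invisible(x)
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.3g%s\n",
              x$df[1L], x$df[2L], x$f_statistic, x$p_value,
              if (x$degenerate) " [degenerate: all observations equal]"
              else ""))
  cat("Tukey HSD pairs:\n")
  print(x$tukey_pairs, row.names = FALSE)
  invisible(x)
}
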