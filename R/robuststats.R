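#' Trimmed mean
#'
#' Mean after removing the `floor(trim * n)` smallest and largest values; the
#' package-wide default trimming level is 20%.
#'
#' @param x numeric vector.
#' @param trim trimming fraction in `[0, 0.5)`.
#' @return Trimmed mean.
#' @export
trimmed_mean <- function(x, trim = 0.2) {
  stopifnot(trim >= 0, trim < 0.5, length(x) >= 1)
  n <- length(x)
  g <- floor(trim * n)
  if (n - 2 * g < 1) stop("over-trimming: no values left after trimming")
  xs <- sort(x)
  mean(xs[(g + 1):(n - g)])
}

# winsorized variance at trimming level trim
.win_var <- function(x, trim = 0.2) {
  n <- length(x)
  g <- floor(trim * n)
  xs <- sort(x)
  xw <- pmin(pmax(xs, xs[g + 1]), xs[n - g])
  stats::var(xw)
}

# Yuen two-sample statistic on trimmed means with winsorized variances
.yuen_stat <- function(x, y, trim) {
  nx <- length(x); ny <- length(y)
  hx <- nx - 2 * floor(trim * nx)
  hy <- ny - 2 * floor(trim * ny)
  dx <- (nx - 1) * .win_var(x, trim) / (hx * (hx - 1))
  dy <- (ny - 1) * .win_var(y, trim) / (hy * (hy - 1))
  se <- sqrt(dx + dy)
  list(stat = (trimmed_mean(x, trim) - trimmed_mean(y, trim)) / se, se = se)
}

.new_robust_htest <- function(method, statistic, p_value, estimate, ci,
                              trim, n_boot, seed, extra = NULL) {
  structure(
    c(list(method = method, statistic = statistic, p_value = p_value,
           estimate = estimate, conf_int = ci, trim = trim,
           n_boot = n_boot, seed = seed), extra),
    class = "robust_htest")
}

#' @export
print.robust_htest <- function(x, ...) {
  cat(sprintf("%s\n  statistic = %.4g, p = %.4g\n", x$method, x$statistic,
              x$p_value))
  if (!is.null(x$estimate) && is.finite(x$estimate)) {
    cat(sprintf("  trimmed-mean difference = %.4g [%.4g, %.4g] (trim %.0f%%, %d bootstrap)\n",
                x$estimate, x$conf_int[1], x$conf_int[2], 100 * x$trim, x$n_boot))
  }
  invisible(x)
}

# sort every column with one radix pass (much faster than apply/sort)
.col_sort <- function(m) {
  matrix(m[order(col(m), m, method = "radix")], nrow(m), ncol(m))
}

# trimmed means and winsorized variances for every column of a matrix
# (columns are bootstrap resamples); vectorized via column sort
.col_trim_stats <- function(m, trim) {
  n <- nrow(m)
  g <- floor(trim * n)
  ms <- .col_sort(m)
  tm <- colMeans(ms[(g + 1):(n - g), , drop = FALSE])
  lo <- ms[g + 1, ]; hi <- ms[n - g, ]
  w <- pmin(pmax(ms, rep(lo, each = n)), rep(hi, each = n))
  wv <- (colSums(w^2) - n * colMeans(w)^2) / (n - 1)
  list(tm = tm, wv = wv)
}

.yuen_stat_cols <- function(mx, my, trim) {
  nx <- nrow(mx); ny <- nrow(my)
  hx <- nx - 2 * floor(trim * nx); hy <- ny - 2 * floor(trim * ny)
  sx <- .col_trim_stats(mx, trim); sy <- .col_trim_stats(my, trim)
  dx <- (nx - 1) * sx$wv / (hx * (hx - 1))
  dy <- (ny - 1) * sy$wv / (hy * (hy - 1))
  (sx$tm - sy$tm) / sqrt(dx + dy)
}

#' Yuen's bootstrap test for two independent groups
#'
#' Yuen's statistic on 20%-trimmed means with winsorized variances; the null
#' distribution is obtained by resampling each group after centering it at
#' its own trimmed mean (bootstrap-t). The two-sided p-value is the smoothed
#' proportion of null statistics at least as extreme as the observed one, and
#' the confidence interval for the trimmed-mean difference is the percentile
#' interval of bootstrap difference estimates.
#'
#' @param x,y numeric vectors (both groups must keep at least 2 values after
#'   trimming).
#' @param trim trimming fraction (default 0.2).
#' @param n_boot bootstrap repetitions (default 5000).
#' @param seed integer seed; all resampling is reproducible.
#' @param conf_level CI level.
#' @return A `robust_htest` with `statistic`, `p_value`, `estimate`
#'   (trimmed-mean difference), `conf_int`, `trim`, `n_boot`, `seed`.
#' @export
yuen_boot <- function(x, y, trim = 0.2, n_boot = 5000, seed = 1,
                      conf_level = 0.95) {
  stopifnot(length(x) - 2 * floor(trim * length(x)) >= 2,
            length(y) - 2 * floor(trim * length(y)) >= 2)
  est <- trimmed_mean(x, trim) - trimmed_mean(y, trim)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    p <- if (est == 0) 1 else 0
    return(.new_robust_htest("Yuen bootstrap test (degenerate: constant groups)",
                             0, p, est, c(est, est), trim, 0L, seed))
  }
  obs <- .yuen_stat(x, y, trim)
  set.seed(seed)
  xc <- x - trimmed_mean(x, trim)
  yc <- y - trimmed_mean(y, trim)
  mx <- matrix(sample(xc, length(x) * n_boot, replace = TRUE), nrow = length(x))
  my <- matrix(sample(yc, length(y) * n_boot, replace = TRUE), nrow = length(y))
  tstar <- .yuen_stat_cols(mx, my, trim)
  tstar <- tstar[is.finite(tstar)]
  p <- (sum(abs(tstar) >= abs(obs$stat)) + 1) / (length(tstar) + 1)
  # percentile CI from non-centered resamples of the difference
  mx2 <- matrix(sample(x, length(x) * n_boot, replace = TRUE), nrow = length(x))
  my2 <- matrix(sample(y, length(y) * n_boot, replace = TRUE), nrow = length(y))
  dstar <- .col_trim_stats(mx2, trim)$tm - .col_trim_stats(my2, trim)$tm
  a <- (1 - conf_level) / 2
  ci <- unname(stats::quantile(dstar, c(a, 1 - a)))
  .new_robust_htest("Yuen bootstrap test on trimmed means", obs$stat, p, est,
                    ci, trim, as.integer(n_boot), seed)
}

#' Yuen's paired robust test
#'
#' Applies the trimmed-mean machinery to paired difference scores `x - y`:
#' the statistic is the trimmed mean of the differences over its winsorized
#' standard error, with a bootstrap-t null from resampled centered
#' differences.
#'
#' @inheritParams yuen_boot
#' @return A `robust_htest`.
#' @export
yuen_paired <- function(x, y, trim = 0.2, n_boot = 5000, seed = 1,
                        conf_level = 0.95) {
  if (length(x) != length(y)) stop("paired test requires equal-length vectors")
  d <- x - y
  n <- length(d)
  g <- floor(trim * n)
  h <- n - 2 * g
  stopifnot(h >= 2)
  est <- trimmed_mean(d, trim)
  if (stats::var(d) == 0) {
    p <- if (est == 0) 1 else 0
    return(.new_robust_htest("Yuen paired robust test (degenerate: constant differences)",
                             0, p, est, c(est, est), trim, 0L, seed))
  }
  se <- sqrt((n - 1) * .win_var(d, trim) / (h * (h - 1)))
  stat <- est / se
  set.seed(seed)
  dc <- d - est
  md <- matrix(sample(dc, n * n_boot, replace = TRUE), nrow = n)
  s <- .col_trim_stats(md, trim)
  sestar <- sqrt((n - 1) * s$wv / (h * (h - 1)))
  tstar <- s$tm / sestar
  tstar <- tstar[is.finite(tstar)]
  p <- (sum(abs(tstar) >= abs(stat)) + 1) / (length(tstar) + 1)
  md2 <- matrix(sample(d, n * n_boot, replace = TRUE), nrow = n)
  dstar <- .col_trim_stats(md2, trim)$tm
  a <- (1 - conf_level) / 2
  ci <- unname(stats::quantile(dstar, c(a, 1 - a)))
  .new_robust_htest("Yuen paired robust test on trimmed differences", stat, p,
                    est, ci, trim, as.integer(n_boot), seed)
}

# heteroscedastic trimmed-means one-way statistic (Welch-type)
.t1way_stat <- function(groups, trim) {
  J <- length(groups)
  h <- vapply(groups, function(g) length(g) - 2 * floor(trim * length(g)), numeric(1))
  d <- mapply(function(g, hj) (length(g) - 1) * .win_var(g, trim) / (hj * (hj - 1)),
              groups, h)
  w <- 1 / d
  tm <- vapply(groups, trimmed_mean, numeric(1), trim = trim)
  U <- sum(w)
  xbar <- sum(w * tm) / U
  A <- sum(w * (tm - xbar)^2) / (J - 1)
  B <- 2 * (J - 2) / (J^2 - 1) * sum((1 - w / U)^2 / (h - 1))
  A / (1 + B)
}

#' Bootstrapped heteroscedastic one-way ANOVA for trimmed means
#'
#' Welch-type one-way statistic on trimmed means with winsorized variances;
#' the null distribution is obtained by resampling each group after centering
#' it at its own trimmed mean. Optional pairwise trimmed-mean contrasts with
#' percentile-bootstrap CIs (no additional multiplicity correction; the
#' choice of correction is left to the caller).
#'
#' @param groups list of numeric vectors (>= 2 groups).
#' @inheritParams yuen_boot
#' @param posthoc also compute pairwise contrasts.
#' @return A `robust_htest`; when `posthoc = TRUE` the element `posthoc` is a
#'   tibble of pairwise trimmed-mean differences with percentile CIs.
#' @export
t1way_boot <- function(groups, trim = 0.2, n_boot = 5000, seed = 1,
                       posthoc = FALSE, conf_level = 0.95) {
  if (length(groups) < 2) stop("at least 2 groups are required")
  stopifnot(all(vapply(groups, function(g)
    length(g) - 2 * floor(trim * length(g)), numeric(1)) >= 2))
  obs <- .t1way_stat(groups, trim)
  set.seed(seed)
  cg <- lapply(groups, function(g) g - trimmed_mean(g, trim))
  boots <- lapply(cg, function(g)
    matrix(sample(g, length(g) * n_boot, replace = TRUE), nrow = length(g)))
  stats_fun <- function(b) {
    J <- length(boots)
    h <- vapply(groups, function(g) length(g) - 2 * floor(trim * length(g)), numeric(1))
    s <- lapply(boots, .col_trim_stats, trim = trim)
    n <- vapply(groups, length, numeric(1))
    d <- mapply(function(sj, nj, hj) (nj - 1) * sj$wv / (hj * (hj - 1)),
                s, n, h, SIMPLIFY = FALSE)
    w <- lapply(d, function(x) 1 / x)
    W <- Reduce(`+`, w)
    tmw <- Reduce(`+`, mapply(function(wj, sj) wj * sj$tm, w, s, SIMPLIFY = FALSE))
    xbar <- tmw / W
    A <- Reduce(`+`, mapply(function(wj, sj) wj * (sj$tm - xbar)^2, w, s,
                            SIMPLIFY = FALSE)) / (J - 1)
    B <- Reduce(`+`, mapply(function(wj, hj) (1 - wj / W)^2 / (hj - 1), w, h,
                            SIMPLIFY = FALSE)) * 2 * (J - 2) / (J^2 - 1)
    A / (1 + B)
  }
  fstar <- stats_fun(boots)
  fstar <- fstar[is.finite(fstar)]
  p <- (sum(fstar >= obs) + 1) / (length(fstar) + 1)
  res <- .new_robust_htest(
    "Bootstrapped heteroscedastic one-way ANOVA for trimmed means",
    obs, p, NA_real_, c(NA_real_, NA_real_), trim, as.integer(n_boot), seed)
  if (posthoc) {
    J <- length(groups)
    pairs <- utils::combn(J, 2)
    ph <- purrr::map_dfr(seq_len(ncol(pairs)), function(c0) {
      i <- pairs[1, c0]; j <- pairs[2, c0]
      mi <- matrix(sample(groups[[i]], length(groups[[i]]) * n_boot, TRUE),
                   nrow = length(groups[[i]]))
      mj <- matrix(sample(groups[[j]], length(groups[[j]]) * n_boot, TRUE),
                   nrow = length(groups[[j]]))
      dstar <- .col_trim_stats(mi, trim)$tm - .col_trim_stats(mj, trim)$tm
      a <- (1 - conf_level) / 2
      q <- stats::quantile(dstar, c(a, 1 - a))
      tibble::tibble(
        group_1 = i, group_2 = j,
        difference = trimmed_mean(groups[[i]], trim) - trimmed_mean(groups[[j]], trim),
        ci_lo = q[[1]], ci_hi = q[[2]])
    })
    res$posthoc <- ph
  }
  res
}

#' Discrimination ratio
#'
#' `(t_novel - t_other) / (t_novel + t_other)` for interaction times in an
#' object-recognition task; the same formula serves single-interaction-time
#' ratios. Bounded in `[-1, 1]`; positive values indicate preference for the
#' novel (or less recent) object.
#'
#' @param t_novel,t_other interaction times in seconds (non-negative;
#'   vectorized).
#' @return Discrimination ratio; `NA` (flagged undefined) when the total
#'   interaction time is zero.
#' @export
discrimination_ratio <- function(t_novel, t_other) {
  stopifnot(all(t_novel >= 0), all(t_other >= 0))
  tot <- t_novel + t_other
  ifelse(tot == 0, NA_real_, (t_novel - t_other) / tot)
}
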