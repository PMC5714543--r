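#' Paired two-sided Wilcoxon signed-rank test
#'
#' Matched-pairs signed-rank test as used for paired cohort comparisons.
#' Zero differences are dropped by default (classic Wilcoxon; the Pratt
#' variant, which ranks zeros before dropping them, is available with
#' `zero_method = "pratt"`). For n <= `exact_max` remaining pairs the
#' two-sided p-value is exact, computed by enumerating the conditional
#' (given the observed tied ranks) null distribution of the signed-rank
#' statistic over all 2^n sign assignments; above that, a normal
#' approximation with tie and continuity corrections is used.
#'
#' @param a,b paired numeric vectors, or `a` alone interpreted as
#'   differences when `b` is NULL.
#' @param zero_method `"wilcox"` (drop zeros) or `"pratt"`.
#' @param exact_max largest n for which the exact enumeration is used
#'   (default 20; a 14-patient cohort is always exact).
#' @return list of class `paired_test` with `statistic` (W, the sum of the
#'   ranks of positive differences), `p_value`, `n_used`, `n_zero` and
#'   `method`. All differences zero gives p = 1 with a warning.
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3), c(0, 0, 0))$p_value # exact 0.25
#' @export
wilcoxon_signed_rank <- function(a, b = NULL, zero_method = c("wilcox", "pratt"),
                                 exact_max = 20L) {
  zero_method <- match.arg(zero_method)
  d <- if (is.null(b)) as.numeric(a) else as.numeric(a) - as.numeric(b)
  if (length(d) < 1L) stop("need at least one pair")
  if (any(!is.finite(d))) stop("differences must be finite")
  n_zero <- sum(d == 0)
  if (all(d == 0)) {
    warning("all paired differences are zero")
    return(structure(list(statistic = 0, p_value = 1, n_used = 0L,
                          n_zero = n_zero, method = "degenerate"),
                     class = "paired_test"))
  }
  if (zero_method == "wilcox") {
    d <- d[d != 0]
    r <- rank(abs(d))
  } else {
    r <- rank(abs(d))
    r <- r[d != 0]
    d <- d[d != 0]
  }
  n <- length(d)
  w <- sum(r[d > 0])
  if (n <= exact_max) {
    # conditional exact distribution: counts over achievable values of 2W
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    cnt <- numeric(total + 1L) # index i holds count of 2W = i - 1
    cnt[1] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), cnt[seq_len(total + 1L - ri)])
      cnt <- cnt + shifted
    }
    w2 <- as.integer(round(2 * w))
    p_le <- sum(cnt[seq_len(w2 + 1L)]) / 2^n
    p_ge <- sum(cnt[(w2 + 1L):(total + 1L)]) / 2^n
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    cc <- sign(w - mu) * 0.5
    z <- (w - mu - cc) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  structure(list(statistic = w, p_value = p, n_used = n, n_zero = n_zero,
                 method = method),
            class = "paired_test")
}

#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank (%s): W = %g, n = %d (%d zero dropped), p = %.4g\n",
              x$method, x$statistic, x$n_used, x$n_zero, x$p_value))
  invisible(x)
}

#' Spearman rank correlation
#'
#' rho is the Pearson correlation of the average ranks; the two-sided
#' p-value uses the t approximation with n - 2 degrees of freedom. An exact
#' permutation p-value is available for small samples with
#' `exact = TRUE` (n <= 10).
#'
#' @param x,y numeric vectors of equal length n >= 3.
#' @param exact use exact permutation p (n <= 10 only).
#' @return list of class `paired_test` with `statistic` (rho), `p_value`,
#'   `n_used` and `method`.
#' @export
spearman_rank <- function(x, y, exact = FALSE) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3L) stop("need at least 3 observations")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("constant input: rho undefined")
  rho <- stats::cor(rx, ry)
  if (exact) {
    if (n > 10L) stop("exact permutation p only for n <= 10")
    perms <- permutations_of(n)
    obs <- abs(rho)
    vals <- apply(perms, 1, function(p) abs(stats::cor(rx, ry[p])))
    p <- mean(vals >= obs - 1e-12)
    method <- "exact permutation"
  } else if (abs(rho) >= 1) {
    p <- 0
    method <- "t approximation"
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "t approximation"
  }
  structure(list(statistic = rho, p_value = p, n_used = n, n_zero = 0L,
                 method = method),
            class = "paired_test")
}

# all n! permutations of 1:n, one per row (insert n at every position)
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- NULL
  for (i in seq_len(n)) {
    block <- cbind(sub[, seq_len(i - 1L), drop = FALSE],
                   n,
                   if (i <= n - 1L) sub[, i:(n - 1L), drop = FALSE])
    out <- rbind(out, block)
  }
  colnames(out) <- NULL
  out
}

#' Group summaries of a cohort metric
#'
#' Sample mean, SD (n - 1 denominator), min and max per group. A
#' single-value group has no sample SD; it is reported as 0 with
#' `sd_defined = FALSE`. Rounding (integers for MU, one decimal for minutes
#' and cc) is left to the presentation layer.
#'
#' @param values numeric vector.
#' @param groups group labels (same length); default one group `"all"`.
#' @return `data.frame` with one row per group: group, n, mean, sd,
#'   sd_defined, min, max.
#' @export
summarize_cohort <- function(values, groups = NULL) {
  values <- as.numeric(values)
  if (is.null(groups)) groups <- rep("all", length(values))
  stopifnot(length(groups) == length(values))
  keep <- !is.na(values)
  if (any(!keep)) warning("dropping ", sum(!keep), " missing values")
  values <- values[keep]; groups <- as.character(groups)[keep]
  out <- do.call(rbind, lapply(split(values, groups), function(v) {
    data.frame(n = length(v), mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else 0,
               sd_defined = length(v) > 1L,
               min = min(v), max = max(v))
  }))
  out <- cbind(group = rownames(out), out)
  rownames(out) <- NULL
  out
}

#' Correlation of tumour motion with technique differences
#'
#' Spearman rank correlation between the 3D motion amplitude and the
#' per-patient (tracking minus fixed) difference of a normal-tissue shell
#' metric, one test per metric column.
#'
#' @param motion numeric 3D motion per patient (mm).
#' @param tracking,fixed `data.frame`s of per-patient shell metrics (same
#'   columns, e.g. `v80_cc`, `v50_cc`, `v30_cc`, `v10_cc`), rows aligned
#'   with `motion`.
#' @param metrics columns to test (default the four shells).
#' @return `data.frame` with metric, rho, p_value, n.
#' @export
motion_vs_difference_correlation <- function(motion, tracking, fixed,
                                             metrics = c("v80_cc", "v50_cc",
                                                         "v30_cc", "v10_cc")) {
  stopifnot(nrow(tracking) == length(motion), nrow(fixed) == length(motion))
  if (length(motion) < 3L) stop("need at least 3 patients")
  rows <- lapply(metrics, function(m) {
    res <- spearman_rank(motion, tracking[[m]] - fixed[[m]])
    data.frame(metric = m, rho = res$statistic, p_value = res$p_value,
               n = res$n_used, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
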