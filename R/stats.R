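#' McNemar's test for paired proportions
#'
#' Compares two paired binary classifications (e.g. per-case detection under
#' white-light vs narrow-band imaging) through the discordant pair counts
#' `b` and `c`. The exact form is the two-sided binomial sign test:
#' `p = min(1, 2 * P(X >= max(b, c)))` with `X ~ Binomial(b + c, 1/2)`. The
#' asymptotic form is the continuity-corrected chi-square on 1 df,
#' `(|b - c| - 1)^2 / (b + c)`. With `method = "auto"` the exact form is
#' used for `b + c < 25`, the asymptotic form otherwise.
#'
#' @param b,c Discordant counts (non-negative integers): pairs positive under
#'   the first condition only, and under the second only.
#' @param method `"auto"`, `"exact"` or `"asymptotic"`.
#' @return List with `b`, `c`, `statistic` (`NA` for the exact form),
#'   `p_value`, `method`, and `degenerate` (`TRUE` when `b = c = 0`, in
#'   which case `p = 1` by convention).
#' @export
mcnemar_test <- function(b, c, method = c("auto", "exact", "asymptotic")) {
  method <- match.arg(method)
  stopifnot(length(b) == 1L, length(c) == 1L, b >= 0, c >= 0)
  b <- as.integer(b); c <- as.integer(c)
  n <- b + c
  if (method == "auto") method <- if (n < 25L) "exact" else "asymptotic"
  if (n == 0L) {
    return(list(b = b, c = c, statistic = NA_real_, p_value = 1,
                method = method, degenerate = TRUE))
  }
  if (method == "exact") {
    k <- max(b, c)
    p <- min(1, 2 * stats::pbinom(k - 1L, n, 0.5, lower.tail = FALSE))
    list(b = b, c = c, statistic = NA_real_, p_value = p, method = "exact",
         degenerate = FALSE)
  } else {
    stat <- (abs(b - c) - 1)^2 / n
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    list(b = b, c = c, statistic = stat, p_value = p,
         method = "asymptotic", degenerate = FALSE)
  }
}

#' Mann-Whitney U test (two-sample rank-sum)
#'
#' U is computed with midrank tie handling:
#' `U = R_x - m(m+1)/2` where `R_x` is the midrank sum of the first sample,
#' so `U(x, y) + U(y, x) = m * n` always. The exact two-sided p-value is
#' found by complete enumeration of all rank assignments when the combined
#' sample size is at most 12 and there are no ties (two-sided p = probability
#' of a U at least as far from `mn/2` as observed); otherwise the normal
#' approximation with tie correction and a 0.5 continuity correction is
#' used. When every value in both samples is identical the p-value is 1 by
#' convention.
#'
#' @param x,y Numeric samples (non-empty).
#' @param method `"auto"`, `"exact"` or `"normal"`.
#' @return List with `U` (statistic of `x` relative to `y`), `p_value`,
#'   `method`.
#' @export
mann_whitney_u <- function(x, y, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  m <- length(x); n <- length(y); N <- m + n
  combined <- c(x, y)
  r <- rank(combined)  # midranks
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  has_ties <- anyDuplicated(combined) > 0L
  if (length(unique(combined)) == 1L) {
    return(list(U = U, p_value = 1, method = "degenerate"))
  }
  if (method == "auto") {
    method <- if (N <= 12L && !has_ties) "exact" else "normal"
  }
  if (method == "exact") {
    if (has_ties) {
      stop("exact enumeration requires tie-free samples", call. = FALSE)
    }
    sets <- utils::combn(N, m)
    ranks <- seq_len(N)
    us <- apply(sets, 2L, function(ix) sum(ranks[ix])) - m * (m + 1) / 2
    dev <- abs(U - m * n / 2)
    p <- mean(abs(us - m * n / 2) >= dev - 1e-9)
    list(U = U, p_value = p, method = "exact")
  } else {
    mu <- m * n / 2
    tie_tab <- table(combined)
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma2 <- m * n / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) return(list(U = U, p_value = 1, method = "normal"))
    z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
    z <- max(z, 0)
    p <- 2 * stats::pnorm(z, lower.tail = FALSE)
    list(U = U, p_value = min(1, p), method = "normal")
  }
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Provided as the statistically conventional alternative for paired reader
#' sensitivities; the default reader comparison in this package remains the
#' two-sample Mann-Whitney test ([mann_whitney_u()]), which is how the
#' assisted/unassisted comparison is defined for this study design.
#'
#' @param x,y Paired numeric samples of equal length.
#' @return The [stats::wilcox.test()] result (paired, two-sided).
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
}
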