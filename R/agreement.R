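#' Method-comparison statistics for paired gait measurements
#'
#' A small harness for validating one measurement system against another
#' (e.g. pipeline estimates against ground truth, or against an
#' instrumented walkway): rank and product-moment correlation, percent
#' error, and Bland-Altman limits of agreement.
#'
#' @name agreement
NULL

.check_pairs <- function(reference, test, min_n = 2) {
  if (length(reference) != length(test)) {
    stop(gait_error("gait_validation_error",
                    "reference and test vectors must have equal length"))
  }
  keep <- is.finite(reference) & is.finite(test)
  if (sum(keep) < min_n) {
    stop(gait_error("gait_validation_error",
                    sprintf("need at least %d complete pairs", min_n)))
  }
  list(reference = reference[keep], test = test[keep], n = sum(keep))
}

# all permutations of 1..n (n <= 9), as an n! x n matrix
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    block <- nrow(sub)
    out[row:(row + block - 1L), 1L] <- k
    out[row:(row + block - 1L), -1L] <- matrix(rest[sub], block, n - 1L)
    row <- row + block
  }
  out
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Rank correlation with average ranks for ties. For `n <= 9` the
#' two-sided p-value is computed by exhaustive enumeration of all `n!`
#' rank permutations (the exact null distribution); for larger samples
#' the t approximation with `n - 2` degrees of freedom is used.
#'
#' @param reference,test Paired numeric vectors.
#' @return List with `rho`, `p`, `n`, and `method` (`"exact"` or
#'   `"t-approximation"`). A constant vector makes the correlation
#'   undefined: `rho` is `NA` and the result is flagged
#'   (`undefined = TRUE`).
#' @export
#' @examples
#' spearman_rho(c(1, 2, 3, 4), c(2, 4, 6, 8))$rho  # 1
spearman_rho <- function(reference, test) {
  p <- .check_pairs(reference, test, min_n = 2)
  rx <- rank(p$reference); ry <- rank(p$test)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = p$n,
                method = "undefined", undefined = TRUE))
  }
  rho <- stats::cor(rx, ry)
  n <- p$n
  if (n < 3) {
    return(list(rho = rho, p = NA_real_, n = n, method = "n<3",
                undefined = FALSE))
  }
  if (n <= 9) {
    perms <- .permutations(n)
    rxc <- rx - mean(rx)
    ryc <- ry - mean(ry)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    stat <- abs(matrix(ryc[perms], nrow(perms), n) %*% rxc) / denom
    pval <- mean(stat >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    pval <- 2 * stats::pt(-abs(tt), n - 2)
    method <- "t-approximation"
  }
  list(rho = rho, p = pval, n = n, method = method, undefined = FALSE)
}

#' Pearson product-moment correlation
#'
#' @inheritParams spearman_rho
#' @return List with `r`, `p` (t distribution, `n - 2` df), `n`; zero
#'   variance in either vector flags the result undefined.
#' @export
pearson_r <- function(reference, test) {
  p <- .check_pairs(reference, test, min_n = 2)
  if (stats::sd(p$reference) == 0 || stats::sd(p$test) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = p$n, undefined = TRUE))
  }
  r <- stats::cor(p$reference, p$test)
  n <- p$n
  pval <- if (n >= 3 && abs(r) < 1) {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tt), n - 2)
  } else if (n >= 3) {
    0
  } else {
    NA_real_
  }
  list(r = r, p = pval, n = n, undefined = FALSE)
}

#' Percent error of paired measurements
#'
#' Relative absolute differences `|test - reference| / reference * 100`
#' per pair, with their maximum and mean: the bound-style agreement
#' summary ("within x percent of the reference system"). Pairs with a
#' zero reference are excluded with a warning.
#'
#' @inheritParams spearman_rho
#' @return List with `per_pair` (percent), `max`, `mean`, `n`.
#' @export
percent_variance <- function(reference, test) {
  p <- .check_pairs(reference, test, min_n = 1)
  zero <- p$reference == 0
  if (any(zero)) {
    warning(gait_warning("gait_undefined_metric",
                         sprintf("%d pair(s) with zero reference excluded",
                                 sum(zero))))
  }
  ref <- p$reference[!zero]; tst <- p$test[!zero]
  pe <- abs(tst - ref) / abs(ref) * 100
  list(per_pair = pe, max = if (length(pe)) max(pe) else NA_real_,
       mean = if (length(pe)) mean(pe) else NA_real_, n = length(pe))
}

#' Bland-Altman limits of agreement
#'
#' Mean difference (bias) of `test - reference` and the 95% limits of
#' agreement `bias +/- 1.96 sd(differences)`.
#'
#' @inheritParams spearman_rho
#' @return List with `bias`, `lower`, `upper`, `sd`, `n`.
#' @export
bland_altman <- function(reference, test) {
  p <- .check_pairs(reference, test, min_n = 2)
  d <- p$test - p$reference
  s <- stats::sd(d)
  list(bias = mean(d), lower = mean(d) - 1.96 * s,
       upper = mean(d) + 1.96 * s, sd = s, n = p$n)
}
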