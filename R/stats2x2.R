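#' Fold change between annotation proportions
#'
#' The enrichment weight used throughout the scoring system:
#' `FC = annotated_pos * total_bg / (annotated_bg * total_pos)`,
#' i.e. the ratio of the positive-set annotation proportion to the
#' background-set annotation proportion. A zero annotated background count
#' yields `Inf` (flagged via the `"undefined"` attribute) rather than an
#' error, so an all-positive feature is visible instead of fatal.
#'
#' @param annotated_pos,total_pos annotated and total counts in the
#'   positive group
#' @param annotated_bg,total_bg annotated and total counts in the
#'   background group
#' @return fold change (vectorised); `Inf` where `annotated_bg == 0`
#' @export
fold_change <- function(annotated_pos, total_pos, annotated_bg, total_bg) {
  if (any(c(annotated_pos, total_pos, annotated_bg, total_bg) < 0))
    stop("counts must be non-negative")
  if (any(total_pos <= 0) || any(total_bg <= 0))
    stop("total counts must be positive")
  fc <- (annotated_pos * total_bg) / (annotated_bg * total_pos)
  fc[annotated_bg == 0 & annotated_pos > 0] <- Inf
  fc[annotated_bg == 0 & annotated_pos == 0] <- NaN
  if (any(!is.finite(fc))) attr(fc, "undefined") <- which(!is.finite(fc))
  fc
}

# Vectorised Pearson chi-square (no continuity correction) on 2x2 counts.
# Returns list(statistic, p). Zero margins give statistic 0, p 1.
.chi2_vec <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  degenerate <- r1 == 0 | r2 == 0 | c1 == 0 | c2 == 0
  stat <- ifelse(degenerate, 0, n * (a * d - b * c)^2 / (r1 * r2 * c1 * c2))
  p <- ifelse(degenerate, 1, stats::pchisq(stat, df = 1, lower.tail = FALSE))
  list(statistic = stat, p = p)
}

# Two-sided Fisher exact p for one 2x2 table by the point-probability rule:
# sum hypergeometric point masses not exceeding the observed one (with the
# customary 1 + 1e-7 relative tolerance for ties).
.fisher_one <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || b + d == 0) return(1)
  lo <- max(0L, k - n); hi <- min(k, m)
  x <- lo:hi
  dens <- stats::dhyper(x, m, n, k)
  min(1, sum(dens[dens <= dens[a - lo + 1L] * (1 + 1e-7)]))
}

.fisher_vec <- function(a, b, c, d) {
  mapply(.fisher_one, a, b, c, d, USE.NAMES = FALSE)
}

# Expected cell counts under independence for the auto-fallback rule.
.min_expected <- function(a, b, c, d) {
  n <- a + b + c + d
  if (n == 0) return(0)
  r <- c(a + b, c + d); k <- c(a + c, b + d)
  min(outer(r, k) / n)
}

#' Exact / chi-square association test on a 2x2 contingency table
#'
#' The table is laid out as annotated/unannotated counts of group 1 (rows
#' `a`, `b`) versus group 2 (rows `c`, `d`). `method = "chi2"` computes the
#' Pearson statistic without continuity correction and falls back to the
#' exact test when any expected cell is below 5 (the `method` field of the
#' result records what was actually used). `method = "fisher"` computes the
#' two-sided exact p by summing hypergeometric point probabilities no
#' larger than the observed table's. Any zero margin short-circuits to a
#' degenerate result (statistic 0, p 1).
#'
#' @param a,b,c,d non-negative cell counts (annotated-group1,
#'   unannotated-group1, annotated-group2, unannotated-group2)
#' @param method `"chi2"` or `"fisher"`
#' @param with_fc also compute [fold_change()] of group 1 vs group 2
#' @return object of class `funsnp_test`: list with `statistic`,
#'   `p_value`, `method`, `degenerate`, and optionally `fold_change`
#' @export
association_test_2x2 <- function(a, b, c, d, method = c("chi2", "fisher"),
                                 with_fc = FALSE) {
  method <- match.arg(method)
  if (any(c(a, b, c, d) < 0)) stop("counts must be non-negative")
  degenerate <- (a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0
  if (degenerate) {
    res <- list(statistic = 0, p_value = 1, method = method, degenerate = TRUE)
  } else if (method == "chi2" && .min_expected(a, b, c, d) >= 5) {
    cs <- .chi2_vec(a, b, c, d)
    res <- list(statistic = cs$statistic, p_value = cs$p,
                method = "chi2", degenerate = FALSE)
  } else {
    res <- list(statistic = NA_real_, p_value = .fisher_one(a, b, c, d),
                method = "fisher", degenerate = FALSE)
  }
  if (with_fc && (a + b) > 0 && (c + d) > 0)
    res$fold_change <- as.numeric(fold_change(a, a + b, c, c + d))
  structure(res, class = "funsnp_test")
}

#' @export
print.funsnp_test <- function(x, ...) {
  cat(sprintf("2x2 association test (%s%s): p = %.4g",
              x$method, if (x$degenerate) ", degenerate margin" else "",
              x$p_value))
  if (!is.null(x$fold_change)) cat(sprintf(", FC = %.3g", x$fold_change))
  cat("\n")
  invisible(x)
}

#' Multiple-testing adjustment
#'
#' Thin wrapper over [stats::p.adjust()] fixing the two procedures the
#' pipeline uses: Bonferroni (`min(1, p*m)`) and Benjamini-Hochberg
#' step-up. Output order matches input order.
#'
#' @param p raw p-values in `[0, 1]`
#' @param method `"bonferroni"` or `"bh"`
#' @return adjusted p-values, same length and order as `p`
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  if (length(p) == 0L) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = if (method == "bh") "BH" else "bonferroni")
}
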