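#' Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test conditioning on the table margins. The odds
#' ratio is the sample odds ratio `(a*d)/(b*c)` with `Inf`/`0` sentinels on
#' zero cells (`NaN` when both products are zero). `side = "right"` tests
#' for enrichment of cell `a` (upper tail), `"left"` the lower tail, and
#' `"two"` sums the probabilities of all tables no more probable than the
#' observed one.
#'
#' @param a,b,c,d non-negative integer cell counts, rows =
#'   condition 1/condition 2, columns = success/failure; alternatively `a`
#'   may be a 2x2 matrix.
#' @param side `"left"`, `"right"` or `"two"`.
#' @return one-row tibble `a`, `b`, `c`, `d`, `odds_ratio`, `p_value`,
#'   `side`.
#' @export
fisher_exact <- function(a, b = NULL, c = NULL, d = NULL,
                         side = c("two", "right", "left")) {
  side <- match.arg(side)
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == 2))
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    abort("cell counts must be non-negative integers")
  }
  orr <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else if (a * d == 0) 0 else (a * d) / (b * c)

  ## a ~ Hypergeometric(m = a + c successes, n = b + d failures,
  ##                    k = a + b draws)
  m <- a + c; n <- b + d; k <- a + b
  if (m == 0 || n == 0 || k == 0 || c + d == 0) {
    ## degenerate margin: only one table possible
    p <- 1
  } else {
    support <- max(0, k - n):min(k, m)
    probs <- dhyper(support, m, n, k)
    p <- switch(side,
                right = sum(probs[support >= a]),
                left = sum(probs[support <= a]),
                two = {
                  obs <- dhyper(a, m, n, k)
                  sum(probs[probs <= obs * (1 + 1e-7)])
                })
    p <- min(p, 1)
  }
  tibble::new_tibble(list(a = a, b = b, c = c, d = d, odds_ratio = orr,
                          p_value = p, side = side), nrow = 1L)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement; the adjusted
#' values are returned in input order.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return adjusted values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    abort("p-values must be in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Combine p-values with Fisher's method
#'
#' The statistic `-2 * sum(log(p))` follows a chi-square distribution with
#' `2m` degrees of freedom under the null; the survival probability is
#' returned. Zero p-values are clipped to the smallest positive
#' representable value with a warning.
#'
#' @param pvalues numeric vector of p-values in `(0, 1]`.
#' @return combined p-value (scalar).
#' @export
fisher_combine <- function(pvalues) {
  pvalues <- pvalues[!is.na(pvalues)]
  if (length(pvalues) == 0) return(NA_real_)
  if (any(pvalues < 0) || any(pvalues > 1)) {
    abort("p-values must be in [0, 1]")
  }
  if (any(pvalues == 0)) {
    warning("p-value of 0 clipped to smallest representable value")
    pvalues[pvalues == 0] <- .Machine$double.xmin
  }
  stat <- -2 * sum(log(pvalues))
  pchisq(stat, df = 2 * length(pvalues), lower.tail = FALSE)
}
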