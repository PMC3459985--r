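#' Hypergeometric gene-list overlap probability
#'
#' Given a universe of `N` genes and two lists of sizes `m` and `n`
#' sharing `k` genes, computes the upper-tail probability of observing an
#' overlap of at least `k` under random draws,
#' `P(X >= k) = sum_{i=k}^{min(m,n)} C(m,i) C(N-m, n-i) / C(N,n)`,
#' evaluated in log space via the hypergeometric distribution.  Set
#' `tail = "point"` for the point probability `P(X = k)`.
#'
#' @param N universe size.
#' @param m,n sizes of the two lists (`m, n <= N`).
#' @param k observed overlap (`0 <= k <= min(m, n)`).
#' @param tail `"upper"` (default) or `"point"`.
#' @return list of class `OverlapResult` with fields `N`, `m`, `n`, `k`,
#'   `p_value`, `tail`, `expected` (the expected overlap `m n / N`) and
#'   `direction` (`"enriched"`/`"depleted"` relative to expectation).
#' @examples
#' hypergeomOverlap(N = 10, m = 5, n = 4, k = 3)$p_value  # 55/210
#' @export
hypergeomOverlap <- function(N, m, n, k, tail = c("upper", "point")) {
    tail <- match.arg(tail)
    for (nm in c("N", "m", "n", "k")) {
        v <- get(nm)
        if (length(v) != 1L || is.na(v) || v < 0 || v != floor(v))
            stop("argument '", nm, "' must be a single non-negative integer")
    }
    if (m > N) stop("list size m exceeds universe N")
    if (n > N) stop("list size n exceeds universe N")
    if (k > min(m, n))
        stop("overlap k exceeds min(m, n)")
    p <- if (tail == "upper") {
        if (k == 0) 1 else
            phyper(k - 1, m, N - m, n, lower.tail = FALSE)
    } else {
        dhyper(k, m, N - m, n)
    }
    expected <- m * n / N
    structure(list(N = N, m = m, n = n, k = k, p_value = p, tail = tail,
                   expected = expected,
                   direction = if (k >= expected) "enriched" else "depleted"),
              class = "OverlapResult")
}

#' @export
print.OverlapResult <- function(x, ...) {
    cat(sprintf(
        "Hypergeometric overlap: k = %d of lists %d x %d in universe %d\n",
        x$k, x$m, x$n, x$N))
    cat(sprintf("  expected %.3g, %s; P(%s) = %.4g\n", x$expected,
                x$direction,
                if (x$tail == "upper") sprintf("X >= %d", x$k)
                else sprintf("X = %d", x$k), x$p_value))
    invisible(x)
}
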