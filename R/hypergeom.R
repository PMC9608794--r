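#' Hypergeometric upper-tail probability P(X >= r)
#'
#' The pair statistic at the heart of ceRNA network inference: the probability
#' that a lncRNA targeted by `n` miRNAs and an mRNA targeted by `t` miRNAs,
#' both drawn from a universe of `m` miRNAs, share at least `r` miRNAs by
#' chance. Equivalently, for `X` hypergeometric with population size `m`,
#' `t` success states and `n` draws, returns `P(X >= r)`.
#'
#' The sum is carried out over the upper tail `i = r, ..., min(n, t)` in log
#' space (via [lchoose]), which is numerically stable where the textbook
#' complement form `1 - sum_{i < r}` suffers catastrophic cancellation for
#' small probabilities.
#'
#' @param r integer, shared (overlap) count, `0 <= r <= min(n, t)`.
#' @param m integer, miRNA universe size, `m >= 1`.
#' @param n integer, miRNAs interacting with the lncRNA, `n <= m`.
#' @param t integer, miRNAs interacting with the mRNA, `t <= m`.
#' @return A single probability in `[0, 1]`; an input `r` of 0 gives exactly 1.
#' @examples
#' hypergeom_tail(2, m = 5, n = 3, t = 3) # 0.7
#' hypergeom_tail(0, m = 10, n = 4, t = 4) # 1
#' @export
hypergeom_tail <- function(r, m, n, t) {
  r <- assert_count(r, "r"); m <- assert_count(m, "m", min = 1)
  n <- assert_count(n, "n"); t <- assert_count(t, "t")
  if (n > m) stop_("bound violated: n (%d) > m (%d)", n, m)
  if (t > m) stop_("bound violated: t (%d) > m (%d)", t, m)
  if (r > min(n, t)) stop_("bound violated: r (%d) > min(n, t) = %d", r, min(n, t))
  if (r == 0L) return(1)
  # support of X is max(0, n + t - m) .. min(n, t)
  lo <- max(r, n + t - m)
  hi <- min(n, t)
  if (r <= max(0L, n + t - m)) return(1)
  i <- lo:hi
  lp <- lchoose(t, i) + lchoose(m - t, n - i) - lchoose(m, n)
  mx <- max(lp)
  min(1, exp(mx) * sum(exp(lp - mx)))
}
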