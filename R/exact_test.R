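## Exact multinomial machinery for testing an excess (or deficit) of
## SA-fusions against the closed-form null. All mass accumulation is done
## in log space so that tail probabilities far below 1e-5 are computed
## without underflow even for totals in the thousands.

check_probs3 <- function(probs, tol = 1e-8) {
  probs <- as.numeric(probs)
  if (length(probs) != 3L || any(!is.finite(probs)) || any(probs < 0))
    stop("'probs' must be three finite non-negative numbers (p_sa, p_aa, p_ss)")
  if (abs(sum(probs) - 1) > tol)
    stop(sprintf("'probs' must sum to 1 (got %.12g)", sum(probs)))
  probs
}

logsumexp <- function(x) {
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

#' Multinomial point probability of a fusion-count triple
#'
#' Probability of observing exactly (`n_sa`, `n_aa`, `n_ss`) fusions of the
#' three classes when each of the `n = n_sa + n_aa + n_ss` fusions falls
#' independently into a class with the given null probabilities:
#' \eqn{\frac{n!}{i!\,j!\,k!} p_{SA}^i p_{AA}^j p_{SS}^k}.
#'
#' @param n_sa,n_aa,n_ss non-negative counts of SA-, AA- and SS-fusions.
#' @param probs the null triple `(p_sa, p_aa, p_ss)`, e.g. a
#'   [fusion_probabilities()] object; must sum to 1.
#' @param log return the log probability.
#' @return a probability (or its log).
#' @export
multinomial_point <- function(n_sa, n_aa, n_ss, probs, log = FALSE) {
  probs <- check_probs3(probs)
  cnt <- c(n_sa, n_aa, n_ss)
  if (any(cnt < 0) || any(cnt != round(cnt)))
    stop("fusion counts must be non-negative integers")
  lp <- lgamma(sum(cnt) + 1) - sum(lgamma(cnt + 1)) +
    sum(ifelse(cnt == 0, 0, cnt * log(probs)))
  if (log) lp else exp(lp)
}

## Upper-tail double sum over i = k_min..n and all AA/SS splits of the
## remainder, in log space. This is the literal tail of the trinomial.
sa_tail_double_sum <- function(k_min, n, probs) {
  if (k_min > n) return(0)
  terms <- unlist(lapply(k_min:n, function(i) {
    vapply(0:(n - i), function(j)
      multinomial_point(i, j, n - i - j, probs, log = TRUE), numeric(1))
  }))
  exp(logsumexp(terms))
}

## The AA/SS split marginalizes out: the tail depends only on p_sa through
## a binomial. Used as the always-on cross-check for the double sum.
sa_tail_binomial <- function(k_min, n, p_sa) {
  if (k_min > n) return(0)
  sum(stats::dbinom(k_min:n, size = n, prob = p_sa))
}

#' Exact upper-tail probability of the SA-fusion count
#'
#' Probability, under the multinomial null, of observing `k_min` or more
#' SA-fusions among `n` fusions in total. The tail is computed twice — as
#' the literal double sum over all AA/SS splits and as the marginal
#' binomial tail in `p_sa` — and the two must agree to 12 significant
#' digits, otherwise an internal error is raised.
#'
#' @param k_min smallest SA-fusion count included in the tail
#'   (`0 <= k_min <= n + 1`; `k_min = 0` gives 1, `k_min = n + 1` gives 0).
#' @param n total number of fusions.
#' @param probs the null triple `(p_sa, p_aa, p_ss)`.
#' @return an object of class `"sa_tail"`: a list with `p_value`, `n`,
#'   `k_min` and `null_probs`.
#' @examples
#' pr <- fusion_probabilities(karyotype(26, x = 2, y = 0), mu = 0)
#' sa_tail_probability(8, 10, pr)
#' @export
sa_tail_probability <- function(k_min, n, probs) {
  probs <- check_probs3(probs)
  if (n < 0 || n != round(n)) stop("'n' must be a non-negative integer")
  if (k_min < 0 || k_min > n + 1 || k_min != round(k_min))
    stop("'k_min' must be an integer in 0..(n + 1)")
  p_dbl <- sa_tail_double_sum(k_min, n, probs)
  p_bin <- sa_tail_binomial(k_min, n, probs[1])
  if (p_bin > 0 && abs(p_dbl - p_bin) > 1e-12 * p_bin)
    stop(sprintf("internal inconsistency: double-sum tail %.15g vs binomial tail %.15g",
                 p_dbl, p_bin))
  structure(list(p_value = p_dbl, n = as.integer(n), k_min = as.integer(k_min),
                 null_probs = c(p_sa = probs[1], p_aa = probs[2], p_ss = probs[3])),
            class = "sa_tail")
}

#' @export
print.sa_tail <- function(x, ...) {
  cat(sprintf("Exact multinomial tail: P(X_SA >= %d | n = %d) = %.6g\n",
              x$k_min, x$n, x$p_value))
  cat(sprintf("  null: p_sa = %.6g, p_aa = %.6g, p_ss = %.6g\n",
              x$null_probs[1], x$null_probs[2], x$null_probs[3]))
  invisible(x)
}

#' Exact test for an excess (or deficit) of SA-fusions
#'
#' Tests observed fusion-class counts against the closed-form null for a
#' given karyotype. The default is the one-sided upper tail — the
#' probability of at least as many SA-fusions as observed — appropriate
#' when asking whether sex chromosome-autosome fusions are over-represented
#' (e.g. the jumping spider pattern). `tail = "lower"` gives the
#' probability of at most the observed count, the direction in which a
#' deficit of SA-fusions (the fly pattern) is extreme. Only the total `n`
#' and the SA count enter the tail: the split of the remainder between AA
#' and SS marginalizes out.
#'
#' @param n_sa,n_aa,n_ss observed counts of the three fusion classes.
#' @param k a [karyotype()] giving the null model's parameters.
#' @param mu sex-bias parameter (proportion of fusions arising in the
#'   homogametic sex).
#' @param tail `"upper"` (excess) or `"lower"` (deficit).
#' @return an object of class `"sa_fusion_test"` with the p-value, the
#'   null probabilities, the counts and the test direction.
#' @examples
#' # X1X2O system with 26 autosomes, 8 SA-, 1 AA- and 1 SS-fusion observed
#' sa_fusion_test(8, 1, 1, karyotype(26, x = 2, y = 0), mu = 0)
#' @export
sa_fusion_test <- function(n_sa, n_aa, n_ss, k, mu = 0.5,
                           tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  cnt <- c(n_sa, n_aa, n_ss)
  if (any(cnt < 0) || any(cnt != round(cnt)))
    stop("fusion counts must be non-negative integers")
  n <- sum(cnt)
  if (n < 1) stop("at least one observed fusion is required to test")
  probs <- fusion_probabilities(k, mu)
  p <- if (tail == "upper") {
    sa_tail_probability(n_sa, n, probs)$p_value
  } else {
    # P(X <= n_sa) = 1 - P(X >= n_sa + 1), computed directly for accuracy
    sum(stats::dbinom(0:n_sa, size = n, prob = probs[1]))
  }
  structure(list(p_value = p, tail = tail,
                 counts = c(n_sa = n_sa, n_aa = n_aa, n_ss = n_ss),
                 n = n, k_min = if (tail == "upper") n_sa else NA_integer_,
                 null_probs = unclass(probs), karyotype = attr(probs, "karyotype"),
                 mu = mu),
            class = "sa_fusion_test")
}

#' @export
print.sa_fusion_test <- function(x, ...) {
  dir <- if (x$tail == "upper") ">=" else "<="
  cat("Exact multinomial test of SA-fusion counts\n")
  cat(sprintf("  observed: SA = %d, AA = %d, SS = %d (n = %d)\n",
              x$counts[1], x$counts[2], x$counts[3], x$n))
  cat(sprintf("  null (mu = %g): p_sa = %.6g, p_aa = %.6g, p_ss = %.6g\n",
              x$mu, x$null_probs[1], x$null_probs[2], x$null_probs[3]))
  cat(sprintf("  P(X_SA %s %d) = %.6g  (one-sided %s tail)\n",
              dir, x$counts[1], x$p_value, x$tail))
  invisible(x)
}
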