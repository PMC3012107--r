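# Core SGoF machinery: counting, exact binomial meta-test, effect count,
# realized threshold, pi0 and plug-in FDR estimation.

# Relative guard when comparing a binomial tail probability to alpha.  The
# comparison is mathematically "tail <= alpha", but pbinom can return
# alpha + 1 ulp at exact boundaries (e.g. P(Bin(1, 0.05) >= 1)), which would
# silently flip the documented boundary behaviour (P = alpha rejects).
.tail_tol <- 1e-9

.tail_leq_alpha <- function(tail, alpha) tail <= alpha * (1 + .tail_tol)

.check_prob <- function(x, what) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x <= 0 || x >= 1) {
    stop(sprintf("`%s` must be a single number in the open interval (0, 1), got %s",
                 what, deparse(x)), call. = FALSE)
  }
  invisible(x)
}

.check_pvalues <- function(pvalues) {
  if (!is.numeric(pvalues)) {
    stop("p-values must be numeric", call. = FALSE)
  }
  bad <- which(is.na(pvalues) | pvalues < 0 | pvalues > 1)
  if (length(bad)) {
    stop(sprintf("p-value out of [0, 1] at index %d (value %s)",
                 bad[1L], deparse(pvalues[bad[1L]])), call. = FALSE)
  }
  invisible(pvalues)
}

#' Construct a p-value set
#'
#' Bundles test identifiers, p-values and (optionally, for simulated data)
#' ground-truth labels into the container consumed by [sgof()],
#' [compute_trace()] and the simulation framework.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @param ids Character vector of test identifiers, recycled-length-checked
#'   against `pvalues`. Defaults to `"t1" ... "tS"`. Duplicates are allowed
#'   and preserved verbatim.
#' @param truth Optional logical vector: `TRUE` marks a genuine effect
#'   (non-true null). `NULL` for real data.
#' @return An object of class `pvalue_set`: a list with elements `ids`,
#'   `pvalues`, `truth` and `S` (number of tests).
#' @examples
#' ps <- pvalue_set(c(0.001, 0.2, 0.8), ids = c("geneA", "geneB", "geneC"))
#' ps$S
#' @export
pvalue_set <- function(pvalues, ids = NULL, truth = NULL) {
  .check_pvalues(pvalues)
  S <- length(pvalues)
  if (is.null(ids)) {
    ids <- if (S) paste0("t", seq_len(S)) else character(0)
  }
  ids <- as.character(ids)
  if (length(ids) != S) {
    stop(sprintf("ids (%d) and pvalues (%d) must have equal length",
                 length(ids), S), call. = FALSE)
  }
  if (!is.null(truth)) {
    truth <- as.logical(truth)
    if (length(truth) != S || anyNA(truth)) {
      stop("truth must be a logical vector of the same length as pvalues, without NA",
           call. = FALSE)
    }
  }
  structure(list(ids = ids, pvalues = as.numeric(pvalues), truth = truth, S = S),
            class = "pvalue_set")
}

#' @export
print.pvalue_set <- function(x, ...) {
  cat(sprintf("p-value set: %d tests%s\n", x$S,
              if (is.null(x$truth)) "" else
                sprintf(" (%d labelled effects)", sum(x$truth))))
  invisible(x)
}

.as_pvalue_set <- function(x) {
  if (inherits(x, "pvalue_set")) return(x)
  if (is.numeric(x)) return(pvalue_set(x))
  stop("expected a `pvalue_set` or a numeric vector of p-values", call. = FALSE)
}

#' Count individual rejections at a working threshold
#'
#' Returns \eqn{K(\gamma) = \#\{p_i \le \gamma\}}, the observed number of
#' p-values at or below `gamma`. Under the intersection null this count is
#' Binomial(S, gamma). The boundary `p == gamma` is counted.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @param gamma Working threshold in (0, 1).
#' @return Integer count.
#' @examples
#' count_rejections(c(0.01, 0.04, 0.2), 0.05)
#' @export
count_rejections <- function(pvalues, gamma) {
  .check_pvalues(pvalues)
  .check_prob(gamma, "gamma")
  sum(pvalues <= gamma)
}

#' Binomial critical count for the SGoF meta-test
#'
#' The smallest integer \eqn{b} such that
#' \eqn{P(\mathrm{Binomial}(S, \gamma) \ge b) \le \alpha}. Rejecting the
#' intersection null whenever \eqn{K(\gamma) \ge b} controls the family-wise
#' error rate at level `alpha` in the weak sense. The value can be `S + 1`
#' when no count is extreme enough (then the meta-test can never reject).
#'
#' @param S Number of tests (non-negative integer).
#' @param gamma Working threshold in (0, 1).
#' @param alpha Weak-FWER level in (0, 1).
#' @return Integer in `0:(S + 1)`.
#' @examples
#' binomial_critical_value(10, 0.5, 0.05)  # 9
#' @export
binomial_critical_value <- function(S, gamma, alpha) {
  if (length(S) != 1L || is.na(S) || S < 0 || S != floor(S)) {
    stop("`S` must be a single non-negative integer", call. = FALSE)
  }
  .check_prob(gamma, "gamma")
  .check_prob(alpha, "alpha")
  # P(X >= b) <= alpha  <=>  P(X <= b - 1) >= 1 - alpha; qbinom gives the
  # smallest q with P(X <= q) >= 1 - alpha, hence b = q + 1 -- then walk the
  # boundary with the guarded tail comparison so that P(X >= b) = alpha
  # (exactly, up to rounding) still rejects.
  b <- stats::qbinom(1 - alpha, S, gamma) + 1L
  while (b >= 1L &&
         .tail_leq_alpha(stats::pbinom(b - 2L, S, gamma, lower.tail = FALSE), alpha)) {
    b <- b - 1L
  }
  while (b <= S &&
         !.tail_leq_alpha(stats::pbinom(b - 1L, S, gamma, lower.tail = FALSE), alpha)) {
    b <- b + 1L
  }
  as.integer(b)
}

#' Exact p-value of the SGoF meta-test
#'
#' Upper binomial tail \eqn{p(\gamma) = P(\mathrm{Binomial}(S, \gamma) \ge K)},
#' computed exactly (no normal approximation). Underflow is floored at
#' `1e-300` so the log-significance trace remains finite.
#'
#' @param S Number of tests.
#' @param gamma Working threshold in (0, 1).
#' @param K Observed count of p-values at or below `gamma`; `0 <= K <= S`.
#' @return Probability in (0, 1\].
#' @examples
#' meta_test_pvalue(10, 0.5, 9)  # 11/1024
#' @export
meta_test_pvalue <- function(S, gamma, K) {
  if (length(K) != 1L || is.na(K) || K < 0 || K != floor(K)) {
    stop("`K` must be a single non-negative integer", call. = FALSE)
  }
  if (K > S) stop(sprintf("K (%d) cannot exceed S (%d)", K, S), call. = FALSE)
  .check_prob(gamma, "gamma")
  if (K == 0) return(1)
  p <- stats::pbinom(K - 1, S, gamma, lower.tail = FALSE)
  max(p, 1e-300)
}

#' Number of effects declared by SGoF
#'
#' Upon rejection of the intersection null (`K >= b`) SGoF declares the
#' \eqn{K - b + 1} smallest p-values as true effects; otherwise none. The
#' capped variant additionally bounds the count by \eqn{K(\alpha)}, the number
#' of p-values at or below `alpha`, so that no declared p-value exceeds
#' `alpha`.
#'
#' @param K Count of p-values at or below gamma.
#' @param b Binomial critical count from [binomial_critical_value()].
#' @param K_at_alpha Count of p-values at or below alpha (used only when
#'   `capped = TRUE`).
#' @param capped Apply the `min(K - b + 1, K_at_alpha)` cap?
#' @return Non-negative integer count.
#' @export
n_effects <- function(K, b, K_at_alpha = NULL, capped = FALSE) {
  if (K < b) return(0L)
  n <- as.integer(K - b + 1L)
  if (isTRUE(capped)) {
    if (is.null(K_at_alpha)) {
      stop("`K_at_alpha` is required when capped = TRUE", call. = FALSE)
    }
    n <- min(n, as.integer(K_at_alpha))
  }
  n
}

#' Realized p-value threshold for a declared-effect count
#'
#' The cut-off \eqn{q} such that the `N` declared effects are the p-values at
#' or below `q`: the `N`-th smallest p-value. Under ties at the cut the
#' defining equation \eqn{N = \#\{p_i \le q\}} has no exact solution; `N`
#' stays authoritative and `achieved_count` (\eqn{\#\{p_i \le q\}}, possibly
#' `> N`) surfaces the discrepancy.
#'
#' @param pvalues Numeric vector of p-values.
#' @param N Number of effects to realize; `0 <= N <= length(pvalues)`.
#' @return List with `threshold` (`NA` when `N == 0`) and `achieved_count`.
#' @export
threshold_for_n <- function(pvalues, N) {
  .check_pvalues(pvalues)
  if (N > length(pvalues)) {
    stop(sprintf("N (%d) exceeds the number of p-values (%d)",
                 N, length(pvalues)), call. = FALSE)
  }
  if (N == 0) return(list(threshold = NA_real_, achieved_count = 0L))
  q <- sort(pvalues, partial = N)[N]
  list(threshold = q, achieved_count = sum(pvalues <= q))
}

#' Estimate the proportion of true null hypotheses
#'
#' The average of \eqn{-\log(1 - p_i)} (natural log). For uniformly
#' distributed p-values this has expectation 1; a surplus of small p-values
#' pulls it below 1, so the mean estimates \eqn{\pi_0}, the proportion of
#' true nulls. The raw value may exceed 1 and is reported as is; [efdr()]
#' truncates it at 1 internally. `p = 1` is clamped to `1 - 1e-15` with a
#' warning (dropping such points would silently change S).
#'
#' @param pvalues Non-empty numeric vector of p-values in \[0, 1\].
#' @return Non-negative estimate of the true-null proportion.
#' @examples
#' pi0_estimate(c(1 - exp(-1)))  # exactly 1
#' @export
pi0_estimate <- function(pvalues) {
  .check_pvalues(pvalues)
  if (!length(pvalues)) stop("cannot estimate pi0 from an empty p-value set", call. = FALSE)
  ones <- pvalues == 1
  if (any(ones)) {
    warning(sprintf("%d p-value(s) equal to 1 clamped to 1 - 1e-15 in pi0 estimate",
                    sum(ones)))
    pvalues[ones] <- 1 - 1e-15
  }
  mean(-log1p(-pvalues))
}

#' Plug-in estimated FDR of an SGoF declaration set
#'
#' \eqn{\mathrm{eFDR} = S \cdot q \cdot \min(\pi_0, 1) / N}, clipped into
#' \[0, 1\]: the expected number of null p-values below the realized
#' threshold `q` (`S * q * pi0`) over the number of declared effects.
#'
#' @param S Number of tests.
#' @param threshold Realized p-value threshold \eqn{q} in \[0, 1\].
#' @param pi0 Estimated proportion of true nulls (raw; truncated at 1 here).
#' @param N Number of declared effects.
#' @return Estimated FDR in \[0, 1\], or `NA` when `N == 0`.
#' @export
efdr <- function(S, threshold, pi0, N) {
  if (N == 0) return(NA_real_)
  min(1, max(0, S * threshold * min(pi0, 1) / N))
}

#' Run the SGoF multiple-testing procedure at one working threshold
#'
#' Compares the observed number of p-values at or below `gamma`,
#' \eqn{K(\gamma)}, with its Binomial(S, gamma) distribution under the
#' intersection null (all S nulls true). If the one-sided exact test rejects
#' at level `alpha` (\eqn{K \ge b_\alpha(\gamma)}), the
#' \eqn{K - b + 1} smallest p-values are declared true effects. This controls
#' the family-wise error rate at `alpha` in the weak sense whatever `gamma`.
#'
#' @param pset A [pvalue_set()] (or bare numeric vector of p-values).
#' @param gamma Working threshold in (0, 1). The classical choice is
#'   `gamma = alpha = 0.05`, but power is often maximized elsewhere; see
#'   [compute_trace()].
#' @param alpha Weak-FWER level in (0, 1); default 0.05.
#' @param capped If `TRUE`, never declare a p-value above `alpha`:
#'   \eqn{N = \min(K - b + 1, K(\alpha))}.
#' @return An object of class `sgof_result`: list with `S`, `gamma`, `alpha`,
#'   `capped`, `K` (count at gamma), `K_at_alpha`, `b` (critical count),
#'   `meta_pvalue`, `n_effects`, `threshold` (`NA` if no effects),
#'   `achieved_count`, `declared_ids`, `declared_idx`, `pi0`, `efdr`.
#' @examples
#' set.seed(1)
#' p <- c(rbeta(50, 0.2, 1), runif(950))
#' res <- sgof(pvalue_set(p), gamma = 0.05)
#' res
#' @export
sgof <- function(pset, gamma = 0.05, alpha = 0.05, capped = FALSE) {
  pset <- .as_pvalue_set(pset)
  if (pset$S == 0) stop("cannot run SGoF on an empty p-value set", call. = FALSE)
  .check_prob(gamma, "gamma")
  .check_prob(alpha, "alpha")
  p <- pset$pvalues
  S <- pset$S
  K <- count_rejections(p, gamma)
  K_at_alpha <- sum(p <= alpha)
  b <- binomial_critical_value(S, gamma, alpha)
  meta_p <- meta_test_pvalue(S, gamma, K)
  N <- n_effects(K, b, K_at_alpha, capped)
  thr <- threshold_for_n(p, N)
  pi0 <- pi0_estimate(p)
  # stable order: ties at the cut resolved by input position
  declared_idx <- if (N > 0) order(p)[seq_len(N)] else integer(0)
  structure(list(
    S = S, gamma = gamma, alpha = alpha, capped = capped,
    K = as.integer(K), K_at_alpha = as.integer(K_at_alpha), b = b,
    meta_pvalue = meta_p, n_effects = as.integer(N),
    threshold = thr$threshold, achieved_count = thr$achieved_count,
    declared_idx = declared_idx, declared_ids = pset$ids[declared_idx],
    pi0 = pi0,
    efdr = if (N > 0) efdr(S, thr$threshold, pi0, N) else NA_real_
  ), class = "sgof_result")
}

#' @export
print.sgof_result <- function(x, ...) {
  cat(sprintf("SGoF at gamma = %g, alpha = %g%s (S = %d tests)\n",
              x$gamma, x$alpha, if (x$capped) ", capped" else "", x$S))
  cat(sprintf("  K(gamma) = %d observed vs %.1f expected under the complete null\n",
              x$K, x$S * x$gamma))
  cat(sprintf("  critical count b = %d; meta-test p-value = %.4g\n",
              x$b, x$meta_pvalue))
  cat(sprintf("  effects declared N = %d", x$n_effects))
  if (x$n_effects > 0) {
    cat(sprintf(" (p-value threshold %.4g, achieved count %d)\n",
                x$threshold, x$achieved_count))
    cat(sprintf("  estimated pi0 = %.4f; estimated FDR = %.4f\n", x$pi0, x$efdr))
  } else {
    cat(sprintf("\n  estimated pi0 = %.4f\n", x$pi0))
  }
  invisible(x)
}

#' Sequential (step-down) form of the SGoF effect count
#'
#' The iterative description of SGoF: starting from the observed count
#' \eqn{k = K(\gamma)}, test \eqn{P(\mathrm{Binomial}(S,\gamma) \ge k) \le
#' \alpha}, decrement `k`, and repeat until significance is lost; the number
#' of successful steps is the number of declared effects. Provided for
#' cross-validation: it equals the closed form \eqn{\max(K - b + 1, 0)}
#' of the uncapped procedure.
#'
#' @inheritParams sgof
#' @return Integer count of declared effects.
#' @export
sgof_sequential <- function(pset, gamma = 0.05, alpha = 0.05) {
  pset <- .as_pvalue_set(pset)
  if (pset$S == 0) stop("cannot run SGoF on an empty p-value set", call. = FALSE)
  .check_prob(gamma, "gamma")
  .check_prob(alpha, "alpha")
  S <- pset$S
  k <- count_rejections(pset$pvalues, gamma)
  n <- 0L
  while (k >= 1L &&
         .tail_leq_alpha(stats::pbinom(k - 1L, S, gamma, lower.tail = FALSE), alpha)) {
    n <- n + 1L
    k <- k - 1L
  }
  n
}
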