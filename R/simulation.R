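# Monte-Carlo evaluation of SGoF and the Benjamini-Hochberg baseline on
# two-component mixture p-values: uniform nulls plus one-sided normal-shift
# effects with p = 1 - pnorm(Z + w).

#' Simulation scenario configuration
#'
#' Defines one mixture scenario: `S` simultaneous tests of which
#' `round(S * effect_proportion)` are genuine effects with shift `w`
#' (in standard-error units), evaluated with SGoF at each gamma in `gammas`
#' and with Benjamini-Hochberg at nominal FDR `bh_fdr`, averaged over
#' `n_trials` Monte-Carlo trials.
#'
#' @param S Total number of tests per trial.
#' @param effect_proportion Fraction of genuine effects in \[0, 1).
#' @param w Effect size: the standardized distance between null and
#'   alternative means of a one-sided normal test.
#' @param n_trials Number of Monte-Carlo trials (>= 1).
#' @param alpha Weak-FWER level for SGoF.
#' @param gammas Gamma values at which SGoF is evaluated (possibly empty).
#' @param bh_fdr Nominal FDR level of the BH baseline.
#' @param seed Integer RNG seed; per-trial substreams are derived from it so
#'   any trial is reproducible in isolation.
#' @param capped Use the capped SGoF effect count?
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(S = 1000, effect_proportion = 0.1, w = 2,
                       n_trials = 1000, alpha = 0.05,
                       gammas = c(0.01, 0.05, 0.09, 0.13, 0.17),
                       bh_fdr = 0.05, seed = 1, capped = FALSE) {
  if (S < 1) stop("S must be >= 1", call. = FALSE)
  if (effect_proportion < 0 || effect_proportion >= 1) {
    stop("effect_proportion must lie in [0, 1)", call. = FALSE)
  }
  if (n_trials < 1) stop("n_trials must be >= 1", call. = FALSE)
  .check_prob(alpha, "alpha")
  .check_prob(bh_fdr, "bh_fdr")
  if (length(gammas)) {
    if (any(gammas <= 0) || any(gammas >= 1)) {
      stop("all gammas must lie in (0, 1)", call. = FALSE)
    }
  }
  if (is.na(seed) || abs(seed) >= 2^31) {
    stop("seed must be an integer below 2^31 in magnitude", call. = FALSE)
  }
  structure(list(S = as.integer(S), effect_proportion = effect_proportion,
                 w = w, n_trials = as.integer(n_trials), alpha = alpha,
                 gammas = as.numeric(gammas), bh_fdr = bh_fdr,
                 seed = as.integer(seed), capped = isTRUE(capped)),
            class = "sim_config")
}

# deterministic per-trial substream, kept inside 32-bit integer range
.trial_seed <- function(seed, trial) {
  as.integer((as.double(seed) + 7919 * as.double(trial)) %% 2147483647)
}

#' Generate one trial of mixture p-values
#'
#' `round(S * effect_proportion)` effect p-values are drawn as
#' \eqn{p = 1 - \Phi(Z + w)} with \eqn{Z \sim N(0,1)} (the p-value of a
#' one-sided normal test whose true standardized shift is `w`); the remaining
#' tests are true nulls with Uniform(0, 1) p-values. Ground-truth labels are
#' attached; identifiers are synthetic and unique. The effect count is
#' deterministic, identical in every trial.
#'
#' @param S Number of tests.
#' @param effect_proportion Fraction of genuine effects in \[0, 1).
#' @param w Standardized effect size.
#' @return A [pvalue_set()] with `truth` labels (`TRUE` = genuine effect).
#'   Uses the current RNG state; seed beforehand for reproducibility.
#' @examples
#' set.seed(42)
#' ps <- generate_pvalues(1000, 0.1, 2)
#' sum(ps$truth)  # exactly 100
#' @export
generate_pvalues <- function(S, effect_proportion, w) {
  if (S < 1) stop("S must be >= 1", call. = FALSE)
  if (effect_proportion < 0 || effect_proportion >= 1) {
    stop("effect_proportion must lie in [0, 1)", call. = FALSE)
  }
  n_eff <- round(S * effect_proportion)
  n_null <- S - n_eff
  p_eff <- stats::pnorm(stats::rnorm(n_eff) + w, lower.tail = FALSE)
  p_null <- stats::runif(n_null)
  pvalue_set(
    pvalues = c(p_eff, p_null),
    ids = sprintf("t%0*d", nchar(S), seq_len(S)),
    truth = c(rep(TRUE, n_eff), rep(FALSE, n_null))
  )
}

#' Benjamini-Hochberg step-up declaration set
#'
#' Classical BH: with sorted p-values \eqn{p_{(1)} \le \dots \le p_{(S)}},
#' find the largest i with \eqn{p_{(i)} \le (i/S)\,q} and declare the i
#' smallest. Implemented through [stats::p.adjust()], whose BH-adjusted
#' p-values satisfy `padj <= q` exactly for the step-up declaration set.
#'
#' @param pvalues Numeric vector of p-values.
#' @param fdr_level Nominal FDR level q in (0, 1).
#' @return Integer vector of declared indices (into `pvalues`); empty when
#'   nothing is declared.
#' @export
bh_procedure <- function(pvalues, fdr_level = 0.05) {
  .check_pvalues(pvalues)
  .check_prob(fdr_level, "fdr_level")
  which(stats::p.adjust(pvalues, method = "BH") <= fdr_level)
}

#' Score one trial against ground truth
#'
#' @param truth Logical vector; `TRUE` marks a genuine effect.
#' @param declared Integer indices of declared tests (subset of
#'   `seq_along(truth)`).
#' @return List with `power` (true positives over genuine effects; `NA` when
#'   there are no genuine effects), `fdp` (false positives over
#'   `max(#declared, 1)`), `n_declared`, `tp`, `fp`.
#' @export
evaluate_trial <- function(truth, declared) {
  truth <- as.logical(truth)
  if (length(declared) && (min(declared) < 1 || max(declared) > length(truth))) {
    stop("declared indices out of range", call. = FALSE)
  }
  n_eff <- sum(truth)
  tp <- sum(truth[declared])
  fp <- length(declared) - tp
  list(
    power = if (n_eff > 0) tp / n_eff else NA_real_,
    fdp = fp / max(length(declared), 1),
    n_declared = length(declared), tp = tp, fp = fp
  )
}

#' Run a Monte-Carlo power/FDR study
#'
#' For each trial a single mixture p-value sample is generated and shared by
#' every method, so SGoF (at each configured gamma) and BH are compared on
#' identical data. Per-trial power and false-discovery proportion are
#' averaged over trials; the mean FDP estimates the method's FDR.
#'
#' @param config A [sim_config()].
#' @param progress Log a line to stderr every 100 trials?
#' @return Object of class `sim_summary`: list with `config` and `table`, a
#'   data frame with one row per method (`SGoF(<gamma>)` rows then `BH`) and
#'   columns `method`, `gamma` (`NA` for BH), `power`, `se_power`, `fdr`,
#'   `se_fdr`, `rejection_rate` (fraction of trials declaring >= 1 effect),
#'   `n_trials`.
#' @examples
#' cfg <- sim_config(S = 200, n_trials = 20, gammas = 0.05, seed = 3)
#' run_simulation(cfg)$table
#' @export
run_simulation <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  gammas <- config$gammas
  n_g <- length(gammas)
  n_methods <- n_g + 1L  # SGoF per gamma, then BH
  S <- config$S
  power <- matrix(NA_real_, config$n_trials, n_methods)
  fdp <- matrix(NA_real_, config$n_trials, n_methods)
  rejected <- matrix(FALSE, config$n_trials, n_methods)
  b_cache <- vapply(gammas, function(g) binomial_critical_value(S, g, config$alpha),
                    integer(1))
  for (t in seq_len(config$n_trials)) {
    set.seed(.trial_seed(config$seed, t))
    pset <- generate_pvalues(S, config$effect_proportion, config$w)
    p <- pset$pvalues
    truth <- pset$truth
    n_eff <- sum(truth)
    ord <- order(p)
    cum_tp <- cumsum(truth[ord])
    K_at_alpha <- sum(p <= config$alpha)
    score <- function(j, R) {
      tp <- if (R > 0) cum_tp[R] else 0L
      power[t, j] <<- if (n_eff > 0) tp / n_eff else NA_real_
      fdp[t, j] <<- (R - tp) / max(R, 1)
      rejected[t, j] <<- R > 0
    }
    for (j in seq_len(n_g)) {
      K <- sum(p <= gammas[j])
      score(j, n_effects(K, b_cache[j], K_at_alpha, config$capped))
    }
    score(n_methods, length(bh_procedure(p, config$bh_fdr)))
    if (progress && t %% 100 == 0) {
      message(sprintf("simulation: %d / %d trials done", t, config$n_trials))
    }
  }
  mc_se <- function(x) stats::sd(x) / sqrt(length(x))
  col_stats <- function(m) {
    list(mean = apply(m, 2, function(x) if (all(is.na(x))) NA_real_ else mean(x)),
         se = apply(m, 2, function(x) if (all(is.na(x))) NA_real_ else mc_se(x)))
  }
  pw <- col_stats(power); fd <- col_stats(fdp)
  table <- data.frame(
    method = c(sprintf("SGoF(%g)", gammas), "BH"),
    gamma = c(gammas, NA_real_),
    power = pw$mean, se_power = pw$se,
    fdr = fd$mean, se_fdr = fd$se,
    rejection_rate = colMeans(rejected),
    n_trials = config$n_trials
  )
  structure(list(config = config, table = table), class = "sim_summary")
}

#' @export
print.sim_summary <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Monte-Carlo study: S = %d, %d%% effects, w = %g, %d trials, alpha = %g\n",
              cfg$S, round(100 * cfg$effect_proportion), cfg$w,
              cfg$n_trials, cfg$alpha))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a simulation summary as TSV
#'
#' Layout mirrors a power/FDR summary table: two rows (`Power`, `FDR`) with
#' one column per method.
#'
#' @param summary A `sim_summary` from [run_simulation()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_simulation_tsv <- function(summary, path) {
  stopifnot(inherits(summary, "sim_summary"))
  tab <- summary$table
  out <- data.frame(quantity = c("Power", "FDR"))
  for (i in seq_len(nrow(tab))) {
    out[[tab$method[i]]] <- c(tab$power[i], tab$fdr[i])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
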