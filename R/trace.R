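# The SGoFicance Trace: SGoF swept over a gamma grid, plus the four-panel
# diagnostic plot (log-significance, declared effects, estimated FDR,
# realized p-value threshold).

.log_floor <- 1e-300

#' Default gamma grid for the SGoFicance Trace
#'
#' `0.01, 0.02, ..., 0.99` — a finite realization of "gamma varying over
#' (0, 1)", matching the grid used in the simulation study.
#'
#' @return Numeric vector of length 99.
#' @export
default_gamma_grid <- function() {
  seq(0.01, 0.99, by = 0.01)
}

#' Compute the SGoFicance Trace
#'
#' Runs [sgof()] at every value of a gamma grid and collects the per-gamma
#' quartet: meta-test p-value (and its natural log), number of declared
#' effects \eqn{N_\alpha(\gamma)}, plug-in estimated FDR, and the realized
#' p-value threshold \eqn{q_\alpha(\gamma)}. The true-null proportion
#' \eqn{\pi_0} is estimated once from the full p-value set and shared by all
#' grid points.
#'
#' @param pset A [pvalue_set()] or numeric vector of p-values.
#' @param gamma_grid Strictly increasing grid inside (0, 1); default
#'   [default_gamma_grid()].
#' @param alpha Weak-FWER level, default 0.05.
#' @param capped Use the capped effect count (no declared p-value above
#'   `alpha`)?
#' @return Object of class `sgof_trace`: list with `points` (data frame with
#'   columns `gamma`, `K`, `meta_pvalue`, `log_meta_pvalue`, `n_effects`,
#'   `efdr`, `threshold`, `achieved_count`), `pi0`, `alpha`, `capped`, `S`,
#'   and `summary` (`gamma_at_max_N`, `max_N`, `efdr_at_max_N`,
#'   `threshold_at_max_N`; ties in `max_N` resolved to the smallest gamma).
#' @examples
#' set.seed(7)
#' p <- c(1 - pnorm(rnorm(100) + 2), runif(900))
#' tr <- compute_trace(p, alpha = 0.05)
#' tr$summary
#' @export
compute_trace <- function(pset, gamma_grid = default_gamma_grid(),
                          alpha = 0.05, capped = FALSE) {
  pset <- .as_pvalue_set(pset)
  if (pset$S == 0) stop("cannot trace an empty p-value set", call. = FALSE)
  if (!length(gamma_grid)) stop("gamma grid must be non-empty", call. = FALSE)
  if (any(gamma_grid <= 0) || any(gamma_grid >= 1)) {
    stop("all gamma grid values must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (is.unsorted(gamma_grid, strictly = TRUE)) {
    stop("gamma grid must be strictly increasing", call. = FALSE)
  }
  .check_prob(alpha, "alpha")
  p <- pset$pvalues
  S <- pset$S
  pi0 <- pi0_estimate(p)
  K_at_alpha <- sum(p <= alpha)
  p_sorted <- sort(p)

  n_pts <- length(gamma_grid)
  K <- integer(n_pts); N <- integer(n_pts)
  meta <- numeric(n_pts); thr <- rep(NA_real_, n_pts)
  achieved <- integer(n_pts); e <- rep(NA_real_, n_pts)
  for (i in seq_len(n_pts)) {
    g <- gamma_grid[i]
    K[i] <- sum(p <= g)
    b <- binomial_critical_value(S, g, alpha)
    meta[i] <- meta_test_pvalue(S, g, K[i])
    N[i] <- n_effects(K[i], b, K_at_alpha, capped)
    if (N[i] > 0) {
      thr[i] <- p_sorted[N[i]]
      achieved[i] <- sum(p <= thr[i])
      e[i] <- efdr(S, thr[i], pi0, N[i])
    }
  }
  points <- data.frame(
    gamma = gamma_grid, K = K, meta_pvalue = meta,
    log_meta_pvalue = log(pmax(meta, .log_floor)),
    n_effects = N, efdr = e, threshold = thr, achieved_count = achieved
  )
  i_max <- which.max(N)  # first index attaining the max: smallest gamma
  structure(list(
    points = points, pi0 = pi0, alpha = alpha, capped = capped, S = S,
    summary = list(
      gamma_at_max_N = gamma_grid[i_max],
      max_N = N[i_max],
      efdr_at_max_N = e[i_max],
      threshold_at_max_N = thr[i_max]
    )
  ), class = "sgof_trace")
}

#' @export
print.sgof_trace <- function(x, ...) {
  s <- x$summary
  cat(sprintf("SGoFicance Trace: %d tests, alpha = %g%s, %d gamma values\n",
              x$S, x$alpha, if (x$capped) " (capped)" else "",
              nrow(x$points)))
  cat(sprintf("  estimated pi0 = %.4f\n", x$pi0))
  if (s$max_N > 0) {
    cat(sprintf("  max effects: N = %d at gamma = %g (threshold %.4g, eFDR %.4f)\n",
                s$max_N, s$gamma_at_max_N, s$threshold_at_max_N, s$efdr_at_max_N))
  } else {
    cat("  no effects declared at any gamma\n")
  }
  invisible(x)
}

#' Plot the four-panel SGoFicance Trace
#'
#' Panel A: natural-log meta-test p-value vs gamma, with a horizontal dashed
#' reference at `log(alpha)`. Panel B: number of declared effects. Panel C:
#' estimated FDR. Panel D: realized p-value threshold. Gamma values where no
#' effect is declared leave gaps in panels C and D.
#'
#' @param x An `sgof_trace` from [compute_trace()].
#' @param ... Ignored.
#' @return `x`, invisibly.
#' @export
plot.sgof_trace <- function(x, ...) {
  pts <- x$points
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2.5, 1))
  on.exit(graphics::par(op), add = TRUE)
  graphics::plot(pts$gamma, pts$log_meta_pvalue, type = "l",
                 xlab = expression(gamma), ylab = "log p-value of SGoF",
                 main = "A: log-significance")
  graphics::abline(h = log(x$alpha), lty = 2)
  graphics::plot(pts$gamma, pts$n_effects, type = "l",
                 xlab = expression(gamma), ylab = "number of effects",
                 main = "B: declared effects")
  graphics::plot(pts$gamma, pts$efdr, type = "l", ylim = c(0, 1),
                 xlab = expression(gamma), ylab = "estimated FDR",
                 main = "C: estimated FDR")
  thr_max <- if (all(is.na(pts$threshold))) 1 else max(pts$threshold, na.rm = TRUE)
  graphics::plot(pts$gamma, pts$threshold, type = "l", ylim = c(0, thr_max),
                 xlab = expression(gamma), ylab = "p-value threshold",
                 main = "D: threshold")
  invisible(x)
}

#' Render the SGoFicance Trace to an image file
#'
#' Writes the four-panel plot of [plot.sgof_trace()] to `path`; the device
#' is chosen by the file extension (`.png`, `.pdf` or `.svg`).
#'
#' @param trace An `sgof_trace`.
#' @param path Output file path ending in `.png`, `.pdf` or `.svg`.
#' @param width,height Figure size in inches.
#' @return `path`, invisibly.
#' @export
render_trace <- function(trace, path, width = 8, height = 6) {
  stopifnot(inherits(trace, "sgof_trace"))
  ext <- tolower(sub(".*\\.", "", path))
  switch(ext,
    png = grDevices::png(path, width = width, height = height,
                         units = "in", res = 150),
    pdf = grDevices::pdf(path, width = width, height = height),
    svg = grDevices::svg(path, width = width, height = height),
    stop(sprintf("unsupported figure extension '.%s' (use .png, .pdf or .svg)",
                 ext), call. = FALSE)
  )
  ok <- FALSE
  tryCatch({ plot(trace); ok <- TRUE }, finally = grDevices::dev.off())
  if (!ok) stop(sprintf("failed to render trace figure to '%s'", path),
                call. = FALSE)
  invisible(path)
}

#' Write a trace table as TSV
#'
#' One row per gamma with columns `gamma`, `meta_pvalue`, `log_meta_pvalue`,
#' `n_effects`, `efdr`, `threshold`, `achieved_count`; missing values are
#' written as `NA`.
#'
#' @param trace An `sgof_trace`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_trace_tsv <- function(trace, path) {
  stopifnot(inherits(trace, "sgof_trace"))
  cols <- c("gamma", "meta_pvalue", "log_meta_pvalue", "n_effects",
            "efdr", "threshold", "achieved_count")
  utils::write.table(trace$points[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}
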