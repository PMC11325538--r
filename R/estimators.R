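## Free-energy estimators over per-window samples: MBAR (self-consistent
## iteration with Newton refinement), BAR (independent one-dimensional
## root solve), thermodynamic integration with Gauss-Legendre quadrature,
## finite-difference dU/dlambda, block-analysis uncertainties, and replica
## statistics. Reduced potentials u = U/RT are dimensionless; results are
## reported in kcal/mol.

#' Per-window energy table
#'
#' Container for the samples a free-energy leg produces: the reduced
#' potential of every sample evaluated in every window (MBAR), and/or
#' per-window dU/dlambda samples (TI).
#'
#' @param u Numeric matrix, `K x N`: `u[k, n]` is the reduced potential of
#'   pooled sample `n` evaluated in window `k`. Columns are ordered by the
#'   window the sample was drawn from.
#' @param n_k Integer vector of per-window sample counts, `sum(n_k) = N`.
#' @param schedule Optional [lambda_schedule()].
#' @param dudl Optional list of per-window dU/dlambda sample vectors
#'   (kcal/mol).
#' @return A `window_table` object.
#' @export
window_table <- function(u, n_k, schedule = NULL, dudl = NULL) {
  u <- as.matrix(u)
  n_k <- as.integer(n_k)
  K <- length(n_k)
  if (nrow(u) != K) abort("nrow(u) must equal length(n_k)")
  if (ncol(u) != sum(n_k)) abort("ncol(u) must equal sum(n_k)")
  if (any(n_k < 1)) abort("every window needs at least one sample")
  if (!all(is.finite(u))) abort("reduced potentials must be finite")
  if (!is.null(dudl) && length(dudl) != K) {
    abort("dudl must have one sample vector per window")
  }
  structure(list(u = unname(u), n_k = n_k, schedule = schedule, dudl = dudl),
            class = "window_table")
}

#' @export
print.window_table <- function(x, ...) {
  cat("Window energy table:", length(x$n_k), "windows,",
      sum(x$n_k), "samples\n")
  invisible(x)
}

# origin window of each pooled sample
sample_windows_of <- function(tab) rep(seq_along(tab$n_k), tab$n_k)

#' Tidy a window table into long format
#'
#' @param x A `window_table`.
#' @param ... Unused.
#' @return Tibble with columns `sample` (index within its window), `window`
#'   (origin), `eval_window`, `u`.
#' @export
tidy.window_table <- function(x, ...) {
  K <- length(x$n_k)
  origin <- sample_windows_of(x)
  within <- unlist(lapply(x$n_k, seq_len))
  tibble::tibble(
    sample = rep(within, each = K),
    window = rep(origin, each = K),
    eval_window = rep(seq_len(K), times = sum(x$n_k)),
    u = as.numeric(x$u)
  )
}

#' Read/write window tables as delimited text
#'
#' The tidy format is one row per (sample, evaluating window) pair with
#' columns `sample`, `window`, `eval_window`, `u`; the matrix format is a
#' `K x N` tab-separated block preceded by a header line `#n_k ...`.
#'
#' @param tab A `window_table`.
#' @param path File path.
#' @param format `"tidy"` or `"matrix"`.
#' @return `path` invisibly for the writer; a `window_table` for the reader.
#' @export
write_window_table <- function(tab, path, format = c("tidy", "matrix")) {
  format <- match.arg(format)
  stopifnot(inherits(tab, "window_table"))
  if (format == "tidy") {
    utils::write.table(tidy.window_table(tab), path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("#n_k\t", paste(tab$n_k, collapse = "\t")), con)
    utils::write.table(tab$u, con, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_window_table
#' @export
read_window_table <- function(path) {
  first <- readLines(path, n = 1)
  if (startsWith(first, "#n_k")) {
    n_k <- as.integer(strsplit(first, "\t")[[1]][-1])
    u <- as.matrix(utils::read.table(path, sep = "\t", skip = 1))
    return(window_table(u, n_k))
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  K <- max(df$eval_window)
  df <- df[order(df$window, df$sample, df$eval_window), ]
  n_k <- as.integer(table(factor(df$window[df$eval_window == 1],
                                 levels = seq_len(K))))
  u <- matrix(df$u, nrow = K)
  window_table(u, n_k)
}

## ---- lambda schedules -----------------------------------------------------

#' Gauss-Legendre lambda schedule
#'
#' The n-point Gauss-Legendre nodes and weights mapped from [-1, 1] to
#' [0, 1]; the weights sum to 1. Each `n` has a unique node/weight set, so
#' choosing `n` fixes the whole schedule.
#'
#' @param n Number of quadrature windows, 1..64.
#' @return A `lambda_schedule` in quadrature mode.
#' @export
gq_schedule <- function(n) {
  if (!is.numeric(n) || length(n) != 1 || n != round(n) || n < 1 || n > 64) {
    abort("n must be an integer in 1..64")
  }
  if (n == 1) {
    lam <- 0.5; w <- 1
  } else {
    g <- pracma::gaussLegendre(n, 0, 1)
    lam <- g$x; w <- g$w
  }
  structure(list(mode = "gauss_quadrature", lambdas = lam, weights = w,
                 n = as.integer(n)),
            class = "lambda_schedule")
}

#' Explicit lambda schedule
#'
#' @param lambdas Numeric vector in [0, 1], strictly increasing.
#' @return A `lambda_schedule` in explicit mode.
#' @export
explicit_schedule <- function(lambdas) {
  stopifnot(all(lambdas >= 0), all(lambdas <= 1))
  if (length(lambdas) > 1 && any(diff(lambdas) <= 0)) {
    abort("lambdas must be strictly increasing")
  }
  structure(list(mode = "explicit", lambdas = lambdas, weights = NULL,
                 n = length(lambdas)),
            class = "lambda_schedule")
}

#' @export
print.lambda_schedule <- function(x, ...) {
  cat("Lambda schedule (", x$mode, "), n = ", x$n, "\n", sep = "")
  invisible(x)
}

## ---- MBAR -----------------------------------------------------------------

col_logsumexp <- function(M) {
  m <- apply(M, 2, max)
  m + log(colSums(exp(sweep(M, 2, m))))
}

mbar_log_denominators <- function(u, f, log_n) {
  col_logsumexp(sweep(-u, 1, f + log_n, "+"))
}

mbar_update <- function(u, f, log_n) {
  ld <- mbar_log_denominators(u, f, log_n)
  B <- -u - matrix(ld, nrow(u), ncol(u), byrow = TRUE)
  f_new <- -apply(B, 1, logsumexp)
  f_new - f_new[1]
}

#' Multistate Bennett acceptance ratio (MBAR)
#'
#' Solves the MBAR self-consistent equations for the dimensionless window
#' free energies `f_k` (with `f_1 = 0`), using self-consistent iteration
#' with an adaptive switch to Newton steps once the iterates are close.
#'
#' @param tab A [window_table()].
#' @param tol Convergence tolerance on the max change in dimensionless `f`.
#' @param max_iter Iteration cap; non-convergence is an error carrying the
#'   last residual.
#' @param temperature Kelvin, used only to convert to kcal/mol.
#' @return An `abfe_mbar` fit with per-window free energies (kcal/mol) and
#'   all pairwise differences; see [tidy.abfe_mbar()].
#' @export
mbar <- function(tab, tol = 1e-8, max_iter = 10000,
                 temperature = DEFAULT_TEMPERATURE) {
  stopifnot(inherits(tab, "window_table"))
  u <- tab$u
  K <- length(tab$n_k)
  log_n <- log(tab$n_k)
  f <- numeric(K)
  if (K == 1) {
    return(new_mbar_fit(tab, f, 0L, 0, temperature, converged = TRUE))
  }
  resid <- Inf
  newton_ok <- FALSE
  for (it in seq_len(max_iter)) {
    f_sc <- mbar_update(u, f, log_n)
    resid <- max(abs(f_sc - f))
    if (resid < tol) {
      return(new_mbar_fit(tab, f_sc, it, resid, temperature, converged = TRUE))
    }
    f_next <- f_sc
    # Newton refinement once self-consistent steps are in the basin
    if (newton_ok || resid < 0.5) {
      newton_ok <- TRUE
      stepped <- try(mbar_newton_step(u, f_sc, log_n), silent = TRUE)
      if (!inherits(stepped, "try-error") && all(is.finite(stepped))) {
        f_try <- stepped - stepped[1]
        r_try <- max(abs(mbar_update(u, f_try, log_n) - f_try))
        if (is.finite(r_try) && r_try < resid) f_next <- f_try
      }
    }
    f <- f_next
  }
  abort(sprintf("MBAR did not converge in %d iterations (residual %.3e)",
                max_iter, resid))
}

mbar_newton_step <- function(u, f, log_n) {
  K <- nrow(u)
  ld <- mbar_log_denominators(u, f, log_n)
  # c[i, n] = N_i exp(f_i - u_in) / denom_n ; columns sum to 1
  C <- exp(sweep(-u, 1, f + log_n, "+") -
             matrix(ld, K, ncol(u), byrow = TRUE))
  g <- rowSums(C) - exp(log_n)
  H <- diag(rowSums(C)) - C %*% t(C)
  delta <- solve(H[-1, -1, drop = FALSE], g[-1])
  f[-1] <- f[-1] - delta
  f
}

new_mbar_fit <- function(tab, f, iterations, residual, temperature,
                         converged) {
  rt <- rt_kcal(temperature)
  structure(list(f_reduced = f, f_kcal = f * rt, table = tab,
                 iterations = iterations, residual = residual,
                 temperature = temperature, converged = converged),
            class = "abfe_mbar")
}

#' @export
print.abfe_mbar <- function(x, ...) {
  cat("MBAR fit:", length(x$f_reduced), "windows; dG(1->K) =",
      sprintf("%.4f", mbar_dg(x)), "kcal/mol\n")
  invisible(x)
}

#' Free-energy difference between two windows of an MBAR fit
#'
#' @param fit An `abfe_mbar` object.
#' @param from,to Window indices (defaults: first to last).
#' @return Free-energy difference in kcal/mol.
#' @export
mbar_dg <- function(fit, from = 1, to = length(fit$f_reduced)) {
  stopifnot(inherits(fit, "abfe_mbar"))
  fit$f_kcal[to] - fit$f_kcal[from]
}

#' Tidy and glance methods for MBAR fits
#'
#' @param x An `abfe_mbar` fit.
#' @param ... Unused.
#' @return `tidy()`: one row per window with the dimensionless and kcal/mol
#'   free energies; `glance()`: one-row fit summary.
#' @export
tidy.abfe_mbar <- function(x, ...) {
  tibble::tibble(window = seq_along(x$f_reduced),
                 n_samples = x$table$n_k,
                 f_reduced = x$f_reduced,
                 f_kcal = x$f_kcal)
}

#' @rdname tidy.abfe_mbar
#' @export
glance.abfe_mbar <- function(x, ...) {
  tibble::tibble(n_windows = length(x$f_reduced),
                 n_samples = sum(x$table$n_k),
                 iterations = x$iterations,
                 residual = x$residual,
                 converged = x$converged,
                 temperature = x$temperature,
                 dg_kcal = mbar_dg(x))
}

#' Window overlap diagnostic
#'
#' Average MBAR weight that samples drawn in window `i` carry in window `j`.
#' Low values between adjacent windows flag poor phase-space overlap.
#'
#' @param fit An `abfe_mbar` fit.
#' @param warn_below Warn if the smallest adjacent-window overlap falls
#'   below this value.
#' @return A `K x K` matrix with rows summing to 1.
#' @export
mbar_overlap <- function(fit, warn_below = 0.01) {
  tab <- fit$table
  u <- tab$u
  K <- length(tab$n_k)
  ld <- mbar_log_denominators(u, fit$f_reduced, log(tab$n_k))
  # normalized sample weight in state j: W[j, n]
  W <- exp(sweep(-u, 1, fit$f_reduced, "+") -
             matrix(ld, K, ncol(u), byrow = TRUE))
  origin <- sample_windows_of(tab)
  O <- t(vapply(seq_len(K), function(i) {
    colMeans(t(W[, origin == i, drop = FALSE]))
  }, numeric(K)))
  if (K > 1) {
    adj <- vapply(seq_len(K - 1), function(i) min(O[i, i + 1], O[i + 1, i]),
                  numeric(1))
    if (min(adj) < warn_below) {
      warn(sprintf("poor window overlap: min adjacent overlap %.3g", min(adj)))
    }
  }
  O
}

## ---- BAR ------------------------------------------------------------------

#' Bennett acceptance ratio for two windows
#'
#' Independent of the multistate solver: for two states the MBAR equations
#' reduce to a single scalar self-consistency condition, solved here by
#' bracketed root finding. Agrees with [mbar()] on the same table to
#' solver tolerance.
#'
#' @param tab A two-window [window_table()].
#' @param temperature Kelvin.
#' @return Free-energy difference window 1 -> 2, kcal/mol.
#' @export
bar <- function(tab, temperature = DEFAULT_TEMPERATURE) {
  stopifnot(inherits(tab, "window_table"))
  if (length(tab$n_k) != 2) abort("bar() requires exactly two windows")
  u <- tab$u
  log_n <- log(tab$n_k)
  g <- function(f2) {
    ld <- mbar_log_denominators(u, c(0, f2), log_n)
    f2 + logsumexp(-u[2, ] - ld)
  }
  # bracket the root
  lo <- -1; hi <- 1
  while (g(lo) < 0 && lo > -1e4) lo <- lo * 2
  while (g(hi) > 0 && hi < 1e4) hi <- hi * 2
  root <- uniroot(g, c(lo, hi), tol = 1e-12)$root
  root * rt_kcal(temperature)
}

## ---- TI with Gaussian quadrature ------------------------------------------

#' Thermodynamic integration with Gaussian quadrature
#'
#' `dG = sum_i w_i <dU/dlambda>_i` over the Gauss-Legendre nodes of the
#' schedule.
#'
#' @param dudl_means Numeric vector of per-node mean dU/dlambda values,
#'   kcal/mol.
#' @param schedule A quadrature-mode [lambda_schedule()] with one node per
#'   mean.
#' @return Free-energy difference, kcal/mol.
#' @export
ti_gq <- function(dudl_means, schedule) {
  stopifnot(inherits(schedule, "lambda_schedule"))
  if (schedule$mode != "gauss_quadrature") {
    abort("ti_gq requires a gauss_quadrature schedule")
  }
  if (length(dudl_means) != schedule$n) {
    abort("need one dU/dlambda mean per quadrature node")
  }
  sum(schedule$weights * dudl_means)
}

#' TI-GQ from a window table carrying dU/dlambda samples
#'
#' @param tab A [window_table()] with `dudl` samples and a quadrature
#'   schedule.
#' @return Free-energy difference, kcal/mol.
#' @export
ti_gq_from_table <- function(tab) {
  stopifnot(inherits(tab, "window_table"))
  if (is.null(tab$dudl)) abort("table has no dU/dlambda samples")
  ti_gq(vapply(tab$dudl, mean, numeric(1)), tab$schedule)
}

#' Finite-difference estimate of <dU/dlambda>
#'
#' Approximates the derivative at `lambda` as `dG_BAR / dlambda`, where
#' `dG_BAR` is the BAR free-energy difference between two windows bracketing
#' `lambda` at `lambda -/+ delta_lambda/2`.
#'
#' @param sampler Function `(lambdas, ...)` returning a two-window
#'   [window_table()] sampled at the given lambda values.
#' @param lambda Point at which to estimate the derivative.
#' @param delta_lambda Bracket width (default 0.001).
#' @param ... Passed to `sampler`.
#' @param temperature Kelvin.
#' @return Estimated `<dU/dlambda>` in kcal/mol.
#' @export
fd_dudl <- function(sampler, lambda, delta_lambda = 0.001, ...,
                    temperature = DEFAULT_TEMPERATURE) {
  stopifnot(is.function(sampler), delta_lambda > 0)
  tab <- sampler(c(lambda - delta_lambda / 2, lambda + delta_lambda / 2), ...)
  bar(tab, temperature = temperature) / delta_lambda
}

## ---- uncertainties --------------------------------------------------------

#' Block-analysis uncertainty
#'
#' Splits a sample series into `n_blocks` contiguous equal blocks (any
#' remainder dropped from the front), recomputes the estimator on each
#' block, and reports `sd(block estimates) / sqrt(n_blocks)`.
#'
#' @param series Numeric vector of per-sample values.
#' @param n_blocks Number of blocks (>= 2).
#' @param estimator Function applied to each block (default [mean()]).
#' @return Uncertainty in the units of `estimator`.
#' @export
block_uncertainty <- function(series, n_blocks = 5, estimator = mean) {
  if (n_blocks < 2) abort("need at least 2 blocks")
  n <- length(series)
  if (n < n_blocks) abort("series shorter than the number of blocks")
  b <- n %/% n_blocks
  series <- tail(series, b * n_blocks)
  vals <- vapply(seq_len(n_blocks), function(i) {
    estimator(series[((i - 1) * b + 1):(i * b)])
  }, numeric(1))
  sd(vals) / sqrt(n_blocks)
}

# split a window table into n_blocks sub-tables, blocking each window's
# samples contiguously (remainder dropped from the front of each window)
split_table_blocks <- function(tab, n_blocks) {
  origin <- sample_windows_of(tab)
  lapply(seq_len(n_blocks), function(i) {
    keep <- unlist(lapply(seq_along(tab$n_k), function(k) {
      idx <- which(origin == k)
      b <- length(idx) %/% n_blocks
      if (b == 0) abort("too few samples per window for the block count")
      idx <- tail(idx, b * n_blocks)
      idx[((i - 1) * b + 1):(i * b)]
    }))
    window_table(tab$u[, keep, drop = FALSE],
                 vapply(seq_along(tab$n_k), function(k) {
                   sum(origin[keep] == k)
                 }, integer(1)),
                 schedule = tab$schedule,
                 dudl = if (is.null(tab$dudl)) NULL else
                   lapply(seq_along(tab$dudl), function(k) {
                     v <- tab$dudl[[k]]
                     b <- length(v) %/% n_blocks
                     tail(v, b * n_blocks)[((i - 1) * b + 1):(i * b)]
                   }))
  })
}

#' Free-energy estimate with block uncertainty
#'
#' Runs the chosen estimator on the full table for the value, and on
#' contiguous sample blocks for the uncertainty (the estimator is recomputed
#' per block; MBAR covariances are not propagated).
#'
#' @param tab A [window_table()].
#' @param method `"mbar"`, `"bar"` or `"ti_gq"`.
#' @param n_blocks Number of data blocks (user choice; default 5).
#' @param temperature Kelvin.
#' @param ... Passed to the estimator.
#' @return One-row tibble: `value`, `uncertainty` (kcal/mol), `method`,
#'   `blocks`.
#' @export
free_energy_estimate <- function(tab, method = c("mbar", "bar", "ti_gq"),
                                 n_blocks = 5,
                                 temperature = DEFAULT_TEMPERATURE, ...) {
  method <- match.arg(method)
  est <- switch(method,
    mbar = function(t) mbar_dg(mbar(t, temperature = temperature, ...)),
    bar = function(t) bar(t, temperature = temperature),
    ti_gq = function(t) ti_gq_from_table(t))
  value <- est(tab)
  blocks <- split_table_blocks(tab, n_blocks)
  bv <- vapply(blocks, est, numeric(1))
  tibble::tibble(value = value,
                 uncertainty = sd(bv) / sqrt(n_blocks),
                 method = toupper(sub("ti_gq", "TI-GQ", method)),
                 blocks = as.integer(n_blocks))
}

#' Replica mean and spread
#'
#' Mean and population standard deviation (divisor `n`) across independent
#' replica free energies — the convention used when an average row reports
#' its spread across replicas. Display columns are rounded to one decimal,
#' half away from zero.
#'
#' @param values Numeric vector of replica free energies (>= 2 values).
#' @return One-row tibble: `mean`, `spread`, `n_replicas`, `mean_1dp`,
#'   `spread_1dp`.
#' @export
replica_stats <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) abort("need at least 2 replicas")
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))
  tibble::tibble(mean = m, spread = s, n_replicas = length(values),
                 mean_1dp = round_half_away(m, 1),
                 spread_1dp = round_half_away(s, 1))
}
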