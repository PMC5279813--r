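## Binless WHAM (multi-state reweighting) over canonical replica-exchange
## energy records: self-consistent dimensionless free energies per
## temperature, pooled-sample weights at a target temperature, and
## multi-trajectory error bars.  Sample-based (binless) iteration with
## log-sum-exp stabilization; no bin-width hyperparameter.

#' Boltzmann constant in kcal/(mol K)
#' @export
KB_KCAL <- 0.0019872041

#' Solve the binless WHAM equations
#'
#' Pools all samples and iterates
#'   f_k <- -log sum_n exp(-beta_k E_n) / sum_m N_m exp(f_m - beta_m E_n)
#' until max |delta f_k| < tolerance, anchoring f_1 = 0.  Deterministic.
#'
#' @param records data.frame with columns `temperature` (K) and `energy`
#'   (kcal/mol), one row per sample (as from
#'   [generate_replica_energies()] / [read_replica_tsv()]).
#' @param tolerance convergence threshold on max |delta f|.
#' @param max_iter iteration cap; non-convergence is an error carrying the
#'   last residual.
#' @return a `wham` object: temperatures, f (dimensionless free energies,
#'   f[1] = 0), iterations, residual, and the pooled records.
#' @export
wham_solve <- function(records, tolerance = 1e-7, max_iter = 1e5) {
  stopifnot(all(c("temperature", "energy") %in% names(records)))
  if (!all(is.finite(records$energy))) stop("non-finite energies")
  temps <- sort(unique(records$temperature))
  K <- length(temps)
  beta <- 1 / (KB_KCAL * temps)
  E <- records$energy
  Nk <- as.numeric(table(factor(records$temperature, levels = temps)))
  if (K == 1) {
    return(structure(list(temperatures = temps, f = 0, iterations = 1L,
                          residual = 0, records = records,
                          kB = KB_KCAL),
                     class = "wham"))
  }
  ## minus_bE[n, k] = -beta_k * E_n
  minus_bE <- -outer(E, beta)
  f <- rep(0, K)
  logNk <- log(Nk)
  lse <- function(M) { # row-wise log-sum-exp of a matrix
    mx <- apply(M, 1, max)
    mx + log(rowSums(exp(M - mx)))
  }
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    ## log denominator per sample: log sum_m N_m exp(f_m - beta_m E_n)
    logden <- lse(sweep(minus_bE, 2, f + logNk, "+"))
    ## new f_k = -log sum_n exp(-beta_k E_n - logden_n)
    A <- minus_bE - logden
    mx <- apply(A, 2, max)
    fnew <- -(mx + log(colSums(exp(sweep(A, 2, mx)))))
    fnew <- fnew - fnew[1]
    resid <- max(abs(fnew - f))
    f <- fnew
    if (resid < tolerance) break
    if (iterations >= max_iter)
      stop(sprintf("WHAM failed to converge: residual %.3e after %d iterations",
                   resid, iterations))
  }
  structure(list(temperatures = temps, f = f, iterations = iterations,
                 residual = resid, records = records, kB = KB_KCAL),
            class = "wham")
}

#' @export
print.wham <- function(x, ...) {
  cat(sprintf("WHAM solution over %d temperature(s), %d pooled samples\n",
              length(x$temperatures), nrow(x$records)))
  cat(sprintf("  converged in %d iteration(s), residual %.2e\n",
              x$iterations, x$residual))
  for (k in seq_along(x$temperatures))
    cat(sprintf("  T = %7.2f K   f = %10.5f\n", x$temperatures[k], x$f[k]))
  invisible(x)
}

#' Pooled-sample weights at a target temperature
#'
#' w_n proportional to exp(-beta_T E_n) / sum_m N_m exp(f_m - beta_m E_n),
#' normalized to sum to 1, in the row order of the solved records.  At the
#' single simulated temperature this reduces exactly to uniform weights.
#'
#' @param solution a [wham_solve()] result.
#' @param t_target target temperature in K.
#' @return numeric vector of nonnegative weights summing to 1.
#' @export
weights_at <- function(solution, t_target) {
  stopifnot(inherits(solution, "wham"))
  E <- solution$records$energy
  temps <- solution$temperatures
  beta <- 1 / (solution$kB * temps)
  bT <- 1 / (solution$kB * t_target)
  if (length(temps) == 1) {
    if (abs(t_target - temps) > 1e-9)
      warning("single-temperature dataset reweighted to a different temperature")
    return(rep(1 / length(E), length(E)))
  }
  Nk <- as.numeric(table(factor(solution$records$temperature, levels = temps)))
  M <- sweep(-outer(E, beta), 2, solution$f + log(Nk), "+")
  mx <- apply(M, 1, max)
  logden <- mx + log(rowSums(exp(M - mx)))
  logw <- -bT * E - logden
  logw <- logw - max(logw)
  w <- exp(logw)
  w / sum(w)
}

#' Weighted ensemble average
#'
#' @param observable per-frame observable values.
#' @param weights per-frame weights (normalized internally).
#' @return sum(w * observable).
#' @export
reweighted_average <- function(observable, weights) {
  if (length(observable) != length(weights)) stop("length mismatch")
  w <- weights / sum(weights)
  sum(w * observable)
}

#' Mean and standard error across independent trajectories
#'
#' @param estimates per-trajectory estimates (>= 2).
#' @param method "sem" (standard error of the mean) or "jackknife"
#'   (leave-one-out jackknife standard error).
#' @return c(mean, err).
#' @export
trajectory_error <- function(estimates, method = c("sem", "jackknife")) {
  method <- match.arg(method)
  n <- length(estimates)
  if (n < 2) stop("need at least 2 trajectory estimates")
  m <- mean(estimates)
  err <- if (method == "sem") {
    stats::sd(estimates) / sqrt(n)
  } else {
    loo <- vapply(seq_len(n), function(i) mean(estimates[-i]), numeric(1))
    sqrt((n - 1) / n * sum((loo - mean(loo))^2))
  }
  c(mean = m, err = err)
}
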