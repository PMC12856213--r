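# EMSA quantification: the quadratic ligand-depletion (tight-binding)
# model and Kd estimation.
#
# With total DNA T0, total protein X and dissociation constant Kd, mass
# action for the 1:1 complex gives the bound fraction
#   Y = [ (T0 + X + Kd) - sqrt((T0 + X + Kd)^2 - 4 T0 X) ] / (2 T0),
# the physically admissible root of the quadratic in the complex
# concentration. No dilute-ligand approximation is made, which matters
# here because probe concentrations run through the same tens-of-nM range
# as the DNA (T0 = 20 nM in the titration design).

#' Bound fraction under the quadratic ligand-depletion model
#'
#' @param T0 Total DNA concentration (nM), > 0.
#' @param X Total protein concentration(s) (nM), >= 0. Vectorized.
#' @param Kd Dissociation constant (nM), >= 0.
#' @return Bound fraction(s) in `[0, 1]`; 0 at `X = 0`.
#' @examples
#' bound_fraction(20, c(0, 100), 10.79)
#' @export
bound_fraction <- function(T0, X, Kd) {
  if (!all(is.finite(T0), is.finite(X), is.finite(Kd))) {
    stop("concentrations must be finite")
  }
  if (T0 <= 0) stop("`T0` must be > 0")
  if (any(X < 0)) stop("`X` must be >= 0")
  if (Kd < 0) stop("`Kd` must be >= 0")
  txk <- T0 + X + Kd
  disc <- pmax(txk * txk - 4 * T0 * X, 0)
  y <- (txk - sqrt(disc)) / (2 * T0)
  pmin(pmax(y, 0), 1)
}

#' Bound fraction from gel band signals
#'
#' The free-DNA band shrinks as protein is added, so the bound fraction is
#' one minus the free-to-total signal ratio, clipped to `[0, 1]`.
#'
#' @param free_signal Free-band signal(s), arbitrary units.
#' @param total_signal Total-lane signal(s), same units, > 0.
#' @param tol Relative tolerance by which `free_signal` may exceed
#'   `total_signal` before erroring (densitometry noise).
#' @return Bound fraction(s) in `[0, 1]`.
#' @export
fraction_from_gel <- function(free_signal, total_signal, tol = 1e-6) {
  if (any(!is.finite(free_signal)) || any(!is.finite(total_signal))) {
    stop("signals must be finite")
  }
  if (any(total_signal <= 0)) stop("`total_signal` must be > 0")
  if (any(free_signal < 0)) stop("`free_signal` must be >= 0")
  if (any(free_signal > total_signal * (1 + tol))) {
    stop("`free_signal` exceeds `total_signal`")
  }
  pmin(pmax(1 - free_signal / total_signal, 0), 1)
}

#' Construct a titration series
#'
#' @param X Total protein concentrations (nM), non-negative, no
#'   duplicates; at least 3 points.
#' @param Y Bound fractions in `[0, 1]`, same length as `X`.
#' @param T0 Total DNA concentration (nM), > 0.
#' @return Object of class `titration_series` (points sorted by `X`).
#' @export
titration_series <- function(X, Y, T0) {
  stopifnot(is.numeric(X), is.numeric(Y), is.numeric(T0), length(T0) == 1L)
  if (length(X) != length(Y)) stop("`X` and `Y` must have equal length")
  if (length(X) < 3L) stop("a titration needs at least 3 points")
  if (!all(is.finite(X)) || any(X < 0)) stop("`X` must be finite and >= 0")
  if (anyDuplicated(X)) stop("`X` must be strictly increasing after sorting")
  if (!all(is.finite(Y)) || any(Y < 0 | Y > 1)) {
    stop("`Y` must lie in [0, 1]")
  }
  if (!is.finite(T0) || T0 <= 0) stop("`T0` must be > 0")
  ord <- order(X)
  structure(list(X = as.numeric(X[ord]), Y = as.numeric(Y[ord]),
                 T0 = as.numeric(T0)),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat("titration_series:", length(x$X), "points, T0 =", x$T0, "nM\n")
  print(data.frame(protein_nM = x$X, bound_fraction = x$Y))
  invisible(x)
}

#' Read a titration table from delimited text
#'
#' Accepts either columns `protein_nM` and `bound_fraction`, or columns
#' `protein_nM`, `free_signal`, `total_signal` (bound fractions are then
#' derived with [fraction_from_gel()]).
#'
#' @param path Path to a tab- or comma-delimited table with a header.
#' @param T0 Total DNA concentration (nM).
#' @param sep Field separator (default tab).
#' @return A [titration_series()].
#' @export
read_titration <- function(path, T0, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  tb <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!"protein_nM" %in% names(tb)) stop("missing column `protein_nM`")
  if ("bound_fraction" %in% names(tb)) {
    y <- tb$bound_fraction
  } else if (all(c("free_signal", "total_signal") %in% names(tb))) {
    y <- fraction_from_gel(tb$free_signal, tb$total_signal)
  } else {
    stop("need `bound_fraction` or `free_signal` + `total_signal` columns")
  }
  titration_series(tb$protein_nM, y, T0)
}

.rss_kd <- function(kd, X, Y, T0) {
  sum((Y - bound_fraction(T0, X, kd))^2)
}

.binding_fit <- function(Kd, Kd_ci = c(NA_real_, NA_real_), rss, converged,
                         n_boot = 0L, seed = NA_integer_, T0, n) {
  structure(list(Kd = Kd, Kd_ci = Kd_ci, rss = rss, converged = converged,
                 n_boot = n_boot, seed = seed, T0 = T0, n = n),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  if (!x$converged) {
    cat("binding_fit: did not converge (", x$n, " points )\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("binding_fit: Kd = %.4g nM (T0 = %g nM, %d points, RSS = %.3g)\n",
              x$Kd, x$T0, x$n, x$rss))
  if (x$n_boot > 0L) {
    cat(sprintf("  95%% bootstrap CI [%.4g, %.4g] nM (%d resamples, seed %d)\n",
                x$Kd_ci[1L], x$Kd_ci[2L], x$n_boot, x$seed))
  }
  invisible(x)
}

# Deterministic one-parameter least squares: coarse log-grid bracketing
# followed by golden-section/parabolic refinement inside the bracketing
# interval.
.fit_kd_core <- function(X, Y, T0, lo, hi, n_grid = 400L) {
  grid <- exp(seq(log(lo), log(hi), length.out = n_grid))
  v <- vapply(grid, function(kd) .rss_kd(kd, X, Y, T0), numeric(1L))
  i <- which.min(v)
  bl <- grid[max(1L, i - 1L)]
  bu <- grid[min(n_grid, i + 1L)]
  o <- stats::optimize(.rss_kd, interval = c(bl, bu), X = X, Y = Y, T0 = T0,
                       tol = max(1e-12, grid[i] * 1e-10))
  o
}

#' Fit the dissociation constant of a titration series
#'
#' Least-squares minimization of the residuals to [bound_fraction()] over
#' `Kd >= 0`, with `T0` fixed and known. The optimizer is a deterministic
#' derivative-free search (log-spaced bracketing grid plus golden-section
#' refinement), so repeated fits of the same series are identical. A
#' series with all-zero bound fractions carries no information about `Kd`
#' (the objective flattens in the large-`Kd` limit) and is returned with
#' `converged = FALSE`.
#'
#' @param series A [titration_series()].
#' @return A `binding_fit` with elements `Kd` (nM), `Kd_ci` (`NA` until
#'   [bootstrap_ci()]), `rss`, `converged`, `n_boot`, `seed`.
#' @examples
#' ts <- make_titration(Kd = 10.79, T0 = 20, noise_sd = 0, seed = 1)
#' fit_kd(ts)
#' @export
fit_kd <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  X <- series$X; Y <- series$Y; T0 <- series$T0
  n <- length(X)
  if (all(Y <= 0)) {
    return(.binding_fit(Kd = NA_real_, rss = sum(Y^2), converged = FALSE,
                        T0 = T0, n = n))
  }
  xpos <- X[X > 0]
  lo <- max(min(T0, min(xpos)) * 1e-6, 1e-9)
  hi <- max(xpos, T0) * 1e4
  o <- .fit_kd_core(X, Y, T0, lo, hi)
  kd <- o$minimum
  converged <- is.finite(o$objective) && kd < 0.99 * hi
  .binding_fit(Kd = kd, rss = o$objective, converged = converged,
               T0 = T0, n = n)
}

# Fast refit for bootstrap resamples: optimize within a wide bracket
# around the point estimate.
.refit_kd <- function(X, Y, T0, kd0) {
  if (all(Y <= 0)) return(NA_real_)
  stats::optimize(.rss_kd, interval = c(kd0 / 1000, kd0 * 1000),
                  X = X, Y = Y, T0 = T0, tol = kd0 * 1e-5)$minimum
}

# Gradient of the binding curve in Kd (central difference) and the
# resulting linearized standard error of the Kd estimate.
.kd_gradient <- function(T0, X, kd) {
  eps <- max(kd, 1e-6) * 1e-4
  (bound_fraction(T0, X, kd + eps) -
     bound_fraction(T0, X, max(kd - eps, 0))) / (2 * eps)
}

.kd_se <- function(T0, X, Y, kd) {
  g <- .kd_gradient(T0, X, kd)
  rss <- .rss_kd(kd, X, Y, T0)
  n <- length(Y)
  sqrt(rss / (n - 1L)) / sqrt(max(sum(g^2), 1e-300))
}

#' Residual-resampling bootstrap confidence interval for Kd
#'
#' Residuals of the point fit are resampled with replacement onto the
#' fitted curve and each pseudo-series is refit. Two small-sample
#' refinements, both standard for regression bootstraps, keep the
#' interval calibrated at typical titration sizes (8 points): the
#' resampling pool uses centered, leverage-studentized residuals
#' `r_i / sqrt(1 - h_i)` (hat values from the local linearization of the
#' binding curve), and the interval is the studentized bootstrap-t --
#' each resample's deviation is pivoted by its own linearized standard
#' error, so the randomness of the noise-variance estimate itself is
#' propagated into the interval. Resampled bound fractions are clipped
#' to `[0, 1]`, mirroring how measured fractions are bounded.
#' Reproducible under a fixed seed.
#'
#' @param series A [titration_series()].
#' @param n_boot Number of bootstrap resamples, >= 100.
#' @param seed Integer RNG seed.
#' @return A `binding_fit` with `Kd_ci` set.
#' @export
bootstrap_ci <- function(series, n_boot = 1000L, seed = 1L) {
  stopifnot(inherits(series, "titration_series"))
  if (!is.numeric(n_boot) || length(n_boot) != 1L || n_boot < 100) {
    stop("`n_boot` must be >= 100")
  }
  n_boot <- as.integer(n_boot)
  fit <- fit_kd(series)
  if (!fit$converged) stop("point fit did not converge; no CI available")
  X <- series$X; Y <- series$Y; T0 <- series$T0
  yhat <- bound_fraction(T0, X, fit$Kd)
  n <- length(Y)
  # leverage of each point under the linearization dY/dKd at the fit
  g <- .kd_gradient(T0, X, fit$Kd)
  h <- if (sum(g^2) > 0) g^2 / sum(g^2) else rep(0, n)
  res <- (Y - yhat) / sqrt(pmax(1 - h, .Machine$double.eps))
  res <- res - mean(res)
  se0 <- .kd_se(T0, X, Y, fit$Kd)
  if (se0 == 0) {  # noiseless series: degenerate interval at the estimate
    return(.binding_fit(Kd = fit$Kd, Kd_ci = c(fit$Kd, fit$Kd),
                        rss = fit$rss, converged = TRUE, n_boot = n_boot,
                        seed = as.integer(seed), T0 = T0, n = n))
  }
  tstat <- .with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      ys <- pmin(pmax(yhat + sample(res, n, replace = TRUE), 0), 1)
      kdb <- .refit_kd(X, ys, T0, fit$Kd)
      (kdb - fit$Kd) / max(.kd_se(T0, X, ys, kdb), 1e-12)
    }, numeric(1L))
  })
  q <- unname(stats::quantile(tstat, c(0.025, 0.975), na.rm = TRUE))
  ci <- c(min(fit$Kd - se0 * q[2L], fit$Kd), max(fit$Kd - se0 * q[1L], fit$Kd))
  .binding_fit(Kd = fit$Kd, Kd_ci = ci, rss = fit$rss, converged = TRUE,
               n_boot = n_boot, seed = as.integer(seed), T0 = T0, n = n)
}
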