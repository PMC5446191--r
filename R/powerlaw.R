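#' Log-likelihood of a discrete truncated power law
#'
#' Model: `P(X = k) = k^-alpha / Z(alpha)` for integers
#' `x_min <= k <= x_max`, with `Z` the finite normalizing sum. Durations
#' and sizes are integers, so discrete likelihoods are used throughout;
#' no continuous approximation.
#'
#' @param x integer samples (only those inside the window are used by the
#'   fitting functions; here all of `x` enters the likelihood).
#' @param alpha exponent.
#' @param x_min,x_max integer window bounds.
#' @return total log-likelihood.
#' @export
powerlaw_loglik <- function(x, alpha, x_min, x_max) {
  k <- x_min:x_max
  logz <- log(sum(k^(-alpha)))
  -alpha * sum(log(x)) - length(x) * logz
}

#' Fit a discrete truncated power law by maximum likelihood
#'
#' Maximizes the discrete truncated power-law likelihood over the exponent
#' by bounded one-dimensional optimization (tolerance recorded in the
#' result). At least 50 in-window samples are required for a reported fit.
#' When every sample sits at `x_min` there is no slope information and the
#' optimizer runs to its upper bound; the fit is then flagged degenerate.
#'
#' @param x positive integer samples.
#' @param x_min,x_max fit window (samples outside are dropped).
#' @param alpha_max upper optimization bound for the exponent.
#' @return an object of class `powerlaw_fit`: list with `exponent`,
#'   `x_min`, `x_max`, `n_in_window`, `loglik`, `degenerate`, `tol`.
#' @export
#' @examples
#' s <- sample_discrete_powerlaw(1.5, 1, 1000, n = 2000, seed = 1)
#' fit_truncated_powerlaw(s, 1, 1000)$exponent
fit_truncated_powerlaw <- function(x, x_min, x_max, alpha_max = 20) {
  if (x_min >= x_max) stop("x_min must be smaller than x_max")
  xs <- x[x >= x_min & x <= x_max]
  if (length(xs) < 50) {
    stop("only ", length(xs), " samples inside [", x_min, ", ", x_max,
         "]; at least 50 are required")
  }
  tol <- 1e-6
  opt <- stats::optimize(function(a) powerlaw_loglik(xs, a, x_min, x_max),
                         interval = c(1 + 1e-8, alpha_max),
                         maximum = TRUE, tol = tol)
  degenerate <- all(xs == x_min) || opt$maximum > alpha_max - 0.01
  structure(
    list(exponent = opt$maximum, x_min = as.integer(x_min),
         x_max = as.integer(x_max), n_in_window = length(xs),
         loglik = opt$objective, degenerate = degenerate, tol = tol,
         model = "truncated_powerlaw"),
    class = "powerlaw_fit"
  )
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat("Discrete ", x$model, " fit: exponent = ", round(x$exponent, 4),
      " on [", x$x_min, ", ", x$x_max, "], n = ", x$n_in_window,
      ", loglik = ", round(x$loglik, 2),
      if (isTRUE(x$degenerate)) " (degenerate)" else "", "\n", sep = "")
  invisible(x)
}

#' Log-likelihood of a discrete power law with exponential cutoff
#'
#' Model: `P(X = k)` proportional to `k^-alpha * exp(-beta k)` for integers
#' `k >= x_min`. The normalizer is computed by direct summation truncated
#' at `k_max`, which must be large enough that the neglected tail mass is
#' negligible (for `beta > 0` the tail decays geometrically).
#'
#' @param x integer samples, all `>= x_min`.
#' @param alpha power-law part of the exponent.
#' @param beta exponential cutoff rate (`beta = 0` with `k_max = x_max`
#'   recovers the truncated pure power-law likelihood).
#' @param x_min lower cutoff.
#' @param k_max summation bound of the normalizer.
#' @return total log-likelihood.
#' @export
expcutoff_loglik <- function(x, alpha, beta, x_min, k_max) {
  k <- x_min:k_max
  z <- sum(k^(-alpha) * exp(-beta * k))
  if (!is.finite(z) || z <= 0) return(-Inf)
  -alpha * sum(log(x)) - beta * sum(x) - length(x) * log(z)
}

#' Fit a discrete power law with exponential cutoff
#'
#' Joint maximum-likelihood fit of `(alpha*, beta*)` by bounded
#' two-dimensional optimization (L-BFGS-B). The same lower cutoff is kept
#' as for the pure power law and the upper cutoff is removed; the
#' normalizer is summed up to `k_max`.
#'
#' @param x positive integer samples.
#' @param x_min lower cutoff (samples below are dropped).
#' @param k_max normalizer summation bound; defaults to ten times the
#'   largest sample (at least 1e5).
#' @return an object of class `expcutoff_fit`: list with `alpha_star`,
#'   `beta_star`, `x_min`, `n`, `loglik`, `k_max`, `convergence`.
#' @export
fit_powerlaw_expcutoff <- function(x, x_min, k_max = NULL) {
  xs <- x[x >= x_min]
  if (length(xs) < 50) {
    stop("only ", length(xs), " samples >= ", x_min,
         "; at least 50 are required")
  }
  if (is.null(k_max)) k_max <- max(1e5, 10 * max(xs))
  nll <- function(par) -expcutoff_loglik(xs, par[1], par[2], x_min, k_max)
  opt <- stats::optim(c(1.5, 1 / mean(xs)), nll, method = "L-BFGS-B",
                      lower = c(1e-4, 1e-9), upper = c(20, 5),
                      control = list(factr = 1e7))
  if (opt$convergence != 0) {
    warning("exponential-cutoff fit did not converge cleanly: ",
            opt$convergence, " (", opt$message, ")")
  }
  structure(
    list(alpha_star = opt$par[1], beta_star = opt$par[2],
         x_min = as.integer(x_min), n = length(xs), loglik = -opt$value,
         k_max = k_max, convergence = opt$convergence,
         model = "powerlaw_expcutoff"),
    class = "expcutoff_fit"
  )
}

#' @export
print.expcutoff_fit <- function(x, ...) {
  cat("Discrete power law with exponential cutoff: alpha* = ",
      round(x$alpha_star, 4), ", beta* = ", signif(x$beta_star, 4),
      ", x_min = ", x$x_min, ", n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' Fit a discrete (truncated) exponential distribution
#'
#' Model: `P(X = k)` proportional to `exp(-lambda k)` on the integer
#' window. The standard alternative model in the power-law-versus-
#' exponential likelihood-ratio comparison.
#'
#' @param x positive integer samples.
#' @param x_min,x_max fit window; `x_max = NULL` means untruncated
#'   (geometric tail, closed-form normalizer).
#' @return list with `lambda`, `x_min`, `x_max`, `n_in_window`, `loglik`,
#'   class `exponential_fit`.
#' @export
fit_discrete_exponential <- function(x, x_min, x_max = NULL) {
  xs <- if (is.null(x_max)) x[x >= x_min] else x[x >= x_min & x <= x_max]
  if (length(xs) < 2) stop("too few in-window samples")
  loglik <- function(lam) {
    if (is.null(x_max)) {
      # sum_{k >= x_min} e^(-lam k) = e^(-lam x_min) / (1 - e^(-lam))
      logz <- -lam * x_min - log(1 - exp(-lam))
    } else {
      logz <- log(sum(exp(-lam * (x_min:x_max))))
    }
    -lam * sum(xs) - length(xs) * logz
  }
  opt <- stats::optimize(loglik, interval = c(1e-9, 20), maximum = TRUE,
                         tol = 1e-9)
  structure(
    list(lambda = opt$maximum, x_min = as.integer(x_min),
         x_max = if (is.null(x_max)) NULL else as.integer(x_max),
         n_in_window = length(xs), loglik = opt$objective,
         model = "discrete_exponential"),
    class = "exponential_fit"
  )
}

#' Log-likelihood ratio between two fitted models
#'
#' `R = loglik(model_a) - loglik(model_b)` on the shared in-window sample
#' set; positive `R` favors the first model. By convention the power law
#' is passed first, so `R > 0` means the data look power-law distributed
#' and `R < 0` favors the alternative. Both fits must have been computed
#' on the same samples (same window and count).
#'
#' @param model_a,model_b fitted model objects carrying `loglik`,
#'   `n_in_window` (or `n`) and window fields.
#' @return the signed log-likelihood ratio.
#' @export
loglik_ratio <- function(model_a, model_b) {
  n_of <- function(m) if (!is.null(m$n_in_window)) m$n_in_window else m$n
  if (n_of(model_a) != n_of(model_b)) {
    stop("models were fitted on different sample counts (",
         n_of(model_a), " vs ", n_of(model_b),
         "); fit both on the same in-window samples")
  }
  model_a$loglik - model_b$loglik
}

#' Exponentially binned empirical density
#'
#' Histograms heavy-tailed samples with logarithmically spaced bin edges
#' `10^(k * b_s)` and returns the per-bin density (count divided by bin
#' width and total sample count) at the geometric-mean bin centers.
#' Leading empty bins are dropped, which is why left cutoffs near 1 are
#' not visible in binned plots.
#'
#' @param x positive samples.
#' @param b_s log-10 bin width (default 0.1).
#' @return an object of class `binned_distribution`: data.frame with
#'   `center`, `density`, `count`, `width`, plus attribute `b_s`.
#' @export
exponential_binning <- function(x, b_s = 0.1) {
  if (b_s <= 0) stop("b_s must be positive")
  if (any(x < 1)) stop("samples must be >= 1")
  kmax <- ceiling(log10(max(x)) / b_s) + 1L
  edges <- 10^(b_s * (0:kmax))
  # right-closed bins [edge_k, edge_{k+1}); top edge inclusive via epsilon
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = kmax)
  widths <- diff(edges)
  centers <- sqrt(edges[-length(edges)] * edges[-1])
  first <- which(counts > 0)[1]
  keep <- first:max(which(counts > 0))
  structure(
    data.frame(center = centers[keep],
               density = counts[keep] / (widths[keep] * length(x)),
               count = counts[keep], width = widths[keep]),
    b_s = b_s, n = length(x),
    class = c("binned_distribution", "data.frame")
  )
}

#' Crackling-noise prediction for the mean-size-versus-duration exponent
#'
#' For a system at criticality the average avalanche size is predicted to
#' scale with duration as `T^((alpha - 1) / (tau - 1))`, where `alpha` and
#' `tau` are the duration and size distribution exponents.
#'
#' @param alpha duration exponent.
#' @param tau size exponent (must exceed 1).
#' @return the predicted scaling exponent `(alpha - 1) / (tau - 1)`.
#' @export
#' @examples
#' crackling_prediction(1.45, 1.28)  # about 1.61
crackling_prediction <- function(alpha, tau) {
  if (tau <= 1) stop("tau must exceed 1")
  (alpha - 1) / (tau - 1)
}

#' Mean avalanche size as a function of duration
#'
#' Groups avalanches by duration, averages their sizes, and fits a line to
#' `log10(mean S)` versus `log10(T)` by least squares over the duration
#' window. The slope is the empirical scaling exponent `gamma_data`,
#' comparable against [crackling_prediction()].
#'
#' @param set an `avalanche_set`.
#' @param fit_window duration window `c(T_min, T_max)` for the regression.
#' @return list with `curve` (data.frame `T`, `mean_S`, `n`), `gamma`
#'   (fitted slope) and `intercept`.
#' @export
mean_size_vs_duration <- function(set, fit_window = c(6, 60)) {
  stopifnot(inherits(set, "avalanche_set"))
  mean_S <- tapply(set$S, set$T, mean)
  curve <- data.frame(T = as.integer(names(mean_S)),
                      mean_S = as.numeric(mean_S),
                      n = as.integer(table(set$T)))
  inw <- curve$T >= fit_window[1] & curve$T <= fit_window[2]
  if (sum(inw) < 2) {
    stop("fewer than 2 distinct durations inside the fit window")
  }
  fit <- stats::lm(log10(mean_S) ~ log10(T), data = curve[inw, ])
  list(curve = curve, gamma = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}

#' Sample from a discrete (truncated) power law
#'
#' Inverse-CDF sampling on the exactly normalized mass function
#' `P(X = k)` proportional to `k^-exponent` on `[x_min, x_max]`. With
#' `x_max = NULL` the support is capped at `x_cap` (the neglected tail
#' mass is tiny for exponents well above 1). Used as the test fixture
#' generator for the fitting routines.
#'
#' @param exponent power-law exponent (> 1).
#' @param x_min,x_max integer support bounds; `x_max = NULL` for an
#'   (effectively) unbounded tail.
#' @param n number of draws.
#' @param seed integer seed.
#' @param x_cap support cap used when `x_max` is NULL.
#' @return integer vector of samples.
#' @export
sample_discrete_powerlaw <- function(exponent, x_min, x_max = NULL, n,
                                     seed, x_cap = 1e6) {
  if (exponent <= 1 && is.null(x_max)) {
    stop("exponent must exceed 1 for an unbounded tail")
  }
  if (n < 1) stop("n must be at least 1")
  hi <- if (is.null(x_max)) as.integer(x_cap) else as.integer(x_max)
  k <- x_min:hi
  pmf <- k^(-exponent)
  cdf <- cumsum(pmf / sum(pmf))
  with_seed(seed, {
    u <- stats::runif(n)
    k[pmin(findInterval(u, cdf) + 1L, length(k))]
  })
}
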