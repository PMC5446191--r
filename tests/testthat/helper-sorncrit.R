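# Shared fixtures: small networks and streams built in code.

tiny_params <- function(N_E = 40L, ...) sorn_params(N_E = N_E, ...)

# a tiny state with a few active units, useful when noise is off
poked_state <- function(params = tiny_params(), seed = 1, n_active = 6L) {
  st <- init_network(params, seed = seed)
  st$x[seq_len(n_active)] <- 1L
  st
}

# naive per-step avalanche scan, independent of the rle-based detector
naive_avalanches <- function(activity, theta) {
  out <- list()
  run_start <- NA
  for (t in seq_along(activity)) {
    if (activity[t] > theta) {
      if (is.na(run_start)) run_start <- t
    } else if (!is.na(run_start)) {
      out[[length(out) + 1L]] <- c(t0 = run_start, T = t - run_start,
                                   S = sum(activity[run_start:(t - 1)] - theta))
      run_start <- NA
    }
  }
  # censor: drop a run touching the start, and any run still open at the end
  df <- do.call(rbind, out)
  if (is.null(df)) {
    return(data.frame(t0 = integer(0), T = integer(0), S = integer(0)))
  }
  df <- as.data.frame(df)
  df[df$t0 > 1, , drop = FALSE]
}

# inverse-CDF sampler for the discrete power law with exponential cutoff
sample_expcutoff <- function(alpha, beta, x_min, n, seed, cap = 1e5) {
  k <- x_min:cap
  pmf <- k^(-alpha) * exp(-beta * k)
  cdf <- cumsum(pmf / sum(pmf))
  withr::with_seed(seed, {
    u <- stats::runif(n)
    k[pmin(findInterval(u, cdf) + 1L, length(k))]
  })
}

# an avalanche_set wrapper around synthetic (T, S) events
synthetic_avalanche_set <- function(T, S, theta = 0L, trace_length = NA_integer_) {
  structure(data.frame(t0 = seq_along(T), T = as.integer(T),
                       S = as.integer(S)),
            theta = theta, trace_length = trace_length,
            class = c("avalanche_set", "data.frame"))
}
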