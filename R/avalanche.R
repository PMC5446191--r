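#' Activity threshold at half the mean activity
#'
#' The standard avalanche threshold: half of the mean network activity,
#' rounded to the nearest integer (half-up, so `2.5` rounds to 3). For a
#' homeostatic network with target rate 0.1 and 200 excitatory units the
#' mean activity is about 20 spikes/step and the threshold about 10.
#'
#' @param activity integer activity trace `a(t)`.
#' @return integer threshold.
#' @export
half_mean_threshold <- function(activity) {
  if (!length(activity)) stop("activity trace is empty")
  round_half_up(mean(activity) / 2)
}

#' Activity threshold at a percentile of the activity distribution
#'
#' @param activity integer activity trace.
#' @param pct percentile in (0, 100).
#' @return integer threshold (rounded half-up).
#' @export
percentile_threshold <- function(activity, pct) {
  if (!length(activity)) stop("activity trace is empty")
  if (pct <= 0 || pct >= 100) stop("pct must lie strictly between 0 and 100")
  round_half_up(stats::quantile(activity, pct / 100, names = FALSE))
}

# deterministic round-half-up (R's round() rounds half to even)
round_half_up <- function(x) as.integer(floor(x + 0.5))

#' Detect neuronal avalanches in an activity trace
#'
#' An avalanche is a maximal run of steps with activity strictly above the
#' threshold `theta` (equality is not exceedance). Its duration `T` is the
#' run length and its size `S` the summed exceedance
#' `sum(a(t) - theta)` over the run. Runs touching the first or last step
#' of the trace are censored (their true duration is unknown) and dropped.
#'
#' @param activity integer activity trace.
#' @param theta non-negative integer threshold.
#' @return an object of class `avalanche_set`: a data.frame with columns
#'   `t0` (1-based start step within the trace), `T` and `S`, with
#'   attributes `theta` and `trace_length`.
#' @export
#' @examples
#' a <- c(0, 3, 5, 2, 0)
#' av <- detect_avalanches(a, theta = 1)
#' av$T  # 3
#' av$S  # (3-1) + (5-1) + (2-1) = 7
detect_avalanches <- function(activity, theta) {
  if (theta < 0) stop("theta must be non-negative")
  above <- activity > theta
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  # censor runs in progress at either trace boundary
  keep <- keep & starts > 1L & ends < length(activity)
  starts <- starts[keep]
  ends <- ends[keep]
  if (length(starts)) {
    cs <- cumsum(as.numeric(activity - theta))
    S <- cs[ends] - c(0, cs)[starts]
  } else {
    S <- numeric(0)
  }
  structure(
    data.frame(t0 = as.integer(starts), T = as.integer(ends - starts + 1L),
               S = as.integer(round(S))),
    theta = as.integer(theta), trace_length = length(activity),
    class = c("avalanche_set", "data.frame")
  )
}

#' @export
print.avalanche_set <- function(x, ...) {
  cat("Avalanche set:", nrow(x), "avalanches from a trace of",
      attr(x, "trace_length"), "steps (theta =", attr(x, "theta"), ")\n")
  if (nrow(x)) {
    cat("  duration range:", min(x$T), "-", max(x$T),
        "; size range:", min(x$S), "-", max(x$S), "\n")
  }
  invisible(x)
}

#' Alternative avalanche size without threshold subtraction
#'
#' Computes `S' = sum(a(t))` over each avalanche in `set`, i.e. the raw
#' spike count rather than the exceedance above threshold. `S' >= S`
#' always, and the two definitions coincide at `theta = 0`.
#'
#' @param activity the activity trace the avalanches were detected in.
#' @param set an `avalanche_set` from [detect_avalanches()].
#' @return integer vector of alternative sizes, one per avalanche.
#' @export
alternative_size <- function(activity, set) {
  stopifnot(inherits(set, "avalanche_set"))
  if (attr(set, "trace_length") != length(activity)) {
    stop("activity trace length does not match the avalanche set")
  }
  vapply(seq_len(nrow(set)), function(k) {
    sum(activity[set$t0[k]:(set$t0[k] + set$T[k] - 1L)])
  }, numeric(1))
}
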