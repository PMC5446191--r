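#' Simulate a SORN for many steps
#'
#' Advances the network `n_steps` steps with the compiled stepping engine,
#' recording the activity trace `a(t)` (number of excitatory spikes per
#' step), the E-to-E connection fraction at a configurable stride, and
#' optionally the full spike raster and the readout features `x'(t)`.
#' Randomness flows through two named, seeded streams (membrane noise and
#' structural-plasticity choices), so runs are reproducible and the
#' noise stream can be shared between a plastic and a frozen copy of the
#' same network.
#'
#' @param state a `sorn_state` from [init_network()] or a previous call.
#' @param n_steps number of steps to simulate (at least 1).
#' @param noise a [noise_model()]; default Gaussian with variance 0.05.
#' @param flags a [plasticity_flags()] object.
#' @param input optional `sorn_input` from [letters_to_input()]; its letter
#'   stream must cover at least `n_steps` steps.
#' @param noise_seed,sp_seed integer seeds of the two named RNG streams.
#' @param record_raster record the spike raster (memory scales with the
#'   total spike count; avoid for multi-million-step runs).
#' @param record_features record the readout feature matrix `x'(t)`
#'   (`n_steps` by `N_E`; intended for the short readout windows).
#' @param features_with_noise include the step's membrane-noise draw in
#'   the recorded feature. By default `x'(t)` is the deterministic
#'   thresholded recurrent drive (external input and noise both removed),
#'   which is what a downstream readout can actually exploit.
#' @param conn_stride record the connection fraction whenever the model
#'   time is a multiple of this stride; 0 disables.
#' @param count_units optional unit indices (1-based) counted into the
#'   activity trace; default all excitatory units.
#' @return a list with `state` (the advanced `sorn_state`) and `record`
#'   (class `sorn_record`): `activity`, `t_start`, `conn_fraction`,
#'   `conn_step`, `seeds` and optionally `raster` (data.frame) and
#'   `features` (binary matrix).
#' @export
#' @examples
#' st <- init_network(sorn_params(N_E = 50), seed = 1)
#' run <- simulate_sorn(st, 1000, noise_seed = 2, sp_seed = 3)
#' mean(run$record$activity) / 50  # approaches mu_ip = 0.1 as homeostasis acts
simulate_sorn <- function(state, n_steps, noise = noise_model("gaussian"),
                          flags = plasticity_flags(), input = NULL,
                          noise_seed = 1L, sp_seed = 2L,
                          record_raster = FALSE, record_features = FALSE,
                          features_with_noise = FALSE,
                          conn_stride = 1000L, count_units = NULL) {
  stopifnot(inherits(state, "sorn_state"))
  n_steps <- as.integer(n_steps)
  if (n_steps < 1L) stop("n_steps must be at least 1")
  p <- state$params

  letters <- integer(0)
  subsets <- list()
  amplitude <- 0
  if (!is.null(input)) {
    stopifnot(inherits(input, "sorn_input"))
    if (length(input$letters) < n_steps) {
      stop("input stream (", length(input$letters),
           " steps) is shorter than n_steps (", n_steps, ")")
    }
    letters <- as.integer(input$letters[seq_len(n_steps)])
    subsets <- lapply(input$subsets, function(s) as.integer(s) - 1L)
    amplitude <- input$amplitude
  }

  subset0 <- if (is.null(noise$active_subset)) {
    integer(0)
  } else {
    if (any(noise$active_subset > p$N_E)) {
      stop("noise active_subset contains indices beyond N_E")
    }
    as.integer(noise$active_subset) - 1L
  }
  noise_cpp <- list(
    kind = match(noise$kind, c("none", "gaussian", "random_spike")) - 1L,
    sd = sqrt(noise$sigma_sq), p_s = noise$p_s, subset = subset0,
    on_inhibitory = isTRUE(noise$inhibitory) && is.null(noise$active_subset)
  )
  rates <- list(eta_stdp = p$eta_stdp, eta_inh = p$eta_inh,
                eta_ip = p$eta_ip, eta_sp = p$eta_sp,
                p_sp = sp_probability(p$N_E, p$p_sp_200), mu_ip = p$mu_ip)
  flagv <- c(flags$stdp, flags$istdp, flags$sn, flags$sp, flags$ip)
  count0 <- if (is.null(count_units)) integer(0) else as.integer(count_units) - 1L

  res <- .sorn_run_cpp(state$W_EE, state$W_EI, state$W_IE, state$mask_EI,
                       state$x, state$y, state$T_E, state$T_I, state$H_ip,
                       state$t, n_steps, flagv, rates, noise_cpp,
                       letters, subsets, amplitude,
                       as.double(noise_seed), as.double(sp_seed),
                       record_raster, record_features,
                       isTRUE(features_with_noise),
                       as.integer(conn_stride), count0)

  new_state <- state
  new_state$x <- res$x
  new_state$y <- res$y
  new_state$W_EE <- res$W_EE
  new_state$W_EI <- res$W_EI
  new_state$T_E <- res$T_E
  new_state$t <- res$t

  record <- structure(
    list(activity = res$activity, t_start = state$t + 1L,
         conn_fraction = res$conn_fraction, conn_step = res$conn_step,
         final_conn_fraction = res$nnz / (p$N_E * (p$N_E - 1)),
         seeds = c(init = state$seed, noise = as.integer(noise_seed),
                   sp = as.integer(sp_seed)),
         N_E = p$N_E, N_I = p$N_I),
    class = "sorn_record"
  )
  if (record_raster) {
    record$raster <- data.frame(time_step = res$raster_t,
                                unit_index = res$raster_unit)
  }
  if (record_features) record$features <- res$features

  list(state = new_state, record = record)
}

#' @export
print.sorn_record <- function(x, ...) {
  cat("SORN simulation record:", length(x$activity), "steps from t =",
      x$t_start, "\n")
  cat("  mean activity:", round(mean(x$activity), 3), "spikes/step (",
      round(mean(x$activity) / x$N_E, 4), "per unit)\n")
  if (length(x$conn_fraction)) {
    cat("  final connection fraction:",
        round(x$conn_fraction[length(x$conn_fraction)], 4), "\n")
  }
  invisible(x)
}

#' Deep-copy a network state for checkpoint/clone protocols
#'
#' R lists copy on modify, so this simply returns its argument; it exists
#' to make the clone step of the frozen-network protocol explicit.
#'
#' @param state a `sorn_state`.
#' @return an independent copy of `state`.
#' @export
clone_state <- function(state) {
  stopifnot(inherits(state, "sorn_state"))
  state
}
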