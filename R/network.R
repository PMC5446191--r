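#' Initialize a SORN network state
#'
#' Draws the initial network: `W_EE` is a sparse Bernoulli(`p_ee_init`)
#' matrix without self-connections, `W_EI` a Bernoulli(`p_ei_init`) matrix,
#' and `W_IE` fully connected. All weights are drawn uniformly on
#' \[0, 0.1\] and each unit's incoming excitatory and incoming inhibitory
#' weights are then normalized to sum 1 separately. Excitatory thresholds
#' are uniform on \[0, `T_E_max`\], inhibitory thresholds uniform on
#' \[0, `T_I_max`\] and fixed for the whole run. Per-unit target rates
#' `H_ip` come from Normal(`mu_ip`, `sigma_ip_sq`), degenerate at `mu_ip`
#' when the variance is 0. Both state vectors start all-zero.
#'
#' @param params a [sorn_params()] object.
#' @param seed integer seed for the initialization draws.
#' @return an object of class `sorn_state`: a list with elements `x`, `y`,
#'   `W_EE`, `W_EI`, `W_IE`, `mask_EI` (fixed I-to-E structure), `T_E`,
#'   `T_I`, `H_ip`, `t` and `params`. Convention: `W[i, j]` is the synapse
#'   from unit `j` to unit `i`.
#' @export
#' @examples
#' st <- init_network(sorn_params(N_E = 50), seed = 1)
#' range(rowSums(st$W_EE))  # every connected row sums to 1
init_network <- function(params, seed) {
  stopifnot(inherits(params, "sorn_params"))
  ne <- params$N_E
  ni <- params$N_I
  with_seed(seed, {
    A_ee <- matrix(stats::runif(ne * ne) < params$p_ee_init, ne, ne)
    diag(A_ee) <- FALSE
    W_ee <- matrix(stats::runif(ne * ne, 0, 0.1), ne, ne) * A_ee
    A_ei <- matrix(stats::runif(ne * ni) < params$p_ei_init, ne, ni)
    W_ei <- matrix(stats::runif(ne * ni, 0, 0.1), ne, ni) * A_ei
    W_ie <- matrix(stats::runif(ni * ne, 0, 0.1), ni, ne)
    T_E <- stats::runif(ne, 0, params$T_E_max)
    T_I <- stats::runif(ni, 0, params$T_I_max)
    H_ip <- if (params$sigma_ip_sq > 0) {
      stats::rnorm(ne, params$mu_ip, sqrt(params$sigma_ip_sq))
    } else {
      rep(params$mu_ip, ne)
    }
    structure(
      list(x = integer(ne), y = integer(ni),
           W_EE = synaptic_normalization(W_ee),
           W_EI = synaptic_normalization(W_ei),
           W_IE = synaptic_normalization(W_ie),
           mask_EI = matrix(as.integer(A_ei), ne, ni),
           T_E = T_E, T_I = T_I, H_ip = H_ip, t = 0L,
           params = params, seed = as.integer(seed)),
      class = "sorn_state"
    )
  })
}

#' @export
print.sorn_state <- function(x, ...) {
  cat("SORN state: N_E =", x$params$N_E, ", N_I =", x$params$N_I,
      ", t =", x$t, "\n")
  cat("  E->E connection fraction:", round(connection_fraction(x), 4), "\n")
  cat("  active units:", sum(x$x), "excitatory,", sum(x$y), "inhibitory\n")
  invisible(x)
}

#' Fraction of existing E-to-E synapses
#'
#' @param state a `sorn_state`.
#' @return number of nonzero `W_EE` entries divided by the number of
#'   ordered off-diagonal unit pairs `N_E (N_E - 1)`.
#' @export
connection_fraction <- function(state) {
  ne <- state$params$N_E
  sum(state$W_EE > 0) / (ne * (ne - 1))
}

#' One state update of all units
#'
#' Applies the threshold dynamics: an excitatory unit fires when its summed
#' excitatory drive minus inhibitory drive, plus external input and noise,
#' reaches its threshold; an inhibitory unit fires when its excitatory
#' drive plus noise reaches its fixed threshold. Inhibition is
#' instantaneous: the inhibitory state follows the newly computed
#' excitatory state within the same step, so the excitatory-inhibitory
#' loop acts with a one-step delay. The step-function convention is
#' `Theta(0) = 1` (drive exactly at threshold fires). The input state is
#' not modified.
#'
#' @param state a `sorn_state`.
#' @param u_ext external input vector of length `N_E` (default all zero).
#' @param xi_E,xi_I noise realizations for excitatory / inhibitory units
#'   (default all zero). Supplying explicit draws keeps this a pure
#'   function; random draws belong to the caller.
#' @return list with binary vectors `x` and `y`, the next states.
#' @export
update_states <- function(state, u_ext = NULL, xi_E = NULL, xi_I = NULL) {
  ne <- state$params$N_E
  ni <- state$params$N_I
  if (is.null(u_ext)) u_ext <- numeric(ne)
  if (is.null(xi_E)) xi_E <- numeric(ne)
  if (is.null(xi_I)) xi_I <- numeric(ni)
  stopifnot(length(u_ext) == ne, all(is.finite(u_ext)))
  drive_E <- as.numeric(state$W_EE %*% state$x) -
    as.numeric(state$W_EI %*% state$y) + u_ext + xi_E - state$T_E
  x_next <- as.integer(drive_E >= 0)
  drive_I <- as.numeric(state$W_IE %*% x_next) + xi_I - state$T_I
  list(x = x_next, y = as.integer(drive_I >= 0))
}

#' Spike-timing dependent plasticity on E-to-E weights
#'
#' For every existing synapse from `j` to `i`, the weight changes by
#' `eta_stdp * (x_i(t) x_j(t-1) - x_j(t) x_i(t-1))`: potentiation when the
#' presynaptic unit fired one step before the postsynaptic one, depression
#' for the reversed order. Only existing (nonzero) synapses are updated,
#' and entries driven to zero or below are pruned (removed from the
#' structure; they can only reappear through structural plasticity).
#'
#' @param W_EE weight matrix, entry `[i, j]` = synapse from `j` to `i`.
#' @param x_now binary excitatory state at the current step.
#' @param x_prev binary excitatory state one step earlier.
#' @param eta_stdp learning rate.
#' @return the updated, pruned weight matrix.
#' @export
stdp_update <- function(W_EE, x_now, x_prev, eta_stdp) {
  stopifnot(length(x_now) == nrow(W_EE), length(x_prev) == nrow(W_EE))
  delta <- eta_stdp * (outer(x_now, x_prev) - outer(x_prev, x_now))
  W <- W_EE + delta * (W_EE > 0)
  W[W <= 0] <- 0
  W
}

#' Inhibitory spike-timing dependent plasticity on I-to-E weights
#'
#' For every existing I-to-E synapse whose presynaptic inhibitory unit
#' fired at the previous step, the weight changes by
#' `-eta_inh * (1 - x_i(t) (1 + 1 / mu_ip))`: it grows by `eta_inh/mu_ip`
#' when the postsynaptic excitatory unit fired anyway, and shrinks by
#' `eta_inh` when the inhibition kept it silent. Weights are floored at 0
#' but the connection slot is retained (the rule can raise it again).
#'
#' @param W_EI weight matrix, entry `[i, j]` = synapse from inhibitory `j`
#'   to excitatory `i`.
#' @param x_now binary excitatory state at the current step.
#' @param y_prev binary inhibitory state one step earlier.
#' @param eta_inh learning rate.
#' @param mu_ip network target rate; must be positive (it divides the
#'   potentiation term).
#' @param mask optional logical/integer matrix marking existing synapses;
#'   defaults to `W_EI > 0`.
#' @return the updated weight matrix.
#' @export
istdp_update <- function(W_EI, x_now, y_prev, eta_inh, mu_ip,
                         mask = NULL) {
  if (mu_ip <= 0) stop("mu_ip must be positive: the rule divides by it")
  stopifnot(length(x_now) == nrow(W_EI), length(y_prev) == ncol(W_EI))
  if (is.null(mask)) mask <- W_EI > 0
  delta <- -eta_inh * outer(1 - x_now * (1 + 1 / mu_ip), y_prev)
  W <- W_EI + delta * (mask > 0)
  W[W < 0] <- 0
  W
}

#' Synaptic normalization
#'
#' Rescales every row (one unit's incoming weights of one class) to sum 1.
#' Rows summing to zero are left unchanged. Applied separately to the
#' incoming excitatory and incoming inhibitory weights of each unit.
#'
#' @param W a non-negative weight matrix.
#' @return the row-normalized matrix.
#' @export
synaptic_normalization <- function(W) {
  if (any(W < 0)) stop("synaptic_normalization expects non-negative weights")
  s <- rowSums(W)
  scale <- ifelse(s > 0, 1 / s, 1)
  W * scale
}

#' Structural plasticity: stochastic synapse creation
#'
#' With probability `p_sp` (one Bernoulli trial per call/time step), one
#' unconnected ordered off-diagonal pair is chosen uniformly at random and
#' a new synapse of weight `eta_sp` is created. When no unconnected pair
#' exists the call is a no-op. Uses R's RNG.
#'
#' @param W_EE square weight matrix with zero diagonal.
#' @param p_sp per-step creation probability (see [sp_probability()]).
#' @param eta_sp weight of the created synapse.
#' @return the (possibly) augmented matrix.
#' @export
structural_plasticity <- function(W_EE, p_sp, eta_sp = 0.001) {
  ne <- nrow(W_EE)
  if (stats::runif(1) >= p_sp) return(W_EE)
  open <- which(W_EE == 0)
  open <- open[((open - 1) %% ne) + 1 != ((open - 1) %/% ne) + 1]  # drop diag
  if (!length(open)) return(W_EE)
  W_EE[open[[sample.int(length(open), 1)]]] <- eta_sp
  W_EE
}

#' Intrinsic plasticity: homeostatic threshold adaptation
#'
#' Each excitatory threshold moves by `eta_ip * (x_i - H_ip_i)`: up after a
#' spike, down after silence, so the long-run rate approaches the unit's
#' target `H_ip_i`. Thresholds are not clipped; homeostasis self-limits
#' their drift.
#'
#' @param T_E current excitatory thresholds.
#' @param x_now binary excitatory state at the current step.
#' @param H_ip per-unit target rates.
#' @param eta_ip learning rate.
#' @return the updated threshold vector.
#' @export
intrinsic_plasticity <- function(T_E, x_now, H_ip, eta_ip) {
  stopifnot(length(T_E) == length(x_now), length(H_ip) == length(T_E))
  T_E + eta_ip * (x_now - H_ip)
}

#' One full SORN step (reference implementation)
#'
#' Composes the update rules in the package's fixed within-step order:
#' state update, STDP, iSTDP, pruning, structural plasticity, intrinsic
#' plasticity, and synaptic normalization last. This pure-R version is the
#' readable reference; long simulations use the compiled engine in
#' [simulate_sorn()], which is pinned to this composition by tests.
#'
#' @param state a `sorn_state`.
#' @param u_ext external input vector (default zero).
#' @param flags a [plasticity_flags()] object.
#' @param xi_E,xi_I explicit noise draws (default zero); random noise is
#'   the caller's responsibility.
#' @return the advanced `sorn_state` (time incremented by 1).
#' @export
step_sorn <- function(state, u_ext = NULL, flags = plasticity_flags(),
                      xi_E = NULL, xi_I = NULL) {
  p <- state$params
  nxt <- update_states(state, u_ext, xi_E, xi_I)
  if (flags$stdp) {
    state$W_EE <- stdp_update(state$W_EE, nxt$x, state$x, p$eta_stdp)
  }
  if (flags$istdp) {
    state$W_EI <- istdp_update(state$W_EI, nxt$x, state$y, p$eta_inh,
                               p$mu_ip, mask = state$mask_EI)
  }
  if (flags$sp) {
    state$W_EE <- structural_plasticity(state$W_EE,
                                        sp_probability(p$N_E, p$p_sp_200),
                                        p$eta_sp)
  }
  if (flags$ip) {
    state$T_E <- intrinsic_plasticity(state$T_E, nxt$x, state$H_ip, p$eta_ip)
  }
  if (flags$sn) {
    state$W_EE <- synaptic_normalization(state$W_EE)
    state$W_EI <- synaptic_normalization(state$W_EI)
  }
  state$x <- nxt$x
  state$y <- nxt$y
  state$t <- state$t + 1L
  state
}

#' Readout feature vector (internal state without external input)
#'
#' Computes the prediction feature `x'(t)`: the excitatory state that the
#' network would reach from its current state with the external input term
#' removed but recurrent drive and noise retained.
#'
#' @inheritParams update_states
#' @return binary vector of length `N_E`.
#' @export
internal_state <- function(state, xi_E = NULL) {
  update_states(state, u_ext = NULL, xi_E = xi_E)$x
}
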