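#' Network parameters for a SORN
#'
#' Bundles all structural and plasticity parameters of the self-organizing
#' recurrent network. Defaults are the standard parameter profile used
#' throughout the package: a network of `N_E` excitatory and
#' `N_I = round(0.2 * N_E)` inhibitory binary units with learning rates
#' `eta_stdp = 0.004`, `eta_inh = 0.001`, `eta_ip = 0.01`, new-synapse
#' weight `eta_sp = 0.001`, structural-plasticity probability
#' `p_sp_200 = 0.1` at `N_E = 200` (scaled quadratically for other sizes,
#' see [sp_probability()]), target mean rate `mu_ip = 0.1` and initial
#' connection probabilities 0.1 (E to E) and 0.2 (I to E).
#'
#' @param N_E number of excitatory units (at least 5).
#' @param eta_stdp STDP learning rate.
#' @param eta_inh inhibitory STDP learning rate.
#' @param eta_ip intrinsic (threshold) plasticity learning rate.
#' @param eta_sp weight assigned to newly created synapses.
#' @param p_sp_200 structural-plasticity probability for a 200-unit network.
#' @param mu_ip network target mean firing rate (spikes per unit per step).
#' @param sigma_ip_sq variance of the per-unit target-rate distribution;
#'   0 gives every unit the common target `mu_ip`.
#' @param T_E_max upper bound of the uniform initial excitatory thresholds.
#' @param T_I_max upper bound of the uniform (fixed) inhibitory thresholds.
#' @param p_ee_init initial E-to-E connection probability.
#' @param p_ei_init initial I-to-E connection probability.
#'
#' @return an object of class `sorn_params`.
#' @export
#' @examples
#' p <- sorn_params(N_E = 200)
#' p$N_I  # 40
sorn_params <- function(N_E = 200L,
                        eta_stdp = 0.004,
                        eta_inh = 0.001,
                        eta_ip = 0.01,
                        eta_sp = 0.001,
                        p_sp_200 = 0.1,
                        mu_ip = 0.1,
                        sigma_ip_sq = 0,
                        T_E_max = 0.5,
                        T_I_max = 1.0,
                        p_ee_init = 0.1,
                        p_ei_init = 0.2) {
  N_E <- as.integer(N_E)
  if (N_E < 5L) {
    stop("N_E must be at least 5: smaller networks cannot form a meaningful sparse graph")
  }
  rates <- c(eta_stdp = eta_stdp, eta_inh = eta_inh, eta_ip = eta_ip,
             eta_sp = eta_sp, mu_ip = mu_ip, sigma_ip_sq = sigma_ip_sq)
  if (any(rates < 0)) {
    stop("learning rates, mu_ip and sigma_ip_sq must all be non-negative")
  }
  probs <- c(p_sp_200 = p_sp_200, p_ee_init = p_ee_init, p_ei_init = p_ei_init)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  structure(
    list(N_E = N_E, N_I = as.integer(round(0.2 * N_E)),
         eta_stdp = eta_stdp, eta_inh = eta_inh, eta_ip = eta_ip,
         eta_sp = eta_sp, p_sp_200 = p_sp_200, mu_ip = mu_ip,
         sigma_ip_sq = sigma_ip_sq, T_E_max = T_E_max, T_I_max = T_I_max,
         p_ee_init = p_ee_init, p_ei_init = p_ei_init),
    class = "sorn_params"
  )
}

#' @export
print.sorn_params <- function(x, ...) {
  cat("SORN parameters: N_E =", x$N_E, ", N_I =", x$N_I, "\n")
  cat("  rates: eta_stdp =", x$eta_stdp, ", eta_inh =", x$eta_inh,
      ", eta_ip =", x$eta_ip, ", eta_sp =", x$eta_sp, "\n")
  cat("  structural p_sp(N_E) =", sp_probability(x$N_E, x$p_sp_200),
      "; target rate mu_ip =", x$mu_ip, "\n")
  invisible(x)
}

#' Structural-plasticity probability for a network of a given size
#'
#' The per-step probability of creating one new E-to-E synapse scales with
#' the number of ordered unit pairs:
#' `p_SP(N_E) = N_E (N_E - 1) / (200 * 199) * p_SP(200)`.
#'
#' @param N_E number of excitatory units.
#' @param p_sp_200 reference probability at `N_E = 200` (default 0.1).
#' @return the per-step creation probability (may exceed 1 for very large
#'   networks; the stepping engine performs at most one creation per step).
#' @export
#' @examples
#' sp_probability(200)  # 0.1
sp_probability <- function(N_E, p_sp_200 = 0.1) {
  N_E * (N_E - 1) / (200 * 199) * p_sp_200
}

#' Membrane-noise model
#'
#' Per-step independent noise added to every unit's input drive. Three
#' kinds are supported: `"gaussian"` (zero mean, variance `sigma_sq`),
#' `"random_spike"` (with probability `p_s` the unit receives a large
#' supra-threshold kick) and `"none"`. When `active_subset` is given, only
#' those excitatory units receive noise and inhibitory units receive none;
#' otherwise all excitatory and inhibitory units draw noise independently.
#'
#' @param kind one of `"gaussian"`, `"random_spike"`, `"none"`.
#' @param sigma_sq Gaussian noise variance.
#' @param p_s per-unit per-step spike probability (random-spike kind).
#' @param active_subset optional integer vector of excitatory unit indices
#'   (1-based) that receive noise.
#' @param inhibitory also draw noise for the inhibitory units. Off by
#'   default: with noise-free inhibitory units and thresholds uniform on
#'   \[0, 1\], the fraction of inhibitory units responding to a given
#'   network activity is linear in that activity with unit gain, the
#'   marginal excitation-inhibition balance in which the critical-like
#'   avalanche statistics emerge. Ignored when `active_subset` is set.
#' @return an object of class `sorn_noise`.
#' @export
noise_model <- function(kind = c("gaussian", "random_spike", "none"),
                        sigma_sq = 0.05, p_s = 0.1, active_subset = NULL,
                        inhibitory = FALSE) {
  kind <- match.arg(kind)
  if (sigma_sq < 0) stop("sigma_sq must be non-negative")
  if (p_s < 0 || p_s > 1) stop("p_s must lie in [0, 1]")
  if (!is.null(active_subset)) {
    active_subset <- sort(unique(as.integer(active_subset)))
    if (length(active_subset) && min(active_subset) < 1L) {
      stop("active_subset must contain positive unit indices")
    }
  }
  structure(list(kind = kind, sigma_sq = sigma_sq, p_s = p_s,
                 active_subset = active_subset,
                 inhibitory = isTRUE(inhibitory)),
            class = "sorn_noise")
}

#' @export
print.sorn_noise <- function(x, ...) {
  cat("SORN noise model:", x$kind)
  if (x$kind == "gaussian") cat(" (variance", x$sigma_sq, ")")
  if (x$kind == "random_spike") cat(" (p_s =", x$p_s, ")")
  if (!is.null(x$active_subset)) {
    cat(", restricted to", length(x$active_subset), "excitatory units")
  }
  cat("\n")
  invisible(x)
}

#' Plasticity rule switches
#'
#' Independent on/off flags for the five plasticity rules: STDP, inhibitory
#' STDP, synaptic normalization (SN), structural plasticity (SP) and
#' intrinsic plasticity (IP). All on by default.
#'
#' @param stdp,istdp,sn,sp,ip logical flags.
#' @return an object of class `sorn_flags`.
#' @export
#' @examples
#' plasticity_flags()                     # full model
#' plasticity_flags(istdp = FALSE, sp = FALSE)  # original-SORN rule set
plasticity_flags <- function(stdp = TRUE, istdp = TRUE, sn = TRUE,
                             sp = TRUE, ip = TRUE) {
  structure(list(stdp = isTRUE(stdp), istdp = isTRUE(istdp), sn = isTRUE(sn),
                 sp = isTRUE(sp), ip = isTRUE(ip)),
            class = "sorn_flags")
}

#' All-off plasticity flags (a frozen network)
#' @return an object of class `sorn_flags` with every rule disabled.
#' @export
frozen_flags <- function() {
  plasticity_flags(FALSE, FALSE, FALSE, FALSE, FALSE)
}

# Evaluate an expression under a temporary RNG seed, restoring the caller's
# RNG state afterwards. Keeps package randomness out of the global stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Derive n reproducible child seeds (< 2^31) from one base seed.
derive_seeds <- function(seed, n, salt = 0L) {
  with_seed(seed + salt, sample.int(.Machine$integer.max - 1L, n))
}
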