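#' Power law versus exponential comparison on one sample set
#'
#' Fits the discrete truncated power law and the discrete truncated
#' exponential on the same window and returns both fits plus the signed
#' log-likelihood ratio (positive favors the power law).
#'
#' @param x positive integer samples (avalanche durations or sizes).
#' @param x_min,x_max fit window.
#' @return list with `powerlaw`, `exponential`, `R`.
#' @export
powerlaw_vs_exponential <- function(x, x_min, x_max) {
  pl <- fit_truncated_powerlaw(x, x_min, x_max)
  ex <- fit_discrete_exponential(x, x_min, x_max)
  list(powerlaw = pl, exponential = ex, R = loglik_ratio(pl, ex))
}

# Pool avalanche (T, S) events across runs into one data.frame.
pool_avalanches <- function(sets) {
  do.call(rbind, lapply(sets, function(s) data.frame(T = s$T, S = s$S)))
}

#' The pooled avalanche-statistics protocol
#'
#' The canonical measurement behind the headline exponents: `n_runs`
#' independent networks are each self-organized for `phase_cut` steps and
#' then recorded for `measure_steps` further steps; avalanches are
#' extracted per run at the half-mean threshold, pooled across runs, and
#' the pooled durations, sizes and alternative sizes are fitted with the
#' discrete truncated power-law MLE. Pooling follows the published
#' protocol (50 runs of 1e6 measured steps in the reference setting):
#' individual self-organized networks settle into stable states whose
#' fine statistics vary from run to run, and the reported exponents
#' describe the pooled ensemble.
#'
#' @param params a [sorn_params()] object.
#' @param n_runs independent simulations pooled (paper-scale 50; a handful
#'   already gives stable pooled fits).
#' @param phase_cut discarded self-organization steps per run.
#' @param measure_steps recorded steps per run.
#' @param noise a [noise_model()].
#' @param seed base seed; all per-run seeds derive from it.
#' @param duration_window,size_window MLE fit windows for durations and
#'   sizes (defaults are the reference windows for `N_E = 200`).
#' @return list with `alpha`, `tau`, `tau_alt` (fits on pooled data),
#'   `gamma` (pooled mean-size-versus-duration slope), `pooled`
#'   (avalanche data.frame with columns `T`, `S`, `S_alt`),
#'   `activity_mode` (mode of the pooled activity distribution),
#'   `activity_distribution`, `per_run` (per-run summary data.frame) and
#'   `thetas`.
#' @export
run_criticality_protocol <- function(params, n_runs = 50, phase_cut = 2e6,
                                     measure_steps = 1e6,
                                     noise = noise_model("gaussian", 0.05),
                                     seed = 1L,
                                     duration_window = c(6, 60),
                                     size_window = c(10, 1500)) {
  seeds <- derive_seeds(seed, 5L * n_runs)
  pooled <- vector("list", n_runs)
  act_tab <- numeric(params$N_E + 1L)
  thetas <- integer(n_runs)
  per_run <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    s <- seeds[(5 * r - 4):(5 * r)]
    st <- init_network(params, seed = s[1])
    warm <- simulate_sorn(st, phase_cut, noise = noise, noise_seed = s[2],
                          sp_seed = s[3], conn_stride = 0L)
    run <- simulate_sorn(warm$state, measure_steps, noise = noise,
                         noise_seed = s[4], sp_seed = s[5], conn_stride = 0L)
    a <- run$record$activity
    theta <- half_mean_threshold(a)
    av <- detect_avalanches(a, theta)
    thetas[r] <- theta
    act_tab <- act_tab + tabulate(a + 1L, nbins = params$N_E + 1L)
    pooled[[r]] <- data.frame(T = av$T, S = av$S,
                              S_alt = as.integer(alternative_size(a, av)))
    per_run[[r]] <- data.frame(
      run = r, n_avalanches = nrow(av), theta = theta,
      mean_activity = mean(a),
      conn_fraction = run$record$final_conn_fraction)
  }
  pooled <- do.call(rbind, pooled)
  pooled_set <- structure(
    data.frame(t0 = seq_len(nrow(pooled)), T = pooled$T, S = pooled$S),
    theta = as.integer(round(mean(thetas))), trace_length = NA_integer_,
    class = c("avalanche_set", "data.frame"))
  list(
    alpha = fit_truncated_powerlaw(pooled$T, duration_window[1],
                                   duration_window[2]),
    tau = fit_truncated_powerlaw(pooled$S, size_window[1], size_window[2]),
    tau_alt = fit_truncated_powerlaw(pooled$S_alt, size_window[1],
                                     size_window[2]),
    gamma = mean_size_vs_duration(pooled_set, duration_window)$gamma,
    pooled = pooled,
    activity_mode = which.max(act_tab) - 1L,
    activity_distribution = data.frame(a = 0:params$N_E,
                                       p = act_tab / sum(act_tab)),
    per_run = do.call(rbind, per_run),
    thetas = thetas
  )
}

#' Simulate network development and segment its phases
#'
#' Runs one or more fresh networks with full plasticity and segments each
#' smoothed connection-fraction trace into the three self-organization
#' phases: *decay* (fast pruning of the random initial graph), *growth*
#' (slow regrowth through structural plasticity) and *stable* (a plateau
#' with minor fluctuations).
#'
#' @param params a [sorn_params()] object.
#' @param n_steps steps per run.
#' @param n_runs independent runs.
#' @param noise a [noise_model()].
#' @param seed base seed.
#' @param conn_stride recording stride of the connection fraction.
#' @param smooth_window moving-average window (steps) of the smoother.
#' @param band relative half-width of the stability band.
#' @param hold steps the smoothed trace must stay inside the band.
#' @return list with one element per run: `conn_fraction`, `conn_step`,
#'   `smoothed`, `phases` (list `decay_end`, `stable_start`, `complete`).
#' @export
run_development <- function(params, n_steps = 3e6, n_runs = 1,
                            noise = noise_model("gaussian", 0.05),
                            seed = 1L, conn_stride = 1000L,
                            smooth_window = 1e4, band = 0.05, hold = 2e5) {
  seeds <- derive_seeds(seed, 3L * n_runs)
  lapply(seq_len(n_runs), function(r) {
    st <- init_network(params, seed = seeds[3 * r - 2])
    run <- simulate_sorn(st, n_steps, noise = noise,
                         noise_seed = seeds[3 * r - 1],
                         sp_seed = seeds[3 * r], conn_stride = conn_stride)
    trace <- run$record$conn_fraction
    steps <- run$record$conn_step
    sm <- moving_average(trace, max(1L, round(smooth_window / conn_stride)))
    phases <- detect_phases(sm, steps, band = band,
                            hold_points = max(2L, round(hold / conn_stride)))
    list(conn_fraction = trace, conn_step = steps, smoothed = sm,
         phases = phases, activity = run$record$activity)
  })
}

moving_average <- function(x, w) {
  if (w <= 1L) return(x)
  as.numeric(stats::filter(x, rep(1 / w, w), sides = 1))
}

#' Segment a smoothed connection-fraction trace into phases
#'
#' The decay phase ends at the global minimum of the smoothed trace; the
#' stable phase starts at the first point from which the trace stays
#' within a relative `band` of the local window mean for `hold_points`
#' consecutive recorded points.
#'
#' @param smoothed smoothed connection-fraction trace (NA-leading values
#'   from the smoother are tolerated).
#' @param steps model-time step of each recorded point.
#' @param band relative half-width of the stability band.
#' @param hold_points number of consecutive points required inside it.
#' @return list with `decay_end`, `stable_start` (model-time steps, NA if
#'   not reached) and `complete`.
#' @export
detect_phases <- function(smoothed, steps, band = 0.05, hold_points = 200L) {
  ok <- which(!is.na(smoothed))
  if (!length(ok)) return(list(decay_end = NA, stable_start = NA, complete = FALSE))
  i_min <- ok[which.min(smoothed[ok])]
  stable_start <- NA
  n <- length(smoothed)
  i <- i_min
  while (i + hold_points - 1L <= n) {
    w <- smoothed[i:(i + hold_points - 1L)]
    m <- mean(w)
    if (all(abs(w - m) <= band * m)) {
      stable_start <- steps[i]
      break
    }
    i <- i + 1L
  }
  list(decay_end = steps[i_min], stable_start = stable_start,
       complete = !is.na(stable_start))
}

#' Frozen-plasticity comparison
#'
#' Self-organizes one network to the stable phase, clones it, and
#' continues the two copies side by side: one with full plasticity, one
#' with the rules in `freeze_set` disabled. Both continuations share the
#' same membrane-noise seed, so any divergence is due to the freeze alone;
#' the segment before the freeze is common to both by construction. A
#' randomly initialized network with no synaptic plasticity serves as the
#' control; its intrinsic plasticity stays on (with random fixed
#' thresholds the activity never crosses the half-mean threshold, so the
#' thresholded avalanche measurement needs the homeostatic rate), and it
#' is given a short equilibration before measuring.
#'
#' @param params a [sorn_params()] object.
#' @param phase_cut self-organization steps before freezing.
#' @param measure_steps steps measured per arm after the cut.
#' @param freeze_set character vector of rules to freeze, subset of
#'   `c("stdp", "istdp", "sn", "sp", "ip")` (default all).
#' @param noise a [noise_model()].
#' @param seed base seed.
#' @return list with `plastic`, `frozen`, `random` (each: `avalanches`,
#'   `activity`, `theta`) and `state_at_cut`.
#' @export
run_frozen_comparison <- function(params, phase_cut = 2e6,
                                  measure_steps = 1e6,
                                  freeze_set = c("stdp", "istdp", "sn",
                                                 "sp", "ip"),
                                  noise = noise_model("gaussian", 0.05),
                                  seed = 1L) {
  if (!length(freeze_set)) stop("freeze_set must name at least one rule")
  freeze_set <- match.arg(freeze_set, several.ok = TRUE)
  seeds <- derive_seeds(seed, 6L)
  st <- init_network(params, seed = seeds[1])
  warm <- simulate_sorn(st, phase_cut, noise = noise,
                        noise_seed = seeds[2], sp_seed = seeds[3],
                        conn_stride = 0L)

  frozen_flags_ <- do.call(plasticity_flags, stats::setNames(
    as.list(!(c("stdp", "istdp", "sn", "sp", "ip") %in% freeze_set)),
    c("stdp", "istdp", "sn", "sp", "ip")))

  measure_arm <- function(state, flags) {
    run <- simulate_sorn(state, measure_steps, noise = noise, flags = flags,
                         noise_seed = seeds[4], sp_seed = seeds[5],
                         conn_stride = 0L)
    a <- run$record$activity
    theta <- half_mean_threshold(a)
    list(avalanches = detect_avalanches(a, theta), activity = a,
         theta = theta)
  }
  plastic <- measure_arm(clone_state(warm$state), plasticity_flags())
  frozen <- measure_arm(clone_state(warm$state), frozen_flags_)

  ip_only <- plasticity_flags(stdp = FALSE, istdp = FALSE, sn = FALSE,
                              sp = FALSE, ip = TRUE)
  rnd_state <- init_network(params, seed = seeds[6])
  rnd_warm <- simulate_sorn(rnd_state, max(1e4, ceiling(phase_cut / 40)),
                            noise = noise, flags = ip_only,
                            noise_seed = seeds[4] + 1L,
                            sp_seed = seeds[5] + 1L, conn_stride = 0L)
  random <- measure_arm(rnd_warm$state, ip_only)

  list(plastic = plastic, frozen = frozen, random = random,
       state_at_cut = warm$state, freeze_set = freeze_set)
}

#' Noise-level sweep
#'
#' Self-organizes and measures one network per noise level and reports,
#' per level, the avalanche set, the empirical activity distribution, the
#' power-law-versus-exponential ratio for sizes, and the binomial
#' reference curve for statistically independent units
#' (`Binomial(N_E, mu_ip)`).
#'
#' @param params a [sorn_params()] object.
#' @param noise_levels list of [noise_model()] objects (at least 2).
#' @param phase_cut,measure_steps protocol lengths.
#' @param seed base seed.
#' @param size_window size-fit window for the model comparison.
#' @return list with one element per level: `noise`, `avalanches`,
#'   `activity_distribution` (data.frame `a`, `p`), `comparison` (or NULL
#'   when too few in-window sizes), `theta`, plus attribute
#'   `binomial_reference`.
#' @export
run_noise_sweep <- function(params, noise_levels, phase_cut = 2e6,
                            measure_steps = 1e6, seed = 1L,
                            size_window = c(10, 1500)) {
  if (length(noise_levels) < 2) stop("give at least 2 noise levels")
  seeds <- derive_seeds(seed, 3L * length(noise_levels))
  out <- lapply(seq_along(noise_levels), function(k) {
    nm <- noise_levels[[k]]
    st <- init_network(params, seed = seeds[3 * k - 2])
    warm <- simulate_sorn(st, phase_cut, noise = nm,
                          noise_seed = seeds[3 * k - 1],
                          sp_seed = seeds[3 * k], conn_stride = 0L)
    run <- simulate_sorn(warm$state, measure_steps, noise = nm,
                         noise_seed = seeds[3 * k - 1] + 1L,
                         sp_seed = seeds[3 * k] + 1L, conn_stride = 0L)
    a <- run$record$activity
    theta <- half_mean_threshold(a)
    av <- detect_avalanches(a, theta)
    tab <- tabulate(a + 1L, nbins = params$N_E + 1L)
    cmp <- tryCatch(
      powerlaw_vs_exponential(av$S, size_window[1], size_window[2]),
      error = function(e) NULL)
    list(noise = nm, avalanches = av, theta = theta,
         activity_distribution = data.frame(a = 0:params$N_E,
                                            p = tab / length(a)),
         comparison = cmp)
  })
  attr(out, "binomial_reference") <-
    data.frame(a = 0:params$N_E,
               p = stats::dbinom(0:params$N_E, params$N_E, params$mu_ip))
  out
}

#' Noise restricted to a subset of excitatory units
#'
#' Random-spike noise is confined to a random fixed subset of the
#' excitatory units (with `p_s = 1` by default the subset is continuously
#' active); inhibitory units receive no noise. The activity trace and the
#' half-mean threshold are computed over the units *outside* the subset,
#' so the continuously active units do not trivially inflate the
#' avalanche statistics. A fraction of 1 with `p_s < 1` reduces to the
#' standard whole-network random-spike condition.
#'
#' @param params a [sorn_params()] object.
#' @param fractions numeric vector of subset fractions in \[0, 1\].
#' @param p_s spike probability of subset units.
#' @param phase_cut,measure_steps protocol lengths.
#' @param seed base seed.
#' @param size_window size-fit window for the model comparison.
#' @return list with one element per fraction: `fraction`, `subset`,
#'   `avalanches`, `theta`, `comparison` (NULL when not fittable).
#' @export
run_subset_noise <- function(params, fractions, p_s = 1,
                             phase_cut = 2e6, measure_steps = 1e6,
                             seed = 1L, size_window = c(10, 1500)) {
  stopifnot(all(fractions >= 0 & fractions <= 1))
  seeds <- derive_seeds(seed, 4L * length(fractions))
  lapply(seq_along(fractions), function(k) {
    f <- fractions[k]
    n_sub <- round(f * params$N_E)
    subset <- if (n_sub > 0) {
      with_seed(seeds[4 * k - 3], sort(sample.int(params$N_E, n_sub)))
    } else {
      integer(0)
    }
    nm <- if (n_sub > 0) {
      noise_model("random_spike", p_s = p_s,
                  active_subset = if (n_sub < params$N_E) subset else NULL)
    } else {
      noise_model("none")
    }
    count_units <- if (n_sub > 0 && n_sub < params$N_E) {
      setdiff(seq_len(params$N_E), subset)
    } else {
      NULL
    }
    st <- init_network(params, seed = seeds[4 * k - 2])
    warm <- simulate_sorn(st, phase_cut, noise = nm,
                          noise_seed = seeds[4 * k - 1],
                          sp_seed = seeds[4 * k], conn_stride = 0L)
    run <- simulate_sorn(warm$state, measure_steps, noise = nm,
                         noise_seed = seeds[4 * k - 1] + 1L,
                         sp_seed = seeds[4 * k] + 1L,
                         count_units = count_units, conn_stride = 0L)
    a <- run$record$activity
    theta <- half_mean_threshold(a)
    av <- detect_avalanches(a, theta)
    cmp <- tryCatch(
      powerlaw_vs_exponential(av$S, size_window[1], size_window[2]),
      error = function(e) NULL)
    list(fraction = f, subset = subset, avalanches = av, theta = theta,
         comparison = cmp)
  })
}

#' External-input onset and readaptation
#'
#' Implements the onset protocol: networks are self-organized to the
#' stable phase without external input, then a random letter stream (one
#' uniformly drawn letter per step, each letter driving a fixed subset of
#' `0.02 * N_E` excitatory units) is switched on. Avalanches starting
#' within the first `transient_window` steps after onset form the
#' transient pool; avalanches over the following `readapt_steps` form the
#' readapted pool; the pre-onset tail gives the before pool. The activity
#' threshold is computed before onset and held fixed. Each trial uses an
#' independently initialized and evolved network. A short stretch of
#' pre-onset activity is kept in front of the post-onset trace so that
#' avalanches already running at onset are attributed correctly rather
#' than censored.
#'
#' @param params a [sorn_params()] object.
#' @param n_trials number of independent onset trials.
#' @param phase_cut self-organization steps per trial.
#' @param before_steps pre-onset steps entering the before pool.
#' @param transient_window steps after onset defining transient avalanches.
#' @param readapt_steps post-transient steps entering the readapted pool.
#' @param n_letters alphabet size of the random stream.
#' @param subset_frac fraction of excitatory units per letter subset.
#' @param amplitude external drive per presented letter.
#' @param noise a [noise_model()].
#' @param seed base seed.
#' @return list with pooled data.frames `before`, `transient`, `readapted`
#'   (columns `T`, `S`), and `thetas` (per-trial thresholds).
#' @export
run_input_onset <- function(params, n_trials = 250, phase_cut = 2e6,
                            before_steps = 1e6, transient_window = 10L,
                            readapt_steps = 2e6, n_letters = 10L,
                            subset_frac = 0.02, amplitude = 1e7,
                            noise = noise_model("gaussian", 0.05),
                            seed = 1L) {
  seeds <- derive_seeds(seed, 5L * n_trials)
  pad <- 100L
  before <- list()
  transient <- list()
  readapted <- list()
  thetas <- integer(n_trials)
  for (r in seq_len(n_trials)) {
    s <- seeds[(5 * r - 4):(5 * r)]
    st <- init_network(params, seed = s[1])
    warm <- simulate_sorn(st, phase_cut, noise = noise, noise_seed = s[2],
                          sp_seed = s[3], conn_stride = 0L)
    a_before <- warm$record$activity
    a_tail <- a_before[max(1, length(a_before) - before_steps + 1):length(a_before)]
    theta <- half_mean_threshold(a_tail)
    thetas[r] <- theta
    before[[r]] <- detect_avalanches(a_tail, theta)

    mapping <- make_letter_mapping(n_letters, params$N_E,
                                   round(subset_frac * params$N_E),
                                   seed = s[4])
    n_post <- transient_window + readapt_steps
    lets <- with_seed(s[5], sample.int(n_letters, n_post, replace = TRUE))
    input <- letters_to_input(list(letters = lets), mapping, amplitude)
    post <- simulate_sorn(warm$state, n_post, noise = noise,
                          input = input, noise_seed = s[2] + 1L,
                          sp_seed = s[3] + 1L, conn_stride = 0L)
    a_post <- c(a_tail[max(1, length(a_tail) - pad + 1):length(a_tail)],
                post$record$activity)
    pad_used <- min(pad, length(a_tail))
    av <- detect_avalanches(a_post, theta)
    onset_rel <- av$t0 - pad_used  # 1 = first post-onset step
    transient[[r]] <- av[onset_rel >= 1 & onset_rel <= transient_window, ]
    readapted[[r]] <- av[onset_rel > transient_window, ]
  }
  list(before = pool_avalanches(before),
       transient = pool_avalanches(transient),
       readapted = pool_avalanches(readapted),
       thetas = thetas)
}

#' Total variation distance between an empirical activity distribution
#' and a binomial reference
#'
#' @param activity integer activity trace.
#' @param size,prob binomial parameters (independent-unit prediction:
#'   `size = N_E`, `prob = mu_ip`).
#' @return half the L1 distance between the two mass functions.
#' @export
activity_binomial_distance <- function(activity, size, prob) {
  emp <- tabulate(activity + 1L, nbins = size + 1L) / length(activity)
  ref <- stats::dbinom(0:size, size, prob)
  sum(abs(emp - ref)) / 2
}
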