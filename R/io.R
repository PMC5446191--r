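#' Default configuration profile
#'
#' The full default configuration: the standard network parameter set,
#' Gaussian membrane noise of variance 0.05, the canonical fit windows
#' (durations \[6, 60\], sizes \[10, 1500\] for a 200-unit network) and the
#' standard experiment lengths. Fit windows for other network sizes scale
#' the size maximum proportionally to `N_E` and the duration maximum with
#' `sqrt(N_E / 200)`.
#'
#' @param N_E network size the profile is resolved for.
#' @return a named list (class `sorn_config`).
#' @export
default_config <- function(N_E = 200L) {
  scale <- N_E / 200
  structure(list(
    N_E = as.integer(N_E),
    eta_stdp = 0.004, eta_inh = 0.001, eta_ip = 0.01, eta_sp = 0.001,
    p_sp_200 = 0.1, mu_ip = 0.1, sigma_ip_sq = 0,
    T_E_max = 0.5, T_I_max = 1.0, p_ee_init = 0.1, p_ei_init = 0.2,
    noise_kind = "gaussian", sigma_sq = 0.05, p_s = 0.1,
    phase_cut = 2e6, measure_steps = 1e6, n_runs = 1,
    T_min = 6L, T_max = as.integer(round(60 * sqrt(scale))),
    S_min = 10L, S_max = as.integer(round(1500 * scale)),
    b_s = 0.1, theta_rule = "half_mean"
  ), class = "sorn_config")
}

#' Load and validate a configuration file
#'
#' Reads a flat key-value YAML file, overlays it on the default profile,
#' rejects unknown keys, and validates types and ranges. An empty file
#' yields the full default profile.
#'
#' @param path path to a YAML configuration file.
#' @return a validated `sorn_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  base <- default_config(if (!is.null(user$N_E)) user$N_E else 200L)
  unknown <- setdiff(names(user), names(base))
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(base, user)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  num_keys <- c("eta_stdp", "eta_inh", "eta_ip", "eta_sp", "mu_ip",
                "sigma_ip_sq", "sigma_sq")
  for (k in num_keys) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] < 0) {
      stop("configuration key '", k, "' must be a non-negative number")
    }
  }
  for (k in c("p_sp_200", "p_ee_init", "p_ei_init", "p_s")) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] < 0 || cfg[[k]] > 1) {
      stop("configuration key '", k, "' must lie in [0, 1]")
    }
  }
  if (cfg$N_E < 5) stop("configuration key 'N_E' must be at least 5")
  if (!cfg$noise_kind %in% c("gaussian", "random_spike", "none")) {
    stop("configuration key 'noise_kind' must be gaussian, random_spike or none")
  }
  class(cfg) <- "sorn_config"
  cfg
}

#' Write a configuration to a YAML file
#' @param cfg a `sorn_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Write / read an avalanche table as TSV
#'
#' Columns `t0`, `T`, `S`, `S_alt`; a comment header records the threshold
#' and trace length so the set round-trips exactly.
#'
#' @param set an `avalanche_set`.
#' @param activity the activity trace (for the alternative size column);
#'   NULL writes `S_alt = NA`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_avalanches_tsv <- function(set, path, activity = NULL) {
  stopifnot(inherits(set, "avalanche_set"))
  s_alt <- if (is.null(activity)) rep(NA_integer_, nrow(set)) else
    as.integer(alternative_size(activity, set))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# theta=%d trace_length=%d", attr(set, "theta"),
                     attr(set, "trace_length")), con)
  utils::write.table(cbind(set, S_alt = s_alt), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_avalanches_tsv
#' @export
read_avalanches_tsv <- function(path) {
  header <- readLines(path, n = 1L)
  m <- regmatches(header, regexec("theta=(\\d+) trace_length=(\\d+)", header))[[1]]
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#")
  structure(df[, c("t0", "T", "S")],
            theta = as.integer(m[2]), trace_length = as.integer(m[3]),
            S_alt = df$S_alt,
            class = c("avalanche_set", "data.frame"))
}

#' Write / read a spike raster as a TSV event list
#'
#' Columns `time_step` and `unit_index`, both 0-based; the comment header
#' records the network size and the named seeds.
#'
#' @param record a `sorn_record` with a raster.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_raster_tsv <- function(record, path) {
  if (is.null(record$raster)) stop("record carries no raster")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# N_E=%d N_I=%d seed_init=%d seed_noise=%d seed_sp=%d",
                     record$N_E, record$N_I, record$seeds[["init"]],
                     record$seeds[["noise"]], record$seeds[["sp"]]), con)
  utils::write.table(
    data.frame(time_step = record$raster$time_step - 1L,
               unit_index = record$raster$unit_index),
    con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_raster_tsv
#' @export
read_raster_tsv <- function(path) {
  header <- readLines(path, n = 1L)
  kv <- regmatches(header, gregexpr("[A-Za-z_]+=-?\\d+", header))[[1]]
  meta <- stats::setNames(
    as.integer(sub(".*=", "", kv)), sub("=.*", "", kv))
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#")
  list(raster = data.frame(time_step = df$time_step + 1L,
                           unit_index = df$unit_index),
       meta = as.list(meta))
}

#' Write / read a power-law fit report as JSON
#'
#' Serializes fit objects (exponents, window, sample count, log-
#' likelihood, optional ratio values) with full double precision, so a
#' round trip preserves the exponent bit-for-bit.
#'
#' @param fit a `powerlaw_fit`, `expcutoff_fit` or plain list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a binned distribution as TSV
#' @param bd a `binned_distribution`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_binned_tsv <- function(bd, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# b_s=%g n=%d", attr(bd, "b_s"), attr(bd, "n")), con)
  utils::write.table(bd, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' A write-once JSON snapshot of a run: parameters, named seeds, package
#' version, wall time, and the content hash (MD5) of every listed output
#' file. A run is reproducible from its manifest alone.
#'
#' @param path manifest path (must not already exist).
#' @param params a `sorn_params` (or coercible list).
#' @param seeds named integer vector of the run's seeds.
#' @param files character vector of output file paths.
#' @param extra optional named list of extra metadata.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, params, seeds, files = character(0),
                           extra = list()) {
  if (file.exists(path)) stop("manifest already exists (write-once): ", path)
  missing <- files[!file.exists(files)]
  if (length(missing)) {
    stop("listed output files do not exist: ", paste(missing, collapse = ", "))
  }
  manifest <- c(list(
    package = "sorncrit",
    version = as.character(utils::packageVersion("sorncrit")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    params = unclass(params),
    seeds = as.list(seeds),
    files = if (length(files)) {
      lapply(files, function(f) list(path = f,
                                     md5 = unname(tools::md5sum(f))))
    } else {
      list()
    }
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Checkpoint a network state to disk
#'
#' Serializes the full state (weights, thresholds, targets, time) with a
#' versioned schema, so long runs can be resumed. Checkpoints are binary
#' runtime artifacts (RDS).
#'
#' @param state a `sorn_state`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_checkpoint <- function(state, path) {
  stopifnot(inherits(state, "sorn_state"))
  saveRDS(list(schema = "sorncrit-checkpoint-1", state = state), path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$schema, "sorncrit-checkpoint-1")) {
    stop("unrecognized checkpoint schema: ", obj$schema)
  }
  obj$state
}
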