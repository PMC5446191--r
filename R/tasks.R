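#' Counting Task letter stream
#'
#' The Counting Task alternates, with equal probability and no gaps, the
#' two sequences `"ABB...BC"` and `"DEE...EF"`, each of length `n + 2`
#' with `n` repetitions of the middle letter. The alphabet is exactly
#' `{A, B, C, D, E, F}`.
#'
#' @param n number of middle-letter repetitions (at least 1).
#' @param n_steps length of the generated stream.
#' @param seed integer seed for the sequence-type draws.
#' @return an object of class `task_stream`: list with `letters` (integer
#'   codes 1..6 for A..F), `alphabet`, `is_first` (logical, marks each
#'   sequence's first letter — excluded from Counting-Task scoring because
#'   sequence identity is random), `task = "ct"`, `sequence_param = n`.
#' @export
#' @examples
#' s <- counting_task_stream(1, 9, seed = 1)
#' intToUtf8(64 + s$letters, multiple = TRUE)  # e.g. "A" "B" "C" "D" "E" "F" ...
counting_task_stream <- function(n, n_steps, seed) {
  if (n < 1) stop("n must be at least 1")
  len <- n + 2L
  n_seq <- ceiling(n_steps / len)
  with_seed(seed, {
    which_seq <- sample.int(2L, n_seq, replace = TRUE)
  })
  seq1 <- c(1L, rep(2L, n), 3L)  # A B..B C
  seq2 <- c(4L, rep(5L, n), 6L)  # D E..E F
  letters <- unlist(lapply(which_seq, function(w) if (w == 1L) seq1 else seq2))
  is_first <- rep(c(TRUE, rep(FALSE, len - 1L)), n_seq)
  structure(
    list(letters = letters[seq_len(n_steps)],
         is_first = is_first[seq_len(n_steps)],
         alphabet = c("A", "B", "C", "D", "E", "F"),
         task = "ct", sequence_param = as.integer(n)),
    class = "task_stream"
  )
}

#' Random Sequence Task letter stream
#'
#' One uniform random word of length `L` over an alphabet of `A_S` letters
#' is fixed at stream creation and then cycled indefinitely.
#'
#' @param L word length (at least 1).
#' @param A_S alphabet size (at least 2; default 10).
#' @param n_steps length of the generated stream.
#' @param seed integer seed for the word draw.
#' @return a `task_stream` with `letters` (integer codes 1..A_S),
#'   `word`, `task = "rst"`, `sequence_param = L`.
#' @export
random_sequence_stream <- function(L, A_S = 10L, n_steps, seed) {
  if (L < 1) stop("L must be at least 1")
  if (A_S < 2) stop("A_S must be at least 2")
  word <- with_seed(seed, sample.int(A_S, L, replace = TRUE))
  letters <- rep_len(word, n_steps)
  structure(
    list(letters = letters, word = word,
         alphabet = as.character(seq_len(A_S)),
         is_first = rep(FALSE, n_steps),
         task = "rst", sequence_param = as.integer(L)),
    class = "task_stream"
  )
}

#' @export
print.task_stream <- function(x, ...) {
  cat("Task stream:", toupper(x$task), "with parameter", x$sequence_param,
      ",", length(x$letters), "steps, alphabet size",
      length(x$alphabet), "\n")
  invisible(x)
}

#' Map letters to excitatory unit subsets
#'
#' Each letter activates a fixed, randomly chosen subset of excitatory
#' units. Subsets of different letters may overlap (they are drawn
#' independently, non-exclusively) and stay fixed for the whole run.
#'
#' @param n_letters alphabet size.
#' @param N_E number of excitatory units.
#' @param subset_size units per letter (the external-input experiment uses
#'   `0.02 * N_E`, the learning tasks `0.05 * N_E`).
#' @param seed integer seed.
#' @return list of integer vectors (1-based unit indices), one per letter.
#' @export
make_letter_mapping <- function(n_letters, N_E, subset_size, seed) {
  subset_size <- as.integer(round(subset_size))
  if (subset_size < 1 || subset_size > N_E) {
    stop("subset_size must lie in [1, N_E]")
  }
  with_seed(seed, {
    lapply(seq_len(n_letters), function(k) sort(sample.int(N_E, subset_size)))
  })
}

#' Turn a letter stream into per-step external input
#'
#' At each step the units of the current letter's subset receive drive
#' `amplitude` and all other units receive 0. The default amplitude 1e7 is
#' far above any threshold, so mapped units fire with certainty.
#'
#' @param stream a `task_stream` (or any list with integer `letters`).
#' @param mapping list of unit subsets from [make_letter_mapping()]; must
#'   cover the stream's alphabet.
#' @param amplitude external drive value.
#' @return an object of class `sorn_input` accepted by [simulate_sorn()].
#' @export
letters_to_input <- function(stream, mapping, amplitude = 1e7) {
  letters <- stream$letters
  if (max(letters) > length(mapping)) {
    stop("mapping covers ", length(mapping), " letters but the stream uses ",
         max(letters))
  }
  structure(
    list(letters = as.integer(letters), subsets = mapping,
         amplitude = amplitude),
    class = "sorn_input"
  )
}

#' Materialize an input object as a dense drive matrix
#'
#' Mainly for inspection and tests: row `t` is the external input vector
#' `u_ext(t)` of length `N_E`.
#'
#' @param input a `sorn_input`.
#' @param N_E number of excitatory units.
#' @param steps how many leading steps to materialize.
#' @return numeric matrix `steps` by `N_E`.
#' @export
as_input_matrix <- function(input, N_E, steps = length(input$letters)) {
  u <- matrix(0, steps, N_E)
  for (t in seq_len(steps)) {
    u[t, input$subsets[[input$letters[t]]]] <- input$amplitude
  }
  u
}

#' Train a linear readout by Moore-Penrose pseudo-inverse
#'
#' Solves the least-squares problem mapping internal-state features to
#' one-hot letter targets: `B = pinv(X) Y`. Prediction is the argmax of
#' the letter scores `x' B`, with ties broken toward the lowest letter
#' index for determinism.
#'
#' @param features numeric matrix, one row per training step (the feature
#'   is the internal state `x'(t)`).
#' @param targets integer letter codes (1-based), one per training step.
#' @param n_letters alphabet size (output dimension); defaults to
#'   `max(targets)`.
#' @return an object of class `readout_model` with `weights`
#'   (`ncol(features)` by `n_letters`) and `n_letters`.
#' @export
train_readout <- function(features, targets, n_letters = max(targets)) {
  features <- as.matrix(features)
  if (nrow(features) != length(targets)) {
    stop("features and targets are not aligned")
  }
  if (nrow(features) < n_letters) {
    stop("need at least as many training steps as letters")
  }
  if (all(features == 0)) stop("degenerate all-zero feature matrix")
  Y <- matrix(0, length(targets), n_letters)
  Y[cbind(seq_along(targets), targets)] <- 1
  B <- MASS::ginv(features) %*% Y
  structure(list(weights = B, n_letters = as.integer(n_letters)),
            class = "readout_model")
}

#' Predict letters with a trained readout
#'
#' @param object a `readout_model`.
#' @param newdata feature matrix, one row per step.
#' @param ... unused.
#' @return integer vector of predicted letter codes.
#' @export
predict.readout_model <- function(object, newdata, ...) {
  scores <- as.matrix(newdata) %*% object$weights
  max.col(scores, ties.method = "first")
}

#' Run a sequence-learning task end to end
#'
#' Protocol: starting from a fresh random network, the SORN is driven by
#' the task's letter stream for `T_plastic` steps with all selected
#' plasticity rules active; a linear readout is then trained on the next
#' `T_train` steps (one-hot letter targets, features `x'(t)`, pseudo-
#' inverse solve) and scored on `T_test` further steps as the fraction of
#' correctly predicted letters. The prediction target at step `t` is the
#' letter presented at `t`, predicted from `x'(t)`, which is built from
#' the step `t - 1` states with the input term removed — i.e. next-letter
#' prediction. For the Counting Task the first letter of each sequence is
#' excluded from scoring (sequence identity is random). By default the
#' plasticity rules are switched off after the plastic phase so that the
#' readout is trained and tested on a static reservoir; set
#' `freeze_after_plastic = FALSE` to keep them running. Optionally,
#' activity is recorded for a further `measure_steps` steps and avalanches
#' are extracted with the standard half-mean threshold.
#'
#' @param params a [sorn_params()] object.
#' @param stream a `task_stream` covering at least
#'   `T_plastic + T_train + T_test + measure_steps` steps.
#' @param noise a [noise_model()]; the tasks default to Gaussian noise of
#'   standard deviation 0.05 (`sigma_sq = 0.0025`).
#' @param flags plasticity flags; [original_sorn_flags()] reproduces the
#'   reduced rule set without iSTDP and SP.
#' @param subset_size units per letter subset; default `0.05 * N_E`.
#' @param T_plastic,T_train,T_test phase lengths.
#' @param freeze_after_plastic disable all plasticity during the readout
#'   training and test phases (default TRUE).
#' @param readout_noise_free run the readout training and test phases
#'   without membrane noise (default TRUE), so the readout is fit and
#'   scored on the reservoir the plastic phase produced; the `noise`
#'   argument then only shapes self-organization. Set FALSE to keep the
#'   noise source active throughout.
#' @param measure_steps extra steps for avalanche measurement (0 = skip);
#'   plasticity stays in whatever state the readout phases used.
#' @param seed base seed; network init, letter mapping and noise streams
#'   are derived from it.
#' @param amplitude external drive per presented letter.
#' @return list with `performance` (fraction correct), `n_scored`,
#'   `readout`, `state`, and when measured, `avalanches` and `activity`.
#' @export
run_task <- function(params, stream,
                     noise = noise_model("gaussian", sigma_sq = 0.0025),
                     flags = plasticity_flags(),
                     subset_size = round(0.05 * params$N_E),
                     T_plastic = 50000L, T_train = 5000L, T_test = 5000L,
                     freeze_after_plastic = TRUE, readout_noise_free = TRUE,
                     measure_steps = 0L, seed = 1L, amplitude = 1e7) {
  total <- T_plastic + T_train + T_test + measure_steps
  if (length(stream$letters) < total) {
    stop("stream too short: ", length(stream$letters), " < ", total)
  }
  seeds <- derive_seeds(seed, 4L)
  mapping <- make_letter_mapping(length(stream$alphabet), params$N_E,
                                 subset_size, seed = seeds[1])
  input <- letters_to_input(stream, mapping, amplitude)
  state <- init_network(params, seed = seeds[2])

  slice_input <- function(from, len) {
    structure(list(letters = input$letters[from:(from + len - 1L)],
                   subsets = input$subsets, amplitude = input$amplitude),
              class = "sorn_input")
  }

  # plastic self-organization under task input
  run1 <- simulate_sorn(state, T_plastic, noise = noise, flags = flags,
                        input = slice_input(1L, T_plastic),
                        noise_seed = seeds[3], sp_seed = seeds[4],
                        conn_stride = 0L)
  # training + test window, recording readout features
  readout_flags <- if (freeze_after_plastic) frozen_flags() else flags
  readout_noise <- if (readout_noise_free) noise_model("none") else noise
  n2 <- T_train + T_test
  run2 <- simulate_sorn(run1$state, n2, noise = readout_noise,
                        flags = readout_flags,
                        input = slice_input(T_plastic + 1L, n2),
                        noise_seed = seeds[3] + 1L, sp_seed = seeds[4] + 1L,
                        record_features = TRUE, conn_stride = 0L)
  feats <- run2$record$features
  lets <- stream$letters[(T_plastic + 1L):(T_plastic + n2)]
  train_idx <- seq_len(T_train)
  test_idx <- (T_train + 1L):n2

  readout <- train_readout(feats[train_idx, , drop = FALSE],
                           lets[train_idx],
                           n_letters = length(stream$alphabet))
  pred <- predict(readout, feats[test_idx, , drop = FALSE])
  truth <- lets[test_idx]
  scored <- rep(TRUE, length(truth))
  if (identical(stream$task, "ct")) {
    scored <- !stream$is_first[(T_plastic + T_train + 1L):(T_plastic + n2)]
  }
  performance <- mean(pred[scored] == truth[scored])

  out <- list(performance = performance, n_scored = sum(scored),
              readout = readout, state = run2$state,
              seeds = seeds, task = stream$task,
              sequence_param = stream$sequence_param)
  if (measure_steps > 0) {
    # avalanche measurement happens under the running task condition
    # (plasticity and noise as in the plastic phase)
    run3 <- simulate_sorn(run2$state, measure_steps, noise = noise,
                          flags = flags,
                          input = slice_input(T_plastic + n2 + 1L,
                                              measure_steps),
                          noise_seed = seeds[3] + 2L,
                          sp_seed = seeds[4] + 2L, conn_stride = 0L)
    theta <- half_mean_threshold(run3$record$activity)
    out$activity <- run3$record$activity
    out$avalanches <- detect_avalanches(run3$record$activity, theta)
    out$state <- run3$state
  }
  out
}

#' Plasticity flags of the original SORN rule set
#'
#' The reduced comparison arm without inhibitory STDP and structural
#' plasticity (used together with `noise_model("none")`).
#'
#' @return a `sorn_flags` object with `istdp = FALSE` and `sp = FALSE`.
#' @export
original_sorn_flags <- function() {
  plasticity_flags(istdp = FALSE, sp = FALSE)
}
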