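test_that("the compiled engine reproduces the composed reference rules", {
  # with noise off and structural plasticity off both paths are
  # deterministic, so they must agree step for step
  p <- tiny_params()
  st <- poked_state(p, seed = 3, n_active = 8L)
  flags <- plasticity_flags(sp = FALSE)
  ref <- st
  for (k in 1:150) ref <- step_sorn(ref, flags = flags)
  eng <- simulate_sorn(st, 150, noise = noise_model("none"), flags = flags,
                       conn_stride = 0)$state
  expect_identical(ref$x, eng$x)
  expect_identical(ref$y, eng$y)
  expect_equal(ref$W_EE, eng$W_EE, tolerance = 1e-12)
  expect_equal(ref$W_EI, eng$W_EI, tolerance = 1e-12)
  expect_equal(ref$T_E, eng$T_E, tolerance = 1e-14)
  expect_equal(ref$t, eng$t)
})

test_that("simulations sharing all named seeds are bit-identical", {
  st <- init_network(tiny_params(), seed = 5)
  r1 <- simulate_sorn(st, 3000, noise_seed = 7, sp_seed = 9,
                      record_raster = TRUE)
  r2 <- simulate_sorn(st, 3000, noise_seed = 7, sp_seed = 9,
                      record_raster = TRUE)
  expect_identical(r1$record$activity, r2$record$activity)
  expect_identical(r1$record$raster, r2$record$raster)
  expect_identical(r1$state$W_EE, r2$state$W_EE)
  expect_identical(r1$state$T_E, r2$state$T_E)
  # a different noise seed diverges
  r3 <- simulate_sorn(st, 3000, noise_seed = 8, sp_seed = 9)
  expect_false(identical(r1$record$activity, r3$record$activity))
})

test_that("row sums stay normalized through long plastic runs", {
  st <- init_network(tiny_params(60L), seed = 6)
  out <- simulate_sorn(st, 20000, noise_seed = 1, sp_seed = 2)$state
  rs_ee <- rowSums(out$W_EE)
  rs_ei <- rowSums(out$W_EI)
  expect_true(all(abs(rs_ee[rs_ee > 0] - 1) < 1e-9))
  expect_true(all(abs(rs_ei[rs_ei > 0] - 1) < 1e-9))
})

test_that("self-connections never appear and weights stay non-negative", {
  st <- init_network(tiny_params(50L), seed = 8)
  out <- simulate_sorn(st, 30000, noise_seed = 3, sp_seed = 4)$state
  expect_true(all(diag(out$W_EE) == 0))
  expect_gte(min(out$W_EE), 0)
  expect_gte(min(out$W_EI), 0)
})

test_that("homeostasis drives each unit's rate to its target", {
  p <- sorn_params(N_E = 200)
  st <- init_network(p, seed = 10)
  warm <- simulate_sorn(st, 150000, noise_seed = 11, sp_seed = 12)
  probe <- simulate_sorn(warm$state, 100000, noise_seed = 13, sp_seed = 14,
                         record_raster = TRUE)
  rates <- tabulate(probe$record$raster$unit_index + 1L, nbins = 200) / 1e5
  expect_true(all(abs(rates - st$H_ip) <= 0.03))
  expect_equal(mean(probe$record$activity) / 200, 0.1, tolerance = 0.01)
})

test_that("the record bookkeeping is consistent", {
  st <- init_network(tiny_params(), seed = 1)
  run <- simulate_sorn(st, 500, noise_seed = 2, sp_seed = 3,
                       record_raster = TRUE, record_features = TRUE,
                       conn_stride = 100)
  expect_length(run$record$activity, 500)
  # activity equals per-step raster spike counts
  counts <- tabulate(run$record$raster$time_step, nbins = 500)
  expect_equal(counts, run$record$activity)
  expect_equal(dim(run$record$features), c(500, 40))
  expect_true(all(run$record$features %in% c(0L, 1L)))
  expect_equal(run$record$conn_step, seq(100, 500, by = 100))
  expect_equal(run$state$t, 500L)
  # n_steps = 1 yields a record of length 1
  expect_length(simulate_sorn(st, 1, noise_seed = 1, sp_seed = 1)$record$activity, 1)
  expect_error(simulate_sorn(st, 0, noise_seed = 1, sp_seed = 1), "at least 1")
})

test_that("an input stream shorter than the run is rejected", {
  st <- init_network(tiny_params(), seed = 1)
  stream <- counting_task_stream(1, 50, seed = 1)
  input <- letters_to_input(stream, make_letter_mapping(6, 40, 2, seed = 2))
  expect_error(simulate_sorn(st, 100, input = input), "shorter")
  run <- simulate_sorn(st, 50, input = input, noise_seed = 1, sp_seed = 1)
  expect_length(run$record$activity, 50)
  # every driven subset fires at its step
  run2 <- simulate_sorn(st, 50, input = input, noise_seed = 1, sp_seed = 1,
                        record_raster = TRUE)
  for (t in c(1, 10, 25)) {
    sub <- input$subsets[[stream$letters[t]]]
    fired <- run2$record$raster$unit_index[run2$record$raster$time_step == t] + 1L
    expect_true(all(sub %in% fired))
  }
})

test_that("isolated units under random-spike noise fire like independent coins", {
  # with the recurrent matrices removed the activity distribution is the
  # binomial reference curve of the high-noise regime
  p <- sorn_params(N_E = 200)
  st <- init_network(p, seed = 20)
  st$W_EE[] <- 0
  st$W_EI[] <- 0
  run <- simulate_sorn(st, 20000, noise = noise_model("random_spike", p_s = 0.1),
                       flags = plasticity_flags(FALSE, FALSE, FALSE, FALSE, TRUE),
                       noise_seed = 21, sp_seed = 22)
  d <- activity_binomial_distance(run$record$activity, 200, 0.1)
  expect_lt(d, 0.05)
})
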