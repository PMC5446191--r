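test_that("initialization produces the documented structure", {
  st <- init_network(sorn_params(N_E = 200), seed = 1)
  expect_equal(dim(st$W_EE), c(200, 200))
  expect_equal(dim(st$W_EI), c(200, 40))
  expect_equal(dim(st$W_IE), c(40, 200))
  expect_true(all(diag(st$W_EE) == 0))
  expect_true(all(st$W_IE > 0))  # fully connected
  # every connected row sums to 1 after initial normalization
  for (W in list(st$W_EE, st$W_EI, st$W_IE)) {
    rs <- rowSums(W)
    expect_true(all(abs(rs[rs > 0] - 1) < 1e-12))
  }
  expect_true(all(st$T_E >= 0 & st$T_E <= 0.5))
  expect_true(all(st$T_I >= 0 & st$T_I <= 1))
  expect_equal(st$H_ip, rep(0.1, 200))  # degenerate at mu_ip when variance 0
  expect_true(all(st$x == 0) && all(st$y == 0))
})

test_that("initial connection fractions match the wiring probabilities", {
  fr_ee <- sapply(1:20, function(s) {
    connection_fraction(init_network(sorn_params(N_E = 200), seed = s))
  })
  expect_equal(mean(fr_ee), 0.1, tolerance = 0.02)
  fr_ei <- sapply(1:20, function(s) {
    st <- init_network(sorn_params(N_E = 200), seed = s + 100)
    mean(st$W_EI > 0)
  })
  expect_equal(mean(fr_ei), 0.2, tolerance = 0.02)
})

test_that("per-unit target rates can be heterogeneous", {
  st <- init_network(sorn_params(N_E = 200, sigma_ip_sq = 0.001), seed = 5)
  expect_gt(stats::sd(st$H_ip), 0)
  expect_lt(abs(mean(st$H_ip) - 0.1), 0.01)
})

test_that("state update follows the threshold dynamics", {
  st <- init_network(tiny_params(), seed = 2)
  # huge external drive fires a unit regardless of thresholds
  u <- numeric(40); u[3] <- 1e7
  expect_equal(update_states(st, u_ext = u)$x[3], 1L)
  # all-silent network with positive thresholds stays silent
  nxt <- update_states(st)
  expect_true(all(nxt$x == 0) && all(nxt$y == 0))
  # drive exactly at threshold fires (step function is 1 at 0)
  st0 <- st
  st0$T_E[] <- 0.5
  u <- numeric(40); u[1] <- 0.5
  expect_equal(update_states(st0, u_ext = u)$x[1], 1L)
})

test_that("STDP potentiates, depresses and cancels by spike order", {
  W <- matrix(0, 4, 4)
  W[2, 1] <- 0.5  # synapse 1 -> 2
  # presynaptic 1 fired first, postsynaptic 2 follows: potentiation
  W1 <- stdp_update(W, x_now = c(0, 1, 0, 0), x_prev = c(1, 0, 0, 0), 0.004)
  expect_equal(W1[2, 1], 0.504)
  # reversed order: depression
  W2 <- stdp_update(W, x_now = c(1, 0, 0, 0), x_prev = c(0, 1, 0, 0), 0.004)
  expect_equal(W2[2, 1], 0.496)
  # both fire at both steps: terms cancel
  W3 <- stdp_update(W, x_now = c(1, 1, 0, 0), x_prev = c(1, 1, 0, 0), 0.004)
  expect_equal(W3[2, 1], 0.5)
})

test_that("STDP only touches existing synapses and prunes to zero", {
  W <- matrix(0, 3, 3)
  W[2, 1] <- 0.003  # weaker than one depression step
  out <- stdp_update(W, x_now = c(1, 0, 0), x_prev = c(0, 1, 0), 0.004)
  expect_equal(out[2, 1], 0)           # pruned
  expect_equal(out[1, 2], 0)           # never existed, not created
  expect_true(all(out >= 0))
})

test_that("iSTDP follows the gated potentiation/depression rule", {
  W <- matrix(0.5, 2, 2)
  # presynaptic inhibitory fired, postsynaptic excitatory fired anyway
  out <- istdp_update(W, x_now = c(1, 0), y_prev = c(1, 0),
                      eta_inh = 0.001, mu_ip = 0.1)
  expect_equal(out[1, 1], 0.5 + 0.01)   # -0.001 * (1 - 11) = +0.01
  expect_equal(out[2, 1], 0.5 - 0.001)  # successful inhibition: depression
  expect_equal(out[1, 2], 0.5)          # presynaptic silent: no change
  expect_error(istdp_update(W, c(1, 0), c(1, 0), 0.001, mu_ip = 0),
               "positive")
})

test_that("iSTDP floors at zero but keeps the connection slot", {
  W <- matrix(0.0005, 1, 1)
  mask <- matrix(1L, 1, 1)
  out <- istdp_update(W, x_now = 0L, y_prev = 1L, 0.001, 0.1, mask = mask)
  expect_equal(out[1, 1], 0)
  # the slot can be potentiated again
  out2 <- istdp_update(out, x_now = 1L, y_prev = 1L, 0.001, 0.1, mask = mask)
  expect_equal(out2[1, 1], 0.01)
})

test_that("synaptic normalization rescales rows and skips empty ones", {
  W <- rbind(c(0.2, 0.3, 0.5), c(2, 2, 0), c(0, 0, 0))
  out <- synaptic_normalization(W)
  expect_equal(out[1, ], c(0.2, 0.3, 0.5))
  expect_equal(out[2, ], c(0.5, 0.5, 0))
  expect_equal(out[3, ], c(0, 0, 0))
  expect_error(synaptic_normalization(matrix(-1, 1, 1)), "non-negative")
})

test_that("structural plasticity creates one synapse of the right weight", {
  W <- matrix(0, 5, 5)
  out <- withr::with_seed(1, structural_plasticity(W, p_sp = 1, eta_sp = 0.001))
  expect_equal(sum(out > 0), 1)
  expect_equal(out[out > 0], 0.001)
  expect_true(all(diag(out) == 0))
  # p = 0 never creates
  out0 <- withr::with_seed(1, structural_plasticity(W, p_sp = 0))
  expect_identical(out0, W)
  # fully connected off-diagonal: no-op
  Wf <- matrix(1, 3, 3); diag(Wf) <- 0
  expect_identical(withr::with_seed(1, structural_plasticity(Wf, p_sp = 1)), Wf)
})

test_that("intrinsic plasticity nudges thresholds toward the target rate", {
  T_E <- c(0.2, 0.2)
  out <- intrinsic_plasticity(T_E, x_now = c(1, 0), H_ip = c(0.1, 0.1),
                              eta_ip = 0.01)
  expect_equal(out, c(0.2 + 0.009, 0.2 - 0.001))
  expect_equal(intrinsic_plasticity(T_E, c(1, 0), c(0.1, 0.1), 0), T_E)
})

test_that("a step with all rules off changes only the states and clock", {
  st <- poked_state()
  nxt <- step_sorn(st, flags = frozen_flags())
  expect_identical(nxt$W_EE, st$W_EE)
  expect_identical(nxt$W_EI, st$W_EI)
  expect_identical(nxt$T_E, st$T_E)
  expect_equal(nxt$t, st$t + 1L)
})

test_that("the internal state ignores external input but keeps recurrence", {
  st <- poked_state()
  without_u <- internal_state(st)
  expect_length(without_u, 40)
  idx <- which(without_u == 0)[1]  # a unit that recurrence alone cannot fire
  u <- numeric(40); u[idx] <- 1e7
  with_u <- update_states(st, u_ext = u)$x
  expect_equal(with_u[idx], 1L)
  expect_equal(without_u[idx], 0L)
  # apart from the driven unit the two agree
  expect_equal(with_u[-idx], without_u[-idx])
})
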