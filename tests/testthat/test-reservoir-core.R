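test_that("topology has requested density, zero diagonal and is reproducible", {
  top <- build_topology(n_res = 200, n_in = 3, n_out = 2, p_conn = 0.1,
                        seed = 42)
  j <- as.matrix(top$j_fast)
  expect_equal(diag(j), rep(0, 200))
  n_offdiag <- 200 * 199
  n_nz <- sum(j != 0)
  # binomial 3-sigma band around p * N(N-1)
  expect_lt(abs(n_nz - 0.1 * n_offdiag), 3 * sqrt(n_offdiag * 0.1 * 0.9))
  # nonzero weights scale: sd ~ g / sqrt(pN)
  expect_equal(sd(j[j != 0]), top$weight_scale / sqrt(0.1 * 200),
               tolerance = 0.05)
  top2 <- build_topology(n_res = 200, n_in = 3, n_out = 2, p_conn = 0.1,
                         seed = 42)
  expect_identical(as.matrix(top$j_fast), as.matrix(top2$j_fast))
  top3 <- build_topology(n_res = 200, n_in = 3, n_out = 2, p_conn = 0.1,
                         seed = 43)
  expect_false(identical(as.matrix(top$j_fast), as.matrix(top3$j_fast)))
})

test_that("dense limit keeps only the diagonal empty", {
  top <- build_topology(n_res = 3, n_in = 1, n_out = 1, p_conn = 1, seed = 1)
  j <- as.matrix(top$j_fast)
  expect_equal(sum(j != 0), 6)
  expect_equal(diag(j), rep(0, 3))
})

test_that("bad topology arguments are rejected", {
  expect_error(build_topology(0, 1, 1, 0.1), class = "dar_argument_error")
  expect_error(build_topology(10, 1, 1, 0), class = "dar_argument_error")
  expect_error(build_topology(10, 1, 1, 1.2), class = "dar_argument_error")
})

test_that("membrane stays at rest without input and first spike matches the closed form", {
  lif <- lif_params()
  st <- reservoir_state(1, lif)
  for (t in 1:50) st <- lif_step(st, 0, lif)
  expect_equal(st$v, lif$v_rest)
  expect_equal(sum(st$spikes_t), 0)

  # constant 25 mV drive: t* = -20 log(1 - 20/25) = 32.19 ms
  st <- reservoir_state(1, lif)
  t_spike <- NA
  for (t in 1:60) {
    st <- lif_step(st, 25, lif)
    if (st$spikes_t[1] == 1) { t_spike <- t; break }
  }
  t_star <- oracle_lif_first_spike(25)
  expect_equal(t_star, 32.19, tolerance = 1e-3)
  expect_lte(abs(t_spike - t_star), 1)  # within one dt
})

test_that("refractory period blocks spikes for t_ref - dt steps after a crossing", {
  lif <- lif_params()
  st <- reservoir_state(1, lif)
  spikes <- integer(0)
  for (t in 1:120) {
    st <- lif_step(st, 500, lif)  # far above threshold every step
    if (st$spikes_t[1] == 1) spikes <- c(spikes, t)
  }
  expect_gt(length(spikes), 3)
  expect_true(all(diff(spikes) == lif$t_ref))  # blocked at t+1 ... t+4 only
})

test_that("constant-current spike period matches closed-form ISI + refractory", {
  lif <- lif_params()
  current <- 60
  st <- reservoir_state(1, lif)
  spikes <- integer(0)
  for (t in 1:400) {
    st <- lif_step(st, current, lif)
    if (st$spikes_t[1] == 1) spikes <- c(spikes, t)
  }
  isi <- unique(diff(spikes))
  t_star <- oracle_lif_first_spike(current)
  expect_lte(max(abs(isi - (lif$t_ref + t_star))), 1)
})

test_that("non-finite currents raise a numeric error naming the neuron", {
  st <- reservoir_state(3)
  expect_error(lif_step(st, c(0, NaN, 0)), class = "dar_numeric_error")
  expect_error(lif_step(st, c(0, 0, Inf)), regexp = "neuron")
})

test_that("traces decay exponentially and jump by one on spikes", {
  syn <- synapse_params()
  st <- reservoir_state(1)
  st$f_trace <- 1
  st$s_trace <- 1
  for (k in 1:5) st <- update_traces(st, 0L, syn)
  expect_equal(st$f_trace, exp(-5 / 5), tolerance = 1e-12)
  expect_equal(st$s_trace, exp(-5 / 100), tolerance = 1e-12)

  st0 <- reservoir_state(1)
  st0 <- update_traces(st0, 1L, syn)
  expect_equal(st0$f_trace, 1)
  expect_equal(st0$s_trace, 1)

  # ratio of the two decays after 10 ms from equal values
  st1 <- reservoir_state(1)
  st1$f_trace <- 2; st1$s_trace <- 2
  for (k in 1:10) st1 <- update_traces(st1, 0L, syn)
  expect_equal(st1$s_trace / st1$f_trace, exp(10 / 5 - 10 / 100),
               tolerance = 1e-12)
})

test_that("trace update rejects non-binary spikes and keeps traces non-negative", {
  st <- reservoir_state(4)
  expect_error(update_traces(st, c(0, 2, 0, 0)), class = "dar_argument_error")
  st <- update_traces(st, c(1L, 0L, 1L, 0L))
  for (k in 1:30) st <- update_traces(st, c(0L, 0L, 0L, 0L))
  expect_true(all(st$f_trace >= 0))
  expect_true(all(st$s_trace >= 0))
})

test_that("reservoir run is quiescent on zero input, pads short input, and is deterministic", {
  dn <- tiny_trained_driven()
  run0 <- run_reservoir(dn, NULL, n_steps = 80)
  expect_equal(sum(run0$raster), 0)

  inp <- matrix(1, 2, 30)  # 30-step drive, 80-step trial
  runA <- run_reservoir(dn, inp * 40, n_steps = 80)
  runB <- run_reservoir(dn, inp * 40, n_steps = 80)
  expect_identical(runA$raster, runB$raster)
  expect_equal(ncol(runA$raster), 80)

  expect_error(run_reservoir(dn, matrix(0, 5, 10), n_steps = 20),
               class = "dar_argument_error")
})

test_that("raster obeys refractoriness and membrane bounds under positive drive", {
  dn <- tiny_trained_driven()
  inp <- matrix(50, 2, 100)
  run <- run_reservoir(dn, inp, n_steps = 100, record = c("spikes", "v"))
  # every neuron: consecutive spikes >= t_ref apart
  for (i in seq_len(nrow(run$raster))) {
    ts <- which(run$raster[i, ] == 1)
    if (length(ts) > 1) expect_true(all(diff(ts) >= dn$lif$t_ref))
  }
  expect_true(all(run$v <= dn$lif$v_th))
})
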