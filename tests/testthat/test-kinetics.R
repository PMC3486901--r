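test_that("propensities implement the pair-counting kinetics", {
  r <- rate_parameters(a1 = 1, a2 = 0.5, b = 2)
  # a single loop: only bulk fission is possible
  a <- propensities(c(0, 40, 0), r)
  expect_equal(unname(a > 0), c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(a[["fiss_tip_tip"]], 2 * 40)
  # two tips: x1 (x1 - 1) = 2, i.e. one pair at rate 2 a1
  expect_equal(propensities(c(2, 0, 0), rate_parameters(a1 = 1, a2 = 0, b = 0))[[1]], 2)
  # branching-point fission carries the 3/2 edge factor
  expect_equal(propensities(c(0, 0, 10), r)[["fiss_tip_side"]], 1.5 * 2 * 10)
  expect_error(propensities(c(-1, 0, 0), r), "non-negative")
})

test_that("a fixed seed reproduces the trajectory bit for bit", {
  cfg <- simulation_config(rate_parameters(c1 = 0.5, c2 = 0.02), L = 60,
                           seed = 99, max_events = 3000, burn_in = 500,
                           sample_every = 250)
  t1 <- simulate_network(cfg, record = "stats")
  t2 <- simulate_network(cfg, record = "stats")
  expect_identical(t1$samples, t2$samples)
  expect_identical(t1$final_state, t2$final_state)
})

test_that("pure fragmentation is absorbed at the fully fragmented state", {
  cfg <- simulation_config(rate_parameters(a1 = 0, a2 = 0, b = 1), L = 40,
                           seed = 5, max_events = 1e5, burn_in = 0,
                           sample_every = 10, initial_state = "loop")
  traj <- simulate_network(cfg)
  expect_true(traj$absorbed)
  expect_equal(unname(census(traj$final_state)), c(80L, 0L, 0L))
})

test_that("pure fusion of two edges absorbs within two events into loops", {
  r <- rate_parameters(a1 = 1, a2 = 0, b = 0)
  set.seed(31)
  for (rep in 1:25) {
    state <- network_state(2, "fragmented")
    n <- 0L
    repeat {
      out <- step_network(state, r)
      if (out$absorbed) break
      state <- out$state
      n <- n + 1L
    }
    expect_lte(n, 2L)
    expect_equal(unname(census(state)), c(0L, 2L, 0L))
  }
})

test_that("waiting times at a fixed census are exponential with the summed propensity", {
  r <- rate_parameters(c1 = 0.2, c2 = 0.1)
  set.seed(17)
  state <- random_state(20, 30)
  total <- sum(propensities(census(state), r))
  dts <- vapply(1:800, function(k) step_network(state, r)$dt, numeric(1))
  ks <- ks.test(dts, "pexp", rate = total)
  expect_gt(ks$p.value, 0.01)
})

test_that("compiled snapshots agree with the R-level censuses", {
  for (seed in 1:5) {
    cfg <- simulation_config(rate_parameters(c1 = 0.5, c2 = 0.02), L = 80,
                             seed = seed, max_events = 4000, burn_in = 2000,
                             sample_every = 4000)
    traj <- simulate_network(cfg, record = "stats")
    state <- traj$final_state
    validate_network_state(state)
    last <- traj$samples[nrow(traj$samples), ]
    expect_identical(unname(census(state)),
                     c(last$x1, last$x2, last$x3))
    # structural statistics recomputed in R match the compiled ones
    cl <- cluster_census(state)
    expect_equal(cl$largest_fraction, last$largest_fraction)
    expect_equal(cl$susceptibility, last$susceptibility)
    # and the R segment census matches the independent traversal oracle
    segs <- segment_census(state)
    got <- segs[order(segs$type, segs$length), c("length", "type")]
    want <- oracle_segments(state)
    expect_equal(unname(as.matrix(got)), unname(as.matrix(want)))
  }
})

test_that("stationary simulation means approach the mean-field steady state", {
  set.seed(1)
  L <- 200
  cfg <- simulation_config(rate_parameters(c1 = 1, c2 = 0.01), L = L,
                           burn_in = 200 * L, max_events = 3000 * 20,
                           sample_every = 20)
  traj <- simulate_network(cfg)
  ss <- steady_state(1, 0.01, L)
  m <- colMeans(traj$samples[, c("x1", "x2", "x3")])
  expect_lt(abs(m[["x1"]] - ss$x1) / ss$x1, 0.06)
  expect_lt(abs(m[["x2"]] - ss$x2) / ss$x2, 0.02)
  expect_lt(abs(m[["x3"]] - ss$x3) / ss$x3, 0.06)
})

test_that("single-step expected drift matches the deterministic kinetics", {
  set.seed(3)
  r <- rate_parameters(c1 = 0.5, c2 = 0.02)
  cfg <- simulation_config(r, L = 100, seed = 3, max_events = 1000,
                           burn_in = 500, sample_every = 1000)
  state <- simulate_network(cfg)$final_state
  cen0 <- census(state)
  n <- 4000
  dx <- matrix(0, n, 3)
  dts <- numeric(n)
  for (k in seq_len(n)) {
    out <- step_network(state, r)
    dx[k, ] <- census(out$state) - cen0
    dts[k] <- out$dt
  }
  emp <- colMeans(dx) / mean(dts)
  rhs <- ode_rhs(cen0, r)
  se <- apply(dx, 2, sd) / sqrt(n) / mean(dts)
  expect_true(all(abs(emp - unname(rhs)) < 3.5 * se + 1e-9))
})

test_that("calibrated rates reproduce the target physical event frequency", {
  cal <- calibrate_rates(1, 0.01, 1000, target_rate = 0.25)
  expect_equal(cal$b2 / cal$b1, 1.5)
  cfg <- simulation_config(cal, L = 1000, seed = 12, burn_in = 2e4,
                           max_events = 2e5, sample_every = 2e4)
  traj <- simulate_network(cfg)
  span <- diff(range(traj$samples$time))
  rate <- (2e5 - 2e4) / span  # events per second over the sampled window
  expect_lt(abs(rate - 0.25) / 0.25, 0.1)
})
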