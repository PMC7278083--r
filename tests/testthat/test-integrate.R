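test_that("one RK4 step reproduces the exact tableau polynomial", {
  # single pool with v = c: m0 follows dy/dt = -y, y0 = 1, so one step of
  # size h gives the degree-4 Taylor polynomial of exp(-h)
  sys <- single_pool_system(v = 1, c = 1)
  y1 <- rk4_step(sys, initial_state(sys), 0, 0.1)
  m0 <- y1[sys$node_tab$weight == 0L]
  expect_equal(m0, 1 - 0.1 + 0.005 - 0.1^3 / 6 + 0.1^4 / 24,
               tolerance = 1e-14)
  # a stationary state is left unchanged
  sys0 <- toy_system(1, model = local({
    m <- toy_model(); m$labeling$A <- c("00" = 1); m
  }))
  y <- initial_state(sys0)
  expect_equal(rk4_step(sys0, y, 0, 0.1), y)
})

test_that("constant-step RK4 converges at fourth order", {
  v <- 2; cc <- 4
  sys <- single_pool_system(v, cc)
  errs <- vapply(c(0.02, 0.01, 0.005), function(h) {
    tr <- integrate_constant(sys, step = h, t_end = 1)
    m1 <- tr$states[sys$node_tab$weight == 1L, ncol(tr$states)]
    abs(m1 - (1 - exp(-(v / cc))))
  }, numeric(1))
  orders <- log2(errs[-length(errs)] / errs[-1])
  expect_true(all(orders > 3.5 & orders < 4.5))
})

test_that("Cash-Karp error estimate decays at fifth order", {
  sys <- single_pool_system(v = 1, c = 1)
  y0 <- initial_state(sys)
  errs <- vapply(c(0.2, 0.1, 0.05), function(h) {
    max(abs(cash_karp_step(sys, y0, 0, h)$err))
  }, numeric(1))
  orders <- log2(errs[-length(errs)] / errs[-1])
  expect_true(all(orders > 4.5 & orders < 5.5))
})

test_that("the toy labeling transient matches the isotopomer oracle", {
  model <- toy_model()
  sys <- toy_system(1)
  tr <- integrate_constant(sys)          # Table-style defaults: h 0.005, 10 s
  # F m4 rises monotonically toward 1 under fully labeled substrate
  m4 <- tr$states[sys$node_tab$key == "F/1,2,3,4.m4", ]
  expect_true(all(diff(m4) >= -1e-12))
  expect_gt(m4[length(m4)], 0.8)
  expect_lt(m4[length(m4)], 1)
  # MID normalization along the whole trajectory
  cons <- conservation_report(tr)
  expect_true(all(cons$mid$max_deviation < 1e-9))
  # against the brute-force full-isotopomer reference
  expect_lt(oracle_deviation(tr, model, seq(0, 10, 0.5)), 1e-8)
})

test_that("unlabeled substrate keeps every m0 at one", {
  model <- toy_model()
  model$labeling$A <- c("00" = 1)
  sys <- toy_system(1, model = model)
  tr <- integrate_constant(sys, step = 0.01, t_end = 2)
  expect_equal(max(abs(tr$states[sys$node_tab$weight == 0L, ] - 1)), 0)
  expect_equal(max(abs(tr$states[sys$node_tab$weight > 0L, ])), 0)
})

test_that("the pilot set covers every metabolite with weight-0 nodes", {
  sys <- toy_system(1)
  pil <- pilot_nodes(sys)
  expect_setequal(pil$node_keys,
                  c("B/1,2.m0", "C/1,2.m0", "E/1,2.m0", "F/1,2,3,4.m0"))
  expect_equal(max(pil$blocks), 4L)
  # single-metabolite model: one pilot node
  sp <- single_pool_system()
  expect_length(pilot_nodes(sp)$node_idx, 1)
  # coverage property on generated fixtures
  for (seed in 1:3) {
    s2 <- toy_system(1, model = random_network(6, seed = seed))
    p2 <- pilot_nodes(s2)
    mets <- unique(s2$node_tab$metabolite)
    pil_mets <- s2$node_tab$metabolite[p2$node_idx]
    expect_setequal(intersect(mets, pil_mets), mets)
  }
})

test_that("adaptive integration tracks a dense reference with fewer steps", {
  sys <- toy_system(1)
  ta <- integrate_adaptive(sys)
  tref <- integrate_constant(sys, step = 5e-4)
  tt <- seq(0, 10, 0.25)
  ref <- tref$states[, match(round(tt, 10), round(tref$times, 10))]
  expect_lt(max(abs(trajectory_states_at(ta, tt) - ref)), 1e-5)
  expect_lt(ta$n_accept, 10 / 0.005)   # far fewer steps than constant h
  # tightening the tolerance 100x reduces the deviation
  ta2 <- integrate_adaptive(sys, controller = step_controller(
    tol_scaling = 1e-11, tol_addition = 1e-9))
  dev1 <- max(abs(trajectory_states_at(ta, tt) - ref))
  dev2 <- max(abs(trajectory_states_at(ta2, tt) - ref))
  expect_lt(dev2, dev1)
  expect_gt(ta2$n_accept, ta$n_accept)
})

test_that("parallel scheduling reproduces the serial trajectory exactly", {
  sys <- toy_system(1)
  ts <- integrate_constant(sys, step = 0.01, t_end = 2)
  for (w in c(1L, 2L, 4L)) {
    tp <- run_parallel(sys, "constant", w, step = 0.01, t_end = 2)
    expect_identical(tp$states, ts$states)
    expect_identical(tp$times, ts$times)
  }
  ta <- integrate_adaptive(sys, t_end = 5)
  for (w in c(1L, 3L)) {
    tap <- run_parallel(sys, "adaptive", w, t_end = 5)
    expect_identical(tap$h, ta$h)       # pilot h-sequence worker-independent
    expect_identical(tap$states, ta$states)
  }
})

test_that("the scheduler watchdog aborts on an unsatisfiable dependency", {
  sys <- toy_system(1)
  sys$blocks[[2]]$deps <- c(sys$blocks[[2]]$deps, 999L)
  expect_error(run_parallel(sys, "constant", 2, step = 0.1, t_end = 0.2),
               "deadlock")
})

test_that("lambda aggregation leaves the integrated labeling unchanged", {
  tr1 <- simulate_labeling(toy_model(), lambda = 1, step = 0.01, t_end = 2)
  tr10 <- simulate_labeling(toy_model(), lambda = 10, step = 0.01, t_end = 2)
  df1 <- tidy(tr1); df10 <- tidy(tr10)
  merged <- merge(df1, df10, by = c("time", "emu", "weight"))
  expect_lt(max(abs(merged$value.x - merged$value.y)), 1e-12)
})

test_that("dense interpolation is exact on grid points and O(h^4) between", {
  v <- 2; cc <- 4
  sys <- single_pool_system(v, cc)
  tr <- integrate_constant(sys, step = 0.1, t_end = 2)
  tt <- c(0.05, 0.55, 1.23, 1.95)
  m1 <- trajectory_states_at(tr, tt)[sys$node_tab$weight == 1L, ]
  expect_lt(max(abs(m1 - (1 - exp(-(v / cc) * tt)))), 1e-6)
  expect_identical(trajectory_states_at(tr, tr$times[5])[, 1], tr$states[, 5])
})
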