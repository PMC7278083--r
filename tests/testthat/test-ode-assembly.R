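test_that("MID convolution matches the brute-force oracle", {
  expect_equal(convolve_mid(c(1, 0), c(1, 0)), c(1, 0, 0))
  expect_equal(convolve_mid(c(0.5, 0.5), c(0.5, 0.5)), c(0.25, 0.5, 0.25))
  set.seed(42)
  for (i in 1:20) {
    a <- runif(3); b <- runif(4)
    expect_equal(convolve_mid(a, b), conv_oracle(a, b), tolerance = 1e-14)
  }
  expect_error(convolve_mid(c(-1, 0), c(1, 0)))
})

test_that("transition tensor entries follow the weight composition rule", {
  net <- trace_emus(toy_model(), list(emu("D", 1:4)))
  prods <- vapply(net$reactions, function(r) emu_key(r$product), character(1))
  r_d <- net$reactions[[which(prods == "D/1,2,3,4")]]
  Q <- build_transition_tensor(r_d)
  expect_true(any(Q$i1 == 1 & Q$i2 == 1 & Q$j == 2))  # m1 + m1 -> m2
  # for any fixed reactant tuple exactly one product index fires
  expect_equal(nrow(Q), nrow(unique(Q[, c("i1", "i2")])))
  expect_equal(Q$j, Q$i1 + Q$i2)
  expect_equal(nrow(Q), 9)  # all 3 x 3 reactant weight tuples

  # unimolecular tensor is the identity pairing of weights
  r_c <- net$reactions[[which(prods == "C/1,2")]]
  Qu <- build_transition_tensor(r_c)
  expect_equal(Qu$j, Qu$i1)
})

test_that("eliminating matrices mark consumed mass isotopomers", {
  expect_equal(build_eliminating_matrix(c("C", "C", "C"), "C"), -diag(3))
  expect_equal(build_eliminating_matrix(c("A", "B", "A"), "B"),
               diag(c(0, -1, 0)))
  # V_5 consumes C, so its eliminating matrix on C's block is -I
  expect_equal(build_eliminating_matrix(rep("C", 3),
                                        toy_model()$reactions[[5]]$reactants),
               -diag(3))
})

test_that("a single labeled pool follows the first-order step response", {
  v <- 2; cc <- 4
  sys <- single_pool_system(v, cc)
  tr <- integrate_constant(sys, step = 0.01, t_end = 5)
  m1 <- tr$states[sys$node_tab$weight == 1L, ]
  expect_lt(max(abs(m1 - (1 - exp(-(v / cc) * tr$times)))), 1e-9)
})

test_that("tensor and vector backends agree at random states", {
  fixtures <- list(toy_system(1), toy_system(4),
                   toy_system(1, model = random_network(6, seed = 2)))
  set.seed(7)
  for (sys_v in fixtures) {
    sys_t <- assemble_cascade(sys_v$partition, sys_v$model, "tensor")
    for (i in 1:100) {
      x <- runif(sys_v$nx)
      expect_lt(max(abs(cascade_rhs(sys_v, x) - cascade_rhs(sys_t, x))),
                1e-12)
    }
  }
})

test_that("rhs weight sums vanish per EMU for flux-balanced models", {
  set.seed(11)
  for (sys in list(toy_system(1), toy_system(1, model = random_network(6, seed = 4)))) {
    nt <- sys$node_tab
    for (i in 1:100) {
      d <- cascade_rhs(sys, random_mid_state(sys))
      for (k in unique(nt$emu_key)) {
        rows <- which(nt$emu_key == k)
        if (length(rows) == nt$size[rows[1]] + 1L) {
          expect_lt(abs(sum(d[rows])), 1e-12 * max(1, max(abs(d[rows]))))
        }
      }
    }
  }
})

test_that("unlabeled substrate makes the unlabeled state a fixed point", {
  model <- toy_model()
  model$labeling$A <- c("00" = 1)
  sys <- toy_system(1, model = model)
  expect_equal(max(abs(cascade_rhs(sys, initial_state(sys)))), 0)
})

test_that("fully labeled substrate drives only one-reaction-reachable nodes", {
  sys <- toy_system(1)
  d <- cascade_rhs(sys, initial_state(sys))
  keys <- sys$node_tab$key
  # hand evaluation: only B gains weight from A in one reaction
  expect_equal(d[keys == "B/1,2.m2"], 2)    # v1 * 1 / C_B = 10/5
  expect_equal(d[keys == "B/1,2.m0"], -2)
  expect_equal(max(abs(d[!(keys %in% c("B/1,2.m0", "B/1,2.m2"))])), 0)
  expect_true(all(d[sys$node_tab$weight > 0] >= 0))
})

test_that("the stationary MID map is a fixed point of the assembled rhs", {
  sys <- toy_system(1)
  ss <- stationary_solution(sys$network)
  x <- numeric(sys$nx)
  for (k in unique(sys$node_tab$emu_key)) {
    rows <- which(sys$node_tab$emu_key == k)
    x[rows] <- ss[[k]][sys$node_tab$weight[rows] + 1L]
  }
  expect_lt(max(abs(cascade_rhs(sys, x))), 1e-12)
})

test_that("rhs is exactly affine without bimolecular EMU reactions", {
  model <- random_network(5, seed = 6, bimolecular_fraction = 0)
  sys <- toy_system(1, model = model)
  expect_length(unlist(lapply(sys$blocks, function(b) b$bl$t_local)), 0)
  set.seed(3)
  x <- runif(sys$nx); y <- runif(sys$nx); al <- 0.3; be <- 0.7
  f0 <- cascade_rhs(sys, numeric(sys$nx))
  lhs <- cascade_rhs(sys, al * x + be * y)
  rhs_aff <- al * cascade_rhs(sys, x) + be * cascade_rhs(sys, y) +
    (1 - al - be) * f0
  expect_lt(max(abs(lhs - rhs_aff)), 1e-12)
})

test_that("system JSON bundle round-trips its block structure", {
  sys <- toy_system(4)
  path <- tempfile(fileext = ".json")
  write_cascade_json(sys, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  expect_equal(length(back$blocks), length(sys$blocks))
  expect_equal(vapply(back$nodes, `[[`, character(1), "key"),
               sys$node_tab$key)
  b1 <- back$blocks[[1]]
  M <- Matrix::sparseMatrix(i = b1$L$i, j = b1$L$j, x = b1$L$x,
                            dims = unlist(b1$L$dim))
  expect_equal(as.matrix(M), as.matrix(sys$blocks[[1]]$Lb))
})
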