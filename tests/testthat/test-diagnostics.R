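test_that("stiffness ratio handles the canonical cases", {
  expect_equal(stiffness_ratio(diag(c(-1, -100))), 100)
  expect_equal(stiffness_ratio(matrix(-0.5)), 1)
  r <- stiffness_ratio(diag(c(0, -1)))
  expect_true(is.na(r))
  expect_true(attr(r, "undefined"))
  # random stable matrices against a characteristic-polynomial root oracle
  set.seed(5)
  for (i in 1:5) {
    M <- matrix(rnorm(25), 5) - 6 * diag(5)
    # oracle: roots of the characteristic polynomial, with coefficients
    # from the Faddeev-LeVerrier trace recursion
    Mk <- diag(5); coefs <- numeric(6); coefs[1] <- 1
    for (k in 1:5) {
      Mk <- M %*% Mk
      if (k > 1) Mk <- Mk + coefs[k] * M
      coefs[k + 1] <- -sum(diag(Mk)) / k
    }
    lam <- polyroot(rev(coefs))
    oracle <- max(abs(Re(lam))) / min(abs(Re(lam)))
    expect_equal(stiffness_ratio(M), oracle, tolerance = 1e-6)
  }
})

test_that("toy cascade spectra are strictly negative and stable", {
  sys <- toy_system(1)
  rep <- spectral_check(sys)
  expect_true(all(rep$stable))
  expect_true(all(rep$max_re < 0))
  # singleton blocks: eigenvalue is exactly -v_out / C
  b_m0 <- which(sys$node_tab$key == "B/1,2.m0")
  expect_equal(rep$max_re[sys$node_tab$block[b_m0]], -10 / 5)
  # stiffness ratio is reported per aggregation level
  for (l in c(1, 4, 14)) {
    s2 <- toy_system(l)
    r2 <- spectral_check(s2)
    expect_true(all(r2$stable))
    expect_true(all(is.finite(r2$stiffness_ratio)))
  }
})

test_that("a zero-flux pool is flagged as neutrally stable", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("reaction\tstoichiometry\ttransition",
               "U\tS -> X\t#A -> #A",
               "O\tX -> X_OUT\t#A -> #A",
               "G1\tX -> G\t#A -> #A",
               "G2\tG -> G_OUT\t#A -> #A"), tsv)
  yml <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    fluxes = list(U = 1, O = 1, G1 = 0, G2 = 0),
    pool_sizes = list(X = 1, G = 1),
    labeling = list(S = list("1" = 1)),
    measured = list(list(metabolite = "G", atoms = list(1)))), yml)
  model <- parse_model(tsv, yml)
  sys <- toy_system(1, model = model)
  rep <- spectral_check(sys)
  expect_true(any(!rep$stable))
  g_block <- sys$node_tab$block[sys$node_tab$metabolite == "G"][1]
  expect_equal(rep$max_re[rep$block == g_block], 0)
})

test_that("stationary solution matches the isotopomer steady state", {
  model <- toy_model()
  model$labeling$A <- c("11" = 0.5, "00" = 0.5)
  net <- trace_emus(model)
  ss <- stationary_solution(net)
  # fully labeled input sends every EMU to m_max = 1
  ss_full <- stationary_solution(net, labeling = list(A = c("11" = 1)))
  for (k in setdiff(names(net$emus), net$input_keys)) {
    expect_equal(unname(ss_full[[k]][length(ss_full[[k]])]), 1,
                 tolerance = 1e-12)
  }
  # 50% labeled substrate: agree with the brute-force oracle run to
  # effective stationarity
  orc <- isotopomer_oracle(model, c(0, 400))
  for (k in names(orc)) {
    expect_lt(max(abs(ss[[k]] - orc[[k]][, 2])), 1e-6)
  }
  # and with a long SCC-based integration
  sys <- assemble_cascade(scc_partition(prune_to_measured(
    build_misotope_graph(net)), 1), model)
  tr <- integrate_adaptive(sys, t_end = 180)
  xend <- tr$states[, ncol(tr$states)]
  for (k in names(orc)) {
    rows <- which(sys$node_tab$emu_key == k)
    rows <- rows[order(sys$node_tab$weight[rows])]
    expect_lt(max(abs(xend[rows] - ss[[k]])), 1e-6)
  }
})

test_that("the isotopomer oracle solves a 2-carbon pool in closed form", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("reaction\tstoichiometry\ttransition",
               "U\tS -> P\t#AB -> #AB",
               "O\tP -> P_OUT\t#AB -> #AB"), tsv)
  yml <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    fluxes = list(U = 3, O = 3),
    pool_sizes = list(P = 2),
    labeling = list(S = list("11" = 1)),
    measured = list(list(metabolite = "P", atoms = list(1, 2)))), yml)
  model <- parse_model(tsv, yml)
  tt <- c(0, 0.5, 1, 2)
  orc <- isotopomer_oracle(model, tt)
  k <- 3 / 2
  expect_lt(max(abs(orc[["P/1,2"]][3, ] - (1 - exp(-k * tt)))), 1e-9)
  expect_lt(max(abs(orc[["P/1,2"]][1, ] - exp(-k * tt))), 1e-9)
  expect_lt(max(abs(orc[["P/1,2"]][2, ])), 1e-9)
  # marginalization: MIDs sum to one exactly
  expect_lt(max(abs(colSums(orc[["P/1,2"]]) - 1)), 1e-9)
  # the guard refuses oversized systems
  expect_error(isotopomer_oracle(model, tt, guard = 2), "exceeds guard")
})

test_that("SCC simulation agrees with the oracle on generated networks", {
  for (seed in c(2, 5)) {
    model <- random_network(6, seed = seed)
    sys <- toy_system(1, model = model)
    mets <- unique(sys$node_tab$metabolite)
    kmax <- max(isocascade:::consumption_rates(model)[mets] /
                  model$pool_sizes[mets])
    h <- 0.03 / kmax
    tr <- integrate_constant(sys, step = h, t_end = 300 * h)
    expect_lt(oracle_deviation(tr, model, seq(0, 300 * h, length.out = 5)),
              1e-8)
  }
})

test_that("conservation report pinpoints a corrupted EMU", {
  tr <- integrate_constant(toy_system(1), step = 0.01, t_end = 1)
  cons <- conservation_report(tr)
  expect_true(all(cons$mid$max_deviation < 1e-9))
  expect_equal(nrow(cons$sensitivity), 0L)  # no sensitivities recorded
  bad <- tr
  row <- which(tr$sys$node_tab$key == "C/1,2.m1")
  bad$states[row, 50] <- bad$states[row, 50] + 0.1
  cons2 <- conservation_report(bad)
  worst <- cons2$mid$emu[which.max(cons2$mid$max_deviation)]
  expect_equal(worst, "C/1,2")
  expect_gt(max(cons2$mid$max_deviation), 0.09)
})

test_that("medium generated fixtures have stable spectra across flux sets", {
  model <- random_network(8, seed = 12, bimolecular_fraction = 0.4)
  for (s in 1:3) {
    m2 <- model
    m2$fluxes <- sample_flux_distribution(model, seed = 100 + s)
    sys <- toy_system(10, model = m2)
    rep <- spectral_check(sys)
    expect_true(all(rep$max_re < 0))
    expect_true(all(is.finite(rep$stiffness_ratio)))
  }
})
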