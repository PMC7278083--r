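toy_graph <- function(targets = list(emu("F", 1:4))) {
  build_misotope_graph(trace_emus(toy_model(), targets))
}

test_that("graph node counts match the hand-enumerated toy network", {
  g1 <- toy_graph()
  expect_equal(sum(!g1$nodes$input), 14L)       # 3+3+3+5 non-input
  g2 <- toy_graph(list(emu("F", 1:4), emu("D", 1:4)))
  expect_equal(sum(!g2$nodes$input), 19L)       # + 5 for D
  # edges never decrease weight
  wt <- setNames(g1$nodes$weight, g1$nodes$key)
  expect_true(all(wt[g1$edges$from] <= wt[g1$edges$to]))
})

test_that("bimolecular edges enumerate all weight compositions", {
  g <- toy_graph(list(emu("D", 1:4)))
  to_d2 <- g$edges[g$edges$to == "D/1,2,3,4.m2", ]
  expect_setequal(to_d2$from,
                  c("B/1,2.m0", "B/1,2.m1", "B/1,2.m2",
                    "C/1,2.m0", "C/1,2.m1", "C/1,2.m2"))
  # unimolecular reactions preserve weight exactly
  to_c <- g$edges[grepl("^C/1,2", g$edges$to) & grepl("^B/1,2", g$edges$from), ]
  expect_true(all(sub(".*\\.m", "", to_c$from) == sub(".*\\.m", "", to_c$to)))
})

test_that("pruning keeps exactly the ancestors of the measured nodes", {
  g <- toy_graph()
  gp <- prune_to_measured(g)
  expect_equal(sum(!gp$nodes$input), 14L)  # nothing prunable: all feed F
  # pruning is idempotent and never removes a measured node
  gpp <- prune_to_measured(gp)
  expect_identical(gpp$nodes, gp$nodes)
  expect_true(all(measured_nodes(g) %in% gp$nodes$key))

  # a single measured node keeps only its ancestor cone
  g4 <- prune_to_measured(g, "F/1,2,3,4.m4")
  expect_setequal(g4$nodes$key[!g4$nodes$input],
                  c("F/1,2,3,4.m4", "C/1,2.m2", "E/1,2.m2", "B/1,2.m2"))

  expect_error(prune_to_measured(g, "Z/1.m0"), "absent from graph: Z/1.m0")
})

test_that("toy SCC decomposition yields 14 singletons in topological order", {
  part <- scc_partition(prune_to_measured(toy_graph()), 1)
  expect_length(part$sccs, 14)
  expect_true(all(vapply(part$sccs, `[[`, integer(1), "size") == 1L))
  w <- vapply(part$sccs, `[[`, integer(1), "weight")
  expect_equal(w, sort(w))           # weight-0 first, F m4 last
  expect_equal(part$sccs[[14]]$members, "F/1,2,3,4.m4")
  # no cross-SCC edge points backward
  expect_true(all(part$cond_edges$from < part$cond_edges$to))
})

test_that("a reversible pair collapses into one 2-node SCC", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("reaction\tstoichiometry\ttransition",
               "U\tS -> X\t#AB -> #AB",
               "F1\tX -> Y\t#AB -> #BA",
               "R1\tY -> X\t#AB -> #BA",
               "O\tY -> Y_OUT\t#AB -> #AB"), tsv)
  yml <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    fluxes = list(U = 1, F1 = 3, R1 = 2, O = 1),
    pool_sizes = list(X = 1, Y = 1),
    labeling = list(S = list("11" = 1)),
    measured = list(list(metabolite = "Y", atoms = list(1, 2)))), yml)
  model <- parse_model(tsv, yml)
  part <- scc_partition(prune_to_measured(build_misotope_graph(
    trace_emus(model))), 1)
  sizes <- vapply(part$sccs, `[[`, integer(1), "size")
  expect_equal(sort(sizes), c(2, 2, 2))  # {X,Y} pair per weight class
})

test_that("SCC partition agrees with the Floyd-Warshall closure oracle", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(10:30, 1)
    keys <- paste0("N", seq_len(n), "/1.m0")
    ne <- sample(1:(3 * n), 1)
    ef <- sample(keys, ne, replace = TRUE)
    et <- sample(keys, ne, replace = TRUE)
    keep <- ef != et
    graph <- structure(list(
      nodes = tibble::tibble(key = keys, emu_key = sub("\\.m0$", "", keys),
                             metabolite = paste0("N", seq_len(n)),
                             weight = 0L, size = 1L, input = FALSE),
      edges = tibble::tibble(from = ef[keep], to = et[keep], reaction = 1L),
      network = NULL), class = "misotope_graph")
    part <- scc_decompose(graph)
    mine <- lapply(part$sccs, `[[`, "members")
    oracle <- fw_scc_oracle(keys, ef[keep], et[keep])
    canon <- function(groups) sort(unname(vapply(groups, function(g)
      paste(sort(g), collapse = "|"), character(1))))
    expect_equal(canon(mine), canon(oracle))
  }
})

test_that("lambda aggregation merges greedily and is monotone", {
  gp <- prune_to_measured(toy_graph())
  p1 <- scc_partition(gp, 1)
  expect_length(p1$sccs, 14)

  p4 <- scc_partition(gp, 4)
  w0 <- Filter(function(s) s$weight == 0L, p4$sccs)
  expect_length(w0, 1)            # the four weight-0 singletons merge
  expect_setequal(w0[[1]]$members,
                  c("B/1,2.m0", "C/1,2.m0", "E/1,2.m0", "F/1,2,3,4.m0"))

  phuge <- scc_partition(gp, 1e6)
  expect_equal(length(phuge$sccs),
               length(unique(vapply(p1$sccs, `[[`, integer(1), "weight"))))

  counts <- vapply(c(1, 2, 3, 4, 8, 16, 1e6), function(l)
    length(scc_partition(gp, l)$sccs), numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(scc_partition(gp, 0), "lambda must be >= 1")
})

test_that("weight homogeneity and order validity survive aggregation", {
  for (seed in 1:3) {
    model <- random_network(6, seed = seed)
    gp <- prune_to_measured(build_misotope_graph(trace_emus(model)))
    for (l in c(1, 5, 50)) {
      part <- scc_partition(gp, l)
      wt <- setNames(gp$nodes$weight, gp$nodes$key)
      for (s in part$sccs) {
        expect_length(unique(wt[s$members]), 1)
      }
      expect_true(all(part$cond_edges$from < part$cond_edges$to))
    }
  }
})
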