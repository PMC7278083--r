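# Independent oracles and tiny fixture builders used across the suite.

# Floyd-Warshall transitive closure; SCC membership by mutual
# reachability.  The reference the graph pipeline is checked against.
fw_scc_oracle <- function(node_keys, edges_from, edges_to) {
  n <- length(node_keys)
  R <- diag(TRUE, n)
  fi <- match(edges_from, node_keys)
  ti <- match(edges_to, node_keys)
  for (i in seq_along(fi)) R[fi[i], ti[i]] <- TRUE
  for (k in seq_len(n)) {
    R <- R | (R[, k] %o% R[k, ])
  }
  mutual <- R & t(R)
  memb <- integer(n)
  nextid <- 0L
  for (i in seq_len(n)) {
    if (memb[i] == 0L) {
      nextid <- nextid + 1L
      memb[mutual[i, ]] <- nextid
    }
  }
  split(node_keys, memb)
}

# Exact integer matrix rank by fraction-free (Bareiss) elimination.
integer_rank_oracle <- function(M) {
  M <- matrix(as.numeric(M), nrow(M), ncol(M))
  stopifnot(all(M == round(M)))
  n <- nrow(M); m <- ncol(M)
  rank <- 0L
  prev <- 1
  r <- 1L
  for (c in seq_len(m)) {
    if (r > n) break
    piv <- which(M[r:n, c] != 0)
    if (!length(piv)) next
    piv <- piv[1] + r - 1L
    if (piv != r) M[c(r, piv), ] <- M[c(piv, r), ]
    for (i in seq_len(n)[-seq_len(r)]) {
      M[i, ] <- (M[r, c] * M[i, ] - M[i, c] * M[r, ]) / prev
    }
    prev <- M[r, c]
    rank <- rank + 1L
    r <- r + 1L
  }
  rank
}

# Brute-force double-loop MID convolution.
conv_oracle <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (u in seq_along(a)) {
    for (v in seq_along(b)) {
      out[u + v - 1L] <- out[u + v - 1L] + a[u] * b[v]
    }
  }
  out
}

# Independent backward atom-set closure, re-derived directly from the
# reaction maps (no caching, no EMU-reaction bookkeeping); returns the
# set of "metabolite/atoms" keys reachable from the targets.
atom_ancestry_oracle <- function(model, metabolite, atoms) {
  seen <- character(0)
  stack <- list(list(met = metabolite, atoms = sort(atoms)))
  substrates <- names(model$labeling)
  while (length(stack)) {
    cur <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- paste0(cur$met, "/", paste(cur$atoms, collapse = ","))
    if (key %in% seen) next
    seen <- c(seen, key)
    if (cur$met %in% substrates) next
    for (r in model$reactions) {
      for (o in which(r$products == cur$met)) {
        for (tr in r$transitions) {
          pl <- strsplit(tr$product_maps[o], "")[[1]][cur$atoms]
          for (j in seq_along(r$reactants)) {
            rl <- strsplit(tr$reactant_maps[j], "")[[1]]
            pos <- sort(which(rl %in% pl))
            if (length(pos)) {
              stack[[length(stack) + 1L]] <-
                list(met = r$reactants[j], atoms = pos)
            }
          }
        }
      }
    }
  }
  sort(seen)
}

# One fully labeled single-carbon pool: dm1/dt = (v/c)(1 - m1), so
# m1(t) = 1 - exp(-(v/c) t).
single_pool_model <- function(v = 2, c = 4, labeled = 1) {
  params <- list(
    fluxes = list(UPT = v, SNK = v),
    pool_sizes = list(P = c),
    labeling = list(S = list("1" = labeled, "0" = 1 - labeled)),
    measured = list(list(metabolite = "P", atoms = list(1)))
  )
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("reaction\tstoichiometry\ttransition",
               "UPT\tS -> P\t#A -> #A",
               "SNK\tP -> P_OUT\t#A -> #A"), tsv)
  yml <- tempfile(fileext = ".yaml")
  yaml::write_yaml(params, yml)
  parse_model(tsv, yml)
}

single_pool_system <- function(v = 2, c = 4, labeled = 1) {
  m <- single_pool_model(v, c, labeled)
  net <- trace_emus(m)
  part <- scc_partition(prune_to_measured(build_misotope_graph(net)), 1)
  assemble_cascade(part, m)
}

toy_system <- function(lambda = 1, backend = "vector", model = toy_model()) {
  net <- trace_emus(model)
  part <- scc_partition(prune_to_measured(build_misotope_graph(net)), lambda)
  assemble_cascade(part, model, backend)
}

# Random normalized state: a proper MID for every complete EMU.
random_mid_state <- function(sys) {
  nt <- sys$node_tab
  x <- numeric(sys$nx)
  for (k in unique(nt$emu_key)) {
    rows <- which(nt$emu_key == k)
    v <- runif(length(rows))
    x[rows] <- v / sum(v)
  }
  x
}

# Max |MID - oracle MID| between a trajectory and the isotopomer oracle
# at the given times.
oracle_deviation <- function(traj, model, times) {
  sys <- traj$sys
  orc <- isotopomer_oracle(model, times)
  sel <- trajectory_states_at(traj, times)
  worst <- 0
  for (k in names(orc)) {
    rows <- which(sys$node_tab$emu_key == k)
    if (length(rows) != nrow(orc[[k]])) next
    rows <- rows[order(sys$node_tab$weight[rows])]
    worst <- max(worst, max(abs(sel[rows, , drop = FALSE] - orc[[k]])))
  }
  worst
}
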