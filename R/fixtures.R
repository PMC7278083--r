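# Packaged fixtures and synthetic-network generators.

#' The classic 8-reaction toy network
#'
#' A -> B -> C -> E with carbon reversal on A->B and C->E, the
#' condensations B + C -> D and C + E -> F, and three sink effluxes.
#' Default fluxes form a balanced vector scaled to a substrate uptake of
#' 10; pool sizes are order-unity so the labeling transient resolves
#' within the default 10 s horizon; the substrate A is fully 13C-labeled
#' and the whole-molecule MID of F is measured.
#'
#' @return a `metabolic_model`.
#' @export
toy_model <- function() {
  rx <- function(id, st, tr) {
    s <- parse_arrow(st, "stoichiometry")
    alts <- lapply(trimws(strsplit(tr, "|", fixed = TRUE)[[1]]), function(a) {
      t2 <- parse_arrow(a, "transition")
      list(reactant_maps = split_maps(t2[1]), product_maps = split_maps(t2[2]))
    })
    new_reaction(id, split_side(s[1]), split_side(s[2]), alts)
  }
  reactions <- list(
    rx("V_1", "A -> B", "#AB -> #BA"),
    rx("V_2", "B -> C", "#AB -> #AB"),
    rx("V_3", "B + C -> D", "#AB + #CD -> #ABCD"),
    rx("V_4", "C -> E", "#AB -> #BA"),
    rx("V_5", "C + E -> F", "#AB + #CD -> #ABCD"),
    rx("V_6", "B -> B_OUT", "#AB -> #AB"),
    rx("V_7", "D -> D_OUT", "#ABCD -> #ABCD"),
    rx("V_8", "F -> F_OUT", "#ABCD -> #ABCD")
  )
  build_model(reactions, list(
    fluxes = list(V_1 = 10, V_2 = 6, V_3 = 2.5, V_4 = 1.75, V_5 = 1.75,
                  V_6 = 1.5, V_7 = 2.5, V_8 = 1.75),
    pool_sizes = list(B = 5, C = 4, D = 5, E = 3, F = 6),
    labeling = list(A = list("11" = 1.0)),
    measured = list(list(metabolite = "F", atoms = list(1, 2, 3, 4)))
  ))
}

#' Sample a balanced, strictly positive flux distribution
#'
#' Rejection sampling in the flux null-space polytope around the model's
#' stored flux vector; deterministic for a given seed.
#'
#' @param model a `metabolic_model` with a feasible stored flux vector.
#' @param seed integer seed.
#' @param spread box half-width in free-flux coordinates, as a fraction
#'   of the smallest stored flux.
#' @param max_tries rejection budget.
#' @return named flux vector satisfying flux balance, all components
#'   positive.
#' @export
sample_flux_distribution <- function(model, seed, spread = 0.5,
                                     max_tries = 1000L) {
  d <- free_flux_dimension(model)
  if (d == 0) stop("empty feasible region: no free fluxes", call. = FALSE)
  N <- attr(d, "basis")
  ids <- rownames(N)
  v0 <- setNames(numeric(length(ids)), ids)
  v0[names(model$fluxes)] <- model$fluxes
  scale <- spread * min(v0[v0 > 0])
  set.seed(seed)
  for (i in seq_len(max_tries)) {
    u <- runif(as.integer(d), -1, 1) * scale
    v <- v0 + as.numeric(N %*% u)
    if (all(v > 0)) return(setNames(v, ids))
  }
  stop("empty feasible region: no positive balanced flux found in ",
       max_tries, " tries", call. = FALSE)
}

#' Sample pool sizes log-uniformly over a physiological range
#'
#' @param model a `metabolic_model`.
#' @param seed integer seed.
#' @param range pool-size range (model concentration units); the default
#'   spans micromolar to millimolar.
#' @return named pool-size vector over intracellular metabolites.
#' @export
sample_pool_sizes <- function(model, seed, range = c(1e-6, 1e-3)) {
  mets <- model$metabolites$id[!model$metabolites$extracellular]
  set.seed(seed)
  setNames(10^runif(length(mets), log10(range[1]), log10(range[2])), mets)
}

#' Generate a random atom-mapped network fixture
#'
#' Emulates the toy topology at a configurable scale: a labeled
#' 2-carbon substrate feeds a randomly wired core of 2-carbon
#' metabolites (random atom permutations, cycles allowed), a fraction of
#' which condense pairwise into 4-carbon products; condensation products
#' are either cleaved back into the core (creating genuine multi-node
#' SCCs) or drained to a sink.  One condensation product's whole-molecule
#' MID is the measured target.  Fluxes are assigned reaction by reaction
#' and every metabolite's deficit is closed exactly by a sink or an
#' uptake, so the model is flux-balanced and strictly positive by
#' construction.
#'
#' @param n_metabolites core metabolite count (>= 2).
#' @param bimolecular_fraction fraction of core pairs condensed.
#' @param seed integer seed.
#' @param pool_range log-uniform pool-size range.
#' @param flux_scale multiplies all sampled fluxes.
#' @param recycle_prob probability that a condensation product is
#'   cleaved back into the core rather than drained.
#' @return a `metabolic_model`.
#' @export
random_network <- function(n_metabolites = 6, bimolecular_fraction = 0.3,
                           seed = 1, pool_range = c(1e-6, 1e-3),
                           flux_scale = 1e-4, recycle_prob = 0.5) {
  stopifnot(n_metabolites >= 2)
  set.seed(seed)
  core <- paste0("M", seq_len(n_metabolites))
  perm2 <- function() if (runif(1) < 0.5) "#AB -> #AB" else "#AB -> #BA"
  reactions <- list()
  fluxes <- list()
  add <- function(id, st, tr, v) {
    s <- parse_arrow(st, "stoichiometry")
    alts <- lapply(trimws(strsplit(tr, "|", fixed = TRUE)[[1]]), function(a) {
      t2 <- parse_arrow(a, "transition")
      list(reactant_maps = split_maps(t2[1]), product_maps = split_maps(t2[2]))
    })
    reactions[[length(reactions) + 1L]] <<-
      new_reaction(id, split_side(s[1]), split_side(s[2]), alts)
    fluxes[[id]] <<- v
  }
  rv <- function() runif(1, 0.5, 1.5) * flux_scale
  add("UPT_1", paste("S ->", core[1]), perm2(), rv())
  for (i in seq_len(n_metabolites)[-1]) {
    j <- sample(i - 1L, 1)
    add(paste0("U", i), paste(core[j], "->", core[i]), perm2(), rv())
  }
  n_extra <- max(1L, n_metabolites %/% 2L)
  for (k in seq_len(n_extra)) {
    pair <- sample(n_metabolites, 2)
    add(paste0("X", k), paste(core[pair[1]], "->", core[pair[2]]),
        perm2(), rv())
  }
  n_bi <- if (bimolecular_fraction > 0) {
    max(1L, round(bimolecular_fraction * n_metabolites / 2))
  } else 0L
  prods <- if (n_bi > 0) paste0("P", seq_len(n_bi)) else character(0)
  shuffle4 <- function(from) {
    paste0("#AB + #CD -> #", paste(sample(strsplit(from, "")[[1]]),
                                   collapse = ""))
  }
  for (k in seq_len(n_bi)) {
    pair <- sample(n_metabolites, 2)
    add(paste0("B", k),
        paste(core[pair[1]], "+", core[pair[2]], "->", prods[k]),
        shuffle4("ABCD"), rv())
    if (runif(1) < recycle_prob) {
      back <- sample(n_metabolites, 2)
      letters4 <- sample(c("A", "B", "C", "D"))
      add(paste0("C", k),
          paste(prods[k], "->", core[back[1]], "+", core[back[2]]),
          paste0("#ABCD -> #", paste(letters4[1:2], collapse = ""),
                 " + #", paste(letters4[3:4], collapse = "")), rv())
    } else {
      add(paste0("D", k), paste(prods[k], "->", prods[k], "_OUT"),
          "#ABCD -> #ABCD", rv())
    }
  }
  # every core/product metabolite must be consumed somewhere, or it would
  # be (mis)classified as an extracellular terminal product
  all_mets <- c(core, prods)
  consumed <- unique(unlist(lapply(reactions, `[[`, "reactants")))
  for (m in setdiff(all_mets, consumed)) {
    nc <- if (m %in% core) 2L else 4L
    idmap <- paste0("#", paste(LETTERS[1:nc], collapse = ""))
    add(paste0("OUT_", m), paste(m, "->", m, "_OUT"),
        paste(idmap, "->", idmap), rv())
  }
  # close every deficit exactly: sinks for surplus, substrate uptake for
  # shortfall
  repeat {
    model <- build_model(reactions, list(
      fluxes = fluxes,
      labeling = list(S = list("11" = 1.0))
    ))
    bal <- validate_flux_balance(model, tol = 1e-12 * flux_scale)
    open <- bal[bal$flagged, ]
    if (!nrow(open)) break
    # close condensation-product deficits first: a FEED reaction consumes
    # core metabolites and would re-open their already-closed balances
    nc_open <- model$metabolites$carbons[match(open$metabolite,
                                               model$metabolites$id)]
    pick <- which.max(nc_open)
    m <- open$metabolite[pick]
    net <- open$net_production[pick]
    if (net > 0) {
      nc <- model$metabolites$carbons[model$metabolites$id == m]
      idmap <- paste0("#", paste(LETTERS[1:nc], collapse = ""))
      add(paste0("SNK_", m), paste(m, "->", m, "_OUT"),
          paste(idmap, "->", idmap), net)
    } else {
      if (model$metabolites$carbons[model$metabolites$id == m] != 2) {
        # shortfall on a 4-carbon product: feed it by an extra condensation
        pair <- sample(n_metabolites, 2)
        add(paste0("FEED_", m),
            paste(core[pair[1]], "+", core[pair[2]], "->", m),
            shuffle4("ABCD"), -net)
      } else {
        add(paste0("UPT_", m), paste("S ->", m), perm2(), -net)
      }
    }
  }
  pools <- sample_pool_sizes(model, seed + 1000L, pool_range)
  measured_met <- if (n_bi > 0) prods[1] else core[n_metabolites]
  measured_atoms <- seq_len(
    if (n_bi > 0) 4L else 2L)
  model <- build_model(reactions, list(
    fluxes = fluxes,
    pool_sizes = as.list(pools),
    labeling = list(S = list("11" = 1.0)),
    measured = list(list(metabolite = measured_met,
                         atoms = as.list(measured_atoms)))
  ))
  bal <- validate_flux_balance(model, tol = 1e-10 * flux_scale)
  stopifnot(!any(bal$flagged), all(unlist(fluxes) > 0))
  model
}

#' End-to-end labeling simulation
#'
#' Convenience pipeline: trace EMUs from the measured targets, build and
#' prune the mass isotopomer graph, decompose/sort/aggregate SCCs,
#' assemble the cascade and integrate.
#'
#' @param model a `metabolic_model` with fluxes, pools, labeling and
#'   measured targets.
#' @param mode `"constant"` or `"adaptive"`.
#' @param backend `"vector"` or `"tensor"`.
#' @param lambda SCC aggregation parameter; defaults to the model
#'   settings.
#' @param sensitivities extend with forward sensitivities?
#' @param workers 1 for the serial integrators; > 1 runs the parallel
#'   scheduler contract.
#' @param step,t_end override the model settings.
#' @return an `iso_trajectory`.
#' @export
simulate_labeling <- function(model, mode = c("constant", "adaptive"),
                              backend = c("vector", "tensor"),
                              lambda = NULL, sensitivities = FALSE,
                              workers = 1L, step = NULL, t_end = NULL) {
  mode <- match.arg(mode)
  backend <- match.arg(backend)
  lambda <- lambda %||% model$settings$lambda
  network <- trace_emus(model)
  graph <- prune_to_measured(build_misotope_graph(network))
  part <- scc_partition(graph, lambda)
  sys <- assemble_cascade(part, model, backend)
  if (sensitivities) sys <- extend_with_sensitivities(sys)
  if (workers > 1L) {
    run_parallel(sys, mode, workers, step = step, t_end = t_end)
  } else if (mode == "constant") {
    integrate_constant(sys, step = step, t_end = t_end)
  } else {
    integrate_adaptive(sys, t_end = t_end)
  }
}
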