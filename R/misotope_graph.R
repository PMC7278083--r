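# The mass isotopomer network G_m.
#
# Every (EMU, weight) pair is a node; a directed edge runs from each
# reactant mass isotopomer to the product mass isotopomer it can help
# generate, one edge set per weight composition of an EMU reaction.
# Because a heavier mass isotopomer never contributes to a lighter one,
# every strongly connected component is weight-homogeneous.

node_key <- function(emu_key, w) paste0(emu_key, ".m", w)

# All tuples (w_1..w_n), 0 <= w_k <= sizes[k], summing to total.
weight_compositions <- function(sizes, total) {
  if (length(sizes) == 1L) {
    if (total >= 0 && total <= sizes[1]) return(matrix(as.integer(total), 1, 1))
    return(matrix(integer(0), 0, 1))
  }
  out <- list()
  for (w in 0:min(sizes[1], total)) {
    rest <- weight_compositions(sizes[-1], total - w)
    if (nrow(rest)) out[[length(out) + 1L]] <- cbind(as.integer(w), rest)
  }
  if (!length(out)) return(matrix(integer(0), 0, length(sizes)))
  do.call(rbind, out)
}

#' Build the mass isotopomer graph of an EMU network
#'
#' @param network an `emu_network` from [trace_emus()].
#' @return a `misotope_graph` with a node table (input substrate nodes
#'   flagged) and a directed edge table annotated with the generating EMU
#'   reaction index.
#' @export
build_misotope_graph <- function(network) {
  emus <- network$emus
  keys <- names(emus)
  sizes <- vapply(emus, `[[`, integer(1), "size")
  nodes <- tibble(
    key = unlist(lapply(keys, function(k) node_key(k, 0:sizes[[k]]))),
    emu_key = rep(keys, sizes + 1L),
    metabolite = rep(vapply(emus, `[[`, character(1), "metabolite"), sizes + 1L),
    weight = unlist(lapply(sizes, function(s) 0:s)),
    size = rep(sizes, sizes + 1L),
    input = rep(keys %in% network$input_keys, sizes + 1L)
  )
  ef <- character(0); et <- character(0); er <- integer(0)
  for (q in seq_along(network$reactions)) {
    r <- network$reactions[[q]]
    rkeys <- vapply(r$reactants, emu_key, character(1))
    rsizes <- vapply(r$reactants, `[[`, integer(1), "size")
    pk <- emu_key(r$product)
    for (w in 0:r$product$size) {
      comps <- weight_compositions(rsizes, w)
      to <- node_key(pk, w)
      for (ci in seq_len(nrow(comps))) {
        for (k in seq_along(rkeys)) {
          ef <- c(ef, node_key(rkeys[k], comps[ci, k]))
          et <- c(et, to)
          er <- c(er, q)
        }
      }
    }
  }
  edges <- tibble(from = ef, to = et, reaction = er)
  edges <- dplyr::distinct(edges)
  structure(list(nodes = nodes, edges = edges, network = network),
            class = "misotope_graph")
}

#' @export
print.misotope_graph <- function(x, ...) {
  cat("<misotope_graph> ", nrow(x$nodes), " nodes (",
      sum(!x$nodes$input), " non-input), ", nrow(x$edges), " edges\n",
      sep = "")
  invisible(x)
}

#' Node keys of the measured mass isotopomers
#'
#' All weights of every measured EMU of the model attached to the graph's
#' network.
#'
#' @param graph a `misotope_graph`.
#' @export
measured_nodes <- function(graph) {
  model <- graph$network$model
  unlist(lapply(model$measured, function(m) {
    e <- emu(m$metabolite, m$atoms)
    node_key(emu_key(e), 0:e$size)
  }))
}

#' Prune a mass isotopomer graph to the ancestors of measured nodes
#'
#' Retains exactly the nodes from which some measured mass isotopomer is
#' reachable (the transitive closure of the measured set on the
#' transposed graph), including the measured nodes themselves, with all
#' induced edges.  Implemented as a reverse breadth-first search, which
#' retains the same node set as a full transitive-closure computation.
#'
#' @param graph a `misotope_graph`.
#' @param measured character vector of node keys; defaults to
#'   [measured_nodes()].
#' @export
prune_to_measured <- function(graph, measured = NULL) {
  if (is.null(measured)) measured <- measured_nodes(graph)
  missing <- setdiff(measured, graph$nodes$key)
  if (length(missing)) {
    stop("measured node(s) absent from graph: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  preds <- split(graph$edges$from, graph$edges$to)
  keep <- unique(measured)
  frontier <- keep
  while (length(frontier)) {
    parents <- unique(unlist(preds[frontier], use.names = FALSE))
    frontier <- setdiff(parents, keep)
    keep <- c(keep, frontier)
  }
  out <- graph
  out$nodes <- graph$nodes[graph$nodes$key %in% keep, , drop = FALSE]
  out$edges <- graph$edges[graph$edges$from %in% keep &
                             graph$edges$to %in% keep, , drop = FALSE]
  out$measured <- unique(measured)
  out
}

#' Strongly connected components of the pruned mass isotopomer graph
#'
#' Decomposes the non-input part of the graph into maximal strongly
#' connected components; a solitary mass isotopomer is an SCC of one
#' node.  Input (substrate) nodes are constants of the ODE system and are
#' not counted as SCCs.  Every SCC is weight-homogeneous, which is
#' asserted.
#'
#' @param graph a (typically pruned) `misotope_graph`.
#' @return an unsorted `scc_partition`; see [topo_sort_sccs()].
#' @export
scc_decompose <- function(graph) {
  nn <- graph$nodes[!graph$nodes$input, , drop = FALSE]
  ee <- graph$edges[graph$edges$from %in% nn$key &
                      graph$edges$to %in% nn$key, c("from", "to")]
  if (nrow(nn) == 0) {
    return(structure(list(sccs = list(), cond_edges = tibble(from = integer(0),
                                                            to = integer(0)),
                          graph = graph, lambda = 1L, sorted = FALSE),
                     class = "scc_partition"))
  }
  g <- igraph::graph_from_data_frame(dplyr::distinct(ee), directed = TRUE,
                                     vertices = nn$key)
  comp <- igraph::components(g, mode = "strong")
  memb <- comp$membership[nn$key]
  wt <- setNames(nn$weight, nn$key)
  sccs <- lapply(seq_len(comp$no), function(i) {
    members <- sort(names(memb)[memb == i])
    w <- unique(wt[members])
    stopifnot(length(w) == 1L)  # weight homogeneity, by construction
    list(weight = as.integer(w), members = members,
         size = length(members))
  })
  m_from <- unname(memb[ee$from]); m_to <- unname(memb[ee$to])
  keep <- m_from != m_to
  cond <- dplyr::distinct(tibble(from = m_from[keep], to = m_to[keep]))
  structure(list(sccs = sccs, cond_edges = cond, graph = graph,
                 lambda = 1L, sorted = FALSE),
            class = "scc_partition")
}

#' Topologically sort an SCC partition
#'
#' Orders SCCs primarily by mass isotopomer weight and within each weight
#' by a topological order of the condensation DAG (Kahn's algorithm, ties
#' broken by the lexicographically smallest member node for determinism),
#' and assigns the (weight, within-weight index) labels.
#'
#' @param partition an `scc_partition` from [scc_decompose()].
#' @export
topo_sort_sccs <- function(partition) {
  sccs <- partition$sccs
  n <- length(sccs)
  if (n == 0) {
    partition$sorted <- TRUE
    return(partition)
  }
  w <- vapply(sccs, `[[`, integer(1), "weight")
  tie <- vapply(sccs, function(s) s$members[1], character(1))
  indeg <- integer(n)
  succ <- vector("list", n)
  for (i in seq_len(nrow(partition$cond_edges))) {
    a <- partition$cond_edges$from[i]; b <- partition$cond_edges$to[i]
    indeg[b] <- indeg[b] + 1L
    succ[[a]] <- c(succ[[a]], b)
  }
  order_out <- integer(0)
  remaining <- rep(TRUE, n)
  indeg_cur <- indeg
  for (step in seq_len(n)) {
    ready <- which(remaining & indeg_cur == 0L)
    stopifnot(length(ready) > 0)  # a cycle among SCCs is impossible
    pick <- ready[order(w[ready], tie[ready])][1]
    order_out <- c(order_out, pick)
    remaining[pick] <- FALSE
    for (s in succ[[pick]]) indeg_cur[s] <- indeg_cur[s] - 1L
  }
  perm <- order_out
  inv <- integer(n); inv[perm] <- seq_len(n)
  sccs <- sccs[perm]
  jj <- integer(n)
  for (ww in unique(vapply(sccs, `[[`, integer(1), "weight"))) {
    idx <- which(vapply(sccs, `[[`, integer(1), "weight") == ww)
    for (k in seq_along(idx)) sccs[[idx[k]]]$j <- k
  }
  cond <- tibble(from = inv[partition$cond_edges$from],
                 to = inv[partition$cond_edges$to])
  stopifnot(all(cond$from < cond$to))  # no edge from later to earlier SCC
  partition$sccs <- sccs
  partition$cond_edges <- cond
  partition$sorted <- TRUE
  partition
}

#' Merge consecutive same-weight SCCs up to a minimum size
#'
#' Adjacent SCCs of the same weight, consecutive in the topological
#' order, are greedily combined head-to-tail until each merged unit holds
#' at least `lambda` mass isotopomers (the last unit of a weight class
#' may be smaller).  `lambda = 1` leaves the partition unchanged; the SCC
#' count is weakly decreasing in `lambda`.
#'
#' @param partition a sorted `scc_partition`.
#' @param lambda minimum mass isotopomer count per merged SCC (>= 1).
#' @export
aggregate_sccs <- function(partition, lambda) {
  lambda <- as.integer(lambda)
  if (is.na(lambda) || lambda < 1L) stop("lambda must be >= 1", call. = FALSE)
  stopifnot(isTRUE(partition$sorted))
  sccs <- partition$sccs
  n <- length(sccs)
  if (n == 0 || lambda == 1L) {
    partition$lambda <- lambda
    return(partition)
  }
  w <- vapply(sccs, `[[`, integer(1), "weight")
  group <- integer(n)
  gid <- 0L
  acc <- 0L
  prev_w <- NA_integer_
  for (i in seq_len(n)) {
    if (is.na(prev_w) || w[i] != prev_w || acc >= lambda) {
      gid <- gid + 1L
      acc <- 0L
    }
    group[i] <- gid
    acc <- acc + sccs[[i]]$size
    prev_w <- w[i]
  }
  merged <- lapply(unique(group), function(g) {
    parts <- sccs[group == g]
    list(weight = parts[[1]]$weight,
         members = sort(unlist(lapply(parts, `[[`, "members"))),
         size = sum(vapply(parts, `[[`, integer(1), "size")))
  })
  jj <- 0L; prev <- NA_integer_
  for (i in seq_along(merged)) {
    if (is.na(prev) || merged[[i]]$weight != prev) jj <- 0L
    jj <- jj + 1L
    merged[[i]]$j <- jj
    prev <- merged[[i]]$weight
  }
  cond <- tibble(from = group[partition$cond_edges$from],
                 to = group[partition$cond_edges$to])
  cond <- dplyr::distinct(cond[cond$from != cond$to, ])
  stopifnot(all(cond$from < cond$to))
  partition$sccs <- merged
  partition$cond_edges <- cond
  partition$lambda <- lambda
  partition
}

#' One-call SCC pipeline
#'
#' [scc_decompose()] + [topo_sort_sccs()] + [aggregate_sccs()].
#'
#' @param graph a pruned `misotope_graph`.
#' @param lambda aggregation parameter (default 1: no merging).
#' @export
scc_partition <- function(graph, lambda = 1L) {
  aggregate_sccs(topo_sort_sccs(scc_decompose(graph)), lambda)
}

#' @export
print.scc_partition <- function(x, ...) {
  cat("<scc_partition> ", length(x$sccs), " SCCs, lambda = ", x$lambda,
      if (isTRUE(x$sorted)) ", topologically sorted" else "", "\n", sep = "")
  invisible(x)
}

#' Tidy an SCC partition into a table
#'
#' @param x an `scc_partition`.
#' @param ... unused.
#' @return tibble with one row per SCC: block, weight, topo index within
#'   weight, size, members.
#' @method tidy scc_partition
#' @export
tidy.scc_partition <- function(x, ...) {
  if (!length(x$sccs)) {
    return(tibble(block = integer(0), weight = integer(0), j = integer(0),
                  size = integer(0), members = character(0)))
  }
  tibble(
    block = seq_along(x$sccs),
    weight = vapply(x$sccs, `[[`, integer(1), "weight"),
    j = vapply(x$sccs, function(s) as.integer(s$j %||% NA_integer_), integer(1)),
    size = vapply(x$sccs, `[[`, integer(1), "size"),
    members = vapply(x$sccs, function(s) paste(s$members, collapse = ";"),
                     character(1))
  )
}

#' Export a mass isotopomer graph (or its condensation) as DOT
#'
#' @param graph a `misotope_graph`.
#' @param path output file.
#' @export
misotope_graph_dot <- function(graph, path) {
  lines <- c("digraph misotope_graph {")
  for (i in seq_len(nrow(graph$nodes))) {
    shape <- if (graph$nodes$input[i]) "box" else "ellipse"
    lines <- c(lines, sprintf("  \"%s\" [shape=%s];", graph$nodes$key[i], shape))
  }
  lines <- c(lines, sprintf("  \"%s\" -> \"%s\";", graph$edges$from,
                            graph$edges$to))
  writeLines(c(lines, "}"), path)
  invisible(path)
}
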