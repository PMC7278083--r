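# Atom-mapped metabolic models: parsing, validation, flux algebra.
#
# The on-disk dialect is a 3-column TSV (reaction, stoichiometry, transition)
# mirroring the way small atom-mapped networks are printed in the literature,
# e.g.
#     V_3   B + C -> D   #AB + #CD -> #ABCD
# plus a YAML parameter document holding fluxes, pool sizes, substrate
# labeling, measured targets and integration settings.

split_side <- function(side) {
  toks <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
  toks <- toks[nzchar(toks)]
  out <- character(0)
  for (tk in toks) {
    m <- regmatches(tk, regexec("^([0-9]+)\\s+(.*)$", tk))[[1]]
    if (length(m) == 3) {
      out <- c(out, rep(m[3], as.integer(m[2])))
    } else {
      out <- c(out, tk)
    }
  }
  out
}

split_maps <- function(side) {
  toks <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
  toks <- toks[nzchar(toks)]
  if (!all(grepl("^#[A-Za-z]+$", toks))) {
    stop("malformed carbon map '", side, "'", call. = FALSE)
  }
  sub("^#", "", toks)
}

parse_arrow <- function(text, what, line = NA) {
  parts <- strsplit(text, "->", fixed = TRUE)[[1]]
  if (length(parts) != 2) {
    stop("line ", line, ": ", what, " must contain exactly one '->': '",
         text, "'", call. = FALSE)
  }
  trimws(parts)
}

new_reaction <- function(id, reactants, products, transitions, line = NA) {
  for (tr in transitions) {
    if (length(tr$reactant_maps) != length(reactants) ||
        length(tr$product_maps) != length(products)) {
      stop("line ", line, ": reaction ", id,
           ": carbon transition arity does not match stoichiometry",
           call. = FALSE)
    }
    rl <- unlist(strsplit(tr$reactant_maps, ""))
    pl <- unlist(strsplit(tr$product_maps, ""))
    if (anyDuplicated(rl) || anyDuplicated(pl)) {
      stop("line ", line, ": reaction ", id,
           ": atom labels must be unique within one side", call. = FALSE)
    }
    if (!identical(sort(rl), sort(pl))) {
      stop("atom conservation violation in reaction ", id, call. = FALSE)
    }
  }
  list(id = id, reactants = reactants, products = products,
       transitions = transitions)
}

#' Parse an atom-mapped metabolic model
#'
#' Reads a tab-separated model file with columns `reaction`,
#' `stoichiometry` and `transition` (alternative transitions for symmetric
#' molecules separated by `|`, each weighted `1/n` of the flux) and an
#' optional YAML parameter file with keys `fluxes`, `pool_sizes`,
#' `labeling`, `measured` and `settings`.
#'
#' @param model_path path to the model TSV.
#' @param params_path optional path to the YAML parameter file.
#' @return a `metabolic_model` object.
#' @export
parse_model <- function(model_path, params_path = NULL) {
  tab <- read.delim(model_path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE, comment.char = "")
  need <- c("reaction", "stoichiometry", "transition")
  if (!all(need %in% names(tab))) {
    stop("model TSV must have header reaction\tstoichiometry\ttransition",
         call. = FALSE)
  }
  reactions <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    line <- i + 1L
    st <- parse_arrow(tab$stoichiometry[i], "stoichiometry", line)
    reactants <- split_side(st[1])
    products <- split_side(st[2])
    alts <- trimws(strsplit(tab$transition[i], "|", fixed = TRUE)[[1]])
    transitions <- lapply(alts, function(a) {
      tr <- parse_arrow(a, "transition", line)
      list(reactant_maps = split_maps(tr[1]), product_maps = split_maps(tr[2]))
    })
    reactions[[i]] <- new_reaction(tab$reaction[i], reactants, products,
                                   transitions, line)
  }
  params <- if (!is.null(params_path)) yaml::read_yaml(params_path) else list()
  build_model(reactions, params)
}

default_settings <- function() {
  list(t_end = 10, step = 0.005, lambda = 10,
       tol_scaling = 1e-9, tol_addition = 1e-7)
}

# Assemble and validate a metabolic_model from parsed reactions + parameters.
build_model <- function(reactions, params = list()) {
  ids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate reaction ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  # carbon counts from the maps, checked for consistency
  carbons <- list()
  note_carbons <- function(met, n, id) {
    if (!is.null(carbons[[met]]) && carbons[[met]] != n) {
      stop("metabolite ", met, " has inconsistent carbon counts (",
           carbons[[met]], " vs ", n, " in reaction ", id, ")", call. = FALSE)
    }
    carbons[[met]] <<- n
  }
  for (r in reactions) {
    tr <- r$transitions[[1]]
    for (j in seq_along(r$reactants)) {
      note_carbons(r$reactants[j], nchar(tr$reactant_maps[j]), r$id)
    }
    for (j in seq_along(r$products)) {
      note_carbons(r$products[j], nchar(tr$product_maps[j]), r$id)
    }
  }
  mets <- sort(names(carbons))
  produced <- unique(unlist(lapply(reactions, `[[`, "products")))
  consumed <- unique(unlist(lapply(reactions, `[[`, "reactants")))
  labeling <- params$labeling %||% list()
  extracellular <- params$extracellular %||%
    mets[!(mets %in% produced) | !(mets %in% consumed)]
  extracellular <- union(extracellular, names(labeling))

  fluxes <- unlist(params$fluxes %||% list())
  if (length(fluxes)) {
    unknown <- setdiff(names(fluxes), ids)
    if (length(unknown)) {
      stop("fluxes refer to unknown reactions: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    if (any(fluxes < 0)) stop("flux values must be >= 0", call. = FALSE)
  }
  pool_sizes <- unlist(params$pool_sizes %||% list())
  intracellular <- setdiff(mets, extracellular)
  if (length(pool_sizes) && any(pool_sizes <= 0)) {
    stop("pool sizes must be positive", call. = FALSE)
  }
  for (met in names(labeling)) {
    frac <- unlist(labeling[[met]])
    if (is.null(carbons[[met]])) {
      stop("labeling for unknown metabolite ", met, call. = FALSE)
    }
    if (!all(nchar(names(frac)) == carbons[[met]]) ||
        !all(grepl("^[01]+$", names(frac)))) {
      stop("labeling patterns for ", met, " must be 0/1 strings of length ",
           carbons[[met]], call. = FALSE)
    }
    if (abs(sum(frac) - 1) > 1e-8) {
      stop("labeling fractions for ", met, " must sum to 1", call. = FALSE)
    }
    labeling[[met]] <- frac
  }
  measured <- lapply(params$measured %||% list(), function(m) {
    atoms <- sort(as.integer(unlist(m$atoms)))
    if (is.null(carbons[[m$metabolite]])) {
      stop("measured target on unknown metabolite ", m$metabolite,
           call. = FALSE)
    }
    if (!length(atoms) || any(atoms < 1 | atoms > carbons[[m$metabolite]])) {
      stop("measured atoms for ", m$metabolite, " out of range", call. = FALSE)
    }
    list(metabolite = m$metabolite, atoms = atoms)
  })
  settings <- utils::modifyList(default_settings(), params$settings %||% list())
  stopifnot(all(unlist(settings) > 0), settings$step <= settings$t_end)

  model <- structure(list(
    metabolites = tibble(
      id = mets,
      carbons = vapply(mets, function(m) carbons[[m]], integer(1)),
      extracellular = mets %in% extracellular
    ),
    reactions = reactions,
    fluxes = fluxes,
    pool_sizes = pool_sizes,
    labeling = labeling,
    measured = measured,
    settings = settings
  ), class = "metabolic_model")
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", length(x$reactions), " reactions, ",
      nrow(x$metabolites), " metabolites (",
      sum(!x$metabolites$extracellular), " balanced)\n", sep = "")
  invisible(x)
}

#' Write a model back to its TSV + YAML representation
#'
#' Inverse of [parse_model()]; `parse -> write -> parse` is an identity on
#' the model.
#'
#' @param model a `metabolic_model`.
#' @param model_path,params_path output paths.
#' @export
write_model <- function(model, model_path, params_path = NULL) {
  fmt_side <- function(x) paste(x, collapse = " + ")
  rows <- lapply(model$reactions, function(r) {
    tr <- vapply(r$transitions, function(t) {
      paste0(fmt_side(paste0("#", t$reactant_maps)), " -> ",
             fmt_side(paste0("#", t$product_maps)))
    }, character(1))
    data.frame(reaction = r$id,
               stoichiometry = paste0(fmt_side(r$reactants), " -> ",
                                      fmt_side(r$products)),
               transition = paste(tr, collapse = " | "))
  })
  tab <- do.call(rbind, rows)
  write.table(tab, model_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(params_path)) {
    params <- list(
      fluxes = as.list(model$fluxes),
      pool_sizes = as.list(model$pool_sizes),
      labeling = lapply(model$labeling, as.list),
      measured = lapply(model$measured, function(m) {
        list(metabolite = m$metabolite, atoms = as.list(m$atoms))
      }),
      settings = model$settings,
      extracellular = as.list(model$metabolites$id[model$metabolites$extracellular])
    )
    yaml::write_yaml(params, params_path)
  }
  invisible(model)
}

# Stoichiometric matrix restricted to balanced (intracellular) metabolites.
stoichiometric_matrix <- function(model, balanced_only = TRUE) {
  mets <- model$metabolites$id
  if (balanced_only) mets <- mets[!model$metabolites$extracellular]
  ids <- vapply(model$reactions, `[[`, character(1), "id")
  S <- matrix(0, length(mets), length(ids), dimnames = list(mets, ids))
  for (r in model$reactions) {
    for (m in r$reactants) if (m %in% mets) S[m, r$id] <- S[m, r$id] - 1
    for (m in r$products) if (m %in% mets) S[m, r$id] <- S[m, r$id] + 1
  }
  S
}

#' Dimension of the free-flux space
#'
#' The number of free fluxes is the dimension of the null space of the
#' stoichiometric matrix restricted to balanced (intracellular)
#' metabolites.  An orthonormal basis of that null space is attached as
#' attribute `"basis"` (rows named by reaction id) for use in sensitivity
#' parameterization.
#'
#' @param model a `metabolic_model`.
#' @return integer dimension with attribute `basis`.
#' @export
free_flux_dimension <- function(model) {
  S <- stoichiometric_matrix(model)
  n <- ncol(S)
  if (nrow(S) == 0) {
    basis <- diag(n)
    rownames(basis) <- colnames(S)
    return(structure(n, basis = basis))
  }
  qt <- qr(t(S))
  r <- qt$rank
  d <- n - r
  Q <- qr.Q(qt, complete = TRUE)
  basis <- if (d > 0) Q[, (r + 1):n, drop = FALSE] else matrix(0, n, 0)
  rownames(basis) <- colnames(S)
  structure(as.integer(d), basis = basis)
}

#' Per-metabolite flux balance report
#'
#' Net production of every balanced metabolite under the model's flux
#' values; metabolites whose absolute imbalance exceeds `tol` are flagged.
#'
#' @param model a `metabolic_model`.
#' @param tol flag threshold.
#' @return tibble with columns metabolite, net_production, flagged.
#' @export
validate_flux_balance <- function(model, tol = 1e-6) {
  if (!length(model$fluxes)) {
    out <- tibble(metabolite = character(0), net_production = numeric(0),
                  flagged = logical(0))
    attr(out, "status") <- "no fluxes"
    return(out)
  }
  S <- stoichiometric_matrix(model)
  v <- setNames(numeric(ncol(S)), colnames(S))
  v[names(model$fluxes)] <- model$fluxes
  net <- as.numeric(S %*% v)
  out <- tibble(metabolite = rownames(S), net_production = net,
                flagged = abs(net) > tol)
  attr(out, "status") <- "ok"
  out
}

# Total consumption rate (sum of flux * multiplicity over consuming
# reactions) per metabolite.
consumption_rates <- function(model) {
  v <- model$fluxes
  out <- setNames(numeric(nrow(model$metabolites)), model$metabolites$id)
  for (r in model$reactions) {
    for (m in r$reactants) out[m] <- out[m] + v[[r$id]]
  }
  out
}
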