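# EMU (elementary metabolite unit) tracing.
#
# An EMU is a specific subset of a metabolite's carbon atoms.  The minimal
# EMU reaction network needed to predict the measured fragments is the
# backward closure of the target EMUs through the atom maps.

#' Construct an EMU
#'
#' @param metabolite metabolite id.
#' @param atoms 1-based carbon positions (unordered; stored sorted).
#' @export
emu <- function(metabolite, atoms) {
  atoms <- sort(unique(as.integer(atoms)))
  stopifnot(length(atoms) >= 1, all(atoms >= 1))
  structure(list(metabolite = metabolite, atoms = atoms, size = length(atoms)),
            class = "emu")
}

emu_key <- function(e) paste0(e$metabolite, "/", paste(e$atoms, collapse = ","))

#' @export
print.emu <- function(x, ...) {
  cat("<emu> ", emu_key(x), "\n", sep = "")
  invisible(x)
}

#' Trace the minimal EMU reaction network backward from target EMUs
#'
#' Starting from the targets, every producing reaction is followed
#' backward through its atom map, splitting the traced atom set across
#' reactants.  EMUs on labeled substrates are marked as inputs and not
#' traced further; equivalent EMUs are merged.  A reaction with `n`
#' symmetric transition alternatives contributes one EMU reaction per
#' alternative, each carrying fractional weight `1/n`.
#'
#' @param model a `metabolic_model`.
#' @param targets list of [emu()] objects; defaults to the model's
#'   measured targets.
#' @return an `emu_network`.
#' @export
trace_emus <- function(model, targets = NULL) {
  if (is.null(targets)) {
    targets <- lapply(model$measured, function(m) emu(m$metabolite, m$atoms))
  }
  if (!length(targets)) stop("no target EMUs", call. = FALSE)
  if (inherits(targets, "emu")) targets <- list(targets)
  carbons <- setNames(model$metabolites$carbons, model$metabolites$id)
  for (e in targets) {
    if (is.na(carbons[e$metabolite])) {
      stop("target EMU on unknown metabolite ", e$metabolite, call. = FALSE)
    }
    if (max(e$atoms) > carbons[e$metabolite]) {
      stop("target EMU atoms exceed carbon count of ", e$metabolite,
           call. = FALSE)
    }
  }
  substrates <- names(model$labeling)

  emus <- list()
  reactions <- list()
  input_keys <- character(0)
  queue <- targets
  queued <- vapply(targets, emu_key, character(1))
  while (length(queue)) {
    e <- queue[[1]]
    queue <- queue[-1]
    key <- emu_key(e)
    if (!is.null(emus[[key]])) next
    emus[[key]] <- e
    if (e$metabolite %in% substrates) {
      input_keys <- c(input_keys, key)
      next
    }
    found <- FALSE
    for (r in model$reactions) {
      occ <- which(r$products == e$metabolite)
      for (o in occ) {
        for (a in seq_along(r$transitions)) {
          tr <- r$transitions[[a]]
          pmap <- strsplit(tr$product_maps[o], "")[[1]]
          letters_needed <- pmap[e$atoms]
          remus <- list()
          for (j in seq_along(r$reactants)) {
            rmap <- strsplit(tr$reactant_maps[j], "")[[1]]
            pos <- which(rmap %in% letters_needed)
            if (length(pos)) {
              remus[[length(remus) + 1L]] <- emu(r$reactants[j], pos)
            }
          }
          stopifnot(sum(vapply(remus, `[[`, integer(1), "size")) == e$size)
          reactions[[length(reactions) + 1L]] <- list(
            rxn = r$id, alt = a, occurrence = o,
            weight = 1 / length(r$transitions),
            reactants = remus, product = e
          )
          found <- TRUE
          for (re in remus) {
            k <- emu_key(re)
            if (is.null(emus[[k]]) && !(k %in% queued)) {
              queue[[length(queue) + 1L]] <- re
              queued <- c(queued, k)
            }
          }
        }
      }
    }
    if (!found) {
      stop("unreachable EMU ", key,
           ": no producing reaction and no substrate labeling", call. = FALSE)
    }
  }

  # deterministic order: EMUs by (size, metabolite, atoms); reactions by
  # (product key, reaction id, alternative, occurrence)
  ord <- order(vapply(emus, `[[`, integer(1), "size"),
               vapply(emus, `[[`, character(1), "metabolite"),
               names(emus))
  emus <- emus[ord]
  rord <- order(vapply(reactions, function(x) emu_key(x$product), character(1)),
                vapply(reactions, `[[`, character(1), "rxn"),
                vapply(reactions, `[[`, numeric(1), "alt"),
                vapply(reactions, `[[`, numeric(1), "occurrence"))
  reactions <- reactions[rord]

  structure(list(
    emus = emus,
    reactions = reactions,
    input_keys = sort(input_keys),
    target_keys = sort(vapply(targets, emu_key, character(1))),
    model = model
  ), class = "emu_network")
}

#' @export
print.emu_network <- function(x, ...) {
  cat("<emu_network> ", length(x$emus), " EMUs (",
      length(x$input_keys), " inputs), ", length(x$reactions),
      " EMU reactions\n", sep = "")
  invisible(x)
}

#' Partition a traced network's EMUs by size
#'
#' @param network an `emu_network`.
#' @return named list mapping size to EMU list, deterministically ordered.
#' @export
emus_by_size <- function(network) {
  if (!length(network$emus)) return(list())
  sizes <- vapply(network$emus, `[[`, integer(1), "size")
  out <- lapply(sort(unique(sizes)), function(s) network$emus[sizes == s])
  names(out) <- as.character(sort(unique(sizes)))
  out
}

# Marginalize the substrate isotopomer fractions onto an input EMU's atoms.
input_emu_mid <- function(model, e) {
  frac <- model$labeling[[e$metabolite]]
  if (is.null(frac)) stop("no labeling for ", e$metabolite, call. = FALSE)
  mid <- numeric(e$size + 1)
  for (i in seq_along(frac)) {
    bits <- as.integer(strsplit(names(frac)[i], "")[[1]])
    w <- sum(bits[e$atoms])
    mid[w + 1] <- mid[w + 1] + frac[[i]]
  }
  mid
}

#' Export an EMU network as a DOT graph
#'
#' @param network an `emu_network`.
#' @param path output file.
#' @export
emu_network_dot <- function(network, path) {
  lines <- c("digraph emu_network {")
  for (k in names(network$emus)) {
    shape <- if (k %in% network$input_keys) "box" else "ellipse"
    lines <- c(lines, sprintf("  \"%s\" [shape=%s];", k, shape))
  }
  for (r in network$reactions) {
    pk <- emu_key(r$product)
    for (re in r$reactants) {
      lines <- c(lines, sprintf("  \"%s\" -> \"%s\" [label=\"%s\"];",
                                emu_key(re), pk, r$rxn))
    }
  }
  writeLines(c(lines, "}"), path)
  invisible(path)
}
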