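# Dollo-style character evolution on a fixed species tree: each
# subclass arises exactly once (at its hypothesised origin node) and can
# only be lost.  The minimal loss set is the set of maximal all-absent
# subtrees within the origin clade, found bottom-up.

node_id <- function(tree, name) {
  ntip <- length(tree$tip.label)
  if (name %in% tree$tip.label) return(match(name, tree$tip.label))
  if (!is.null(tree$node.label) && name %in% tree$node.label) {
    return(ntip + match(name, tree$node.label))
  }
  t3_stop("node '", name, "' not found in species tree")
}

node_name <- function(tree, id) {
  ntip <- length(tree$tip.label)
  if (id <= ntip) tree$tip.label[id]
  else if (!is.null(tree$node.label)) tree$node.label[id - ntip]
  else paste0("node_", id)
}

tips_under <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, function(k) tips_under(tree, k)))
}

#' Default subclass origin map
#'
#' The packaged single-origin hypothesis: the secreted alpha subclass is
#' ancestral (origin at the root), the cytosolic beta subclass arose on
#' the unikont stem, and the membrane-bound gamma subclass on the
#' metazoan stem.
#'
#' @return Named character vector mapping subclass to tree-node name.
#' @export
default_origin_map <- function() {
  c(alpha = "root", beta = "unikonta", gamma = "metazoa")
}

#' Infer Dollo losses of a subclass on a species tree
#'
#' Given presence/absence at the tips and the subclass origin node, the
#' minimal set of branches whose removal explains every absent tip is
#' the set of maximal all-absent subtrees inside the origin clade,
#' computed bottom-up.  Presence outside the origin clade contradicts
#' the single-origin hypothesis and raises an error.
#'
#' @param tree Rooted [ape::phylo] species tree with named internal
#'   nodes (`node.label`).
#' @param presence Named logical vector over all tree tips.
#' @param origins Named vector mapping subclass to origin node name.
#' @param subclass Subclass whose losses are wanted.
#' @return Data.frame with one row per loss branch: `node` (label of
#'   the lost subtree's root) and `n_tips` (absent tips it covers).
#' @export
infer_losses <- function(tree, presence, origins = default_origin_map(),
                         subclass) {
  if (!subclass %in% names(origins)) {
    t3_stop("no origin for subclass '", subclass, "'")
  }
  tips <- tree$tip.label
  if (!all(tips %in% names(presence))) {
    t3_stop("presence vector must cover every tree tip")
  }
  presence <- presence[tips]
  origin <- node_id(tree, origins[[subclass]])
  clade_tips <- tips_under(tree, origin)
  outside <- setdiff(tips, clade_tips)
  conflict <- outside[presence[outside]]
  if (length(conflict) > 0) {
    t3_stop("species present outside the ", subclass, " origin clade (",
            origins[[subclass]], "), conflicting with the single-origin ",
            "hypothesis: ", paste(conflict, collapse = ", "))
  }
  ntip <- length(tips)
  # bottom-up: is the whole subtree of each node absent?
  all_absent <- rep(TRUE, ntip + tree$Nnode)
  all_absent[seq_len(ntip)] <- !presence
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]; kid <- po$edge[e, 2]
    all_absent[par] <- all_absent[par] && all_absent[kid]
  }
  in_clade <- function(nd) {
    while (nd != origin) {
      par <- tree$edge[tree$edge[, 2] == nd, 1]
      if (length(par) == 0) return(FALSE)
      nd <- par
    }
    TRUE
  }
  losses <- integer(0)
  if (all_absent[origin]) {
    losses <- origin
  } else {
    for (nd in seq_len(ntip + tree$Nnode)) {
      if (!all_absent[nd] || nd == origin) next
      par <- tree$edge[tree$edge[, 2] == nd, 1]
      if (length(par) == 1 && !all_absent[par] && in_clade(nd)) {
        losses <- c(losses, nd)
      }
    }
  }
  if (length(losses) == 0) {
    return(data.frame(node = character(), n_tips = integer(),
                      stringsAsFactors = FALSE))
  }
  df <- data.frame(node = vapply(losses, function(nd) node_name(tree, nd), ""),
                   n_tips = vapply(losses, function(nd)
                     length(tips_under(tree, nd)), integer(1)),
                   stringsAsFactors = FALSE)
  df[order(df$node), , drop = FALSE]
}

#' Flag lineage-specific subclass expansions
#'
#' All (species, subclass) census cells with at least `threshold` genes,
#' sorted by count descending.  The default threshold of 4 is the
#' smallest repertoire the census treats as an expansion.
#'
#' @param census A [build_census()] result.
#' @param threshold Minimum gene count.
#' @return Data.frame with columns `species`, `subclass`, `count`.
#' @export
flag_expansions <- function(census, threshold = 4L) {
  counts <- census$counts
  rows <- list()
  for (sc in c("alpha", "beta", "gamma")) {
    hit <- which(counts[[sc]] >= threshold)
    if (length(hit) > 0) {
      rows[[sc]] <- data.frame(species = counts$species[hit], subclass = sc,
                               count = counts[[sc]][hit],
                               stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(species = character(), subclass = character(),
                      count = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$count, out$species, out$subclass), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-subclass loss and expansion report
#'
#' Combines Dollo loss reconstruction and expansion flags for all three
#' subclasses, and lists the species with no type-3 copper proteins at
#' all.
#'
#' @param tree Rooted species tree with named internal nodes.
#' @param census A [build_census()] result covering the tree's tips.
#' @param origins Named vector mapping subclass to origin node name.
#' @param expansion_threshold Passed to [flag_expansions()].
#' @return A list of class `evolution_report`: `losses` (data.frame
#'   `subclass`, `node`, `n_tips`), `expansions`
#'   ([flag_expansions()] layout) and `all_absent_species`.
#' @export
evolution_report <- function(tree, census, origins = default_origin_map(),
                             expansion_threshold = 4L) {
  counts <- census$counts
  missing <- setdiff(tree$tip.label, counts$species)
  if (length(missing) > 0) {
    t3_stop("census has no entry for tree tip(s): ",
            paste(missing, collapse = ", "))
  }
  losses <- list()
  for (sc in c("alpha", "beta", "gamma")) {
    pres <- counts[[sc]][match(tree$tip.label, counts$species)] > 0
    names(pres) <- tree$tip.label
    l <- infer_losses(tree, pres, origins, sc)
    if (nrow(l) > 0) losses[[sc]] <- cbind(subclass = sc, l,
                                           stringsAsFactors = FALSE)
  }
  losses <- if (length(losses) > 0) do.call(rbind, losses) else
    data.frame(subclass = character(), node = character(),
               n_tips = integer(), stringsAsFactors = FALSE)
  rownames(losses) <- NULL
  structure(list(losses = losses,
                 expansions = flag_expansions(census, expansion_threshold),
                 all_absent_species = sort(intersect(census$zero_species,
                                                     tree$tip.label))),
            class = "evolution_report")
}

#' @export
print.evolution_report <- function(x, ...) {
  cat(sprintf("Subclass losses: %d branches (%s)\n", nrow(x$losses),
              paste(sprintf("%s=%d", c("alpha", "beta", "gamma"),
                            vapply(c("alpha", "beta", "gamma"), function(s)
                              sum(x$losses$subclass == s), integer(1))),
                    collapse = ", ")))
  cat(sprintf("Expansions (>= threshold): %d\n", nrow(x$expansions)))
  cat(sprintf("Species without any type-3 copper protein: %s\n",
              if (length(x$all_absent_species))
                paste(x$all_absent_species, collapse = ", ") else "none"))
  invisible(x)
}
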