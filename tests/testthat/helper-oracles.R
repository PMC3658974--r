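# Independent oracles used to cross-check the package's algorithms.

# --- brute-force histidine-triad enumeration -------------------------

oracle_triads <- function(sequence, kind, params = scan_params()) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  hpos <- which(chars == "H") - 1L
  out <- NULL
  if (length(hpos) >= 3) {
    combos <- t(utils::combn(sort(hpos), 3))
    s12 <- combos[, 2] - combos[, 1] - 1L
    s23 <- combos[, 3] - combos[, 2] - 1L
    keep <- if (kind == "A") {
      s12 >= params$cuA_h1_h2_range[1] & s12 <= params$cuA_h1_h2_range[2] &
        (s23 == params$cuA_h2_h3_fixed |
           (s23 >= params$cuA_h2_h3_beta_range[1] &
              s23 <= params$cuA_h2_h3_beta_range[2]))
    } else {
      s12 == params$cuB_h1_h2_fixed &
        s23 >= params$cuB_h2_h3_range[1] & s23 <= params$cuB_h2_h3_range[2]
    }
    out <- combos[keep, , drop = FALSE]
  }
  if (is.null(out) || nrow(out) == 0) {
    return(data.frame(h1 = integer(), h2 = integer(), h3 = integer()))
  }
  df <- data.frame(h1 = out[, 1], h2 = out[, 2], h3 = out[, 3])
  df[order(df$h1, df$h2, df$h3), , drop = FALSE]
}

# --- exhaustive unrooted-topology enumeration and OLS minimum evolution

# topologies as edge matrices over tips 1..n and internal nodes n+1, ...
enumerate_topologies <- function(n) {
  grow <- function(edges, next_tip, next_internal) {
    if (next_tip > n) return(list(edges))
    out <- list()
    for (e in seq_len(nrow(edges))) {
      u <- edges[e, 1]; v <- edges[e, 2]
      new_edges <- rbind(edges[-e, , drop = FALSE],
                         c(u, next_internal), c(next_internal, v),
                         c(next_internal, next_tip))
      out <- c(out, grow(new_edges, next_tip + 1L, next_internal + 1L))
    }
    out
  }
  start <- rbind(c(n + 1L, 1L), c(n + 1L, 2L), c(n + 1L, 3L))
  grow(start, 4L, n + 2L)
}

# per-topology path-edge incidence over all tip pairs (rows: i<j pairs)
topology_incidence <- function(edges, n) {
  nodes <- sort(unique(as.vector(edges)))
  adj <- lapply(seq_len(max(nodes)), function(i) integer(0))
  for (e in seq_len(nrow(edges))) {
    u <- edges[e, 1]; v <- edges[e, 2]
    adj[[u]] <- c(adj[[u]], e); adj[[v]] <- c(adj[[v]], e)
  }
  other <- function(e, x) if (edges[e, 1] == x) edges[e, 2] else edges[e, 1]
  path_edges <- function(from, to) {
    # DFS from tip to tip
    stack <- list(list(node = from, used = integer(0), prev = 0L))
    while (length(stack) > 0) {
      st <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      if (st$node == to) return(st$used)
      for (e in adj[[st$node]]) {
        if (e != st$prev) {
          stack[[length(stack) + 1L]] <-
            list(node = other(e, st$node), used = c(st$used, e), prev = e)
        }
      }
    }
    stop("no path")
  }
  pairs <- t(utils::combn(n, 2))
  A <- matrix(0, nrow(pairs), nrow(edges))
  for (r in seq_len(nrow(pairs))) {
    A[r, path_edges(pairs[r, 1], pairs[r, 2])] <- 1
  }
  A
}

# split keys of a topology, matching cuproclass's canonical form
topology_splits <- function(edges, n, labels) {
  internal <- edges[, 1] > n & edges[, 2] > n
  keys <- character(0)
  for (e in which(internal)) {
    # tips on the side of edges[e, 2] after removing edge e
    seen <- edges[e, 2]; frontier <- edges[e, 2]
    sub <- edges[-e, , drop = FALSE]
    while (length(frontier) > 0) {
      nxt <- c(sub[sub[, 1] %in% frontier, 2], sub[sub[, 2] %in% frontier, 1])
      frontier <- setdiff(nxt, seen)
      seen <- c(seen, frontier)
    }
    tips <- labels[seen[seen <= n]]
    keys <- c(keys, cuproclass:::canon_split(tips, labels))
  }
  sort(keys)
}

phylo_splits <- function(tree) {
  keys <- cuproclass:::tree_splits(tree)
  sort(keys[!is.na(keys)])
}

# minimum-evolution by exhaustive search: OLS branch lengths per
# topology, minimise total tree length
oracle_me_splits <- function(dm, topos, incidences, labels) {
  dvec <- dm[t(utils::combn(nrow(dm), 2))]
  best <- NULL; best_len <- Inf
  for (t in seq_along(topos)) {
    A <- incidences[[t]]
    x <- qr.coef(qr(A), dvec)
    len <- sum(x)
    if (len < best_len - 1e-12) { best_len <- len; best <- t }
  }
  topology_splits(topos[[best]], nrow(dm), labels)
}

# random additive matrix from a random topology with positive lengths
random_additive <- function(n, topos, incidences, labels) {
  t <- sample.int(length(topos), 1)
  A <- incidences[[t]]
  x <- stats::runif(ncol(A), 0.1, 1)
  dvec <- as.vector(A %*% x)
  dm <- matrix(0, n, n, dimnames = list(labels, labels))
  dm[t(utils::combn(n, 2))] <- dvec
  dm <- dm + t(dm)
  list(dm = dm, splits = topology_splits(topos[[t]], n, labels))
}

# --- exhaustive Dollo minimisation -----------------------------------

oracle_dollo_min <- function(tree, presence) {
  tips <- tree$tip.label
  absent <- tips[!presence[tips]]
  if (length(absent) == 0) return(0L)
  ntip <- length(tips)
  nodes <- seq_len(ntip + tree$Nnode)
  subtree_tips <- lapply(nodes, function(nd) cuproclass:::tips_under(tree, nd))
  # candidate loss branches: subtree holds only absent tips
  cand <- nodes[vapply(subtree_tips, function(tp) all(tp %in% absent),
                       logical(1))]
  for (k in seq_along(cand)) {
    sets <- utils::combn(cand, k, simplify = FALSE)
    for (s in sets) {
      covered <- unique(unlist(subtree_tips[s]))
      if (all(absent %in% covered)) return(k)
    }
  }
  stop("unreachable")
}

# --- shared synthetic panel ------------------------------------------

make_panel <- function(n_per = 8, noise = 0.02) {
  recs <- list()
  for (sc in c("alpha", "beta", "gamma")) {
    for (k in seq_len(n_per)) {
      r <- make_template(sc, placeholder = if (sc == "beta") "F" else "V",
                         id = sprintf("%s%02d", sc, k))
      r <- mutate_protein(r, noise,
                          seed = k + 1000L * match(sc, c("alpha", "beta", "gamma")))
      recs[[length(recs) + 1L]] <- r
    }
  }
  do.call(rbind, recs)
}

panel_labels <- function(ids) {
  setNames(sub("[0-9]+$", "", ids), ids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
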