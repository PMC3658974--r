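# Motif-anchored alignment and distance-based phylogenetics for the
# copper-binding region.  The six histidine anchors (three per copper
# site) are pinned into shared columns; inter-anchor blocks are
# left-justified and gap-padded, which keeps the alignment deterministic
# and confined to the conserved region.

#' Build a motif-anchored alignment of copper-binding regions
#'
#' For each record the region `[cuA_h1 - flank, cuB_h3 + flank]`
#' (clipped to the sequence) is extracted, the six histidine positions
#' are pinned into shared anchor columns, and every inter-anchor block
#' (including the two flanks) is left-justified and padded with `-` to
#' the block's maximum length over all records.  Rows are ordered by
#' record id.
#'
#' @param records Data.frame of protein records.
#' @param sites Data.frame of binuclear sites keyed by `id`
#'   ([scan_records()] layout); every record must have a site.
#' @param flank Residues kept on each side of the binuclear site.
#' @return A list of class `anchored_alignment`: `matrix` (character
#'   matrix, one row per record), `anchor_cols` (the six anchor column
#'   indices) and `flank`.
#' @export
anchor_align <- function(records, sites, flank = 10L) {
  ids <- sort(records$id)
  hit <- match(ids, sites$id)
  missing <- ids[is.na(hit) | is.na(sites$cuA_h1[hit])]
  if (length(missing) > 0) {
    t3_stop("record(s) without a binuclear site: ",
            paste(missing, collapse = ", "))
  }
  blocks <- lapply(ids, function(id) {
    rec <- records[records$id == id, ]
    s <- sites[sites$id == id, ]
    chars <- seq_chars(rec$sequence)
    n <- length(chars)
    a <- c(s$cuA_h1, s$cuA_h2, s$cuA_h3, s$cuB_h1, s$cuB_h2, s$cuB_h3)
    lo <- max(0L, a[1] - flank)
    hi <- min(n, a[6] + 1L + flank)  # half-open
    cut <- function(from, to) if (to > from) chars[(from + 1):to] else character(0)
    list(pre = cut(lo, a[1]),
         b1 = cut(a[1] + 1L, a[2]), b2 = cut(a[2] + 1L, a[3]),
         inter = cut(a[3] + 1L, a[4]),
         b3 = cut(a[4] + 1L, a[5]), b4 = cut(a[5] + 1L, a[6]),
         post = cut(a[6] + 1L, hi),
         anchors = chars[a + 1L])
  })
  names(blocks) <- ids
  block_names <- c("pre", "b1", "b2", "inter", "b3", "b4", "post")
  maxlen <- vapply(block_names, function(b) {
    max(vapply(blocks, function(x) length(x[[b]]), integer(1)))
  }, integer(1))
  pad <- function(x, len) c(x, rep("-", len - length(x)))
  rows <- lapply(blocks, function(x) {
    c(pad(x$pre, maxlen["pre"]), x$anchors[1],
      pad(x$b1, maxlen["b1"]), x$anchors[2],
      pad(x$b2, maxlen["b2"]), x$anchors[3],
      pad(x$inter, maxlen["inter"]), x$anchors[4],
      pad(x$b3, maxlen["b3"]), x$anchors[5],
      pad(x$b4, maxlen["b4"]), x$anchors[6],
      pad(x$post, maxlen["post"]))
  })
  m <- do.call(rbind, rows)
  rownames(m) <- ids
  anchor_cols <- cumsum(c(maxlen["pre"] + 1L,
                          maxlen["b1"] + 1L, maxlen["b2"] + 1L,
                          maxlen["inter"] + 1L,
                          maxlen["b3"] + 1L, maxlen["b4"] + 1L))
  structure(list(matrix = m, anchor_cols = unname(anchor_cols),
                 flank = as.integer(flank)),
            class = "anchored_alignment")
}

#' Pairwise distances from an anchored alignment
#'
#' The p-distance of a pair is the mismatch fraction over columns where
#' neither row holds a gap or X (pairwise deletion; complete deletion
#' drops such columns for all pairs first).  The Poisson-corrected
#' distance is `-ln(1 - p)`.
#'
#' @param aln An [anchor_align()] result.
#' @param model `"p"` or `"poisson"`.
#' @param deletion `"pairwise"` (default) or `"complete"`.
#' @return A symmetric numeric matrix keyed by record id, with
#'   attribute `model`.
#' @export
aln_distances <- function(aln, model = c("p", "poisson"),
                          deletion = c("pairwise", "complete")) {
  model <- match.arg(model)
  deletion <- match.arg(deletion)
  m <- aln$matrix
  if (nrow(m) < 2) t3_stop("distance computation needs at least 2 rows")
  if (deletion == "complete") {
    keep <- colSums(m == "-" | m == "X") == 0
    m <- m[, keep, drop = FALSE]
  }
  n <- nrow(m)
  ids <- rownames(m)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  usable <- m != "-" & m != "X"
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      comp <- usable[i, ] & usable[j, ]
      if (!any(comp)) {
        t3_stop("no comparable columns for pair ", ids[i], " / ", ids[j])
      }
      p <- mean(m[i, comp] != m[j, comp])
      if (model == "poisson") {
        if (p >= 1) {
          t3_stop("p-distance of 1 for pair ", ids[i], " / ", ids[j],
                  " cannot be Poisson-corrected; use model 'p'")
        }
        d[i, j] <- d[j, i] <- -log(1 - p)
      } else {
        d[i, j] <- d[j, i] <- p
      }
    }
  }
  attr(d, "model") <- model
  d
}

fmt_len <- function(x) sprintf("%.12g", x)

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration on the Q criterion.  Ties in Q are
#' broken by the pair whose clusters carry the lexicographically
#' smallest representative tip labels (each cluster is represented by
#' its smallest member label).  Negative branch-length estimates are
#' clamped to zero with a message.  For an additive input matrix the
#' tree's path lengths reproduce the matrix.
#'
#' @param dm Symmetric distance matrix with row/column names.
#' @return An unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(dm) {
  n <- nrow(dm)
  if (is.null(rownames(dm))) t3_stop("distance matrix must have names")
  if (n < 3) t3_stop("neighbor-joining needs at least 3 taxa")
  labs <- rownames(dm)
  d <- dm
  news <- labs                 # newick fragment per active cluster
  reps <- labs                 # lexicographic representative per cluster
  composite <- rep(FALSE, n)
  clamped <- 0L
  clamp <- function(x) {
    if (x < 0) { clamped <<- clamped + 1L; 0 } else x
  }
  while (nrow(d) > 2) {
    k <- nrow(d)
    r <- rowSums(d)
    q <- (k - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    minq <- min(q)
    cand <- which(q - minq <= 1e-12 * max(1, abs(minq)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- vapply(seq_len(nrow(cand)), function(t) {
      pr <- sort(c(reps[cand[t, 1]], reps[cand[t, 2]]))
      paste(pr, collapse = "\r")
    }, "")
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    dij <- d[i, j]
    bi <- clamp(0.5 * dij + (r[i] - r[j]) / (2 * (k - 2)))
    bj <- clamp(dij - bi)
    newfrag <- sprintf("(%s:%s,%s:%s)", news[i], fmt_len(bi),
                       news[j], fmt_len(bj))
    newrep <- min(reps[i], reps[j])
    dnew <- 0.5 * (d[i, ] + d[j, ] - dij)
    keep <- setdiff(seq_len(k), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    nm <- c(rownames(d)[keep], newrep)
    dimnames(d2) <- list(nm, nm)
    d <- d2
    news <- c(news[keep], newfrag)
    reps <- c(reps[keep], newrep)
    composite <- c(composite[keep], TRUE)
  }
  dfin <- clamp(d[1, 2])
  if (composite[1]) {
    inner <- substr(news[1], 2, nchar(news[1]) - 1)
    txt <- sprintf("(%s,%s:%s);", inner, news[2], fmt_len(dfin))
  } else if (composite[2]) {
    inner <- substr(news[2], 2, nchar(news[2]) - 1)
    txt <- sprintf("(%s,%s:%s);", inner, news[1], fmt_len(dfin))
  } else {
    txt <- sprintf("(%s:%s,%s:0);", news[1], fmt_len(dfin), news[2])
  }
  if (clamped > 0) {
    message("nj_tree: ", clamped, " negative branch-length estimate(s) clamped to 0")
  }
  ape::read.tree(text = txt)
}

#' Midpoint-root a tree
#'
#' Places the root at the midpoint of the longest tip-to-tip path.  A
#' two-tip tree is rooted at the midpoint of its single edge.
#'
#' @param tree An unrooted [ape::phylo] tree with branch lengths.
#' @return A rooted [ape::phylo] tree.
#' @export
midpoint_root <- function(tree) {
  if (is.null(tree$edge.length) || sum(tree$edge.length) <= 0) {
    t3_stop("midpoint rooting needs positive branch lengths")
  }
  if (length(tree$tip.label) == 2) {
    half <- sum(tree$edge.length) / 2
    return(ape::read.tree(text = sprintf("(%s:%s,%s:%s);",
                                         tree$tip.label[1], fmt_len(half),
                                         tree$tip.label[2], fmt_len(half))))
  }
  phangorn::midpoint(tree)
}

# Non-trivial bipartitions of an unrooted tree, as canonical keys.
# Each internal edge separates a tip set from the rest; the canonical
# key is the side not containing the alphabetically first tip.
canon_split <- function(tips, all_tips) {
  ref <- min(all_tips)
  side <- if (ref %in% tips) setdiff(all_tips, tips) else tips
  paste(sort(side), collapse = "\r")
}

tree_splits <- function(tree) {
  all_tips <- tree$tip.label
  pp <- ape::prop.part(tree)
  keys <- vapply(pp, function(ix) {
    tips <- all_tips[ix]
    if (length(tips) <= 1 || length(tips) >= length(all_tips)) NA_character_
    else canon_split(tips, all_tips)
  }, "")
  keys  # one entry per internal node, in node-number order
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree
#' per replicate, and reports for each internal edge of the original
#' tree the percentage of replicates containing the same bipartition.
#' Supports are stored as `node.label` (the root node is left blank).
#'
#' @param aln An [anchor_align()] result.
#' @param model Distance model passed to [aln_distances()].
#' @param replicates Number of bootstrap replicates.
#' @param seed Integer seed; required for reproducibility.
#' @return The original NJ tree with `node.label` support percentages.
#' @export
bootstrap_support <- function(aln, model = "p", replicates = 1000L, seed) {
  if (missing(seed)) t3_stop("bootstrap_support requires a seed")
  if (replicates < 1) t3_stop("replicates must be >= 1")
  base_tree <- nj_tree(aln_distances(aln, model))
  keys <- tree_splits(base_tree)
  hits <- numeric(length(keys))
  nc <- ncol(aln$matrix)
  set.seed(seed)
  for (b in seq_len(replicates)) {
    cols <- sample.int(nc, nc, replace = TRUE)
    rep_aln <- aln
    rep_aln$matrix <- aln$matrix[, cols, drop = FALSE]
    rep_tree <- tryCatch(suppressMessages(nj_tree(aln_distances(rep_aln, model))),
                         error = function(e) NULL)
    if (is.null(rep_tree)) next
    rep_keys <- tree_splits(rep_tree)
    hits <- hits + as.numeric(keys %in% rep_keys[!is.na(rep_keys)])
  }
  support <- 100 * hits / replicates
  labels <- ifelse(is.na(keys), "", fmt_len(support))
  base_tree$node.label <- labels
  attr(base_tree, "support") <- ifelse(is.na(keys), NA_real_, support)
  base_tree
}

#' Bootstrap support of one clade
#'
#' @param tree A [bootstrap_support()] result.
#' @param tips Tip subset whose bipartition support is wanted.
#' @return Support percentage, or `NA` when the tip set is not a
#'   bipartition of the tree.
#' @export
clade_support <- function(tree, tips) {
  support <- attr(tree, "support")
  if (is.null(support)) t3_stop("tree carries no bootstrap support")
  keys <- tree_splits(tree)
  key <- canon_split(tips, tree$tip.label)
  hit <- which(!is.na(keys) & keys == key)
  if (length(hit) == 0) NA_real_ else support[hit[1]]
}

#' Test monophyly of a tip set on an unrooted tree
#'
#' TRUE iff some bipartition of the unrooted tree separates exactly the
#' given tips from the rest.  Singleton sets and the full tip set are
#' monophyletic by convention.
#'
#' @param tree An [ape::phylo] tree.
#' @param tips Non-empty character vector of tip labels.
#' @return Logical.
#' @export
is_monophyletic <- function(tree, tips) {
  if (length(tips) == 0) t3_stop("tip subset must be non-empty")
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown) > 0) {
    t3_stop("unknown tip(s): ", paste(unknown, collapse = ", "))
  }
  n <- length(tree$tip.label)
  if (length(tips) == 1 || length(tips) == n) return(TRUE)
  keys <- tree_splits(tree)
  canon_split(tips, tree$tip.label) %in% keys[!is.na(keys)]
}

#' Mean interclass divergence per class
#'
#' For each class, the mean distance from its members to all members of
#' the other classes.
#'
#' @param dm Distance matrix keyed by taxon.
#' @param labels Named character vector (names = taxa, values = class).
#' @return Named numeric vector, one entry per class.
#' @export
mean_interclass_divergence <- function(dm, labels) {
  labels <- labels[rownames(dm)]
  if (any(is.na(labels))) t3_stop("every taxon must be labeled")
  classes <- sort(unique(labels))
  out <- vapply(classes, function(cl) {
    inside <- which(labels == cl)
    outside <- which(labels != cl)
    if (length(inside) == 0) t3_stop("class with zero members: ", cl)
    if (length(outside) == 0) t3_stop("class ", cl, " has no outside members")
    mean(dm[inside, outside])
  }, numeric(1))
  names(out) <- classes
  out
}
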