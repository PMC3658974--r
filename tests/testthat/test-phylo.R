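# Two tiny hand-made records with planted sites for alignment arithmetic:
# spacings differ by 2 in the Cu(A) H1-H2 block.
toy_records <- function() {
  mk <- function(id, n1) {
    chars <- rep("A", 80)
    h1 <- 10; h2 <- h1 + n1 + 1; h3 <- h2 + 9
    b1 <- h3 + 15; b2 <- b1 + 4; b3 <- b2 + 5
    chars[c(h1, h2, h3, b1, b2, b3) + 1] <- "H"
    data.frame(id = id, species = NA, lineage = NA,
               sequence = paste(chars, collapse = ""),
               stringsAsFactors = FALSE)
  }
  rbind(mk("r1", 4), mk("r2", 6))
}

test_that("anchored alignment pins histidines and pads blocks", {
  a <- make_template("alpha")
  two <- rbind(a, transform(a, id = "alpha_2"))
  aln <- anchor_align(two, scan_records(two))
  expect_equal(nrow(aln$matrix), 2)
  expect_false(any(aln$matrix == "-"))  # equal spacings, no gaps
  expect_true(all(aln$matrix[, aln$anchor_cols] == "H"))

  toys <- toy_records()
  taln <- anchor_align(toys, scan_records(toys))
  expect_equal(sum(taln$matrix["r1", ] == "-"), 2)
  expect_equal(sum(taln$matrix["r2", ] == "-"), 0)
  # the two gaps sit in the first inter-anchor block (before anchor 2)
  gap_cols <- which(taln$matrix["r1", ] == "-")
  expect_true(all(gap_cols < taln$anchor_cols[2] &
                    gap_cols > taln$anchor_cols[1]))

  # single record: alignment equals its extracted region
  one <- toys[1, ]
  oaln <- anchor_align(one, scan_records(one))
  expect_false(any(oaln$matrix == "-"))

  norec <- data.frame(id = "x", species = NA, lineage = NA,
                      sequence = strrep("A", 30), stringsAsFactors = FALSE)
  expect_error(anchor_align(norec, scan_records(norec)), "without a binuclear site")
})

test_that("row degapping recovers the extracted region", {
  recs <- make_panel(n_per = 2, noise = 0.05)
  sites <- scan_records(recs)
  aln <- anchor_align(recs, sites, flank = 10)
  for (id in rownames(aln$matrix)) {
    row <- aln$matrix[id, ]
    s <- sites[sites$id == id, ]
    seqn <- strsplit(recs$sequence[recs$id == id], "")[[1]]
    lo <- max(0, s$cuA_h1 - 10); hi <- min(length(seqn), s$cuB_h3 + 1 + 10)
    expect_equal(paste(row[row != "-"], collapse = ""),
                 paste(seqn[(lo + 1):hi], collapse = ""))
  }
})

test_that("distances implement p and Poisson models with pairwise deletion", {
  aln <- structure(list(matrix = rbind(r1 = strsplit("AAAAAAAAAA", "")[[1]],
                                       r2 = strsplit("AACCAAAAAA", "")[[1]])),
                   class = "anchored_alignment")
  expect_equal(aln_distances(aln, "p")["r1", "r2"], 0.2)
  expect_equal(aln_distances(aln, "poisson")["r1", "r2"], -log(0.8),
               tolerance = 1e-12)

  same <- aln; same$matrix[2, ] <- same$matrix[1, ]
  expect_equal(same |> aln_distances("p") |> max(), 0)

  allx <- aln; allx$matrix[2, ] <- rep("X", 10)
  expect_error(aln_distances(allx, "p"), "no comparable")

  alldiff <- aln; alldiff$matrix[2, ] <- rep("C", 10)
  expect_error(aln_distances(alldiff, "poisson"), "model 'p'")
})

test_that("neighbor-joining recovers the 4-taxon additive example", {
  dm <- matrix(c(0, 3, 5, 6,
                 3, 0, 6, 7,
                 5, 6, 0, 7,
                 6, 7, 7, 0), 4, 4,
               dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- nj_tree(dm)
  expect_true(is_monophyletic(tr, c("A", "B")))
  expect_false(is_monophyletic(tr, c("A", "C")))
  expect_equal(max(abs(ape::cophenetic.phylo(tr)[rownames(dm), rownames(dm)] - dm)),
               0, tolerance = 1e-9)
})

test_that("3-taxon neighbor-joining uses the closed-form star lengths", {
  dm <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(dm)
  len <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(len[["A"]], (5 + 9 - 10) / 2)
  expect_equal(len[["B"]], (5 + 10 - 9) / 2)
  expect_equal(len[["C"]], (9 + 10 - 5) / 2)

  expect_error(nj_tree(dm[1:2, 1:2]), "at least 3")
})

test_that("NJ equals exhaustive minimum evolution on additive matrices", {
  set.seed(23)
  for (n in 4:6) {
    labels <- paste0("t", seq_len(n))
    topos <- enumerate_topologies(n)
    inc <- lapply(topos, topology_incidence, n = n)
    for (trial in 1:10) {
      ra <- random_additive(n, topos, inc, labels)
      tr <- suppressMessages(nj_tree(ra$dm))
      expect_equal(phylo_splits(tr), ra$splits)
      expect_equal(phylo_splits(tr), oracle_me_splits(ra$dm, topos, inc, labels))
      expect_equal(max(abs(ape::cophenetic.phylo(tr)[labels, labels] - ra$dm)),
                   0, tolerance = 1e-9)
    }
  }
})

test_that("midpoint rooting splits the longest tip-to-tip path", {
  # edges A-X=1, B-X=2, X-Y=1, C-Y=3, D-Y=4; longest path B-D = 7
  tr <- ape::read.tree(text = "((A:1,B:2):1,C:3,D:4);")
  mr <- midpoint_root(tr)
  expect_true(ape::is.rooted(mr))
  depths <- ape::node.depth.edgelength(mr)
  tip_depth <- setNames(depths[seq_along(mr$tip.label)], mr$tip.label)
  expect_equal(tip_depth[["B"]], 3.5)
  expect_equal(tip_depth[["D"]], 3.5)

  bal <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  mb <- midpoint_root(ape::unroot(bal))
  d2 <- ape::node.depth.edgelength(mb)
  expect_equal(max(d2[1:4]), min(d2[1:4]))  # all tips equidistant

  two <- midpoint_root(ape::read.tree(text = "(A:1,B:3);"))
  d3 <- ape::node.depth.edgelength(two)
  expect_equal(d3[1:2], c(2, 2))

  zero <- ape::read.tree(text = "(A:0,B:0,C:0);")
  expect_error(midpoint_root(zero), "positive")
})

test_that("bootstrap supports are reproducible and bounded", {
  recs <- make_panel(n_per = 3, noise = 0.02)
  aln <- anchor_align(recs, scan_records(recs))
  b1 <- suppressMessages(bootstrap_support(aln, "p", replicates = 30, seed = 5))
  b2 <- suppressMessages(bootstrap_support(aln, "p", replicates = 30, seed = 5))
  expect_identical(b1$node.label, b2$node.label)
  sup <- attr(b1, "support")
  expect_true(all(sup[!is.na(sup)] >= 0 & sup[!is.na(sup)] <= 100))

  one <- suppressMessages(bootstrap_support(aln, "p", replicates = 1, seed = 9))
  s1 <- attr(one, "support")
  expect_true(all(s1[!is.na(s1)] %in% c(0, 100)))

  # degenerate data: identical rows duplicated with distinct ids
  a <- make_template("alpha")
  four <- do.call(rbind, lapply(1:4, function(i) transform(a, id = paste0("d", i))))
  daln <- anchor_align(four, scan_records(four))
  expect_no_error(suppressMessages(
    bootstrap_support(daln, "p", replicates = 5, seed = 2)))
})

test_that("monophyly testing works on quartets and degenerate subsets", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_true(is_monophyletic(tr, c("A", "B")))
  expect_false(is_monophyletic(tr, c("A", "C")))
  expect_true(is_monophyletic(tr, c("A", "B", "C", "D")))
  expect_true(is_monophyletic(tr, "A"))
  expect_error(is_monophyletic(tr, c("A", "Z")), "unknown tip")
})

test_that("interclass divergence averages distances across classes", {
  dm <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(dm) <- 0
  labs <- setNames(c("x", "x", "y", "y"), letters[1:4])
  div <- mean_interclass_divergence(dm, labs)
  expect_equal(unname(div["x"]), unname(div["y"]))

  dm2 <- matrix(c(0, 2, 4, 2, 0, 6, 4, 6, 0), 3, 3,
                dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  labs2 <- setNames(c("p", "q", "r"), c("a", "b", "c"))
  div2 <- mean_interclass_divergence(dm2, labs2)
  expect_equal(unname(div2["p"]), 3)  # mean of 2 and 4
  expect_equal(unname(div2["q"]), 4)
  expect_equal(unname(div2["r"]), 5)

  expect_error(mean_interclass_divergence(dm2, setNames(c("p", "p", NA),
                                                        c("a", "b", "c"))),
               "labeled")
})

test_that("the cytosolic subclass is the most divergent on the panel", {
  recs <- make_panel(n_per = 6, noise = 0.02)
  aln <- anchor_align(recs, scan_records(recs))
  dm <- aln_distances(aln, "p")
  div <- mean_interclass_divergence(dm, panel_labels(rownames(dm)))
  expect_equal(names(which.max(div)), "beta")
})
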