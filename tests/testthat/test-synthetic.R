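test_that("templates are deterministic and validated", {
  expect_identical(make_template("alpha"), make_template("alpha"))
  expect_error(make_template("delta"), "unknown subclass")
  expect_error(make_template("alpha", placeholder = "ZZ"), "placeholder")
  expect_error(make_template("alpha", disulfide_bridges = 3), "disulfide")
})

test_that("every packaged feature profile survives the full round trip", {
  spec <- default_census_spec()
  profs <- unique(spec$entries[, c("subclass", "lineage", "label",
                                   "placeholder", "cys_his_bond",
                                   "disulfide_bridges")])
  for (i in seq_len(nrow(profs))) {
    pr <- profs[i, ]
    rec <- make_template(pr$subclass, placeholder = pr$placeholder,
                         cys_his_bond = pr$cys_his_bond,
                         disulfide_bridges = pr$disulfide_bridges,
                         lineage = pr$lineage)
    site <- best_binuclear_site(rec)
    call <- assign_subclass(build_architecture(rec), site)
    expect_equal(call$subclass, pr$subclass)
    compat <- functional_compatibility(call, site, pr$lineage)
    expect_true(pr$label %in% compat)
  }
})

test_that("mutation respects rate, protection and determinism", {
  tmpl <- make_template("alpha")
  expect_identical(mutate_protein(tmpl, 0, seed = 1)$sequence, tmpl$sequence)
  expect_identical(mutate_protein(tmpl, 0.3, seed = 4)$sequence,
                   mutate_protein(tmpl, 0.3, seed = 4)$sequence)
  expect_error(mutate_protein(tmpl, 1, seed = 1), "rate")

  # rate close to 1 changes every unprotected position
  hot <- mutate_protein(tmpl, 0.999999, seed = 2)
  a <- strsplit(tmpl$sequence, "")[[1]]
  b <- strsplit(hot$sequence, "")[[1]]
  prot <- attr(tmpl, "protected") + 1
  expect_true(all(a[prot] == b[prot]))
  expect_true(all(a[-prot] != b[-prot]))

  # realised substitution fraction within 3 standard errors of the rate
  rate <- 0.1
  n_free <- length(a) - length(prot)
  changed <- mean(vapply(1:20, function(k) {
    m <- strsplit(mutate_protein(tmpl, rate, seed = 100 + k)$sequence, "")[[1]]
    sum(m[-prot] != a[-prot])
  }, numeric(1))) / n_free
  se <- sqrt(rate * (1 - rate) / (20 * n_free))
  expect_lt(abs(changed - rate), 3 * se)
})

test_that("census spec matches the published aggregate structure", {
  spec <- default_census_spec()
  expect_equal(sum(spec$entries$count), 179)
  sp <- spec$species
  has <- sp$species %in% spec$entries$species
  expect_equal(sum(has & sp$metazoan), 35)
  expect_equal(sum(has & !sp$metazoan), 17)
  expect_equal(sum(!has), 4)

  per <- tapply(spec$entries$count, list(spec$entries$species,
                                         spec$entries$subclass), sum)
  per[is.na(per)] <- 0
  all3 <- rownames(per)[rowSums(per > 0) == 3]
  expect_equal(all3, "Ciona_intestinalis")

  named <- function(species, subclass) per[species, subclass]
  expect_equal(named("Glycine_max", "alpha"), 12, ignore_attr = TRUE)
  expect_equal(named("Ectocarpus_siliculosus", "alpha"), 18, ignore_attr = TRUE)
  expect_equal(named("Caenorhabditis_elegans", "alpha"), 5, ignore_attr = TRUE)
  expect_equal(named("Caenorhabditis_briggsae", "alpha"), 6, ignore_attr = TRUE)
  expect_equal(named("Caenorhabditis_remanei", "alpha"), 5, ignore_attr = TRUE)
  expect_equal(named("Brugia_malayi", "alpha"), 4, ignore_attr = TRUE)
  expect_equal(named("Anopheles_gambiae", "beta"), 9, ignore_attr = TRUE)
  expect_equal(named("Branchiostoma_floridae", "gamma"), 18, ignore_attr = TRUE)
})

test_that("census generation is spec-driven and seed-invariant in counts", {
  f1 <- generate_census(noise_rate = 0.05, seed = 1)
  f2 <- generate_census(noise_rate = 0.05, seed = 2)
  expect_equal(nrow(f1$records), 179)
  expect_identical(f1$records$id, f2$records$id)
  expect_identical(f1$truth, f2$truth)
  expect_false(identical(f1$records$sequence, f2$records$sequence))
  expect_identical(generate_census(noise_rate = 0.05, seed = 1)$records,
                   f1$records)
})

test_that("coordinate fixture realises the cluster plan", {
  loci <- generate_coords()
  calls <- data.frame(id = loci$protein_id,
                      subclass = ifelse(grepl("_g_", loci$protein_id), "gamma",
                                 ifelse(grepl("_b_", loci$protein_id), "beta",
                                        "alpha")),
                      stringsAsFactors = FALSE)
  cl <- find_clusters(loci, calls)
  expect_equal(max(cl$size), 7)
  expect_true(all(cl$size >= 2 & cl$size <= 7))
  expect_setequal(unique(cl$size), 2:7)

  # singleton-only plan yields no clusters
  plan <- default_cluster_plan()
  solo <- plan[!grepl(",", plan$ids), ]
  expect_equal(nrow(find_clusters(generate_coords(solo), calls)), 0)

  # overlapping loci are rejected
  bad <- plan[1, ]
  bad$gap_bp <- -3000L
  expect_error(generate_coords(bad), "overlapping")
})

test_that("species tree and presence matrix respect the subclass origins", {
  st <- generate_species_tree()
  spec <- default_census_spec()
  expect_setequal(st$tree$tip.label, spec$species$species)
  expect_true(all(c("root", "unikonta", "opisthokonta", "metazoa") %in%
                    st$tree$node.label))

  metazoa_tips <- cuproclass:::tips_under(st$tree,
                                          cuproclass:::node_id(st$tree, "metazoa"))
  unikont_tips <- cuproclass:::tips_under(st$tree,
                                          cuproclass:::node_id(st$tree, "unikonta"))
  expect_true(all(rownames(st$presence)[st$presence[, "gamma"]] %in%
                    metazoa_tips))
  expect_true(all(rownames(st$presence)[st$presence[, "beta"]] %in%
                    unikont_tips))
  # outside the unikonts only the secreted subclass occurs
  outside <- setdiff(rownames(st$presence), unikont_tips)
  expect_false(any(st$presence[outside, c("beta", "gamma")]))
  # the four protein-free genomes are tips of the tree
  zero <- c("Strongylocentrotus_purpuratus", "Trichoplax_adhaerens",
            "Monosiga_brevicolis", "Capsaspora_owczarzaki")
  expect_true(all(zero %in% st$tree$tip.label))
  expect_false(any(st$presence[zero, ]))
})
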