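test_that("subclass assignment follows the architecture rules", {
  site_v <- best_binuclear_site(make_template("alpha", placeholder = "V"))
  arch_a <- build_architecture(make_template("alpha"))
  call_a <- assign_subclass(arch_a, site_v)
  expect_equal(call_a$subclass, "alpha")
  expect_gte(call_a$confidence, 1)

  beta <- make_template("beta", placeholder = "F")
  call_b <- assign_subclass(build_architecture(beta), best_binuclear_site(beta))
  expect_equal(call_b$subclass, "beta")
  expect_equal(call_b$confidence, 3)   # sp_absent + shifted_h2 + placeholder F
  expect_setequal(call_b$evidence, c("sp_absent", "shifted_h2", "placeholder_F"))

  gam <- make_template("gamma", placeholder = "V")
  call_g <- assign_subclass(build_architecture(gam), best_binuclear_site(gam))
  expect_equal(call_g$subclass, "gamma")
  expect_equal(call_g$confidence, 4)   # sp + tm + cys_rich + placeholder V

  expect_equal(assign_subclass(arch_a, NULL)$subclass, "unclassified")
})

test_that("discordant evidence lowers confidence but never overrides", {
  gam <- make_template("gamma", placeholder = "F")  # beta-like placeholder
  call <- assign_subclass(build_architecture(gam), best_binuclear_site(gam))
  expect_equal(call$subclass, "gamma")
  expect_lt(call$confidence, 4)
  expect_gte(call$confidence, 1)
})

test_that("feature-table lookups reproduce the packaged active-site rows", {
  tab <- feature_table()
  mh <- tab[tab$subclass == "alpha" & tab$lineage == "mollusca" &
              tab$label == "hemocyanin", ]
  expect_equal(mh$disulfide_bridges, 2)
  expect_true(mh$cys_his_bond)
  pb <- tab[tab$subclass == "beta" & tab$lineage == "porifera", ]
  expect_equal(pb$disulfide_bridges, 1)
  expect_true(all(tab$placeholder[tab$subclass == "beta"] == "F"))
  expect_true(all(tab$placeholder[tab$subclass == "gamma"] == "V"))
})

test_that("functional compatibility matches sites against table rows", {
  hemo <- make_template("alpha", placeholder = "L", cys_his_bond = TRUE,
                        disulfide_bridges = 2)
  call <- list(subclass = "alpha")
  expect_equal(functional_compatibility(call, best_binuclear_site(hemo),
                                        "mollusca"),
               "hemocyanin")

  arth <- make_template("beta", placeholder = "F", disulfide_bridges = 2)
  expect_equal(functional_compatibility(list(subclass = "beta"),
                                        best_binuclear_site(arth),
                                        "arthropoda"),
               c("hemocyanin", "tyrosinase"))

  vert <- make_template("gamma", placeholder = "V")
  expect_equal(functional_compatibility(list(subclass = "gamma"),
                                        best_binuclear_site(vert),
                                        "vertebrata"),
               "tyrosinase")

  # mismatched features yield the empty set, unknown lineages an error
  expect_length(functional_compatibility(list(subclass = "gamma"),
                                         best_binuclear_site(hemo),
                                         "vertebrata"), 0)
  expect_error(functional_compatibility(list(subclass = "alpha"),
                                        best_binuclear_site(hemo),
                                        "atlantis"),
               "valid tags")
})

test_that("every record with a site gets exactly one subclass", {
  recs <- make_panel(n_per = 4, noise = 0.05)
  calls <- classify_records(recs)
  expect_true(all(calls$subclass %in% c("alpha", "beta", "gamma")))
  expect_equal(nrow(calls), nrow(recs))
})

test_that("census aggregation conserves counts and summarises species", {
  fix <- generate_census(noise_rate = 0, seed = 3)
  calls <- classify_records(fix$records)
  census <- build_census(calls, fix$species)
  expect_equal(census$total_proteins,
               sum(calls$subclass %in% c("alpha", "beta", "gamma")))
  expect_equal(sum(census$counts$alpha + census$counts$beta +
                     census$counts$gamma), census$total_proteins)
  expect_equal(census$all_three_species, "Ciona_intestinalis")
  expect_setequal(census$zero_species,
                  c("Strongylocentrotus_purpuratus", "Trichoplax_adhaerens",
                    "Monosiga_brevicolis", "Capsaspora_owczarzaki"))

  empty <- build_census(calls[0, ], fix$species)
  expect_equal(empty$total_proteins, 0)
  expect_equal(length(empty$zero_species), nrow(fix$species))
})

test_that("subclass recovery accuracy is non-increasing in noise", {
  acc <- vapply(c(0, 0.05, 0.1, 0.2), function(nr) {
    fix <- generate_census(noise_rate = nr, seed = 17)
    calls <- classify_records(fix$records)
    mean(calls$subclass == fix$truth$subclass)
  }, numeric(1))
  expect_equal(acc[1], 1)
  expect_true(all(diff(acc) <= 0))
})
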