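rec_of <- function(seq, id = "t") {
  data.frame(id = id, species = NA, lineage = NA, sequence = seq,
             stringsAsFactors = FALSE)
}

test_that("triad scan finds canonical Cu(A) and Cu(B) spacings", {
  a <- scan_his_triads(rec_of("MHAAAAHAAAAAAAAH"), "A")  # H at 1, 6, 15
  expect_equal(nrow(a), 1)
  expect_equal(a$spacing12, 4)
  expect_equal(a$spacing23, 8)

  b <- scan_his_triads(rec_of("MHAAAHAAAAAH"), "B")      # H at 1, 5, 11
  expect_equal(nrow(b), 1)
  expect_equal(b$spacing12, 3)
  expect_equal(b$spacing23, 5)

  expect_equal(nrow(scan_his_triads(rec_of(strrep("A", 50)), "A")), 0)
  expect_equal(nrow(scan_his_triads(rec_of(strrep("A", 50)), "B")), 0)
})

test_that("triad scan equals brute-force enumeration on random sequences", {
  set.seed(11)
  letters20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:50) {
    n <- sample(30:500, 1)
    seqn <- paste(sample(letters20, n, TRUE,
                         prob = c(rep(1, 6), 4, rep(1, 13))), collapse = "")
    for (kind in c("A", "B")) {
      got <- scan_his_triads(rec_of(seqn), kind)
      want <- oracle_triads(seqn, kind)
      expect_equal(got[, c("h1", "h2", "h3")], want, ignore_attr = TRUE)
    }
  }
})

test_that("pairing respects the intersite gap range and scores pairs", {
  # canonical A at (1,6,15); B too far: gap 404 > 400
  far <- paste0("MHAAAAHAAAAAAAAH", strrep("A", 404),
                "HAAAHAAAAH", strrep("A", 5))
  recf <- rec_of(far)
  pf <- pair_sites(recf, scan_his_triads(recf, "A"),
                   scan_his_triads(recf, "B"))
  expect_true(all(pf$intersite_gap <= 400))
  expect_false(any(pf$cuA_h3 == 15 & pf$cuB_h1 == 420))

  # B at (50, 54, 60): gap 34 in range
  chars <- rep("A", 70)
  chars[c(2, 7, 16)] <- "H"            # A triad at 1, 6, 15 (0-based)
  chars[c(51, 55, 61)] <- "H"          # B triad at 50, 54, 60
  recn <- rec_of(paste(chars, collapse = ""))
  pn <- pair_sites(recn, scan_his_triads(recn, "A"),
                   scan_his_triads(recn, "B"))
  expect_equal(nrow(pn), 1)
  expect_equal(pn$intersite_gap, 34)
})

test_that("pairing is exhaustive and sorted by score then position", {
  # two A candidates (shifted and canonical), one B
  chars <- rep("A", 120)
  chars[c(2, 7, 16)] <- "H"        # canonical A at 1,6,15 (spacing23 = 8)
  chars[c(21, 26, 36)] <- "H"      # shifted A at 20,25,35 (spacing23 = 9)
  chars[c(81, 85, 91)] <- "H"      # B at 80,84,90
  recn <- rec_of(paste(chars, collapse = ""))
  sa <- scan_his_triads(recn, "A")
  sb <- scan_his_triads(recn, "B")
  p <- pair_sites(recn, sa, sb)
  expect_lte(nrow(p), nrow(sa) * nrow(sb))
  expect_true(all(diff(p$score) <= 0))
  # canonical (unshifted) pair outscores the shifted one
  expect_false(p$shifted_h2[1])
})

test_that("diagnostic probes read Phe/Asp at the configured offsets", {
  a <- make_template("alpha")
  site <- best_binuclear_site(a)
  expect_true(site$phe_A_ok && site$phe_B_ok && site$asp_B_ok)

  # F -> A at cuA_h3 - 4 turns phe_A off only, and never raises the score
  chars <- strsplit(a$sequence, "")[[1]]
  chars[site$cuA_h3 - 4 + 1] <- "A"
  mut <- rec_of(paste(chars, collapse = ""))
  msite <- best_binuclear_site(mut)
  expect_false(msite$phe_A_ok)
  expect_true(msite$phe_B_ok && msite$asp_B_ok)
  expect_lt(msite$score, site$score)

  # Asp probe beyond the C-terminus is FALSE, not an error
  chars2 <- rep("A", 60)
  chars2[c(2, 7, 16)] <- "H"
  chars2[c(51, 55, 60)] <- "H"     # cuB_h3 = 59 is the last residue
  recb <- rec_of(paste(chars2, collapse = ""))
  p <- pair_sites(recb, scan_his_triads(recb, "A"),
                  scan_his_triads(recb, "B"))
  expect_false(p$asp_B_ok[1])
})

test_that("placeholder extraction follows the anchor convention", {
  b <- make_template("beta", placeholder = "F")
  sb <- best_binuclear_site(b)
  expect_equal(sb$placeholder_residue, "F")
  expect_equal(sb$placeholder_position, sb$cuB_h1 - 6)

  g <- make_template("gamma", placeholder = "V")
  expect_equal(best_binuclear_site(g)$placeholder_residue, "V")

  # anchor + offset out of bounds -> NA
  chars <- rep("A", 60)
  chars[c(1, 6, 15)] <- "H"
  chars[c(31, 35, 41)] <- "H"
  recn <- rec_of(paste(chars, collapse = ""))
  site <- best_binuclear_site(recn, convention =
                                placeholder_convention("cuA_h1", -10L))
  expect_true(is.na(site$placeholder_residue))
  expect_true(is.na(site$placeholder_position))
})

test_that("cysteine features follow the packaged feature profiles", {
  hemo <- make_template("alpha", placeholder = "L", cys_his_bond = TRUE,
                        disulfide_bridges = 2)
  sh <- best_binuclear_site(hemo)
  expect_true(sh$cys_his_bond)
  expect_equal(sh$disulfide_count, 2)

  pori <- make_template("beta", placeholder = "F", disulfide_bridges = 1)
  sp <- best_binuclear_site(pori)
  expect_false(sp$cys_his_bond)
  expect_equal(sp$disulfide_count, 1)

  plain <- make_template("gamma")
  s0 <- best_binuclear_site(plain)
  expect_false(s0$cys_his_bond)
  expect_equal(s0$disulfide_count, 0)
})

test_that("best site is deterministic and breaks ties leftmost", {
  a <- make_template("alpha")
  s1 <- best_binuclear_site(a)
  s2 <- best_binuclear_site(a)
  expect_identical(s1, s2)

  # concatenating two templates keeps the site of the first
  double <- rec_of(paste0(a$sequence, a$sequence))
  sd <- best_binuclear_site(double)
  expect_equal(sd$cuA_h1, s1$cuA_h1)
  expect_equal(sd$cuB_h1, s1$cuB_h1)

  expect_null(best_binuclear_site(rec_of(strrep("AKLE", 50))))
})

test_that("planted sites are recovered exactly under 5% noise", {
  for (sc in c("alpha", "beta", "gamma")) {
    tmpl <- make_template(sc, placeholder = if (sc == "beta") "F" else "V")
    planted <- attr(tmpl, "site")
    for (k in 1:20) {
      noisy <- mutate_protein(tmpl, 0.05, seed = 7000 + k)
      site <- best_binuclear_site(noisy)
      expect_equal(c(site$cuA_h1, site$cuA_h2, site$cuA_h3,
                     site$cuB_h1, site$cuB_h2, site$cuB_h3), planted)
    }
  }
})
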