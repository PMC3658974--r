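# Synthetic census generator.  Templates are the constructive inverse of
# the classifier: each subclass template carries the planted architecture
# (signal peptide, transmembrane segment, cysteine-rich region), the
# planted binuclear site with subclass-specific spacings, the conserved
# Phe/Phe/Asp diagnostics, and a species-specific active-site feature
# profile (placeholder residue, Cys-His bond, disulfide-bridge pairs).
# Background residues near the active site exclude H, C, F and D so the
# planted motif and feature counts stay unique; elsewhere the background
# is uniform over non-His residues with 2% His allowed, so spurious-triad
# handling is still exercised.

ACTIVE_BG <- setdiff(AA_LETTERS, c("H", "C", "F", "D"))
HYDROPHILIC_BG <- c("D", "E", "K", "R", "N", "Q", "S", "T", "G", "P")

# run expr with a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

sample_general <- function(n) {
  prob <- c(rep(0.98 / 19, 19), 0.02)
  sample(c(setdiff(AA_LETTERS, "H"), "H"), n, replace = TRUE, prob = prob)
}

# local (0-based) coordinates of the planted active-site region
region_layout <- function(subclass) {
  if (subclass %in% c("alpha", "gamma")) {
    list(len = 140L, h = c(25L, 32L, 41L, 102L, 106L, 114L),
         pheA = 37L, pheB = 110L, aspB = 118L,
         placeholder = 96L, bond = 31L, bridges = c(47L, 53L, 59L, 65L),
         bond_window = 30:34)
  } else if (subclass == "beta") {
    list(len = 152L, h = c(25L, 34L, 45L, 112L, 116L, 126L),
         pheA = 41L, pheB = 122L, aspB = 130L,
         placeholder = 106L, bond = 33L, bridges = c(51L, 57L, 63L, 69L),
         bond_window = 32:36)
  } else {
    t3_stop("unknown subclass '", subclass, "'")
  }
}

# Consensus active-site region per subclass.  All three consensi descend
# from one ancestral region: the secreted (alpha) consensus copies it
# unchanged, the membrane-bound (gamma) consensus diverges from alpha at
# 25% of free positions, and the cytosolic (beta) consensus diverges at
# 50% (and with its shifted spacings), making beta the most divergent
# subclass without saturating its distances.  Blocks are copied
# left-justified, matching the anchored-alignment padding, so aligned
# columns stay homologous across subclasses.
region_consensus <- function(subclass) {
  lay <- region_layout(subclass)
  # inter-anchor block sizes: pre, H1-H2, H2-H3, linker, B1-B2, B2-B3, post
  anc_sizes <- c(25L, 8L, 10L, 66L, 3L, 9L, 25L)     # beta geometry (max)
  sizes <- if (subclass == "beta") anc_sizes else c(25L, 6L, 8L, 60L, 3L, 7L, 25L)
  anc <- with_seed(100L, sample(ACTIVE_BG, sum(anc_sizes), replace = TRUE))
  anc_blocks <- split(anc, rep(seq_along(anc_sizes), anc_sizes))
  chars <- character(0)
  for (b in seq_along(sizes)) {
    chars <- c(chars, anc_blocks[[b]][seq_len(sizes[b])],
               if (b < length(sizes)) "H")
  }
  stopifnot(length(chars) == lay$len)
  fixed <- c(lay$h, lay$pheA, lay$pheB, lay$aspB, lay$placeholder,
             lay$bond_window, lay$bridges)
  free <- setdiff(seq_len(lay$len) - 1L, fixed)
  flip <- function(chars, seed, rate) with_seed(seed, {
    hit <- free[stats::runif(length(free)) < rate]
    chars[hit + 1L] <- sample(ACTIVE_BG, length(hit), replace = TRUE)
    chars
  })
  if (subclass == "beta") {
    chars <- flip(chars, 202L, 0.5)
  } else {
    chars <- flip(chars, 150L, 0.05)         # shared alpha/gamma stem
    chars <- if (subclass == "alpha") flip(chars, 101L, 0.10)
             else flip(chars, 303L, 0.25)
  }
  chars[lay$h + 1L] <- "H"
  chars[c(lay$pheA, lay$pheB) + 1L] <- "F"
  chars[lay$aspB + 1L] <- "D"
  chars
}

#' Packaged subclass sequence template
#'
#' Deterministic scaffold of one subclass: planted architecture segments
#' plus the consensus active-site region.  Feature-profile positions
#' (placeholder, Cys-His bond, disulfide Cys) are slots overwritten by
#' [make_template()].
#'
#' @param subclass `"alpha"`, `"beta"` or `"gamma"`.
#' @return A list with `chars`, `region_offset`, `layout`, `protected`
#'   (0-based positions never mutated) and the planted spans.
#' @keywords internal
subclass_template <- function(subclass) {
  lay <- region_layout(subclass)
  region <- region_consensus(subclass)
  if (subclass == "alpha") {
    nterm <- c("M", rep("L", 12), with_seed(111L, sample(HYDROPHILIC_BG, 7, TRUE)))
    tail <- with_seed(112L, sample_general(30))
    chars <- c(nterm, region, tail)
    off <- 20L
    protected_extra <- 0:12
    spans <- list(sp = c(0L, 20L), tm = NULL, cys_rich = NULL)
  } else if (subclass == "beta") {
    nterm <- c("M", with_seed(211L, sample(HYDROPHILIC_BG, 19, TRUE)))
    tail <- with_seed(212L, sample_general(30))
    chars <- c(nterm, region, tail)
    off <- 20L
    protected_extra <- 0:19
    spans <- list(sp = NULL, tm = NULL, cys_rich = NULL)
  } else {
    nterm <- c("M", rep("L", 27), rep("S", 10))          # 0..37
    cys_local <- c(0L, 4L, 8L, 12L, 16L, 20L, 24L, 28L)
    cysrich <- with_seed(311L, sample(setdiff(ACTIVE_BG, "X"), 30, TRUE))
    cysrich[cys_local + 1L] <- "C"                       # 38..67
    spacer <- with_seed(312L, sample_general(10))        # 68..77
    insulator <- c("D", "E", "K", "N", "S")              # after region
    tm <- with_seed(313L, sample(c("L", "I", "V"), 25, TRUE))
    tailseg <- with_seed(314L, sample_general(8))
    chars <- c(nterm, cysrich, spacer, region, insulator, tm, tailseg)
    off <- 78L
    tm_start <- off + lay$len + 5L
    protected_extra <- c(0:27, 38L + cys_local, tm_start:(tm_start + 24L))
    spans <- list(sp = c(0L, 38L), tm = c(tm_start, tm_start + 25L),
                  cys_rich = c(38L, 68L))
  }
  # Besides the planted features, protect every position where a noise
  # histidine could complete a triad tying the planted site's score and
  # stealing the leftmost tie-break: the window upstream of H1 within
  # H1-H2 spacing range of the planted H2, and the two H2-H3 spacers.
  tie_guard <- c(max(0L, off + lay$h[2] - 41L):(off + lay$h[1] - 1L),
                 (off + lay$h[2] + 1L):(off + lay$h[3] - 1L),
                 (off + lay$h[5] + 1L):(off + lay$h[6] - 1L),
                 off + lay$h[4] - 4L)
  protected <- sort(unique(c(protected_extra, tie_guard,
                             off + c(lay$h, lay$pheA, lay$pheB, lay$aspB,
                                     lay$placeholder, lay$bond_window,
                                     lay$bridges))))
  list(chars = chars, region_offset = off, layout = lay,
       protected = protected, spans = spans, subclass = subclass,
       site = off + lay$h)
}

#' Generate a subclass template protein with a feature profile
#'
#' Builds the packaged subclass scaffold and plants the requested
#' active-site feature profile: the placeholder residue, a Cys adjacent
#' to the Cu(A) H2 when a Cys-His bond is requested, and one Cys pair
#' per disulfide bridge inside the active-site region.  The result is
#' deterministic; use [mutate_protein()] to add substitution noise.
#'
#' @param subclass `"alpha"`, `"beta"` or `"gamma"`.
#' @param placeholder Single placeholder residue letter.
#' @param cys_his_bond Plant a Cys at the Cu(A) H2 - 1 position?
#' @param disulfide_bridges Number of disulfide bridges (0--2); each
#'   plants one Cys pair.
#' @param id,species,lineage Metadata for the returned record.
#' @return One-row data.frame in the [read_fasta()] layout with
#'   attributes `protected` (0-based positions carrying planted
#'   features) and `site` (the six planted His positions).
#' @export
make_template <- function(subclass, placeholder = "V", cys_his_bond = FALSE,
                          disulfide_bridges = 0L, id = paste0(subclass, "_1"),
                          species = NA_character_, lineage = NA_character_) {
  if (!subclass %in% c("alpha", "beta", "gamma")) {
    t3_stop("unknown subclass '", subclass, "'")
  }
  if (!placeholder %in% AA_LETTERS) {
    t3_stop("placeholder must be one of the 20 amino-acid letters")
  }
  if (disulfide_bridges < 0 || disulfide_bridges > 2) {
    t3_stop("disulfide_bridges must be 0, 1 or 2")
  }
  tmpl <- subclass_template(subclass)
  chars <- tmpl$chars
  off <- tmpl$region_offset
  lay <- tmpl$layout
  chars[off + lay$placeholder + 1L] <- placeholder
  if (cys_his_bond) chars[off + lay$bond + 1L] <- "C"
  if (disulfide_bridges > 0) {
    slots <- lay$bridges[seq_len(2L * disulfide_bridges)]
    chars[off + slots + 1L] <- "C"
  }
  rec <- data.frame(id = id, species = species, lineage = lineage,
                    sequence = paste(chars, collapse = ""),
                    stringsAsFactors = FALSE)
  attr(rec, "protected") <- tmpl$protected
  attr(rec, "site") <- tmpl$site
  rec
}

#' Substitution noise on unprotected positions
#'
#' Each unprotected position is substituted, with the given per-site
#' probability, by a uniformly drawn different residue.  Deterministic
#' for a fixed seed; protected positions are never touched.
#'
#' @param record One-row protein record.
#' @param rate Per-site substitution probability in `[0, 1)`.
#' @param protected 0-based positions to leave untouched (defaults to
#'   the record's `protected` attribute).
#' @param seed Integer seed.
#' @return The record with a mutated sequence (attributes preserved).
#' @export
mutate_protein <- function(record, rate, protected = attr(record, "protected"),
                           seed) {
  if (rate < 0 || rate >= 1) t3_stop("rate must be in [0, 1)")
  if (missing(seed)) t3_stop("mutate_protein requires a seed")
  chars <- seq_chars(record$sequence)
  idx <- setdiff(seq_along(chars) - 1L, protected)
  with_seed(seed, {
    hit <- idx[stats::runif(length(idx)) < rate]
    for (p in hit) {
      chars[p + 1L] <- sample(setdiff(AA_LETTERS, chars[p + 1L]), 1)
    }
  })
  record$sequence <- paste(chars, collapse = "")
  record
}

#' Packaged census specification
#'
#' The packaged synthetic census mirrors the published survey structure:
#' 179 proteins across 35 metazoan and 17 non-metazoan species, the
#' named lineage-specific expansions (Glycine max alpha = 12, Ectocarpus
#' siliculosus alpha = 18, the Caenorhabditis/Brugia alpha repertoires,
#' Anopheles gambiae beta = 9, Branchiostoma floridae gamma = 18), a
#' single species (Ciona intestinalis) carrying all three subclasses,
#' and four surveyed genomes with no type-3 copper proteins at all.
#' Unnamed filler species carry 1--3 genes each.  Every entry points at
#' the feature-table row its proteins are generated from.
#'
#' @return A list with `entries` (one row per species x subclass:
#'   `species`, `lineage`, `metazoan`, `subclass`, `count`, `label`,
#'   `placeholder`, `cys_his_bond`, `disulfide_bridges`) and `species`
#'   (all surveyed species incl. the four empty genomes).
#' @export
default_census_spec <- function() {
  e <- function(species, lineage, subclass, count, label, ph, bond, br) {
    data.frame(species = species, lineage = lineage,
               metazoan = is_metazoan(lineage), subclass = subclass,
               count = as.integer(count), label = label, placeholder = ph,
               cys_his_bond = bond, disulfide_bridges = as.integer(br),
               stringsAsFactors = FALSE)
  }
  entries <- rbind(
    # --- non-metazoan species (17) ---------------------------------
    e("Bacillus_megaterium", "eubacteria", "alpha", 1, "tyrosinase", "V", FALSE, 0),
    e("Streptomyces_griseus", "eubacteria", "alpha", 2, "tyrosinase", "V", FALSE, 0),
    e("Haloferax_volcanii", "archaebacteria", "alpha", 1, "tyrosinase", "V", FALSE, 0),
    e("Sulfolobus_solfataricus", "archaebacteria", "alpha", 1, "tyrosinase", "V", FALSE, 0),
    e("Glycine_max", "plantae", "alpha", 12, "catechol_oxidase", "L", TRUE, 2),
    e("Oryza_sativa", "plantae", "alpha", 2, "catechol_oxidase", "L", TRUE, 2),
    e("Ipomoea_batatas", "plantae", "alpha", 2, "catechol_oxidase", "L", TRUE, 2),
    e("Chlamydomonas_reinhardtii", "plantae", "alpha", 1, "catechol_oxidase", "L", TRUE, 2),
    e("Ectocarpus_siliculosus", "chromoalveolata", "alpha", 18, "tyrosinase", "V", FALSE, 0),
    e("Phytophthora_infestans", "chromoalveolata", "alpha", 2, "tyrosinase", "V", FALSE, 0),
    e("Thalassiosira_pseudonana", "chromoalveolata", "alpha", 1, "tyrosinase", "V", FALSE, 0),
    e("Dictyostelium_discoideum", "amoebozoa", "alpha", 1, "tyrosinase", "V", FALSE, 0),
    e("Dictyostelium_discoideum", "amoebozoa", "beta", 2, "tyrosinase", "F", FALSE, 0),
    e("Polysphondylium_pallidum", "amoebozoa", "beta", 2, "tyrosinase", "F", FALSE, 0),
    e("Neurospora_tetrasperma", "fungi", "alpha", 2, "tyrosinase", "V", TRUE, 0),
    e("Neurospora_tetrasperma", "fungi", "beta", 1, "tyrosinase", "F", FALSE, 0),
    e("Aspergillus_aculeatus", "fungi", "alpha", 2, "tyrosinase", "V", TRUE, 0),
    e("Aspergillus_aculeatus", "fungi", "beta", 1, "tyrosinase", "F", FALSE, 0),
    e("Agaricus_bisporus", "fungi", "alpha", 2, "tyrosinase", "V", TRUE, 0),
    e("Podospora_anserina", "fungi", "beta", 1, "tyrosinase", "F", FALSE, 0),
    # --- metazoan species (35) -------------------------------------
    e("Amphimedon_queenslandica", "porifera", "beta", 1, "tyrosinase", "F", FALSE, 1),
    e("Amphimedon_queenslandica", "porifera", "gamma", 1, "tyrosinase", "V", FALSE, 0),
    e("Oscarella_carmela", "porifera", "beta", 2, "tyrosinase", "F", FALSE, 1),
    e("Nematostella_vectensis", "cnidaria", "alpha", 3, "tyrosinase", "V", FALSE, 0),
    e("Hydra_magnipapillata", "cnidaria", "alpha", 3, "tyrosinase", "V", FALSE, 0),
    e("Acropora_digitifera", "cnidaria", "alpha", 3, "tyrosinase", "V", FALSE, 0),
    e("Schistosoma_mansoni", "platyhelminthes", "gamma", 3, "tyrosinase", "V", FALSE, 0),
    e("Schmidtea_mediterranea", "platyhelminthes", "gamma", 2, "tyrosinase", "V", FALSE, 0),
    e("Capitella_teleta", "annelida", "gamma", 3, "tyrosinase", "V", FALSE, 0),
    e("Helobdella_robusta", "annelida", "gamma", 2, "tyrosinase", "V", FALSE, 0),
    e("Lottia_gigantea", "mollusca", "alpha", 3, "tyrosinase", "V", FALSE, 0),
    e("Crassostrea_gigas", "mollusca", "alpha", 3, "tyrosinase", "V", FALSE, 0),
    e("Megathura_crenulata", "mollusca", "alpha", 3, "hemocyanin", "L", TRUE, 2),
    e("Caenorhabditis_elegans", "nematoda", "alpha", 5, "tyrosinase", "I", FALSE, 0),
    e("Caenorhabditis_briggsae", "nematoda", "alpha", 6, "tyrosinase", "I", FALSE, 0),
    e("Caenorhabditis_remanei", "nematoda", "alpha", 5, "tyrosinase", "I", FALSE, 0),
    e("Brugia_malayi", "nematoda", "alpha", 4, "tyrosinase", "I", FALSE, 0),
    e("Pristionchus_pacificus", "nematoda", "alpha", 2, "tyrosinase", "I", FALSE, 0),
    e("Anopheles_gambiae", "arthropoda", "beta", 9, "tyrosinase", "F", FALSE, 2),
    e("Drosophila_melanogaster", "arthropoda", "beta", 3, "tyrosinase", "F", FALSE, 2),
    e("Aedes_aegypti", "arthropoda", "beta", 3, "tyrosinase", "F", FALSE, 2),
    e("Tribolium_castaneum", "arthropoda", "beta", 3, "tyrosinase", "F", FALSE, 2),
    e("Daphnia_pulex", "arthropoda", "beta", 3, "hemocyanin", "F", FALSE, 2),
    e("Apis_mellifera", "arthropoda", "beta", 2, "tyrosinase", "F", FALSE, 2),
    e("Ixodes_scapularis", "arthropoda", "beta", 2, "hemocyanin", "F", FALSE, 2),
    e("Saccoglossus_kowalevskii", "hemichordata", "beta", 1, "hemocyanin", "F", FALSE, 0),
    e("Saccoglossus_kowalevskii", "hemichordata", "gamma", 1, "tyrosinase", "V", FALSE, 0),
    e("Ptychodera_flava", "hemichordata", "gamma", 1, "tyrosinase", "V", FALSE, 0),
    e("Branchiostoma_floridae", "cephalochordata", "gamma", 18, "tyrosinase", "V", FALSE, 0),
    e("Ciona_intestinalis", "urochordata", "alpha", 2, "hemocyanin", "L", TRUE, 2),
    e("Ciona_intestinalis", "urochordata", "beta", 1, "tyrosinase", "F", FALSE, 0),
    e("Ciona_intestinalis", "urochordata", "gamma", 2, "tyrosinase", "V", FALSE, 0),
    e("Ciona_savignyi", "urochordata", "alpha", 1, "hemocyanin", "L", TRUE, 2),
    e("Ciona_savignyi", "urochordata", "gamma", 1, "tyrosinase", "V", FALSE, 0),
    e("Danio_rerio", "vertebrata", "gamma", 3, "tyrosinase", "V", FALSE, 0),
    e("Takifugu_rubripes", "vertebrata", "gamma", 2, "tyrosinase", "V", FALSE, 0),
    e("Xenopus_tropicalis", "vertebrata", "gamma", 3, "tyrosinase", "V", FALSE, 0),
    e("Gallus_gallus", "vertebrata", "gamma", 2, "tyrosinase", "V", FALSE, 0),
    e("Mus_musculus", "vertebrata", "gamma", 3, "tyrosinase", "V", FALSE, 0),
    e("Homo_sapiens", "vertebrata", "gamma", 2, "tyrosinase", "V", FALSE, 0))
  zero <- data.frame(
    species = c("Strongylocentrotus_purpuratus", "Trichoplax_adhaerens",
                "Monosiga_brevicolis", "Capsaspora_owczarzaki"),
    lineage = c("echinodermata", "placozoa", "choanoflagellata", "filasterea"),
    stringsAsFactors = FALSE)
  zero$metazoan <- is_metazoan(zero$lineage)
  species <- unique(entries[, c("species", "lineage", "metazoan")])
  species <- rbind(species, zero)
  rownames(entries) <- rownames(species) <- NULL
  list(entries = entries, species = species)
}

#' Generate the synthetic protein census
#'
#' One protein per census count: the subclass template with the species'
#' feature profile, noised at `noise_rate` outside protected positions.
#' Counts and metadata are spec-driven and therefore seed-invariant;
#' only the background noise differs between seeds.
#'
#' @param spec A [default_census_spec()]-shaped list.
#' @param noise_rate Per-site substitution probability.
#' @param seed Integer seed.
#' @return A list of class `census_fixture`: `records` (protein
#'   records), `species` (all surveyed species), `truth` (planted
#'   per-record labels for round-trip tests).
#' @export
generate_census <- function(spec = default_census_spec(), noise_rate = 0.05,
                            seed) {
  if (missing(seed)) t3_stop("generate_census requires a seed")
  entries <- spec$entries
  n_total <- sum(entries$count)
  rec_seeds <- with_seed(seed, sample.int(2^30, n_total))
  records <- vector("list", n_total)
  truth <- vector("list", n_total)
  k <- 0L
  for (i in seq_len(nrow(entries))) {
    en <- entries[i, ]
    for (j in seq_len(en$count)) {
      k <- k + 1L
      id <- sprintf("%s_%s_%02d", en$species, substr(en$subclass, 1, 1), j)
      rec <- make_template(en$subclass, placeholder = en$placeholder,
                           cys_his_bond = en$cys_his_bond,
                           disulfide_bridges = en$disulfide_bridges,
                           id = id, species = en$species,
                           lineage = en$lineage)
      if (noise_rate > 0) {
        rec <- mutate_protein(rec, noise_rate, seed = rec_seeds[k])
      }
      records[[k]] <- rec
      truth[[k]] <- data.frame(id = id, species = en$species,
                               lineage = en$lineage, metazoan = en$metazoan,
                               subclass = en$subclass, label = en$label,
                               placeholder = en$placeholder,
                               cys_his_bond = en$cys_his_bond,
                               disulfide_bridges = en$disulfide_bridges,
                               stringsAsFactors = FALSE)
    }
  }
  structure(list(records = do.call(rbind, records),
                 species = spec$species,
                 truth = do.call(rbind, truth)),
            class = "census_fixture")
}

#' Packaged tandem-cluster plan
#'
#' Lays the tandem-expansion species' genes out as linked clusters:
#' cluster sizes 2 through 7 all occur, the largest (7) in the
#' Branchiostoma floridae gamma expansion, plus singleton scaffolds.
#' Gene ids match the [generate_census()] record ids.
#'
#' @return Data.frame with one row per cluster or singleton: `species`,
#'   `subclass`, `scaffold`, `ids` (comma-joined), `gap_bp`.
#' @export
default_cluster_plan <- function() {
  mk <- function(species, subclass, scaffold_no, members, gap_bp = 10000L) {
    ids <- sprintf("%s_%s_%02d", species, substr(subclass, 1, 1), members)
    data.frame(species = species, subclass = subclass,
               scaffold = sprintf("%s_sc%d", species, scaffold_no),
               ids = paste(ids, collapse = ","), gap_bp = as.integer(gap_bp),
               stringsAsFactors = FALSE)
  }
  rbind(
    mk("Branchiostoma_floridae", "gamma", 1, 1:7),
    mk("Branchiostoma_floridae", "gamma", 2, 8:12),
    mk("Branchiostoma_floridae", "gamma", 3, 13:16),
    mk("Branchiostoma_floridae", "gamma", 4, 17:18),
    mk("Anopheles_gambiae", "beta", 1, 1:3),
    mk("Anopheles_gambiae", "beta", 2, 4:6),
    mk("Anopheles_gambiae", "beta", 3, 7:8),
    mk("Anopheles_gambiae", "beta", 4, 9),          # singleton
    mk("Glycine_max", "alpha", 1, 1:6),
    mk("Glycine_max", "alpha", 2, 7:10),
    mk("Glycine_max", "alpha", 3, 11:12),
    mk("Ectocarpus_siliculosus", "alpha", 1, 1:5),
    mk("Ectocarpus_siliculosus", "alpha", 2, 6:9),
    mk("Ectocarpus_siliculosus", "alpha", 3, 10:12),
    mk("Ectocarpus_siliculosus", "alpha", 4, 13:14),
    mk("Ectocarpus_siliculosus", "alpha", 5, 15),   # singleton
    mk("Ectocarpus_siliculosus", "alpha", 6, 16),   # singleton
    mk("Ectocarpus_siliculosus", "alpha", 7, 17:18))
}

#' Generate gene coordinates for the cluster plan
#'
#' Genes are 2 kb long; consecutive genes on a scaffold are separated by
#' the plan's `gap_bp` (or, when `gap_bp` is `NA`, a seed-drawn gap of
#' 5--40 kb).  Strands alternate.
#'
#' @param plan A [default_cluster_plan()]-shaped data.frame.
#' @param seed Integer seed (used only for `NA` gaps).
#' @param gene_len Gene length in base pairs.
#' @return Data.frame of gene loci in the [read_gene_coords()] layout.
#' @export
generate_coords <- function(plan = default_cluster_plan(), seed = 1L,
                            gene_len = 2000L) {
  rows <- list()
  for (i in seq_len(nrow(plan))) {
    ids <- strsplit(plan$ids[i], ",", fixed = TRUE)[[1]]
    gaps <- if (is.na(plan$gap_bp[i])) {
      with_seed(seed + i, sample(5000:40000, length(ids), replace = TRUE))
    } else rep(plan$gap_bp[i], length(ids))
    start <- 5000L
    for (j in seq_along(ids)) {
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = ids[j], scaffold = plan$scaffold[i],
        start = start, end = start + gene_len,
        strand = if (j %% 2 == 1) "+" else "-", stringsAsFactors = FALSE)
      start <- start + gene_len + gaps[j]
    }
  }
  out <- do.call(rbind, rows)
  for (sc in unique(out$scaffold)) {
    sub <- out[out$scaffold == sc, ]
    sub <- sub[order(sub$start), ]
    if (nrow(sub) > 1 && any(sub$start[-1] < sub$end[-nrow(sub)])) {
      t3_stop("overlapping loci in plan on scaffold ", sc)
    }
  }
  rownames(out) <- NULL
  out
}

#' Write gene loci as GFF3
#'
#' @param loci Data.frame in the [read_gene_coords()] layout (0-based
#'   half-open coordinates).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(loci, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tcuproclass\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     loci$scaffold, loci$start + 1L, loci$end, loci$strand,
                     loci$protein_id))
  writeLines(lines, path)
  invisible(path)
}

#' Packaged species tree and presence matrix
#'
#' A rooted species tree over all census species (including the four
#' genomes without type-3 copper proteins) with named internal nodes at
#' the resolution the loss/expansion synthesis needs: `root`,
#' `unikonta`, `opisthokonta`, `holozoa`, `metazoa` and the phylum
#' clades; unresolved groups are polytomies.  The presence matrix is
#' implied by the packaged census spec.
#'
#' @param spec A [default_census_spec()]-shaped list.
#' @return A list with `tree` (rooted [ape::phylo] with `node.label`)
#'   and `presence` (logical species x subclass matrix).
#' @export
generate_species_tree <- function(spec = default_census_spec()) {
  newick <- paste0(
    "((Bacillus_megaterium,Streptomyces_griseus)eubacteria_clade,",
    "(Haloferax_volcanii,Sulfolobus_solfataricus)archaebacteria_clade,",
    "(((Glycine_max,Oryza_sativa,Ipomoea_batatas,Chlamydomonas_reinhardtii)plantae_clade,",
    "(Ectocarpus_siliculosus,Phytophthora_infestans,Thalassiosira_pseudonana)chromoalveolata_clade)bikonta,",
    "((Dictyostelium_discoideum,Polysphondylium_pallidum)amoebozoa_clade,",
    "((Neurospora_tetrasperma,Aspergillus_aculeatus,Podospora_anserina,Agaricus_bisporus)fungi_clade,",
    "(Monosiga_brevicolis,Capsaspora_owczarzaki,",
    "((Amphimedon_queenslandica,Oscarella_carmela)porifera_clade,",
    "(Trichoplax_adhaerens,",
    "(Nematostella_vectensis,Hydra_magnipapillata,Acropora_digitifera)cnidaria_clade,",
    "(((Schistosoma_mansoni,Schmidtea_mediterranea)platyhelminthes_clade,",
    "(Capitella_teleta,Helobdella_robusta)annelida_clade,",
    "(Lottia_gigantea,Crassostrea_gigas,Megathura_crenulata)mollusca_clade,",
    "(Caenorhabditis_elegans,Caenorhabditis_briggsae,Caenorhabditis_remanei,",
    "Brugia_malayi,Pristionchus_pacificus)nematoda_clade,",
    "(Anopheles_gambiae,Aedes_aegypti,Drosophila_melanogaster,Tribolium_castaneum,",
    "Apis_mellifera,Daphnia_pulex,Ixodes_scapularis)arthropoda_clade)protostomia,",
    "(Strongylocentrotus_purpuratus,",
    "(Saccoglossus_kowalevskii,Ptychodera_flava)hemichordata_clade,",
    "(Branchiostoma_floridae,",
    "(Ciona_intestinalis,Ciona_savignyi)urochordata_clade,",
    "(Danio_rerio,Takifugu_rubripes,Xenopus_tropicalis,Gallus_gallus,",
    "Mus_musculus,Homo_sapiens)vertebrata_clade)chordata)deuterostomia)bilateria)eumetazoa)metazoa)holozoa)opisthokonta)unikonta)eukaryota)root;")
  tree <- ape::read.tree(text = newick)
  sp <- spec$species$species
  presence <- matrix(FALSE, nrow = length(sp), ncol = 3,
                     dimnames = list(sp, c("alpha", "beta", "gamma")))
  for (i in seq_len(nrow(spec$entries))) {
    en <- spec$entries[i, ]
    if (en$count > 0) presence[en$species, en$subclass] <- TRUE
  }
  if (!setequal(tree$tip.label, sp)) {
    t3_stop("species tree tips do not match the census species")
  }
  list(tree = tree, presence = presence)
}
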