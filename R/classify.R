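# Subclass assignment.  The subclass definition is architectural:
# secreted (alpha) = signal peptide, no membrane segment; cytosolic
# (beta) = no signal peptide; membrane-bound (gamma) = signal peptide
# plus a transmembrane segment (with a cysteine-rich region as
# supporting evidence).  Active-site features (shifted Cu(A) H2,
# placeholder residue) adjust confidence but never override the
# architecture rule.

METAZOAN_LINEAGES <- c("porifera", "cnidaria", "mollusca", "annelida",
                       "platyhelminthes", "nematoda", "arthropoda",
                       "onychophora", "hemichordata", "cephalochordata",
                       "urochordata", "vertebrata", "echinodermata",
                       "placozoa")

#' Is a lineage tag metazoan?
#'
#' @param lineage Character vector of lineage tags.
#' @return Logical vector.
#' @export
is_metazoan <- function(lineage) lineage %in% METAZOAN_LINEAGES

#' Active-site feature table
#'
#' The packaged lookup of active-site structural features per subclass
#' and lineage group: the placeholder residue(s) observed, whether a
#' Cys-His thioether bond is present at the Cu(A) H2, and the number of
#' disulfide bridges around the active site.  Functional labels follow
#' the family's functional classes: tyrosinase, catechol oxidase,
#' hemocyanin (tyrosinase-related proteins carry the `tyrosinase_related`
#' label in the vocabulary but have no dedicated feature row).
#'
#' @return A data.frame with columns `subclass`, `lineage`, `label`,
#'   `placeholder` (allowed residues, `/`-separated), `cys_his_bond`
#'   (logical) and `disulfide_bridges` (integer).
#' @export
feature_table <- function() {
  tab <- rbind(
    # subclass, lineage,          label,              placeholder, bond, bridges
    c("alpha", "eubacteria",      "tyrosinase",       "V",     "no",  0),
    c("alpha", "archaebacteria",  "tyrosinase",       "V",     "no",  0),
    c("alpha", "plantae",         "catechol_oxidase", "F/L",   "yes", 2),
    c("alpha", "chromoalveolata", "tyrosinase",       "V",     "no",  0),
    c("alpha", "amoebozoa",       "tyrosinase",       "V",     "no",  0),
    c("alpha", "fungi",           "tyrosinase",       "V/L/I", "yes", 0),
    c("alpha", "cnidaria",        "tyrosinase",       "V",     "no",  0),
    c("alpha", "mollusca",        "hemocyanin",       "L",     "yes", 2),
    c("alpha", "mollusca",        "tyrosinase",       "V/I",   "no",  0),
    c("alpha", "nematoda",        "tyrosinase",       "I",     "no",  0),
    c("alpha", "urochordata",     "hemocyanin",       "L",     "yes", 2),
    c("beta",  "amoebozoa",       "tyrosinase",       "F",     "no",  0),
    c("beta",  "fungi",           "tyrosinase",       "F",     "no",  0),
    c("beta",  "porifera",        "tyrosinase",       "F",     "no",  1),
    c("beta",  "arthropoda",      "tyrosinase",       "F",     "no",  2),
    c("beta",  "arthropoda",      "hemocyanin",       "F",     "no",  2),
    c("beta",  "hemichordata",    "hemocyanin",       "F",     "no",  0),
    c("beta",  "urochordata",     "tyrosinase",       "F",     "no",  0),
    c("gamma", "porifera",        "tyrosinase",       "V",     "no",  0),
    c("gamma", "platyhelminthes", "tyrosinase",       "V",     "no",  0),
    c("gamma", "annelida",        "tyrosinase",       "V",     "no",  0),
    c("gamma", "hemichordata",    "tyrosinase",       "V",     "no",  0),
    c("gamma", "cephalochordata", "tyrosinase",       "V",     "no",  0),
    c("gamma", "urochordata",     "tyrosinase",       "V",     "no",  0),
    c("gamma", "vertebrata",      "tyrosinase",       "V",     "no",  0))
  data.frame(subclass = tab[, 1], lineage = tab[, 2], label = tab[, 3],
             placeholder = tab[, 4], cys_his_bond = tab[, 5] == "yes",
             disulfide_bridges = as.integer(tab[, 6]),
             stringsAsFactors = FALSE)
}

#' Functional-class label vocabulary
#' @return Character vector of the four functional-class labels.
#' @export
functional_labels <- function() {
  c("tyrosinase", "catechol_oxidase", "hemocyanin", "tyrosinase_related")
}

#' Assign a protein to the alpha/beta/gamma subclass
#'
#' Rules, in order: no binuclear site, unclassified; signal peptide and
#' at least one transmembrane segment, gamma; signal peptide and no
#' transmembrane segment, alpha; no signal peptide, beta.  Supporting
#' evidence (Cys-rich region for gamma, shifted Cu(A) H2 and placeholder
#' Phe for beta, placeholder Val for gamma) raises confidence when
#' concordant with the architectural call and lowers it when discordant,
#' but never overrides it.
#'
#' @param arch A [build_architecture()] result.
#' @param site A single binuclear-site row from
#'   [best_binuclear_site()], or `NULL`.
#' @return A list of class `subclass_call` with elements `subclass`
#'   (`"alpha"`, `"beta"`, `"gamma"` or `"unclassified"`), `evidence`
#'   (character vector of satisfied rules) and `confidence` (integer).
#' @export
assign_subclass <- function(arch, site) {
  if (is.null(site) || nrow(site) == 0) {
    return(structure(list(subclass = "unclassified",
                          evidence = character(0), confidence = 0L),
                     class = "subclass_call"))
  }
  sp <- !is.null(arch$signal_peptide)
  tm <- nrow(arch$tm_segments) > 0
  cys <- nrow(arch$cys_rich_regions) > 0
  subclass <- if (sp && tm) "gamma" else if (sp) "alpha" else "beta"
  evidence <- c(if (sp) "sp_present" else "sp_absent",
                if (tm) "tm_present",
                if (cys) "cys_rich_present",
                if (isTRUE(site$shifted_h2)) "shifted_h2",
                if (!is.na(site$placeholder_residue) &&
                    site$placeholder_residue == "F") "placeholder_F",
                if (!is.na(site$placeholder_residue) &&
                    site$placeholder_residue == "V") "placeholder_V")
  supports <- list(
    alpha = "sp_present",
    beta  = c("sp_absent", "shifted_h2", "placeholder_F"),
    gamma = c("sp_present", "tm_present", "cys_rich_present", "placeholder_V"))
  against <- setdiff(unlist(supports[setdiff(names(supports), subclass)]),
                     supports[[subclass]])
  concordant <- sum(evidence %in% supports[[subclass]])
  discordant <- sum(evidence %in% against)
  structure(list(subclass = subclass, evidence = evidence,
                 confidence = max(1L, concordant - discordant)),
            class = "subclass_call")
}

#' Compatible functional classes for a classified protein
#'
#' Returns every feature-table label whose subclass and lineage match the
#' call and whose placeholder residue, Cys-His bond and disulfide-bridge
#' count are all consistent with the observed binuclear site.  The result
#' is a set and may hold several labels: the packaged features render
#' some rows indistinguishable (e.g. arthropod tyrosinases and arthropod
#' hemocyanins).  An empty set means no packaged row matches.
#'
#' @param call A [assign_subclass()] result.
#' @param site The binuclear-site row of the same record.
#' @param lineage Lineage tag of the record's species.
#' @param table A [feature_table()] data.frame.
#' @return Character vector (possibly empty) of functional labels.
#' @export
functional_compatibility <- function(call, site, lineage,
                                     table = feature_table()) {
  if (!lineage %in% valid_lineages()) {
    t3_stop("unknown lineage tag '", lineage, "'; valid tags: ",
            paste(valid_lineages(), collapse = ", "))
  }
  if (call$subclass == "unclassified") return(character(0))
  rows <- table[table$subclass == call$subclass & table$lineage == lineage, ,
                drop = FALSE]
  if (nrow(rows) == 0) return(character(0))
  ok <- vapply(seq_len(nrow(rows)), function(i) {
    allowed <- strsplit(rows$placeholder[i], "/", fixed = TRUE)[[1]]
    !is.na(site$placeholder_residue) &&
      site$placeholder_residue %in% allowed &&
      isTRUE(site$cys_his_bond == rows$cys_his_bond[i]) &&
      isTRUE(site$disulfide_count == rows$disulfide_bridges[i])
  }, logical(1))
  sort(unique(rows$label[ok]))
}

#' Classify a set of protein records end-to-end
#'
#' For each record: best binuclear site, domain architecture, subclass
#' call and functional compatibility.
#'
#' @param records Data.frame of protein records ([read_fasta()] layout).
#' @param params A [scan_params()] object.
#' @param arch_params An [architecture_params()] object.
#' @param convention A [placeholder_convention()].
#' @param table A [feature_table()] data.frame.
#' @return A data.frame with one row per record: `id`, `species`,
#'   `lineage`, `subclass`, `confidence`, `evidence` (comma-joined),
#'   `placeholder`, `shifted_h2`, `cys_his_bond`, `disulfide_count` and
#'   `functional_compat` (comma-joined label set).
#' @export
classify_records <- function(records, params = scan_params(),
                             arch_params = architecture_params(),
                             convention = placeholder_convention(),
                             table = feature_table()) {
  rows <- lapply(seq_len(nrow(records)), function(i) {
    rec <- records[i, ]
    site <- best_binuclear_site(rec, params, convention)
    arch <- build_architecture(rec, arch_params)
    call <- assign_subclass(arch, site)
    compat <- if (call$subclass != "unclassified" && !is.na(rec$lineage)) {
      functional_compatibility(call, site, rec$lineage, table)
    } else character(0)
    data.frame(id = rec$id, species = rec$species, lineage = rec$lineage,
               subclass = call$subclass, confidence = call$confidence,
               evidence = paste(call$evidence, collapse = ","),
               placeholder = if (is.null(site)) NA_character_ else site$placeholder_residue,
               shifted_h2 = if (is.null(site)) NA else site$shifted_h2,
               cys_his_bond = if (is.null(site)) NA else site$cys_his_bond,
               disulfide_count = if (is.null(site)) NA_integer_ else site$disulfide_count,
               functional_compat = paste(compat, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate subclass calls into a per-species census
#'
#' @param calls A [classify_records()] data.frame.
#' @param species_table Optional data.frame of all surveyed species
#'   (columns `species`, `lineage`, and optionally `metazoan`); species
#'   absent from `calls` are reported with zero counts.
#' @return A list of class `census_table`: `counts` (data.frame with
#'   `species`, `lineage`, `metazoan`, `alpha`, `beta`, `gamma`,
#'   `total`), plus summary fields `total_proteins`,
#'   `n_metazoan_species`, `n_nonmetazoan_species` (species with at
#'   least one classified protein), `all_three_species` and
#'   `zero_species`.
#' @export
build_census <- function(calls, species_table = NULL) {
  classified <- calls[calls$subclass %in% c("alpha", "beta", "gamma"), ,
                      drop = FALSE]
  if (is.null(species_table)) {
    species_table <- unique(calls[, c("species", "lineage"), drop = FALSE])
  }
  species_table <- unique(species_table[, intersect(c("species", "lineage", "metazoan"),
                                                    names(species_table)),
                                        drop = FALSE])
  if (is.null(species_table$metazoan)) {
    species_table$metazoan <- is_metazoan(species_table$lineage)
  }
  counts <- species_table
  for (sc in c("alpha", "beta", "gamma")) {
    n <- table(factor(classified$species[classified$subclass == sc],
                      levels = counts$species))
    counts[[sc]] <- as.integer(n[counts$species])
  }
  counts$total <- counts$alpha + counts$beta + counts$gamma
  counts <- counts[order(counts$species), , drop = FALSE]
  rownames(counts) <- NULL
  has <- counts$total > 0
  structure(list(
    counts = counts,
    total_proteins = sum(counts$total),
    n_metazoan_species = sum(has & counts$metazoan),
    n_nonmetazoan_species = sum(has & !counts$metazoan),
    all_three_species = counts$species[counts$alpha > 0 & counts$beta > 0 &
                                         counts$gamma > 0],
    zero_species = counts$species[!has]),
    class = "census_table")
}

#' @export
print.census_table <- function(x, ...) {
  cat(sprintf("Type-3 copper protein census: %d proteins in %d metazoan and %d non-metazoan species\n",
              x$total_proteins, x$n_metazoan_species, x$n_nonmetazoan_species))
  cat(sprintf("Species with all three subclasses: %s\n",
              if (length(x$all_three_species)) paste(x$all_three_species, collapse = ", ") else "none"))
  cat(sprintf("Species with no type-3 copper proteins: %s\n",
              if (length(x$zero_species)) paste(x$zero_species, collapse = ", ") else "none"))
  invisible(x)
}
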