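# Motif grammar for the binuclear copper site.
#
# The Cu(A)-binding site follows an H1(n)-H2(8)-H3 pattern and the
# Cu(B)-binding site an H1(3)-H2(n)-H3 pattern, where the number in
# parentheses counts residues strictly between the two histidines
# (PROSITE-style spacing).  Cytosolic (beta) proteins shift the second
# Cu(A) histidine, modelled as a Cu(A) H2-H3 spacing in `cuA_h2_h3_beta_range`
# other than the canonical 8.

#' Scan parameters for the binuclear-site motif grammar
#'
#' All spacings count residues strictly between two positions.  Defaults
#' encode the canonical Cu(A) `H1(n)-H2(8)-H3` and Cu(B) `H1(3)-H2(n)-H3`
#' grammars, a beta-like shifted Cu(A) H2 accepted at spacings 6--12
#' (excluding the canonical 8), the conserved Phe four residues upstream
#' of H3 in both sites and Asp four residues downstream of the Cu(B) H3.
#'
#' @param cuA_h1_h2_range Inclusive range for the variable Cu(A) H1-H2 spacing.
#' @param cuA_h2_h3_fixed Canonical Cu(A) H2-H3 spacing.
#' @param cuA_h2_h3_beta_range Range accepted for the beta-shifted Cu(A) H2.
#' @param cuB_h1_h2_fixed Fixed Cu(B) H1-H2 spacing.
#' @param cuB_h2_h3_range Inclusive range for the variable Cu(B) H2-H3 spacing.
#' @param intersite_gap_range Allowed residue count strictly between the
#'   Cu(A) H3 and the Cu(B) H1.
#' @param phe_offset Offset upstream of H3 probed for the conserved Phe.
#' @param asp_offset Offset downstream of the Cu(B) H3 probed for the
#'   conserved Asp.
#' @param cys_bond_window Half-width of the window around the Cu(A) H2 in
#'   which a Cys counts as a Cys-His thioether bond candidate.
#' @param cys_region_pad Padding (residues) added on both sides of the
#'   binuclear site when counting Cys for disulfide-bridge candidates.
#' @return A list of class `scan_params`.
#' @export
scan_params <- function(cuA_h1_h2_range = c(2L, 40L),
                        cuA_h2_h3_fixed = 8L,
                        cuA_h2_h3_beta_range = c(6L, 12L),
                        cuB_h1_h2_fixed = 3L,
                        cuB_h2_h3_range = c(2L, 40L),
                        intersite_gap_range = c(10L, 400L),
                        phe_offset = 4L,
                        asp_offset = 4L,
                        cys_bond_window = 2L,
                        cys_region_pad = 20L) {
  p <- list(cuA_h1_h2_range = as.integer(cuA_h1_h2_range),
            cuA_h2_h3_fixed = as.integer(cuA_h2_h3_fixed),
            cuA_h2_h3_beta_range = as.integer(cuA_h2_h3_beta_range),
            cuB_h1_h2_fixed = as.integer(cuB_h1_h2_fixed),
            cuB_h2_h3_range = as.integer(cuB_h2_h3_range),
            intersite_gap_range = as.integer(intersite_gap_range),
            phe_offset = as.integer(phe_offset),
            asp_offset = as.integer(asp_offset),
            cys_bond_window = as.integer(cys_bond_window),
            cys_region_pad = as.integer(cys_region_pad))
  stopifnot(p$cuA_h1_h2_range[1] <= p$cuA_h1_h2_range[2],
            p$cuA_h2_h3_beta_range[1] <= p$cuA_h2_h3_beta_range[2],
            p$cuB_h2_h3_range[1] <= p$cuB_h2_h3_range[2],
            p$intersite_gap_range[1] <= p$intersite_gap_range[2],
            p$cuA_h2_h3_fixed >= 1, p$cuB_h1_h2_fixed >= 1,
            p$phe_offset >= 1, p$asp_offset >= 1)
  class(p) <- "scan_params"
  p
}

seq_chars <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1]]

# residue at 0-based position, or NA when out of bounds
res_at <- function(chars, pos0) {
  if (is.na(pos0) || pos0 < 0 || pos0 >= length(chars)) NA_character_
  else chars[pos0 + 1]
}

#' Scan a sequence for candidate copper-site histidine triads
#'
#' Returns every ordered histidine triple satisfying the spacing grammar
#' of the requested site kind.  For kind `"A"` the H2-H3 spacing may be
#' either the canonical fixed value or within the beta-shifted range; for
#' kind `"B"` the H1-H2 spacing must equal the fixed value.  Spacings
#' count residues strictly between the histidines; positions are 0-based.
#'
#' @param record A single protein record (one row of a [read_fasta()]
#'   data.frame), or any list with `id` and `sequence`.
#' @param kind `"A"` or `"B"`.
#' @param params A [scan_params()] object.
#' @return A data.frame with columns `kind`, `h1`, `h2`, `h3`,
#'   `spacing12`, `spacing23`, ordered by `h1`, then `h2`, then `h3`.
#' @export
scan_his_triads <- function(record, kind = c("A", "B"), params = scan_params()) {
  kind <- match.arg(kind)
  chars <- seq_chars(record$sequence)
  hpos <- which(chars == "H") - 1L  # 0-based
  empty <- data.frame(kind = character(), h1 = integer(), h2 = integer(),
                      h3 = integer(), spacing12 = integer(),
                      spacing23 = integer(), stringsAsFactors = FALSE)
  if (length(hpos) < 3) return(empty)
  out <- list()
  if (kind == "A") {
    s12lo <- params$cuA_h1_h2_range[1]; s12hi <- params$cuA_h1_h2_range[2]
    s23ok <- sort(unique(c(params$cuA_h2_h3_fixed,
                           seq(params$cuA_h2_h3_beta_range[1],
                               params$cuA_h2_h3_beta_range[2]))))
  } else {
    s12lo <- params$cuB_h1_h2_fixed; s12hi <- params$cuB_h1_h2_fixed
    s23ok <- seq(params$cuB_h2_h3_range[1], params$cuB_h2_h3_range[2])
  }
  for (h1 in hpos) {
    h2s <- hpos[hpos - h1 - 1L >= s12lo & hpos - h1 - 1L <= s12hi]
    for (h2 in h2s) {
      h3s <- hpos[(hpos - h2 - 1L) %in% s23ok & hpos > h2]
      for (h3 in h3s) {
        out[[length(out) + 1L]] <- c(h1, h2, h3)
      }
    }
  }
  if (length(out) == 0) return(empty)
  m <- do.call(rbind, out)
  df <- data.frame(kind = kind, h1 = m[, 1], h2 = m[, 2], h3 = m[, 3],
                   spacing12 = m[, 2] - m[, 1] - 1L,
                   spacing23 = m[, 3] - m[, 2] - 1L,
                   stringsAsFactors = FALSE)
  df[order(df$h1, df$h2, df$h3), , drop = FALSE]
}

#' Pair Cu(A) and Cu(B) candidate triads into binuclear sites
#'
#' All non-overlapping pairs (the Cu(A) triad entirely before the Cu(B)
#' triad) whose intersite gap lies within the configured range are kept
#' and scored.  The score is `2 - shifted_h2 + phe_A_ok + phe_B_ok +
#' asp_B_ok`, so a canonical site with all three conserved diagnostics
#' scores 5.  Results are sorted by score (descending), then by Cu(A) H1,
#' then Cu(B) H1 (ascending).
#'
#' @param record The protein record both triad sets were scanned from.
#' @param sitesA,sitesB Data.frames from [scan_his_triads()].
#' @param params A [scan_params()] object.
#' @return A data.frame of binuclear sites (one row per pair) with triad
#'   positions, spacings, intersite gap, diagnostic flags, and score.
#' @export
pair_sites <- function(record, sitesA, sitesB, params = scan_params()) {
  empty <- empty_binuclear()
  if (nrow(sitesA) == 0 || nrow(sitesB) == 0) return(empty)
  rows <- list()
  for (i in seq_len(nrow(sitesA))) {
    for (j in seq_len(nrow(sitesB))) {
      gap <- sitesB$h1[j] - sitesA$h3[i] - 1L
      if (sitesA$h3[i] < sitesB$h1[j] &&
          gap >= params$intersite_gap_range[1] &&
          gap <= params$intersite_gap_range[2]) {
        site <- binuclear_row(sitesA[i, ], sitesB[j, ], gap, params)
        rows[[length(rows) + 1L]] <- check_diagnostics(record, site, params)
      }
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out$score <- site_score(out)
  out[order(-out$score, out$cuA_h1, out$cuB_h1), , drop = FALSE]
}

empty_binuclear <- function() {
  data.frame(cuA_h1 = integer(), cuA_h2 = integer(), cuA_h3 = integer(),
             cuA_spacing12 = integer(), cuA_spacing23 = integer(),
             cuB_h1 = integer(), cuB_h2 = integer(), cuB_h3 = integer(),
             cuB_spacing12 = integer(), cuB_spacing23 = integer(),
             intersite_gap = integer(), shifted_h2 = logical(),
             phe_A_ok = logical(), phe_B_ok = logical(), asp_B_ok = logical(),
             placeholder_residue = character(), placeholder_position = integer(),
             cys_his_bond = logical(), disulfide_count = integer(),
             score = numeric(), stringsAsFactors = FALSE)
}

binuclear_row <- function(a, b, gap, params) {
  data.frame(cuA_h1 = a$h1, cuA_h2 = a$h2, cuA_h3 = a$h3,
             cuA_spacing12 = a$spacing12, cuA_spacing23 = a$spacing23,
             cuB_h1 = b$h1, cuB_h2 = b$h2, cuB_h3 = b$h3,
             cuB_spacing12 = b$spacing12, cuB_spacing23 = b$spacing23,
             intersite_gap = gap,
             shifted_h2 = a$spacing23 != params$cuA_h2_h3_fixed,
             phe_A_ok = NA, phe_B_ok = NA, asp_B_ok = NA,
             placeholder_residue = NA_character_,
             placeholder_position = NA_integer_,
             cys_his_bond = NA, disulfide_count = NA_integer_,
             score = NA_real_, stringsAsFactors = FALSE)
}

site_score <- function(site) {
  2 - as.integer(site$shifted_h2) + as.integer(site$phe_A_ok) +
    as.integer(site$phe_B_ok) + as.integer(site$asp_B_ok)
}

#' Evaluate the conserved diagnostic residues of a binuclear site
#'
#' Probes the conserved Phe `phe_offset` residues upstream of H3 in both
#' copper sites and the conserved Asp `asp_offset` residues downstream of
#' the Cu(B) H3.  Out-of-bounds probes (and X) yield `FALSE`, never an
#' error.
#'
#' @param record Protein record the site was found in.
#' @param site One or more binuclear-site rows.
#' @param params A [scan_params()] object.
#' @return `site` with `phe_A_ok`, `phe_B_ok`, `asp_B_ok` and `score`
#'   filled in.
#' @export
check_diagnostics <- function(record, site, params = scan_params()) {
  chars <- seq_chars(record$sequence)
  probe <- function(pos0, expected) {
    r <- vapply(pos0, function(p) res_at(chars, p), "")
    !is.na(r) & r == expected
  }
  site$phe_A_ok <- probe(site$cuA_h3 - params$phe_offset, "F")
  site$phe_B_ok <- probe(site$cuB_h3 - params$phe_offset, "F")
  site$asp_B_ok <- probe(site$cuB_h3 + params$asp_offset, "D")
  site$score <- site_score(site)
  site
}

#' Placeholder-residue extraction convention
#'
#' The placeholder (gatekeeper) residue sits above the Cu(A) pocket in the
#' folded protein; at the sequence level this package locates it by a
#' signed offset from one of the six histidine anchors.  The default
#' anchor is the Cu(B) H1 with offset -6.
#'
#' @param anchor One of `"cuA_h1"`, `"cuA_h2"`, `"cuA_h3"`, `"cuB_h1"`,
#'   `"cuB_h2"`, `"cuB_h3"`.
#' @param offset Signed integer offset from the anchor.
#' @return A list of class `placeholder_convention`.
#' @export
placeholder_convention <- function(anchor = "cuB_h1", offset = -6L) {
  stopifnot(anchor %in% c("cuA_h1", "cuA_h2", "cuA_h3",
                          "cuB_h1", "cuB_h2", "cuB_h3"))
  structure(list(anchor = anchor, offset = as.integer(offset)),
            class = "placeholder_convention")
}

#' Extract the placeholder residue of a binuclear site
#'
#' @param record Protein record.
#' @param site One or more binuclear-site rows.
#' @param convention A [placeholder_convention()].
#' @return `site` with `placeholder_residue` (letter, or NA when the
#'   probed position is out of bounds or X) and `placeholder_position`
#'   filled in.
#' @export
extract_placeholder <- function(record, site,
                                convention = placeholder_convention()) {
  chars <- seq_chars(record$sequence)
  pos <- site[[convention$anchor]] + convention$offset
  res <- vapply(pos, function(p) res_at(chars, p), "")
  res[!is.na(res) & res == "X"] <- NA_character_
  site$placeholder_residue <- res
  site$placeholder_position <- ifelse(is.na(res), NA_integer_, pos)
  site
}

#' Flag cysteine features of a binuclear site
#'
#' A Cys within `cys_bond_window` residues of the Cu(A) H2 (excluding the
#' H2 position itself) marks a Cys-His thioether bond candidate.  The
#' disulfide-bridge candidate count is `floor(c / 2)` where `c` is the
#' number of Cys inside the padded active-site region
#' `[cuA_h1 - cys_region_pad, cuB_h3 + cys_region_pad]`, excluding any
#' Cys inside the bond window.
#'
#' @param record Protein record.
#' @param site One or more binuclear-site rows.
#' @param params A [scan_params()] object.
#' @return `site` with `cys_his_bond` and `disulfide_count` filled in.
#' @export
flag_cys_features <- function(record, site, params = scan_params()) {
  chars <- seq_chars(record$sequence)
  cpos <- which(chars == "C") - 1L
  for (i in seq_len(nrow(site))) {
    h2 <- site$cuA_h2[i]
    in_bond <- abs(cpos - h2) <= params$cys_bond_window & cpos != h2
    site$cys_his_bond[i] <- any(in_bond)
    lo <- site$cuA_h1[i] - params$cys_region_pad
    hi <- site$cuB_h3[i] + params$cys_region_pad
    region <- cpos >= lo & cpos <= hi & !in_bond
    site$disulfide_count[i] <- sum(region) %/% 2L
  }
  site
}

#' Find the best-scoring binuclear copper site of a protein
#'
#' Runs the full chain: triad scan for both site kinds, pairing,
#' diagnostics, placeholder extraction and cysteine flags, and returns
#' the top-scoring site.  Ties are broken by the leftmost Cu(A) H1, then
#' the leftmost Cu(B) H1.
#'
#' @param record Protein record.
#' @param params A [scan_params()] object.
#' @param convention A [placeholder_convention()].
#' @return A single-row binuclear-site data.frame, or `NULL` when no
#'   histidine-triad pair satisfies the grammar.
#' @export
best_binuclear_site <- function(record, params = scan_params(),
                                convention = placeholder_convention()) {
  sitesA <- scan_his_triads(record, "A", params)
  sitesB <- scan_his_triads(record, "B", params)
  pairs <- pair_sites(record, sitesA, sitesB, params)
  if (nrow(pairs) == 0) return(NULL)
  best <- pairs[1, , drop = FALSE]
  best <- extract_placeholder(record, best, convention)
  flag_cys_features(record, best, params)
}

#' Scan a set of records and tabulate their best binuclear sites
#'
#' @param records Data.frame of protein records.
#' @param params A [scan_params()] object.
#' @param convention A [placeholder_convention()].
#' @return A data.frame with one row per record (`id` plus the
#'   binuclear-site columns; NA columns for records without a site).
#' @export
scan_records <- function(records, params = scan_params(),
                         convention = placeholder_convention()) {
  rows <- lapply(seq_len(nrow(records)), function(i) {
    rec <- records[i, ]
    site <- best_binuclear_site(rec, params, convention)
    if (is.null(site)) {
      site <- empty_binuclear()[1, ]  # all-NA row
    }
    cbind(data.frame(id = rec$id, stringsAsFactors = FALSE), site)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
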