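# Amino-acid alphabet shared by every module: the 20 standard residues plus
# X for anything unknown.  X never satisfies a motif or diagnostic check.
AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_ALPHABET_X <- c(AA_LETTERS, "X")

#' Lineage vocabulary
#'
#' Controlled vocabulary of lineage tags used for species metadata.  The
#' tags name the taxonomic colour-code groups used throughout the package
#' (three domains of life plus the metazoan phyla and subphyla tracked by
#' the census), together with the groups that appear in the species tree
#' only because their genomes carry no type-3 copper proteins.
#'
#' @return Character vector of valid lineage tags.
#' @export
valid_lineages <- function() {
  c("eubacteria", "archaebacteria", "plantae", "chromoalveolata",
    "amoebozoa", "fungi", "porifera", "cnidaria", "mollusca", "annelida",
    "platyhelminthes", "nematoda", "arthropoda", "onychophora",
    "hemichordata", "cephalochordata", "urochordata", "vertebrata",
    # groups present in the species tree but devoid of type-3 proteins
    "echinodermata", "placozoa", "choanoflagellata", "filasterea")
}

t3_stop <- function(..., class = "cuproclass_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

sanitize_sequence <- function(seq, id = "?") {
  seq <- toupper(gsub("[[:space:]]", "", seq))
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- !(chars %in% AA_ALPHABET_X)
  if (any(bad)) {
    warning(sprintf("sequence '%s': %d character(s) outside the amino-acid alphabet replaced by X (%s)",
                    id, sum(bad), paste(unique(chars[bad]), collapse = ",")),
            call. = FALSE)
    chars[bad] <- "X"
  }
  paste(chars, collapse = "")
}

#' Read protein records from a FASTA file
#'
#' Species and lineage metadata are parsed from a `species=...;lineage=...`
#' key-value tail in each FASTA header.  A companion metadata TSV (columns
#' `id`, `species`, `lineage`) can supply or override metadata; on conflict
#' the TSV wins with a warning.  Sequences are upper-cased and any
#' character outside the 20-letter alphabet plus X is replaced by X with a
#' warning.
#'
#' @param path Path to a FASTA file of protein sequences.
#' @param metadata Optional path to a metadata TSV with columns
#'   `id`, `species`, `lineage`.
#' @return A data.frame with columns `id`, `species`, `lineage`,
#'   `sequence`, one row per FASTA record.
#' @export
read_fasta <- function(path, metadata = NULL) {
  if (!file.exists(path)) t3_stop("FASTA file not found: ", path)
  if (file.size(path) == 0) t3_stop("empty FASTA file: ", path)
  aa <- Biostrings::readBStringSet(path)
  if (length(aa) == 0) t3_stop("empty FASTA file: ", path)
  headers <- names(aa)
  ids <- sub("[[:space:]].*$", "", headers)
  if (anyDuplicated(ids)) {
    t3_stop("duplicate record id(s): ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  parse_kv <- function(header, key) {
    m <- regmatches(header, regexec(paste0(key, "=([^;]*)"), header))[[1]]
    if (length(m) == 2) trimws(m[2]) else NA_character_
  }
  species <- vapply(headers, parse_kv, "", key = "species", USE.NAMES = FALSE)
  lineage <- vapply(headers, parse_kv, "", key = "lineage", USE.NAMES = FALSE)
  recs <- data.frame(id = ids, species = species, lineage = lineage,
                     sequence = vapply(seq_along(aa), function(i) {
                       sanitize_sequence(as.character(aa[[i]]), ids[i])
                     }, ""),
                     stringsAsFactors = FALSE)
  if (!is.null(metadata)) {
    md <- utils::read.delim(metadata, stringsAsFactors = FALSE)
    if (!all(c("id", "species", "lineage") %in% names(md))) {
      t3_stop("metadata TSV must have columns id, species, lineage")
    }
    hit <- match(recs$id, md$id)
    for (col in c("species", "lineage")) {
      new <- md[[col]][hit]
      conflict <- !is.na(new) & !is.na(recs[[col]]) & new != recs[[col]]
      if (any(conflict)) {
        warning(sprintf("metadata TSV overrides FASTA-header %s for %d record(s)",
                        col, sum(conflict)), call. = FALSE)
      }
      recs[[col]] <- ifelse(is.na(new), recs[[col]], new)
    }
  }
  nz <- nchar(recs$sequence) >= 1
  if (!all(nz)) t3_stop("zero-length sequence for record(s): ",
                        paste(recs$id[!nz], collapse = ", "))
  recs
}

#' Write protein records to a FASTA file
#'
#' Metadata is embedded in headers as `species=...;lineage=...` so the
#' file round-trips through [read_fasta()] without a companion TSV.
#'
#' @param records Data.frame as returned by [read_fasta()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path) {
  hdr <- ifelse(is.na(records$species) & is.na(records$lineage),
                records$id,
                sprintf("%s species=%s;lineage=%s", records$id,
                        records$species, records$lineage))
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, path, width = 70)
  invisible(path)
}

#' Read gene coordinates from GFF3 or BED
#'
#' Coordinates are normalised to the package-wide 0-based half-open
#' convention: a GFF3 feature `start=100, end=200` (1-based inclusive)
#' becomes the internal interval `(99, 200)`; BED intervals pass through
#' unchanged.  The protein id is taken from the GFF3 `ID` attribute or
#' the BED name column.
#'
#' @param path Path to the coordinate file.
#' @param dialect Either `"gff3"` or `"bed"`.
#' @return A data.frame with columns `protein_id`, `scaffold`, `start`,
#'   `end` (0-based half-open) and `strand` (`+` or `-`).
#' @export
read_gene_coords <- function(path, dialect = c("gff3", "bed")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) t3_stop("coordinate file not found: ", path)
  gr <- rtracklayer::import(path, format = if (dialect == "gff3") "GFF3" else "BED")
  df <- as.data.frame(gr)
  pid <- if (dialect == "gff3") {
    if (!is.null(df$ID)) as.character(df$ID) else as.character(df$Name)
  } else {
    as.character(df$name)
  }
  if (any(is.na(pid) | pid == "")) {
    t3_stop("record(s) without an identifier at row(s): ",
            paste(which(is.na(pid) | pid == ""), collapse = ", "))
  }
  # rtracklayer yields 1-based inclusive coordinates for both dialects
  start0 <- df$start - 1L
  end0 <- df$end
  if (dialect == "gff3") {
    degen <- df$start == df$end
    if (any(degen)) {
      t3_stop("degenerate interval (start = end) at GFF3 data row(s): ",
              paste(which(degen), collapse = ", "))
    }
  }
  bad <- start0 >= end0
  if (any(bad)) {
    t3_stop("start >= end after normalisation at data row(s): ",
            paste(which(bad), collapse = ", "))
  }
  strand <- as.character(df$strand)
  strand[!(strand %in% c("+", "-"))] <- "+"
  data.frame(protein_id = pid, scaffold = as.character(df$seqnames),
             start = start0, end = end0, strand = strand,
             stringsAsFactors = FALSE)
}

#' Write a phylogenetic tree to newick
#'
#' Branch lengths are written with enough digits to round-trip within
#' 1e-9; internal-node support values, when present as `node.label`, are
#' emitted as internal-node labels.
#'
#' @param tree An [ape::phylo] tree with named tips.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  if (!inherits(tree, "phylo")) t3_stop("tree must be an ape 'phylo' object")
  if (length(tree$tip.label) < 2) t3_stop("tree must have at least 2 tips")
  if (any(is.na(tree$tip.label)) || any(tree$tip.label == "")) {
    t3_stop("tree has unnamed tips")
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    t3_stop("tree has negative branch lengths")
  }
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Write a tabular report as TSV
#'
#' UTF-8, header line, deterministic column order (the order of `rows`).
#' Tab characters are forbidden inside cells.
#'
#' @param rows A data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(rows, path) {
  if (!is.data.frame(rows)) t3_stop("rows must be a data.frame")
  for (col in names(rows)) {
    if (is.character(rows[[col]]) && any(grepl("\t", rows[[col]], fixed = TRUE))) {
      t3_stop("tab character inside cells of column '", col, "'")
    }
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
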