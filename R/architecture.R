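# Sequence-only architecture heuristics for the three features that define
# the alpha/beta/gamma subclasses: an N-terminal signal peptide, a
# transmembrane segment and a cysteine-rich region.  All spans are
# 0-based half-open.

# Kyte-Doolittle hydropathy index; X contributes 0.
KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2, X = 0)

#' Architecture-detection parameters
#'
#' Heuristic stand-ins for dedicated signal-peptide and transmembrane
#' predictors.  A signal peptide is called when a hydrophobic core window
#' appears near the N-terminus; a transmembrane segment when a long run
#' of high windowed hydropathy appears outside the signal peptide; a
#' Cys-rich region when a window holds many cysteines.
#'
#' @param sp_search_len Residues from the N-terminus searched for a
#'   signal peptide (and cap on the reported span).
#' @param sp_core_window Length of the hydrophobic-core window.
#' @param sp_core_min_hydropathy Minimum mean Kyte-Doolittle value of the
#'   core window.
#' @param sp_max_start Latest 0-based start of the core window.
#' @param tm_window Hydropathy window length (odd) and minimum run length
#'   for a transmembrane call.
#' @param tm_min_hydropathy Minimum windowed hydropathy inside a
#'   transmembrane run.
#' @param cys_window Window length for the Cys-rich detector.
#' @param cys_min_count Minimum cysteines per window.
#' @return A list of class `architecture_params`.
#' @export
architecture_params <- function(sp_search_len = 35L, sp_core_window = 8L,
                                sp_core_min_hydropathy = 1.6,
                                sp_max_start = 12L, tm_window = 19L,
                                tm_min_hydropathy = 1.6, cys_window = 30L,
                                cys_min_count = 6L) {
  p <- list(sp_search_len = as.integer(sp_search_len),
            sp_core_window = as.integer(sp_core_window),
            sp_core_min_hydropathy = sp_core_min_hydropathy,
            sp_max_start = as.integer(sp_max_start),
            tm_window = as.integer(tm_window),
            tm_min_hydropathy = tm_min_hydropathy,
            cys_window = as.integer(cys_window),
            cys_min_count = as.integer(cys_min_count))
  stopifnot(p$sp_core_window >= 1, p$tm_window >= 1, p$cys_window >= 1)
  class(p) <- "architecture_params"
  p
}

kd_values <- function(sequence) {
  v <- KD_SCALE[seq_chars(sequence)]
  v[is.na(v)] <- 0
  unname(v)
}

#' Windowed Kyte-Doolittle hydropathy profile
#'
#' Value at position i is the mean Kyte-Doolittle index over the window
#' centred at i.  Positions where the window would overrun either end are
#' `NA`.  X contributes 0.
#'
#' @param sequence Amino-acid string.
#' @param window Odd window length, at most the sequence length.
#' @return Numeric vector of length `nchar(sequence)`; entry `i`
#'   corresponds to 0-based position `i - 1`.
#' @export
hydropathy <- function(sequence, window = 19L) {
  n <- nchar(sequence)
  if (window %% 2 == 0) t3_stop("hydropathy window must be odd")
  if (window > n) t3_stop("hydropathy window longer than sequence")
  v <- kd_values(sequence)
  as.numeric(stats::filter(v, rep(1 / window, window), sides = 2))
}

# maximal runs of TRUE in a logical vector -> 0-based half-open spans
runs_to_spans <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  cbind(start = starts[keep] - 1L, end = ends[keep])
}

#' Detect an N-terminal signal peptide
#'
#' Present iff, within the first `sp_search_len` residues, some window of
#' `sp_core_window` consecutive residues starting at a 0-based index of
#' at most `sp_max_start` has mean hydropathy at least
#' `sp_core_min_hydropathy`.  The reported span starts at 0 and ends
#' three residues past the first qualifying core window, capped at
#' `sp_search_len`.
#'
#' @param sequence Amino-acid string.
#' @param params An [architecture_params()] object.
#' @return Integer `c(start, end)` span (0-based half-open), or `NULL`.
#' @export
detect_signal_peptide <- function(sequence, params = architecture_params()) {
  n <- nchar(sequence)
  w <- params$sp_core_window
  if (n < w) return(NULL)
  v <- kd_values(sequence)[seq_len(min(n, params$sp_search_len))]
  last_start <- min(params$sp_max_start, length(v) - w)
  if (last_start < 0) return(NULL)
  for (s in 0:last_start) {
    if (mean(v[(s + 1):(s + w)]) >= params$sp_core_min_hydropathy) {
      end <- min(s + w + 3L, params$sp_search_len, n)
      return(c(start = 0L, end = as.integer(end)))
    }
  }
  NULL
}

#' Detect transmembrane segments
#'
#' Maximal runs of positions whose centred windowed hydropathy is at
#' least `tm_min_hydropathy`, after masking positions inside `exclude`
#' (normally the signal peptide); runs separated by fewer than 5
#' positions are merged, and merged runs shorter than `tm_window` are
#' dropped.
#'
#' @param sequence Amino-acid string.
#' @param params An [architecture_params()] object.
#' @param exclude Optional `c(start, end)` 0-based half-open span whose
#'   positions are masked before run-finding.
#' @return Integer matrix with columns `start`, `end` (0-based half-open
#'   spans), zero rows when none.
#' @export
detect_tm_segments <- function(sequence, params = architecture_params(),
                               exclude = NULL) {
  n <- nchar(sequence)
  if (n < params$tm_window) return(cbind(start = integer(), end = integer()))
  h <- hydropathy(sequence, params$tm_window)
  ok <- !is.na(h) & h >= params$tm_min_hydropathy
  if (!is.null(exclude)) {
    span <- (exclude[1] + 1):exclude[2]
    span <- span[span >= 1 & span <= n]
    ok[span] <- FALSE
  }
  spans <- runs_to_spans(ok)
  if (nrow(spans) == 0) return(spans)
  # merge runs separated by < 5 positions
  merged <- spans[1, , drop = FALSE]
  if (nrow(spans) > 1) {
    for (i in 2:nrow(spans)) {
      if (spans[i, "start"] - merged[nrow(merged), "end"] < 5) {
        merged[nrow(merged), "end"] <- spans[i, "end"]
      } else {
        merged <- rbind(merged, spans[i, , drop = FALSE])
      }
    }
  }
  merged[merged[, "end"] - merged[, "start"] >= params$tm_window, ,
         drop = FALSE]
}

#' Detect cysteine-rich regions
#'
#' Every window of `cys_window` residues holding at least
#' `cys_min_count` Cys qualifies; overlapping or adjacent qualifying
#' windows are merged into one span.
#'
#' @param sequence Amino-acid string.
#' @param params An [architecture_params()] object.
#' @return Integer matrix with columns `start`, `end` (0-based half-open).
#' @export
detect_cys_rich <- function(sequence, params = architecture_params()) {
  n <- nchar(sequence)
  w <- params$cys_window
  none <- cbind(start = integer(), end = integer())
  if (n < w) return(none)
  isc <- as.integer(seq_chars(sequence) == "C")
  counts <- as.numeric(stats::filter(isc, rep(1, w), sides = 1))[w:n]
  qual <- which(counts >= params$cys_min_count)  # window ending at w+qual-1
  if (length(qual) == 0) return(none)
  starts <- qual - 1L            # 0-based window starts
  ends <- starts + w             # half-open ends
  spans <- cbind(start = starts, end = ends)
  merged <- spans[1, , drop = FALSE]
  if (nrow(spans) > 1) {
    for (i in 2:nrow(spans)) {
      if (spans[i, "start"] <= merged[nrow(merged), "end"]) {
        merged[nrow(merged), "end"] <- spans[i, "end"]
      } else {
        merged <- rbind(merged, spans[i, , drop = FALSE])
      }
    }
  }
  merged
}

#' Build the full domain architecture of a protein
#'
#' Composes the three detectors; transmembrane detection excludes the
#' signal-peptide span so the hydrophobic core of a signal peptide is not
#' double-reported as a membrane segment.
#'
#' @param record Protein record (list or one-row data.frame with
#'   `sequence`).
#' @param params An [architecture_params()] object.
#' @return A list of class `domain_architecture` with elements
#'   `signal_peptide` (span or NULL), `tm_segments` (span matrix) and
#'   `cys_rich_regions` (span matrix).
#' @export
build_architecture <- function(record, params = architecture_params()) {
  seqn <- record$sequence
  sp <- detect_signal_peptide(seqn, params)
  tm <- detect_tm_segments(seqn, params, exclude = sp)
  cys <- detect_cys_rich(seqn, params)
  structure(list(signal_peptide = sp, tm_segments = tm,
                 cys_rich_regions = cys),
            class = "domain_architecture")
}
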