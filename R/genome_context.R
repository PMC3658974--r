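# Tandem-cluster detection from genomic coordinates.  Physically linked
# paralogs on one scaffold are chained by single linkage, which makes
# membership independent of input order.

#' Detect tandem clusters of type-3 copper genes
#'
#' Loci are sorted by start within each scaffold and chained by single
#' linkage: consecutive loci join one cluster iff the intergenic gap
#' (`next start - previous end`) is at most `max_gap` and, when
#' `same_subclass_only`, their proteins share a subclass.  Singletons
#' are discarded.  Strand is ignored for membership but reported.
#'
#' @param loci Data.frame of gene loci ([read_gene_coords()] layout).
#' @param calls Data.frame mapping `id` to `subclass`
#'   ([classify_records()] layout); required when `same_subclass_only`.
#' @param max_gap Maximum intergenic gap in base pairs (inclusive).
#' @param same_subclass_only Restrict chaining to same-subclass
#'   neighbours.
#' @return A data.frame with one row per cluster: `cluster_id`,
#'   `scaffold`, `size`, `subclass` (or `"mixed"`), `members`
#'   (comma-joined, ordered by start), `max_intergenic_gap`.
#' @export
find_clusters <- function(loci, calls = NULL, max_gap = 50000L,
                          same_subclass_only = TRUE) {
  if (same_subclass_only) {
    if (is.null(calls)) t3_stop("same_subclass_only needs a calls table")
    hit <- match(loci$protein_id, calls$id)
    if (any(is.na(hit))) {
      t3_stop("locus references unknown protein id(s): ",
              paste(unique(loci$protein_id[is.na(hit)]), collapse = ", "))
    }
    loci$subclass <- calls$subclass[hit]
  } else if (!is.null(calls)) {
    loci$subclass <- calls$subclass[match(loci$protein_id, calls$id)]
  } else {
    loci$subclass <- NA_character_
  }
  out <- list()
  for (sc in sort(unique(loci$scaffold))) {
    sub <- loci[loci$scaffold == sc, , drop = FALSE]
    sub <- sub[order(sub$start, sub$end, sub$protein_id), , drop = FALSE]
    if (nrow(sub) == 0) next
    grp <- 1L
    grps <- integer(nrow(sub))
    grps[1] <- grp
    if (nrow(sub) > 1) {
      for (i in 2:nrow(sub)) {
        gap <- sub$start[i] - sub$end[i - 1]
        linked <- gap <= max_gap &&
          (!same_subclass_only || identical(sub$subclass[i], sub$subclass[i - 1]))
        if (!linked) grp <- grp + 1L
        grps[i] <- grp
      }
    }
    for (g in unique(grps)) {
      mem <- sub[grps == g, , drop = FALSE]
      if (nrow(mem) < 2) next
      gaps <- mem$start[-1] - mem$end[-nrow(mem)]
      subclasses <- unique(mem$subclass)
      out[[length(out) + 1L]] <- data.frame(
        scaffold = sc, size = nrow(mem),
        subclass = if (length(subclasses) == 1 && !is.na(subclasses[1]))
          subclasses[1] else "mixed",
        members = paste(mem$protein_id, collapse = ","),
        max_intergenic_gap = max(gaps),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(cluster_id = character(), scaffold = character(),
                      size = integer(), subclass = character(),
                      members = character(), max_intergenic_gap = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$scaffold, res$members), , drop = FALSE]
  res <- cbind(cluster_id = sprintf("cluster_%03d", seq_len(nrow(res))), res,
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
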