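# Pipeline wiring: one entry point per stage plus an `all` chain over
# the packaged synthetic fixture.  Configuration is a nested list
# mirroring the per-module parameter objects; a YAML file can override
# defaults and unknown keys are rejected before any computation.

#' Default pipeline configuration
#'
#' @return Nested list with one block per stage plus `seed` and
#'   `verbose`.
#' @export
default_config <- function() {
  list(scan = unclass(scan_params()),
       architecture = unclass(architecture_params()),
       placeholder = unclass(placeholder_convention()),
       phylo = list(model = "p", replicates = 25L, flank = 10L),
       clusters = list(max_gap = 50000L, same_subclass_only = TRUE),
       evolve = list(origins = as.list(default_origin_map()),
                     expansion_threshold = 4L),
       simulate = list(noise_rate = 0.05),
       seed = 1L, verbose = FALSE)
}

merge_config <- function(base, override, path = "") {
  for (key in names(override)) {
    full <- if (path == "") key else paste0(path, ".", key)
    if (!key %in% names(base)) t3_stop("unknown config key: ", full)
    if (is.list(base[[key]]) && is.list(override[[key]])) {
      base[[key]] <- merge_config(base[[key]], override[[key]], full)
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

#' Load a pipeline configuration file
#'
#' YAML file whose keys mirror [default_config()]; missing keys keep
#' their defaults, unknown keys raise an error.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return Configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) t3_stop("config file not found: ", path)
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  cfg
}

cfg_scan <- function(cfg) do.call(scan_params, cfg$scan)
cfg_arch <- function(cfg) do.call(architecture_params, cfg$architecture)
cfg_conv <- function(cfg) do.call(placeholder_convention, cfg$placeholder)

arch_summary_row <- function(rec, params) {
  arch <- build_architecture(rec, params)
  sp <- arch$signal_peptide
  tms <- arch$tm_segments
  data.frame(id = rec$id,
             sp_start = if (is.null(sp)) NA_integer_ else sp[1],
             sp_end = if (is.null(sp)) NA_integer_ else sp[2],
             n_tm = nrow(tms),
             tm_spans = paste(sprintf("%d-%d", tms[, 1], tms[, 2]),
                              collapse = ";"),
             n_cys_rich = nrow(arch$cys_rich_regions),
             stringsAsFactors = FALSE)
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (emit the packaged synthetic fixture), `scan`,
#' `architecture`, `classify`, `census`, `phylo`, `clusters`, `evolve`,
#' and `all`, which chains simulate, classify, census, phylo, clusters
#' and evolve on the fixture.  Outputs are TSV/FASTA/GFF3/newick files
#' in `out_dir`; the resolved configuration is echoed to
#' `config_used.yaml` for provenance.
#'
#' @param name Stage name.
#' @param out_dir Output directory (created if needed).
#' @param config Configuration list ([default_config()] layout).
#' @param paths Named list of input paths (`fasta`, `metadata`,
#'   `coords`, `calls`, `census`, `tree`), as each stage needs.
#' @return Invisibly, a named list of the paths written.
#' @export
run_subcommand <- function(name = c("all", "simulate", "scan", "architecture",
                                    "classify", "census", "phylo", "clusters",
                                    "evolve"),
                           out_dir, config = default_config(),
                           paths = list()) {
  name <- match.arg(name)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(config, file.path(out_dir, "config_used.yaml"))
  if (isTRUE(config$verbose)) {
    message("stage ", name, " (seed ", config$seed, ")")
  }
  need <- function(key) {
    p <- paths[[key]]
    if (is.null(p)) t3_stop("stage '", name, "' needs input path '", key, "'")
    if (!file.exists(p)) t3_stop("input path does not exist: ", p)
    p
  }
  out <- list()
  if (name == "simulate" || name == "all") {
    fix <- generate_census(noise_rate = config$simulate$noise_rate,
                           seed = config$seed)
    loci <- generate_coords(seed = config$seed)
    st <- generate_species_tree()
    out$fasta <- write_fasta(fix$records, file.path(out_dir, "census.fasta"))
    out$metadata <- write_report(fix$species, file.path(out_dir, "species.tsv"))
    out$truth <- write_report(fix$truth, file.path(out_dir, "truth.tsv"))
    out$coords <- write_gff3(loci, file.path(out_dir, "coords.gff3"))
    out$tree <- write_newick(st$tree, file.path(out_dir, "species_tree.nwk"))
    if (name == "simulate") return(invisible(out))
    records <- fix$records
    species_table <- fix$species
    species_tree <- st$tree
  } else {
    records <- NULL
  }
  if (name == "scan") {
    records <- read_fasta(need("fasta"), paths$metadata)
    tab <- scan_records(records, cfg_scan(config), cfg_conv(config))
    out$scan <- write_report(tab, file.path(out_dir, "scan.tsv"))
    return(invisible(out))
  }
  if (name == "architecture") {
    records <- read_fasta(need("fasta"), paths$metadata)
    ap <- cfg_arch(config)
    tab <- do.call(rbind, lapply(seq_len(nrow(records)), function(i)
      arch_summary_row(records[i, ], ap)))
    out$architecture <- write_report(tab, file.path(out_dir, "architecture.tsv"))
    return(invisible(out))
  }
  if (name %in% c("classify", "census", "phylo") && is.null(records)) {
    records <- read_fasta(need("fasta"), paths$metadata)
  }
  if (name %in% c("classify", "census", "all")) {
    calls <- classify_records(records, cfg_scan(config), cfg_arch(config),
                              cfg_conv(config))
    out$calls <- write_report(calls, file.path(out_dir, "classification.tsv"))
    if (name == "classify") return(invisible(out))
    species_table <- if (name == "all") species_table
      else if (!is.null(paths$metadata)) utils::read.delim(paths$metadata)
      else NULL
    census <- build_census(calls, species_table)
    out$census <- write_report(census$counts, file.path(out_dir, "census.tsv"))
    summary_df <- data.frame(
      key = c("total_proteins", "n_metazoan_species", "n_nonmetazoan_species",
              "all_three_species", "zero_species"),
      value = c(census$total_proteins, census$n_metazoan_species,
                census$n_nonmetazoan_species,
                paste(census$all_three_species, collapse = ","),
                paste(census$zero_species, collapse = ",")),
      stringsAsFactors = FALSE)
    out$census_summary <- write_report(summary_df,
                                       file.path(out_dir, "census_summary.tsv"))
    if (name == "census") return(invisible(out))
  }
  if (name %in% c("phylo", "all")) {
    sites <- scan_records(records, cfg_scan(config), cfg_conv(config))
    with_site <- records[records$id %in% sites$id[!is.na(sites$cuA_h1)], ,
                         drop = FALSE]
    aln <- anchor_align(with_site, sites, flank = config$phylo$flank)
    tree <- bootstrap_support(aln, model = config$phylo$model,
                              replicates = config$phylo$replicates,
                              seed = config$seed)
    out$newick <- write_newick(tree, file.path(out_dir, "nj_tree.nwk"))
    dm <- aln_distances(aln, config$phylo$model)
    dm_df <- cbind(data.frame(id = rownames(dm), stringsAsFactors = FALSE),
                   as.data.frame(dm))
    out$distances <- write_report(dm_df, file.path(out_dir, "distances.tsv"))
    if (name == "phylo") return(invisible(out))
  }
  if (name %in% c("clusters", "all")) {
    if (name == "clusters") {
      loci <- read_gene_coords(need("coords"), "gff3")
      calls <- utils::read.delim(need("calls"), stringsAsFactors = FALSE)
    } else {
      loci <- read_gene_coords(out$coords, "gff3")
    }
    clus <- find_clusters(loci, calls, max_gap = config$clusters$max_gap,
                          same_subclass_only = config$clusters$same_subclass_only)
    out$clusters <- write_report(clus, file.path(out_dir, "clusters.tsv"))
    if (name == "clusters") return(invisible(out))
  }
  if (name %in% c("evolve", "all")) {
    if (name == "evolve") {
      species_tree <- ape::read.tree(need("tree"))
      counts <- utils::read.delim(need("census"), stringsAsFactors = FALSE)
      census <- list(counts = counts,
                     zero_species = counts$species[counts$total == 0])
      class(census) <- "census_table"
    }
    origins <- unlist(config$evolve$origins)
    evrep <- evolution_report(species_tree, census, origins,
                            config$evolve$expansion_threshold)
    out$losses <- write_report(evrep$losses, file.path(out_dir, "losses.tsv"))
    out$expansions <- write_report(evrep$expansions,
                                   file.path(out_dir, "expansions.tsv"))
    out$absent <- write_report(
      data.frame(species = evrep$all_absent_species, stringsAsFactors = FALSE),
      file.path(out_dir, "species_without_type3.tsv"))
  }
  invisible(out)
}
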