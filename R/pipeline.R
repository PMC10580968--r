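# Pipeline driver: a single hierarchical config drives every stage in
# dependency order and writes a run directory of TSV/JSON artifacts plus a
# manifest (config hash, seeds, package version, stage outputs), so a run
# is reproducible from its manifest alone.

#' Default run configuration
#'
#' Every threshold defaults to the value conventional for this analysis:
#' rarefaction depth 10,000 reads; abundant/rare cut at 1% relative
#' abundance; generalist/specialist deciles at 10%; network inclusion at
#' 0.1% relative abundance with |r| > 0.6 and p < 0.05; hub/keystone
#' percentile bands at 30%; Mapper resolution 40, overlap 0.75, minimum
#' cluster size 2, eps at the 98th distance percentile.
#'
#' @param seed master seed; stage seeds are derived from it.
#' @return a nested list of class `run_config`.
#' @export
default_run_config <- function(seed = 1) {
  structure(list(
    seed = seed,
    input = list(otu_table = NULL, metadata = NULL, functions = NULL),
    simulate = list(enabled = TRUE, n_taxa = 500, n_samples = 60,
                    depth = 10000, Nm = 1000, gradient_strength = 0.002),
    rarefaction = list(depth = 10000),
    traits = list(abundance_threshold = 0.01, niche_fraction = 0.10),
    decay = list(transform = "log10_distance", n_perm = 999),
    ncm = list(d = NULL),
    ordination = list(method = "cca", n_perm = 999,
                      factors = c("longitude", "latitude", "MAT", "MAP",
                                  "MDTR")),
    network = list(min_relab = 0.001, r_min = 0.6, p_max = 0.05,
                   n_dirichlet = 20, n_perm = 100, role_fraction = 0.30,
                   max_otus = 150),
    tda = list(resolution = 40, overlap = 0.75, min_samples = 2,
               eps_percentile = 98, n_perm = 1000)
  ), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Values present in the file override the defaults of
#' [default_run_config()]; everything else keeps its default.
#'
#' @param path YAML file path.
#' @return a `run_config` list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_run_config(user$seed %||% 1)
  merge_cfg <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && is.list(over[[nm]])) {
        base[[nm]] <- merge_cfg(base[[nm]], over[[nm]])
      } else {
        base[[nm]] <- over[[nm]]
      }
    }
    base
  }
  structure(merge_cfg(unclass(cfg), user), class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input (or simulation), rarefaction, trait
#' partitioning, distance-decay regression, neutral-model fit, CCA with
#' permutation tests, SparCC network with hub/keystone roles, and the
#' Mapper/SAFE topological analysis. Artifacts are TSV/JSON files in
#' `outdir`; the manifest records the config, its hash, seeds and the
#' file list. Outputs are deterministic given the config.
#'
#' @param config a `run_config` (see [default_run_config()]).
#' @param outdir output directory (created if needed).
#' @return invisibly, a list of the main stage results.
#' @export
run_pipeline <- function(config = default_run_config(), outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  art <- function(name) file.path(outdir, name)
  written <- character(0)
  note <- function(path) written <<- c(written, basename(path))

  # --- inputs ----------------------------------------------------------
  if (isTRUE(config$simulate$enabled)) {
    spec <- neutral_sim_spec(n_taxa = config$simulate$n_taxa,
                             n_samples = config$simulate$n_samples,
                             depth = config$simulate$depth,
                             Nm = config$simulate$Nm, seed = seed)
    table <- simulate_neutral_table(spec)
    metadata <- simulate_coastline_metadata(config$simulate$n_samples,
                                            seed = seed)
    if (config$simulate$gradient_strength > 0) {
      table <- plant_gradient(table, metadata,
                              config$simulate$gradient_strength,
                              seed = seed + 1)
    }
    truth <- list(Nm = spec$Nm, depth = spec$depth,
                  gradient_strength = config$simulate$gradient_strength)
    jsonlite::write_json(truth, art("ground_truth.json"), auto_unbox = TRUE,
                         digits = NA)
    note(art("ground_truth.json"))
    write_otu_table(table, art("simulated_otu_table.tsv"))
    note(art("simulated_otu_table.tsv"))
    utils::write.table(metadata, art("simulated_metadata.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    note(art("simulated_metadata.tsv"))
  } else {
    if (is.null(config$input$otu_table) || is.null(config$input$metadata)) {
      stop("config error: input$otu_table and input$metadata are required ",
           "when simulate$enabled is FALSE")
    }
    table <- read_otu_table(config$input$otu_table)
    metadata <- read_sample_metadata(config$input$metadata)
  }
  metadata <- validate_sample_metadata(metadata)

  # --- rarefaction -----------------------------------------------------
  rar <- rarefy(table, config$rarefaction$depth, seed = seed + 2)
  metadata <- metadata[match(rownames(rar), metadata$sample_id), ]
  if (anyNA(metadata$sample_id)) stop("metadata missing retained samples")

  # --- traits ----------------------------------------------------------
  traits <- trait_partition(rar, config$traits$abundance_threshold,
                            config$traits$niche_fraction)
  write_trait_partition(traits, art("trait_partition.tsv"))
  note(art("trait_partition.tsv"))

  # --- distance decay --------------------------------------------------
  sim <- community_similarity(rar)
  dist_km <- pairwise_distance_km(metadata)
  decay <- distance_decay_fit(sim, dist_km,
                              transform = config$decay$transform,
                              n_perm = config$decay$n_perm,
                              seed = seed + 3)
  jsonlite::write_json(decay[c("slope", "intercept", "r", "p_ols",
                               "p_mantel", "n_pairs")],
                       art("distance_decay.json"), auto_unbox = TRUE,
                       digits = NA)
  note(art("distance_decay.json"))

  # --- neutral model ---------------------------------------------------
  ncm <- fit_ncm(rar, d = config$ncm$d)
  jsonlite::write_json(ncm[c("Nm", "m", "d", "R2", "n_samples")],
                       art("ncm_fit.json"), auto_unbox = TRUE, digits = NA)
  note(art("ncm_fit.json"))
  utils::write.table(ncm$otus, art("ncm_otus.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  note(art("ncm_otus.tsv"))

  # --- ordination ------------------------------------------------------
  factors <- config$ordination$factors
  X <- metadata[, factors, drop = FALSE]
  cca <- cca_fit(rar, X)
  pvals <- cca_permutation_test(rar, X, n_perm = config$ordination$n_perm,
                                seed = seed + 4)
  jsonlite::write_json(list(constrained_proportion = cca$constrained_proportion,
                            eigenvalues = as.list(cca$eig_constrained),
                            p = stats::setNames(as.list(pvals$p),
                                                pvals$factor)),
                       art("cca.json"), auto_unbox = TRUE, digits = NA)
  note(art("cca.json"))

  # --- co-occurrence network ------------------------------------------
  nettab <- prevalence_filter(rar, config$network$min_relab)
  # keep the network tractable: cap at the most abundant OTUs
  if (ncol(nettab) > config$network$max_otus) {
    ord <- order(colSums(nettab), decreasing = TRUE)
    nettab <- otu_table(unclass_counts(nettab)[, sort(ord[seq_len(
      config$network$max_otus)]), drop = FALSE])
  }
  r <- sparcc_correlations(nettab, n_dirichlet = config$network$n_dirichlet,
                           seed = seed + 5)
  p <- sparcc_pvalues(nettab, r, n_perm = config$network$n_perm,
                      seed = seed + 6)
  net <- build_network(r, p, config$network$r_min, config$network$p_max,
                       relab = colMeans(relative_abundance(nettab)))
  metrics <- classify_roles(node_metrics(net),
                            config$network$role_fraction)
  write_edge_list(net, art("network_edges.tsv"))
  note(art("network_edges.tsv"))
  write_node_table(metrics, art("network_nodes.tsv"))
  note(art("network_nodes.tsv"))
  jsonlite::write_json(network_summary(net), art("network_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  note(art("network_summary.json"))
  if (!is.null(config$input$functions)) {
    fn <- read_function_table(config$input$functions)
    ov <- overlay_functions(net, fn)
    jsonlite::write_json(as.list(ov$fractions),
                         art("pathway_fractions.json"), auto_unbox = TRUE,
                         digits = NA)
    note(art("pathway_fractions.json"))
  }

  # --- Mapper / SAFE ---------------------------------------------------
  cfg_tda <- tda_config(resolution = config$tda$resolution,
                        overlap = config$tda$overlap,
                        min_samples = config$tda$min_samples,
                        eps_percentile = config$tda$eps_percentile,
                        n_perm = config$tda$n_perm, seed = seed + 7)
  lens <- mds_lens(1 - sim)
  tda <- mapper_network(lens, 1 - sim, cfg_tda)
  if (igraph::vcount(tda$graph) > 0) {
    onehot <- stats::model.matrix(~ location - 1, metadata)
    colnames(onehot) <- sub("^location", "", colnames(onehot))
    rownames(onehot) <- metadata$sample_id
    safe <- safe_scores(tda, onehot, cfg_tda)
    dom <- dominant_variable_map(tda, safe)
    utils::write.table(
      data.frame(node = rownames(tda$membership),
                 n_members = rowSums(tda$membership),
                 members = vapply(tda$members, paste, character(1),
                                  collapse = ","),
                 round(safe$safe, 6)),
      art("tda_nodes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    note(art("tda_nodes.tsv"))
    utils::write.table(dom, art("tda_dominant.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    note(art("tda_dominant.tsv"))
  }

  # --- manifest --------------------------------------------------------
  cfg_path <- art("config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  note(cfg_path)
  manifest <- list(
    package = "microassembly",
    version = as.character(utils::packageVersion("microassembly")),
    seed = seed,
    config_hash = unname(tools::md5sum(cfg_path)),
    artifacts = sort(unique(written))
  )
  jsonlite::write_json(manifest, art("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(table = rar, metadata = metadata, traits = traits,
                 decay = decay, ncm = ncm, cca = cca, cca_p = pvals,
                 network = net, roles = metrics, tda = tda))
}
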