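# End-to-end pipeline: preprocess -> discretize -> learn taxa network ->
# arc report -> cluster -> constructs/scores -> structural model ->
# cross-validation -> effects, with every intermediate written to a run
# directory and a manifest recording config hash and seeds.

#' Pipeline run configuration
#'
#' All seeds are explicit; a config round-trips losslessly through JSON.
#'
#' @param out_dir Output directory for run artifacts.
#' @param counts_path,metadata_path Input TSVs; leave `NULL` to simulate.
#' @param simulate `"study"`, `"strong"`, `"mediation"`, a
#'   [generator_spec()] object, or `NULL`.
#' @param filter_threshold Relative-abundance filter (default 1e-4).
#' @param log_base Log base for abundances.
#' @param ra_k_candidates,ra_r2_target Taxa discretization controls.
#' @param weight_k Weight classes (default 5).
#' @param taxa_sc,structural_sc Structural coefficients for the two
#'   learning stages.
#' @param max_parents,n_restarts Search controls.
#' @param max_cluster_size,mi_floor Clustering controls.
#' @param n_boot_struct,freq_threshold Structural-priors bagging controls.
#' @param crossval_folds Folds for the target ROC validation.
#' @param n_boot_effects Bootstrap resamples for effect CIs.
#' @param effect_delta Perturbation size for total effects.
#' @param seed Master seed.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir = tempfile("psem_run_"),
                       counts_path = NULL, metadata_path = NULL,
                       simulate = "study", filter_threshold = 1e-4,
                       log_base = 10, ra_k_candidates = 2:5,
                       ra_r2_target = 0.95, weight_k = 5, taxa_sc = 0.85,
                       structural_sc = 0.45, max_parents = 4,
                       n_restarts = 2, max_cluster_size = 10,
                       mi_floor = 0.02, n_boot_struct = 30,
                       freq_threshold = 0.5, crossval_folds = 10,
                       n_boot_effects = 200, effect_delta = 0.1, seed = 1L) {
  cfg <- as.list(environment())
  structure(cfg, class = "run_config")
}

#' Write / read a run configuration as JSON
#' @param config A `run_config`.
#' @param path File path.
#' @export
write_run_config <- function(config, path) {
  cfg <- unclass(config)
  if (inherits(cfg$simulate, "generator_spec")) {
    cfg$simulate <- c(unclass(cfg$simulate), list(.generator_spec = TRUE))
  }
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$ra_k_candidates <- as.integer(x$ra_k_candidates)
  if (is.list(x$simulate) && isTRUE(x$simulate$.generator_spec)) {
    x$simulate$.generator_spec <- NULL
    x$simulate <- structure(x$simulate, class = "generator_spec")
  }
  structure(x, class = "run_config")
}

#' Run the full pSEM pipeline
#'
#' Executes every stage and writes tabular artifacts (TSV/CSV), DOT/GraphML
#' graphs and a JSON manifest into `config$out_dir`.  Reruns with an
#' identical config produce byte-identical tabular outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with all in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = run_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_run_config(config, file.path(config$out_dir, "resolved_config.json"))
  stages <- character(0)
  note <- function(s) stages <<- c(stages, s)

  # --- inputs -----------------------------------------------------------
  truth <- NULL
  if (!is.null(config$counts_path)) {
    counts <- read_count_table(config$counts_path)
    metadata <- read_sample_metadata(config$metadata_path)
  } else {
    spec <- if (inherits(config$simulate, "generator_spec")) {
      config$simulate
    } else {
      switch(config$simulate %||% "study",
             study = preset_study(seed = config$seed),
             strong = preset_strong(seed = config$seed),
             mediation = preset_mediation(seed = config$seed))
    }
    sim <- generate_microbiome(spec)
    counts <- sim$counts
    metadata <- sim$metadata
    truth <- sim$truth
    readr::write_tsv(counts, file.path(config$out_dir, "simulated_counts.tsv"))
    readr::write_tsv(metadata, file.path(config$out_dir, "simulated_metadata.tsv"))
  }
  note("inputs")

  # --- preprocess -------------------------------------------------------
  at <- compute_relative_abundances(counts, metadata)
  at <- filter_low_abundance(at, threshold = config$filter_threshold)
  readr::write_csv(filter_report(at), file.path(config$out_dir, "filter_report.csv"))
  logra <- log_transform_nonzero(at, base = config$log_base)
  note("preprocess")

  # --- discretize -------------------------------------------------------
  binnings <- lapply(at$taxa, function(v) {
    r2_optimal_discretize(logra[, v], k_candidates = config$ra_k_candidates,
                          r2_target = config$ra_r2_target, variable = v)
  })
  names(binnings) <- at$taxa
  disc <- lapply(at$taxa, function(v) {
    binning_factor(apply_binning(logra[, v], binnings[[v]]), binnings[[v]])
  })
  names(disc) <- at$taxa
  disc <- as_tibble(disc)
  bind_rows(lapply(binnings, tidy)) |>
    readr::write_csv(file.path(config$out_dir, "taxa_binnings.csv"))
  note("discretize")

  # --- taxa network -----------------------------------------------------
  cfg_taxa <- mdl_config(sc = config$taxa_sc, max_parents = config$max_parents,
                         n_restarts = config$n_restarts, seed = config$seed)
  taxa_dag <- tabu_search(disc, cfg_taxa)
  readr::write_csv(dag_arcs(taxa_dag), file.path(config$out_dir, "taxa_network_arcs.csv"))
  write_dot(taxa_dag, file.path(config$out_dir, "taxa_network.dot"))
  write_graphml(taxa_dag, file.path(config$out_dir, "taxa_network.graphml"))
  note("learn_network")

  # --- arc report -------------------------------------------------------
  bn_taxa <- fit_cpts_mle(taxa_dag, disc, pseudocount = 0)
  report <- arc_report(bn_taxa, disc, raw_values = logra)
  readr::write_csv(report, file.path(config$out_dir, "arc_report.csv"))
  note("arc_report")

  # --- clustering + constructs -----------------------------------------
  clustering <- cluster_variables(taxa_dag, disc,
                                  max_size = config$max_cluster_size,
                                  mi_floor = config$mi_floor)
  readr::write_csv(tidy(clustering), file.path(config$out_dir, "clusters.csv"))
  constructs <- build_constructs(clustering, disc, logra, binnings,
                                 seed = config$seed,
                                 r2_target = config$ra_r2_target,
                                 k_candidates = config$ra_k_candidates)
  readr::write_csv(constructs$summary,
                   file.path(config$out_dir, "construct_summary.csv"))
  scores <- lc_scores(constructs, sample_ids = at$samples)
  readr::write_tsv(scores, file.path(config$out_dir, "lc_scores.tsv"))
  note("constructs")

  # --- structural model -------------------------------------------------
  sdata <- assemble_structural_data(constructs, at$metadata,
                                    weight_k = config$weight_k)
  cfg_struct <- mdl_config(max_parents = config$max_parents,
                           n_restarts = config$n_restarts, seed = config$seed)
  smodel <- learn_structural_model(sdata, sc = config$structural_sc,
                                   n_boot = config$n_boot_struct,
                                   freq_threshold = config$freq_threshold,
                                   config = cfg_struct, seed = config$seed)
  # Table-3-style: arc metrics of the structural network
  raw_struct <- structural_raw_values(sdata, constructs, at$metadata)
  sreport <- arc_report(smodel$bn, sdata$data, raw_values = raw_struct)
  readr::write_csv(sreport, file.path(config$out_dir, "structural_arc_report.csv"))
  readr::write_csv(smodel$arc_freq, file.path(config$out_dir, "structural_arc_freq.csv"))
  write_dot(smodel$dag, file.path(config$out_dir, "structural_network.dot"))
  write_graphml(smodel$dag, file.path(config$out_dir, "structural_network.graphml"))
  note("learn_structural")

  # --- cross-validation -------------------------------------------------
  auc <- crossval_target_auc(sdata, target = "weight",
                             folds = config$crossval_folds,
                             config = cfg_struct, sc = config$structural_sc,
                             seed = config$seed)
  auc_out <- as_tibble(auc[, c("class", "n", "auc")])
  auc_out$macro_auc <- attr(auc, "macro_auc")
  readr::write_csv(auc_out, file.path(config$out_dir, "crossval_auc.csv"))
  note("crossval")

  # --- effects ----------------------------------------------------------
  effects <- effect_significance(smodel, target = "weight",
                                 n_boot = config$n_boot_effects,
                                 delta = config$effect_delta,
                                 seed = config$seed)
  readr::write_csv(effects, file.path(config$out_dir, "effects.csv"))
  note("effects")

  manifest <- list(
    package = "micropsem",
    config_hash = hash(unclass(config)),
    seed = config$seed,
    stages = stages,
    outputs = sort(list.files(config$out_dir))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(
    abundance = at, logra = logra, binnings = binnings, disc = disc,
    taxa_dag = taxa_dag, arc_report = report, clustering = clustering,
    constructs = constructs, scores = scores, structural_data = sdata,
    structural_model = smodel, structural_arc_report = sreport, auc = auc,
    effects = effects, truth = truth, manifest = manifest
  ))
}

# continuous values backing the structural nodes, for correlations
structural_raw_values <- function(sdata, constructs, metadata) {
  out <- list(
    weight = metadata$weight_g,
    age = as.numeric(metadata$age_d),
    sex = as.numeric(factor(metadata$sex)) - 1,
    compartment = as.numeric(factor(metadata$compartment)) - 1,
    bsf = as.numeric(metadata$bsf_pct)
  )
  for (id in names(constructs$constructs)) {
    out[[id]] <- constructs$constructs[[id]]$scores
  }
  m <- do.call(cbind, out)
  rownames(m) <- metadata$sample_id
  m
}

#' Export a DAG to DOT / GraphML
#'
#' @param dag A `dag`.
#' @param path Output file.
#' @export
write_dot <- function(dag, path) {
  g <- igraph_from_dag(dag)
  igraph::write_graph(g, path, format = "dot")
  invisible(path)
}

#' @rdname write_dot
#' @export
write_graphml <- function(dag, path) {
  g <- igraph_from_dag(dag)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

igraph_from_dag <- function(dag) {
  arcs <- dag_arcs(dag)
  igraph::graph_from_data_frame(arcs, directed = TRUE,
                                vertices = data.frame(name = dag$nodes))
}
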