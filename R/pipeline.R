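#' Configure an end-to-end pipeline run
#'
#' Collects input paths and analysis settings; defaults reproduce the
#' reference analysis choices (alpha 0.05 uncorrected, adjusted Spearman
#' correlations, inverse-weight shortest-path lengths, default block-pair
#' policy, strict >80% per-group missingness exclusion).
#'
#' @param abundance Path to the subjects-by-genera relative-abundance table.
#' @param phenotype Path to the subjects-by-phenotypes table.
#' @param covariates Path to the covariate table (`subject_id`, `group`,
#'   `age`, `sex`).
#' @param centrality Path to a precomputed subjects-by-features centrality
#'   table (`X_Y_Z` columns), or `NULL` when `connectivity_dir` is given.
#' @param connectivity_dir Directory of per-subject connectivity matrices to
#'   run through the connectome stage, or `NULL`.
#' @param out_dir Output directory (created if needed).
#' @param alpha Significance threshold in (0, 1).
#' @param method Correlation flavour, `"spearman"` or `"pearson"`.
#' @param policy A [block_pair_policy()].
#' @param distance Betweenness edge-length transform (`"inverse"` or
#'   `"neglog"`).
#' @param roi Region-of-interest abbreviations for the connectome stage;
#'   `NULL` derives them from the matrix labels (stripping `_L`/`_R`).
#' @param genus_panel Genus names for the missingness filter; `NULL` uses
#'   every genus column of the abundance table.
#' @param max_missing_fraction Per-group missingness exclusion threshold.
#' @param seed Integer seed recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return A `trip_run_config` list.
#' @export
pipeline_config <- function(abundance, phenotype, covariates,
                            centrality = NULL, connectivity_dir = NULL,
                            out_dir, alpha = 0.05,
                            method = c("spearman", "pearson"),
                            policy = block_pair_policy(),
                            distance = c("inverse", "neglog"),
                            roi = NULL,
                            genus_panel = NULL,
                            max_missing_fraction = 0.80,
                            seed = 1L) {
  method <- match.arg(method)
  distance <- match.arg(distance)
  stopifnot(alpha > 0, alpha < 1)
  if (is.null(centrality) && is.null(connectivity_dir)) {
    abort("supply either a centrality table or a connectivity matrix directory")
  }
  structure(list(abundance = abundance, phenotype = phenotype,
                 covariates = covariates, centrality = centrality,
                 connectivity_dir = connectivity_dir, out_dir = out_dir,
                 alpha = alpha, method = method, policy = policy,
                 distance = distance, roi = roi, genus_panel = genus_panel,
                 max_missing_fraction = max_missing_fraction,
                 seed = as.integer(seed)),
            class = "trip_run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; `policy` is a list of
#' block pairs.
#'
#' @param path Path to a YAML file.
#' @return A `trip_run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("the 'yaml' package is required to read YAML configs")
  }
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$policy)) raw$policy <- block_pair_policy(unlist(raw$policy))
  do.call(pipeline_config, raw)
}

#' Run the full tripartite analysis pipeline
#'
#' Reads and validates the input tables, optionally computes centrality
#' features from connectivity matrices, aligns the blocks, applies the
#' per-group genus missingness filter, computes all adjusted correlations
#' and Fisher-z difference tests, builds the HC, IBS, and difference
#' networks, extracts a first-neighbour subnetwork for every genus present
#' in the difference network, and writes the group-comparison report. All
#' outputs plus a JSON manifest (stage counts, settings, config hash) go to
#' `config$out_dir`; identical inputs and config give identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results: `table` (the
#'   filtered [cohort_table()]), `edges`, `networks` (list of three
#'   `trip_network`s), `subnetworks`, `report`, and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "trip_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("[", name, "] ", conditionMessage(e)))
    })
  }

  microbe <- stage("read", read_abundance_table(config$abundance))
  phenotype <- stage("read", read_phenotype_table(config$phenotype))
  covariates <- stage("read", read_covariate_table(config$covariates))
  brain <- if (!is.null(config$centrality)) {
    stage("read", read_centrality_table(config$centrality))
  } else {
    mats <- stage("connectome", read_connectivity_stack(config$connectivity_dir))
    roi <- config$roi %||% unique(sub("_(L|R)$", "", rownames(mats[[1]])))
    stage("connectome", centrality_table(mats, roi = roi, distance = config$distance))
  }

  table <- stage("preprocess", align_blocks(microbe, phenotype, brain, covariates))
  panel <- config$genus_panel %||%
    names(var_blocks(table))[var_blocks(table) == "microbe"]
  table <- stage("preprocess",
                 filter_genera(table, panel = panel,
                               max_missing_fraction = config$max_missing_fraction))

  edges <- stage("tripartite",
                 correlate_all(table, policy = config$policy, method = config$method))
  networks <- list(
    `group-HC` = build_network(edges, "group-HC", alpha = config$alpha),
    `group-IBS` = build_network(edges, "group-IBS", alpha = config$alpha),
    difference = build_network(edges, "difference", alpha = config$alpha)
  )
  diff_net <- networks$difference
  genera_in_net <- diff_net$nodes$name[diff_net$nodes$block == "microbe"]
  subnetworks <- lapply(setNames(genera_in_net, genera_in_net), function(g) {
    extract_subnetwork(diff_net, g)
  })
  report <- stage("cohortstats", cohort_report(table))

  out <- function(f) file.path(config$out_dir, f)
  write_delim_auto(as_tibble(table), out("analysis_table.csv"))
  write_delim_auto(filter_report(table), out("filter_report.csv"))
  write_delim_auto(as_tibble(edges), out("edges.csv"))
  for (nm in names(networks)) {
    stem <- gsub("[^A-Za-z0-9]+", "_", tolower(nm))
    export_network(networks[[nm]], out(paste0("network_", stem, ".graphml")), "graphml")
    export_network(networks[[nm]], out(paste0("network_", stem, ".sif")), "sif")
  }
  for (g in names(subnetworks)) {
    stem <- gsub("[^A-Za-z0-9]+", "_", g)
    export_network(subnetworks[[g]], out(paste0("subnet_", stem, ".csv")), "edge-table")
  }
  write_delim_auto(report, out("report.csv"))

  cfg_plain <- unclass(config)
  cfg_plain$policy <- unclass(cfg_plain$policy)
  manifest <- list(
    package = "tripnet",
    version = as.character(utils::packageVersion("tripnet")),
    seed = config$seed,
    config = cfg_plain,
    config_hash = rlang::hash(cfg_plain),
    counts = list(
      subjects = nrow(table),
      subjects_hc = sum(table$group == "HC"),
      subjects_ibs = sum(table$group == "IBS"),
      genera_retained = sum(var_blocks(table) == "microbe"),
      genera_excluded = sum(!filter_report(table)$retained),
      edges_computed = nrow(edges),
      edges_skipped = nrow(attr(edges, "skipped")),
      edges_difference = nrow(diff_net$edges),
      edges_group_hc = nrow(networks$`group-HC`$edges),
      edges_group_ibs = nrow(networks$`group-IBS`$edges),
      subnetworks = length(subnetworks)
    )
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(table = table, edges = edges, networks = networks,
                 subnetworks = subnetworks, report = report, manifest = manifest))
}
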