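# Two-phase orchestration: (1) gene-set-restricted networks on multiple
# platforms with consensus and DE overlay; (2) all-gene network,
# biclustering, per-bicluster regulator calls, locus overlap, and optional
# domain scoring. Every run directory receives the config, seed, and a log
# sufficient to reproduce the outputs.

#' Pipeline configuration
#'
#' Defaults equal the reference parameterization: CLR likelihood cutoff
#' 2.5 (or FDR 0.05), MI significance 1e-7 with DPI tolerance 0.15 for the
#' ARACNE-style network, DE thresholds p = 0.01 / FDR = 0.01, bicluster
#' counts {5, 10, 20} with 500 iterations and sparseness 0.1.
#'
#' @param ... overrides of the default fields.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    mi_method = "bspline", mi_bins = 10, mi_order = 3,
    clr_mode = "cutoff", clr_cutoff = 2.5, clr_fdr = 0.05, clr_n_perm = 3,
    aracne_p = 1e-7, dpi_tolerance = 0.15, aracne_n_null = 2000,
    de_p = 0.01, de_fdr = 0.01,
    bicluster_p = c(5, 10, 20), bicluster_iters = 500,
    bicluster_sparseness = 0.1,
    regulator_interactions = TRUE, regulator_pair_budget = 200,
    domain_fp = 0.05, domain_fn = 0.10,
    seed = 1)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop2("unknown config field '", unknown[[1]], "'")
  cfg[names(over)] <- over
  class(cfg) <- "pipeline_config"
  cfg
}

write_run_provenance <- function(out_dir, config, seed, stage_log) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(sprintf("seed: %d", seed),
               sprintf("R: %s", R.version.string),
               stage_log),
             file.path(out_dir, "run.log"))
  invisible(out_dir)
}

run_stage <- function(name, log_env, expr) {
  log_env$log <- c(log_env$log, sprintf("stage %s: start", name))
  res <- tryCatch(expr, error = function(e) {
    stop2("pipeline stage '", name, "' failed (seed ",
          log_env$seed, "): ", conditionMessage(e))
  })
  log_env$log <- c(log_env$log, sprintf("stage %s: done", name))
  res
}

#' Phase 1: gene-set-restricted networks, consensus, overlay
#'
#' Restricts each platform's expression matrix to the union of the named
#' gene sets, infers a CLR and an ARACNE-style network per platform,
#' unions the per-platform networks per algorithm, and reports hub
#' ranking, consensus direct neighbors of the top hubs, and (when a DE
#' result is supplied) the direction overlay.
#'
#' @param expr_list named list of [expression_matrix()] objects (one per
#'   platform).
#' @param gene_sets a gene-set collection (see [read_gene_sets()]).
#' @param set_names which sets define the focus genes.
#' @param regulators character vector of designated transcription
#'   regulators (must be nonempty).
#' @param de optional `de_result` for the node overlay.
#' @param config a [pipeline_config()].
#' @param out_dir optional run directory for SIF/TSV outputs + provenance.
#' @param seed integer seed (overrides `config$seed`).
#' @param n_hubs how many top hubs enter the consensus report.
#' @return list: `clr` (union network), `aracne`, `per_platform`, `hubs`,
#'   `consensus`, `config`.
#' @export
run_phase1 <- function(expr_list, gene_sets, set_names, regulators,
                       de = NULL, config = pipeline_config(),
                       out_dir = NULL, seed = config$seed, n_hubs = 5) {
  if (!length(regulators)) stop2("empty regulator list")
  if (!is.list(expr_list) || is.null(names(expr_list)))
    expr_list <- stats::setNames(list(expr_list), "platform1")
  lg <- new.env()
  lg$log <- character(); lg$seed <- seed
  per_platform <- list()
  clr_union <- NULL
  ara_union <- NULL
  for (pf in names(expr_list)) {
    sub <- run_stage(paste0("subset_", pf), lg,
                     subnetwork_by_sets(expr_list[[pf]], gene_sets,
                                        set_names))
    regs <- intersect(regulators, rownames(sub))
    if (!length(regs)) stop2("no designated regulator in platform ", pf)
    mi <- run_stage(paste0("mi_", pf), lg,
                    mi_matrix(sub, method = config$mi_method,
                              bins = config$mi_bins,
                              order = config$mi_order,
                              regulators = regs))
    cs <- clr_scores(mi)
    cn <- run_stage(paste0("clr_", pf), lg, {
      if (config$clr_mode == "cutoff")
        clr_network(cs, "cutoff", cutoff = config$clr_cutoff)
      else
        clr_network(cs, "fdr", fdr = config$clr_fdr, X = sub,
                    n_perm = config$clr_n_perm, seed = seed)
    })
    an <- run_stage(paste0("aracne_", pf), lg,
                    aracne_network(mi, p_threshold = config$aracne_p,
                                   dpi_tolerance = config$dpi_tolerance,
                                   X = sub, n_null = config$aracne_n_null,
                                   seed = seed))
    per_platform[[pf]] <- list(clr = cn, aracne = an$network,
                               dpi = an$dpi)
    clr_union <- if (is.null(clr_union)) cn else union_networks(clr_union, cn)
    ara_union <- if (is.null(ara_union)) an$network else
      union_networks(ara_union, an$network)
  }
  if (!is.null(de)) {
    clr_union <- overlay_de(clr_union, de)
    ara_union <- overlay_de(ara_union, de)
  }
  hubs <- hub_rank(clr_union)
  top <- utils::head(hubs$gene[hubs$degree > 0], n_hubs)
  consensus <- if (length(top))
    consensus_neighbors(clr_union, ara_union, top) else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_network(clr_union, file.path(out_dir, "clr_union.sif"), "sif")
    write_network(clr_union, file.path(out_dir, "clr_union_edges.tsv"),
                  "edge_tsv")
    write_network(ara_union, file.path(out_dir, "aracne_union_edges.tsv"),
                  "edge_tsv")
    if (!is.null(consensus))
      utils::write.table(consensus, file.path(out_dir, "consensus.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(hubs, file.path(out_dir, "hubs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_run_provenance(out_dir, config, seed, lg$log)
  }
  list(clr = clr_union, aracne = ara_union, per_platform = per_platform,
       hubs = hubs, consensus = consensus, config = config)
}

#' Phase 2: all-gene network, biclusters, regulator calls, locus, domains
#'
#' Runs CLR at the likelihood cutoff on the full matrix, fits the sparse
#' factor model at each requested bicluster count, infers per-bicluster
#' CLR networks and signed regulator calls, classifies top-hub neighbors
#' against a susceptibility locus (when a band map is given), and scores
#' network edges with domain-composed interaction probabilities (when
#' domain annotations and an interactome are given).
#'
#' @param expr an [expression_matrix()].
#' @param regulators designated regulator ids (nonempty).
#' @param de optional `de_result` for the overlay.
#' @param bands optional [cytoband_map()].
#' @param locus locus string (default the chromosome 2q susceptibility
#'   interval `"2q33.3-2q37.2"`).
#' @param domains optional named list protein -> domains.
#' @param interactions optional observed interactome for the domain MLE.
#' @param config a [pipeline_config()].
#' @param out_dir optional run directory.
#' @param seed integer seed.
#' @param n_hubs hubs entering the locus analysis.
#' @return list: `network`, `hubs`, `models`, `biclusters` (per p),
#'   `bicluster_networks`, `regulator_calls`, `locus`, `domain_scores`,
#'   `summary` (parameter table), `config`.
#' @export
run_phase2 <- function(expr, regulators, de = NULL, bands = NULL,
                       locus = "2q33.3-2q37.2", domains = NULL,
                       interactions = NULL, config = pipeline_config(),
                       out_dir = NULL, seed = config$seed, n_hubs = 5) {
  if (!length(regulators)) stop2("empty regulator list")
  lg <- new.env()
  lg$log <- character(); lg$seed <- seed
  mi <- run_stage("mi_full", lg,
                  mi_matrix(expr, method = config$mi_method,
                            bins = config$mi_bins, order = config$mi_order))
  net <- run_stage("clr_full", lg,
                   clr_network(clr_scores(mi), "cutoff",
                               cutoff = config$clr_cutoff))
  if (!is.null(de)) net <- overlay_de(net, de)
  hubs <- hub_rank(net)
  models <- list()
  bicsets <- list()
  for (p in config$bicluster_p) {
    fm <- run_stage(paste0("factor_model_p", p), lg,
                    fit_factor_model(expr, p = p,
                                     n_iter = config$bicluster_iters,
                                     sparseness = config$bicluster_sparseness,
                                     seed = seed))
    models[[as.character(p)]] <- fm
    bicsets[[as.character(p)]] <- extract_biclusters(fm)
  }
  main_p <- as.character(utils::tail(config$bicluster_p, 1))
  main_set <- bicsets[[main_p]]
  bic_nets <- run_stage("within_bicluster_clr", lg, {
    nets <- lapply(main_set$biclusters, function(b)
      within_bicluster_network(expr, b, cutoff = config$clr_cutoff,
                               method = config$mi_method,
                               bins = config$mi_bins,
                               order = config$mi_order))
    nets[!vapply(nets, is.null, logical(1))]
  })
  calls <- run_stage("regulator_calls", lg,
                     infer_bicluster_regulators(
                       expr, main_set, intersect(regulators, rownames(expr)),
                       interactions = config$regulator_interactions,
                       pair_budget = config$regulator_pair_budget,
                       seed = seed))
  locus_report <- NULL
  if (!is.null(bands)) {
    top <- utils::head(hubs$gene[hubs$degree > 0], n_hubs)
    rows <- do.call(rbind, lapply(top, function(h) {
      nb <- network_neighbors(net, h)
      if (!length(nb)) return(NULL)
      data.frame(hub = h, gene = nb, stringsAsFactors = FALSE)
    }))
    if (!is.null(rows)) {
      rows <- rows[rows$gene %in% bands$gene, , drop = FALSE]
      if (nrow(rows))
        locus_report <- locus_overlap(rows, bands, locus)
    }
  }
  domain_scores <- NULL
  if (!is.null(domains) && !is.null(interactions)) {
    dm <- run_stage("domain_mle", lg,
                    suppressWarnings(
                      fit_domain_mle(domains, interactions,
                                     fp = config$domain_fp,
                                     fn = config$domain_fn, seed = seed)))
    mappable <- net$edges$from %in% names(domains) &
      net$edges$to %in% names(domains)
    if (any(mappable))
      domain_scores <- score_network_pairs(dm, net, domains)
  }
  summary <- data.frame(
    parameter = c("clr_cutoff", "aracne_p", "dpi_tolerance", "de_p",
                  "de_fdr", "bicluster_iters", "bicluster_sparseness"),
    value = c(config$clr_cutoff, config$aracne_p, config$dpi_tolerance,
              config$de_p, config$de_fdr, config$bicluster_iters,
              config$bicluster_sparseness),
    stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_network(net, file.path(out_dir, "clr_full_edges.tsv"), "edge_tsv")
    utils::write.table(hubs, file.path(out_dir, "hubs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(calls, file.path(out_dir, "regulator_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(locus_report))
      utils::write.table(locus_report, file.path(out_dir, "locus.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(summary, file.path(out_dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_run_provenance(out_dir, config, seed, lg$log)
  }
  list(network = net, hubs = hubs, models = models, biclusters = bicsets,
       bicluster_networks = bic_nets, regulator_calls = calls,
       locus = locus_report, domain_scores = domain_scores,
       summary = summary, config = config)
}
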