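#' Read a pipeline configuration file
#'
#' YAML config with the paths and parameters consumed by [run_pipeline()].
#'
#' @param path YAML file path.
#' @return named list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

.cfg_default <- function(config, name, default) {
  if (is.null(config[[name]])) default else config[[name]]
}

#' Run the full network-to-signature pipeline
#'
#' Executes the stages in order — node metrics, feedback-loop enumeration,
#' node criteria (pathway flags, random-walk prioritization, fold-change
#' contrast), multi-scenario motif ranking, core assembly, logic model,
#' input-space sweep, perturbation scan, signature extraction — writing each
#' stage's table into `outdir` plus a machine-readable `summary.json`. The
#' run is deterministic for a fixed config and seed.
#'
#' Config fields (paths relative to the working directory):
#' \describe{
#'   \item{network, network_dialect}{edge file and dialect (default `sif`).}
#'   \item{gene_set, gene_set_name}{GMT file and the set to use (default:
#'     first set).}
#'   \item{expression, invasive, noninvasive}{expression TSV and the two
#'     sample groups; alternatively `fold_changes` (precomputed TSV).}
#'   \item{seeds}{text file of seed genes for prioritization (default:
#'     packaged EMT markers present in the network).}
#'   \item{rules}{optional logic-model rule file; when absent, rules are
#'     derived from the assembled core and `phenotype` (rule text) if given,
#'     else the logic stages are skipped.}
#'   \item{max_loop_length, top_k, restart_prob, perturb_order, scenarios}{
#'     parameters; `scenarios` is a YAML/JSON weight-vector file.}
#' }
#'
#' @param config list (or path to a YAML file) as above.
#' @param outdir output directory; created if needed.
#' @param seed integer seed for the stochastic stages.
#' @return the summary list, invisibly.
#' @export
run_pipeline <- function(config, outdir = NULL, seed = 1L) {
  if (is.character(config)) config <- read_pipeline_config(config)
  outdir <- if (is.null(outdir)) .cfg_default(config, "outdir", "regcore_run")
            else outdir
  # fail early on missing inputs, before any stage runs
  for (f in c("network", "gene_set", "expression", "fold_changes", "seeds",
              "rules", "scenarios")) {
    p <- config[[f]]
    if (!is.null(p) && !file.exists(p))
      stop("config path for '", f, "' does not exist: ", p)
  }
  if (is.null(config$network)) stop("config must name a network file")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(seed = seed)
  stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  net <- stage("load_network", function()
    load_network(config$network,
                 .cfg_default(config, "network_dialect", "sif")))
  stats <- stage("network_summary", function() network_summary(net))
  summary$network <- list(nodes = stats$node_count, edges = stats$edge_count)

  metrics <- stage("node_metrics", function() compute_node_metrics(net))
  write.table(metrics, file.path(outdir, "node_metrics.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  loops <- stage("feedback_loops", function()
    enumerate_feedback_loops(net, .cfg_default(config, "max_loop_length", 3L)))
  write_loops(loops, file.path(outdir, "feedback_loops.tsv"))
  summary$loops <- list(total = nrow(loops),
                        positive = sum(loops$sign == "positive"),
                        negative = sum(loops$sign == "negative"),
                        neutral = sum(loops$sign == "neutral"))
  if (nrow(loops[loops$length > 1L, ]) == 0L)
    stop("pipeline stage 'feedback_loops' failed: no multi-node loop found")

  flags <- stage("pathway_flags", function() {
    if (is.null(config$gene_set)) return(flag_pathway_membership(net, "\r"))
    sets <- read_gmt(config$gene_set)
    nm <- .cfg_default(config, "gene_set_name", names(sets)[1])
    flag_pathway_membership(net, sets[[nm]])
  })
  gp <- stage("prioritization", function() {
    seeds <- if (!is.null(config$seeds))
      trimws(readLines(config$seeds, warn = FALSE))
    else intersect(emt_markers(), net$nodes$id)
    rwr_prioritize(net, seeds,
                   restart_prob = .cfg_default(config, "restart_prob", 0.7))
  })
  fc <- stage("fold_change", function() {
    if (!is.null(config$fold_changes)) read_fold_changes(config$fold_changes)
    else if (!is.null(config$expression))
      fold_change_contrast(read_expression(config$expression),
                           config$invasive, config$noninvasive,
                           pseudocount = .cfg_default(config, "pseudocount", 0))
    else NULL
  })

  scenarios <- if (!is.null(config$scenarios)) read_scenarios(config$scenarios)
               else default_scenarios()
  sel <- stage("ranking", function() {
    feats <- motif_features(loops, metrics, flags, gp, fc)
    rank_and_select(feats, scenarios, k = .cfg_default(config, "top_k", 10L))
  })
  write.table(sel$selected, file.path(outdir, "selected_motifs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  summary$motifs_selected <- nrow(sel$selected)

  core <- stage("core_assembly", function() {
    merged <- merge_motifs(loops[loops$key %in% sel$selected$key, ], full = net)
    connect_components(merged, net)
  })
  write_core(core, file.path(outdir, "core_edges.tsv"))
  summary$core <- list(nodes = nrow(core$network$nodes),
                       edges = nrow(core$network$interactions),
                       bridges = nrow(core$bridges))

  model <- stage("logic_model", function() {
    if (!is.null(config$rules)) read_logic_model(config$rules)
    else if (!is.null(config$phenotype))
      derive_boolean_rules(core, fc, phenotype = config$phenotype)
    else NULL
  })
  if (!is.null(model) && !is.null(model$phenotype) &&
      length(model$inputs) <= 20L) {
    sweep <- stage("input_sweep", function() enumerate_input_space(model))
    write.table(sweep, file.path(outdir, "input_sweep.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    summary$input_space <- nrow(sweep)
    classes <- stage("equivalence_classes", function()
      collapse_equivalence_classes(sweep))
    sig <- extract_driver_signature(classes)
    write.table(sig, file.path(outdir, "driver_signature.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    summary$signature <- if (nrow(sig)) paste0(sig$input, ":", sig$direction)
                         else character(0)
    base <- classes[which.max(classes$phenotype), , drop = FALSE]
    base_input <- setNames(rep(0L, length(model$inputs)), model$inputs)
    for (i in attr(classes, "influential"))
      base_input[i] <- as.integer(base[[i]])
    scan <- stage("perturbation_scan", function()
      perturbation_scan(model, base_input,
                        .cfg_default(config, "perturb_order", 2L)))
    write.table(scan, file.path(outdir, "perturbations.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    top <- scan[scan$order > 0L & !is.na(scan$reduction), , drop = FALSE]
    summary$top_perturbations <- head(top$label, 5L)
    summary$baseline_phenotype <- attr(scan, "baseline")
  } else {
    summary$logic <- "skipped (no rule file or phenotype rule configured)"
  }

  rs <- stage("random_signatures", function()
    random_signatures(core, count = .cfg_default(config, "n_random_signatures", 30L),
                      size = min(3L, nrow(core$network$nodes)), seed = seed))
  write.table(rs, file.path(outdir, "random_signatures.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(summary)
}

#' Build a self-contained demo configuration
#'
#' Generates a synthetic signed network, a matching GMT gene set and a
#' two-group expression table with planted fold-changes into `dir`, plus the
#' packaged bladder rule file for the logic stages, and returns a config list
#' ready for [run_pipeline()].
#'
#' @param dir directory for the generated inputs.
#' @param seed RNG seed.
#' @param n_nodes synthetic network size.
#' @return config list.
#' @export
demo_config <- function(dir, seed = 1L, n_nodes = 30L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  net <- random_signed_network(n_nodes, edge_prob = 0.12,
                               inhibition_frac = 0.3, seed = seed)
  net_path <- file.path(dir, "network.sif")
  write_network(net, net_path, "sif")
  ids <- net$nodes$id
  gmt_path <- file.path(dir, "pathway.gmt")
  writeLines(paste(c("disease_pathway", "synthetic cancer pathway",
                     ids[seq_len(max(3L, n_nodes %/% 3L))]), collapse = "\t"),
             gmt_path)
  planted <- setNames(c(2, -1.5), ids[1:2])
  xp <- synthetic_expression(ids, n_per_group = 10L,
                             planted_log2fc = planted, seed = seed + 1L)
  expr_path <- file.path(dir, "expression.tsv")
  write.table(data.frame(gene = rownames(xp$expr), xp$expr,
                         check.names = FALSE),
              expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  seeds_path <- file.path(dir, "seeds.txt")
  writeLines(ids[1:3], seeds_path)
  list(network = net_path, network_dialect = "sif",
       gene_set = gmt_path, expression = expr_path,
       invasive = xp$invasive, noninvasive = xp$noninvasive,
       seeds = seeds_path,
       rules = system.file("extdata", "bladder_core_rules.txt",
                           package = "regcore"),
       top_k = 10L, max_loop_length = 3L)
}
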