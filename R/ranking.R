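#' Default weighting scenarios for motif ranking
#'
#' Thirteen weight vectors `(w1, w2, w3, w4)` spanning the Pareto directions
#' of the multi-objective ranking function: the four one-hot vectors, the six
#' equal-weight pairs, the uniform vector, and two mixed emphases (on topology
#' and on fold-change). All rows sum to 1. Fully overridable via
#' [weighting_scenarios()].
#'
#' @return data.frame with columns `id`, `w1`, `w2`, `w3`, `w4`.
#' @export
default_scenarios <- function() {
  w <- rbind(
    diag(4),
    t(utils::combn(4, 2, function(ix) { v <- numeric(4); v[ix] <- 0.5; v })),
    rep(0.25, 4),
    c(0.4, 0.2, 0.2, 0.2),
    c(0.2, 0.2, 0.2, 0.4))
  weighting_scenarios(w)
}

#' Validate a set of weighting scenarios
#'
#' @param w numeric matrix or data.frame with 4 columns (`w1`..`w4`);
#'   weights must be non-negative and each row must sum to 1 (tolerance 1e-9).
#' @return data.frame with columns `id`, `w1`, `w2`, `w3`, `w4`.
#' @export
weighting_scenarios <- function(w) {
  w <- as.matrix(w)
  if ("id" %in% colnames(w)) w <- w[, setdiff(colnames(w), "id"), drop = FALSE]
  if (ncol(w) != 4L) stop("scenarios need 4 weight columns")
  if (any(w < 0)) stop("weights must be non-negative")
  if (any(abs(rowSums(w) - 1) > 1e-9))
    stop("each scenario's weights must sum to 1")
  out <- data.frame(id = seq_len(nrow(w)), w1 = w[, 1], w2 = w[, 2],
                    w3 = w[, 3], w4 = w[, 4])
  rownames(out) <- NULL
  out
}

#' Read weighting scenarios from a YAML or JSON config
#'
#' The file holds a list of 4-element weight vectors.
#'
#' @param path file path ending in `.yaml`/`.yml` or `.json`.
#' @return data.frame as in [default_scenarios()].
#' @export
read_scenarios <- function(path) {
  lst <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  weighting_scenarios(do.call(rbind, lapply(lst, as.numeric)))
}

#' Per-motif ranking features
#'
#' For every feedback loop, computes the five raw criteria of the ranking
#' function: mean node degree `nd`, mean betweenness `bc`, the *count* of
#' member nodes flagged as disease-pathway members `dp`, mean gene
#' prioritization score `gp`, and mean absolute expression fold-change `afc`.
#' Nodes missing from the metrics, pathway-flag or prioritization tables raise
#' an error naming the node; genes absent from the fold-change table carry
#' `fc = 0` (the convention for unmeasured species such as complexes).
#'
#' @param loops a `feedback_loops` data.frame ([enumerate_feedback_loops()]).
#' @param metrics data.frame from [compute_node_metrics()].
#' @param flags named logical vector from [flag_pathway_membership()].
#' @param gp named numeric vector from [rwr_prioritize()].
#' @param fc data.frame from [fold_change_contrast()] or
#'   [read_fold_changes()], or `NULL` for all-zero fold-changes.
#' @return data.frame with columns `key`, `length`, `sign`, `nd`, `bc`, `dp`,
#'   `gp`, `afc`.
#' @export
motif_features <- function(loops, metrics, flags, gp, fc = NULL) {
  deg <- setNames(metrics$degree, metrics$node)
  btw <- setNames(metrics$betweenness, metrics$node)
  fcv <- if (is.null(fc)) numeric(0) else setNames(fc$fc, fc$gene)
  nl <- loop_nodes(loops)
  feat <- t(vapply(nl, function(nodes) {
    for (tbl in list(deg = deg, flags = flags, gp = gp)) {
      miss <- setdiff(nodes, names(tbl))
      if (length(miss))
        stop("node missing from input table: ", paste(miss, collapse = ", "))
    }
    f <- fcv[nodes]
    f[is.na(f)] <- 0
    c(nd = mean(deg[nodes]), bc = mean(btw[nodes]),
      dp = sum(flags[nodes]), gp = mean(gp[nodes]), afc = mean(abs(f)))
  }, numeric(5)))
  cbind(loops[, c("key", "length", "sign")],
        as.data.frame(feat, stringsAsFactors = FALSE))
}

#' Score motifs under one weighting scenario
#'
#' The weighted multi-objective score of motif *i*:
#' \deqn{S_i = \frac{w_1}{2}\frac{\langle ND\rangle_i}{\max(ND)}
#'   + \frac{w_1}{2}\frac{\langle BC\rangle_i}{\max(BC)}
#'   + w_2\frac{\langle DP\rangle_i}{\max(DP)}
#'   + w_3\frac{\langle GP\rangle_i}{\max(GP)}
#'   + w_4\frac{\langle|FC|\rangle_i}{\max(|FC|)}}
#' The topology weight `w1` is split evenly between degree and betweenness so
#' topological criteria are not over-emphasized. Each criterion is normalized
#' by its maximum over all motifs in `features`; a zero maximum makes the term
#' contribute 0 for every motif. When the weights sum to 1, `0 <= S <= 1`.
#'
#' @param features data.frame from [motif_features()].
#' @param weights numeric vector `c(w1, w2, w3, w4)`, non-negative.
#' @return `features` with added columns `score` and the five normalized
#'   component terms (`nd_n`, `bc_n`, `dp_n`, `gp_n`, `afc_n`).
#' @export
score_motifs <- function(features, weights) {
  weights <- as.numeric(weights)
  stopifnot(length(weights) == 4L)
  if (any(weights < 0)) stop("weights must be non-negative")
  norm <- function(x) {
    m <- max(x)
    if (m > 0) x / m else rep(0, length(x))
  }
  out <- features
  out$nd_n <- norm(features$nd)
  out$bc_n <- norm(features$bc)
  out$dp_n <- norm(features$dp)
  out$gp_n <- norm(features$gp)
  out$afc_n <- norm(features$afc)
  out$score <- weights[1] / 2 * out$nd_n + weights[1] / 2 * out$bc_n +
    weights[2] * out$dp_n + weights[3] * out$gp_n + weights[4] * out$afc_n
  out
}

#' Rank motifs per scenario and select the non-redundant union
#'
#' Scores every motif under every weighting scenario, takes the top `k` per
#' scenario (ties broken deterministically: score descending, then mean
#' absolute fold-change descending, then canonical key ascending) and returns
#' the deduplicated union across scenarios. Self-loops are excluded from
#' ranking by default.
#'
#' @param features data.frame from [motif_features()].
#' @param scenarios data.frame from [default_scenarios()] /
#'   [weighting_scenarios()].
#' @param k motifs kept per scenario (>= 1).
#' @param exclude_self_loops drop length-1 loops before ranking.
#' @return list with `selected` (features of the non-redundant union, sorted
#'   by key) and `rankings` (per-scenario scored tables, ranked).
#' @export
rank_and_select <- function(features, scenarios = default_scenarios(),
                            k = 10L, exclude_self_loops = TRUE) {
  stopifnot(k >= 1L)
  if (exclude_self_loops) features <- features[features$length > 1L, , drop = FALSE]
  if (nrow(features) == 0L) stop("no motifs to rank")
  rankings <- lapply(seq_len(nrow(scenarios)), function(j) {
    sc <- score_motifs(features, as.numeric(scenarios[j, c("w1", "w2", "w3", "w4")]))
    sc <- sc[order(-sc$score, -sc$afc, sc$key), , drop = FALSE]
    sc$rank <- seq_len(nrow(sc))
    sc$scenario <- scenarios$id[j]
    rownames(sc) <- NULL
    sc
  })
  names(rankings) <- paste0("scenario_", scenarios$id)
  top_keys <- unique(unlist(lapply(rankings, function(r)
    r$key[seq_len(min(k, nrow(r)))])))
  selected <- features[features$key %in% top_keys, , drop = FALSE]
  selected <- selected[order(selected$key), , drop = FALSE]
  rownames(selected) <- NULL
  list(selected = selected, rankings = rankings)
}
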