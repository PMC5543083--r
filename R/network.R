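#' @importFrom stats setNames
#' @importFrom utils read.delim write.table head
NULL

.EFFECTS <- c("activation", "inhibition", "unknown")

.NODE_CATEGORIES <- c("gene", "protein", "miRNA", "complex", "receptor",
                      "ligand", "phenotype", "other")

#' Construct a signed directed regulatory network
#'
#' A `regnet` holds a set of nodes (with a category tag) and a set of signed
#' directed interactions. Interactions are regulatory edges whose `effect` is
#' one of `"activation"`, `"inhibition"` or `"unknown"`; the `unknown` class is
#' what makes "neutral" feedback loops possible downstream.
#'
#' Duplicate `(source, target, effect)` triples are collapsed with a warning.
#' Parallel edges between the same pair with *different* effects are kept: they
#' carry distinct regulatory evidence and generate distinct signed loops.
#'
#' @param interactions data.frame with columns `source`, `target`, `effect`
#'   and optionally `provenance` (free-text reference).
#' @param nodes optional data.frame with columns `id` and `category`
#'   (one of gene, protein, miRNA, complex, receptor, ligand, phenotype,
#'   other). Nodes absent from this table default to category `"other"`.
#' @return An object of class `regnet`: a list with elements `nodes`
#'   (data.frame `id`, `category`) and `interactions` (data.frame `source`,
#'   `target`, `effect`, `provenance`).
#' @export
regnet <- function(interactions, nodes = NULL) {
  stopifnot(is.data.frame(interactions))
  req <- c("source", "target", "effect")
  if (!all(req %in% names(interactions)))
    stop("interactions must have columns source, target, effect")
  it <- interactions
  it$source <- trimws(as.character(it$source))
  it$target <- trimws(as.character(it$target))
  it$effect <- as.character(it$effect)
  if (is.null(it$provenance)) it$provenance <- rep(NA_character_, nrow(it))
  if (nrow(it) == 0L && is.null(nodes))
    stop("no interactions")
  if (any(!nzchar(it$source)) || any(!nzchar(it$target)))
    stop("source and target identifiers must be non-empty strings")
  bad <- !(it$effect %in% .EFFECTS)
  if (any(bad))
    stop("invalid effect value(s): ", paste(unique(it$effect[bad]), collapse = ", "))
  key <- paste(it$source, it$target, it$effect, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate interaction(s) collapsed")
    it <- it[!duplicated(key), , drop = FALSE]
  }
  ids <- sort(unique(c(it$source, it$target)))
  if (is.null(nodes)) {
    nodes <- data.frame(id = ids, category = "other",
                        stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("id", "category") %in% names(nodes)))
    nodes$id <- trimws(as.character(nodes$id))
    nodes$category <- as.character(nodes$category)
    if (anyDuplicated(nodes$id)) stop("duplicate node identifiers")
    badc <- !(nodes$category %in% .NODE_CATEGORIES)
    if (any(badc))
      stop("invalid node category: ", paste(unique(nodes$category[badc]), collapse = ", "))
    missing_ids <- setdiff(ids, nodes$id)
    if (length(missing_ids))
      nodes <- rbind(nodes, data.frame(id = missing_ids, category = "other",
                                       stringsAsFactors = FALSE))
    nodes <- nodes[order(nodes$id), , drop = FALSE]
  }
  rownames(it) <- NULL
  rownames(nodes) <- NULL
  structure(list(nodes = nodes,
                 interactions = it[, c("source", "target", "effect", "provenance")]),
            class = "regnet")
}

#' @export
print.regnet <- function(x, ...) {
  cat("regnet: ", nrow(x$nodes), " nodes, ", nrow(x$interactions),
      " interactions\n", sep = "")
  eff <- table(factor(x$interactions$effect, levels = .EFFECTS))
  cat("  effects: ", paste(names(eff), eff, sep = "=", collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

# map heterogeneous relation tokens onto the effect enum
.map_effect <- function(token) {
  t <- tolower(trimws(token))
  if (t %in% c("activates", "activation", "->", "activate", "a"))
    return("activation")
  if (t %in% c("inhibits", "inhibition", "-|", "inhibit", "i"))
    return("inhibition")
  if (t %in% c("unknown", "?", "u"))
    return("unknown")
  NA_character_
}

#' Read a signed regulatory network from disk
#'
#' Supports two dialects: Cytoscape-style SIF (`source <tab> relation <tab>
#' target [target ...]`) and an extended edge table (TSV with header columns
#' `source`, `target`, `effect` and optional `provenance`). Relation tokens
#' `activates`/`activation`/`->` map to activation, `inhibits`/`inhibition`/
#' `-|` to inhibition; any other token is mapped to `unknown` with a warning
#' naming the offending line.
#'
#' @param path file path.
#' @param dialect `"sif"` or `"edge_table"`.
#' @return A [regnet].
#' @export
load_network <- function(path, dialect = c("sif", "edge_table")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cannot read network file: ", path)
  if (dialect == "sif") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("no interactions in ", path)
    rows <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
      if (length(f) < 3L)
        stop("SIF parse error at line ", i, ": expected at least 3 fields")
      eff <- .map_effect(f[2])
      if (is.na(eff)) {
        warning("line ", i, ": unrecognized relation token '", f[2],
                "' mapped to unknown")
        eff <- "unknown"
      }
      rows[[i]] <- data.frame(source = f[1], target = f[-(1:2)], effect = eff,
                              stringsAsFactors = FALSE)
    }
    it <- do.call(rbind, rows)
    it$provenance <- NA_character_
  } else {
    it <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (!all(c("source", "target", "effect") %in% names(it)))
      stop("edge table must have columns source, target, effect")
    if (nrow(it) == 0L) stop("no interactions in ", path)
    eff <- vapply(it$effect, .map_effect, character(1))
    bad <- which(is.na(eff))
    if (length(bad)) {
      warning("line(s) ", paste(bad + 1L, collapse = ", "),
              ": unrecognized effect token mapped to unknown")
      eff[bad] <- "unknown"
    }
    it$effect <- unname(eff)
    if (is.null(it$provenance)) it$provenance <- NA_character_
  }
  regnet(it)
}

#' Write a network back to disk
#'
#' Writes canonical effect tokens (`activation`, `inhibition`, `unknown`) so a
#' written file re-parses into an identical network.
#'
#' @param net a [regnet].
#' @param path output file path.
#' @param dialect `"sif"` or `"edge_table"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, dialect = c("sif", "edge_table")) {
  dialect <- match.arg(dialect)
  it <- net$interactions
  if (dialect == "sif") {
    writeLines(paste(it$source, it$effect, it$target, sep = "\t"), path)
  } else {
    write.table(it, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

# igraph view of a regnet; multi-edges preserved unless collapse = TRUE
as_igraph <- function(net, directed = TRUE, collapse = FALSE) {
  g <- igraph::graph_from_data_frame(
    net$interactions[, c("source", "target", "effect")],
    directed = directed, vertices = net$nodes$id)
  if (collapse) g <- igraph::simplify(g, remove.multiple = TRUE,
                                      remove.loops = FALSE)
  g
}

#' Per-node topology metrics
#'
#' Degree (in + out, counting direction multiplicity of parallel edges) and
#' directed, unnormalized betweenness centrality (raw shortest-path counts).
#' These are the `ND` and `BC` criteria of the motif ranking function, which
#' self-normalizes by the maximum over all motifs, so no normalization is
#' applied here.
#'
#' @param net a [regnet].
#' @return data.frame with columns `node`, `degree`, `betweenness`.
#' @export
compute_node_metrics <- function(net) {
  if (nrow(net$nodes) == 0L) stop("empty network")
  g <- as_igraph(net)
  data.frame(node = igraph::V(g)$name,
             degree = unname(igraph::degree(g, mode = "all")),
             betweenness = unname(igraph::betweenness(g, directed = TRUE,
                                                      normalized = FALSE)),
             stringsAsFactors = FALSE)
}

#' Global network statistics
#'
#' Node/edge counts, average (local) clustering coefficient, diameter, radius,
#' characteristic path length and average number of neighbors. Distance-based
#' statistics use directed shortest paths over *reachable* pairs only; the
#' `connected` flag reports whether the underlying graph is weakly connected
#' (the convention for networks, like large literature-curated maps, that are
#' not strongly connected).
#'
#' @param net a [regnet].
#' @return list of class `regnet_summary`.
#' @export
network_summary <- function(net) {
  if (nrow(net$nodes) == 0L) stop("empty network")
  g <- as_igraph(net)
  gu <- igraph::as_undirected(g, mode = "collapse")
  d <- igraph::distances(g, mode = "out")
  diag(d) <- Inf
  finite <- d[is.finite(d)]
  if (length(finite) == 0L) {
    diameter <- 0L; radius <- 0L; cpl <- 0
  } else {
    ecc <- apply(d, 1L, function(r) {
      f <- r[is.finite(r)]
      if (length(f)) max(f) else Inf
    })
    ecc <- ecc[is.finite(ecc)]
    diameter <- as.integer(max(finite))
    radius <- as.integer(min(ecc))
    cpl <- mean(finite)
  }
  cc <- igraph::transitivity(gu, type = "localaverage", isolates = "zero")
  if (is.nan(cc)) cc <- 0
  structure(list(
    node_count = nrow(net$nodes),
    edge_count = nrow(net$interactions),
    clustering_coefficient = cc,
    diameter = diameter,
    radius = radius,
    characteristic_path_length = cpl,
    average_neighbors = mean(igraph::degree(gu)),
    connected = igraph::is_connected(g, mode = "weak")
  ), class = "regnet_summary")
}

#' @export
print.regnet_summary <- function(x, ...) {
  cat("network summary\n")
  for (f in setdiff(names(x), "connected"))
    cat(sprintf("  %-28s %s\n", f, format(x[[f]], digits = 4)))
  if (!x$connected)
    cat("  [not weakly connected: path statistics over reachable pairs only]\n")
  invisible(x)
}
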