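#' Merge selected motifs into one network
#'
#' Node set = union of motif nodes; edge set = union of motif edges,
#' deduplicated. Phenotype-category nodes are excluded (they belong to the
#' logic model's output layer, not the regulatory core); categories and edge
#' provenance are taken from `full` when supplied.
#'
#' @param loops a `feedback_loops` data.frame of the selected motifs (or any
#'   subset thereof); at least one motif.
#' @param full optional [regnet] providing node categories and provenance.
#' @param drop_phenotype exclude nodes tagged with category `"phenotype"`.
#' @return a [regnet].
#' @export
merge_motifs <- function(loops, full = NULL, drop_phenotype = TRUE) {
  if (nrow(loops) == 0L) stop("no motifs to merge")
  edges <- do.call(rbind, lapply(seq_len(nrow(loops)), function(i) {
    nodes <- strsplit(loops$nodes[i], ">", fixed = TRUE)[[1]]
    effects <- strsplit(loops$effects[i], ">", fixed = TRUE)[[1]]
    data.frame(source = nodes, target = c(nodes[-1], nodes[1]),
               effect = effects, stringsAsFactors = FALSE)
  }))
  edges <- edges[!duplicated(paste(edges$source, edges$target, edges$effect,
                                   sep = "\r")), , drop = FALSE]
  nodes <- NULL
  if (!is.null(full)) {
    nodes <- full$nodes[full$nodes$id %in% unique(c(edges$source, edges$target)), ,
                        drop = FALSE]
  }
  if (drop_phenotype && !is.null(nodes)) {
    pheno <- nodes$id[nodes$category == "phenotype"]
    if (length(pheno)) {
      edges <- edges[!(edges$source %in% pheno | edges$target %in% pheno), ,
                     drop = FALSE]
      nodes <- nodes[!(nodes$id %in% pheno), , drop = FALSE]
    }
  }
  if (nrow(edges) == 0L) stop("no edges left after merging")
  regnet(edges, nodes = nodes)
}

#' Reconnect disjoint sub-networks of a regulatory core
#'
#' Motif merging usually leaves several disjoint sub-networks. This adds *all*
#' direct interactions from the full network whose endpoints lie in different
#' weak components of the core, labeling them as bridges. Optionally (off by
#' default), component pairs still unlinked after that are connected through
#' shortest length-2 paths of the full network, importing the intermediate
#' node.
#'
#' @param core a [regnet] (e.g. from [merge_motifs()]); its nodes must all
#'   exist in `full`.
#' @param full the complete [regnet].
#' @param add_length2 enable the length-2 fallback.
#' @return object of class `regulatory_core`: list with `network` (the
#'   reconnected [regnet]), `bridges` (data.frame of added edges) and
#'   `component_labels` (named integer vector: original sub-network id per
#'   node).
#' @export
connect_components <- function(core, full, add_length2 = FALSE) {
  missing <- setdiff(core$nodes$id, full$nodes$id)
  if (length(missing))
    stop("core node(s) absent from full network: ",
         paste(missing, collapse = ", "))
  g <- as_igraph(core)
  comp <- igraph::components(g, mode = "weak")$membership
  labels <- setNames(as.integer(comp), names(comp))
  edge_key <- function(e) paste(e$source, e$target, e$effect, sep = "\r")
  core_keys <- edge_key(core$interactions)
  bridges <- full$interactions[
    full$interactions$source %in% core$nodes$id &
    full$interactions$target %in% core$nodes$id, , drop = FALSE]
  bridges <- bridges[labels[bridges$source] != labels[bridges$target], ,
                     drop = FALSE]
  bridges <- bridges[!(edge_key(bridges) %in% core_keys), , drop = FALSE]
  edges <- rbind(core$interactions, bridges)
  nodes <- core$nodes
  if (add_length2) {
    # components still unlinked after direct bridging
    gb <- igraph::graph_from_data_frame(
      edges[, c("source", "target")], directed = FALSE,
      vertices = nodes$id)
    comp2 <- igraph::components(gb)$membership
    if (max(comp2) > 1L) {
      fi <- full$interactions
      for (x in setdiff(full$nodes$id, nodes$id)) {
        inc_in <- fi[fi$target == x & fi$source %in% nodes$id, , drop = FALSE]
        inc_out <- fi[fi$source == x & fi$target %in% nodes$id, , drop = FALSE]
        ends <- unique(c(inc_in$source, inc_out$target))
        if (length(unique(comp2[ends])) > 1L) {
          new_edges <- rbind(inc_in, inc_out)
          bridges <- rbind(bridges, new_edges)
          edges <- rbind(edges, new_edges)
          nodes <- rbind(nodes, full$nodes[full$nodes$id == x, , drop = FALSE])
        }
      }
    }
  }
  net <- suppressWarnings(regnet(edges, nodes = nodes))
  rownames(bridges) <- NULL
  structure(list(network = net, bridges = bridges,
                 component_labels = labels),
            class = "regulatory_core")
}

#' @export
print.regulatory_core <- function(x, ...) {
  cat("regulatory core: ", nrow(x$network$nodes), " nodes, ",
      nrow(x$network$interactions), " edges (",
      nrow(x$bridges), " bridges across ",
      max(x$component_labels), " original sub-network(s))\n", sep = "")
  invisible(x)
}

#' Export a regulatory core as an edge table with a bridge flag
#'
#' @param core a `regulatory_core`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_core <- function(core, path) {
  it <- core$network$interactions
  bk <- paste(core$bridges$source, core$bridges$target, core$bridges$effect,
              sep = "\r")
  it$bridge <- paste(it$source, it$target, it$effect, sep = "\r") %in% bk
  write.table(it, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
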