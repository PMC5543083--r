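#' Random walk with restart gene prioritization
#'
#' Scores every node by its proximity to a set of seed genes using the
#' stationary distribution of a random walk with restart: iterate
#' `p <- (1 - r) W p + r p0` until the L1 change drops below `tol`, where `W`
#' is the column-normalized transition operator and `p0` is uniform over the
#' seeds. By default the walk runs on the undirected skeleton of the signed
#' digraph (prioritization measures proximity, not regulation direction);
#' signs are ignored. Columns of `W` with no outgoing transition (dangling
#' nodes) redirect their mass to the restart vector, so unreachable nodes
#' score exactly zero and the result remains a probability vector.
#'
#' @param net a [regnet].
#' @param seeds character vector of seed node identifiers; at least one must
#'   be present in the network.
#' @param restart_prob restart probability `r` in (0, 1); default 0.7.
#' @param tol L1 convergence tolerance; default 1e-10.
#' @param directed walk on the directed graph instead of the undirected
#'   skeleton.
#' @param max_iter iteration cap.
#' @return named numeric vector of scores summing to 1.
#' @export
rwr_prioritize <- function(net, seeds, restart_prob = 0.7, tol = 1e-10,
                           directed = FALSE, max_iter = 10000L) {
  stopifnot(restart_prob > 0, restart_prob < 1)
  ids <- net$nodes$id
  seeds <- intersect(trimws(seeds), ids)
  if (length(seeds) == 0L) stop("no seed present in the network")
  g <- as_igraph(net, directed = directed, collapse = TRUE)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  if (!directed) A <- pmax(A, t(A))
  A <- A[ids, ids, drop = FALSE]
  colsum <- colSums(A)
  W <- A
  nz <- colsum > 0
  W[, nz] <- sweep(A[, nz, drop = FALSE], 2L, colsum[nz], "/")
  p0 <- setNames(numeric(length(ids)), ids)
  p0[seeds] <- 1 / length(seeds)
  p <- p0
  r <- restart_prob
  for (i in seq_len(max_iter)) {
    dangling_mass <- sum(p[!nz])
    p_new <- (1 - r) * (drop(W %*% p) + dangling_mass * p0) + r * p0
    if (sum(abs(p_new - p)) < tol) {
      p <- p_new
      break
    }
    p <- p_new
  }
  p / sum(p)
}

#' Read a GMT gene-set file
#'
#' GMT format: one set per line, `name <tab> description <tab> gene1 <tab> ...`.
#'
#' @param path file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("malformed GMT line: ", substr(l, 1, 60))
    trimws(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}

#' Flag disease-pathway membership
#'
#' Marks which network nodes belong to a disease gene set (e.g. a cancer
#' pathway membership list). Matching is exact string equality after
#' whitespace trimming; nodes absent from the set are `FALSE`.
#'
#' @param net a [regnet].
#' @param gene_set character vector of gene identifiers (non-empty).
#' @return named logical vector over all network nodes.
#' @export
flag_pathway_membership <- function(net, gene_set) {
  if (length(gene_set) == 0L) stop("gene set is empty")
  ids <- net$nodes$id
  setNames(ids %in% trimws(gene_set), ids)
}

#' Read an expression table
#'
#' TSV with gene identifiers in the first column and one column per sample.
#'
#' @param path file path.
#' @return numeric matrix, genes in rows.
#' @export
read_expression <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

#' Two-group expression fold-change contrast
#'
#' Per-gene log2 fold-change of the invasive group over the non-invasive
#' group: `fc = log2((mean_invasive + pc) / (mean_noninvasive + pc))`. This is
#' the plain contrast used by the motif ranking; precomputed tables from a
#' dedicated differential-expression tool can be substituted via
#' [read_fold_changes()].
#'
#' @param expr numeric matrix, genes in rows, samples in columns.
#' @param invasive,noninvasive character vectors of sample (column) names;
#'   both non-empty and present in `expr`.
#' @param pseudocount value added to both group means before the ratio.
#' @return data.frame with columns `gene`, `fc`, `abs_fc`.
#' @export
fold_change_contrast <- function(expr, invasive, noninvasive,
                                 pseudocount = 0) {
  stopifnot(length(invasive) > 0L, length(noninvasive) > 0L)
  missing <- setdiff(c(invasive, noninvasive), colnames(expr))
  if (length(missing))
    stop("sample(s) not in expression table: ", paste(missing, collapse = ", "))
  m_inv <- rowMeans(expr[, invasive, drop = FALSE])
  m_non <- rowMeans(expr[, noninvasive, drop = FALSE])
  fc <- log2((m_inv + pseudocount) / (m_non + pseudocount))
  data.frame(gene = rownames(expr), fc = unname(fc), abs_fc = abs(unname(fc)),
             stringsAsFactors = FALSE)
}

#' Read a precomputed fold-change table
#'
#' TSV with columns `gene` and `log2fc` (or a two-column file in that order),
#' e.g. output of an external differential-expression fit.
#'
#' @param path file path.
#' @return data.frame with columns `gene`, `fc`, `abs_fc`.
#' @export
read_fold_changes <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  gene_col <- if ("gene" %in% names(df)) "gene" else names(df)[1]
  fc_col <- if ("log2fc" %in% names(df)) "log2fc" else names(df)[2]
  data.frame(gene = as.character(df[[gene_col]]),
             fc = as.numeric(df[[fc_col]]),
             abs_fc = abs(as.numeric(df[[fc_col]])),
             stringsAsFactors = FALSE)
}

#' Packaged EMT marker gene list
#'
#' Default seed list for [rwr_prioritize()]: canonical epithelial and
#' mesenchymal transition markers. Shipped as an editable plain-text file in
#' `inst/extdata/emt_markers.txt` (one symbol per line, `#` comments).
#'
#' @return character vector of gene symbols.
#' @export
emt_markers <- function() {
  path <- system.file("extdata", "emt_markers.txt", package = "regcore")
  lines <- trimws(readLines(path, warn = FALSE))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}
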