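# Synthetic-data generators: random signed digraphs and two-group expression
# matrices with planted fold-changes, emulating the statistical structure the
# workflow consumes (a curated signed interaction map; a non-invasive vs
# invasive cell-line contrast). All generators are pure functions of their
# arguments and seed.

#' Random signed directed network
#'
#' Each ordered node pair (i != j) carries an edge independently with
#' probability `edge_prob`; effects are drawn as inhibition with probability
#' `inhibition_frac`, unknown with `unknown_frac`, activation otherwise.
#'
#' @param n_nodes number of nodes (labelled `n01`, `n02`, ...).
#' @param edge_prob edge probability in (0, 1).
#' @param inhibition_frac,unknown_frac effect fractions in `[0, 1]`
#'   (summing to at most 1).
#' @param seed RNG seed (mandatory).
#' @return a [regnet].
#' @export
random_signed_network <- function(n_nodes, edge_prob = 0.1,
                                  inhibition_frac = 0.3, unknown_frac = 0,
                                  seed) {
  stopifnot(n_nodes >= 1L, edge_prob > 0, edge_prob < 1,
            inhibition_frac >= 0, unknown_frac >= 0,
            inhibition_frac + unknown_frac <= 1)
  if (missing(seed)) stop("seed is required")
  ids <- sprintf("n%02d", seq_len(n_nodes))
  .with_seed(seed, function() {
    pairs <- expand.grid(source = ids, target = ids,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$source != pairs$target, , drop = FALSE]
    keep <- stats::runif(nrow(pairs)) < edge_prob
    pairs <- pairs[keep, , drop = FALSE]
    eff <- sample(.EFFECTS, nrow(pairs), replace = TRUE,
                  prob = c(1 - inhibition_frac - unknown_frac,
                           inhibition_frac, unknown_frac))
    pairs$effect <- eff
    if (nrow(pairs) == 0L)
      return(regnet(data.frame(source = character(0), target = character(0),
                               effect = character(0)),
                    nodes = data.frame(id = ids, category = "other")))
    regnet(pairs, nodes = data.frame(id = ids, category = "other",
                                     stringsAsFactors = FALSE))
  })
}

#' Two-group synthetic expression data with planted fold-changes
#'
#' Log-normal expression values: per gene and sample,
#' `2^(base_log2 + N(0, noise_sd) + planted_log2fc * [invasive])`. Genes named
#' in `planted_log2fc` are shifted by that amount (on the log2 scale) in the
#' invasive group; all other genes are null. Noise is log-normal rather than
#' count-based because the downstream contrast consumes group means only.
#'
#' @param genes character vector of gene names.
#' @param n_per_group samples per group (default 20).
#' @param planted_log2fc named numeric vector gene -> log2 fold-change.
#' @param noise_sd log2-scale within-group standard deviation (default 0.3,
#'   typical cell-line microarray variability).
#' @param base_log2 baseline log2 expression level.
#' @param seed RNG seed (mandatory).
#' @return list with `expr` (matrix genes x samples), `invasive`,
#'   `noninvasive` (column name vectors).
#' @export
synthetic_expression <- function(genes, n_per_group = 20L,
                                 planted_log2fc = NULL, noise_sd = 0.3,
                                 base_log2 = 6, seed) {
  stopifnot(n_per_group >= 1L, noise_sd >= 0)
  if (missing(seed)) stop("seed is required")
  .with_seed(seed, function() {
    ni <- paste0("inv_", seq_len(n_per_group))
    nn <- paste0("non_", seq_len(n_per_group))
    shift <- setNames(numeric(length(genes)), genes)
    if (!is.null(planted_log2fc)) {
      bad <- setdiff(names(planted_log2fc), genes)
      if (length(bad)) stop("planted gene(s) not in gene list: ",
                            paste(bad, collapse = ", "))
      shift[names(planted_log2fc)] <- planted_log2fc
    }
    log2val <- matrix(stats::rnorm(length(genes) * 2L * n_per_group,
                                   mean = base_log2, sd = noise_sd),
                      nrow = length(genes))
    log2val[, seq_len(n_per_group)] <-
      log2val[, seq_len(n_per_group)] + shift
    expr <- 2^log2val
    dimnames(expr) <- list(genes, c(ni, nn))
    list(expr = expr, invasive = ni, noninvasive = nn)
  })
}

#' Packaged bladder cancer EMT core logic model
#'
#' Three-layer logic model of the bladder cancer regulatory core: input layer
#' \{E2F1, TGFBR1, FGFR1, EGFR, CXCR1, RARA\} (64 input vectors), a Boolean
#' regulatory layer, and the multi-valued EMT output
#' `EMT = ((SMAD2/3/4 AND SNAI1) OR (ZEB1 AND TWIST1)) + (NOT CDH1) + FGFR1`.
#' The regulatory rules are a documented reconstruction constrained to
#' reproduce the published input-output table and perturbation outcomes; the
#' shipped rule file `inst/extdata/bladder_core_rules.txt` is the single
#' source of truth.
#'
#' @return a [logic_model].
#' @export
bladder_core_model <- function() {
  read_logic_model(system.file("extdata", "bladder_core_rules.txt",
                               package = "regcore"))
}

#' Packaged breast cancer EMT core logic model
#'
#' Input layer \{E2F1, TGFBR2, EGFR, HMMR, THRB, IL1R1, RARA\} (128 input
#' vectors); output
#' `EMT = (SNAI1 AND SNAI2 AND FN1 AND SRC) + (NOT CDH1) + EGFR`.
#' Reconstruction notes as for [bladder_core_model()]; rule file
#' `inst/extdata/breast_core_rules.txt`.
#'
#' @return a [logic_model].
#' @export
breast_core_model <- function() {
  read_logic_model(system.file("extdata", "breast_core_rules.txt",
                               package = "regcore"))
}
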