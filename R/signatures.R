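#' Collapse an input sweep into equivalence classes
#'
#' An input is *influential* if there is at least one context in which
#' toggling it alone changes the phenotype (decided exactly, by full-sweep
#' comparison). Input vectors differing only in non-influential (free) inputs
#' form an equivalence class and share one phenotype level, so a 2^m sweep
#' collapses to one row per combination of influential inputs.
#'
#' @param sweep an `input_sweep` from [enumerate_input_space()], covering the
#'   full input space.
#' @return data.frame of class `equivalence_classes`: one 0/1 column per
#'   influential input plus `class_size` and `phenotype`; free input names in
#'   `attr(, "free_inputs")`.
#' @export
collapse_equivalence_classes <- function(sweep) {
  inputs <- attr(sweep, "inputs")
  m <- length(inputs)
  if (nrow(sweep) != 2^m || anyDuplicated(sweep[, inputs, drop = FALSE]))
    stop("sweep must cover the full input space exactly once")
  pheno <- sweep$phenotype
  influential <- vapply(inputs, function(i) {
    others <- setdiff(inputs, i)
    key <- do.call(paste, c(sweep[, others, drop = FALSE], sep = "\r"))
    any(vapply(split(pheno, key), function(lv) length(unique(lv)) > 1L,
               logical(1)))
  }, logical(1))
  infl <- inputs[influential]
  free <- inputs[!influential]
  if (length(infl) == 0L) {
    out <- data.frame(class_size = nrow(sweep), phenotype = pheno[1])
  } else {
    key <- do.call(paste, c(sweep[, infl, drop = FALSE], sep = "\r"))
    groups <- split(seq_len(nrow(sweep)), key)
    out <- do.call(rbind, lapply(groups, function(ix) {
      lv <- unique(pheno[ix])
      stopifnot(length(lv) == 1L)   # guaranteed by the influence definition
      cbind(sweep[ix[1], infl, drop = FALSE],
            data.frame(class_size = length(ix), phenotype = lv))
    }))
    out <- out[do.call(order, out[, infl, drop = FALSE]), , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("equivalence_classes", "data.frame")
  attr(out, "influential") <- infl
  attr(out, "free_inputs") <- free
  out
}

#' Extract the driver signature of a phenotype
#'
#' The driver signature is the set of influential inputs together with the
#' direction (`high`/`low`) they take in the equivalence class attaining the
#' maximal phenotype level. When that class is unique (as for the packaged
#' tumor models, where joint activation of the three driver receptors yields
#' the top level) the result is the minimal input set whose states pin down
#' the most aggressive phenotype; tied maximal classes are all reported, with
#' a `tied` attribute.
#'
#' @param classes an `equivalence_classes` table.
#' @return data.frame with columns `input`, `direction` (and a `class` column
#'   when maximal classes tie); empty for constant-output models.
#' @export
extract_driver_signature <- function(classes) {
  infl <- attr(classes, "influential")
  if (length(infl) == 0L) {
    out <- data.frame(input = character(0), direction = character(0))
    attr(out, "tied") <- FALSE
    return(out)
  }
  top <- which(classes$phenotype == max(classes$phenotype))
  sig_of <- function(row_ix)
    data.frame(input = infl,
               direction = ifelse(unlist(classes[row_ix, infl]) == 1,
                                  "high", "low"),
               stringsAsFactors = FALSE, row.names = NULL)
  if (length(top) == 1L) {
    out <- sig_of(top)
    attr(out, "tied") <- FALSE
  } else {
    out <- do.call(rbind, lapply(seq_along(top), function(k)
      cbind(class = k, sig_of(top[k]))))
    attr(out, "tied") <- TRUE
  }
  out
}

# run fn with a temporary RNG state seeded by `seed`
.with_seed <- function(seed, fn) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  fn()
}

#' Random signature controls
#'
#' Draws `count` distinct random node subsets of the given size from a
#' regulatory core and arbitrarily labels each member high or low — the null
#' ensemble against which a predicted driver signature's discriminative power
#' is compared on cohort data (that comparison itself is external to this
#' package).
#'
#' @param core a `regulatory_core`, [regnet], or character vector of node
#'   identifiers.
#' @param count number of signatures.
#' @param size nodes per signature (<= number of core nodes).
#' @param seed RNG seed (mandatory: output is reproducible for a fixed seed).
#' @return data.frame with columns `signature` (index), `gene`, `direction`.
#' @export
random_signatures <- function(core, count = 30L, size = 3L, seed) {
  ids <- if (inherits(core, "regulatory_core")) core$network$nodes$id
         else if (inherits(core, "regnet")) core$nodes$id
         else as.character(core)
  if (size > length(ids))
    stop("size exceeds the number of core nodes (", length(ids), ")")
  if (missing(seed)) stop("seed is required")
  .with_seed(seed, function() {
    seen <- character(0)
    out <- vector("list", count)
    guard <- 0L
    k <- 1L
    while (k <= count) {
      genes <- sort(sample(ids, size))
      key <- paste(genes, collapse = "\r")
      guard <- guard + 1L
      if (guard > 1000L * count)
        stop("cannot draw ", count, " distinct subsets of size ", size)
      if (key %in% seen) next
      seen <- c(seen, key)
      out[[k]] <- data.frame(signature = k, gene = genes,
                             direction = sample(c("high", "low"), size,
                                                replace = TRUE),
                             stringsAsFactors = FALSE)
      k <- k + 1L
    }
    do.call(rbind, out)
  })
}
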