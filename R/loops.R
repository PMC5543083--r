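#' Classify the sign of a feedback loop
#'
#' A loop is `negative` if it contains an odd number of inhibitory edges and no
#' edge of unknown effect, `positive` for an even number of inhibitions (again
#' with no unknown edge), and `neutral` as soon as any edge has unknown effect.
#'
#' @param effects character vector of edge effects along the cycle.
#' @return `"positive"`, `"negative"` or `"neutral"`.
#' @export
classify_loop_sign <- function(effects) {
  stopifnot(all(effects %in% .EFFECTS))
  if (any(effects == "unknown")) return("neutral")
  if (sum(effects == "inhibition") %% 2L == 1L) "negative" else "positive"
}

# canonical rotation: start cycle at its lexicographically smallest node
.canonical_rotation <- function(nodes, effects) {
  k <- which(nodes == min(nodes))[1L]   # unique: cycles are simple
  if (k > 1L) {
    idx <- c(k:length(nodes), seq_len(k - 1L))
    nodes <- nodes[idx]
    effects <- effects[idx]
  }
  list(nodes = nodes, effects = effects)
}

#' Enumerate signed feedback loops
#'
#' Finds every simple directed cycle of length up to `max_length` (default 3,
#' the convention for regulatory-motif analysis: longer loops are typically
#' composed of shorter ones). Each cycle is reported exactly once under a
#' rotation-invariant canonical key; parallel edges with different effects
#' between the same node pair generate distinct loops, so sign classes are
#' preserved. Output order is deterministic (sorted by canonical key).
#'
#' @param net a [regnet].
#' @param max_length maximum cycle length (>= 1). Self-loops (length 1) are
#'   enumerated; downstream ranking excludes them by default.
#' @return data.frame of class `feedback_loops` with columns `key`, `length`,
#'   `sign`, `nodes` (`"A>B>C"`), `effects` (`"activation>..."`).
#' @export
enumerate_feedback_loops <- function(net, max_length = 3L) {
  stopifnot(max_length >= 1L)
  it <- net$interactions
  out <- list()
  add_loop <- function(nodes, effects) {
    cn <- .canonical_rotation(nodes, effects)
    key <- paste(paste(cn$nodes, collapse = ">"),
                 paste(substr(cn$effects, 1L, 1L), collapse = ""), sep = "#")
    out[[length(out) + 1L]] <<- data.frame(
      key = key, length = length(nodes),
      sign = classify_loop_sign(cn$effects),
      nodes = paste(cn$nodes, collapse = ">"),
      effects = paste(cn$effects, collapse = ">"),
      stringsAsFactors = FALSE)
  }
  if (nrow(it) > 0L) {
    # out-edge index: for each source, rows of (target, effect)
    by_src <- split(seq_len(nrow(it)), it$source)
    nodes <- sort(net$nodes$id)
    # DFS anchored at the smallest node of each cycle: only visit nodes > anchor
    dfs <- function(anchor, path, effects) {
      last <- path[length(path)]
      for (i in by_src[[last]]) {
        tgt <- it$target[i]
        eff <- it$effect[i]
        if (tgt == anchor && length(path) >= 1L) {
          add_loop(path, c(effects, eff))
        } else if (length(path) < max_length && tgt > anchor &&
                   !(tgt %in% path)) {
          dfs(anchor, c(path, tgt), c(effects, eff))
        }
      }
    }
    for (a in nodes) if (!is.null(by_src[[a]])) dfs(a, a, character(0))
  }
  if (length(out) == 0L) {
    res <- data.frame(key = character(0), length = integer(0),
                      sign = character(0), nodes = character(0),
                      effects = character(0), stringsAsFactors = FALSE)
  } else {
    res <- do.call(rbind, out)
    res <- res[order(res$key), , drop = FALSE]
    rownames(res) <- NULL
  }
  class(res) <- c("feedback_loops", "data.frame")
  res
}

#' Node identifiers of each loop
#' @param loops a `feedback_loops` data.frame.
#' @return list of character vectors.
#' @export
loop_nodes <- function(loops) strsplit(loops$nodes, ">", fixed = TRUE)

#' Write a loop table to TSV
#' @param loops a `feedback_loops` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_loops <- function(loops, path) {
  write.table(as.data.frame(loops), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @export
print.feedback_loops <- function(x, ...) {
  cat("feedback loops: ", nrow(x), " total (",
      sum(x$sign == "positive"), " positive, ",
      sum(x$sign == "negative"), " negative, ",
      sum(x$sign == "neutral"), " neutral)\n", sep = "")
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 10L))
  invisible(x)
}
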