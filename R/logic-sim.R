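#' Evaluate the multi-valued phenotype rule on a state
#'
#' Ordinal phenotype level = sum of the model's Boolean factor expressions
#' evaluated on `state` (for the packaged EMT models: 0 = no EMT to 3 = high
#' EMT).
#'
#' @param state named 0/1 (or logical) vector defining every marker the
#'   phenotype rule references.
#' @param model a [logic_model] with a phenotype rule.
#' @return integer level.
#' @export
evaluate_phenotype <- function(state, model) {
  if (is.null(model$phenotype)) stop("model has no phenotype rule")
  needed <- unique(unlist(lapply(model$phenotype, `[[`, "vars")))
  miss <- setdiff(needed, names(state))
  if (length(miss))
    stop("state is missing marker(s): ", paste(miss, collapse = ", "))
  .state <- as.list(as.logical(state))
  names(.state) <- names(state)
  sum(vapply(model$phenotype, function(f) as.integer(f$fun(.state)),
             integer(1)))
}

.normalize_clamps <- function(clamps) {
  if (is.null(clamps) || length(clamps) == 0L) return(NULL)
  v <- as.integer(unlist(clamps))
  names(v) <- names(clamps)
  if (is.null(names(v)) || any(!nzchar(names(v))))
    stop("clamps must be a named vector of 0/1 values")
  if (!all(v %in% c(0L, 1L))) stop("clamp values must be 0 or 1")
  v
}

#' Synchronous attractor of a logic model
#'
#' Runs deterministic synchronous updates from the initial state (inputs
#' clamped to `input`; regulatory nodes start at `init`, default 0) until a
#' fixed point or a revisited state. Clamped nodes (perturbations) are never
#' updated. A fixed point satisfies `X = BF(X)` for every unclamped
#' regulatory node; cycles are reported with per-state phenotype levels, not
#' aggregated.
#'
#' @param model a [logic_model].
#' @param input named 0/1 vector covering exactly the input layer.
#' @param clamps optional named 0/1 vector of clamped nodes (knockout = 0,
#'   constitutive activation = 1); overrides inputs and rules.
#' @param init initial value of unclamped regulatory nodes (0 or 1).
#' @return object of class `sim_result`: list with `input`, `clamps`, `type`
#'   (`"fixed"` or `"cycle"`), `states` (matrix, one row per attractor
#'   state), `phenotype` (level for fixed points, `NA` for cycles),
#'   `levels` (per-state levels) and `steps`.
#' @export
steady_state <- function(model, input, clamps = NULL, init = 0L) {
  input <- setNames(as.integer(unlist(input)), names(input))
  if (!setequal(names(input), model$inputs) ||
      length(input) != length(model$inputs))
    stop("input must cover exactly the model's input nodes")
  if (!all(input %in% c(0L, 1L))) stop("input values must be 0 or 1")
  clamps <- .normalize_clamps(clamps)
  all_nodes <- c(model$inputs, model$regulatory)
  if (!is.null(clamps)) {
    bad <- setdiff(names(clamps), all_nodes)
    if (length(bad)) stop("clamp targets unknown node(s): ",
                          paste(bad, collapse = ", "))
  }
  state <- setNames(integer(length(all_nodes)), all_nodes)
  state[model$inputs] <- input[model$inputs]
  state[model$regulatory] <- as.integer(init)
  if (!is.null(clamps)) state[names(clamps)] <- clamps
  free_reg <- setdiff(model$regulatory, names(clamps))
  rules <- model$rules[free_reg]
  max_steps <- min(2^length(free_reg), 100000L) + 1L
  seen <- new.env(parent = emptyenv(), hash = TRUE)
  trace <- list()
  step <- 0L
  repeat {
    key <- paste(state, collapse = "")
    prev <- get0(key, envir = seen)
    if (!is.null(prev)) {
      cycle_states <- do.call(rbind, trace[prev:length(trace)])
      type <- if (nrow(cycle_states) == 1L) "fixed" else "cycle"
      break
    }
    assign(key, length(trace) + 1L, envir = seen)
    trace[[length(trace) + 1L]] <- state
    new_state <- state
    .state <- as.list(state == 1L)
    for (nm in free_reg)
      new_state[[nm]] <- as.integer(rules[[nm]]$fun(.state))
    step <- step + 1L
    if (step > max_steps) stop("state-space guard exceeded")  # unreachable
    state <- new_state
  }
  levels <- if (is.null(model$phenotype)) rep(NA_integer_, nrow(cycle_states))
            else apply(cycle_states, 1L, evaluate_phenotype, model = model)
  structure(list(input = input, clamps = clamps, type = type,
                 states = cycle_states,
                 phenotype = if (type == "fixed") levels[1] else NA_integer_,
                 levels = as.integer(levels), steps = step),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("attractor: ", x$type, sep = "")
  if (x$type == "fixed") cat(", phenotype level ", x$phenotype, sep = "")
  else cat(" of length ", nrow(x$states), ", per-state levels ",
           paste(x$levels, collapse = ","), sep = "")
  cat(" (", x$steps, " update steps)\n", sep = "")
  invisible(x)
}

#' Exhaustive input-space sweep
#'
#' Simulates the model for every Boolean combination of the input layer (2^m
#' vectors, in lexicographic order with the first input as the most
#' significant bit).
#'
#' @param model a [logic_model] with at most 20 inputs.
#' @param clamps optional perturbation applied to every simulation.
#' @return data.frame of class `input_sweep`: one 0/1 column per input plus
#'   `type` and `phenotype` (`NA` for cyclic attractors).
#' @export
enumerate_input_space <- function(model, clamps = NULL) {
  m <- length(model$inputs)
  if (m > 20L)
    stop("more than 20 inputs (2^m explodes); sample the input space instead")
  grid <- if (m == 0L) data.frame(row.names = 1L) else
    expand.grid(rev(replicate(m, 0:1, simplify = FALSE)),
                KEEP.OUT.ATTRS = FALSE)[, m:1, drop = FALSE]
  names(grid) <- model$inputs
  res <- lapply(seq_len(nrow(grid)), function(i) {
    sim <- steady_state(model, setNames(as.integer(grid[i, ]), model$inputs),
                        clamps = clamps)
    data.frame(type = sim$type, phenotype = sim$phenotype)
  })
  out <- cbind(grid, do.call(rbind, res))
  rownames(out) <- NULL
  class(out) <- c("input_sweep", "data.frame")
  attr(out, "inputs") <- model$inputs
  out
}

.clamp_label <- function(clamps) {
  if (is.null(clamps) || length(clamps) == 0L) return("baseline")
  paste(paste0(names(clamps), "=", clamps), collapse = "+")
}

#' Single and double perturbation scan
#'
#' Starting from the fixed point reached under `base_input`, applies every
#' single and (for `max_order = 2`) every unordered pair of clamped
#' perturbations of regulatory-layer nodes, in both modes per target
#' (knockout = clamp 0, activation = clamp 1), and reports the resulting
#' phenotype and its reduction relative to baseline, sorted by reduction
#' (descending). Cyclic attractors are flagged with `type = "cycle"` and an
#' `NA` phenotype.
#'
#' @param model a [logic_model] with a phenotype rule.
#' @param base_input named 0/1 vector over the input layer; must yield a
#'   fixed point.
#' @param max_order 1 or 2.
#' @return data.frame of class `perturbation_table` with columns `label`,
#'   `order`, `type`, `phenotype`, `reduction`.
#' @export
perturbation_scan <- function(model, base_input, max_order = 2L) {
  stopifnot(max_order %in% 1:2)
  base <- steady_state(model, base_input)
  if (base$type != "fixed")
    stop("base input does not yield a fixed point")
  baseline <- base$phenotype
  clamp_sets <- list(NULL)
  reg <- model$regulatory
  for (nm in reg) for (v in 0:1)
    clamp_sets[[length(clamp_sets) + 1L]] <- setNames(v, nm)
  if (max_order >= 2L && length(reg) >= 2L) {
    pairs <- utils::combn(reg, 2L, simplify = FALSE)
    for (p in pairs) for (v1 in 0:1) for (v2 in 0:1)
      clamp_sets[[length(clamp_sets) + 1L]] <- setNames(c(v1, v2), p)
  }
  rows <- lapply(clamp_sets, function(cl) {
    sim <- steady_state(model, base_input, clamps = cl)
    data.frame(label = .clamp_label(cl),
               order = length(cl),
               type = sim$type,
               phenotype = sim$phenotype,
               reduction = baseline - sim$phenotype,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-ifelse(is.na(out$reduction), -Inf, out$reduction),
                   out$label), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("perturbation_table", "data.frame")
  attr(out, "baseline") <- baseline
  out
}

#' Look up one perturbation in a scan table
#'
#' @param scan a `perturbation_table`.
#' @param clamps named 0/1 vector identifying the row (order-insensitive).
#' @return the matching row.
#' @export
perturbation_result <- function(scan, clamps = NULL) {
  clamps <- .normalize_clamps(clamps)
  if (!is.null(clamps)) clamps <- clamps[order(names(clamps))]
  labels <- vapply(strsplit(scan$label, "+", fixed = TRUE), function(parts) {
    parts <- sort(parts)
    paste(parts, collapse = "+")
  }, character(1))
  hit <- which(labels == .clamp_label(clamps))
  if (length(hit) == 0L) stop("perturbation not present in scan")
  scan[hit[1], , drop = FALSE]
}
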