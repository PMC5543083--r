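# Independent oracles and small fixture builders used across the suite.

# build a regnet from parallel vectors
mknet <- function(source, target, effect, nodes = NULL) {
  regnet(data.frame(source = source, target = target, effect = effect,
                    stringsAsFactors = FALSE), nodes = nodes)
}

# --- betweenness oracle ------------------------------------------------------
# Directed unnormalized betweenness from first principles: Floyd-Warshall
# distances, shortest-path counts by distance-ordered dynamic programming,
# and the pair-sum definition sum_{s!=t} sigma_st(v) / sigma_st.
oracle_betweenness <- function(net) {
  ids <- net$nodes$id
  n <- length(ids)
  A <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  it <- net$interactions
  for (i in seq_len(nrow(it))) A[it$source[i], it$target[i]] <- TRUE
  diag(A) <- FALSE
  D <- matrix(Inf, n, n)
  D[A] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  N <- matrix(0, n, n)
  diag(N) <- 1
  for (s in seq_len(n)) {
    for (t in order(D[s, ])) {
      if (t == s || !is.finite(D[s, t])) next
      preds <- which(A[, t] & D[s, ] == D[s, t] - 1)
      N[s, t] <- sum(N[s, preds])
    }
  }
  btw <- stats::setNames(numeric(n), ids)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t || !is.finite(D[s, t])) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
          D[s, v] + D[v, t] == D[s, t])
        btw[v] <- btw[v] + N[s, v] * N[v, t] / N[s, t]
    }
  }
  btw
}

# --- feedback-loop oracle ----------------------------------------------------
# Exhaustive test of every node (self-loop), node pair and node triple for
# cyclic closure, expanded over parallel-edge effect variants. Returns the
# canonical keys in regcore's format.
oracle_loop_keys <- function(net, max_length = 3L) {
  it <- net$interactions
  ids <- sort(net$nodes$id)
  rows_between <- function(a, b) which(it$source == a & it$target == b)
  key_of <- function(nodes, effects)
    paste(paste(nodes, collapse = ">"),
          paste(substr(effects, 1, 1), collapse = ""), sep = "#")
  keys <- character(0)
  for (a in ids)
    for (i in rows_between(a, a))
      keys <- c(keys, key_of(a, it$effect[i]))
  if (max_length >= 2L && length(ids) >= 2L) {
    for (ab in utils::combn(ids, 2L, simplify = FALSE)) {
      a <- ab[1]; b <- ab[2]
      for (i in rows_between(a, b)) for (j in rows_between(b, a))
        keys <- c(keys, key_of(c(a, b), c(it$effect[i], it$effect[j])))
    }
  }
  if (max_length >= 3L && length(ids) >= 3L) {
    for (abc in utils::combn(ids, 3L, simplify = FALSE)) {
      a <- abc[1]
      for (perm in list(c(abc[2], abc[3]), c(abc[3], abc[2]))) {
        b <- perm[1]; c_ <- perm[2]
        for (i in rows_between(a, b)) for (j in rows_between(b, c_))
          for (k in rows_between(c_, a))
            keys <- c(keys, key_of(c(a, b, c_),
                                   c(it$effect[i], it$effect[j], it$effect[k])))
      }
    }
  }
  sort(keys)
}

# --- RWR closed-form oracle --------------------------------------------------
# Stationary distribution by direct linear solve: p = r (I - (1-r) W)^-1 p0.
# Valid when the undirected skeleton has no isolated node.
oracle_rwr <- function(net, seeds, r) {
  ids <- net$nodes$id
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  it <- net$interactions
  for (i in seq_len(nrow(it))) {
    A[it$source[i], it$target[i]] <- 1
    A[it$target[i], it$source[i]] <- 1
  }
  diag(A) <- 0
  stopifnot(all(colSums(A) > 0))
  W <- sweep(A, 2, colSums(A), "/")
  p0 <- stats::setNames(numeric(n), ids)
  p0[seeds] <- 1 / length(seeds)
  drop(r * solve(diag(n) - (1 - r) * W, p0))
}

# random connected test network: Erdos-Renyi edges plus a ring (so the
# undirected skeleton has no isolated node and the closed form applies)
random_ring_network <- function(n, p, seed) {
  net <- random_signed_network(n, edge_prob = p, inhibition_frac = 0.3,
                               seed = seed)
  ids <- net$nodes$id
  ring <- data.frame(source = ids, target = c(ids[-1], ids[1]),
                     effect = "activation", stringsAsFactors = FALSE)
  both <- rbind(net$interactions[, 1:3], ring)
  both <- both[!duplicated(paste(both$source, both$target, both$effect)), ]
  regnet(both, nodes = net$nodes)
}

# --- exhaustive attractor oracle --------------------------------------------
# Builds the complete 2^k synchronous state-transition table over the
# unclamped regulatory nodes and walks the functional graph from the initial
# state; independent of the trajectory-hashing logic under test.
oracle_attractor <- function(model, input, clamps = NULL, init = 0L) {
  free <- setdiff(model$regulatory, names(clamps))
  k <- length(free)
  fixed <- stats::setNames(as.integer(input[model$inputs]), model$inputs)
  if (!is.null(clamps)) fixed <- c(fixed, stats::setNames(as.integer(clamps),
                                                          names(clamps)))
  states <- as.matrix(expand.grid(replicate(k, 0:1, simplify = FALSE)))
  colnames(states) <- free
  enc <- function(v) sum(v * 2^(seq_along(v) - 1)) + 1
  trans <- integer(nrow(states))
  for (si in seq_len(nrow(states))) {
    full <- c(fixed, stats::setNames(as.integer(states[si, ]), free))
    .state <- as.list(full == 1L)
    nxt <- vapply(free, function(nm)
      as.integer(model$rules[[nm]]$fun(.state)), integer(1))
    trans[si] <- enc(nxt)
  }
  cur <- enc(stats::setNames(rep(as.integer(init), k), free))
  seen <- integer(0)
  while (!(cur %in% seen)) {
    seen <- c(seen, cur)
    cur <- trans[cur]
  }
  cyc <- seen[which(seen == cur):length(seen)]
  attr_states <- states[cyc, , drop = FALSE]
  full_states <- cbind(matrix(rep(fixed, each = length(cyc)),
                              nrow = length(cyc),
                              dimnames = list(NULL, names(fixed))),
                       attr_states)
  list(type = if (length(cyc) == 1L) "fixed" else "cycle",
       states = full_states[, c(model$inputs, model$regulatory), drop = FALSE])
}

# random logic model: k regulatory nodes with random 1-3-literal rules over
# inputs and regulatory nodes
random_logic_model <- function(n_inputs, n_reg, seed) {
  set.seed(seed)
  inputs <- paste0("I", seq_len(n_inputs))
  reg <- paste0("R", seq_len(n_reg))
  vars <- c(inputs, reg)
  rand_rule <- function() {
    k <- sample(1:3, 1)
    vs <- sample(vars, k)
    lits <- ifelse(stats::runif(k) < 0.3, paste("NOT", vs), vs)
    if (k == 1) return(lits)
    ops <- sample(c("AND", "OR"), k - 1, replace = TRUE)
    out <- lits[1]
    for (i in seq_len(k - 1)) out <- paste(out, ops[i], lits[i + 1])
    out
  }
  rules <- stats::setNames(lapply(reg, function(x) rand_rule()), reg)
  logic_model(inputs = inputs, rules = rules,
              phenotype = reg[1], output = "PHEN")
}

# canonical sorted edge table for network comparisons
sorted_edges <- function(net) {
  it <- net$interactions[, c("source", "target", "effect")]
  it <- it[order(it$source, it$target, it$effect), ]
  rownames(it) <- NULL
  it
}

# driver/base-input helpers for the packaged models
bladder_base <- function(active = c("E2F1", "TGFBR1", "FGFR1")) {
  v <- stats::setNames(rep(0L, 6), c("E2F1", "TGFBR1", "FGFR1", "EGFR",
                                     "CXCR1", "RARA"))
  v[active] <- 1L
  v
}
breast_base <- function(active = c("E2F1", "TGFBR2", "EGFR")) {
  v <- stats::setNames(rep(0L, 7), c("E2F1", "TGFBR2", "EGFR", "HMMR",
                                     "THRB", "IL1R1", "RARA"))
  v[active] <- 1L
  v
}
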