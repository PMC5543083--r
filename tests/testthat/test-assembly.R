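test_that("merging a single loop returns its own nodes and edges", {
  net <- mknet(c("A", "B", "C"), c("B", "C", "A"), rep("activation", 3))
  loops <- enumerate_feedback_loops(net)
  merged <- merge_motifs(loops)
  expect_equal(nrow(merged$nodes), 3L)
  expect_equal(sorted_edges(merged), sorted_edges(net))
})

test_that("shared edges appear once after merging", {
  net <- mknet(c("A", "B", "A", "B", "C"), c("B", "A", "C", "C", "A"),
               rep("activation", 5))
  loops <- enumerate_feedback_loops(net)   # A<->B, plus two triangles via C
  merged <- merge_motifs(loops)
  ek <- paste(merged$interactions$source, merged$interactions$target)
  expect_false(anyDuplicated(ek) > 0)
})

test_that("merged node/edge sets equal a brute-force set-union oracle", {
  for (s in 1:100) {
    net <- random_signed_network(sample(6:10, 1), edge_prob = 0.3,
                                 inhibition_frac = 0.3, seed = 4000 + s)
    loops <- enumerate_feedback_loops(net)
    loops <- loops[loops$length > 1L, ]
    if (nrow(loops) < 2L) next
    pick <- loops[sample(nrow(loops), min(4L, nrow(loops))), ]
    merged <- merge_motifs(pick)
    # oracle: accumulate unions directly from the loop strings
    nodes <- unique(unlist(strsplit(pick$nodes, ">", fixed = TRUE)))
    edges <- unique(unlist(lapply(seq_len(nrow(pick)), function(i) {
      nn <- strsplit(pick$nodes[i], ">", fixed = TRUE)[[1]]
      ee <- strsplit(pick$effects[i], ">", fixed = TRUE)[[1]]
      paste(nn, c(nn[-1], nn[1]), ee)
    })))
    expect_setequal(merged$nodes$id, nodes)
    expect_equal(nrow(merged$interactions), length(edges))
  }
})

test_that("phenotype-category nodes are excluded from merging", {
  full <- regnet(data.frame(source = c("A", "B", "B", "EMT"),
                            target = c("B", "A", "EMT", "B"),
                            effect = "activation"),
                 nodes = data.frame(id = c("A", "B", "EMT"),
                                    category = c("gene", "gene", "phenotype")))
  loops <- enumerate_feedback_loops(full)
  merged <- merge_motifs(loops, full = full)
  expect_false("EMT" %in% merged$nodes$id)
})

test_that("an already-connected core is returned unchanged with zero bridges", {
  full <- mknet(c("A", "B", "C"), c("B", "C", "A"), rep("activation", 3))
  core <- connect_components(full, full)
  expect_equal(nrow(core$bridges), 0L)
  expect_equal(sorted_edges(core$network), sorted_edges(full))
})

test_that("a single direct edge between two components becomes a bridge", {
  core <- mknet(c("A", "B", "C", "D"), c("B", "A", "D", "C"),
                rep("activation", 4))
  full <- regnet(rbind(core$interactions[, 1:3],
                       data.frame(source = "B", target = "C",
                                  effect = "inhibition")))
  out <- connect_components(core, full)
  expect_equal(nrow(out$bridges), 1L)
  expect_equal(out$bridges$source, "B")
  expect_equal(out$bridges$effect, "inhibition")
  g <- igraph::graph_from_data_frame(out$network$interactions[, 1:2],
                                     directed = FALSE)
  expect_true(igraph::is_connected(g))
  expect_equal(max(out$component_labels), 2L)
})

test_that("core nodes absent from the full network raise an error", {
  core <- mknet("X", "Y", "activation")
  full <- mknet("A", "B", "activation")
  expect_error(connect_components(core, full), "X")
})

test_that("reconnection achieves weak connectivity whenever the full network allows it, and is idempotent", {
  for (s in 1:40) {
    full <- random_signed_network(12, edge_prob = 0.25, seed = 5000 + s)
    loops <- enumerate_feedback_loops(full)
    loops <- loops[loops$length > 1L, ]
    if (nrow(loops) < 2L) next
    set.seed(s)
    pick <- loops[sample(nrow(loops), min(3L, nrow(loops))), ]
    core <- merge_motifs(pick)
    out <- connect_components(core, full)
    # oracle: is the core's node set weakly connected inside the full graph?
    gf <- igraph::graph_from_data_frame(full$interactions[, 1:2],
                                        directed = FALSE,
                                        vertices = full$nodes$id)
    sub <- igraph::induced_subgraph(gf, core$nodes$id)
    gc <- igraph::graph_from_data_frame(out$network$interactions[, 1:2],
                                        directed = FALSE,
                                        vertices = out$network$nodes$id)
    if (igraph::is_connected(sub)) expect_true(igraph::is_connected(gc))
    # idempotence: a second pass adds nothing
    again <- connect_components(out$network, full)
    expect_equal(nrow(again$network$interactions),
                 nrow(out$network$interactions))
    # no invented edges: everything is in full
    fk <- paste(full$interactions$source, full$interactions$target,
                full$interactions$effect)
    ck <- paste(out$network$interactions$source,
                out$network$interactions$target,
                out$network$interactions$effect)
    expect_true(all(ck %in% fk))
  }
})

test_that("length-2 fallback imports an intermediate node when enabled", {
  core <- mknet(c("A", "B", "C", "D"), c("B", "A", "D", "C"),
                rep("activation", 4))
  full <- regnet(rbind(core$interactions[, 1:3],
                       data.frame(source = c("B", "X"), target = c("X", "C"),
                                  effect = "activation")))
  plain <- connect_components(core, full)
  expect_equal(nrow(plain$bridges), 0L)
  out <- connect_components(core, full, add_length2 = TRUE)
  expect_true("X" %in% out$network$nodes$id)
  g <- igraph::graph_from_data_frame(out$network$interactions[, 1:2],
                                     directed = FALSE)
  expect_true(igraph::is_connected(g))
})

test_that("core export carries a bridge flag column", {
  core <- mknet(c("A", "B", "C", "D"), c("B", "A", "D", "C"),
                rep("activation", 4))
  full <- regnet(rbind(core$interactions[, 1:3],
                       data.frame(source = "B", target = "C",
                                  effect = "activation")))
  out <- connect_components(core, full)
  f <- tempfile(fileext = ".tsv")
  write_core(out, f)
  back <- utils::read.delim(f, stringsAsFactors = FALSE)
  expect_equal(sum(back$bridge), 1L)
})
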