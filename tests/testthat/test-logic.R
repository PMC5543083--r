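test_that("rule files parse, validate and round-trip through write/read", {
  model <- bladder_core_model()
  expect_equal(model$inputs,
               c("E2F1", "TGFBR1", "FGFR1", "EGFR", "CXCR1", "RARA"))
  expect_equal(model$output, "EMT")
  expect_length(model$phenotype, 3L)
  f <- tempfile(fileext = ".txt")
  write_logic_model(model, f)
  back <- read_logic_model(f)
  expect_equal(back$inputs, model$inputs)
  expect_equal(back$regulatory, model$regulatory)
  expect_equal(lapply(back$rules, `[[`, "text"),
               lapply(model$rules, `[[`, "text"))
})

test_that("malformed models are rejected with informative errors", {
  expect_error(logic_model(inputs = "A", rules = list(A = "A")),
               "disjoint")
  expect_error(logic_model(inputs = "A", rules = list(B = "A AND Z")),
               "Z")
  expect_error(logic_model(inputs = "A", rules = list(B = "A"),
                           phenotype = "B + QQ"), "QQ")
  expect_error(logic_model(inputs = "A", rules = list(B = "A AND (B")),
               "parenthesis")
})

test_that("Boolean rule templates are derived from structure and expression dominance", {
  # a node with a single activator gets the activator as its rule
  net1 <- mknet("A", "Y", "activation")
  m1 <- derive_boolean_rules(net1)
  out1 <- steady_state(m1, c(A = 1))
  expect_equal(unname(out1$states[1, "Y"]), 1L)
  expect_equal(unname(steady_state(m1, c(A = 0))$states[1, "Y"]), 0L)

  # E-Cadherin example: six inhibitors, only SNAI1 and TWIST1 upregulated
  inh <- c("SNAI1", "SNAI2", "TWIST1", "SRC", "miR-25", "MDM2")
  net2 <- mknet(inh, rep("CDH1", 6), rep("inhibition", 6))
  contrast <- data.frame(
    gene = c(inh, "CDH1"),
    fc = c(1.2, -1.0, 0.8, -0.5, -2.0, -0.3, -1.5))
  contrast$abs_fc <- abs(contrast$fc)
  m2 <- derive_boolean_rules(net2, contrast)
  expect_equal(m2$rules[["CDH1"]]$text, "NOT (SNAI1 AND TWIST1)")
  st <- steady_state(m2, stats::setNames(c(1, 0, 1, 1, 1, 1), inh))
  expect_equal(unname(st$states[1, "CDH1"]), 0L)  # both dominant repressors on
  st2 <- steady_state(m2, stats::setNames(c(1, 1, 0, 1, 1, 1), inh))
  expect_equal(unname(st2$states[1, "CDH1"]), 1L) # TWIST1 off: CDH1 stays on

  # overrides replace the template verbatim
  m3 <- derive_boolean_rules(net2, contrast,
                             overrides = list(CDH1 = "NOT SNAI2"))
  expect_equal(m3$rules[["CDH1"]]$text, "NOT SNAI2")
  expect_error(derive_boolean_rules(net2, contrast,
                                    overrides = list(NOPE = "SNAI1")), "NOPE")
  # a node with neither regulators nor override is an error
  net3 <- mknet("A", "B", "activation")
  expect_error(derive_boolean_rules(net3, inputs = character(0)),
               "no incoming edge")
})

test_that("fixed points satisfy X = BF(X) and clamps persist in the attractor", {
  set.seed(10)
  for (s in 1:25) {
    model <- random_logic_model(n_inputs = 2, n_reg = sample(3:8, 1),
                                seed = 6000 + s)
    input <- stats::setNames(sample(0:1, 2, TRUE), model$inputs)
    clamps <- if (s %% 2 == 0)
      stats::setNames(sample(0:1, 1), sample(model$regulatory, 1)) else NULL
    res <- steady_state(model, input, clamps = clamps)
    for (row in seq_len(nrow(res$states))) {
      st <- res$states[row, ]
      if (!is.null(clamps))
        expect_equal(unname(st[names(clamps)]), unname(clamps))
      if (res$type == "fixed") {
        .state <- as.list(st == 1L)
        for (nm in setdiff(model$regulatory, names(clamps)))
          expect_equal(unname(st[nm]),
                       as.integer(model$rules[[nm]]$fun(.state)))
      }
    }
  }
})

test_that("synchronous attractors equal the exhaustive state-transition-graph oracle", {
  for (s in 1:40) {
    model <- random_logic_model(n_inputs = 2, n_reg = sample(4:8, 1),
                                seed = 7000 + s)
    set.seed(s)
    input <- stats::setNames(sample(0:1, 2, TRUE), model$inputs)
    clamps <- if (s %% 3 == 0)
      stats::setNames(0L, sample(model$regulatory, 1)) else NULL
    res <- steady_state(model, input, clamps = clamps)
    orc <- oracle_attractor(model, input, clamps = clamps)
    expect_equal(res$type, orc$type)
    cols <- colnames(orc$states)
    canon <- function(m) {
      rows <- apply(m[, cols, drop = FALSE], 1, paste, collapse = "")
      sort(rows)
    }
    expect_equal(canon(res$states), canon(orc$states))
  }
})

test_that("cyclic attractors are reported with per-state phenotype levels", {
  model <- logic_model(inputs = "I", rules = list(A = "NOT A"),
                       phenotype = "A", output = "P")
  res <- steady_state(model, c(I = 0))
  expect_equal(res$type, "cycle")
  expect_equal(nrow(res$states), 2L)
  expect_true(is.na(res$phenotype))
  expect_setequal(res$levels, c(0L, 1L))
})

test_that("multi-valued phenotype evaluation follows the printed EMT function", {
  model <- bladder_core_model()
  lvl <- function(...) evaluate_phenotype(c(...), model)
  expect_equal(lvl(`SMAD2/3/4` = 1, SNAI1 = 1, ZEB1 = 0, TWIST1 = 0,
                   CDH1 = 0, FGFR1 = 1), 3L)
  expect_equal(lvl(`SMAD2/3/4` = 0, SNAI1 = 0, ZEB1 = 0, TWIST1 = 0,
                   CDH1 = 1, FGFR1 = 0), 0L)
  expect_equal(lvl(`SMAD2/3/4` = 0, SNAI1 = 0, ZEB1 = 1, TWIST1 = 1,
                   CDH1 = 1, FGFR1 = 0), 1L)
  expect_error(lvl(CDH1 = 1), "missing marker")
})

test_that("input-space enumeration covers 2^m vectors in lexicographic order", {
  bm <- bladder_core_model()
  sw <- enumerate_input_space(bm)
  expect_equal(nrow(sw), 64L)
  expect_equal(unname(unlist(sw[1, bm$inputs])), rep(0L, 6))
  expect_equal(unname(unlist(sw[64, bm$inputs])), rep(1L, 6))
  expect_equal(sw$E2F1, rep(0:1, each = 32))

  rm <- breast_core_model()
  expect_equal(nrow(enumerate_input_space(rm)), 128L)

  m0 <- logic_model(inputs = character(0), rules = list(A = "NOT A OR A"),
                    phenotype = "A", output = "P")
  expect_equal(nrow(enumerate_input_space(m0)), 1L)

  big <- logic_model(inputs = paste0("I", 1:21),
                     rules = list(A = "I1"), phenotype = "A", output = "P")
  expect_error(enumerate_input_space(big), "sample")
})

test_that("the bladder model reproduces the published steady states", {
  bm <- bladder_core_model()
  expect_equal(steady_state(bm, bladder_base(character(0)))$phenotype, 0L)
  expect_equal(steady_state(bm, bladder_base())$phenotype, 3L)
  # phenotype equals the number of active drivers for every input vector
  sw <- enumerate_input_space(bm)
  expect_true(all(sw$type == "fixed"))
  expect_equal(sw$phenotype, rowSums(sw[, c("E2F1", "TGFBR1", "FGFR1")]))
})

test_that("the breast model reproduces the published steady-state pattern", {
  rm <- breast_core_model()
  sw <- enumerate_input_space(rm)
  expect_true(all(sw$type == "fixed"))
  expect_equal(sw$phenotype, rowSums(sw[, c("E2F1", "TGFBR2", "EGFR")]))
  expect_equal(steady_state(rm, breast_base())$phenotype, 3L)
})

test_that("perturbation scans reproduce the published double-perturbation rescues", {
  bm <- bladder_core_model()
  scan <- perturbation_scan(bm, bladder_base())
  expect_equal(attr(scan, "baseline"), 3L)
  expect_equal(perturbation_result(scan, NULL)$phenotype, 3L)
  # every published bladder rescue reduces EMT from 3 to 1
  rescues <- list(c(ZEB1 = 0, SNAI1 = 0), c(ZEB1 = 0, TWIST1 = 0),
                  c(ZEB1 = 0, NFKB1 = 0), c(ZEB1 = 0, CDH1 = 1),
                  stats::setNames(c(0, 0), c("SMAD2/3/4", "TWIST1")),
                  stats::setNames(c(0, 0), c("SMAD2/3/4", "NFKB1")))
  for (cl in rescues)
    expect_equal(perturbation_result(scan, cl)$phenotype, 1L)

  rmod <- breast_core_model()
  scan2 <- perturbation_scan(rmod, breast_base())
  targets <- c("SRC", "FN1", "SNAI1", "SNAI2")
  for (p in utils::combn(targets, 2, simplify = FALSE))
    expect_equal(perturbation_result(scan2,
                                     stats::setNames(c(0, 0), p))$phenotype, 1L)
  for (x in targets)
    expect_equal(perturbation_result(scan2,
                                     stats::setNames(c(1, 0),
                                                     c("CDH1", x)))$phenotype, 1L)
  # table is sorted by reduction, baseline included, order <= 2
  expect_true(all(diff(scan$reduction[!is.na(scan$reduction)]) <= 0))
  expect_true(all(scan$order <= 2L))
})

test_that("perturbations do not propagate upstream on a feed-forward chain", {
  model <- logic_model(inputs = "I",
                       rules = list(B = "I", C = "B", D = "C"),
                       phenotype = "D", output = "P")
  base <- steady_state(model, c(I = 1))
  pert <- steady_state(model, c(I = 1), clamps = c(D = 0))
  for (nm in c("B", "C"))
    expect_equal(unname(pert$states[1, nm]), unname(base$states[1, nm]))
})
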