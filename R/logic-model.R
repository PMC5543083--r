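# ---- Boolean expression parsing --------------------------------------------
#
# Rule dialect: identifiers (gene symbols; '/', '.', '-', ':' allowed so names
# like SMAD2/3/4 or miR-25 are single tokens), operators AND / OR / NOT,
# parentheses. The multi-valued phenotype rule is a sum of Boolean factor
# expressions joined by top-level '+'.

.TOKEN_RE <- "\\(|\\)|\\+|[A-Za-z0-9_./:-]+"

.tokenize <- function(text) {
  m <- gregexpr(.TOKEN_RE, text)[[1]]
  toks <- regmatches(text, list(m))[[1]]
  residue <- gsub(.TOKEN_RE, "", text)
  if (grepl("[^[:space:]]", residue))
    stop("unexpected character(s) in expression: ",
         gsub("[[:space:]]", "", residue))
  toks
}

# recursive-descent parser; returns list(code = R code string, vars)
.parse_bool <- function(toks) {
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  vars <- character(0)
  parse_expr <- function() {
    out <- parse_term()
    while (identical(toupper(peek()), "OR")) {
      take()
      out <- paste0("(", out, " | ", parse_term(), ")")
    }
    out
  }
  parse_term <- function() {
    out <- parse_factor()
    while (identical(toupper(peek()), "AND")) {
      take()
      out <- paste0("(", out, " & ", parse_factor(), ")")
    }
    out
  }
  parse_factor <- function() {
    t <- take()
    if (is.na(t)) stop("unexpected end of expression")
    if (toupper(t) == "NOT") return(paste0("(!", parse_factor(), ")"))
    if (t == "(") {
      out <- parse_expr()
      if (!identical(take(), ")")) stop("missing closing parenthesis")
      return(out)
    }
    if (t %in% c(")", "+")) stop("unexpected token '", t, "'")
    vars <<- union(vars, t)
    sprintf('.state[["%s"]]', t)
  }
  code <- parse_expr()
  if (pos <= length(toks))
    stop("trailing token(s): ", paste(toks[pos:length(toks)], collapse = " "))
  list(code = code, vars = vars)
}

# compile one Boolean expression into list(text, vars, fun)
.compile_rule <- function(text) {
  parsed <- .parse_bool(.tokenize(text))
  fn <- eval(parse(text = paste0("function(.state) ", parsed$code)),
             envir = baseenv())
  list(text = trimws(text), vars = parsed$vars, fun = fn)
}

# split a phenotype rule at top-level '+' into factor expressions
.split_factors <- function(text) {
  toks <- .tokenize(text)
  depth <- 0L
  cuts <- integer(0)
  for (i in seq_along(toks)) {
    if (toks[[i]] == "(") depth <- depth + 1L
    else if (toks[[i]] == ")") depth <- depth - 1L
    else if (toks[[i]] == "+" && depth == 0L) cuts <- c(cuts, i)
  }
  bounds <- c(0L, cuts, length(toks) + 1L)
  lapply(seq_len(length(bounds) - 1L), function(k)
    toks[seq.int(bounds[k] + 1L, bounds[k + 1L] - 1L)])
}

# ---- Logic model ------------------------------------------------------------

#' Construct a three-layer logic model
#'
#' A logic model has a clamped Boolean input layer, a regulatory layer of
#' Boolean update rules `X_i(t+1) = BF(X(t))`, and a single multi-valued
#' output node whose ordinal level is the sum of Boolean factor expressions
#' (multi-valued logic is confined to the output; every other node is strictly
#' Boolean).
#'
#' @param inputs character vector of input node names (clamped; no rules).
#' @param rules named list/character vector: regulatory node -> Boolean rule
#'   text over declared nodes (`AND`/`OR`/`NOT`/parentheses).
#' @param phenotype phenotype rule text: Boolean factor expressions joined by
#'   top-level `+` (ordinal level = sum of factors), or `NULL` for a model
#'   without an output layer.
#' @param output name of the output node (default `"EMT"`).
#' @return object of class `logic_model`.
#' @export
logic_model <- function(inputs, rules, phenotype = NULL, output = "EMT") {
  inputs <- as.character(inputs)
  rules <- as.list(rules)
  regulatory <- names(rules)
  if (is.null(regulatory) || any(!nzchar(regulatory)))
    stop("rules must be a named list")
  if (length(intersect(inputs, regulatory)))
    stop("layers must be disjoint; input nodes cannot carry rules: ",
         paste(intersect(inputs, regulatory), collapse = ", "))
  if (output %in% c(inputs, regulatory))
    stop("output node must not appear in the input or regulatory layer")
  compiled <- lapply(rules, function(r)
    if (is.character(r)) .compile_rule(r) else r)
  declared <- c(inputs, regulatory)
  for (nm in regulatory) {
    undeclared <- setdiff(compiled[[nm]]$vars, declared)
    if (length(undeclared))
      stop("rule for ", nm, " references undeclared node(s): ",
           paste(undeclared, collapse = ", "))
  }
  pheno <- NULL
  if (!is.null(phenotype)) {
    factor_toks <- .split_factors(phenotype)
    pheno <- lapply(factor_toks, function(tk) {
      parsed <- .parse_bool(tk)
      fn <- eval(parse(text = paste0("function(.state) ", parsed$code)),
                 envir = baseenv())
      list(text = paste(tk, collapse = " "), vars = parsed$vars, fun = fn)
    })
    pvars <- unique(unlist(lapply(pheno, `[[`, "vars")))
    undeclared <- setdiff(pvars, declared)
    if (length(undeclared))
      stop("phenotype rule references undeclared node(s): ",
           paste(undeclared, collapse = ", "))
  }
  structure(list(inputs = inputs, regulatory = regulatory, output = output,
                 rules = compiled, phenotype = pheno),
            class = "logic_model")
}

#' @export
print.logic_model <- function(x, ...) {
  cat("logic model: ", length(x$inputs), " inputs, ",
      length(x$regulatory), " regulatory nodes, output ", x$output, "\n",
      sep = "")
  cat("  inputs: ", paste(x$inputs, collapse = ", "), "\n", sep = "")
  for (nm in x$regulatory)
    cat("  ", nm, " = ", x$rules[[nm]]$text, "\n", sep = "")
  if (!is.null(x$phenotype))
    cat("  ", x$output, " = ",
        paste(vapply(x$phenotype, `[[`, "", "text"), collapse = " + "),
        "\n", sep = "")
  invisible(x)
}

#' Read a logic model from a rule file
#'
#' BoolNet-style text dialect: one `target, factor-expression` line per
#' regulatory node, an optional `targets, factors` header, `#` comments, and
#' `#!` metadata lines declaring the layers:
#' \preformatted{
#' #! inputs: E2F1, TGFBR1, FGFR1
#' #! output: EMT
#' targets, factors
#' SMAD2/3/4, TGFBR1
#' EMT, (SMAD2/3/4 AND SNAI1) + (NOT CDH1) + FGFR1
#' }
#' The output node's line is the multi-valued phenotype rule (factors joined
#' by top-level `+`). If the `inputs` metadata line is absent, inputs are
#' inferred as nodes referenced by some rule but carrying none.
#'
#' @param path file path.
#' @return a [logic_model].
#' @export
read_logic_model <- function(path) {
  if (!file.exists(path)) stop("cannot read rule file: ", path)
  lines <- readLines(path, warn = FALSE)
  meta <- list()
  for (l in grep("^#!", lines, value = TRUE)) {
    kv <- sub("^#!\\s*", "", l)
    key <- trimws(sub(":.*$", "", kv))
    val <- trimws(strsplit(sub("^[^:]*:", "", kv), ",", fixed = TRUE)[[1]])
    meta[[tolower(key)]] <- val[nzchar(val)]
  }
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  body <- body[tolower(gsub("\\s", "", body)) != "targets,factors"]
  if (length(body) == 0L) stop("no rules in ", path)
  targets <- trimws(sub(",.*$", "", body))
  exprs <- trimws(sub("^[^,]*,", "", body))
  if (any(targets == "" | exprs == ""))
    stop("malformed rule line(s) in ", path)
  output <- if (!is.null(meta$output)) meta$output else "EMT"
  is_out <- targets == output
  phenotype <- if (any(is_out)) exprs[is_out][1] else NULL
  rules <- as.list(exprs[!is_out])
  names(rules) <- targets[!is_out]
  inputs <- meta$inputs
  if (is.null(inputs)) {
    referenced <- unique(unlist(lapply(rules, function(r)
      .parse_bool(.tokenize(r))$vars)))
    inputs <- setdiff(referenced, names(rules))
  }
  logic_model(inputs = inputs, rules = rules, phenotype = phenotype,
              output = output)
}

#' Write a logic model to a rule file
#' @param model a [logic_model].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_logic_model <- function(model, path) {
  out <- c(sprintf("#! inputs: %s", paste(model$inputs, collapse = ", ")),
           sprintf("#! output: %s", model$output),
           "targets, factors",
           vapply(model$regulatory, function(nm)
             paste0(nm, ", ", model$rules[[nm]]$text), character(1)))
  if (!is.null(model$phenotype))
    out <- c(out, paste0(model$output, ", ",
                         paste(vapply(model$phenotype, `[[`, "", "text"),
                               collapse = " + ")))
  writeLines(out, path)
  invisible(path)
}

#' Derive Boolean rules from a regulatory core and an expression contrast
#'
#' Template per regulatory node: ON iff (OR over its activators) AND NOT
#' (dominance expression over its inhibitors). Dominant inhibitors are those
#' upregulated in the invasive contrast (`fc > 0`); when two or more are
#' dominant they are combined with AND (joint repression, mirroring how CDH1
#' is governed by its co-upregulated repressors), a single dominant inhibitor
#' stands alone, and if none is upregulated all inhibitors are combined with
#' OR. Regulators of unknown effect count as activators. Explicit `overrides`
#' replace the template rule verbatim.
#'
#' @param core a `regulatory_core` or [regnet].
#' @param contrast data.frame from [fold_change_contrast()] (may be `NULL`:
#'   no inhibitor is then dominant).
#' @param overrides named character vector/list of rule texts, or path to a
#'   rule file whose rules take precedence.
#' @param inputs input-layer node names; default: nodes with no incoming core
#'   edge.
#' @param phenotype phenotype rule text (optional).
#' @param output output node name.
#' @return a [logic_model].
#' @export
derive_boolean_rules <- function(core, contrast = NULL, overrides = NULL,
                                 inputs = NULL, phenotype = NULL,
                                 output = "EMT") {
  net <- if (inherits(core, "regulatory_core")) core$network else core
  it <- net$interactions
  ids <- net$nodes$id
  if (is.character(overrides) && length(overrides) == 1L &&
      file.exists(overrides)) {
    om <- read_logic_model(overrides)
    overrides <- lapply(om$rules, `[[`, "text")
  }
  overrides <- as.list(overrides)
  unknown_override <- setdiff(names(overrides), ids)
  if (length(unknown_override))
    stop("override references unknown node(s): ",
         paste(unknown_override, collapse = ", "))
  if (is.null(inputs)) inputs <- ids[!(ids %in% it$target)]
  fcv <- if (is.null(contrast)) numeric(0) else setNames(contrast$fc, contrast$gene)
  regulatory <- setdiff(ids, inputs)
  rules <- list()
  for (nm in regulatory) {
    if (!is.null(overrides[[nm]])) {
      rules[[nm]] <- overrides[[nm]]
      next
    }
    inc <- it[it$target == nm, , drop = FALSE]
    if (nrow(inc) == 0L)
      stop("node ", nm, " has no incoming edge and no override")
    act <- unique(inc$source[inc$effect != "inhibition"])
    inh <- unique(inc$source[inc$effect == "inhibition"])
    parts <- character(0)
    if (length(act))
      parts <- paste0("(", paste(act, collapse = " OR "), ")")
    if (length(inh)) {
      dom <- inh[!is.na(fcv[inh]) & fcv[inh] > 0]
      inner <- if (length(dom) >= 2L) paste(dom, collapse = " AND ")
               else if (length(dom) == 1L) dom
               else paste(inh, collapse = " OR ")
      parts <- c(parts, paste0("NOT (", inner, ")"))
    }
    rules[[nm]] <- paste(parts, collapse = " AND ")
  }
  logic_model(inputs = inputs, rules = rules, phenotype = phenotype,
              output = output)
}
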