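# SBML (Level 2/3 core) import and export.
#
# Import supports the ODE-expressible subset: species, global parameters,
# reactions with kinetic laws (local parameters are namespaced), and rate
# rules.  Events, algebraic rules, assignment rules, function definitions
# and non-unit compartment sizes are rejected with an explicit
# unsupported-construct error.  Export writes each state as a species with a
# rate rule, which round-trips any model this package can represent.

# ---- MathML <-> R expressions ---------------------------------------------

mathml_to_expr <- function(node) {
  name <- xml2::xml_name(node)
  if (name == "math") {
    kids <- xml2::xml_children(node)
    if (length(kids) != 1L) stop("malformed MathML", call. = FALSE)
    return(mathml_to_expr(kids[[1]]))
  }
  if (name == "ci") return(as.name(trimws(xml2::xml_text(node))))
  if (name == "cn") {
    type <- xml2::xml_attr(node, "type")
    if (!is.na(type) && type == "e-notation") {
      parts <- xml2::xml_contents(node)
      mant <- as.numeric(xml2::xml_text(parts[[1]]))
      expo <- as.numeric(xml2::xml_text(parts[[length(parts)]]))
      return(mant * 10^expo)
    }
    return(as.numeric(trimws(xml2::xml_text(node))))
  }
  if (name == "csymbol") {
    url <- xml2::xml_attr(node, "definitionURL")
    if (!is.na(url) && grepl("time", url)) return(as.name("t"))
    stop("unsupported MathML csymbol: ", xml2::xml_text(node), call. = FALSE)
  }
  if (name == "pi") return(pi)
  if (name == "exponentiale") return(exp(1))
  if (name != "apply")
    stop("unsupported MathML element: ", name, call. = FALSE)
  kids <- xml2::xml_children(node)
  op <- xml2::xml_name(kids[[1]])
  args <- lapply(kids[-1], mathml_to_expr)
  bin <- function(fun) Reduce(function(a, b) call(fun, a, b), args)
  switch(op,
    plus = if (length(args) == 0L) 0 else bin("+"),
    times = if (length(args) == 0L) 1 else bin("*"),
    minus = if (length(args) == 1L) call("-", args[[1]]) else bin("-"),
    divide = bin("/"),
    power = bin("^"),
    exp = call("exp", args[[1]]),
    ln = call("log", args[[1]]),
    log = if (length(args) == 1L) call("log10", args[[1]]) else
      call("log", args[[2]], args[[1]]),
    root = call("sqrt", args[[length(args)]]),
    sin = call("sin", args[[1]]),
    cos = call("cos", args[[1]]),
    tan = call("tan", args[[1]]),
    abs = call("abs", args[[1]]),
    stop("unsupported MathML operator: ", op, call. = FALSE)
  )
}

expr_to_mathml <- function(e) {
  if (is.numeric(e)) {
    if (e < 0) return(sprintf("<apply><minus/>%s</apply>",
                              expr_to_mathml(-e)))
    return(sprintf("<cn>%s</cn>", format(e, digits = 17)))
  }
  if (is.name(e)) {
    s <- as.character(e)
    if (s == "t")
      return(paste0('<csymbol encoding="text" definitionURL=',
                    '"http://www.sbml.org/sbml/symbols/time">t</csymbol>'))
    return(sprintf("<ci>%s</ci>", s))
  }
  if (!is.call(e)) stop("cannot export expression element", call. = FALSE)
  op <- as.character(e[[1]])
  args <- as.list(e)[-1]
  ml <- vapply(args, expr_to_mathml, character(1))
  wrap <- function(tag) sprintf("<apply><%s/>%s</apply>", tag,
                                paste(ml, collapse = ""))
  switch(op,
    "+" = wrap("plus"),
    "-" = wrap("minus"),
    "*" = wrap("times"),
    "/" = wrap("divide"),
    "^" = wrap("power"),
    "(" = expr_to_mathml(args[[1]]),
    "exp" = wrap("exp"),
    "log" = wrap("ln"),
    "sqrt" = wrap("root"),
    "sin" = wrap("sin"),
    "cos" = wrap("cos"),
    "abs" = wrap("abs"),
    stop("cannot export operator to MathML: ", op, call. = FALSE)
  )
}

# ---- export ----------------------------------------------------------------

#' Export a model to SBML
#'
#' Writes the model as an SBML Level 3 document in which every state is a
#' species governed by a rate rule, parameters are global parameters and
#' known inputs are non-constant parameters (annotated so that
#' [load_sbml()] restores them as inputs).  The output map is stored in an
#' annotation since core SBML has no output concept.
#'
#' @param model an [ode_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  esc <- function(s) gsub("&", "&amp;", s, fixed = TRUE)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    sprintf('  <model id="%s">', esc(model$name)),
    '    <listOfCompartments>',
    '      <compartment id="default" size="1" constant="true"/>',
    '    </listOfCompartments>',
    '    <listOfSpecies>')
  for (i in seq_len(model$n_states))
    lines <- c(lines, sprintf(
      '      <species id="%s" compartment="default" initialAmount="%s" hasOnlySubstanceUnits="true" boundaryCondition="false" constant="false"/>',
      model$state_labels[i], format(model$initial_state[i], digits = 17)))
  lines <- c(lines, '    </listOfSpecies>', '    <listOfParameters>')
  for (nm in names(model$parameters))
    lines <- c(lines, sprintf(
      '      <parameter id="%s" value="%s" constant="true"/>',
      nm, format(model$parameters[[nm]], digits = 17)))
  for (nm in model$input_names)
    lines <- c(lines, sprintf(
      '      <parameter id="%s" value="0" constant="false"/>', nm))
  lines <- c(lines, '    </listOfParameters>', '    <listOfRules>')
  for (i in seq_len(model$n_states))
    lines <- c(lines, sprintf(
      '      <rateRule variable="%s"><math xmlns="http://www.w3.org/1998/Math/MathML">%s</math></rateRule>',
      model$state_labels[i], expr_to_mathml(model$odes[[i]])))
  lines <- c(lines, '    </listOfRules>',
             '    <annotation>',
             '      <dynelnet xmlns="https://example.org/dynelnet">')
  if (length(model$input_names))
    lines <- c(lines, sprintf('        <inputs names="%s"/>',
                              paste(model$input_names, collapse = " ")))
  for (j in seq_len(model$n_outputs))
    lines <- c(lines, sprintf(
      '        <output id="%s"><math xmlns="http://www.w3.org/1998/Math/MathML">%s</math></output>',
      model$output_labels[j], expr_to_mathml(model$output_exprs[[j]])))
  lines <- c(lines, '      </dynelnet>', '    </annotation>',
             '  </model>', '</sbml>')
  writeLines(lines, path)
  invisible(path)
}

# ---- import ----------------------------------------------------------------

#' Import an ODE model from SBML
#'
#' Reads an SBML Level 2/3 core document and converts it to an
#' [ode_model()].  Species become states; kinetic laws and rate rules become
#' the rate expressions.  Constructs outside the ODE-expressible subset
#' (events, algebraic or assignment rules, function definitions, non-unit
#' compartments) raise an explicit error naming the construct.
#'
#' Documents without the package's output annotation get the identity output
#' map (every state observed), which can be overridden with `outputs`.
#'
#' @param path SBML file path.
#' @param outputs optional named list of output expressions overriding the
#'   file's (or the identity) output map.
#' @param name optional model name override.
#' @return an [ode_model()].
#' @export
load_sbml <- function(path, outputs = NULL, name = NULL) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  mdl <- xml2::xml_find_first(doc, ".//model")
  if (inherits(mdl, "xml_missing")) stop("no <model> element found", call. = FALSE)

  unsupported <- c(listOfEvents = "events", listOfConstraints = "constraints",
                   listOfFunctionDefinitions = "function definitions",
                   algebraicRule = "algebraic rule",
                   assignmentRule = "assignment rule")
  for (tag in names(unsupported)) {
    if (!inherits(xml2::xml_find_first(mdl, paste0(".//", tag)), "xml_missing"))
      stop("unsupported SBML construct: ", unsupported[[tag]], call. = FALSE)
  }
  comps <- xml2::xml_find_all(mdl, ".//compartment")
  for (cp in comps) {
    size <- xml2::xml_attr(cp, "size")
    if (!is.na(size) && abs(as.numeric(size) - 1) > 1e-12)
      stop("unsupported SBML construct: non-unit compartment size", call. = FALSE)
  }

  sp_nodes <- xml2::xml_find_all(mdl, ".//listOfSpecies/species")
  if (!length(sp_nodes)) stop("SBML model has no species", call. = FALSE)
  species <- xml2::xml_attr(sp_nodes, "id")
  x0 <- vapply(sp_nodes, function(s) {
    v <- xml2::xml_attr(s, "initialAmount")
    if (is.na(v)) v <- xml2::xml_attr(s, "initialConcentration")
    if (is.na(v)) 0 else as.numeric(v)
  }, numeric(1))
  boundary <- xml2::xml_attr(sp_nodes, "boundaryCondition") %in% "true"

  par_nodes <- xml2::xml_find_all(mdl, ".//listOfParameters/parameter")
  par_ids <- xml2::xml_attr(par_nodes, "id")
  par_vals <- as.numeric(xml2::xml_attr(par_nodes, "value"))
  par_const <- !(xml2::xml_attr(par_nodes, "constant") %in% "false")

  ann_inputs <- xml2::xml_find_first(mdl, ".//annotation//inputs")
  input_names <- if (!inherits(ann_inputs, "xml_missing")) {
    strsplit(trimws(xml2::xml_attr(ann_inputs, "names")), "\\s+")[[1]]
  } else {
    par_ids[!par_const]  # non-constant parameters act as external inputs
  }
  is_par <- par_const & !(par_ids %in% input_names)
  parameters <- stats::setNames(par_vals[is_par], par_ids[is_par])

  n <- length(species)
  dx <- stats::setNames(vector("list", n), species)
  for (i in seq_len(n)) dx[[i]] <- 0

  # rate rules
  for (rr in xml2::xml_find_all(mdl, ".//rateRule")) {
    var <- xml2::xml_attr(rr, "variable")
    if (!var %in% species)
      stop("rate rule for non-species variable: ", var, call. = FALSE)
    math <- xml2::xml_find_first(rr, "./math")
    dx[[var]] <- mathml_to_expr(math)
  }

  # reactions
  add_expr <- function(acc, term) {
    if (identical(acc, 0)) term else call("+", acc, term)
  }
  rx_nodes <- xml2::xml_find_all(mdl, ".//listOfReactions/reaction")
  for (rx in rx_nodes) {
    rid <- xml2::xml_attr(rx, "id")
    kl <- xml2::xml_find_first(rx, "./kineticLaw")
    if (inherits(kl, "xml_missing"))
      stop("reaction without kinetic law: ", rid, call. = FALSE)
    math <- xml2::xml_find_first(kl, "./math")
    rate <- mathml_to_expr(math)
    # namespace local parameters into globals
    lp <- xml2::xml_find_all(kl, ".//localParameter|.//parameter")
    for (lpn in lp) {
      lid <- xml2::xml_attr(lpn, "id")
      gid <- paste(rid, lid, sep = "_")
      rate <- substitute_name(rate, lid, as.name(gid))
      parameters[gid] <- as.numeric(xml2::xml_attr(lpn, "value"))
    }
    for (ref in xml2::xml_find_all(rx, "./listOfReactants/speciesReference")) {
      sp <- xml2::xml_attr(ref, "species")
      st0 <- xml2::xml_attr(ref, "stoichiometry")
      st <- if (is.na(st0)) 1 else as.numeric(st0)
      if (!sp %in% species || boundary[match(sp, species)]) next
      term <- if (st == 1) rate else call("*", st, rate)
      dx[[sp]] <- if (identical(dx[[sp]], 0)) call("-", term) else
        call("-", dx[[sp]], term)
    }
    for (ref in xml2::xml_find_all(rx, "./listOfProducts/speciesReference")) {
      sp <- xml2::xml_attr(ref, "species")
      st0 <- xml2::xml_attr(ref, "stoichiometry")
      st <- if (is.na(st0)) 1 else as.numeric(st0)
      if (!sp %in% species || boundary[match(sp, species)]) next
      term <- if (st == 1) rate else call("*", st, rate)
      dx[[sp]] <- add_expr(dx[[sp]], term)
    }
  }

  # boundary species stay constant
  for (i in which(boundary)) dx[[i]] <- 0

  # outputs: annotation > argument > identity
  out_exprs <- outputs
  if (is.null(out_exprs)) {
    out_nodes <- xml2::xml_find_all(mdl, ".//annotation//output")
    if (length(out_nodes)) {
      out_exprs <- stats::setNames(
        lapply(out_nodes, function(o)
          mathml_to_expr(xml2::xml_find_first(o, "./math"))),
        xml2::xml_attr(out_nodes, "id"))
    } else {
      out_exprs <- stats::setNames(lapply(species, as.name),
                                   paste0("obs_", species))
    }
  }

  mname <- if (!is.null(name)) name else {
    v <- xml2::xml_attr(mdl, "id"); if (is.na(v)) "sbml_model" else v
  }
  ode_model(odes = dx, outputs = out_exprs, parameters = parameters,
            initial_state = x0, input_names = input_names, name = mname)
}

# rename a symbol inside an expression tree
substitute_name <- function(e, from, to) {
  if (is.name(e)) {
    if (as.character(e) == from) return(to)
    return(e)
  }
  if (is.call(e)) {
    for (i in seq_along(e)[-1]) e[[i]] <- substitute_name(e[[i]], from, to)
    return(e)
  }
  e
}
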