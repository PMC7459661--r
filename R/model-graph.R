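#' Declarative stock-and-flow model graph
#'
#' A `model_graph` is the engine's description of a system-dynamics model:
#' named variables with roles (`stock`, `flow`, `auxiliary`, `constant`),
#' equations for auxiliaries and flows as R expression strings over variable
#' names and table functions, the net-flow wiring of each stock, and a signed
#' causal-edge list used for feedback-loop enumeration and sign checking.
#'
#' Auxiliaries and flows must form an acyclic dependency graph once stocks
#' and constants are treated as givens; they are evaluated in topological
#' order (alphabetical tie-break for reproducibility) each step.
#'
#' @param variables Named character vector mapping variable name to role,
#'   one of `"stock"`, `"flow"`, `"auxiliary"`, `"constant"`.
#' @param equations Named character vector/list of R expression strings, one
#'   per auxiliary and flow. Expressions may reference variables, table
#'   functions declared in `tables` (called as functions), and the package's
#'   rate helpers.
#' @param net_flow Named list, one entry per stock:
#'   `list(inflows = <flow names>, outflows = <flow names>)`.
#' @param edges Data frame with columns `source`, `target`, `sign`
#'   (`"+"`/`"-"`) and optionally `delayed` (logical), declaring the causal
#'   diagram. At most one edge per ordered pair.
#' @param tables Named list of [table_function()]s available to equations.
#' @param bounds Named list: variable name -> `c(lower, upper)`. Declared
#'   variables are clamped to their interval after each evaluation/step
#'   (the engine's default behavioural band is \eqn{[0,1]}).
#' @param reference_state Named numeric vector giving the model's reference
#'   state (typically the initial state) used by [check_edge_signs()].
#' @param process Optional named character vector tagging variables with a
#'   process label (used for diagram export grouping).
#' @return An object of class `model_graph`.
#' @export
model_graph <- function(variables, equations = list(), net_flow = list(),
                        edges = NULL, tables = list(), bounds = list(),
                        reference_state = NULL, process = NULL) {
  roles <- c("stock", "flow", "auxiliary", "constant")
  if (is.null(names(variables)) || any(!nzchar(names(variables)))) {
    validation_error("model_graph: variables must be a named vector of roles")
  }
  variables <- vapply(variables, as.character, character(1))
  if (!all(variables %in% roles)) {
    validation_error(paste0("model_graph: unknown role(s): ",
                            paste(setdiff(variables, roles), collapse = ", ")))
  }
  vnames <- names(variables)
  if (anyDuplicated(vnames)) {
    validation_error("model_graph: duplicated variable names")
  }

  computed <- vnames[variables %in% c("flow", "auxiliary")]
  equations <- as.list(equations)
  missing_eq <- setdiff(computed, names(equations))
  if (length(missing_eq)) {
    validation_error(paste0("model_graph: missing equations for: ",
                            paste(missing_eq, collapse = ", ")))
  }
  extra_eq <- setdiff(names(equations), computed)
  if (length(extra_eq)) {
    validation_error(paste0("model_graph: equations given for non-computed variables: ",
                            paste(extra_eq, collapse = ", ")))
  }
  parsed <- lapply(equations, function(e) str2lang(as.character(e)))

  # Every stock's net flow must reference declared flows only.
  for (s in names(net_flow)) {
    if (!s %in% vnames || variables[[s]] != "stock") {
      validation_error(paste0("model_graph: net_flow entry for non-stock '", s, "'"))
    }
    fl <- unlist(net_flow[[s]][c("inflows", "outflows")], use.names = FALSE)
    bad <- fl[!(fl %in% vnames) | variables[fl] != "flow"]
    if (length(bad)) {
      validation_error(paste0("model_graph: net flow of '", s,
                              "' references non-flow variable(s): ",
                              paste(unique(bad), collapse = ", ")))
    }
  }
  stocks <- vnames[variables == "stock"]
  no_flow <- setdiff(stocks, names(net_flow))
  if (length(no_flow)) {
    validation_error(paste0("model_graph: stocks without net_flow: ",
                            paste(no_flow, collapse = ", ")))
  }

  if (is.null(edges)) {
    edges <- data.frame(source = character(), target = character(),
                        sign = character(), delayed = logical())
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!"delayed" %in% names(edges)) edges$delayed <- FALSE
  if (nrow(edges)) {
    if (!all(edges$sign %in% c("+", "-"))) {
      validation_error("model_graph: edge signs must be '+' or '-'")
    }
    bad <- setdiff(c(edges$source, edges$target), vnames)
    if (length(bad)) {
      validation_error(paste0("model_graph: edges reference unknown variable(s): ",
                              paste(unique(bad), collapse = ", ")))
    }
    if (anyDuplicated(paste(edges$source, edges$target))) {
      validation_error("model_graph: at most one edge per ordered pair")
    }
  }

  for (tf in tables) {
    if (!inherits(tf, "table_function")) {
      validation_error("model_graph: tables must be table_function objects")
    }
  }

  # Dependencies among computed variables (stocks/constants are givens).
  deps <- lapply(parsed, function(expr) intersect(all.vars(expr), computed))
  order <- topological_order(computed, deps)

  m <- structure(list(
    variables = variables,
    equations = lapply(parsed, identity),
    equation_text = lapply(equations, as.character),
    net_flow = net_flow,
    edges = edges,
    tables = tables,
    bounds = bounds,
    eval_order = order,
    deps = deps,
    reference_state = reference_state,
    process = process
  ), class = "model_graph")
  m
}

# Kahn's algorithm with alphabetical tie-break; on a cycle, names it.
topological_order <- function(nodes, deps) {
  nodes <- sort(nodes)
  remaining <- nodes
  resolved <- character()
  out <- character()
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(n) {
      all(deps[[n]] %in% resolved)
    }, logical(1))]
    if (!length(ready)) {
      structural_error(paste0(
        "cyclic auxiliary/flow dependency among: ",
        paste(remaining, collapse = " -> ")))
    }
    nxt <- ready[1]  # alphabetical: remaining is sorted
    out <- c(out, nxt)
    resolved <- c(resolved, nxt)
    remaining <- setdiff(remaining, nxt)
  }
  out
}

#' @export
print.model_graph <- function(x, ...) {
  tab <- table(factor(x$variables, levels = c("stock", "flow", "auxiliary", "constant")))
  cat("<model_graph> ", length(x$variables), " variables (",
      tab[["stock"]], " stocks, ", tab[["flow"]], " flows, ",
      tab[["auxiliary"]], " auxiliaries, ", tab[["constant"]], " constants), ",
      nrow(x$edges), " causal edges\n", sep = "")
  invisible(x)
}

# Evaluation environment for one step: state values + table closures,
# with the package namespace as parent so equations can call rate helpers.
model_eval_env <- function(model, state) {
  env <- new.env(parent = asNamespace("burnoutSD"))
  for (nm in names(state)) assign(nm, state[[nm]], envir = env)
  for (nm in names(model$tables)) assign(nm, as_closure(model$tables[[nm]]), envir = env)
  env
}

# Evaluate auxiliaries and flows at the given state, in topological order,
# clamping declared-bounded variables as they are produced.
evaluate_auxiliaries <- function(model, state) {
  env <- model_eval_env(model, state)
  out <- numeric(0)
  for (nm in model$eval_order) {
    val <- eval(model$equations[[nm]], envir = env)
    if (!is.finite(val)) {
      structural_error(paste0("non-finite value for variable '", nm, "'"))
    }
    b <- model$bounds[[nm]]
    if (!is.null(b)) val <- clamp01(val, b[1], b[2])
    assign(nm, val, envir = env)
    out[nm] <- val
  }
  out
}

#' Check declared edge signs against numerical partial derivatives
#'
#' For every declared causal edge, perturbs the source variable around the
#' model's reference state and recomputes the target's equation (for a stock
#' target, its net-flow rate). The declared sign must agree with the sign of
#' the central finite difference. A derivative of exactly zero is accepted as
#' consistent: the packaged models contain `min()`/`max()` saturations whose
#' inactive branch is locally flat, so a flat response does not contradict
#' the declared ceteris-paribus polarity.
#'
#' @param model A [model_graph()].
#' @param state Named numeric reference state (defaults to the model's
#'   stored `reference_state`).
#' @param eps Perturbation size.
#' @return Invisibly, a data frame with one row per edge (`source`,
#'   `target`, `sign`, `derivative`, `consistent`). Throws a structural
#'   error if any edge contradicts its declared sign.
#' @export
check_edge_signs <- function(model, state = NULL, eps = 1e-4) {
  state <- state %||% model$reference_state
  if (is.null(state)) {
    parameter_error("check_edge_signs: no reference state available")
  }
  aux <- evaluate_auxiliaries(model, state)
  full <- c(state[setdiff(names(state), names(aux))], aux)

  target_rate <- function(target, values) {
    env <- model_eval_env(model, values)
    role <- model$variables[[target]]
    if (role %in% c("auxiliary", "flow")) {
      return(eval(model$equations[[target]], envir = env))
    }
    if (role == "stock") {
      nf <- model$net_flow[[target]]
      fl <- function(nms) {
        if (!length(nms)) return(0)
        sum(vapply(nms, function(f) eval(model$equations[[f]], envir = env),
                   numeric(1)))
      }
      return(fl(nf$inflows) - fl(nf$outflows))
    }
    structural_error(paste0("edge targets constant '", target, "'"))
  }

  res <- model$edges
  res$derivative <- NA_real_
  res$consistent <- NA
  for (i in seq_len(nrow(res))) {
    src <- res$source[i]; tgt <- res$target[i]
    up <- full; up[src] <- up[src] + eps
    dn <- full; dn[src] <- dn[src] - eps
    d <- (target_rate(tgt, up) - target_rate(tgt, dn)) / (2 * eps)
    res$derivative[i] <- d
    res$consistent[i] <- (abs(d) < 1e-9) ||
      (d > 0 && res$sign[i] == "+") || (d < 0 && res$sign[i] == "-")
  }
  if (!all(res$consistent)) {
    bad <- res[!res$consistent, , drop = FALSE]
    structural_error(paste0(
      "edge sign inconsistency: ",
      paste(sprintf("%s -> %s declared '%s' but derivative %.3g",
                    bad$source, bad$target, bad$sign, bad$derivative),
            collapse = "; ")))
  }
  invisible(res)
}

#' Serialize a model graph to JSON
#'
#' Writes the declarative content of a [model_graph()] (variables, equation
#' strings, net flows, signed edges, table functions, bounds) so a model can
#' be stored or exchanged and rebuilt with [read_model_graph()].
#'
#' @param model A [model_graph()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_graph <- function(model, path) {
  obj <- list(
    variables = as.list(model$variables),
    equations = model$equation_text,
    net_flow = model$net_flow,
    edges = model$edges,
    tables = lapply(model$tables, function(tf) list(xs = tf$xs, ys = tf$ys)),
    bounds = model$bounds,
    reference_state = as.list(model$reference_state %||% numeric()),
    process = as.list(model$process %||% character())
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a model graph from JSON
#'
#' @param path File written by [write_model_graph()].
#' @return A [model_graph()].
#' @export
read_model_graph <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ref <- unlist(obj$reference_state)
  proc <- unlist(obj$process)
  model_graph(
    variables = unlist(obj$variables),
    equations = obj$equations,
    net_flow = lapply(obj$net_flow, function(nf) {
      list(inflows = as.character(nf$inflows %||% character()),
           outflows = as.character(nf$outflows %||% character()))
    }),
    edges = if (length(obj$edges)) obj$edges else NULL,
    tables = lapply(obj$tables, function(tf) table_function(tf$xs, tf$ys)),
    bounds = lapply(obj$bounds, as.numeric),
    reference_state = if (length(ref)) ref else NULL,
    process = if (length(proc)) proc else NULL
  )
}
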