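# Independent oracles used across the suite. These deliberately avoid the
# package's own algorithms.

# All simple cycles of a signed digraph by exhaustive subset/permutation
# search (feasible for n <= 6). Returns a sorted character key per cycle:
# "smallest-rotation-cycle|polarity".
brute_force_cycles <- function(edges, max_len = Inf) {
  nodes <- sort(unique(c(edges$source, edges$target)))
  ekey <- paste(edges$source, edges$target)
  esign <- stats::setNames(edges$sign, ekey)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  keys <- character()
  for (k in 2:min(length(nodes), max_len)) {
    if (k > length(nodes)) break
    subsets <- utils::combn(nodes, k, simplify = FALSE)
    for (sub in subsets) {
      anchor <- sub[1]  # smallest; fixes rotation
      for (p in perms(sub[-1])) {
        cyc <- c(anchor, p)
        pairs <- paste(cyc, c(cyc[-1], cyc[1]))
        if (all(pairs %in% ekey)) {
          negs <- sum(esign[pairs] == "-")
          pol <- if (negs %% 2 == 0) "reinforcing" else "balancing"
          keys <- c(keys, paste(paste(cyc, collapse = ">"), pol, sep = "|"))
        }
      }
    }
  }
  sort(unique(keys))
}

loop_keys <- function(loops) {
  sort(vapply(loops, function(l) {
    paste(paste(l$cycle, collapse = ">"), l$polarity, sep = "|")
  }, character(1)))
}

random_signed_digraph <- function(seed, n_max = 6, p_edge = 0.35) {
  set.seed(seed)
  n <- sample(2:n_max, 1)
  nodes <- paste0("v", seq_len(n))
  pairs <- expand.grid(source = nodes, target = nodes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  keep <- stats::runif(nrow(pairs)) < p_edge
  e <- pairs[keep, , drop = FALSE]
  if (!nrow(e)) e <- pairs[1, , drop = FALSE]
  e$sign <- sample(c("+", "-"), nrow(e), replace = TRUE)
  e$delayed <- FALSE
  rownames(e) <- NULL
  e
}

# A one-stock test model: inflow and outflow given as constant-referencing
# expressions.
one_stock_model <- function(inflow_expr = "inflow_rate",
                            outflow_expr = "outflow_rate") {
  model_graph(
    variables = c(level = "stock", inflow = "flow", outflow = "flow",
                  inflow_rate = "constant", outflow_rate = "constant"),
    equations = list(inflow = inflow_expr, outflow = outflow_expr),
    net_flow = list(level = list(inflows = "inflow", outflows = "outflow"))
  )
}

persona_run_cached <- local({
  cache <- list()
  function(id, dt = 0.125) {
    key <- paste(id, dt)
    if (is.null(cache[[key]])) {
      cache[[key]] <<- run_persona(persona_params(id), run_config(dt = dt))
    }
    cache[[key]]
  }
})

`%||%` <- function(a, b) if (is.null(a)) b else a
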