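#' Signed feedback loop
#'
#' @param cycle Character vector of variable names in cycle order, starting
#'   at the lexicographically smallest rotation.
#' @param polarity `"reinforcing"` (even number of negative edges) or
#'   `"balancing"` (odd).
#' @param label Optional loop name.
#' @return An object of class `feedback_loop`.
#' @export
feedback_loop <- function(cycle, polarity, label = NULL) {
  stopifnot(polarity %in% c("reinforcing", "balancing"))
  structure(list(cycle = cycle, polarity = polarity, label = label),
            class = "feedback_loop")
}

#' @export
print.feedback_loop <- function(x, ...) {
  cat("<feedback_loop", if (!is.null(x$label)) paste0(" '", x$label, "'"),
      "> ", paste(x$cycle, collapse = " -> "), " -> ", x$cycle[1],
      " (", x$polarity, ")\n", sep = "")
  invisible(x)
}

#' Enumerate signed feedback loops of a model graph
#'
#' Finds all simple cycles of length up to `max_len` in the declared causal
#' edge graph. Each cycle's polarity is the parity of its negative-edge
#' count: even = reinforcing, odd = balancing. Cycles are reported once,
#' rotated to start at their lexicographically smallest variable, and the
#' list is ordered by (length, cycle names) for determinism.
#'
#' The search is a depth-first walk restricted, for each start node, to
#' nodes that sort after it; this yields each simple cycle exactly once.
#'
#' @param model A [model_graph()] (or a bare data frame of signed edges).
#' @param max_len Maximum cycle length.
#' @return List of [feedback_loop()] objects (empty for acyclic graphs).
#' @export
enumerate_feedback_loops <- function(model, max_len = 10L) {
  edges <- if (inherits(model, "model_graph")) model$edges else as.data.frame(model)
  if (!nrow(edges)) return(list())
  nodes <- sort(unique(c(edges$source, edges$target)))
  adj <- split(seq_len(nrow(edges)), factor(edges$source, levels = nodes))
  sign_neg <- edges$sign == "-"
  target_of <- match(edges$target, nodes)

  loops <- list()
  n <- length(nodes)
  for (s in seq_len(n)) {
    # path as node indices; only visit nodes >= s so each cycle is found
    # once, anchored at its smallest node.
    walk <- function(path, neg_count) {
      v <- path[length(path)]
      for (ei in adj[[nodes[v]]]) {
        w <- target_of[ei]
        neg2 <- neg_count + sign_neg[ei]
        if (w == s) {
          pol <- if (neg2 %% 2 == 0) "reinforcing" else "balancing"
          loops[[length(loops) + 1L]] <<- feedback_loop(nodes[path], pol)
        } else if (w > s && !(w %in% path) && length(path) < max_len) {
          walk(c(path, w), neg2)
        }
      }
    }
    walk(s, 0L)
  }
  key <- vapply(loops, function(l) {
    sprintf("%03d|%s", length(l$cycle), paste(l$cycle, collapse = "|"))
  }, character(1))
  loops[order(key)]
}
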