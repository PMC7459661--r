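#' Write a trajectory set to CSV
#'
#' Writes `week,<var1>,<var2>,...` with one row per grid point, at full
#' float precision (`%.17g`), so [read_trajectory_table()] round trips are
#' lossless.
#'
#' @param traj A [trajectory_set()] with at least one variable.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_table <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory_set"))
  if (ncol(traj$series) == 0) {
    validation_error("refusing to write a trajectory with no variables")
  }
  df <- as.data.frame(traj)
  fmt <- as.data.frame(lapply(df, function(x) sprintf("%.17g", x)),
                       check.names = FALSE)
  names(fmt) <- names(df)
  utils::write.table(fmt, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a trajectory set from CSV
#'
#' @param path File written by [write_trajectory_table()] (header
#'   `week,<vars...>`).
#' @return A [trajectory_set()].
#' @export
read_trajectory_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "week" || ncol(df) < 2) {
    validation_error("expected a CSV with header week,<var1>,...")
  }
  trajectory_set(df$week, as.matrix(df[-1]))
}

cld_processes <- function() {
  c("regulating demands", "regulating effort", "impacts on body and mind",
    "burnout symptoms")
}

#' Export a model graph as a DOT causal-loop diagram
#'
#' Nodes are grouped into subgraph clusters by their process tag (the four
#' processes of the full model), edges are labelled with their polarity
#' (dashed when delayed), and every named/enumerated feedback loop is
#' annotated as a comment line.
#'
#' @param model A [model_graph()].
#' @param path Output path for the DOT file.
#' @param max_loop_len Maximum loop length to annotate.
#' @return `path`, invisibly.
#' @export
export_cld <- function(model, path, max_loop_len = 8L) {
  proc <- model$process
  if (!is.null(proc)) {
    bad <- setdiff(unique(proc), cld_processes())
    if (length(bad)) {
      validation_error(paste0("unknown process tag(s): ",
                              paste(bad, collapse = ", ")))
    }
  }
  colors <- stats::setNames(
    c("lightblue", "palegreen", "lightsalmon", "plum"), cld_processes())
  q <- function(x) paste0('"', x, '"')
  lines <- c("digraph cld {", "  rankdir=LR;", "  node [shape=box];")

  loops <- enumerate_feedback_loops(model, max_len = max_loop_len)
  for (l in loops) {
    lines <- c(lines, paste0(
      "  // loop (", l$polarity, ")",
      if (!is.null(l$label)) paste0(" '", l$label, "'"), ": ",
      paste(l$cycle, collapse = " -> "), " -> ", l$cycle[1]))
  }

  vnames <- names(model$variables)
  if (!is.null(proc)) {
    for (i in seq_along(cld_processes())) {
      p <- cld_processes()[i]
      members <- intersect(vnames, names(proc)[proc == p])
      if (!length(members)) next
      lines <- c(lines,
                 paste0("  subgraph cluster_", i, " {"),
                 paste0('    label="', p, '"; style=filled; color=',
                        colors[[p]], ";"),
                 paste0("    ", q(members), ";"),
                 "  }")
    }
    untagged <- setdiff(vnames, names(proc))
  } else {
    untagged <- vnames
  }
  lines <- c(lines, paste0("  ", q(untagged), ";"))

  e <- model$edges
  if (nrow(e)) {
    lines <- c(lines, sprintf('  %s -> %s [label="%s"%s];',
                              q(e$source), q(e$target), e$sign,
                              ifelse(e$delayed, " style=dashed", "")))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}

#' Write a run manifest
#'
#' Records what produced a set of output files: command name, configuration
#' snapshot, seed, package version, input/output paths and MD5 digests of
#' the outputs. Re-running the same command with the same configuration and
#' seed reproduces digest-identical outputs.
#'
#' @param command Command name.
#' @param config List of configuration values.
#' @param seed Integer seed.
#' @param inputs,outputs Character vectors of paths.
#' @param path Manifest output path (JSON).
#' @return The manifest list, invisibly.
#' @export
write_run_manifest <- function(command, config, seed, inputs, outputs, path) {
  digests <- as.list(tools::md5sum(outputs))
  manifest <- list(
    command = command,
    config = config,
    seed = seed,
    package_version = as.character(utils::packageVersion("burnoutSD")),
    inputs = as.list(inputs),
    outputs = as.list(outputs),
    output_md5 = digests
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

#' Write a pattern report as JSON
#'
#' @param report A `pattern_report` from [classify_trajectory()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pattern_report <- function(report, path) {
  stopifnot(inherits(report, "pattern_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
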