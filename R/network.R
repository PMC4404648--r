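#' Construct a directed network
#'
#' The basic container consumed by every scoring and optimisation function
#' in the package: an ordered set of node identifiers plus a list of
#' directed edges. Duplicate (source, target) pairs are collapsed (the
#' hierarchy scores are defined on binary interaction sets, not weighted
#' multigraphs); self-loops are kept, since e.g. auto-phosphorylation is a
#' genuine interaction of a kinase network.
#'
#' @param edges a two-column matrix or data frame of character identifiers
#'   (source, target), or NULL for an edgeless network.
#' @param nodes optional character vector of node identifiers; defaults to
#'   the nodes appearing in `edges`, in order of first appearance. Extra
#'   names declare isolated nodes.
#' @param quiet suppress the duplicate-collapse message.
#' @return an object of class `directed_network` with elements `nodes`
#'   (character vector) and `edges` (two-column character matrix).
#' @examples
#' net <- directed_network(rbind(c("A", "B"), c("B", "C")))
#' net
#' @export
directed_network <- function(edges = NULL, nodes = NULL, quiet = FALSE) {
  if (is.null(edges) || NROW(edges) == 0L) {
    em <- matrix(character(0), ncol = 2L)
  } else {
    em <- as.matrix(edges)[, 1:2, drop = FALSE]
    storage.mode(em) <- "character"
  }
  colnames(em) <- c("from", "to")
  rownames(em) <- NULL
  key <- paste(em[, 1L], em[, 2L], sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    if (!quiet)
      message(sum(dup), " duplicate edge(s) collapsed")
    em <- em[!dup, , drop = FALSE]
  }
  edge_nodes <- unique(as.vector(t(em)))
  if (is.null(nodes)) {
    nodes <- edge_nodes
  } else {
    nodes <- unique(as.character(nodes))
    missing <- setdiff(edge_nodes, nodes)
    if (length(missing))
      stop("edge endpoint(s) not in node set: ", paste(missing, collapse = ", "))
  }
  if (length(nodes) == 0L)
    stop("empty network: no nodes")
  structure(list(nodes = nodes, edges = em), class = "directed_network")
}

#' @export
print.directed_network <- function(x, ...) {
  nl <- sum(x$edges[, 1L] == x$edges[, 2L])
  cat(sprintf("directed_network: %d nodes, %d edges%s\n",
              length(x$nodes), nrow(x$edges),
              if (nl > 0L) sprintf(" (%d self-loop%s)", nl, if (nl > 1L) "s" else "") else ""))
  invisible(x)
}

#' Number of nodes / edges of a directed network
#' @param net a `directed_network`.
#' @return an integer count.
#' @export
n_nodes <- function(net) length(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edges)

is_directed_network <- function(x) inherits(x, "directed_network")

stop_if_not_network <- function(net) {
  if (!is_directed_network(net))
    stop("expected a 'directed_network' object; see directed_network()")
  invisible(net)
}

#' Convert a directed network to an igraph graph
#'
#' Used internally for reachability computations and GraphML export; exposed
#' because igraph is the natural environment for any further topology work.
#'
#' @param net a `directed_network`.
#' @return a directed `igraph` graph whose vertex `name` attribute carries
#'   the node identifiers.
#' @export
as_igraph <- function(net) {
  stop_if_not_network(net)
  igraph::graph_from_data_frame(
    as.data.frame(net$edges, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = net$nodes, stringsAsFactors = FALSE)
  )
}

#' Read a directed network from a file
#'
#' Supported dialects:
#' \describe{
#'   \item{edgelist}{two whitespace- or tab-separated columns, source then
#'     target; lines starting with `#` are comments.}
#'   \item{sif}{Cytoscape simple-interaction format: `source relation
#'     target1 [target2 ...]`; a line with a single token declares an
#'     isolated node.}
#'   \item{graphml}{parsed by igraph; isolated nodes are retained.}
#' }
#' Duplicate edges are collapsed with a message; edge direction is
#' source to target as written.
#'
#' @param path path to the network file.
#' @param format one of `"edgelist"`, `"sif"`, `"graphml"`; default guesses
#'   from the file extension (`.sif`, `.graphml`/`.xml`, otherwise edgelist).
#' @return a `directed_network`.
#' @export
read_network <- function(path, format = c("auto", "edgelist", "sif", "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, sif = "sif", graphml = "graphml", xml = "graphml",
                     "edgelist")
  }
  switch(format,
    edgelist = read_edgelist(path),
    sif = read_sif(path),
    graphml = read_graphml(path))
}

read_edgelist <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  toks <- strsplit(trimws(lines[keep]), "[ \t]+")
  bad <- which(vapply(toks, length, 1L) != 2L)
  if (length(bad))
    stop("malformed edge list line ", idx[bad[1L]], ": '",
         lines[idx[bad[1L]]], "' (expected two columns)")
  if (length(toks) == 0L)
    stop("empty network: ", path)
  directed_network(do.call(rbind, toks))
}

read_sif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  toks <- strsplit(trimws(lines[keep]), "[ \t]+")
  edges <- list()
  nodes <- character(0)
  for (i in seq_along(toks)) {
    tk <- toks[[i]]
    if (length(tk) == 1L) {          # isolated node declaration
      nodes <- c(nodes, tk)
    } else if (length(tk) >= 3L) {   # source relation target...
      src <- tk[1L]
      tgt <- tk[-(1:2)]
      edges[[length(edges) + 1L]] <- cbind(src, tgt)
      nodes <- c(nodes, src, tgt)
    } else {
      stop("malformed SIF line ", idx[i], ": '", lines[idx[i]],
           "' (expected 'source relation target...' or a lone node)")
    }
  }
  if (length(nodes) == 0L)
    stop("empty network: ", path)
  em <- if (length(edges)) do.call(rbind, edges) else NULL
  directed_network(em, nodes = unique(nodes))
}

read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  if (!igraph::is_directed(g))
    stop("GraphML graph is undirected; a directed network is required")
  nm <- igraph::vertex_attr(g, "name")
  if (is.null(nm))
    nm <- igraph::vertex_attr(g, "id")
  if (is.null(nm))
    nm <- as.character(seq_len(igraph::vcount(g)))
  el <- igraph::as_edgelist(g, names = FALSE)
  em <- if (nrow(el)) cbind(nm[el[, 1L]], nm[el[, 2L]]) else NULL
  directed_network(em, nodes = nm)
}

#' Write a network as an edge-list TSV
#'
#' @param net a `directed_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(net, path) {
  stop_if_not_network(net)
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write the result bundle of a hierarchy inference
#'
#' Writes three files into `out_dir`:
#' \itemize{
#'   \item `levels.tsv` — node, assigned_level, max_probability;
#'   \item `probability_matrix.tsv` — node by level assignment probabilities;
#'   \item `scores.json` — HS, CHS, PHS (with exact numerator/denominator),
#'     L, significance fields when present, and run metadata including the
#'     seed.
#' }
#'
#' @param result a `hierarchy_result` from [run_hsm()].
#' @param out_dir output directory, created if absent.
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(result, out_dir) {
  if (!inherits(result, "hierarchy_result"))
    stop("expected a 'hierarchy_result' from run_hsm()")
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)

  pm <- result$probability_matrix
  asg <- result$best_assignment
  lev <- data.frame(node = names(asg),
                    assigned_level = as.integer(asg),
                    max_probability = apply(pm, 1L, max),
                    stringsAsFactors = FALSE)
  utils::write.table(lev, file.path(out_dir, "levels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  pm_df <- data.frame(node = rownames(pm), pm, check.names = FALSE,
                      stringsAsFactors = FALSE)
  colnames(pm_df) <- c("node", paste0("level_", seq_len(ncol(pm))))
  utils::write.table(pm_df, file.path(out_dir, "probability_matrix.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  scores <- list(
    L = attr(pm, "L"),
    k = attr(pm, "k"),
    hs = score_as_list(result$hs),
    chs = score_as_list(result$chs),
    phs = score_as_list(result$phs),
    meta = result$meta
  )
  if (!is.null(result$significance))
    scores$significance <- unclass(result$significance)
  jsonlite::write_json(scores, file.path(out_dir, "scores.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "string")
  invisible(out_dir)
}

#' Read back a probability-matrix TSV written by [write_results()]
#'
#' @param path path to `probability_matrix.tsv`.
#' @return a numeric matrix, nodes in rows, levels in columns.
#' @export
read_probability_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  attr(m, "L") <- ncol(m)
  m
}
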