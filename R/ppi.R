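#' Undirected protein-protein interaction graph
#'
#' Holds a deduplicated, undirected PPI edge set over gene symbols.
#' Edge `(a, b)` and `(b, a)` are the same edge and are stored once, with
#' the pair ordered lexicographically; self-interactions are dropped.
#' The graph is backed by an igraph object (used for export) plus a
#' plain adjacency list used by the sub-pathway enumerator.
#'
#' @param edges two-column character matrix or data.frame of gene pairs.
#' @return An object of class `interaction_graph` with fields `nodes`
#'   (sorted symbol vector), `edges` (data.frame `a`, `b`, with `a < b`),
#'   `adj` (named list gene -> sorted neighbor vector), `n_self_dropped`,
#'   and `ig` (the igraph object).
#' @examples
#' g <- interaction_graph(rbind(c("A", "B"), c("B", "A"), c("A", "A")))
#' g$edges       # one row: A B
#' neighbors_of(g, "B")
#' @export
interaction_graph <- function(edges) {
  if (is.data.frame(edges)) edges <- as.matrix(edges[, 1:2])
  edges <- matrix(as.character(edges), ncol = 2)
  self <- edges[, 1] == edges[, 2]
  n_self <- sum(self)
  edges <- edges[!self, , drop = FALSE]
  a <- pmin(edges[, 1], edges[, 2])
  b <- pmax(edges[, 1], edges[, 2])
  key <- paste(a, b, sep = "\r")
  keep <- !duplicated(key)
  ed <- data.frame(a = a[keep], b = b[keep], stringsAsFactors = FALSE)
  ord <- order(ed$a, ed$b, method = "radix")
  ed <- ed[ord, , drop = FALSE]
  rownames(ed) <- NULL
  nodes <- sort(unique(c(ed$a, ed$b)), method = "radix")
  adj <- lapply(
    split(c(ed$b, ed$a), factor(c(ed$a, ed$b), levels = nodes)),
    function(x) sort(x, method = "radix"))
  ig <- igraph::graph_from_data_frame(ed, directed = FALSE,
                                      vertices = data.frame(name = nodes))
  structure(
    list(nodes = nodes, edges = ed, adj = adj,
         n_self_dropped = n_self, ig = ig),
    class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat(sprintf("interaction_graph: %d nodes, %d edges (%d self-interactions dropped at load)\n",
              length(x$nodes), nrow(x$edges), x$n_self_dropped))
  invisible(x)
}

#' Neighbors of a gene in the interaction graph
#' @param graph an [interaction_graph()].
#' @param gene gene symbol.
#' @return Sorted character vector of interaction partners (empty if the
#'   gene is absent from the graph).
#' @export
neighbors_of <- function(graph, gene) {
  nb <- graph$adj[[gene]]
  if (is.null(nb)) character(0) else nb
}

#' Does the graph contain an interaction between two genes?
#' @inheritParams neighbors_of
#' @param gene_a,gene_b gene symbols (order irrelevant).
#' @return Logical scalar.
#' @export
has_interaction <- function(graph, gene_a, gene_b) {
  gene_b %in% graph$adj[[gene_a]]
}

#' Read a PPI edge list from a two-column TSV
#'
#' Expects a header row with at least columns `gene_a` and `gene_b`
#' (the first two columns are used if those names are absent). `#`
#' comment lines are skipped. Self-pairs are dropped with a message;
#' reversed duplicates collapse to one undirected edge.
#'
#' @param path path to the TSV file.
#' @return An [interaction_graph()].
#' @export
read_ppi <- function(path) {
  if (!file.exists(path)) stop("PPI file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("PPI table needs two gene columns: ", path)
  cols <- if (all(c("gene_a", "gene_b") %in% names(df))) c("gene_a", "gene_b") else 1:2
  g <- interaction_graph(df[, cols])
  if (g$n_self_dropped > 0L)
    message(sprintf("read_ppi: dropped %d self-interaction row(s)", g$n_self_dropped))
  g
}
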