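fmt_num <- function(x) sprintf("%.6g", x)

#' Write a scored sub-pathway table to TSV
#'
#' Columns: rank, mirna, target, g1, g2, js_bp, js_mf, p1, p2, p_value,
#' pathways. Scores and p-values are printed to 6 significant digits.
#'
#' @param records records from [build_mrsp_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rsps_tsv <- function(records, path) {
  df <- data.frame(
    rank = seq_len(nrow(records)),
    mirna = records$mirna, target = records$target,
    g1 = records$g1, g2 = records$g2,
    js_bp = fmt_num(records$js_bp), js_mf = fmt_num(records$js_mf),
    p1 = fmt_num(records$p1), p2 = fmt_num(records$p2),
    p_value = fmt_num(records$p_value),
    pathways = records$pathways,
    stringsAsFactors = FALSE)
  if (nrow(records) == 0L) df <- df[0, , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a comorbid gene table to TSV
#' @param genes result of [comorbid_genes()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_comorbid_tsv <- function(genes, path) {
  out <- genes
  out$cancer_tag[is.na(out$cancer_tag)] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a regulatory network
#'
#' Writes the network in any of: SIF (`source<TAB>interaction<TAB>target`,
#' interaction `regulates` for miRNA-target edges and `pp` for PPI
#' edges), GraphML (via igraph, with node kind/cancer-tag/tissue and
#' edge kind attributes), a JSON node/edge document, and a node
#' attribute TSV.
#'
#' @param network a [assemble_network()] result.
#' @param dir output directory (created if needed).
#' @param name file stem, default `"network"`.
#' @param formats subset of `c("sif", "graphml", "json", "nodes")`.
#' @return Character vector of the files written, invisibly.
#' @export
write_network <- function(network, dir, name = "network",
                          formats = c("sif", "graphml", "json", "nodes")) {
  formats <- match.arg(formats, several.ok = TRUE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  nodes <- network$nodes
  edges <- network$edges
  if ("sif" %in% formats) {
    p <- file.path(dir, paste0(name, ".sif"))
    rel <- ifelse(edges$kind == "regulation", "regulates", "pp")
    lines <- sprintf("%s\t%s\t%s", edges$from, rel, edges$to)
    solo <- setdiff(nodes$id, c(edges$from, edges$to))
    writeLines(c(lines, solo), p)
    written <- c(written, p)
  }
  if ("graphml" %in% formats) {
    p <- file.path(dir, paste0(name, ".graphml"))
    v <- nodes
    v$cancer_tag[is.na(v$cancer_tag)] <- ""
    names(v)[names(v) == "id"] <- "name"
    ig <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = v)
    igraph::write_graph(ig, p, format = "graphml")
    written <- c(written, p)
  }
  if ("json" %in% formats) {
    p <- file.path(dir, paste0(name, ".json"))
    doc <- list(
      nodes = lapply(seq_len(nrow(nodes)), function(i) list(
        id = nodes$id[i], kind = nodes$kind[i],
        cancer_tag = if (is.na(nodes$cancer_tag[i])) NULL else nodes$cancer_tag[i],
        tissues = if (nzchar(nodes$tissues[i]))
          strsplit(nodes$tissues[i], ";", fixed = TRUE)[[1]] else list())),
      edges = lapply(seq_len(nrow(edges)), function(i) list(
        from = edges$from[i], to = edges$to[i], kind = edges$kind[i])))
    jsonlite::write_json(doc, p, auto_unbox = TRUE, pretty = TRUE)
    written <- c(written, p)
  }
  if ("nodes" %in% formats) {
    p <- file.path(dir, paste0(name, "_nodes.tsv"))
    out <- nodes
    out$cancer_tag[is.na(out$cancer_tag)] <- ""
    utils::write.table(out, p, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, p)
  }
  invisible(written)
}
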