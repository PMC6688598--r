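#' Build a query specification
#'
#' Collects every filter/option of a single-disease or disease-pair
#' query: the ranking namespace (BP or MF) that also gates viability and
#' the p-value, the p-value threshold, the experimental-validation
#' filter on miRNA targets, the tissue filter, the cancer-gene filter,
#' the top-N / specific-gene / pathway restrictions.
#'
#' `disease` may also be a miRNA id, in which case the query runs
#' miRNA-centric over that miRNA's targets.
#'
#' @param disease disease name (matched case-insensitively after
#'   trimming) or a miRNA id; `disease2` for comorbidity queries.
#' @param disease2 optional second disease.
#' @param tissue,tissue2 optional tissue label per disease; genes not
#'   recorded for the tissue are excluded.
#' @param tissue_scope `"all_genes"` (tissue filter constrains T, G1 and
#'   G2) or `"target_only"`.
#' @param namespace `"BP"` or `"MF"`.
#' @param p_threshold keep sub-pathways with p-value <= this; in (0, 1].
#' @param require_validated keep only targets with at least one method
#'   in `validated_methods`.
#' @param validated_methods method names; default the seven direct
#'   assays of [direct_validation_methods()].
#' @param cancer_filter `"none"`, `"target_only"` (T must carry a
#'   CRG/OCG/TSG tag) or `"all_genes"` (all of T, G1, G2 tagged).
#' @param top_n optional: keep only the N smallest-p sub-pathways.
#' @param gene_filter optional gene symbol: keep only sub-pathways
#'   containing it.
#' @param kegg_filter optional pathway id: keep only sub-pathways tagged
#'   with it.
#' @param tail use upper-tail p-values (see [pair_pvalue()]).
#' @param pathway_rule pathway-tag rule, see [assign_pathways()].
#' @return An object of class `query_spec`.
#' @export
query_spec <- function(disease, disease2 = NULL,
                       tissue = NULL, tissue2 = NULL,
                       tissue_scope = c("all_genes", "target_only"),
                       namespace = c("MF", "BP"),
                       p_threshold = 0.001,
                       require_validated = FALSE,
                       validated_methods = direct_validation_methods(),
                       cancer_filter = c("none", "target_only", "all_genes"),
                       top_n = NULL, gene_filter = NULL, kegg_filter = NULL,
                       tail = FALSE, pathway_rule = c("all", "any")) {
  namespace <- match.arg(namespace)
  cancer_filter <- match.arg(cancer_filter)
  tissue_scope <- match.arg(tissue_scope)
  pathway_rule <- match.arg(pathway_rule)
  stopifnot(is.numeric(p_threshold), length(p_threshold) == 1,
            p_threshold > 0, p_threshold <= 1)
  if (!is.null(top_n)) {
    if (!is.numeric(top_n) || length(top_n) != 1 || top_n < 1 ||
        top_n != round(top_n))
      stop("top_n must be a positive integer")
    top_n <- as.integer(top_n)
  }
  structure(
    list(disease = disease, disease2 = disease2,
         tissue = tissue, tissue2 = tissue2, tissue_scope = tissue_scope,
         namespace = namespace, p_threshold = p_threshold,
         require_validated = require_validated,
         validated_methods = validated_methods,
         cancer_filter = cancer_filter, top_n = top_n,
         gene_filter = gene_filter, kegg_filter = kegg_filter,
         tail = tail, pathway_rule = pathway_rule),
    class = "query_spec")
}

match_disease <- function(disease, known) {
  hit <- which(tolower(trimws(known)) == tolower(trimws(disease)))
  if (length(hit) == 0L) NULL else known[hit[[1]]]
}

#' Select the disease's miRNAs and their filtered target sets
#'
#' Collects all miRNAs associated with the query disease and their
#' target genes, then applies the experimental-validation filter (keep
#' targets with at least one method among the query's
#' `validated_methods`) and the tissue filter to the targets. When the
#' query names a miRNA instead of a disease, that single miRNA's targets
#' are used.
#'
#' @param query a [query_spec()].
#' @param bundle a [load_bundle()] result.
#' @param which_disease 1 or 2: use `disease`/`tissue` or
#'   `disease2`/`tissue2`.
#' @return Named list: miRNA id -> sorted character vector of targets.
#'   Empty target sets are dropped; an all-empty result warns.
#' @export
select_disease_inputs <- function(query, bundle, which_disease = 1L) {
  name <- if (which_disease == 1L) query$disease else query$disease2
  tissue <- if (which_disease == 1L) query$tissue else query$tissue2
  dm <- bundle$assoc$disease_mirnas
  mt <- bundle$assoc$mirna_targets
  disease <- match_disease(name, unique(dm$disease))
  if (is.null(disease)) {
    if (name %in% mt$mirna) {
      mirnas <- name           # miRNA/siRNA-centric single search
    } else {
      stop(sprintf("unknown disease or miRNA '%s'; known diseases: %s",
                   name, paste(sort(unique(dm$disease), method = "radix"),
                               collapse = ", ")))
    }
  } else {
    mirnas <- sort(unique(dm$mirna[dm$disease == disease]), method = "radix")
  }
  out <- list()
  for (m in mirnas) {
    rows <- mt[mt$mirna == m, , drop = FALSE]
    if (query$require_validated && nrow(rows) > 0L) {
      keep <- vapply(strsplit(rows$methods, ";", fixed = TRUE), function(ms)
        any(trimws(ms) %in% query$validated_methods), logical(1))
      rows <- rows[keep, , drop = FALSE]
    }
    targets <- sort(unique(rows$gene), method = "radix")
    if (!is.null(tissue)) {
      ti <- bundle$assoc$gene_tissues
      in_tissue <- unique(ti$gene[ti$tissue == tissue])
      targets <- targets[targets %in% in_tissue]
    }
    if (length(targets) > 0L) out[[m]] <- targets
  }
  if (length(out) == 0L)
    warning(sprintf("no targets remain for '%s' after filters", name),
            call. = FALSE)
  out
}

#' Build the scored, filtered miRNA-specific sub-pathway set
#'
#' For each (miRNA, target) pair, enumerates all sub-pathways of the
#' target, keeps those viable in the query namespace with p-value at or
#' below the threshold, then applies the tissue filter to G1/G2 (under
#' the default all-genes scope), the cancer-gene filter, and the
#' gene/pathway restrictions. The union over all miRNAs is returned
#' sorted by ascending p-value with deterministic tie-breaking
#' (p ascending, selected-namespace Jaccard score descending, then
#' lexicographic target, g1, g2, mirna).
#'
#' @param inputs result of [select_disease_inputs()].
#' @param bundle a [load_bundle()] result.
#' @param query a [query_spec()].
#' @param which_disease which disease's tissue setting applies.
#' @return data.frame of records (`mirna`, `target`, `g1`, `g2`,
#'   `js_bp`, `js_mf`, `viable_bp`, `viable_mf`, `p1`, `p2`, `p_value`,
#'   `pathways`), with attributes `n_raw` (enumerated paths) and
#'   `n_viable` (after the viability + p filter, before the optional
#'   filters).
#' @export
build_mrsp_set <- function(inputs, bundle, query, which_disease = 1L) {
  tissue <- if (which_disease == 1L) query$tissue else query$tissue2
  cache <- new.env(parent = emptyenv())
  n_raw <- 0L; n_viable <- 0L
  sel_js <- if (query$namespace == "BP") "js_bp" else "js_mf"
  pieces <- list()
  for (m in sort(names(inputs), method = "radix")) {
    for (tg in inputs[[m]]) {
      if (!exists(tg, envir = cache, inherits = FALSE)) {
        rec <- score_target_rsps(tg, bundle, query$namespace,
                                 tail = query$tail,
                                 pathway_rule = query$pathway_rule)
        assign(tg, rec, envir = cache)
      }
      rec <- get(tg, envir = cache)
      n_raw <- n_raw + (attr(rec, "n_raw") %||% 0L)
      rec <- rec[rec$p_value <= query$p_threshold, , drop = FALSE]
      n_viable <- n_viable + nrow(rec)
      if (!is.null(tissue) && query$tissue_scope == "all_genes" &&
          nrow(rec) > 0L) {
        ti <- bundle$assoc$gene_tissues
        in_tissue <- unique(ti$gene[ti$tissue == tissue])
        rec <- rec[rec$g1 %in% in_tissue & rec$g2 %in% in_tissue, ,
                   drop = FALSE]
      }
      if (query$cancer_filter != "none" && nrow(rec) > 0L) {
        tags <- bundle$assoc$cancer_tags
        tagged <- function(g) g %in% names(tags)
        keep <- if (query$cancer_filter == "target_only") tagged(rec$target)
                else tagged(rec$target) & tagged(rec$g1) & tagged(rec$g2)
        rec <- rec[keep, , drop = FALSE]
      }
      if (!is.null(query$gene_filter) && nrow(rec) > 0L)
        rec <- rec[rec$target == query$gene_filter |
                   rec$g1 == query$gene_filter |
                   rec$g2 == query$gene_filter, , drop = FALSE]
      if (!is.null(query$kegg_filter) && nrow(rec) > 0L) {
        keep <- vapply(strsplit(rec$pathways, ";", fixed = TRUE),
                       function(p) query$kegg_filter %in% p, logical(1))
        rec <- rec[keep, , drop = FALSE]
      }
      if (nrow(rec) > 0L) {
        rec <- cbind(mirna = m, rec, stringsAsFactors = FALSE)
        pieces[[length(pieces) + 1L]] <- rec
      }
    }
  }
  out <- if (length(pieces) == 0L) cbind(mirna = character(0), empty_records())
         else do.call(rbind, pieces)
  ord <- order(out$p_value, -out[[sel_js]], out$target, out$g1, out$g2,
               out$mirna, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_raw") <- n_raw
  attr(out, "n_viable") <- n_viable
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Keep the top-N sub-pathways by p-value
#'
#' Expects the p-value-sorted record set produced by [build_mrsp_set()]
#' (ties already broken by higher selected-namespace Jaccard score, then
#' lexicographic gene order) and returns its first `n` rows.
#'
#' @param records sorted records from [build_mrsp_set()].
#' @param n positive integer.
#' @return The first `min(n, nrow)` records.
#' @export
top_rsps <- function(records, n) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n))
    stop("n must be a positive integer")
  utils::head(records, n)
}

#' Assemble the miRNA regulatory network from a sub-pathway set
#'
#' Nodes are all miRNAs, target genes, and interactors (G1, G2) of the
#' record set; a regulation edge joins each miRNA to each of its
#' targets; PPI edges are the union of the sub-pathway hops and the
#' closure over every unlinked gene pair of the network that interacts
#' in the source PPI graph. Gene nodes carry their cancer tag and tissue
#' labels.
#'
#' @param mrsps records from [build_mrsp_set()] (optionally truncated by
#'   [top_rsps()]).
#' @param graph the source [interaction_graph()].
#' @param bundle a [load_bundle()] result (node annotations).
#' @return Object of class `regulatory_network`: list with `nodes`
#'   (data.frame `id`, `kind` in mirna/target_gene/gene, `cancer_tag`,
#'   `tissues`) and `edges` (data.frame `from`, `to`, `kind` in
#'   regulation/ppi).
#' @export
assemble_network <- function(mrsps, graph, bundle) {
  mirnas <- sort(unique(mrsps$mirna), method = "radix")
  targets <- sort(unique(mrsps$target), method = "radix")
  others <- sort(setdiff(unique(c(mrsps$g1, mrsps$g2)), targets),
                 method = "radix")
  genes <- c(targets, others)
  tags <- bundle$assoc$cancer_tags
  ti <- bundle$assoc$gene_tissues
  tiss <- vapply(genes, function(g)
    paste(sort(unique(ti$tissue[ti$gene == g]), method = "radix"),
          collapse = ";"), character(1))
  nodes <- data.frame(
    id = c(mirnas, genes),
    kind = c(rep("mirna", length(mirnas)),
             rep("target_gene", length(targets)),
             rep("gene", length(others))),
    cancer_tag = c(rep(NA_character_, length(mirnas)),
                   ifelse(genes %in% names(tags), tags[genes], NA_character_)),
    tissues = c(rep("", length(mirnas)), tiss),
    stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$kind, nodes$id, method = "radix"), , drop = FALSE]
  rownames(nodes) <- NULL

  reg <- unique(mrsps[, c("mirna", "target")])
  reg_edges <- if (nrow(reg) == 0L)
    data.frame(from = character(0), to = character(0), stringsAsFactors = FALSE)
  else data.frame(from = reg$mirna, to = reg$target, stringsAsFactors = FALSE)

  # PPI closure: every interacting pair among network genes becomes an
  # edge; sub-pathway hop edges are graph edges, so they are subsumed.
  ge <- graph$edges
  closure <- ge[ge$a %in% genes & ge$b %in% genes, , drop = FALSE]
  ppi_edges <- data.frame(from = closure$a, to = closure$b,
                          stringsAsFactors = FALSE)
  edges <- rbind(
    cbind(reg_edges, kind = rep("regulation", nrow(reg_edges)),
          stringsAsFactors = FALSE),
    cbind(ppi_edges, kind = rep("ppi", nrow(ppi_edges)),
          stringsAsFactors = FALSE))
  edges <- edges[order(edges$kind, edges$from, edges$to, method = "radix"), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf(
    "regulatory_network: %d nodes (%d miRNA, %d target, %d other), %d edges (%d regulation, %d ppi)\n",
    nrow(x$nodes), sum(x$nodes$kind == "mirna"),
    sum(x$nodes$kind == "target_gene"), sum(x$nodes$kind == "gene"),
    nrow(x$edges), sum(x$edges$kind == "regulation"),
    sum(x$edges$kind == "ppi")))
  invisible(x)
}

#' Genes common to the sub-pathway sets of two diseases
#'
#' The comorbid gene set of a disease pair: the intersection of the two
#' diseases' sub-pathway gene sets, where a disease's gene set comprises
#' every T, G1 and G2 over its filtered records. Each comorbid gene is
#' annotated with its cancer tag and pathway memberships.
#'
#' @param records1,records2 filtered record sets from [build_mrsp_set()]
#'   for the two diseases.
#' @param bundle a [load_bundle()] result, for annotations.
#' @return data.frame (`gene`, `cancer_tag`, `pathways`), genes in
#'   lexicographic order.
#' @export
comorbid_genes <- function(records1, records2, bundle) {
  gs1 <- unique(c(records1$target, records1$g1, records1$g2))
  gs2 <- unique(c(records2$target, records2$g1, records2$g2))
  genes <- sort(intersect(gs1, gs2), method = "radix")
  tags <- bundle$assoc$cancer_tags
  pw <- bundle$assoc$pathway_catalog
  data.frame(
    gene = genes,
    cancer_tag = ifelse(genes %in% names(tags), tags[genes], NA_character_),
    pathways = vapply(genes, function(g)
      paste(gene_terms(pw, g), collapse = ";"), character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}
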