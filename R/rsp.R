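#' Enumerate target-specific regulatory sub-pathways
#'
#' A regulatory sub-pathway (RSP) for a target gene T is an ordered
#' triple (T, G1, G2) in which T-G1 and G1-G2 are edges of the PPI
#' graph: all paths obtained by extending two levels of interaction out
#' from T. Sub-pathways are simple paths: G1 differs from both ends and
#' G2 != T, so a path may not fold back onto its target (relax with
#' `allow_return = TRUE`).
#'
#' @param target gene symbol T. If absent from the graph the result is
#'   empty (with a message).
#' @param graph an [interaction_graph()].
#' @param allow_return if `TRUE`, permits G2 == T (non-simple paths).
#' @return data.frame with columns `target`, `g1`, `g2`, ordered
#'   lexicographically by (g1, g2).
#' @examples
#' g <- interaction_graph(rbind(c("T", "A"), c("A", "B"), c("A", "C")))
#' enumerate_rsps("T", g)
#' @export
enumerate_rsps <- function(target, graph, allow_return = FALSE) {
  stopifnot(inherits(graph, "interaction_graph"))
  empty <- data.frame(target = character(0), g1 = character(0),
                      g2 = character(0), stringsAsFactors = FALSE)
  if (!(target %in% graph$nodes)) {
    message("enumerate_rsps: target not in PPI graph: ", target)
    return(empty)
  }
  g1s <- neighbors_of(graph, target)
  out_g1 <- character(0); out_g2 <- character(0)
  for (g1 in g1s) {
    g2s <- neighbors_of(graph, g1)
    g2s <- g2s[g2s != g1]
    if (!allow_return) g2s <- g2s[g2s != target]
    if (length(g2s) > 0L) {
      out_g1 <- c(out_g1, rep(g1, length(g2s)))
      out_g2 <- c(out_g2, g2s)
    }
  }
  if (length(out_g1) == 0L) return(empty)
  df <- data.frame(target = target, g1 = out_g1, g2 = out_g2,
                   stringsAsFactors = FALSE)
  df <- df[order(df$g1, df$g2, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Jaccard similarity coefficient of two term sets
#'
#' JC(S1, S2) = |S1 n S2| / |S1 u S2|, in [0, 1]. Two empty sets give 0
#' rather than 0/0; a zero coefficient marks the gene pair as sharing no
#' annotation, which makes the enclosing sub-pathway non-viable.
#'
#' @param set_a,set_b character vectors of term identifiers.
#' @return Numeric scalar in [0, 1].
#' @examples
#' jaccard(c("a", "b", "c"), c("b", "c", "d"))  # 2/4 = 0.5
#' @export
jaccard <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  u <- length(set_a) + length(set_b) - (i <- sum(set_a %in% set_b))
  if (u == 0L) return(0)
  i / u
}

#' Jaccard score of a sub-pathway in one annotation namespace
#'
#' JS_X(T, G1, G2) = ( JC([T]_X, [G1]_X) + JC([G1]_X, [G2]_X) ) / 2,
#' where [G]_X is the set of namespace-X terms annotating gene G. A
#' sub-pathway is viable in X only when both hop-wise coefficients are
#' strictly positive; a zero hop means the pair shares no annotation and
#' the sub-pathway is discarded.
#'
#' @param target,g1,g2 gene symbols of the sub-pathway.
#' @param catalog an [annotation_catalog()] (namespace BP or MF).
#' @return List with `score` (the mean of the two JCs), `jc1`, `jc2`,
#'   and `viable` (both JCs > 0).
#' @export
js_score <- function(target, g1, g2, catalog) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  jc1 <- jaccard(gene_terms(catalog, target), gene_terms(catalog, g1))
  jc2 <- jaccard(gene_terms(catalog, g1), gene_terms(catalog, g2))
  list(score = (jc1 + jc2) / 2, jc1 = jc1, jc2 = jc2,
       viable = jc1 > 0 && jc2 > 0)
}

choose_exact_limit <- 2^53

#' Hypergeometric overlap p-value for a gene pair
#'
#' Probability that two term sets of sizes `size_a` and `size_b`, drawn
#' from a universe of `universe` terms, share exactly `shared` terms:
#' the hypergeometric point probability
#' C(size_a, shared) C(universe - size_a, size_b - shared) /
#' C(universe, size_b). With `tail = TRUE` the upper-tail sum over
#' overlaps >= `shared` is returned instead (an enrichment-style
#' p-value); the point form is the default.
#'
#' Binomial coefficients are taken as exact integer-valued doubles while
#' they fit the double-precision integer range, with a log-gamma fall
#' back for large universes.
#'
#' @param size_a,size_b term-set sizes (x and y).
#' @param shared observed overlap count (n).
#' @param universe total number of distinct terms in the namespace (N).
#' @param tail return the upper-tail sum instead of the point
#'   probability.
#' @return Probability in [0, 1].
#' @examples
#' pair_pvalue(3, 2, 1, 5)  # C(3,1)*C(2,1)/C(5,2) = 0.6
#' @export
pair_pvalue <- function(size_a, size_b, shared, universe, tail = FALSE) {
  x <- size_a; y <- size_b; n <- shared; N <- universe
  ok <- length(x) == 1 && length(y) == 1 && length(n) == 1 && length(N) == 1 &&
    all(c(x, y, n, N) >= 0) && all(c(x, y, n, N) == round(c(x, y, n, N))) &&
    x <= N && y <= N && n <= min(x, y) && n >= x + y - N
  if (!ok)
    stop(sprintf("infeasible overlap: size_a=%s size_b=%s shared=%s universe=%s",
                 size_a, size_b, shared, universe))
  ks <- if (tail) n:min(x, y) else n
  sum(vapply(ks, hyper_point, numeric(1), x = x, y = y, N = N))
}

hyper_point <- function(k, x, y, N) {
  num1 <- choose(x, k); num2 <- choose(N - x, y - k); den <- choose(N, y)
  if (num1 < choose_exact_limit && num2 < choose_exact_limit &&
      den < choose_exact_limit && num1 * num2 < choose_exact_limit) {
    (num1 * num2) / den
  } else {
    exp(lchoose(x, k) + lchoose(N - x, y - k) - lchoose(N, y))
  }
}

#' Literal triple-binomial form of the pair p-value
#'
#' Evaluates C(N, n) C(N - n, x - n) C(N - x, y - n) / (C(N, x) C(N, y))
#' in log space. This printed form is algebraically identical to the
#' hypergeometric point probability computed by [pair_pvalue()]; it is
#' kept as an independent evaluation route and is the form used by the
#' fixture oracle [expected_scores()].
#'
#' @inheritParams pair_pvalue
#' @return Probability in [0, 1].
#' @export
pair_pvalue_literal <- function(size_a, size_b, shared, universe) {
  x <- size_a; y <- size_b; n <- shared; N <- universe
  exp(lchoose(N, n) + lchoose(N - n, x - n) + lchoose(N - x, y - n) -
        lchoose(N, x) - lchoose(N, y))
}

#' Score one sub-pathway: Jaccard scores, viability, and p-value
#'
#' Computes both namespace Jaccard scores (JS_BP, JS_MF) and, in the
#' selected ranking namespace, the two hop-wise overlap p-values P1 (for
#' the T-G1 pair) and P2 (for G1-G2). The sub-pathway's p-value is the
#' greater of P1 and P2. Viability is gated on the selected namespace:
#' if either hop-wise Jaccard coefficient there is zero the sub-pathway
#' is discarded (`NULL` is returned).
#'
#' @param target,g1,g2 gene symbols of the sub-pathway.
#' @param bp,mf the BP and MF [annotation_catalog()]s.
#' @param namespace `"BP"` or `"MF"`: the namespace used for the
#'   viability gate and the p-value.
#' @param pathway_catalog optional PATHWAY catalog for pathway tags
#'   (see [assign_pathways()]).
#' @param tail use upper-tail p-values (see [pair_pvalue()]).
#' @param pathway_rule `"all"` or `"any"`, passed to [assign_pathways()].
#' @return One-row data.frame (`target`, `g1`, `g2`, `js_bp`, `js_mf`,
#'   `viable_bp`, `viable_mf`, `p1`, `p2`, `p_value`, `pathways` as a
#'   `;`-joined string), or `NULL` when not viable in the selected
#'   namespace.
#' @export
score_rsp <- function(target, g1, g2, bp, mf, namespace = c("BP", "MF"),
                      pathway_catalog = NULL, tail = FALSE,
                      pathway_rule = c("all", "any")) {
  namespace <- match.arg(namespace)
  pathway_rule <- match.arg(pathway_rule)
  sb <- js_score(target, g1, g2, bp)
  sm <- js_score(target, g1, g2, mf)
  sel <- if (namespace == "BP") sb else sm
  if (!sel$viable) return(NULL)
  cat_sel <- if (namespace == "BP") bp else mf
  ts <- gene_terms(cat_sel, target)
  g1s <- gene_terms(cat_sel, g1)
  g2s <- gene_terms(cat_sel, g2)
  N <- cat_sel$universe_size
  p1 <- pair_pvalue(length(ts), length(g1s), sum(ts %in% g1s), N, tail = tail)
  p2 <- pair_pvalue(length(g1s), length(g2s), sum(g1s %in% g2s), N, tail = tail)
  pw <- if (is.null(pathway_catalog)) character(0)
        else assign_pathways(target, g1, g2, pathway_catalog, rule = pathway_rule)
  data.frame(target = target, g1 = g1, g2 = g2,
             js_bp = sb$score, js_mf = sm$score,
             viable_bp = sb$viable, viable_mf = sm$viable,
             p1 = p1, p2 = p2, p_value = max(p1, p2),
             pathways = paste(pw, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Pathways containing a sub-pathway
#'
#' Returns the ids of pathways whose gene set contains the sub-pathway.
#' Under the default `"all"` rule a pathway must contain all three genes
#' T, G1, G2; under `"any"` one member suffices.
#'
#' @param target,g1,g2 gene symbols.
#' @param pathway_catalog a PATHWAY [annotation_catalog()].
#' @param rule `"all"` (default) or `"any"`.
#' @return Sorted character vector of pathway ids (possibly empty).
#' @export
assign_pathways <- function(target, g1, g2, pathway_catalog,
                            rule = c("all", "any")) {
  rule <- match.arg(rule)
  pt <- gene_terms(pathway_catalog, target)
  p1 <- gene_terms(pathway_catalog, g1)
  p2 <- gene_terms(pathway_catalog, g2)
  ids <- if (rule == "all") intersect(intersect(pt, p1), p2)
         else unique(c(pt, p1, p2))
  sort(ids, method = "radix")
}

# Enumerate and score every viable sub-pathway of one target.
# Returns the scored records data.frame (possibly zero rows).
score_target_rsps <- function(target, bundle, namespace, tail = FALSE,
                              pathway_rule = "all") {
  rsps <- enumerate_rsps(target, bundle$ppi)
  if (nrow(rsps) == 0L)
    return(empty_records())
  rows <- vector("list", nrow(rsps))
  for (i in seq_len(nrow(rsps))) {
    rows[[i]] <- score_rsp(rsps$target[i], rsps$g1[i], rsps$g2[i],
                           bundle$bp, bundle$mf, namespace,
                           pathway_catalog = bundle$assoc$pathway_catalog,
                           tail = tail, pathway_rule = pathway_rule)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows) == 0L) empty_records() else do.call(rbind, rows)
  attr(out, "n_raw") <- nrow(rsps)
  out
}

empty_records <- function() {
  data.frame(target = character(0), g1 = character(0), g2 = character(0),
             js_bp = numeric(0), js_mf = numeric(0),
             viable_bp = logical(0), viable_mf = logical(0),
             p1 = numeric(0), p2 = numeric(0), p_value = numeric(0),
             pathways = character(0), stringsAsFactors = FALSE)
}
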