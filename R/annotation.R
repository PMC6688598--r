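#' Annotation catalogs
#'
#' An annotation catalog maps gene symbols to sets of annotation-term
#' identifiers within a single namespace: Gene Ontology Biological Process
#' (`"BP"`), Molecular Function (`"MF"`), or reaction pathways
#' (`"PATHWAY"`, e.g. KEGG). The catalog also carries the term-universe
#' size `N`, the number of distinct terms annotating at least one gene,
#' which is the universe parameter of the hypergeometric overlap test.
#'
#' @param term_sets named list; one character vector of term ids per gene.
#' @param namespace one of `"BP"`, `"MF"`, `"PATHWAY"`.
#' @return An object of class `annotation_catalog` with fields
#'   `namespace`, `term_sets` (named list, genes to sorted unique term
#'   ids), `universe` (sorted vector of all distinct terms) and
#'   `universe_size` (`N`).
#' @examples
#' cat <- annotation_catalog(list(A = c("T1", "T2"), B = "T2"), "BP")
#' cat$universe_size
#' gene_terms(cat, "A")
#' gene_terms(cat, "unknown")   # empty set
#' @export
annotation_catalog <- function(term_sets, namespace = c("BP", "MF", "PATHWAY")) {
  namespace <- match.arg(namespace)
  stopifnot(is.list(term_sets))
  if (length(term_sets) > 0L && is.null(names(term_sets)))
    stop("term_sets must be a named list (gene -> term ids)")
  term_sets <- lapply(term_sets, function(x) sort(unique(as.character(x)), method = "radix"))
  universe <- sort(unique(unlist(term_sets, use.names = FALSE)), method = "radix")
  structure(
    list(namespace = namespace, term_sets = term_sets,
         universe = universe, universe_size = length(universe)),
    class = "annotation_catalog")
}

#' @export
print.annotation_catalog <- function(x, ...) {
  cat(sprintf("annotation_catalog [%s]: %d genes, %d terms (N)\n",
              x$namespace, length(x$term_sets), x$universe_size))
  invisible(x)
}

#' Terms annotating a gene
#'
#' Looks up a gene's term set in a catalog. A gene absent from the
#' annotation source has the empty term set; such genes are later removed
#' from results by the zero-Jaccard viability rule rather than at load.
#'
#' @param catalog an [annotation_catalog()].
#' @param gene a gene symbol (case-sensitive).
#' @return Character vector of term ids (possibly empty).
#' @export
gene_terms <- function(catalog, gene) {
  ts <- catalog$term_sets[[gene]]
  if (is.null(ts)) character(0) else ts
}

#' Read a GMT gene-set file into an annotation catalog
#'
#' Standard GMT: one term per line, tab-separated
#' `term_id<TAB>description<TAB>gene1<TAB>gene2...`. The term-to-genes
#' lines are inverted into a gene-to-terms map. Duplicate term lines are
#' merged by union of their gene lists. Lines starting with `#` are
#' skipped.
#'
#' @param path path to a GMT file.
#' @inheritParams annotation_catalog
#' @return An [annotation_catalog()].
#' @export
read_gmt <- function(path, namespace = c("BP", "MF", "PATHWAY")) {
  namespace <- match.arg(namespace)
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  gene2terms <- new.env(parent = emptyenv())
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stop(sprintf("malformed GMT line %d in %s: fewer than 3 tab-separated fields", i, path))
    term <- fields[[1]]
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    for (g in genes)
      assign(g, c(if (exists(g, envir = gene2terms, inherits = FALSE))
        get(g, envir = gene2terms), term), envir = gene2terms)
  }
  annotation_catalog(as.list(gene2terms), namespace)
}

#' Write an annotation catalog to a GMT file
#'
#' Inverse of [read_gmt()]: the gene-to-terms map is re-inverted to
#' term-to-genes lines, written in sorted term order with sorted gene
#' lists, so that write followed by reload yields an equal catalog.
#'
#' @param catalog an [annotation_catalog()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(catalog, path) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  genes <- names(catalog$term_sets)
  pairs_gene <- rep(genes, lengths(catalog$term_sets))
  pairs_term <- unlist(catalog$term_sets, use.names = FALSE)
  by_term <- split(pairs_gene, pairs_term)
  terms <- sort(names(by_term), method = "radix")
  lines <- vapply(terms, function(tm) {
    paste(c(tm, "na", sort(unique(by_term[[tm]]), method = "radix")), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Test two annotation catalogs for equality
#' @param a,b catalogs to compare.
#' @return `TRUE` if namespace, gene set and every term set agree.
#' @export
catalog_equal <- function(a, b) {
  if (a$namespace != b$namespace) return(FALSE)
  ga <- sort(names(a$term_sets), method = "radix")
  gb <- sort(names(b$term_sets), method = "radix")
  if (!identical(ga, gb)) return(FALSE)
  all(vapply(ga, function(g) identical(a$term_sets[[g]], b$term_sets[[g]]), logical(1)))
}
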