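#' @keywords internal
"_PACKAGE"

#' Validation methods treated as direct experimental evidence
#'
#' The seven direct assay types used by the "experimentally validated"
#' target filter: HITS-CLIP, PAR-CLIP, IMPACT-Seq, CLASH, Luciferase
#' Reporter Assay, 3LIFE, and Genetic Testing.
#'
#' @return Character vector of method names.
#' @export
direct_validation_methods <- function() {
  c("HITS-CLIP", "PAR-CLIP", "IMPACT-Seq", "CLASH",
    "Luciferase Reporter Assay", "3LIFE", "Genetic Testing")
}

table_roles <- c("bp", "mf", "pathway", "ppi",
                 "disease_mirna", "mirna_target", "tissue", "cancer_tags")

read_tsv_table <- function(path, required, role) {
  if (is.null(path) || !file.exists(path))
    stop(sprintf("input table '%s' not found%s", role,
                 if (is.null(path)) " (missing from config)" else paste0(": ", path)))
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop(sprintf("table '%s' (%s) lacks column(s): %s",
                 role, path, paste(missing, collapse = ", ")))
  df
}

#' Load a complete dataset bundle from a config file or fixture directory
#'
#' Reads and cross-validates the input tables the pipeline consumes:
#' GO BP and MF gene sets plus pathway gene sets (GMT), a PPI edge list,
#' disease-to-miRNA associations, miRNA-to-target associations with
#' validation-method evidence and regulation direction, gene-to-tissue
#' labels, and gene-to-cancer-tag labels (CRG/OCG/TSG).
#'
#' `config` may be a YAML file with a `tables:` block naming a path per
#' role (`bp`, `mf`, `pathway`, `ppi`, `disease_mirna`, `mirna_target`,
#' `tissue`, `cancer_tags`; relative paths resolve against the config
#' file's directory) and an optional `options:` block with query
#' defaults, or a directory containing `config.yaml`. Loading is
#' idempotent: re-reading the same files yields an equal bundle.
#'
#' Unknown validation-method strings (outside
#' [direct_validation_methods()] plus `options$extra_methods`) warn but
#' do not fail. Cancer tags outside CRG/OCG/TSG are an error.
#'
#' @param config path to a YAML config file or a fixture directory.
#' @param quiet suppress the per-table count report.
#' @return An object of class `dataset_bundle` with fields `bp`, `mf`,
#'   `ppi` and `assoc` (list: `disease_mirnas`, `mirna_targets`,
#'   `gene_tissues`, `cancer_tags`, `pathway_catalog`), plus `options`
#'   from the config.
#' @export
load_bundle <- function(config, quiet = FALSE) {
  if (dir.exists(config)) config <- file.path(config, "config.yaml")
  if (!file.exists(config)) stop("config file not found: ", config)
  cfg <- yaml::read_yaml(config)
  if (is.null(cfg$tables)) stop("config has no 'tables' block: ", config)
  base <- dirname(normalizePath(config))
  paths <- lapply(cfg$tables, function(p)
    if (grepl("^/", p)) p else file.path(base, p))
  missing_roles <- setdiff(table_roles, names(paths))
  if (length(missing_roles) > 0L)
    stop("config missing table role(s): ", paste(missing_roles, collapse = ", "))

  bp <- read_gmt(paths$bp, "BP")
  mf <- read_gmt(paths$mf, "MF")
  pathway <- read_gmt(paths$pathway, "PATHWAY")
  ppi <- read_ppi(paths$ppi)

  dm <- read_tsv_table(paths$disease_mirna, c("disease", "mirna"), "disease_mirna")
  mt <- read_tsv_table(paths$mirna_target,
                       c("mirna", "gene", "methods", "direction"), "mirna_target")
  ti <- read_tsv_table(paths$tissue, c("gene", "tissue"), "tissue")
  ct <- read_tsv_table(paths$cancer_tags, c("gene", "tag"), "cancer_tags")

  bad_dir <- setdiff(unique(mt$direction), c("positive", "negative"))
  if (length(bad_dir) > 0L)
    stop("mirna_target direction must be positive/negative; got: ",
         paste(bad_dir, collapse = ", "))
  bad_tag <- setdiff(unique(ct$tag), c("CRG", "OCG", "TSG"))
  if (length(bad_tag) > 0L)
    stop("cancer tag must be CRG/OCG/TSG; got: ", paste(bad_tag, collapse = ", "))

  vocab <- unique(c(direct_validation_methods(),
                    unlist(cfg$options$extra_methods)))
  seen <- unique(unlist(strsplit(mt$methods, ";", fixed = TRUE)))
  seen <- trimws(seen[nzchar(seen)])
  unknown <- setdiff(seen, vocab)
  if (length(unknown) > 0L)
    warning("unknown validation method(s): ", paste(unknown, collapse = ", "),
            call. = FALSE)

  # every disease needs >= 1 miRNA row; miRNAs without targets are logged
  no_targets <- setdiff(unique(dm$mirna), unique(mt$mirna))
  if (length(no_targets) > 0L && !quiet)
    message("miRNA(s) with no target rows (empty target sets): ",
            paste(sort(no_targets, method = "radix"), collapse = ", "))

  bundle <- structure(
    list(bp = bp, mf = mf, ppi = ppi,
         assoc = list(
           disease_mirnas = dm[order(dm$disease, dm$mirna, method = "radix"), ,
                               drop = FALSE],
           mirna_targets = mt[order(mt$mirna, mt$gene, method = "radix"), ,
                              drop = FALSE],
           gene_tissues = ti[order(ti$gene, ti$tissue, method = "radix"), ,
                             drop = FALSE],
           cancer_tags = stats::setNames(ct$tag, ct$gene),
           pathway_catalog = pathway),
         options = if (is.null(cfg$options)) list() else cfg$options),
    class = "dataset_bundle")
  rownames(bundle$assoc$disease_mirnas) <- NULL
  rownames(bundle$assoc$mirna_targets) <- NULL
  rownames(bundle$assoc$gene_tissues) <- NULL
  if (!quiet) {
    message(sprintf(
      "loaded bundle: %d BP terms, %d MF terms, %d pathways, %d PPI edges, %d disease-miRNA rows, %d miRNA-target rows, %d tissue rows, %d cancer tags",
      bp$universe_size, mf$universe_size, pathway$universe_size,
      nrow(ppi$edges), nrow(dm), nrow(mt), nrow(ti),
      length(bundle$assoc$cancer_tags)))
  }
  bundle
}

#' @export
print.dataset_bundle <- function(x, ...) {
  cat("dataset_bundle\n")
  cat(sprintf("  BP: N=%d terms over %d genes\n", x$bp$universe_size, length(x$bp$term_sets)))
  cat(sprintf("  MF: N=%d terms over %d genes\n", x$mf$universe_size, length(x$mf$term_sets)))
  cat(sprintf("  pathways: %d\n", x$assoc$pathway_catalog$universe_size))
  cat(sprintf("  PPI: %d nodes, %d edges\n", length(x$ppi$nodes), nrow(x$ppi$edges)))
  cat(sprintf("  diseases: %d, miRNAs: %d\n",
              length(unique(x$assoc$disease_mirnas$disease)),
              length(unique(x$assoc$disease_mirnas$mirna))))
  invisible(x)
}

#' Tissues recorded for a gene
#' @param bundle a [load_bundle()] result.
#' @param gene gene symbol.
#' @return Character vector of tissue labels (empty if unannotated).
#' @export
gene_tissues <- function(bundle, gene) {
  ti <- bundle$assoc$gene_tissues
  ti$tissue[ti$gene == gene]
}
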