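#' Run a single-disease (or miRNA-centric) query end to end
#'
#' Executes select -> enumerate/score -> filter -> (optional top-N) ->
#' assemble -> export, writing `rsps.tsv`, the network files and a
#' `report.yaml` into `out_dir`.
#'
#' @param bundle a [load_bundle()] result, or a path accepted by
#'   [load_bundle()].
#' @param query a [query_spec()]; defaults (namespace, p-threshold) can
#'   come from the bundle config via [query_from_options()].
#' @param out_dir output directory; created if needed.
#' @param formats network export formats, see [write_network()].
#' @return A `run_report` (list of per-stage counts and output paths),
#'   invisibly.
#' @export
run_single <- function(bundle, query, out_dir,
                       formats = c("sif", "graphml", "json", "nodes")) {
  t0 <- Sys.time()
  if (is.character(bundle)) bundle <- load_bundle(bundle, quiet = TRUE)
  stopifnot(inherits(query, "query_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- select_disease_inputs(query, bundle)
  records <- build_mrsp_set(inputs, bundle, query)
  n_postfilter <- nrow(records)
  if (!is.null(query$top_n)) records <- top_rsps(records, query$top_n)
  net <- assemble_network(records, bundle$ppi, bundle)
  rsps_path <- file.path(out_dir, "rsps.tsv")
  write_rsps_tsv(records, rsps_path)
  net_paths <- write_network(net, out_dir, formats = formats)
  report <- structure(list(
    query = unclass(query)[!vapply(unclass(query), is.null, logical(1))],
    counts = list(
      mirnas = length(inputs),
      targets = length(unique(unlist(inputs, use.names = FALSE))),
      raw_rsps = attr(records, "n_raw") %||% attr(records, "n_raw"),
      viable_rsps = attr(records, "n_viable"),
      postfilter_rsps = n_postfilter,
      exported_rsps = nrow(records),
      network_nodes = nrow(net$nodes),
      network_edges = nrow(net$edges)),
    outputs = c(rsps_path, net_paths),
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "run_report")
  report$counts$raw_rsps <- attr(records, "n_raw")
  yaml::write_yaml(report_to_yaml(report), file.path(out_dir, "report.yaml"))
  report$outputs <- c(report$outputs, file.path(out_dir, "report.yaml"))
  invisible(report)
}

#' Run a comorbidity (disease-pair) query
#'
#' Runs each disease as a single query (disease 1 with `tissue`,
#' disease 2 with `tissue2`), intersects the two sub-pathway gene sets
#' with [comorbid_genes()], and writes per-disease outputs under
#' `disease1/` and `disease2/` plus `comorbid_genes.tsv` and a combined
#' report.
#'
#' @inheritParams run_single
#' @return A `run_report` with per-disease counts and the comorbid gene
#'   count, invisibly.
#' @export
run_comorbid <- function(bundle, query, out_dir,
                         formats = c("sif", "graphml", "json", "nodes")) {
  t0 <- Sys.time()
  if (is.character(bundle)) bundle <- load_bundle(bundle, quiet = TRUE)
  stopifnot(inherits(query, "query_spec"))
  if (is.null(query$disease2)) stop("comorbidity query needs disease2")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  run_one <- function(which) {
    inputs <- select_disease_inputs(query, bundle, which_disease = which)
    records <- build_mrsp_set(inputs, bundle, query, which_disease = which)
    n_post <- nrow(records)
    if (!is.null(query$top_n)) records <- top_rsps(records, query$top_n)
    sub <- file.path(out_dir, paste0("disease", which))
    dir.create(sub, showWarnings = FALSE)
    write_rsps_tsv(records, file.path(sub, "rsps.tsv"))
    net <- assemble_network(records, bundle$ppi, bundle)
    write_network(net, sub, formats = formats)
    list(inputs = inputs, records = records, n_post = n_post, net = net)
  }
  r1 <- run_one(1L)
  r2 <- run_one(2L)
  genes <- comorbid_genes(r1$records, r2$records, bundle)
  write_comorbid_tsv(genes, file.path(out_dir, "comorbid_genes.tsv"))
  per_disease <- function(r) list(
    mirnas = length(r$inputs),
    targets = length(unique(unlist(r$inputs, use.names = FALSE))),
    raw_rsps = attr(r$records, "n_raw"),
    viable_rsps = attr(r$records, "n_viable"),
    postfilter_rsps = r$n_post,
    exported_rsps = nrow(r$records),
    network_nodes = nrow(r$net$nodes),
    network_edges = nrow(r$net$edges))
  report <- structure(list(
    query = unclass(query)[!vapply(unclass(query), is.null, logical(1))],
    counts = list(disease1 = per_disease(r1), disease2 = per_disease(r2),
                  comorbid_genes = nrow(genes)),
    outputs = file.path(out_dir,
                        c("disease1/rsps.tsv", "disease2/rsps.tsv",
                          "comorbid_genes.tsv")),
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "run_report")
  yaml::write_yaml(report_to_yaml(report), file.path(out_dir, "report.yaml"))
  invisible(report)
}

#' Generate a fixture from the command line front end
#'
#' Thin wrapper over [generate_fixture()]: builds a [fixture_spec()]
#' from a seed (plus optional overrides) and writes the fixture.
#'
#' @param out_dir output directory.
#' @param seed master seed.
#' @param ... overrides passed to [fixture_spec()].
#' @return `out_dir`, invisibly.
#' @export
run_genfixture <- function(out_dir, seed = 1L, ...) {
  generate_fixture(fixture_spec(seed = seed, ...), out_dir)
  invisible(out_dir)
}

#' Build a query_spec using defaults from a bundle's config options
#'
#' Any argument not supplied explicitly falls back to the `options`
#' block of the bundle's config file (`namespace`, `p_threshold`), then
#' to the [query_spec()] defaults.
#'
#' @param bundle a [load_bundle()] result.
#' @param disease disease name or miRNA id.
#' @param ... further [query_spec()] arguments.
#' @return A [query_spec()].
#' @export
query_from_options <- function(bundle, disease, ...) {
  args <- list(...)
  opts <- bundle$options
  if (is.null(args$namespace) && !is.null(opts$namespace))
    args$namespace <- opts$namespace
  if (is.null(args$p_threshold) && !is.null(opts$p_threshold))
    args$p_threshold <- opts$p_threshold
  do.call(query_spec, c(list(disease = disease), args))
}

report_to_yaml <- function(report) {
  r <- unclass(report)
  r$query$validated_methods <- as.list(r$query$validated_methods)
  r
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report\n")
  utils::str(x$counts, give.attr = FALSE, no.list = TRUE)
  cat(sprintf("  wall time: %.2f s\n", x$wall_time_s))
  invisible(x)
}
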