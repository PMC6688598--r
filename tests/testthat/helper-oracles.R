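# Independent oracles and shared fixtures for the test suite.

# Exhaustive ordered-triple enumeration oracle: every ordered (T, G1, G2)
# over the node set with both hops present and all three genes distinct.
brute_force_rsps <- function(target, edges) {
  nodes <- sort(unique(c(edges$a, edges$b)), method = "radix")
  ekey <- c(paste(edges$a, edges$b, sep = "\r"),
            paste(edges$b, edges$a, sep = "\r"))
  has <- function(u, v) paste(u, v, sep = "\r") %in% ekey
  out <- list()
  for (g1 in nodes) for (g2 in nodes) {
    if (g1 != target && g2 != target && g2 != g1 &&
        has(target, g1) && has(g1, g2))
      out[[length(out) + 1L]] <- data.frame(target = target, g1 = g1, g2 = g2,
                                            stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(target = character(0), g1 = character(0),
                      g2 = character(0), stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  df[order(df$g1, df$g2, method = "radix"), , drop = FALSE]
}

# Random undirected edge list on n nodes, edge probability p.
random_edges <- function(n, p) {
  pairs <- utils::combn(sprintf("N%02d", seq_len(n)), 2L)
  keep <- stats::runif(ncol(pairs)) < p
  data.frame(a = pairs[1, keep], b = pairs[2, keep], stringsAsFactors = FALSE)
}

# Exact fraction of y-subsets of 1..N whose intersection with the fixed
# x-subset 1..x has exactly n elements (subset-enumeration oracle).
subset_overlap_fraction <- function(x, y, n, N) {
  if (y == 0L) return(as.numeric(n == 0L))
  subsets <- utils::combn(N, y)
  hits <- sum(apply(subsets, 2, function(s) sum(s <= x) == n))
  hits / ncol(subsets)
}

# Literal triple-binomial expression, exact integer-valued choose().
literal_num_den <- function(x, y, n, N) {
  c(num = choose(N, n) * choose(N - n, x - n) * choose(N - x, y - n),
    den = choose(N, x) * choose(N, y))
}

# Shared fixture directory, generated once per session per seed.
fixture_dir <- function(seed = 1L) {
  d <- file.path(tempdir(), sprintf("rspnet_fixture_%d", seed))
  if (!dir.exists(d)) generate_fixture(fixture_spec(seed = seed), d)
  d
}

fixture_bundle <- function(seed = 1L) {
  suppressMessages(load_bundle(fixture_dir(seed), quiet = TRUE))
}

fixture_manifest <- function(seed = 1L) {
  yaml::read_yaml(file.path(fixture_dir(seed), "manifest.yaml"))
}

# A hand-built miniature dataset whose every score is checkable on
# paper.  BP/MF universes are {t1..t4}/{m1..m4}; from target T1 the
# paths through A are annotation-sharing while the C branch has a
# zero-overlap first hop.
tiny_dir <- function() {
  d <- file.path(tempdir(), "rspnet_tiny")
  if (dir.exists(d)) return(d)
  dir.create(d)
  w <- function(lines, f) writeLines(lines, file.path(d, f))
  w(c("t1\tna\tT1\tT2\tT3", "t2\tna\tT1\tT2\tT3\tA",
      "t3\tna\tA\tB", "t4\tna\tB"), "go_bp.gmt")
  w(c("m1\tna\tT1\tT2\tT3", "m2\tna\tT1\tT2\tT3\tA",
      "m3\tna\tA\tB", "m4\tna\tB"), "go_mf.gmt")
  w(c("P1\tna\tT1\tA\tB", "P2\tna\tA\tB"), "pathways.gmt")
  w(c("gene_a\tgene_b", "T1\tA", "T2\tA", "T3\tA", "A\tB", "T1\tC", "C\tB"),
    "ppi.tsv")
  w(c("disease\tmirna\tsource", "dA\tm1\tlit", "dA\tm2\tlit", "dB\tm3\tlit"),
    "disease_mirna.tsv")
  w(c("mirna\tgene\tmethods\tdirection",
      "m1\tT1\tCLASH\tnegative",
      "m1\tT2\tMicroarray\tnegative",
      "m2\tT3\tLuciferase Reporter Assay\tnegative",
      "m3\tT3\tPAR-CLIP\tnegative"), "mirna_target.tsv")
  w(c("gene\ttissue", "T1\ttx", "T2\ttx", "T3\ttx", "A\ttx", "B\ttx",
      "T1\tty"), "tissue.tsv")
  w(c("gene\ttag", "T1\tCRG", "A\tOCG", "B\tTSG"), "cancer_tags.tsv")
  yaml::write_yaml(list(
    tables = list(bp = "go_bp.gmt", mf = "go_mf.gmt",
                  pathway = "pathways.gmt", ppi = "ppi.tsv",
                  disease_mirna = "disease_mirna.tsv",
                  mirna_target = "mirna_target.tsv",
                  tissue = "tissue.tsv", cancer_tags = "cancer_tags.tsv"),
    options = list(namespace = "BP", p_threshold = 1,
                   extra_methods = list("Microarray"))),
    file.path(d, "config.yaml"))
  d
}

tiny_bundle <- function() {
  suppressMessages(suppressWarnings(load_bundle(tiny_dir(), quiet = TRUE)))
}

dir_checksums <- function(d) {
  files <- sort(list.files(d, recursive = TRUE), method = "radix")
  stats::setNames(tools::md5sum(file.path(d, files)), files)
}
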