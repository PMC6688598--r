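#' Specification for a synthetic dataset fixture
#'
#' Controls the size and overlap structure of a generated dataset
#' bundle. Defaults describe a small but realistic benchmark: 500
#' background genes with a PPI density giving about 2,000 expected
#' edges, 300 BP and 150 MF terms with 3-10 terms per gene, 40
#' pathways, 4 diseases with 3 miRNAs of 3 targets each, 6 tissues and
#' 15% of genes carrying a cancer tag.
#'
#' On top of the random background, a PPI-isolated planted component is
#' always injected: two planted targets (`TGT1`, `TGT2`, one per
#' planted disease) joined to a shared interactor branch `SHB1`-`SHB2`
#' with hand-set term overlaps, and a decoy gene `DCY1` with no
#' annotations whose paths are non-viable by the zero-Jaccard rule.
#'
#' @param seed master seed; each table draws from its own stream
#'   derived from it.
#' @param n_genes background genes.
#' @param n_terms_bp,n_terms_mf background term-universe sizes.
#' @param n_pathways background pathway count.
#' @param ppi_density expected edge probability between background
#'   genes.
#' @param terms_per_gene length-2 integer range of terms per gene and
#'   namespace.
#' @param edge_overlap_boost probability that an interacting background
#'   pair is given an extra shared term (raises typical Jaccard overlap
#'   of interacting pairs).
#' @param n_diseases total diseases (>= 2; the first two carry the
#'   planted comorbidity pair).
#' @param mirnas_per_disease,targets_per_mirna background association
#'   sizes.
#' @param n_tissues tissue labels.
#' @param cancer_tag_fraction fraction of background genes tagged
#'   CRG/OCG/TSG.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_genes = 500L,
                         n_terms_bp = 300L, n_terms_mf = 150L,
                         n_pathways = 40L, ppi_density = 0.016,
                         terms_per_gene = c(3L, 10L),
                         edge_overlap_boost = 0.3,
                         n_diseases = 4L, mirnas_per_disease = 3L,
                         targets_per_mirna = 3L, n_tissues = 6L,
                         cancer_tag_fraction = 0.15) {
  sp <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
             n_terms_bp = as.integer(n_terms_bp),
             n_terms_mf = as.integer(n_terms_mf),
             n_pathways = as.integer(n_pathways),
             ppi_density = ppi_density,
             terms_per_gene = as.integer(terms_per_gene),
             edge_overlap_boost = edge_overlap_boost,
             n_diseases = as.integer(n_diseases),
             mirnas_per_disease = as.integer(mirnas_per_disease),
             targets_per_mirna = as.integer(targets_per_mirna),
             n_tissues = as.integer(n_tissues),
             cancer_tag_fraction = cancer_tag_fraction)
  counts <- c(sp$n_genes, sp$n_terms_bp, sp$n_terms_mf, sp$n_pathways,
              sp$mirnas_per_disease, sp$targets_per_mirna, sp$n_tissues)
  if (any(counts < 1L)) stop("all fixture counts must be positive")
  if (sp$n_diseases < 2L)
    stop("n_diseases must be >= 2 (the planted comorbidity pair occupies two)")
  probs <- c(sp$ppi_density, sp$edge_overlap_boost, sp$cancer_tag_fraction)
  if (any(probs < 0) || any(probs > 1))
    stop("probabilities must lie in [0, 1]")
  if (length(sp$terms_per_gene) != 2L ||
      sp$terms_per_gene[1] > sp$terms_per_gene[2])
    stop("terms_per_gene must be a (lo, hi) range")
  if (sp$terms_per_gene[2] > min(sp$n_terms_bp, sp$n_terms_mf))
    stop("terms_per_gene exceeds the term universe")
  if (sp$n_terms_bp < 5L || sp$n_terms_mf < 5L)
    stop("need at least 5 terms per namespace for the planted overlaps")
  if (sp$n_genes < sp$n_diseases * sp$mirnas_per_disease * sp$targets_per_mirna)
    stop("n_genes too small for the requested association table")
  structure(sp, class = "fixture_spec")
}

with_stream <- function(seed, k, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed + 1000L * k, kind = "Mersenne-Twister")
  expr
}

planted_genes <- c("TGT1", "TGT2", "SHB1", "SHB2", "DCY1", "DCY2")

#' Generate a synthetic dataset fixture with planted ground truth
#'
#' Writes the full set of input tables consumed by [load_bundle()]
#' (GO BP, GO MF and pathway GMT files; PPI, disease-miRNA,
#' miRNA-target, tissue and cancer-tag TSVs; a `config.yaml`) plus a
#' `manifest.yaml` recording the planted ground truth. The same seed
#' always produces byte-identical files; each table is drawn from its
#' own pseudo-random stream so table sizes can change independently.
#'
#' Planted structure (isolated from the background PPI component):
#' \itemize{
#'   \item Disease 1's miRNA targets `TGT1`, disease 2's targets `TGT2`;
#'     edges `TGT1-SHB1`, `TGT2-SHB1`, `SHB1-SHB2` make the shared
#'     branch, so each disease's viable sub-pathways are
#'     `(TGTi, SHB1, SHB2)` and the cross path `(TGTi, SHB1, TGTj)` and
#'     the comorbid gene set is exactly
#'     `{SHB1, SHB2, TGT1, TGT2}`.
#'   \item Term sets are fixed so each planted sub-pathway has overlaps
#'     x=3, y=3, z=3, n1=2, n2=2 in both namespaces.
#'   \item `DCY1` carries no annotation, so the decoy paths
#'     `(TGTi, DCY1, *)` have a zero-Jaccard first hop and must be
#'     discarded.
#' }
#'
#' @param spec a [fixture_spec()].
#' @param outdir output directory (created if needed).
#' @return The manifest, invisibly (also written as
#'   `manifest.yaml`).
#' @export
generate_fixture <- function(spec = fixture_spec(), outdir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  genes <- sprintf("GEN%04d", seq_len(spec$n_genes))
  bp_terms <- sprintf("BP%04d", seq_len(spec$n_terms_bp))
  mf_terms <- sprintf("MF%04d", seq_len(spec$n_terms_mf))
  tissues <- sprintf("tissue_%d", seq_len(spec$n_tissues))
  diseases <- sprintf("disease_%02d", seq_len(spec$n_diseases))

  # --- PPI: background Bernoulli edges + the planted component -------
  ppi <- with_stream(spec$seed, 1L, {
    pairs <- utils::combn(genes, 2L)
    keep <- stats::runif(ncol(pairs)) < spec$ppi_density
    data.frame(gene_a = pairs[1, keep], gene_b = pairs[2, keep],
               stringsAsFactors = FALSE)
  })
  planted_edges <- data.frame(
    gene_a = c("TGT1", "TGT2", "SHB1", "TGT1", "TGT2", "DCY1"),
    gene_b = c("SHB1", "SHB1", "SHB2", "DCY1", "DCY1", "DCY2"),
    stringsAsFactors = FALSE)
  ppi <- rbind(ppi, planted_edges)

  # --- annotation term sets ------------------------------------------
  draw_sets <- function(stream, universe) with_stream(spec$seed, stream, {
    k <- sample(spec$terms_per_gene[1]:spec$terms_per_gene[2],
                length(genes), replace = TRUE)
    stats::setNames(lapply(k, function(ki) sample(universe, ki)), genes)
  })
  bp_sets <- draw_sets(2L, bp_terms)
  mf_sets <- draw_sets(3L, mf_terms)
  # boost: interacting background pairs share an extra term
  boost <- function(stream, sets, universe) with_stream(spec$seed, stream, {
    bg <- ppi$gene_a %in% genes & ppi$gene_b %in% genes
    hit <- which(bg & stats::runif(nrow(ppi)) < spec$edge_overlap_boost)
    for (i in hit) {
      tm <- sample(universe, 1L)
      sets[[ppi$gene_a[i]]] <- union(sets[[ppi$gene_a[i]]], tm)
      sets[[ppi$gene_b[i]]] <- union(sets[[ppi$gene_b[i]]], tm)
    }
    sets
  })
  bp_sets <- boost(4L, bp_sets, bp_terms)
  mf_sets <- boost(5L, mf_sets, mf_terms)
  # planted overlaps: x=3, y=3, z=3, n1=2, n2=2 in both namespaces;
  # DCY1 gets no annotation at all (zero-Jaccard decoy hop).
  bp_sets[["TGT1"]] <- bp_terms[1:3]; bp_sets[["TGT2"]] <- bp_terms[1:3]
  bp_sets[["SHB1"]] <- bp_terms[2:4]; bp_sets[["SHB2"]] <- bp_terms[3:5]
  bp_sets[["DCY2"]] <- bp_terms[1:3]
  mf_sets[["TGT1"]] <- mf_terms[1:3]; mf_sets[["TGT2"]] <- mf_terms[1:3]
  mf_sets[["SHB1"]] <- mf_terms[2:4]; mf_sets[["SHB2"]] <- mf_terms[3:5]
  mf_sets[["DCY2"]] <- mf_terms[1:3]

  bp_cat <- annotation_catalog(bp_sets, "BP")
  mf_cat <- annotation_catalog(mf_sets, "MF")

  # --- pathways -------------------------------------------------------
  pw_sets <- with_stream(spec$seed, 6L, {
    ids <- sprintf("PWY%03d", seq_len(spec$n_pathways))
    out <- lapply(ids, function(id)
      sample(genes, sample(5:15, 1L)))
    stats::setNames(out, ids)
  })
  pw_sets[["PWY900"]] <- c("TGT1", "TGT2", "SHB1", "SHB2")
  # invert pathway->genes into gene->pathways for the catalog
  g2p <- list()
  for (id in names(pw_sets)) for (g in pw_sets[[id]])
    g2p[[g]] <- c(g2p[[g]], id)
  pw_cat <- annotation_catalog(g2p, "PATHWAY")

  # --- associations ---------------------------------------------------
  assoc <- with_stream(spec$seed, 7L, {
    mir_ids <- sprintf("hsa-mir-1%03d",
                       seq_len(spec$n_diseases * spec$mirnas_per_disease))
    dm <- data.frame(disease = character(0), mirna = character(0),
                     source = character(0), stringsAsFactors = FALSE)
    mt <- data.frame(mirna = character(0), gene = character(0),
                     methods = character(0), direction = character(0),
                     stringsAsFactors = FALSE)
    vocab <- direct_validation_methods()
    k <- 0L
    for (d in diseases[-(1:2)]) {
      for (j in seq_len(spec$mirnas_per_disease)) {
        k <- k + 1L
        m <- mir_ids[k]
        dm <- rbind(dm, data.frame(disease = d, mirna = m,
                                   source = "synthetic-background",
                                   stringsAsFactors = FALSE))
        tg <- sample(genes, spec$targets_per_mirna)
        meth <- vapply(tg, function(g) {
          if (stats::runif(1) < 0.3) "Microarray"
          else paste(sample(vocab, sample(1:2, 1L)), collapse = ";")
        }, character(1))
        mt <- rbind(mt, data.frame(
          mirna = m, gene = tg, methods = meth,
          direction = sample(c("negative", "positive"), length(tg),
                             replace = TRUE, prob = c(0.8, 0.2)),
          stringsAsFactors = FALSE))
      }
    }
    list(dm = dm, mt = mt)
  })
  planted_mirnas <- c("hsa-mir-9001", "hsa-mir-9002")
  dm <- rbind(data.frame(disease = diseases[1:2], mirna = planted_mirnas,
                         source = "synthetic-planted",
                         stringsAsFactors = FALSE),
              assoc$dm)
  mt <- rbind(data.frame(mirna = planted_mirnas, gene = c("TGT1", "TGT2"),
                         methods = c("Luciferase Reporter Assay;HITS-CLIP",
                                     "PAR-CLIP"),
                         direction = "negative", stringsAsFactors = FALSE),
              assoc$mt)

  # --- tissues and cancer tags ---------------------------------------
  ti <- with_stream(spec$seed, 8L, {
    rows <- lapply(genes, function(g)
      data.frame(gene = g,
                 tissue = sample(tissues, min(sample(1:3, 1L), length(tissues))),
                 stringsAsFactors = FALSE))
    do.call(rbind, rows)
  })
  planted_tissues <- tissues[seq_len(min(2L, length(tissues)))]
  ti <- rbind(ti, expand.grid(gene = planted_genes,
                              tissue = planted_tissues,
                              stringsAsFactors = FALSE))
  ct <- with_stream(spec$seed, 9L, {
    tagged <- sample(genes, round(spec$cancer_tag_fraction * length(genes)))
    data.frame(gene = tagged,
               tag = sample(c("CRG", "OCG", "TSG"), length(tagged),
                            replace = TRUE),
               stringsAsFactors = FALSE)
  })
  ct <- rbind(ct, data.frame(gene = c("TGT1", "TGT2", "SHB1", "SHB2"),
                             tag = c("CRG", "CRG", "OCG", "TSG"),
                             stringsAsFactors = FALSE))

  # --- write tables ---------------------------------------------------
  wt <- function(df, file) {
    df <- df[do.call(order, c(unname(as.list(df)), method = "radix")), ,
             drop = FALSE]
    utils::write.table(df, file.path(outdir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_gmt(bp_cat, file.path(outdir, "go_bp.gmt"))
  write_gmt(mf_cat, file.path(outdir, "go_mf.gmt"))
  write_gmt(pw_cat, file.path(outdir, "pathways.gmt"))
  wt(ppi, "ppi.tsv")
  wt(dm, "disease_mirna.tsv")
  wt(mt, "mirna_target.tsv")
  wt(ti, "tissue.tsv")
  wt(ct, "cancer_tags.tsv")
  yaml::write_yaml(list(
    tables = list(bp = "go_bp.gmt", mf = "go_mf.gmt",
                  pathway = "pathways.gmt", ppi = "ppi.tsv",
                  disease_mirna = "disease_mirna.tsv",
                  mirna_target = "mirna_target.tsv",
                  tissue = "tissue.tsv", cancer_tags = "cancer_tags.tsv"),
    options = list(namespace = "MF", p_threshold = 0.005,
                   extra_methods = list("Microarray"))),
    file.path(outdir, "config.yaml"))

  overlaps <- function(N) list(x = 3L, y = 3L, z = 3L, n1 = 2L, n2 = 2L, N = N)
  manifest <- list(
    seed = spec$seed,
    spec = unclass(spec),
    tables = list(ppi = nrow(ppi), disease_mirna = nrow(dm),
                  mirna_target = nrow(mt), tissue = nrow(ti),
                  cancer_tags = nrow(ct),
                  bp_terms = bp_cat$universe_size,
                  mf_terms = mf_cat$universe_size,
                  pathways = pw_cat$universe_size),
    planted = list(
      diseases = diseases[1:2],
      mirnas = planted_mirnas,
      tissues = planted_tissues,
      pathway = "PWY900",
      rsps = list(
        list(disease = diseases[1], mirna = planted_mirnas[1],
             target = "TGT1", g1 = "SHB1", g2 = "SHB2",
             overlaps = list(BP = overlaps(bp_cat$universe_size),
                             MF = overlaps(mf_cat$universe_size))),
        list(disease = diseases[2], mirna = planted_mirnas[2],
             target = "TGT2", g1 = "SHB1", g2 = "SHB2",
             overlaps = list(BP = overlaps(bp_cat$universe_size),
                             MF = overlaps(mf_cat$universe_size)))),
      decoys = list(
        list(disease = diseases[1], mirna = planted_mirnas[1],
             target = "TGT1", g1 = "DCY1", g2 = "DCY2"),
        list(disease = diseases[2], mirna = planted_mirnas[2],
             target = "TGT2", g1 = "DCY1", g2 = "DCY2")),
      # per-disease expectations: paths from TGTi are (SHB1,SHB2),
      # (SHB1,TGTj), (DCY1,DCY2), (DCY1,TGTj); only the SHB1 ones viable
      per_disease = stats::setNames(lapply(1:2, function(i) list(
        n_mirnas = 1L, n_targets = 1L, n_raw = 4L, n_viable = 2L,
        genes = sort(c("SHB1", "SHB2", "TGT1", "TGT2"), method = "radix"))),
        diseases[1:2]),
      shared_genes = sort(c("SHB1", "SHB2", "TGT1", "TGT2"),
                          method = "radix")))
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  invisible(manifest)
}

#' Reference scores for the planted sub-pathways of a fixture
#'
#' Computes, purely from the overlap counts (x, y, z, n1, n2, N)
#' recorded in a fixture manifest and never from the pipeline, the
#' expected Jaccard score JS = (n1/(x+y-n1) + n2/(y+z-n2))/2 and the
#' pair p-values P1, P2 (via the literal triple-binomial form,
#' [pair_pvalue_literal()]) with p = max(P1, P2), for every planted
#' sub-pathway and namespace. Used as the parameter-recovery oracle.
#'
#' @param manifest a manifest as returned by [generate_fixture()] or
#'   read from `manifest.yaml`.
#' @return data.frame: `disease`, `mirna`, `target`, `g1`, `g2`,
#'   `namespace`, `js`, `p1`, `p2`, `p`.
#' @export
expected_scores <- function(manifest) {
  rows <- list()
  for (r in manifest$planted$rsps) {
    for (ns in names(r$overlaps)) {
      o <- r$overlaps[[ns]]
      js <- (o$n1 / (o$x + o$y - o$n1) + o$n2 / (o$y + o$z - o$n2)) / 2
      p1 <- pair_pvalue_literal(o$x, o$y, o$n1, o$N)
      p2 <- pair_pvalue_literal(o$y, o$z, o$n2, o$N)
      rows[[length(rows) + 1L]] <- data.frame(
        disease = r$disease, mirna = r$mirna, target = r$target,
        g1 = r$g1, g2 = r$g2, namespace = ns,
        js = js, p1 = p1, p2 = p2, p = max(p1, p2),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
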