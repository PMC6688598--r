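test_that("disease selection collects miRNAs with validation and tissue filters", {
  b <- tiny_bundle()
  q <- query_spec("dA", namespace = "BP", p_threshold = 1)
  inputs <- select_disease_inputs(q, b)
  expect_identical(inputs, list(m1 = c("T1", "T2"), m2 = "T3"))

  qv <- query_spec("dA", namespace = "BP", p_threshold = 1,
                   require_validated = TRUE)
  expect_identical(select_disease_inputs(qv, b),
                   list(m1 = "T1", m2 = "T3"))   # T2 is Microarray-only

  qt <- query_spec("dA", tissue = "ty", namespace = "BP", p_threshold = 1)
  expect_identical(select_disease_inputs(qt, b), list(m1 = "T1"))

  qe <- query_spec("dA", tissue = "no_such_tissue", namespace = "BP",
                   p_threshold = 1)
  expect_warning(out <- select_disease_inputs(qe, b), "no targets")
  expect_identical(out, list())

  expect_error(select_disease_inputs(query_spec("dX", p_threshold = 1), b),
               "known diseases.*dA")
  # disease names match case-insensitively after trimming
  expect_identical(select_disease_inputs(query_spec(" DA ", namespace = "BP",
                                                    p_threshold = 1), b),
                   inputs)
})

test_that("a miRNA id in place of the disease runs a miRNA-centric query", {
  b <- tiny_bundle()
  q <- query_spec("m2", namespace = "BP", p_threshold = 1)
  expect_identical(select_disease_inputs(q, b), list(m2 = "T3"))
})

test_that("the sub-pathway set keeps annotation-sharing paths and drops zero-JC ones", {
  b <- tiny_bundle()
  q <- query_spec("dA", namespace = "BP", p_threshold = 1)
  rec <- build_mrsp_set(select_disease_inputs(q, b), b, q)
  keys <- paste(rec$target, rec$g1, rec$g2)
  expect_true("T1 A B" %in% keys)
  expect_false(any(rec$g1 == "C"))             # zero-overlap first hop
  expect_identical(attr(rec, "n_raw"), 10L)    # 4 paths from T1, 3 from T2, 3 from T3
  # every record: p = max(p1, p2), viable in selected namespace
  expect_identical(rec$p_value, pmax(rec$p1, rec$p2))
  expect_true(all(rec$js_bp > 0))

  # p-threshold below every p empties the set; raising it is monotone
  q0 <- query_spec("dA", namespace = "BP", p_threshold = 1e-6)
  expect_identical(nrow(build_mrsp_set(select_disease_inputs(q0, b), b, q0)), 0L)
  q5 <- query_spec("dA", namespace = "BP", p_threshold = 0.5)
  expect_lte(nrow(build_mrsp_set(select_disease_inputs(q5, b), b, q5)),
             nrow(rec))
})

test_that("gene, pathway and cancer filters restrict but never grow the set", {
  b <- tiny_bundle()
  base_q <- query_spec("dA", namespace = "BP", p_threshold = 1)
  inputs <- select_disease_inputs(base_q, b)
  base <- build_mrsp_set(inputs, b, base_q)

  qg <- query_spec("dA", namespace = "BP", p_threshold = 1, gene_filter = "B")
  recg <- build_mrsp_set(inputs, b, qg)
  expect_true(all(recg$target == "B" | recg$g1 == "B" | recg$g2 == "B"))
  expect_lte(nrow(recg), nrow(base))

  qk <- query_spec("dA", namespace = "BP", p_threshold = 1, kegg_filter = "P1")
  reck <- build_mrsp_set(inputs, b, qk)
  expect_identical(paste(reck$target, reck$g1, reck$g2), "T1 A B")

  qc <- query_spec("dA", namespace = "BP", p_threshold = 1,
                   cancer_filter = "all_genes")
  recc <- build_mrsp_set(inputs, b, qc)
  expect_identical(paste(recc$target, recc$g1, recc$g2), "T1 A B")
  qt <- query_spec("dA", namespace = "BP", p_threshold = 1,
                   cancer_filter = "target_only")
  rect <- build_mrsp_set(inputs, b, qt)
  expect_true(all(rect$target == "T1"))        # only T1 carries a tag
})

test_that("top-N truncates the p-sorted list with deterministic tie-breaking", {
  b <- tiny_bundle()
  q <- query_spec("dA", namespace = "BP", p_threshold = 1)
  rec <- build_mrsp_set(select_disease_inputs(q, b), b, q)
  expect_identical(top_rsps(rec, 3), rec[1:3, ])
  expect_identical(top_rsps(rec, 1000), rec)
  expect_error(top_rsps(rec, 0), "positive")
  expect_true(!is.unsorted(rec$p_value))
  # within a p tie, higher selected-namespace JS first, then lexicographic
  ties <- split(seq_len(nrow(rec)), rec$p_value)
  for (ix in ties) {
    expect_true(!is.unsorted(-rec$js_bp[ix]))
  }
})

test_that("network assembly adds regulation edges and the PPI closure", {
  g <- interaction_graph(rbind(c("T", "G1"), c("G1", "G2")))
  b <- tiny_bundle()
  mrsps <- data.frame(mirna = "M", target = "T", g1 = "G1", g2 = "G2",
                      js_bp = 1, js_mf = 1, viable_bp = TRUE, viable_mf = TRUE,
                      p1 = 0.1, p2 = 0.1, p_value = 0.1, pathways = "",
                      stringsAsFactors = FALSE)
  net <- assemble_network(mrsps, g, b)
  expect_identical(nrow(net$nodes), 4L)
  expect_identical(sum(net$edges$kind == "regulation"), 1L)
  expect_identical(sum(net$edges$kind == "ppi"), 2L)

  # two sub-pathways sharing G1, with an interaction between their G2s:
  # the closure must link the G2 pair even though no path contains it
  g2 <- interaction_graph(rbind(c("T", "G1"), c("G1", "A"), c("G1", "B"),
                                c("A", "B")))
  mr2 <- rbind(mrsps, mrsps)
  mr2$g2 <- c("A", "B")
  net2 <- assemble_network(mr2, g2, b)
  ppi <- net2$edges[net2$edges$kind == "ppi", ]
  expect_true(any(ppi$from == "A" & ppi$to == "B"))
  # no node invented by closure
  expect_identical(sort(net2$nodes$id[net2$nodes$kind != "mirna"]),
                   sort(unique(c(mr2$target, mr2$g1, mr2$g2))))
})

test_that("closure invariant holds exhaustively on a fixture network", {
  b <- fixture_bundle()
  q <- query_from_options(b, "disease_03")
  rec <- build_mrsp_set(select_disease_inputs(q, b), b, q)
  net <- assemble_network(rec, b$ppi, b)
  genes <- net$nodes$id[net$nodes$kind != "mirna"]
  ppi_keys <- with(net$edges[net$edges$kind == "ppi", ],
                   paste(pmin(from, to), pmax(from, to)))
  for (i in seq_along(genes)) {
    for (j in seq_len(i - 1L)) {
      u <- genes[i]; v <- genes[j]
      if (has_interaction(b$ppi, u, v))
        expect_true(paste(min(u, v), max(u, v)) %in% ppi_keys)
    }
  }
  # and nothing beyond the graph's interactions
  expect_true(all(vapply(strsplit(ppi_keys, " ", fixed = TRUE),
                         function(p) has_interaction(b$ppi, p[1], p[2]),
                         logical(1))))
})

test_that("comorbid genes are a symmetric intersection of the two gene sets", {
  b <- tiny_bundle()
  qa <- query_spec("dA", namespace = "BP", p_threshold = 1)
  qb <- query_spec("dB", namespace = "BP", p_threshold = 1)
  ra <- build_mrsp_set(select_disease_inputs(qa, b), b, qa)
  rb <- build_mrsp_set(select_disease_inputs(qb, b), b, qb)
  ab <- comorbid_genes(ra, rb, b)
  ba <- comorbid_genes(rb, ra, b)
  expect_identical(ab, ba)
  ga <- unique(c(ra$target, ra$g1, ra$g2))
  gb <- unique(c(rb$target, rb$g1, rb$g2))
  expect_true(all(ab$gene %in% ga) && all(ab$gene %in% gb))
  # identical record lists return the full gene set
  aa <- comorbid_genes(ra, ra, b)
  expect_identical(aa$gene, sort(ga, method = "radix"))
  # annotation columns carry the cancer tag and pathway memberships
  expect_identical(ab$cancer_tag[ab$gene == "A"], "OCG")
  expect_identical(ab$pathways[ab$gene == "A"], "P1;P2")
})

test_that("exports write SIF, GraphML, JSON and node tables that parse back", {
  b <- tiny_bundle()
  q <- query_spec("dA", namespace = "BP", p_threshold = 1)
  rec <- build_mrsp_set(select_disease_inputs(q, b), b, q)
  net <- assemble_network(rec, b$ppi, b)
  d <- withr::local_tempdir()
  files <- write_network(net, d)
  expect_true(all(file.exists(files)))
  sif <- read.delim(file.path(d, "network.sif"), header = FALSE)
  expect_identical(nrow(sif), nrow(net$edges))   # no isolated nodes here
  expect_setequal(unique(sif$V2), c("regulates", "pp"))
  ig <- igraph::read_graph(file.path(d, "network.graphml"), format = "graphml")
  expect_equal(igraph::gorder(ig), nrow(net$nodes), ignore_attr = TRUE)
  expect_equal(igraph::gsize(ig), nrow(net$edges), ignore_attr = TRUE)
  js <- jsonlite::read_json(file.path(d, "network.json"))
  expect_identical(length(js$nodes), nrow(net$nodes))
  nt <- read.delim(file.path(d, "network_nodes.tsv"))
  expect_identical(nrow(nt), nrow(net$nodes))

  p <- file.path(d, "rsps.tsv")
  write_rsps_tsv(rec, p)
  tab <- read.delim(p)
  expect_identical(nrow(tab), nrow(rec))
  expect_identical(tab$rank, seq_len(nrow(rec)))
})
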