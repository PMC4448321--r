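# BIO-side rule outputs: abstraction layers, annotation and interaction
# patterns, restriction reuse, conflict tolerance.

test_that("one annotation on a fresh BIO side emits the five-triple pattern", {
  b <- micro_build()
  counts <- b$build$rule_counts
  expect_identical(counts$triples[counts$rule == "goa-process"], 5L)
})

test_that("one drug-gene interaction on a fresh graph emits nine triples", {
  b <- micro_build()
  counts <- b$build$rule_counts
  expect_identical(counts$triples[counts$rule == "drug-gene-interaction"], 9L)
})

test_that("aggregates have the expected members and template links", {
  b <- micro_build()
  g <- b$build$graph
  gene <- kb_find(g, p = "rdfs:subClassOf", o = "obo:SO_0000704")$s
  gene <- gene[startsWith(gene, kbio_prefix())]
  expect_length(gene, 1L)
  gorgp <- mint_bio_uri("aggregate", c("GorGP", gene), prefix = "GorGP_BIO_")
  gorgpv <- mint_bio_uri("aggregate", c("GorGPorV", gene), prefix = "GorGPorV_BIO_")
  # one gene + one protein in each aggregate
  expect_identical(nrow(kb_find(g, p = "rdfs:subClassOf", o = gorgp)), 2L)
  expect_identical(nrow(kb_find(g, p = "rdfs:subClassOf", o = gorgpv)), 2L)
  protein <- setdiff(kb_find(g, p = "rdfs:subClassOf", o = gorgp)$s, gene)
  expect_identical(kb_find(g, s = protein, p = "kro:has_indirect_template")$o, gene)
})

test_that("subclass-link arithmetic holds across the default fixture", {
  b <- default_build()
  g <- b$build$graph
  genes <- kb_find(g, p = "rdfs:subClassOf", o = "obo:SO_0000704")$s
  genes <- genes[startsWith(genes, kbio_prefix())]
  proteins <- kb_find(g, p = "rdfs:subClassOf", o = "obo:PR_000000001")$s
  proteins <- proteins[startsWith(proteins, kbio_prefix())]
  agg_links <- kb_find(g, p = "rdfs:subClassOf")
  agg_links <- agg_links[startsWith(agg_links$o, kbio_prefix("GorGP"))]
  coded <- kb_find(g, p = "kro:has_indirect_template")
  # every gene joins 2 aggregates; every coded protein joins its gene's 2
  expect_identical(nrow(agg_links), 2L * length(genes) + 2L * nrow(unique(coded)))
})

test_that("re-asserting an identical binding adds nothing; restrictions are reused", {
  b <- default_build()
  g <- b$build$graph
  # second run of every batch: dedup means zero new template triples
  for (f in c("20-abstractions.yaml", "30-goa.yaml", "40-interactions.yaml",
              "50-pathways.yaml")) {
    res <- run_rule_batch(g, f)
    expect_identical(sum(res$counts$triples), 0L)
  }
  # restriction-node count equals distinct (onProperty, someValuesFrom) pairs
  rtype <- kb_find(g, p = "rdf:type", o = "owl:Restriction")$s
  onp <- kb_find(g, p = "owl:onProperty")
  svf <- kb_find(g, p = "owl:someValuesFrom")
  pairs <- merge(onp, svf, by = "s")
  expect_identical(length(unique(rtype)), nrow(unique(pairs[, c("o.x", "o.y")])))
  expect_setequal(rtype, pairs$s)
})

test_that("a duplicated interaction from a second record re-mints identical triples", {
  b <- default_build()
  g <- b$build$graph
  # the fixture repeats its first drug-target pair under a new record id
  ints <- kb_find(g, p = "rdfs:subClassOf", o = "obo:MI_0000")$s
  men <- kb_find(g, p = "iao:mentions")
  men_counts <- table(men$o[men$o %in% ints])
  expect_true(any(men_counts >= 2L)) # one interaction mentioned by two records
})

test_that("goa emission accounting: 2 per fresh binding + 3 per fresh restriction", {
  b <- default_build()
  g0 <- b$build$graph
  counts <- b$build$rule_counts
  goa <- counts$triples[counts$rule == "goa-process"]
  # brute-force recount from the graph
  proc <- kb_find(g0, p = "rdfs:subClassOf")
  goa_classes <- unique(proc$s[startsWith(proc$s, kbio_prefix("GOA_"))])
  goa_restr <- unique(proc$o[proc$s %in% goa_classes & startsWith(proc$o, kbio_prefix("R_"))])
  expect_identical(goa, 2L * length(goa_classes) + 3L * length(goa_restr))
})

test_that("contradictory annotations coexist as independent subclasses", {
  d <- tempfile()
  generate_micro_sources(d)
  # same protein annotated to two disjoint-ish processes in two records
  gaf <- function(go) paste("UniProtKB", "P30049", "ATP5D", "", go, "REF:1",
                            "IEA", "", "P", "", "", "protein", "taxon:9606",
                            "20260101", "icekb", "", "", sep = "\t")
  writeLines(c("!gaf-version: 2.1", gaf("GO:0006119"), gaf("GO:0006810")),
             file.path(d, "goa.gaf"))
  res <- kb_build(d)
  g <- res$graph
  goa_classes <- kb_find(g, p = "rdfs:subClassOf")
  goa_classes <- unique(goa_classes$s[startsWith(goa_classes$s, kbio_prefix("GOA_"))])
  expect_length(goa_classes, 2L)
  # and no rule head ever asserts on an imported ontology class directly
  deriv <- kb_derivations(g)
  rule_subjects <- unique(deriv$s[deriv$rule %in% names(g$rules)])
  expect_false(any(startsWith(rule_subjects, kb_namespaces()[["obo"]])))
})

test_that("pathway pattern arithmetic: one subclass, one restriction per protein", {
  d <- tempfile()
  generate_micro_sources(d)
  writeLines(c("pathway_id\tpathway_name\tmember_ids", "PW:1\tpw\tP30049"),
             file.path(d, "pathway.tsv"))
  # drop the annotation so the participant restriction is fresh here
  writeLines("!gaf-version: 2.1", file.path(d, "goa.gaf"))
  res <- kb_build(d)
  counts <- res$rule_counts
  # 1 protein: subclass-of-pathway + 3 restriction triples + subclass-of-restriction
  expect_identical(counts$triples[counts$rule == "pathway-participants"], 5L)
  # with the annotation present, the same restriction is shared: the pathway
  # and annotation rules coexist over one protein without conflict
  d2 <- tempfile()
  generate_micro_sources(d2)
  writeLines(c("pathway_id\tpathway_name\tmember_ids", "PW:1\tpw\tP30049"),
             file.path(d2, "pathway.tsv"))
  res <- kb_build(d2)
  expect_identical(res$rule_counts$triples[res$rule_counts$rule == "pathway-participants"], 2L)
  g <- res$graph
  prot <- kb_find(g, p = "rdfs:subClassOf", o = "obo:PR_000000001")$s
  prot <- prot[startsWith(prot, kbio_prefix())]
  restr <- mint_restriction_uri(expand_curie("obo:RO_0000057"), prot)
  users <- kb_find(g, p = "rdfs:subClassOf", o = restr)$s
  expect_true(any(startsWith(users, kbio_prefix("PWY_"))))
  expect_true(any(startsWith(users, kbio_prefix("GOA_"))))
})
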