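# ICE record model: shared field values, 3-triple definitions, reduction.

d_ice <- kb_dialects()
sc_pm <- kb_schemas()[["protein_mapping"]]

test_that("records sharing a field value share one node defined by 3 triples", {
  rows <- list(c(up_id = "UP:P10001", ipi_id = "IPI100001"),
               c(up_id = "UP:P10002", ipi_id = "IPI100001")) # shared IPI value
  g <- kb_graph()
  batch <- rdfize_table(rows, sc_pm, d_ice, g)
  ipi_uri <- canonical_id_uri("IPI", "100001", d_ice)
  fv <- kb_find(g, p = "kiao:has_field_value", o = ipi_uri)$s
  expect_length(fv, 1L)
  # the shared node's defining triples appear exactly once in the output
  expect_identical(nrow(batch$triples[batch$triples$s == fv]), 3L)
  # both records link to it
  expect_identical(nrow(kb_find(g, p = "obo:has_part", o = fv)), 2L)
})

test_that("every field-value node has exactly 3 triples with it as subject", {
  b <- default_build()
  dt <- b$build$graph$dt
  fv_nodes <- unique(dt$s[grepl("/fv/", dt$s, fixed = TRUE)])
  counts <- table(dt$s[dt$s %in% fv_nodes])
  expect_true(length(fv_nodes) > 50L)
  expect_true(all(counts == 3L))
})

test_that("a record with no populated fields gets only type and template triples", {
  res <- rdfize_record(c(up_id = "", ipi_id = "  "), sc_pm, d_ice)
  expect_identical(res$fv_instances, 0L)
  expect_setequal(res$triples$p,
                  expand_curie(c("rdf:type", "kiao:has_template")))
})

test_that("row keys outside the schema raise SchemaMismatch", {
  expect_error(rdfize_record(c(up_id = "UP:P10001", rogue = "x"), sc_pm, d_ice),
               class = "SchemaMismatch")
})

test_that("unknown-dialect rows are quarantined, not fatal", {
  rows <- list(c(up_id = "UP:P10001", ipi_id = "IPI100001"),
               c(up_id = "???", ipi_id = "IPI100002"))
  batch <- rdfize_table(rows, sc_pm, d_ice)
  expect_identical(batch$quarantined, 1L)
  expect_match(batch$messages, "no dialect rule")
  expect_length(batch$record_uris, 1L)
})

test_that("field-value node count equals distinct (field, value) pairs", {
  set.seed(23)
  rows <- lapply(1:10, function(i) {
    c(up_id = paste0("UP:P100", sprintf("%02d", sample(3, 1))),
      ipi_id = paste0("IPI1000", sprintf("%02d", sample(4, 1))))
  })
  batch <- rdfize_table(rows, sc_pm, d_ice)
  # brute-force pair enumeration with canonicalization as the oracle
  pairs <- unique(unlist(lapply(rows, function(r) c(
    paste0("up|", canonicalize_identifier(r[["up_id"]], list(space = "UP"), d_ice)),
    paste0("ipi|", canonicalize_identifier(r[["ipi_id"]], list(space = "IPI"), d_ice))))))
  expect_identical(batch$fv_nodes, length(pairs))
})

test_that("RDFizing the same rows twice yields the identical triple set", {
  b <- default_build()
  sc <- kb_schemas()[["gene_catalog"]]
  rows <- read_delimited(file.path(b$dir, "gene_catalog.tsv"), sc)$rows
  t1 <- rdfize_table(rows, sc, d_ice)$triples
  t2 <- rdfize_table(rows, sc, d_ice)$triples
  expect_identical(data.table::setkeyv(t1, c("s", "p", "o")),
                   data.table::setkeyv(t2, c("s", "p", "o")))
})

test_that("triple-reduction statistics match an independent count", {
  # all-distinct values: zero reduction
  rows <- lapply(1:4, function(i) c(up_id = paste0("UP:P1000", i),
                                    ipi_id = paste0("IPI10000", i)))
  expect_identical(triple_reduction_stats(rdfize_table(rows, sc_pm, d_ice))$percent_reduction, 0)
  # n records all sharing one single-field value: 3n raw -> 3 dedup
  n <- 6L
  shared <- lapply(seq_len(n), function(i) c(ipi_id = "IPI100001"))
  st <- triple_reduction_stats(rdfize_table(shared, sc_pm, d_ice))
  expect_identical(st$raw_triples, 3L * n)
  expect_identical(st$dedup_triples, 3L)
  # randomized batch against recomputation from first principles
  set.seed(31)
  rows <- lapply(1:12, function(i) c(up_id = paste0("UP:P100", sprintf("%02d", sample(4, 1))),
                                     ipi_id = paste0("IPI1000", sprintf("%02d", sample(3, 1)))))
  batch <- rdfize_table(rows, sc_pm, d_ice)
  st <- triple_reduction_stats(batch)
  raw_slots <- sum(lengths(lapply(rows, function(r) r[nzchar(r)])))
  expect_identical(st$raw_triples, 3L * raw_slots)
  expect_equal(st$percent_reduction, 100 * (1 - batch$fv_nodes / raw_slots))
})
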