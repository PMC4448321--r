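# Identity resolution: type guards, union-find, sets, BIO entities.

test_that("union-find groups the worked example's four identifiers into one set", {
  d <- kb_dialects()
  ids <- c(canonical_id_uri("HGNC", "837", d), canonical_id_uri("EG", "513", d),
           canonical_id_uri("MGI", "88115", d), canonical_id_uri("EG", "11957", d))
  # three pairwise exact-match links chaining the four identifiers
  edges <- data.table::data.table(left = ids[c(1, 2, 3)], right = ids[c(2, 3, 4)])
  sets <- union_find_closure(edges, ids)
  expect_length(sets, 1L)
  expect_setequal(sets[[1]], ids)
})

test_that("identifiers without edges form singleton sets", {
  ids <- paste0("http://icekb.org/kiao/eg/EG_", 1:9, "_ICE")
  sets <- union_find_closure(NULL, ids)
  expect_length(sets, 9L)
  expect_true(all(lengths(sets) == 1L))
})

test_that("union-find equals BFS connected components on random graphs", {
  set.seed(53)
  for (trial in 1:8) {
    n <- sample(20:200, 1)
    ids <- paste0("http://icekb.org/kiao/eg/EG_", seq_len(n), "_ICE")
    m <- sample(0:(2 * n), 1)
    edges <- data.table::data.table(left = sample(ids, m, replace = TRUE),
                                    right = sample(ids, m, replace = TRUE))
    expect_identical(union_find_closure(edges, ids), bfs_components(edges, ids))
  }
})

test_that("one erroneous mapping merges exactly the two affected components", {
  ids <- paste0("http://icekb.org/kiao/eg/EG_", 1:8, "_ICE")
  edges <- data.table::data.table(left = ids[c(1, 3, 5, 7)],
                                  right = ids[c(2, 4, 6, 8)])
  base <- union_find_closure(edges, ids)
  expect_length(base, 4L)
  bad <- rbind(edges, data.table::data.table(left = ids[1], right = ids[3]))
  merged <- union_find_closure(bad, ids)
  expect_length(merged, 3L)
  affected <- Filter(function(s) ids[1] %in% s, merged)[[1]]
  expect_setequal(affected, ids[1:4])
  expect_true(all(vapply(base[3:4], function(s)
    any(vapply(merged, identical, logical(1), s)), logical(1))))
})

test_that("set materialization emits exactly one membership triple per member", {
  d <- kb_dialects()
  four <- vapply(as.character(1:4), canonical_id_uri, space = "EG",
                 dialects = d, FUN.VALUE = character(1))
  m <- materialize_id_set(four)
  expect_identical(nrow(m$triples), 4L)
  expect_true(all(m$triples$p == expand_curie("kro:hasMember")))
  expect_true(all(m$triples$s == m$uri))
  expect_identical(nrow(materialize_id_set(four[1])$triples), 1L)
  # k sets with m total members -> m triples (brute-force sum)
  set.seed(59)
  sizes <- sample(1:5, 6, replace = TRUE)
  total <- 0L
  offset <- 10L
  for (k in sizes) {
    mem <- vapply(as.character(offset + seq_len(k)), canonical_id_uri,
                  space = "EG", dialects = d, FUN.VALUE = character(1))
    total <- total + nrow(materialize_id_set(mem)$triples)
    offset <- offset + k
  }
  expect_identical(total, sum(sizes))
})

test_that("type guards keep gene-protein and cross-type pairs unlinked", {
  b <- default_build()
  g <- b$build$graph
  edges <- b$build$edges
  hgnc_eg <- edges[grepl("/hgnc/", edges$left) | grepl("/hgnc/", edges$right)]
  expect_true(nrow(edges) > 0L)
  # no edge touches a protein id on one side and a gene id on the other
  sp <- cbind(id_space(edges$left), id_space(edges$right))
  gene_spaces <- c("EG", "HGNC", "MGI")
  prot_spaces <- c("UP", "IPI")
  expect_false(any(sp[, 1] %in% gene_spaces & sp[, 2] %in% prot_spaces))
  expect_false(any(sp[, 1] %in% prot_spaces & sp[, 2] %in% gene_spaces))
  # graph-wide scan: every exactMatch joins compatible denoted types
  xm <- kb_find(g, p = "skos:exactMatch")
  types <- kb_find(g, p = "kiao:denotesSubClassOf")
  type_of <- stats::setNames(types$o, types$s)
  expect_false(anyNA(type_of[xm$s]))
  expect_false(anyNA(type_of[xm$o]))
})

test_that("dbXref extraction matches a brute-force type filter on the fixture", {
  b <- default_build()
  g <- b$build$graph
  d <- kb_dialects()
  sc <- kb_schemas()[["gene_catalog"]]
  rows <- read_delimited(file.path(b$dir, "gene_catalog.tsv"), sc)$rows
  want <- character()
  for (r in rows) {
    left <- canonicalize_identifier(r[["gene_id"]], list(space = "EG"), d)
    for (x in strsplit(r[["dbxref"]], ";", fixed = TRUE)[[1]]) {
      right <- canonicalize_identifier(x, list(space = NULL), d)
      if (id_space(right) %in% c("EG", "HGNC", "MGI") && right != left) {
        want <- c(want, paste(left, right))
      }
    }
  }
  got <- b$build$edges[b$build$edges$schema == "gene_catalog"]
  expect_setequal(paste(got$left, got$right), unique(want))
})

test_that("BIO entities denote every member and reject mixed-type sets", {
  g <- kb_graph()
  # small hand-built hierarchy: gene subclass of DNA; protein separate
  kb_add(g, kb_triples(c("obo:SO_0000704", "obo:PR_000000001"),
                       "rdfs:subClassOf", c("obo:SO_0000352", "obo:BFO_0000040")))
  d <- kb_dialects()
  hgnc <- canonical_id_uri("HGNC", "837", d)
  eg <- canonical_id_uri("EG", "513", d)
  up <- canonical_id_uri("UP", "P30049", d)
  # subsumption-compatible guards: one id typed gene, one typed DNA
  kb_add(g, kb_triples(c(hgnc, eg, up), "kiao:denotesSubClassOf",
                       c("obo:SO_0000704", "obo:SO_0000352", "obo:PR_000000001")))
  m <- materialize_id_set(c(hgnc, eg))
  ent <- create_bio_entity(m$uri, c(hgnc, eg), g)
  expect_identical(nrow(ent$triples), 3L) # 1 subclass + 2 denotes
  expect_setequal(kb_find({kb_add(g, ent$triples); g}, p = "iao:denotes",
                          o = ent$uri)$s, c(hgnc, eg))
  # most specific shared guard wins
  expect_identical(ent$triples$o[ent$triples$p == expand_curie("rdfs:subClassOf")],
                   expand_curie("obo:SO_0000704"))
  # singleton: 1 denotes + 1 subclass
  s1 <- materialize_id_set(up)
  expect_identical(nrow(create_bio_entity(s1$uri, up, g)$triples), 2L)
  # incomparable guards signal an upstream filtering bug
  mix <- materialize_id_set(c(eg, up))
  expect_error(create_bio_entity(mix$uri, c(eg, up), g), class = "MixedTypeSet")
})

test_that("every typed identifier lands in exactly one set", {
  b <- default_build()
  g <- b$build$graph
  sets <- b$build$sets
  typed <- unique(kb_find(g, p = "kiao:denotesSubClassOf")$s)
  expect_setequal(sets$member, typed)
  expect_identical(anyDuplicated(sets$member), 0L)
})
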