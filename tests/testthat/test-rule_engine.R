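# Forward chaining: matching, instantiation, fixpoint, macro expansion.

goa_batch <- parse_rule_file(system.file("rules", "30-goa.yaml", package = "icekb"))
goa_rule_def <- goa_batch$rules[[1]]

test_that("single patterns and empty graphs match as expected", {
  g <- kb_graph()
  kb_add(g, kb_triples(c("kiao:a", "kiao:b", "kiao:c"),
                       c("rdf:type", "rdf:type", "rdfs:label"),
                       c("kiao:T", "kiao:T", kb_literal("c"))))
  b <- match_body(list(c("?x", "rdf:type", "kiao:T")), g)
  expect_identical(nrow(b), 2L)
  expect_setequal(b$x, expand_curie(c("kiao:a", "kiao:b")))
  expect_identical(nrow(match_body(list(c("?x", "rdf:type", "kiao:T")), kb_graph())), 0L)
})

test_that("match agrees with a nested-loop join oracle on random graphs", {
  set.seed(41)
  bodies <- list(
    list(c("?a", "http://x.org/p1", "?b"), c("?b", "http://x.org/p2", "?c")),
    list(c("?a", "http://x.org/p1", "?b"), c("?b", "http://x.org/p1", "?a")),
    list(c("?a", "?p", "?b"), c("?b", "http://x.org/p2", "?c"),
         c("?c", "http://x.org/p3", "?d")),
    list(c("?a", "http://x.org/p1", "?a")),
    list(c("http://x.org/n1", "?p", "?b"), c("?b", "?q", "?c")))
  for (size in c(40L, 150L, 500L)) {
    trip <- random_graph(size)
    g <- kb_graph()
    kb_add(g, trip)
    for (body in bodies) {
      got <- match_body(body, g)
      want <- nested_loop_join(body, g$dt)
      if (nrow(want) == 0L) {
        expect_identical(nrow(got), 0L)
      } else {
        cols <- sort(names(want))
        expect_setequal(do.call(paste, got[, cols, with = FALSE]),
                        do.call(paste, want[, cols, with = FALSE]))
      }
    }
  }
})

test_that("the annotation head instantiates to exactly its five template triples", {
  binding <- c(r = "http://icekb.org/kiao/rec/R_x",
               afv = "http://icekb.org/kiao/fv/F_a", pfv = "http://icekb.org/kiao/fv/F_p",
               gfv = "http://icekb.org/kiao/fv/F_g",
               pid = "http://icekb.org/kiao/up/UP_P30049_ICE",
               gid = "http://icekb.org/kiao/go/GO_0006119_ICE",
               protein = "http://icekb.org/kbio/BIO_prot",
               goProcess = expand_curie("obo:GO_0006119"))
  trip <- instantiate(goa_rule_def$head, binding, goa_rule_def$mint)
  expect_identical(nrow(trip), 5L)
  restr <- mint_restriction_uri(expand_curie("obo:RO_0000057"), binding[["protein"]])
  expect_true(all(kb_has({g <- kb_graph(); kb_add(g, trip); g}, kb_triples(
    c(restr, restr, restr),
    c("rdf:type", "owl:onProperty", "owl:someValuesFrom"),
    c("owl:Restriction", "obo:RO_0000057", binding[["protein"]])))))
  newp <- setdiff(unique(trip$s), restr)
  expect_length(newp, 1L)
  expect_setequal(trip$o[trip$s == newp], c(binding[["goProcess"]], restr))
  # determinism across repeated instantiation
  expect_identical(trip, instantiate(goa_rule_def$head, binding, goa_rule_def$mint))
})

test_that("a head variable without binding or mint directive is an error", {
  expect_error(instantiate(list(c("?ghost", "rdf:type", "owl:Class")),
                           c(x = "http://x.org/a"), NULL),
               class = "UnboundVariable")
})

test_that("batches reach fixpoint, are idempotent, and match a saturation oracle", {
  # rule B consumes rule A's output
  batch <- list(batch = "chain", rules = list(
    list(name = "A", body = list(c("?x", "http://x.org/p1", "?y")),
         head = list(c("?x", "http://x.org/p2", "?y"))),
    list(name = "B", body = list(c("?x", "http://x.org/p2", "?y"),
                                 c("?y", "http://x.org/p2", "?z")),
         head = list(c("?x", "http://x.org/p3", "?z")))))
  set.seed(43)
  trip <- random_graph(60, n_nodes = 10L, n_preds = 1L)
  g <- kb_graph()
  kb_add(g, trip)
  res <- run_batch_to_fixpoint(batch, g)
  expect_true(res$iterations <= 3L)
  # idempotence: re-running on its own output adds nothing
  res2 <- run_batch_to_fixpoint(batch, g)
  expect_identical(sum(res2$counts$triples), 0L)
  # independent naive saturation oracle using the nested-loop matcher
  sat <- data.table::copy(trip)
  repeat {
    new <- list()
    for (r in batch$rules) {
      b <- nested_loop_join(r$body, sat)
      if (nrow(b) == 0L) next
      for (i in seq_len(nrow(b))) {
        env <- as.list(b[i, ])
        for (h in r$head) {
          new[[length(new) + 1L]] <- data.table::data.table(
            s = env[[substring(h[1], 2)]], p = expand_curie(h[2]),
            o = env[[substring(h[3], 2)]])
        }
      }
    }
    new <- unique(data.table::rbindlist(new))
    before <- nrow(sat)
    sat <- unique(rbind(sat, new))
    if (nrow(sat) == before) break
  }
  expect_setequal(paste(g$dt$s, g$dt$p, g$dt$o), paste(sat$s, sat$p, sat$o))
})

test_that("rules only ever add triples (monotonicity)", {
  b <- micro_build()
  g <- b$build$graph
  before <- graph_lines(g)
  run_rule_batch(g, "30-goa.yaml")
  expect_true(all(before %in% graph_lines(g)))
})

test_that("the non-termination guard aborts with diagnostics", {
  # a rule that mints a fresh node from its own output grows forever
  batch <- list(batch = "bad", rules = list(list(
    name = "grow",
    body = list(c("?x", "http://x.org/p1", "?y")),
    head = list(c("?y", "http://x.org/p1", "?fresh")),
    mint = list("?fresh" = list(kind = "bio-class", subtag = "generic",
                                components = list("?x", "?y"))))))
  g <- kb_graph()
  kb_add(g, kb_triples("kiao:a", "<http://x.org/p1>", "kiao:b"))
  expect_error(run_batch_to_fixpoint(batch, g, max_iter = 5L),
               class = "NonTermination")
})

test_that("the denotesSubClassOf macro expands to exactly two triples per assertion", {
  g <- kb_graph()
  n <- 7L
  ids <- paste0(kb_namespaces()[["kiao"]], "eg/EG_", seq_len(n), "_ICE")
  kb_add(g, kb_triples(ids, "kiao:denotesSubClassOf", "obo:SO_0000704"))
  expect_identical(expand_macro(g), 2L * n)
  expect_identical(expand_macro(g), 0L) # same Y, same triples
  ys <- kb_find(g, p = "iao:denotes")$o
  expect_length(unique(ys), n)
  expect_identical(nrow(kb_find(g, p = "rdfs:subClassOf", o = "obo:SO_0000704")), n)
})

test_that("property paths walk the reflexive-transitive closure", {
  g <- kb_graph()
  kb_add(g, kb_triples(c("obo:A", "obo:B", "obo:C"),
                       "rdfs:subClassOf", c("obo:B", "obo:C", "obo:D")))
  b <- match_body(list(c("?x", "rdfs:subClassOf*", "obo:D")), g)
  expect_setequal(b$x, expand_curie(c("obo:A", "obo:B", "obo:C", "obo:D")))
  b2 <- match_body(list(c("obo:A", "rdfs:subClassOf*", "?y")), g)
  expect_setequal(b2$y, expand_curie(c("obo:A", "obo:B", "obo:C", "obo:D")))
})
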