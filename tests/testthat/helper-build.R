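# Shared fixtures and independent oracles.
# Builds are cached per test run so the suite stays fast.

.build_cache <- new.env(parent = emptyenv())

cached <- function(key, maker) {
  if (is.null(.build_cache[[key]])) .build_cache[[key]] <- maker()
  .build_cache[[key]]
}

default_build <- function() {
  cached("default", function() {
    d <- tempfile("fx-default-")
    m <- generate_sources(fixture_spec(seed = 101L), d)
    list(dir = d, manifest = m, build = kb_build(d))
  })
}

clean_build <- function() {
  cached("clean", function() {
    d <- tempfile("fx-clean-")
    m <- generate_sources(fixture_spec_clean(seed = 101L), d)
    list(dir = d, manifest = m, build = kb_build(d))
  })
}

micro_build <- function() {
  cached("micro", function() {
    d <- tempfile("fx-micro-")
    generate_micro_sources(d)
    list(dir = d, build = kb_build(d))
  })
}

# ---- independent oracles ---------------------------------------------------

# brute-force nested-loop conjunctive join over a plain triple table;
# independent of the engine's data.table joins
nested_loop_join <- function(body, triples) {
  is_var <- function(x) startsWith(x, "?")
  results <- list(list())
  for (pattern in body) {
    terms <- vapply(pattern, function(t) if (is_var(t)) t else expand_curie(t),
                    character(1))
    nxt <- list()
    for (b in results) {
      for (k in seq_len(nrow(triples))) {
        row <- c(triples$s[k], triples$p[k], triples$o[k])
        b2 <- b
        ok <- TRUE
        for (i in 1:3) {
          t <- terms[i]
          if (is_var(t)) {
            v <- substring(t, 2L)
            if (!is.null(b2[[v]])) {
              if (b2[[v]] != row[i]) { ok <- FALSE; break }
            } else b2[[v]] <- row[i]
          } else if (t != row[i]) { ok <- FALSE; break }
        }
        if (ok) nxt[[length(nxt) + 1L]] <- b2
      }
    }
    results <- nxt
  }
  if (length(results) == 0L) return(data.table::data.table())
  unique(data.table::rbindlist(lapply(results, data.table::as.data.table)))
}

# breadth-first connected components over undirected edges
bfs_components <- function(edges, universe) {
  adj <- list()
  add_edge <- function(a, b) adj[[a]] <<- unique(c(adj[[a]], b))
  if (nrow(edges) > 0L) {
    for (k in seq_len(nrow(edges))) {
      add_edge(edges[[1]][k], edges[[2]][k])
      add_edge(edges[[2]][k], edges[[1]][k])
    }
  }
  seen <- character()
  comps <- list()
  for (n in sort(unique(universe), method = "radix")) {
    if (n %in% seen) next
    comp <- n
    frontier <- n
    while (length(frontier) > 0L) {
      nbrs <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), comp)
      nbrs <- intersect(nbrs, universe)
      comp <- c(comp, nbrs)
      frontier <- nbrs
    }
    comp <- sort(comp, method = "radix")
    seen <- c(seen, comp)
    comps[[length(comps) + 1L]] <- comp
  }
  comps[order(vapply(comps, `[[`, character(1), 1L), method = "radix")]
}

# random triple table over small node/predicate vocabularies
random_graph <- function(n_triples, n_nodes = 12L, n_preds = 3L) {
  nodes <- paste0("http://x.org/n", seq_len(n_nodes))
  preds <- paste0("http://x.org/p", seq_len(n_preds))
  unique(data.table::data.table(
    s = sample(nodes, n_triples, replace = TRUE),
    p = sample(preds, n_triples, replace = TRUE),
    o = sample(nodes, n_triples, replace = TRUE)))
}

# sorted-line serialization used by determinism checks
graph_lines <- function(graph) {
  sort(paste(graph$dt$s, graph$dt$p, graph$dt$o), method = "radix")
}

kbio_prefix <- function(p = "BIO_") paste0(kb_namespaces()[["kbio"]], p)
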