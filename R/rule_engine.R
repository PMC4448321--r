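# Declarative forward-chaining over the triple graph.
#
# A rule has a body (conjunctive triple patterns over ?variables and
# constants, with an optional declarative uri-prefix filter), a head (template
# triples), and mint directives that deterministically skolemize the head
# variables the body does not bind -- no blank nodes anywhere. Batches are run
# naively to fixpoint with global duplicate suppression; every emitted triple
# is tagged in a side index with (rule name, supporting binding) for
# provenance.

.is_var <- function(x) startsWith(x, "?")
.var_name <- function(x) substring(x, 2L)

#' Parse a rule batch file
#'
#' YAML layout: `batch:` label plus `rules:`, each rule with `name`, `body`
#' (list of `[s, p, o]` term triplets; `?x` variables, CURIEs/URIs/`"literals"`
#' as constants; a predicate ending in `*` matches the reflexive-transitive
#' closure), optional `filters` (`{var, prefix, negate}` uri-prefix guards),
#' `head` (template triplets), `mint` (variable -> mint recipe) and optional
#' `mentions` (`{record, concept}`: provenance links asserted alongside the
#' template, accounted separately).
#'
#' @param path Rule file path.
#' @return List with `batch` label and `rules`.
#' @export
parse_rule_file <- function(path) {
  cfg <- yaml::read_yaml(path)
  stopifnot(!is.null(cfg$rules))
  nms <- vapply(cfg$rules, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicate rule names in ", path)
  for (i in seq_along(cfg$rules)) {
    r <- cfg$rules[[i]]
    stopifnot(length(r$body) >= 1L, length(r$head) >= 1L)
    cfg$rules[[i]] <- r
  }
  if (is.null(cfg$batch)) cfg$batch <- tools::file_path_sans_ext(basename(path))
  cfg
}

# term resolution: variables stay, constants are namespace-expanded
.resolve_term <- function(t) if (.is_var(t)) t else expand_curie(t)

# reflexive-transitive reachability for path patterns
.reachable <- function(edges_from, edges_to, starts, reverse = FALSE) {
  if (reverse) { tmp <- edges_from; edges_from <- edges_to; edges_to <- tmp }
  adj <- split(edges_to, factor(edges_from, levels = unique(edges_from)))
  out <- list()
  for (s in starts) {
    seen <- s
    frontier <- s
    while (length(frontier) > 0L) {
      nxt <- unique(unlist(adj[intersect(frontier, names(adj))], use.names = FALSE))
      nxt <- setdiff(nxt, seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    out[[s]] <- seen
  }
  out
}

# candidate bindings for one path pattern, given bindings so far
.match_path <- function(pattern, graph, bindings) {
  pred <- expand_curie(sub("\\*$", "", pattern[[2]]))
  edges <- graph$dt[graph$dt$p == pred]
  sterm <- pattern[[1]]; oterm <- pattern[[3]]
  bound <- function(t) {
    if (!.is_var(t)) return(expand_curie(t))
    v <- .var_name(t)
    if (!is.null(bindings) && v %in% names(bindings)) return(unique(bindings[[v]]))
    NULL
  }
  sv <- bound(sterm); ov <- bound(oterm)
  if (!is.null(sv)) {
    reach <- .reachable(edges$s, edges$o, sv)
    cand <- data.table::rbindlist(lapply(names(reach), function(x) {
      data.table::data.table(s = x, o = reach[[x]])
    }))
  } else if (!is.null(ov)) {
    reach <- .reachable(edges$s, edges$o, ov, reverse = TRUE)
    cand <- data.table::rbindlist(lapply(names(reach), function(x) {
      data.table::data.table(s = reach[[x]], o = x)
    }))
  } else {
    nodes <- unique(c(graph$dt$s, graph$dt$o[!kb_is_literal(graph$dt$o)]))
    reach <- .reachable(edges$s, edges$o, nodes)
    cand <- data.table::rbindlist(lapply(names(reach), function(x) {
      data.table::data.table(s = x, o = reach[[x]])
    }))
  }
  if (nrow(cand) == 0L) cand <- data.table::data.table(s = character(), o = character())
  if (!is.null(ov)) cand <- cand[cand$o %in% ov]
  if (!is.null(sv)) cand <- cand[cand$s %in% sv]
  cand
}

#' Match a rule body against the graph
#'
#' Returns exactly the variable bindings satisfying all patterns
#' conjunctively, without duplicates (set semantics); the empty result is
#' valid.
#'
#' @param body List of `[s, p, o]` term triplets.
#' @param graph A [kb_graph()].
#' @param filters Optional list of `{var, prefix, negate}` uri-prefix guards
#'   applied to the final bindings.
#' @return data.table of bindings, one column per variable (without the `?`).
#' @export
match_body <- function(body, graph, filters = NULL) {
  bindings <- NULL
  empty <- FALSE
  for (pattern in body) {
    stopifnot(length(pattern) == 3L)
    is_path <- grepl("\\*$", pattern[[2]])
    terms <- vapply(pattern, .resolve_term, character(1))
    if (is_path) {
      cand <- .match_path(pattern, graph, bindings)
      cand_terms <- terms[c(1, 3)]
      keep <- c("s", "o")
    } else {
      cand <- graph$dt
      for (i in 1:3) {
        col <- c("s", "p", "o")[i]
        if (!.is_var(terms[i])) cand <- cand[cand[[col]] == terms[i]]
      }
      cand_terms <- terms
      keep <- c("s", "p", "o")
    }
    # project variable columns; enforce intra-pattern repeated variables
    vars <- character(); cols <- character()
    for (i in seq_along(cand_terms)) {
      if (!.is_var(cand_terms[i])) next
      v <- .var_name(cand_terms[i])
      if (v %in% vars) {
        other <- cols[match(v, vars)]
        cand <- cand[cand[[keep[i]]] == cand[[other]]]
      } else {
        vars <- c(vars, v); cols <- c(cols, keep[i])
      }
    }
    proj <- unique(stats::setNames(cand[, cols, with = FALSE], vars))
    if (length(vars) == 0L) {
      # all-constant pattern: acts as an existence guard
      if (nrow(cand) == 0L) empty <- TRUE
      next
    }
    if (is.null(bindings)) {
      bindings <- proj
    } else {
      shared <- intersect(names(bindings), names(proj))
      if (length(shared) > 0L) {
        bindings <- merge(bindings, proj, by = shared, allow.cartesian = TRUE)
      } else {
        bindings <- data.table::setDT(merge.data.frame(bindings, proj, by = NULL))
      }
    }
    if (nrow(bindings) == 0L) { empty <- TRUE; break }
  }
  if (is.null(bindings)) {
    bindings <- data.table::data.table()
  }
  if (empty) bindings <- bindings[0L]
  bindings <- unique(bindings)
  for (f in filters) {
    v <- if (.is_var(f$var)) .var_name(f$var) else f$var
    if (!v %in% names(bindings)) next
    hit <- startsWith(bindings[[v]], expand_curie(f$prefix))
    if (isTRUE(f$negate)) hit <- !hit
    bindings <- bindings[hit]
  }
  unique(bindings)
}

# resolve mint directives for one binding (named character vector);
# directives may reference each other, resolved to a fixed point
.resolve_mints <- function(mint, env) {
  if (is.null(mint) || length(mint) == 0L) return(env)
  todo <- names(mint)
  repeat {
    progressed <- FALSE
    for (v in todo) {
      d <- mint[[v]]
      comps <- vapply(d$components, function(cp) {
        if (.is_var(cp)) {
          val <- env[[.var_name(cp)]]
          if (is.null(val)) NA_character_ else val
        } else expand_curie(cp)
      }, character(1))
      if (anyNA(comps)) next
      uri <- switch(d$kind,
        "restriction" = mint_restriction_uri(comps[[1]], comps[[2]]),
        "bio-class" = mint_bio_uri(d$subtag %||% "generic", comps,
                                   prefix = d$prefix %||% "BIO_"),
        "id-set" = mint_set_uri(comps),
        "field-value" = mint_fieldvalue_uri(comps[[1]], comps[[2]]),
        stop("unknown mint kind: ", d$kind))
      env[[.var_name(v)]] <- uri
      todo <- setdiff(todo, v)
      progressed <- TRUE
    }
    if (length(todo) == 0L) break
    if (!progressed) {
      stop(.condition("UnboundVariable",
                      paste0("mint directives cannot be resolved for: ",
                             paste(todo, collapse = ", "))))
    }
  }
  env
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Instantiate a rule head for one binding
#'
#' Substitutes bound variables into the head template, minting fresh URIs for
#' head variables that carry a mint directive; minted URIs are identical
#' across repeated calls with identical bindings. A head variable with neither
#' a binding nor a directive raises `UnboundVariable`.
#'
#' @param head List of `[s, p, o]` template triplets.
#' @param binding Named character vector or single-row binding table.
#' @param mint Named list of mint directives (`?var -> {kind, components,
#'   subtag, prefix}`).
#' @return data.table of instantiated triples (duplicates within the template
#'   collapsed).
#' @export
instantiate <- function(head, binding, mint = NULL) {
  if (is.data.frame(binding)) {
    stopifnot(nrow(binding) == 1L)
    binding <- unlist(binding[1, ])
  }
  env <- as.list(binding)
  env <- .resolve_mints(mint, env)
  subst <- function(t) {
    if (.is_var(t)) {
      val <- env[[.var_name(t)]]
      if (is.null(val)) {
        stop(.condition("UnboundVariable",
                        paste0("head variable ", t,
                               " has neither a binding nor a mint directive")))
      }
      val
    } else expand_curie(t)
  }
  rows <- lapply(head, function(tr) vapply(tr, subst, character(1)))
  mat <- do.call(rbind, rows)
  unique(data.table::data.table(s = mat[, 1], p = mat[, 2], o = mat[, 3]))
}

# run one rule once; returns list(new = count of new template triples,
# mentions_new, triples, derivations)
.apply_rule <- function(rule, graph) {
  bindings <- match_body(rule$body, graph, rule$filters)
  out_triples <- list()
  out_deriv <- list()
  mentions_new <- 0L
  n_new <- 0L
  if (nrow(bindings) > 0L && ncol(bindings) > 0L) {
    for (i in seq_len(nrow(bindings))) {
      b <- unlist(bindings[i, ])
      trip <- instantiate(rule$head, b, rule$mint)
      n_new <- n_new + kb_add(graph, trip)
      env <- .resolve_mints(rule$mint, as.list(b))
      recs <- unname(unlist(env))
      recs <- recs[grepl("/rec/", recs, fixed = TRUE)]
      deriv <- data.table::data.table(
        s = trip$s, p = trip$p, o = trip$o,
        rule = rule$name,
        binding = as.character(jsonlite::toJSON(env, auto_unbox = TRUE)),
        records = paste(unique(recs), collapse = " "))
      out_deriv[[length(out_deriv) + 1L]] <- deriv
      if (!is.null(rule$mentions)) {
        m <- kb_triples(env[[.var_name(rule$mentions$record)]],
                        "iao:mentions",
                        env[[.var_name(rule$mentions$concept)]])
        mentions_new <- mentions_new + kb_add(graph, m)
        out_deriv[[length(out_deriv) + 1L]] <- data.table::data.table(
          s = m$s, p = m$p, o = m$o, rule = rule$name,
          binding = as.character(jsonlite::toJSON(env, auto_unbox = TRUE)),
          records = paste(unique(recs), collapse = " "))
      }
    }
  }
  kb_record_derivations(graph, data.table::rbindlist(out_deriv))
  list(new = n_new, mentions_new = mentions_new)
}

#' Run a rule batch to fixpoint
#'
#' Applies the batch's rules repeatedly (naive re-evaluation with global
#' duplicate suppression) until an iteration adds zero new triples. Per-rule
#' emission counts are returned and logged -- a rule emitting zero triples
#' over the whole batch flags a broken mapping. Parsed rules are registered on
#' the graph for later derivation replay.
#'
#' @param batch Parsed batch from [parse_rule_file()] (or a list with `batch`
#'   and `rules`).
#' @param graph A [kb_graph()].
#' @param max_iter Non-termination guard; exceeding it aborts with a
#'   `NonTermination` error carrying diagnostics.
#' @return List: `counts` (data.table: rule, template triples, mentions
#'   triples), `iterations`.
#' @export
run_batch_to_fixpoint <- function(batch, graph, max_iter = 50L) {
  if (is.null(graph$rules)) graph$rules <- list()
  counts <- stats::setNames(integer(length(batch$rules)),
                            vapply(batch$rules, `[[`, character(1), "name"))
  mentions <- counts
  for (r in batch$rules) graph$rules[[r$name]] <- r
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_iter) {
      stop(.condition("NonTermination",
                      paste0("batch '", batch$batch, "' did not reach fixpoint ",
                             "after ", max_iter, " iterations (",
                             kb_size(graph), " triples)")))
    }
    added <- 0L
    for (r in batch$rules) {
      res <- .apply_rule(r, graph)
      counts[[r$name]] <- counts[[r$name]] + res$new
      mentions[[r$name]] <- mentions[[r$name]] + res$mentions_new
      added <- added + res$new + res$mentions_new
    }
    if (added == 0L) break
  }
  for (nm in names(counts)) {
    kb_log(graph, "rule ", nm, ": ", counts[[nm]], " template triples, ",
           mentions[[nm]], " mentions triples",
           if (counts[[nm]] == 0L) "  [ZERO EMISSION - check mapping]" else "")
  }
  list(counts = data.table::data.table(rule = names(counts),
                                       triples = unname(counts),
                                       mentions = unname(mentions)),
       iterations = iter)
}

#' Expand kiao:denotesSubClassOf macro assertions
#'
#' `X kiao:denotesSubClassOf Z` is a macrorelation for the property chain of
#' iao:denotes and rdfs:subClassOf: each assertion entails exactly the two
#' triples `X iao:denotes Y` and `Y rdfs:subClassOf Z`, where the intermediate
#' class Y is minted deterministically from X (expanding twice yields the same
#' Y).
#'
#' @param graph A [kb_graph()].
#' @return Number of new triples added.
#' @export
expand_macro <- function(graph) {
  asserts <- kb_find(graph, p = "kiao:denotesSubClassOf")
  if (nrow(asserts) == 0L) return(0L)
  y <- vapply(asserts$s, function(x) mint_bio_uri("denoted", x, prefix = "D_"),
              character(1), USE.NAMES = FALSE)
  trip <- rbind(kb_triples(asserts$s, "iao:denotes", y),
                kb_triples(y, "rdfs:subClassOf", asserts$o))
  n <- kb_add(graph, trip)
  kb_record_derivations(graph, data.table::data.table(
    s = trip$s, p = trip$p, o = trip$o, rule = "macro:denotesSubClassOf",
    binding = c(sprintf('{"x":"%s"}', asserts$s), sprintf('{"x":"%s"}', asserts$s)),
    records = ""))
  n
}
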