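# Identifier canonicalization.
#
# Source files render the same identifier in many lexical dialects ("EG513",
# "EG_513", "EG:513", bare "513" in a field designated for the space). Every
# dialect of one identifier is canonicalized to a single ICE URI of the form
# <kiao>/<dir>/<SPACE>_<local>_ICE, so downstream identity resolution never
# sees lexical variation. Dialect rules live in a declarative YAML config, not
# in code, so new sources add no code.

.condition <- function(class, msg) {
  structure(class = c(class, "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

#' Load identifier dialect rules
#'
#' @param path YAML config path; defaults to the table shipped with the
#'   package. Each space has full-string `patterns` (one capture group, valid
#'   in any context) and an optional `bare_pattern` valid only in fields
#'   designated for that space.
#' @return Object of class `kb_dialects`.
#' @export
kb_dialects <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "config", "dialects.yaml", package = "icekb")
  }
  cfg <- yaml::read_yaml(path)
  stopifnot(!is.null(cfg$spaces))
  for (sp in names(cfg$spaces)) {
    if (is.null(cfg$spaces[[sp]]$uri_dir)) cfg$spaces[[sp]]$uri_dir <- tolower(sp)
  }
  structure(cfg, class = "kb_dialects")
}

#' Canonical identifier ICE URI for a space and local part
#'
#' @param space Identifier-space label (e.g. `"EG"`).
#' @param local Local part of the identifier.
#' @param dialects A [kb_dialects()] table.
#' @return Canonical ICE URI string, ending in `_ICE`.
#' @export
canonical_id_uri <- function(space, local, dialects) {
  dir <- dialects$spaces[[space]]$uri_dir
  if (is.null(dir)) dir <- tolower(space)
  paste0(kb_namespaces()[["kiao"]], dir, "/", space, "_", local, "_ICE")
}

#' Identifier space of canonical ICE URIs
#'
#' @param uri Character vector of canonical identifier ICE URIs.
#' @return Space labels (`NA` for non-identifier URIs).
#' @export
id_space <- function(uri) {
  loc <- basename(uri)
  m <- regmatches(loc, regexec("^([A-Za-z]+)_(.+)_ICE$", loc))
  vapply(seq_along(uri), function(i) {
    if (length(m[[i]]) == 3L && is_ice_uri(uri[i])) m[[i]][2] else NA_character_
  }, character(1))
}

#' Canonicalize a raw identifier string
#'
#' Maps any accepted lexical dialect of an identifier to its one canonical
#' ICE URI. Idempotent: a canonical URI canonicalizes to itself. In a
#' designated-space context the bare pattern is also accepted; in a mixed
#' context (e.g. a dbXref field) only prefixed forms are, and a value matching
#' no space raises an `UnknownDialect` condition (callers quarantine the
#' record and continue the build).
#'
#' @param raw Raw identifier string.
#' @param context List with `space` (designated space label or `NULL`) and
#'   optionally `field` (field name, for error messages).
#' @param dialects A [kb_dialects()] table.
#' @return Canonical identifier ICE URI.
#' @export
#' @examples
#' d <- kb_dialects()
#' canonicalize_identifier("EG:513", list(space = "EG"), d)
canonicalize_identifier <- function(raw, context = list(space = NULL), dialects) {
  raw <- trimws(raw)
  if (!nzchar(raw)) stop(.condition("UnknownDialect", "empty identifier"))
  if (is_ice_uri(raw) && endsWith(raw, "_ICE")) return(raw)
  try_space <- function(space, allow_bare) {
    rules <- dialects$spaces[[space]]
    for (pat in rules$patterns) {
      m <- regmatches(raw, regexec(pat, raw, perl = TRUE))[[1]]
      if (length(m) == 2L) return(canonical_id_uri(space, m[2], dialects))
    }
    if (allow_bare && !is.null(rules$bare_pattern)) {
      m <- regmatches(raw, regexec(rules$bare_pattern, raw, perl = TRUE))[[1]]
      if (length(m) == 2L) return(canonical_id_uri(space, m[2], dialects))
    }
    NULL
  }
  if (!is.null(context$space)) {
    hit <- try_space(context$space, allow_bare = TRUE)
    if (!is.null(hit)) return(hit)
  } else {
    hits <- character()
    for (space in names(dialects$spaces)) {
      h <- try_space(space, allow_bare = FALSE)
      if (!is.null(h)) hits <- c(hits, h)
    }
    if (length(unique(hits)) == 1L) return(hits[[1]])
    if (length(hits) > 1L) {
      stop("ambiguous identifier dialect for '", raw, "': ",
           paste(hits, collapse = ", "))
    }
  }
  stop(.condition("UnknownDialect",
                  paste0("no dialect rule matches '", raw, "'",
                         if (!is.null(context$field)) paste0(" in field '", context$field, "'"),
                         if (!is.null(context$space)) paste0(" (designated space ", context$space, ")"))))
}
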