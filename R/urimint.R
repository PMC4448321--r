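# Deterministic URI minting.
#
# Every generated node (field value, record, identifier set, OWL restriction,
# dynamically generated BIO class) gets a URI built from a SHA-1 hash of the
# values that functionally define it, so identical inputs always re-mint the
# identical URI across builds and no blank nodes are ever needed. Payloads are
# UTF-8 bytes of "<kind-tag>|" followed by the pipe-joined defining
# components; the kind tag makes cross-kind collisions impossible even for
# identical raw components.

.mint_kinds <- c("field-value", "record", "id-set", "restriction", "bio-class")

#' URL-safe base64 token of a SHA-1 digest
#'
#' Hashes a payload with SHA-1 and encodes the 20-byte digest with the
#' URL-safe base64 alphabet (`A-Z a-z 0-9 - _`), padding stripped, giving a
#' 27-character token. Pure function; the empty payload gives
#' `"2jmj7l5rSw0yVb_vlWAYkK_YBwk"`.
#'
#' @param payload Character scalar (hashed as UTF-8 bytes) or raw vector.
#' @return 27-character token string.
#' @export
#' @examples
#' sha1_b64url("")
sha1_b64url <- function(payload) {
  if (is.character(payload)) {
    stopifnot(length(payload) == 1L)
    payload <- charToRaw(enc2utf8(payload))
  }
  stopifnot(is.raw(payload))
  hex <- digest::digest(payload, algo = "sha1", serialize = FALSE)
  dig <- as.raw(strtoi(substring(hex, seq(1, 39, 2), seq(2, 40, 2)), 16L))
  tok <- jsonlite::base64_enc(dig)
  tok <- chartr("+/", "-_", tok)
  sub("=+$", "", tok)
}

#' Mint a URI from a kind tag and its defining components
#'
#' Core recipe shared by all minting helpers: the payload is
#' `"<kind>|comp1|comp2|..."` (UTF-8), hashed with [sha1_b64url()], and the
#' token is appended to `namespace + prefix`.
#'
#' @param kind One of `r paste(.mint_kinds, collapse=", ")`.
#' @param components Character vector of defining components, in order.
#' @param namespace Base URI the minted URI lives under.
#' @param prefix Fixed local-name prefix ahead of the hash token.
#' @return Minted URI string.
#' @export
mint_uri <- function(kind, components, namespace, prefix = "") {
  kind <- match.arg(kind, .mint_kinds)
  stopifnot(is.character(components), length(components) >= 1L)
  tok <- sha1_b64url(paste(c(kind, components), collapse = "|"))
  paste0(namespace, prefix, tok)
}

#' Mint a field-value ICE URI
#'
#' One node per distinct (field, value) pair graph-wide: the URI is a pure
#' function of the field ICE URI and the (already canonicalized) value, so a
#' value shared by many records is represented once.
#'
#' @param field_uri URI of the field ICE the value instantiates.
#' @param value Field value (canonical identifier URI or literal string).
#' @param field_label Human-oriented label woven into the local name.
#' @return Field-value ICE URI under the kiao namespace.
#' @export
mint_fieldvalue_uri <- function(field_uri, value, field_label = "value") {
  mint_uri("field-value", c(field_uri, value),
           paste0(kb_namespaces()[["kiao"]], "fv/"),
           paste0("F_", field_label, "_"))
}

#' Mint a record ICE URI from its schema and primary-key value
#'
#' @param schema_uri Schema ICE URI.
#' @param key Primary-key field value of the row.
#' @return Record ICE URI.
#' @export
mint_record_uri <- function(schema_uri, key) {
  mint_uri("record", c(schema_uri, key),
           paste0(kb_namespaces()[["kiao"]], "rec/"), "R_")
}

#' Mint a permutation-invariant identifier-set URI
#'
#' Members are lexicographically sorted before hashing, so `{A,B}` and
#' `{B,A}` mint the identical URI and distinct member sets mint distinct URIs.
#'
#' @param members Character vector of canonical identifier ICE URIs (>= 1,
#'   all distinct).
#' @return Set URI of the form `kiao:.../idset/ID-Set-<token>`.
#' @export
mint_set_uri <- function(members) {
  if (length(members) == 0L) stop("EmptySet: an identifier set needs >= 1 member")
  if (anyDuplicated(members)) stop("identifier-set members must be distinct")
  # C-locale byte order keeps sorting platform-independent
  sorted <- sort(members, method = "radix")
  mint_uri("id-set", sorted,
           paste0(kb_namespaces()[["kiao"]], "idset/"), "ID-Set-")
}

#' Mint an OWL restriction URI from its property and filler
#'
#' All-some restrictions are reused graph-wide: the URI is a pure function of
#' the (owl:onProperty, owl:someValuesFrom) pair, so the same restriction is
#' represented once however many rules need it.
#'
#' @param property Property URI.
#' @param filler Filler class URI.
#' @return Restriction URI of the form `kbio:R_<token>`.
#' @export
mint_restriction_uri <- function(property, filler) {
  mint_uri("restriction", c(property, filler),
           kb_namespaces()[["kbio"]], "R_")
}

#' Mint a dynamically generated BIO class URI
#'
#' @param subtag Sub-kind of BIO class (e.g. `"set-entity"`, `"goa-process"`,
#'   `"interaction"`, `"aggregate"`, `"denoted"`, `"pathway"`,
#'   `"localization"`); becomes the first payload component after the kind
#'   tag.
#' @param components Defining component URIs/values.
#' @param prefix Local-name prefix (default `"BIO_"`).
#' @return BIO class URI under the kbio namespace.
#' @export
mint_bio_uri <- function(subtag, components, prefix = "BIO_") {
  mint_uri("bio-class", c(subtag, components),
           kb_namespaces()[["kbio"]], prefix)
}
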