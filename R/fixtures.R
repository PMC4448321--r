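# Deterministic synthetic-fixture generator.
#
# Emulates the shapes of the real inputs at desk scale: a mini-ontology with
# the classes and relations the shipped rules touch, a gene catalog with a
# mixed-type dbXref column, identifier-mapping tables, a GAF 2.x annotation
# file, a drug-target table and a pathway table -- with identifier dialects
# deliberately varied across files, and a ground-truth manifest (identity
# partition, annotations, planted errors, demo answer) emitted alongside, so
# acceptance checks are never circular. Identical (seed, counts, error plan)
# give byte-identical files.

#' Fixture specification
#'
#' @param seed Integer RNG seed; drives every random choice.
#' @param genes_per_taxon Genes per organism (two organisms: a human-like and
#'   a mouse-like taxon).
#' @param n_drugs Number of drugs.
#' @param n_interactions Drug-target rows (in addition to the guaranteed
#'   hit-gene interactions and one duplicated row emulating a second source).
#' @param n_pathways,pathway_size Pathway count and proteins per pathway.
#' @param errors Error plan: planted `cross_taxon_mapping` (erroneous
#'   mouse-human protein mapping rows), `many_to_one_mapping` (two drug
#'   records mapped to one external identifier), `cross_type_xref` (drug
#'   identifiers planted in gene dbXref fields, which type guards must
#'   filter).
#' @return List of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 101L, genes_per_taxon = 12L, n_drugs = 8L,
                         n_interactions = 12L, n_pathways = 2L,
                         pathway_size = 3L,
                         errors = list(cross_taxon_mapping = 1L,
                                       many_to_one_mapping = 1L,
                                       cross_type_xref = 2L)) {
  spec <- list(seed = as.integer(seed), genes_per_taxon = as.integer(genes_per_taxon),
               n_drugs = as.integer(n_drugs), n_interactions = as.integer(n_interactions),
               n_pathways = as.integer(n_pathways), pathway_size = as.integer(pathway_size),
               errors = lapply(errors, as.integer))
  class(spec) <- "fixture_spec"
  spec
}

#' Clean error plan (no planted errors)
#' @param ... Passed to [fixture_spec()].
#' @return A `fixture_spec` with all planted-error counts zero.
#' @export
fixture_spec_clean <- function(...) {
  fixture_spec(..., errors = list(cross_taxon_mapping = 0L,
                                  many_to_one_mapping = 0L,
                                  cross_type_xref = 0L))
}

# ontology constants used by generator, rules and demo
.onto <- list(
  taxa = c(human = "9606", mouse = "10090"),
  oxphos = "GO_0006119", oxphos_child = "GO_0042773",
  mito = "GO_0005739",
  other_processes = c("GO_0006810", "GO_0008152", "GO_0022900"),
  other_components = c("GO_0005634", "GO_0005886"))

#' Generate the mini-ontology
#'
#' ~40 classes: a DNA/gene/protein sequence branch, a small process hierarchy
#' with an oxidative-phosphorylation-like leaf (and a child of it, to
#' exercise transitive queries), cellular components, two disjoint taxa, an
#' interaction class, a drug class, a pathway class, and the relation
#' vocabulary (has-participant, located-in, denotes/mentions/is-about,
#' hasMember, in-taxon, templates).
#'
#' @param spec A [fixture_spec()].
#' @param path Output Turtle path.
#' @return `path`, invisibly.
#' @export
generate_mini_ontology <- function(spec, path) {
  if (length(.onto$taxa) == 0L) stop("at least one taxon is mandatory")
  t3 <- function(s, p, o) kb_triples(s, p, o)
  lbl <- function(uri, text) kb_triples(uri, "rdfs:label", kb_literal(text))
  cls <- function(uri, parent, label) {
    rbind(t3(uri, "rdf:type", "owl:Class"),
          if (!is.null(parent)) t3(uri, "rdfs:subClassOf", parent),
          lbl(uri, label))
  }
  prop <- function(uri, label) {
    rbind(t3(uri, "rdf:type", "owl:ObjectProperty"), lbl(uri, label))
  }
  trip <- rbind(
    cls("obo:BFO_0000001", NULL, "entity"),
    cls("obo:BFO_0000040", "obo:BFO_0000001", "material entity"),
    cls("obo:BFO_0000015", "obo:BFO_0000001", "process"),
    cls("obo:SO_0000110", "obo:BFO_0000040", "sequence feature"),
    cls("obo:SO_0000352", "obo:SO_0000110", "DNA"),
    cls("obo:SO_0000704", "obo:SO_0000352", "gene"),
    cls("obo:SO_0001217", "obo:SO_0000704", "protein coding gene"),
    cls("obo:PR_000000001", "obo:BFO_0000040", "protein"),
    cls("obo:CHEBI_24431", "obo:BFO_0000040", "chemical entity"),
    cls("obo:CHEBI_23888", "obo:CHEBI_24431", "drug"),
    cls("obo:GO_0008150", "obo:BFO_0000015", "biological process"),
    cls("obo:GO_0008152", "obo:GO_0008150", "metabolic process"),
    cls("obo:GO_0006091", "obo:GO_0008152", "energy derivation"),
    cls("obo:GO_0006119", "obo:GO_0006091", "oxidative phosphorylation"),
    cls("obo:GO_0042773", "obo:GO_0006119", "ATP synthesis coupled electron transport"),
    cls("obo:GO_0022900", "obo:GO_0006091", "electron transport chain"),
    cls("obo:GO_0006810", "obo:GO_0008150", "transport"),
    cls("obo:GO_0051179", "obo:GO_0008150", "localization"),
    cls("obo:GO_0005575", "obo:BFO_0000040", "cellular component"),
    cls("obo:GO_0005739", "obo:GO_0005575", "mitochondrion"),
    cls("obo:GO_0005634", "obo:GO_0005575", "nucleus"),
    cls("obo:GO_0005886", "obo:GO_0005575", "plasma membrane"),
    cls("obo:MI_0000", "obo:BFO_0000015", "molecular interaction"),
    cls("obo:PW_0000001", "obo:GO_0008150", "pathway"),
    cls("obo:NCBITaxon_1", NULL, "root taxon"),
    cls("obo:NCBITaxon_9606", "obo:NCBITaxon_1", "Homo sapiens"),
    cls("obo:NCBITaxon_10090", "obo:NCBITaxon_1", "Mus musculus"),
    t3("obo:NCBITaxon_9606", "owl:disjointWith", "obo:NCBITaxon_10090"),
    prop("obo:RO_0000057", "has participant"),
    prop("obo:RO_0001025", "located in"),
    prop("iao:denotes", "denotes"),
    prop("iao:mentions", "mentions"),
    prop("iao:is_about", "is about"),
    t3("iao:denotes", "rdfs:subPropertyOf", "iao:is_about"),
    t3("iao:mentions", "rdfs:subPropertyOf", "iao:is_about"),
    prop("kro:hasMember", "has member"),
    prop("kro:in_taxon", "in taxon"),
    prop("kro:has_indirect_template", "has indirect template"),
    prop("kiao:has_template", "has template"),
    prop("kiao:has_field_value", "has field value"),
    prop("kiao:denotesSubClassOf", "denotes subclass of"),
    prop("obo:has_part", "has part"),
    prop("skos:exactMatch", "exact match"))
  write_turtle(unique(trip), path)
  invisible(path)
}

# internal: the deterministic entity tables every file is rendered from
.fixture_entities <- function(spec, dialects) {
  n <- spec$genes_per_taxon
  if (n < 8L) stop("genes_per_taxon must be >= 8 to place hit, decoy and background genes")
  mk <- function(taxon, idx) {
    human <- taxon == "9606"
    data.table::data.table(
      taxon = taxon,
      symbol = paste0(if (human) "HSG" else "MMG", idx),
      eg = as.character((if (human) 100L else 200L) + idx),
      alt_space = if (human) "HGNC" else "MGI",
      alt = as.character((if (human) 800L else 900L) + idx),
      up = sprintf(if (human) "P10%03d" else "Q20%03d", idx),
      ipi = sprintf(if (human) "10%04d" else "20%04d", idx))
  }
  genes <- rbind(mk("9606", seq_len(n)), mk("10090", seq_len(n)))
  # roles: 3 hit genes (oxphos + mitochondrion), 2 process decoys, 2
  # component decoys, all human; everything else background
  genes$role <- "background"
  genes$role[1:3] <- "hit"
  genes$role[4:5] <- "decoy_process"
  genes$role[6:7] <- "decoy_component"
  drugs <- data.table::data.table(
    name = sprintf("cmpd-%02d", seq_len(spec$n_drugs)),
    db = as.character(1000L + seq_len(spec$n_drugs)),
    cid = as.character(5000L + seq_len(spec$n_drugs)))
  list(genes = genes, drugs = drugs)
}

.pick <- function(x, n = 1L, replace = n > length(x)) {
  if (length(x) == 1L) rep(x, n) else sample(x, n, replace = replace)
}

#' Generate the full fixture set
#'
#' Writes `ontology.ttl`, `gene_catalog.tsv`, `protein_mapping.tsv`,
#' `drug_mapping.tsv`, `drug_targets.csv`, `pathway.tsv`, `goa.gaf` and the
#' ground-truth `manifest.yaml` into `dir`.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @param dialects A [kb_dialects()] table (for canonical URIs in the
#'   manifest).
#' @return The manifest, invisibly.
#' @export
generate_sources <- function(spec, dir, dialects = kb_dialects()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)
  generate_mini_ontology(spec, file.path(dir, "ontology.ttl"))
  ent <- .fixture_entities(spec, dialects)
  genes <- ent$genes; drugs <- ent$drugs
  can <- function(space, local) canonical_id_uri(space, local, dialects)

  # --- gene catalog (EG ids in varied dialects; mixed-type dbXref) ---------
  eg_dialects <- c("EG%s", "EG:%s", "EG_%s", "%s")
  up_dialects <- c("UP:%s", "UniProtKB:%s", "%s")
  planted_xref <- list()
  xref_genes <- if (spec$errors$cross_type_xref > 0L)
    .pick(seq_len(nrow(genes)), spec$errors$cross_type_xref) else integer()
  cat_rows <- character(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    xref <- paste0(g$alt_space, ":", g$alt)
    if (stats::runif(1) < 0.5) xref <- c(xref, paste0("UP:", g$up))            # cross-type by design
    if (stats::runif(1) < 0.3) xref <- c(xref, paste0("MIM:", 600000L + i))    # untyped space
    if (i %in% xref_genes) {
      db <- .pick(drugs$db)
      xref <- c(xref, paste0("DB", db))
      planted_xref[[length(planted_xref) + 1L]] <-
        list(kind = "cross-type-xref", left = can("EG", g$eg), right = can("DB", db))
    }
    cat_rows[i] <- paste(
      sprintf(.pick(eg_dialects), g$eg), g$symbol, g$taxon,
      sprintf(.pick(up_dialects), g$up),
      paste(sample(xref), collapse = ";"),
      paste0("synthetic gene ", g$symbol), sep = "\t")
  }
  writeLines(c(paste("gene_id", "symbol", "taxon_id", "protein_id", "dbxref",
                     "description", sep = "\t"), cat_rows),
             file.path(dir, "gene_catalog.tsv"))

  # --- protein mapping (UP <-> IPI), planted cross-taxon rows --------------
  pm <- sprintf("%s\t%s",
                sprintf(.pick(up_dialects, nrow(genes)), genes$up),
                ifelse(stats::runif(nrow(genes)) < 0.5, paste0("IPI", genes$ipi), genes$ipi))
  planted_ct <- list()
  if (spec$errors$cross_taxon_mapping > 0L) {
    mouse <- which(genes$taxon == "10090")
    human <- which(genes$taxon == "9606" & genes$role == "background")
    for (k in seq_len(spec$errors$cross_taxon_mapping)) {
      mi <- mouse[k]; hi <- human[k]
      pm <- c(pm, sprintf("UP:%s\t%s", genes$up[mi], genes$ipi[hi]))
      planted_ct[[k]] <- list(kind = "cross-taxon-mapping",
                              left = can("UP", genes$up[mi]),
                              right = can("IPI", genes$ipi[hi]))
    }
  }
  writeLines(c("up_id\tipi_id", pm), file.path(dir, "protein_mapping.tsv"))

  # --- drug mapping (DB <-> CID), planted many-to-one ----------------------
  dm <- sprintf("DB%s\tCID:%s", drugs$db, drugs$cid)
  planted_m2o <- list()
  if (spec$errors$many_to_one_mapping > 0L) {
    for (k in seq_len(spec$errors$many_to_one_mapping)) {
      # use drugs from the top of the range so planted merges never touch
      # the hit drugs the demo query is scored on
      b <- nrow(drugs) - 2L * (k - 1L); a <- b - 1L
      dm[b] <- sprintf("DB%s\tCID:%s", drugs$db[b], drugs$cid[a])
      planted_m2o[[k]] <- list(kind = "many-to-one-mapping",
                               target = can("CID", drugs$cid[a]),
                               sources = list(can("DB", drugs$db[a]),
                                              can("DB", drugs$db[b])))
    }
  }
  writeLines(c("db_id\tcid_id", dm), file.path(dir, "drug_mapping.tsv"))

  # --- drug targets: every hit gene gets a drug; rest random ---------------
  hit_idx <- which(genes$role == "hit")
  hit_drugs <- drugs[seq_along(hit_idx), ]
  pairs <- data.table::data.table(drug = seq_along(hit_idx), gene = hit_idx)
  extra_d <- sample(seq_len(nrow(drugs)), spec$n_interactions, replace = TRUE)
  extra_g <- sample(which(genes$role != "hit"), spec$n_interactions, replace = TRUE)
  pairs <- unique(rbind(pairs, data.table::data.table(drug = extra_d, gene = extra_g)))
  pairs <- rbind(pairs, pairs[1, ]) # same interaction from a "second source"
  render_target <- function(i) {
    g <- genes[i, ]
    if (stats::runif(1) < 0.5) sprintf(.pick(c("EG%s", "EG:%s")), g$eg)
    else paste0(g$alt_space, ":", g$alt)
  }
  dt_rows <- vapply(seq_len(nrow(pairs)), function(k) {
    d <- drugs[pairs$drug[k], ]
    paste(sprintf("r%03d", k), paste0("DB", d$db), d$name,
          render_target(pairs$gene[k]), "binds", sep = ",")
  }, character(1))
  writeLines(c("row_id,drug_id,drug_name,target_id,action", dt_rows),
             file.path(dir, "drug_targets.csv"))

  # --- GO annotations ------------------------------------------------------
  ann <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    proc <- switch(g$role,
                   hit = .pick(c(.onto$oxphos, .onto$oxphos_child)),
                   decoy_process = .onto$oxphos,
                   .pick(.onto$other_processes))
    comp <- switch(g$role,
                   hit = .onto$mito,
                   decoy_component = .onto$mito,
                   .pick(.onto$other_components))
    ann[[length(ann) + 1L]] <- list(up = g$up, go = proc, aspect = "P",
                                    taxon = g$taxon, symbol = g$symbol)
    ann[[length(ann) + 1L]] <- list(up = g$up, go = comp, aspect = "C",
                                    taxon = g$taxon, symbol = g$symbol)
  }
  gaf_line <- function(a) {
    paste("UniProtKB", a$up, a$symbol, "", sub("_", ":", a$go), "REF:0001",
          "IEA", "", a$aspect, "", "", "protein", paste0("taxon:", a$taxon),
          "20260101", "icekb", "", "", sep = "\t")
  }
  writeLines(c("!gaf-version: 2.1", "!generated synthetically",
               vapply(ann, gaf_line, character(1))),
             file.path(dir, "goa.gaf"))

  # --- pathways ------------------------------------------------------------
  pw_rows <- character(spec$n_pathways)
  for (k in seq_len(spec$n_pathways)) {
    members <- genes$up[.pick(seq_len(nrow(genes)), spec$pathway_size)]
    pw_rows[k] <- paste(paste0("PW:", k), paste0("pathway-", k),
                        paste(members, collapse = ";"), sep = "\t")
  }
  writeLines(c("pathway_id\tpathway_name\tmember_ids", pw_rows),
             file.path(dir, "pathway.tsv"))

  # --- ground truth --------------------------------------------------------
  # true identity partition over identifiers actually present in the files
  # (planted erroneous rows add no new true co-membership)
  partition <- c(
    lapply(seq_len(nrow(genes)), function(i) {
      sort(c(can("EG", genes$eg[i]), can(genes$alt_space[i], genes$alt[i])))
    }),
    lapply(seq_len(nrow(genes)), function(i) {
      sort(c(can("UP", genes$up[i]), can("IPI", genes$ipi[i])))
    }),
    lapply(seq_len(nrow(drugs)), function(i) {
      cid_present <- grepl(paste0("\tCID:", drugs$cid[i], "$"), dm)
      sort(c(can("DB", drugs$db[i]), if (any(cid_present)) can("CID", drugs$cid[i])))
    }),
    lapply(seq_len(spec$n_pathways), function(k) can("PW", as.character(k))))
  # a planted many-to-one error may leave a CID unreferenced; drop empty and
  # re-sort for a canonical ordering
  partition <- Filter(function(s) length(s) > 0L, partition)
  partition <- partition[order(vapply(partition, `[[`, character(1), 1L), method = "radix")]

  # demo ground truth, computed from the generated tables + known hierarchy
  oxphos_closure <- c(.onto$oxphos, .onto$oxphos_child)
  ann_dt <- data.table::rbindlist(lapply(ann, data.table::as.data.table))
  good_up <- intersect(
    ann_dt$up[ann_dt$aspect == "P" & ann_dt$go %in% oxphos_closure],
    ann_dt$up[ann_dt$aspect == "C" & ann_dt$go == .onto$mito])
  good_genes <- which(genes$up %in% good_up)
  demo_drugs <- sort(unique(pairs$drug[pairs$gene %in% good_genes]))

  manifest <- list(
    seed = spec$seed,
    counts = list(genes = nrow(genes), drugs = nrow(drugs),
                  annotations = length(ann), pathways = spec$n_pathways,
                  interactions = nrow(pairs)),
    partition = partition,
    planted_errors = c(planted_ct, planted_m2o, planted_xref),
    demo = list(process = paste0("obo:", .onto$oxphos),
                component = paste0("obo:", .onto$mito),
                drug_ids = as.list(can("DB", drugs$db[demo_drugs])),
                drug_names = as.list(drugs$name[demo_drugs])))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(manifest)
}

#' Generate a worked-example-scale fixture
#'
#' The smallest build that exercises every stage: one gene (two gene
#' identifiers via dbXref), one protein (two protein identifiers), one drug
#' (two drug identifiers), one process annotation and one drug-target row.
#' First-occurrence rule emissions on this fixture are exactly the pattern
#' sizes: 5 triples for the annotation, 9 for the interaction.
#'
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
generate_micro_sources <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  generate_mini_ontology(fixture_spec(), file.path(dir, "ontology.ttl"))
  writeLines(c("gene_id\tsymbol\ttaxon_id\tprotein_id\tdbxref\tdescription",
               "EG513\tATP5D\t9606\tP30049\tHGNC:837\tATP synthase subunit delta"),
             file.path(dir, "gene_catalog.tsv"))
  writeLines(c("up_id\tipi_id", "UP:P30049\tIPI100001"),
             file.path(dir, "protein_mapping.tsv"))
  writeLines(c("db_id\tcid_id", "DB1001\tCID:5001"),
             file.path(dir, "drug_mapping.tsv"))
  writeLines(c("row_id,drug_id,drug_name,target_id,action",
               "r001,DB1001,cmpd-01,EG513,binds"),
             file.path(dir, "drug_targets.csv"))
  writeLines("pathway_id\tpathway_name\tmember_ids",
             file.path(dir, "pathway.tsv"))
  writeLines(c("!gaf-version: 2.1",
               paste("UniProtKB", "P30049", "ATP5D", "", "GO:0006119",
                     "REF:0001", "IEA", "", "P", "", "", "protein",
                     "taxon:9606", "20260101", "icekb", "", "", sep = "\t")),
             file.path(dir, "goa.gaf"))
  invisible(dir)
}

#' Read a fixture manifest
#' @param dir Fixture directory.
#' @return Parsed manifest list.
#' @export
read_manifest <- function(dir) yaml::read_yaml(file.path(dir, "manifest.yaml"))
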