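# Domain model: markers, alleles, genotypes, annotations, and catalog
# validation.  All containers are plain named lists so catalogs serialize
# losslessly to JSON (see load_catalog/write_catalog).

#' Controlled vocabularies
#'
#' Closed vocabularies for marker classes, allele generation methods, and
#' curated allele attributes.  Unknown strings in a catalog are reported by
#' [validate_catalog()] rather than silently accepted, because a misspelled
#' attribute would silently change rule outcomes.
#'
#' @name vocabularies
#' @keywords internal
NULL

MARKER_CLASSES <- c("gene", "transgene", "multi_genic_region")
GENERATION_METHODS <- c("targeted", "transgenic", "endogenous", "other")
ALLELE_ATTRIBUTES <- c(
  "reporter", "recombinase", "transactivator", "inserted_expressed_sequence",
  "null_knockout", "hypomorph", "modified_isoform"
)
ONTOLOGIES <- c(phenotype = "MP:", disease = "OMIM:")

chk_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    stop(sprintf("field '%s' must be a single non-empty string", what),
         call. = FALSE)
  }
  x
}

chk_flag <- function(x, what) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("field '%s' must be TRUE or FALSE", what), call. = FALSE)
  }
  x
}

as_chr <- function(x) as.character(unlist(x, use.names = FALSE))

#' Create a genetic marker record
#'
#' A marker is any genetic locus that can be the subject of a derived
#' annotation: an endogenous gene, a transgene, or a single marker standing
#' for a multi-genic mutation region (e.g. an engineered deletion).
#'
#' @param id Accession string, unique within a catalog (opaque; MGI-style
#'   `"MGI:97490"` ids are typical).
#' @param symbol Display symbol.
#' @param marker_class One of `"gene"`, `"transgene"`,
#'   `"multi_genic_region"`.
#' @param region_genes For multi-genic region markers only: ids of the
#'   endogenous genes inside the mutation region.  Region membership is
#'   curated, never computed from genomic coordinates.
#' @return A list of class `"gr_marker"`.
#' @export
#' @examples
#' marker("MGI:104735", "Gt(ROSA)26Sor")
marker <- function(id, symbol, marker_class = "gene",
                   region_genes = character()) {
  structure(
    list(
      id = chk_string(id, "id"),
      symbol = chk_string(symbol, "symbol"),
      marker_class = chk_string(marker_class, "marker_class"),
      region_genes = as_chr(region_genes)
    ),
    class = "gr_marker"
  )
}

#' Create an expressed-gene association
#'
#' Records that an allele expresses the product of a gene inserted into the
#' construct (the "cargo").  Curation conventions mirrored here: only genes
#' that are mouse genes or have a mouse ortholog are recorded; the tool
#' product itself (cre, Flp, tTA) and expression-modifying motifs (ERT,
#' ERT2) are never recorded as expressed genes.
#'
#' @param gene_id A catalog marker id (mouse) or an external symbol
#'   (non-mouse ortholog source, e.g. human `"FLI1"`).
#' @param species `"mouse"` or `"non_mouse"`.
#' @return A list of class `"gr_expressed_gene"`.
#' @export
expressed_gene <- function(gene_id, species = "mouse") {
  structure(
    list(
      gene_id = chk_string(gene_id, "gene_id"),
      species = chk_string(species, "species")
    ),
    class = "gr_expressed_gene"
  )
}

#' Create an allele record
#'
#' An allele is a mutation event (or a wild-type variant).  It carries
#' exactly one generation method and zero-to-many curated attributes; the
#' attributes, not the nomenclature string, drive the tool-allele filter.
#'
#' @param id,symbol Accession string and display symbol.
#' @param generation_method One of `"targeted"` (knock-in/knock-out),
#'   `"transgenic"`, `"endogenous"` (spontaneous/induced point mutations),
#'   `"other"`.  Only the transgenic/targeted distinction is rule-relevant.
#' @param attributes Character vector drawn from the closed attribute
#'   vocabulary (`reporter`, `recombinase`, `transactivator`,
#'   `inserted_expressed_sequence`, `null_knockout`, `hypomorph`,
#'   `modified_isoform`).
#' @param mutated_markers Ids of the endogenous loci disrupted by the
#'   mutation, or the transgene marker itself, or the multi-genic region
#'   marker.
#' @param expressed_genes List of [expressed_gene()] records.
#' @param is_wild_type `TRUE` for wild-type alleles (which must carry no
#'   attributes, no expressed genes, and exactly one mutated marker).
#' @return A list of class `"gr_allele"`.
#' @export
#' @examples
#' allele("MGI:2136847", "App<tm1Dbo>", "targeted",
#'        attributes = "null_knockout", mutated_markers = "syn:App")
allele <- function(id, symbol, generation_method,
                   attributes = character(),
                   mutated_markers = character(),
                   expressed_genes = list(),
                   is_wild_type = FALSE) {
  eg <- lapply(expressed_genes, function(e) {
    if (inherits(e, "gr_expressed_gene")) e
    else expressed_gene(e$gene_id, e$species %||% "mouse")
  })
  structure(
    list(
      id = chk_string(id, "id"),
      symbol = chk_string(symbol, "symbol"),
      generation_method = chk_string(generation_method, "generation_method"),
      attributes = as_chr(attributes),
      mutated_markers = as_chr(mutated_markers),
      expressed_genes = eg,
      is_wild_type = chk_flag(is_wild_type, "is_wild_type")
    ),
    class = "gr_allele"
  )
}

#' Create an allele pair
#'
#' Pair order carries no meaning.  `allele2 = NA` represents hemizygous or
#' indeterminate second alleles (typical for transgenes).
#'
#' @param allele1 Allele id (required).
#' @param allele2 Allele id or `NA`.
#' @return A list of class `"gr_allele_pair"`.
#' @export
allele_pair <- function(allele1, allele2 = NA_character_) {
  if (length(allele2) != 1L || (!is.na(allele2) && !is.character(allele2))) {
    stop("field 'allele2' must be a single allele id or NA", call. = FALSE)
  }
  structure(
    list(allele1 = chk_string(allele1, "allele1"),
         allele2 = as.character(allele2)),
    class = "gr_allele_pair"
  )
}

#' Create a genotype record
#'
#' A genotype is the curated genetic representation of the mice in an
#' experiment: a set of allele pairs plus strain background.  The
#' conditional flag marks genotypes in which a recombinase acts on a
#' recombination-site-flanked allele; it is curated input and never
#' inferred.
#'
#' @param id Accession string.
#' @param allele_pairs List of [allele_pair()] records (at least one).
#' @param is_conditional Curated conditional flag.
#' @param strain_background Opaque strain descriptor; carried through to
#'   traces but never consulted by the rules.
#' @return A list of class `"gr_genotype"`.
#' @export
genotype <- function(id, allele_pairs, is_conditional = FALSE,
                     strain_background = "involves: unspecified") {
  if (!is.list(allele_pairs) || length(allele_pairs) == 0L) {
    stop("a genotype needs at least one allele pair", call. = FALSE)
  }
  ap <- lapply(allele_pairs, function(p) {
    if (inherits(p, "gr_allele_pair")) p
    else allele_pair(p$allele1, p$allele2 %||% NA_character_)
  })
  structure(
    list(
      id = chk_string(id, "id"),
      allele_pairs = ap,
      is_conditional = chk_flag(is_conditional, "is_conditional"),
      strain_background = chk_string(strain_background, "strain_background")
    ),
    class = "gr_genotype"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble a catalog
#'
#' A catalog bundles markers, alleles and genotypes.  Records are stored in
#' id-named lists; duplicate ids are retained (and flagged by
#' [validate_catalog()]).
#'
#' @param markers,alleles,genotypes Lists of records built with [marker()],
#'   [allele()], [genotype()].
#' @return A list of class `"gr_catalog"`.
#' @export
catalog <- function(markers = list(), alleles = list(), genotypes = list()) {
  named <- function(xs) stats::setNames(xs, vapply(xs, `[[`, "", "id"))
  structure(
    list(markers = named(markers), alleles = named(alleles),
         genotypes = named(genotypes)),
    class = "gr_catalog"
  )
}

#' @export
print.gr_catalog <- function(x, ...) {
  cat(sprintf("<catalog> %d markers, %d alleles, %d genotypes\n",
              length(x$markers), length(x$alleles), length(x$genotypes)))
  invisible(x)
}

# Fast lookup environments for large catalogs; pass-through if already built.
catalog_index <- function(cat) {
  if (is.environment(cat)) return(cat)
  idx <- new.env(parent = emptyenv())
  idx$markers <- list2env(as.list(cat$markers), parent = emptyenv())
  idx$alleles <- list2env(as.list(cat$alleles), parent = emptyenv())
  idx$genotypes <- list2env(as.list(cat$genotypes), parent = emptyenv())
  idx
}

lookup <- function(env, id) {
  if (exists(id, envir = env, inherits = FALSE)) {
    get(id, envir = env, inherits = FALSE)
  } else NULL
}

violation <- function(entity, id, rule, message) {
  data.frame(entity = entity, id = id, rule = rule, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a catalog
#'
#' Checks referential integrity and every type invariant.  Violations are
#' data, not exceptions: the result names the offending entity and rule so
#' a curator can fix the source records.  Validation is deterministic and
#' order-independent (the result is sorted), and a catalog that validates
#' cleanly is guaranteed not to raise cross-reference errors downstream.
#'
#' @param cat A [catalog()].
#' @return A data frame with columns `entity`, `id`, `rule`, `message`;
#'   zero rows iff the catalog is internally consistent.
#' @export
validate_catalog <- function(cat) {
  stopifnot(inherits(cat, "gr_catalog"))
  v <- list()
  add <- function(...) v[[length(v) + 1L]] <<- violation(...)

  mids <- names(cat$markers)
  aids <- names(cat$alleles)
  gids <- names(cat$genotypes)
  for (d in unique(mids[duplicated(mids)])) {
    add("marker", d, "unique_id", sprintf("marker id '%s' occurs more than once", d))
  }
  for (d in unique(aids[duplicated(aids)])) {
    add("allele", d, "unique_id", sprintf("allele id '%s' occurs more than once", d))
  }
  for (d in unique(gids[duplicated(gids)])) {
    add("genotype", d, "unique_id", sprintf("genotype id '%s' occurs more than once", d))
  }

  marker_class_of <- function(id) {
    m <- cat$markers[[id]]
    if (is.null(m)) NA_character_ else m$marker_class
  }

  for (m in cat$markers) {
    if (!m$marker_class %in% MARKER_CLASSES) {
      add("marker", m$id, "marker_class_vocabulary",
          sprintf("unknown marker_class '%s'", m$marker_class))
    }
    if (m$marker_class == "multi_genic_region") {
      if (length(m$region_genes) == 0L) {
        add("marker", m$id, "region_genes_required",
            "multi_genic_region marker must list its region genes")
      }
      for (g in m$region_genes) {
        cls <- marker_class_of(g)
        if (is.na(cls)) {
          add("marker", m$id, "region_gene_ref",
              sprintf("region gene '%s' is not in the catalog", g))
        } else if (cls != "gene") {
          add("marker", m$id, "region_gene_class",
              sprintf("region gene '%s' is not a gene-class marker", g))
        }
      }
    } else if (length(m$region_genes) > 0L) {
      add("marker", m$id, "region_genes_forbidden",
          "region_genes present on a non-region marker")
    }
  }

  for (a in cat$alleles) {
    if (!a$generation_method %in% GENERATION_METHODS) {
      add("allele", a$id, "generation_method_vocabulary",
          sprintf("unknown generation_method '%s'", a$generation_method))
    }
    for (at in setdiff(a$attributes, ALLELE_ATTRIBUTES)) {
      add("allele", a$id, "attribute_vocabulary",
          sprintf("unknown attribute '%s'", at))
    }
    if (length(a$mutated_markers) == 0L) {
      add("allele", a$id, "mutated_markers_required",
          "an allele must reference at least one mutated marker")
    }
    for (mm in a$mutated_markers) {
      if (is.null(cat$markers[[mm]])) {
        add("allele", a$id, "mutated_marker_ref",
            sprintf("mutated marker '%s' is not in the catalog", mm))
      }
    }
    if (a$is_wild_type) {
      if (length(a$attributes) > 0L) {
        add("allele", a$id, "wild_type_plain",
            "a wild-type allele cannot carry attributes")
      }
      if (length(a$expressed_genes) > 0L) {
        add("allele", a$id, "wild_type_plain",
            "a wild-type allele cannot carry expressed genes")
      }
      if (length(a$mutated_markers) != 1L) {
        add("allele", a$id, "wild_type_single_marker",
            "a wild-type allele must reference exactly one marker")
      }
    }
    if (a$generation_method == "transgenic") {
      tg <- a$mutated_markers[vapply(a$mutated_markers, function(x)
        identical(marker_class_of(x), "transgene"), NA)]
      if (length(a$mutated_markers) != 1L || length(tg) != 1L) {
        add("allele", a$id, "transgenic_marker",
            "a transgenic allele must reference exactly one transgene-class marker")
      }
    }
    for (eg in a$expressed_genes) {
      if (!eg$species %in% c("mouse", "non_mouse")) {
        add("allele", a$id, "expressed_species_vocabulary",
            sprintf("unknown expressed-gene species '%s'", eg$species))
      } else if (eg$species == "mouse") {
        cls <- marker_class_of(eg$gene_id)
        if (is.na(cls)) {
          add("allele", a$id, "expressed_gene_ref",
              sprintf("expressed mouse gene '%s' is not in the catalog", eg$gene_id))
        } else if (cls != "gene") {
          add("allele", a$id, "expressed_gene_class",
              sprintf("expressed mouse gene '%s' is not a gene-class marker", eg$gene_id))
        }
      }
    }
  }

  for (g in cat$genotypes) {
    for (p in g$allele_pairs) {
      for (aid in c(p$allele1, p$allele2)) {
        if (!is.na(aid) && is.null(cat$alleles[[aid]])) {
          add("genotype", g$id, "allele_ref",
              sprintf("allele '%s' is not in the catalog", aid))
        }
      }
    }
  }

  out <- if (length(v)) do.call(rbind, v) else
    violation(character(), character(), character(), character())[0, ]
  out <- unique(out)
  out <- out[order(out$entity, out$id, out$rule, out$message), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Derivation configuration
#'
#' The docking-site policy.  Three endogenous genes — Gt(ROSA)26Sor, Col1a1
#' and Hprt — are routinely used as landing pads for expression constructs;
#' a genotype resolving to a docking site plus one inserted expressed mouse
#' gene is attributed to the expressed gene.  Gt(ROSA)26Sor additionally
#' never receives annotations itself (no phenotypes are known to result
#' from its disruption), so it is also a member of
#' `never_self_annotate_ids`.
#'
#' Docking behaviour comes only from config membership: a knock-in at any
#' other intergenic site is deliberately not treated as a docking site.
#'
#' @param cat Optional catalog; when given with the default arguments, the
#'   docking ids are looked up by the symbols `Gt(ROSA)26Sor`, `Col1a1`,
#'   `Hprt`.
#' @param docking_site_ids Marker ids treated as docking sites.
#' @param never_self_annotate_ids Subset of `docking_site_ids` that must
#'   never appear as derived-annotation subjects.
#' @return A list of class `"gr_config"`.
#' @export
derivation_config <- function(cat = NULL,
                              docking_site_ids = NULL,
                              never_self_annotate_ids = NULL) {
  if (is.null(docking_site_ids)) {
    docking_site_ids <- character()
    never_default <- character()
    if (!is.null(cat)) {
      syms <- vapply(cat$markers, `[[`, "", "symbol")
      docking_site_ids <- unname(names(syms)[syms %in%
        c("Gt(ROSA)26Sor", "Col1a1", "Hprt")])
      never_default <- unname(names(syms)[syms == "Gt(ROSA)26Sor"])
    }
    if (is.null(never_self_annotate_ids)) never_self_annotate_ids <- never_default
  }
  if (is.null(never_self_annotate_ids)) never_self_annotate_ids <- character()
  docking_site_ids <- sort(unique(as_chr(docking_site_ids)))
  never_self_annotate_ids <- sort(unique(as_chr(never_self_annotate_ids)))
  if (!all(never_self_annotate_ids %in% docking_site_ids)) {
    stop("never_self_annotate_ids must be a subset of docking_site_ids",
         call. = FALSE)
  }
  structure(
    list(docking_site_ids = docking_site_ids,
         never_self_annotate_ids = never_self_annotate_ids),
    class = "gr_config"
  )
}
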