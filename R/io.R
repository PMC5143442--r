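# Serialization: JSON catalogs, TSV annotation tables, and the derived /
# trace output files.  All output is deterministic (fully specified sort
# order and formatting) so that reruns on identical input are
# byte-identical and diffs are meaningful.

#' Read a catalog document
#'
#' The catalog format is a JSON document with top-level keys `markers`,
#' `alleles`, `genotypes`, whose records carry exactly the fields of
#' [marker()], [allele()] and [genotype()].  The document is parsed, each
#' record is built through the constructors (so malformed fields fail with
#' a named-field error), and [validate_catalog()] is run; a catalog with
#' violations is still returned so the violations can be inspected.
#'
#' @param path Path to a catalog JSON file.
#' @return A list with `catalog` and `violations` (see
#'   [validate_catalog()]).
#' @export
load_catalog <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop(sprintf("cannot parse '%s' as JSON: %s",
                                     path, conditionMessage(e)), call. = FALSE)
  )
  for (key in c("markers", "alleles", "genotypes")) {
    if (is.null(doc[[key]])) {
      stop(sprintf("catalog document is missing the '%s' section", key),
           call. = FALSE)
    }
  }
  wrap <- function(kind, f) function(rec) {
    tryCatch(f(rec), error = function(e)
      stop(sprintf("bad %s record%s: %s", kind,
                   if (!is.null(rec$id)) sprintf(" '%s'", rec$id) else "",
                   conditionMessage(e)), call. = FALSE))
  }
  cat <- catalog(
    markers = lapply(doc$markers, wrap("marker", function(m)
      marker(m$id, m$symbol, m$marker_class %||% "gene",
             as_chr(m$region_genes)))),
    alleles = lapply(doc$alleles, wrap("allele", function(a)
      allele(a$id, a$symbol, a$generation_method,
             attributes = as_chr(a$attributes),
             mutated_markers = as_chr(a$mutated_markers),
             expressed_genes = lapply(a$expressed_genes, function(e)
               expressed_gene(e$gene_id, e$species %||% "mouse")),
             is_wild_type = a$is_wild_type %||% FALSE))),
    genotypes = lapply(doc$genotypes, wrap("genotype", function(g)
      genotype(g$id,
               lapply(g$allele_pairs, function(p)
                 allele_pair(p$allele1,
                             if (is.null(p$allele2)) NA_character_
                             else p$allele2)),
               is_conditional = g$is_conditional %||% FALSE,
               strain_background = g$strain_background %||%
                 "involves: unspecified")))
  )
  list(catalog = cat, violations = validate_catalog(cat))
}

catalog_to_document <- function(cat) {
  list(
    markers = lapply(unname(cat$markers), function(m) list(
      id = jsonlite::unbox(m$id), symbol = jsonlite::unbox(m$symbol),
      marker_class = jsonlite::unbox(m$marker_class),
      region_genes = m$region_genes
    )),
    alleles = lapply(unname(cat$alleles), function(a) list(
      id = jsonlite::unbox(a$id), symbol = jsonlite::unbox(a$symbol),
      generation_method = jsonlite::unbox(a$generation_method),
      attributes = a$attributes,
      mutated_markers = a$mutated_markers,
      expressed_genes = lapply(a$expressed_genes, function(e) list(
        gene_id = jsonlite::unbox(e$gene_id),
        species = jsonlite::unbox(e$species)
      )),
      is_wild_type = jsonlite::unbox(a$is_wild_type)
    )),
    genotypes = lapply(unname(cat$genotypes), function(g) list(
      id = jsonlite::unbox(g$id),
      allele_pairs = lapply(g$allele_pairs, function(p) list(
        allele1 = jsonlite::unbox(p$allele1),
        allele2 = if (is.na(p$allele2)) NULL else jsonlite::unbox(p$allele2)
      )),
      is_conditional = jsonlite::unbox(g$is_conditional),
      strain_background = jsonlite::unbox(g$strain_background)
    ))
  )
}

#' Write a catalog document
#'
#' Inverse of [load_catalog()]: `load_catalog(write_catalog(cat, f))`
#' reproduces `cat` exactly.
#'
#' @param cat A [catalog()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(cat, path) {
  json <- jsonlite::toJSON(catalog_to_document(cat), pretty = TRUE,
                           null = "null", digits = NA)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

ANNOTATION_COLUMNS <- c("genotype_id", "term_id", "ontology", "qualifier",
                        "reference")

#' Read a genotype-level annotation table
#'
#' Tab-separated with header
#' `genotype_id  term_id  ontology  qualifier  reference`.  Term ids carry
#' an `MP:` (phenotype) or `OMIM:` (disease) prefix; a blank ontology cell
#' is inferred from the prefix, and a prefix/ontology mismatch is a
#' row-level error.
#'
#' @param path Path to the TSV file.
#' @return A data frame with the five columns above plus `row` (source row
#'   number, for error reporting downstream).
#' @export
load_annotations <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- utils::read.delim(path, colClasses = "character",
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(ANNOTATION_COLUMNS, names(df))
  if (length(missing)) {
    stop(sprintf("annotation table is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df <- df[, ANNOTATION_COLUMNS, drop = FALSE]
  df$row <- seq_len(nrow(df)) + 1L  # +1 for the header line
  if (nrow(df) == 0L) return(df)

  prefix_ontology <- ifelse(startsWith(df$term_id, "MP:"), "phenotype",
                     ifelse(startsWith(df$term_id, "OMIM:"), "disease",
                            NA_character_))
  bad_prefix <- which(is.na(prefix_ontology))
  if (length(bad_prefix)) {
    stop(sprintf("row %s: term id '%s' has neither an MP: nor an OMIM: prefix",
                 df$row[bad_prefix[1]], df$term_id[bad_prefix[1]]),
         call. = FALSE)
  }
  blank <- !nzchar(df$ontology)
  df$ontology[blank] <- prefix_ontology[blank]
  clash <- which(df$ontology != prefix_ontology)
  if (length(clash)) {
    stop(sprintf(
      "row %s: term '%s' is inconsistent with ontology '%s'",
      df$row[clash[1]], df$term_id[clash[1]], df$ontology[clash[1]]),
      call. = FALSE)
  }
  df
}

#' Write an annotation table
#'
#' @param annotations Data frame with the standard annotation columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(annotations[, ANNOTATION_COLUMNS, drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

locus_set_to_document <- function(ls) {
  list(
    provenance = if (length(ls$provenance)) ls$provenance else
      structure(list(), names = character()),
    non_mouse = ls$non_mouse
  )
}

trace_to_document <- function(tr) {
  res <- tr$resolution
  list(
    genotype_id = jsonlite::unbox(tr$genotype_id),
    strain_background = jsonlite::unbox(tr$strain_background),
    verdicts = lapply(seq_len(nrow(tr$verdicts)), function(i) list(
      allele_id = jsonlite::unbox(tr$verdicts$allele_id[i]),
      verdict = jsonlite::unbox(tr$verdicts$verdict[i]),
      reason = jsonlite::unbox(tr$verdicts$reason[i])
    )),
    loci_before = locus_set_to_document(tr$loci_before),
    loci_after = locus_set_to_document(tr$loci_after),
    resolution = list(
      terminal_box = jsonlite::unbox(res$terminal_box),
      annotate_markers = res$annotate_markers,
      exclusion_reason = if (is.na(res$exclusion_reason)) NULL
                         else jsonlite::unbox(res$exclusion_reason)
    )
  )
}

document_to_trace <- function(doc) {
  vs <- doc$verdicts
  res <- doc$resolution
  ls_from <- function(d) locus_set(
    provenance = lapply(d$provenance, as_chr),
    non_mouse = as_chr(d$non_mouse)
  )
  structure(
    list(
      genotype_id = doc$genotype_id,
      verdicts = data.frame(
        allele_id = vapply(vs, `[[`, "", "allele_id"),
        verdict = vapply(vs, `[[`, "", "verdict"),
        reason = vapply(vs, `[[`, "", "reason"),
        stringsAsFactors = FALSE
      ),
      loci_before = ls_from(doc$loci_before),
      loci_after = ls_from(doc$loci_after),
      resolution = new_resolution(doc$genotype_id, res$terminal_box,
                                  as_chr(res$annotate_markers),
                                  res$exclusion_reason %||% NA_character_),
      strain_background = doc$strain_background
    ),
    class = "gr_trace"
  )
}

#' Write the outputs of a derivation run
#'
#' Writes `derived_annotations.tsv` (sorted by marker id, term id,
#' ontology; provenance columns semicolon-joined) and `traces.json` (one
#' entry per genotype, keyed and sorted by genotype id).  Output is
#' byte-identical across runs on identical input.
#'
#' @param derived,traces As returned by [derive_annotations()].
#' @param outdir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_outputs <- function(derived, traces, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tsv <- file.path(outdir, "derived_annotations.tsv")
  utils::write.table(derived, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tj <- file.path(outdir, "traces.json")
  traces <- traces[order(names(traces))]
  docs <- lapply(traces, trace_to_document)
  writeLines(jsonlite::toJSON(docs, pretty = TRUE, null = "null",
                              digits = NA),
             tj, useBytes = TRUE)
  invisible(c(derived = tsv, traces = tj))
}

#' Read back a traces file
#'
#' @param path A `traces.json` written by [write_outputs()].
#' @return List of decision traces named by genotype id.
#' @export
load_traces <- function(path) {
  docs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(docs, document_to_trace)
}

#' Read a run-configuration file
#'
#' JSON with optional keys `catalog`, `annotations`, `out` (paths),
#' `docking_site_ids`, `never_self_annotate_ids`, `log_level`, `seed`.
#' Referenced input paths must exist; the seed must be a non-negative
#' integer.
#'
#' @param path Path to the config file.
#' @return A named list of settings.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (key in c("catalog", "annotations")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      stop(sprintf("config '%s' path does not exist: %s", key, cfg[[key]]),
           call. = FALSE)
    }
  }
  if (!is.null(cfg$seed) &&
      (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || cfg$seed < 0)) {
    stop("config 'seed' must be a non-negative integer", call. = FALSE)
  }
  cfg
}
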