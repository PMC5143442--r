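# The resolution engine: walk each annotated genotype through the
# derivation flow chart and decide which marker(s), if any, inherit its
# annotations.

TERMINAL_BOXES <- c(
  "B1_SINGLE", "B3_SINGLE_AFTER_FILTER", "B4_MULTIGENIC_MARKER",
  "B6_TRANSGENE_ONLY", "B8_TRANSGENE_PLUS_GENE",
  "B9_TRANSGENE_ENDOGENOUS_MATCH", "B10_DOCKING_SITE", "B11_SELF_EXPRESSED",
  "EXCLUDED"
)

GENOTYPE_EXCLUSION_REASONS <- c(
  "multiple_multigenic", "multigenic_plus_outside", "multi_marker_no_expressed",
  "multi_expressed_not_single_transgene", "non_mouse_expressed",
  "unresolved_multi", "all_alleles_excluded", "rosa_suppressed"
)

new_resolution <- function(genotype_id, terminal_box, annotate_markers,
                           exclusion_reason = NA_character_) {
  structure(
    list(genotype_id = genotype_id, terminal_box = terminal_box,
         annotate_markers = sort(unique(as_chr(annotate_markers))),
         exclusion_reason = exclusion_reason),
    class = "gr_resolution"
  )
}

#' @export
print.gr_resolution <- function(x, ...) {
  cat(sprintf("<resolution> %s: %s -> {%s}%s\n", x$genotype_id,
              x$terminal_box, paste(x$annotate_markers, collapse = ", "),
              if (is.na(x$exclusion_reason)) "" else
                paste0(" [", x$exclusion_reason, "]")))
  invisible(x)
}

#' Resolve one genotype to its causative marker set
#'
#' Walks the derivation flow chart:
#'
#' 1. Count the loci of all alleles.  A single locus resolves immediately
#'    (`B1_SINGLE`) — the one-marker genotype case that needs no filtering.
#' 2. Otherwise remove non-causative tool alleles
#'    ([filter_noncausative()]) and recount over the retained alleles; if
#'    nothing is retained the genotype is excluded
#'    (`all_alleles_excluded`).
#' 3. A single remaining locus resolves to that marker
#'    (`B3_SINGLE_AFTER_FILTER`), or to `B11_SELF_EXPRESSED` when the sole
#'    remaining gene is itself the inserted expressed gene (a knock-in
#'    expressing a variant of its own host gene).
#' 4. A single multi-genic region marker together with (a subset of) its
#'    region genes resolves to the region marker alone
#'    (`B4_MULTIGENIC_MARKER`); two region markers, or a region marker plus
#'    any locus outside the region, exclude the genotype.
#' 5. Multiple remaining loci with no inserted expressed gene exclude the
#'    genotype (`multi_marker_no_expressed`).
#' 6. Multiple expressed genes resolve to the transgene alone
#'    (`B6_TRANSGENE_ONLY`) when there is exactly one transgene and no
#'    endogenous mutated gene remains — the transgene as a whole, not its
#'    individual cargo genes, is taken as causative.
#' 7. A single expressed non-mouse gene excludes the genotype: no
#'    assumption is made that the mouse ortholog would produce the same
#'    phenotype.
#' 8. / 9. Exactly one transgene plus its single expressed mouse gene
#'    annotates both (`B8`; `B9` when the same gene is additionally
#'    mutated endogenously — the two boxes differ only in the trace).
#' 10. A docking-site gene plus one expressed mouse gene annotates the
#'    expressed gene only (`B10_DOCKING_SITE`).
#' 11. Anything else is excluded (`unresolved_multi`): causality cannot be
#'    pinned on a single marker, and the rules prefer a false negative to a
#'    false positive.
#'
#' On every path, markers in `config$never_self_annotate_ids` (by default
#' Gt(ROSA)26Sor) are stripped from the result; if that empties it, the
#' genotype is excluded with reason `rosa_suppressed`.
#'
#' @param g A [genotype()].
#' @param cat A [catalog()].
#' @param config A [derivation_config()]; defaults to docking sites looked
#'   up by symbol in `cat`.
#' @return A decision trace (class `"gr_trace"`): `genotype_id`,
#'   `verdicts`, `loci_before`, `loci_after`, `resolution`,
#'   `strain_background`.
#' @export
resolve_genotype <- function(g, cat, config = NULL) {
  idx <- catalog_index(cat)
  if (is.null(config)) config <- derivation_config(cat)

  loci_before <- genotype_loci(g, idx)
  verdicts <- data.frame(allele_id = character(), verdict = character(),
                         reason = character(), stringsAsFactors = FALSE)

  finish <- function(box, markers, loci_after) {
    keep <- setdiff(markers, config$never_self_annotate_ids)
    res <- if (length(markers) > 0L && length(keep) == 0L) {
      new_resolution(g$id, "EXCLUDED", character(), "rosa_suppressed")
    } else {
      new_resolution(g$id, box, keep)
    }
    structure(
      list(genotype_id = g$id, verdicts = verdicts,
           loci_before = loci_before, loci_after = loci_after,
           resolution = res, strain_background = g$strain_background),
      class = "gr_trace"
    )
  }
  excluded <- function(reason, loci_after) {
    structure(
      list(genotype_id = g$id, verdicts = verdicts,
           loci_before = loci_before, loci_after = loci_after,
           resolution = new_resolution(g$id, "EXCLUDED", character(), reason),
           strain_background = g$strain_background),
      class = "gr_trace"
    )
  }

  # Box 1: one-marker genotypes need no filtering.
  if (length(loci_before$members) == 1L) {
    return(finish("B1_SINGLE", loci_before$members, loci_before))
  }

  # Box 2: drop tool alleles, recount.
  fl <- filter_noncausative(g, idx)
  verdicts <- fl$verdicts
  if (length(fl$retained) == 0L) {
    return(excluded("all_alleles_excluded", locus_set()))
  }
  after <- genotype_loci(g, idx, allele_ids = fl$retained)
  A <- after$members
  prov <- after$provenance

  if (length(A) == 1L) {
    self_expressed <- all(c("mutated", "expressed") %in% prov[[A]])
    box <- if (self_expressed) "B11_SELF_EXPRESSED" else "B3_SINGLE_AFTER_FILTER"
    return(finish(box, A, after))
  }

  class_of <- function(id) {
    m <- lookup(idx$markers, id)
    if (is.null(m)) NA_character_ else m$marker_class
  }
  classes <- vapply(A, class_of, "")
  regions <- A[!is.na(classes) & classes == "multi_genic_region"]

  # Box 4: multi-genic mutation regions.
  if (length(regions) >= 2L) {
    return(excluded("multiple_multigenic", after))
  }
  if (length(regions) == 1L) {
    rg <- lookup(idx$markers, regions)$region_genes
    if (all(A %in% c(regions, rg))) {
      return(finish("B4_MULTIGENIC_MARKER", regions, after))
    }
    return(excluded("multigenic_plus_outside", after))
  }

  E <- A[vapply(A, function(m) "expressed" %in% prov[[m]], NA)]
  transgenes <- A[!is.na(classes) & classes == "transgene"]
  endogenous <- A[vapply(A, function(m) "mutated" %in% prov[[m]], NA) &
                    !(A %in% transgenes)]

  # Box 5: several markers, nothing inserted-expressed.
  if (length(E) == 0L) {
    return(excluded("multi_marker_no_expressed", after))
  }

  # Box 6: several expressed genes -> the single transgene, if that is all.
  if (length(E) > 1L) {
    if (length(transgenes) == 1L && length(endogenous) == 0L) {
      return(finish("B6_TRANSGENE_ONLY", transgenes, after))
    }
    return(excluded("multi_expressed_not_single_transgene", after))
  }

  # Box 7: one expressed gene; non-mouse cargo stops here.
  gexp <- E
  if (gexp %in% after$non_mouse) {
    return(excluded("non_mouse_expressed", after))
  }

  # Boxes 8/9: one transgene plus its expressed mouse gene.
  if (length(transgenes) == 1L && setequal(A, c(transgenes, gexp))) {
    box <- if ("mutated" %in% prov[[gexp]]) "B9_TRANSGENE_ENDOGENOUS_MATCH"
           else "B8_TRANSGENE_PLUS_GENE"
    return(finish(box, c(transgenes, gexp), after))
  }

  # Box 10: docking site plus one expressed mouse gene.
  if (length(A) == 2L) {
    dock <- setdiff(A, gexp)
    if (length(dock) == 1L && dock %in% config$docking_site_ids) {
      return(finish("B10_DOCKING_SITE", gexp, after))
    }
  }

  excluded("unresolved_multi", after)
}

#' @export
print.gr_trace <- function(x, ...) {
  cat(sprintf("<trace> genotype %s\n", x$genotype_id))
  if (nrow(x$verdicts)) {
    ex <- x$verdicts[x$verdicts$verdict == "exclude", , drop = FALSE]
    if (nrow(ex)) {
      cat("  excluded alleles:\n")
      for (i in seq_len(nrow(ex))) {
        cat(sprintf("    %s (%s)\n", ex$allele_id[i], ex$reason[i]))
      }
    }
  }
  cat(sprintf("  loci: %d before, %d after filtering\n",
              length(x$loci_before$members), length(x$loci_after$members)))
  print(x$resolution)
  invisible(x)
}

#' Derive marker-level annotations from genotype-level annotations
#'
#' Resolves every genotype that carries at least one source annotation
#' (genotypes without annotations are not resolved), then fans each source
#' annotation out to one derived annotation per causative marker and
#' deduplicates on (marker, term, ontology), merging provenance.
#'
#' @param annotations Data frame of source annotations with columns
#'   `genotype_id`, `term_id`, `ontology` (and optionally `qualifier`,
#'   `reference`), as returned by [load_annotations()].
#' @param cat A [catalog()].
#' @param config A [derivation_config()].
#' @return A list with `derived` — a data frame sorted by
#'   (`marker_id`, `term_id`, `ontology`) with columns `marker_id`,
#'   `marker_symbol`, `term_id`, `ontology`, `source_genotype_ids`
#'   (semicolon-joined, sorted), `terminal_boxes` (semicolon-joined) — and
#'   `traces`, a list of decision traces named by genotype id.
#' @export
#' @examples
#' fx <- mgi_fixture_catalog()
#' out <- derive_annotations(fx$annotations, fx$catalog)
#' head(out$derived)
derive_annotations <- function(annotations, cat, config = NULL) {
  idx <- catalog_index(cat)
  if (is.null(config)) config <- derivation_config(cat)
  stopifnot(all(c("genotype_id", "term_id", "ontology") %in% names(annotations)))

  gids <- unique(annotations$genotype_id)
  unknown <- gids[vapply(gids, function(id)
    is.null(lookup(idx$genotypes, id)), NA)]
  if (length(unknown)) {
    stop(sprintf("annotations reference unknown genotype id(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }

  traces <- lapply(gids, function(id)
    resolve_genotype(lookup(idx$genotypes, id), idx, config))
  names(traces) <- gids

  rows <- vector("list", length(gids))
  for (i in seq_along(gids)) {
    tr <- traces[[i]]
    mk <- tr$resolution$annotate_markers
    if (length(mk) == 0L) next
    ann <- annotations[annotations$genotype_id == gids[i], , drop = FALSE]
    rows[[i]] <- data.frame(
      marker_id = rep(mk, each = nrow(ann)),
      term_id = rep(ann$term_id, times = length(mk)),
      ontology = rep(ann$ontology, times = length(mk)),
      genotype_id = rep(ann$genotype_id, times = length(mk)),
      terminal_box = tr$resolution$terminal_box,
      stringsAsFactors = FALSE
    )
  }
  flat <- do.call(rbind, rows[!vapply(rows, is.null, NA)])

  if (is.null(flat) || nrow(flat) == 0L) {
    derived <- data.frame(
      marker_id = character(), marker_symbol = character(),
      term_id = character(), ontology = character(),
      source_genotype_ids = character(), terminal_boxes = character(),
      stringsAsFactors = FALSE
    )
    return(list(derived = derived, traces = traces))
  }

  key <- paste(flat$marker_id, flat$term_id, flat$ontology, sep = "\r")
  groups <- split(flat, key)
  derived <- do.call(rbind, lapply(unname(groups), function(gdf) {
    data.frame(
      marker_id = gdf$marker_id[1],
      marker_symbol = {
        m <- lookup(idx$markers, gdf$marker_id[1])
        if (is.null(m)) gdf$marker_id[1] else m$symbol
      },
      term_id = gdf$term_id[1],
      ontology = gdf$ontology[1],
      source_genotype_ids = paste(sort(unique(gdf$genotype_id)),
                                  collapse = ";"),
      terminal_boxes = paste(sort(unique(gdf$terminal_box)), collapse = ";"),
      stringsAsFactors = FALSE
    )
  }))
  derived <- derived[order(derived$marker_id, derived$term_id,
                           derived$ontology), , drop = FALSE]
  rownames(derived) <- NULL
  list(derived = derived, traces = traces)
}
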