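# Locus accounting: which genetic loci does an allele / genotype touch?
# This is the entry box of the derivation flow: genetic loci include genes
# within the mutation region, genes expressed by the allele, and transgene
# markers themselves.

#' Construct a locus set
#'
#' A locus set maps marker ids to the kinds of evidence connecting them to
#' an allele or genotype: `mutated` (endogenous locus disrupted),
#' `expressed` (inserted expressed-gene cargo), `transgene_self` (the
#' transgene marker of a transgenic allele), `region_gene` (endogenous gene
#' inside a multi-genic mutation region).  Members that are non-mouse
#' expressed genes are listed in `non_mouse`; they count as loci but are
#' never annotation subjects.
#'
#' @param provenance Named list: marker id -> character vector of kinds.
#' @param non_mouse Ids of members that are non-mouse expressed genes.
#' @return A list of class `"locus_set"` with `members`, `provenance`,
#'   `non_mouse`.
#' @export
locus_set <- function(provenance = list(), non_mouse = character()) {
  provenance <- lapply(provenance, function(k) sort(unique(as_chr(k))))
  if (length(provenance)) provenance <- provenance[order(names(provenance))]
  else names(provenance) <- character()
  structure(
    list(members = names(provenance),
         provenance = provenance,
         non_mouse = sort(unique(as_chr(non_mouse)))),
    class = "locus_set"
  )
}

#' @export
print.locus_set <- function(x, ...) {
  cat(sprintf("<locus_set> %d loci\n", length(x$members)))
  for (m in x$members) {
    cat(sprintf("  %s [%s]%s\n", m, paste(x$provenance[[m]], collapse = ","),
                if (m %in% x$non_mouse) " (non-mouse)" else ""))
  }
  invisible(x)
}

locus_union <- function(a, b) {
  prov <- a$provenance
  for (m in names(b$provenance)) {
    prov[[m]] <- sort(unique(c(prov[[m]], b$provenance[[m]])))
  }
  locus_set(prov, non_mouse = c(a$non_mouse, b$non_mouse))
}

#' Loci associated with one allele
#'
#' The union of (a) the allele's mutated markers (tagged `mutated`, or
#' `transgene_self` for the transgene marker of a transgenic allele), (b)
#' the region genes of any multi-genic region marker among them (tagged
#' `region_gene`), and (c) its expressed-gene cargo (tagged `expressed`).
#' A multi-genic region marker therefore contributes both itself and its
#' region genes: a deletion spanning 39 genes counts as 40 loci.
#' Wild-type alleles contribute their single marker (they are removed later
#' by the tool-allele filter, not here).
#'
#' @param a An [allele()].
#' @param cat A [catalog()] (or an internal index environment).
#' @return A [locus_set()].
#' @export
#' @examples
#' cat <- catalog(markers = list(marker("syn:App", "App")),
#'                alleles = list(allele("syn:App<tm1>", "App<tm1Dbo>",
#'                                      "targeted",
#'                                      mutated_markers = "syn:App")))
#' allele_loci(cat$alleles[[1]], cat)
allele_loci <- function(a, cat) {
  idx <- catalog_index(cat)
  prov <- list()
  non_mouse <- character()
  tag <- function(id, kind) prov[[id]] <<- c(prov[[id]], kind)

  for (mm in a$mutated_markers) {
    m <- lookup(idx$markers, mm)
    if (is.null(m)) {
      stop(sprintf("allele '%s' references unknown marker '%s'", a$id, mm),
           call. = FALSE)
    }
    tag(mm, if (m$marker_class == "transgene") "transgene_self" else "mutated")
    if (m$marker_class == "multi_genic_region") {
      for (g in m$region_genes) tag(g, "region_gene")
    }
  }
  for (eg in a$expressed_genes) {
    tag(eg$gene_id, "expressed")
    if (eg$species == "non_mouse") non_mouse <- c(non_mouse, eg$gene_id)
  }
  locus_set(prov, non_mouse)
}

#' Loci associated with a genotype (or a subset of its alleles)
#'
#' Merged [allele_loci()] over the distinct alleles of the genotype.
#' Homozygous pairs count once (the union is idempotent), and the result is
#' invariant under allele and pair order.
#'
#' @param g A [genotype()].
#' @param cat A [catalog()].
#' @param allele_ids Optional subset of the genotype's allele ids (default:
#'   all).  An empty subset yields an empty locus set.
#' @return A [locus_set()].
#' @export
genotype_loci <- function(g, cat, allele_ids = NULL) {
  idx <- catalog_index(cat)
  all_ids <- genotype_allele_ids(g)
  if (is.null(allele_ids)) {
    allele_ids <- all_ids
  } else {
    allele_ids <- unique(as_chr(allele_ids))
    bad <- setdiff(allele_ids, all_ids)
    if (length(bad)) {
      stop(sprintf("alleles not in genotype '%s': %s", g$id,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  out <- locus_set()
  for (aid in allele_ids) {
    a <- lookup(idx$alleles, aid)
    if (is.null(a)) {
      stop(sprintf("genotype '%s' references unknown allele '%s'", g$id, aid),
           call. = FALSE)
    }
    out <- locus_union(out, allele_loci(a, idx))
  }
  out
}

#' Distinct allele ids of a genotype
#'
#' @param g A [genotype()].
#' @return Character vector of distinct allele ids, in first-appearance
#'   order; hemizygous `NA` partners are dropped.
#' @export
genotype_allele_ids <- function(g) {
  ids <- unlist(lapply(g$allele_pairs, function(p) c(p$allele1, p$allele2)),
                use.names = FALSE)
  unique(ids[!is.na(ids)])
}
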