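# Tool-allele filter: identify non-causative alleles so they never become
# (or contribute) derived-annotation subjects.

EXCLUSION_REASONS <- c("wild_type", "transgenic_transactivator",
                       "transgenic_reporter", "conditional_recombinase")

#' Classify one allele as causative or tool
#'
#' The non-causative allele types are: wild-type alleles, transgenic
#' transactivator alleles, transgenic reporter alleles, and (in conditional
#' genotypes only) recombinase alleles of any generation method.  Knock-in
#' transactivators and reporters are always retained, because many of them
#' are simultaneously knock-outs of the endogenous gene and thus causative.
#'
#' A recombinase or transactivator allele is excluded only when it expresses
#' nothing beyond its own tool product.  The tool product (cre, tTA) is
#' never a recorded expressed gene, so the test is an empty
#' `expressed_genes` list; an allele that additionally expresses cargo
#' (e.g. a cre transgene also expressing Hras1 and Trap1a) is retained.
#' A transgenic reporter is excluded on attributes alone: `reporter`
#' present, `inserted_expressed_sequence` absent.
#'
#' Rules are tested in a fixed order (wild-type, transactivator, reporter,
#' recombinase) so reason codes are reproducible when several apply.
#'
#' @param a An [allele()].
#' @param is_conditional The genotype's conditional flag.
#' @return A list of class `"gr_verdict"`: `allele_id`, `verdict`
#'   (`"retain"`/`"exclude"`), `reason` (`"not_applicable"` when retained).
#' @export
classify_allele_causality <- function(a, is_conditional) {
  cargo <- length(a$expressed_genes)
  reason <- NULL
  if (a$is_wild_type) {
    reason <- "wild_type"
  } else if (a$generation_method == "transgenic" &&
             "transactivator" %in% a$attributes && cargo == 0L) {
    reason <- "transgenic_transactivator"
  } else if (a$generation_method == "transgenic" &&
             "reporter" %in% a$attributes &&
             !"inserted_expressed_sequence" %in% a$attributes) {
    reason <- "transgenic_reporter"
  } else if ("recombinase" %in% a$attributes && isTRUE(is_conditional) &&
             cargo == 0L) {
    reason <- "conditional_recombinase"
  }
  structure(
    list(allele_id = a$id,
         verdict = if (is.null(reason)) "retain" else "exclude",
         reason = reason %||% "not_applicable"),
    class = "gr_verdict"
  )
}

#' Remove non-causative alleles from a genotype
#'
#' Applies [classify_allele_causality()] to every distinct allele.  All
#' verdicts, including retains, are returned for the decision trace.  A
#' genotype whose alleles are all excluded yields an empty retained set; it
#' resolves downstream to no annotation rather than erroring.
#'
#' Classification of one allele never depends on the other alleles, so the
#' filter is order-invariant and idempotent.
#'
#' @param g A [genotype()].
#' @param cat A [catalog()].
#' @return A list with `retained` (character vector of allele ids, in
#'   genotype order) and `verdicts` (data frame with columns `allele_id`,
#'   `verdict`, `reason`).
#' @export
filter_noncausative <- function(g, cat) {
  idx <- catalog_index(cat)
  ids <- genotype_allele_ids(g)
  vs <- lapply(ids, function(aid) {
    a <- lookup(idx$alleles, aid)
    if (is.null(a)) {
      stop(sprintf("genotype '%s' references unknown allele '%s'", g$id, aid),
           call. = FALSE)
    }
    classify_allele_causality(a, g$is_conditional)
  })
  verdicts <- data.frame(
    allele_id = vapply(vs, `[[`, "", "allele_id"),
    verdict = vapply(vs, `[[`, "", "verdict"),
    reason = vapply(vs, `[[`, "", "reason"),
    stringsAsFactors = FALSE
  )
  list(retained = verdicts$allele_id[verdicts$verdict == "retain"],
       verdicts = verdicts)
}
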