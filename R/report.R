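# Breakdown reporting: tabulate a derivation run the way the curated
# corpus is summarized (one-marker genotypes vs resolved multi-marker
# genotypes, and removals by tool-allele class).

REMOVAL_CLASSES <- c(
  conditional_recombinase = "recombinase",
  transgenic_reporter = "reporter_transgene",
  transgenic_transactivator = "transactivator_transgene",
  wild_type = "wild_type"
)

#' Summarize a derivation run
#'
#' Tabulates the decision traces of one [derive_annotations()] run:
#' how many genotypes received derived annotations (split into one-marker
#' genotypes resolved at the entry box and multi-marker genotypes resolved
#' by the later rules), the markers reachable only through multi-marker
#' genotypes ("novel" markers), exclusions by reason, and tool-allele
#' removals by class (counting, per class, both affected genotypes and
#' distinct alleles).  Recombinase removals only ever occur in conditional
#' genotypes, since that is the only situation in which the filter excludes
#' them.
#'
#' @param traces List of decision traces (from [derive_annotations()] or
#'   repeated [resolve_genotype()] calls).
#' @return A list of class `"gr_breakdown"`: `total_genotypes`,
#'   `with_derived`, `one_marker`, `resolved_multi`,
#'   `novel_markers_from_multi`, `exclusions_by_reason` (named integer),
#'   `removals_by_allele_class` (data frame `class`, `genotypes`,
#'   `alleles`).
#' @export
summarize_run <- function(traces) {
  boxes <- vapply(traces, function(t) t$resolution$terminal_box, "")
  derived <- vapply(traces, function(t)
    length(t$resolution$annotate_markers) > 0L, NA)

  one_marker <- derived & boxes == "B1_SINGLE"
  resolved_multi <- derived & boxes != "B1_SINGLE"

  single_markers <- unique(unlist(lapply(traces[one_marker], function(t)
    t$resolution$annotate_markers), use.names = FALSE))
  multi_markers <- unique(unlist(lapply(traces[resolved_multi], function(t)
    t$resolution$annotate_markers), use.names = FALSE))

  reasons <- vapply(traces[!derived], function(t)
    t$resolution$exclusion_reason, "")
  exclusions <- if (length(reasons)) {
    tab <- table(reasons)
    stats::setNames(as.integer(tab), names(tab))
  } else stats::setNames(integer(), character())

  removals <- do.call(rbind, lapply(names(REMOVAL_CLASSES), function(r) {
    per <- lapply(traces, function(t) {
      v <- t$verdicts
      v$allele_id[v$verdict == "exclude" & v$reason == r]
    })
    hit <- vapply(per, function(x) length(x) > 0L, NA)
    data.frame(
      class = REMOVAL_CLASSES[[r]],
      genotypes = sum(hit),
      alleles = length(unique(unlist(per, use.names = FALSE))),
      stringsAsFactors = FALSE
    )
  }))
  rownames(removals) <- NULL

  structure(
    list(
      total_genotypes = length(traces),
      with_derived = sum(derived),
      one_marker = sum(one_marker),
      resolved_multi = sum(resolved_multi),
      novel_markers_from_multi = length(setdiff(multi_markers, single_markers)),
      exclusions_by_reason = exclusions,
      removals_by_allele_class = removals
    ),
    class = "gr_breakdown"
  )
}

#' @export
print.gr_breakdown <- function(x, ...) {
  pct <- function(n) if (x$total_genotypes == 0) "" else
    sprintf(" (%.1f%%)", 100 * n / x$total_genotypes)
  cat("Derivation run breakdown\n")
  cat(sprintf("  genotypes processed:          %d\n", x$total_genotypes))
  cat(sprintf("  with derived annotations:     %d%s\n", x$with_derived,
              pct(x$with_derived)))
  cat(sprintf("    one-marker genotypes:       %d%s\n", x$one_marker,
              pct(x$one_marker)))
  cat(sprintf("    resolved multi-marker:      %d%s\n", x$resolved_multi,
              pct(x$resolved_multi)))
  cat(sprintf("    novel markers via multi:    %d\n",
              x$novel_markers_from_multi))
  if (length(x$exclusions_by_reason)) {
    cat("  exclusions by reason:\n")
    for (r in names(x$exclusions_by_reason)) {
      cat(sprintf("    %-36s %d\n", r, x$exclusions_by_reason[[r]]))
    }
  }
  cat("  tool-allele removals (genotypes / distinct alleles):\n")
  for (i in seq_len(nrow(x$removals_by_allele_class))) {
    row <- x$removals_by_allele_class[i, ]
    cat(sprintf("    %-24s %d / %d\n", row$class, row$genotypes, row$alleles))
  }
  invisible(x)
}
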