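## Lineage-level KO presence/absence and the dual-threshold
## endosphere-enrichment rule.

#' Lineage-level KO presence matrix
#'
#' A lineage scores 1 for a KO iff any genome in the lineage carries at
#' least one gene with that KO (presence, not gene count).
#'
#' @param annotations annotation `data.frame` (needs `strain_id`, `ko`).
#' @param lm a [LineageMap-class] covering every annotated strain.
#' @return binary matrix lineages x KOs with attribute
#'   `"endosphere_lineages"` copied from `lm`.
#' @export
lineagePresence <- function(annotations, lm) {
  stopifnot(is(lm, "LineageMap"))
  strains <- unique(annotations$strain_id)
  missing <- setdiff(strains, names(lineageAssignment(lm)))
  if (length(missing))
    stop("strain(s) without lineage: ", paste(missing, collapse = ", "))
  ann <- annotations[!is.na(annotations$ko) & annotations$ko != "", ,
                     drop = FALSE]
  lin <- lineageAssignment(lm)[ann$strain_id]
  kos <- sort(unique(ann$ko))
  lins <- sort(unique(unname(lineageAssignment(lm))))
  m <- matrix(0L, length(lins), length(kos),
              dimnames = list(lins, kos))
  if (nrow(ann))
    m[cbind(match(lin, lins), match(ann$ko, kos))] <- 1L
  attr(m, "endosphere_lineages") <- endosphereLineages(lm)
  m
}

#' Dual-threshold lineage KO enrichment rule
#'
#' A KO is endosphere-enriched iff it is present in at least `min_endo`
#' endosphere-associated lineages and in no more than `max_non`
#' non-endosphere lineages.  Group frequencies are the proportion of
#' lineages in each group containing the KO.
#'
#' @param presence binary lineages x KOs matrix from
#'   [lineagePresence()].
#' @param endosphere_lineages lineage ids of the endosphere group
#'   (default: the matrix's attribute).
#' @param min_endo minimum endosphere lineage count (default 2).
#' @param max_non maximum non-endosphere lineage count (default 4).
#' @return `data.frame`: `ko`, `endo_count`, `non_endo_count`,
#'   `endo_freq`, `non_endo_freq`, `enriched`.
#' @export
koEnrichmentRule <- function(presence,
                             endosphere_lineages =
                               attr(presence, "endosphere_lineages"),
                             min_endo = 2, max_non = 4) {
  lins <- rownames(presence)
  endo <- lins %in% endosphere_lineages
  if (!any(endo) || all(endo))
    stop("both endosphere and non-endosphere lineage groups must be non-empty")
  if (min_endo > sum(endo))
    stop("min_endo (", min_endo, ") exceeds the number of ",
         "endosphere lineages (", sum(endo), ")")
  endo_count <- colSums(presence[endo, , drop = FALSE])
  non_count <- colSums(presence[!endo, , drop = FALSE])
  data.frame(
    ko = colnames(presence),
    endo_count = as.integer(endo_count),
    non_endo_count = as.integer(non_count),
    endo_freq = endo_count / sum(endo),
    non_endo_freq = non_count / sum(!endo),
    enriched = endo_count >= min_endo & non_count <= max_non,
    row.names = NULL, stringsAsFactors = FALSE
  )
}
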