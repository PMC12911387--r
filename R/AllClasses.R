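## Central S4 containers.  Count matrices live in SummarizedExperiment
## (sample metadata in colData, quantification level in metadata()).

#' DefCom: a defined community with ground truth
#'
#' Container for a defined community of bacterial strains: one genome per
#' strain, gene annotations (0-based half-open coordinates), and -- when the
#' community was produced by [buildCommunity()] -- full generative ground
#' truth: the ancestral sequence, per-strain substitution/deletion
#' bookkeeping, the true pairwise ANI matrix, the true lineage partition and
#' the planted endosphere-enriched KO/orthogroup sets.
#'
#' @slot genomes [Biostrings::DNAStringSet] of strain genomes, named by
#'   strain id.
#' @slot annotations `data.frame` with columns `gene_id`, `strain_id`,
#'   `start`, `end` (0-based half-open), `strand`, `ko`, `cog`,
#'   `orthogroup`.
#' @slot ancestor character(1), the ancestral core sequence ("" for
#'   communities loaded from files).
#' @slot bookkeeping named list per strain: `sub_pos` (0-based ancestor
#'   coordinates), `sub_base` (final base at those positions), `deleted`
#'   (2-column matrix of 0-based half-open ancestor intervals).
#' @slot groundTruth list with elements `true_ani` (percent matrix),
#'   `lineage_assignment` (named character), `planted_enriched_kos`,
#'   `planted_enriched_ogs` (character), `dominant_strains` (character),
#'   plus generator bookkeeping; empty for real data.
#' @slot hostDecoy character(1) host decoy sequence used by the read
#'   simulator and the host filter ("" if none).
#' @slot config list of generator parameters actually used.
#'
#' @seealso [buildCommunity()], [simulateReads()], [trueANI()]
#' @export
setClass("DefCom",
  slots = c(
    genomes = "DNAStringSet",
    annotations = "data.frame",
    ancestor = "character",
    bookkeeping = "list",
    groundTruth = "list",
    hostDecoy = "character",
    config = "list"
  )
)

setValidity("DefCom", function(object) {
  msg <- character()
  ids <- names(object@genomes)
  if (length(object@genomes) > 0 && (is.null(ids) || anyDuplicated(ids)))
    msg <- c(msg, "genomes must be uniquely named by strain id")
  ann <- object@annotations
  need <- c("gene_id", "strain_id", "start", "end", "strand", "ko", "cog",
            "orthogroup")
  if (nrow(ann) > 0) {
    if (!all(need %in% names(ann)))
      msg <- c(msg, paste("annotations need columns:",
                          paste(need, collapse = ", ")))
    else {
      if (any(ann$start < 0) || any(ann$end <= ann$start))
        msg <- c(msg, "gene intervals must satisfy 0 <= start < end")
      if (!all(ann$strain_id %in% ids))
        msg <- c(msg, "annotations refer to unknown strain ids")
      glen <- width(object@genomes)[match(ann$strain_id, ids)]
      if (any(ann$end > glen))
        msg <- c(msg, "gene intervals exceed genome length")
      by_strain <- split(ann[, c("start", "end")], ann$strain_id)
      for (s in names(by_strain)) {
        d <- by_strain[[s]][order(by_strain[[s]]$start), , drop = FALSE]
        if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)])) {
          msg <- c(msg, sprintf("overlapping gene intervals in strain %s", s))
          break
        }
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' ANIMatrix: pairwise average nucleotide identity
#'
#' Symmetric matrix of pairwise ANI percentages with a 100 diagonal.
#' Entries may be `NA` where no orthologous fraction was detected.
#'
#' @slot ani numeric matrix of percents, dimnames = strain ids.
#' @export
setClass("ANIMatrix", slots = c(ani = "matrix"))

setValidity("ANIMatrix", function(object) {
  a <- object@ani
  msg <- character()
  if (nrow(a) != ncol(a) || is.null(rownames(a)) ||
      !identical(rownames(a), colnames(a)))
    msg <- c(msg, "ani must be square with matching dimnames")
  else {
    if (any(abs(diag(a) - 100) > 1e-9)) msg <- c(msg, "diagonal must be 100")
    off <- a[!is.na(a)]
    if (any(off < 0 | off > 100)) msg <- c(msg, "ANI must lie in [0, 100]")
    d <- abs(a - t(a))
    if (any(d[!is.na(d)] > 1e-9)) msg <- c(msg, "ani must be symmetric")
  }
  if (length(msg)) msg else TRUE
})

#' LineageMap: ANI-threshold lineage partition
#'
#' Partition of strains into lineages (single-linkage components of the
#' ANI >= tau graph) plus the set of endosphere-associated lineages.
#' Lineage ids are the lexicographically smallest member strain id.
#'
#' @slot assignment named character: strain id -> lineage id.
#' @slot endosphereAssociated character vector of lineage ids.
#' @slot tau numeric(1), the ANI threshold in percent.
#' @export
setClass("LineageMap",
  slots = c(assignment = "character", endosphereAssociated = "character",
            tau = "numeric")
)

setValidity("LineageMap", function(object) {
  msg <- character()
  if (is.null(names(object@assignment)) ||
      anyDuplicated(names(object@assignment)))
    msg <- c(msg, "assignment must be named uniquely by strain id")
  if (!all(object@endosphereAssociated %in% object@assignment))
    msg <- c(msg, "endosphereAssociated must be a subset of lineage ids")
  if (length(object@tau) != 1 || object@tau <= 0 || object@tau > 100)
    msg <- c(msg, "tau must be a single percent in (0, 100]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DefCom", function(object) {
  cat(sprintf("DefCom with %d strains\n", length(object@genomes)))
  if (length(object@genomes)) {
    w <- width(object@genomes)
    cat(sprintf("  genome length: %d-%d bp; %d annotated genes\n",
                min(w), max(w), nrow(object@annotations)))
  }
  gt <- object@groundTruth
  if (length(gt))
    cat(sprintf(
      "  ground truth: %d lineages, %d planted KOs, %d planted orthogroups\n",
      length(unique(gt$lineage_assignment)),
      length(gt$planted_enriched_kos), length(gt$planted_enriched_ogs)))
})

setMethod("show", "ANIMatrix", function(object) {
  a <- object@ani
  cat(sprintf("ANIMatrix for %d strains\n", nrow(a)))
  off <- a[upper.tri(a)]
  off <- off[!is.na(off)]
  if (length(off))
    cat(sprintf("  off-diagonal ANI: %.2f-%.2f%%\n", min(off), max(off)))
})

setMethod("show", "LineageMap", function(object) {
  cat(sprintf("LineageMap: %d strains in %d lineages (tau = %g%%)\n",
              length(object@assignment),
              length(unique(object@assignment)), object@tau))
  if (length(object@endosphereAssociated))
    cat("  endosphere-associated:",
        paste(sort(object@endosphereAssociated), collapse = ", "), "\n")
})
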