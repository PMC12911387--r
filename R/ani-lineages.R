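## k-mer ANI estimation and ANI-threshold lineage clustering.

#' Pairwise ANI from fragment k-mer containment
#'
#' Estimates average nucleotide identity between two genomes without
#' alignment.  The query is split into non-overlapping fragments; for
#' each fragment the containment `c` of its k-mer set in the reference's
#' full k-mer set is computed and converted to an equal-size Jaccard
#' `J = c / (2 - c)`.  Fragments with `J` below `min_jaccard` are
#' discarded as non-orthologous (accessory regions).  Retained fragments
#' are scored with the Mash distance `d = -(1/k) * log(2J/(1+J))` and a
#' Poisson-corrected identity `100 * exp(-d)` (equivalently
#' `100 * c^(1/k)`), whose expectation equals the true nucleotide
#' identity under an i.i.d. substitution model across the whole 0-20%
#' divergence range.  Each direction's estimate is the median fragment
#' identity -- robust to fragments straddling a core/accessory boundary,
#' which pass the mapping floor with depressed identity -- and the final
#' ANI is the arithmetic mean of the two query/reference directions.
#'
#' @param a,b genome sequences (character strings, `DNAString` or
#'   length-1 `DNAStringSet`).
#' @param k k-mer size, in `[11, 31]`.
#' @param fragment fragment length in bp (both sequences must be at
#'   least this long).
#' @param min_jaccard mapping floor on the per-fragment Jaccard.
#' @return ANI percent as numeric(1).
#' @examples
#' s <- paste(sample(c("A","C","G","T"), 5000, TRUE), collapse = "")
#' kmerANI(s, s, fragment = 1000)  # 100
#' @export
kmerANI <- function(a, b, k = 16, fragment = 3000, min_jaccard = 0.01) {
  a <- .asSequence(a)
  b <- .asSequence(b)
  stopifnot(k >= 11, k <= 31)
  if (nchar(a) < fragment || nchar(b) < fragment)
    stop("both sequences must be at least one fragment long")
  one_direction <- function(q, r) {
    fr <- cpp_fragment_containment(q, r, as.integer(k),
                                   as.integer(fragment))
    cont <- fr$containment
    J <- cont / (2 - cont)
    keep <- !is.na(J) & J >= min_jaccard
    if (!any(keep)) return(NULL)
    d <- -log(2 * J[keep] / (1 + J[keep])) / k
    100 * median(exp(-d))
  }
  est <- c(one_direction(a, b), one_direction(b, a))
  if (is.null(est)) stop("no orthologous fraction")
  mean(est)
}

.asSequence <- function(x) {
  if (is.character(x)) return(x)
  as.character(x)
}

#' All-pairs ANI matrix
#'
#' @param x a [DefCom-class] or named `DNAStringSet`.
#' @inheritParams kmerANI
#' @param na_if_no_fraction if TRUE, pairs with no orthologous fraction
#'   yield `NA` instead of an error.
#' @return an [ANIMatrix-class].
#' @export
aniMatrix <- function(x, k = 16, fragment = 3000, min_jaccard = 0.01,
                      na_if_no_fraction = TRUE) {
  g <- if (is(x, "DefCom")) genomes(x) else x
  ids <- names(g)
  stopifnot(!is.null(ids), !anyDuplicated(ids))
  seqs <- as.character(g)
  if (any(nchar(seqs) < fragment))
    stop("all genomes must be at least one fragment long")
  n <- length(ids)
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  ## one shared k-mer hash serves every query/reference direction
  cont <- cpp_all_pairs_containment(seqs, as.integer(k),
                                    as.integer(fragment))
  direction <- function(q, r) {
    cc <- cont[[q]][, r]
    J <- cc / (2 - cc)
    keep <- !is.na(J) & J >= min_jaccard
    if (!any(keep)) return(NULL)
    d <- -log(2 * J[keep] / (1 + J[keep])) / k
    100 * median(exp(-d))
  }
  if (n > 1) for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    est <- c(direction(i, j), direction(j, i))
    if (is.null(est)) {
      if (!na_if_no_fraction)
        stop("no orthologous fraction between ", ids[i], " and ", ids[j])
      est <- NA_real_
    }
    m[i, j] <- m[j, i] <- mean(est)
  }
  new("ANIMatrix", ani = m)
}

#' Cluster strains into lineages at an ANI threshold
#'
#' Single-linkage connected components of the graph with an edge
#' wherever pairwise ANI is at least `tau`; equivalently single-linkage
#' hierarchical clustering of `100 - ANI` cut at height `100 - tau`.
#' Raising `tau` can only refine the partition.  Lineage ids are the
#' lexicographically smallest member strain id; singletons are ordinary
#' one-strain lineages.
#'
#' @param m an [ANIMatrix-class] (`NA` entries are treated as no edge).
#' @param tau ANI threshold in percent, in `(0, 100]`.
#' @return a [LineageMap-class] with an empty endosphere set.
#' @export
clusterLineages <- function(m, tau = 97) {
  stopifnot(is(m, "ANIMatrix"), tau > 0, tau <= 100)
  a <- aniValues(m)
  ids <- rownames(a)
  if (length(ids) == 1) {
    cl <- setNames(1L, ids)
  } else {
    d <- 100 - a
    d[is.na(d)] <- 100 + 1  # no detectable homology: never joined
    hc <- hclust(as.dist(d), method = "single")
    cl <- cutree(hc, h = 100 - tau)
  }
  labels <- vapply(split(ids, cl), min, "")
  assignment <- setNames(labels[as.character(cl)], ids)
  new("LineageMap", assignment = assignment,
      endosphereAssociated = character(), tau = tau)
}

#' Flag endosphere-associated lineages
#'
#' A lineage is endosphere-associated iff it contains at least one
#' dominant endosphere colonizer strain.
#'
#' @param lm a [LineageMap-class].
#' @param dominant_strains character vector of dominant colonizer strain
#'   ids (must all be assigned in `lm`).
#' @return the updated [LineageMap-class].
#' @export
labelEndosphereLineages <- function(lm, dominant_strains) {
  stopifnot(is(lm, "LineageMap"))
  unknown <- setdiff(dominant_strains, names(lm@assignment))
  if (length(unknown))
    stop("unknown strain id(s): ", paste(unknown, collapse = ", "))
  lm@endosphereAssociated <-
    sort(unique(unname(lm@assignment[dominant_strains])))
  validObject(lm)
  lm
}

#' Read/write ANI matrices and lineage maps as TSV
#'
#' `writeANIMatrix()` writes a strains x strains TSV;
#' `readANIMatrix()` reads it back.  `writeLineageMap()` writes
#' one row per strain (`strain`, `lineage`, `endosphere_flag`).
#'
#' @param m an [ANIMatrix-class]; `lm` a [LineageMap-class].
#' @param path file path.
#' @return `readANIMatrix()` returns an [ANIMatrix-class]; the writers
#'   return the path invisibly.
#' @export
writeANIMatrix <- function(m, path) {
  write.table(aniValues(m), path, sep = "\t", quote = FALSE,
              col.names = NA)
  invisible(path)
}

#' @rdname writeANIMatrix
#' @export
readANIMatrix <- function(path) {
  x <- as.matrix(read.delim(path, row.names = 1, check.names = FALSE))
  new("ANIMatrix", ani = x)
}

#' @rdname writeANIMatrix
#' @param lm a [LineageMap-class].
#' @export
writeLineageMap <- function(lm, path) {
  a <- lineageAssignment(lm)
  df <- data.frame(strain = names(a), lineage = unname(a),
                   endosphere_flag = unname(a) %in% endosphereLineages(lm))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Compare two lineage partitions
#'
#' TRUE iff the two assignments induce the same partition of the same
#' strain set (labels themselves need not match).
#'
#' @param a,b named character vectors strain -> lineage.
#' @export
samePartition <- function(a, b) {
  if (!setequal(names(a), names(b))) return(FALSE)
  b <- b[names(a)]
  all(outer(a, a, "==") == outer(b, b, "=="))
}
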