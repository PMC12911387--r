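## Host filtering, competitive read assignment and count matrices.

#' Filter host-derived reads by k-mer matching
#'
#' A read is removed iff the fraction of its k-mers found in the host
#' decoy sequence is at least `host_match_floor`; survivors pass through
#' unchanged.
#'
#' @param reads a named `DNAStringSet` (or character vector) of reads.
#' @param host host decoy sequence (character, `DNAString` or length-1
#'   `DNAStringSet`).
#' @param k k-mer size (must match the assignment index k).
#' @param host_match_floor removal threshold on the k-mer match
#'   fraction.
#' @return list with `reads` (the survivors, same class as input),
#'   `n_input`, `n_removed`.
#' @export
filterHostReads <- function(reads, host, k = 31, host_match_floor = 0.5) {
  rseq <- if (is.character(reads)) reads else as.character(reads)
  frac <- cpp_match_fraction(rseq, .asSequence(host), as.integer(k))
  drop <- !is.na(frac) & frac >= host_match_floor
  list(reads = reads[!drop], n_input = length(reads),
       n_removed = sum(drop))
}

#' Build a reusable k-mer index over member genomes
#'
#' Precomputes the combined k-mer -> genome map used by [assignReads()],
#' so that many samples can be scored against the same community without
#' rebuilding the index.  The index holds an external pointer and cannot
#' be serialized; rebuild it in each session.
#'
#' @param genomes_or_defcom a [DefCom-class] or named `DNAStringSet`.
#' @param k k-mer size (default 31).
#' @return an object of class `GenomeIndex`.
#' @export
buildGenomeIndex <- function(genomes_or_defcom, k = 31) {
  g <- if (is(genomes_or_defcom, "DefCom")) genomes(genomes_or_defcom)
       else genomes_or_defcom
  ids <- names(g)
  stopifnot(!is.null(ids))
  structure(list(ptr = cpp_build_index(as.character(g), as.integer(k)),
                 k = k, strain_ids = ids),
            class = "GenomeIndex")
}

#' Competitively assign reads to member genomes
#'
#' Scores every read against every member genome as the number of shared
#' k-mers.  The best set is the argmax over genomes among those whose
#' score reaches `min_score_frac` of the read's k-mer count.  Under the
#' `unique` policy, reads whose best set contains more than one genome
#' (equally good hits in several strains) are discarded with weight 0;
#' under `fractional`, each member of the best set receives weight
#' `1/|best set|`.  The reported read start is the genome position of
#' the leftmost anchoring k-mer minus its offset in the read (0-based).
#'
#' @param reads named `DNAStringSet` or character vector of reads.
#' @param genomes_or_defcom a [DefCom-class] or a named `DNAStringSet`
#'   of member genomes.
#' @param k k-mer size (default 31).
#' @param min_score_frac minimum shared-k-mer fraction for a hit.
#' @param mode `"unique"` or `"fractional"` multi-mapping policy.
#' @param index optional [buildGenomeIndex()] result reused across
#'   samples (its `k` overrides the `k` argument).
#' @return list of class `AssignmentResult`: `assignments` (data.frame
#'   `read`, `read_name`, `strain`, `start`, `width`, `weight`),
#'   `per_read` (data.frame `n_kmers`, `best_score`, `n_best`), `mode`,
#'   `n_reads`, `n_unassigned` (below the score floor),
#'   `n_discarded_multi` (unique-mode ties).
#' @export
assignReads <- function(reads, genomes_or_defcom, k = 31,
                        min_score_frac = 0.25,
                        mode = c("unique", "fractional"),
                        index = NULL) {
  mode <- match.arg(mode)
  if (is.null(index)) {
    index <- buildGenomeIndex(genomes_or_defcom, k = k)
  } else {
    stopifnot(inherits(index, "GenomeIndex"))
    k <- index$k
  }
  ids <- index$strain_ids
  rseq <- if (is.character(reads)) reads else as.character(reads)
  widths <- nchar(rseq)
  if (length(rseq) && min(widths) < k)
    stop("read(s) shorter than k = ", k)
  sc <- cpp_score_reads_idx(rseq, index$ptr, min_score_frac)
  n_best <- sc$n_best
  asg <- data.frame(read = sc$read, strain = ids[sc$strain],
                    start = sc$start, stringsAsFactors = FALSE)
  nb_of_row <- n_best[asg$read]
  if (mode == "unique") {
    keep <- nb_of_row == 1L
    n_disc <- sum(n_best > 1L)
    asg <- asg[keep, , drop = FALSE]
    asg$weight <- rep(1, nrow(asg))
  } else {
    n_disc <- 0L
    asg$weight <- 1 / nb_of_row
  }
  nm <- names(reads)
  asg$read_name <- if (!is.null(nm)) nm[asg$read] else NA_character_
  asg$width <- widths[asg$read]
  rownames(asg) <- NULL
  structure(list(
    assignments = asg[, c("read", "read_name", "strain", "start",
                          "width", "weight")],
    per_read = data.frame(n_kmers = sc$n_kmers,
                          best_score = sc$best_score, n_best = n_best),
    mode = mode, strain_ids = ids, n_reads = length(rseq),
    n_unassigned = sum(n_best == 0L),
    n_discarded_multi = n_disc
  ), class = "AssignmentResult")
}

#' Build a count matrix from per-sample read assignments
#'
#' At `level = "strain"`, read weights are summed per strain.  At
#' `level = "gene"`, each assigned read is counted (with its weight) to
#' the gene of its strain that it overlaps by the largest number of
#' bases (>= 1 bp); overlap ties discard the read at gene level and are
#' logged in `metadata()$gene_tie_discards`.
#'
#' @param assignments named list (one `AssignmentResult` per sample).
#' @param level `"strain"` or `"gene"`.
#' @param defcom a [DefCom-class] (required at gene level, and for the
#'   strain universe).
#' @param design optional [sampleDesign()] table (rows matching the
#'   assignment names).
#' @return `SummarizedExperiment` (features x samples) with `counts`
#'   assay; gene level carries the annotation in `rowData`.
#' @export
countMatrix <- function(assignments, level = c("strain", "gene"),
                        defcom, design = NULL) {
  level <- match.arg(level)
  samples <- names(assignments)
  if (is.null(samples)) stop("assignments must be a named per-sample list")
  if (!is.null(design)) {
    if (!setequal(design$sample_id, samples))
      stop("assignment samples and design samples disagree")
    design <- design[match(samples, design$sample_id), , drop = FALSE]
  }
  ids <- strainIds(defcom)
  if (level == "strain") {
    counts <- matrix(0, length(ids), length(samples),
                     dimnames = list(ids, samples))
    for (s in samples) {
      a <- assignments[[s]]$assignments
      if (nrow(a)) {
        tot <- tapply(a$weight, factor(a$strain, levels = ids), sum)
        counts[, s] <- ifelse(is.na(tot), 0, tot)
      }
    }
    rd <- S4Vectors::DataFrame(row.names = ids)
    ties <- NULL
  } else {
    ann <- annotations(defcom)
    genes <- ann$gene_id
    counts <- matrix(0, length(genes), length(samples),
                     dimnames = list(genes, samples))
    gene_ir <- split(seq_len(nrow(ann)), ann$strain_id)
    ties <- setNames(numeric(length(samples)), samples)
    for (s in samples) {
      a <- assignments[[s]]$assignments
      if (!nrow(a)) next
      for (st in unique(a$strain)) {
        gi <- gene_ir[[st]]
        rows <- which(a$strain == st)
        if (is.null(gi) || !length(gi)) next
        q <- IRanges(start = a$start[rows] + 1L,
                     width = a$width[rows])
        subj <- IRanges(start = ann$start[gi] + 1L,
                        end = ann$end[gi])
        ov <- findOverlaps(q, subj, minoverlap = 1L)
        if (!length(ov)) next
        ow <- width(pintersect(q[S4Vectors::queryHits(ov)],
                               subj[S4Vectors::subjectHits(ov)]))
        qh <- S4Vectors::queryHits(ov)
        best <- tapply(ow, qh, max)
        is_best <- ow == best[as.character(qh)]
        nb <- tapply(is_best, qh, sum)
        keep_q <- as.integer(names(nb)[nb == 1L])
        ties[s] <- ties[s] + sum(nb > 1L)
        sel <- is_best & qh %in% keep_q
        if (!any(sel)) next
        gidx <- gi[S4Vectors::subjectHits(ov)[sel]]
        wts <- a$weight[rows][qh[sel]]
        add <- tapply(wts, factor(gidx, levels = seq_len(nrow(ann))), sum)
        add[is.na(add)] <- 0
        counts[, s] <- counts[, s] + as.numeric(add)
      }
    }
    rd <- S4Vectors::DataFrame(ann, row.names = genes)
  }
  cd <- if (is.null(design))
    S4Vectors::DataFrame(row.names = samples)
  else S4Vectors::DataFrame(design, row.names = samples)
  md <- list(level = level)
  if (!is.null(ties)) md$gene_tie_discards <- ties
  SummarizedExperiment(assays = list(counts = counts), rowData = rd,
                       colData = cd, metadata = md)
}

#' Aggregate gene counts to orthogroups
#'
#' Orthogroup counts are the sum of member-gene counts across all
#' strains.  With `per_copy = TRUE` each orthogroup's counts are divided
#' by its gene-copy number, by default the total number of copies in the
#' community reference (`copy_universe = "community"`), alternatively
#' the number of copies among strains detected (nonzero strain-level
#' total) in the matrix (`"detected"` is computed per the supplied
#' detected strain set).
#'
#' @param gene_counts `SummarizedExperiment` from
#'   [countMatrix()] / [simulateGeneCounts()] at gene level, with
#'   `orthogroup` in `rowData`.
#' @param per_copy divide by orthogroup copy number.
#' @param copy_universe `"community"` or `"detected"`.
#' @param detected_strains strain ids counted as detected when
#'   `copy_universe = "detected"`.
#' @return `SummarizedExperiment` (orthogroups x samples); `rowData`
#'   carries the copy number used.
#' @export
aggregateOrthogroups <- function(gene_counts, per_copy = FALSE,
                                 copy_universe = c("community", "detected"),
                                 detected_strains = NULL) {
  copy_universe <- match.arg(copy_universe)
  rd <- rowData(gene_counts)
  og <- rd$orthogroup
  if (is.null(og)) stop("gene counts carry no orthogroup annotation")
  bad <- is.na(og) | og == ""
  if (any(bad))
    stop("unannotated gene(s): ",
         paste(utils::head(rownames(gene_counts)[bad], 10), collapse = ", "))
  counts <- rowsum(assay(gene_counts, "counts"), og)
  copies <- as.vector(table(og)[rownames(counts)])
  if (copy_universe == "detected") {
    if (is.null(detected_strains))
      stop("detected_strains required for copy_universe = 'detected'")
    in_det <- rd$strain_id %in% detected_strains
    cop <- table(og[in_det])
    copies <- as.vector(cop[rownames(counts)])
    copies[is.na(copies)] <- 0
  }
  out <- counts
  if (per_copy) {
    nz <- copies > 0
    out[nz, ] <- counts[nz, , drop = FALSE] / copies[nz]
  }
  SummarizedExperiment(
    assays = list(counts = out),
    rowData = S4Vectors::DataFrame(copies = copies,
                                   row.names = rownames(counts)),
    colData = colData(gene_counts),
    metadata = list(level = "orthogroup", per_copy = per_copy,
                    copy_universe = copy_universe)
  )
}

.countsOf <- function(x) {
  if (is(x, "SummarizedExperiment")) assay(x, "counts") else as.matrix(x)
}

#' Counts-per-million normalization
#'
#' `cpm[f, s] = counts[f, s] / colsum(s) * 1e6`.
#'
#' @param x `SummarizedExperiment` or counts matrix.
#' @return CPM matrix; every column sums to 1e6.
#' @export
cpmNormalize <- function(x) {
  m <- .countsOf(x)
  cs <- colSums(m)
  if (any(cs == 0))
    stop("zero column sum in sample(s): ",
         paste(colnames(m)[cs == 0], collapse = ", "))
  sweep(m, 2, cs, "/") * 1e6
}

#' TMM scale factors
#'
#' Trimmed-mean-of-M-values normalization factors (reference sample by
#' upper-quartile ratio closest to the mean; 30%/5% trimming of the
#' M/A tails; precision-weighted mean M; factors rescaled to geometric
#' mean 1), as implemented in edgeR's `calcNormFactors`.
#'
#' @param x `SummarizedExperiment` or counts matrix with >= 2 samples.
#' @return named numeric vector of per-sample factors.
#' @export
tmmFactors <- function(x) {
  m <- .countsOf(x)
  if (ncol(m) < 2) stop("TMM needs at least 2 samples")
  f <- edgeR::calcNormFactors(m, method = "TMM")
  setNames(as.numeric(f), colnames(m))
}

#' Write a count matrix (features x samples) as TSV with a JSON sidecar
#'
#' @param se `SummarizedExperiment`.
#' @param path TSV path; the sidecar is `<path>.json`.
#' @param params optional list of parameters/discard statistics to
#'   record in the sidecar.
#' @return invisibly, the TSV path.
#' @export
writeCountsTSV <- function(se, path, params = list()) {
  write.table(as.data.frame(assay(se, "counts")), path, sep = "\t",
              quote = FALSE, col.names = NA)
  meta <- S4Vectors::metadata(se)
  jsonlite::write_json(c(list(level = meta$level), params,
                         meta[setdiff(names(meta), "level")]),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(path)
}
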