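## Loading a community from standard files (FASTA + annotation TSV),
## for analyses of real or externally generated data.

#' Load a community from FASTA genomes and an annotation table
#'
#' @param genome_files named character vector of per-strain FASTA paths
#'   (names become strain ids; unnamed vectors use the FASTA record
#'   name of the first record).
#' @param annotation_file TSV with columns `gene_id`, `strain_id`,
#'   `start`, `end` (0-based half-open), `strand`, `ko`, `cog`,
#'   `orthogroup`.
#' @param host_fasta optional host decoy FASTA.
#' @return a [DefCom-class] with empty ground truth.
#' @export
loadCommunity <- function(genome_files, annotation_file,
                          host_fasta = NULL) {
  seqs <- vapply(genome_files, function(f)
    paste(as.character(readDNAStringSet(f)), collapse = ""), "")
  ids <- names(genome_files)
  if (is.null(ids))
    ids <- vapply(genome_files, function(f)
      sub("\\s.*", "", names(readDNAStringSet(f))[1]), "")
  g <- DNAStringSet(unname(seqs))
  names(g) <- ids
  ann <- read.delim(annotation_file, stringsAsFactors = FALSE)
  ann$ko[ann$ko == ""] <- NA
  ann$cog[ann$cog == ""] <- NA
  ann$anc_start <- NA_integer_
  ann$anc_end <- NA_integer_
  decoy <- ""
  if (!is.null(host_fasta))
    decoy <- paste(as.character(readDNAStringSet(host_fasta)),
                   collapse = "")
  new("DefCom", genomes = g, annotations = ann, ancestor = "",
      bookkeeping = list(), groundTruth = list(), hostDecoy = decoy,
      config = list())
}

#' Read a sample design TSV
#'
#' @param path TSV with `sample_id`, `host`, `compartment`,
#'   `replicate`.
#' @return validated design `data.frame`.
#' @export
readDesign <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "host", "compartment", "replicate")
  if (!all(need %in% names(d)))
    stop("design needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(d[, c("host", "compartment", "replicate")]))
    stop("(host, compartment, replicate) must be unique")
  rownames(d) <- d$sample_id
  d
}
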