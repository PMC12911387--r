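## Synthetic defined-community generator.
##
## Strains are derived from a single ancestral sequence by substitution
## only; indels are confined to whole-gene accessory edits (deletions of
## core genes, novel genes appended after the core).  This keeps the true
## ANI of any strain pair exactly computable from the recorded
## substitution/deletion bookkeeping, in ancestor coordinates.

COG_CATEGORIES <- c("C", "D", "E", "F", "G", "H", "I", "J", "K", "L", "M",
                    "N", "O", "P", "Q", "T", "U", "V")

#' Generate an ancestral genome with non-overlapping gene annotations
#'
#' Draws an i.i.d. nucleotide sequence at the requested GC content and
#' places `n_genes` non-overlapping genes of fixed length, separated by
#' multinomially distributed intergenic gaps.  Every gene receives a
#' unique orthogroup id; a configurable fraction additionally receives a
#' KO id and a COG category.
#'
#' @param length genome length in bp.
#' @param gc GC fraction in `[0, 1]`.
#' @param n_genes number of genes to place.
#' @param gene_length gene length in bp.
#' @param ko_fraction fraction of genes receiving a KO id.
#' @param seed optional integer seed (`set.seed` is called when non-NULL).
#' @return list with `sequence` (character string) and `annotations`
#'   (`data.frame` in 0-based half-open coordinates; `anc_start`/`anc_end`
#'   mirror `start`/`end` and track ancestor coordinates through later
#'   accessory edits).
#' @examples
#' anc <- generateAncestor(20000, 0.5, n_genes = 10, seed = 1)
#' nrow(anc$annotations)
#' @export
generateAncestor <- function(length, gc = 0.5, n_genes = 50,
                             gene_length = 900, ko_fraction = 0.7,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length > 0, gc >= 0, gc <= 1, n_genes >= 0, gene_length > 0)
  if (n_genes * gene_length > 0.9 * length)
    stop("infeasible packing: n_genes * gene_length exceeds 90% of length")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  sequence <- paste(sample(names(p), length, replace = TRUE, prob = p),
                    collapse = "")
  if (n_genes > 0) {
    leftover <- length - n_genes * gene_length
    gaps <- as.vector(rmultinom(1, leftover, rep(1, n_genes + 1)))
    starts <- cumsum(gaps[seq_len(n_genes)]) +
      (seq_len(n_genes) - 1L) * gene_length
    has_ko <- seq_len(n_genes) %in%
      sample.int(n_genes, round(ko_fraction * n_genes))
    ann <- data.frame(
      gene_id = sprintf("g%04d", seq_len(n_genes)),
      strain_id = "ancestor",
      start = as.integer(starts),
      end = as.integer(starts + gene_length),
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      ko = ifelse(has_ko, sprintf("K%05d", seq_len(n_genes)), NA_character_),
      cog = ifelse(has_ko, sample(COG_CATEGORIES, n_genes, replace = TRUE),
                   NA_character_),
      orthogroup = sprintf("OG%04d", seq_len(n_genes)),
      stringsAsFactors = FALSE
    )
  } else {
    ann <- emptyAnnotations()
  }
  ann$anc_start <- ann$start
  ann$anc_end <- ann$end
  list(sequence = sequence, annotations = ann)
}

emptyAnnotations <- function() {
  data.frame(gene_id = character(), strain_id = character(),
             start = integer(), end = integer(), strand = character(),
             ko = character(), cog = character(), orthogroup = character(),
             anc_start = integer(), anc_end = integer(),
             stringsAsFactors = FALSE)
}

## internal strain representation used during construction
## list(strain_id, sub_pos (0-based ancestor coords), sub_base,
##      deleted (2-col matrix, 0-based half-open ancestor intervals),
##      annotations, insertions (data.frame gene rows + sequence column))

.ancestorStrain <- function(anc, id = "ancestor") {
  list(strain_id = id, sub_pos = integer(), sub_base = character(),
       deleted = matrix(integer(), ncol = 2),
       annotations = anc$annotations,
       insertions = data.frame())
}

.coreMask <- function(anc_len, deleted) {
  keep <- rep(TRUE, anc_len)
  if (nrow(deleted))
    for (i in seq_len(nrow(deleted)))
      keep[(deleted[i, 1] + 1L):deleted[i, 2]] <- FALSE
  keep
}

## final base at 0-based ancestor positions for a strain
.baseAt <- function(strain, pos, anc_chars) {
  out <- anc_chars[pos + 1L]
  idx <- match(pos, strain$sub_pos)
  hit <- !is.na(idx)
  out[hit] <- strain$sub_base[idx[hit]]
  out
}

#' Derive a strain from a parent genome
#'
#' Applies substitution-only divergence at rate `target_divergence`
#' (uniform positions over the parent's retained core, substituted base
#' drawn from the three alternatives) plus optional accessory edits:
#' deletion of whole core genes and insertion of novel genes appended
#' after the core sequence.  Substitutions and deletions are recorded in
#' ancestor coordinates so that the true ANI of any strain pair over
#' their shared regions is exactly computable.
#'
#' @param parent a strain object as returned by [generateAncestor()]
#'   (wrap with the ancestor itself) or a previous `deriveStrain()` call;
#'   internally a bookkeeping list.
#' @param ancestor_sequence the ancestral sequence string (coordinates
#'   reference).
#' @param target_divergence substitution rate in `[0, 0.2]`.
#' @param strain_id identifier for the derived strain.
#' @param delete_genes character vector of parent core gene ids to delete.
#' @param insert_genes optional `data.frame` with columns `ko`, `cog`,
#'   `orthogroup`, `length` describing novel genes to append.
#' @param gc GC content for inserted gene sequences.
#' @param seed optional integer seed.
#' @return a strain bookkeeping list (fields `strain_id`, `sub_pos`,
#'   `sub_base`, `deleted`, `annotations`, `insertions`); materialize the
#'   sequence with [strainSequence()].
#' @export
deriveStrain <- function(parent, ancestor_sequence, target_divergence,
                         strain_id, delete_genes = character(),
                         insert_genes = NULL, gc = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(target_divergence >= 0, target_divergence <= 0.2)
  anc_len <- nchar(ancestor_sequence)
  anc_chars <- strsplit(ancestor_sequence, "", fixed = TRUE)[[1]]
  child <- parent
  child$strain_id <- strain_id

  ## substitutions over the parent's retained core
  keep <- .coreMask(anc_len, parent$deleted)
  core_pos <- which(keep) - 1L
  n_sub <- rbinom(1, length(core_pos), target_divergence)
  if (n_sub > 0) {
    pos <- sort(sample(core_pos, n_sub))
    cur <- .baseAt(parent, pos, anc_chars)
    alt <- vapply(cur, function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    idx <- match(pos, child$sub_pos)
    hit <- !is.na(idx)
    child$sub_base[idx[hit]] <- alt[hit]
    child$sub_pos <- c(child$sub_pos, pos[!hit])
    child$sub_base <- c(child$sub_base, alt[!hit])
    o <- order(child$sub_pos)
    child$sub_pos <- child$sub_pos[o]
    child$sub_base <- child$sub_base[o]
  }

  ## accessory deletions: whole core genes, by parent gene id
  if (length(delete_genes)) {
    ann <- child$annotations
    core <- !is.na(ann$anc_start)
    miss <- setdiff(delete_genes, ann$gene_id[core])
    if (length(miss))
      stop("accessory gene id(s) absent from parent core: ",
           paste(miss, collapse = ", "))
    del <- ann[ann$gene_id %in% delete_genes, c("anc_start", "anc_end")]
    child$deleted <- rbind(child$deleted,
                           as.matrix(del, rownames.force = FALSE))
    child$annotations <- ann[!(ann$gene_id %in% delete_genes), , drop = FALSE]
  }

  ## accessory insertions: novel genes appended after the core
  if (!is.null(insert_genes) && nrow(insert_genes)) {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    seqs <- vapply(insert_genes$length, function(L)
      paste(sample(names(p), L, replace = TRUE, prob = p), collapse = ""), "")
    spacers <- vapply(rep(100L, nrow(insert_genes)), function(L)
      paste(sample(names(p), L, replace = TRUE, prob = p), collapse = ""), "")
    ins <- data.frame(
      gene_id = sprintf("%s_acc%03d", strain_id,
                        nrow(child$insertions) + seq_len(nrow(insert_genes))),
      strain_id = strain_id,
      strand = sample(c("+", "-"), nrow(insert_genes), replace = TRUE),
      ko = insert_genes$ko, cog = insert_genes$cog,
      orthogroup = insert_genes$orthogroup,
      length = insert_genes$length, sequence = seqs, spacer = spacers,
      stringsAsFactors = FALSE
    )
    child$insertions <- rbind(child$insertions, ins)
  }
  if (nrow(child$annotations))
    child$annotations$strain_id <- strain_id
  child
}

#' Materialize a strain's sequence and annotation table
#'
#' Applies the recorded substitutions and deletions to the ancestral
#' sequence, appends accessory insertions (100 bp spacers between novel
#' genes), and shifts annotation coordinates consistently.
#'
#' @param strain a strain bookkeeping list from [deriveStrain()].
#' @param ancestor_sequence the ancestral sequence string.
#' @return list with `sequence` and `annotations` (0-based half-open,
#'   including `anc_start`/`anc_end` bookkeeping columns, NA for novel
#'   genes).
#' @export
strainSequence <- function(strain, ancestor_sequence) {
  raw <- charToRaw(ancestor_sequence)
  if (length(strain$sub_pos))
    raw[strain$sub_pos + 1L] <- charToRaw(paste(strain$sub_base,
                                                collapse = ""))
  keep <- .coreMask(length(raw), strain$deleted)
  core <- rawToChar(raw[keep])
  ## coordinate shift: deleted bp strictly before each position
  shift_at <- function(anc_pos) {
    if (!nrow(strain$deleted)) return(anc_pos)
    del_bp <- vapply(anc_pos, function(x)
      sum(pmax(0L, pmin(strain$deleted[, 2], x) - strain$deleted[, 1])), 0L)
    anc_pos - del_bp
  }
  ann <- strain$annotations
  if (nrow(ann)) {
    ann$start <- as.integer(shift_at(ann$anc_start))
    ann$end <- as.integer(shift_at(ann$anc_end))
  }
  parts <- core
  offset <- nchar(core)
  ins <- strain$insertions
  if (!is.null(ins) && nrow(ins)) {
    acc_ann <- vector("list", nrow(ins))
    pieces <- character(2 * nrow(ins))
    for (i in seq_len(nrow(ins))) {
      spacer <- nchar(ins$spacer[i])
      pieces[2 * i - 1] <- ins$spacer[i]
      pieces[2 * i] <- ins$sequence[i]
      gstart <- offset + spacer
      acc_ann[[i]] <- data.frame(
        gene_id = ins$gene_id[i], strain_id = ins$strain_id[i],
        start = as.integer(gstart), end = as.integer(gstart + ins$length[i]),
        strand = ins$strand[i], ko = ins$ko[i], cog = ins$cog[i],
        orthogroup = ins$orthogroup[i],
        anc_start = NA_integer_, anc_end = NA_integer_,
        stringsAsFactors = FALSE
      )
      offset <- gstart + ins$length[i]
    }
    parts <- paste0(core, paste(pieces, collapse = ""))
    ann <- rbind(ann, do.call(rbind, acc_ann))
  }
  list(sequence = parts, annotations = ann[order(ann$start), , drop = FALSE])
}

#' True ANI between two strains from substitution bookkeeping
#'
#' Exact average nucleotide identity over the shared (non-deleted in
#' either strain) ancestor positions: `100 * (1 - differing / shared)`,
#' by integer arithmetic on the recorded substitution maps.  Accessory
#' insertions are never shared and do not enter the calculation.
#'
#' @param a,b strain bookkeeping lists.
#' @param ancestor_sequence the ancestral sequence string.
#' @return ANI percent as numeric(1).
#' @export
truePairANI <- function(a, b, ancestor_sequence) {
  anc_len <- nchar(ancestor_sequence)
  anc_chars <- strsplit(ancestor_sequence, "", fixed = TRUE)[[1]]
  keep <- .coreMask(anc_len, rbind(a$deleted, b$deleted))
  shared <- sum(keep)
  if (shared == 0) stop("no shared region between strains")
  pos <- union(a$sub_pos, b$sub_pos)
  pos <- pos[keep[pos + 1L]]
  if (length(pos)) {
    diff_n <- sum(.baseAt(a, pos, anc_chars) != .baseAt(b, pos, anc_chars))
  } else diff_n <- 0L
  100 * (1 - diff_n / shared)
}

#' Default community configuration
#'
#' Parameters for a ten-strain, seven-lineage community on 0.5 Mb
#' genomes: one three-strain lineage plus one singleton lineage carry the
#' dominant endosphere colonizers (mirroring a community in which a
#' multi-strain lineage and independent singletons both colonize), six
#' planted endosphere KOs/orthogroups are inserted into exactly those
#' lineages, and every strain carries strain-specific accessory genes.
#'
#' @param ... overrides for any configuration element.
#' @return a named list of generator parameters.
#' @export
communityConfig <- function(...) {
  cfg <- list(
    genome_length = 5e5, gc = 0.5, n_genes = 450, gene_length = 900,
    ko_fraction = 0.7,
    lineage_sizes = c(3, 2, 1, 1, 1, 1, 1),
    within_divergence = 0.005, between_divergence = 0.08,
    ani_within_min = 98.5, ani_between_max = 95,
    accessory_per_strain = 25, accessory_gene_length = 900,
    accessory_ko_fraction = 0.5,
    dominant_lineages = c(1L, 3L),
    n_planted = 6, planted_gene_length = 900,
    host_decoy_length = 2e5, host_decoy_gc = 0.34,
    host_effect_sd = 0.5
  )
  modifyList(cfg, list(...))
}

#' A 28-strain, 15-lineage configuration
#'
#' Community layout matching a 28-strain defined community partitioned
#' into 15 ANI lineages of which 4 (one three-strain lineage and three
#' singletons, 6 strains in total) contain the dominant endosphere
#' colonizers and 11 do not.  Genomes are kept small (50 kb) since this
#' configuration is used for lineage-level analyses.
#'
#' @param ... overrides for any configuration element.
#' @return a named list of generator parameters.
#' @export
studyMimicConfig <- function(...) {
  communityConfig(
    genome_length = 5e4, n_genes = 45,
    lineage_sizes = c(3, 3, 3, 3, 2, 2, 2, 2, 2, 1, 1, 1, 1, 1, 1),
    dominant_lineages = c(1L, 10L, 11L, 12L),
    accessory_per_strain = 5,
    ...
  )
}

#' Build a synthetic defined community
#'
#' Generates an ancestral genome, derives one founder per lineage at half
#' the between-lineage divergence and each member at half the
#' within-lineage divergence from its founder, appends strain-specific
#' accessory genes and the planted endosphere KO/orthogroup genes (one
#' copy per member of each carrier lineage), and records full ground
#' truth: true pairwise ANI, the lineage partition, planted feature sets
#' and the dominant colonizer strains.
#'
#' @param config list from [communityConfig()] or [studyMimicConfig()].
#' @param seed integer seed; the whole construction is deterministic
#'   given `(config, seed)`.
#' @return a [DefCom-class] object.
#' @examples
#' dc <- buildCommunity(communityConfig(genome_length = 3e4, n_genes = 20,
#'   accessory_per_strain = 3), seed = 1)
#' dc
#' @export
buildCommunity <- function(config = communityConfig(), seed = 1) {
  set.seed(seed)
  cfg <- config
  n_lin <- length(cfg$lineage_sizes)
  n_strain <- sum(cfg$lineage_sizes)
  w <- cfg$within_divergence
  b <- cfg$between_divergence
  ## feasibility of the configured ANI thresholds
  if (100 * (1 - w) < cfg$ani_within_min)
    stop("thresholds cannot be realized: within_divergence ",
         w, " is incompatible with ani_within_min ", cfg$ani_within_min)
  if (100 * (1 - b) > cfg$ani_between_max)
    stop("thresholds cannot be realized: between_divergence ",
         b, " is incompatible with ani_between_max ", cfg$ani_between_max)
  if (any(cfg$dominant_lineages > n_lin))
    stop("dominant_lineages index exceeds the number of lineages")

  anc <- generateAncestor(cfg$genome_length, cfg$gc, cfg$n_genes,
                          cfg$gene_length, cfg$ko_fraction)
  anc_strain <- .ancestorStrain(anc)

  strain_ids <- sprintf("S%02d", seq_len(n_strain))
  lineage_of <- rep(seq_len(n_lin), cfg$lineage_sizes)

  ## planted endosphere features: same KO + orthogroup inserted into every
  ## member of the dominant lineages
  planted_ko <- sprintf("K9%04d", seq_len(cfg$n_planted))
  planted_og <- sprintf("OGP%03d", seq_len(cfg$n_planted))
  planted_genes <- data.frame(
    ko = planted_ko, cog = sample(COG_CATEGORIES, cfg$n_planted,
                                  replace = TRUE),
    orthogroup = planted_og, length = cfg$planted_gene_length,
    stringsAsFactors = FALSE
  )

  strains <- vector("list", n_strain)
  k <- 0L
  for (l in seq_len(n_lin)) {
    founder <- deriveStrain(anc_strain, anc$sequence, b / 2,
                            sprintf("F%02d", l))
    for (m in seq_len(cfg$lineage_sizes[l])) {
      k <- k + 1L
      sid <- strain_ids[k]
      n_acc <- cfg$accessory_per_strain
      acc <- NULL
      if (n_acc > 0) {
        has_ko <- runif(n_acc) < cfg$accessory_ko_fraction
        acc <- data.frame(
          ko = ifelse(has_ko, sprintf("K8%04d", sample.int(9999, n_acc)),
                      NA_character_),
          cog = ifelse(has_ko, sample(COG_CATEGORIES, n_acc, replace = TRUE),
                       NA_character_),
          orthogroup = sprintf("OGA_%s_%03d", sid, seq_len(n_acc)),
          length = cfg$accessory_gene_length, stringsAsFactors = FALSE
        )
      }
      if (l %in% cfg$dominant_lineages && cfg$n_planted > 0)
        acc <- rbind(planted_genes, acc)
      strains[[k]] <- deriveStrain(founder, anc$sequence, w / 2, sid,
                                   insert_genes = acc, gc = cfg$gc)
    }
  }
  names(strains) <- strain_ids

  ## lineage ids: lexicographically smallest member strain id
  lin_label <- vapply(seq_len(n_lin), function(l)
    min(strain_ids[lineage_of == l]), "")
  lineage_assignment <- setNames(lin_label[lineage_of], strain_ids)

  ## true ANI and threshold verification
  true_ani <- matrix(100, n_strain, n_strain,
                     dimnames = list(strain_ids, strain_ids))
  for (i in seq_len(n_strain - 1)) for (j in (i + 1):n_strain) {
    true_ani[i, j] <- true_ani[j, i] <-
      truePairANI(strains[[i]], strains[[j]], anc$sequence)
  }
  same <- outer(lineage_of, lineage_of, "==")
  off <- !diag(n_strain)
  if (any(true_ani[same & off] < cfg$ani_within_min) ||
      any(true_ani[!same] > cfg$ani_between_max))
    stop("thresholds cannot be realized: generated community violates ",
         "the configured within/between ANI bounds")

  mat <- lapply(strains, strainSequence, ancestor_sequence = anc$sequence)
  gseq <- DNAStringSet(vapply(mat, `[[`, "", "sequence"))
  names(gseq) <- strain_ids
  ann <- do.call(rbind, lapply(mat, `[[`, "annotations"))
  ann$gene_id <- paste(ann$strain_id, ann$gene_id, sep = "_")
  rownames(ann) <- NULL

  decoy <- paste(sample(c("A", "C", "G", "T"), cfg$host_decoy_length,
                        replace = TRUE,
                        prob = c((1 - cfg$host_decoy_gc) / 2,
                                 cfg$host_decoy_gc / 2,
                                 cfg$host_decoy_gc / 2,
                                 (1 - cfg$host_decoy_gc) / 2)),
                 collapse = "")

  dominant_strains <- strain_ids[lineage_of %in% cfg$dominant_lineages]
  host_effects <- setNames(rnorm(n_strain, 0, cfg$host_effect_sd),
                           strain_ids)

  gt <- list(
    true_ani = true_ani,
    lineage_assignment = lineage_assignment,
    planted_enriched_kos = planted_ko,
    planted_enriched_ogs = planted_og,
    dominant_strains = dominant_strains,
    host_effects = host_effects
  )
  new("DefCom", genomes = gseq, annotations = ann,
      ancestor = anc$sequence,
      bookkeeping = lapply(strains, function(s)
        s[c("sub_pos", "sub_base", "deleted")]),
      groundTruth = gt, hostDecoy = decoy,
      config = c(cfg, list(seed = seed)))
}

#' True pairwise ANI matrix of a generated community
#'
#' @param defcom a [DefCom-class] built by [buildCommunity()].
#' @return an [ANIMatrix-class] with the exact bookkeeping-derived ANI.
#' @export
trueANI <- function(defcom) {
  stopifnot(is(defcom, "DefCom"), !is.null(defcom@groundTruth$true_ani))
  new("ANIMatrix", ani = defcom@groundTruth$true_ani)
}

#' Sample design for a two-host, two-compartment experiment
#'
#' Builds the sample sheet for an endosphere/rhizosphere comparison
#' across two host species, defaulting to 7 endosphere and 8 rhizosphere
#' samples split near-evenly between hosts.
#'
#' @param n_endosphere,n_rhizosphere number of samples per compartment.
#' @param hosts two host labels.
#' @return `data.frame` with `sample_id`, `host`, `compartment`,
#'   `replicate`; `(host, compartment, replicate)` is unique.
#' @export
sampleDesign <- function(n_endosphere = 7, n_rhizosphere = 8,
                         hosts = c("speciesA", "speciesB")) {
  stopifnot(length(hosts) == 2, n_endosphere >= 2, n_rhizosphere >= 2)
  one <- function(n, compartment) {
    nh <- c(ceiling(n / 2), floor(n / 2))
    h <- rep(hosts, nh)
    r <- c(seq_len(nh[1]), seq_len(nh[2]))
    data.frame(
      sample_id = sprintf("%s_%s_r%d", substr(compartment, 1, 5), h, r),
      host = h, compartment = compartment, replicate = r,
      stringsAsFactors = FALSE
    )
  }
  d <- rbind(one(n_endosphere, "endosphere"), one(n_rhizosphere, "rhizosphere"))
  rownames(d) <- d$sample_id
  d
}

#' Abundance model for read/count simulation
#'
#' Per sample, strain proportions are drawn log-normal
#' `(base_log_mean, base_log_sd)` (natural-log scale), multiplied by
#' `2^compartment_effect` in the endosphere and `2^host_effect` in the
#' second host, then renormalized.  Reads start uniformly on the chosen
#' strain; per-base substitution errors are i.i.d.; a `host_read_fraction`
#' of reads is drawn from the host decoy.
#'
#' @param compartment_effects named numeric, log2 endosphere multiplier
#'   per strain.
#' @param host_effects named numeric, log2 multiplier applied in the
#'   second host (first host is reference).
#' @param base_log_mean,base_log_sd log-normal baseline parameters.
#' @param depth reads per sample.
#' @param host_read_fraction fraction of reads from the host decoy,
#'   in `[0, 1)`.
#' @param error_rate per-base substitution probability, in `[0, 0.05)`.
#' @param read_length read length in bp.
#' @return a list of class `AbundanceModel`.
#' @export
abundanceModel <- function(compartment_effects, host_effects = NULL,
                           base_log_mean = 0, base_log_sd = 0.35,
                           depth = 50000, host_read_fraction = 0.1,
                           error_rate = 0.005, read_length = 150) {
  stopifnot(depth > 0, error_rate >= 0, error_rate < 0.05,
            host_read_fraction >= 0, host_read_fraction < 1,
            all(is.finite(compartment_effects)))
  if (is.null(host_effects))
    host_effects <- setNames(numeric(length(compartment_effects)),
                             names(compartment_effects))
  structure(list(compartment_effects = compartment_effects,
                 host_effects = host_effects,
                 base_log_mean = base_log_mean, base_log_sd = base_log_sd,
                 depth = depth, host_read_fraction = host_read_fraction,
                 error_rate = error_rate, read_length = read_length),
            class = "AbundanceModel")
}

#' Default abundance model for a generated community
#'
#' Encodes the endosphere bottleneck observed in defined-community
#' colonization experiments: dominant colonizer strains gain `+2` log2
#' units in the endosphere while all other strains lose `2` log2 units,
#' so the endosphere is dominated by the colonizers.  Host effects come
#' from the community's ground truth draw.
#'
#' @param defcom a [DefCom-class] from [buildCommunity()].
#' @param ... overrides passed to [abundanceModel()].
#' @export
defaultAbundanceModel <- function(defcom, ...) {
  ids <- strainIds(defcom)
  dom <- groundTruth(defcom)$dominant_strains
  ce <- setNames(ifelse(ids %in% dom, 2, -2), ids)
  abundanceModel(compartment_effects = ce,
                 host_effects = groundTruth(defcom)$host_effects, ...)
}

## per-sample true strain proportions under the model
.sampleProportions <- function(model, design, strain_ids) {
  n <- length(strain_ids)
  ce <- model$compartment_effects[strain_ids]
  he <- model$host_effects[strain_ids]
  ce[is.na(ce)] <- 0; he[is.na(he)] <- 0
  hosts <- unique(design$host)
  p <- matrix(0, n, nrow(design),
              dimnames = list(strain_ids, design$sample_id))
  for (j in seq_len(nrow(design))) {
    base <- rlnorm(n, model$base_log_mean, model$base_log_sd)
    is_h2 <- length(hosts) >= 2 && design$host[j] == hosts[2]
    mult <- 2^(ce * (design$compartment[j] == "endosphere") +
               he * is_h2)
    pj <- base * mult
    p[, j] <- pj / sum(pj)
  }
  p
}

#' Simulate per-sample shotgun reads from a community
#'
#' Draws each sample's strain proportions from the abundance model,
#' samples read start positions uniformly along the chosen strain's
#' genome (forward strand, single-end), injects i.i.d. substitution
#' errors, and mixes in host-decoy reads.  Read provenance (strain of
#' origin or host flag, start position, sample) is encoded in the read
#' names so that assignment accuracy is measurable.
#'
#' @param defcom a [DefCom-class].
#' @param design a [sampleDesign()] table.
#' @param model an [abundanceModel()].
#' @param outdir if non-NULL, write one gzip FASTQ per sample here and
#'   return file paths; otherwise reads are returned in memory.
#' @param seed optional integer seed.
#' @return list with `reads` (named list of `DNAStringSet`, NULL when
#'   written to disk), `fastq` (paths or NULL), `true_abundance`
#'   (strains x samples), `design`.
#' @export
simulateReads <- function(defcom, design, model, outdir = NULL,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(design) == 0) stop("empty design")
  ids <- strainIds(defcom)
  glen <- width(genomes(defcom))
  rl <- model$read_length
  if (rl > min(glen)) stop("read length exceeds the shortest genome")
  gstr <- as.character(genomes(defcom))
  decoy <- defcom@hostDecoy
  if (model$host_read_fraction > 0 && nchar(decoy) < rl)
    stop("host decoy shorter than the read length")
  p <- .sampleProportions(model, design, ids)
  reads <- if (is.null(outdir)) vector("list", nrow(design)) else NULL
  paths <- if (is.null(outdir)) NULL else character(nrow(design))
  if (!is.null(outdir)) dir.create(outdir, showWarnings = FALSE,
                                   recursive = TRUE)
  for (j in seq_len(nrow(design))) {
    sid <- design$sample_id[j]
    n_host <- rbinom(1, model$depth, model$host_read_fraction)
    n_bact <- model$depth - n_host
    strain_of <- sample.int(length(ids), n_bact, replace = TRUE,
                            prob = p[, j])
    seqs <- character(n_bact)
    starts <- integer(n_bact)
    for (s in seq_along(ids)) {
      w <- which(strain_of == s)
      if (!length(w)) next
      st <- sample.int(glen[s] - rl + 1L, length(w), replace = TRUE)
      seqs[w] <- substring(gstr[s], st, st + rl - 1L)
      starts[w] <- st - 1L
    }
    prov <- ids[strain_of]
    if (n_host > 0) {
      st <- sample.int(nchar(decoy) - rl + 1L, n_host, replace = TRUE)
      seqs <- c(seqs, substring(decoy, st, st + rl - 1L))
      starts <- c(starts, st - 1L)
      prov <- c(prov, rep("host", n_host))
    }
    if (model$error_rate > 0)
      seqs <- as.character(cpp_mutate_reads(seqs, model$error_rate))
    nm <- sprintf("%s_r%07d|strain=%s|start=%d", sid, seq_along(seqs),
                  prov, starts)
    x <- DNAStringSet(seqs)
    names(x) <- nm
    if (is.null(outdir)) {
      reads[[j]] <- x
    } else {
      paths[j] <- file.path(outdir, paste0(sid, ".fastq.gz"))
      writeXStringSet(x, paths[j], format = "fastq", compress = TRUE)
    }
  }
  if (is.null(outdir)) names(reads) <- design$sample_id
  else names(paths) <- design$sample_id
  list(reads = reads, fastq = paths, true_abundance = p, design = design)
}

#' Parse provenance tags from simulated read names
#'
#' @param nm character vector of read names from [simulateReads()].
#' @return `data.frame` with `strain` ("host" for decoy reads) and
#'   `start` (0-based true start).
#' @export
parseReadNames <- function(nm) {
  strain <- sub(".*\\|strain=([^|]+)\\|.*", "\\1", nm)
  start <- as.integer(sub(".*\\|start=([0-9]+).*", "\\1", nm))
  data.frame(strain = strain, start = start, stringsAsFactors = FALSE)
}

#' Simulate strain-level counts without reads
#'
#' Read-free shortcut sharing the abundance model with [simulateReads()]:
#' per sample, strain read counts are multinomial draws of size `depth`
#' from the model's true proportions.  Used for statistical recovery
#' experiments where the read strings themselves are irrelevant.
#'
#' @inheritParams simulateReads
#' @param strain_ids strain identifiers (defaults to the names of the
#'   model's compartment effects).
#' @return a `SummarizedExperiment` (strains x samples) with the design
#'   in `colData` and the true proportion matrix in
#'   `metadata()$true_abundance`.
#' @export
simulateStrainCounts <- function(design, model,
                                 strain_ids = names(model$compartment_effects),
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(design) == 0) stop("empty design")
  p <- .sampleProportions(model, design, strain_ids)
  counts <- apply(p, 2, function(pj) rmultinom(1, model$depth, pj))
  dimnames(counts) <- dimnames(p)
  SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(design, row.names = design$sample_id),
    metadata = list(level = "strain", true_abundance = p)
  )
}

#' Simulate gene-level counts without reads
#'
#' Per sample, gene counts are multinomial: the probability of a gene is
#' its strain's model proportion times the gene's share of its strain's
#' annotated length.  Shares the abundance model with [simulateReads()].
#'
#' @inheritParams simulateReads
#' @return a `SummarizedExperiment` (genes x samples) with gene metadata
#'   in `rowData`.
#' @export
simulateGeneCounts <- function(defcom, design, model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(design) == 0) stop("empty design")
  ids <- strainIds(defcom)
  ann <- annotations(defcom)
  p <- .sampleProportions(model, design, ids)
  glen <- ann$end - ann$start
  per_strain_len <- tapply(glen, ann$strain_id, sum)[ids]
  w <- glen / as.numeric(per_strain_len[match(ann$strain_id, ids)])
  counts <- matrix(0L, nrow(ann), nrow(design),
                   dimnames = list(ann$gene_id, design$sample_id))
  for (j in seq_len(nrow(design))) {
    pg <- p[match(ann$strain_id, ids), j] * w
    counts[, j] <- rmultinom(1, model$depth, pg)
  }
  SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(ann, row.names = ann$gene_id),
    colData = S4Vectors::DataFrame(design, row.names = design$sample_id),
    metadata = list(level = "gene", true_abundance = p)
  )
}

#' Simulate orthogroup counts with planted compartment effects
#'
#' Negative-binomial feature counts for differential-abundance
#' experiments: per-feature baselines are log-normal, a chosen set of
#' features gains `effect_log2` log2 units in the endosphere, and counts
#' are NB with a common dispersion.
#'
#' @param design a [sampleDesign()] table.
#' @param n_features total number of orthogroups.
#' @param n_planted number of endosphere-enriched features (the first
#'   `n_planted` features).
#' @param effect_log2 planted endosphere effect in log2 units.
#' @param meanlog,sdlog log-normal baseline parameters (natural log).
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param seed optional integer seed.
#' @return a `SummarizedExperiment` with logical `rowData()$planted`.
#' @export
simulateOrthogroupCounts <- function(design, n_features = 330,
                                     n_planted = 30, effect_log2 = 2,
                                     meanlog = log(100), sdlog = 1,
                                     dispersion = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_planted <= n_features)
  base <- rlnorm(n_features, meanlog, sdlog)
  planted <- seq_len(n_features) <= n_planted
  endo <- design$compartment == "endosphere"
  counts <- matrix(0L, n_features, nrow(design),
                   dimnames = list(sprintf("OG%04d", seq_len(n_features)),
                                   design$sample_id))
  for (j in seq_len(nrow(design))) {
    mu <- base * ifelse(planted & endo[j], 2^effect_log2, 1)
    counts[, j] <- rnbinom(n_features, mu = mu, size = 1 / dispersion)
  }
  SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(planted = planted,
                                   row.names = rownames(counts)),
    colData = S4Vectors::DataFrame(design, row.names = design$sample_id),
    metadata = list(level = "orthogroup")
  )
}

#' Write a community to disk
#'
#' One FASTA per strain, the host decoy FASTA, the annotation table as
#' TSV (0-based half-open), the design as TSV and the ground truth as
#' JSON.
#'
#' @param defcom a [DefCom-class].
#' @param dir output directory (created).
#' @param design optional design table to write alongside.
#' @return invisibly, the named list of written paths.
#' @export
writeCommunity <- function(defcom, dir, design = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (s in strainIds(defcom)) {
    f <- file.path(dir, paste0(s, ".fasta"))
    writeXStringSet(genomes(defcom)[s], f)
    paths$genomes <- c(paths$genomes, f)
  }
  if (nchar(defcom@hostDecoy)) {
    f <- file.path(dir, "host_decoy.fasta")
    d <- DNAStringSet(defcom@hostDecoy)
    names(d) <- "host_decoy"
    writeXStringSet(d, f)
    paths$host_decoy <- f
  }
  ann <- annotations(defcom)
  keep <- c("gene_id", "strain_id", "start", "end", "strand", "ko", "cog",
            "orthogroup")
  paths$annotations <- file.path(dir, "annotations.tsv")
  write.table(ann[, keep], paths$annotations, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(design)) {
    paths$design <- file.path(dir, "design.tsv")
    write.table(design, paths$design, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  gt <- groundTruth(defcom)
  if (length(gt)) {
    paths$ground_truth <- file.path(dir, "ground_truth.json")
    jsonlite::write_json(
      list(true_ani = gt$true_ani,
           lineage_assignment = as.list(gt$lineage_assignment),
           planted_enriched_kos = gt$planted_enriched_kos,
           planted_enriched_ogs = gt$planted_enriched_ogs,
           dominant_strains = gt$dominant_strains),
      paths$ground_truth, auto_unbox = TRUE, digits = NA)
  }
  invisible(paths)
}
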