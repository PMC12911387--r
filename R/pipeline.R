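## End-to-end orchestration: configuration, stage execution, manifest.

#' Pipeline configuration with defaults
#'
#' Assembles the full configuration for [runPipeline()].  Stage
#' defaults follow the values used throughout the package: lineage
#' threshold `tau = 97`, KO rule thresholds `min_endo = 2` /
#' `max_non = 4`, `alpha = 0.05`, ANI estimation with `k = 16` on 3 kb
#' fragments, read assignment with `k = 31` and a 25% shared-k-mer
#' floor, unique-mode counting as the primary policy.  The synthetic
#' block defaults to a ten-strain community on 0.5 Mb genomes with 7
#' endosphere + 8 rhizosphere samples of 50,000 reads.
#'
#' @param ... overrides (nested lists are merged).
#' @return a `PipelineConfig` list.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    community = communityConfig(),
    design = list(n_endosphere = 7, n_rhizosphere = 8,
                  hosts = c("speciesA", "speciesB")),
    model = list(depth = 50000, base_log_sd = 0.35,
                 host_read_fraction = 0.1, error_rate = 0.005,
                 read_length = 150),
    ani = list(k = 16, fragment = 3000, min_jaccard = 0.01),
    assign = list(k = 31, min_score_frac = 0.25, mode = "unique",
                  host_match_floor = 0.5),
    lineage = list(tau = 97),
    ko_rule = list(min_endo = 2, max_non = 4),
    stats = list(alpha = 0.05, n_perm = 999, css_quantile = 0.5,
                 abundance_quantile = 0.5, per_copy = FALSE)
  )
  over <- list(...)
  for (nm in names(over)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      modifyList(cfg[[nm]], over[[nm]]) else over[[nm]]
  }
  cfg
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Values in the file override [pipelineConfig()] defaults.
#'
#' @param path YAML or JSON file.
#' @return a `PipelineConfig` list.
#' @export
readPipelineConfig <- function(path) {
  over <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                           simplifyVector = TRUE)
          else yaml::read_yaml(path)
  do.call(pipelineConfig, over)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes generate (synthetic community + reads) -> ANI/lineages ->
#' host filter -> competitive assignment and counting -> strain
#' enrichment -> lineage KO rule -> orthogroup profiles and diversity
#' -> three-method consensus differential abundance -> cross-framework
#' KO intersection, writing every declared TSV/JSON output plus a
#' manifest with a deterministic content hash.  Any stage error aborts
#' with the stage name.
#'
#' @param config a [pipelineConfig()] list.
#' @param outdir output directory (created).
#' @param seed integer seed governing every source of randomness.
#' @return invisibly, a list with `outputs` (paths), `manifest`
#'   (including `manifest_hash`), and key in-memory results.
#' @export
runPipeline <- function(config = pipelineConfig(), outdir, seed = 1) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  paths <- character()

  ## --- generate ------------------------------------------------------
  sim <- .stage("generate", {
    dc <- buildCommunity(config$community, seed = seed)
    design <- do.call(sampleDesign, config$design)
    model <- do.call(defaultAbundanceModel, c(list(dc), config$model))
    writeCommunity(dc, file.path(outdir, "community"), design = design)
    rs <- simulateReads(dc, design, model,
                        outdir = file.path(outdir, "reads"))
    list(dc = dc, design = design, model = model, reads = rs)
  })
  dc <- sim$dc; design <- sim$design
  paths <- c(paths, list.files(file.path(outdir, "community"),
                               full.names = TRUE))

  ## --- ani -----------------------------------------------------------
  ani_res <- .stage("ani", {
    am <- do.call(aniMatrix, c(list(dc), config$ani))
    writeANIMatrix(am, file.path(outdir, "ani_matrix.tsv"))
    lm <- clusterLineages(am, tau = config$lineage$tau)
    lm <- labelEndosphereLineages(lm, groundTruth(dc)$dominant_strains)
    writeLineageMap(lm, file.path(outdir, "lineages.tsv"))
    list(am = am, lm = lm)
  })
  lmap <- ani_res$lm
  paths <- c(paths, file.path(outdir, c("ani_matrix.tsv", "lineages.tsv")))

  ## --- quantify ------------------------------------------------------
  quant <- .stage("quantify", {
    asg <- list()
    stats <- list()
    idx <- buildGenomeIndex(dc, k = config$assign$k)
    for (s in design$sample_id) {
      reads <- readDNAStringSet(sim$reads$fastq[s], format = "fastq")
      filt <- filterHostReads(reads, dc@hostDecoy, k = config$assign$k,
                              host_match_floor = config$assign$host_match_floor)
      asg[[s]] <- assignReads(filt$reads, dc, index = idx,
                              min_score_frac = config$assign$min_score_frac,
                              mode = config$assign$mode)
      stats[[s]] <- list(n_input = filt$n_input,
                         n_host_removed = filt$n_removed,
                         n_unassigned = asg[[s]]$n_unassigned,
                         n_discarded_multi = asg[[s]]$n_discarded_multi)
    }
    strain_se <- countMatrix(asg, "strain", dc, design)
    gene_se <- countMatrix(asg, "gene", dc, design)
    og_se <- aggregateOrthogroups(gene_se,
                                  per_copy = config$stats$per_copy)
    writeCountsTSV(strain_se, file.path(outdir, "strain_counts.tsv"),
                   params = c(config$assign, list(discards = stats)))
    writeCountsTSV(og_se, file.path(outdir, "orthogroup_counts.tsv"),
                   params = config$assign["mode"])
    list(strain = strain_se, gene = gene_se, og = og_se, stats = stats)
  })
  paths <- c(paths, file.path(outdir, c("strain_counts.tsv",
                                        "orthogroup_counts.tsv")))

  ## --- enrich-strains ------------------------------------------------
  et <- .stage("enrich-strains", {
    et <- strainEnrichment(quant$strain, alpha = config$stats$alpha)
    et <- classifyStrategies(et, alpha = config$stats$alpha,
                             abundance_quantile =
                               config$stats$abundance_quantile)
    writeEnrichmentTSV(et, file.path(outdir, "strain_enrichment.tsv"))
    et
  })
  paths <- c(paths, file.path(outdir, "strain_enrichment.tsv"))

  ## --- enrich-kos ----------------------------------------------------
  ko <- .stage("enrich-kos", {
    pres <- lineagePresence(annotations(dc), lmap)
    kr <- koEnrichmentRule(pres, min_endo = config$ko_rule$min_endo,
                           max_non = config$ko_rule$max_non)
    writeEnrichmentTSV(kr, file.path(outdir, "ko_enrichment.tsv"))
    kr
  })
  paths <- c(paths, file.path(outdir, "ko_enrichment.tsv"))

  ## --- diversity -----------------------------------------------------
  div <- .stage("diversity", {
    cpm <- cpmNormalize(quant$og)
    ad <- alphaDiversity(cpm)
    cmp <- compareAlpha(ad$shannon, design$compartment)
    bc <- brayCurtis(cpm)
    nm <- nmdsOrdination(bc, seed = seed + 1)
    pm <- permanova(bc, design, c("compartment", "host"),
                    n_perm = config$stats$n_perm, seed = seed + 2)
    write.table(bc, file.path(outdir, "bray_curtis.tsv"), sep = "\t",
                quote = FALSE, col.names = NA)
    write.table(data.frame(sample = rownames(nm$points), nm$points),
                file.path(outdir, "nmds_coordinates.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(pm, file.path(outdir, "permanova.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeEnrichmentTSV(ad, file.path(outdir, "alpha_diversity.tsv"))
    list(alpha = ad, alpha_tests = cmp, bray = bc, nmds = nm,
         permanova = pm)
  })
  paths <- c(paths, file.path(outdir, c("bray_curtis.tsv",
                                        "nmds_coordinates.tsv",
                                        "permanova.tsv",
                                        "alpha_diversity.tsv")))

  ## --- da ------------------------------------------------------------
  da <- .stage("da", {
    X <- makeDesignMatrix(design)
    og_counts <- round(assay(quant$og, "counts"))
    res <- list(
      nb_wald = nbWaldDA(og_counts, X, alpha = config$stats$alpha),
      voom_mod_t = voomDA(og_counts, X, alpha = config$stats$alpha),
      css_zig = cssZigDA(og_counts, X,
                         css_quantile = config$stats$css_quantile,
                         alpha = config$stats$alpha)
    )
    cons <- consensusDA(res, alpha = config$stats$alpha)
    ph <- perHostEnrichment(quant$og, alpha = config$stats$alpha)
    ann <- annotations(dc)
    og2ko <- tapply(ann$ko, ann$orthogroup, function(k) {
      k <- unique(k[!is.na(k)])
      if (length(k)) k[1] else NA_character_
    })
    ko_set <- intersectFrameworks(cons$features, og2ko,
                                  ko$ko[ko$enriched])
    for (m in names(res))
      writeEnrichmentTSV(res[[m]],
                         file.path(outdir, paste0("da_", m, ".tsv")))
    writeEnrichmentTSV(cons$table, file.path(outdir, "da_consensus.tsv"))
    jsonlite::write_json(
      list(alpha = config$stats$alpha,
           n_significant = lapply(res, function(r) sum(r$significant)),
           n_consensus = length(cons$features),
           per_host_upset = as.list(ph$upset),
           shared_orthogroups = ph$shared,
           intersected_kos = ko_set, seed = seed),
      file.path(outdir, "da_summary.json"), auto_unbox = TRUE,
      digits = NA)
    list(methods = res, consensus = cons, per_host = ph,
         intersected_kos = ko_set)
  })
  paths <- c(paths, file.path(outdir, c("da_nb_wald.tsv",
                                        "da_voom_mod_t.tsv",
                                        "da_css_zig.tsv",
                                        "da_consensus.tsv",
                                        "da_summary.json")))

  ## --- manifest ------------------------------------------------------
  paths <- c(paths, unname(sim$reads$fastq))
  md5 <- tools::md5sum(paths)
  rel <- sub(paste0("^", normalizePath(outdir), "/?"), "",
             normalizePath(paths))
  files <- data.frame(file = rel, md5 = unname(md5),
                      stringsAsFactors = FALSE)
  files <- files[order(files$file), ]
  hash_input <- tempfile()
  writeLines(paste(files$file, files$md5), hash_input)
  manifest <- list(
    package_version = as.character(utils::packageVersion("DefComTools")),
    seed = seed,
    parameters = config,
    files = files,
    manifest_hash = unname(tools::md5sum(hash_input))
  )
  unlink(hash_input)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(outputs = paths, manifest = manifest, community = dc,
                 ani = ani_res$am,
                 lineages = lmap, counts = quant, enrichment = et,
                 ko = ko, diversity = div, da = da))
}
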