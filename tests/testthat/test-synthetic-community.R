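test_that("ancestor generation satisfies packing, composition and determinism", {
  anc <- generateAncestor(100000, 0.5, n_genes = 50, seed = 1)
  ann <- anc$annotations
  expect_equal(nrow(ann), 50)
  expect_true(all(ann$start >= 0 & ann$end <= 100000))
  o <- order(ann$start)
  expect_true(all(ann$start[o][-1] >= ann$end[o][-50]))

  gc_only <- generateAncestor(5000, 1.0, n_genes = 0, seed = 2)
  expect_true(grepl("^[GC]+$", gc_only$sequence))

  a1 <- generateAncestor(20000, 0.4, n_genes = 10, seed = 7)
  a2 <- generateAncestor(20000, 0.4, n_genes = 10, seed = 7)
  expect_identical(a1, a2)

  expect_error(generateAncestor(1000, 0.5, n_genes = 10, gene_length = 900),
               "packing")
})

test_that("derived strains record divergence exactly", {
  anc <- generateAncestor(100000, 0.5, n_genes = 40, seed = 3)
  a0 <- DefComTools:::.ancestorStrain(anc)

  s_same <- deriveStrain(a0, anc$sequence, 0, "Z", seed = 1)
  expect_identical(strainSequence(s_same, anc$sequence)$sequence,
                   anc$sequence)
  expect_equal(truePairANI(a0, s_same, anc$sequence), 100)

  s2 <- deriveStrain(a0, anc$sequence, 0.02, "Y", seed = 2)
  ani <- truePairANI(a0, s2, anc$sequence)
  ## binomial sd of the substitution count: sqrt(n p (1-p)) / n ~ 0.044 pp
  expect_true(abs(ani - 98) < 0.15)
  ## bookkeeping ANI equals Hamming identity on the actual sequences
  seq2 <- strainSequence(s2, anc$sequence)$sequence
  ham <- sum(strsplit(anc$sequence, "")[[1]] != strsplit(seq2, "")[[1]])
  expect_equal(ani, 100 * (1 - ham / nchar(anc$sequence)))
})

test_that("accessory gene deletion shifts coordinates consistently", {
  anc <- generateAncestor(20000, 0.5, n_genes = 10, seed = 4)
  a0 <- DefComTools:::.ancestorStrain(anc)
  g7 <- anc$annotations$gene_id[7]
  s <- deriveStrain(a0, anc$sequence, 0, "D", delete_genes = g7)
  mat <- strainSequence(s, anc$sequence)
  expect_false(g7 %in% mat$annotations$gene_id)
  glen <- anc$annotations$end[7] - anc$annotations$start[7]
  expect_equal(nchar(mat$sequence), 20000 - glen)
  ## genes after the deletion shift left by the gene length; sequence at
  ## each annotated gene is unchanged
  for (i in seq_len(nrow(mat$annotations))) {
    g <- mat$annotations[i, ]
    orig <- anc$annotations[anc$annotations$gene_id == g$gene_id, ]
    expect_identical(substr(mat$sequence, g$start + 1, g$end),
                     substr(anc$sequence, orig$start + 1, orig$end))
  }
  expect_error(deriveStrain(a0, anc$sequence, 0, "E",
                            delete_genes = "nope"), "absent")
})

test_that("buildCommunity realizes the configured lineage structure", {
  dc <- smallCommunity()
  gt <- groundTruth(dc)
  expect_equal(length(strainIds(dc)), 5)
  expect_equal(length(unique(gt$lineage_assignment)), 3)
  ## within >= 98.5, between <= 95 as configured
  ta <- gt$true_ani
  same <- outer(gt$lineage_assignment, gt$lineage_assignment, "==")
  off <- row(ta) != col(ta)
  expect_true(all(ta[same & off] >= 98.5))
  expect_true(all(ta[!same] <= 95))
  expect_setequal(gt$planted_enriched_kos, c("K90001", "K90002", "K90003"))
  ## planted genes sit in every member of the dominant lineages only
  ann <- annotations(dc)
  carriers <- unique(ann$strain_id[ann$ko %in% gt$planted_enriched_kos])
  expect_setequal(carriers, gt$dominant_strains)

  ## determinism
  dc2 <- buildCommunity(dc@config[setdiff(names(dc@config), "seed")],
                        seed = 42)
  expect_identical(as.character(genomes(dc2)), as.character(genomes(dc)))
  expect_identical(groundTruth(dc2), groundTruth(dc))

  ## infeasible thresholds error
  expect_error(buildCommunity(communityConfig(within_divergence = 0.05),
                              seed = 1), "cannot be realized")
})

test_that("read simulation respects provenance, depth and host fraction", {
  dc <- smallCommunity()
  design <- sampleDesign(2, 2)

  ## single dominant strain, no error: every read is a genome substring
  ce <- setNames(c(50, rep(-50, 4)), strainIds(dc))
  m1 <- abundanceModel(ce, depth = 500, host_read_fraction = 0,
                       error_rate = 0)
  sim <- simulateReads(dc, design[1, ], m1, seed = 5)
  rd <- sim$reads[[1]]
  expect_equal(length(rd), 500)
  prov <- parseReadNames(names(rd))
  expect_true(all(prov$strain == "S01"))
  g <- as.character(genomes(dc))[["S01"]]
  expect_true(all(as.character(rd) ==
                    sliceReads(g, prov$start, 150)))

  ## host fraction: binomial 99% band around 0.3 * 1000
  m2 <- defaultAbundanceModel(dc, depth = 1000, host_read_fraction = 0.3,
                              error_rate = 0)
  sim2 <- simulateReads(dc, design[1, ], m2, seed = 6)
  nh <- sum(parseReadNames(names(sim2$reads[[1]]))$strain == "host")
  band <- qbinom(c(0.005, 0.995), 1000, 0.3)
  expect_true(nh >= band[1] && nh <= band[2])

  ## empty design errors
  expect_error(simulateReads(dc, design[0, ], m1), "empty design")

  ## determinism: same seed, byte-identical reads
  sim3 <- simulateReads(dc, design[1, ], m2, seed = 6)
  expect_identical(as.character(sim2$reads[[1]]),
                   as.character(sim3$reads[[1]]))
})

test_that("compartment effects scale pre-normalization proportions as built", {
  dc <- smallCommunity()
  ce <- setNames(c(2, rep(0, 4)), strainIds(dc))
  model <- abundanceModel(ce, base_log_sd = 0, depth = 100)
  d <- sampleDesign(2, 2)
  p <- DefComTools:::.sampleProportions(model, d, strainIds(dc))
  endo <- d$compartment == "endosphere"
  ## with zero baseline noise, S01's endo odds are exactly 4x its rhizo odds
  odds <- p["S01", ] / (1 - p["S01", ])
  expect_equal(unique(round(odds[endo] / odds[!endo], 10)), 4)
})

test_that("simulated strain counts match true abundances (chi-square, aggregate)", {
  ## aggregate goodness-of-fit across 20 seeds must not reject at 0.01
  design <- sampleDesign(2, 2)[1, , drop = FALSE]
  ids <- sprintf("S%02d", 1:5)
  model <- abundanceModel(setNames(rep(0, 5), ids), depth = 5000)
  total_chi <- 0
  total_df <- 0
  for (seed in 1:20) {
    se <- simulateStrainCounts(design, model, strain_ids = ids,
                               seed = seed)
    obs <- SummarizedExperiment::assay(se)[, 1]
    exp_p <- S4Vectors::metadata(se)$true_abundance[, 1]
    total_chi <- total_chi + sum((obs - 5000 * exp_p)^2 / (5000 * exp_p))
    total_df <- total_df + (length(ids) - 1)
  }
  expect_gt(pchisq(total_chi, total_df, lower.tail = FALSE), 0.01)
})
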