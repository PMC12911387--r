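test_that("host filtering removes decoy reads and keeps community reads", {
  set.seed(4)
  decoy <- randSeq(20000)
  strain <- randSeq(20000)
  host_reads <- sliceReads(decoy, sample(0:19850, 50), 150)
  strain_reads <- sliceReads(strain, sample(0:19850, 50), 150)
  f <- filterHostReads(c(host_reads, strain_reads), decoy)
  expect_equal(f$n_removed, 50)
  expect_identical(unname(f$reads), strain_reads)
})

test_that("host removal count sits in the binomial 99% band", {
  dc <- smallCommunity()
  model <- defaultAbundanceModel(dc, depth = 1000,
                                 host_read_fraction = 0.3, error_rate = 0)
  sim <- simulateReads(dc, sampleDesign(2, 2)[1, ], model, seed = 9)
  f <- filterHostReads(sim$reads[[1]], dc@hostDecoy)
  band <- qbinom(c(0.005, 0.995), 1000, 0.3)
  expect_true(f$n_removed >= band[1] && f$n_removed <= band[2])
  ## and the removed reads are exactly the decoy-provenance ones
  kept <- parseReadNames(names(f$reads))
  expect_false(any(kept$strain == "host"))
})

test_that("tie semantics on a constructed two-strain shared segment", {
  set.seed(5)
  shared <- randSeq(6000)
  g1 <- paste0(randSeq(8000), shared, randSeq(8000))
  g2 <- paste0(randSeq(9000), shared, randSeq(7000))
  genomes <- Biostrings::DNAStringSet(c(SA = g1, SB = g2))
  ## reads tiled across g1, error-free
  starts <- seq(0, nchar(g1) - 150, by = 37)
  reads <- sliceReads(g1, starts, 150)
  names(reads) <- sprintf("r%04d", seq_along(reads))
  asg_u <- assignReads(reads, genomes, mode = "unique")
  asg_f <- assignReads(reads, genomes, mode = "fractional")
  ## a read ties iff it lies entirely within the shared segment
  inside <- starts >= 8000 & (starts + 150) <= 14000
  tied <- asg_u$per_read$n_best > 1
  expect_identical(tied, inside)
  expect_equal(asg_u$n_discarded_multi, sum(inside))
  ## unique mode: survivors all map to SA with weight 1
  expect_true(all(asg_u$assignments$strain == "SA"))
  expect_true(all(asg_u$assignments$weight == 1))
  ## fractional mode: tied reads get 0.5 to each strain, total conserved
  w_by_read <- tapply(asg_f$assignments$weight, asg_f$assignments$read, sum)
  expect_true(all(w_by_read == 1))
  tied_rows <- asg_f$assignments$read %in% which(inside)
  expect_true(all(asg_f$assignments$weight[tied_rows] == 0.5))
})

test_that("assignment recovers provenance and position on error-free reads", {
  dc <- smallCommunity()
  model <- defaultAbundanceModel(dc, depth = 2000,
                                 host_read_fraction = 0, error_rate = 0)
  sim <- simulateReads(dc, sampleDesign(2, 2)[1, ], model, seed = 10)
  asg <- assignReads(sim$reads[[1]], dc, mode = "unique")
  prov <- parseReadNames(asg$assignments$read_name)
  expect_true(all(asg$assignments$strain == prov$strain))
  expect_true(all(asg$assignments$start == prov$start))
  expect_error(assignReads("ACGT", dc), "shorter than k")
})

test_that("strain counts sum assignment weights; modes agree for isolated strains", {
  dc <- smallCommunity()
  design <- sampleDesign(2, 2)
  model <- defaultAbundanceModel(dc, depth = 2000,
                                 host_read_fraction = 0, error_rate = 0)
  sim <- simulateReads(dc, design, model, seed = 11)
  asg_u <- lapply(sim$reads, assignReads, dc, mode = "unique")
  asg_f <- lapply(sim$reads, assignReads, dc, mode = "fractional")
  se_u <- countMatrix(asg_u, "strain", dc, design)
  se_f <- countMatrix(asg_f, "strain", dc, design)
  cu <- SummarizedExperiment::assay(se_u)
  cf <- SummarizedExperiment::assay(se_f)
  ## conservation: fractional totals equal assigned reads per sample
  for (s in design$sample_id) {
    n_assigned <- length(unique(asg_f[[s]]$assignments$read))
    expect_equal(sum(cf[, s]), n_assigned)
    expect_true(sum(cu[, s]) <= n_assigned)
  }
  ## lineage singletons (no close relative): modes agree within 1%
  gt <- groundTruth(dc)
  sizes <- table(gt$lineage_assignment)
  singletons <- names(gt$lineage_assignment)[
    gt$lineage_assignment %in% names(sizes)[sizes == 1]]
  for (s in singletons)
    expect_lt(max(abs(cu[s, ] - cf[s, ]) / pmax(cf[s, ], 1)), 0.01)
  ## strains in a >=99% ANI lineage are depressed under unique counting
  multi <- setdiff(strainIds(dc), singletons)
  expect_true(all(colSums(cu[multi, , drop = FALSE]) <
                    colSums(cf[multi, , drop = FALSE])))
})

test_that("gene counting applies the largest-overlap rule", {
  ## two adjacent genes: a read overlapping g1 by 80 bp and g2 by 20 bp
  ## counts to g1; a perfectly split read is dropped and logged
  g <- randSeq(1000)
  dc <- new("DefCom",
    genomes = Biostrings::DNAStringSet(c(S1 = g)),
    annotations = data.frame(
      gene_id = c("g1", "g2"), strain_id = "S1",
      start = c(100L, 250L), end = c(250L, 400L), strand = "+",
      ko = NA_character_, cog = NA_character_,
      orthogroup = c("OG1", "OG2"), anc_start = NA_integer_,
      anc_end = NA_integer_),
    ancestor = "", bookkeeping = list(), groundTruth = list(),
    hostDecoy = "", config = list())
  asg <- structure(list(assignments = data.frame(
    read = 1:3, read_name = c("a", "b", "c"), strain = "S1",
    start = c(170L, 200L, 500L), width = 100L, weight = 1,
    stringsAsFactors = FALSE), mode = "unique"),
    class = "AssignmentResult")
  se <- countMatrix(list(sm = asg), "gene", dc,
                    design = NULL)
  cts <- SummarizedExperiment::assay(se)
  expect_equal(unname(cts["g1", "sm"]), 1)  # read a: 80 vs 20 bp overlap
  expect_equal(unname(cts["g2", "sm"]), 0)
  expect_equal(unname(S4Vectors::metadata(se)$gene_tie_discards[["sm"]]), 1)
  ## gene-level counts never exceed strain-level counts
  se_s <- countMatrix(list(sm = asg), "strain", dc, design = NULL)
  expect_lte(sum(cts), SummarizedExperiment::assay(se_s)["S1", "sm"])
})

test_that("orthogroup aggregation sums, per-copy divides, zeros retained", {
  counts <- matrix(c(3, 4, 0, 5), 4, 1,
                   dimnames = list(c("g1", "g2", "g3", "g4"), "s1"))
  ann <- S4Vectors::DataFrame(
    orthogroup = c("OG1", "OG1", "OG2", "OG3"),
    strain_id = c("A", "B", "A", "B"),
    row.names = rownames(counts))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowData = ann)
  og <- aggregateOrthogroups(se)
  m <- SummarizedExperiment::assay(og)
  expect_equal(unname(m[, 1]), c(7, 0, 5))  # OG2 all-zero row retained
  expect_equal(sum(m), sum(counts))          # conservation
  og_pc <- aggregateOrthogroups(se, per_copy = TRUE)
  expect_equal(unname(SummarizedExperiment::assay(og_pc)["OG1", 1]), 3.5)

  bad <- se
  SummarizedExperiment::rowData(bad)$orthogroup[2] <- NA
  expect_error(aggregateOrthogroups(bad), "unannotated gene")
})

test_that("CPM normalization and TMM factors behave canonically", {
  m <- matrix(c(10, 90, 20, 180), 2, 2,
              dimnames = list(c("f1", "f2"), c("s1", "s2")))
  cpm <- cpmNormalize(m)
  expect_equal(unname(colSums(cpm)), c(1e6, 1e6))
  expect_equal(unname(cpm["f1", "s1"]), 1e5)
  expect_error(cpmNormalize(cbind(m, s3 = c(0, 0))), "s3")

  set.seed(6)
  base <- rpois(200, 50)
  mm <- cbind(a = base, b = base, c = 2L * base)
  f <- tmmFactors(mm)
  ## pure depth differences normalize out; geometric mean is 1
  expect_equal(unname(f), rep(1, 3), tolerance = 1e-6)
  expect_equal(prod(f)^(1 / 3), 1, tolerance = 1e-12)
  expect_error(tmmFactors(mm[, 1, drop = FALSE]), "2 samples")
})
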