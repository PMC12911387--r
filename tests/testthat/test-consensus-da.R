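test_that("median-of-ratios size factors recover scalar multiples", {
  set.seed(20)
  base <- rpois(100, 50) + 1
  m <- cbind(a = base, b = 3L * base, c = 2L * base)
  sf <- sizeFactorsMoR(m)
  expect_equal(unname(sf["b"] / sf["a"]), 3, tolerance = 1e-12)
  expect_equal(unname(sf["c"] / sf["a"]), 2, tolerance = 1e-12)
  expect_error(sizeFactorsMoR(matrix(c(0, 1, 1, 0), 2, 2)),
               "no feature without zeros")
})

test_that("NB Wald reduces to the Poisson GLM in the zero-dispersion limit", {
  set.seed(21)
  design <- sampleDesign(4, 4)
  X <- makeDesignMatrix(design)
  counts <- matrix(rpois(30 * 8, 50), 30, 8,
                   dimnames = list(sprintf("f%02d", 1:30),
                                   design$sample_id))
  r <- nbWaldDA(counts, X, dispersion = 0)
  sf <- sizeFactorsMoR(counts)
  idx <- which(colnames(X) == "compartmentendosphere")
  for (f in c(1, 15, 30)) {
    g <- glm(counts[f, ] ~ 0 + X + offset(log(sf)), family = poisson())
    expect_equal(r$log2fc[f] * log(2), unname(coef(g)[idx]),
                 tolerance = 1e-6)
    z <- summary(g)$coefficients[idx, "z value"]
    expect_equal(r$p[f], 2 * pnorm(-abs(z)), tolerance = 1e-5)
  }
  expect_error(nbWaldDA(counts + 0.5, X), "integer")
})

test_that("all-zero features get the p = 1 convention", {
  set.seed(22)
  design <- sampleDesign(3, 3)
  X <- makeDesignMatrix(design)
  counts <- matrix(rpois(20 * 6, 40), 20, 6,
                   dimnames = list(sprintf("f%02d", 1:20),
                                   design$sample_id))
  counts[5, ] <- 0L
  r <- nbWaldDA(counts, X)
  expect_equal(r$p[5], 1)
  expect_equal(r$log2fc[5], 0)
  expect_equal(r$note[5], "all_zero")
})

test_that("voomDA shares the strain-enrichment code path and handles per-copy input", {
  set.seed(23)
  design <- sampleDesign(4, 4)
  ids <- sprintf("S%02d", 1:12)
  model <- abundanceModel(setNames(c(2, 2, rep(0, 10)), ids),
                          depth = 20000)
  se <- simulateStrainCounts(design, model, seed = 24)
  X <- makeDesignMatrix(design)
  et <- strainEnrichment(se)
  da <- voomDA(SummarizedExperiment::assay(se), X)
  expect_equal(da$log2fc, et$log2fc, tolerance = 1e-12)
  expect_equal(da$p, et$p, tolerance = 1e-12)
  ## per-copy (non-integer) counts are rounded with a message
  expect_message(voomDA(SummarizedExperiment::assay(se) / 2, X),
                 "rounded")
})

test_that("CSS scales and the degenerate (no-zero) ZIG path", {
  set.seed(25)
  design <- sampleDesign(3, 3)
  X <- makeDesignMatrix(design)
  counts <- matrix(rpois(40 * 6, 100) + 1L, 40, 6,
                   dimnames = list(sprintf("f%02d", 1:40),
                                   design$sample_id))
  counts[, 2] <- counts[, 1]  # two identical samples
  sc <- DefComTools:::.cssScales(counts, 0.5)
  expect_equal(unname(sc[1]), unname(sc[2]))
  ## no zeros: reduces to CSS + moderated t with unit weights
  r <- cssZigDA(counts, X)
  expect_true(all(attr(r, "zero_posterior") == 0))
  y <- log2(sweep(counts, 2, sc, "/") * 1000 + 1)
  ref <- moderatedFit(y, NULL, X)
  expect_equal(r$p, ref$p, tolerance = 1e-12)
  expect_error(cssZigDA(matrix(0:8, 3, 3), X[1:3, ]), "nonzero")
})

test_that("the zero-inflation EM separates structural from sampling zeros", {
  set.seed(26)
  design <- sampleDesign(8, 8)
  X <- makeDesignMatrix(design)
  n_feat <- 150
  mu <- rlnorm(n_feat, log(80), 0.6)
  counts <- matrix(rpois(n_feat * 16, rep(mu, 16)), n_feat, 16,
                   dimnames = list(sprintf("f%03d", 1:n_feat),
                                   design$sample_id))
  ## plant structural zeros: 30% of cells in 50 features forced to zero
  struct <- matrix(FALSE, n_feat, 16)
  hot <- sample(n_feat, 50)
  for (f in hot) struct[f, sample(16, 5)] <- TRUE
  counts[struct] <- 0L
  r <- cssZigDA(counts, X)
  post <- attr(r, "zero_posterior")
  zero <- counts == 0
  truth <- struct[zero]
  pred <- post[zero] > 0.5
  acc <- mean(pred == truth)
  expect_gte(acc, 0.8)
})

test_that("consensus requires joint significance and direction agreement", {
  mk <- function(q, fc) {
    r <- data.frame(feature = c("f1", "f2", "f3", "f4"),
                    log2fc = fc, p = q, q = q, significant = q < 0.05)
    attr(r, "method") <- "m"
    r
  }
  r1 <- mk(c(0.01, 0.01, 0.01, 0.2), c(1, 1, 1, 1))
  r2 <- mk(c(0.01, 0.20, 0.01, 0.01), c(1, 1, -1, 1))
  r3 <- mk(c(0.01, 0.01, 0.01, 0.01), c(1, 1, 1, 1))
  cons <- consensusDA(list(r1, r2, r3))
  expect_equal(cons$features, "f1")     # f2: 2/3; f3: sign flip; f4: 2/3
  ## consensus is a subset of every method's significant set
  for (r in list(r1, r2, r3))
    expect_true(all(cons$features %in% r$feature[r$significant]))
  ## direction filter
  cons_rhizo <- consensusDA(list(r1, r2, r3), direction = "rhizosphere")
  expect_length(cons_rhizo$features, 0)
  expect_error(consensusDA(list(r1, r2, mk(c(1, 1, 1, 1), 1:4)[1:3, ])),
               "universes")
})

test_that("per-host analysis separates host-specific from shared effects", {
  set.seed(27)
  design <- sampleDesign(8, 8)
  hosts <- unique(design$host)
  n_feat <- 120
  base <- rlnorm(n_feat, log(100), 0.5)
  counts <- matrix(0L, n_feat, 16,
                   dimnames = list(sprintf("f%03d", 1:n_feat),
                                   design$sample_id))
  ## f001 enriched in host A endosphere only; f002 in both hosts
  for (j in seq_len(16)) {
    mu <- base
    endo <- design$compartment[j] == "endosphere"
    if (endo && design$host[j] == hosts[1]) mu[1] <- mu[1] * 8
    if (endo) mu[2] <- mu[2] * 8
    counts[, j] <- rnbinom(n_feat, mu = mu, size = 12)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(design, row.names = design$sample_id))
  ph <- perHostEnrichment(se)
  expect_true("f001" %in% ph$enriched[[hosts[1]]])
  expect_false("f001" %in% ph$enriched[[hosts[2]]])
  expect_false("f001" %in% ph$shared)
  expect_true("f002" %in% ph$shared)
  ## UpSet cardinalities partition the union
  expect_equal(sum(ph$upset),
               length(union(ph$enriched[[1]], ph$enriched[[2]])))
})

test_that("framework intersection is a subset of the lineage KO set", {
  og2ko <- c(OG1 = "K1", OG2 = "K2", OG3 = NA, OG4 = "K4")
  expect_setequal(intersectFrameworks(c("OG1", "OG3"), og2ko,
                                      c("K1", "K9")), "K1")
  expect_length(intersectFrameworks(c("OG2"), og2ko, c("K1")), 0)
  out <- intersectFrameworks(names(og2ko), og2ko, c("K1", "K4"))
  expect_true(all(out %in% c("K1", "K4")))
})
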