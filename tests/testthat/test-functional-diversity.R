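test_that("alpha diversity closed forms", {
  cpm <- cbind(u = rep(2e5, 5), single = c(1e6, 0, 0, 0, 0))
  rownames(cpm) <- sprintf("f%d", 1:5)
  ad <- alphaDiversity(cpm)
  expect_equal(ad$richness, c(5L, 1L))
  expect_equal(ad$shannon, c(log(5), 0))
  ## invariant to feature order
  ad2 <- alphaDiversity(cpm[5:1, ])
  expect_equal(ad2$shannon, ad$shannon)
})

test_that("group comparison: exact Wilcoxon and ANOVA behave", {
  v <- c(1, 2, 3, 10, 11, 12)
  g <- rep(c("a", "b"), each = 3)
  res <- compareAlpha(v, g)
  expect_equal(res$wilcoxon_p, 0.1)  # extreme ranking, 2/20 splits
  expect_lt(res$anova_p, 0.01)
  expect_error(compareAlpha(1:3, c("a", "a", "b")), "at least 2")
})

test_that("null p-values of both alpha tests are approximately uniform", {
  set.seed(15)
  wp <- ap <- numeric(200)
  g <- rep(c("a", "b"), c(10, 10))
  for (i in 1:200) {
    v <- rnorm(20)
    r <- compareAlpha(v, g)
    wp[i] <- r$wilcoxon_p
    ap[i] <- r$anova_p
  }
  expect_gt(suppressWarnings(ks.test(wp, "punif"))$p.value, 0.01)
  expect_gt(ks.test(ap, "punif")$p.value, 0.01)
})

test_that("Bray-Curtis formula and bounds", {
  m <- cbind(x = c(2, 1), y = c(1, 1), z = c(2, 1))
  rownames(m) <- c("f1", "f2")
  d <- brayCurtis(m)
  expect_equal(d["x", "y"], 0.2)
  expect_equal(d["x", "z"], 0)
  disj <- cbind(a = c(5, 0), b = c(0, 7))
  expect_equal(brayCurtis(disj)["a", "b"], 1)
  expect_true(all(diag(d) == 0))
  expect_equal(d, t(d))
  expect_error(brayCurtis(cbind(a = c(0, 0), b = c(0, 0))), "all-zero")
})

test_that("NMDS recovers an embeddable configuration and planted clusters", {
  set.seed(16)
  pts <- matrix(rnorm(20), 10, 2)
  d <- as.matrix(dist(pts))
  fit <- nmdsOrdination(d, n_starts = 5, seed = 1)
  expect_lt(fit$stress, 0.01)
  ## the best-of-starts stress is no worse than a single default start
  one <- nmdsOrdination(d, n_starts = 1, seed = 1)
  expect_lte(fit$stress, one$stress + 1e-12)

  ## two planted abundance clusters separate in the ordination
  base <- rep(c(100, 5), each = 10)
  cpm <- sapply(1:12, function(i) {
    prof <- if (i <= 6) base else rev(base)
    x <- rpois(20, prof) + 0.5
    x / sum(x) * 1e6
  })
  rownames(cpm) <- sprintf("f%02d", 1:20)
  colnames(cpm) <- sprintf("s%02d", 1:12)
  f2 <- nmdsOrdination(brayCurtis(cpm), n_starts = 5, seed = 2)
  lab <- rep(c(1, 2), each = 6)
  ## silhouette of the known labels on the coordinates
  dd <- as.matrix(dist(f2$points))
  sil <- vapply(1:12, function(i) {
    a <- mean(dd[i, lab == lab[i]][-which(which(lab == lab[i]) == i)])
    b <- mean(dd[i, lab != lab[i]])
    (b - a) / max(a, b)
  }, 0)
  expect_gt(mean(sil), 0.5)
})

test_that("PERMANOVA matches vegan and partitions variance additively", {
  set.seed(17)
  design <- sampleDesign(6, 6)
  cpm <- matrix(rpois(40 * 12, 60), 40, 12,
                dimnames = list(sprintf("f%02d", 1:40), design$sample_id))
  cpm <- cpmNormalize(cpm)
  d <- brayCurtis(cpm)
  pm <- permanova(d, design, c("compartment", "host"), n_perm = 199,
                  seed = 3)
  expect_equal(sum(pm$R2[pm$term != "Total"]), 1, tolerance = 1e-9)
  ## R2 invariant to scaling the distance matrix
  pm2 <- permanova(2 * d, design, c("compartment", "host"),
                   n_perm = 199, seed = 3)
  expect_equal(pm2$R2, pm$R2, tolerance = 1e-9)
  ## cross-check SS / R2 / F against vegan::adonis2
  ad <- vegan::adonis2(as.dist(d) ~ compartment + host,
                       data = design, permutations = 99, by = "terms")
  expect_equal(pm$SS[1:2], ad$SumOfSqs[1:2], tolerance = 1e-8)
  expect_equal(pm$R2[1:2], ad$R2[1:2], tolerance = 1e-8)
  expect_equal(pm$F[1:2], ad$F[1:2], tolerance = 1e-8)
})

test_that("exhaustive PERMANOVA p equals a brute-force enumeration", {
  set.seed(18)
  ## n = 6, one factor: independent oracle via within-group distance sums
  g <- rep(c("a", "b"), each = 3)
  x <- matrix(rnorm(6 * 4), 6, 4)
  d <- as.matrix(dist(x))
  oracleF <- function(d2, lab) {
    n <- nrow(d2)
    sst <- sum(d2[upper.tri(d2)]) / n
    ssw <- 0
    for (lv in unique(lab)) {
      idx <- which(lab == lv)
      ssw <- ssw + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
    }
    ((sst - ssw) / 1) / (ssw / (n - 2))
  }
  d2 <- d^2
  perms <- DefComTools:::.allPermutations(6)
  Fobs <- oracleF(d2, g)
  Fall <- vapply(perms, function(p) oracleF(d2, g[p]), 0)
  p_oracle <- mean(Fall >= Fobs - 1e-12)
  pm <- permanova(d, data.frame(grp = g), "grp", exhaustive = TRUE)
  expect_equal(pm$p[1], p_oracle)
  expect_equal(pm$F[1], Fobs, tolerance = 1e-10)
})

test_that("PERMANOVA null rejection rate is calibrated", {
  set.seed(19)
  rej <- 0
  g <- rep(c("a", "b"), each = 6)
  for (i in 1:200) {
    x <- matrix(rnorm(12 * 5), 12, 5)
    d <- as.matrix(dist(x))
    pm <- permanova(d, data.frame(grp = sample(g)), "grp", n_perm = 199)
    rej <- rej + (pm$p[1] <= 0.05)
  }
  expect_gte(rej / 200, 0.03)
  expect_lte(rej / 200, 0.08)
})

test_that("confounded terms are rejected", {
  design <- data.frame(a = rep(c("x", "y"), each = 3),
                       b = rep(c("x", "y"), each = 3))
  d <- as.matrix(dist(matrix(rnorm(12), 6, 2)))
  expect_error(permanova(d, design[, "a", drop = FALSE],
                         c("a"), n_perm = 99, seed = 1), NA)
  one_per_cell <- data.frame(a = letters[1:6])
  expect_error(permanova(d, one_per_cell, "a", n_perm = 99),
               "confounded|zero residual")
})
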