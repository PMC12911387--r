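## Three differential-abundance procedures on orthogroup counts and
## their FDR consensus.  The three methods are deliberately lightweight
## reimplementations of the three standard modelling families for
## microbiome count data -- median-of-ratios + negative-binomial Wald,
## voom + moderated t, and CSS normalization + zero-inflation-weighted
## moderated t.  The contract is distributional (type-I error control,
## power ordering), not numerical identity with any specific package.

#' Median-of-ratios size factors
#'
#' Per-feature geometric means across samples form the pseudo-reference;
#' a sample's size factor is the median of its ratios to the reference
#' over features with no zero count.
#'
#' @param counts integer count matrix.
#' @return named numeric vector of size factors.
#' @export
sizeFactorsMoR <- function(counts) {
  nz <- rowSums(counts == 0) == 0
  if (!any(nz))
    stop("no feature without zeros; cannot compute median-of-ratios")
  logg <- rowMeans(log(counts[nz, , drop = FALSE]))
  sf <- apply(counts[nz, , drop = FALSE], 2, function(x)
    exp(median(log(x) - logg)))
  setNames(sf, colnames(counts))
}

## NB GLM by IRLS with log link and offsets; returns contrast Wald parts
.nbGlmWald <- function(y, X, offset, dispersion, contrast,
                       max_iter = 25, tol = 1e-8) {
  beta <- qr.coef(qr(X), log((y + 0.5) / exp(offset)))
  beta[is.na(beta)] <- 0
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta) + offset
    eta <- pmin(eta, 30)
    mu <- exp(eta)
    W <- mu / (1 + dispersion * mu)
    z <- (eta - offset) + (y - mu) / mu
    fit <- lm.wfit(X, z, W)
    new_beta <- fit$coefficients
    new_beta[is.na(new_beta)] <- 0
    if (max(abs(new_beta - beta)) < tol) { beta <- new_beta; break }
    beta <- new_beta
  }
  eta <- pmin(drop(X %*% beta) + offset, 30)
  mu <- exp(eta)
  W <- mu / (1 + dispersion * mu)
  XtWX <- crossprod(X * W, X)
  cov_beta <- tryCatch(chol2inv(chol(XtWX)), error = function(e) NULL)
  if (is.null(cov_beta)) return(c(est = NA, se = NA))
  c(est = sum(contrast * beta),
    se = sqrt(drop(t(contrast) %*% cov_beta %*% contrast)))
}

#' Negative-binomial Wald differential abundance
#'
#' Raw integer counts; size factors by median-of-ratios; per-feature
#' method-of-moments dispersions shrunk toward a lowess mean-dispersion
#' trend (`shrink_weight` on the trend); NB GLM by IRLS with log link
#' and log size-factor offsets; Wald z test on the contrast; BH
#' q-values.  All-zero features get `p = 1` and are flagged in the
#' `note` column.
#'
#' @param x integer counts (`SummarizedExperiment` or matrix).
#' @param design_matrix design matrix with a `"contrast"` attribute, or
#'   pass `contrast`.
#' @param contrast numeric contrast vector.
#' @param shrink_weight weight on the dispersion trend in `[0, 1]`.
#' @param alpha FDR level.
#' @param dispersion optional fixed dispersion (overrides estimation;
#'   `0` gives the Poisson GLM limit).
#' @return `data.frame` with `feature`, `log2fc`, `p`, `q`,
#'   `significant`, `note`, and attribute `method = "nb_wald"`.
#' @export
nbWaldDA <- function(x, design_matrix, contrast = NULL,
                     shrink_weight = 0.5, alpha = 0.05,
                     dispersion = NULL) {
  counts <- .countsOf(x)
  if (any(counts != round(counts)))
    stop("nbWaldDA requires integer counts")
  X <- design_matrix
  if (is.null(contrast)) contrast <- attr(X, "contrast")
  stopifnot(length(contrast) == ncol(X))
  sf <- sizeFactorsMoR(counts)
  offset <- log(sf)
  norm <- sweep(counts, 2, sf, "/")
  mu_bar <- rowMeans(norm)
  all_zero <- rowSums(counts) == 0
  if (is.null(dispersion)) {
    v <- apply(norm, 1, var)
    disp_raw <- pmax((v - mu_bar) / mu_bar^2, 1e-8)
    ok <- mu_bar > 0
    lo <- lowess(log(mu_bar[ok]), log(disp_raw[ok]), f = 0.5)
    disp_trend <- rep(median(disp_raw[ok]), length(mu_bar))
    disp_trend[ok] <- exp(approx(lo$x, lo$y, xout = log(mu_bar[ok]),
                                 rule = 2, ties = mean)$y)
    disp <- pmax((1 - shrink_weight) * disp_raw +
                 shrink_weight * disp_trend, 1e-8)
  } else {
    disp <- rep(max(dispersion, 0), nrow(counts))
  }
  est <- se <- rep(NA_real_, nrow(counts))
  for (f in which(!all_zero)) {
    w <- .nbGlmWald(counts[f, ], X, offset, disp[f], contrast)
    est[f] <- w["est"]; se[f] <- w["se"]
  }
  z <- est / se
  p <- 2 * pnorm(-abs(z))
  p[all_zero | is.na(p)] <- 1
  est[all_zero] <- 0
  q <- p.adjust(p, method = "BH")
  res <- data.frame(
    feature = rownames(counts), log2fc = est / log(2), p = p, q = q,
    significant = q < alpha,
    note = ifelse(all_zero, "all_zero", ""),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(res, "method") <- "nb_wald"
  res
}

#' Voom + moderated t differential abundance
#'
#' TMM factors, voom transformation and moderated t on the contrast --
#' the same code path as [strainEnrichment()], applied to orthogroup
#' counts.  Non-integer input (per-copy normalized counts) is rounded
#' to pseudo-counts first, with a message.
#'
#' @inheritParams nbWaldDA
#' @param factors optional per-sample scale factors.
#' @return `data.frame` with attribute `method = "voom_mod_t"`.
#' @export
voomDA <- function(x, design_matrix, contrast = NULL, factors = NULL,
                   alpha = 0.05) {
  counts <- .countsOf(x)
  if (any(counts != round(counts))) {
    message("non-integer counts rounded to pseudo-counts for voom")
    counts <- round(counts)
  }
  v <- voomTransform(counts, design_matrix, factors = factors)
  res <- moderatedFit(v$logcpm, v$weights, design_matrix,
                      contrast = contrast, alpha = alpha)
  res <- res[, c("feature", "log2fc", "p", "q", "significant")]
  attr(res, "method") <- "voom_mod_t"
  res
}

## cumulative-sum-scaling scale per sample: sum of counts at or below
## the css_quantile of that sample's nonzero counts
.cssScales <- function(counts, css_quantile) {
  apply(counts, 2, function(x) {
    nz <- x[x > 0]
    if (length(nz) < 10)
      stop("sample with fewer than 10 nonzero features; CSS unstable")
    sum(x[x <= quantile(nz, css_quantile)])
  })
}

#' CSS normalization + zero-inflation-weighted moderated t
#'
#' Counts are scaled by each sample's cumulative sum up to the
#' `css_quantile` of its nonzero counts and transformed as
#' `log2(count / scale * 1000 + 1)`.  A two-component EM (point mass at
#' zero whose mixing weight depends logistically on log library size,
#' versus a per-feature Gaussian) estimates the posterior probability
#' that each observed zero is structural; observation weights are 1 for
#' nonzero entries and one minus that posterior for zeros.  The
#' weighted moderated-t machinery of [moderatedFit()] then tests the
#' contrast.  If the EM does not converge within `max_iter_em`, weights
#' fall back to 1 with a warning.
#'
#' @inheritParams nbWaldDA
#' @param css_quantile CSS quantile (default 0.5).
#' @param max_iter_em,tol_em EM iteration cap and log-likelihood
#'   tolerance.
#' @return `data.frame` with attribute `method = "css_zig"`; the EM
#'   posterior matrix is attached as attribute `zero_posterior`.
#' @export
cssZigDA <- function(x, design_matrix, contrast = NULL,
                     css_quantile = 0.5, alpha = 0.05,
                     max_iter_em = 100, tol_em = 1e-6) {
  counts <- .countsOf(x)
  if (any(counts < 0)) stop("counts must be non-negative")
  scales <- .cssScales(counts, css_quantile)
  y <- log2(sweep(counts, 2, scales, "/") * 1000 + 1)
  zero <- counts == 0
  w <- matrix(1, nrow(y), ncol(y), dimnames = dimnames(y))
  post <- matrix(0, nrow(y), ncol(y), dimnames = dimnames(y))
  if (any(zero)) {
    loglib <- log(colSums(counts))
    loglib_m <- matrix(loglib, nrow(y), ncol(y), byrow = TRUE)
    pz <- matrix(0.5, nrow(y), ncol(y))  # posterior structural | zero
    ll_old <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter_em)) {
      ## M step: Gaussian component from nonzeros plus sampling zeros
      wobs <- ifelse(zero, 1 - pz, 1)
      mu_f <- rowSums(wobs * y) / rowSums(wobs)
      resid <- y - mu_f
      sigma <- sqrt(sum(wobs * resid^2) / sum(wobs))
      sigma <- max(sigma, 1e-3)
      ## logistic mixing weight on log library size
      zr <- as.vector(pz[zero])
      ll_cov <- cbind(1, as.vector(loglib_m[zero]))
      cf <- tryCatch(
        suppressWarnings(glm.fit(ll_cov, zr,
                                 family = binomial())$coefficients),
        error = function(e) c(0, 0))
      cf[is.na(cf)] <- 0
      pi_z <- plogis(drop(ll_cov %*% cf))
      ## E step
      dens <- dnorm(0, mean = mu_f[row(y)[zero]], sd = sigma)
      pz_new <- pi_z / (pi_z + (1 - pi_z) * dens)
      pz[zero] <- pz_new
      ll <- sum(log(pi_z + (1 - pi_z) * dens)) +
        sum(dnorm(y[!zero], mu_f[row(y)[!zero]], sigma, log = TRUE))
      if (is.finite(ll) && abs(ll - ll_old) < tol_em) {
        converged <- TRUE
        break
      }
      ll_old <- ll
    }
    if (!converged) {
      warning("zero-inflation EM did not converge; using unit weights")
      pz[] <- 0
    }
    post <- pz * zero
    w <- ifelse(zero, 1 - post, 1)
    w <- pmax(w, 1e-6)
  }
  res <- moderatedFit(y, w, design_matrix, contrast = contrast,
                      alpha = alpha)
  res <- res[, c("feature", "log2fc", "p", "q", "significant")]
  attr(res, "method") <- "css_zig"
  attr(res, "zero_posterior") <- post
  res
}

#' Consensus of three differential-abundance results
#'
#' A feature is in the consensus set iff its q-value is below `alpha`
#' in all supplied methods, the sign of its log2 fold change agrees
#' across methods (when `require_direction`), and matches the requested
#' direction (endosphere-enriched = positive).
#'
#' @param results list of DA `data.frame`s over the same feature
#'   universe.
#' @param alpha FDR level.
#' @param direction `"endosphere"` (positive log2fc), `"rhizosphere"`
#'   (negative) or `"any"`.
#' @param require_direction require sign agreement across methods.
#' @return list with `features` (the consensus set), `table` (per
#'   feature per-method flags) -- the consensus is always a subset of
#'   each method's significant set.
#' @export
consensusDA <- function(results, alpha = 0.05,
                        direction = c("endosphere", "rhizosphere", "any"),
                        require_direction = TRUE) {
  direction <- match.arg(direction)
  feats <- results[[1]]$feature
  for (r in results[-1])
    if (!identical(sort(r$feature), sort(feats)))
      stop("feature universes differ between methods")
  sig <- sapply(results, function(r)
    r$q[match(feats, r$feature)] < alpha)
  fc <- sapply(results, function(r) r$log2fc[match(feats, r$feature)])
  all_sig <- rowSums(sig, na.rm = FALSE) == length(results)
  all_sig[is.na(all_sig)] <- FALSE
  same_sign <- apply(sign(fc), 1, function(s)
    all(s == s[1]) && all(s != 0))
  dir_ok <- switch(direction,
    endosphere = rowSums(fc > 0) == length(results),
    rhizosphere = rowSums(fc < 0) == length(results),
    any = rep(TRUE, length(feats)))
  in_set <- all_sig & dir_ok & (!require_direction | same_sign)
  methods <- vapply(results, function(r)
    if (!is.null(attr(r, "method"))) attr(r, "method") else "method", "")
  colnames(sig) <- make.unique(paste0("sig_", methods))
  tab <- data.frame(feature = feats, sig, consensus = in_set,
                    row.names = NULL, check.names = FALSE)
  list(features = feats[in_set], table = tab, alpha = alpha,
       direction = direction)
}

#' Per-host enrichment with set intersections
#'
#' Runs the voom differential-abundance path separately within each
#' host (endosphere vs rhizosphere), returns per-host significant
#' endosphere-enriched sets, their intersection, UpSet-style disjoint
#' intersection cardinalities, and presence/absence detection sets per
#' host x compartment (a feature is detected iff CPM > 0 in at least
#' `min_detect` samples of the cell).
#'
#' @param x counts (`SummarizedExperiment` with `host`, `compartment`
#'   in `colData`).
#' @param design design data.frame if `x` is a bare matrix.
#' @param alpha FDR level.
#' @param min_detect samples with CPM > 0 required for detection.
#' @return list with `per_host` (named list of per-host DA tables),
#'   `enriched` (named list of per-host enriched feature sets),
#'   `shared` (intersection), `upset` (disjoint cardinalities),
#'   `detected` (per host x compartment feature sets).
#' @export
perHostEnrichment <- function(x, design = NULL, alpha = 0.05,
                              min_detect = 1) {
  if (is(x, "SummarizedExperiment")) {
    design <- as.data.frame(colData(x))
    counts <- assay(x, "counts")
  } else counts <- as.matrix(x)
  hosts <- unique(design$host)
  if (length(hosts) != 2) stop("exactly two hosts required")
  cells <- table(design$host, design$compartment)
  if (any(cells < 2))
    stop("every host x compartment cell needs >= 2 replicates")
  per_host <- enriched <- list()
  for (h in hosts) {
    idx <- design$host == h
    Xh <- makeDesignMatrix(design[idx, , drop = FALSE])
    res <- voomDA(counts[, idx, drop = FALSE], Xh, alpha = alpha)
    per_host[[h]] <- res
    enriched[[h]] <- res$feature[res$significant & res$log2fc > 0]
  }
  both <- intersect(enriched[[1]], enriched[[2]])
  only1 <- setdiff(enriched[[1]], enriched[[2]])
  only2 <- setdiff(enriched[[2]], enriched[[1]])
  upset <- setNames(c(length(only1), length(only2), length(both)),
                    c(paste0(hosts[1], "_only"),
                      paste0(hosts[2], "_only"), "shared"))
  cpm <- cpmNormalize(counts)
  detected <- list()
  for (h in hosts) for (cp in unique(design$compartment)) {
    idx <- design$host == h & design$compartment == cp
    detected[[paste(h, cp, sep = ".")]] <-
      rownames(cpm)[rowSums(cpm[, idx, drop = FALSE] > 0) >= min_detect]
  }
  list(per_host = per_host, enriched = enriched, shared = both,
       upset = upset, detected = detected)
}

#' Intersect orthogroup-level consensus with lineage-level KO enrichment
#'
#' KOs that annotate at least one consensus orthogroup and are in the
#' lineage-level enriched KO set.
#'
#' @param consensus_features character vector of consensus orthogroups.
#' @param og_to_ko named character map orthogroup -> KO (NA allowed).
#' @param lineage_kos character vector of lineage-enriched KOs.
#' @return character vector of KOs (subset of `lineage_kos`).
#' @export
intersectFrameworks <- function(consensus_features, og_to_ko,
                                lineage_kos) {
  kos <- og_to_ko[intersect(consensus_features, names(og_to_ko))]
  kos <- unique(kos[!is.na(kos)])
  intersect(kos, lineage_kos)
}
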