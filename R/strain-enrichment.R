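## Voom-style precision weights, empirical-Bayes moderated t statistics,
## and colonization-strategy classification.

#' Design matrix for compartment/host contrasts
#'
#' Treatment-coded design with rhizosphere and the first host as
#' reference levels, so the compartment coefficient is endosphere minus
#' rhizosphere (positive = endosphere enrichment).
#'
#' @param design [sampleDesign()] table (or `colData` data.frame).
#' @param interaction include the compartment x host interaction.
#' @return numeric design matrix with attribute `"contrast"`: the unit
#'   contrast vector selecting the compartment coefficient.
#' @export
makeDesignMatrix <- function(design, interaction = FALSE) {
  design <- as.data.frame(design)
  design$compartment <- factor(design$compartment,
                               levels = c("rhizosphere", "endosphere"))
  single_host <- length(unique(design$host)) < 2
  f <- if (single_host) ~compartment
       else if (interaction) ~compartment * host
       else ~compartment + host
  X <- model.matrix(f, data = design)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design")
  rownames(X) <- design$sample_id
  ctr <- as.numeric(colnames(X) == "compartmentendosphere")
  attr(X, "contrast") <- ctr
  X
}

#' Voom transformation: log-CPM and precision weights
#'
#' `logCPM[f,s] = log2((count + 0.5) / (libsize * factor + 1) * 1e6)`.
#' Per-feature residual standard deviations from an ordinary
#' least-squares fit of the design are floored at `sd_floor`, a lowess
#' trend (span 0.5, 2 robustness iterations) of sqrt(sd) against mean
#' log2 count is fitted, and each observation's weight is the trend
#' prediction at its fitted log2 count raised to the power -4, clipped
#' to `[1e-6, 1e6]`.
#'
#' @param x `SummarizedExperiment` or counts matrix (non-negative).
#' @param design_matrix numeric design matrix (full column rank).
#' @param factors per-sample scale factors (default [tmmFactors()]).
#' @param sd_floor floor on the residual standard deviation.
#' @param span,iter lowess span and robustness iterations.
#' @return list with `logcpm`, `weights` (same dimension), `lib_size`,
#'   `factors`, `trend` (the lowess curve).
#' @export
voomTransform <- function(x, design_matrix, factors = NULL,
                          sd_floor = 1e-4, span = 0.5, iter = 2) {
  counts <- .countsOf(x)
  if (any(counts < 0)) stop("counts must be non-negative")
  X <- design_matrix
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design")
  if (is.null(factors))
    factors <- if (ncol(counts) >= 2) tmmFactors(counts)
               else setNames(1, colnames(counts))
  lib <- colSums(counts)
  eff <- lib * factors[colnames(counts)]
  logcpm <- log2(sweep(counts + 0.5, 2, eff + 1, "/") * 1e6)
  fit <- lm.fit(X, t(logcpm))
  df_resid <- nrow(X) - ncol(X)
  if (df_resid < 1) stop("no residual degrees of freedom")
  res <- as.matrix(fit$residuals)
  sigma <- pmax(sqrt(colSums(res^2) / df_resid), sd_floor)
  ## mean and fitted values on the log2-count scale
  shift <- log2(eff + 1) - log2(1e6)
  sx <- rowMeans(logcpm) + mean(shift)
  sy <- sqrt(sigma)
  lo <- lowess(sx, sy, f = span, iter = iter)
  fitted_logcpm <- t(as.matrix(fit$fitted.values))
  fitted_count <- sweep(fitted_logcpm, 2, shift, "+")
  pred <- if (length(unique(lo$x)) < 2) {
    rep(mean(lo$y), length(fitted_count))
  } else {
    approx(lo$x, lo$y, xout = as.vector(fitted_count),
           rule = 2, ties = mean)$y
  }
  w <- matrix(pmin(pmax(pred^-4, 1e-6), 1e6), nrow(logcpm),
              dimnames = dimnames(logcpm))
  list(logcpm = logcpm, weights = w, lib_size = lib, factors = factors,
       trend = lo)
}

## Newton inversion of the trigamma function (for moment matching of a
## scaled F prior on the sample variances).
trigammaInverse <- function(x) {
  y <- 0.5 + 1 / x
  for (i in 1:60) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  y
}

## moment matching of (d0, s0^2) on log sample variances:
## E log s^2 = log s0^2 + digamma(d/2) - log(d/2) - digamma(d0/2) + log(d0/2)
## Var log s^2 = trigamma(d/2) + trigamma(d0/2)
.fitVariancePrior <- function(s2, df) {
  s2 <- pmax(s2, 1e-10)
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- var(e) * (length(e) - 1) / length(e)
  evar <- evar - mean(trigamma(df / 2))
  if (is.na(evar) || evar <= 0) {
    list(df_prior = Inf, var_prior = exp(emean))
  } else {
    d0 <- 2 * trigammaInverse(evar)
    list(df_prior = d0,
         var_prior = exp(emean + digamma(d0 / 2) - log(d0 / 2)))
  }
}

#' Weighted least squares with empirical-Bayes variance moderation
#'
#' Fits each feature by weighted least squares, shrinks the residual
#' variances toward a common prior estimated by moment matching on the
#' log sample variances, and tests the requested contrast with a
#' moderated t statistic on `prior df + residual df` degrees of
#' freedom.  Benjamini-Hochberg q-values are computed over all features.
#'
#' @param y matrix of responses (features x samples), e.g. voom logCPM.
#' @param weights observation weight matrix (same dimension), or NULL.
#' @param design_matrix numeric design matrix.
#' @param contrast numeric contrast vector (length = design columns);
#'   default: the matrix's `"contrast"` attribute.
#' @param alpha significance level for the `significant` flag.
#' @param prior_df,prior_var optional overrides of the estimated prior
#'   (`prior_df = 0` gives the ordinary t; `prior_df = Inf` with
#'   `prior_var` gives a pooled-variance z-like statistic).
#' @return `data.frame` (one row per feature): `feature`, `log2fc`
#'   (contrast estimate), `mean_value`, `t`, `df_total`, `p`, `q`,
#'   `significant`.
#' @export
moderatedFit <- function(y, weights = NULL, design_matrix,
                         contrast = NULL, alpha = 0.05,
                         prior_df = NULL, prior_var = NULL) {
  X <- design_matrix
  if (is.null(contrast)) contrast <- attr(X, "contrast")
  stopifnot(length(contrast) == ncol(X))
  n <- ncol(y)
  df_resid <- n - ncol(X)
  if (df_resid < 1) stop("fewer than 1 residual degree of freedom")
  if (is.null(weights)) weights <- matrix(1, nrow(y), ncol(y))
  nf <- nrow(y)
  beta_c <- se_unit <- s2 <- numeric(nf)
  for (f in seq_len(nf)) {
    w <- weights[f, ]
    yw <- y[f, ] * sqrt(w)
    Xw <- X * sqrt(w)
    fit <- lm.fit(Xw, yw)
    XtX_inv <- chol2inv(chol(crossprod(Xw)))
    beta_c[f] <- sum(contrast * fit$coefficients)
    se_unit[f] <- sqrt(drop(t(contrast) %*% XtX_inv %*% contrast))
    s2[f] <- sum(fit$residuals^2) / df_resid
  }
  if (is.null(prior_df)) {
    pri <- .fitVariancePrior(s2, df_resid)
  } else {
    pri <- list(df_prior = prior_df,
                var_prior = if (!is.null(prior_var)) prior_var
                            else mean(s2))
  }
  d0 <- pri$df_prior
  s2_post <- if (is.infinite(d0)) rep(pri$var_prior, nf)
             else (d0 * pri$var_prior + df_resid * s2) / (d0 + df_resid)
  tstat <- beta_c / (se_unit * sqrt(s2_post))
  df_total <- d0 + df_resid
  p <- 2 * pt(-abs(tstat), df = df_total)
  q <- p.adjust(p, method = "BH")
  data.frame(
    feature = rownames(y), log2fc = beta_c,
    mean_value = rowMeans(y), t = tstat,
    df_total = rep(df_total, nf)[seq_len(nf)], p = p, q = q,
    significant = q < alpha, row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Strain-level compartment enrichment
#'
#' TMM + voom + moderated t on the compartment contrast (positive log2
#' fold change = endosphere enrichment), plus mean CPM per compartment
#' and an alternative log2 fold change computed directly from mean CPM.
#'
#' @param se strain-level `SummarizedExperiment` with `compartment` and
#'   `host` in `colData`.
#' @param alpha FDR level.
#' @param interaction include compartment x host interaction in the
#'   design.
#' @return `data.frame`: `feature`, `log2fc` (voom-fitted, the default),
#'   `log2fc_cpm` (ratio of mean CPM), `mean_cpm`, `endo_cpm`,
#'   `rhizo_cpm`, `t`, `p`, `q`, `significant`.
#' @export
strainEnrichment <- function(se, alpha = 0.05, interaction = FALSE) {
  X <- makeDesignMatrix(colData(se), interaction = interaction)
  v <- voomTransform(se, X)
  et <- moderatedFit(v$logcpm, v$weights, X, alpha = alpha)
  cpm <- cpmNormalize(se)
  endo <- colData(se)$compartment == "endosphere"
  et$endo_cpm <- rowMeans(cpm[, endo, drop = FALSE])
  et$rhizo_cpm <- rowMeans(cpm[, !endo, drop = FALSE])
  et$mean_cpm <- rowMeans(cpm)
  et$log2fc_cpm <- log2((et$endo_cpm + 0.5) / (et$rhizo_cpm + 0.5))
  et$mean_value <- NULL
  et[, c("feature", "log2fc", "log2fc_cpm", "mean_cpm", "endo_cpm",
         "rhizo_cpm", "t", "df_total", "p", "q", "significant")]
}

#' Classify strains into colonization strategies
#'
#' Rule-based labels from the enrichment table and compartment mean
#' abundances: `strong_colonizer` = significant positive log2fc and
#' endosphere abundance at or above the quantile threshold;
#' `niche_specialist` = significant positive log2fc below the
#' threshold; `generalist` = not significant with abundance at or above
#' the threshold in both compartments; `rhizosphere_associated` =
#' significant negative log2fc; otherwise `unclassified`.
#'
#' @param et enrichment table from [strainEnrichment()].
#' @param alpha significance level on the q-value.
#' @param abundance_quantile quantile (in `(0,1)`) defining
#'   "moderate-to-high" abundance within each compartment.
#' @return `et` with an added `strategy` column (exactly one label per
#'   strain).
#' @export
classifyStrategies <- function(et, alpha = 0.05,
                               abundance_quantile = 0.5) {
  stopifnot(abundance_quantile > 0, abundance_quantile < 1)
  thr_endo <- quantile(et$endo_cpm, abundance_quantile)
  thr_rhizo <- quantile(et$rhizo_cpm, abundance_quantile)
  sig <- et$q < alpha
  strategy <- rep("unclassified", nrow(et))
  strategy[sig & et$log2fc > 0 & et$endo_cpm >= thr_endo] <-
    "strong_colonizer"
  strategy[sig & et$log2fc > 0 & et$endo_cpm < thr_endo] <-
    "niche_specialist"
  strategy[!sig & et$endo_cpm >= thr_endo & et$rhizo_cpm >= thr_rhizo] <-
    "generalist"
  strategy[sig & et$log2fc < 0] <- "rhizosphere_associated"
  et$strategy <- strategy
  et
}

#' Write an enrichment table as TSV
#'
#' @param et enrichment table data.frame.
#' @param path file path.
#' @export
writeEnrichmentTSV <- function(et, path) {
  write.table(et, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
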