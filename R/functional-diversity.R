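## Alpha diversity, Bray-Curtis, NMDS ordination and PERMANOVA on
## orthogroup CPM profiles.

#' Per-sample richness and Shannon diversity
#'
#' Richness counts features with CPM > 0; Shannon H uses natural log
#' over the nonzero relative abundances (`base` configurable).
#'
#' @param cpm CPM matrix (features x samples).
#' @param base logarithm base (default `exp(1)`).
#' @return `data.frame`: `sample`, `richness`, `shannon`.
#' @export
alphaDiversity <- function(cpm, base = exp(1)) {
  res <- apply(cpm, 2, function(x) {
    p <- x[x > 0] / sum(x)
    c(richness = sum(x > 0), shannon = -sum(p * log(p, base = base)))
  })
  data.frame(sample = colnames(cpm), richness = as.integer(res[1, ]),
             shannon = res[2, ], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Compare alpha diversity between two or more groups
#'
#' Two-sided Wilcoxon rank-sum (exact for combined n <= 20 without
#' ties, normal approximation with tie correction otherwise; only for
#' two groups) and one-way ANOVA F test.
#'
#' @param values numeric vector.
#' @param groups factor-like group labels aligned with `values`.
#' @return list with `wilcoxon_p` (NA for > 2 groups) and `anova_p`.
#' @export
compareAlpha <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 values")
  wp <- NA_real_
  if (nlevels(groups) == 2) {
    x <- values[groups == levels(groups)[1]]
    y <- values[groups == levels(groups)[2]]
    exact <- (length(x) + length(y) <= 20) &&
      !anyDuplicated(c(x, y))
    wp <- suppressWarnings(
      wilcox.test(x, y, exact = exact, correct = FALSE)$p.value)
  }
  ap <- anova(aov(values ~ groups))[["Pr(>F)"]][1]
  list(wilcoxon_p = wp, anova_p = ap)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = sum |x - y| / sum (x + y)` over features, computed with
#' `vegan::vegdist`.
#'
#' @param cpm non-negative matrix (features x samples).
#' @return symmetric samples x samples matrix with zero diagonal.
#' @export
brayCurtis <- function(cpm) {
  if (any(cpm < 0)) stop("negative abundances")
  zero <- colSums(cpm) == 0
  if (sum(zero) >= 2)
    stop("all-zero samples: ", paste(colnames(cpm)[zero], collapse = ", "))
  d <- as.matrix(vegan::vegdist(t(cpm), method = "bray"))
  dimnames(d) <- list(colnames(cpm), colnames(cpm))
  d
}

#' Non-metric multidimensional scaling
#'
#' Kruskal stress-1 NMDS via `vegan::monoMDS` (global model, monotone
#' regression), best configuration over one metric-scaling start plus
#' `n_starts - 1` random starts.
#'
#' @param d distance matrix (square matrix or `dist`).
#' @param dims embedding dimension.
#' @param n_starts number of starts.
#' @param max_iter maximum iterations per start.
#' @param tol stress convergence tolerance.
#' @param seed optional integer seed for the random starts.
#' @return list with `points` (samples x dims), `stress` (stress-1),
#'   `converged` (logical: any start converged).
#' @export
nmdsOrdination <- function(d, dims = 2, n_starts = 20, max_iter = 300,
                           tol = 1e-6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dd <- as.dist(d)
  n <- attr(dd, "Size")
  if (n < dims + 2) stop("need at least dims + 2 samples")
  best <- NULL
  for (s in seq_len(max(1, n_starts))) {
    fit <- if (s == 1) {
      vegan::monoMDS(dd, k = dims, model = "global",
                     maxit = max_iter, sratmax = 1 - tol)
    } else {
      init <- matrix(rnorm(n * dims), n, dims)
      vegan::monoMDS(dd, y = init, k = dims, model = "global",
                     maxit = max_iter, sratmax = 1 - tol)
    }
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  pts <- best$points
  rownames(pts) <- attr(dd, "Labels")
  converged <- best$iters < max_iter
  if (!converged)
    warning("NMDS did not converge within max_iter; returning best found")
  list(points = pts, stress = best$stress, converged = converged)
}

## all permutations of seq_len(n) as a list (n! must be modest)
.allPermutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- .allPermutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (i in seq_len(n)) for (p in sub) {
    k <- k + 1L
    out[[k]] <- c(i, ifelse(p >= i, p + 1L, p))
  }
  out
}

#' PERMANOVA: permutational multivariate ANOVA on a distance matrix
#'
#' Partitions the total sum of squares of a distance matrix among
#' design terms by sequential (type-I) projection onto nested design
#' subspaces of the Gower-centered inner-product matrix.  Pseudo-F per
#' term uses the residual mean square; p-values come from free
#' permutation of sample labels, `p = (1 + #{F* >= F}) / (n_perm + 1)`,
#' or from exhaustive enumeration of all `n!` label permutations
#' (`p = #{F_perm >= F} / n!`, identity included) when
#' `exhaustive = TRUE`.
#'
#' @param d distance matrix (square matrix or `dist`).
#' @param design data.frame of factors (rows aligned with samples).
#' @param terms character vector naming design columns, in the order
#'   they enter the model.
#' @param n_perm number of permutations (>= 99).
#' @param seed optional integer seed.
#' @param exhaustive enumerate all `n!` permutations (n <= 8).
#' @return `data.frame` with one row per term plus `Residual` and
#'   `Total`: `term`, `df`, `SS`, `R2`, `F`, `p`.
#' @export
permanova <- function(d, design, terms, n_perm = 999, seed = NULL,
                      exhaustive = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  D <- as.matrix(as.dist(d))
  n <- nrow(D)
  design <- as.data.frame(design)
  stopifnot(all(terms %in% names(design)), nrow(design) == n,
            exhaustive || n_perm >= 99)
  ## Gower-centered inner product matrix
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  ## nested hat matrices for the sequential design
  hats <- vector("list", length(terms) + 1)
  dfs <- integer(length(terms))
  X <- matrix(1, n, 1)
  hats[[1]] <- tcrossprod(qr.Q(qr(X)))
  for (t in seq_along(terms)) {
    X <- cbind(X, model.matrix(~., design[, terms[seq_len(t)],
                                          drop = FALSE])[, -1, drop = FALSE])
    q <- qr(X)
    if (q$rank < ncol(X)) X <- X[, q$pivot[seq_len(q$rank)], drop = FALSE]
    hats[[t + 1]] <- tcrossprod(qr.Q(qr(X)))
    dfs[t] <- sum(diag(hats[[t + 1]])) - sum(diag(hats[[t]]))
  }
  df_res <- n - round(sum(diag(hats[[length(hats)]])))
  if (df_res < 1) stop("confounded terms: zero residual degrees of freedom")
  stat <- function(Gm) {
    tr <- vapply(hats, function(H) sum(H * Gm), 0)
    ss_terms <- diff(tr)
    ss_total <- sum(diag(Gm))
    ss_res <- ss_total - tr[length(tr)]
    Fv <- (ss_terms / dfs) / (ss_res / df_res)
    list(ss = ss_terms, ss_res = ss_res, ss_total = ss_total, F = Fv)
  }
  obs <- stat(G)
  if (exhaustive) {
    if (n > 8) stop("exhaustive enumeration limited to n <= 8")
    perms <- .allPermutations(n)
    hits <- numeric(length(terms))
    for (p in perms) {
      Fp <- stat(G[p, p])$F
      hits <- hits + (Fp >= obs$F - 1e-12)
    }
    pval <- hits / length(perms)
  } else {
    hits <- numeric(length(terms))
    for (i in seq_len(n_perm)) {
      p <- sample.int(n)
      Fp <- stat(G[p, p])$F
      hits <- hits + (Fp >= obs$F - 1e-12)
    }
    pval <- (1 + hits) / (n_perm + 1)
  }
  data.frame(
    term = c(terms, "Residual", "Total"),
    df = c(round(dfs), df_res, n - 1),
    SS = c(obs$ss, obs$ss_res, obs$ss_total),
    R2 = c(obs$ss, obs$ss_res, obs$ss_total) / obs$ss_total,
    F = c(obs$F, NA, NA),
    p = c(pval, NA, NA),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
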