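# Principal coordinates, PERMANOVA and ordination-environment correlations.

.check_dissimilarity <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || !is.numeric(d) || nrow(d) != ncol(d)) {
    .stopf("dissimilarity input must be a square numeric matrix or dist")
  }
  if (max(abs(d - t(d))) > 1e-12) .stopf("dissimilarity matrix is not symmetric")
  if (any(abs(diag(d)) > 1e-12)) .stopf("dissimilarity matrix must have a zero diagonal")
  d
}

#' Principal coordinates analysis (classical metric MDS)
#'
#' Gower double-centering of \eqn{-D^2/2} followed by a symmetric
#' eigendecomposition. Coordinates are eigenvectors scaled by the square root
#' of their (positive) eigenvalues; negative eigenvalues — which Bray-Curtis
#' matrices can produce — are excluded from both the coordinates and the
#' variance-explained denominator (no Lingoes/Cailliez correction).
#'
#' @param d Square symmetric dissimilarity matrix (or `dist`).
#' @param n_axes Number of axes to return (capped at the number of positive
#'   eigenvalues).
#' @return List of class `"dsl_pcoa"`: `coordinates` (samples x axes),
#'   `eigenvalues` (all, non-increasing), `proportion_explained` (over positive
#'   eigenvalues only, one entry per returned axis).
#' @export
pcoa <- function(d, n_axes = 2L) {
  d <- .check_dissimilarity(d)
  n <- nrow(d)
  ctr <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * ctr %*% (d * d) %*% ctr
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  pos <- e$values > max(abs(e$values)) * 1e-10
  n_pos <- sum(pos)
  k <- min(n_axes, n_pos)
  coords <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(e$values[seq_len(k)]), k, k)
  dimnames(coords) <- list(rownames(d), paste0("PCoA", seq_len(k)))
  structure(list(
    coordinates = coords,
    eigenvalues = e$values,
    n_positive = n_pos,
    proportion_explained = e$values[seq_len(k)] / sum(e$values[pos])
  ), class = "dsl_pcoa")
}

#' @export
print.dsl_pcoa <- function(x, ...) {
  cat(sprintf("PCoA: %d samples, %d positive eigenvalues\n",
              nrow(x$coordinates), x$n_positive))
  cat(sprintf("Variance explained by returned axes: %s\n",
              paste(sprintf("%.1f%%", 100 * x$proportion_explained), collapse = ", ")))
  invisible(x)
}

# Within-group sum of squared dissimilarities divided by group size, summed
# over groups (Anderson's SSW), from the squared-distance matrix.
.ssw <- function(d2, groups) {
  s <- 0
  for (lev in levels(groups)) {
    idx <- groups == lev
    s <- s + sum(d2[idx, idx]) / (2 * sum(idx))
  }
  s
}

#' One-way PERMANOVA
#'
#' Distance-based pseudo-F (Anderson): with total sum of squares
#' \eqn{SS_T = \sum_{i<j} d_{ij}^2 / N} and within-group
#' \eqn{SS_W = \sum_g \sum_{i<j \in g} d_{ij}^2 / n_g},
#' \eqn{F = ((SS_T - SS_W)/(a-1)) / (SS_W/(N-a))}. Significance by permuting
#' group labels; \eqn{p = (\#\{F^* \ge F\} + 1) / (n_{perm} + 1)}.
#'
#' @param d Dissimilarity matrix (or `dist`).
#' @param groups Factor-like grouping, one entry per sample; >= 2 groups with
#'   >= 2 samples each.
#' @param n_perm Number of label permutations (>= 99).
#' @param seed Optional seed for reproducible permutations.
#' @param label Optional comparison label carried into the result.
#' @return List of class `"dsl_permanova"`: `f`, `r2`, `p`, `n_perm`, `df`,
#'   `label`.
#' @export
permanova <- function(d, groups, n_perm = 999L, seed = NULL, label = NULL) {
  d <- .check_dissimilarity(d)
  groups <- droplevels(as.factor(groups))
  if (length(groups) != nrow(d)) .stopf("groups length must match the matrix dimension")
  if (nlevels(groups) < 2L) .stopf("need at least two groups")
  sizes <- table(groups)
  if (any(sizes < 2L)) {
    .stopf("group(s) with fewer than 2 samples: %s",
           paste(names(sizes)[sizes < 2L], collapse = ", "))
  }
  if (n_perm < 99L) .stopf("n_perm must be >= 99")

  d2 <- d * d
  n <- nrow(d2)
  a <- nlevels(groups)
  sst <- sum(d2) / (2 * n)
  ssw <- .ssw(d2, groups)
  ssa <- sst - ssw
  f_obs <- (ssa / (a - 1)) / (ssw / (n - a))

  exceed <- .with_seed(seed, {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      gp <- groups[sample.int(n)]
      ssw_p <- .ssw(d2, gp)
      f_p <- ((sst - ssw_p) / (a - 1)) / (ssw_p / (n - a))
      if (f_p >= f_obs) hits <- hits + 1L
    }
    hits
  })

  structure(list(
    f = f_obs, r2 = ssa / sst, p = (exceed + 1) / (n_perm + 1),
    n_perm = as.integer(n_perm), df = c(a - 1L, n - a), label = label
  ), class = "dsl_permanova")
}

#' @export
print.dsl_permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA%s: F(%d,%d) = %.3f, R2 = %.3f, p = %.4g (%d permutations)\n",
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
              x$df[1L], x$df[2L], x$f, x$r2, x$p, x$n_perm))
  invisible(x)
}

#' Pairwise PERMANOVA with p-value adjustment
#'
#' Runs [permanova()] on the sub-matrix of every unordered pair of groups and
#' adjusts the p-values across pairs (Bonferroni by default, as in
#' pairwiseAdonis).
#'
#' @inheritParams permanova
#' @param adjust_method One of [stats::p.adjust.methods].
#' @return Data.frame with one row per pair: `comparison`, `f`, `r2`, `p`,
#'   `p_adjusted`.
#' @export
pairwise_permanova <- function(d, groups, n_perm = 999L, seed = NULL,
                               adjust_method = "bonferroni") {
  d <- .check_dissimilarity(d)
  groups <- droplevels(as.factor(groups))
  levs <- levels(groups)
  if (length(levs) < 2L) .stopf("need at least two groups")
  pairs <- utils::combn(levs, 2L, simplify = FALSE)
  res <- lapply(seq_along(pairs), function(k) {
    pr <- pairs[[k]]
    idx <- groups %in% pr
    sub_seed <- if (is.null(seed)) NULL else seed + k - 1L
    fit <- permanova(d[idx, idx, drop = FALSE], groups[idx], n_perm = n_perm,
                     seed = sub_seed, label = paste(pr, collapse = " vs "))
    data.frame(comparison = fit$label, f = fit$f, r2 = fit$r2, p = fit$p)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- stats::p.adjust(out$p, method = adjust_method)
  out
}

#' Correlate ordination axes with environmental covariates
#'
#' Pearson correlation between PCoA axis coordinates and zero-centred,
#' unit-scaled covariates; samples with a missing covariate value are excluded
#' pairwise (with a message).
#'
#' @param ordination A `"dsl_pcoa"` object.
#' @param metadata Sample metadata (rownames = sample ids) containing the
#'   covariate columns.
#' @param covariates Character vector of covariate column names.
#' @param axes Integer vector of axis numbers (default the available axes).
#' @return Data.frame: `axis`, `covariate`, `r`, `p`, `n`, `significant`
#'   (p < 0.05). A constant covariate yields `r = NA`.
#' @export
axis_env_correlation <- function(ordination, metadata, covariates,
                                 axes = NULL) {
  if (!inherits(ordination, "dsl_pcoa")) .stopf("ordination must come from pcoa()")
  coords <- ordination$coordinates
  if (is.null(axes)) axes <- seq_len(ncol(coords))
  if (any(axes > ncol(coords))) .stopf("requested axis beyond the ordination")
  missing_cov <- setdiff(covariates, colnames(metadata))
  if (length(missing_cov)) {
    .stopf("covariate(s) not in metadata: %s", paste(missing_cov, collapse = ", "))
  }
  samples <- rownames(coords)
  orphan <- setdiff(samples, rownames(metadata))
  if (length(orphan)) {
    .stopf("ordination sample(s) missing from metadata: %s", paste(orphan, collapse = ", "))
  }
  rows <- list()
  for (cov in covariates) {
    v <- metadata[samples, cov]
    ok <- is.finite(v)
    if (sum(!ok)) message(sprintf("%s: %d sample(s) excluded (missing values)", cov, sum(!ok)))
    vs <- if (stats::sd(v[ok]) > 0) as.numeric(scale(v[ok])) else rep(NA_real_, sum(ok))
    for (ax in axes) {
      if (anyNA(vs) || sum(ok) < 3L) {
        rows[[length(rows) + 1L]] <- data.frame(
          axis = ax, covariate = cov, r = NA_real_, p = NA_real_,
          n = sum(ok), significant = NA)
        next
      }
      ct <- stats::cor.test(coords[ok, ax], vs, method = "pearson")
      rows[[length(rows) + 1L]] <- data.frame(
        axis = ax, covariate = cov, r = unname(ct$estimate), p = ct$p.value,
        n = sum(ok), significant = ct$p.value < 0.05)
    }
  }
  do.call(rbind, rows)
}
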