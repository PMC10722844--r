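# Dufrene-Legendre indicator value (IndVal) analysis with permutation
# inference and the seasonal indicator selection/summary used at the DSL.

# Core vectorized IndVal on a relative-abundance matrix (ASV x sample).
# Returns A (specificity), B (fidelity) and indval = A*B as ASV x group
# matrices. A uses the mean-abundance formulation: group mean divided by the
# sum of group means.
.indval_core <- function(relab, groups) {
  g <- droplevels(as.factor(groups))
  memb <- stats::model.matrix(~ g - 1)                  # samples x groups
  colnames(memb) <- levels(g)
  memb_norm <- sweep(memb, 2L, colSums(memb), "/")
  mean_ab <- relab %*% memb_norm                        # ASV x group means
  tot <- rowSums(mean_ab)
  A <- mean_ab / ifelse(tot > 0, tot, 1)                # absent ASV -> A = 0
  A[tot == 0, ] <- 0
  B <- (relab > 0) %*% memb_norm
  list(A = A, B = B, indval = A * B)
}

#' Indicator value (IndVal) analysis
#'
#' For every ASV and group: specificity `A` (mean relative abundance in the
#' group divided by the sum of group mean abundances), fidelity `B` (fraction
#' of the group's samples where the ASV occurs) and `indval = A * B`. The
#' index is 1 exactly when a taxon occurs in all samples of one group and
#' nowhere else. Input counts are converted to per-sample relative abundances.
#'
#' @param counts Count table (or relative-abundance matrix).
#' @param groups Factor-like grouping, one entry per sample; >= 2 groups.
#' @return List of class `"dsl_indval"`: matrices `A`, `B`, `indval`
#'   (ASV x group), plus per-ASV `best_group` and `best_indval` (argmax over
#'   groups; ties broken by group order).
#' @export
indval <- function(counts, groups) {
  if (!is.matrix(counts) || !is.numeric(counts)) .stopf("counts must be a numeric matrix")
  g <- droplevels(as.factor(groups))
  if (length(g) != ncol(counts)) .stopf("groups length must match the sample count")
  if (nlevels(g) < 2L) .stopf("need at least two groups")
  relab <- relative_abundance(counts)
  core <- .indval_core(relab, g)
  best <- max.col(core$indval, ties.method = "first")
  structure(list(
    A = core$A, B = core$B, indval = core$indval,
    best_group = factor(levels(g)[best], levels = levels(g)),
    best_indval = core$indval[cbind(seq_len(nrow(counts)), best)],
    groups = g
  ), class = "dsl_indval")
}

#' Permutation p-values for IndVal
#'
#' Permutes group labels across samples; for each ASV the statistic is its
#' best-group indval, and \eqn{p = (\#\{indval^* \ge indval\} + 1)/(n_{perm}+1)}.
#'
#' @inheritParams indval
#' @param n_perm Number of permutations (>= 99).
#' @param seed Optional seed; identical seeds give identical p-values.
#' @return Named numeric vector of p-values, one per ASV.
#' @export
indval_significance <- function(counts, groups, n_perm = 999L, seed = NULL) {
  if (n_perm < 99L) .stopf("n_perm must be >= 99")
  obs <- indval(counts, groups)
  relab <- relative_abundance(counts)
  g <- obs$groups
  n <- ncol(counts)
  exceed <- rep(0L, nrow(counts))
  .with_seed(seed, {
    for (b in seq_len(n_perm)) {
      iv <- .indval_core(relab, g[sample.int(n)])$indval
      stat <- iv[cbind(seq_len(nrow(iv)), max.col(iv, ties.method = "first"))]
      exceed <- exceed + (stat >= obs$best_indval)
    }
  })
  p <- (exceed + 1) / (n_perm + 1)
  names(p) <- rownames(counts)
  p
}

#' Select indicator taxa
#'
#' Applies the strict selection rule `p < p_thresh` and
#' `indval > indval_thresh` (defaults 0.05 and 0.5) to the best group of each
#' ASV.
#'
#' @param result A `"dsl_indval"` object.
#' @param p Named p-value vector from [indval_significance()] (same ASVs).
#' @param p_thresh,indval_thresh Strict thresholds in (0, 1).
#' @return Data.frame of selected (ASV, group) pairs with their `A`, `B`,
#'   `indval` and `p`.
#' @export
select_indicators <- function(result, p, p_thresh = 0.05, indval_thresh = 0.5) {
  if (!inherits(result, "dsl_indval")) .stopf("result must come from indval()")
  if (any(c(p_thresh, indval_thresh) <= 0) || any(c(p_thresh, indval_thresh) >= 1)) {
    .stopf("thresholds must lie in (0, 1)")
  }
  ids <- rownames(result$indval)
  p <- p[ids]
  keep <- !is.na(p) & p < p_thresh & result$best_indval > indval_thresh
  data.frame(
    asv_id = ids[keep],
    group = as.character(result$best_group[keep]),
    A = result$A[cbind(which(keep), as.integer(result$best_group[keep]))],
    B = result$B[cbind(which(keep), as.integer(result$best_group[keep]))],
    indval = result$best_indval[keep],
    p = unname(p[keep]),
    row.names = NULL
  )
}

#' Summarize indicator taxa per group
#'
#' Per group: number of indicator ASVs, mean and standard error (sd/sqrt(n))
#' of their summed per-sample relative abundance across the group's samples,
#' and the order-level breakdown of the indicators' mean abundance (top
#' `top_orders`).
#'
#' @param selected Output of [select_indicators()].
#' @param counts Count table used for the analysis.
#' @param taxonomy Taxonomy table (or `NULL` to skip the order breakdown).
#' @param groups The grouping used for the analysis.
#' @param top_orders How many orders to keep in the breakdown.
#' @return List with `summary` (data.frame: group, n_indicators,
#'   mean_abundance, se_abundance) and `orders` (data.frame: group, order,
#'   mean_abundance), both on the relative-abundance (0-1) scale.
#' @export
indicator_summary <- function(selected, counts, taxonomy, groups, top_orders = 15L) {
  g <- droplevels(as.factor(groups))
  relab <- relative_abundance(counts)
  rows <- lapply(levels(g), function(lev) {
    asvs <- selected$asv_id[selected$group == lev]
    if (!length(asvs)) {
      return(data.frame(group = lev, n_indicators = 0L,
                        mean_abundance = 0, se_abundance = 0))
    }
    per_sample <- colSums(relab[asvs, g == lev, drop = FALSE])
    data.frame(group = lev, n_indicators = length(asvs),
               mean_abundance = mean(per_sample),
               se_abundance = stats::sd(per_sample) / sqrt(length(per_sample)))
  })
  summary <- do.call(rbind, rows)

  orders <- NULL
  if (!is.null(taxonomy) && nrow(selected)) {
    ord_rows <- lapply(levels(g), function(lev) {
      asvs <- selected$asv_id[selected$group == lev]
      if (!length(asvs)) return(NULL)
      ords <- as.character(taxonomy[asvs, "order"])
      ords[is.na(ords)] <- "unassigned"
      mean_ab <- rowMeans(relab[asvs, g == lev, drop = FALSE])
      agg <- sort(tapply(mean_ab, ords, sum), decreasing = TRUE)
      agg <- utils::head(agg, top_orders)
      data.frame(group = lev, order = names(agg), mean_abundance = as.numeric(agg))
    })
    orders <- do.call(rbind, ord_rows)
  }
  list(summary = summary, orders = orders)
}
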