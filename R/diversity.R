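# Alpha diversity and Bray-Curtis dissimilarity.

#' Shannon diversity (natural log)
#'
#' \eqn{H = -\sum_i p_i \ln p_i} over the positive entries of one sample's
#' count (or abundance) vector, with \eqn{p_i} the relative abundances.
#'
#' @param x Non-negative numeric vector with at least one positive entry.
#' @return H in nats, >= 0.
#' @export
shannon <- function(x) {
  if (anyNA(x) || any(x < 0)) .stopf("counts must be non-negative and non-missing")
  total <- sum(x)
  if (total <= 0) .stopf("all-zero sample: Shannon diversity undefined")
  p <- x[x > 0] / total
  -sum(p * log(p))
}

#' Observed richness
#'
#' Number of taxa with a strictly positive count.
#'
#' @param x Non-negative numeric vector.
#' @return Integer count >= 0.
#' @export
richness <- function(x) {
  if (anyNA(x) || any(x < 0)) .stopf("counts must be non-negative and non-missing")
  sum(x > 0)
}

#' Pielou's evenness
#'
#' \eqn{J = H / \ln n}; 1 for a perfectly even community.
#'
#' @param H Shannon diversity in nats.
#' @param n Richness (must be >= 2; J is undefined otherwise).
#' @return J in `[0, 1]`.
#' @export
pielou <- function(H, n) {
  if (n <= 1) .stopf("Pielou evenness undefined for richness <= 1")
  H / log(n)
}

#' Per-sample alpha diversity table
#'
#' @param counts Count table.
#' @return Data.frame with one row per sample: `shannon` (H, nats), `richness`
#'   (n) and `pielou` (J; `NA` when n <= 1).
#' @export
alpha_diversity <- function(counts) {
  validate_count_table(counts)
  H <- apply(counts, 2L, shannon)
  n <- apply(counts, 2L, richness)
  J <- ifelse(n > 1, H / log(n), NA_real_)
  data.frame(sample_id = colnames(counts), shannon = H, richness = n,
             pielou = J, row.names = colnames(counts))
}

#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{d(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)} between sample
#' columns; 0 for identical samples, 1 for disjoint supports.
#'
#' @param x Count table or relative-abundance matrix (samples in columns); no
#'   all-zero sample allowed.
#' @return Square symmetric matrix with zero diagonal, sample ids as dimnames.
#' @export
bray_curtis <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) .stopf("input must be a numeric matrix")
  if (ncol(x) < 2L) .stopf("need at least two samples")
  zero <- !(colSums(x) > 0)
  if (any(zero)) {
    .stopf("all-zero sample(s): %s", paste(colnames(x)[zero], collapse = ", "))
  }
  n <- ncol(x)
  d <- matrix(0, n, n, dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(n - 1L)) {
    xi <- x[, i]
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- sum(abs(xi - x[, j])) / sum(xi + x[, j])
    }
  }
  d
}
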