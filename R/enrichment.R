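# Clade-level epipelagic vs mesopelagic enrichment: log odds ratios with
# Fisher's exact significance.

# Build the 2x2 table for one clade: rows clade/other, columns meso/epi.
.zone_table <- function(counts, taxonomy, metadata, clade, rank,
                        method = c("reads", "presence")) {
  method <- match.arg(method)
  validate_metadata(metadata, counts)
  agg <- aggregate_rank(counts, taxonomy, rank)
  if (!clade %in% rownames(agg)) .stopf("clade '%s' not found at rank %s", clade, rank)
  zone <- ifelse(metadata[colnames(agg), "layer"] %in% .meso_layers, "meso", "epi")
  if (!all(c("meso", "epi") %in% zone)) .stopf("both zones need at least one sample")
  if (method == "presence") agg <- (agg > 0) * 1
  clade_row <- agg[clade, ]
  other <- colSums(agg) - clade_row
  tab <- matrix(c(sum(clade_row[zone == "meso"]), sum(other[zone == "meso"]),
                  sum(clade_row[zone == "epi"]), sum(other[zone == "epi"])),
                nrow = 2L,
                dimnames = list(c("clade", "other"), c("meso", "epi")))
  if (sum(tab["clade", ]) == 0) .stopf("clade '%s' absent from both zones", clade)
  tab
}

#' Log odds ratio with Fisher's exact test for a 2x2 table
#'
#' The estimator behind [zone_odds()]: natural-log odds ratio
#' \eqn{\ln(ad/bc)} with a Haldane-Anscombe +0.5 on every cell when any cell
#' is zero (applied to the estimate only), and the two-sided Fisher exact
#' p-value — the sum of the probabilities of all tables with the observed
#' margins no more probable than the observed one — computed on the
#' uncorrected table.
#'
#' @param tab 2x2 matrix of non-negative counts; rows = focal/other, columns
#'   = zone 1/zone 2.
#' @return List: `log_or`, `p`.
#' @export
odds_ratio_test <- function(tab) {
  if (!is.matrix(tab) || any(dim(tab) != 2L) || any(tab < 0)) {
    .stopf("tab must be a 2x2 matrix of non-negative counts")
  }
  est <- if (any(tab == 0)) tab + 0.5 else tab
  log_or <- log((est[1, 1] * est[2, 2]) / (est[1, 2] * est[2, 1]))
  p <- if (sum(tab) == 0) 1 else stats::fisher.test(round(tab))$p.value
  list(log_or = log_or, p = p)
}

#' Zone enrichment odds ratio for one clade
#'
#' Aggregates reads at `rank`, pools them by zone (mesopelagic = MS/DSL/MD,
#' epipelagic = SURF/DCM) and forms the 2x2 table clade/other x meso/epi.
#' Reports the natural-log odds ratio (positive = the clade is relatively more
#' frequent in the mesopelagic) with a Haldane-Anscombe +0.5 applied to the
#' estimate only when any cell is zero, and the two-sided Fisher exact p
#' computed on the uncorrected table.
#'
#' @param counts Count table.
#' @param taxonomy Taxonomy table.
#' @param metadata Sample metadata.
#' @param clade Taxon name at `rank`.
#' @param rank Taxonomic rank (e.g. `"phylum"` or `"class"`).
#' @param method `"reads"` (pooled read counts, default) or `"presence"`
#'   (per-sample occurrence).
#' @return List of class `"dsl_zone_odds"`: `clade`, `table` (2x2), `log_or`,
#'   `p`, `significant` (p < 0.05).
#' @export
zone_odds <- function(counts, taxonomy, metadata, clade, rank = "phylum",
                      method = c("reads", "presence")) {
  tab <- .zone_table(counts, taxonomy, metadata, clade, rank, method)
  fit <- odds_ratio_test(tab)
  structure(list(clade = clade, table = tab, log_or = fit$log_or, p = fit$p,
                 significant = fit$p < 0.05), class = "dsl_zone_odds")
}

#' @export
print.dsl_zone_odds <- function(x, ...) {
  cat(sprintf("%s: log OR = %+.3f (%s), Fisher p = %.3g%s\n", x$clade, x$log_or,
              if (x$log_or > 0) "mesopelagic" else "epipelagic", x$p,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Zone odds panel for the dominant clades
#'
#' Ranks clades at `rank` by overall mean relative abundance and computes
#' [zone_odds()] for the `top_k`, optionally replacing one phylum by its most
#' abundant classes (the usual treatment of Proteobacteria).
#'
#' @inheritParams zone_odds
#' @param top_k Number of top clades to report.
#' @param split_phylum Optional phylum name to expand into its classes.
#' @param split_top_k Number of classes kept for the split phylum.
#' @return Data.frame: `clade`, `rank`, the four 2x2 cells (`a` = clade reads
#'   meso, `b` = other meso, `c` = clade epi, `d` = other epi), `log_or`, `p`,
#'   `significant`, ordered by decreasing mean relative abundance.
#' @export
zone_odds_panel <- function(counts, taxonomy, metadata, rank = "phylum",
                            top_k = 10L, split_phylum = NULL, split_top_k = 3L,
                            method = c("reads", "presence")) {
  if (top_k < 1L) .stopf("top_k must be >= 1")
  agg <- aggregate_rank(counts, taxonomy, rank)
  mean_ra <- rowMeans(.relab(agg))
  clades <- setdiff(names(sort(mean_ra, decreasing = TRUE)), "unassigned")
  clades <- utils::head(clades, top_k)

  entries <- lapply(clades, function(cl) list(clade = cl, rank = rank))
  if (!is.null(split_phylum) && split_phylum %in% clades) {
    entries <- entries[vapply(entries, function(e) e$clade != split_phylum, TRUE)]
    in_phy <- rownames(taxonomy)[!is.na(taxonomy$phylum) & taxonomy$phylum == split_phylum]
    sub <- counts[intersect(rownames(counts), in_phy), , drop = FALSE]
    cl_agg <- aggregate_rank(sub, taxonomy, "class")
    cl_ra <- sort(rowSums(cl_agg), decreasing = TRUE)
    classes <- utils::head(setdiff(names(cl_ra), "unassigned"), split_top_k)
    entries <- c(entries, lapply(classes, function(cl) list(clade = cl, rank = "class")))
  }

  rows <- lapply(entries, function(e) {
    z <- zone_odds(counts, taxonomy, metadata, e$clade, e$rank, method = method)
    data.frame(clade = e$clade, rank = e$rank,
               a = z$table[1, 1], b = z$table[2, 1],
               c = z$table[1, 2], d = z$table[2, 2],
               log_or = z$log_or, p = z$p, significant = z$significant)
  })
  do.call(rbind, rows)
}
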