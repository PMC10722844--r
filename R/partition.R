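# Source partitioning of DSL diversity: per-profile classification of DSL
# ASVs into epipelagic-shared, unique, and mesopelagic-shared categories, the
# ANOVA+Tukey flag for DSL-enriched taxa, the per-profile/pooled summaries and
# the 3-way seasonal overlap. This is the analytical centre of the package.

.categories <- c("EPI_shared", "unique_DSL", "MS_only_shared",
                 "MD_only_shared", "all_meso_shared")

#' Per-profile layer presence sets
#'
#' For one vertical profile, the sets of ASV ids present (count > 0) in each
#' layer's sample(s), with SURF and DCM merged into the epipelagic set `EPI`.
#'
#' @param counts Count table (normally the normalized table).
#' @param metadata Sample metadata.
#' @param profile_id Which profile to use; it must contain a DSL sample and at
#'   least one of SURF/DCM. Absent MS or MD layers yield empty sets with a
#'   warning.
#' @return List of class `"dsl_layer_sets"` with character vectors `EPI`,
#'   `SURF`, `DCM`, `MS`, `DSL`, `MD` and the `profile_id`.
#' @export
layer_sets <- function(counts, metadata, profile_id) {
  validate_metadata(metadata, counts)
  samples <- rownames(metadata)[metadata$profile_id == profile_id]
  samples <- intersect(samples, colnames(counts))
  if (!length(samples)) .stopf("no samples for profile '%s'", profile_id)
  layer_of <- metadata[samples, "layer"]
  present <- function(layer) {
    cols <- samples[layer_of == layer]
    if (!length(cols)) return(character(0))
    sub <- counts[, cols, drop = FALSE]
    rownames(sub)[rowSums(sub) > 0]
  }
  sets <- lapply(stats::setNames(.layers, .layers), present)
  if (!length(sets$DSL) && !"DSL" %in% layer_of) {
    .stopf("profile '%s' has no DSL sample", profile_id)
  }
  if (!any(c("SURF", "DCM") %in% layer_of)) {
    .stopf("profile '%s' has no epipelagic (SURF/DCM) sample", profile_id)
  }
  for (lay in c("MS", "MD")) {
    if (!lay %in% layer_of) .warnf("profile '%s' has no %s sample; empty set", profile_id, lay)
  }
  structure(c(list(EPI = union(sets$SURF, sets$DCM)), sets,
              list(profile_id = profile_id)),
            class = "dsl_layer_sets")
}

#' Classify one profile's DSL ASVs by source
#'
#' Precedence order: a DSL ASV also present in the epipelagic (EPI = SURF or
#' DCM) is `EPI_shared`; otherwise, if absent from both MS and MD it is
#' `unique_DSL`; otherwise it is mesopelagic-shared, subdivided into
#' `MS_only_shared`, `MD_only_shared` or `all_meso_shared`. Categories are
#' disjoint and exhaustive over the DSL set.
#'
#' @param sets A `"dsl_layer_sets"` object.
#' @return Named factor (levels the five categories), one entry per DSL ASV.
#' @export
partition_profile <- function(sets) {
  if (!inherits(sets, "dsl_layer_sets")) .stopf("sets must come from layer_sets()")
  dsl <- sets$DSL
  in_epi <- dsl %in% sets$EPI
  in_ms <- dsl %in% sets$MS
  in_md <- dsl %in% sets$MD
  cat <- ifelse(in_epi, "EPI_shared",
         ifelse(!in_ms & !in_md, "unique_DSL",
         ifelse(in_ms & in_md, "all_meso_shared",
         ifelse(in_ms, "MS_only_shared", "MD_only_shared"))))
  stats::setNames(factor(cat, levels = .categories), dsl)
}

#' Flag DSL-enriched ASVs by ANOVA + Tukey
#'
#' For each candidate (mesopelagic-shared) ASV, a one-way ANOVA of per-sample
#' relative abundance across the mesopelagic layers it occupies, with depth
#' profiles as replicates. An ASV is enriched when the ANOVA p-value is below
#' `alpha`, every Tukey HSD comparison of DSL against an occupied adjacent
#' layer has adjusted p below `alpha`, and the DSL mean is the largest. ASVs
#' shared with a single adjacent layer are tested DSL-vs-that-layer only.
#'
#' @param counts Count table.
#' @param metadata Sample metadata; only mesopelagic (MS/DSL/MD) samples are
#'   used. Restrict `metadata`/`counts` beforehand to focus on one season.
#' @param candidate_asvs ASV ids to test (normally the mesopelagic-shared
#'   ones).
#' @param alpha Significance level (default 0.05).
#' @param adjust `"none"` (default, raw per-ASV decisions) or `"BH"` to apply
#'   Benjamini-Hochberg across the candidate ANOVA p-values.
#' @return Character vector: the enriched subset of `candidate_asvs`. ASVs
#'   with fewer than 2 replicate samples in a compared layer are skipped with
#'   a warning.
#' @export
detect_enriched <- function(counts, metadata, candidate_asvs, alpha = 0.05,
                            adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  validate_metadata(metadata, counts)
  meso_samples <- rownames(metadata)[metadata$layer %in% .meso_layers]
  meso_samples <- intersect(meso_samples, colnames(counts))
  if (!"DSL" %in% metadata[meso_samples, "layer"]) .stopf("no DSL samples available")
  relab <- relative_abundance(counts)[, meso_samples, drop = FALSE]
  layer <- factor(metadata[meso_samples, "layer"], levels = .meso_layers)

  candidate_asvs <- intersect(candidate_asvs, rownames(relab))
  anova_p <- rep(NA_real_, length(candidate_asvs))
  details <- vector("list", length(candidate_asvs))
  skipped <- character(0)

  for (k in seq_along(candidate_asvs)) {
    y <- relab[candidate_asvs[k], ]
    occupied <- .meso_layers[vapply(.meso_layers,
      function(l) any(y[layer == l] > 0), TRUE)]
    occupied <- union(occupied, "DSL")
    use <- layer %in% occupied
    lay <- droplevels(layer[use])
    if (nlevels(lay) < 2L) { details[[k]] <- FALSE; next }
    if (any(table(lay) < 2L)) {
      skipped <- c(skipped, candidate_asvs[k])
      details[[k]] <- FALSE
      next
    }
    yy <- y[use]
    if (stats::var(yy) == 0) { details[[k]] <- FALSE; next }
    fit <- stats::aov(yy ~ lay)
    anova_p[k] <- summary(fit)[[1L]][["Pr(>F)"]][1L]
    means <- tapply(yy, lay, mean)
    if (which.max(means) != match("DSL", names(means))) { details[[k]] <- FALSE; next }
    tuk <- stats::TukeyHSD(fit)$lay
    dsl_rows <- grepl("(^DSL-|-DSL$)", rownames(tuk))
    details[[k]] <- all(tuk[dsl_rows, "p adj"] < alpha)
  }
  if (length(skipped)) {
    .warnf("%d candidate ASV(s) skipped (fewer than 2 replicates in a layer)",
           length(skipped))
  }
  p_use <- if (adjust == "BH") stats::p.adjust(anova_p, "BH") else anova_p
  enriched <- !is.na(p_use) & p_use < alpha & vapply(details, isTRUE, TRUE)
  candidate_asvs[enriched]
}

#' Partition the DSL community of one season, profile by profile
#'
#' Runs [layer_sets()] + [partition_profile()] for every profile of `season`
#' that has a DSL sample, flags DSL-enriched ASVs with [detect_enriched()]
#' (candidates = the union of mesopelagic-shared ASVs across profiles, tested
#' on the season's mesopelagic samples), and assembles per-profile counts,
#' percentages and relative-abundance shares.
#'
#' @param counts Count table.
#' @param metadata Sample metadata.
#' @param season Season whose profiles to analyse (default `"spring"`, the
#'   only season with MS and MD sampled in the study design).
#' @param alpha,adjust Passed to [detect_enriched()]; `alpha = NA` skips
#'   enrichment testing.
#' @return List of class `"dsl_partition"` with one element per profile, each
#'   containing `profile_id`, `category` (named factor), `enriched` (character
#'   vector), `n_dsl`, `counts`, `percent` (sums to 100), `abundance`
#'   (relative-abundance share of the profile's DSL sample(s) per category),
#'   `percent_enriched`, `percent_meso_origin` and `percent_attributable`
#'   (unique + enriched).
#' @export
partition_dsl <- function(counts, metadata, season = "spring", alpha = 0.05,
                          adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  validate_metadata(metadata, counts)
  md <- metadata[metadata$season == season, , drop = FALSE]
  md <- md[rownames(md) %in% colnames(counts), , drop = FALSE]
  if (!nrow(md)) .stopf("no samples in season '%s'", season)
  counts <- counts[, rownames(md), drop = FALSE]
  profiles <- unique(md$profile_id[md$layer == "DSL"])
  if (!length(profiles)) .stopf("no DSL profiles in season '%s'", season)

  sets <- lapply(profiles, function(p) layer_sets(counts, md, p))
  cats <- lapply(sets, partition_profile)

  meso_shared <- unique(unlist(lapply(cats, function(cc)
    names(cc)[cc %in% c("MS_only_shared", "MD_only_shared", "all_meso_shared")])))
  enriched_all <- character(0)
  if (!is.na(alpha) && length(meso_shared)) {
    enriched_all <- detect_enriched(counts, md, meso_shared, alpha = alpha,
                                    adjust = adjust)
  }

  relab <- relative_abundance(counts)
  out <- lapply(seq_along(profiles), function(i) {
    cc <- cats[[i]]
    n_dsl <- length(cc)
    tab <- table(cc)
    pct <- 100 * as.numeric(tab) / n_dsl
    names(pct) <- names(tab)
    dsl_cols <- rownames(md)[md$profile_id == profiles[i] & md$layer == "DSL"]
    ab_per_asv <- rowMeans(relab[names(cc), dsl_cols, drop = FALSE])
    ab <- vapply(.categories, function(k) sum(ab_per_asv[cc == k]), 0)
    enr <- intersect(names(cc), enriched_all)
    enr <- enr[cc[enr] %in% c("MS_only_shared", "MD_only_shared", "all_meso_shared")]
    list(profile_id = profiles[i], category = cc, enriched = enr,
         n_dsl = n_dsl, counts = as.numeric(tab), percent = pct,
         abundance = ab,
         percent_enriched = 100 * length(enr) / n_dsl,
         percent_meso_origin = sum(pct[c("MS_only_shared", "MD_only_shared",
                                         "all_meso_shared")]),
         percent_attributable = pct[["unique_DSL"]] + 100 * length(enr) / n_dsl)
  })
  names(out) <- profiles
  structure(out, class = "dsl_partition", season = season)
}

#' Average the per-profile partitions
#'
#' Mean percentage per category across profiles (the study's Fig-style
#' summary), mean DSL ASV total with its standard error, mean enriched
#' percentage and the DSL-attributable percentage (mean unique + mean
#' enriched).
#'
#' @param partition A `"dsl_partition"` object (or plain list of its
#'   elements).
#' @return List with `n_profiles`, `mean_percent` (named, the five
#'   categories), `mean_n_dsl`, `se_n_dsl`, `mean_percent_enriched`,
#'   `mean_percent_meso_origin`, `percent_attributable`.
#' @export
summarize_partition <- function(partition) {
  if (!length(partition)) .stopf("need at least one profile")
  pct <- do.call(rbind, lapply(partition, `[[`, "percent"))
  n_dsl <- vapply(partition, `[[`, 0, "n_dsl")
  enr <- vapply(partition, `[[`, 0, "percent_enriched")
  list(
    n_profiles = length(partition),
    mean_percent = colMeans(pct),
    mean_n_dsl = mean(n_dsl),
    se_n_dsl = if (length(n_dsl) > 1L) stats::sd(n_dsl) / sqrt(length(n_dsl)) else 0,
    mean_percent_enriched = mean(enr),
    mean_percent_meso_origin = mean(vapply(partition, `[[`, 0, "percent_meso_origin")),
    percent_attributable = colMeans(pct)[["unique_DSL"]] + mean(enr)
  )
}

#' Pooled DSL contribution to mesopelagic diversity
#'
#' Pools every mesopelagic (MS/DSL/MD) sample across profiles and reports the
#' ASVs present in DSL samples but in no MS or MD sample (pooled-unique), as a
#' fraction of all mesopelagic ASVs and of total mesopelagic reads; optionally
#' augmented with the DSL-enriched set.
#'
#' @param counts Count table.
#' @param metadata Sample metadata; MS and MD samples must exist somewhere.
#' @param enriched Optional character vector of enriched ASVs (e.g. from
#'   [detect_enriched()]) to add for the "unique + enriched" accounting.
#' @return List: `n_meso_asvs`, `n_unique`, `fraction_unique`,
#'   `abundance_unique` (share of mesopelagic reads), and, when `enriched` is
#'   given, `fraction_with_enriched` and `abundance_with_enriched`.
#' @export
pooled_contribution <- function(counts, metadata, enriched = NULL) {
  validate_metadata(metadata, counts)
  in_layer <- function(lay) {
    cols <- rownames(metadata)[metadata$layer == lay]
    intersect(cols, colnames(counts))
  }
  cols <- lapply(stats::setNames(.meso_layers, .meso_layers), in_layer)
  if (!length(cols$MS) || !length(cols$MD)) {
    .stopf("pooling undefined: need MS and MD samples somewhere in the dataset")
  }
  if (!length(cols$DSL)) .stopf("no DSL samples")
  present <- function(cc) {
    sub <- counts[, cc, drop = FALSE]
    rownames(sub)[rowSums(sub) > 0]
  }
  set_dsl <- present(cols$DSL)
  set_adj <- union(present(cols$MS), present(cols$MD))
  meso_asvs <- union(set_dsl, set_adj)
  uniq <- setdiff(set_dsl, set_adj)
  meso_cols <- unlist(cols, use.names = FALSE)
  reads <- rowSums(counts[, meso_cols, drop = FALSE])
  total_reads <- sum(reads)
  out <- list(
    n_meso_asvs = length(meso_asvs),
    n_unique = length(uniq),
    fraction_unique = length(uniq) / length(meso_asvs),
    abundance_unique = sum(reads[uniq]) / total_reads
  )
  if (!is.null(enriched)) {
    both <- union(uniq, intersect(enriched, meso_asvs))
    out$n_with_enriched <- length(both)
    out$fraction_with_enriched <- length(both) / length(meso_asvs)
    out$abundance_with_enriched <- sum(reads[both]) / total_reads
  }
  out
}

#' Seasonal presence overlap within one layer
#'
#' Splits the layer's ASVs by the combination of seasons they occur in (the
#' regions of a 3-way Venn diagram for three seasons) and reports, per region,
#' the ASV count, the fraction of the layer's ASV total and the fraction of
#' total relative abundance (mean per-sample relative abundance over all of
#' the layer's samples).
#'
#' @param counts Count table.
#' @param metadata Sample metadata.
#' @param layer Layer to analyse (default `"DSL"`); needs samples in at least
#'   two seasons.
#' @return Data.frame with one row per non-empty region: `region` (seasons
#'   joined by `+`), `n_asvs`, `fraction_asvs`, `fraction_abundance`.
#' @export
seasonal_overlap <- function(counts, metadata, layer = "DSL") {
  validate_metadata(metadata, counts)
  cols <- rownames(metadata)[metadata$layer == layer]
  cols <- intersect(cols, colnames(counts))
  if (!length(cols)) .stopf("layer '%s' has no samples", layer)
  season_of <- metadata[cols, "season"]
  seasons <- intersect(.seasons, unique(season_of))
  if (length(seasons) < 2L) .stopf("layer '%s' sampled in fewer than 2 seasons", layer)
  pres <- vapply(seasons, function(s) {
    rowSums(counts[, cols[season_of == s], drop = FALSE]) > 0
  }, logical(nrow(counts)))
  in_layer <- rowSums(pres) > 0
  pres <- pres[in_layer, , drop = FALSE]
  region <- apply(pres, 1L, function(z) paste(seasons[z], collapse = "+"))
  mean_ab <- rowMeans(.relab(counts[, cols, drop = FALSE]))[in_layer]
  total_ab <- sum(mean_ab)
  agg_n <- table(region)
  agg_ab <- tapply(mean_ab, region, sum)
  data.frame(
    region = names(agg_n),
    n_asvs = as.integer(agg_n),
    fraction_asvs = as.numeric(agg_n) / sum(agg_n),
    fraction_abundance = as.numeric(agg_ab[names(agg_n)]) / total_ab,
    row.names = NULL
  )
}
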