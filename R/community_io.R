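# Reading, validation, filtering and normalization of ASV community tables.
#
# The count table is a plain base-R matrix: one row per ASV, one column per
# sample, integer counts, unique dimnames. Taxonomy and metadata are
# data.frames. Validators below enforce the container contracts that every
# downstream operation relies on.

#' Validate an ASV count table
#'
#' A count table is a numeric matrix of non-negative integer read counts with
#' one row per ASV and one column per sample, both with unique identifiers.
#'
#' @param x Matrix to validate.
#' @return `x`, invisibly, if valid; otherwise an error describing the first
#'   violated invariant.
#' @export
validate_count_table <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    .stopf("count table must be a numeric matrix (got %s)", class(x)[1L])
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    .stopf("count table must carry ASV rownames and sample colnames")
  }
  if (anyDuplicated(rownames(x))) {
    .stopf("duplicated ASV ids: %s",
           paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(x))) {
    .stopf("duplicated sample ids: %s",
           paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  }
  if (anyNA(x) || any(x < 0)) .stopf("counts must be non-negative and non-missing")
  if (any(x != round(x))) .stopf("counts must be integers (found fractional values)")
  invisible(x)
}

#' Validate a taxonomy table
#'
#' Taxonomy is a data.frame with ASV ids as rownames and the ordered lineage
#' ranks domain, phylum, class, order, family, genus (species optional) as
#' character columns. `NA` (or empty string on disk) marks an unassigned rank.
#'
#' @param taxonomy Data.frame to validate.
#' @return `taxonomy`, invisibly.
#' @export
validate_taxonomy <- function(taxonomy) {
  if (!is.data.frame(taxonomy)) .stopf("taxonomy must be a data.frame")
  need <- .ranks[1:6]
  missing <- setdiff(need, colnames(taxonomy))
  if (length(missing)) {
    .stopf("taxonomy is missing rank column(s): %s", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(rownames(taxonomy))) .stopf("duplicated ASV ids in taxonomy")
  invisible(taxonomy)
}

#' Validate sample metadata
#'
#' Metadata is a data.frame with sample ids as rownames and mandatory columns
#' `station`, `season` (winter/spring/summer), `layer` (SURF/DCM/MS/DSL/MD),
#' `profile_id` and `depth_m` (> 0); any further columns are treated as
#' environmental covariates.
#'
#' @param metadata Data.frame to validate.
#' @param counts Optional count table; if given, every sample column must have
#'   a metadata record.
#' @return `metadata`, invisibly.
#' @export
validate_metadata <- function(metadata, counts = NULL) {
  if (!is.data.frame(metadata)) .stopf("metadata must be a data.frame")
  need <- c("station", "season", "layer", "profile_id", "depth_m")
  missing <- setdiff(need, colnames(metadata))
  if (length(missing)) {
    .stopf("metadata is missing column(s): %s", paste(missing, collapse = ", "))
  }
  bad <- setdiff(unique(metadata$season), .seasons)
  if (length(bad)) .stopf("unknown season value(s): %s", paste(bad, collapse = ", "))
  bad <- setdiff(unique(metadata$layer), .layers)
  if (length(bad)) .stopf("unknown layer value(s): %s", paste(bad, collapse = ", "))
  if (any(!is.finite(metadata$depth_m)) || any(metadata$depth_m <= 0)) {
    .stopf("depth_m must be finite and > 0")
  }
  if (anyDuplicated(rownames(metadata))) .stopf("duplicated sample ids in metadata")
  if (!is.null(counts)) {
    orphans <- setdiff(colnames(counts), rownames(metadata))
    if (length(orphans)) {
      .stopf("sample(s) in count table missing from metadata: %s",
             paste(orphans, collapse = ", "))
    }
  }
  invisible(metadata)
}

.read_tsv <- function(path, ...) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  out <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                      comment.char = "", quote = "", stringsAsFactors = FALSE, ...),
    error = function(e) .stopf("parse error in %s: %s", path, conditionMessage(e)))
  out
}

#' Read a community dataset (counts, taxonomy, metadata)
#'
#' @param count_path Tab-separated ASV x sample matrix (first column ASV id,
#'   header of sample ids), or, with `format = "triples"`, a three-column
#'   `asv_id` / `sample_id` / `count` table (BIOM-style sparse dialect).
#' @param taxonomy_path Tab-separated table: ASV id column plus rank columns
#'   domain..genus (species optional); `NA` or empty = unassigned. May be
#'   `NULL` (taxonomy optional and possibly partial).
#' @param metadata_path Tab-separated table with mandatory columns `sample_id`,
#'   `station`, `season`, `layer`, `profile_id`, `depth_m` and free covariate
#'   columns.
#' @param format `"tsv"` (dense matrix) or `"triples"`.
#' @return A list with elements `counts` (matrix), `taxonomy` (data.frame or
#'   `NULL`) and `metadata` (data.frame), all validated and cross-referenced.
#' @export
read_community <- function(count_path, taxonomy_path = NULL, metadata_path,
                           format = c("tsv", "triples")) {
  format <- match.arg(format)
  if (format == "tsv") {
    raw <- .read_tsv(count_path)
    if (anyDuplicated(raw[[1L]])) {
      .stopf("duplicated ASV ids in %s: %s", count_path,
             paste(unique(raw[[1L]][duplicated(raw[[1L]])]), collapse = ", "))
    }
    counts <- as.matrix(raw[, -1L, drop = FALSE])
    rownames(counts) <- as.character(raw[[1L]])
  } else {
    raw <- .read_tsv(count_path)
    if (ncol(raw) < 3L) .stopf("triples format needs columns asv_id, sample_id, count")
    counts <- unclass(stats::xtabs(raw[[3L]] ~ factor(raw[[1L]]) + factor(raw[[2L]])))
    dimnames(counts) <- lapply(dimnames(counts), as.character)
    names(dimnames(counts)) <- NULL
  }
  storage.mode(counts) <- "double"
  validate_count_table(counts)

  taxonomy <- NULL
  if (!is.null(taxonomy_path)) {
    tax_raw <- .read_tsv(taxonomy_path)
    if (anyDuplicated(tax_raw[[1L]])) .stopf("duplicated ASV ids in %s", taxonomy_path)
    taxonomy <- tax_raw[, -1L, drop = FALSE]
    rownames(taxonomy) <- as.character(tax_raw[[1L]])
    taxonomy[taxonomy == ""] <- NA
    validate_taxonomy(taxonomy)
  }

  md_raw <- .read_tsv(metadata_path)
  if (!"sample_id" %in% colnames(md_raw)) .stopf("metadata must have a sample_id column")
  metadata <- md_raw[, setdiff(colnames(md_raw), "sample_id"), drop = FALSE]
  rownames(metadata) <- as.character(md_raw$sample_id)
  validate_metadata(metadata, counts)

  list(counts = counts, taxonomy = taxonomy, metadata = metadata)
}

#' Write a community dataset as tab-separated text
#'
#' Inverse of [read_community()] for the dense dialect; round-trips exactly.
#'
#' @param counts,taxonomy,metadata As returned by [read_community()] or
#'   [generate_community()]; `taxonomy`/`metadata` may be `NULL` to skip.
#' @param count_path,taxonomy_path,metadata_path Output file paths.
#' @return Invisibly, the count path.
#' @export
write_community <- function(counts, taxonomy = NULL, metadata = NULL,
                            count_path, taxonomy_path = NULL, metadata_path = NULL) {
  validate_count_table(counts)
  df <- data.frame(asv_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, count_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(taxonomy) && !is.null(taxonomy_path)) {
    td <- data.frame(asv_id = rownames(taxonomy), taxonomy, check.names = FALSE)
    utils::write.table(td, taxonomy_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(metadata) && !is.null(metadata_path)) {
    md <- data.frame(sample_id = rownames(metadata), metadata, check.names = FALSE)
    utils::write.table(md, metadata_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(count_path)
}

#' Default taxon exclusion rules
#'
#' Drop ASVs whose domain is neither Bacteria nor Archaea, and ASVs carrying
#' Chloroplast or Mitochondria at any rank — the standard pre-analysis clean-up
#' for 16S surveys.
#'
#' @return A list of rules understood by [filter_taxa()]: each rule is a list
#'   with `rank` (a rank name, or `NULL` for any rank), `values` (taxon names)
#'   and `type` (`"keep_only"` flags lineages whose rank value is NOT in
#'   `values`; `"drop"` flags lineages whose value IS in `values`).
#' @export
default_exclude_rules <- function() {
  list(
    list(rank = "domain", type = "keep_only", values = c("Bacteria", "Archaea")),
    list(rank = NULL, type = "drop", values = c("Chloroplast", "Mitochondria"))
  )
}

#' Filter ASVs by taxonomic exclusion rules
#'
#' @param counts Count table.
#' @param taxonomy Taxonomy table.
#' @param rules List of rules (see [default_exclude_rules()]); an empty list
#'   returns the table unchanged.
#' @param missing Policy for ASVs present in `counts` but absent from
#'   `taxonomy`: `"drop"` (default, with a warning) or `"keep"`.
#' @return The count table restricted to rows not flagged by any rule; column
#'   order preserved, counts untouched.
#' @export
filter_taxa <- function(counts, taxonomy, rules = default_exclude_rules(),
                        missing = c("drop", "keep")) {
  validate_count_table(counts)
  validate_taxonomy(taxonomy)
  missing <- match.arg(missing)

  ids <- rownames(counts)
  known <- ids %in% rownames(taxonomy)
  if (any(!known)) {
    .warnf("%d ASV(s) missing from taxonomy (%s policy)", sum(!known), missing)
  }
  drop <- !known & (missing == "drop")

  if (any(known) && length(rules)) {
    lin <- taxonomy[ids[known], , drop = FALSE]
    flagged <- rep(FALSE, nrow(lin))
    for (rule in rules) {
      cols <- if (is.null(rule$rank)) colnames(lin) else rule$rank
      bad <- setdiff(cols, colnames(lin))
      if (length(bad)) .stopf("rule refers to unknown rank: %s", paste(bad, collapse = ", "))
      sub <- as.matrix(lin[, cols, drop = FALSE])
      hit <- switch(rule$type,
        keep_only = !(sub %in% rule$values),   # unassigned counts as "not kept"
        drop = sub %in% rule$values & !is.na(sub),
        .stopf("unknown rule type: %s", rule$type))
      hit <- matrix(hit, nrow = nrow(sub))
      flagged <- flagged | apply(hit, 1L, any)
    }
    drop[known] <- drop[known] | flagged
  }
  counts[!drop, , drop = FALSE]
}

#' Remove dataset-wide singleton ASVs
#'
#' Drops every ASV whose total count summed over all samples is below
#' `min_total` (default 2, i.e. exactly the singletons).
#'
#' @param counts Count table.
#' @param min_total Minimum dataset-wide total to retain a row.
#' @return Filtered count table; an empty result is allowed.
#' @export
remove_singletons <- function(counts, min_total = 2) {
  validate_count_table(counts)
  counts[rowSums(counts) >= min_total, , drop = FALSE]
}

#' Rarefy samples to a common depth
#'
#' Subsamples each sample's reads without replacement down to `depth`,
#' emulating normalization of all samples "to the minimum number of reads".
#'
#' @param counts Count table.
#' @param depth Target reads per sample (positive integer).
#' @param seed Optional integer seed; identical seeds give identical output and
#'   the caller's RNG stream is left untouched.
#' @return Count table of the same shape with every column summing to `depth`.
#'   Samples whose total is below `depth` raise an error naming them (drop them
#'   first, e.g. `counts[, colSums(counts) >= depth]`).
#' @export
rarefy <- function(counts, depth, seed = NULL) {
  validate_count_table(counts)
  if (length(depth) != 1L || !is.finite(depth) || depth < 1 || depth != round(depth)) {
    .stopf("depth must be a single positive integer")
  }
  totals <- colSums(counts)
  low <- totals < depth
  if (any(low)) {
    .stopf("sample(s) below rarefaction depth %d: %s", depth,
           paste(colnames(counts)[low], collapse = ", "))
  }
  out <- counts
  .with_seed(seed, {
    for (j in seq_len(ncol(counts))) {
      if (totals[j] == depth) next
      cs <- cumsum(counts[, j])
      picks <- sample.int(totals[j], depth)           # read positions kept
      rows <- findInterval(picks - 0.5, cs) + 1L      # position -> ASV row
      out[, j] <- tabulate(rows, nbins = nrow(counts))
    }
  })
  out
}

#' Column-wise relative abundances
#'
#' @param counts Count table (or any non-negative matrix) with positive column
#'   totals.
#' @return Matrix of the same shape; every column sums to 1.
#' @export
relative_abundance <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts)) .stopf("counts must be a numeric matrix")
  totals <- colSums(counts)
  zero <- !(totals > 0)
  if (any(zero)) {
    .stopf("all-zero sample(s): %s", paste(colnames(counts)[zero], collapse = ", "))
  }
  sweep(counts, 2L, totals, "/")
}

#' Aggregate a count table at a taxonomic rank
#'
#' Sums ASV counts within each distinct taxon at `rank`. ASVs unassigned at
#' that rank (or missing from the taxonomy entirely) are pooled into a single
#' `"unassigned"` row by default, so column totals are conserved exactly.
#'
#' @param counts Count table.
#' @param taxonomy Taxonomy table.
#' @param rank One of domain, phylum, class, order, family, genus.
#' @param unassigned `"pool"` (default) or `"drop"`.
#' @return Aggregated count table, one row per taxon at `rank`.
#' @export
aggregate_rank <- function(counts, taxonomy, rank, unassigned = c("pool", "drop")) {
  validate_count_table(counts)
  validate_taxonomy(taxonomy)
  unassigned <- match.arg(unassigned)
  if (!rank %in% .ranks[1:6]) {
    .stopf("unknown rank '%s' (expected one of %s)", rank,
           paste(.ranks[1:6], collapse = ", "))
  }
  taxa <- rep(NA_character_, nrow(counts))
  hit <- rownames(counts) %in% rownames(taxonomy)
  taxa[hit] <- as.character(taxonomy[rownames(counts)[hit], rank])
  if (unassigned == "pool") {
    taxa[is.na(taxa)] <- "unassigned"
  } else {
    counts <- counts[!is.na(taxa), , drop = FALSE]
    taxa <- taxa[!is.na(taxa)]
  }
  rowsum(counts, group = taxa)
}
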