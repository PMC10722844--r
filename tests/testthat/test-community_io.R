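# IO, validation, filtering and normalization.

test_that("read_community round-trips a written synthetic table exactly", {
  sim <- generate_community(community_spec(
    n_cosmopolitan = 5L, n_surface = 2L, n_dcm = 2L, n_meso_generalist = 5L,
    n_dsl_unique = 2L, n_dsl_enriched = 2L, n_indicator = 1L,
    n_profiles = c(spring = 2L), depth = 500L, seed = 11L))
  dir <- withr::local_tempdir()
  paths <- file.path(dir, c("counts.tsv", "tax.tsv", "meta.tsv"))
  write_community(sim$counts, sim$taxonomy, sim$metadata,
                  paths[1], paths[2], paths[3])
  back <- read_community(paths[1], paths[2], paths[3])
  expect_identical(back$counts, sim$counts)
  expect_identical(dim(back$taxonomy), dim(sim$taxonomy))
  expect_identical(back$metadata$layer, sim$metadata$layer)
})

test_that("read_community reads the sparse triples dialect", {
  dir <- withr::local_tempdir()
  triples <- data.frame(asv_id = c("A1", "A1", "A2"),
                        sample_id = c("S1", "S2", "S1"),
                        count = c(3L, 1L, 2L))
  write.table(triples, file.path(dir, "triples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  md <- data.frame(sample_id = c("S1", "S2"), station = "st01",
                   season = "spring", layer = c("SURF", "DSL"),
                   profile_id = "P1", depth_m = c(5, 550))
  write.table(md, file.path(dir, "meta.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  out <- read_community(file.path(dir, "triples.tsv"), NULL,
                        file.path(dir, "meta.tsv"), format = "triples")
  expect_equal(out$counts["A1", "S1"], 3)
  expect_equal(out$counts["A2", "S2"], 0)
})

test_that("cross-reference and duplicate errors name the offenders", {
  x <- make_counts(matrix(1:6, 3, 2), samp = c("S1", "S9"))
  md <- profile_metadata("SURF")
  rownames(md) <- "S1"
  expect_error(validate_metadata(md, x), "S9")
  bad <- x
  rownames(bad) <- c("A1", "A1", "A2")
  expect_error(validate_count_table(bad), "duplicated ASV ids.*A1")
  neg <- x; neg[1, 1] <- -1
  expect_error(validate_count_table(neg), "non-negative")
  frac <- x; frac[1, 1] <- 0.5
  expect_error(validate_count_table(frac), "integers")
})

test_that("filter_taxa drops chloroplasts/mitochondria and non-prokaryotes", {
  x <- make_counts(matrix(5L, 4, 2), asv = paste0("A", 1:4))
  tax <- tiny_taxonomy(paste0("A", 1:4))
  tax["A2", "order"] <- "Chloroplast"
  tax["A3", "domain"] <- "Eukaryota"
  out <- filter_taxa(x, tax)
  expect_setequal(rownames(out), c("A1", "A4"))
  # unassigned domain is removed by the keep_only rule too
  tax2 <- tiny_taxonomy(paste0("A", 1:4))
  tax2["A1", "domain"] <- NA
  expect_false("A1" %in% rownames(filter_taxa(x, tax2)))
})

test_that("filter_taxa with empty rules is the identity; random set-difference oracle", {
  x <- rand_counts(10, 3, seed = 1)
  tax <- tiny_taxonomy(rownames(x))
  expect_identical(filter_taxa(x, tax, rules = list()), x)

  flagged <- rownames(x)[c(2, 5, 9)]
  tax[flagged, "order"] <- "Mitochondria"
  out <- filter_taxa(x, tax)
  expect_identical(rownames(out), setdiff(rownames(x), flagged))
  expect_identical(out, x[setdiff(rownames(x), flagged), ])
})

test_that("ASVs missing from taxonomy follow the drop/keep policy", {
  x <- rand_counts(4, 2, seed = 2)
  tax <- tiny_taxonomy(rownames(x)[1:3])
  expect_warning(out <- filter_taxa(x, tax), "missing from taxonomy")
  expect_false(rownames(x)[4] %in% rownames(out))
  expect_warning(kept <- filter_taxa(x, tax, missing = "keep"), "missing")
  expect_true(rownames(x)[4] %in% rownames(kept))
})

test_that("remove_singletons uses the dataset-wide total and is idempotent", {
  x <- make_counts(rbind(c(1, 0, 0), c(1, 1, 0), c(0, 0, 5)))
  out <- remove_singletons(x)
  expect_setequal(rownames(out), c("ASV02", "ASV03"))

  r <- rand_counts(50, 4, lambda = 0.3, seed = 3)
  out <- remove_singletons(r)
  expect_identical(rownames(out), rownames(r)[rowSums(r) >= 2])
  expect_identical(remove_singletons(out), out)
})

test_that("taxa filtering and singleton removal commute", {
  x <- rand_counts(30, 3, lambda = 0.5, seed = 4)
  tax <- tiny_taxonomy(rownames(x))
  tax[seq(1, 30, by = 7), "domain"] <- "Eukaryota"
  a <- remove_singletons(filter_taxa(x, tax))
  b <- filter_taxa(remove_singletons(x), tax)
  expect_identical(a, b)
})

test_that("rarefy: totals, determinism, bounds and edge cases", {
  x <- make_counts(rbind(c(50, 100), c(50, 0)))
  expect_identical(rarefy(x, 100, seed = 1)[, 2], c(ASV01 = 100, ASV02 = 0))
  out <- rarefy(x, 60, seed = 9)
  expect_true(all(colSums(out) == 60))
  expect_true(all(out <= x))
  expect_identical(out, rarefy(x, 60, seed = 9))
  expect_error(rarefy(x, 150), "below rarefaction depth 150.*S01")

  single <- make_counts(matrix(c(200), 1, 1))
  expect_equal(as.numeric(rarefy(single, 37, seed = 2)), 37)
})

test_that("rarefied counts match the hypergeometric expectation", {
  col <- c(300, 120, 60, 20)
  x <- make_counts(matrix(col, ncol = 1))
  depth <- 250
  total <- sum(col)
  draws <- vapply(1:1000, function(s) rarefy(x, depth, seed = s)[, 1],
                  numeric(4))
  mu <- depth * col / total
  v <- depth * (col / total) * (1 - col / total) * (total - depth) / (total - 1)
  se <- sqrt(v / 1000)
  expect_true(all(abs(rowMeans(draws) - mu) < 3 * se + 1e-9))
})

test_that("relative_abundance normalizes columns and rejects empty samples", {
  x <- make_counts(rbind(c(2, 82130), c(2, 0)))
  ra <- relative_abundance(x)
  expect_equal(ra[, 1], c(ASV01 = 0.5, ASV02 = 0.5))
  expect_equal(ra[, 2], c(ASV01 = 1, ASV02 = 0))
  r <- rand_counts(20, 5, seed = 5) + 1
  expect_true(all(abs(colSums(relative_abundance(r)) - 1) < 1e-12))
  bad <- make_counts(cbind(c(1, 1), c(0, 0)))
  expect_error(relative_abundance(bad), "S02")
})

test_that("aggregate_rank sums within taxa and conserves column totals", {
  x <- rand_counts(8, 3, seed = 6)
  tax <- tiny_taxonomy(rownames(x))
  agg <- aggregate_rank(x, tax, "phylum")
  expect_identical(colSums(agg), colSums(x))
  # three ASVs of one phylum collapse to one summed row
  protbact <- rownames(tax)[tax$phylum == "Proteobacteria"]
  expect_equal(agg["Proteobacteria", ], colSums(x[protbact, ]))
  expect_error(aggregate_rank(x, tax, "kingdom"), "unknown rank")
})

test_that("genus-level aggregation re-aggregated to phylum equals direct phylum", {
  x <- rand_counts(8, 3, seed = 7)
  tax <- tiny_taxonomy(rownames(x))
  by_genus <- aggregate_rank(x, tax, "genus")
  genus_map <- unique(tax[, c("domain", "phylum", "class", "order", "family", "genus")])
  rownames(genus_map) <- genus_map$genus
  direct <- aggregate_rank(x, tax, "phylum")
  redone <- aggregate_rank(by_genus, genus_map, "phylum")
  expect_identical(direct[rownames(redone), ], redone)
})

test_that("unassigned handling pools by default, drops on request", {
  x <- rand_counts(4, 2, seed = 8)
  tax <- tiny_taxonomy(rownames(x))
  tax[1, "phylum"] <- NA
  pooled <- aggregate_rank(x, tax, "phylum")
  expect_true("unassigned" %in% rownames(pooled))
  expect_identical(colSums(pooled), colSums(x))
  dropped <- aggregate_rank(x, tax, "phylum", unassigned = "drop")
  expect_false("unassigned" %in% rownames(dropped))
})
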