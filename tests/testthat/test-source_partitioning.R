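# Layer sets, DSL source classification, enrichment flags, summaries.

# Occupancy-driven fixture: one profile, binary presence matrix
# (rows = ASVs, columns = SURF, DCM, MS, DSL, MD), counts = presence * 10.
occupancy_fixture <- function(occ, layers = c("SURF", "DCM", "MS", "DSL", "MD")) {
  md <- profile_metadata(layers)
  counts <- make_counts(occ * 10L, samp = rownames(md))
  # guard: relative_abundance & friends need non-empty samples
  counts <- rbind(counts, BG = rep(10L, ncol(counts)))
  rownames(counts)[nrow(counts)] <- "BG"
  list(counts = counts, md = md)
}

test_that("layer_sets equals a brute-force column scan and merges EPI", {
  occ <- rbind(A1 = c(1, 0, 0, 1, 1),   # SURF + DSL + MD
               A2 = c(0, 0, 0, 1, 0),   # DSL only
               A3 = c(0, 1, 1, 0, 0))   # DCM + MS
  f <- occupancy_fixture(occ)
  sets <- layer_sets(f$counts, f$md, "P1")
  expect_setequal(sets$EPI, c("A1", "A3", "BG"))
  expect_setequal(sets$DSL, c("A1", "A2", "BG"))
  expect_setequal(sets$MD, c("A1", "BG"))
  expect_setequal(sets$MS, c("A3", "BG"))
  # brute force over every layer
  for (lay in c("SURF", "DCM", "MS", "DSL", "MD")) {
    cols <- rownames(f$md)[f$md$layer == lay]
    expect_setequal(sets[[lay]],
                    rownames(f$counts)[f$counts[, cols] > 0])
  }
})

test_that("layer_sets enforces profile preconditions", {
  occ <- rbind(A1 = c(1, 1, 1))
  f <- occupancy_fixture(occ, layers = c("SURF", "DCM", "MS"))
  expect_error(layer_sets(f$counts, f$md, "P1"), "no DSL sample")
  f2 <- occupancy_fixture(rbind(A1 = c(1, 1)), layers = c("MS", "DSL"))
  expect_error(layer_sets(f2$counts, f2$md, "P1"), "epipelagic")
  f3 <- occupancy_fixture(rbind(A1 = c(1, 1)), layers = c("SURF", "DSL"))
  expect_warning(expect_warning(layer_sets(f3$counts, f3$md, "P1"), "MS"), "MD")
})

test_that("partition_profile matches the 8-pattern truth table", {
  # all membership patterns of (EPI, MS, MD) for a DSL ASV
  patterns <- expand.grid(epi = c(FALSE, TRUE), ms = c(FALSE, TRUE),
                          md = c(FALSE, TRUE))
  expected <- with(patterns, ifelse(epi, "EPI_shared",
                     ifelse(!ms & !md, "unique_DSL",
                     ifelse(ms & md, "all_meso_shared",
                     ifelse(ms, "MS_only_shared", "MD_only_shared")))))
  occ <- cbind(SURF = as.integer(patterns$epi), DCM = 0L,
               MS = as.integer(patterns$ms), DSL = 1L,
               MD = as.integer(patterns$md))
  rownames(occ) <- sprintf("A%d", seq_len(nrow(occ)))
  f <- occupancy_fixture(occ)
  cat <- partition_profile(layer_sets(f$counts, f$md, "P1"))
  expect_identical(as.character(cat[rownames(occ)]), expected)
  # disjoint and exhaustive over the DSL set
  expect_false(anyNA(cat))
  expect_setequal(names(cat), c(rownames(occ), "BG"))
})

test_that("EPI has precedence and DCM counts as epipelagic", {
  occ <- rbind(A1 = c(0, 1, 1, 1, 1))   # DCM + all meso
  f <- occupancy_fixture(occ)
  cat <- partition_profile(layer_sets(f$counts, f$md, "P1"))
  expect_identical(as.character(cat[["A1"]]), "EPI_shared")
})

test_that("adding an MS occurrence never creates EPI_shared", {
  withr::with_seed(51, {
    for (i in 1:20) {
      occ <- matrix(rbinom(5 * 5, 1, 0.5), 5, 5)
      occ[, 4] <- 1L   # all in DSL
      rownames(occ) <- sprintf("A%d", 1:5)
      f <- occupancy_fixture(occ)
      before <- partition_profile(layer_sets(f$counts, f$md, "P1"))
      pick <- sample(5, 1)
      bumped <- f$counts
      bumped[pick, "P1_MS"] <- 10L
      after <- partition_profile(layer_sets(bumped, f$md, "P1"))
      id <- rownames(occ)[pick]
      if (before[[id]] == "EPI_shared") {
        expect_identical(after[[id]], before[[id]])
      } else {
        expect_true(as.character(after[[id]]) %in%
                      c("MS_only_shared", "all_meso_shared"))
      }
      others <- setdiff(names(before), id)
      expect_identical(after[others], before[others])
    }
  })
})

# 5-profile spring community with a 10x DSL-enriched taxon, a flat taxon and
# an MS-skewed taxon, low sampling noise.
enrichment_fixture <- function(seed = 52, fold = 10) {
  md <- spring_metadata(5)
  withr::with_seed(seed, {
    n <- nrow(md)
    enr <- ifelse(md$layer == "DSL", 100 * fold, 100) + rpois(n, 4)
    flat <- rep(200, n) + rpois(n, 4)
    ms <- ifelse(md$layer == "MS", 800, 100) + rpois(n, 4)
    bg <- rep(2000, n) + rpois(n, 10)
    counts <- make_counts(rbind(ENR = enr, FLAT = flat, MSUP = ms, BG = bg),
                          samp = rownames(md))
  })
  list(counts = counts, md = md)
}

test_that("detect_enriched flags the planted taxon and only it", {
  f <- enrichment_fixture()
  enr <- detect_enriched(f$counts, f$md, c("ENR", "FLAT", "MSUP"))
  expect_identical(enr, "ENR")
})

test_that("detect_enriched requires DSL to dominate and enough replicates", {
  # exactly constant relative abundance: zero between-layer variance
  md <- spring_metadata(3)
  counts <- make_counts(rbind(A = rep(50L, nrow(md)), BG = rep(950L, nrow(md))),
                        samp = rownames(md))
  expect_identical(detect_enriched(counts, md, "A"), character(0))
  # single profile: every mesopelagic layer has one replicate -> skip + warn
  md1 <- spring_metadata(1)
  c1 <- make_counts(rbind(A = c(10L, 10L, 5L, 50L, 5L), BG = rep(100L, 5)),
                    samp = rownames(md1))
  expect_warning(out <- detect_enriched(c1, md1, "A"), "skipped")
  expect_identical(out, character(0))
})

test_that("10x planted enrichment is detected in >= 95% of runs", {
  hits <- sum(vapply(1:100, function(i) {
    f <- enrichment_fixture(seed = 1000 + i)
    identical(detect_enriched(f$counts, f$md, c("ENR", "FLAT", "MSUP")), "ENR")
  }, logical(1)))
  expect_gte(hits, 95)
})

test_that("partition percentages are exhaustive and sum to 100", {
  sim <- generate_community(community_spec(seed = 53, depth = 10000,
                                           n_profiles = c(spring = 3L)))
  pt <- partition_dsl(sim$counts, sim$metadata, "spring", alpha = NA)
  for (pr in pt) {
    expect_equal(sum(pr$percent), 100, tolerance = 1e-9)
    expect_equal(sum(pr$counts), pr$n_dsl)
    expect_equal(sum(pr$abundance),
                 sum(relative_abundance(sim$counts)[names(pr$category),
                     paste0(pr$profile_id, "_DSL")]), tolerance = 1e-12)
  }
})

test_that("summarize_partition: single profile identity and linearity", {
  sim <- generate_community(community_spec(seed = 54, depth = 5000,
                                           n_profiles = c(spring = 2L)))
  pt <- partition_dsl(sim$counts, sim$metadata, "spring", alpha = NA)
  s1 <- summarize_partition(pt[1])
  expect_equal(s1$mean_percent, pt[[1]]$percent[names(s1$mean_percent)])
  expect_equal(s1$mean_n_dsl, pt[[1]]$n_dsl)
  s <- summarize_partition(pt)
  expect_equal(sum(s$mean_percent), 100, tolerance = 1e-9)
  expect_equal(s$mean_percent_meso_origin,
               sum(s$mean_percent[c("MS_only_shared", "MD_only_shared",
                                    "all_meso_shared")]))
})

test_that("pooled_contribution equals brute-force set arithmetic", {
  md <- spring_metadata(3)
  withr::with_seed(55, {
    occ <- matrix(rbinom(20 * nrow(md), 1, 0.4), 20, nrow(md))
    occ[1, ] <- 1L
    counts <- make_counts(occ * (5L + matrix(rpois(20 * nrow(md), 3),
                                             20, nrow(md))),
                          samp = rownames(md))
  })
  pc <- pooled_contribution(counts, md)
  meso_cols <- rownames(md)[md$layer %in% c("MS", "DSL", "MD")]
  pres <- function(lay) {
    cols <- rownames(md)[md$layer == lay]
    rownames(counts)[rowSums(counts[, cols, drop = FALSE]) > 0]
  }
  uniq <- setdiff(pres("DSL"), union(pres("MS"), pres("MD")))
  allm <- union(pres("DSL"), union(pres("MS"), pres("MD")))
  expect_equal(pc$n_unique, length(uniq))
  expect_equal(pc$fraction_unique, length(uniq) / length(allm))
  reads <- rowSums(counts[, meso_cols])
  expect_equal(pc$abundance_unique, sum(reads[uniq]) / sum(reads))

  # enriched augmentation is a superset accounting
  pc2 <- pooled_contribution(counts, md, enriched = allm[1:2])
  expect_gte(pc2$fraction_with_enriched, pc$fraction_unique)
})

test_that("pooled_contribution edge cases", {
  md <- spring_metadata(2)
  n <- nrow(md)
  # no DSL-exclusive ASVs
  counts <- make_counts(matrix(5L, 4, n), samp = rownames(md))
  expect_equal(pooled_contribution(counts, md)$fraction_unique, 0)
  # all DSL ASVs exclusive
  counts2 <- counts
  counts2[1:2, md$layer %in% c("MS", "MD")] <- 0L
  counts2[3:4, md$layer == "DSL"] <- 0L
  pc <- pooled_contribution(counts2, md)
  expect_equal(pc$fraction_unique, 2 / 4)
  # pooling undefined without MS/MD anywhere
  md3 <- md[md$layer %in% c("SURF", "DSL"), ]
  expect_error(pooled_contribution(counts[, rownames(md3)], md3), "MS and MD")
})

test_that("seasonal_overlap regions match brute-force enumeration", {
  md <- do.call(rbind, lapply(c("winter", "spring", "summer"), function(s) {
    m <- profile_metadata("DSL", profile = paste0("P", s), season = s)
    rbind(m, `rownames<-`(profile_metadata("DSL", profile = paste0("Q", s),
                                           season = s),
                          paste0("Q", s, "_DSL")))
  }))
  withr::with_seed(56, {
    occ <- matrix(rbinom(12 * nrow(md), 1, 0.5), 12, nrow(md))
    occ[1, ] <- 1L
    counts <- make_counts(occ * 10L, samp = rownames(md))
  })
  so <- seasonal_overlap(counts, md, "DSL")
  expect_equal(sum(so$fraction_asvs), 1)
  expect_equal(sum(so$fraction_abundance), 1, tolerance = 1e-12)
  # brute force: triple intersection count
  pres <- vapply(c("winter", "spring", "summer"), function(s) {
    cols <- rownames(md)[md$season == s]
    rowSums(counts[, cols, drop = FALSE]) > 0
  }, logical(12))
  triple <- sum(rowSums(pres) == 3)
  expect_equal(so$n_asvs[so$region == "winter+spring+summer"], triple)
  expect_equal(sum(so$n_asvs), sum(rowSums(pres) > 0))
})

test_that("seasonal_overlap degenerate designs", {
  md <- do.call(rbind, lapply(c("winter", "spring", "summer"), function(s)
    profile_metadata("DSL", profile = paste0("P", s), season = s)))
  # identical presence in all seasons: everything in the triple region
  counts <- make_counts(matrix(7L, 5, 3), samp = rownames(md))
  so <- seasonal_overlap(counts, md, "DSL")
  expect_equal(nrow(so), 1L)
  expect_equal(so$fraction_asvs, 1)
  # pairwise-disjoint seasons: no triple region
  counts2 <- make_counts(rbind(c(5L, 0L, 0L), c(0L, 5L, 0L), c(0L, 0L, 5L)),
                         samp = rownames(md))
  so2 <- seasonal_overlap(counts2, md, "DSL")
  expect_false("winter+spring+summer" %in% so2$region)
  expect_equal(sum(so2$n_asvs), 3L)
  expect_error(seasonal_overlap(counts, md, "MS"), "no samples")
})
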