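# Shared fixture builders. All fixtures are constructed in code; no files on
# disk beyond tempfiles created inside individual tests.

make_counts <- function(mat, asv = NULL, samp = NULL) {
  if (is.null(asv)) {
    asv <- if (!is.null(rownames(mat))) rownames(mat) else
      sprintf("ASV%02d", seq_len(nrow(mat)))
  }
  if (is.null(samp)) {
    samp <- if (!is.null(colnames(mat))) colnames(mat) else
      sprintf("S%02d", seq_len(ncol(mat)))
  }
  dimnames(mat) <- list(asv, samp)
  mat
}

rand_counts <- function(n_asv, n_samp, lambda = 5, seed = NULL) {
  draw <- function() make_counts(matrix(stats::rpois(n_asv * n_samp, lambda),
                                        n_asv, n_samp))
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# One-profile metadata over a set of layers (one sample per layer).
profile_metadata <- function(layers, profile = "P1", season = "spring") {
  depth <- c(SURF = 5, DCM = 80, MS = 275, DSL = 550, MD = 825)
  md <- data.frame(
    station = "st01", season = season, layer = layers, profile_id = profile,
    depth_m = depth[layers],
    row.names = paste0(profile, "_", layers))
  md
}

# Multi-profile spring metadata: one sample per layer per profile.
spring_metadata <- function(n_profiles, layers = c("SURF", "DCM", "MS", "DSL", "MD")) {
  do.call(rbind, lapply(seq_len(n_profiles), function(i) {
    profile_metadata(layers, profile = sprintf("P%02d", i))
  }))
}

# Tiny fully-assigned taxonomy for a set of ASV ids, cycling through a pool.
tiny_taxonomy <- function(asv_ids) {
  pool <- data.frame(
    domain = c("Bacteria", "Bacteria", "Bacteria", "Archaea"),
    phylum = c("Proteobacteria", "Proteobacteria", "Bacteroidetes", "Thaumarchaeota"),
    class = c("Alphaproteobacteria", "Gammaproteobacteria", "Bacteroidia", "Nitrososphaeria"),
    order = c("SAR11 clade", "Alteromonadales", "Flavobacteriales", "Nitrosopumilales"),
    family = c("Clade I", "Alteromonadaceae", "Flavobacteriaceae", "Nitrosopumilaceae"),
    genus = c("Clade Ia", "Alteromonas", "NS5", "Nitrosopumilus"))
  out <- pool[rep_len(seq_len(nrow(pool)), length(asv_ids)), , drop = FALSE]
  rownames(out) <- asv_ids
  out
}
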