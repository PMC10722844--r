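# Internal helpers shared across modules.

# Controlled vocabularies used throughout the survey design.
.seasons <- c("winter", "spring", "summer")
.layers <- c("SURF", "DCM", "MS", "DSL", "MD")
.epi_layers <- c("SURF", "DCM")
.meso_layers <- c("MS", "DSL", "MD")
.ranks <- c("domain", "phylum", "class", "order", "family", "genus", "species")

#' Layer vocabularies
#'
#' The five sampled depth layers and their grouping into the epipelagic
#' (SURF, DCM) and mesopelagic (MS, DSL, MD) zones.
#'
#' @return Character vector of layer codes.
#' @export
dsl_layers <- function() .layers

#' @rdname dsl_layers
#' @export
epipelagic_layers <- function() .epi_layers

#' @rdname dsl_layers
#' @export
mesopelagic_layers <- function() .meso_layers

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL means "use the current stream".
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Column-wise relative abundances without the validation overhead of the
# exported relative_abundance(); assumes positive column totals.
.relab <- function(x) sweep(x, 2L, colSums(x), "/")
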