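# Biological index (BIX) of DOM fluorescence from excitation-emission
# matrices, plus a synthetic EEM constructor for testing.

# Linear interpolation of EEM rows (excitation) to a target wavelength,
# returning the emission spectrum at that excitation.
.eem_row_at <- function(eem, ex) {
  ex_grid <- as.numeric(rownames(eem))
  if (anyNA(ex_grid)) .stopf("EEM rownames must be numeric excitation wavelengths (nm)")
  if (ex < min(ex_grid) || ex > max(ex_grid)) {
    .stopf("excitation %g nm outside EEM grid [%g, %g]", ex, min(ex_grid), max(ex_grid))
  }
  if (ex %in% ex_grid) return(eem[match(ex, ex_grid), ])
  hi <- which(ex_grid > ex)[1L]
  lo <- hi - 1L
  w <- (ex - ex_grid[lo]) / (ex_grid[hi] - ex_grid[lo])
  (1 - w) * eem[lo, ] + w * eem[hi, ]
}

.spectrum_at <- function(spec, em_grid, em) {
  if (em < min(em_grid) || em > max(em_grid)) {
    .stopf("emission %g nm outside EEM grid [%g, %g]", em, min(em_grid), max(em_grid))
  }
  stats::approx(em_grid, spec, xout = em)$y
}

#' Biological index of DOM (BIX)
#'
#' Ratio of fluorescence emission at 380 nm over 430 nm at 310 nm excitation.
#' Values near or above 1 indicate recently produced, autochthonous DOM.
#' Wavelengths falling between grid points are linearly interpolated.
#'
#' @param eem Excitation-emission matrix: numeric matrix with excitation
#'   wavelengths (nm) as rownames and emission wavelengths (nm) as colnames.
#' @param excitation,em_numerator,em_denominator Wavelengths (nm) defining the
#'   index; defaults give the standard BIX.
#' @return The dimensionless ratio.
#' @export
bix <- function(eem, excitation = 310, em_numerator = 380, em_denominator = 430) {
  if (!is.matrix(eem) || !is.numeric(eem)) .stopf("EEM must be a numeric matrix")
  em_grid <- as.numeric(colnames(eem))
  if (anyNA(em_grid)) .stopf("EEM colnames must be numeric emission wavelengths (nm)")
  spec <- .eem_row_at(eem, excitation)
  num <- .spectrum_at(spec, em_grid, em_numerator)
  den <- .spectrum_at(spec, em_grid, em_denominator)
  if (!is.finite(den) || den == 0) .stopf("zero or non-finite denominator emission")
  num / den
}

#' Synthetic EEM with a prescribed BIX
#'
#' Builds a smooth, separable excitation-emission matrix (Gaussian excitation
#' band around 310 nm times a piecewise-linear emission profile) whose [bix()]
#' evaluates to `target_bix` exactly, including when 310/380/430 nm fall
#' between grid points: the emission profile is linear over 370-445 nm, so
#' linear interpolation reproduces it without error.
#'
#' @param target_bix Desired BIX (must lie in (0.2, 4) so the emission profile
#'   stays positive over the grid).
#' @param excitation,emission Wavelength grids in nm (defaults: 3 nm steps,
#'   240-600 and 250-600 as used by bench spectrofluorometers).
#' @return EEM matrix suitable for [bix()].
#' @export
generate_eem <- function(target_bix, excitation = seq(240, 600, by = 3),
                         emission = seq(250, 600, by = 3)) {
  if (target_bix <= 0.2 || target_bix >= 4) {
    .stopf("target_bix must be in (0.2, 4) for a positive emission profile")
  }
  if (min(excitation) > 310 || max(excitation) < 310) .stopf("excitation grid must cover 310 nm")
  if (min(emission) > 380 || max(emission) < 430) .stopf("emission grid must cover 380-430 nm")
  # Neighbours of 380 and 430 nm must fall inside the linear 370-445 segment.
  for (wl in c(380, 430)) {
    lo <- max(emission[emission <= wl]); hi <- min(emission[emission >= wl])
    if (lo < 370 || hi > 445) .stopf("emission grid too coarse around %g nm", wl)
  }
  slope <- (1 - target_bix) / 50          # through (380, target) and (430, 1)
  h <- function(em) {
    em <- pmin(pmax(em, 370), 445)        # flat outside the linear segment
    target_bix + slope * (em - 380)
  }
  g <- 0.2 + exp(-((excitation - 310) / 60)^2)
  eem <- outer(g, h(emission))
  dimnames(eem) <- list(excitation, emission)
  eem
}
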