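# Vegetation indices from four-band reflectance.
#
# The 14 candidate remote-sensing variables are the four HJ-CCD-style band
# reflectances plus ten classical vegetation indices. The index algebra is
# kept exactly as used in the GPC study this pipeline reproduces; note the
# EVI there carries the green band in its soil/aerosol term where the
# standard formulation uses blue — both variants are available.

#' Canonical names of the 14 remote-sensing variables
#' @return Character vector of variable names in canonical column order.
#' @export
variable_names <- function() {
  c("R_blue", "R_green", "R_red", "R_nir",
    "NDVI", "SAVI", "OSAVI", "NRI", "GNDVI",
    "SIPI", "PSRI", "EVI", "DVI", "RVI")
}

#' Compute the ten vegetation indices for band samples
#'
#' Vectorized evaluation of: NDVI, SAVI, OSAVI, NRI, GNDVI, SIPI, PSRI,
#' EVI, DVI, RVI from the four band reflectances. Samples with a zero
#' denominator in any ratio (e.g. `r_red = 0` for RVI) are flagged: their
#' index values are set to `NA` and the logical attribute `flagged` marks
#' them, rather than emitting infinities.
#'
#' @param samples Data frame with columns `r_blue`, `r_green`, `r_red`,
#'   `r_nir`, all in `[0, 1]`.
#' @param evi_variant `"green"` (default) uses the green band in the EVI
#'   soil/aerosol-resistance term
#'   (`2.5 (NIR - red) / (NIR + 6 red - 7.5 green + 1)`), the four-band
#'   formulation this pipeline reproduces; `"blue"` is the standard EVI
#'   with the blue band in that term.
#' @return Data frame of the ten indices with attribute `flagged`
#'   (logical per row).
#' @export
#' @examples
#' compute_indices(data.frame(r_blue = 0.05, r_green = 0.08,
#'                            r_red = 0.10, r_nir = 0.50))
compute_indices <- function(samples, evi_variant = c("green", "blue")) {
  evi_variant <- match.arg(evi_variant)
  stopifnot(all(band_names() %in% names(samples)))
  b <- samples$r_blue; g <- samples$r_green
  r <- samples$r_red;  n <- samples$r_nir
  if (anyNA(c(b, g, r, n))) {
    stop("band reflectances contain missing values", call. = FALSE)
  }
  if (any(c(b, g, r, n) < 0 | c(b, g, r, n) > 1)) {
    stop("band reflectances must lie in [0, 1]", call. = FALSE)
  }
  evi_den <- if (evi_variant == "green") n + 6 * r - 7.5 * g + 1
             else n + 6 * r - 7.5 * b + 1
  flagged <- (n + r) == 0 | (g + r) == 0 | (n + g) == 0 | (n + b) == 0 |
    n == 0 | r == 0 | evi_den == 0
  out <- data.frame(
    NDVI  = (n - r) / (n + r),
    SAVI  = (n - r) / (n + r + 0.5) * 1.5,
    OSAVI = (n - r) / (n + r + 0.16) * 1.16,
    NRI   = (g - r) / (g + r),
    GNDVI = (n - g) / (n + g),
    SIPI  = (n - b) / (n + b),
    PSRI  = (r - b) / n,
    EVI   = 2.5 * (n - r) / evi_den,
    DVI   = n - r,
    RVI   = n / r
  )
  out[flagged, ] <- NA_real_
  attr(out, "flagged") <- flagged
  out
}

#' Build the n x 14 variable table from band samples
#'
#' Combines the four band reflectances (renamed to `R_blue` ... `R_nir`)
#' with the ten indices of [compute_indices()], in the canonical order of
#' [variable_names()]. Samples flagged for a degenerate denominator are
#' excluded, with a message reporting the count. A `gpc` column is attached
#' as response when present in `samples`.
#'
#' @inheritParams compute_indices
#' @return A data frame of class `variable_table` with the 14 variable
#'   columns and, when available, `gpc`.
#' @export
build_variable_table <- function(samples, evi_variant = c("green", "blue")) {
  if (nrow(samples) < 1) stop("at least one sample required", call. = FALSE)
  idx <- compute_indices(samples, evi_variant)
  flagged <- attr(idx, "flagged")
  if (any(flagged)) {
    message(sprintf("build_variable_table: excluded %d sample(s) with degenerate denominators",
                    sum(flagged)))
  }
  keep <- !flagged
  out <- cbind(
    data.frame(R_blue = samples$r_blue, R_green = samples$r_green,
               R_red = samples$r_red, R_nir = samples$r_nir)[keep, ,
                                                             drop = FALSE],
    idx[keep, , drop = FALSE]
  )
  out <- out[, variable_names()]
  if ("gpc" %in% names(samples)) out$gpc <- samples$gpc[keep]
  rownames(out) <- NULL
  class(out) <- c("variable_table", "data.frame")
  out
}

#' Compute per-index grids from band grids
#'
#' Element-wise [compute_indices()] over congruent band matrices. Masked or
#' `NA` cells are invalid (`NA`) in every output grid. The four band grids
#' are passed through (masked the same way) so the result holds all 14
#' variables, ready for [predict_grid()].
#'
#' @param bands Named list of four matrices: `r_blue`, `r_green`, `r_red`,
#'   `r_nir`.
#' @param mask Optional logical matrix congruent with the bands.
#' @inheritParams compute_indices
#' @return Named list of 14 matrices in [variable_names()] order.
#' @export
compute_index_grids <- function(bands, mask = NULL,
                                evi_variant = c("green", "blue")) {
  stopifnot(all(band_names() %in% names(bands)))
  dims <- dim(bands$r_blue)
  if (is.null(dims)) stop("band grids must be matrices", call. = FALSE)
  for (nm in band_names()) {
    if (!identical(dim(bands[[nm]]), dims)) {
      stop("band grids are not congruent in shape", call. = FALSE)
    }
  }
  valid <- !Reduce(`|`, lapply(bands[band_names()], is.na))
  if (!is.null(mask)) {
    if (!identical(dim(mask), dims)) {
      stop("`mask` shape does not match band grids", call. = FALSE)
    }
    valid <- valid & mask
  }
  flat <- data.frame(
    r_blue = as.vector(bands$r_blue)[as.vector(valid)],
    r_green = as.vector(bands$r_green)[as.vector(valid)],
    r_red = as.vector(bands$r_red)[as.vector(valid)],
    r_nir = as.vector(bands$r_nir)[as.vector(valid)]
  )
  idx <- if (nrow(flat) > 0) compute_indices(flat, evi_variant) else NULL
  empty <- matrix(NA_real_, dims[1], dims[2])
  out <- lapply(variable_names(), function(v) {
    m <- empty
    if (nrow(flat) > 0) {
      vals <- switch(v,
        R_blue = flat$r_blue, R_green = flat$r_green,
        R_red = flat$r_red, R_nir = flat$r_nir,
        idx[[v]]
      )
      m[valid] <- vals
    }
    m
  })
  names(out) <- variable_names()
  out
}
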