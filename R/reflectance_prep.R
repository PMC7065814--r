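# Empirical-line reflectance calibration and validity masking.
#
# Raw digital numbers (DN) from a multispectral sensor are converted to
# surface reflectance by fitting, per band, an ordinary-least-squares line
# reflectance = gain * DN + offset through calibration targets of known
# reflectance. This is the classical empirical-line atmospheric/reflectance
# correction; it assumes the scene-wide DN-reflectance relation is affine.

#' Fit the per-band empirical line from calibration targets
#'
#' @param pairs Data frame with columns `band`, `dn`, `reflectance`; at
#'   least two targets with distinct DN values per band.
#' @return An object of class `line_calibration`: a data frame with one row
#'   per band and columns `band`, `gain` (reflectance per DN), `offset`
#'   (reflectance), `n_targets`, `residual_rmse`.
#' @export
#' @examples
#' pairs <- data.frame(band = "r_red", dn = c(100, 900),
#'                     reflectance = c(0.05, 0.45))
#' calibrate_empirical_line(pairs)
calibrate_empirical_line <- function(pairs) {
  stopifnot(is.data.frame(pairs),
            all(c("band", "dn", "reflectance") %in% names(pairs)))
  fits <- lapply(split(pairs, pairs$band), function(d) {
    if (nrow(d) < 2) {
      stop(sprintf("band '%s': at least 2 calibration pairs required",
                   d$band[1]), call. = FALSE)
    }
    if (length(unique(d$dn)) < 2) {
      stop(sprintf("band '%s': all DN values identical (singular fit)",
                   d$band[1]), call. = FALSE)
    }
    fit <- lm(reflectance ~ dn, data = d)
    gain <- unname(coef(fit)[2])
    # a gain whose full-DN-range effect is below machine noise is zero
    span <- abs(gain) * diff(range(d$dn))
    if (!is.finite(gain) || span <= 1e-12 * max(abs(d$reflectance), 1)) {
      stop(sprintf("band '%s': fitted gain is zero (reflectance does not depend on DN)",
                   d$band[1]), call. = FALSE)
    }
    data.frame(
      band = d$band[1],
      gain = gain,
      offset = unname(coef(fit)[1]),
      n_targets = nrow(d),
      residual_rmse = sqrt(mean(stats::residuals(fit)^2))
    )
  })
  out <- do.call(rbind, fits)
  rownames(out) <- NULL
  class(out) <- c("line_calibration", "data.frame")
  out
}

#' Apply an empirical-line calibration to a DN grid
#'
#' Element-wise affine map `reflectance = gain * DN + offset`, followed by
#' clipping to `[0, 1]`. `NA` cells and masked-out cells propagate as `NA`.
#' The number of clipped cells is reported with a message; slight
#' out-of-range values are routine for satellite DNs and are not an error.
#'
#' @param dn_grid Numeric matrix (or vector) of digital numbers.
#' @param cal A [calibrate_empirical_line()] result.
#' @param band Which band row of `cal` to apply.
#' @param mask Optional logical grid congruent with `dn_grid`; cells where
#'   it is `FALSE` become `NA`.
#' @return Reflectance grid of the same shape, with attribute
#'   `n_clipped` (count of cells clipped into `[0, 1]`).
#' @export
apply_calibration <- function(dn_grid, cal, band = cal$band[1], mask = NULL) {
  stopifnot(inherits(cal, "line_calibration"))
  row <- cal[cal$band == band, ]
  if (nrow(row) != 1L) {
    stop(sprintf("band '%s' not present in calibration", band), call. = FALSE)
  }
  refl <- row$gain * dn_grid + row$offset
  n_clipped <- sum(refl < 0 | refl > 1, na.rm = TRUE)
  refl <- pmin(pmax(refl, 0), 1)
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(refl)) &&
        !identical(length(mask), length(refl))) {
      stop("`mask` must be congruent with `dn_grid`", call. = FALSE)
    }
    refl[!mask] <- NA_real_
  }
  if (n_clipped > 0) {
    message(sprintf("apply_calibration: clipped %d cell(s) into [0, 1]",
                    n_clipped))
  }
  attr(refl, "n_clipped") <- n_clipped
  refl
}

#' Binarize a classified grid into a wheat mask
#'
#' @param class_grid Categorical grid (character, factor or integer matrix).
#' @param wheat_label The class value marking wheat cells.
#' @return Logical matrix, `TRUE` exactly where `class_grid == wheat_label`.
#'   If the label is absent an all-`FALSE` mask is returned with a warning.
#' @export
binarize_mask <- function(class_grid, wheat_label) {
  vals <- class_grid
  if (is.factor(vals)) vals <- as.character(vals)
  mask <- vals == wheat_label
  mask[is.na(mask)] <- FALSE
  if (!any(mask)) {
    warning(sprintf("wheat label '%s' absent from class grid; mask is all FALSE",
                    wheat_label), call. = FALSE)
  }
  if (!is.null(dim(class_grid))) dim(mask) <- dim(class_grid)
  mask
}
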