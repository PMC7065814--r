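# Synthetic field-campaign and scene generator.
#
# Stands in for a real four-band satellite acquisition plus ground-truth
# grain protein content (GPC) sampling, so that every downstream stage of
# the pipeline (calibration, indices, regression, mapping) can be exercised
# and tested on data whose generating process is known exactly.

#' Parameters of the synthetic wheat scene generator
#'
#' Bundles and validates the knobs of the synthetic data model. GPC (grain
#' protein content, % of dry matter) is drawn from a truncated normal
#' distribution; each spectral band is an affine response to the
#' standardized GPC plus independent Gaussian noise:
#' `band = band_base + band_loading * z(GPC) + noise`, clipped to
#' `[0.001, 0.999]`.
#'
#' The defaults emulate a multi-year winter-wheat campaign at flowering:
#' GPC mean 12.1%, SD 1.4%, range 9.3-14.6%; mean reflectances of a closed
#' green canopy (low visible, high NIR); loadings negative in the visible
#' bands and positive in the NIR so that protein-rich (dense, nitrogen-rich)
#' canopies are darker in the red and brighter in the NIR, which yields an
#' NDVI-GPC correlation near 0.8 at large n.
#'
#' @param n_samples Number of field samples to generate.
#' @param gpc_mean,gpc_sd Mean and standard deviation of GPC (% dry matter).
#' @param gpc_min,gpc_max Truncation bounds for GPC (%).
#' @param band_base Length-4 vector of mean reflectances
#'   (blue, green, red, NIR), each in (0, 1).
#' @param band_loadings Length-4 vector: change of mean reflectance per one
#'   standard deviation of GPC.
#' @param band_noise_sd Length-4 vector of residual reflectance SDs
#'   (non-negative; zero gives a noiseless deterministic band).
#' @param seed Integer RNG seed; identical parameters give identical output.
#'
#' @return An object of class `scene_params`.
#' @export
#' @examples
#' p <- scene_params(n_samples = 50, seed = 7)
#' s <- generate_samples(p)
#' head(s)
scene_params <- function(n_samples = 255,
                         gpc_mean = 12.1,
                         gpc_sd = 1.4,
                         gpc_min = 9.3,
                         gpc_max = 14.6,
                         band_base = c(0.06, 0.09, 0.07, 0.45),
                         band_loadings = c(-0.004, -0.002, -0.013, 0.050),
                         band_noise_sd = c(0.018, 0.025, 0.012, 0.040),
                         seed = 1L) {
  if (length(n_samples) != 1L || !is.finite(n_samples) || n_samples < 1) {
    stop("`n_samples` must be a positive count", call. = FALSE)
  }
  if (!(gpc_min < gpc_mean && gpc_mean < gpc_max)) {
    stop("GPC truncation bounds must satisfy gpc_min < gpc_mean < gpc_max",
         call. = FALSE)
  }
  if (gpc_sd < 0) stop("`gpc_sd` must be non-negative", call. = FALSE)
  for (nm in c("band_base", "band_loadings", "band_noise_sd")) {
    v <- get(nm)
    if (length(v) != 4L || !is.numeric(v)) {
      stop(sprintf("`%s` must be a numeric vector of length 4", nm),
           call. = FALSE)
    }
  }
  if (any(band_base <= 0) || any(band_base >= 1)) {
    stop("all `band_base` values must lie in (0, 1)", call. = FALSE)
  }
  if (any(band_noise_sd < 0)) {
    stop("`band_noise_sd` must be non-negative", call. = FALSE)
  }
  structure(
    list(
      n_samples = as.integer(n_samples),
      gpc_mean = gpc_mean, gpc_sd = gpc_sd,
      gpc_min = gpc_min, gpc_max = gpc_max,
      band_base = unname(band_base),
      band_loadings = unname(band_loadings),
      band_noise_sd = unname(band_noise_sd),
      seed = as.integer(seed)
    ),
    class = "scene_params"
  )
}

band_names <- function() c("r_blue", "r_green", "r_red", "r_nir")

# Truncated normal by rejection; exact for the mild truncations used here.
rtruncnorm_reject <- function(n, mean, sd, lower, upper) {
  if (sd == 0) {
    if (mean < lower || mean > upper) {
      stop("degenerate truncation interval: mean outside bounds",
           call. = FALSE)
    }
    return(rep(mean, n))
  }
  accept_p <- stats::pnorm(upper, mean, sd) - stats::pnorm(lower, mean, sd)
  if (accept_p <= 0) {
    stop("degenerate truncation interval: zero acceptance probability",
         call. = FALSE)
  }
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rnorm(max(n, ceiling((n - length(out)) / accept_p)), mean, sd)
    out <- c(out, draw[draw >= lower & draw <= upper])
  }
  out[seq_len(n)]
}

#' Generate synthetic field samples of band reflectance and GPC
#'
#' Draws `params$n_samples` ground samples: GPC from a truncated normal,
#' each band as an affine response to standardized GPC plus independent
#' Gaussian noise, clipped to `[0.001, 0.999]`.
#'
#' @param params A [scene_params()] object.
#' @return A data frame with columns `r_blue`, `r_green`, `r_red`, `r_nir`
#'   (reflectance in `[0, 1]`) and `gpc` (% dry matter).
#' @export
generate_samples <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  n <- params$n_samples
  with_seed(params$seed, {
    gpc <- rtruncnorm_reject(n, params$gpc_mean, params$gpc_sd,
                             params$gpc_min, params$gpc_max)
    z <- if (params$gpc_sd > 0) (gpc - params$gpc_mean) / params$gpc_sd
         else rep(0, n)
    bands <- vapply(1:4, function(b) {
      noise <- if (params$band_noise_sd[b] > 0) {
        rnorm(n, 0, params$band_noise_sd[b])
      } else rep(0, n)
      pmin(pmax(params$band_base[b] + params$band_loadings[b] * z + noise,
                0.001), 0.999)
    }, numeric(n))
    out <- as.data.frame(bands)
    names(out) <- band_names()
    out$gpc <- gpc
    out
  })
}

# Separable Gaussian smoothing of a matrix with edge renormalization
# (weights falling outside the grid are dropped and the kernel re-scaled,
# so edges are not darkened).
smooth_gaussian <- function(m, width) {
  radius <- max(1L, ceiling(2 * width))
  offsets <- -radius:radius
  w <- exp(-offsets^2 / (2 * width^2))
  smooth_1d <- function(v) {
    n <- length(v)
    num <- numeric(n)
    den <- numeric(n)
    for (j in seq_along(offsets)) {
      src <- seq_len(n) + offsets[j]
      ok <- src >= 1 & src <= n
      num[ok] <- num[ok] + w[j] * v[src[ok]]
      den[ok] <- den[ok] + w[j]
    }
    num / den
  }
  m <- apply(m, 2, smooth_1d)
  t(apply(m, 1, smooth_1d))
}

#' Generate a gridded synthetic scene (band grids + wheat mask)
#'
#' Builds a spatially smooth GPC field (Gaussian white noise smoothed with a
#' fixed-width kernel, rescaled to the GPC distribution and clipped to its
#' bounds), derives the four band grids from it with the same per-band
#' model as [generate_samples()], and thresholds a second smooth field to
#' obtain a wheat/non-wheat mask covering approximately `wheat_fraction`
#' of the cells.
#'
#' @param rows,cols Grid dimensions (cells), both at least 1.
#' @param wheat_fraction Fraction of cells flagged as wheat, in `[0, 1]`.
#' @param params A [scene_params()] object (its `n_samples` is ignored).
#' @param kernel_width Gaussian smoothing kernel width in cells.
#' @return A list with `bands` (named list of four reflectance matrices),
#'   `mask` (logical matrix), `gpc` (true GPC field, % dry matter), and
#'   `params`.
#' @export
generate_scene <- function(rows, cols, wheat_fraction, params,
                           kernel_width = 5) {
  stopifnot(inherits(params, "scene_params"))
  if (rows < 1 || cols < 1) stop("zero-area grid", call. = FALSE)
  if (wheat_fraction < 0 || wheat_fraction > 1) {
    stop("`wheat_fraction` must lie in [0, 1]", call. = FALSE)
  }
  with_seed(params$seed, {
    field <- smooth_gaussian(matrix(rnorm(rows * cols), rows, cols),
                             kernel_width)
    fs <- sd(as.vector(field))
    z <- if (fs > 0) (field - mean(field)) / fs else field * 0
    gpc <- pmin(pmax(params$gpc_mean + params$gpc_sd * z,
                     params$gpc_min), params$gpc_max)
    zg <- if (params$gpc_sd > 0) (gpc - params$gpc_mean) / params$gpc_sd
          else gpc * 0
    bands <- lapply(1:4, function(b) {
      noise <- if (params$band_noise_sd[b] > 0) {
        matrix(rnorm(rows * cols, 0, params$band_noise_sd[b]), rows, cols)
      } else 0
      pmin(pmax(params$band_base[b] + params$band_loadings[b] * zg + noise,
                0.001), 0.999)
    })
    names(bands) <- band_names()
    mask_field <- smooth_gaussian(matrix(rnorm(rows * cols), rows, cols),
                                  kernel_width)
    mask <- if (wheat_fraction <= 0) {
      matrix(FALSE, rows, cols)
    } else if (wheat_fraction >= 1) {
      matrix(TRUE, rows, cols)
    } else {
      mask_field >= quantile(mask_field, 1 - wheat_fraction)
    }
    list(bands = bands, mask = mask, gpc = gpc, params = params)
  })
}

#' Generate raw digital numbers and calibration-target pairs
#'
#' Simulates the uncalibrated sensor side: per-band digital numbers
#' `DN = gain * reflectance + offset + noise`, plus a set of
#' calibration-target pairs (known reflectance, observed DN) per band as
#' input for [calibrate_empirical_line()].
#'
#' @param samples Data frame of band reflectances (columns `r_blue`,
#'   `r_green`, `r_red`, `r_nir`).
#' @param gain DN per unit reflectance; scalar or length-4 (per band);
#'   must be nonzero.
#' @param offset DN offset; scalar or length-4.
#' @param noise_sd DN noise SD applied to both sample DNs and target DNs.
#' @param n_targets Number of calibration targets per band (at least 2).
#' @param target_reflectance Reflectances of the calibration targets.
#' @param seed RNG seed for the DN noise.
#' @return A list with `dn` (data frame `dn_blue` ... `dn_nir`) and
#'   `targets` (data frame `band`, `dn`, `reflectance`).
#' @export
generate_dn <- function(samples, gain = 1000, offset = 50, noise_sd = 0,
                        n_targets = 5,
                        target_reflectance = seq(0.05, 0.6,
                                                 length.out = n_targets),
                        seed = 1L) {
  gain <- rep_len(gain, 4L)
  offset <- rep_len(offset, 4L)
  if (any(gain == 0)) stop("`gain` must be nonzero", call. = FALSE)
  if (n_targets < 2) stop("at least 2 calibration targets per band required",
                          call. = FALSE)
  bands <- band_names()
  stopifnot(all(bands %in% names(samples)))
  n <- nrow(samples)
  with_seed(seed, {
    dn <- lapply(1:4, function(b) {
      noise <- if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0
      gain[b] * samples[[bands[b]]] + offset[b] + noise
    })
    names(dn) <- sub("^r_", "dn_", bands)
    targets <- do.call(rbind, lapply(1:4, function(b) {
      noise <- if (noise_sd > 0) {
        rnorm(length(target_reflectance), 0, noise_sd)
      } else 0
      data.frame(
        band = bands[b],
        dn = gain[b] * target_reflectance + offset[b] + noise,
        reflectance = target_reflectance
      )
    }))
    list(dn = as.data.frame(dn), targets = targets)
  })
}
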