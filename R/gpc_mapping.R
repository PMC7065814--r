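# Gridded GPC prediction and class mapping: apply a fitted linear-form
# model cell-wise over index grids under a wheat mask and bin the result
# into protein-content classes.

#' Predict GPC over index grids
#'
#' Applies the model's linear form to every valid cell. A cell is valid
#' when the mask (if given) is `TRUE` and every predictor grid is
#' non-missing there; all other cells are `NA` in the output.
#'
#' @param model A fitted `pls_model` or `linear_model` (incl.
#'   [new_linear_model()]).
#' @param index_grids Named list of congruent matrices holding at least
#'   the model's predictor variables (e.g. from [compute_index_grids()]).
#' @param mask Optional logical matrix congruent with the grids.
#' @return An object of class `gpc_grid`: list with `predicted` (matrix,
#'   % GPC), `mask` (logical matrix of valid cells), `bin_edges` and
#'   `class_raster` (both `NULL` until [classify_gpc()] is applied).
#' @export
predict_grid <- function(model, index_grids, mask = NULL) {
  missing_pred <- setdiff(model$predictor_names, names(index_grids))
  if (length(missing_pred) > 0) {
    stop(sprintf("missing predictor grid(s): %s",
                 paste(missing_pred, collapse = ", ")), call. = FALSE)
  }
  grids <- index_grids[model$predictor_names]
  dims <- dim(grids[[1]])
  for (g in grids) {
    if (!identical(dim(g), dims)) stop("grid shape mismatch", call. = FALSE)
  }
  valid <- !Reduce(`|`, lapply(grids, is.na))
  if (!is.null(mask)) {
    if (!identical(dim(mask), dims)) {
      stop("`mask` shape does not match grids", call. = FALSE)
    }
    valid <- valid & mask
  }
  predicted <- matrix(NA_real_, dims[1], dims[2])
  if (any(valid)) {
    X <- vapply(grids, function(g) g[valid], numeric(sum(valid)))
    X <- matrix(X, ncol = length(grids),
                dimnames = list(NULL, model$predictor_names))
    predicted[valid] <- predict(model, X)
  }
  structure(
    list(predicted = predicted, mask = valid,
         bin_edges = NULL, class_raster = NULL),
    class = "gpc_grid"
  )
}

gpc_class_labels <- function(bin_edges) {
  k <- length(bin_edges)
  c(sprintf("<%g", bin_edges[1]),
    if (k > 1) sprintf("%g-%g", bin_edges[-k], bin_edges[-1]),
    sprintf(">%g", bin_edges[k]))
}

#' Classify a GPC grid into protein-content bins
#'
#' Bins are half-open on the right, `[low, high)`: a cell exactly on an
#' edge belongs to the class above it. Three edges (the default
#' 11.3 / 11.8 / 12.5 % GPC) give four classes. Invalid cells stay `NA`.
#'
#' @param grid A [predict_grid()] result (or a bare numeric matrix, which
#'   is wrapped with an all-valid mask).
#' @param bin_edges Strictly increasing numeric vector of class boundaries
#'   (% GPC).
#' @return The `gpc_grid` with `class_raster` (integer matrix of class
#'   codes, attribute `labels`) and `bin_edges` filled in.
#' @export
classify_gpc <- function(grid, bin_edges = c(11.3, 11.8, 12.5)) {
  if (is.matrix(grid)) {
    grid <- structure(list(predicted = grid, mask = !is.na(grid),
                           bin_edges = NULL, class_raster = NULL),
                      class = "gpc_grid")
  }
  stopifnot(inherits(grid, "gpc_grid"))
  if (length(bin_edges) < 1 || any(diff(bin_edges) <= 0)) {
    stop("`bin_edges` must be strictly increasing", call. = FALSE)
  }
  labels <- gpc_class_labels(bin_edges)
  cls <- matrix(NA_integer_, nrow(grid$predicted), ncol(grid$predicted))
  valid <- grid$mask & !is.na(grid$predicted)
  cls[valid] <- findInterval(grid$predicted[valid], bin_edges) + 1L
  attr(cls, "labels") <- labels
  grid$class_raster <- cls
  grid$bin_edges <- bin_edges
  grid
}

#' Export a GPC grid to plain-text layers plus a JSON legend
#'
#' Writes `predicted.txt` (tab-separated matrix, `NA` for invalid cells),
#' `classes.txt` (integer class codes, if classified) and `legend.json`
#' holding the bin edges, class labels and per-class cell counts.
#'
#' @param grid A `gpc_grid`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
export_map <- function(grid, dir) {
  stopifnot(inherits(grid, "gpc_grid"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- file.path(dir, "predicted.txt")
  write.table(grid$predicted, files, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  legend <- list(
    n_rows = nrow(grid$predicted),
    n_cols = ncol(grid$predicted),
    n_valid = sum(grid$mask & !is.na(grid$predicted))
  )
  if (!is.null(grid$class_raster)) {
    cf <- file.path(dir, "classes.txt")
    write.table(grid$class_raster, cf, sep = "\t",
                row.names = FALSE, col.names = FALSE)
    files <- c(files, cf)
    labels <- attr(grid$class_raster, "labels")
    counts <- tabulate(grid$class_raster[!is.na(grid$class_raster)],
                       nbins = length(labels))
    legend$bin_edges <- grid$bin_edges
    legend$classes <- data.frame(code = seq_along(labels), label = labels,
                                 cells = counts)
  }
  lf <- file.path(dir, "legend.json")
  jsonlite::write_json(legend, lf, auto_unbox = TRUE, digits = NA)
  invisible(c(files, lf))
}

#' Read back a GPC grid exported with [export_map()]
#'
#' @param dir Directory holding `predicted.txt` (and optionally
#'   `classes.txt`, `legend.json`).
#' @return A `gpc_grid`.
#' @export
read_map <- function(dir) {
  pred <- as.matrix(read.table(file.path(dir, "predicted.txt"), sep = "\t"))
  dimnames(pred) <- NULL
  grid <- structure(list(predicted = pred, mask = !is.na(pred),
                         bin_edges = NULL, class_raster = NULL),
                    class = "gpc_grid")
  cf <- file.path(dir, "classes.txt")
  lf <- file.path(dir, "legend.json")
  if (file.exists(cf)) {
    cls <- as.matrix(read.table(cf, sep = "\t"))
    dimnames(cls) <- NULL
    storage.mode(cls) <- "integer"
    if (file.exists(lf)) {
      legend <- jsonlite::read_json(lf, simplifyVector = TRUE)
      attr(cls, "labels") <- legend$classes$label
      grid$bin_edges <- legend$bin_edges
    }
    grid$class_raster <- cls
  }
  grid
}
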