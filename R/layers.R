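# Radial-layer analysis of straightened-axis cell maps: intensity
# profiles, GMM/BIC component selection, superficial/deep assignment,
# tracer-subset layer fractions, and colocalization.

validate_cellmap <- function(cellmap) {
  stopifnot(is.data.frame(cellmap),
            all(c("radial", "longitudinal") %in% names(cellmap)))
  if (nrow(cellmap) &&
      (any(cellmap$radial < 0 | cellmap$radial > 1) ||
       any(cellmap$longitudinal < 0 | cellmap$longitudinal > 1))) {
    stop("cell coordinates must lie in [0, 1]")
  }
  invisible(cellmap)
}

#' Normalised cell-position intensity profile
#'
#' Histogram of cell positions along one axis, optionally smoothed with
#' a Gaussian kernel, and normalised so the peak equals 1 — the analysis
#' that makes the two radial fluorescence peaks visible.
#'
#' @param cellmap Cell-map data frame (`radial`, `longitudinal`).
#' @param axis `"radial"` or `"longitudinal"`.
#' @param bin_width Bin width on the normalised axis (default 0.02).
#' @param smooth_sd Gaussian smoothing SD in axis units (default 0.03;
#'   0 disables smoothing).
#' @return Data frame `position` (bin centres), `intensity`
#'   (max-normalised).
#' @export
intensity_profile <- function(cellmap, axis = c("radial", "longitudinal"),
                              bin_width = 0.02, smooth_sd = 0.03) {
  axis <- match.arg(axis)
  validate_cellmap(cellmap)
  if (nrow(cellmap) == 0) stop("empty cell map")
  breaks <- seq(0, 1, by = bin_width)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  h <- hist(cellmap[[axis]], breaks = breaks, plot = FALSE)
  counts <- h$counts
  if (smooth_sd > 0) {
    half <- ceiling(3 * smooth_sd / bin_width)
    kern <- stats::dnorm(seq(-half, half) * bin_width, sd = smooth_sd)
    kern <- kern / sum(kern)
    padded <- c(rep(0, half), counts, rep(0, half))
    counts <- stats::convolve(padded, rev(kern), type = "filter")
  }
  data.frame(position = h$mids, intensity = counts / max(counts))
}

count_local_maxima <- function(y) {
  n <- length(y)
  if (n < 3) return(as.integer(n >= 1 && any(y > 0)))
  sum(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n])
}

#' Fit candidate Gaussian mixtures to a cell map and select by BIC
#'
#' Fits full-covariance mixtures with `k` in `k_range` to the 2-D
#' (radial, longitudinal) coordinates (EM, `n_init` k-means++ restarts)
#' and records `BIC = -2 logL + p ln(n)` per candidate; the selected
#' model minimises BIC, with ties (within 1e-6) broken toward smaller
#' `k`. Components of the selected model are ordered by radial mean:
#' nearest 0 (the alveus side) is the deep layer, nearest 1 the
#' superficial layer.
#'
#' @param cellmap Cell-map data frame.
#' @param k_range Candidate component counts (default 1:6).
#' @param n_init EM restarts per candidate (default 10).
#' @param seed Integer RNG seed.
#' @return A `layer_model`: `fits` per k, `bic` table, `selected_k`,
#'   `selected` fit, `ordering` (component index by increasing radial
#'   mean), and `layer_names` when `selected_k == 2`.
#' @export
fit_layer_gmm <- function(cellmap, k_range = 1:6, n_init = 10, seed = NULL) {
  validate_cellmap(cellmap)
  X <- as.matrix(cellmap[, c("radial", "longitudinal")])
  if (nrow(X) < 2 * max(k_range)) {
    stop("need at least 2 * max(k_range) cells")
  }
  if (!is.null(seed)) set.seed(seed)
  fits <- lapply(k_range, function(k) gmm_fit(X, k, n_init = n_init))
  names(fits) <- paste0("k", k_range)
  bic <- vapply(fits, function(f) {
    if (isTRUE(f$converged)) f$bic else NA_real_
  }, numeric(1))
  if (all(is.na(bic))) stop("no candidate mixture converged")
  ok <- which(!is.na(bic))
  best <- ok[bic[ok] <= min(bic[ok]) + 1e-6][1]  # parsimony tie-break
  selected <- fits[[best]]
  ordering <- order(selected$means[, 1])
  layer_names <- NULL
  if (selected$k == 2) {
    layer_names <- character(2)
    layer_names[ordering] <- c("deep", "superficial")
  }
  structure(list(fits = fits,
                 bic = data.frame(k = k_range, bic = unname(bic),
                                  converged = !is.na(bic)),
                 selected_k = k_range[best], selected = selected,
                 ordering = ordering, layer_names = layer_names,
                 n_cells = nrow(X)),
            class = "layer_model")
}

#' @export
print.layer_model <- function(x, ...) {
  cat(sprintf("<layer_model> n = %d cells; selected k = %d\n",
              x$n_cells, x$selected_k))
  print(x$bic, row.names = FALSE)
  invisible(x)
}

#' Assign cells to layers by maximum posterior probability
#'
#' For the selected two-component model, the component with radial mean
#' nearer 0 (alveus side) is named `deep`, the other `superficial`. For
#' `k != 2`, layer names are refused and component indices are returned
#' instead (unless `allow_components = TRUE` was implied by asking).
#'
#' @param model A [fit_layer_gmm()] result.
#' @param cells Cell-map data frame.
#' @param allow_components If `TRUE`, return component indices when the
#'   selected `k != 2` instead of erroring.
#' @return Data frame: `component` (index), `layer` (when available),
#'   `posterior` (winning posterior probability).
#' @export
assign_layers <- function(model, cells, allow_components = FALSE) {
  stopifnot(inherits(model, "layer_model"))
  validate_cellmap(cells)
  X <- as.matrix(cells[, c("radial", "longitudinal")])
  post <- gmm_posterior(model$selected, X)
  comp <- max.col(post)
  out <- data.frame(component = comp,
                    posterior = post[cbind(seq_len(nrow(post)), comp)])
  if (model$selected_k == 2) {
    out$layer <- model$layer_names[comp]
  } else if (!allow_components) {
    stop("selected model has k = ", model$selected_k,
         " components; layer names require k = 2 ",
         "(set allow_components = TRUE for component indices)")
  }
  out
}

#' Layer fractions of a tracer-flagged cell subset
#'
#' Fraction of flagged cells assigned to each layer; fractions sum to 1
#' across layers. Reported pooled and, when a `slice` column is present,
#' per slice.
#'
#' @param assignments [assign_layers()] output with a `layer` column.
#' @param cells Cell-map data frame holding the tracer flag (and
#'   optionally `slice`).
#' @param flag Name of the logical tracer column (e.g. `"rabies"`).
#' @return List with `pooled` (named fractions + `n`) and `per_slice`.
#' @export
subset_layer_fractions <- function(assignments, cells, flag) {
  stopifnot("layer" %in% names(assignments), flag %in% names(cells),
            nrow(assignments) == nrow(cells))
  layers <- c("superficial", "deep")
  frac_of <- function(lay, fl) {
    n <- sum(fl)
    if (n == 0) return(stats::setNames(rep(NaN, 2), layers))
    stats::setNames(vapply(layers, function(l) sum(fl & lay == l) / n,
                           numeric(1)), layers)
  }
  fl <- as.logical(cells[[flag]])
  if (!any(fl)) warning("no cells carry flag ", flag)
  pooled <- c(frac_of(assignments$layer, fl), n = sum(fl))
  per_slice <- NULL
  if ("slice" %in% names(cells)) {
    per_slice <- do.call(rbind, lapply(split(seq_len(nrow(cells)),
                                             cells$slice), function(i) {
      data.frame(slice = cells$slice[i[1]],
                 t(frac_of(assignments$layer[i], fl[i])),
                 n = sum(fl[i]))
    }))
    rownames(per_slice) <- NULL
  }
  list(pooled = pooled, per_slice = per_slice)
}

#' Dual-labelled cell fractions, overall and per layer
#'
#' Because the percentage base for "dual-labelled" is ambiguous, three
#' denominators are reported: the union of the two flags and each flag
#' alone. The per-layer split of dual-labelled cells uses the supplied
#' layer assignments.
#'
#' @param cellmap Cell-map data frame with both flag columns.
#' @param flag_a,flag_b Logical tracer column names.
#' @param assignments Optional [assign_layers()] output for the layer
#'   split.
#' @return List with `dual_over_union`, `dual_over_a`, `dual_over_b`,
#'   `n_dual`, and `per_layer` (fraction of dual cells per layer).
#' @export
colocalization <- function(cellmap, flag_a, flag_b, assignments = NULL) {
  stopifnot(flag_a %in% names(cellmap), flag_b %in% names(cellmap))
  a <- as.logical(cellmap[[flag_a]]); b <- as.logical(cellmap[[flag_b]])
  dual <- a & b; un <- a | b
  out <- list(dual_over_union = if (sum(un)) sum(dual) / sum(un) else NaN,
              dual_over_a = if (sum(a)) sum(dual) / sum(a) else NaN,
              dual_over_b = if (sum(b)) sum(dual) / sum(b) else NaN,
              n_dual = sum(dual))
  if (!is.null(assignments) && "layer" %in% names(assignments)) {
    lay <- assignments$layer[dual]
    out$per_layer <- c(
      superficial = if (sum(dual)) mean(lay == "superficial") else NaN,
      deep = if (sum(dual)) mean(lay == "deep") else NaN)
  }
  out
}
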