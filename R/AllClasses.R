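#' @import methods
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' JsomDataset: one modality's cell-by-feature matrix
#'
#' Container for a single dataset entering the alignment: a numeric matrix
#' with cells in rows and features in columns, plus optional per-cell
#' cell-type labels and batch assignments. Feature names and cell ids are
#' carried in the matrix dimnames and must be unique.
#'
#' @slot values numeric matrix, cells x features, no missing values; rownames
#'   are cell ids, colnames are feature names.
#' @slot labels character vector of per-cell labels (length \code{nrow(values)})
#'   or \code{NULL}.
#' @slot batch character vector of per-cell batch assignments or \code{NULL}.
#'
#' @seealso [jsomDataset()] for the user-facing constructor.
#' @export
setClass("JsomDataset",
  representation(values = "matrix", labels = "characterOrNULL",
                 batch = "characterOrNULL"),
  validity = function(object) {
    v <- object@values
    msg <- character()
    if (!is.numeric(v)) msg <- c(msg, "'values' must be a numeric matrix")
    if (anyNA(v)) msg <- c(msg, "'values' must not contain missing values")
    if (is.null(rownames(v)) || is.null(colnames(v)))
      msg <- c(msg, "'values' must have cell ids (rownames) and feature names (colnames)")
    if (!is.null(rownames(v)) && anyDuplicated(rownames(v)))
      msg <- c(msg, "cell ids must be unique")
    if (!is.null(colnames(v)) && anyDuplicated(colnames(v)))
      msg <- c(msg, "feature names must be unique")
    if (!is.null(object@labels) && length(object@labels) != nrow(v))
      msg <- c(msg, "'labels' must have one entry per cell")
    if (!is.null(object@batch) && length(object@batch) != nrow(v))
      msg <- c(msg, "'batch' must have one entry per cell")
    if (length(msg)) msg else TRUE
  })

#' Construct a JsomDataset
#'
#' @param values numeric matrix, cells in rows, features in columns. Missing
#'   dimnames are filled with \code{cell_i} / \code{feat_j}.
#' @param labels optional per-cell cell-type labels (coerced to character).
#' @param batch optional per-cell batch labels (coerced to character).
#' @param cellIds,featureNames optional overrides for the dimnames.
#'
#' @return A [JsomDataset-class] object.
#' @examples
#' d <- jsomDataset(matrix(rnorm(20), 5, 4), labels = rep(c("A", "B"), c(2, 3)))
#' nCells(d)
#' @export
jsomDataset <- function(values, labels = NULL, batch = NULL,
                        cellIds = NULL, featureNames = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.null(cellIds)) rownames(values) <- cellIds
  if (!is.null(featureNames)) colnames(values) <- featureNames
  if (is.null(rownames(values)))
    rownames(values) <- paste0("cell_", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("feat_", seq_len(ncol(values)))
  if (!is.null(labels)) labels <- as.character(labels)
  if (!is.null(batch)) batch <- as.character(batch)
  new("JsomDataset", values = values, labels = labels, batch = batch)
}

#' SharedFeatures: positional correspondence of feature columns
#'
#' Records which columns of dataset 1 correspond to which columns of
#' dataset 2, in matched order: position k of \code{idx1} pairs with
#' position k of \code{idx2}. Indices are 1-based column indices.
#'
#' @slot idx1,idx2 integer vectors of equal positive length.
#' @seealso [sharedFeatures()]
#' @export
setClass("SharedFeatures",
  representation(idx1 = "integer", idx2 = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@idx1) != length(object@idx2))
      msg <- c(msg, "'idx1' and 'idx2' must have the same length")
    if (length(object@idx1) < 1L) msg <- c(msg, "at least one shared feature is required")
    if (any(object@idx1 < 1L) || any(object@idx2 < 1L))
      msg <- c(msg, "indices must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' Construct a SharedFeatures correspondence
#'
#' Accepts either 1-based column indices or feature names, resolved against
#' the two datasets when given. Order is meaningful: the k-th entry of
#' \code{features1} corresponds to the k-th entry of \code{features2}.
#'
#' @param features1,features2 integer indices or character feature names.
#' @param d1,d2 optional [JsomDataset-class] objects used to resolve names and
#'   range-check indices.
#' @return A [SharedFeatures-class] object.
#' @export
sharedFeatures <- function(features1, features2, d1 = NULL, d2 = NULL) {
  resolve <- function(f, d, which) {
    if (is.character(f)) {
      if (is.null(d)) stop("dataset ", which, " required to resolve feature names")
      i <- match(f, featureNames(d))
      if (anyNA(i)) stop("unknown feature name(s) in dataset ", which, ": ",
                         paste(f[is.na(i)], collapse = ", "))
      i
    } else {
      i <- as.integer(f)
      if (!is.null(d) && any(i > nFeatures(d)))
        stop("feature index out of range for dataset ", which)
      i
    }
  }
  new("SharedFeatures",
      idx1 = resolve(features1, d1, 1L), idx2 = resolve(features2, d2, 2L))
}

#' JsomMatching: datapoint-to-datapoint matching functions and weights
#'
#' The cross-dataset matching evaluated on the shared features: for each cell
#' of one dataset, the index of its most related cell in the other dataset
#' and the matching weight delta in [0, 1] that scales its learning updates.
#'
#' @slot match1to2 integer vector (length n1), 1-based row indices into dataset 2.
#' @slot match2to1 integer vector (length n2), indices into dataset 1.
#' @slot delta1,delta2 numeric matching weights in [0, 1] (unless negative
#'   correlations were explicitly retained).
#' @slot mode \code{"correlation"} or \code{"binary"}.
#' @export
setClass("JsomMatching",
  representation(match1to2 = "integer", match2to1 = "integer",
                 delta1 = "numeric", delta2 = "numeric", mode = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@match1to2) != length(object@delta1))
      msg <- c(msg, "'match1to2' and 'delta1' lengths differ")
    if (length(object@match2to1) != length(object@delta2))
      msg <- c(msg, "'match2to1' and 'delta2' lengths differ")
    if (!object@mode %in% c("correlation", "binary"))
      msg <- c(msg, "'mode' must be 'correlation' or 'binary'")
    if (any(object@delta1 > 1 + 1e-12) || any(object@delta2 > 1 + 1e-12))
      msg <- c(msg, "delta values must be <= 1")
    if (length(msg)) msg else TRUE
  })

#' JsomConfig: training configuration
#'
#' Holds the grid size, schedule endpoints, downsampling cap and the switches
#' controlling the coupled-map training. See [jsomConfig()] for defaults and
#' the meaning of each field.
#'
#' @slot m,n grid rows / columns.
#' @slot epochs number of passes over the larger dataset.
#' @slot alpha0,alphaFinal learning-rate schedule endpoints.
#' @slot epsilon0 initial neighborhood radius (grid units).
#' @slot downsampleTarget training-size cap per dataset.
#' @slot downsample logical, use density-dependent downsampling above the cap.
#' @slot outlierPercentile density percentile below which cells are treated as
#'   outliers during downsampling (0 disables).
#' @slot seed integer seed driving all randomness.
#' @slot joint logical, apply the joint (cross-map) updates.
#' @slot deltaInIndependent logical, weight independent updates by delta.
#' @slot allowNegativeDelta logical, keep negative correlations as deltas.
#' @slot sampling \code{"permutation"} (each point used \code{epochs} times) or
#'   \code{"iid"}.
#' @export
setClass("JsomConfig",
  representation(m = "integer", n = "integer", epochs = "integer",
                 alpha0 = "numeric", alphaFinal = "numeric", epsilon0 = "numeric",
                 downsampleTarget = "integer", downsample = "logical",
                 outlierPercentile = "numeric", seed = "integer",
                 joint = "logical", deltaInIndependent = "logical",
                 allowNegativeDelta = "logical", sampling = "character"),
  validity = function(object) {
    msg <- character()
    if (object@m < 2L || object@n < 2L) msg <- c(msg, "grid must be at least 2 x 2")
    if (object@epochs < 1L) msg <- c(msg, "'epochs' must be >= 1")
    if (!(object@alphaFinal > 0 && object@alphaFinal < object@alpha0 &&
          object@alpha0 <= 1))
      msg <- c(msg, "need 0 < alphaFinal < alpha0 <= 1")
    if (object@epsilon0 < 0) msg <- c(msg, "'epsilon0' must be >= 0")
    if (object@downsampleTarget < 1L) msg <- c(msg, "'downsampleTarget' must be >= 1")
    if (object@outlierPercentile < 0 || object@outlierPercentile >= 50)
      msg <- c(msg, "'outlierPercentile' must be in [0, 50)")
    if (!object@sampling %in% c("permutation", "iid"))
      msg <- c(msg, "'sampling' must be 'permutation' or 'iid'")
    if (length(msg)) msg else TRUE
  })

#' Default initial neighborhood radius for an m x n grid
#'
#' \code{ceiling(2 * (max(m, n) - 1) / 3)}: one third of the grid diameter,
#' rounded up (6 for the default 10 x 10 grid), so early updates reach a broad
#' neighborhood and the radius can shrink linearly to a single node.
#'
#' @param m,n grid dimensions.
#' @param literal if \code{TRUE} use the alternative rule
#'   \code{2 * max(m, n) - 13} (clamped at 0), which coincides with a radius of
#'   7 on a 10 x 10 grid but degenerates on small grids.
#' @return A non-negative scalar radius.
#' @export
defaultEpsilon0 <- function(m, n, literal = FALSE) {
  if (literal) max(0, 2 * max(m, n) - 13) else ceiling(2 * (max(m, n) - 1) / 3)
}

#' Construct a training configuration
#'
#' @param m,n grid rows and columns (default 10 x 10, i.e. 100 nodes).
#' @param epochs passes over the larger dataset (default 3, so every training
#'   point is used at least three times).
#' @param alpha0 initial learning rate (default 0.9), decayed linearly.
#' @param alphaFinal learning rate at the last iteration (default 0.01).
#' @param epsilon0 initial neighborhood radius in grid units; defaults to
#'   [defaultEpsilon0()] of the grid. Decays linearly to 0, after which only
#'   the best-matching unit is updated.
#' @param downsampleTarget per-dataset training-size cap (default 10000).
#' @param downsample if \code{TRUE} (default), datasets above the cap are
#'   reduced by density-dependent downsampling; if \code{FALSE}, by plain
#'   uniform sampling.
#' @param outlierPercentile density percentile treated as outliers when
#'   downsampling (default 1; set 0 to keep all cells).
#' @param seed integer seed for initialization, sampling order and downsampling.
#' @param joint apply the joint cross-map updates (default \code{TRUE};
#'   \code{FALSE} reduces training to two independent self-organizing maps).
#' @param deltaInIndependent weight the independent updates by the matching
#'   weight delta (default \code{TRUE}, as in the update formula; \code{FALSE}
#'   uses delta only for joint updates).
#' @param allowNegativeDelta keep negative correlations as matching weights
#'   instead of clamping at 0 (default \code{FALSE}).
#' @param sampling \code{"permutation"} or \code{"iid"} draw order.
#' @return A [JsomConfig-class] object.
#' @examples
#' cfg <- jsomConfig(seed = 1)
#' cfg
#' @export
jsomConfig <- function(m = 10, n = 10, epochs = 3, alpha0 = 0.9,
                       alphaFinal = 0.01, epsilon0 = defaultEpsilon0(m, n),
                       downsampleTarget = 10000, downsample = TRUE,
                       outlierPercentile = 1, seed = 1L, joint = TRUE,
                       deltaInIndependent = TRUE, allowNegativeDelta = FALSE,
                       sampling = c("permutation", "iid")) {
  new("JsomConfig", m = as.integer(m), n = as.integer(n),
      epochs = as.integer(epochs), alpha0 = alpha0, alphaFinal = alphaFinal,
      epsilon0 = as.numeric(epsilon0),
      downsampleTarget = as.integer(downsampleTarget),
      downsample = isTRUE(downsample),
      outlierPercentile = as.numeric(outlierPercentile),
      seed = as.integer(seed), joint = isTRUE(joint),
      deltaInIndependent = isTRUE(deltaInIndependent),
      allowNegativeDelta = isTRUE(allowNegativeDelta),
      sampling = match.arg(sampling))
}

#' JsomMap: the two coupled codebook grids
#'
#' The trained (or initialized) pair of maps: one m x n rectangular grid of
#' nodes shared by both datasets, with a codebook matrix per dataset. Node j
#' sits at grid coordinate \code{(row, col) = ((j-1) \%/\% n, (j-1) \%\% n)}
#' (0-based coordinates, 1-based node indices, row-major order).
#'
#' @slot m,n grid dimensions.
#' @slot V1 numeric matrix [m*n x d1]: codebook vectors for dataset 1.
#' @slot V2 numeric matrix [m*n x d2]: codebook vectors for dataset 2.
#' @slot config the [JsomConfig-class] used to build the map.
#' @export
setClass("JsomMap",
  representation(m = "integer", n = "integer", V1 = "matrix", V2 = "matrix",
                 config = "JsomConfig"),
  validity = function(object) {
    msg <- character()
    k <- object@m * object@n
    if (nrow(object@V1) != k || nrow(object@V2) != k)
      msg <- c(msg, "codebook matrices must have m*n rows")
    if (length(msg)) msg else TRUE
  })

#' JsomAssignment: per-cell node assignment
#'
#' Node index (1-based, row-major) of the best-matching unit of every cell of
#' each dataset on its own map.
#'
#' @slot nodes1,nodes2 integer vectors of node indices in \code{1..m*n}.
#' @slot nNodes total number of nodes m*n.
#' @export
setClass("JsomAssignment",
  representation(nodes1 = "integer", nodes2 = "integer", nNodes = "integer"),
  validity = function(object) {
    bad <- c(object@nodes1, object@nodes2)
    if (length(bad) && (any(bad < 1L) || any(bad > object@nNodes)))
      "node indices out of range" else TRUE
  })

#' JsomFit: result of the full alignment pipeline
#'
#' Bundles the trained maps, the matching, the full-data node assignment and
#' the indices of the cells retained for training.
#'
#' @slot maps trained [JsomMap-class].
#' @slot matching the [JsomMatching-class] used during training (computed on
#'   the retained training cells).
#' @slot assignment [JsomAssignment-class] of the FULL datasets.
#' @slot keep1,keep2 integer indices of the training cells within each dataset.
#' @export
setClass("JsomFit",
  representation(maps = "JsomMap", matching = "JsomMatching",
                 assignment = "JsomAssignment",
                 keep1 = "integer", keep2 = "integer"))

# ---- show methods -----------------------------------------------------------

setMethod("show", "JsomDataset", function(object) {
  cat("JsomDataset:", nrow(object@values), "cells x", ncol(object@values),
      "features\n")
  if (!is.null(object@labels))
    cat("  labels:", paste(utils::head(sort(unique(object@labels)), 6),
                           collapse = ", "),
        if (length(unique(object@labels)) > 6) "..." else "", "\n")
  if (!is.null(object@batch))
    cat("  batches:", length(unique(object@batch)), "\n")
})

setMethod("show", "JsomMatching", function(object) {
  cat("JsomMatching (mode =", object@mode, "):",
      length(object@match1to2), "x", length(object@match2to1), "cells\n")
  cat("  mean delta1:", round(mean(object@delta1), 4),
      " mean delta2:", round(mean(object@delta2), 4), "\n")
})

setMethod("show", "JsomConfig", function(object) {
  cat("JsomConfig:", object@m, "x", object@n, "grid,", object@epochs,
      "epochs\n")
  cat("  alpha:", object@alpha0, "->", object@alphaFinal,
      " epsilon0:", object@epsilon0, "\n")
  cat("  downsample:", if (object@downsample) "density-dependent" else "uniform",
      "cap", object@downsampleTarget, " seed:", object@seed, "\n")
  cat("  joint:", object@joint, " deltaInIndependent:",
      object@deltaInIndependent, " sampling:", object@sampling, "\n")
})

setMethod("show", "JsomMap", function(object) {
  cat("JsomMap:", object@m, "x", object@n, "grid;",
      "d1 =", ncol(object@V1), "features, d2 =", ncol(object@V2), "features\n")
})

setMethod("show", "JsomAssignment", function(object) {
  occ <- length(unique(c(object@nodes1, object@nodes2)))
  cat("JsomAssignment:", length(object@nodes1), "+", length(object@nodes2),
      "cells on", object@nNodes, "nodes (", occ, "occupied )\n")
})

setMethod("show", "JsomFit", function(object) {
  cat("JsomFit\n")
  show(object@maps)
  show(object@matching)
  show(object@assignment)
})
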