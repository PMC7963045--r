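# Readers and writers: dense CSV/TSV matrices, MatrixMarket triplets with
# feature/barcode companions, JSON map containers, and assignment exports.

#' Read a cell-by-feature matrix into a JsomDataset
#'
#' Dense CSV/TSV files must carry a header row of feature names and cell ids
#' in the first column; optional \code{label} and \code{batch} columns (by
#' those names) are split off into the dataset's metadata. MatrixMarket
#' (\code{format = "mtx"}) input follows the common genomics convention of
#' features x cells with companion \code{features.tsv} / \code{barcodes.tsv}
#' name files, and is transposed to cells x features on read.
#'
#' @param path file path.
#' @param format \code{"csv"}, \code{"tsv"} or \code{"mtx"} (default guessed
#'   from the extension).
#' @param transpose flip the orientation after reading.
#' @param featurePath,barcodePath companion name files for mtx input
#'   (default \code{features.tsv} / \code{barcodes.tsv} next to the matrix).
#' @return A [JsomDataset-class].
#' @export
readMatrix <- function(path, format = c("auto", "csv", "tsv", "mtx"),
                       transpose = FALSE, featurePath = NULL,
                       barcodePath = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv", mtx = "mtx",
                     stop("cannot guess format from extension '", ext, "'"))
  }
  if (format == "mtx") {
    if (is.null(featurePath)) featurePath <- file.path(dirname(path), "features.tsv")
    if (is.null(barcodePath)) barcodePath <- file.path(dirname(path), "barcodes.tsv")
    m <- as.matrix(Matrix::readMM(path))
    feats <- utils::read.table(featurePath, sep = "\t",
                               stringsAsFactors = FALSE)[, 1L]
    cells <- utils::read.table(barcodePath, sep = "\t",
                               stringsAsFactors = FALSE)[, 1L]
    if (length(feats) != nrow(m) || length(cells) != ncol(m))
      stop("companion name files do not match the matrix dimensions")
    vals <- t(m)
    dimnames(vals) <- list(cells, feats)
    if (transpose) vals <- t(vals)
    return(jsomDataset(vals))
  }
  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  labels <- batch <- NULL
  if ("label" %in% colnames(df)) { labels <- as.character(df[["label"]]); df[["label"]] <- NULL }
  if ("batch" %in% colnames(df)) { batch <- as.character(df[["batch"]]); df[["batch"]] <- NULL }
  nonNum <- !vapply(df, is.numeric, logical(1))
  if (any(nonNum))
    stop("non-numeric column(s): ", paste(colnames(df)[nonNum], collapse = ", "))
  vals <- as.matrix(df)
  if (transpose) vals <- t(vals)
  jsomDataset(vals, labels = labels, batch = batch)
}

#' Write a JsomDataset to CSV/TSV
#'
#' Inverse of [readMatrix()] for dense formats: cell ids in the first column,
#' feature names as the header, and \code{label} / \code{batch} columns
#' appended when present.
#'
#' @param d a [JsomDataset-class].
#' @param path output file.
#' @param format \code{"csv"} (default) or \code{"tsv"}.
#' @export
writeMatrix <- function(d, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  df <- as.data.frame(values(d), check.names = FALSE)
  if (!is.null(cellLabels(d))) df$label <- cellLabels(d)
  if (!is.null(cellBatch(d))) df$batch <- cellBatch(d)
  utils::write.table(cbind(cell_id = cellIds(d), df), path,
                     sep = if (format == "csv") "," else "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

.configToList <- function(cfg) {
  list(m = cfg@m, n = cfg@n, epochs = cfg@epochs, alpha0 = cfg@alpha0,
       alphaFinal = cfg@alphaFinal, epsilon0 = cfg@epsilon0,
       downsampleTarget = cfg@downsampleTarget, downsample = cfg@downsample,
       outlierPercentile = cfg@outlierPercentile, seed = cfg@seed,
       joint = cfg@joint, deltaInIndependent = cfg@deltaInIndependent,
       allowNegativeDelta = cfg@allowNegativeDelta, sampling = cfg@sampling)
}

.configFromList <- function(x) {
  do.call(jsomConfig, x)
}

#' Save / load a trained map container
#'
#' The container is a single JSON file holding the grid dimensions, both
#' codebook matrices at full double precision (17 significant digits, so the
#' round trip is bit-exact), the training configuration and the package
#' version. Loading a file written by a newer major version fails with an
#' explicit incompatibility error.
#'
#' @param maps a [JsomMap-class].
#' @param path file path (conventionally \code{.json}).
#' @return \code{saveMaps} returns the path invisibly; \code{loadMaps}
#'   returns the restored [JsomMap-class].
#' @export
saveMaps <- function(maps, path) {
  payload <- list(
    container = "jsomap-maps",
    version = as.character(utils::packageVersion("jsomap")),
    m = maps@m, n = maps@n,
    V1 = maps@V1, V2 = maps@V2,
    config = .configToList(maps@config))
  writeLines(jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE),
             path)
  invisible(path)
}

#' @rdname saveMaps
#' @export
loadMaps <- function(path) {
  payload <- tryCatch(jsonlite::fromJSON(path),
                      error = function(e) stop("corrupt map container: ",
                                               conditionMessage(e)))
  if (!identical(payload$container, "jsomap-maps"))
    stop("not a jsomap map container")
  fileMajor <- as.integer(strsplit(payload$version, ".", fixed = TRUE)[[1L]][1L])
  pkgMajor <- as.integer(unlist(utils::packageVersion("jsomap"))[1L])
  if (is.na(fileMajor) || fileMajor > pkgMajor)
    stop("map container written by a newer major version (", payload$version,
         "); please upgrade")
  V1 <- matrix(as.numeric(payload$V1), nrow = nrow(payload$V1))
  V2 <- matrix(as.numeric(payload$V2), nrow = nrow(payload$V2))
  if (nrow(V1) != payload$m * payload$n || nrow(V2) != payload$m * payload$n)
    stop("corrupt map container: codebook dimensions disagree with the grid")
  new("JsomMap", m = as.integer(payload$m), n = as.integer(payload$n),
      V1 = V1, V2 = V2, config = .configFromList(payload$config))
}

#' Export an assignment table
#'
#' Writes one row per cell: cell id, dataset of origin, 1-based node index,
#' 0-based grid row/column, and (when supplied) the node cluster and the
#' node's majority label.
#'
#' @param assignment a [JsomAssignment-class].
#' @param d1,d2 the assigned [JsomDataset-class] objects (for cell ids and
#'   labels).
#' @param maps the [JsomMap-class] (for grid coordinates).
#' @param path output CSV path.
#' @param clustering optional per-node clusters from [superposeCluster()].
#' @return The combined data.frame, invisibly.
#' @export
writeAssignment <- function(assignment, d1, d2, maps, path, clustering = NULL) {
  coords <- gridCoordinates(maps@m, maps@n)
  oneBlock <- function(d, nodes, tag, labels) {
    data.frame(cell_id = cellIds(d), dataset = tag, node = nodes,
               grid_row = coords[nodes, 1L], grid_col = coords[nodes, 2L],
               cluster = if (is.null(clustering)) NA_integer_
                         else clustering[nodes],
               label = if (is.null(labels)) NA_character_ else labels,
               stringsAsFactors = FALSE)
  }
  out <- rbind(oneBlock(d1, nodes1(assignment), "dataset1", cellLabels(d1)),
               oneBlock(d2, nodes2(assignment), "dataset2", cellLabels(d2)))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(out)
}
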