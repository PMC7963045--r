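# Accessor generics and methods. Slot access stays internal to the package;
# user code goes through these.

#' @rdname accessors
#' @export
setGeneric("values", function(x) standardGeneric("values"))
#' @rdname accessors
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))
#' @rdname accessors
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))
#' @rdname accessors
#' @export
setGeneric("cellLabels", function(x) standardGeneric("cellLabels"))
#' @rdname accessors
#' @export
setGeneric("cellBatch", function(x) standardGeneric("cellBatch"))
#' @rdname accessors
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))
#' @rdname accessors
#' @export
setGeneric("nFeatures", function(x) standardGeneric("nFeatures"))

#' Accessors for jsomap objects
#'
#' Extract the components of [JsomDataset-class], [JsomMap-class],
#' [JsomMatching-class], [JsomAssignment-class] and [JsomFit-class] objects.
#'
#' @param x the object.
#' @param i for \code{subsetCells}, integer or logical cell index.
#' @return The requested component: matrices for \code{values}/\code{codebook1}/
#'   \code{codebook2}, character vectors for names and labels, integer vectors
#'   for node assignments and matches.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("values", "JsomDataset", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("cellIds", "JsomDataset", function(x) rownames(x@values))
#' @rdname accessors
#' @export
setMethod("featureNames", "JsomDataset", function(x) colnames(x@values))
#' @rdname accessors
#' @export
setMethod("cellLabels", "JsomDataset", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("cellBatch", "JsomDataset", function(x) x@batch)
#' @rdname accessors
#' @export
setMethod("nCells", "JsomDataset", function(x) nrow(x@values))
#' @rdname accessors
#' @export
setMethod("nFeatures", "JsomDataset", function(x) ncol(x@values))

#' @rdname accessors
#' @export
subsetCells <- function(x, i) {
  stopifnot(is(x, "JsomDataset"))
  jsomDataset(x@values[i, , drop = FALSE],
              labels = if (!is.null(x@labels)) x@labels[i],
              batch = if (!is.null(x@batch)) x@batch[i])
}

#' @rdname accessors
#' @export
subsetFeatures <- function(x, j) {
  stopifnot(is(x, "JsomDataset"))
  jsomDataset(x@values[, j, drop = FALSE], labels = x@labels, batch = x@batch)
}

#' @rdname accessors
#' @export
setGeneric("codebook1", function(x) standardGeneric("codebook1"))
#' @rdname accessors
#' @export
setGeneric("codebook2", function(x) standardGeneric("codebook2"))
#' @rdname accessors
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))
#' @rdname accessors
#' @export
setMethod("codebook1", "JsomMap", function(x) x@V1)
#' @rdname accessors
#' @export
setMethod("codebook2", "JsomMap", function(x) x@V2)
#' @rdname accessors
#' @export
setMethod("gridDim", "JsomMap", function(x) c(m = x@m, n = x@n))

#' @rdname accessors
#' @export
setGeneric("matchIndices", function(x, direction = c("1to2", "2to1"))
  standardGeneric("matchIndices"))
#' @rdname accessors
#' @export
setMethod("matchIndices", "JsomMatching", function(x, direction = c("1to2", "2to1")) {
  if (match.arg(direction) == "1to2") x@match1to2 else x@match2to1
})
#' @rdname accessors
#' @export
setGeneric("matchWeights", function(x, which = c(1, 2)) standardGeneric("matchWeights"))
#' @rdname accessors
#' @export
setMethod("matchWeights", "JsomMatching", function(x, which = c(1, 2)) {
  if (which[1] == 1) x@delta1 else x@delta2
})
#' @rdname accessors
#' @export
setGeneric("matchingMode", function(x) standardGeneric("matchingMode"))
#' @rdname accessors
#' @export
setMethod("matchingMode", "JsomMatching", function(x) x@mode)

#' @rdname accessors
#' @export
setGeneric("nodes1", function(x) standardGeneric("nodes1"))
#' @rdname accessors
#' @export
setGeneric("nodes2", function(x) standardGeneric("nodes2"))
#' @rdname accessors
#' @export
setMethod("nodes1", "JsomAssignment", function(x) x@nodes1)
#' @rdname accessors
#' @export
setMethod("nodes2", "JsomAssignment", function(x) x@nodes2)

#' @rdname accessors
#' @export
setGeneric("trainedMaps", function(x) standardGeneric("trainedMaps"))
#' @rdname accessors
#' @export
setMethod("trainedMaps", "JsomFit", function(x) x@maps)
#' @rdname accessors
#' @export
setGeneric("fitMatching", function(x) standardGeneric("fitMatching"))
#' @rdname accessors
#' @export
setMethod("fitMatching", "JsomFit", function(x) x@matching)
#' @rdname accessors
#' @export
setGeneric("fitAssignment", function(x) standardGeneric("fitAssignment"))
#' @rdname accessors
#' @export
setMethod("fitAssignment", "JsomFit", function(x) x@assignment)
#' @rdname accessors
#' @export
setGeneric("trainingCells", function(x) standardGeneric("trainingCells"))
#' @rdname accessors
#' @export
setMethod("trainingCells", "JsomFit", function(x) list(keep1 = x@keep1, keep2 = x@keep2))

#' @rdname accessors
#' @export
setGeneric("sharedIdx1", function(x) standardGeneric("sharedIdx1"))
#' @rdname accessors
#' @export
setGeneric("sharedIdx2", function(x) standardGeneric("sharedIdx2"))
#' @rdname accessors
#' @export
setMethod("sharedIdx1", "SharedFeatures", function(x) x@idx1)
#' @rdname accessors
#' @export
setMethod("sharedIdx2", "SharedFeatures", function(x) x@idx2)
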