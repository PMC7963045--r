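# End-to-end pipeline: downsample -> match -> train -> assign.

#' Run the full alignment pipeline
#'
#' Applies the training-size cap (density-dependent downsampling by default,
#' uniform sampling when disabled), builds the cross-dataset matching on the
#' retained cells, trains the coupled maps, and assigns the FULL datasets to
#' the trained nodes.
#'
#' @param d1,d2 [JsomDataset-class] objects (already preprocessed: transforms,
#'   filtering, HVG/PCA reduction as appropriate for the modality).
#' @param shared a [SharedFeatures-class] correspondence between the two
#'   datasets' feature columns.
#' @param config a [JsomConfig-class].
#' @param mode matching mode, \code{"correlation"} (default) or
#'   \code{"binary"}.
#' @param verbose print stage summaries.
#' @return A [JsomFit-class].
#' @examples
#' sim <- generatePaired(simSpec(kClusters = 3, cellsPerCluster = 40, seed = 2))
#' fit <- runJsom(sim$d1, sim$d2, sim$shared, jsomConfig(epochs = 1, seed = 2))
#' fit
#' @export
runJsom <- function(d1, d2, shared, config = jsomConfig(),
                    mode = c("correlation", "binary"), verbose = FALSE) {
  mode <- match.arg(mode)
  say <- function(...) if (verbose) message(...)
  say("datasets: ", nCells(d1), " x ", nFeatures(d1), " and ",
      nCells(d2), " x ", nFeatures(d2))

  capOne <- function(d, which) {
    if (nCells(d) <= config@downsampleTarget) return(seq_len(nCells(d)))
    if (config@downsample) {
      say("density-dependent downsampling of dataset ", which, " to ",
          config@downsampleTarget)
      densityDownsample(values(d), targetSize = config@downsampleTarget,
                        outlierPercentile = config@outlierPercentile,
                        seed = config@seed + which)
    } else {
      say("uniform downsampling of dataset ", which, " to ",
          config@downsampleTarget)
      uniformDownsample(values(d), targetSize = config@downsampleTarget,
                        seed = config@seed + which)
    }
  }
  keep1 <- capOne(d1, 1L)
  keep2 <- capOne(d2, 2L)
  t1 <- subsetCells(d1, keep1)
  t2 <- subsetCells(d2, keep2)

  matching <- buildMatching(t1, t2, shared, mode = mode,
                            allowNegative = config@allowNegativeDelta)
  say("matching (", mode, "): mean delta ",
      round(mean(matchWeights(matching, 1)), 3), " / ",
      round(mean(matchWeights(matching, 2)), 3))

  maps <- trainJsom(t1, t2, matching, config)
  say("trained ", config@m, "x", config@n, " maps; quantization error ",
      round(quantizationError(values(t1), codebook1(maps)), 3), " / ",
      round(quantizationError(values(t2), codebook2(maps)), 3))

  assignment <- assignToNodes(d1, d2, maps)
  new("JsomFit", maps = maps, matching = matching, assignment = assignment,
      keep1 = as.integer(keep1), keep2 = as.integer(keep2))
}

#' Score a fitted alignment
#'
#' Convenience wrapper computing the standard report for a [JsomFit-class]:
#' node purity score, matching score, alignment RMSE over the shared features
#' (meaningful when the shared features are commensurate in the two training
#' spaces), and the average KL batch-mixing divergence over nodes with the
#' dataset of origin as the batch label.
#'
#' @param fit a [JsomFit-class].
#' @param labels1,labels2 per-cell labels for the full datasets.
#' @param shared optional [SharedFeatures-class] within the TRAINING feature
#'   spaces for the RMSE (skipped when \code{NULL}).
#' @return Named list with \code{purity}, \code{matching}, \code{rmse}
#'   (possibly \code{NA}) and \code{avgKL}.
#' @export
scoreFit <- function(fit, labels1, labels2, shared = NULL) {
  asg <- fitAssignment(fit)
  nNodes <- asg@nNodes
  purity <- nodePurityScore(nodes1(asg), labels1, nodes2(asg), labels2, nNodes)
  matching <- matchingScore(nodes1(asg), labels1, nodes2(asg), labels2, nNodes)
  rmse <- if (is.null(shared)) NA_real_ else alignmentRMSE(trainedMaps(fit), shared)
  batch <- rep(c("dataset1", "dataset2"),
               c(length(nodes1(asg)), length(nodes2(asg))))
  avgKL <- averageKLDivergence(c(nodes1(asg), nodes2(asg)), batch)
  list(purity = purity, matching = matching, rmse = rmse, avgKL = avgKL)
}
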