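#' Accessors for lncTempo result objects
#'
#' `centroids()` and `memberships()` extract the cluster centroid and
#' membership matrices from a [SoftClusterResult-class];
#' `objectiveTrace()` the per-iteration objective values.
#' `edgeTable()`, `networkNodes()` and `miThreshold()` extract the edge list,
#' node set and MI cutoff of an [MINetwork-class].
#' `moduleLabels()` extracts the gene -> module assignment of a
#' [CoexpressionResult-class].
#'
#' @param x a result object.
#' @return the corresponding slot value.
#' @examples
#' z <- matrix(rnorm(80), 10, 8,
#'             dimnames = list(paste0("g", 1:10), paste0("t", 1:8)))
#' res <- fcmCluster(z, c = 2, seed = 1)
#' dim(memberships(res))
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))

#' @rdname accessors
#' @export
setGeneric("memberships", function(x) standardGeneric("memberships"))

#' @rdname accessors
#' @export
setGeneric("objectiveTrace", function(x) standardGeneric("objectiveTrace"))

#' @rdname accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname accessors
#' @export
setGeneric("miThreshold", function(x) standardGeneric("miThreshold"))

#' @rdname accessors
#' @export
setGeneric("moduleLabels", function(x) standardGeneric("moduleLabels"))

#' @rdname accessors
#' @export
setMethod("centroids", "SoftClusterResult", function(x) x@centroids)

#' @rdname accessors
#' @export
setMethod("memberships", "SoftClusterResult", function(x) x@memberships)

#' @rdname accessors
#' @export
setMethod("objectiveTrace", "SoftClusterResult", function(x) x@objectiveTrace)

#' @rdname accessors
#' @export
setMethod("edgeTable", "MINetwork", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("networkNodes", "MINetwork", function(x) x@nodes)

#' @rdname accessors
#' @export
setMethod("miThreshold", "MINetwork", function(x) x@threshold)

#' @rdname accessors
#' @export
setMethod("moduleLabels", "CoexpressionResult", function(x) x@modules)

setMethod("show", "SoftClusterResult", function(object) {
    cat("SoftClusterResult\n",
        "  genes: ", nrow(object@memberships),
        "  clusters: ", nrow(object@centroids),
        "  timepoints: ", ncol(object@centroids), "\n",
        "  iterations: ", object@iterations,
        "  objective: ", format(object@objective, digits = 6), "\n",
        sep = "")
})

setMethod("show", "MINetwork", function(object) {
    cat("MINetwork\n",
        "  nodes: ", length(object@nodes),
        "  edges: ", nrow(object@edges), "\n",
        "  MI threshold (bits): ", format(object@threshold, digits = 4),
        if (!is.na(object@dpiTolerance))
            paste0("  DPI tolerance: ", object@dpiTolerance) else
            "  (DPI not applied)",
        "\n", sep = "")
})

setMethod("show", "CoexpressionResult", function(object) {
    nm <- length(setdiff(unique(object@modules), 0L))
    cat("CoexpressionResult\n",
        "  genes: ", length(object@modules),
        "  power: ", object@power,
        "  modules: ", nm, "\n", sep = "")
})

setMethod("show", "BiotypeExperiment", function(object) {
    callNextMethod()
    bt <- table(rowData(object)$biotype)
    if (length(bt))
        cat("lncRNA biotypes:",
            paste(names(bt), bt, sep = "=", collapse = " "), "\n")
})
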