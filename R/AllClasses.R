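#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assay<- assayNames rowData rowData<-
NULL

#' BiotypeExperiment: a biotype-annotated expression time course
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with the invariants
#' required for a gene x timepoint RPKM matrix: a single `"rpkm"` assay with
#' finite, non-negative values; unique gene identifiers; and row metadata
#' describing each gene's class (`protein_coding`, `lncRNA`, `unannotated`),
#' its positional biotype (lncRNA rows), the coding partner of each lncRNA,
#' and, for coding genes, the biotype of the lncRNA they partner
#' (`assoc_biotype`).
#'
#' A second `"z"` assay holding the time-standardized matrix is added by
#' [standardizeTime()].
#'
#' @slot ... see [SummarizedExperiment::SummarizedExperiment].
#' @seealso [loadExpressionMatrix()], [filterExpressed()], [standardizeTime()]
#' @export
setClass("BiotypeExperiment", contains = "SummarizedExperiment")

setValidity("BiotypeExperiment", function(object) {
    msg <- character()
    if (!"rpkm" %in% assayNames(object))
        msg <- c(msg, "assay 'rpkm' is required")
    else {
        v <- assay(object, "rpkm")
        if (any(!is.finite(v)))
            msg <- c(msg, "rpkm values must be finite")
        else if (any(v < 0))
            msg <- c(msg, "rpkm values must be >= 0")
    }
    if (is.null(rownames(object)))
        msg <- c(msg, "gene identifiers (rownames) are required")
    else if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate gene identifiers")
    need <- c("gene_class", "biotype", "partner_id", "assoc_biotype")
    miss <- setdiff(need, colnames(rowData(object)))
    if (length(miss))
        msg <- c(msg, paste0("rowData is missing: ",
                             paste(miss, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' SoftClusterResult: fuzzy c-means output
#'
#' Holds the centroid matrix (clusters x timepoints), the full membership
#' matrix mu (genes x clusters, rows summing to 1), the iteration count, the
#' final value of the fuzzy c-means objective and its per-iteration trace,
#' and the largest deviation of any membership row sum from 1 observed at
#' any iteration (a numerical self-check).
#'
#' @slot centroids numeric matrix, clusters x timepoints.
#' @slot memberships numeric matrix, genes x clusters, entries in `[0, 1]`.
#' @slot iterations integer, iterations until convergence.
#' @slot objective numeric, final objective sum(mu^m * d^2).
#' @slot objectiveTrace numeric vector, objective after each iteration.
#' @slot rowsumDeviation numeric, max |rowSums(mu) - 1| over all iterations.
#' @seealso [fcmCluster()], [assignStages()]
#' @export
setClass("SoftClusterResult",
    representation(centroids = "matrix", memberships = "matrix",
                   iterations = "integer", objective = "numeric",
                   objectiveTrace = "numeric", rowsumDeviation = "numeric"))

setValidity("SoftClusterResult", function(object) {
    mu <- object@memberships
    msg <- character()
    if (any(mu < -1e-12) || any(mu > 1 + 1e-12))
        msg <- c(msg, "memberships must lie in [0, 1]")
    if (max(abs(rowSums(mu) - 1)) > 1e-9)
        msg <- c(msg, "membership rows must sum to 1 (tol 1e-9)")
    if (any(!is.finite(object@centroids)))
        msg <- c(msg, "centroids must be finite")
    if (nrow(object@centroids) != ncol(mu))
        msg <- c(msg, "centroid count must equal membership columns")
    if (length(msg)) msg else TRUE
})

#' MINetwork: a mutual-information gene network
#'
#' An undirected weighted gene graph. Edges are stored canonically with
#' `gene_i < gene_j` (lexicographic), carry the estimated mutual information
#' in bits, and all satisfy `mi >= threshold`. After
#' [applyDPI()] the `dpiTolerance` slot records the pruning tolerance used.
#'
#' @slot nodes character vector of gene identifiers.
#' @slot edges data.frame with columns `gene_i`, `gene_j`, `mi`.
#' @slot threshold numeric MI cutoff applied at inference.
#' @slot dpiTolerance numeric in `[0, 1]`, or `NA` before DPI pruning.
#' @seealso [inferNetwork()], [applyDPI()], [hubRank()]
#' @export
setClass("MINetwork",
    representation(nodes = "character", edges = "data.frame",
                   threshold = "numeric", dpiTolerance = "numeric"))

setValidity("MINetwork", function(object) {
    e <- object@edges
    msg <- character()
    if (!all(c("gene_i", "gene_j", "mi") %in% colnames(e)))
        msg <- c(msg, "edges need columns gene_i, gene_j, mi")
    else if (nrow(e)) {
        if (any(e$gene_i >= e$gene_j))
            msg <- c(msg, "edges must be canonical: gene_i < gene_j")
        if (anyDuplicated(paste(e$gene_i, e$gene_j)))
            msg <- c(msg, "duplicate edges")
        if (!all(e$gene_i %in% object@nodes) ||
            !all(e$gene_j %in% object@nodes))
            msg <- c(msg, "edge endpoints must be network nodes")
        if (any(e$mi < object@threshold - 1e-12))
            msg <- c(msg, "all retained edges must have mi >= threshold")
    }
    if (!is.na(object@dpiTolerance) &&
        (object@dpiTolerance < 0 || object@dpiTolerance > 1))
        msg <- c(msg, "dpiTolerance must be in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' CoexpressionResult: weighted co-expression network and modules
#'
#' @slot power numeric soft-threshold power (beta).
#' @slot adjacency gene x gene unsigned adjacency, entries in `[0, 1]`.
#' @slot tom topological overlap matrix, entries in `[0, 1]`, unit diagonal.
#' @slot modules named integer vector, gene -> module label (0 = unassigned).
#' @slot scaleFreeFit data.frame with `power` and `r2` for each candidate.
#' @seealso [coexpressionModules()], [tomFromAdjacency()]
#' @export
setClass("CoexpressionResult",
    representation(power = "numeric", adjacency = "matrix", tom = "matrix",
                   modules = "integer", scaleFreeFit = "data.frame"))

setValidity("CoexpressionResult", function(object) {
    msg <- character()
    if (nrow(object@tom) &&
        max(abs(object@tom - t(object@tom))) > 1e-10)
        msg <- c(msg, "TOM must be symmetric")
    if (length(object@modules) != nrow(object@tom))
        msg <- c(msg, "one module label per gene required")
    if (length(msg)) msg else TRUE
})
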