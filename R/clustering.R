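# squared Euclidean distances, rows of x to rows of cen
.sqDist <- function(x, cen) {
    d2 <- matrix(rowSums(x^2), nrow(x), nrow(cen)) +
        matrix(rowSums(cen^2), nrow(x), nrow(cen), byrow = TRUE) -
        2 * tcrossprod(x, cen)
    pmax(d2, 0)
}

# k-means++ centroid seeding (deterministic given the RNG state)
.kmeansppInit <- function(x, c) {
    n <- nrow(x)
    idx <- integer(c)
    idx[1] <- sample.int(n, 1L)
    d2 <- rowSums((x - rep(x[idx[1], ], each = n))^2)
    for (j in seq_len(c - 1L) + 1L) {
        p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
        idx[j] <- sample.int(n, 1L, prob = p)
        d2 <- pmin(d2, rowSums((x - rep(x[idx[j], ], each = n))^2))
    }
    x[idx, , drop = FALSE]
}

#' Fuzzy c-means clustering of temporal profiles
#'
#' Soft clustering by alternating the textbook fuzzy c-means updates with
#' Euclidean distance: memberships
#' `mu_ij = 1 / sum_k (d_ij / d_ik)^(2/(m-1))` and centroids
#' `c_j = sum_i mu_ij^m x_i / sum_i mu_ij^m`, iterated until the largest
#' absolute centroid change falls below `tol` or `maxIter` is reached.
#' A gene coinciding with a centroid (`d = 0`) receives membership 1 there
#' (split equally if it coincides with several). Membership rows sum to 1
#' after every iteration and the objective `sum(mu^m d^2)` is
#' non-increasing; both are recorded on the result for inspection.
#'
#' Centroids are seeded with k-means++ under `seed`: `nInit` candidate
#' seedings are drawn and the one with the lowest one-step objective is
#' kept, which makes the initialization reproducible and robust to an
#' occasional bad draw. Pass an explicit `init` matrix to bypass seeding
#' entirely. The default
#' fuzzifier `m = 1.25` and the membership threshold used downstream
#' (`min.acore = 0.5`, see [assignStages()]) follow common practice for
#' time-course transcriptome clustering.
#'
#' @param x standardized matrix (genes x timepoints), or a
#'   [BiotypeExperiment-class] carrying a `"z"` assay (see
#'   [standardizeTime()]).
#' @param c number of clusters (>= 2; the time-course data themselves do not
#'   fix `c` - choose per design, see the vignette).
#' @param m fuzzifier, > 1 (default 1.25).
#' @param tol convergence tolerance on the max absolute centroid change
#'   (default 1e-6).
#' @param maxIter iteration cap (default 1000).
#' @param seed integer seed for the k-means++ initialization.
#' @param nInit number of candidate k-means++ seedings (default 10).
#' @param init optional c x timepoints matrix of initial centroids.
#' @return a [SoftClusterResult-class].
#' @examples
#' z <- rbind(matrix(rnorm(40, -2, .1), 5), matrix(rnorm(40, 2, .1), 5))
#' rownames(z) <- paste0("g", 1:10)
#' res <- fcmCluster(z, c = 2, seed = 1)
#' round(memberships(res), 3)
#' @export
fcmCluster <- function(x, c, m = 1.25, tol = 1e-6, maxIter = 1000L,
                       seed = 1L, nInit = 10L, init = NULL) {
    if (methods::is(x, "BiotypeExperiment")) {
        if (!"z" %in% assayNames(x))
            stop("run standardizeTime() first: no 'z' assay found")
        x <- assay(x, "z")
    }
    stopifnot(is.matrix(x), m > 1, c >= 2)
    if (any(!is.finite(x))) stop("non-finite values in input")
    if (c > nrow(x)) stop("more clusters than genes")
    expo <- 1 / (m - 1)
    oneStepObjective <- function(cen) {
        d2 <- .sqDist(x, cen)
        dmin <- apply(d2, 1, min)
        zero <- dmin < .Machine$double.eps
        w <- (d2 / pmax(dmin, .Machine$double.eps))^(-expo)
        u <- w / rowSums(w)
        if (any(zero)) {
            z <- (d2[zero, , drop = FALSE] < .Machine$double.eps) + 0
            u[zero, ] <- z / rowSums(z)
        }
        sum(u^m * d2)
    }
    cen <- if (is.null(init)) withSeed(seed, {
        best <- NULL; bestJ <- Inf
        for (t in seq_len(max(1L, nInit))) {
            cand <- .kmeansppInit(x, c)
            J <- oneStepObjective(cand)
            if (J < bestJ) { bestJ <- J; best <- cand }
        }
        best
    }) else { stopifnot(nrow(init) == c, ncol(init) == ncol(x)); init }
    trace <- numeric(0)
    rdev <- 0
    u <- NULL
    for (it in seq_len(maxIter)) {
        d2 <- .sqDist(x, cen)
        zero <- d2 < .Machine$double.eps
        u <- matrix(0, nrow(x), c)
        hasZero <- rowSums(zero) > 0
        if (any(hasZero))
            u[hasZero, ] <- zero[hasZero, , drop = FALSE] /
                rowSums(zero[hasZero, , drop = FALSE])
        if (any(!hasZero)) {
            dd <- d2[!hasZero, , drop = FALSE]
            w <- (dd / apply(dd, 1, min))^(-expo)
            u[!hasZero, ] <- w / rowSums(w)
        }
        rdev <- max(rdev, abs(rowSums(u) - 1))
        trace <- c(trace, sum(u^m * d2))
        um <- u^m
        newCen <- crossprod(um, x) / colSums(um)
        shift <- max(abs(newCen - cen))
        cen <- newCen
        if (shift < tol) break
    }
    dimnames(u) <- list(rownames(x), paste0("cluster", seq_len(c)))
    dimnames(cen) <- list(paste0("cluster", seq_len(c)), colnames(x))
    methods::new("SoftClusterResult", centroids = cen, memberships = u,
                 iterations = as.integer(it), objective = trace[length(trace)],
                 objectiveTrace = trace, rowsumDeviation = rdev)
}

#' Legacy marker symbol aliases
#'
#' Developmental-stage marker lists are often written with legacy symbols;
#' this mapping translates them to current HGNC symbols at load time
#' (POU5F/OCT4 -> POU5F1, TDGF -> TDGF1, CTIP2 -> BCL11B).
#'
#' @return named character vector, legacy symbol -> current symbol.
#' @export
markerAliases <- function() {
    c(POU5F = "POU5F1", OCT4 = "POU5F1", TDGF = "TDGF1", CTIP2 = "BCL11B")
}

#' Default developmental-stage marker genes
#'
#' The marker panel for in vitro corticogenesis: pluripotency (day 0)
#' POU5F1, NANOG, NODAL, TDGF1; neuronal commitment (day 7) PAX6, SOX1;
#' later development (day 26 onwards) EMX2, TBR1, BCL11B, CACNA1E, PRSS12,
#' CARTPT.
#'
#' @return named list stage -> character vector of gene symbols.
#' @export
defaultStageMarkers <- function() {
    list(pluripotency = c("POU5F1", "NANOG", "NODAL", "TDGF1"),
         commitment   = c("PAX6", "SOX1"),
         later        = c("EMX2", "TBR1", "BCL11B", "CACNA1E",
                          "PRSS12", "CARTPT"))
}

#' Read a stage -> marker gene table
#'
#' TSV with columns `stage` and `gene_id`; legacy symbols are translated via
#' [markerAliases()].
#'
#' @param path TSV file.
#' @param aliases named character vector of symbol aliases.
#' @return named list stage -> gene ids.
#' @export
readStageMarkers <- function(path, aliases = markerAliases()) {
    df <- utils::read.delim(path, colClasses = "character")
    stopifnot(all(c("stage", "gene_id") %in% colnames(df)))
    ids <- df$gene_id
    hit <- ids %in% names(aliases)
    ids[hit] <- aliases[ids[hit]]
    split(ids, df$stage)
}

#' Assign clusters to developmental stages via marker memberships
#'
#' For each cluster, computes the mean membership of every stage's marker
#' genes and assigns the stage with the highest mean if it reaches
#' `minAcore`; otherwise the cluster is `unassigned`. A tie between two
#' stages leaves the cluster unassigned with a warning rather than making an
#' arbitrary choice. Markers absent from the clustered matrix are dropped
#' with a message; it is an error if no marker is present at all.
#'
#' @param res a [SoftClusterResult-class].
#' @param markers named list stage -> marker gene ids (see
#'   [defaultStageMarkers()], [readStageMarkers()]).
#' @param minAcore minimum mean marker membership (default 0.5).
#' @param aliases symbol aliases applied to the marker lists.
#' @return list with `assignment` (named character vector cluster -> stage)
#'   and `evidence` (stages x clusters matrix of mean marker memberships).
#' @export
assignStages <- function(res, markers = defaultStageMarkers(),
                         minAcore = 0.5, aliases = markerAliases()) {
    mu <- memberships(res)
    markers <- lapply(markers, function(ids) {
        hit <- ids %in% names(aliases)
        ids[hit] <- aliases[ids[hit]]
        ids
    })
    present <- lapply(markers, intersect, rownames(mu))
    missing <- mapply(setdiff, markers, present, SIMPLIFY = FALSE)
    nMiss <- sum(lengths(missing))
    if (nMiss)
        message(nMiss, " marker gene(s) absent from the clustered matrix: ",
                paste(unlist(missing), collapse = ", "))
    if (!sum(lengths(present)))
        stop("no marker genes present in the clustered matrix")
    ev <- vapply(present, function(ids) {
        if (!length(ids)) return(rep(NA_real_, ncol(mu)))
        colMeans(mu[ids, , drop = FALSE])
    }, numeric(ncol(mu)))
    ev <- t(ev)  # stages x clusters
    colnames(ev) <- colnames(mu)
    assignment <- apply(ev, 2, function(e) {
        e <- e[!is.na(e)]
        if (!length(e)) return("unassigned")
        top <- max(e)
        if (top < minAcore) return("unassigned")
        winners <- names(e)[e == top]
        if (length(winners) > 1L) {
            warning("stage tie for a cluster; left unassigned")
            return("unassigned")
        }
        winners
    })
    list(assignment = assignment, evidence = ev)
}

#' Count stage-enriched genes per biotype
#'
#' Each gene is attributed to its argmax cluster; if that cluster carries a
#' stage label and the gene's membership there reaches `minAcore`, the gene
#' is counted once under (stage, biotype). Genes whose argmax cluster is
#' unassigned, or whose membership falls short, are not counted.
#'
#' @param res a [SoftClusterResult-class].
#' @param stages output of [assignStages()].
#' @param annotations named character vector gene_id -> biotype (genes
#'   without a biotype are grouped under `"other"`).
#' @param minAcore membership threshold (default 0.5).
#' @return data.frame of counts, one row per (stage, biotype).
#' @export
stageGeneCounts <- function(res, stages, annotations, minAcore = 0.5) {
    mu <- memberships(res)
    amax <- max.col(mu, ties.method = "first")
    memb <- mu[cbind(seq_len(nrow(mu)), amax)]
    stage <- stages$assignment[amax]
    bt <- annotations[rownames(mu)]
    bt[is.na(bt)] <- "other"
    keep <- stage != "unassigned" & memb >= minAcore
    if (!any(keep))
        return(data.frame(stage = character(), biotype = character(),
                          count = integer()))
    tab <- table(stage = stage[keep], biotype = bt[keep])
    as.data.frame(tab, responseName = "count", stringsAsFactors = FALSE)
}
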