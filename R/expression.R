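#' Construct a BiotypeExperiment
#'
#' Builds the package's expression container from an RPKM matrix and a
#' biotype assignment table (see [classifyBiotypes()]). Genes not covered by
#' the assignments (and not listed as partners) are carried with class
#' `"unannotated"`. Coding genes inherit, as `assoc_biotype`, the biotype of
#' the lncRNA they partner (the first by lncRNA id if several).
#'
#' @param rpkm numeric matrix, genes x timepoints, rownames = gene ids,
#'   colnames = timepoint labels.
#' @param assignments optional data.frame from [classifyBiotypes()].
#' @param geneClasses optional named character vector gene_id -> class,
#'   overriding classes inferred from `assignments`.
#' @return a [BiotypeExperiment-class].
#' @export
BiotypeExperiment <- function(rpkm, assignments = NULL, geneClasses = NULL) {
    stopifnot(is.matrix(rpkm), !is.null(rownames(rpkm)))
    ids <- rownames(rpkm)
    cls <- rep("unannotated", length(ids))
    biotype <- rep(NA_character_, length(ids))
    partner <- rep(NA_character_, length(ids))
    assoc <- rep(NA_character_, length(ids))
    if (!is.null(assignments)) {
        j <- match(ids, assignments$lnc_id)
        hit <- !is.na(j)
        cls[hit] <- "lncRNA"
        biotype[hit] <- assignments$biotype[j[hit]]
        partner[hit] <- assignments$partner_id[j[hit]]
        a2 <- assignments[order(assignments$lnc_id), ]
        a2 <- a2[!is.na(a2$partner_id) & !duplicated(a2$partner_id), ]
        k <- match(ids, a2$partner_id)
        chit <- !is.na(k)
        cls[chit] <- "protein_coding"
        assoc[chit] <- a2$biotype[k[chit]]
    }
    if (!is.null(geneClasses)) {
        hit <- ids %in% names(geneClasses)
        cls[hit] <- geneClasses[ids[hit]]
    }
    rd <- DataFrame(gene_class = cls, biotype = biotype,
                    partner_id = partner, assoc_biotype = assoc,
                    row.names = ids)
    se <- SummarizedExperiment(assays = list(rpkm = rpkm), rowData = rd)
    methods::new("BiotypeExperiment", se)
}

#' Load a gene x timepoint RPKM matrix
#'
#' Reads a TSV whose header row carries the timepoint labels and whose first
#' column carries gene identifiers, validates it (numeric, finite,
#' non-negative, no duplicated ids) and attaches biotype annotations.
#' Row order is preserved. A non-numeric cell raises a parse error naming
#' its row and column; a duplicated gene id or a negative value is an error.
#'
#' @param path TSV file.
#' @inheritParams BiotypeExperiment
#' @return a [BiotypeExperiment-class].
#' @export
loadExpressionMatrix <- function(path, assignments = NULL,
                                 geneClasses = NULL) {
    df <- utils::read.delim(path, check.names = FALSE,
                            colClasses = "character")
    ids <- df[[1L]]
    if (anyDuplicated(ids))
        stop("duplicate gene id: ",
             paste(unique(ids[duplicated(ids)])[1:3], collapse = ", "))
    raw <- as.matrix(df[, -1L, drop = FALSE])
    suppressWarnings(num <- matrix(as.numeric(raw), nrow(raw), ncol(raw)))
    bad <- which(is.na(num) & !is.na(raw), arr.ind = TRUE)
    if (nrow(bad))
        stop(sprintf("non-numeric value '%s' at gene '%s', column '%s'",
                     raw[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
                     colnames(raw)[bad[1, 2]]))
    if (any(!is.finite(num))) stop("missing or non-finite expression values")
    if (any(num < 0)) stop("negative RPKM values are not allowed")
    dimnames(num) <- list(ids, colnames(raw))
    BiotypeExperiment(num, assignments, geneClasses)
}

#' Filter genes by expression
#'
#' Keeps genes with RPKM `>= threshold` in at least `minTimepoints`
#' timepoints (the ">= 1 RPKM" expressed-gene rule, with an optional
#' persistence requirement). Row order is preserved and the operation is
#' idempotent. An empty result is a warning, not an error.
#'
#' @param x a [BiotypeExperiment-class].
#' @param threshold RPKM cutoff (default 1).
#' @param minTimepoints minimum number of qualifying timepoints (default 1).
#' @return the filtered `BiotypeExperiment`.
#' @export
filterExpressed <- function(x, threshold = 1, minTimepoints = 1) {
    stopifnot(methods::is(x, "BiotypeExperiment"), threshold > 0)
    keep <- rowSums(assay(x, "rpkm") >= threshold) >= minTimepoints
    if (!any(keep)) warning("no genes pass the expression filter")
    x[keep, ]
}

#' Fraction of biotype-associated coding genes that are expressed
#'
#' For each positional biotype, the fraction of its partner coding genes
#' (the coding genes paired with lncRNAs of that biotype, restricted to
#' genes present in the matrix) with RPKM `>= threshold` in at least one
#' timepoint. Biotypes with no partner genes in the matrix get `NA`.
#'
#' @inheritParams filterExpressed
#' @return data.frame with columns `biotype`, `n_partners`, `fraction`.
#' @export
fractionExpressedByBiotype <- function(x, threshold = 1) {
    stopifnot(methods::is(x, "BiotypeExperiment"))
    rd <- rowData(x)
    expressed <- rowSums(assay(x, "rpkm") >= threshold) >= 1
    names(expressed) <- rownames(x)
    lncIdx <- which(rd$gene_class == "lncRNA" & !is.na(rd$biotype))
    bts <- sort(unique(rd$biotype[lncIdx]))
    res <- lapply(bts, function(b) {
        partners <- unique(rd$partner_id[lncIdx][rd$biotype[lncIdx] == b])
        partners <- partners[!is.na(partners) & partners %in% rownames(x)]
        data.frame(biotype = b, n_partners = length(partners),
                   fraction = if (length(partners))
                       mean(expressed[partners]) else NA_real_)
    })
    do.call(rbind, res)
}

#' Time-based standardization of expression profiles
#'
#' Transforms each gene's temporal profile to mean 0 and standard deviation
#' 1 across timepoints (the time-based standardization used ahead of fuzzy
#' clustering). RPKM values are `log2(x + 1)`-transformed first by default.
#' The standard deviation uses the population denominator `n`, matching the
#' Mfuzz convention. Constant rows map to all-zero rows with a warning.
#' The result gains a `"z"` assay; the `"rpkm"` assay is kept.
#'
#' Standardization is invariant under a positive per-row affine rescaling of
#' the (log) input.
#'
#' @param x a [BiotypeExperiment-class] or a plain numeric matrix.
#' @param log2Transform apply `log2(x + 1)` before z-scoring (default TRUE).
#' @return same class as `x`: a `BiotypeExperiment` with a `"z"` assay, or
#'   the z-scored matrix.
#' @export
standardizeTime <- function(x, log2Transform = TRUE) {
    m <- if (methods::is(x, "BiotypeExperiment")) assay(x, "rpkm") else x
    stopifnot(is.matrix(m))
    if (ncol(m) < 2L) stop("standardization needs at least 2 timepoints")
    if (log2Transform) m <- log2(m + 1)
    mu <- rowMeans(m)
    sdev <- sqrt(rowMeans((m - mu)^2))
    z <- (m - mu) / sdev
    flat <- sdev == 0
    if (any(flat)) {
        warning(sum(flat), " constant gene profile(s) mapped to zero rows")
        z[flat, ] <- 0
    }
    if (methods::is(x, "BiotypeExperiment")) {
        assay(x, "z") <- z
        x
    } else z
}
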