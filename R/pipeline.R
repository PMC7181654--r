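#' Biotype enrichment in a target gene set
#'
#' For each biotype's set of associated coding genes, the percentage lying
#' in the target set and a one-sided hypergeometric p-value for
#' over-representation against the background universe. No multiple-testing
#' correction is applied by default (set `adjust = TRUE` for
#' Benjamini-Hochberg).
#'
#' @param biotypeSets named list biotype -> coding partner gene ids.
#' @param targetSet character vector of target gene ids (must be a subset of
#'   `background`).
#' @param background character vector: the gene universe.
#' @param adjust apply BH adjustment across biotypes (default FALSE).
#' @return data.frame `biotype`, `n_set`, `n_in_target`, `percent`,
#'   `p_hyper` (empty biotype sets give `NA` rows).
#' @export
enrichmentPercent <- function(biotypeSets, targetSet, background,
                              adjust = FALSE) {
    stopifnot(!is.null(names(biotypeSets)))
    if (!all(targetSet %in% background))
        stop("targetSet must be a subset of background")
    targetSet <- unique(targetSet)
    background <- unique(background)
    rows <- lapply(names(biotypeSets), function(b) {
        set <- unique(intersect(biotypeSets[[b]], background))
        if (!length(set))
            return(data.frame(biotype = b, n_set = 0L,
                              n_in_target = NA_integer_,
                              percent = NA_real_, p_hyper = NA_real_))
        ov <- length(intersect(set, targetSet))
        p <- stats::phyper(ov - 1, length(targetSet),
                           length(background) - length(targetSet),
                           length(set), lower.tail = FALSE)
        data.frame(biotype = b, n_set = length(set), n_in_target = ov,
                   percent = 100 * ov / length(set), p_hyper = p)
    })
    out <- do.call(rbind, rows)
    if (adjust) out$p_adj <- stats::p.adjust(out$p_hyper, "BH")
    out
}

#' Rank genes by stage signal and cluster them for a heatmap
#'
#' Orders genes by decreasing standardized expression (z-score) at the stage
#' timepoint, ties broken by gene id, and computes an average-linkage
#' hierarchical clustering of the genes under correlation distance
#' (`1 - cor`) for heatmap display. Constant (all-zero) rows are excluded
#' from the linkage (they have no defined correlation) but keep their place
#' in the ranking.
#'
#' @param z standardized genes x timepoints matrix.
#' @param timepoint column name of the stage timepoint (e.g. `"D7"`).
#' @return list with `ranking` (data.frame `gene`, `z`, best first) and
#'   `linkage` (an `hclust`, or `NULL` if fewer than 2 variable genes).
#' @export
rankGenesByStageSignal <- function(z, timepoint) {
    stopifnot(is.matrix(z), timepoint %in% colnames(z))
    if (nrow(z) < 2L) stop("need at least 2 genes")
    ord <- order(-z[, timepoint], rownames(z))
    ranking <- data.frame(gene = rownames(z)[ord],
                          z = unname(z[ord, timepoint]),
                          stringsAsFactors = FALSE)
    variable <- apply(z, 1, stats::sd) > 0
    linkage <- NULL
    if (sum(variable) >= 2L) {
        d <- 1 - stats::cor(t(z[variable, , drop = FALSE]))
        linkage <- stats::hclust(stats::as.dist(d), method = "average")
    }
    list(ranking = ranking, linkage = linkage)
}

#' Assemble a pipeline configuration
#'
#' Collects input paths and stage parameters into a validated configuration
#' for [runPipeline()]. All referenced paths must exist at run start. The
#' seed is propagated to every stochastic stage.
#'
#' @param annotation GTF path.
#' @param expression RPKM TSV path.
#' @param markers stage/marker TSV path.
#' @param geneSet optional path to a plain gene-id list (one per line); when
#'   absent the enrichment stage is skipped and noted in the report.
#' @param fasta optional transcript FASTA for coding-potential scoring.
#' @param coexpr optional named list biotype -> replicate-matrix TSV
#'   (samples x genes, first column sample ids).
#' @param networks optional list with `t0`, `t1` replicate-matrix TSVs for
#'   the network-change analysis.
#' @param hub optional replicate-matrix TSV for hub identification.
#' @param outputDir directory for intermediates and the report.
#' @param seed integer seed.
#' @param rpkmThreshold,minTimepoints expression filter (see
#'   [filterExpressed()]).
#' @param fcmClusters,fuzzifier,minAcore fuzzy clustering parameters.
#' @param power soft-threshold power for co-expression (default 6).
#' @param cutHeight,minModuleSize module detection (see [detectModules()]).
#' @param alpha,nPerm,bins,dpiTolerance MI network parameters (see
#'   [inferNetwork()], [applyDPI()]).
#' @param stageTimepoint timepoint used for the stage-signal ranking.
#' @return a `pipeline_config` list.
#' @export
pipelineConfig <- function(annotation, expression, markers, geneSet = NULL,
                           fasta = NULL, coexpr = NULL, networks = NULL,
                           hub = NULL, outputDir = tempfile("lncTempo_run"),
                           seed = 1L, rpkmThreshold = 1, minTimepoints = 1,
                           fcmClusters = 4L, fuzzifier = 1.25,
                           minAcore = 0.5, power = 6, cutHeight = 0.99,
                           minModuleSize = 10, alpha = 0.001, nPerm = 4000L,
                           bins = "auto", dpiTolerance = 0.15,
                           stageTimepoint = "D7") {
    cfg <- list(paths = list(annotation = annotation,
                             expression = expression, markers = markers,
                             geneSet = geneSet, fasta = fasta,
                             coexpr = coexpr, networks = networks,
                             hub = hub),
                outputDir = outputDir, seed = as.integer(seed),
                rpkmThreshold = rpkmThreshold,
                minTimepoints = minTimepoints, fcmClusters = fcmClusters,
                fuzzifier = fuzzifier, minAcore = minAcore, power = power,
                cutHeight = cutHeight, minModuleSize = minModuleSize,
                alpha = alpha, nPerm = as.integer(nPerm), bins = bins,
                dpiTolerance = dpiTolerance,
                stageTimepoint = stageTimepoint)
    class(cfg) <- "pipeline_config"
    cfg
}

.checkPaths <- function(paths) {
    flat <- unlist(paths, use.names = TRUE)
    missing <- flat[!file.exists(flat)]
    if (length(missing))
        stop("configuration references missing file(s): ",
             paste(missing, collapse = ", "))
}

.readSampleMatrix <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE, row.names = 1L)
    as.matrix(df)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order: annotation parsing and biotype
#' classification; expression loading, filtering and time standardization;
#' fuzzy c-means clustering with marker-based stage assignment and
#' per-biotype stage counts; per-biotype co-expression module detection
#' (when replicate matrices are supplied); MI network inference with DPI
#' pruning, the multiedge-partner change statistic and hub ranking;
#' transcript coding-potential scoring; biotype enrichment against a target
#' gene set; and a stage-signal gene ranking for the divergent (XH) biotype.
#' Every intermediate is persisted as TSV under `outputDir` and the run
#' report is written both as JSON (`report.json`, no timestamps, so reruns
#' with an identical configuration are byte-identical) and as readable text.
#' A stage failure aborts with the stage name; earlier outputs are retained.
#'
#' @param cfg a [pipelineConfig()] object.
#' @return the report, invisibly (a named list of tables).
#' @export
runPipeline <- function(cfg) {
    stopifnot(inherits(cfg, "pipeline_config"))
    .checkPaths(cfg$paths)
    dir.create(cfg$outputDir, recursive = TRUE, showWarnings = FALSE)
    out <- function(...) file.path(cfg$outputDir, ...)
    report <- list()
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }
    # resolved configuration (hashed for provenance)
    cfgJson <- out("config.json")
    jsonlite::write_json(cfg, cfgJson, auto_unbox = TRUE, null = "null",
                         pretty = TRUE, force = TRUE)

    ## annotation and biotype classification
    assignments <- stage("classify", {
        genes <- readAnnotation(cfg$paths$annotation)
        lnc <- genes[genes$gene_class == "lncRNA"]
        coding <- genes[genes$gene_class == "protein_coding"]
        a <- classifyBiotypes(lnc, coding)
        writeTsv(a, out("biotype_assignments.tsv"))
        a
    })
    report$biotype_counts <- as.data.frame(table(biotype =
        assignments$biotype), responseName = "count",
        stringsAsFactors = FALSE)

    ## expression preparation
    prep <- stage("prep", {
        be <- loadExpressionMatrix(cfg$paths$expression, assignments)
        fractions <- fractionExpressedByBiotype(be, cfg$rpkmThreshold)
        writeTsv(fractions, out("fraction_expressed.tsv"))
        bef <- filterExpressed(be, cfg$rpkmThreshold, cfg$minTimepoints)
        bez <- suppressWarnings(standardizeTime(bef))
        writeMatrixTsv(assay(bez, "z"), out("standardized.tsv"))
        list(be = be, bez = bez, fractions = fractions)
    })
    report$fraction_expressed <- prep$fractions
    report$genes_total <- nrow(prep$be)
    report$genes_expressed <- nrow(prep$bez)

    ## fuzzy clustering and stage assignment
    lncBiotype <- stats::setNames(assignments$biotype, assignments$lnc_id)
    stageRes <- stage("cluster", {
        res <- fcmCluster(prep$bez, c = cfg$fcmClusters,
                          m = cfg$fuzzifier, seed = cfg$seed)
        writeMatrixTsv(memberships(res), out("memberships.tsv"))
        writeMatrixTsv(centroids(res), out("centroids.tsv"),
                       idCol = "cluster")
        markers <- readStageMarkers(cfg$paths$markers)
        stg <- assignStages(res, markers, cfg$minAcore)
        counts <- stageGeneCounts(res, stg, lncBiotype, cfg$minAcore)
        writeTsv(counts, out("stage_gene_counts.tsv"))
        list(res = res, stages = stg, counts = counts)
    })
    report$stage_assignment <- data.frame(
        cluster = names(stageRes$stages$assignment),
        stage = unname(stageRes$stages$assignment),
        stringsAsFactors = FALSE)
    report$stage_gene_counts <- stageRes$counts

    ## per-biotype co-expression modules
    if (!is.null(cfg$paths$coexpr)) {
        report$module_counts <- stage("modules", {
            rows <- lapply(names(cfg$paths$coexpr), function(b) {
                m <- .readSampleMatrix(cfg$paths$coexpr[[b]])
                cx <- coexpressionModules(m, beta = cfg$power,
                                          cutHeight = cfg$cutHeight,
                                          minModuleSize = cfg$minModuleSize)
                lab <- moduleLabels(cx)
                writeTsv(data.frame(gene_id = names(lab),
                                    module_label = lab, biotype = b),
                         out(paste0("modules_", b, ".tsv")))
                data.frame(biotype = b,
                           modules = length(setdiff(unique(lab), 0L)))
            })
            do.call(rbind, rows)
        })
    }

    ## MI networks: temporal change and hub identification
    if (!is.null(cfg$paths$networks)) {
        report$network_delta <- stage("network", {
            sets <- split(assignments$lnc_id, assignments$biotype)
            n0 <- applyDPI(inferNetwork(
                .readSampleMatrix(cfg$paths$networks$t0),
                alpha = cfg$alpha, nPerm = cfg$nPerm, bins = cfg$bins,
                seed = cfg$seed + 101L), cfg$dpiTolerance)
            n1 <- applyDPI(inferNetwork(
                .readSampleMatrix(cfg$paths$networks$t1),
                alpha = cfg$alpha, nPerm = cfg$nPerm, bins = cfg$bins,
                seed = cfg$seed + 102L), cfg$dpiTolerance)
            sets <- lapply(sets, intersect, networkNodes(n0))
            sets <- sets[lengths(sets) > 0]
            delta <- networkDelta(n0, n1, sets)
            writeTsv(edgeTable(n0), out("network_t0_edges.tsv"))
            writeTsv(edgeTable(n1), out("network_t1_edges.tsv"))
            writeTsv(delta, out("network_delta.tsv"))
            delta
        })
    }
    if (!is.null(cfg$paths$hub)) {
        report$hub_ranking <- stage("hub", {
            hn <- applyDPI(inferNetwork(
                .readSampleMatrix(cfg$paths$hub),
                alpha = cfg$alpha, nPerm = cfg$nPerm, bins = cfg$bins,
                seed = cfg$seed + 103L), cfg$dpiTolerance)
            hr <- hubRank(hn)
            writeTsv(hr, out("hub_ranking.tsv"))
            utils::head(hr, 10L)
        })
    }

    ## coding potential
    if (!is.null(cfg$paths$fasta)) {
        report$coding_potential <- stage("codpot", {
            cp <- suppressWarnings(codingPotentialReport(cfg$paths$fasta))
            writeTsv(cp, out("coding_potential.tsv"))
            cp
        })
    }

    ## biotype enrichment in the target gene set
    if (!is.null(cfg$paths$geneSet)) {
        report$enrichment <- stage("enrichment", {
            target <- readLines(cfg$paths$geneSet)
            target <- target[nzchar(target)]
            genes <- readAnnotation(cfg$paths$annotation)
            background <- genes$gene_id[genes$gene_class ==
                                        "protein_coding"]
            sets <- lapply(split(assignments$partner_id,
                                 assignments$biotype),
                           function(p) unique(p[!is.na(p)]))
            enr <- enrichmentPercent(sets, target, background)
            writeTsv(enr, out("enrichment.tsv"))
            enr
        })
    } else {
        report$enrichment_note <- "no target gene set supplied; skipped"
    }

    ## stage-signal ranking of divergent-biotype coding partners
    report$stage_ranking <- stage("ranking", {
        xhPartners <- unique(stats::na.omit(
            assignments$partner_id[assignments$biotype == "XH"]))
        z <- assay(prep$bez, "z")
        z <- z[rownames(z) %in% xhPartners, , drop = FALSE]
        if (nrow(z) >= 2L && cfg$stageTimepoint %in% colnames(z)) {
            rk <- rankGenesByStageSignal(z, cfg$stageTimepoint)
            writeTsv(rk$ranking, out("stage_ranking.tsv"))
            utils::head(rk$ranking, 20L)
        } else data.frame(gene = character(), z = numeric())
    })

    report$provenance <- list(
        package = "lncTempo",
        version = as.character(utils::packageVersion("lncTempo")),
        seed = cfg$seed,
        config_md5 = unname(tools::md5sum(cfgJson)))
    jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
    txt <- utils::capture.output(utils::str(report, max.level = 2))
    writeLines(txt, out("report.txt"))
    invisible(report)
}
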