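# planted-truth constants of the default bundle: pair counts per biotype,
# planted module blocks, and the planted multiedge-unit counts at the two
# network timepoints
.bundleDesign <- function() {
    list(pairs = c(XH = 100L, XT = 60L, XO = 60L, XI = 100L, SD = 100L,
                   SU = 100L, IG = 120L),
         moduleBlocks = c(XH = 4L, IG = 3L, XI = 2L, SD = 2L, SU = 0L,
                          XO = 0L),
         blockSize = 12L,
         multiedgeUnits = list(t0 = c(XH = 22L, IG = 38L, XI = 26L),
                               t1 = c(XH = 26L, IG = 14L, XI = 16L)),
         enrichedPartners = c(XH = 7L, XI = 5L, SD = 3L, SU = 1L,
                              XT = 2L, XO = 0L),
         expressedFraction = 0.85)
}

# cycling geometry parameters used to fill each biotype's pair list
.bundleSpecs <- function(design) {
    ovGrid <- c(50L, 150L, 599L, 300L, 80L)
    gapGrid <- c(100L, 1200L, 4000L, 2500L, 600L)
    igGrid <- c(6000L, 8000L, 12000L, 9000L)
    strands <- c("+", "-")
    specs <- list(); lncIds <- character(); pcIds <- character()
    for (bt in names(design$pairs)) {
        n <- design$pairs[[bt]]
        for (i in seq_len(n)) {
            st <- strands[(i - 1L) %% 2L + 1L]
            sp <- if (bt == "XH" && i == 1L)
                # the canonical divergent pair: a long coding gene whose 5'
                # end shares a 599-bp overlap with a 3316-bp antisense lncRNA
                geometrySpec("XH", overlap = 599, codingLen = 58000,
                             lncLen = 3316)
            else switch(bt,
                XH = if (i %% 2L)
                        geometrySpec("XH", overlap = ovGrid[(i - 1L) %% 5L
                                                            + 1L],
                                     strandCoding = st)
                     else geometrySpec("XH", gap = gapGrid[(i - 1L) %% 5L
                                                           + 1L],
                                       strandCoding = st),
                XT = if (i %% 2L)
                        geometrySpec("XT", overlap = ovGrid[(i - 1L) %% 5L
                                                            + 1L],
                                     strandCoding = st)
                     else geometrySpec("XT", gap = gapGrid[(i - 1L) %% 5L
                                                           + 1L],
                                       strandCoding = st),
                XO = geometrySpec("XO", codingLen = 800L, lncLen = 2400L,
                                  strandCoding = st),
                XI = geometrySpec("XI", codingLen = 2400L, lncLen = 800L,
                                  strandCoding = st),
                SD = geometrySpec("SD", gap = gapGrid[(i - 1L) %% 5L + 1L],
                                  strandCoding = st),
                SU = geometrySpec("SU", gap = gapGrid[(i - 1L) %% 5L + 1L],
                                  strandCoding = st),
                IG = geometrySpec("IG", gap = igGrid[(i - 1L) %% 4L + 1L],
                                  strandCoding = st,
                                  strandLnc = strands[i %% 2L + 1L]))
            specs[[length(specs) + 1L]] <- sp
            if (bt == "XH" && i == 1L) {
                lncIds <- c(lncIds, "BASP1-AS1")
                pcIds <- c(pcIds, "BASP1")
            } else {
                lncIds <- c(lncIds, sprintf("LNC_%s_%03d", bt, i))
                pcIds <- c(pcIds, sprintf("PC_%s_%03d", bt, i))
            }
        }
    }
    list(specs = specs,
         ids = data.frame(lnc_id = lncIds, coding_id = pcIds,
                          stringsAsFactors = FALSE))
}

# block-correlated replicate matrix: `blocks` latent factors, `blockSize`
# genes each at pairwise correlation `rho`; remaining genes independent
.blockMatrix <- function(geneIds, blocks, blockSize, nSamples, rho, seed) {
    withSeed(seed, {
        m <- matrix(stats::rnorm(nSamples * length(geneIds)), nSamples,
                    length(geneIds), dimnames = list(NULL, geneIds))
        s <- sqrt(rho)
        for (b in seq_len(blocks)) {
            f <- stats::rnorm(nSamples)
            idx <- (b - 1L) * blockSize + seq_len(blockSize)
            m[, idx] <- s * f + sqrt(1 - rho) * m[, idx]
        }
        m
    })
}

# chain-unit matrix for the multiedge-partner analysis: `units` independent
# 3-gene Markov chains (middle gene has planted degree 2), remaining genes
# independent
.chainUnitMatrix <- function(geneIds, units, nSamples, r, seed) {
    withSeed(seed, {
        m <- matrix(stats::rnorm(nSamples * length(geneIds)), nSamples,
                    length(geneIds), dimnames = list(NULL, geneIds))
        for (u in seq_len(units)) {
            i <- (u - 1L) * 3L
            m[, i + 2L] <- r * m[, i + 1L] + sqrt(1 - r^2) * m[, i + 2L]
            m[, i + 3L] <- r * m[, i + 2L] + sqrt(1 - r^2) * m[, i + 3L]
        }
        m
    })
}

.writeSampleMatrix <- function(m, path) {
    df <- data.frame(sample_id = sprintf("S%03d", seq_len(nrow(m))), m,
                     check.names = FALSE)
    writeTsv(df, path)
}

#' Generate the default synthetic analysis bundle
#'
#' Writes a complete, internally consistent set of inputs for
#' [runPipeline()] with known planted truth, emulating a biotype-resolved
#' corticogenesis study at desk scale:
#'
#' * `annotation.gtf` + `biotype_truth.tsv`: 640 coding/lncRNA pairs over
#'   all seven biotypes, including a canonical divergent pair
#'   (`BASP1`/`BASP1-AS1`, 599-bp 5' overlap).
#' * `expression.tsv` + `expression_truth.tsv`: an 8-timepoint RPKM matrix.
#'   Three stage clusters are planted - pluripotency (D0 peak; the four
#'   pluripotency markers, 30 IG and 20 XI lncRNAs), neuronal commitment
#'   (D7 peak; PAX6/SOX1, 30 XH lncRNAs and their coding partners, with
#'   graded peak sharpness so the D7 ranking is deterministic and `BASP1`
#'   ranks second), and later development (rising profile; the six later
#'   markers and 30 IG lncRNAs). 85% of the remaining genes are expressed
#'   flat at 5 RPKM; the rest sit below the 1-RPKM cutoff.
#' * `markers.tsv`: the stage markers, deliberately written with legacy
#'   symbols (POU5F, TDGF, CTIP2) to exercise alias mapping.
#' * `gene_set.txt`: a target set containing 7% of XH partners, 5% XI,
#'   3% SD, 1% SU, 2% XT and 0% XO.
#' * `coexpr_<biotype>.tsv`: replicate matrices (60 samples) with planted
#'   correlation blocks - 4 modules for XH, 3 IG, 2 XI, 2 SD, none for SU
#'   and XO.
#' * `network_t0.tsv` / `network_t1.tsv`: replicate matrices (250 samples)
#'   with planted 3-gene chain units so the multiedge-partner counts are
#'   22 -> 26 (XH), 38 -> 14 (IG) and 26 -> 16 (XI).
#' * `hub.tsv`: a 200-sample hub fixture with `BASP1` as the planted hub of
#'   20 XH coding partners.
#' * `transcripts.fasta` + `sequence_labels.tsv`: 25 coding and 25
#'   noncoding 1200-nt transcripts plus a 3316-nt noncoding `BASP1-AS1`.
#'
#' @param dir output directory.
#' @param seed integer master seed (sub-seeds are derived by small offsets).
#' @return list with `config` (a ready [pipelineConfig()]), `truth`
#'   (planted truths: biotypes, expression clusters, module/multiedge
#'   design, sequence labels) and `dir`.
#' @export
simulateBundle <- function(dir, seed = 1L) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    seed <- as.integer(seed)
    design <- .bundleDesign()
    bs <- .bundleSpecs(design)
    ann <- simulateAnnotation(bs$specs, dir = dir, ids = bs$ids)

    ## --- expression with planted stage clusters -------------------------
    allGenes <- ann$genes$gene_id
    lncOf <- function(bt, i) ifelse(bt == "XH" & i == 1L, "BASP1-AS1",
                                    sprintf("LNC_%s_%03d", bt, i))
    pcOf <- function(bt, i) ifelse(bt == "XH" & i == 1L, "BASP1",
                                   sprintf("PC_%s_%03d", bt, i))
    pluriProfile <- c(3, 2.2, 1.2, 0.6, 0.2, 0, 0, 0)
    sharp <- c(0.2, 3.2, 1.2, 0.6, 0.4, 0.3, 0.2, 0.2)
    broad <- c(0.6, 1.6, 2.2, 1.4, 0.8, 0.5, 0.3, 0.2)  # peak at D12
    impulse <- c(0.1, 4, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1)
    laterProfile <- c(0, 0, 0.2, 0.6, 1.2, 2.2, 2.8, 3.2)
    blend <- function(alpha) alpha * sharp + (1 - alpha) * broad
    xhLnc <- lncOf("XH", 1:30); xhPc <- pcOf("XH", 1:30)
    clusters <- list(
        plantedCluster("pluripotency",
                       c("POU5F1", "NANOG", "NODAL", "TDGF1",
                         lncOf("IG", 1:30), lncOf("XI", 1:20)),
                       pluriProfile),
        plantedCluster("commitment", c("PAX6", "SOX1", xhLnc),
                       blend(0.85), noiseSd = 0.15),
        plantedCluster("later",
                       c("EMX2", "TBR1", "BCL11B", "CACNA1E", "PRSS12",
                         "CARTPT", lncOf("IG", 31:60)),
                       laterProfile))
    # coding partners of the commitment lncRNAs: individually graded peak
    # sharpness at D7, with well-separated z margins so the D7 ranking is
    # deterministic: one near-impulse gene ranks first, BASP1 second
    alphas <- stats::setNames(seq(0.2, 0.55, length.out = 30), xhPc)
    alphas["BASP1"] <- 1.0
    for (g in xhPc)
        clusters[[length(clusters) + 1L]] <- plantedCluster(
            "commitment", g,
            if (g == "PC_XH_010") impulse else blend(alphas[[g]]),
            noiseSd = 0.05)
    # expressed-but-flat genes: the leading share of every biotype's genes
    flat <- character(0)
    planted <- unlist(lapply(clusters, `[[`, "genes"))
    for (bt in names(design$pairs)) {
        n <- design$pairs[[bt]]
        nExpr <- round(design$expressedFraction * n)
        flat <- c(flat, lncOf(bt, seq_len(nExpr)), pcOf(bt, seq_len(nExpr)))
    }
    flat <- setdiff(flat, planted)
    clusters[[length(clusters) + 1L]] <-
        plantedCluster("flat_expressed", flat, rep(log(5), 8), noiseSd = 0)
    expr <- simulateExpression(c(allGenes,
                                 unlist(defaultStageMarkers(),
                                        use.names = FALSE)),
                               clusters, seed = seed + 11L,
                               path = file.path(dir, "expression.tsv"))
    writeTsv(expr$truth, file.path(dir, "expression_truth.tsv"))

    ## --- markers (legacy symbols) and target gene set -------------------
    markerDf <- data.frame(
        stage = rep(c("pluripotency", "commitment", "later"),
                    c(4L, 2L, 6L)),
        gene_id = c("POU5F", "NANOG", "NODAL", "TDGF",
                    "PAX6", "SOX1",
                    "EMX2", "TBR1", "CTIP2", "CACNA1E", "PRSS12",
                    "CARTPT"))
    writeTsv(markerDf, file.path(dir, "markers.tsv"))
    target <- character(0)
    for (bt in names(design$enrichedPartners)) {
        k <- design$enrichedPartners[[bt]]
        if (k > 0L) target <- c(target, pcOf(bt, seq_len(k)))
    }
    writeLines(target, file.path(dir, "gene_set.txt"))

    ## --- per-biotype co-expression replicate matrices -------------------
    coexpr <- list()
    off <- 20L
    for (bt in names(design$moduleBlocks)) {
        ids <- lncOf(bt, seq_len(design$pairs[[bt]]))
        p <- file.path(dir, paste0("coexpr_", bt, ".tsv"))
        m <- .blockMatrix(ids, design$moduleBlocks[[bt]],
                          design$blockSize, nSamples = 60L, rho = 0.8,
                          seed = seed + off)
        .writeSampleMatrix(m, p)
        coexpr[[bt]] <- p
        off <- off + 1L
    }

    ## --- network-change and hub replicate matrices ----------------------
    netGenes <- c(lncOf("XH", 1:78), lncOf("IG", 1:114), lncOf("XI", 1:78))
    units <- design$multiedgeUnits
    mkNet <- function(unitCounts, s) {
        m <- NULL
        blockStart <- c(XH = 0L, IG = 78L, XI = 192L)
        mm <- withSeed(s, matrix(stats::rnorm(250L * length(netGenes)),
                                 250L, length(netGenes),
                                 dimnames = list(NULL, netGenes)))
        for (bt in names(unitCounts)) {
            idx <- blockStart[[bt]]
            sub <- .chainUnitMatrix(netGenes[idx + seq_len(
                       3L * unitCounts[[bt]])],
                       unitCounts[[bt]], 250L, r = 0.9,
                       seed = s + match(bt, names(unitCounts)))
            mm[, colnames(sub)] <- sub
        }
        mm
    }
    net0 <- mkNet(units$t0, seed + 31L)
    net1 <- mkNet(units$t1, seed + 41L)
    .writeSampleMatrix(net0, file.path(dir, "network_t0.tsv"))
    .writeSampleMatrix(net1, file.path(dir, "network_t1.tsv"))
    hubGenes <- c("BASP1", pcOf("XH", 2:21))
    hubM <- simulateNetworkSamples("hub", nNodes = 21L, nSamples = 200L,
                                   edgeStrength = 0.8, seed = seed + 51L,
                                   geneIds = hubGenes)
    .writeSampleMatrix(hubM$data, file.path(dir, "hub.tsv"))

    ## --- transcript sequences -------------------------------------------
    seqs <- simulateSequences(25L, 25L, lengthBp = 1200L,
                              seed = seed + 61L)
    aslnc <- withSeed(seed + 62L, paste(
        sample(c("A", "C", "G", "T"), 3316L, TRUE), collapse = ""))
    fa <- c(seqs$seqs, Biostrings::DNAStringSet(stats::setNames(
        aslnc, "BASP1-AS1")))
    faPath <- file.path(dir, "transcripts.fasta")
    Biostrings::writeXStringSet(fa, faPath)
    labels <- rbind(seqs$labels,
                    data.frame(transcript_id = "BASP1-AS1",
                               class = "noncoding"))
    writeTsv(labels, file.path(dir, "sequence_labels.tsv"))

    cfg <- pipelineConfig(
        annotation = file.path(dir, "annotation.gtf"),
        expression = file.path(dir, "expression.tsv"),
        markers = file.path(dir, "markers.tsv"),
        geneSet = file.path(dir, "gene_set.txt"),
        fasta = faPath,
        coexpr = coexpr,
        networks = list(t0 = file.path(dir, "network_t0.tsv"),
                        t1 = file.path(dir, "network_t1.tsv")),
        hub = file.path(dir, "hub.tsv"),
        outputDir = file.path(dir, "results"),
        seed = seed, fcmClusters = 5L,
        alpha = 1e-6, nPerm = 50000L, bins = 8L)
    list(config = cfg,
         truth = list(biotypes = ann$truth, expression = expr$truth,
                      design = design, sequences = labels,
                      hub = "BASP1"),
         dir = dir)
}
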