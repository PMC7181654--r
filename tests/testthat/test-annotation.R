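test_that("GTF coordinates convert to gene models of the right length", {
    gtf <- tempfile(fileext = ".gtf")
    writeLines(c(
        paste("chr1\tsrc\tgene\t101\t200\t.\t+\t.",
              'gene_id "g1"; gene_biotype "protein_coding";',
              sep = "\t"),
        paste("chr1\tsrc\texon\t101\t200\t.\t+\t.",
              paste('gene_id "g1"; transcript_id "g1.t1";',
                    'gene_biotype "protein_coding";'),
              sep = "\t")), gtf)
    g <- readAnnotation(gtf)
    expect_equal(GenomicRanges::width(g), 100)
    expect_equal(GenomicRanges::start(g), 101)
    expect_equal(g$gene_class, "protein_coding")
})

test_that("generated annotation round-trips through the parser exactly", {
    d <- tempfile()
    b <- simulateAnnotation(list(
        geometrySpec("XH", overlap = 599, codingLen = 58000, lncLen = 3316),
        geometrySpec("SD", gap = 42),
        geometrySpec("IG", gap = 7000, strandCoding = "-")), dir = d)
    g <- readAnnotation(b$paths["gtf"])
    expect_setequal(g$gene_id, b$genes$gene_id)
    m <- match(b$genes$gene_id, g$gene_id)
    expect_equal(GenomicRanges::start(g)[m],
                 GenomicRanges::start(b$genes))
    expect_equal(GenomicRanges::end(g)[m], GenomicRanges::end(b$genes))
    expect_equal(as.character(GenomicRanges::strand(g))[m],
                 as.character(GenomicRanges::strand(b$genes)))
})

test_that("exon-less gene records are kept with a warning", {
    gtf <- tempfile(fileext = ".gtf")
    writeLines(paste("chr1\tsrc\tgene\t11\t90\t.\t-\t.",
                     'gene_id "g1"; gene_biotype "lncRNA";',
                     sep = "\t"), gtf)
    expect_warning(g <- readAnnotation(gtf), "without exon")
    expect_equal(g$n_exons, 1L)
})

test_that("records without strand or with unknown class are dropped", {
    gtf <- tempfile(fileext = ".gtf")
    writeLines(c(
        paste("chr1\tsrc\tgene\t1\t50\t.\t.\t.",
              'gene_id "gNo"; gene_biotype "protein_coding";',
              sep = "\t"),
        paste("chr1\tsrc\tgene\t1\t60\t.\t+\t.",
              'gene_id "gOdd"; gene_biotype "miRNA";',
              sep = "\t"),
        paste("chr1\tsrc\tgene\t1\t70\t.\t+\t.",
              'gene_id "gOk"; gene_biotype "lncRNA";',
              sep = "\t")), gtf)
    w <- testthat::capture_warnings(g <- readAnnotation(gtf))
    expect_match(w, "without strand", all = FALSE)
    expect_match(w, "unknown class", all = FALSE)
    expect_equal(g$gene_id, "gOk")
})

test_that("overlapAndDistance matches per-base counting and edge cases", {
    mk <- function(s, e) GenomicRanges::GRanges("chr1",
                                                IRanges::IRanges(s, e))
    expect_equal(unname(overlapAndDistance(mk(1, 100), mk(51, 150))),
                 c(50, 0))
    # adjacent gene bodies: no overlap and zero gap
    expect_equal(unname(overlapAndDistance(mk(1, 100), mk(101, 200))),
                 c(0, 0))
    expect_error(overlapAndDistance(
        mk(1, 10), GenomicRanges::GRanges("chr2", IRanges::IRanges(1, 10))),
        "different chromosomes")
    set.seed(11)
    for (i in 1:50) {
        s1 <- sample(200, 1); e1 <- s1 + sample(100, 1)
        s2 <- sample(200, 1); e2 <- s2 + sample(100, 1)
        got <- overlapAndDistance(mk(s1, e1), mk(s2, e2))
        ov <- length(intersect(seq(s1, e1), seq(s2, e2)))
        gap <- if (ov > 0) 0 else max(s1, s2) - min(e1, e2) - 1
        expect_equal(unname(got), c(ov, gap))
        # symmetry
        expect_equal(got, overlapAndDistance(mk(s2, e2), mk(s1, e1)))
    }
})

test_that("pairPartner follows overlap > distance > gene_id priority", {
    lnc <- GenomicRanges::GRanges("chr1:1000-1999", strand = "+")
    mk <- function(s, e, id) {
        g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(s, e),
                                    strand = "+")
        g$gene_id <- id
        g
    }
    near <- mk(2100, 2999, "nearGene")   # 100 bp away
    far <- mk(4000, 4999, "farGene")     # 2 kb away
    expect_equal(pairPartner(lnc, c(near, far)), "nearGene")
    ovl <- mk(1950, 2400, "ovlGene")     # 50 bp overlap
    ten <- mk(2010, 2500, "tenGene")     # 10 bp away
    expect_equal(pairPartner(lnc, c(ovl, ten)), "ovlGene")
    a <- mk(2100, 2999, "geneA"); b2 <- mk(2100, 2999, "geneB")
    expect_equal(pairPartner(lnc, c(b2, a)), "geneA")
    expect_true(is.na(pairPartner(lnc, mk(8000, 9000, "offGene"))))
})

test_that("the canonical divergent geometry is classified XH", {
    # a long coding gene and a 3316-bp antisense lncRNA sharing a 599-bp
    # overlap at both 5' ends
    coding <- GenomicRanges::GRanges("chr5", IRanges::IRanges(20000, 77999),
                                     strand = "+")
    coding$gene_id <- "BASP1"
    lnc <- GenomicRanges::GRanges("chr5",
                                  IRanges::IRanges(20000 + 599 - 3316,
                                                   20000 + 598),
                                  strand = "-")
    lnc$gene_id <- "BASP1-AS1"
    a <- classifyBiotypes(lnc, coding)
    expect_equal(a$biotype, "XH")
    expect_equal(a$overlap_bp, 599)
    expect_true(a$five_prime_overlap)
    expect_equal(a$partner_id, "BASP1")
})

test_that("the genic window boundary is inclusive at 5000 bp", {
    mk <- function(s, e, st, id, cls) {
        g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(s, e),
                                    strand = st)
        g$gene_id <- id
        g
    }
    coding <- mk(1, 1000, "+", "pc1")
    atBoundary <- mk(6002, 7001, "+", "l1")     # gap exactly 5001
    justInside <- mk(6001, 7000, "+", "l2")     # gap exactly 5000
    a <- classifyBiotypes(c(atBoundary, justInside), coding)
    expect_equal(a$biotype, c("IG", "SD"))
    expect_equal(a$distance_bp, c(5001L, 5000L))
    expect_true(is.na(a$partner_id[1]))
})

test_that("same-strand overlap is reported explicitly, never as IG", {
    coding <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, 2000),
                                     strand = "+")
    coding$gene_id <- "pc1"
    lnc <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1500, 2500),
                                  strand = "+")
    lnc$gene_id <- "l1"
    a <- classifyBiotypes(lnc, coding)
    expect_equal(a$biotype, "unclassified_sense_overlap")
    expect_equal(a$partner_id, "pc1")
})

test_that("classification equals the rule-table oracle on the full grid", {
    grid <- biotypeGrid()
    expect_gte(length(grid$specs), 500)
    b <- simulateAnnotation(grid$specs, dir = tempfile())
    g <- readAnnotation(b$paths["gtf"])
    lnc <- g[g$gene_class == "lncRNA"]
    coding <- g[g$gene_class == "protein_coding"]
    got <- classifyBiotypes(lnc, coding)
    recs <- asOracleRecords(coding)
    oracle <- vapply(asOracleRecords(lnc), oracleBiotype, character(1),
                     codingList = recs)
    expect_equal(got$biotype, oracle)
    # and the realized geometry matches the requested biotype throughout
    expect_equal(got$biotype[match(b$truth$lnc_id, got$lnc_id)],
                 b$truth$biotype)
})

test_that("labels survive a strand flip with mirrored coordinates", {
    sub <- biotypeGrid()
    idx <- seq(1, length(sub$specs), by = 7)
    b <- simulateAnnotation(sub$specs[idx], dir = tempfile())
    g <- readAnnotation(b$paths["gtf"])
    lnc <- g[g$gene_class == "lncRNA"]
    coding <- g[g$gene_class == "protein_coding"]
    before <- classifyBiotypes(lnc, coding)$biotype
    mirror <- function(gr, L) {
        s <- L - GenomicRanges::end(gr) + 1
        e <- L - GenomicRanges::start(gr) + 1
        out <- GenomicRanges::GRanges("chrS", IRanges::IRanges(s, e),
            strand = ifelse(as.character(GenomicRanges::strand(gr)) == "+",
                            "-", "+"))
        out$gene_id <- gr$gene_id
        out
    }
    L <- max(GenomicRanges::end(g)) + 1000
    after <- classifyBiotypes(mirror(lnc, L), mirror(coding, L))$biotype
    expect_equal(after, before)
})

test_that("labels ignore exon structure (gene-body geometry only)", {
    gtf <- tempfile(fileext = ".gtf")
    # same gene bodies, once with one exon and once with three
    hdr <- function(id, bt, s, e, st, tx = FALSE, exs = NULL) {
        lines <- sprintf(
            "chr1\tsrc\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; gene_biotype \"%s\";",
            s, e, st, id, bt)
        if (!is.null(exs))
            lines <- c(lines, vapply(seq_len(nrow(exs)), function(i)
                sprintf(paste0("chr1\tsrc\texon\t%d\t%d\t.\t%s\t.\t",
                               "gene_id \"%s\"; transcript_id \"%s.t1\"; ",
                               "gene_biotype \"%s\";"),
                        exs[i, 1], exs[i, 2], st, id, id, bt),
                character(1)))
        lines
    }
    writeLines(c(
        hdr("pc", "protein_coding", 1000, 3000, "+",
            exs = cbind(c(1000, 2500), c(1500, 3000))),
        hdr("ln", "lncRNA", 2800, 4000, "-",
            exs = cbind(c(2800, 3500, 3900), c(3000, 3600, 4000)))), gtf)
    g <- readAnnotation(gtf)
    a <- classifyBiotypes(g[g$gene_class == "lncRNA"],
                          g[g$gene_class == "protein_coding"])
    expect_equal(a$biotype, "XT")  # 3' ends overlap, exons irrelevant
    expect_equal(a$overlap_bp, 201)
})
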