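# well-separated two-cluster fixture
twoBlobs <- function(n = 20, gap = 4, sd = 0.1, seed = 1) {
    withr::with_seed(seed, {
        z <- rbind(matrix(rnorm(n * 8, -gap / 2, sd), n),
                   matrix(rnorm(n * 8, gap / 2, sd), n))
        rownames(z) <- paste0("g", seq_len(2 * n))
        z
    })
}

test_that("tight planted clusters get near-hard memberships", {
    z <- twoBlobs()
    res <- fcmCluster(z, c = 2, seed = 3)
    mu <- memberships(res)
    expect_true(all(apply(mu, 1, max) >= 0.99))
    truth <- rep(1:2, each = 20)
    expect_equal(adjustedRand(max.col(mu), truth), 1)
})

test_that("a gene equidistant from two symmetric centroids splits 0.5/0.5", {
    z <- rbind(rep(-1, 8), rep(1, 8), rep(0, 8))
    rownames(z) <- c("a", "b", "mid")
    init <- rbind(rep(-1, 8), rep(1, 8))
    res <- fcmCluster(z, c = 2, init = init)
    expect_equal(unname(memberships(res)["mid", ]), c(0.5, 0.5),
                 tolerance = 1e-9)
})

test_that("a gene coincident with a centroid takes membership 1 there", {
    z <- twoBlobs(n = 10)
    res <- fcmCluster(z, c = 2, seed = 2)
    cen <- centroids(res)
    z2 <- rbind(z, onCentroid = cen[1, ])
    res2 <- fcmCluster(z2, c = 2, init = cen, maxIter = 1)
    expect_equal(max(memberships(res2)["onCentroid", ]), 1)
})

test_that("memberships agree with the textbook implementation to 1e-6", {
    withr::with_seed(42, {
        z <- rbind(matrix(rnorm(160, -1, .5), 20),
                   matrix(rnorm(160, 1, .5), 20),
                   matrix(rnorm(160, 0, .5), 20))
    })
    rownames(z) <- paste0("g", 1:60)
    init <- z[c(5, 25, 45), , drop = FALSE]
    got <- fcmCluster(z, c = 3, init = init)
    ref <- fcmOracle(z, init)
    expect_equal(unname(memberships(got)), ref$memberships,
                 tolerance = 1e-6)
    expect_equal(unname(centroids(got)), unname(ref$centroids),
                 tolerance = 1e-6)
})

test_that("membership rows sum to 1 at every iteration and J never rises", {
    z <- twoBlobs(sd = 0.8, seed = 5)
    res <- fcmCluster(z, c = 3, seed = 7)
    expect_lte(res@rowsumDeviation, 1e-9)
    expect_true(all(diff(objectiveTrace(res)) <= 1e-9))
})

test_that("the m -> 1 limit reproduces k-means hard labels", {
    z <- twoBlobs(sd = 0.3, seed = 6)
    init <- z[c(1, 21), , drop = FALSE]
    soft <- fcmCluster(z, c = 2, m = 1.01, init = init)
    km <- stats::kmeans(z, centers = init, algorithm = "Lloyd")
    expect_equal(adjustedRand(max.col(memberships(soft)), km$cluster), 1)
})

test_that("permuting gene order permutes membership rows identically", {
    z <- twoBlobs(sd = 0.5, seed = 9)
    init <- rbind(rep(-2, 8), rep(2, 8))
    r1 <- fcmCluster(z, c = 2, init = init)
    perm <- sample(nrow(z))
    r2 <- fcmCluster(z[perm, ], c = 2, init = init)
    expect_equal(memberships(r2), memberships(r1)[perm, ])
})

test_that("degenerate inputs are rejected", {
    z <- twoBlobs(n = 3)
    expect_error(fcmCluster(z, c = 10, seed = 1), "more clusters")
    z[1, 1] <- NA
    expect_error(fcmCluster(z, c = 2, seed = 1), "non-finite")
})

test_that("planted three-stage structure is recovered across seeds", {
    aris <- vapply(1:10, function(sd) {
        cl <- list(
            plantedCluster("pluripotency", sprintf("p%02d", 1:50),
                           c(3, 2, 1, 0.4, 0.1, 0, 0, 0), noiseSd = 0.3),
            plantedCluster("commitment", sprintf("c%02d", 1:50),
                           c(0.3, 3, 1.2, 0.6, 0.4, 0.2, 0.1, 0),
                           noiseSd = 0.3),
            plantedCluster("later", sprintf("t%02d", 1:50),
                           c(0, 0, 0.2, 0.6, 1.2, 2.2, 2.8, 3.2),
                           noiseSd = 0.3))
        e <- simulateExpression(character(0), cl, seed = sd)
        z <- standardizeTime(e$rpkm)
        res <- fcmCluster(z, c = 3, seed = sd)
        adjustedRand(max.col(memberships(res)),
                     e$truth$stage[match(rownames(z), e$truth$gene_id)])
    }, numeric(1))
    expect_true(all(aris >= 0.9))
})

test_that("marker memberships drive stage assignment", {
    cl <- list(
        plantedCluster("pluripotency",
                       c("POU5F1", "NANOG", "NODAL", "TDGF1",
                         sprintf("p%02d", 1:20)),
                       c(3, 2, 1, 0.4, 0.1, 0, 0, 0)),
        plantedCluster("commitment",
                       c("PAX6", "SOX1", sprintf("c%02d", 1:20)),
                       c(0.3, 3, 1.2, 0.6, 0.4, 0.2, 0.1, 0)),
        plantedCluster("later",
                       c("EMX2", "TBR1", "BCL11B", "CACNA1E", "PRSS12",
                         "CARTPT", sprintf("t%02d", 1:20)),
                       c(0, 0, 0.2, 0.6, 1.2, 2.2, 2.8, 3.2)))
    e <- simulateExpression(character(0), cl, seed = 4)
    z <- standardizeTime(e$rpkm)
    res <- fcmCluster(z, c = 3, seed = 4)
    stg <- assignStages(res)
    expect_setequal(unname(stg$assignment),
                    c("pluripotency", "commitment", "later"))
    # stage counts: the planted commitment genes land in the commitment row
    bt <- stats::setNames(rep("XH", 20), sprintf("c%02d", 1:20))
    counts <- stageGeneCounts(res, stg, bt)
    expect_equal(counts$count[counts$stage == "commitment" &
                              counts$biotype == "XH"], 20L)
    # brute-force recount from the membership matrix
    mu <- memberships(res)
    amax <- max.col(mu)
    commitCluster <- which(stg$assignment == "commitment")
    manual <- sum(names(bt) %in% rownames(mu)[amax == commitCluster &
                      mu[cbind(seq_len(nrow(mu)), amax)] >= 0.5])
    expect_equal(counts$count[counts$stage == "commitment" &
                              counts$biotype == "XH"], manual)
})

test_that("legacy marker symbols are mapped through aliases", {
    p <- tempfile()
    utils::write.table(
        data.frame(stage = c("pluripotency", "later"),
                   gene_id = c("POU5F", "CTIP2")),
        p, sep = "\t", quote = FALSE, row.names = FALSE)
    mk <- readStageMarkers(p)
    expect_equal(mk$pluripotency, "POU5F1")
    expect_equal(mk$later, "BCL11B")
})

test_that("weak or tied marker evidence leaves clusters unassigned", {
    mu <- matrix(c(0.4, 0.3, 0.3,
                   0.4, 0.3, 0.3), 2, 3, byrow = TRUE,
                 dimnames = list(c("PAX6", "SOX1"), NULL))
    colnames(mu) <- paste0("cluster", 1:3)
    res <- methods::new("SoftClusterResult",
                        centroids = matrix(0, 3, 8),
                        memberships = mu, iterations = 1L, objective = 0,
                        objectiveTrace = 0, rowsumDeviation = 0)
    stg <- suppressMessages(assignStages(
        res, markers = list(commitment = c("PAX6", "SOX1"))))
    expect_true(all(stg$assignment == "unassigned"))
    # a tie between two stages is also unassigned, with a warning
    mu2 <- matrix(c(0.6, 0.4, 0.6, 0.4), 2, 2, byrow = TRUE,
                  dimnames = list(c("PAX6", "POU5F1"),
                                  paste0("cluster", 1:2)))
    res2 <- methods::new("SoftClusterResult",
                         centroids = matrix(0, 2, 8),
                         memberships = mu2, iterations = 1L, objective = 0,
                         objectiveTrace = 0, rowsumDeviation = 0)
    expect_warning(stg2 <- assignStages(res2,
        markers = list(commitment = "PAX6", pluripotency = "POU5F1")),
        "tie")
    expect_equal(unname(stg2$assignment[1]), "unassigned")
    expect_error(suppressMessages(assignStages(res,
        markers = list(commitment = "NOPE"))), "no marker genes")
})
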