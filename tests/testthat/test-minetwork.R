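test_that("MI of a vector with itself is log2(B) under equal-freq binning", {
    x <- withr::with_seed(1, rnorm(1024))
    expect_equal(mutualInformation(x, x, bins = 32), 5)       # floor(sqrt(n))
    expect_equal(mutualInformation(x, x, bins = "auto"), 5)
    expect_equal(mutualInformation(x, x, bins = 4), 2)
})

test_that("MI is exactly symmetric and handles degenerate input", {
    withr::with_seed(2, { x <- rnorm(200); y <- x + rnorm(200) })
    expect_identical(mutualInformation(x, y), mutualInformation(y, x))
    expect_warning(mi0 <- mutualInformation(rep(1, 50), rnorm(50)),
                   "constant")
    expect_equal(mi0, 0)
    expect_error(mutualInformation(1:10, 1:9), "length mismatch")
    expect_error(mutualInformation(1:5, 1:5), "at least 8")
})

test_that("a 2x2 joint histogram matches hand arithmetic to 1e-12", {
    # joint counts 40/10/10/40 over n = 100
    x <- rep(c(0, 1), each = 50)
    y <- c(rep(0, 40), rep(1, 10), rep(0, 10), rep(1, 40))
    hand <- 2 * 0.4 * log2(0.4 / 0.25) + 2 * 0.1 * log2(0.1 / 0.25)
    expect_equal(mutualInformation(x, y, bins = 2), hand,
                 tolerance = 1e-12)
})

test_that("independent pairs score near zero with modest bins", {
    mi <- withr::with_seed(11,
        mutualInformation(rnorm(1000), rnorm(1000), bins = 5))
    expect_lt(mi, 0.05)
})

test_that("independent genes produce few edges at alpha = 0.05", {
    counts <- vapply(1:5, function(sd) {
        s <- simulateNetworkSamples("independent", 20, 100, 0.5, seed = sd)
        suppressWarnings(
            nrow(edgeTable(inferNetwork(s$data, alpha = 0.05, seed = sd))))
    }, numeric(1))
    # 190 pairs at a 5% pooled-null cutoff: mean ~9.5 false edges
    expect_lt(mean(counts), 30)
})

test_that("alpha = 1 keeps the complete graph", {
    s <- simulateNetworkSamples("hub", 6, 60, 0.8, seed = 3)
    net <- inferNetwork(s$data, alpha = 1, nPerm = 100, seed = 3)
    expect_equal(nrow(edgeTable(net)), choose(6, 2))
})

test_that("planted hub edges are recovered and the hub ranks first", {
    hits <- 0L; recalls <- numeric(20)
    for (sd in 1:20) {
        s <- simulateNetworkSamples("hub", 21, 200, 0.8, seed = sd)
        net <- applyDPI(inferNetwork(s$data, alpha = 0.01, seed = sd))
        truth <- paste(s$edges$gene_i, s$edges$gene_j)
        e <- edgeTable(net)
        recalls[sd] <- mean(truth %in% paste(e$gene_i, e$gene_j))
        if (hubRank(net)$gene[1] == "G1") hits <- hits + 1L
    }
    expect_gte(mean(recalls == 1), 0.9)  # all 20 true edges, most seeds
    expect_gte(hits, 18L)                # hub top-ranked in >= 90% of seeds
})

test_that("DPI removes the planted chain's indirect edge", {
    removed <- vapply(1:20, function(sd) {
        s <- simulateNetworkSamples("chain", 3, 500, 0.9, seed = sd)
        # bins = 8 keeps the plug-in bias small; auto-binning at n = 500
        # inflates every MI by ~0.6 bits and masks the indirect edge
        net <- applyDPI(inferNetwork(s$data, alpha = 0.01, bins = 8,
                                     seed = sd))
        e <- edgeTable(net)
        !any(e$gene_i == "G1" & e$gene_j == "G3")
    }, logical(1))
    expect_gte(mean(removed), 0.95)
})

test_that("DPI protects ties, skips triangle-free graphs, only removes", {
    tri <- makeNet(data.frame(gene_i = c("a", "a", "b"),
                              gene_j = c("b", "c", "c"),
                              mi = c(1, 1, 1)))
    expect_equal(nrow(edgeTable(applyDPI(tri))), 3L)
    path <- makeNet(data.frame(gene_i = c("a", "b"),
                               gene_j = c("b", "c"), mi = c(1, 2)))
    expect_equal(edgeTable(applyDPI(path)), edgeTable(path))
    # pruned edge set is always a subset of the input edge set
    tri2 <- makeNet(data.frame(gene_i = c("a", "a", "b"),
                               gene_j = c("b", "c", "c"),
                               mi = c(1, 0.5, 1)))
    out <- edgeTable(applyDPI(tri2))
    expect_true(all(paste(out$gene_i, out$gene_j) %in%
                    paste(edgeTable(tri2)$gene_i, edgeTable(tri2)$gene_j)))
    expect_equal(nrow(out), 2L)
    expect_false(any(out$mi == 0.5))
})

test_that("DPI never removes the maximal edge of any triangle", {
    for (sd in 1:1000) {
        ed <- withr::with_seed(sd, {
            nodes <- paste0("n", 1:8)
            pairs <- t(combn(nodes, 2))
            keep <- runif(nrow(pairs)) < 0.45
            data.frame(gene_i = pairs[keep, 1], gene_j = pairs[keep, 2],
                       mi = round(runif(sum(keep)), 3) + 0.001)
        })
        if (nrow(ed) < 3) next
        net <- makeNet(ed)
        pruned <- edgeTable(applyDPI(net))
        prunedKey <- paste(pruned$gene_i, pruned$gene_j)
        e <- edgeTable(net)
        key <- paste(e$gene_i, e$gene_j)
        mi <- stats::setNames(e$mi, key)
        nodes <- networkNodes(net)
        for (a in nodes) for (b in nodes) for (c_ in nodes) {
            if (!(a < b && b < c_)) next
            k <- c(paste(a, b), paste(a, c_), paste(b, c_))
            if (!all(k %in% key)) next
            kmax <- k[which.max(mi[k])]
            expect_true(kmax %in% prunedKey)
        }
    }
})

test_that("hub ranking breaks ties by summed MI then gene id", {
    star <- makeNet(data.frame(gene_i = rep("hub", 5),
                               gene_j = paste0("s", 1:5), mi = 1))
    r <- hubRank(star)
    expect_equal(r$gene[1], "hub")
    expect_equal(r$degree[1], 5L)
    two <- makeNet(data.frame(gene_i = "a", gene_j = "b", mi = 2))
    r2 <- hubRank(two)
    expect_equal(r2$gene, c("a", "b"))  # equal degree and MI: id order
    empty <- makeNet(data.frame(gene_i = character(),
                                gene_j = character(), mi = numeric()),
                     nodes = "x")
    expect_equal(nrow(hubRank(empty)), 0L)
})

test_that("multiedge partner counts match a brute-force degree filter", {
    path <- makeNet(data.frame(gene_i = c("a", "b"),
                               gene_j = c("b", "c"), mi = c(1, 1)))
    expect_equal(multiedgePartnerCount(path, c("a", "b", "c")), 1L)
    empty <- makeNet(data.frame(gene_i = character(),
                                gene_j = character(), mi = numeric()),
                     nodes = c("a", "b"))
    expect_equal(multiedgePartnerCount(empty, c("a", "b")), 0L)
    for (sd in 1:20) {
        ed <- withr::with_seed(sd, {
            pairs <- t(combn(paste0("n", 1:10), 2))
            keep <- runif(nrow(pairs)) < 0.3
            data.frame(gene_i = pairs[keep, 1], gene_j = pairs[keep, 2],
                       mi = runif(sum(keep)))
        })
        if (!nrow(ed)) next
        net <- makeNet(ed)
        set <- paste0("n", 1:6)
        deg <- table(factor(c(ed$gene_i, ed$gene_j),
                            levels = paste0("n", 1:10)))
        expect_equal(multiedgePartnerCount(net, set),
                     sum(deg[set] >= 2))
    }
})

test_that("network deltas are zero for identical nets and additive", {
    ed <- data.frame(gene_i = c("a", "b", "c"), gene_j = c("b", "c", "d"),
                     mi = c(1, 1, 1))
    net <- makeNet(ed)
    d <- networkDelta(net, net, list(XH = c("a", "b"), IG = c("c", "d")))
    expect_true(all(d$change == 0L))
    whole <- multiedgePartnerCount(net, c("a", "b", "c", "d"))
    expect_equal(sum(d$count_t0), whole)  # disjoint sets partition the graph
})
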