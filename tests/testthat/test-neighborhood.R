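# Minimal replicon with n trivially distinct genes for geometry tests.
toyReplicon <- function(n, topology = "linear") {
    g <- data.frame(locus_tag = sprintf("t%02d", 1:n),
                    protein_id = sprintf("p%02d", 1:n),
                    start = seq(100L, by = 400L, length.out = n),
                    end = seq(100L, by = 400L, length.out = n) + 300L,
                    strand = "+", product = "x",
                    protein_seq = "MACDEFGHIKLMNPQRSTVWY",
                    is_partial = FALSE, is_pseudo = FALSE,
                    index = 0:(n - 1), stringsAsFactors = FALSE)
    new("Replicon", genomeId = "g1", repliconId = "r1",
        lengthBp = as.integer(max(g$end) + 100L), topology = topology,
        genes = g)
}

test_that("windows truncate at linear ends and cap at 2k+1 inside", {
    rep <- toyReplicon(30L)
    w0 <- extractWindow(rep, 0L, neighborhoodParams(windowK = 5L))
    expect_equal(nrow(w0$members), 6L)         # query + 5 downstream
    expect_equal(w0$members$index, 0:5)
    wMid <- extractWindow(rep, 15L, neighborhoodParams(windowK = 10L))
    expect_equal(nrow(wMid$members), 21L)      # 2k + 1
    expect_equal(range(wMid$members$index), c(5L, 25L))
    wEnd <- extractWindow(rep, 29L, neighborhoodParams(windowK = 5L))
    expect_equal(nrow(wEnd$members), 6L)
    expect_error(extractWindow(rep, 30L), "out of range")
    expect_error(extractWindow(rep, -1L), "out of range")
})

test_that("windows wrap on circular replicons without duplication", {
    rep <- toyReplicon(8L, topology = "circular")
    w <- extractWindow(rep, 3L, neighborhoodParams(windowK = 5L))
    expect_equal(nrow(w$members), 8L)          # capped at replicon size
    expect_equal(anyDuplicated(w$members$protein_id), 0L)
    big <- toyReplicon(30L, topology = "circular")
    w2 <- extractWindow(big, 1L, neighborhoodParams(windowK = 5L))
    expect_equal(nrow(w2$members), 11L)
    expect_true(all(c("p29", "p01", "p07") %in% w2$members$protein_id))
})

test_that("window parameters are validated", {
    expect_error(neighborhoodParams(windowK = 0L), "1..25")
    expect_error(neighborhoodParams(windowK = 26L), "1..25")
})

test_that("pooling uses set semantics and excludes queries", {
    rep <- toyReplicon(20L)
    p <- neighborhoodParams(windowK = 5L)
    w1 <- extractWindow(rep, 5L, p)
    w2 <- extractWindow(rep, 8L, p)   # overlaps w1
    pool <- poolNeighbors(list(w1, w2))
    expect_equal(anyDuplicated(names(pool)), 0L)
    expect_false(any(c("p06", "p09") %in% names(pool)))  # the queries
    shared <- intersect(w1$members$protein_id, w2$members$protein_id)
    expect_true(all(setdiff(shared, c("p06", "p09")) %in% names(pool)))
})

test_that("cluster annotation follows majority, ties and unknown rules", {
    mem <- setNames(c("C1", "C1", "C1", "C1", "C1", "C2", "C3", "C3"),
                    sprintf("p%d", 1:8))
    cs <- new("ClusterSet", membership = mem,
              representatives = c(C1 = "p1", C2 = "p6", C3 = "p7"))
    hits <- data.frame(
        protein_id = c("p1", "p2", "p3", "p4", "p5", "p7", "p8"),
        family = c("WYL", "WYL", "WYL", "WYL", "other", "X", "Y"),
        start = 1L, end = 50L,
        evalue = c(rep(1e-10, 5), 1e-9, 1e-12),
        score = 50, stringsAsFactors = FALSE)
    ann <- annotateClusters(cs, hits)
    expect_equal(unname(ann["C1"]), "WYL")        # majority 4/5
    expect_equal(unname(ann["C2"]), "unknown")    # no hits
    expect_equal(unname(ann["C3"]), "Y")          # tie -> best e-value
    # hits above the e-value cutoff are ignored
    hits$evalue[hits$protein_id == "p8"] <- 0.5
    expect_equal(unname(annotateClusters(cs, hits)["C3"]), "X")
})

test_that("co-occurrence counts window-level presence exactly", {
    coll <- smallCollection(seed = 40L, nGenera = 10L,
                            wylNearCarfProb = 1)
    gf <- geneFamilies(coll$truth$hits)
    w <- extractWindows(coll$replicons, names(gf)[gf == "CARF"],
                        neighborhoodParams(windowK = 5L))
    cs <- poolAndCluster(w)
    ann <- annotateClusters(cs, coll$truth$hits)
    co <- coOccurrence(w, cs, ann)
    expect_equal(attr(co, "totalQueries"), 10L)
    expect_equal(co$count[co$family == "WYL"], 10L)   # probability one
    # exact agreement with the planted event list at p < 1
    coll2 <- smallCollection(seed = 41L, nGenera = 12L,
                             wylNearCarfProb = 0.6)
    gf2 <- geneFamilies(coll2$truth$hits)
    w2 <- extractWindows(coll2$replicons, names(gf2)[gf2 == "CARF"],
                         neighborhoodParams(windowK = 5L))
    cs2 <- poolAndCluster(w2)
    ann2 <- annotateClusters(cs2, coll2$truth$hits)
    co2 <- coOccurrence(w2, cs2, ann2)
    wylRow <- co2$count[co2$family == "WYL"]
    if (length(wylRow) == 0L) wylRow <- 0L
    expect_equal(wylRow, sum(coll2$truth$events$wyl_same_window))
})

test_that("planted neighbor families are recovered as single labeled clusters", {
    coll <- smallCollection(seed = 42L, nGenera = 10L,
                            wylNearCarfProb = 1)
    gf <- geneFamilies(coll$truth$hits)
    w <- extractWindows(coll$replicons, names(gf)[gf == "CARF"],
                        neighborhoodParams(windowK = 5L))
    cs <- poolAndCluster(w)
    ann <- annotateClusters(cs, coll$truth$hits)
    wylIds <- intersect(names(membership(cs)),
                        coll$truth$proteins$protein_id[
                            coll$truth$proteins$family == "WYL"])
    expect_gt(length(wylIds), 1L)
    wylClusters <- unique(membership(cs)[wylIds])
    expect_length(wylClusters, 1L)
    expect_equal(unname(ann[wylClusters]), "WYL")
    # the WYL cluster contains nothing but planted WYL members
    inCluster <- names(membership(cs))[membership(cs) == wylClusters]
    expect_setequal(inCluster, wylIds)
})

test_that("co-occurrence counts are non-decreasing in the window size", {
    coll <- smallCollection(seed = 43L, nGenera = 8L)
    gf <- geneFamilies(coll$truth$hits)
    qids <- names(gf)[gf == "CARF"]
    counts <- lapply(c(3L, 5L), function(k) {
        w <- extractWindows(coll$replicons, qids,
                            neighborhoodParams(windowK = k))
        cs <- poolAndCluster(w)
        coOccurrence(w, cs, annotateClusters(cs, coll$truth$hits))
    })
    shared <- intersect(counts[[1]]$family, counts[[2]]$family)
    for (f in shared)
        expect_lte(counts[[1]]$count[counts[[1]]$family == f],
                   counts[[2]]$count[counts[[2]]$family == f])
})

test_that("reverse cas-linkage matches the planted association events", {
    collAll <- smallCollection(seed = 44L, nGenera = 8L,
                               carfNearCasProb = 1, casFreeProb = 0)
    gf <- geneFamilies(collAll$truth$hits)
    sig <- casSignatureTable()
    w <- extractWindows(collAll$replicons, names(gf)[gf == "CARF"],
                        neighborhoodParams(windowK = 5L))
    rl <- reverseCasLinkage(w, gf, casFamilies(sig))
    expect_equal(unname(rl["casLinked"]), unname(rl["total"]))

    collNone <- smallCollection(seed = 45L, nGenera = 8L,
                                carfNearCasProb = 0)
    gf0 <- geneFamilies(collNone$truth$hits)
    w0 <- extractWindows(collNone$replicons, names(gf0)[gf0 == "CARF"],
                         neighborhoodParams(windowK = 5L))
    rl0 <- reverseCasLinkage(w0, gf0, casFamilies(sig))
    expect_equal(unname(rl0["casLinked"]), 0L)
    expect_equal(unname(rl0["total"]), 8L)

    collMid <- smallCollection(seed = 46L, nGenera = 12L)
    gfm <- geneFamilies(collMid$truth$hits)
    wm <- extractWindows(collMid$replicons, names(gfm)[gfm == "CARF"],
                         neighborhoodParams(windowK = 5L))
    rlm <- reverseCasLinkage(wm, gfm, casFamilies(sig))
    expect_equal(unname(rlm["casLinked"]),
                 sum(collMid$truth$events$near_cas))
})
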