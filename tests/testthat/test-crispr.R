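# Replicon whose genes carry chosen family labels (via the returned
# geneFams vector); everything else is background.
labeledReplicon <- function(families) {
    n <- length(families)
    g <- data.frame(locus_tag = sprintf("t%02d", 1:n),
                    protein_id = sprintf("p%02d", 1:n),
                    start = seq(100L, by = 400L, length.out = n),
                    end = seq(100L, by = 400L, length.out = n) + 300L,
                    strand = "+", product = "x",
                    protein_seq = "MACDEFGHIKLMNPQRSTVWY",
                    is_partial = FALSE, is_pseudo = FALSE,
                    index = 0:(n - 1), stringsAsFactors = FALSE)
    rep <- new("Replicon", genomeId = "g1", repliconId = "r1",
               lengthBp = as.integer(max(g$end) + 100L),
               topology = "linear", genes = g)
    keep <- !is.na(families)
    list(replicon = rep,
         geneFams = setNames(families[keep], g$protein_id[keep]))
}

test_that("contiguous cas runs become one locus and gaps split them", {
    lr <- labeledReplicon(c(NA, "cas1", "cas2", "cas10", "csm2", NA, NA,
                            NA, "cas10", NA))
    loci <- callLoci(lr$replicon, lr$geneFams)
    # gap of 3 background genes (> default 2) splits the runs
    expect_equal(nrow(loci), 2L)
    expect_equal(loci$start_index[1], 1L)
    expect_equal(loci$end_index[1], 4L)
    expect_equal(loci$families[1], "cas1,cas2,cas10,csm2")
    expect_equal(loci$assigned_type, c("III-A", "III-unspecified"))
    # with a more tolerant gap the runs merge
    sig3 <- casSignatureTable(locusMaxGap = 3L)
    expect_equal(nrow(callLoci(lr$replicon, lr$geneFams, sig3)), 1L)
    # calling twice gives the same table
    expect_identical(loci, callLoci(lr$replicon, lr$geneFams))
})

test_that("type assignment follows the signature rules", {
    expect_equal(assignType(c("cas10", "csm2", "cas1"))$type, "III-A")
    expect_equal(assignType(c("cas10", "cmr5"))$type, "III-B")
    expect_equal(assignType(c("cas10", "cas1"))$type, "III-unspecified")
    expect_equal(assignType(c("cas3", "cas1", "cas2"))$type, "I")
    expect_equal(assignType(c("cas9", "cas1"))$type, "II")
    un <- assignType(c("cas1", "cas2"))
    expect_equal(un$type, "unknown")
    expect_false(un$composite)
    comp <- assignType(c("cas3", "cas9", "cas1"))
    expect_true(comp$composite)
    expect_setequal(comp$types, c("I", "II"))
})

test_that("the signature table round-trips through TSV", {
    sig <- casSignatureTable(locusMaxGap = 3L)
    path <- withr::local_tempfile(fileext = ".tsv")
    writeCasSignatures(sig, path)
    back <- readCasSignatures(path)
    expect_identical(back$roles, sig$roles)
    expect_identical(back$locusMaxGap, 3L)
    expect_error(casSignatureTable(c(casX = "not_a_role")), "unknown")
})

test_that("template-generated loci recover their true type exactly", {
    coll <- smallCollection(seed = 50L, nGenera = 12L,
                            speciesPerGenus = c(1L, 2L))
    gf <- geneFamilies(coll$truth$hits)
    loci <- do.call(rbind, c(lapply(coll$replicons, callLoci,
                                    geneFams = gf,
                                    sig = casSignatureTable()),
                             list(make.row.names = FALSE)))
    tr <- coll$truth$loci
    expect_equal(nrow(loci), nrow(tr))
    m <- merge(loci, tr, by = c("replicon_id", "start_index",
                                "end_index"))
    expect_equal(nrow(m), nrow(tr))
    expect_equal(m$assigned_type, m$true_type)
    expect_false(any(m$composite))
})

test_that("a query inside a typed locus window produces the expected row", {
    lr <- labeledReplicon(c("cas10", "csm2", "cas1", NA, "CARF", NA))
    loci <- callLoci(lr$replicon, lr$geneFams)
    q <- data.frame(protein_id = "p05", family = "CARF",
                    genome_id = "g1", replicon_id = "r1", index = 4L,
                    stringsAsFactors = FALSE)
    tab <- familyTypeAssociation(q, loci, windowK = 5L)
    expect_equal(tab$total, 1L)
    expect_equal(tab$near_cas, 1L)
    expect_equal(tab$`III-A`, 1L)
    expect_equal(tab$I + tab$II + tab$`III-B`, 0L)
    # out of window -> not associated
    far <- familyTypeAssociation(transform(q, index = 30L), loci,
                                 windowK = 5L)
    expect_equal(far$near_cas, 0L)
})

test_that("the association table matches ground truth on a generated fixture", {
    coll <- smallCollection(seed = 51L, nGenera = 15L)
    gf <- geneFamilies(coll$truth$hits)
    loci <- do.call(rbind, c(lapply(coll$replicons, callLoci,
                                    geneFams = gf),
                             list(make.row.names = FALSE)))
    tr <- coll$truth
    q <- tr$proteins[tr$proteins$family == "CARF", ]
    q$family <- "CARF"
    tab <- familyTypeAssociation(
        q[, c("protein_id", "family", "genome_id", "replicon_id",
              "index")], loci, windowK = 5L)
    want <- truthAssociation(tr, windowK = 5L)
    expect_equal(tab$total, unname(want["total"]))
    expect_equal(tab$near_cas, unname(want["near_cas"]))
    for (ty in c("I", "II", "III-A", "III-B"))
        expect_equal(tab[[ty]], unname(want[ty]), info = ty)
    # per-type counts never exceed near_cas
    expect_lte(tab$I + tab$II + tab$`III-A` + tab$`III-B` +
               tab$`III-unspecified`, tab$near_cas)
})

test_that("genome categories and the presence summary match ground truth", {
    coll <- smallCollection(seed = 52L, nGenera = 20L, casFreeProb = 0.1)
    gf <- geneFamilies(coll$truth$hits)
    sig <- casSignatureTable()
    loci <- do.call(rbind, c(lapply(coll$replicons, callLoci,
                                    geneFams = gf, sig = sig),
                             list(make.row.names = FALSE)))
    inv <- genomeInventory(coll$replicons, gf, loci, coll$truth$hits)
    # categories equal the truth-derived categories
    want <- truthCategories(coll$truth)
    part <- genomeCoOccurrence(inv)
    wantTab <- table(factor(want, levels = unique(part$category)))
    for (cat in names(wantTab))
        expect_equal(sum(part$n[part$category == cat]),
                     unname(wantTab[[cat]]), info = cat)
    # effector cross-tab sums to genome count
    expect_equal(sum(part$n), nrow(inv))
    # presence summary: every genome has a CARF gene; only cas-free
    # genomes lack both cas1 and cas10
    ps <- presenceSummary(inv)
    expect_equal(unname(ps["nGenomesWithQuery"]), nrow(inv))
    expect_equal(unname(ps["nLackingCas1Cas10"]),
                 sum(coll$truth$events$cas_free))
    # carf_with_effector agrees with the planted effector flags
    ev <- coll$truth$events
    expect_equal(inv$carf_with_effector[match(ev$genome_id,
                                              inv$genome_id)],
                 ev$carf_effector)
})

test_that("an empty collection yields an empty summary", {
    lr <- labeledReplicon(c(NA, NA, NA))
    inv <- genomeInventory(list(lr$replicon), setNames(character(),
                                                       character()),
                           callLoci(lr$replicon,
                                    setNames(character(), character())),
                           data.frame(protein_id = character(),
                                      family = character(),
                                      start = integer(), end = integer(),
                                      evalue = numeric(),
                                      score = numeric()))
    expect_equal(unname(presenceSummary(inv)), c(0L, 0L))
})
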