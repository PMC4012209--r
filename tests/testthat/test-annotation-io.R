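# A hand-written GenBank record exercising strands, partial markers,
# pseudo genes and out-of-order CDS features.
gbkFixture <- c(
    "LOCUS       TESTREP 9000 bp    DNA     linear   BCT",
    "DEFINITION  Test organism replicon TESTREP.",
    "ACCESSION   TESTREP",
    "COMMENT     genome_id=TESTG",
    "FEATURES             Location/Qualifiers",
    "     source          1..9000",
    "     CDS             complement(2000..2100)",
    "                     /locus_tag=\"t3\"",
    "                     /protein_id=\"p3\"",
    "                     /product=\"gamma\"",
    "                     /translation=\"MKVLAWYHDECCHHRRAKLGNDPTTSVVILMKVLAWYHDECCH",
    "                     HRRAKLG\"",
    "     CDS             100..400",
    "                     /locus_tag=\"t1\"",
    "                     /protein_id=\"p1\"",
    "                     /product=\"alpha protein\"",
    "                     /translation=\"MACDEFGHIKLMNPQRSTVWY\"",
    "     CDS             <500..>700",
    "                     /locus_tag=\"t2\"",
    "                     /protein_id=\"p2\"",
    "                     /product=\"beta\"",
    "                     /translation=\"MWYHDECCHHRR\"",
    "     CDS             3000..3500",
    "                     /locus_tag=\"t4\"",
    "                     /product=\"degraded thing\"",
    "                     /pseudo",
    "ORIGIN",
    "//")

test_that("GenBank CDS features map onto the gene table", {
    path <- withr::local_tempfile(fileext = ".gbk")
    writeLines(gbkFixture, path)
    reps <- readGenbank(path)
    expect_length(reps, 1L)
    rep <- reps[[1]]
    expect_equal(repliconId(rep), "TESTREP")
    expect_equal(genomeId(rep), "TESTG")
    expect_equal(lengthBp(rep), 9000L)
    expect_equal(topology(rep), "linear")
    g <- genes(rep)
    expect_equal(nrow(g), 4L)
    # sorted by start with 0-based index
    expect_equal(g$locus_tag, c("t1", "t2", "t3", "t4"))
    expect_equal(g$index, 0:3)
    expect_true(all(diff(g$start) > 0))
    expect_equal(g$start[1], 100L)
    expect_equal(g$end[1], 400L)
    expect_equal(g$strand, c("+", "+", "-", "+"))
    # multiline translation re-joined
    expect_equal(nchar(g$protein_seq[3]), 50L)
    # partial markers
    expect_equal(g$is_partial, c(FALSE, TRUE, FALSE, FALSE))
    # pseudo gene: flagged, no protein
    expect_equal(g$is_pseudo, c(FALSE, FALSE, FALSE, TRUE))
    expect_true(is.na(g$protein_seq[4]))
    expect_true(is.na(g$protein_id[4]))
})

test_that("malformed and degenerate GenBank input is reported", {
    path <- withr::local_tempfile(fileext = ".gbk")
    writeLines(c("DEFINITION  nothing here"), path)
    expect_error(readGenbank(path), "LOCUS")
    bad <- gbkFixture
    bad[1] <- "LOCUS       BADREP xyz bp    DNA     linear   BCT"
    writeLines(bad, path)
    expect_error(readGenbank(path), "BADREP")
})

test_that("PTT rows map onto gene records and FASTA joins by PID", {
    ptt <- withr::local_tempfile(fileext = ".ptt")
    faa <- withr::local_tempfile(fileext = ".faa")
    writeLines(c(
        "genome_id=TESTG replicon_id=TESTREP topology=linear - 1..9000",
        "2 proteins",
        paste(c("Location", "Strand", "Length", "PID", "Gene", "Synonym",
                "Code", "COG", "Product"), collapse = "\t"),
        "190..255\t+\t21\t16127995\tthrL\tb0001\t-\t-\tthr operon leader",
        "500..800\t-\t99\t16127996\t-\tb0002\t-\t-\tsomething else",
        "900..1000\t+\t30\t16127999\t-\tb0003\t-\t-\tmissing from fasta"),
        ptt)
    writeLines(c(">16127995 thr operon leader",
                 "MACDEFGHIKLMNPQRSTVWY",
                 ">16127996 something else",
                 "MKVLAWYHDECCHHRRAKLG"), faa)
    rep <- readPtt(ptt, faa)
    g <- genes(rep)
    expect_equal(genomeId(rep), "TESTG")
    expect_equal(nrow(g), 3L)
    expect_equal(g$start[1], 190L)
    expect_equal(g$end[1], 255L)
    expect_equal(g$strand, c("+", "-", "+"))
    expect_equal(g$protein_seq[1], "MACDEFGHIKLMNPQRSTVWY")
    # unmatched PID retained without sequence
    expect_true(is.na(g$protein_seq[3]))
    expect_false(g$is_partial[3])
})

test_that("PTT header problems and duplicate PIDs are errors", {
    ptt <- withr::local_tempfile(fileext = ".ptt")
    faa <- withr::local_tempfile(fileext = ".faa")
    writeLines(">x", faa)
    writeLines(c("just one line"), ptt)
    expect_error(readPtt(ptt, faa), "header")
    writeLines(c("desc - 1..9000", "2 proteins",
                 paste(c("Location", "Strand", "Length", "PID", "Gene",
                         "Synonym", "Code", "COG", "Product"),
                       collapse = "\t"),
                 "1..30\t+\t9\tdup\t-\ta\t-\t-\t-",
                 "40..70\t+\t9\tdup\t-\tb\t-\t-\t-"), ptt)
    expect_error(readPtt(ptt, faa), "duplicate PID")
})

test_that("GenBank and PTT round-trips preserve the gene table", {
    coll <- smallCollection(seed = 20L, nGenera = 2L)
    rep <- coll$replicons[[1]]
    gbk <- withr::local_tempfile(fileext = ".gbk")
    writeGenbank(rep, gbk)
    back <- readGenbank(gbk)[[1]]
    expect_equal(genes(back), genes(rep))
    expect_equal(repliconId(back), repliconId(rep))
    expect_equal(lengthBp(back), lengthBp(rep))
    # a second round trip is byte-stable
    gbk2 <- withr::local_tempfile(fileext = ".gbk")
    writeGenbank(back, gbk2)
    expect_identical(readLines(gbk), readLines(gbk2))

    ptt <- withr::local_tempfile(fileext = ".ptt")
    faa <- withr::local_tempfile(fileext = ".faa")
    writePtt(rep, ptt, faa)
    back2 <- readPtt(ptt, faa)
    expect_equal(genes(back2)[, c("locus_tag", "protein_id", "start",
                                  "end", "strand", "protein_seq",
                                  "is_partial", "is_pseudo", "index")],
                 genes(rep)[, c("locus_tag", "protein_id", "start",
                                "end", "strand", "protein_seq",
                                "is_partial", "is_pseudo", "index")])
})

test_that("the same genome parses identically from GenBank and PTT", {
    dir <- withr::local_tempdir()
    coll <- smallCollection(seed = 21L, nGenera = 3L)
    casNeighbors:::.writeCollection(coll, dir)
    for (gid in names(coll$replicons)) {
        fromGbk <- readGenbank(file.path(dir, "genomes",
                                         paste0(gid, ".gbk")))[[1]]
        fromPtt <- readPtt(file.path(dir, "genomes", paste0(gid, ".ptt")),
                           file.path(dir, "genomes", paste0(gid, ".faa")))
        cols <- c("locus_tag", "protein_id", "start", "end", "strand",
                  "protein_seq", "is_partial", "is_pseudo", "index")
        expect_equal(genes(fromPtt)[, cols], genes(fromGbk)[, cols])
        expect_equal(genomeId(fromPtt), genomeId(fromGbk))
        expect_equal(lengthBp(fromPtt), lengthBp(fromGbk))
    }
})

test_that("the completeness filter removes partial, pseudo and sequence-less records", {
    g <- genes(smallCollection(seed = 22L, nGenera = 2L)$replicons[[1]])
    res <- filterIncomplete(g)
    expect_equal(nrow(res$genes) + res$nRemoved, nrow(g))
    expect_false(any(res$genes$is_partial | res$genes$is_pseudo |
                     is.na(res$genes$protein_seq)))
    expect_true(all(res$removed$is_partial | res$removed$is_pseudo |
                    is.na(res$removed$protein_seq)))
    # order preserved
    expect_true(!is.unsorted(res$genes$index))
    # identity case
    clean <- res$genes
    expect_equal(filterIncomplete(clean)$nRemoved, 0L)
    expect_equal(filterIncomplete(clean)$genes, clean)
})

test_that("parsed gene tables match the generator's ground truth", {
    coll <- smallCollection(seed = 23L, nGenera = 3L)
    dir <- withr::local_tempdir()
    casNeighbors:::.writeCollection(coll, dir)
    tr <- coll$truth$proteins
    for (gid in names(coll$replicons)) {
        g <- genes(readGenbank(file.path(dir, "genomes",
                                         paste0(gid, ".gbk")))[[1]])
        t <- tr[tr$genome_id == gid, ]
        expect_equal(nrow(g), nrow(t))
        expect_equal(g$is_partial, t$is_partial)
        expect_equal(g$is_pseudo, t$is_pseudo)
        # planted family genes sit at the recorded indices
        fam <- t[t$family != "background", ]
        expect_true(all(g$protein_id[fam$index + 1L] == fam$protein_id))
    }
    # planted partial count is exact
    expect_equal(sum(genes(coll$replicons[[1]])$is_partial),
                 sum(tr$is_partial[tr$genome_id ==
                                   names(coll$replicons)[1]]))
})

test_that("circular replicons may carry origin-spanning genes", {
    g <- data.frame(locus_tag = c("a", "b"), protein_id = c("pa", "pb"),
                    start = c(100L, 900L), end = c(400L, 50L),
                    strand = c("+", "+"), product = c("x", "y"),
                    protein_seq = c("MACDE", "MWYH"),
                    is_partial = FALSE, is_pseudo = FALSE, index = 0:1,
                    stringsAsFactors = FALSE)
    rep <- new("Replicon", genomeId = "g", repliconId = "r",
               lengthBp = 1000L, topology = "circular", genes = g)
    expect_true(validObject(rep))
    expect_error(new("Replicon", genomeId = "g", repliconId = "r",
                     lengthBp = 1000L, topology = "linear", genes = g),
                 "circular")
})
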