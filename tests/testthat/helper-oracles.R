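# Shared fixtures and independent oracles for the test suite.

setLogLevel("quiet")

.aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

randProtein <- function(n) paste(sample(.aa20, n, TRUE), collapse = "")

blosum62 <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62
    storage.mode(m) <- "integer"
    m
})

# Deterministic point mutation: replace each listed position with the
# next residue in the alphabet (always a real substitution).
mutateAt <- function(seq, pos) {
    ch <- strsplit(seq, "")[[1]]
    for (p in pos) {
        i <- match(ch[p], .aa20)
        ch[p] <- .aa20[i %% 20L + 1L]
    }
    paste(ch, collapse = "")
}

# Exhaustive local-alignment oracle: dynamic program over chains of
# aligned columns, charging affine runs gc(g) = open + ext * g between
# consecutive columns.  Structurally independent of the Gotoh
# three-state recurrence used by the implementation.
bruteSW <- function(a, b, mat = blosum62, open = 11, ext = 1) {
    A <- strsplit(a, "")[[1]]
    B <- strsplit(b, "")[[1]]
    la <- length(A); lb <- length(B)
    gc <- function(g) if (g > 0) open + ext * g else 0
    h <- matrix(-Inf, la, lb)
    best <- 0
    for (i in seq_len(la)) for (j in seq_len(lb)) {
        s <- mat[A[i], B[j]]
        prev <- 0
        if (i > 1L && j > 1L) {
            for (i2 in seq_len(i - 1L)) for (j2 in seq_len(j - 1L)) {
                v <- h[i2, j2] - gc(i - i2 - 1L) - gc(j - j2 - 1L)
                if (v > prev) prev <- v
            }
        }
        h[i, j] <- s + prev
        if (h[i, j] > best) best <- h[i, j]
    }
    best
}

# Transitive-closure clustering oracle: boolean matrix closure over the
# pairwise linked() relation; labels components by smallest member row.
closureClusters <- function(proteins, params = clusteringParams()) {
    n <- length(proteins)
    adj <- diag(n) > 0
    if (n > 1L)
        for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
            l <- linked(proteins[[i]], proteins[[j]], params)
            adj[i, j] <- adj[j, i] <- l
        }
    R <- adj
    repeat {
        R2 <- R | ((R %*% R) > 0)
        if (identical(R2, R)) break
        R <- R2
    }
    apply(R, 1L, function(r) min(which(r)))
}

# Normalize a partition (membership vector keyed by protein id) into
# canonical integer labels for comparison.
canonicalPartition <- function(mem, ids = sort(names(mem))) {
    mem <- mem[ids]
    as.integer(factor(mem, levels = unique(mem)))
}

# A small generated collection for unit tests (window 5 keeps the
# clustering pools small).
smallCollection <- function(seed, nGenera = 6L, speciesPerGenus = c(1L, 1L),
                            ...) {
    cfg <- simulationConfig(seed = seed, nGenera = nGenera,
                            speciesPerGenus = speciesPerGenus,
                            genesPerReplicon = c(40L, 55L),
                            windowK = 5L, ...)
    generateCollection(cfg)
}

# Expected per-type association counts derived from ground truth alone:
# for each query gene, the types of truth loci whose span lies within
# windowK of the gene.
truthAssociation <- function(truth, windowK) {
    ev <- truth$events
    out <- c(total = nrow(ev), near_cas = 0L,
             setNames(integer(6), c("I", "II", "III-A", "III-B",
                                    "III-unspecified", "unknown")))
    for (i in seq_len(nrow(ev))) {
        lg <- truth$loci[truth$loci$genome_id == ev$genome_id[i], ,
                         drop = FALSE]
        if (is.null(lg) || nrow(lg) == 0L) next
        d <- pmax(lg$start_index - ev$carf_index[i],
                  ev$carf_index[i] - lg$end_index, 0L)
        hit <- d <= windowK
        if (!any(hit)) next
        out["near_cas"] <- out["near_cas"] + 1L
        ty <- lg$true_type[hit][which.min(d[hit])]
        out[ty] <- out[ty] + 1L
    }
    out
}

# Expected genome categories from ground truth.
truthCategories <- function(truth) {
    gids <- truth$taxa$genome_id
    vapply(gids, function(gid) {
        lg <- truth$loci[truth$loci$genome_id == gid, , drop = FALSE]
        types <- if (is.null(lg)) character() else lg$true_type
        hasIII <- any(grepl("^III", types))
        hasI <- "I" %in% types
        hasII <- "II" %in% types
        if (hasIII && (hasI || hasII)) "III_with_I_or_II"
        else if (hasIII) "III_sole"
        else if (hasI && hasII) "I_and_II"
        else if (hasI) "I_only"
        else if (hasII) "II_only"
        else "none"
    }, character(1))
}

hashTree <- function(dir) {
    files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
    unname(tools::md5sum(files))
}
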