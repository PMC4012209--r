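#' @include pairwise.R
NULL

#' Clustering parameters
#'
#' Thresholds for the BLASTCLUST-style linkage criterion: two proteins
#' are linked when the local alignment covers at least `lengthCoverage`
#' of *both* sequences and its score density (bit score divided by
#' alignment length in columns) is at least `scoreDensity` bits per
#' column.  Both thresholds default to 0.8.
#'
#' `ungappedScreen` is a performance knob for large all-pairs runs: a
#' pair whose best *ungapped* local segment scores below this raw-score
#' value is classified unlinked without computing the full affine-gap
#' alignment.  The screen only applies when both sequences are at least
#' `screenMinLen` residues long, so short-sequence comparisons always
#' take the exact path.  Set `ungappedScreen = 0` to disable.  The
#' default (60) sits far below the raw score any linked pair of
#' >= 100-residue proteins must reach (> 150) and far above the best
#' segment expected between unrelated proteins (~30); see the package
#' vignette for the margin analysis.
#'
#' @param lengthCoverage minimum aligned fraction of each sequence.
#' @param scoreDensity minimum bit score per alignment column.
#' @param scoring a [scoringParams()] object.
#' @param symmetricCoverage if `FALSE`, only the shorter sequence must
#'   reach `lengthCoverage` (the laxer reading of the coverage filter).
#' @param ungappedScreen raw-score pre-screen threshold (0 disables).
#' @param screenMinLen minimum sequence length for the screen to apply.
#' @param maxPairs cap on the number of pairwise comparisons; exceeding
#'   it is an error rather than a silent truncation.
#' @return A list of class `ClusteringParams`.
#' @export
clusteringParams <- function(lengthCoverage = 0.8, scoreDensity = 0.8,
                             scoring = scoringParams(),
                             symmetricCoverage = TRUE,
                             ungappedScreen = 60L, screenMinLen = 100L,
                             maxPairs = 5e6) {
    if (lengthCoverage <= 0 || scoreDensity <= 0)
        stop("thresholds must be positive")
    structure(list(lengthCoverage = lengthCoverage,
                   scoreDensity = scoreDensity,
                   scoring = scoring,
                   symmetricCoverage = isTRUE(symmetricCoverage),
                   ungappedScreen = as.integer(ungappedScreen),
                   screenMinLen = as.integer(screenMinLen),
                   maxPairs = maxPairs),
              class = "ClusteringParams")
}

#' Are two proteins linked under the clustering thresholds?
#'
#' @param a,b protein sequences.
#' @param params a [clusteringParams()] object.
#' @return logical(1).
#' @examples
#' linked(strrep("ACDEFGHIKL", 10), strrep("ACDEFGHIKL", 10))
#' @export
linked <- function(a, b, params = clusteringParams()) {
    al <- localAlign(a, b, params$scoring)
    if (al@alnLength == 0L) return(FALSE)
    covOk <- if (params$symmetricCoverage) {
        al@coverageA >= params$lengthCoverage &&
            al@coverageB >= params$lengthCoverage
    } else {
        max(al@coverageA, al@coverageB) >= params$lengthCoverage
    }
    covOk && (al@bitScore / al@alnLength >= params$scoreDensity)
}

# All linked pairs among a set of proteins, as a 2-column index matrix.
.linkedPairs <- function(proteins, params) {
    n <- length(proteins)
    if (n * (n - 1) / 2 > params$maxPairs)
        stop("number of pairwise comparisons (", n * (n - 1) / 2,
             ") exceeds maxPairs (", params$maxPairs, ")")
    sp <- params$scoring
    alpha <- rownames(sp$matrix)
    enc <- lapply(unname(proteins), .encodeSeq, alphabet = alpha)
    if (!params$symmetricCoverage)
        # the exact kernel implements the symmetric criterion; fall back
        # to per-pair evaluation for the shorter-only variant
        return(.linkedPairsR(proteins, params))
    .cppLinkedPairs(enc, sp$matrix, sp$gapOpen + sp$gapExtend,
                    sp$gapExtend, params$lengthCoverage,
                    params$scoreDensity, sp$lambda, log(sp$K),
                    params$ungappedScreen, params$screenMinLen)
}

.linkedPairsR <- function(proteins, params) {
    n <- length(proteins)
    out <- matrix(0L, 0L, 2L)
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
        if (linked(proteins[[i]], proteins[[j]], params))
            out <- rbind(out, c(i, j))
    }
    out
}

#' Single-linkage clustering of proteins
#'
#' Partitions proteins into the connected components of the pairwise
#' "linked" graph (see [linked()]), the BLASTCLUST partition semantics.
#' The representative of each cluster is its longest member, ties broken
#' by lexicographically smallest protein id.  The partition is invariant
#' under permutation of the input order.
#'
#' @param proteins named character vector or `AAStringSet` of protein
#'   sequences with unique ids.
#' @param params a [clusteringParams()] object.
#' @return A [ClusterSet-class] object.
#' @export
singleLinkage <- function(proteins, params = clusteringParams()) {
    proteins <- .asProteinVector(proteins)
    .checkProtein(proteins)
    n <- length(proteins)
    if (n == 0L) stop("no proteins to cluster")
    ids <- names(proteins)
    edges <- .linkedPairs(proteins, params)
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    if (nrow(edges) > 0L)
        g <- igraph::add_edges(g, t(edges))
    comp <- igraph::components(g)$membership
    # deterministic representatives and cluster ids
    reps <- vapply(split(seq_len(n), comp), function(ix) {
        lens <- nchar(proteins[ix])
        cand <- ix[lens == max(lens)]
        cand[order(ids[cand])][1L]
    }, integer(1))
    ord <- order(ids[reps])
    reps <- reps[ord]
    width <- max(nchar(as.character(length(reps))), 3L)
    clIds <- paste0("C", formatC(seq_along(reps), width = width, flag = "0"))
    compToCl <- setNames(clIds, names(table(comp))[ord])
    mem <- setNames(unname(compToCl[as.character(comp)]), ids)
    new("ClusterSet", membership = mem,
        representatives = setNames(ids[reps], clIds))
}

#' Dereplicate proteins to one representative per cluster
#'
#' Clusters with [singleLinkage()] and returns the representative
#' sequences, one per cluster (the non-redundant set construction).
#'
#' @inheritParams singleLinkage
#' @return Named character vector of representative sequences.
#' @export
dereplicate <- function(proteins, params = clusteringParams()) {
    proteins <- .asProteinVector(proteins)
    cs <- singleLinkage(proteins, params)
    proteins[unname(representatives(cs))]
}

#' Write a ClusterSet in BLASTCLUST output dialect
#'
#' One line per cluster: representative first, remaining members by
#' decreasing length then id, whitespace-separated.
#'
#' @param clusters a [ClusterSet-class].
#' @param proteins the clustered sequences (named), used for length
#'   ordering.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeClusters <- function(clusters, proteins, path) {
    proteins <- .asProteinVector(proteins)
    mem <- membership(clusters)
    reps <- representatives(clusters)
    lines <- vapply(names(reps), function(cl) {
        members <- names(mem)[mem == cl]
        rest <- setdiff(members, reps[[cl]])
        rest <- rest[order(-nchar(proteins[rest]), rest)]
        paste(c(reps[[cl]], rest), collapse = " ")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}
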