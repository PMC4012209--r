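#' @include clustering.R annotation-io.R
NULL

#' Neighborhood window parameters
#'
#' @param windowK genes on each side of the query (1-25; default 10,
#'   the upper end of the 5-10 range commonly used for initial
#'   screening).
#' @param includePseudoPositions whether pseudo genes count as window
#'   positions (default `TRUE`; their proteins are never pooled either
#'   way).
#' @return A list of class `NeighborhoodParams`.
#' @export
neighborhoodParams <- function(windowK = 10L,
                               includePseudoPositions = TRUE) {
    windowK <- as.integer(windowK)
    if (is.na(windowK) || windowK < 1L || windowK > 25L)
        stop("windowK must be in 1..25")
    structure(list(windowK = windowK,
                   includePseudoPositions = isTRUE(includePseudoPositions)),
              class = "NeighborhoodParams")
}

#' Extract the gene window around a query gene
#'
#' Returns the genes with index in `[query - k, query + k]` on the
#' query's replicon.  Windows are truncated at the ends of linear
#' replicons and wrap (without duplication) on circular ones; they
#' never span replicons.
#'
#' @param replicon a [Replicon-class].
#' @param queryIndex 0-based gene index of the query.
#' @param params a [neighborhoodParams()].
#' @return A list of class `NeighborhoodWindow` with elements
#'   `queryIndex`, `queryProteinId`, `genomeId`, `repliconId`, and
#'   `members` (gene rows including the query, in genomic order).
#' @export
extractWindow <- function(replicon, queryIndex,
                          params = neighborhoodParams()) {
    g <- genes(replicon)
    if (!params$includePseudoPositions) {
        g <- g[!g$is_pseudo, , drop = FALSE]
        g$index <- seq_len(nrow(g)) - 1L
        queryIndex <- which(g$protein_id == genes(replicon)$protein_id[
            genes(replicon)$index == queryIndex]) - 1L
    }
    n <- nrow(g)
    queryIndex <- as.integer(queryIndex)
    if (length(queryIndex) != 1L || is.na(queryIndex) ||
        queryIndex < 0L || queryIndex >= n)
        stop("query index out of range: ", queryIndex)
    k <- params$windowK
    if (topology(replicon) == "circular" && n <= 2L * k + 1L) {
        sel <- seq_len(n)                       # whole replicon, once
    } else if (topology(replicon) == "circular") {
        sel <- ((queryIndex - k):(queryIndex + k)) %% n + 1L
    } else {
        sel <- (max(0L, queryIndex - k):min(n - 1L, queryIndex + k)) + 1L
    }
    structure(list(queryIndex = queryIndex,
                   queryProteinId = g$protein_id[queryIndex + 1L],
                   genomeId = genomeId(replicon),
                   repliconId = repliconId(replicon),
                   members = g[sel, , drop = FALSE]),
              class = "NeighborhoodWindow")
}

#' Extract windows around all query proteins of a collection
#'
#' @param replicons list of [Replicon-class] objects.
#' @param queryProteinIds character vector of query protein ids.
#' @param params a [neighborhoodParams()].
#' @return List of `NeighborhoodWindow` objects (queries not found are
#'   skipped with a warning).
#' @export
extractWindows <- function(replicons, queryProteinIds,
                           params = neighborhoodParams()) {
    out <- list()
    found <- character()
    for (rep in replicons) {
        g <- genes(rep)
        hit <- g[!is.na(g$protein_id) &
                 g$protein_id %in% queryProteinIds, , drop = FALSE]
        for (i in seq_len(nrow(hit))) {
            out[[length(out) + 1L]] <- extractWindow(rep, hit$index[i],
                                                     params)
            found <- c(found, hit$protein_id[i])
        }
    }
    miss <- setdiff(queryProteinIds, found)
    if (length(miss) > 0L)
        .casnLog("warn", length(miss), " query protein(s) not found in ",
                 "the collection")
    out
}

#' Pool neighbor proteins across windows and cluster them
#'
#' The pool is the union of the windows' member proteins: each protein
#' appears once even if shared between overlapping windows, all query
#' proteins are excluded, and the completeness filter is applied
#' (partial, pseudo and sequence-less records are dropped).
#'
#' @param windows list of `NeighborhoodWindow` objects.
#' @param cparams a [clusteringParams()].
#' @return A [ClusterSet-class] over the pooled neighbor proteins.
#' @export
poolAndCluster <- function(windows, cparams = clusteringParams()) {
    if (length(windows) == 0L) stop("no windows supplied")
    pool <- poolNeighbors(windows)
    if (length(pool) == 0L)
        return(new("ClusterSet"))
    singleLinkage(pool, cparams)
}

#' @rdname poolAndCluster
#' @export
poolNeighbors <- function(windows) {
    queryIds <- vapply(windows, `[[`, character(1), "queryProteinId")
    members <- do.call(rbind, lapply(windows, `[[`, "members"))
    members <- filterIncomplete(members)$genes
    members <- members[!is.na(members$protein_id) &
                       !(members$protein_id %in% queryIds), , drop = FALSE]
    members <- members[!duplicated(members$protein_id), , drop = FALSE]
    setNames(members$protein_seq, members$protein_id)
}

#' Read a domain-hit table
#'
#' TSV with columns `protein_id`, `family`, `start`, `end`, `evalue`,
#' `score` (hmmscan/rpsblast-style tabular hits).
#'
#' @param path path to the TSV file.
#' @return A `data.frame` of hits.
#' @export
readDomainHits <- function(path) {
    h <- .readTsv(path)
    need <- c("protein_id", "family", "start", "end", "evalue", "score")
    if (!all(need %in% names(h)))
        stop("domain-hit table must have columns: ",
             paste(need, collapse = ", "))
    h
}

#' Best family label per protein from a domain-hit table
#'
#' Hits are filtered at `evalue <= evalueMax`, then each protein is
#' labelled with the family of its best hit (lowest e-value, ties by
#' higher score then family name).
#'
#' @param hits domain-hit `data.frame` (see [readDomainHits()]).
#' @param evalueMax e-value cutoff (default 0.01).
#' @return Named character vector: protein id -> family.
#' @export
geneFamilies <- function(hits, evalueMax = 0.01) {
    hits <- hits[hits$evalue <= evalueMax, , drop = FALSE]
    if (nrow(hits) == 0L)
        return(setNames(character(), character()))
    hits <- hits[order(hits$protein_id, hits$evalue, -hits$score,
                       hits$family), , drop = FALSE]
    hits <- hits[!duplicated(hits$protein_id), , drop = FALSE]
    setNames(hits$family, hits$protein_id)
}

#' Annotate clusters from a domain-hit table
#'
#' Each cluster's label is the most frequent family among its members'
#' hits (filtered at `evalue <= evalueMax`); ties are broken by the
#' family holding the best (lowest) e-value; clusters with no hits are
#' labelled `"unknown"`.
#'
#' @param clusters a [ClusterSet-class].
#' @param hits domain-hit `data.frame`.
#' @param evalueMax e-value cutoff (default 0.01).
#' @return Named character vector: cluster id -> family label.
#' @export
annotateClusters <- function(clusters, hits, evalueMax = 0.01) {
    hits <- hits[hits$evalue <= evalueMax, , drop = FALSE]
    mem <- membership(clusters)
    out <- setNames(rep("unknown", nClusters(clusters)),
                    names(representatives(clusters)))
    for (cl in names(out)) {
        ids <- names(mem)[mem == cl]
        h <- hits[hits$protein_id %in% ids, , drop = FALSE]
        if (nrow(h) == 0L) next
        tab <- table(h$family)
        top <- names(tab)[tab == max(tab)]
        if (length(top) > 1L) {
            h2 <- h[h$family %in% top, , drop = FALSE]
            top <- h2$family[order(h2$evalue, h2$family)][1L]
        }
        out[[cl]] <- top
    }
    out
}

#' Family co-occurrence with query windows
#'
#' For each family label, counts the number of query windows that
#' contain at least one member of a cluster with that label
#' (window-level presence, not gene counts) - the machine-readable
#' analog of a neighborhood co-occurrence histogram.
#'
#' @param windows list of `NeighborhoodWindow` objects.
#' @param clusters a [ClusterSet-class] over the pooled neighbors.
#' @param annotation cluster labels from [annotateClusters()].
#' @return A `data.frame` with columns `family` and `count`, sorted by
#'   decreasing count; the total number of query windows is in
#'   attribute `"totalQueries"`.
#' @export
coOccurrence <- function(windows, clusters, annotation) {
    mem <- membership(clusters)
    queryIds <- vapply(windows, `[[`, character(1), "queryProteinId")
    fams <- sort(unique(unname(annotation)))
    counts <- setNames(integer(length(fams)), fams)
    for (w in windows) {
        ids <- setdiff(w$members$protein_id, queryIds)
        ids <- ids[!is.na(ids) & ids %in% names(mem)]
        if (length(ids) == 0L) next
        present <- unique(unname(annotation[mem[ids]]))
        counts[present] <- counts[present] + 1L
    }
    out <- data.frame(family = names(counts), count = unname(counts),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$count, out$family), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "totalQueries") <- length(windows)
    out
}

#' Reverse cas-linkage of a set of query windows
#'
#' Counts how many of the windows contain at least one gene annotated
#' with any cas family (the query gene itself is excluded).  The
#' conventional report string is `"total (casLinked)"`.
#'
#' @param windows list of `NeighborhoodWindow` objects (typically the
#'   windows around all genes of one family).
#' @param geneFams named character vector protein id -> family (see
#'   [geneFamilies()]).
#' @param casFamilies character vector of cas family ids.
#' @return Named integer vector `c(total = ..., casLinked = ...)`.
#' @export
reverseCasLinkage <- function(windows, geneFams, casFamilies) {
    linked <- vapply(windows, function(w) {
        ids <- setdiff(w$members$protein_id, w$queryProteinId)
        ids <- ids[!is.na(ids)]
        any(geneFams[ids] %in% casFamilies, na.rm = TRUE)
    }, logical(1))
    c(total = length(windows), casLinked = sum(linked))
}
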