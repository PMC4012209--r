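#' @include neighborhood.R
NULL

.CAS_ROLES <- c("signature_type_I", "signature_type_II",
                "signature_type_III", "signature_III-A",
                "signature_III-B", "adaptation", "other_cas")

#' Cas signature table
#'
#' Maps cas families to their classification role.  The defaults follow
#' the signature-gene scheme underlying types I/II/III: cas3 is the
#' type I signature, cas9 type II, cas10 type III, with csm2 / cmr5
#' resolving III-A / III-B; cas1, cas2 and cas4 are adaptation-module
#' genes and everything else `other_cas`.  `locusMaxGap` is the number
#' of intervening non-cas genes tolerated inside one locus.
#'
#' @param roles named character vector family -> role (one of
#'   `signature_type_I`, `signature_type_II`, `signature_type_III`,
#'   `signature_III-A`, `signature_III-B`, `adaptation`, `other_cas`).
#' @param locusMaxGap nonnegative integer, default 2.
#' @return A list of class `CasSignatureTable`.
#' @export
casSignatureTable <- function(roles = NULL, locusMaxGap = 2L) {
    if (is.null(roles))
        roles <- c(cas3 = "signature_type_I", cas9 = "signature_type_II",
                   cas10 = "signature_type_III", csm2 = "signature_III-A",
                   cmr5 = "signature_III-B", cas1 = "adaptation",
                   cas2 = "adaptation", cas4 = "adaptation",
                   csx19 = "other_cas", csx15 = "other_cas")
    bad <- setdiff(unique(roles), .CAS_ROLES)
    if (length(bad) > 0L)
        stop("unknown cas roles: ", paste(bad, collapse = ", "))
    if (is.null(names(roles)) || anyDuplicated(names(roles)))
        stop("roles must be uniquely named by cas family")
    locusMaxGap <- as.integer(locusMaxGap)
    if (is.na(locusMaxGap) || locusMaxGap < 0L)
        stop("locusMaxGap must be a nonnegative integer")
    structure(list(roles = roles, locusMaxGap = locusMaxGap),
              class = "CasSignatureTable")
}

#' @rdname casSignatureTable
#' @param sig a `CasSignatureTable`.
#' @export
casFamilies <- function(sig) names(sig$roles)

#' Read / write a cas signature table as two-column TSV
#'
#' Columns `family` and `role`; `locusMaxGap` travels as a
#' `# locus_max_gap=<n>` comment line.
#'
#' @param path TSV path.
#' @param sig a [casSignatureTable()] (for writing).
#' @return `readCasSignatures()`: a `CasSignatureTable`;
#'   `writeCasSignatures()`: `path`, invisibly.
#' @export
readCasSignatures <- function(path) {
    lines <- readLines(path)
    gap <- 2L
    gm <- grep("^#\\s*locus_max_gap=", lines, value = TRUE)
    if (length(gm) > 0L)
        gap <- as.integer(sub("^#\\s*locus_max_gap=(\\d+).*", "\\1", gm[1]))
    lines <- lines[!grepl("^#", lines)]
    df <- read.table(text = lines, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
    casSignatureTable(setNames(df$role, df$family), locusMaxGap = gap)
}

#' @rdname readCasSignatures
#' @export
writeCasSignatures <- function(sig, path) {
    lines <- c(sprintf("# locus_max_gap=%d", sig$locusMaxGap),
               "family\trole",
               sprintf("%s\t%s", names(sig$roles), unname(sig$roles)))
    writeLines(lines, path)
    invisible(path)
}

#' Assign a CRISPR-Cas system type from a locus's cas families
#'
#' cas9 implies type II; cas3 implies type I; cas10 with csm2 implies
#' III-A, cas10 with cmr5 implies III-B, cas10 alone III-unspecified.
#' When several signatures conflict, all matching types are reported
#' and the locus is flagged composite; with no signature the type is
#' `"unknown"`.
#'
#' @param families character vector of cas families in the locus.
#' @param sig a [casSignatureTable()].
#' @return List with `type` (comma-joined, sorted, when composite),
#'   `types` (character vector), and `composite` (logical).
#' @export
assignType <- function(families, sig = casSignatureTable()) {
    role <- function(r) names(sig$roles)[sig$roles == r]
    types <- character()
    if (any(families %in% role("signature_type_I"))) types <- c(types, "I")
    if (any(families %in% role("signature_type_II"))) types <- c(types, "II")
    if (any(families %in% role("signature_type_III"))) {
        sub3 <- character()
        if (any(families %in% role("signature_III-A")))
            sub3 <- c(sub3, "III-A")
        if (any(families %in% role("signature_III-B")))
            sub3 <- c(sub3, "III-B")
        if (length(sub3) == 0L) sub3 <- "III-unspecified"
        types <- c(types, sub3)
    }
    if (length(types) == 0L)
        return(list(type = "unknown", types = "unknown",
                    composite = FALSE))
    types <- sort(types)
    list(type = paste(types, collapse = ","), types = types,
         composite = length(types) > 1L)
}

#' Call cas loci on a replicon
#'
#' Maximal runs of cas-family genes, merged across gaps of at most
#' `locusMaxGap` intervening non-cas genes; each run becomes one locus
#' and is typed with [assignType()].
#'
#' @param replicon a [Replicon-class].
#' @param geneFams named character vector protein id -> family (see
#'   [geneFamilies()]).
#' @param sig a [casSignatureTable()].
#' @return A `data.frame` with one row per locus: `genome_id`,
#'   `replicon_id`, `start_index`, `end_index`, `families`
#'   (comma-joined, in gene order), `assigned_type`, `composite`.
#' @export
callLoci <- function(replicon, geneFams, sig = casSignatureTable()) {
    g <- genes(replicon)
    fam <- rep(NA_character_, nrow(g))
    ok <- !is.na(g$protein_id) & g$protein_id %in% names(geneFams)
    fam[ok] <- unname(geneFams[g$protein_id[ok]])
    isCas <- !is.na(fam) & fam %in% casFamilies(sig)
    idx <- g$index[isCas]
    out <- data.frame(genome_id = character(), replicon_id = character(),
                      start_index = integer(), end_index = integer(),
                      families = character(), assigned_type = character(),
                      composite = logical(), stringsAsFactors = FALSE)
    if (length(idx) == 0L) return(out)
    brk <- c(0L, which(diff(idx) - 1L > sig$locusMaxGap), length(idx))
    for (b in seq_len(length(brk) - 1L)) {
        run <- idx[(brk[b] + 1L):brk[b + 1L]]
        fams <- fam[g$index %in% run & isCas]
        ty <- assignType(fams, sig)
        out <- rbind(out, data.frame(
            genome_id = genomeId(replicon),
            replicon_id = repliconId(replicon),
            start_index = min(run), end_index = max(run),
            families = paste(fams, collapse = ","),
            assigned_type = ty$type, composite = ty$composite,
            stringsAsFactors = FALSE))
    }
    out
}

.TYPE_LEVELS <- c("I", "II", "III-A", "III-B", "III-unspecified", "unknown")

#' Per-family association with CRISPR-Cas system types
#'
#' A query gene is `near_cas` when its window (`windowK` genes each
#' side) overlaps the index span of any called locus on its replicon;
#' it is associated with the type(s) of the nearest overlapping locus
#' (distance in gene-index space; ties count toward all tied loci, and
#' composite loci toward each of their types).
#'
#' @param queries `data.frame` with columns `protein_id`, `family`,
#'   `genome_id`, `replicon_id`, `index` (one row per query gene).
#' @param loci locus table from [callLoci()] (rows from all replicons).
#' @param windowK neighborhood half-width in genes.
#' @return A `data.frame` with one row per query family: `family`,
#'   `total`, `near_cas`, and one count column per type level.
#' @export
familyTypeAssociation <- function(queries, loci, windowK = 10L) {
    fams <- sort(unique(queries$family))
    typeCols <- .TYPE_LEVELS
    out <- data.frame(family = fams,
                      total = integer(length(fams)),
                      near_cas = integer(length(fams)),
                      stringsAsFactors = FALSE)
    for (tc in typeCols) out[[tc]] <- integer(length(fams))
    for (qi in seq_len(nrow(queries))) {
        q <- queries[qi, ]
        r <- which(out$family == q$family)
        out$total[r] <- out$total[r] + 1L
        lr <- loci[loci$replicon_id == q$replicon_id, , drop = FALSE]
        if (nrow(lr) == 0L) next
        dist <- pmax(0L, pmax(lr$start_index - (q$index + windowK),
                              (q$index - windowK) - lr$end_index))
        inside <- pmax(lr$start_index - q$index, q$index - lr$end_index,
                       0L)
        hit <- dist == 0L
        if (!any(hit)) next
        out$near_cas[r] <- out$near_cas[r] + 1L
        gdist <- inside[hit]
        nearest <- which(hit)[gdist == min(gdist)]
        types <- unique(unlist(strsplit(
            lr$assigned_type[nearest], ",")))
        for (ty in types)
            if (ty %in% typeCols) out[[ty]][r] <- out[[ty]][r] + 1L
    }
    out
}

#' Per-genome CRISPR-Cas inventory
#'
#' Summarizes, for each genome: the set of system types among its
#' called loci, presence of cas1 / cas10 genes, presence of the query
#' family, and whether any query protein carries a C-terminal effector
#' domain (see [classifyEffector()]).
#'
#' @param replicons named list of [Replicon-class] objects (one or more
#'   per genome).
#' @param geneFams named character protein id -> family.
#' @param loci locus table from [callLoci()].
#' @param hits domain-hit `data.frame` (for effector classification).
#' @param effectorCfg an [effectorConfig()].
#' @param queryFamilies family ids counted as the query family
#'   (default `"CARF"`).
#' @return A `data.frame` with one row per genome: `genome_id`,
#'   `types` (comma-joined), `has_cas1`, `has_cas10`, `has_query`,
#'   `carf_with_effector`.
#' @export
genomeInventory <- function(replicons, geneFams, loci, hits,
                            effectorCfg = effectorConfig(),
                            queryFamilies = "CARF") {
    gids <- unique(vapply(replicons, genomeId, character(1)))
    byGenome <- split(replicons,
                      vapply(replicons, genomeId, character(1)))
    out <- lapply(gids, function(gid) {
        pids <- unlist(lapply(byGenome[[gid]], function(r) {
            p <- genes(r)$protein_id
            p[!is.na(p)]
        }))
        fams <- unname(geneFams[intersect(pids, names(geneFams))])
        lg <- loci[loci$genome_id == gid, , drop = FALSE]
        types <- unique(unlist(strsplit(lg$assigned_type, ",")))
        types <- setdiff(types, "unknown")
        qids <- intersect(pids, names(geneFams)[geneFams %in%
                                                queryFamilies])
        withEff <- FALSE
        for (qid in qids) {
            arch <- resolveOverlaps(hits[hits$protein_id == qid, ,
                                         drop = FALSE],
                                    evalueMax = effectorCfg$evalueMax)
            if (classifyEffector(arch, effectorCfg) == "effector_bearing") {
                withEff <- TRUE
                break
            }
        }
        data.frame(genome_id = gid,
                   types = paste(sort(types), collapse = ","),
                   has_cas1 = "cas1" %in% fams,
                   has_cas10 = "cas10" %in% fams,
                   has_query = length(qids) > 0L,
                   carf_with_effector = withEff,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' Genome-level co-occurrence partition of CRISPR-Cas types
#'
#' Classifies each genome into one of: `III_with_I_or_II` (a type III
#' system co-occurring with type I or II in the same genome),
#' `III_sole` (type III is the only system class present), `I_only`,
#' `II_only`, `I_and_II`, or `none`; cross-tabulated with whether the
#' genome carries an effector-bearing query protein.
#'
#' @param inventories output of [genomeInventory()].
#' @return A `data.frame` with columns `category`,
#'   `carf_with_effector`, `n`.
#' @export
genomeCoOccurrence <- function(inventories) {
    cat1 <- vapply(seq_len(nrow(inventories)), function(i) {
        types <- strsplit(inventories$types[i], ",")[[1]]
        types <- types[nzchar(types)]
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
    levs <- c("III_with_I_or_II", "III_sole", "I_only", "II_only",
              "I_and_II", "none")
    tab <- table(factor(cat1, levels = levs),
                 factor(inventories$carf_with_effector,
                        levels = c(FALSE, TRUE)))
    out <- as.data.frame(tab, stringsAsFactors = FALSE)
    names(out) <- c("category", "carf_with_effector", "n")
    out$carf_with_effector <- as.logical(out$carf_with_effector)
    out
}

#' Query-family presence summary over a genome set
#'
#' Counts genomes carrying at least one query-family protein, and -
#' among those - genomes possessing neither cas1 nor cas10 (the
#' signature protein families of CRISPR-Cas systems).
#'
#' @param inventories output of [genomeInventory()].
#' @return Named integer vector
#'   `c(nGenomesWithQuery = ..., nLackingCas1Cas10 = ...)`.
#' @export
presenceSummary <- function(inventories) {
    withQ <- inventories$has_query
    c(nGenomesWithQuery = sum(withQ),
      nLackingCas1Cas10 = sum(withQ & !inventories$has_cas1 &
                              !inventories$has_cas10))
}
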