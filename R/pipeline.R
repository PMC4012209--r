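#' @include synthetic-data.R crispr.R architecture.R representatives.R
NULL

#' Pipeline configuration
#'
#' Bundles input locations and stage parameters for [runPipeline()].
#'
#' @param genomeDir directory holding genome annotations: `*.gbk`
#'   (format `"genbank"`) or `*.ptt` + `*.faa` pairs (format `"ptt"`).
#' @param hitsFile domain-hit TSV (see [readDomainHits()]).
#' @param taxaFile optional taxa TSV (`genome_id`, `genus`, `species`,
#'   `genome_size_bp`) enabling representative selection.
#' @param casSignatureFile optional cas signature TSV (see
#'   [readCasSignatures()]); defaults to [casSignatureTable()].
#' @param outDir output directory for stage TSVs and the run report.
#' @param format `"genbank"` or `"ptt"`.
#' @param neighborhood a [neighborhoodParams()].
#' @param clustering a [clusteringParams()].
#' @param effector an [effectorConfig()].
#' @param overrides a [selectionOverrides()].
#' @param queryFamilies family label(s) defining the query genes.
#' @param reverseFamilies families for which reverse cas-linkage of
#'   their own neighborhoods is also computed.
#' @param useRepresentatives restrict genome-level summaries to one
#'   representative per genus (requires `taxaFile`).
#' @param seed integer seed echoed in the report (the pipeline stages
#'   are deterministic).
#' @param logLevel one of `"debug"`, `"info"`, `"warn"`, `"quiet"`.
#' @return A list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(genomeDir, hitsFile, taxaFile = NULL,
                           casSignatureFile = NULL, outDir,
                           format = c("genbank", "ptt"),
                           neighborhood = neighborhoodParams(),
                           clustering = clusteringParams(),
                           effector = effectorConfig(),
                           overrides = selectionOverrides(),
                           queryFamilies = "CARF",
                           reverseFamilies = "WYL",
                           useRepresentatives = TRUE,
                           seed = 1L,
                           logLevel = "info") {
    format <- match.arg(format)
    for (p in c(genomeDir, hitsFile, taxaFile, casSignatureFile))
        if (!is.null(p) && !file.exists(p))
            stop("input path does not exist: ", p)
    structure(list(genomeDir = genomeDir, hitsFile = hitsFile,
                   taxaFile = taxaFile,
                   casSignatureFile = casSignatureFile,
                   outDir = outDir, format = format,
                   neighborhood = neighborhood, clustering = clustering,
                   effector = effector, overrides = overrides,
                   queryFamilies = queryFamilies,
                   reverseFamilies = reverseFamilies,
                   useRepresentatives = isTRUE(useRepresentatives),
                   seed = as.integer(seed), logLevel = logLevel),
              class = "PipelineConfig")
}

.readGenomeDir <- function(dir, format) {
    if (format == "genbank") {
        files <- sort(list.files(dir, pattern = "\\.gbk$",
                                 full.names = TRUE))
        if (length(files) == 0L) stop("no .gbk files in ", dir)
        reps <- unlist(lapply(files, readGenbank), recursive = FALSE)
    } else {
        ptts <- sort(list.files(dir, pattern = "\\.ptt$",
                                full.names = TRUE))
        if (length(ptts) == 0L) stop("no .ptt files in ", dir)
        reps <- lapply(ptts, function(p)
            readPtt(p, sub("\\.ptt$", ".faa", p)))
    }
    names(reps) <- vapply(reps, repliconId, character(1))
    reps
}

# all genes of a replicon list as one data.frame with genome/replicon
.allGenes <- function(replicons) {
    do.call(rbind, lapply(replicons, function(r) {
        g <- genes(r)
        if (nrow(g) == 0L) return(NULL)
        cbind(genome_id = genomeId(r), replicon_id = repliconId(r), g,
              stringsAsFactors = FALSE)
    }))
}

#' Run the full gene-neighborhood association pipeline
#'
#' Stages, in order: parse annotations; apply the completeness filter;
#' label genes from the domain-hit table; extract neighborhood windows
#' around the query-family genes; pool and single-linkage-cluster the
#' neighbor proteins; annotate clusters; build the co-occurrence table
#' and reverse cas-linkage counts; call and type cas loci; build the
#' per-family type-association table; build per-genome inventories, the
#' genome-level type co-occurrence partition and the presence summary
#' (on the per-genus representative set when taxa are supplied); write
#' every stage's table under `outDir` plus a `report.yaml` echoing all
#' parameters and counts.
#'
#' @param config a [pipelineConfig()].
#' @return A list of class `casnRunReport` (invisibly) with elements
#'   `counts`, `coOccurrence`, `reverseLinkage`, `association`,
#'   `genomePartition`, `presence`, `representatives`, `clusters`,
#'   `annotation`, `loci`, `inventories`, `config`.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "PipelineConfig"))
    oldLvl <- setLogLevel(config$logLevel)
    on.exit(setLogLevel(oldLvl))
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    sig <- if (is.null(config$casSignatureFile)) casSignatureTable()
           else readCasSignatures(config$casSignatureFile)
    k <- config$neighborhood$windowK

    .casnLog("info", "stage 1/7: parsing annotations")
    replicons <- .readGenomeDir(config$genomeDir, config$format)
    genesAll <- .allGenes(replicons)
    .casnLog("info", "  ", length(replicons), " replicons, ",
             nrow(genesAll), " genes")

    .casnLog("info", "stage 2/7: completeness filter")
    filt <- filterIncomplete(genesAll)
    .casnLog("info", "  removed ", filt$nRemoved, " incomplete records")

    .casnLog("info", "stage 3/7: gene family labels")
    hits <- readDomainHits(config$hitsFile)
    geneFams <- geneFamilies(hits, config$effector$evalueMax)
    queries <- filt$genes[!is.na(filt$genes$protein_id) &
        filt$genes$protein_id %in% names(geneFams), , drop = FALSE]
    queries$family <- unname(geneFams[queries$protein_id])
    queries <- queries[queries$family %in% config$queryFamilies, ,
                       drop = FALSE]
    .casnLog("info", "  ", nrow(queries), " query genes")

    .casnLog("info", "stage 4/7: neighborhood windows + clustering")
    windows <- if (nrow(queries) > 0L)
        extractWindows(replicons, queries$protein_id,
                       config$neighborhood) else list()
    clusters <- if (length(windows) > 0L)
        poolAndCluster(windows, config$clustering)
    else methods::new("ClusterSet")
    annotation <- annotateClusters(clusters, hits,
                                   config$effector$evalueMax)
    .casnLog("info", "  ", length(windows), " windows, ",
             length(membership(clusters)), " pooled proteins, ",
             nClusters(clusters), " clusters")

    .casnLog("info", "stage 5/7: co-occurrence + reverse cas-linkage")
    cooc <- if (length(windows) > 0L)
        coOccurrence(windows, clusters, annotation)
    else {
        z <- data.frame(family = character(), count = integer(),
                        stringsAsFactors = FALSE)
        attr(z, "totalQueries") <- 0L
        z
    }
    casFams <- casFamilies(sig)
    revRows <- list()
    for (fam in unique(c(config$queryFamilies, config$reverseFamilies))) {
        ids <- names(geneFams)[geneFams == fam]
        ids <- intersect(ids, filt$genes$protein_id)
        if (length(ids) == 0L) next
        w <- if (fam %in% config$queryFamilies && length(windows) > 0L)
            windows else extractWindows(replicons, ids,
                                        config$neighborhood)
        rl <- reverseCasLinkage(w, geneFams, casFams)
        revRows[[fam]] <- data.frame(family = fam,
                                     total = rl[["total"]],
                                     cas_linked = rl[["casLinked"]],
                                     stringsAsFactors = FALSE)
    }
    reverse <- if (length(revRows)) do.call(rbind, revRows)
               else data.frame(family = character(), total = integer(),
                               cas_linked = integer(),
                               stringsAsFactors = FALSE)
    rownames(reverse) <- NULL

    .casnLog("info", "stage 6/7: cas locus calling + typing")
    loci <- do.call(rbind, c(lapply(replicons, callLoci,
                                    geneFams = geneFams, sig = sig),
                             list(make.row.names = FALSE)))
    assoc <- familyTypeAssociation(
        queries[, c("protein_id", "family", "genome_id", "replicon_id",
                    "index")], loci, k)
    .casnLog("info", "  ", nrow(loci), " loci")

    .casnLog("info", "stage 7/7: genome-level summaries")
    inventories <- genomeInventory(replicons, geneFams, loci, hits,
                                   config$effector,
                                   config$queryFamilies)
    repIds <- NULL
    invUsed <- inventories
    if (!is.null(config$taxaFile)) {
        taxa <- .readTsv(config$taxaFile)
        repIds <- selectRepresentatives(taxa, config$overrides)
        if (config$useRepresentatives)
            invUsed <- inventories[inventories$genome_id %in% repIds, ,
                                   drop = FALSE]
    }
    partition <- genomeCoOccurrence(invUsed)
    presence <- presenceSummary(invUsed)

    report <- structure(list(
        counts = c(replicons = length(replicons),
                   genes = nrow(genesAll),
                   removedIncomplete = filt$nRemoved,
                   completeProteins = nrow(filt$genes),
                   queryGenes = nrow(queries),
                   windows = length(windows),
                   pooledProteins = length(membership(clusters)),
                   clusters = nClusters(clusters),
                   labeledClusters = sum(annotation != "unknown"),
                   loci = nrow(loci)),
        coOccurrence = cooc, reverseLinkage = reverse,
        association = assoc, genomePartition = partition,
        presence = presence, representatives = repIds,
        clusters = clusters, annotation = annotation, loci = loci,
        inventories = inventories, windows = windows,
        config = config), class = "casnRunReport")
    .writeReport(report, config$outDir)
    invisible(report)
}

.writeReport <- function(report, outDir) {
    cfg <- report$config
    if (length(report$windows) > 0L) {
        wdf <- do.call(rbind, lapply(seq_along(report$windows),
                                     function(i) {
            w <- report$windows[[i]]
            data.frame(window_id = i, query_protein_id = w$queryProteinId,
                       genome_id = w$genomeId, replicon_id = w$repliconId,
                       query_index = w$queryIndex,
                       n_members = nrow(w$members),
                       member_ids = paste(stats::na.omit(
                           w$members$protein_id), collapse = ","),
                       stringsAsFactors = FALSE)
        }))
        .writeTsv(wdf, file.path(outDir, "windows.tsv"))
    }
    ann <- data.frame(cluster_id = names(report$annotation),
                      family = unname(report$annotation),
                      representative = unname(
                          representatives(report$clusters)[
                              names(report$annotation)]),
                      stringsAsFactors = FALSE)
    .writeTsv(ann, file.path(outDir, "cluster_annotation.tsv"))
    if (length(membership(report$clusters)) > 0L) {
        mem <- membership(report$clusters)
        .writeTsv(data.frame(protein_id = names(mem),
                             cluster_id = unname(mem),
                             stringsAsFactors = FALSE),
                  file.path(outDir, "cluster_membership.tsv"))
    }
    .writeTsv(report$coOccurrence, file.path(outDir, "cooccurrence.tsv"))
    .writeTsv(report$reverseLinkage,
              file.path(outDir, "reverse_linkage.tsv"))
    if (!is.null(report$loci))
        .writeTsv(report$loci, file.path(outDir, "loci.tsv"))
    .writeTsv(report$association, file.path(outDir, "association.tsv"))
    .writeTsv(report$genomePartition,
              file.path(outDir, "genome_partition.tsv"))
    .writeTsv(report$inventories, file.path(outDir, "inventories.tsv"))
    .writeTsv(data.frame(metric = names(report$presence),
                         value = unname(report$presence),
                         stringsAsFactors = FALSE),
              file.path(outDir, "presence.tsv"))
    if (!is.null(report$representatives))
        writeLines(report$representatives,
                   file.path(outDir, "representatives.txt"))
    yaml::write_yaml(list(
        counts = as.list(report$counts),
        presence = as.list(report$presence),
        parameters = list(
            windowK = cfg$neighborhood$windowK,
            includePseudoPositions =
                cfg$neighborhood$includePseudoPositions,
            lengthCoverage = cfg$clustering$lengthCoverage,
            scoreDensity = cfg$clustering$scoreDensity,
            evalueMax = cfg$effector$evalueMax,
            queryFamilies = cfg$queryFamilies,
            useRepresentatives = cfg$useRepresentatives,
            seed = cfg$seed)),
        file.path(outDir, "report.yaml"))
    invisible(outDir)
}

#' @export
print.casnRunReport <- function(x, ...) {
    cat("casNeighbors run report\n")
    cat("  counts:\n")
    for (nm in names(x$counts))
        cat(sprintf("    %-18s %d\n", nm, x$counts[[nm]]))
    cat(sprintf("  presence: %d genomes with query family, %d lacking both cas1 and cas10\n",
                x$presence[["nGenomesWithQuery"]],
                x$presence[["nLackingCas1Cas10"]]))
    tq <- attr(x$coOccurrence, "totalQueries")
    cat(sprintf("  co-occurrence over %d query windows (top families):\n",
                if (is.null(tq)) 0L else tq))
    print(utils::head(x$coOccurrence, 8L), row.names = FALSE)
    invisible(x)
}

#' Generate a demo collection and run the pipeline on it
#'
#' Quickstart entry point: generates a small synthetic collection
#' (written to `dir`), then runs the full pipeline on the emitted
#' GenBank files, hit table and taxa table.
#'
#' @param seed integer seed controlling the generated collection.
#' @param dir working directory (default: a fresh tempdir subfolder).
#' @param config optional [simulationConfig()] replacing the demo
#'   default (6 genera, 1-2 genomes each).
#' @param logLevel log level passed to the pipeline run.
#' @return List with elements `collection` (see
#'   [generateCollection()]), `report` (see [runPipeline()]) and `dir`.
#' @examples
#' \donttest{
#' demo <- makeDemo(seed = 1)
#' demo$report
#' }
#' @export
makeDemo <- function(seed = 1L, dir = tempfile("casn_demo_"),
                     config = NULL, logLevel = "info") {
    if (is.null(config))
        config <- simulationConfig(seed = seed, nGenera = 6L,
                                   speciesPerGenus = c(1L, 2L))
    coll <- generateCollection(config, outDir = dir)
    pcfg <- pipelineConfig(
        genomeDir = file.path(dir, "genomes"),
        hitsFile = file.path(dir, "truth", "hits.tsv"),
        taxaFile = file.path(dir, "truth", "taxa.tsv"),
        outDir = file.path(dir, "results"),
        format = "genbank",
        neighborhood = neighborhoodParams(windowK = config$windowK),
        queryFamilies = config$queryFamily,
        reverseFamilies = config$associateFamily,
        seed = seed, logLevel = logLevel)
    report <- runPipeline(pcfg)
    list(collection = coll, report = report, dir = dir)
}
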