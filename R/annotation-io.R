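#' @include AllClasses.R utils.R
NULL

# --- gene-table helpers -----------------------------------------------------

.emptyGeneTable <- function() {
    data.frame(locus_tag = character(), protein_id = character(),
               start = integer(), end = integer(), strand = character(),
               product = character(), protein_seq = character(),
               is_partial = logical(), is_pseudo = logical(),
               index = integer(), stringsAsFactors = FALSE)
}

# Sort by start (stable; ties by end) and assign the 0-based index.
.finalizeGeneTable <- function(g) {
    if (nrow(g) == 0L) return(.emptyGeneTable())
    g <- g[order(g$start, g$end), , drop = FALSE]
    g$index <- seq_len(nrow(g)) - 1L
    rownames(g) <- NULL
    g
}

.newReplicon <- function(genomeId, repliconId, lengthBp, topology, genes) {
    new("Replicon", genomeId = genomeId, repliconId = repliconId,
        lengthBp = as.integer(lengthBp), topology = topology,
        genes = .finalizeGeneTable(genes))
}

# --- GenBank flat files -----------------------------------------------------

# Parse a location string: "190..255", "complement(<190..>255)",
# "join(900..1000,1..50)".  Returns list(start, end, strand, partial).
.parseLocation <- function(loc) {
    strand <- "+"
    raw <- loc
    if (grepl("^complement\\(", loc)) {
        strand <- "-"
        loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
    }
    partial <- grepl("[<>]", loc)
    loc <- gsub("[<>]", "", loc)
    if (grepl("^join\\(", loc))
        loc <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(loc, ",")[[1]]
    first <- strsplit(parts[1], "\\.\\.")[[1]]
    last <- strsplit(parts[length(parts)], "\\.\\.")[[1]]
    start <- suppressWarnings(as.integer(first[1]))
    end <- suppressWarnings(as.integer(last[length(last)]))
    if (is.na(start) || is.na(end))
        return(NULL)
    list(start = start, end = end, strand = strand, partial = partial,
         raw = raw)
}

# Split a FEATURES block into features; each feature is a key plus its
# raw continuation lines.
.splitFeatures <- function(lines) {
    feats <- list()
    cur <- NULL
    for (ln in lines) {
        if (grepl("^     \\S", ln)) {
            if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
            key <- trimws(substr(ln, 1, 20))
            cur <- list(key = key, lines = trimws(substr(ln, 21, nchar(ln))))
        } else if (!is.null(cur)) {
            cur$lines <- c(cur$lines, trimws(ln))
        }
    }
    if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
    feats
}

# Parse the qualifier lines of one feature into location + named list.
.parseFeature <- function(feat) {
    lines <- feat$lines
    qstart <- grep("^/", lines)[1]
    locLines <- if (is.na(qstart)) lines else head(lines, qstart - 1L)
    loc <- paste(locLines, collapse = "")
    quals <- list()
    if (!is.na(qstart)) {
        # re-join wrapped qualifier values
        joined <- character()
        for (ln in lines[qstart:length(lines)]) {
            if (grepl("^/", ln)) joined <- c(joined, ln)
            else joined[length(joined)] <-
                    paste0(joined[length(joined)], ln)
        }
        for (q in joined) {
            m <- regmatches(q, regexec("^/([^=]+)(=(.*))?$", q))[[1]]
            key <- m[2]
            val <- if (m[3] == "") TRUE else gsub("^\"|\"$", "", m[4])
            quals[[key]] <- val
        }
    }
    list(key = feat$key, location = loc, qualifiers = quals)
}

#' Read a GenBank flat file into Replicon objects
#'
#' Parses one or more LOCUS records.  Each CDS feature becomes one gene
#' row; `/translation` supplies the protein sequence, `/pseudo` (or
#' `/pseudogene`) sets `is_pseudo`, and partial location operators
#' (`<`, `>`) or a `/partial` qualifier set `is_partial`.  Genes are
#' ordered by start coordinate.  The genome identifier is taken from a
#' `COMMENT` line of the form `genome_id=<id>` when present, otherwise
#' it defaults to the LOCUS name.
#'
#' @param path path to a GenBank flat file.
#' @return A list of [Replicon-class] objects, one per LOCUS record.
#' @export
readGenbank <- function(path) {
    lines <- readLines(path)
    ends <- grep("^//\\s*$", lines)
    starts <- grep("^LOCUS", lines)
    if (length(starts) == 0L)
        stop("no LOCUS record found in ", path)
    if (length(ends) < length(starts))
        stop("malformed GenBank file (unterminated record) in ", path)
    out <- vector("list", length(starts))
    for (k in seq_along(starts)) {
        rec <- lines[starts[k]:ends[k]]
        toks <- strsplit(trimws(rec[1]), "\\s+")[[1]]
        locName <- toks[2]
        bpPos <- match("bp", toks)
        lenBp <- suppressWarnings(as.integer(toks[bpPos - 1L]))
        if (is.na(bpPos) || is.na(lenBp))
            stop("malformed LOCUS line for record ", locName)
        topo <- if (any(toks == "circular")) "circular" else "linear"
        gid <- locName
        cm <- grep("genome_id=", rec, value = TRUE)
        if (length(cm) > 0L)
            gid <- sub(".*genome_id=(\\S+).*", "\\1", cm[1])
        fstart <- grep("^FEATURES", rec)
        g <- .emptyGeneTable()
        if (length(fstart) == 1L) {
            fend <- grep("^(ORIGIN|CONTIG|//)", rec)
            fend <- min(fend[fend > fstart])
            fl <- rec[(fstart + 1L):(fend - 1L)]
            feats <- lapply(.splitFeatures(fl), .parseFeature)
            for (f in feats) {
                if (f$key != "CDS") next
                loc <- .parseLocation(f$location)
                if (is.null(loc)) {
                    .casnLog("warn", "CDS without parseable location ",
                             "skipped in record ", locName)
                    next
                }
                q <- f$qualifiers
                pseudo <- isTRUE(q$pseudo) || isTRUE(q$pseudogene) ||
                    is.character(q$pseudogene)
                partial <- loc$partial || isTRUE(q$partial) ||
                    identical(q$partial, "true")
                seq <- if (!is.null(q$translation) && !pseudo)
                    gsub("\\s", "", q$translation) else NA_character_
                g <- rbind(g, data.frame(
                    locus_tag = if (!is.null(q$locus_tag)) q$locus_tag
                                else NA_character_,
                    protein_id = if (!is.null(q$protein_id)) q$protein_id
                                 else NA_character_,
                    start = loc$start, end = loc$end, strand = loc$strand,
                    product = if (!is.null(q$product)) q$product
                              else NA_character_,
                    protein_seq = seq, is_partial = partial,
                    is_pseudo = pseudo, index = 0L,
                    stringsAsFactors = FALSE))
            }
        }
        rep <- try(.newReplicon(gid, locName, lenBp, topo, g), silent = TRUE)
        if (inherits(rep, "try-error"))
            stop("parse error in record ", locName, ": ",
                 attr(rep, "condition")$message)
        out[[k]] <- rep
    }
    out
}

.wrapText <- function(x, width = 58L, indent = 21L) {
    n <- nchar(x)
    starts <- seq(1L, n, by = width)
    pieces <- substring(x, starts, pmin(starts + width - 1L, n))
    paste0(strrep(" ", indent), pieces)
}

#' Write Replicon objects as a GenBank flat file
#'
#' Emits the dialect [readGenbank()] parses: LOCUS / DEFINITION /
#' COMMENT (`genome_id=`) headers and CDS features with `locus_tag`,
#' `protein_id`, `product`, `translation`, `pseudo` and partial location
#' markers.  No nucleotide sequence is written (the ORIGIN section is
#' empty); gene coordinates are the only nucleotide-level information
#' this toolkit uses.
#'
#' @param replicons a [Replicon-class] or list of them.
#' @param path output file.
#' @param species optional organism name written to SOURCE/ORGANISM.
#' @return `path`, invisibly.
#' @export
writeGenbank <- function(replicons, path, species = "synthetic organism") {
    if (methods::is(replicons, "Replicon")) replicons <- list(replicons)
    con <- file(path, open = "wt")
    on.exit(close(con))
    for (rep in replicons) {
        validObject(rep)
        g <- genes(rep)
        w <- function(...) writeLines(paste0(...), con)
        w(sprintf("LOCUS       %s %d bp    DNA     %s   BCT",
                  repliconId(rep), lengthBp(rep), topology(rep)))
        w(sprintf("DEFINITION  %s replicon %s.", species, repliconId(rep)))
        w(sprintf("ACCESSION   %s", repliconId(rep)))
        w(sprintf("SOURCE      %s", species))
        w(sprintf("  ORGANISM  %s", species))
        w(sprintf("COMMENT     genome_id=%s", genomeId(rep)))
        w("FEATURES             Location/Qualifiers")
        w(sprintf("     source          1..%d", lengthBp(rep)))
        w(sprintf("                     /organism=\"%s\"", species))
        for (i in seq_len(nrow(g))) {
            loc <- sprintf("%s%d..%s%d",
                           if (g$is_partial[i]) "<" else "", g$start[i],
                           if (g$is_partial[i]) ">" else "", g$end[i])
            if (g$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
            w(sprintf("     CDS             %s", loc))
            if (!is.na(g$locus_tag[i]))
                w(sprintf("                     /locus_tag=\"%s\"",
                          g$locus_tag[i]))
            if (!is.na(g$protein_id[i]))
                w(sprintf("                     /protein_id=\"%s\"",
                          g$protein_id[i]))
            if (!is.na(g$product[i]))
                w(sprintf("                     /product=\"%s\"",
                          g$product[i]))
            if (g$is_pseudo[i])
                w("                     /pseudo")
            if (!is.na(g$protein_seq[i])) {
                tr <- paste0("/translation=\"", g$protein_seq[i], "\"")
                writeLines(.wrapText(tr), con)
            }
        }
        w("ORIGIN")
        w("//")
    }
    invisible(path)
}

# --- PTT tables -------------------------------------------------------------

.PTT_COLUMNS <- c("Location", "Strand", "Length", "PID", "Gene", "Synonym",
                  "Code", "COG", "Product")

#' Read an NCBI PTT table plus protein FASTA into a Replicon
#'
#' The PTT table supplies coordinates, strand and identifiers; protein
#' sequences are joined from the FASTA by PID (falling back to the
#' Synonym/locus tag).  The canonical 9 columns are required; two
#' optional extension columns `Partial` and `Pseudo` (0/1) carry the
#' completeness flags the canonical format lacks, and are written by
#' [writePtt()] so that PTT round-trips preserve them.  The first header
#' line may carry `genome_id=... replicon_id=... topology=...` tokens
#' (the [writePtt()] dialect); otherwise the replicon id is derived from
#' the file name.
#'
#' @param pttPath path to the PTT file.
#' @param faaPath path to the protein FASTA file.
#' @return A [Replicon-class] object.
#' @export
readPtt <- function(pttPath, faaPath) {
    lines <- readLines(pttPath)
    if (length(lines) < 3L)
        stop("PTT file is missing its two header lines: ", pttPath)
    desc <- lines[1]
    m <- regmatches(desc, regexec("- 1\\.\\.(\\d+)", desc))[[1]]
    if (length(m) < 2L)
        stop("PTT description line lacks the '- 1..<length>' range: ",
             pttPath)
    lenBp <- as.integer(m[2])
    getTok <- function(key, default) {
        mm <- regmatches(desc, regexec(paste0(key, "=(\\S+)"), desc))[[1]]
        if (length(mm) >= 2L) mm[2] else default
    }
    gid <- getTok("genome_id", NA_character_)
    rid <- getTok("replicon_id",
                  sub("\\.ptt$", "", basename(pttPath)))
    topo <- getTok("topology", "linear")
    if (is.na(gid)) gid <- rid
    header <- strsplit(lines[3], "\t")[[1]]
    if (!identical(header[seq_along(.PTT_COLUMNS)], .PTT_COLUMNS))
        stop("PTT column header does not match the canonical 9 columns: ",
             pttPath)
    hasPartial <- "Partial" %in% header
    hasPseudo <- "Pseudo" %in% header
    body <- lines[-(1:3)]
    body <- body[nzchar(body)]
    seqs <- character()
    if (file.exists(faaPath)) {
        aa <- Biostrings::readAAStringSet(faaPath)
        ids <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1L)
        seqs <- setNames(as.character(aa), ids)
    }
    g <- .emptyGeneTable()
    pids <- character()
    for (ln in body) {
        f <- strsplit(ln, "\t")[[1]]
        locm <- strsplit(f[1], "\\.\\.")[[1]]
        pid <- if (f[4] == "-") NA_character_ else f[4]
        if (!is.na(pid)) {
            if (pid %in% pids) stop("duplicate PID in PTT: ", pid)
            pids <- c(pids, pid)
        }
        seq <- NA_character_
        if (!is.na(pid) && pid %in% names(seqs)) seq <- unname(seqs[pid])
        else if (f[6] %in% names(seqs)) seq <- unname(seqs[f[6]])
        else if (!is.na(pid)) {
            .casnLog("warn", "PTT PID ", pid,
                     " absent from FASTA; protein_seq left absent")
        }
        g <- rbind(g, data.frame(
            locus_tag = f[6], protein_id = pid,
            start = as.integer(locm[1]), end = as.integer(locm[2]),
            strand = f[2],
            product = if (f[9] == "-") NA_character_ else f[9],
            protein_seq = seq,
            is_partial = hasPartial &&
                f[match("Partial", header)] == "1",
            is_pseudo = hasPseudo && f[match("Pseudo", header)] == "1",
            index = 0L, stringsAsFactors = FALSE))
    }
    # pseudo genes carry no protein
    g$protein_seq[g$is_pseudo] <- NA_character_
    .newReplicon(gid, rid, lenBp, topo, g)
}

#' Write a Replicon as PTT + protein FASTA
#'
#' @param replicon a [Replicon-class].
#' @param pttPath,faaPath output files.
#' @param extendedFlags write the `Partial`/`Pseudo` extension columns
#'   (default `TRUE`); the canonical format cannot represent these
#'   flags.
#' @return `pttPath`, invisibly.
#' @export
writePtt <- function(replicon, pttPath, faaPath, extendedFlags = TRUE) {
    validObject(replicon)
    g <- genes(replicon)
    header <- .PTT_COLUMNS
    if (extendedFlags) header <- c(header, "Partial", "Pseudo")
    lines <- c(
        sprintf("genome_id=%s replicon_id=%s topology=%s - 1..%d",
                genomeId(replicon), repliconId(replicon),
                topology(replicon), lengthBp(replicon)),
        sprintf("%d proteins", sum(!is.na(g$protein_id))),
        paste(header, collapse = "\t"))
    for (i in seq_len(nrow(g))) {
        f <- c(sprintf("%d..%d", g$start[i], g$end[i]), g$strand[i],
               as.character(
                   if (is.na(g$protein_seq[i])) max(
                       (g$end[i] - g$start[i] + 1L) %/% 3L - 1L, 0L)
                   else nchar(g$protein_seq[i])),
               ifelse(is.na(g$protein_id[i]), "-", g$protein_id[i]),
               "-", g$locus_tag[i], "-", "-",
               ifelse(is.na(g$product[i]), "-", g$product[i]))
        if (extendedFlags)
            f <- c(f, as.character(as.integer(g$is_partial[i])),
                   as.character(as.integer(g$is_pseudo[i])))
        lines <- c(lines, paste(f, collapse = "\t"))
    }
    writeLines(lines, pttPath)
    keep <- !is.na(g$protein_seq) & !is.na(g$protein_id)
    aa <- Biostrings::AAStringSet(setNames(g$protein_seq[keep],
                                           g$protein_id[keep]))
    Biostrings::writeXStringSet(aa, faaPath, width = 70L)
    invisible(pttPath)
}

# --- completeness filter ----------------------------------------------------

#' Discard incomplete protein records
#'
#' Removes gene records flagged partial or pseudo, and records with no
#' protein sequence, preserving order.  This is the completeness filter
#' applied before any protein-level analysis (clustering, pooling,
#' dereplication).
#'
#' @param genes a gene `data.frame` (the `genes` slot of a
#'   [Replicon-class]) or a [Replicon-class] object.
#' @return A list with elements `genes` (the retained rows), `nRemoved`,
#'   and `removed` (the discarded rows).
#' @export
filterIncomplete <- function(genes) {
    if (methods::is(genes, "Replicon")) genes <- genes(genes)
    drop <- genes$is_partial | genes$is_pseudo | is.na(genes$protein_seq)
    list(genes = genes[!drop, , drop = FALSE],
         nRemoved = sum(drop),
         removed = genes[drop, , drop = FALSE])
}
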