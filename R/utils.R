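#' @include AllClasses.R
NULL

# Minimal leveled logging to stderr.  Levels: debug < info < warn.
.casnLogLevel <- new.env(parent = emptyenv())
.casnLogLevel$level <- "info"

#' Set the package log level
#'
#' @param level one of `"debug"`, `"info"`, `"warn"`, `"quiet"`.
#' @return The previous level, invisibly.
#' @export
setLogLevel <- function(level = c("info", "debug", "warn", "quiet")) {
    level <- match.arg(level)
    old <- .casnLogLevel$level
    .casnLogLevel$level <- level
    invisible(old)
}

.logRank <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)

.casnLog <- function(level, ...) {
    if (.logRank[[level]] >= .logRank[[.casnLogLevel$level]])
        message(sprintf("[%s] %s", toupper(level), paste0(...)))
    invisible(NULL)
}

# Validate a protein sequence alphabet: 20 standard residues plus X.
.checkProtein <- function(seqs, what = "protein sequence") {
    seqs <- seqs[!is.na(seqs)]
    if (length(seqs) == 0L) return(invisible(TRUE))
    letters <- unique(strsplit(paste(seqs, collapse = ""), "")[[1]])
    extra <- setdiff(letters, .AA_ALPHABET)
    if (length(extra) > 0L)
        stop(what, " contains letters outside the 20 standard residues",
             " plus X: ", paste(extra, collapse = ""))
    invisible(TRUE)
}

# Encode a protein string as 0-based integer codes into the rows of a
# substitution matrix.
.encodeSeq <- function(seq, alphabet) {
    codes <- match(strsplit(seq, "")[[1]], alphabet)
    if (anyNA(codes))
        stop("sequence contains letters absent from the scoring matrix")
    as.integer(codes - 1L)
}

# Coerce an AAStringSet / character vector of proteins to a named
# character vector, requiring unique non-empty names.
.asProteinVector <- function(proteins) {
    if (methods::is(proteins, "XStringSet"))
        proteins <- setNames(as.character(proteins), names(proteins))
    if (!is.character(proteins))
        stop("proteins must be a named character vector or AAStringSet")
    if (is.null(names(proteins)) || any(names(proteins) == "") ||
        anyNA(names(proteins)))
        stop("proteins must be named")
    if (anyDuplicated(names(proteins)))
        stop("duplicate protein ids")
    proteins
}

# Deterministic TSV writer (no quoting, no scientific notation).
.writeTsv <- function(df, path) {
    old <- options(scipen = 15)
    on.exit(options(old))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE)
    invisible(path)
}

.readTsv <- function(path, ...) {
    read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
               quote = "", comment.char = "", check.names = FALSE, ...)
}
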