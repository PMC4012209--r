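#' @include utils.R
NULL

#' Scoring parameters for local protein alignment
#'
#' Bundles the substitution matrix, affine gap penalties and
#' Karlin-Altschul statistical parameters used by [localAlign()],
#' [bitScore()] and the clustering layer.  Defaults are the standard
#' gapped BLOSUM62 practice: gap open 11, gap extend 1 (a gap of length
#' L costs 11 + L), lambda = 0.267, K = 0.041.
#'
#' @param matrix integer substitution matrix with residue row/column
#'   names; defaults to BLOSUM62 as shipped with Biostrings.
#' @param gapOpen,gapExtend positive gap penalties (BLAST convention).
#' @param lambda,K positive Karlin-Altschul parameters for the gapped
#'   scoring system.
#' @return A list of class `ScoringParams`.
#' @examples
#' sp <- scoringParams()
#' bitScore(24, sp)
#' @export
scoringParams <- function(matrix = NULL, gapOpen = 11, gapExtend = 1,
                          lambda = 0.267, K = 0.041) {
    if (is.null(matrix)) {
        e <- new.env()
        utils::data("BLOSUM62", package = "Biostrings", envir = e)
        matrix <- e$BLOSUM62
    }
    stopifnot(is.matrix(matrix),
              !is.null(rownames(matrix)),
              identical(rownames(matrix), colnames(matrix)))
    if (gapOpen <= 0 || gapExtend <= 0)
        stop("gap penalties must be positive")
    if (lambda <= 0 || K <= 0)
        stop("lambda and K must be positive")
    storage.mode(matrix) <- "integer"
    structure(list(matrix = matrix, gapOpen = as.integer(gapOpen),
                   gapExtend = as.integer(gapExtend),
                   lambda = lambda, K = K),
              class = "ScoringParams")
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the plain-text matrix layout used by NCBI BLAST data files
#' (comment lines starting with `#`, a header row of residue letters,
#' then one labelled row per residue).
#'
#' @param path path to the matrix file.
#' @return An integer matrix with residue dimnames.
#' @export
readScoringMatrix <- function(path) {
    lines <- readLines(path)
    lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
    header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
    rows <- strsplit(trimws(lines[-1]), "\\s+")
    lab <- vapply(rows, `[`, character(1), 1L)
    vals <- t(vapply(rows, function(r) as.integer(r[-1]),
                     integer(length(header))))
    dimnames(vals) <- list(lab, header)
    vals
}

#' Optimal local alignment of two proteins
#'
#' Smith-Waterman alignment under affine gap penalties.  Returns the raw
#' score, the Karlin-Altschul bit score, the alignment length in columns
#' (gap columns included), and the coverage of each sequence (aligned
#' span divided by full sequence length).  When no residue pair scores
#' positively the alignment is empty: raw score 0, zero-length spans,
#' zero coverage.
#'
#' @param a,b protein sequences (character(1) or AAString), 20 standard
#'   residues plus X.
#' @param params a [scoringParams()] object.
#' @return An [AlignmentResult-class] object.
#' @examples
#' localAlign("ACDE", "ACDE")   # raw score 24
#' @export
localAlign <- function(a, b, params = scoringParams()) {
    a <- as.character(a); b <- as.character(b)
    if (nchar(a) == 0L || nchar(b) == 0L)
        stop("sequences must be nonempty")
    .checkProtein(c(a, b))
    alpha <- rownames(params$matrix)
    r <- .cppSwFull(.encodeSeq(a, alpha), .encodeSeq(b, alpha),
                    params$matrix,
                    params$gapOpen + params$gapExtend, params$gapExtend)
    empty <- r$score <= 0L
    covA <- if (empty) 0 else (r$endA - r$startA + 1) / nchar(a)
    covB <- if (empty) 0 else (r$endB - r$startB + 1) / nchar(b)
    new("AlignmentResult",
        rawScore = as.integer(max(r$score, 0L)),
        bitScore = bitScore(max(r$score, 0L), params),
        alnLength = if (empty) 0L else as.integer(r$cols),
        coverageA = covA, coverageB = covB,
        startA = if (empty) 0L else as.integer(r$startA),
        endA = if (empty) 0L else as.integer(r$endA),
        startB = if (empty) 0L else as.integer(r$startB),
        endB = if (empty) 0L else as.integer(r$endB))
}

#' Convert a raw alignment score to bits
#'
#' `(lambda * raw - ln K) / ln 2` with the parameters of the scoring
#' system.
#'
#' @param raw nonnegative raw score(s).
#' @param params a [scoringParams()] object.
#' @return Numeric bit score(s).
#' @export
bitScore <- function(raw, params = scoringParams()) {
    if (any(raw < 0)) stop("raw score must be >= 0")
    (params$lambda * raw - log(params$K)) / log(2)
}
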