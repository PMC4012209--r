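#' @include casNeighbors-package.R
NULL

.AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

.GENE_COLUMNS <- c("locus_tag", "protein_id", "start", "end", "strand",
                   "product", "protein_seq", "is_partial", "is_pseudo",
                   "index")

#' Replicon: an annotated replicon and its ordered gene table
#'
#' One chromosome or plasmid of a genome.  The `genes` slot is a
#' `data.frame` with one row per gene, columns `locus_tag`, `protein_id`,
#' `start`, `end`, `strand`, `product`, `protein_seq`, `is_partial`,
#' `is_pseudo`, `index`.  Genes are sorted by start coordinate and
#' `index` is the 0-based rank in that ordering; neighborhood windows are
#' defined on this index space.  Coordinates are 1-based inclusive base
#' pairs (the PTT "Location" convention).  On circular replicons a gene
#' may span the origin, in which case `end < start`; this is legal and is
#' not an error.
#'
#' @slot genomeId character(1), identifier of the parent genome.
#' @slot repliconId character(1), identifier of this replicon.
#' @slot lengthBp integer(1), replicon length in base pairs.
#' @slot topology `"linear"` or `"circular"`.
#' @slot genes data.frame as described above.
#'
#' @exportClass Replicon
setClass("Replicon",
    representation(genomeId = "character", repliconId = "character",
                   lengthBp = "integer", topology = "character",
                   genes = "data.frame"),
    prototype(genomeId = NA_character_, repliconId = NA_character_,
              lengthBp = 0L, topology = "linear",
              genes = data.frame()))

setValidity("Replicon", function(object) {
    msgs <- character()
    if (length(object@topology) != 1L ||
        !object@topology %in% c("linear", "circular"))
        msgs <- c(msgs, "topology must be 'linear' or 'circular'")
    g <- object@genes
    if (nrow(g) > 0L) {
        if (!all(.GENE_COLUMNS %in% names(g)))
            msgs <- c(msgs, paste("gene table must have columns:",
                                  paste(.GENE_COLUMNS, collapse = ", ")))
        else {
            if (is.unsorted(g$start))
                msgs <- c(msgs, "genes must be sorted by start coordinate")
            if (!identical(as.integer(g$index), seq_len(nrow(g)) - 1L))
                msgs <- c(msgs, "gene index must equal 0-based rank by start")
            if (!all(g$strand %in% c("+", "-")))
                msgs <- c(msgs, "strand must be '+' or '-'")
            bad <- g$start < 1L | g$end > object@lengthBp
            if (object@topology == "linear") {
                if (any(g$end < g$start))
                    msgs <- c(msgs,
                        "end < start is only allowed on circular replicons")
            }
            if (any(bad))
                msgs <- c(msgs, "gene coordinates outside [1, lengthBp]")
            sq <- g$protein_seq[!is.na(g$protein_seq)]
            if (length(sq) > 0L) {
                letters <- unique(strsplit(paste(sq, collapse = ""), "")[[1]])
                extra <- setdiff(letters, .AA_ALPHABET)
                if (length(extra) > 0L)
                    msgs <- c(msgs, paste0("protein sequences may contain ",
                        "only the 20 standard residues plus X; found: ",
                        paste(extra, collapse = "")))
            }
        }
    }
    if (length(msgs)) msgs else TRUE
})

setMethod("show", "Replicon", function(object) {
    cat("Replicon", object@repliconId,
        sprintf("(genome %s)", object@genomeId), "\n",
        sprintf("  %d bp, %s, %d genes\n", object@lengthBp,
                object@topology, nrow(object@genes)))
})

#' ClusterSet: a single-linkage partition of proteins
#'
#' @slot membership named character; protein id -> cluster id.
#' @slot representatives named character; cluster id -> protein id of the
#'   representative (longest member, ties broken by lexicographically
#'   smallest id).
#'
#' @exportClass ClusterSet
setClass("ClusterSet",
    representation(membership = "character", representatives = "character"),
    prototype(membership = setNames(character(), character()),
              representatives = setNames(character(), character())))

setValidity("ClusterSet", function(object) {
    msgs <- character()
    m <- object@membership
    r <- object@representatives
    if (is.null(names(m)) && length(m) > 0L)
        msgs <- c(msgs, "membership must be named by protein id")
    if (anyDuplicated(names(m)))
        msgs <- c(msgs, "each protein must be in exactly one cluster")
    if (!setequal(unique(unname(m)), names(r)))
        msgs <- c(msgs, "representatives must cover exactly the cluster ids")
    bad <- vapply(names(r), function(cl) {
        !(r[[cl]] %in% names(m)) || m[[r[[cl]]]] != cl
    }, logical(1))
    if (any(bad))
        msgs <- c(msgs, "each representative must be a member of its cluster")
    if (length(msgs)) msgs else TRUE
})

setMethod("show", "ClusterSet", function(object) {
    cat(sprintf("ClusterSet: %d proteins in %d clusters\n",
                length(object@membership), length(object@representatives)))
})

#' AlignmentResult: a local protein alignment summary
#'
#' @slot rawScore integer(1), optimal Smith-Waterman score.
#' @slot bitScore numeric(1), Karlin-Altschul bit score.
#' @slot alnLength integer(1), alignment columns including gap columns.
#' @slot coverageA,coverageB numeric(1), aligned span / sequence length.
#' @slot startA,endA,startB,endB integer(1), 1-based aligned spans
#'   (0 when the alignment is empty).
#'
#' @exportClass AlignmentResult
setClass("AlignmentResult",
    representation(rawScore = "integer", bitScore = "numeric",
                   alnLength = "integer",
                   coverageA = "numeric", coverageB = "numeric",
                   startA = "integer", endA = "integer",
                   startB = "integer", endB = "integer"))

setValidity("AlignmentResult", function(object) {
    msgs <- character()
    if (object@rawScore < 0L) msgs <- c(msgs, "rawScore must be >= 0")
    if (object@coverageA < 0 || object@coverageA > 1 ||
        object@coverageB < 0 || object@coverageB > 1)
        msgs <- c(msgs, "coverage must be in [0, 1]")
    if (length(msgs)) msgs else TRUE
})

setMethod("show", "AlignmentResult", function(object) {
    cat(sprintf(paste0("AlignmentResult: raw %d, %.2f bits, %d columns, ",
                       "coverage %.2f/%.2f\n"),
                object@rawScore, object@bitScore, object@alnLength,
                object@coverageA, object@coverageB))
})
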