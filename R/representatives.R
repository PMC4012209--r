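#' @include utils.R
NULL

#' Representative-genome selection overrides
#'
#' Named genus -> genome label (matched against the `species` column or
#' the `genome_id`).  The defaults pin the model organisms for the two
#' genera conventionally overridden: Bacillus subtilis 168 and
#' Escherichia coli K12 substr. MG1655.
#'
#' @param ... named genus = label pairs replacing the defaults.
#' @return Named character vector of class `SelectionOverrides`.
#' @export
selectionOverrides <- function(...) {
    args <- c(...)
    if (length(args) == 0L)
        args <- c(Bacillus = "Bacillus subtilis 168",
                  Escherichia = "Escherichia coli K12 substr. MG1655")
    if (is.null(names(args)) || any(names(args) == ""))
        stop("overrides must be named by genus")
    structure(args, class = "SelectionOverrides")
}

#' Select one representative genome per genus
#'
#' For each genus the genome with the largest total genome size is
#' selected (ties broken by lexicographically smallest `genome_id`),
#' except for genera listed in `overrides`, whose named genome is
#' selected instead; an override naming a genome absent from the
#' collection is an error.  Selection is deterministic and idempotent.
#'
#' @param taxa `data.frame` with columns `genome_id`, `genus`,
#'   `species`, `genome_size_bp`.
#' @param overrides a [selectionOverrides()] vector.
#' @return Character vector of selected genome ids, ordered by genus.
#' @export
selectRepresentatives <- function(taxa, overrides = selectionOverrides()) {
    need <- c("genome_id", "genus", "species", "genome_size_bp")
    if (!all(need %in% names(taxa)))
        stop("taxa table must have columns: ", paste(need, collapse = ", "))
    genera <- sort(unique(taxa$genus))
    vapply(genera, function(gn) {
        rows <- taxa[taxa$genus == gn, , drop = FALSE]
        if (gn %in% names(overrides)) {
            lab <- overrides[[gn]]
            hit <- rows$species == lab | rows$genome_id == lab
            if (!any(hit))
                stop("override genome '", lab, "' for genus ", gn,
                     " not found in the collection")
            return(rows$genome_id[hit][1L])
        }
        best <- rows[rows$genome_size_bp == max(rows$genome_size_bp), ,
                     drop = FALSE]
        sort(best$genome_id)[1L]
    }, character(1), USE.NAMES = FALSE)
}
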