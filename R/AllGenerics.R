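#' @include AllClasses.R
NULL

#' Accessors for Replicon and ClusterSet objects
#'
#' `genes()` returns the ordered gene table of a [Replicon];
#' `genomeId()`, `repliconId()`, `lengthBp()` and `topology()` return the
#' corresponding scalar slots.  `membership()` returns the protein ->
#' cluster mapping of a [ClusterSet], `representatives()` the cluster ->
#' representative-protein mapping, and `nClusters()` the cluster count.
#'
#' @param x a `Replicon` or `ClusterSet` object.
#' @return See details above.
#' @name accessors
#' @aliases genes genomeId repliconId lengthBp topology membership
#'   representatives nClusters
NULL

#' @rdname accessors
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))
#' @rdname accessors
#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))
#' @rdname accessors
#' @export
setGeneric("repliconId", function(x) standardGeneric("repliconId"))
#' @rdname accessors
#' @export
setGeneric("lengthBp", function(x) standardGeneric("lengthBp"))
#' @rdname accessors
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))
#' @rdname accessors
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))
#' @rdname accessors
#' @export
setGeneric("representatives", function(x) standardGeneric("representatives"))
#' @rdname accessors
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' @rdname accessors
setMethod("genes", "Replicon", function(x) x@genes)
#' @rdname accessors
setMethod("genomeId", "Replicon", function(x) x@genomeId)
#' @rdname accessors
setMethod("repliconId", "Replicon", function(x) x@repliconId)
#' @rdname accessors
setMethod("lengthBp", "Replicon", function(x) x@lengthBp)
#' @rdname accessors
setMethod("topology", "Replicon", function(x) x@topology)
#' @rdname accessors
setMethod("membership", "ClusterSet", function(x) x@membership)
#' @rdname accessors
setMethod("representatives", "ClusterSet", function(x) x@representatives)
#' @rdname accessors
setMethod("nClusters", "ClusterSet", function(x) length(x@representatives))
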