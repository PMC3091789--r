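#' @rdname GenomeRecord-class
#' @param object,x a `GenomeRecord`.
#' @export
setGeneric("accession", function(x) standardGeneric("accession"))

#' @rdname GenomeRecord-class
#' @export
setGeneric("genomeSequence", function(x) standardGeneric("genomeSequence"))

#' @rdname GenomeRecord-class
#' @export
setGeneric("features", function(x) standardGeneric("features"))

#' @rdname GenomeRecord-class
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))

#' @rdname GeneCluster-class
#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' @rdname GeneCluster-class
#' @export
setGeneric("classification", function(x) standardGeneric("classification"))

#' @rdname GeneCluster-class
#' @export
setGeneric("clusterSpan", function(x) standardGeneric("clusterSpan"))
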