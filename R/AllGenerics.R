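#' @rdname PolymorphismTrack-class
#' @param object,x a `PolymorphismTrack`.
#' @export
setGeneric("inbredName", function(x) standardGeneric("inbredName"))

#' @rdname PolymorphismTrack-class
#' @export
setGeneric("trackRecords", function(x) standardGeneric("trackRecords"))

#' @rdname PolymorphismTrack-class
#' @export
setGeneric("trackTable", function(x) standardGeneric("trackTable"))

#' @rdname segmentSize
#' @export
setGeneric("segmentSize",
           function(haplotype, chrom, start, end) standardGeneric("segmentSize"))

#' @rdname haplotypeSeq
#' @export
setGeneric("haplotypeSeq",
           function(haplotype, chrom, start, end) standardGeneric("haplotypeSeq"))
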