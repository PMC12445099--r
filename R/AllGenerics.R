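#' @rdname GenomeRecord-class
#' @param object a `GenomeRecord`
#' @export
setGeneric("genomeId", function(object) standardGeneric("genomeId"))

#' @rdname GenomeRecord-class
#' @export
setGeneric("speciesLabel", function(object) standardGeneric("speciesLabel"))

#' @rdname GenomeRecord-class
#' @export
setGeneric("contigs", function(object) standardGeneric("contigs"))

#' @rdname GenomeRecord-class
#' @export
setGeneric("cdsFeatures", function(object) standardGeneric("cdsFeatures"))

#' @rdname ProfileHMM-class
#' @param object a `ProfileHMM`
#' @export
setGeneric("profileLength", function(object) standardGeneric("profileLength"))

#' @rdname ProfileHMM-class
#' @export
setGeneric("matchEmissions", function(object) standardGeneric("matchEmissions"))

#' @rdname ProfileHMM-class
#' @export
setGeneric("calibration", function(object) standardGeneric("calibration"))

#' @rdname RepertoireMatrix-class
#' @param object a `RepertoireMatrix`
#' @export
setGeneric("presenceMatrix", function(object) standardGeneric("presenceMatrix"))

#' @rdname GenomeRecord-class
#' @export
setMethod("genomeId", "GenomeRecord", function(object) object@genomeId)

#' @rdname GenomeRecord-class
#' @export
setMethod("speciesLabel", "GenomeRecord", function(object) object@speciesLabel)

#' @rdname GenomeRecord-class
#' @export
setMethod("contigs", "GenomeRecord", function(object) object@contigs)

#' @rdname GenomeRecord-class
#' @export
setMethod("cdsFeatures", "GenomeRecord", function(object) object@features)

#' @rdname ProfileHMM-class
#' @export
setMethod("profileLength", "ProfileHMM",
          function(object) nrow(object@matchEmissions))

#' @rdname ProfileHMM-class
#' @export
setMethod("matchEmissions", "ProfileHMM",
          function(object) object@matchEmissions)

#' @rdname ProfileHMM-class
#' @export
setMethod("calibration", "ProfileHMM", function(object) object@calibration)

#' @rdname RepertoireMatrix-class
#' @export
setMethod("presenceMatrix", "RepertoireMatrix",
          function(object) object@presence)

#' @rdname RepertoireMatrix-class
#' @param x,i,j,drop matrix-style subsetting of a `RepertoireMatrix`
#' @export
setMethod("[", "RepertoireMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@presence))
  if (missing(j)) j <- seq_len(ncol(x@presence))
  methods::new("RepertoireMatrix",
    presence = x@presence[i, j, drop = FALSE],
    speciesLabels = x@speciesLabels[i])
})
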