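#' @rdname offsets
#' @export
setGeneric("offsets", function(x) standardGeneric("offsets"))

#' @rdname offsets
#' @export
setGeneric("referenceOffset", function(x) standardGeneric("referenceOffset"))

#' @rdname poolAccessors
#' @export
setGeneric("amplitudes", function(x, ...) standardGeneric("amplitudes"))

#' @rdname poolAccessors
#' @export
setGeneric("fwhms", function(x, ...) standardGeneric("fwhms"))

#' @rdname poolAccessors
#' @export
setGeneric("centers", function(x, ...) standardGeneric("centers"))

#' @rdname zvalues
#' @export
setGeneric("zValues", function(x) standardGeneric("zValues"))

#' @rdname correctB0
#' @export
setGeneric("correctB0", function(x, shift, ...) standardGeneric("correctB0"))

#' @rdname tissueLabels
#' @export
setGeneric("tissueLabels", function(x) standardGeneric("tissueLabels"))

#' @rdname noeMtrMap
#' @export
setGeneric("noeMtrMap", function(x) standardGeneric("noeMtrMap"))
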