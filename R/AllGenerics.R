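#' Extract the beta-value matrix
#' @param object a \linkS4class{BetaSet}
#' @return numeric matrix, probe x sample
#' @export
setGeneric("getBeta", function(object) standardGeneric("getBeta"))

#' @rdname getBeta
setMethod("getBeta", "BetaSet", function(object) {
  SummarizedExperiment::assay(object, "beta")
})

#' Probe annotation accessor
#' @param object a \linkS4class{MethIntensitySet} or \linkS4class{BetaSet}
#' @return data.frame of probe annotation (one row per probe)
#' @export
setGeneric("probeAnnotation",
           function(object) standardGeneric("probeAnnotation"))

#' @rdname probeAnnotation
setMethod("probeAnnotation", "SummarizedExperiment", function(object) {
  as.data.frame(SummarizedExperiment::rowData(object))
})

#' Surrogate component accessors
#' @param object a \linkS4class{SurrogateSet}
#' @param selectedOnly return only components passing the screen
#' @return sample x k numeric matrix of component scores
#' @export
setGeneric("surrogates", function(object, selectedOnly = TRUE) {
  standardGeneric("surrogates")
})

#' @rdname surrogates
setMethod("surrogates", "SurrogateSet", function(object, selectedOnly = TRUE) {
  if (selectedOnly) object@components[, object@selected, drop = FALSE]
  else object@components
})

#' @rdname surrogates
#' @export
setGeneric("surrogateReport", function(object) {
  standardGeneric("surrogateReport")
})

#' @rdname surrogates
setMethod("surrogateReport", "SurrogateSet", function(object) object@report)

#' Information content of ontology terms
#' @param object a \linkS4class{TermUniverse}
#' @param terms optional term ids; default all
#' @return named numeric vector of IC values (0 at the root)
#' @export
setGeneric("informationContent", function(object, terms = NULL) {
  standardGeneric("informationContent")
})

#' @rdname informationContent
setMethod("informationContent", "TermUniverse", function(object, terms = NULL) {
  if (is.null(terms)) return(object@ic)
  missing <- setdiff(terms, names(object@ic))
  if (length(missing)) {
    stop("unknown term(s): ", paste(missing, collapse = ", "))
  }
  object@ic[terms]
})

#' Propagated gene sets of ontology terms
#' @param object a \linkS4class{TermUniverse}
#' @param terms optional term ids; default all
#' @return named list of character vectors
#' @export
setGeneric("termGenes", function(object, terms = NULL) {
  standardGeneric("termGenes")
})

#' @rdname termGenes
setMethod("termGenes", "TermUniverse", function(object, terms = NULL) {
  if (is.null(terms)) return(object@termGenes)
  missing <- setdiff(terms, names(object@termGenes))
  if (length(missing)) {
    stop("unknown term(s): ", paste(missing, collapse = ", "))
  }
  object@termGenes[terms]
})
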