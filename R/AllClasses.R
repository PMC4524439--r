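#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Paired methylated/unmethylated intensity container
#'
#' A \linkS4class{SummarizedExperiment} holding the two fluorescence channels
#' of a 450K-style methylation array: assay \code{"Meth"} (methylated signal
#' M) and assay \code{"Unmeth"} (unmethylated signal U), one row per probe and
#' one column per sample. Probe annotation (chromosome, position, probe
#' chemistry type, SNP/cross-hybridization flags, nearest gene) lives in
#' \code{rowData}; sample covariates in \code{colData}.
#'
#' @slot .Data inherited SummarizedExperiment representation
#' @seealso [MethIntensitySet()], [computeBeta()]
#' @export
setClass("MethIntensitySet", contains = "SummarizedExperiment")

setValidity("MethIntensitySet", function(object) {
  nms <- SummarizedExperiment::assayNames(object)
  if (!all(c("Meth", "Unmeth") %in% nms)) {
    return("assays 'Meth' and 'Unmeth' are required")
  }
  M <- SummarizedExperiment::assay(object, "Meth")
  U <- SummarizedExperiment::assay(object, "Unmeth")
  if (any(M < 0, na.rm = TRUE) || any(U < 0, na.rm = TRUE)) {
    return("intensities must be non-negative")
  }
  TRUE
})

#' Methylation beta-value container
#'
#' A \linkS4class{SummarizedExperiment} with a single assay \code{"beta"} of
#' methylation levels in [0, 1], plus provenance flags recording which
#' preprocessing steps (normalization, probe-type adjustment, probe
#' filtering) have been applied. Probe annotation is carried in
#' \code{rowData}.
#'
#' @slot normalized logical; quantile normalization applied on intensities
#' @slot typeAdjusted logical; probe-type bias adjustment applied
#' @slot filtered logical; exclusion filters applied
#' @seealso [computeBeta()], [adjustProbeType()], [filterProbes()]
#' @export
setClass("BetaSet", contains = "SummarizedExperiment",
         representation(normalized = "logical", typeAdjusted = "logical",
                        filtered = "logical"),
         prototype(normalized = FALSE, typeAdjusted = FALSE,
                   filtered = FALSE))

setValidity("BetaSet", function(object) {
  if (!"beta" %in% SummarizedExperiment::assayNames(object)) {
    return("assay 'beta' is required")
  }
  b <- SummarizedExperiment::assay(object, "beta")
  if (any(b < 0 | b > 1, na.rm = TRUE)) {
    return("beta values must lie in [0, 1]")
  }
  TRUE
})

#' Estimated surrogate variables for technical confounding
#'
#' Result of [estimateSurrogates()]: latent components of the residual
#' (exposure-protected) data matrix, screened for association with measured
#' confounder surrogates (chip, row, column, ethnicity).
#'
#' @slot components numeric matrix, samples x k, orthonormal columns
#' @slot report data.frame with one row per component x confounder test
#'   (columns component, confounder, p, q)
#' @slot selected logical vector flagging components with q below the
#'   selection threshold against any confounder
#' @slot method character; decomposition used
#' @export
setClass("SurrogateSet",
         representation(components = "matrix", report = "data.frame",
                        selected = "logical", method = "character"))

setValidity("SurrogateSet", function(object) {
  k <- ncol(object@components)
  if (length(object@selected) != k) {
    return("'selected' length must equal number of components")
  }
  if (k > 1) {
    cp <- crossprod(object@components)
    if (max(abs(cp - diag(k))) > 1e-6) return("components must be orthonormal")
  }
  TRUE
})

#' Gene-ontology-like term universe
#'
#' A rooted directed acyclic graph of terms with gene annotations propagated
#' from each term to all its ancestors, and the information content
#' IC(t) = -log(annotated(t) / annotated(root)) precomputed for semantic
#' similarity. Construct with [termUniverse()].
#'
#' @slot parents named list; for each term, the character vector of its
#'   direct parents (empty for the root)
#' @slot termGenes named list of character vectors; propagated gene sets
#' @slot ic named numeric; information content per term
#' @slot root character(1); the root term id
#' @export
setClass("TermUniverse",
         representation(parents = "list", termGenes = "list",
                        ic = "numeric", root = "character"))

setValidity("TermUniverse", function(object) {
  ids <- names(object@parents)
  if (is.null(ids) || anyDuplicated(ids)) return("terms must be uniquely named")
  if (!identical(sort(ids), sort(names(object@termGenes)))) {
    return("termGenes must cover exactly the terms in 'parents'")
  }
  if (!object@root %in% ids) return("root term missing")
  if (abs(object@ic[[object@root]]) > 1e-12) return("IC(root) must be 0")
  TRUE
})

setMethod("show", "MethIntensitySet", function(object) {
  cat(sprintf("MethIntensitySet: %d probes x %d samples\n",
              nrow(object), ncol(object)))
  callNextMethod()
})

setMethod("show", "BetaSet", function(object) {
  cat(sprintf(
    "BetaSet: %d probes x %d samples [normalized=%s, typeAdjusted=%s, filtered=%s]\n",
    nrow(object), ncol(object), object@normalized, object@typeAdjusted,
    object@filtered))
  callNextMethod()
})

setMethod("show", "SurrogateSet", function(object) {
  cat(sprintf("SurrogateSet: %d component(s), %d selected (%s)\n",
              ncol(object@components), sum(object@selected), object@method))
})

setMethod("show", "TermUniverse", function(object) {
  cat(sprintf("TermUniverse: %d terms, %d genes, root '%s'\n",
              length(object@parents),
              length(unique(unlist(object@termGenes, use.names = FALSE))),
              object@root))
})

# zero-column colData with the right number of rows, named or not
.emptyColData <- function(m) {
  cd <- S4Vectors::DataFrame(matrix(nrow = ncol(m), ncol = 0))
  rownames(cd) <- colnames(m)
  cd
}

#' Construct a MethIntensitySet
#'
#' @param Meth,Unmeth non-negative numeric matrices (probe x sample) of
#'   methylated and unmethylated signal, identical dimensions.
#' @param probeAnnot data.frame of probe annotation with one row per probe
#'   (columns \code{probe_id}, \code{chrom}, \code{pos}, \code{probe_type},
#'   \code{snp_at_target}, \code{cross_hyb_x}, \code{nearest_gene_id}).
#' @param colData optional data.frame of sample covariates.
#' @return A \linkS4class{MethIntensitySet}.
#' @export
MethIntensitySet <- function(Meth, Unmeth, probeAnnot = NULL, colData = NULL) {
  stopifnot(identical(dim(Meth), dim(Unmeth)))
  if (is.null(colData)) colData <- .emptyColData(Meth)
  rd <- if (is.null(probeAnnot)) NULL else S4Vectors::DataFrame(probeAnnot)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(Meth = Meth, Unmeth = Unmeth),
    rowData = rd, colData = colData)
  new("MethIntensitySet", se)
}

#' @describeIn BetaSet-class construct a BetaSet from a beta matrix
#' @param beta numeric matrix in [0,1], probe x sample.
#' @param probeAnnot,colData as for [MethIntensitySet()].
#' @param normalized,typeAdjusted,filtered provenance flags.
#' @export
BetaSet <- function(beta, probeAnnot = NULL, colData = NULL,
                    normalized = FALSE, typeAdjusted = FALSE,
                    filtered = FALSE) {
  if (is.null(colData)) colData <- .emptyColData(beta)
  rd <- if (is.null(probeAnnot)) NULL else S4Vectors::DataFrame(probeAnnot)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(beta = beta), rowData = rd, colData = colData)
  new("BetaSet", se, normalized = normalized, typeAdjusted = typeAdjusted,
      filtered = filtered)
}
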