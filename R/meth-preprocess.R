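#' Convert channel intensities to beta values
#'
#' The methylation level of a probe is `beta = M / (M + U + 100)`, where M
#' and U are the methylated and unmethylated signal intensities; the +100
#' offset regularizes low-intensity probes and keeps beta strictly below 1.
#'
#' @param object a \linkS4class{MethIntensitySet}, or the methylated
#'   intensity matrix/vector when `U` is supplied.
#' @param U unmethylated intensities (matrix method only).
#' @param offset regularizing constant, default 100.
#' @return A \linkS4class{BetaSet} (for the container method) or a numeric
#'   object of the same shape as the inputs.
#' @export
#' @examples
#' computeBeta(100, 100)  # 1/3
setGeneric("computeBeta", function(object, U, offset = 100) {
  standardGeneric("computeBeta")
})

.betaFromMU <- function(M, U, offset) {
  bad <- which(M < 0 | U < 0)
  if (length(bad)) {
    loc <- if (is.matrix(M)) {
      ij <- arrayInd(bad[1], dim(M))
      sprintf(" (first at probe %s, sample %s)",
              if (!is.null(rownames(M))) rownames(M)[ij[1]] else ij[1],
              if (!is.null(colnames(M))) colnames(M)[ij[2]] else ij[2])
    } else ""
    stop("negative intensities are not allowed", loc)
  }
  M / (M + U + offset)
}

#' @rdname computeBeta
setMethod("computeBeta", "numeric", function(object, U, offset = 100) {
  .betaFromMU(object, U, offset)
})

#' @rdname computeBeta
setMethod("computeBeta", "matrix", function(object, U, offset = 100) {
  .betaFromMU(object, U, offset)
})

#' @rdname computeBeta
setMethod("computeBeta", "MethIntensitySet", function(object, U,
                                                      offset = 100) {
  b <- .betaFromMU(SummarizedExperiment::assay(object, "Meth"),
                   SummarizedExperiment::assay(object, "Unmeth"), offset)
  BetaSet(b, probeAnnot = probeAnnotation(object),
          colData = SummarizedExperiment::colData(object))
})

#' Quantile normalization across samples
#'
#' Forces every column (sample) to share the mean empirical distribution,
#' preserving within-sample ranks; ties receive the average of the tied
#' quantiles. Backed by [limma::normalizeQuantiles()].
#'
#' @param x numeric matrix, features x samples, no missing values.
#' @return matrix of the same dimension; every column has identical sorted
#'   values.
#' @export
quantileNormalize <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("missing values are not supported")
  if (ncol(x) < 2) {
    warning("single-sample input: quantile normalization is the identity")
    return(x)
  }
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Quantile-normalize the intensity channels of a MethIntensitySet
#'
#' Both channels are normalized jointly (one matrix of stacked M and U
#' columns), mirroring between-array normalization on signal intensities
#' before beta conversion.
#'
#' @param object a \linkS4class{MethIntensitySet}.
#' @return a \linkS4class{MethIntensitySet} with normalized channels.
#' @export
normalizeIntensities <- function(object) {
  stopifnot(is(object, "MethIntensitySet"))
  M <- SummarizedExperiment::assay(object, "Meth")
  U <- SummarizedExperiment::assay(object, "Unmeth")
  stacked <- quantileNormalize(cbind(M, U))
  k <- ncol(M)
  SummarizedExperiment::assay(object, "Meth") <-
    stacked[, seq_len(k), drop = FALSE]
  SummarizedExperiment::assay(object, "Unmeth") <-
    stacked[, k + seq_len(k), drop = FALSE]
  object
}

#' Adjust probe-type bias by quantile mapping
#'
#' Type II probes report betas compressed relative to type I chemistry.
#' Per sample, type II values are mapped onto the type I empirical
#' distribution (a distributional-alignment stand-in for a beta-mixture
#' probe-type normalization; the quantile map preserves type II rank order
#' and leaves type I values untouched). Samples with fewer than
#' `minPerType` probes of either type are skipped with a warning.
#'
#' @param object a \linkS4class{BetaSet} whose annotation has a
#'   `probe_type` column, or a beta matrix (then `annot` is required).
#' @param annot probe annotation (matrix method).
#' @param minPerType minimum probes of each type required per sample.
#' @return object of the same class with type II betas remapped.
#' @export
setGeneric("adjustProbeType", function(object, annot, minPerType = 50) {
  standardGeneric("adjustProbeType")
})

.adjustTypeMatrix <- function(b, type, minPerType) {
  isI <- type == "I"
  isII <- type == "II"
  if (!any(isI) || !any(isII)) stop("both probe types must be present")
  nI <- sum(isI); nII <- sum(isII)
  if (nI < minPerType || nII < minPerType) {
    warning("fewer than ", minPerType,
            " probes of one type: probe-type adjustment skipped")
    return(b)
  }
  out <- b
  for (s in seq_len(ncol(b))) {
    xI <- b[isI, s]
    xII <- b[isII, s]
    r <- rank(xII, ties.method = "average")
    pr <- if (nII > 1) (r - 1) / (nII - 1) else 0.5
    out[isII, s] <- as.numeric(quantile(xI, pr, type = 7, names = FALSE))
  }
  out
}

#' @rdname adjustProbeType
setMethod("adjustProbeType", "matrix", function(object, annot,
                                                minPerType = 50) {
  .adjustTypeMatrix(object, annot$probe_type, minPerType)
})

#' @rdname adjustProbeType
setMethod("adjustProbeType", "BetaSet", function(object, annot,
                                                 minPerType = 50) {
  type <- probeAnnotation(object)$probe_type
  if (is.null(type)) stop("annotation lacks 'probe_type'")
  b <- .adjustTypeMatrix(getBeta(object), type, minPerType)
  SummarizedExperiment::assay(object, "beta") <- b
  object@typeAdjusted <- TRUE
  object
})

#' Apply the probe exclusion filters
#'
#' Retains autosomal probes without a SNP at the target locus and without
#' cross-hybridization to the X chromosome. Every probe must be annotated;
#' a probe with missing annotation raises an error rather than being
#' silently retained. The removal report counts each criterion
#' independently, so a probe failing two criteria is counted under both
#' (but removed once).
#'
#' @param object a \linkS4class{BetaSet} with `chrom`, `snp_at_target` and
#'   `cross_hyb_x` in its annotation.
#' @return filtered \linkS4class{BetaSet}; the removal report is attached
#'   as `metadata(object)$filter_report` (a named integer vector).
#' @export
filterProbes <- function(object) {
  stopifnot(is(object, "BetaSet"))
  ann <- probeAnnotation(object)
  need <- c("chrom", "snp_at_target", "cross_hyb_x")
  if (!all(need %in% names(ann))) {
    stop("annotation must contain: ", paste(need, collapse = ", "))
  }
  bad <- !complete.cases(ann[, need])
  if (any(bad)) {
    stop("probe(s) missing annotation: ",
         paste(head(rownames(ann)[bad], 5), collapse = ", "))
  }
  sexChrom <- grepl("X|Y", ann$chrom)
  snp <- ann$snp_at_target
  xhyb <- ann$cross_hyb_x
  keep <- !sexChrom & !snp & !xhyb
  report <- c(sex_chromosome = sum(sexChrom), snp_at_target = sum(snp),
              cross_hyb_x = sum(xhyb), removed = sum(!keep),
              retained = sum(keep))
  out <- object[keep, ]
  out@filtered <- TRUE
  S4Vectors::metadata(out)$filter_report <- report
  out
}

#' Standard methylation preprocessing chain
#'
#' Quantile-normalizes intensities, converts to betas, adjusts probe-type
#' bias and applies the probe filters, setting the provenance flags.
#'
#' @param intensities a \linkS4class{MethIntensitySet}.
#' @param normalize,typeAdjust,filter stage toggles.
#' @return a \linkS4class{BetaSet}.
#' @export
preprocessMethylation <- function(intensities, normalize = TRUE,
                                  typeAdjust = TRUE, filter = TRUE) {
  x <- intensities
  if (normalize) x <- normalizeIntensities(x)
  b <- computeBeta(x)
  b@normalized <- normalize
  if (typeAdjust) b <- adjustProbeType(b)
  if (filter) b <- filterProbes(b)
  b
}
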