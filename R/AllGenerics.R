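#' Accessors for package classes
#'
#' Small accessor generics so downstream code never touches slots directly:
#' \code{diagramPairs}/\code{diagramDimension}/\code{isReduced} for
#' \linkS4class{PersistenceDiagram}; \code{curveGrid}/\code{curveValues}/
#' \code{curveKind} for \linkS4class{PersistenceCurve}; \code{subtypes} and
#' \code{probeData} for \linkS4class{CNProfileSet}; \code{sensitivity},
#' \code{specificity}, \code{accuracy} for
#' \linkS4class{ClassificationSummary}.
#'
#' @param x an object of the documented class.
#' @return The slot contents (a matrix, vector, or scalar rate).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("diagramPairs", function(x) standardGeneric("diagramPairs"))
#' @rdname accessors
#' @export
setGeneric("diagramDimension", function(x) standardGeneric("diagramDimension"))
#' @rdname accessors
#' @export
setGeneric("isReduced", function(x) standardGeneric("isReduced"))
#' @rdname accessors
#' @export
setGeneric("curveGrid", function(x) standardGeneric("curveGrid"))
#' @rdname accessors
#' @export
setGeneric("curveValues", function(x) standardGeneric("curveValues"))
#' @rdname accessors
#' @export
setGeneric("curveKind", function(x) standardGeneric("curveKind"))
#' @rdname accessors
#' @export
setGeneric("subtypes", function(x) standardGeneric("subtypes"))
#' @rdname accessors
#' @export
setGeneric("probeData", function(x) standardGeneric("probeData"))
#' @rdname accessors
#' @export
setGeneric("sensitivity", function(x) standardGeneric("sensitivity"))
#' @rdname accessors
#' @export
setGeneric("specificity", function(x) standardGeneric("specificity"))
#' @rdname accessors
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))

#' @rdname accessors
setMethod("diagramPairs", "PersistenceDiagram", function(x) x@pairs)
#' @rdname accessors
setMethod("diagramDimension", "PersistenceDiagram", function(x) x@dimension)
#' @rdname accessors
setMethod("isReduced", "PersistenceDiagram", function(x) x@reduced)
#' @rdname accessors
setMethod("curveGrid", "PersistenceCurve", function(x) x@grid)
#' @rdname accessors
setMethod("curveValues", "PersistenceCurve", function(x) x@values)
#' @rdname accessors
setMethod("curveKind", "PersistenceCurve", function(x) x@kind)
#' @rdname accessors
setMethod("subtypes", "CNProfileSet", function(x) {
    s <- colData(x)$Subtype
    names(s) <- colnames(x)
    s
})
#' @rdname accessors
setMethod("probeData", "CNProfileSet",
    function(x) as.data.frame(rowData(x)))
#' @rdname accessors
setMethod("sensitivity", "ClassificationSummary",
    function(x) x@tp / (x@tp + x@fn))
#' @rdname accessors
setMethod("specificity", "ClassificationSummary",
    function(x) x@tn / (x@tn + x@fp))
#' @rdname accessors
setMethod("accuracy", "ClassificationSummary",
    function(x) (x@tp + x@tn) / (x@tp + x@fp + x@tn + x@fn))

setMethod("show", "PersistenceDiagram", function(object) {
    cat(sprintf("PersistenceDiagram: dim %d, %d pair(s)%s\n",
                object@dimension, nrow(object@pairs),
                if (object@reduced) " (reduced)" else ""))
    if (nrow(object@pairs))
        print(utils::head(object@pairs, 6))
})

setMethod("show", "PersistenceCurve", function(object) {
    lab <- if (object@kind == "landscape")
        sprintf("landscape(k=%d)", object@k) else object@kind
    cat(sprintf("PersistenceCurve: %s, dim %d, %d grid points on [%g, %g]\n",
                lab, object@dimension, length(object@grid),
                min(object@grid), max(object@grid)))
})

setMethod("show", "SimConfig", function(object) {
    cat(sprintf(
        "SimConfig: mu=%g sigma=%g lambda=%d mix=%d%% | %d probes, %d test + %d ctrl, %d sims\n",
        object@mu, object@sigma, object@lambda, round(100 * object@mix),
        object@nProbes, object@nTest, object@nCtrl, object@nSims))
})

setMethod("show", "LogisticModel", function(object) {
    cat("LogisticModel (forward-AIC logistic fit)\n")
    cat("  covariates:",
        if (length(object@covariates)) paste(object@covariates, collapse = ", ")
        else "(null model)", "\n")
    co <- stats::coef(object@fit)
    cat("  coefficients:",
        paste(sprintf("%s=%.3f", names(co), co), collapse = ", "), "\n")
    cat(sprintf("  AIC = %.3f, logLik = %.3f%s\n", object@aic, object@logLik,
                if (object@separated) " [separated fit]" else ""))
})

setMethod("show", "ClassificationSummary", function(object) {
    cat(sprintf("ClassificationSummary: TP=%g FP=%g TN=%g FN=%g\n",
                object@tp, object@fp, object@tn, object@fn))
    cat(sprintf("  sensitivity=%.3f specificity=%.3f accuracy=%.3f\n",
                sensitivity(object), specificity(object), accuracy(object)))
})
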