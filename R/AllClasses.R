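#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

#' CNProfileSet: a cohort of copy-number profiles on a shared probe panel
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding one
#' log2-ratio assay (probes in rows, patients in columns), probe genomic
#' coordinates in \code{rowData} (columns \code{ProbeID}, \code{Chrom},
#' \code{Arm}, \code{Position}) and the patient phenotype in
#' \code{colData$Subtype}. Chromosome X is stored as the integer 23 so
#' that regions sort and print as \code{23q...}. Probes are required to be
#' sorted by (chromosome, position) with the p arm preceding the q arm.
#'
#' @seealso [loadProfiles()], [simulateCohort()]
#' @export
setClass("CNProfileSet", contains = "SummarizedExperiment")

.validCNProfileSet <- function(object) {
    msg <- NULL
    rd <- rowData(object)
    need <- c("ProbeID", "Chrom", "Arm", "Position")
    if (!all(need %in% colnames(rd)))
        return(paste("rowData must contain columns:", paste(need, collapse = ", ")))
    if (!all(rd$Chrom %in% 1:23))
        msg <- c(msg, "Chrom must be integers in 1..23 (X coded as 23)")
    if (!all(rd$Arm %in% c("p", "q")))
        msg <- c(msg, "Arm must be 'p' or 'q'")
    key <- order(rd$Chrom, match(rd$Arm, c("p", "q")), rd$Position)
    if (is.unsorted(key))
        msg <- c(msg, "probes must be sorted by (Chrom, Arm, Position)")
    if (!"Subtype" %in% colnames(colData(object)))
        msg <- c(msg, "colData must contain a Subtype column")
    else if (anyNA(colData(object)$Subtype))
        msg <- c(msg, "every patient needs exactly one Subtype label")
    x <- assay(object)
    if (!all(is.finite(x)))
        msg <- c(msg, "log2-ratio values must all be finite")
    if (is.null(msg)) TRUE else msg
}
setValidity("CNProfileSet", .validCNProfileSet)

#' Construct a CNProfileSet
#'
#' @param values numeric matrix of log2 ratios, probes x patients.
#' @param probes data.frame with columns \code{ProbeID}, \code{Chrom}
#'   (integer 1-23), \code{Arm} ("p"/"q") and \code{Position} (bp).
#' @param subtype character vector of phenotype labels, one per patient,
#'   named by patient id (or in column order of \code{values}).
#' @return A \linkS4class{CNProfileSet}.
#' @examples
#' ps <- CNProfileSet(matrix(rnorm(6), 3, 2,
#'                    dimnames = list(NULL, c("s1", "s2"))),
#'     probes = data.frame(ProbeID = paste0("P", 1:3), Chrom = 1L,
#'                         Arm = "q", Position = c(10, 20, 30)),
#'     subtype = c(s1 = "A", s2 = "B"))
#' subtypes(ps)
#' @export
CNProfileSet <- function(values, probes, subtype) {
    values <- as.matrix(values)
    if (is.null(colnames(values)))
        colnames(values) <- if (!is.null(names(subtype))) names(subtype)
                            else paste0("patient", seq_len(ncol(values)))
    if (!is.null(names(subtype))) {
        missing <- setdiff(colnames(values), names(subtype))
        if (length(missing))
            stop("no phenotype label for patient(s): ",
                 paste(missing, collapse = ", "))
        subtype <- subtype[colnames(values)]
    }
    probes$Chrom <- normalizeChrom(probes$Chrom)
    ord <- order(probes$Chrom, match(probes$Arm, c("p", "q")), probes$Position)
    probes <- probes[ord, , drop = FALSE]
    values <- values[ord, , drop = FALSE]
    se <- SummarizedExperiment(
        assays = list(log2ratio = values),
        rowData = DataFrame(probes, row.names = NULL),
        colData = DataFrame(Subtype = unname(as.character(subtype)),
                            row.names = colnames(values)))
    new("CNProfileSet", se)
}

#' PersistenceDiagram: birth-death pairs of one homology dimension
#'
#' Stores the multiset of (birth, death) filtration values of the homology
#' generators of a Vietoris-Rips filtration in a fixed dimension. Dimension-0
#' diagrams carry one infinitely-persistent pair until reduced (see
#' [reduceDiagram()]); \code{reduced = TRUE} marks reduced homology where
#' that generator has been dropped or capped.
#'
#' @slot dimension integer homology degree (0 or 1 here).
#' @slot pairs two-column numeric matrix (\code{birth}, \code{death}),
#'   \code{birth <= death}, death may be \code{Inf} only in dimension 0
#'   before reduction.
#' @slot reduced logical flag for reduced homology in dimension 0.
#' @export
setClass("PersistenceDiagram",
    representation(dimension = "integer", pairs = "matrix",
                   reduced = "logical"),
    prototype(dimension = 0L,
              pairs = matrix(numeric(0), 0, 2,
                             dimnames = list(NULL, c("birth", "death"))),
              reduced = FALSE))

setValidity("PersistenceDiagram", function(object) {
    p <- object@pairs
    if (ncol(p) != 2) return("pairs must have two columns (birth, death)")
    if (nrow(p)) {
        if (anyNA(p)) return("pairs must not contain NA")
        if (any(p[, 1] > p[, 2])) return("birth must be <= death")
        if (any(!is.finite(p[, 1]))) return("births must be finite")
        if (object@reduced && any(!is.finite(p[, 2])))
            return("reduced diagrams must have finite deaths")
    }
    TRUE
})

#' Construct a PersistenceDiagram
#'
#' @param pairs two-column matrix (or empty) of (birth, death) values.
#' @param dimension homology degree.
#' @param reduced logical; reduced homology flag (dimension 0).
#' @export
PersistenceDiagram <- function(pairs = matrix(numeric(0), 0, 2),
                               dimension = 0L, reduced = FALSE) {
    pairs <- matrix(as.numeric(pairs), ncol = 2,
                    dimnames = list(NULL, c("birth", "death")))
    new("PersistenceDiagram", dimension = as.integer(dimension),
        pairs = pairs, reduced = reduced)
}

#' PersistenceCurve: a persistence summary sampled on a filtration grid
#'
#' Represents a Betti curve, a lifespan curve or the k-th persistence
#' landscape of a diagram, evaluated on an increasing grid of filtration
#' values. All group comparisons in the pipeline happen between curves
#' sharing one grid.
#'
#' @slot kind one of "betti", "lifespan", "landscape".
#' @slot k landscape level (NA unless kind == "landscape").
#' @slot dimension homology degree the curve summarises.
#' @slot grid increasing numeric filtration values.
#' @slot values numeric curve values, same length as grid.
#' @export
setClass("PersistenceCurve",
    representation(kind = "character", k = "integer", dimension = "integer",
                   grid = "numeric", values = "numeric"))

setValidity("PersistenceCurve", function(object) {
    if (!object@kind %in% c("betti", "lifespan", "landscape"))
        return("kind must be betti, lifespan or landscape")
    if (length(object@grid) != length(object@values))
        return("grid and values must have equal length")
    if (length(object@grid) > 1 && any(diff(object@grid) <= 0))
        return("grid must be strictly increasing")
    if (any(object@values < -1e-12))
        return("curve values must be nonnegative")
    if (object@kind == "landscape" &&
        (is.na(object@k) || object@k < 1L))
        return("landscape curves need k >= 1")
    TRUE
})

PersistenceCurve <- function(kind, grid, values, dimension = 0L, k = NA_integer_) {
    new("PersistenceCurve", kind = kind, k = as.integer(k),
        dimension = as.integer(dimension), grid = as.numeric(grid),
        values = as.numeric(values))
}

#' SimConfig: parameter bundle for the synthetic cohort generator
#'
#' Defines one simulation condition: 20-probe profiles where aberrant test
#' patients carry a single contiguous block of \code{lambda} probes drawn
#' from Normal(\code{mu}, \code{sigma}) on a Normal(0, \code{sigma})
#' background, controls are pure background, and \code{mix} (penetrance) is
#' the fraction of the test group that actually carries the aberration.
#'
#' @slot mu aberration mean (study values -1, 0.6, 1).
#' @slot sigma shared standard deviation (study values 0.20-0.50).
#' @slot lambda aberration length in probes (study values 1,2,3,5,10,15).
#' @slot mix penetrance in (0, 1].
#' @slot nProbes probes per profile (20).
#' @slot nTest,nCtrl group sizes (60/60).
#' @slot nSims cohorts per condition (50).
#' @export
setClass("SimConfig",
    representation(mu = "numeric", sigma = "numeric", lambda = "integer",
                   mix = "numeric", nProbes = "integer", nTest = "integer",
                   nCtrl = "integer", nSims = "integer"))

setValidity("SimConfig", function(object) {
    msg <- NULL
    if (object@sigma < 0) msg <- c(msg, "sigma must be nonnegative")
    if (object@lambda < 1L || object@lambda > object@nProbes)
        msg <- c(msg, "lambda must be in 1..nProbes")
    if (object@mix <= 0 || object@mix > 1)
        msg <- c(msg, "mix must be in (0, 1]")
    if (object@nSims < 1L) msg <- c(msg, "nSims must be >= 1")
    if (object@nTest < 1L || object@nCtrl < 1L)
        msg <- c(msg, "group sizes must be positive")
    if (is.null(msg)) TRUE else msg
})

#' @param mu,sigma,lambda,mix,nProbes,nTest,nCtrl,nSims see slot docs.
#' @return A validated \linkS4class{SimConfig}.
#' @rdname SimConfig-class
#' @examples
#' simConfig(mu = 1, sigma = 0.2, lambda = 10, mix = 1)
#' @export
simConfig <- function(mu = 1, sigma = 0.2, lambda = 10L, mix = 1,
                      nProbes = 20L, nTest = 60L, nCtrl = 60L, nSims = 50L) {
    new("SimConfig", mu = mu, sigma = sigma, lambda = as.integer(lambda),
        mix = mix, nProbes = as.integer(nProbes), nTest = as.integer(nTest),
        nCtrl = as.integer(nCtrl), nSims = as.integer(nSims))
}

#' LogisticModel: a forward-AIC selected logistic classifier
#'
#' Wraps the maximum-likelihood logistic fit chosen by forward addition
#' under AIC (AIC = 2k - 2 ln Lhat with k counting all estimated
#' coefficients including the intercept).
#'
#' @slot fit the underlying \code{glm} object.
#' @slot covariates character names of selected indicator columns.
#' @slot aic model AIC.
#' @slot logLik maximised log-likelihood.
#' @slot separated TRUE if the fit ran to (quasi-)complete separation, in
#'   which case coefficients are large but finite (IRLS stopped at its
#'   iteration cap, matching standard software behaviour).
#' @export
setClass("LogisticModel",
    representation(fit = "ANY", covariates = "character", aic = "numeric",
                   logLik = "numeric", separated = "logical"))

#' ClassificationSummary: confusion counts and rates
#'
#' @slot tp,fp,tn,fn confusion counts.
#' @export
setClass("ClassificationSummary",
    representation(tp = "numeric", fp = "numeric", tn = "numeric",
                   fn = "numeric"))

setValidity("ClassificationSummary", function(object) {
    v <- c(object@tp, object@fp, object@tn, object@fn)
    if (any(v < 0)) "counts must be nonnegative" else TRUE
})

ClassificationSummary <- function(tp, fp, tn, fn)
    new("ClassificationSummary", tp = tp, fp = fp, tn = tn, fn = fn)
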