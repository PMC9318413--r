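## Per-patient persistence curves of one segment, as a patients x grid
## matrix. `segValues` is a probes x patients matrix of log2 ratios.
.segmentCurveMatrix <- function(segValues, kind = "lifespan", k = 2L,
                                dim = 0L, s = 2L, nGrid = 100L) {
    diags <- lapply(seq_len(ncol(segValues)), function(i) {
        cloud <- slidingWindowEmbed(segValues[, i], s = s)
        d <- vrPersistence(cloud, dims = dim)[[as.character(dim)]]
        if (dim == 0L) d <- reduceDiagram(d) else d
    })
    grid <- makeGrid(diags, nPoints = nGrid)
    curves <- t(vapply(diags, function(d)
        curveValues(persistenceCurve(d, grid, kind = kind, k = k)),
        numeric(length(grid))))
    rownames(curves) <- colnames(segValues)
    attr(curves, "grid") <- grid
    curves
}

#' Per-patient persistence curves for one genome segment
#'
#' Runs the per-segment part of the pipeline: sliding-window embedding of
#' each patient's probe values, VR persistence (dimension-0 diagrams
#' reduced), a shared grid spanning the cohort's deaths, and one curve per
#' patient.
#'
#' @param segValues numeric matrix, probes x patients.
#' @param kind,k curve kind and landscape level (see [persistenceCurve()]).
#' @param dim homology degree (0 or 1).
#' @param s sliding-window size.
#' @param nGrid grid resolution.
#' @return patients x grid numeric matrix with the grid in
#'   \code{attr(, "grid")}.
#' @export
segmentCurves <- function(segValues, kind = c("lifespan", "betti",
                                              "landscape"),
                          k = 2L, dim = 0L, s = 2L, nGrid = 100L) {
    kind <- match.arg(kind)
    .segmentCurveMatrix(segValues, kind, k, dim, s, nGrid)
}

.groupStat <- function(curves, isTest) {
    mt <- colMeans(curves[isTest, , drop = FALSE])
    mc <- colMeans(curves[!isTest, , drop = FALSE])
    sqrt(sum((mt - mc)^2))
}

#' Segment test statistic: L2 distance between group-average curves
#'
#' @param testCurves,ctrlCurves lists of \linkS4class{PersistenceCurve} on
#'   one grid (the per-group patient curves).
#' @return nonnegative scalar statistic.
#' @export
segmentStatistic <- function(testCurves, ctrlCurves) {
    if (!length(testCurves) || !length(ctrlCurves))
        stop("both groups must be nonempty")
    curveDistance(meanCurve(testCurves), meanCurve(ctrlCurves), "l2")
}

#' Permutation test of the segment statistic
#'
#' Group labels are permuted uniformly at random with fixed group sizes;
#' the p-value uses add-one smoothing,
#' p = (1 + #{permuted >= observed}) / (1 + nPerm).
#'
#' @param curves patients x grid matrix of per-patient curve values (see
#'   [segmentCurves()]).
#' @param isTest logical vector marking the test-group rows.
#' @param nPerm number of permutations (default 1000).
#' @param seed optional integer seed for reproducibility.
#' @return list with \code{statistic}, \code{p.value}, \code{nPerm}.
#' @export
permutationTest <- function(curves, isTest, nPerm = 1000L, seed = NULL) {
    curves <- as.matrix(curves)
    isTest <- as.logical(isTest)
    if (length(isTest) != nrow(curves))
        stop("isTest must have one entry per curve row")
    if (!any(isTest) || all(isTest))
        stop("both groups must be present")
    if (nPerm < 1L) stop("nPerm must be >= 1")
    if (!is.null(seed)) set.seed(seed)
    n <- nrow(curves); nt <- sum(isTest); nc <- n - nt
    obs <- .groupStat(curves, isTest)
    tot <- colSums(curves)
    ## B x n 0/1 indicator of permuted test groups -> B x grid group sums
    ind <- matrix(0, nPerm, n)
    for (b in seq_len(nPerm))
        ind[b, sample.int(n, nt)] <- 1
    st <- ind %*% curves
    mt <- st / nt
    mc <- (matrix(tot, nPerm, ncol(curves), byrow = TRUE) - st) / nc
    perm <- sqrt(rowSums((mt - mc)^2))
    list(statistic = obs,
         p.value = (1 + sum(perm >= obs - 1e-12)) / (1 + nPerm),
         nPerm = nPerm)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values (monotone enforced), applied across all
#' segments tested for one phenotype.
#'
#' @param pValues numeric vector of p-values in [0, 1].
#' @return q-values, same length.
#' @export
fdrAdjust <- function(pValues) {
    if (any(pValues < 0 | pValues > 1, na.rm = TRUE) || anyNA(pValues))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(pValues, method = "BH")
}

#' Genome-wide topological association scan
#'
#' The full significance pipeline: each chromosome arm is cut into
#' overlapping 20-probe segments, each patient's segment profile is embedded
#' as a sliding-window cloud and summarised as a persistence curve, the L2
#' distance between the average test and control curves is the segment
#' statistic, its significance is assessed by permutation, and
#' Benjamini-Hochberg q-values are computed across all tested segments.
#'
#' @param pset a \linkS4class{CNProfileSet}.
#' @param phenotype subtype defining the test group.
#' @param exclude subtypes dropped from the control group.
#' @param kind,k curve kind and landscape level.
#' @param dim homology degree (default 0).
#' @param segLen,overlap segmentation parameters.
#' @param s sliding-window size.
#' @param nGrid filtration grid resolution.
#' @param nPerm permutations per segment.
#' @param alpha FDR level for the \code{Significant} flag.
#' @param seed integer seed; segment-level permutation draws are derived
#'   from it deterministically.
#' @return data.frame with one row per segment: \code{Chrom}, \code{Arm},
#'   \code{Ordinal}, \code{Name}, \code{FirstProbe}, \code{LastProbe},
#'   \code{Statistic}, \code{P}, \code{Q}, \code{Significant}.
#' @export
runTAaCGH <- function(pset, phenotype, exclude = character(0),
                      kind = c("lifespan", "betti", "landscape"), k = 2L,
                      dim = 0L, segLen = 20L, overlap = 10L, s = 2L,
                      nGrid = 100L, nPerm = 1000L, alpha = 0.05,
                      seed = NULL) {
    kind <- match.arg(kind)
    groups <- splitTestControl(pset, phenotype, exclude)
    keep <- c(groups$test, groups$control)
    vals <- assay(pset)[, keep, drop = FALSE]
    isTest <- keep %in% groups$test
    segs <- armSegments(pset, segLen, overlap)
    segs$Statistic <- segs$P <- NA_real_
    for (i in seq_len(nrow(segs))) {
        sv <- vals[segs$FirstProbe[i]:segs$LastProbe[i], , drop = FALSE]
        if (nrow(sv) < s) next   # arm shorter than the window
        curves <- .segmentCurveMatrix(sv, kind, k, dim, s, nGrid)
        res <- permutationTest(curves, isTest, nPerm,
                               seed = if (is.null(seed)) NULL
                                      else childSeed(seed, i))
        segs$Statistic[i] <- res$statistic
        segs$P[i] <- res$p.value
    }
    tested <- !is.na(segs$P)
    segs$Q <- NA_real_
    segs$Q[tested] <- fdrAdjust(segs$P[tested])
    segs$Significant <- !is.na(segs$Q) & segs$Q < alpha
    segs
}

#' Maximal non-intersecting set of significant segments
#'
#' Greedy selection in ascending p-value order: a segment is kept only if
#' its probe range does not intersect an already-selected segment. Ties are
#' broken by genomic coordinate (lower first).
#'
#' @param results data.frame as returned by [runTAaCGH()] (rows already
#'   filtered to the significant segments, or pass \code{onlySignificant}).
#' @param onlySignificant if TRUE (default), keep only rows with
#'   \code{Significant == TRUE} before selecting.
#' @return subset of \code{results} rows, the selected set K.
#' @export
maximalNonintersecting <- function(results, onlySignificant = TRUE) {
    if (onlySignificant && "Significant" %in% colnames(results))
        results <- results[results$Significant %in% TRUE, , drop = FALSE]
    if (!nrow(results)) return(results)
    ord <- order(results$P, results$Chrom,
                 match(results$Arm, c("p", "q")), results$FirstProbe)
    results <- results[ord, , drop = FALSE]
    keep <- logical(nrow(results))
    for (i in seq_len(nrow(results))) {
        ok <- TRUE
        for (j in which(keep)) {
            if (results$Chrom[i] == results$Chrom[j] &&
                results$Arm[i] == results$Arm[j] &&
                results$FirstProbe[i] <= results$LastProbe[j] &&
                results$LastProbe[i] >= results$FirstProbe[j]) {
                ok <- FALSE; break
            }
        }
        keep[i] <- ok
    }
    out <- results[keep, , drop = FALSE]
    out[order(out$Chrom, match(out$Arm, c("p", "q")), out$FirstProbe), ,
        drop = FALSE]
}

## deterministic child seed below 2^31 for per-segment / per-simulation RNG
childSeed <- function(seed, index) {
    (as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483647
}
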