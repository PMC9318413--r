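#' Shared filtration grid for a set of diagrams
#'
#' A uniform grid from 0 to the largest finite death across the supplied
#' diagrams. Every patient in a segment-level comparison is evaluated on the
#' same grid. If no finite death exists the grid degenerates to the single
#' point 0 and carries attribute \code{degenerate = TRUE} (all curves on it
#' are identically zero).
#'
#' @param diagrams list of \linkS4class{PersistenceDiagram}.
#' @param nPoints grid resolution (default 100).
#' @return increasing numeric vector.
#' @export
makeGrid <- function(diagrams, nPoints = 100L) {
    if (nPoints < 2L) stop("nPoints must be >= 2")
    deaths <- unlist(lapply(diagrams, function(d) {
        p <- diagramPairs(d)
        p[is.finite(p[, 2]), 2]
    }))
    if (!length(deaths) || max(deaths) <= 0)
        return(structure(0, degenerate = TRUE))
    seq(0, max(deaths), length.out = nPoints)
}

.finitePairs <- function(diag) {
    p <- diagramPairs(diag)
    if (nrow(p) && any(!is.finite(p[, 2])))
        stop("diagram has infinite pairs; reduce it first (reduceDiagram)")
    p
}

#' Betti, lifespan and landscape curves of a persistence diagram
#'
#' For a diagram D and filtration value t, with membership rule t in (b, d]:
#' the Betti curve counts the pairs alive at t; the lifespan curve sums the
#' lifespans d - b of the pairs alive at t; the k-th persistence landscape
#' is the k-th largest tent value max(min(t - b, d - t), 0) over pairs
#' (0 when fewer than k pairs exist).
#'
#' @param diag a finite (reduced) \linkS4class{PersistenceDiagram}.
#' @param grid increasing numeric filtration grid (see [makeGrid()]).
#' @param k landscape level, k >= 1.
#' @return A \linkS4class{PersistenceCurve} on \code{grid}.
#' @examples
#' d <- PersistenceDiagram(cbind(c(0, 0), c(1, 2)), reduced = TRUE)
#' curveValues(bettiCurve(d, c(0.5, 1, 1.5)))  # 2 2 1
#' @export
bettiCurve <- function(diag, grid) {
    p <- .finitePairs(diag)
    if (!length(grid)) stop("empty grid")
    v <- if (nrow(p)) colSums(outer(p[, 1], grid, "<") &
                              outer(p[, 2], grid, ">="))
         else rep(0, length(grid))
    PersistenceCurve("betti", grid, v, dimension = diagramDimension(diag))
}

#' @rdname bettiCurve
#' @export
lifespanCurve <- function(diag, grid) {
    p <- .finitePairs(diag)
    if (!length(grid)) stop("empty grid")
    if (nrow(p)) {
        alive <- outer(p[, 1], grid, "<") & outer(p[, 2], grid, ">=")
        v <- colSums(alive * (p[, 2] - p[, 1]))
    } else v <- rep(0, length(grid))
    PersistenceCurve("lifespan", grid, v,
                     dimension = diagramDimension(diag))
}

#' @rdname bettiCurve
#' @export
landscapeCurve <- function(diag, k = 1L, grid) {
    k <- as.integer(k)
    if (k < 1L) stop("landscape level k must be >= 1")
    p <- .finitePairs(diag)
    if (!length(grid)) stop("empty grid")
    if (nrow(p) >= k) {
        tents <- pmax(pmin(outer(grid, p[, 1], "-"),
                           outer(-grid, p[, 2], "+")), 0)
        v <- apply(tents, 1, function(r) sort(r, decreasing = TRUE)[k])
    } else v <- rep(0, length(grid))
    PersistenceCurve("landscape", grid, v,
                     dimension = diagramDimension(diag), k = k)
}

#' Compute one persistence curve by name
#'
#' Convenience dispatcher used by the pipeline: \code{kind} is "betti",
#' "lifespan" or "landscape" (with level \code{k}).
#'
#' @inheritParams bettiCurve
#' @param kind curve kind.
#' @export
persistenceCurve <- function(diag, grid,
                             kind = c("lifespan", "betti", "landscape"),
                             k = 2L) {
    kind <- match.arg(kind)
    switch(kind,
           betti = bettiCurve(diag, grid),
           lifespan = lifespanCurve(diag, grid),
           landscape = landscapeCurve(diag, k, grid))
}

.checkSameGrid <- function(a, b) {
    if (length(curveGrid(a)) != length(curveGrid(b)) ||
        any(abs(curveGrid(a) - curveGrid(b)) > 1e-9))
        stop("curves must share one filtration grid")
}

#' Pointwise mean of persistence curves
#'
#' @param curves nonempty list of \linkS4class{PersistenceCurve} of
#'   identical kind, dimension and grid.
#' @return The pointwise arithmetic mean curve.
#' @export
meanCurve <- function(curves) {
    if (!length(curves)) stop("need at least one curve")
    ref <- curves[[1]]
    for (cv in curves[-1]) {
        .checkSameGrid(ref, cv)
        if (curveKind(cv) != curveKind(ref) ||
            cv@dimension != ref@dimension)
            stop("curves must share kind and dimension")
    }
    vals <- rowMeans(vapply(curves, curveValues,
                            numeric(length(curveGrid(ref)))))
    PersistenceCurve(curveKind(ref), curveGrid(ref), vals,
                     dimension = ref@dimension, k = ref@k)
}

#' Distance between two persistence curves on a shared grid
#'
#' \code{"l2"} is the plain Euclidean norm of the pointwise difference
#' (no grid-spacing weighting), the segment test statistic. \code{"ss"} is
#' its square, the unscaled sum of squared differences used for the
#' per-patient segment indicators. \code{"l1"} is the left-rule Riemann sum
#' of |difference| with grid-spacing weighting, approximating the continuum
#' L1 distance used in the stability bounds.
#'
#' @param a,b \linkS4class{PersistenceCurve} on the same grid.
#' @param norm "l2", "ss" or "l1".
#' @return nonnegative scalar.
#' @export
curveDistance <- function(a, b, norm = c("l2", "ss", "l1")) {
    norm <- match.arg(norm)
    .checkSameGrid(a, b)
    d <- curveValues(a) - curveValues(b)
    switch(norm,
           l2 = sqrt(sum(d^2)),
           ss = sum(d^2),
           l1 = {
               g <- curveGrid(a)
               if (length(g) < 2L) 0
               else sum(abs(d[-length(d)]) * diff(g))
           })
}

#' Serialize a persistence curve as two-column text
#'
#' A one-line JSON header (kind, k, dimension) followed by (epsilon, value)
#' columns.
#'
#' @param curve a \linkS4class{PersistenceCurve}.
#' @param path output path.
#' @export
writeCurve <- function(curve, path) {
    hdr <- jsonlite::toJSON(list(kind = curve@kind,
                                 k = if (is.na(curve@k)) NULL else curve@k,
                                 dimension = curve@dimension),
                            auto_unbox = TRUE)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# ", hdr), con)
    write.table(data.frame(epsilon = curveGrid(curve),
                           value = curveValues(curve)),
                con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeCurve
#' @export
readCurve <- function(path) {
    hdr <- jsonlite::fromJSON(sub("^# ", "", readLines(path, n = 1L)))
    tab <- read.delim(path, skip = 1L)
    PersistenceCurve(hdr$kind, tab$epsilon, tab$value,
                     dimension = hdr$dimension,
                     k = if (is.null(hdr$k)) NA_integer_ else hdr$k)
}
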