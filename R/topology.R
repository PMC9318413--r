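#' Sliding-window embedding of an ordered value sequence
#'
#' Maps an ordered sequence (log2 ratios along the genome) into a point
#' cloud in R^s by taking consecutive windows of \code{s} values: point i is
#' (values[i], ..., values[i + s - 1]). With step 1 an m-value input yields
#' m - s + 1 points; there is no wraparound.
#'
#' @param values ordered numeric vector.
#' @param s window size / embedding dimension (default 2).
#' @param step offset between consecutive windows (default 1).
#' @return numeric matrix with one point per row and \code{s} columns.
#' @examples
#' slidingWindowEmbed(c(0.1, 0.2, 0.3), s = 2)
#' @export
slidingWindowEmbed <- function(values, s = 2L, step = 1L) {
    values <- as.numeric(values)
    s <- as.integer(s); step <- as.integer(step)
    if (step < 1L) stop("step must be >= 1")
    if (length(values) < s)
        stop("need at least s = ", s, " values, got ", length(values))
    starts <- seq.int(1L, length(values) - s + 1L, by = step)
    out <- vapply(0:(s - 1L), function(j) values[starts + j],
                  numeric(length(starts)))
    matrix(out, nrow = length(starts), ncol = s)
}

#' Diameter of a point cloud
#'
#' @param cloud numeric matrix, one point per row.
#' @return largest pairwise Euclidean distance (0 for a single point).
#' @export
cloudDiameter <- function(cloud) {
    cloud <- as.matrix(cloud)
    if (nrow(cloud) < 2L) return(0)
    max(stats::dist(cloud))
}

## Dim-0 persistence by Kruskal's algorithm on the distance graph:
## union-find merge heights are exactly the reduced dim-0 deaths
## (single-linkage merge heights / MST edge weights). Returns sorted deaths.
.dim0Deaths <- function(dmat) {
    n <- nrow(dmat)
    if (n < 2L) return(numeric(0))
    ij <- which(upper.tri(dmat), arr.ind = TRUE)
    w <- dmat[ij]
    ord <- order(w)
    parent <- seq_len(n)
    find <- function(x) {
        while (parent[x] != x) {
            parent[x] <<- parent[parent[x]]
            x <- parent[x]
        }
        x
    }
    deaths <- numeric(n - 1L)
    k <- 0L
    for (e in ord) {
        a <- find(ij[e, 1]); b <- find(ij[e, 2])
        if (a != b) {
            parent[a] <- b
            k <- k + 1L
            deaths[k] <- w[e]
            if (k == n - 1L) break
        }
    }
    sort(deaths[seq_len(k)])
}

## Dim-1 persistence by standard boundary-matrix reduction over GF(2) of the
## VR 2-skeleton up to maxScale. Simplex filtration value = max pairwise
## distance of its vertices. Returns a 2-column matrix of (birth, death)
## pairs with positive persistence.
.dim1Pairs <- function(dmat, maxScale) {
    n <- nrow(dmat)
    if (n < 4L) return(matrix(numeric(0), 0, 2))
    ij <- which(upper.tri(dmat), arr.ind = TRUE)
    ew <- dmat[ij]
    keep <- ew <= maxScale + 1e-12
    ij <- ij[keep, , drop = FALSE]; ew <- ew[keep]
    ne <- nrow(ij)
    if (ne < 3L) return(matrix(numeric(0), 0, 2))
    ## triangles among retained edges
    eid <- matrix(0L, n, n)
    eid[cbind(ij[, 1], ij[, 2])] <- seq_len(ne)
    eid[cbind(ij[, 2], ij[, 1])] <- seq_len(ne)
    tri <- utils::combn(n, 3L)
    e1 <- eid[cbind(tri[1, ], tri[2, ])]
    e2 <- eid[cbind(tri[1, ], tri[3, ])]
    e3 <- eid[cbind(tri[2, ], tri[3, ])]
    ok <- e1 > 0L & e2 > 0L & e3 > 0L
    e1 <- e1[ok]; e2 <- e2[ok]; e3 <- e3[ok]
    nt <- length(e1)
    tw <- if (nt) pmax(ew[e1], pmax(ew[e2], ew[e3])) else numeric(0)

    ## global filtration order: vertices (filt 0, dim 0), then edges and
    ## triangles sorted by (value, dim). Ties broken deterministically.
    nv <- n
    simDim <- c(rep(0L, nv), rep(1L, ne), rep(2L, nt))
    simVal <- c(rep(0, nv), ew, tw)
    ord <- order(simVal, simDim)
    pos <- integer(length(ord)); pos[ord] <- seq_along(ord)

    ## boundary columns in sorted positions
    m <- length(ord)
    cols <- vector("list", m)
    for (e in seq_len(ne)) {
        cols[[pos[nv + e]]] <- sort(pos[c(ij[e, 1], ij[e, 2])])
    }
    if (nt) for (t in seq_len(nt)) {
        cols[[pos[nv + ne + t]]] <- sort(pos[nv + c(e1[t], e2[t], e3[t])])
    }
    valSorted <- simVal[ord]
    dimSorted <- simDim[ord]

    lowOf <- integer(m)         # pivot row -> column that owns it (0 = free)
    births <- deaths <- numeric(0)
    for (j in seq_len(m)) {
        col <- cols[[j]]
        while (length(col)) {
            low <- col[length(col)]
            other <- lowOf[low]
            if (other == 0L) break
            ## symmetric difference over GF(2)
            oc <- cols[[other]]
            col <- as.integer(sort(c(setdiff(col, oc), setdiff(oc, col))))
        }
        cols[j] <- list(col)   # keep the slot even when col is empty
        if (length(col)) {
            low <- col[length(col)]
            lowOf[low] <- j
            if (dimSorted[j] == 2L) {   # triangle kills an edge-born 1-cycle
                b <- valSorted[low]; d <- valSorted[j]
                if (d > b + 1e-12) {
                    births <- c(births, b)
                    deaths <- c(deaths, d)
                }
            }
        }
    }
    cbind(birth = births, death = deaths)
}

#' Vietoris-Rips persistent homology of a point cloud
#'
#' Computes persistence diagrams of the Vietoris-Rips filtration under the
#' max-edge-length convention: a simplex enters the filtration at the
#' largest pairwise distance of its vertices. Dimension 0 is computed
#' exactly via minimum-spanning-tree merge heights (equivalently
#' single-linkage clustering) and, unreduced, contains one infinite pair for
#' the component that never dies. Dimension 1 is computed by boundary
#' reduction of the 2-skeleton up to \code{maxScale}; the default
#' \code{maxScale} is the cloud diameter, beyond which no generator in any
#' dimension can persist.
#'
#' @param cloud numeric matrix, one point per row (see
#'   [slidingWindowEmbed()]).
#' @param maxScale filtration cutoff, or \code{"auto"} for the cloud
#'   diameter.
#' @param dims integer homology degrees to compute (subset of 0:1).
#' @return named list of \linkS4class{PersistenceDiagram} objects
#'   (\code{"0"}, \code{"1"}).
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
#' diagramPairs(vrPersistence(sq, dims = 1L)[["1"]])  # one cycle born at 1
#' @export
vrPersistence <- function(cloud, maxScale = "auto", dims = 0L) {
    cloud <- as.matrix(cloud)
    if (!nrow(cloud)) stop("empty point cloud")
    dims <- as.integer(dims)
    if (!all(dims %in% 0:1)) stop("only dimensions 0 and 1 are supported")
    dmat <- as.matrix(stats::dist(cloud))
    diam <- if (nrow(cloud) > 1L) max(dmat) else 0
    if (identical(maxScale, "auto")) maxScale <- diam
    if (!is.numeric(maxScale) || maxScale < 0)
        stop("maxScale must be 'auto' or a nonnegative number")
    out <- list()
    if (0L %in% dims) {
        deaths <- .dim0Deaths(dmat)
        pairs <- cbind(birth = rep(0, length(deaths) + 1L),
                       death = c(deaths, Inf))
        out[["0"]] <- PersistenceDiagram(pairs, dimension = 0L,
                                         reduced = FALSE)
    }
    if (1L %in% dims) {
        out[["1"]] <- PersistenceDiagram(.dim1Pairs(dmat, maxScale),
                                         dimension = 1L, reduced = FALSE)
    }
    out
}

#' Reduce a dimension-0 diagram
#'
#' Reduced homology in dimension 0: the infinitely-persistent connected
#' component is either removed (\code{mode = "drop"}, the default) or
#' asserted to die at a predetermined filtration value
#' (\code{mode = "cap"}). Zero-persistence pairs (all merges at 0, e.g. a
#' zero-diameter cloud) are dropped as well, so a constant profile yields an
#' empty reduced diagram.
#'
#' @param diag a dimension-0 \linkS4class{PersistenceDiagram}.
#' @param mode "drop" or "cap".
#' @param capValue death value assigned to the infinite pair when capping.
#' @return A reduced \linkS4class{PersistenceDiagram}.
#' @export
reduceDiagram <- function(diag, mode = c("drop", "cap"), capValue = NULL) {
    mode <- match.arg(mode)
    if (diagramDimension(diag) != 0L)
        stop("reduction applies to dimension-0 diagrams")
    p <- diagramPairs(diag)
    inf <- !is.finite(p[, 2])
    if (sum(inf) > 1L) stop("diagram has more than one infinite pair")
    if (mode == "cap") {
        if (is.null(capValue)) stop("cap mode requires capValue")
        p[inf, 2] <- capValue
    } else {
        p <- p[!inf, , drop = FALSE]
    }
    p <- p[p[, 2] > p[, 1], , drop = FALSE]   # drop zero-persistence pairs
    PersistenceDiagram(p, dimension = 0L, reduced = TRUE)
}

#' Serialize / read persistence diagrams as plain text
#'
#' Three whitespace-separated columns (dim, birth, death); "inf" marks the
#' unreduced infinite dimension-0 pair.
#'
#' @param diags list of \linkS4class{PersistenceDiagram}.
#' @param path output (input) file path.
#' @return \code{writeDiagrams}: invisible path; \code{readDiagrams}: list
#'   of diagrams keyed by dimension.
#' @export
writeDiagrams <- function(diags, path) {
    rows <- lapply(diags, function(d) {
        p <- diagramPairs(d)
        if (!nrow(p)) return(NULL)
        data.frame(dim = diagramDimension(d), birth = p[, 1],
                   death = ifelse(is.finite(p[, 2]),
                                  format(p[, 2], digits = 17), "inf"))
    })
    tab <- do.call(rbind, rows)
    if (is.null(tab)) tab <- data.frame(dim = integer(0), birth = numeric(0),
                                        death = character(0))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeDiagrams
#' @export
readDiagrams <- function(path) {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    tab$death <- ifelse(tab$death == "inf", Inf, as.numeric(tab$death))
    lapply(split(tab, tab$dim), function(s)
        PersistenceDiagram(cbind(s$birth, s$death),
                           dimension = s$dim[1], reduced = FALSE))
}
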