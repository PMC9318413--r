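## number of pairs / total lifespan of a finite diagram
.nPairs <- function(diag) nrow(diagramPairs(diag))
.totalLifespan <- function(diag) {
    p <- diagramPairs(diag)
    if (!nrow(p)) 0 else sum(p[, 2] - p[, 1])
}

## Kuhn's augmenting-path maximum bipartite matching.
## adj: list over left nodes of integer vectors of right neighbours.
.maxBipartiteMatching <- function(adj, nRight) {
    matchR <- integer(nRight)      # right node -> left node (0 = free)
    seen <- logical(nRight)
    aug <- function(u) {
        for (v in adj[[u]]) {
            if (seen[v]) next
            seen[v] <<- TRUE
            if (matchR[v] == 0L || aug(matchR[v])) {
                matchR[v] <<- u
                return(TRUE)
            }
        }
        FALSE
    }
    matched <- 0L
    for (u in seq_along(adj)) {
        seen <- logical(nRight)   # aug() writes here via <<-
        if (aug(u)) matched <- matched + 1L
    }
    matched
}

#' Bottleneck distance between two persistence diagrams
#'
#' Exact bottleneck distance for finite diagrams: the minimum over partial
#' matchings (unmatched points pair with the diagonal at cost
#' (death - birth) / 2) of the maximal L-infinity matching cost. Computed by
#' binary search over the finite set of candidate costs with a bipartite
#' perfect-matching feasibility test, so it is exact for the small diagrams
#' arising from 20-probe windows.
#'
#' @param C,D \linkS4class{PersistenceDiagram} with finite pairs (reduce
#'   dimension-0 diagrams first).
#' @return nonnegative scalar.
#' @examples
#' C <- PersistenceDiagram(cbind(0, 1), reduced = TRUE)
#' D <- PersistenceDiagram(cbind(0, 1.2), reduced = TRUE)
#' bottleneckDistance(C, D)  # 0.2
#' @export
bottleneckDistance <- function(C, D) {
    pc <- .finitePairs(C); pd <- .finitePairs(D)
    nc <- nrow(pc); nd <- nrow(pd)
    if (nc == 0L && nd == 0L) return(0)
    diagC <- if (nc) (pc[, 2] - pc[, 1]) / 2 else numeric(0)
    diagD <- if (nd) (pd[, 2] - pd[, 1]) / 2 else numeric(0)
    cross <- if (nc && nd)
        pmax(abs(outer(pc[, 1], pd[, 1], "-")),
             abs(outer(pc[, 2], pd[, 2], "-")))
    else matrix(numeric(0), nc, nd)
    cand <- sort(unique(c(0, diagC, diagD, as.numeric(cross))))

    feasible <- function(delta) {
        ## Standard augmented bipartite construction: left nodes are the C
        ## points plus one diagonal copy per D point; right nodes are the D
        ## points plus one diagonal copy per C point. C_i -- D_j iff the
        ## L-infinity cost fits delta; a point may pair with its own
        ## diagonal copy iff persistence/2 fits; diagonal copies pair with
        ## each other freely. Bottleneck <= delta iff a perfect matching of
        ## all nc + nd left nodes exists.
        tol <- delta + 1e-12
        nL <- nc + nd
        adj <- vector("list", nL)
        for (i in seq_len(nc)) {
            ok <- if (nd) which(cross[i, ] <= tol) else integer(0)
            if (diagC[i] <= tol) ok <- c(ok, nd + i)
            adj[[i]] <- as.integer(ok)
        }
        for (j in seq_len(nd)) {
            ok <- if (diagD[j] <= tol) j else integer(0)
            adj[[nc + j]] <- as.integer(c(ok, nd + seq_len(nc)))
        }
        .maxBipartiteMatching(adj, nd + nc) == nL
    }

    lo <- 1L; hi <- length(cand)
    while (lo < hi) {
        mid <- (lo + hi) %/% 2L
        if (feasible(cand[mid])) hi <- mid else lo <- mid + 1L
    }
    cand[lo]
}

#' General stability bounds on persistence-curve L1 distances
#'
#' Upper bounds on the continuum L1 distance between the curves of two
#' diagrams in terms of the bottleneck distance: for Betti curves,
#' 2 max(nC, nD) Winf + min(LC, LD); for lifespan curves,
#' 2 (LC + LD) Winf, where n is the pair count and L the total lifespan of
#' a diagram.
#'
#' @param C,D finite \linkS4class{PersistenceDiagram}s.
#' @param winf optional precomputed bottleneck distance (computed if
#'   missing).
#' @return nonnegative bound.
#' @export
bettiBoundGeneral <- function(C, D, winf = NULL) {
    if (is.null(winf)) winf <- bottleneckDistance(C, D)
    2 * max(.nPairs(C), .nPairs(D)) * winf +
        min(.totalLifespan(C), .totalLifespan(D))
}

#' @rdname bettiBoundGeneral
#' @export
lifespanBoundGeneral <- function(C, D, winf = NULL) {
    if (is.null(winf)) winf <- bottleneckDistance(C, D)
    2 * (.totalLifespan(C) + .totalLifespan(D)) * winf
}

#' Maximal first Betti number of a clique complex on n vertices
#'
#' Closed form floor(n/2) * ceiling(n/2) - (n - 1), attained by the complete
#' bipartite (triangle-free, Mantel-extremal) graph. This also bounds the
#' number of 1-dimensional birth-death pairs of a VR filtration on n points
#' with pairwise-distinct distances.
#'
#' @param n number of vertices (points), n >= 1.
#' @return integer bound.
#' @examples
#' maxBetti1Clique(4)  # 1, the square
#' @export
maxBetti1Clique <- function(n) {
    n <- as.integer(n)
    if (any(n < 1L)) stop("n must be >= 1")
    as.integer(floor(n / 2) * ceiling(n / 2) - (n - 1L))
}

#' Brute-force maximal clique-complex first Betti number
#'
#' Independent oracle for [maxBetti1Clique()]: enumerates every simple graph
#' on n labelled vertices (2^choose(n,2) graphs) and computes the first
#' Betti number of its clique complex as
#' |E| - n + #components - rank_GF2(triangle boundary). Implemented in C++;
#' n is capped at 7.
#'
#' @param n number of vertices, 1 <= n <= 7.
#' @return integer maximum.
#' @export
bruteForceMaxBetti1 <- function(n) {
    n <- as.integer(n)
    if (n < 1L) stop("n must be >= 1")
    if (n > 7L) stop("enumeration capped at n = 7 (2^21 graphs)")
    brute_force_max_betti1_cpp(n)
}

#' Explicit curve-stability bounds for sliding-window clouds
#'
#' Plug-in bounds for clouds of n points built from copy-number values in
#' [cmin, cmax] with window size s, whose diameter is at most
#' d = sqrt(s) (cmax - cmin). With N the dimension-specific bound on the
#' number of pairs (N = floor(n/2) ceiling(n/2) - (n-1) in dimension 1;
#' N = n in dimension 0), the Betti bound is N (2 Winf + d) and the lifespan
#' bound is 4 N d Winf.
#'
#' @param n number of points in each cloud.
#' @param s sliding-window size.
#' @param cmin,cmax copy-number value range.
#' @param winf bottleneck distance between the two diagrams.
#' @return named numeric vector \code{c(betti = ..., lifespan = ...)}.
#' @export
dim1CloudBounds <- function(n, s, cmin, cmax, winf) {
    if (cmin > cmax) stop("cmin must be <= cmax")
    d <- sqrt(s) * (cmax - cmin)
    N <- maxBetti1Clique(n)
    c(betti = N * (2 * winf + d), lifespan = 4 * N * d * winf)
}

#' @rdname dim1CloudBounds
#' @export
dim0CloudBounds <- function(n, s, cmin, cmax, winf) {
    if (cmin > cmax) stop("cmin must be <= cmax")
    d <- sqrt(s) * (cmax - cmin)
    c(betti = n * (2 * winf + d), lifespan = 4 * n * d * winf)
}

#' Perturbation experiment verifying the stability bounds
#'
#' Perturbs every coordinate of a base cloud uniformly in [-eta, eta],
#' computes both diagrams (dimension 0 reduced), their bottleneck distance,
#' the actual L1 distance between Betti and between lifespan curves on a
#' fine grid, and the applicable bounds (the general diagram bounds plus the
#' sliding-window cloud bounds for the requested dimension). Reports
#' violation counts — expected 0 — and tightness ratios (actual / bound).
#'
#' @param cloud base point cloud (points x coordinates matrix).
#' @param eta perturbation half-width, > 0.
#' @param nTrials number of perturbation trials.
#' @param dim homology degree (0 or 1).
#' @param seed integer seed.
#' @param cRange copy-number value range c(cmin, cmax) used for the cloud
#'   bounds; defaults to the range of the base cloud expanded by eta.
#' @param nGrid fine-grid resolution for the actual L1 distances
#'   (default 10000).
#' @return list with \code{violations} (named counts), \code{tightness}
#'   (data.frame of per-trial ratios) and \code{nTrials}.
#' @export
verifyBoundExperiment <- function(cloud, eta, nTrials = 100L, dim = 0L,
                                  seed = 1L, cRange = NULL,
                                  nGrid = 10000L) {
    if (eta <= 0) stop("eta must be > 0")
    cloud <- as.matrix(cloud)
    set.seed(seed)
    dim <- as.integer(dim)
    if (is.null(cRange)) cRange <- range(cloud) + c(-eta, eta)
    n <- nrow(cloud); s <- ncol(cloud)
    getDiag <- function(pts) {
        d <- vrPersistence(pts, dims = dim)[[as.character(dim)]]
        if (dim == 0L) reduceDiagram(d) else d
    }
    base <- getDiag(cloud)
    viol <- c(bettiGeneral = 0L, lifespanGeneral = 0L,
              bettiCloud = 0L, lifespanCloud = 0L)
    ratios <- vector("list", nTrials)
    for (tr in seq_len(nTrials)) {
        pert <- cloud + matrix(stats::runif(n * s, -eta, eta), n, s)
        pd <- getDiag(pert)
        winf <- bottleneckDistance(base, pd)
        grid <- makeGrid(list(base, pd), nPoints = nGrid)
        actB <- curveDistance(bettiCurve(base, grid),
                              bettiCurve(pd, grid), "l1")
        actL <- curveDistance(lifespanCurve(base, grid),
                              lifespanCurve(pd, grid), "l1")
        ## The bounds constrain the continuum L1 distance; the left-rule sum
        ## on the grid can differ from it by at most (grid spacing) x (total
        ## jump variation of the difference curve): 2 per pair for Betti
        ## curves, 2 x total lifespan for lifespan curves. The measured
        ## value gets exactly this numerical allowance, which is reported.
        dx <- if (length(grid) > 1L) diff(grid)[1] else 0
        discB <- dx * 2 * (.nPairs(base) + .nPairs(pd))
        discL <- dx * 2 * (.totalLifespan(base) + .totalLifespan(pd))
        bG <- bettiBoundGeneral(base, pd, winf)
        lG <- lifespanBoundGeneral(base, pd, winf)
        cb <- if (dim == 1L)
            dim1CloudBounds(n, s, cRange[1], cRange[2], winf)
        else dim0CloudBounds(n, s, cRange[1], cRange[2], winf)
        viol["bettiGeneral"] <- viol["bettiGeneral"] +
            (actB > bG + discB + 1e-9)
        viol["lifespanGeneral"] <- viol["lifespanGeneral"] +
            (actL > lG + discL + 1e-9)
        viol["bettiCloud"] <- viol["bettiCloud"] +
            (actB > cb["betti"] + discB + 1e-9)
        viol["lifespanCloud"] <- viol["lifespanCloud"] +
            (actL > cb["lifespan"] + discL + 1e-9)
        ratios[[tr]] <- data.frame(
            winf = winf, actualBetti = actB, actualLifespan = actL,
            bettiGeneral = bG, lifespanGeneral = lG,
            bettiCloud = unname(cb["betti"]),
            lifespanCloud = unname(cb["lifespan"]),
            discErrBetti = discB, discErrLifespan = discL)
    }
    list(violations = viol, tightness = do.call(rbind, ratios),
         nTrials = nTrials)
}
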