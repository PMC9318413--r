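#' Simulate one 20-probe copy-number profile
#'
#' Aberrant profiles carry a single contiguous block of \code{lambda} probes
#' drawn from Normal(\code{mu}, \code{sigma}); all remaining probes (and all
#' probes of non-aberrant profiles) are drawn from Normal(0, \code{sigma}).
#' The block offset is uniform at random among valid positions unless fixed
#' with \code{offset} (0-based; useful for debugging).
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @param aberrant logical; does this profile carry the aberration?
#' @param offset optional fixed 0-based block offset.
#' @return numeric vector of length \code{cfg@nProbes}.
#' @export
simulateProfile <- function(cfg, aberrant = TRUE, offset = NULL) {
    stopifnot(is(cfg, "SimConfig"))
    m <- cfg@nProbes
    x <- stats::rnorm(m, 0, cfg@sigma)
    if (aberrant) {
        lam <- cfg@lambda
        if (is.null(offset))
            offset <- sample.int(m - lam + 1L, 1L) - 1L
        if (offset < 0L || offset + lam > m)
            stop("block offset out of range")
        x[(offset + 1L):(offset + lam)] <- stats::rnorm(lam, cfg@mu,
                                                        cfg@sigma)
    }
    x
}

#' Simulate a test/control cohort
#'
#' Generates \code{nTest} test patients — of which
#' \code{round(mix * nTest)} carry the aberration, the rest being background
#' profiles — and \code{nCtrl} background control patients, and wraps them
#' as a \linkS4class{CNProfileSet} on a single synthetic arm (chromosome 1q,
#' unit-spaced positions) with subtype labels "Test" and "Ctrl".
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @param seed optional integer seed.
#' @return A \linkS4class{CNProfileSet} of \code{nTest + nCtrl} patients.
#' @export
simulateCohort <- function(cfg, seed = NULL) {
    stopifnot(is(cfg, "SimConfig"))
    if (!is.null(seed)) set.seed(seed)
    nAb <- round(cfg@mix * cfg@nTest)
    test <- vapply(seq_len(cfg@nTest),
                   function(i) simulateProfile(cfg, aberrant = i <= nAb),
                   numeric(cfg@nProbes))
    ctrl <- vapply(seq_len(cfg@nCtrl),
                   function(i) simulateProfile(cfg, aberrant = FALSE),
                   numeric(cfg@nProbes))
    vals <- cbind(test, ctrl)
    colnames(vals) <- c(sprintf("T%03d", seq_len(cfg@nTest)),
                        sprintf("C%03d", seq_len(cfg@nCtrl)))
    CNProfileSet(vals,
                 probes = data.frame(
                     ProbeID = sprintf("probe%02d", seq_len(cfg@nProbes)),
                     Chrom = 1L, Arm = "q",
                     Position = seq_len(cfg@nProbes)),
                 subtype = stats::setNames(
                     rep(c("Test", "Ctrl"), c(cfg@nTest, cfg@nCtrl)),
                     colnames(vals)))
}

## curve matrix for a simulated cohort (single 20-probe segment)
.cohortCurves <- function(pset, kind, k, dim = 0L, s = 2L, nGrid = 100L)
    .segmentCurveMatrix(assay(pset), kind, k, dim, s, nGrid)

#' Detection experiment: permutation-test sensitivity over simulated cohorts
#'
#' For each configuration, \code{nSims} cohorts are generated and the
#' segment permutation test is run on each (test vs control group). Every
#' cohort is a true positive, so sensitivity is the fraction of cohorts with
#' p < alpha.
#'
#' @param cfgs list of \linkS4class{SimConfig} (or a single one).
#' @param kind,k curve kind and landscape level.
#' @param nPerm permutations per cohort test.
#' @param alpha significance level (default 0.05).
#' @param seed root seed; per-cohort child seeds are derived
#'   deterministically so results do not depend on evaluation order.
#' @param nGrid grid resolution.
#' @return data.frame with one row per configuration: the parameters plus
#'   \code{Sensitivity}.
#' @export
runDetectionExperiment <- function(cfgs, kind = "lifespan", k = 2L,
                                   nPerm = 1000L, alpha = 0.05, seed = 1L,
                                   nGrid = 100L) {
    if (is(cfgs, "SimConfig")) cfgs <- list(cfgs)
    rows <- lapply(seq_along(cfgs), function(ci) {
        cfg <- cfgs[[ci]]
        hits <- vapply(seq_len(cfg@nSims), function(si) {
            sd <- childSeed(seed, (ci - 1L) * 100000L + si)
            ps <- simulateCohort(cfg, seed = sd)
            curves <- .cohortCurves(ps, kind, k, nGrid = nGrid)
            isTest <- subtypes(ps) == "Test"
            res <- permutationTest(curves, isTest, nPerm,
                                   seed = childSeed(sd, 1L))
            res$p.value < alpha
        }, logical(1))
        data.frame(mu = cfg@mu, sigma = cfg@sigma, lambda = cfg@lambda,
                   mix = cfg@mix, nSims = cfg@nSims,
                   Sensitivity = mean(hits))
    })
    do.call(rbind, rows)
}

#' Classification experiment: nearest-mean patient classification
#'
#' For each cohort, every patient's persistence curve is compared with the
#' test-group and control-group average curves; the patient is classified
#' as a test profile iff the L2 distance to the test average is strictly
#' smaller (ties go to control). By default the group averages include the
#' patient being classified; set \code{leaveOneOut = TRUE} to remove them
#' first. Sensitivity (among test patients) and specificity (among
#' controls) are averaged over the \code{nSims} cohorts.
#'
#' @inheritParams runDetectionExperiment
#' @param leaveOneOut remove the classified patient from their group
#'   average.
#' @return data.frame with one row per configuration: parameters plus
#'   \code{Sensitivity} and \code{Specificity} (proportions in [0, 1]).
#' @export
runClassificationExperiment <- function(cfgs, kind = "lifespan", k = 2L,
                                        seed = 1L, nGrid = 100L,
                                        leaveOneOut = FALSE) {
    if (is(cfgs, "SimConfig")) cfgs <- list(cfgs)
    rows <- lapply(seq_along(cfgs), function(ci) {
        cfg <- cfgs[[ci]]
        sens <- spec <- numeric(cfg@nSims)
        for (si in seq_len(cfg@nSims)) {
            sd <- childSeed(seed, (ci - 1L) * 100000L + si)
            ps <- simulateCohort(cfg, seed = sd)
            curves <- .cohortCurves(ps, kind, k, nGrid = nGrid)
            isTest <- subtypes(ps) == "Test"
            cls <- classifyNearestMean(curves, isTest, leaveOneOut)
            sens[si] <- mean(cls[isTest])
            spec[si] <- mean(!cls[!isTest])
        }
        data.frame(mu = cfg@mu, sigma = cfg@sigma, lambda = cfg@lambda,
                   mix = cfg@mix, nSims = cfg@nSims,
                   Sensitivity = mean(sens), Specificity = mean(spec))
    })
    do.call(rbind, rows)
}

#' Nearest-group-mean classification of patient curves
#'
#' @param curves patients x grid curve matrix.
#' @param isTest logical test membership per row.
#' @param leaveOneOut drop the classified patient from their own group mean.
#' @return logical vector: TRUE where the patient is classified as test.
#' @export
classifyNearestMean <- function(curves, isTest, leaveOneOut = FALSE) {
    curves <- as.matrix(curves)
    isTest <- as.logical(isTest)
    sumT <- colSums(curves[isTest, , drop = FALSE])
    sumC <- colSums(curves[!isTest, , drop = FALSE])
    nT <- sum(isTest); nC <- sum(!isTest)
    out <- logical(nrow(curves))
    for (i in seq_len(nrow(curves))) {
        if (leaveOneOut && isTest[i]) {
            mt <- (sumT - curves[i, ]) / (nT - 1L); mc <- sumC / nC
        } else if (leaveOneOut) {
            mt <- sumT / nT; mc <- (sumC - curves[i, ]) / (nC - 1L)
        } else {
            mt <- sumT / nT; mc <- sumC / nC
        }
        dT <- sum((curves[i, ] - mt)^2)
        dC <- sum((curves[i, ] - mc)^2)
        out[i] <- dT < dC
    }
    out
}

#' Compare lifespan-curve sensitivity against another curve kind
#'
#' Given aligned sensitivity tables (one row per configuration) for lifespan
#' curves and a competitor, reports the percentage of configurations where
#' lifespan sensitivity is greater, equal, or smaller, optionally stratified
#' by a fixed parameter (\code{"mix"}, \code{"sigma"} or \code{"lambda"}).
#'
#' @param lifespan,other data.frames from [runDetectionExperiment()] or
#'   [runClassificationExperiment()] on identical configuration grids.
#' @param fixedParam optional stratification column name.
#' @return data.frame with columns \code{Level} (or "all"),
#'   \code{Greater}, \code{Equal}, \code{Less} (percentages summing to 100).
#' @export
compareCurvesReport <- function(lifespan, other, fixedParam = NULL) {
    keys <- c("mu", "sigma", "lambda", "mix")
    if (nrow(lifespan) != nrow(other) ||
        !isTRUE(all.equal(lifespan[keys], other[keys],
                          check.attributes = FALSE)))
        stop("configuration grids must be aligned")
    strat <- if (is.null(fixedParam)) rep("all", nrow(lifespan))
             else as.character(lifespan[[fixedParam]])
    out <- lapply(unique(strat), function(lv) {
        i <- strat == lv
        d <- lifespan$Sensitivity[i] - other$Sensitivity[i]
        data.frame(Level = lv,
                   Greater = 100 * mean(d > 0),
                   Equal = 100 * mean(d == 0),
                   Less = 100 * mean(d < 0))
    })
    do.call(rbind, out)
}
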