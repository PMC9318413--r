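test_that("Betti and lifespan curves use the (b, d] membership rule", {
    D <- PersistenceDiagram(cbind(c(0, 0), c(1, 2)), reduced = TRUE)
    expect_equal(curveValues(bettiCurve(D, c(0.5, 1, 1.5, 2, 2.5))),
                 c(2, 2, 1, 1, 0))   # t = death still counts
    expect_equal(curveValues(lifespanCurve(D, c(0.5, 1.5))), c(3, 2))
    empty <- PersistenceDiagram(reduced = TRUE)
    expect_equal(curveValues(bettiCurve(empty, c(0, 1))), c(0, 0))
    expect_equal(curveValues(lifespanCurve(empty, c(0, 1))), c(0, 0))
    expect_error(bettiCurve(D, numeric(0)), "grid")
})

test_that("landscape curves take the k-th largest tent value", {
    D1 <- PersistenceDiagram(cbind(0, 2), reduced = TRUE)
    expect_equal(curveValues(landscapeCurve(D1, 1, c(0, 1, 2))), c(0, 1, 0))
    expect_equal(curveValues(landscapeCurve(D1, 2, c(0.5, 1, 1.7))),
                 c(0, 0, 0))          # fewer than k pairs
    D2 <- PersistenceDiagram(cbind(c(0, 1), c(2, 3)), reduced = TRUE)
    expect_equal(curveValues(landscapeCurve(D2, 2, 1.5)), 0.5)
    expect_error(landscapeCurve(D1, 0, c(0, 1)), "k")
})

test_that("shared grids span zero to the cohort-wide max death", {
    d1 <- PersistenceDiagram(cbind(0, 2), reduced = TRUE)
    d2 <- PersistenceDiagram(cbind(c(0, 0), c(1, Inf)))
    g <- makeGrid(list(d1, d2), nPoints = 5)
    expect_equal(g, c(0, 0.5, 1, 1.5, 2))   # inf deaths ignored
    expect_true(all(diff(g) > 0))
    g0 <- makeGrid(list(PersistenceDiagram(reduced = TRUE)))
    expect_true(attr(g0, "degenerate"))
    expect_equal(as.numeric(g0), 0)
})

test_that("curve means are pointwise and demand matching grids", {
    g <- seq(0, 2, length.out = 10)
    D <- PersistenceDiagram(cbind(0, 2), reduced = TRUE)
    c1 <- lifespanCurve(D, g)
    zero <- lifespanCurve(PersistenceDiagram(reduced = TRUE), g)
    expect_equal(curveValues(meanCurve(list(c1, c1, c1))), curveValues(c1))
    expect_equal(curveValues(meanCurve(list(c1, zero))),
                 curveValues(c1) / 2)
    short <- lifespanCurve(D, g[1:5])
    expect_error(meanCurve(list(c1, short)), "grid")
    expect_error(meanCurve(list()), "at least one")
})

test_that("curve distances: l2 is unweighted, ss its square, l1 grid-weighted", {
    g <- c(0, 1)
    a <- PersistenceCurve("betti", g, c(1, 1))
    b <- PersistenceCurve("betti", g, c(0, 0))
    expect_equal(curveDistance(a, b, "ss"), 2)
    expect_equal(curveDistance(a, b, "l2"), sqrt(2))
    expect_equal(curveDistance(a, b, "l1"), 1)   # left rule, one interval
    expect_equal(curveDistance(a, a, "l2"), 0)
    expect_equal(curveDistance(a, b, "l2"), curveDistance(b, a, "l2"))
})

test_that("curve integrals converge to the diagram moments", {
    set.seed(5)
    D <- randomDiagram(8, scale = 1)
    p <- diagramPairs(D)
    life <- p[, 2] - p[, 1]
    g <- seq(0, max(p[, 2]), length.out = 5000)
    dx <- diff(g)[1]
    intBetti <- sum(curveValues(bettiCurve(D, g))[-length(g)] * dx)
    expect_equal(intBetti, sum(life), tolerance = dx * nrow(p) * 2)
    intLife <- sum(curveValues(lifespanCurve(D, g))[-length(g)] * dx)
    expect_equal(intLife, sum(life^2), tolerance = dx * sum(life) * 2)
})

test_that("landscapes are 1-Lipschitz and supported where Betti >= k", {
    set.seed(9)
    for (rep in 1:5) {
        D <- randomDiagram(6)
        g <- seq(0, max(diagramPairs(D)[, 2]), length.out = 400)
        dx <- diff(g)[1]
        for (k in 1:3) {
            lk <- curveValues(landscapeCurve(D, k, g))
            expect_true(all(abs(diff(lk)) <= dx + 1e-9))
            bet <- curveValues(bettiCurve(D, g))
            expect_true(all(bet[lk > 1e-9] >= k))
            if (k > 1) {
                prev <- curveValues(landscapeCurve(D, k - 1, g))
                expect_true(all(prev >= lk - 1e-12))
            }
        }
    }
})

test_that("curve text serialization round-trips", {
    path <- withr::local_tempfile(fileext = ".tsv")
    D <- PersistenceDiagram(cbind(c(0, 0.5), c(2, 1.5)), reduced = TRUE)
    cv <- landscapeCurve(D, 2, seq(0, 2, length.out = 20))
    writeCurve(cv, path)
    back <- readCurve(path)
    expect_equal(curveValues(back), curveValues(cv))
    expect_identical(curveKind(back), "landscape")
    expect_identical(back@k, 2L)
})
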