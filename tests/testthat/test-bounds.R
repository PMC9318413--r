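test_that("bottleneck distance handles diagonal and off-diagonal matches", {
    C <- PersistenceDiagram(cbind(0, 1), reduced = TRUE)
    D <- PersistenceDiagram(cbind(0, 1.2), reduced = TRUE)
    expect_equal(bottleneckDistance(C, C), 0)
    expect_equal(bottleneckDistance(C, D), 0.2)
    # matching a lone pair to the diagonal costs persistence / 2
    expect_equal(bottleneckDistance(PersistenceDiagram(cbind(0, 2),
                                                       reduced = TRUE),
                                    PersistenceDiagram(reduced = TRUE)), 1)
    # diagonal beats a distant off-diagonal match
    E <- PersistenceDiagram(cbind(5, 5.4), reduced = TRUE)
    expect_equal(bottleneckDistance(C, E), 0.5)
})

test_that("bottleneck distance satisfies the metric axioms", {
    set.seed(3)
    for (rep in 1:10) {
        A <- randomDiagram(sample(1:5, 1))
        B <- randomDiagram(sample(1:5, 1))
        C <- randomDiagram(sample(1:5, 1))
        ab <- bottleneckDistance(A, B)
        expect_equal(ab, bottleneckDistance(B, A))
        expect_equal(bottleneckDistance(A, A), 0)
        expect_lte(ab, bottleneckDistance(A, C) +
                       bottleneckDistance(C, B) + 1e-9)
        expect_gte(ab, 0)
    }
})

test_that("general curve bounds match their plug-in formulas and hold", {
    C <- PersistenceDiagram(cbind(0, 1), reduced = TRUE)
    D <- PersistenceDiagram(cbind(0, 1.2), reduced = TRUE)
    expect_equal(bettiBoundGeneral(C, C), 1)          # 0 + min(L) = 1
    expect_equal(bettiBoundGeneral(C, D), 2 * 1 * 0.2 + 1)
    expect_equal(lifespanBoundGeneral(C, D), 2 * (1 + 1.2) * 0.2)
    expect_equal(lifespanBoundGeneral(C, C), 0)
    # the actual L1 distances respect both bounds on a fine grid
    g <- seq(0, 1.2, length.out = 4000)
    actB <- curveDistance(bettiCurve(C, g), bettiCurve(D, g), "l1")
    actL <- curveDistance(lifespanCurve(C, g), lifespanCurve(D, g), "l1")
    expect_equal(actB, 0.2, tolerance = 1e-3)  # curves differ on (1, 1.2]
    expect_equal(actL, 0.44, tolerance = 1e-3) # |1-1.2|*1 + 1.2*0.2
    expect_lte(actB, bettiBoundGeneral(C, D))
    expect_lte(actL, lifespanBoundGeneral(C, D))
})

test_that("sliding-window cloud bounds follow the reconstructed formulas", {
    b1 <- dim1CloudBounds(n = 4, s = 2, cmin = 0, cmax = 1, winf = 0.1)
    expect_equal(unname(b1["betti"]), 1 * (0.2 + sqrt(2)))
    expect_equal(unname(b1["lifespan"]), 4 * 1 * sqrt(2) * 0.1)
    expect_equal(unname(dim1CloudBounds(5, 2, 0, 1, 0)["lifespan"]), 0)
    b0 <- dim0CloudBounds(n = 19, s = 2, cmin = 0, cmax = 1, winf = 0.05)
    expect_equal(unname(b0["betti"]), 19 * (0.1 + sqrt(2)))
    expect_equal(unname(dim0CloudBounds(1, 2, 0, 1, 0.1)["betti"]),
                 0.2 + sqrt(2))
    # lifespan bounds scale linearly in the value range
    l1 <- dim1CloudBounds(6, 2, 0, 1, 0.1)["lifespan"]
    l2 <- dim1CloudBounds(6, 2, 0, 2, 0.1)["lifespan"]
    expect_equal(unname(l2 / l1), 2)
})

test_that("clique-complex Betti-1 closed form matches brute force for small n", {
    expect_identical(maxBetti1Clique(3), 0L)
    expect_identical(maxBetti1Clique(4), 1L)
    expect_identical(maxBetti1Clique(6), 4L)
    for (n in 1:5)
        expect_identical(bruteForceMaxBetti1(n), maxBetti1Clique(n))
    expect_error(bruteForceMaxBetti1(9), "capped")
})

test_that("the quadratic bound first beats the linear 5n bound at n = 24", {
    n <- 1:30
    better <- maxBetti1Clique(n) < 5 * n
    expect_true(all(better[n < 24]))
    expect_false(any(better[n >= 24]))
})

test_that("perturbation trials never violate the stability bounds", {
    set.seed(12)
    cloud <- slidingWindowEmbed(rnorm(20, 0, 0.3), s = 2)
    r0 <- verifyBoundExperiment(cloud, eta = 0.05, nTrials = 40, dim = 0,
                                seed = 5, nGrid = 2000)
    expect_true(all(r0$violations == 0))
    cloud8 <- slidingWindowEmbed(rnorm(9, 0, 0.3), s = 2)
    r1 <- verifyBoundExperiment(cloud8, eta = 0.05, nTrials = 40, dim = 1,
                                seed = 5, nGrid = 2000)
    expect_true(all(r1$violations == 0))
    # continuity: small eta keeps the bottleneck distance small
    expect_lt(max(r0$tightness$winf), 0.05 * sqrt(2) * 2 + 1e-9)
})
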