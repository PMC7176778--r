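test_that("linearViewInterp inserts convex combinations", {
    s <- Sinogram(cbind(c(1, 1), c(3, 3)), coverageDeg = 360)
    out <- linearViewInterp(s, 2L)
    v <- sinogramValues(out)
    expect_equal(nViews(out), 4L)
    expect_equal(v[, 2], c(2, 2))            # midpoint of views 1 and 2
    expect_equal(v[, 1], c(1, 1))            # measured pass-through
    expect_equal(deltaGammaDeg(out), deltaGammaDeg(s) / 2)

    # factor 3 between 0 and 3: inserted 1 and 2
    s3 <- Sinogram(cbind(c(0, 0), c(3, 3)), coverageDeg = 360)
    v3 <- sinogramValues(linearViewInterp(s3, 3L))
    expect_equal(v3[, 2], c(1, 1))
    expect_equal(v3[, 3], c(2, 2))

    # identical views stay identical everywhere
    si <- Sinogram(matrix(rep(runif(8), 5), 8, 5), coverageDeg = 360)
    vi <- sinogramValues(linearViewInterp(si, 4L))
    expect_lt(max(abs(vi - vi[, 1])), 1e-14)

    expect_error(linearViewInterp(s, 1L), "factor")
})

test_that("the 180-degree wrap pair uses the conjugate mirror", {
    # one asymmetric profile: the view inserted after the last measured one
    # must blend toward the radial mirror of view 1, not view 1 itself
    p <- c(0, 1, 4, 2, 0)
    s <- Sinogram(cbind(p, p + 1), coverageDeg = 180)
    v <- sinogramValues(linearViewInterp(s, 2L))
    expect_equal(v[, 4], 0.5 * (p + 1) + 0.5 * rev(p))
})

test_that("sincViewInterp reproduces harmonics and measured views", {
    M <- 12L
    m <- 0:(M - 1)
    harm <- cos(2 * pi * m / M)
    s <- Sinogram(rbind(harm, 2 * harm + 1), coverageDeg = 360)
    out <- sincViewInterp(s, 3L)
    v <- sinogramValues(out)
    fine <- 0:(3 * M - 1)
    expect_equal(v[1, ], cos(2 * pi * fine / (3 * M)), tolerance = 1e-9)
    expect_equal(v[2, ], 2 * cos(2 * pi * fine / (3 * M)) + 1,
                 tolerance = 1e-9)
    # measured positions are exact
    expect_equal(v[, seq(1, 3 * M, by = 3)], sinogramValues(s),
                 tolerance = 1e-9)
    # constant along views stays constant
    sc <- Sinogram(matrix(rep(runif(6), 8), 6, 8), coverageDeg = 360)
    vc <- sinogramValues(sincViewInterp(sc, 2L))
    expect_lt(max(abs(vc - vc[, 1])), 1e-9)
    expect_error(sincViewInterp(s, 0L), "factor")
})

test_that("regularizer and objective match hand-evaluated cases", {
    # both slopes positive -> 0 ; opposite slopes -> 4 ; zero vs positive -> 1
    expect_equal(regularizerR(c(0, 1), c(0, 2), 2, 0), 0)
    expect_equal(regularizerR(c(1, 0), c(0, 1), 2, 0), 4)
    expect_equal(regularizerR(c(1, 1), c(0, 2), 2, 0), 1)
    # first-index rule: no slope information
    expect_equal(regularizerR(c(5, 1), c(7, 1), 1, 0), 0)

    expect_equal(objectiveF(c(0, 1), c(0, 2), 2, 0, 0.001), 1.0)
    expect_equal(objectiveF(c(1, 0), c(0, 1), 2, 0, 0.001), 1.004)
    expect_equal(objectiveF(c(1, 2, 3), c(1, 2, 3), 2, 0, 0.001), 0)
    # out-of-range samples are zero-filled
    expect_equal(objectiveF(c(1, 2), c(0, 3), 2, 5, 0), 9)
})

test_that("estimateDisplacement recovers shifts and honours the bound", {
    L <- 48L
    p1 <- monotoneBump(L, 20L, 5L)
    cfg <- estimatorConfig()
    # identity pair: u is identically zero
    expect_true(all(displacement(estimateDisplacement(p1, p1, cfg)) == 0L))

    # right-shift by k is recovered as u = -k on the bump support
    for (k in c(-7L, -2L, 2L, 7L)) {
        p2 <- monotoneBump(L, 20L + k, 5L)
        u <- displacement(estimateDisplacement(p1, p2, cfg))
        support <- which(p2 > 0)
        expect_true(all(u[support] == -k),
                    label = sprintf("shift %d tracked on support", k))
    }

    # shifts beyond N stay clamped to [-N, N]
    p2 <- monotoneBump(L, 40L, 5L)
    u <- displacement(estimateDisplacement(p1, p2, cfg))
    expect_lte(max(abs(u)), 12L)

    expect_error(estimateDisplacement(1:4, 1:5), "lengths differ")
})

test_that("estimation attains the exhaustive minimum exactly", {
    set.seed(33)
    cfg <- estimatorConfig(normalize = FALSE)
    for (rep in 1:20) {
        p1 <- runif(32)
        p2 <- runif(32)
        u <- displacement(estimateDisplacement(p1, p2, cfg))
        achieved <- vapply(seq_along(p2), function(n)
            objectiveF(p1, p2, n, u[n], 0.001), numeric(1))
        expect_identical(achieved, naiveBestObjective(p1, p2))
    }
})

test_that("ties prefer the smallest displacement magnitude", {
    # strictly constant views: every u matches equally well; scan order
    # keeps u = 0
    p <- rep(2, 10)
    expect_true(all(displacement(estimateDisplacement(p, p)) == 0L))
    # symmetric two-sided tie resolves to the negative candidate
    p1 <- c(0, 1, 0, 1, 0)
    p2 <- c(1, 0, 1, 0, 1)
    u <- displacement(estimateDisplacement(p1, p2,
                                           estimatorConfig(lambdaReg = 0)))
    expect_true(all(u[p2 == 1 & seq_along(p2) > 1] == -1L))
})

test_that("synthesizeViews interpolates fractional displacements", {
    u1 <- DisplacementField(rep(1L, 3), boundN = 12L)
    out <- synthesizeViews(c(0, 4, 8), u1, 2L)
    expect_identical(out[[1]], c(0, 4, 8))       # fraction 0 is the source
    expect_equal(out[[2]], c(2, 6, 4))           # zero-fill past the end

    # zero displacement reproduces the source at every fraction
    u0 <- DisplacementField(rep(0L, 5), boundN = 3L)
    p <- runif(5)
    for (v in synthesizeViews(p, u0, 4L)) expect_identical(v, p)

    # the midpoint view applies half the displacement: u = 2 shifts an
    # impulse by exactly one sample at t = 0.5
    imp <- c(0, 0, 0, 1, 0, 0, 0)
    u2 <- DisplacementField(rep(-2L, 7), boundN = 4L)
    mid <- synthesizeViews(imp, u2, 2L)[[2]]
    expect_equal(mid, c(0, 0, 0, 0, 1, 0, 0))

    expect_error(synthesizeViews(p, u0, 0L), "M")
    expect_error(synthesizeViews(runif(4), u0, 2L), "length")
})

test_that("upsampleSinogram multiplies views and preserves measured ones", {
    ph <- makePhantom("rotating_features")
    s60 <- sinogramFromPhantom(ph, 60, 360, 64)
    s180 <- upsampleSinogram(s60, 3L)
    expect_equal(nViews(s180), 180L)
    expect_equal(deltaGammaDeg(s180), 2)
    expect_identical(sinogramValues(s180)[, seq(1, 180, by = 3)],
                     sinogramValues(s60))
    expect_equal(viewAngles(s180)[seq(1, 180, by = 3)], viewAngles(s60))

    s120 <- sinogramFromPhantom(ph, 120, 360, 64)
    expect_equal(nViews(upsampleSinogram(s120, 3L)), 360L)

    # rotational symmetry: u is zero everywhere, all views equal
    disk <- sinogramFromPhantom(makePhantom("disk"), 24, 360, 64)
    v <- sinogramValues(upsampleSinogram(disk, 3L))
    expect_lt(max(abs(v - v[, 1])), 1e-12)

    expect_error(upsampleSinogram(s60, 1L), "factor")
})

test_that("displacement filling beats the baselines on the packaged phantom", {
    # canonical simulation geometry: 60 measured views filled to 180 over
    # 360 degrees, 256 radial samples
    ph <- makePhantom("rotating_features")
    full <- sinogramFromPhantom(ph, 180, 360, 256)
    meas <- undersampleViews(full, 3L)
    errs <- vapply(c(displacement = "displacement", linear = "linear",
                     sinc = "sinc"), function(m) {
        filled <- switch(m,
            displacement = upsampleSinogram(meas, 3L),
            linear = linearViewInterp(meas, 3L),
            sinc = sincViewInterp(meas, 3L))
        sumAbsError(filled, full)
    }, numeric(1))
    expect_lt(errs[["displacement"]], errs[["sinc"]])
    expect_lt(errs[["sinc"]], errs[["linear"]])
})
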