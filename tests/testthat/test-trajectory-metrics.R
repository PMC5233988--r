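ionOnly <- function() data.frame(role = "ion", chain = "A", resno = 1,
                                 resname = "SOD", atom = "NA")

test_that("ion RMSF matches closed-form cases", {
    part <- ionOnly()
    # static ion
    tr <- trajectoryFromFrames(rep(list(matrix(c(1, 2, 3), 1)), 5), part)
    expect_equal(ionRMSF(tr, metricWindow(0, 250))$mean, 0)
    # two frames 1 A apart: deviation 0.5 A each side
    tr <- trajectoryFromFrames(list(matrix(c(0, 0, 0), 1),
                                    matrix(c(1, 0, 0), 1)), part)
    expect_equal(ionRMSF(tr, metricWindow(0, 50))$mean, 0.5)
    # single-frame window is insufficient
    expect_error(ionRMSF(tr, metricWindow(0, 10)), "insufficient")
})

test_that("isotropic Gaussian jitter gives RMSF near sigma * sqrt(3)", {
    spec <- plantedStateSpec("x", sigma = 0.2, lambda = 0, nFrames = 2000,
                             replicas = 1, seed = 42)
    tr <- simulateTrajectory(spec)[[1]]
    r <- ionRMSF(tr, metricWindow(0, max(frameTimes(tr))))
    expect_equal(r$mean, 0.2 * sqrt(3), tolerance = 0.05)
})

test_that("RMSF is invariant under rigid motion and scales about the mean", {
    set.seed(11)
    tr <- randomTinyTrajectory(nIons = 3, nWaters = 0, nFrames = 6)
    w <- metricWindow(0, max(frameTimes(tr)))
    base <- ionRMSF(tr, w)$perIon
    # global translation
    shifted <- tr
    shifted@coords <- tr@coords + 100
    expect_equal(ionRMSF(shifted, w)$perIon, base, tolerance = 1e-12)
    # global rotation (about z by 40 degrees)
    th <- 40 * pi / 180
    R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
    rot <- tr
    for (f in seq_len(nFrames(tr)))
        rot@coords[, , f] <- tr@coords[, , f] %*% R
    expect_equal(ionRMSF(rot, w)$perIon, base, tolerance = 1e-10)
    # uniform scaling about each ion's mean doubles the RMSF
    scaled <- tr
    for (i in seq_len(nParticles(tr))) {
        mu <- rowMeans(tr@coords[i, , ])
        for (f in seq_len(nFrames(tr)))
            scaled@coords[i, , f] <- mu + 2 * (tr@coords[i, , f] - mu)
    }
    expect_equal(ionRMSF(scaled, w)$perIon, 2 * base, tolerance = 1e-12)
})

test_that("hydration count applies the unique-water rule at the cutoff", {
    ions <- data.frame(role = "ion", chain = "A", resno = 1:3,
                       resname = "SOD", atom = "NA")
    wat <- data.frame(role = "water_oxygen", chain = "W", resno = 1:2,
                      resname = "HOH", atom = "OW")
    part <- rbind(ions, wat)
    frame <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0),  # ions
                   c(4, 0, 0),                            # 4 A from ion 1
                   c(0, 0, 6))                            # 6 A from all
    tr <- trajectoryFromFrames(list(frame, frame), part)
    h <- hydrationCount(tr, cutoff = 5, window = metricWindow(0, 50))
    expect_identical(h$perFrame, c(1L, 1L))
    # a water within 5 A of two ions counts once
    frame2 <- rbind(c(0, 0, 0), c(6, 0, 0), c(0, 10, 0),
                    c(3, 0, 0),      # 3 A from ion 1 AND 3 A from ion 2
                    c(50, 50, 50))
    tr2 <- trajectoryFromFrames(list(frame2, frame2), part)
    expect_identical(hydrationCount(tr2, 5, metricWindow(0, 50))$perFrame,
                     c(1L, 1L))
    # no waters at all: zero with a warning
    tr3 <- trajectoryFromFrames(list(frame[1:3, ], frame[1:3, ]), ions)
    expect_warning(h3 <- hydrationCount(tr3, 5, metricWindow(0, 50)),
                   "no water")
    expect_equal(h3$mean, 0)
})

test_that("planted Poisson occupancy is recovered within sampling error", {
    spec <- plantedStateSpec("x", sigma = 0.1, lambda = 6, nFrames = 2000,
                             replicas = 1, seed = 99)
    tr <- simulateTrajectory(spec)[[1]]
    h <- hydrationCount(tr, 5, metricWindow(0, max(frameTimes(tr))))
    se <- sqrt(6 / 2000)
    expect_lt(abs(h$mean - 6), 3 * se)
})

test_that("metrics match brute-force references on a randomized tiny suite", {
    set.seed(2024)
    for (k in 1:12) {
        tr <- randomTinyTrajectory(nIons = sample(1:3, 1),
                                   nWaters = sample(0:15, 1),
                                   nFrames = sample(2:10, 1))
        w <- metricWindow(0, max(frameTimes(tr)))
        frames <- seq_len(nFrames(tr))
        expect_equal(ionRMSF(tr, w)$perIon, bruteRMSF(tr, frames)$perIon,
                     tolerance = 1e-10, ignore_attr = TRUE)
        if (any(particles(tr)$role == "water_oxygen"))
            expect_equal(hydrationCount(tr, 5, w)$mean,
                         bruteNwater(tr, frames)$mean, tolerance = 1e-10)
    }
})

test_that("minimum-image convention is honoured when a box is present", {
    ions <- ionOnly()
    wat <- data.frame(role = "water_oxygen", chain = "W", resno = 1,
                      resname = "HOH", atom = "OW")
    frame <- rbind(c(1, 1, 1), c(19, 1, 1))  # 18 A apart, 2 A across the box
    tr <- trajectoryFromFrames(list(frame, frame), rbind(ions, wat))
    tr@box <- c(20, 20, 20)
    expect_identical(hydrationCount(tr, 5, metricWindow(0, 50))$perFrame,
                     c(1L, 1L))
    tr@box <- numeric(0)
    expect_identical(hydrationCount(tr, 5, metricWindow(0, 50))$perFrame,
                     c(0L, 0L))
})

test_that("unbinding uses the final-frame displacement rule", {
    part <- ionOnly()
    near <- matrix(c(0.5, 0, 0), 1)
    far <- matrix(c(8, 0, 0), 1)
    home <- matrix(c(0, 0, 0), 1)
    # fluctuating close: bound
    tr <- trajectoryFromFrames(list(home, near, home), part)
    expect_false(any(detectUnbinding(tr, window = metricWindow(0, 100))))
    # 8 A away at the final frame: unbound
    tr <- trajectoryFromFrames(list(home, near, far), part)
    expect_true(any(detectUnbinding(tr, window = metricWindow(0, 100))))
    # excursion that returns inside the threshold by the final frame
    tr <- trajectoryFromFrames(list(home, far, near), part)
    expect_false(any(detectUnbinding(tr, window = metricWindow(0, 100))))
})

test_that("stability classification enforces the all-replica strict box", {
    ok <- data.frame(replica = 1:3, mean_nwater = c(7.0, 6.5, 7.9),
                     mean_rmsf = c(0.40, 0.45, 0.49), unbound = FALSE)
    expect_identical(verdict(classifyStability(ok, "3[EEE]")), "stable")
    oneBad <- data.frame(replica = 1:3, mean_nwater = c(7.0, 8.2, 7.0),
                         mean_rmsf = c(0.40, 0.30, 0.40), unbound = FALSE)
    rep <- classifyStability(oneBad, "2[0EE]")
    expect_identical(verdict(rep), "unstable")
    expect_identical(rep@failures$replica, 2L)
    expect_identical(rep@failures$criterion, "nwater")
    # exactly on the thresholds fails (strict inequalities)
    edge <- data.frame(replica = 1L, mean_nwater = 8.0, mean_rmsf = 0.50,
                       unbound = FALSE)
    expect_identical(verdict(classifyStability(edge)), "unstable")
    # any unbinding excludes the state
    ub <- ok
    ub$unbound[2] <- TRUE
    expect_identical(verdict(classifyStability(ub)), "excluded_unbinding")
    expect_error(classifyStability(ok[0, ]), "at least one replica")
})
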