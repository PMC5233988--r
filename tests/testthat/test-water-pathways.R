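pw <- pathwayDefinition("C-terminal", mouthPoint = c(0, 40, 0),
                        sitePoint = c(0, 20, 0), corridorRadius = 5)

waterPart <- function(n = 1) data.frame(
    role = "water_oxygen", chain = "W", resno = seq_len(n),
    resname = "HOH", atom = "OW")

pathTraj <- function(positions) {
    trajectoryFromFrames(lapply(positions, function(p) matrix(p, 1)),
                         waterPart(1))
}

test_that("transit counting follows the zone-sequence rule", {
    # static water far away: nothing
    tr <- pathTraj(rep(list(c(100, 100, 100)), 5))
    expect_identical(nrow(countTransits(tr, pw)), 0L)
    # scripted mouth -> corridor -> site: one inward transit
    tr <- pathTraj(list(c(0, 40, 0), c(0, 30, 0), c(0, 20, 0)))
    tt <- countTransits(tr, pw)
    expect_identical(nrow(tt), 1L)
    expect_identical(tt$direction, "inward")
    expect_lt(tt$entry_frame, tt$completion_frame)
    # enters the corridor then backs out through the mouth: no transit
    tr <- pathTraj(list(c(0, 40, 0), c(0, 30, 0), c(0, 40, 0),
                        c(0, 60, 0)))
    expect_identical(nrow(countTransits(tr, pw)), 0L)
    # leaving the corridor sideways resets the attempt
    tr <- pathTraj(list(c(0, 40, 0), c(0, 30, 0), c(20, 30, 0),
                        c(0, 20, 0)))
    expect_identical(nrow(countTransits(tr, pw)), 0L)
    # round trip: one inward then one outward, re-entries separate
    tr <- pathTraj(list(c(0, 40, 0), c(0, 30, 0), c(0, 20, 0),
                        c(0, 30, 0), c(0, 40, 0)))
    tt <- countTransits(tr, pw)
    expect_identical(tt$direction, c("inward", "outward"))
})

test_that("reversing frame order maps inward to outward one-to-one", {
    set.seed(7)
    for (k in 1:6) {
        # random walk biased along the corridor axis
        n <- 20
        pos <- matrix(0, n, 3)
        pos[1, ] <- c(0, 45, 0)
        for (f in 2:n)
            pos[f, ] <- pos[f - 1, ] + c(rnorm(1, 0, 2), rnorm(1, -2, 4),
                                         rnorm(1, 0, 2))
        tr <- pathTraj(asplit(pos, 1))
        rev_tr <- pathTraj(asplit(pos[n:1, ], 1))
        fwd <- countTransits(tr, pw)
        bwd <- countTransits(rev_tr, pw)
        expect_identical(sum(fwd$direction == "inward"),
                         sum(bwd$direction == "outward"))
        expect_identical(sum(fwd$direction == "outward"),
                         sum(bwd$direction == "inward"))
    }
})

test_that("resampling that keeps zone-visit frames preserves counts", {
    # a transit with redundant corridor frames: dropping some corridor
    # frames (order-preserving) must not change the event list
    pos <- list(c(0, 40, 0), c(0, 36, 0), c(0, 32, 0), c(0, 28, 0),
                c(0, 24, 0), c(0, 20, 0))
    full <- countTransits(pathTraj(pos), pw)
    thin <- countTransits(pathTraj(pos[c(1, 3, 6)]), pw)
    expect_identical(nrow(full), 1L)
    expect_identical(thin$direction, full$direction)
})

test_that("planted transit schedules are recovered exactly", {
    sched <- data.frame(water = 1:12, pathway = "C-terminal",
                        start = round(seq(2, 90, length.out = 12)))
    spec <- plantedStateSpec("3[EED]", sigma = 0.1, lambda = 0,
                             nFrames = 100, replicas = 1,
                             transits = sched, seed = 5)
    tr <- simulateTrajectory(spec)[[1]]
    tt <- countTransits(tr, syntheticPathways()[["C-terminal"]])
    expect_identical(sum(tt$direction == "inward"), 12L)
    # nothing leaks into the other corridors
    for (other in c("extracellular", "N-terminal"))
        expect_identical(nrow(countTransits(tr, syntheticPathways()[[other]])),
                         0L)
})

test_that("flux summaries compute replica statistics and the gate call", {
    fs <- fluxSummary(c(0, 0, 0, 0))
    expect_equal(fs@mean, 0)
    expect_identical(fs@gateCall, "closed")
    fs <- fluxSummary(c(12, 12, 12, 12))
    expect_equal(fs@mean, 12)
    expect_equal(fs@se, 0)
    expect_identical(fs@gateCall, "open")
    # open in some replicas, closed in others: large SE
    fs <- fluxSummary(c(0, 0, 20, 20))
    expect_equal(fs@mean, 10)
    expect_equal(fs@se, sd(c(0, 0, 20, 20)) / 2)
    expect_gt(fs@se, 5)
    expect_true(is.na(fluxSummary(3)@se))
    expect_error(fluxSummary(numeric(0)), "at least one")
    expect_error(fluxSummary(c(-1, 2)), "non-negative")
})

test_that("the glutamate gate association is detected from planted fluxes", {
    closed <- c("extracellular" = 0, "N-terminal" = 0, "C-terminal" = 0)
    fluxes <- list(
        "3[EEE]" = closed,
        "3[DEE]" = replace(closed, "extracellular", 15),
        "3[EDE]" = replace(closed, "N-terminal", 14),
        "3[EED]" = replace(closed, "C-terminal", 15))
    res <- gateAssociationTest(fluxes)
    expect_identical(res$direction$association[res$direction$site == "III"],
                     "Glu954 deprotonation opens C-terminal pathway")
    expect_identical(res$direction$association[res$direction$site == "I"],
                     "Glu779 deprotonation opens extracellular pathway")
    expect_identical(res$direction$association[res$direction$site == "II"],
                     "Glu327 deprotonation opens N-terminal pathway")
    expect_identical(nrow(res$exceptions), 0L)
    # all-equal fluxes: no association anywhere
    flat <- list("3[EEE]" = closed, "3[DEE]" = closed, "3[EDE]" = closed,
                 "3[EED]" = closed)
    res <- gateAssociationTest(flat)
    expect_true(all(res$direction$association == "no association"))
    # a 4-proton state with a deprotonated site glutamate but a closed
    # pathway is an exception to the water-gate pattern (4[022] has
    # Glu779 deprotonated — site I code 0 — yet shows no flux)
    fluxes[["4[022]"]] <- closed
    res <- gateAssociationTest(fluxes)
    expect_true(any(res$exceptions$state == "4[022]" &
                    res$exceptions$site == "I"))
    # missing contrast states are an error
    expect_error(gateAssociationTest(fluxes[c("3[EEE]", "3[DEE]")]),
                 "contrast")
})
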