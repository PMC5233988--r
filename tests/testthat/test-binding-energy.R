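toyLedger <- function() {
    energyLedger(data.frame(
        state = c("3[EEE]", "3[EEE]", "*"),
        replica = c(1L, 1L, 1L),
        fragment = c("full", "without_I", "ion"),
        energy = c(-5000, -4985, -10),
        unit = "kcal/mol"))
}

test_that("binding energy is the counterpoise fragment difference", {
    be <- bindingEnergy(toyLedger(), "3[EEE]", "I")
    expect_equal(be$dE, -5.0)
    expect_equal(be$strength, 5.0)
    expect_true(is.na(be$se))     # single replica: no standard error
    # non-interacting limit: E_full = E_without + E_ion -> dE = 0
    led <- energyLedger(data.frame(
        state = "1[E00]", replica = 1L,
        fragment = c("full", "without_II", "ion"),
        energy = c(-4995, -4985, -10), unit = "kcal/mol"))
    expect_equal(bindingEnergy(led, "1[E00]", "II")$dE, 0)
    # missing fragments are ledger errors
    expect_error(bindingEnergy(toyLedger(), "3[EEE]", "III"),
                 "missing fragment")
    expect_error(bindingEnergy(toyLedger(), "9[999]", "I"), "no 'full'")
})

test_that("planted strengths are recovered exactly at zero noise", {
    planted <- list("3[EEE]" = c(I = 185, II = 190, III = 172),
                    "4[E2E]" = c(I = 155, II = 160, III = 142))
    led <- simulateEnergyLedger(planted, hydrationStrength = 170,
                                noiseSD = 0, replicas = 3, seed = 8)
    for (sym in names(planted)) for (site in c("I", "II", "III")) {
        be <- bindingEnergy(led, sym, site)
        expect_equal(be$strength, unname(planted[[sym]][site]))
        expect_equal(be$se, 0)
    }
    expect_equal(hydrationEnergy(led)$strength, 170)
})

test_that("unit conversion round-trips and reference shifts cancel", {
    x <- c(-0.3, 0, 2.5)
    expect_equal(convertEnergy(convertEnergy(x, "hartree", "kcal/mol"),
                               "kcal/mol", "hartree"), x,
                 tolerance = 1e-9)
    expect_equal(convertEnergy(1, "hartree", "kcal/mol"), 627.509)
    expect_error(convertEnergy(1, "eV", "kcal/mol"), "units")
    # adding a constant to both E_full and E_without leaves dE unchanged
    led <- toyLedger()
    shifted <- ledgerEntries(led)
    idx <- shifted$fragment %in% c("full", "without_I")
    shifted$energy[idx] <- shifted$energy[idx] + 123.456
    expect_equal(bindingEnergy(energyLedger(shifted), "3[EEE]", "I")$dE,
                 bindingEnergy(led, "3[EEE]", "I")$dE, tolerance = 1e-12)
    # a hartree ledger reports in kcal/mol on request
    h <- ledgerEntries(led)
    h$energy <- h$energy / 627.509
    h$unit <- "hartree"
    expect_equal(bindingEnergy(energyLedger(h), "3[EEE]", "I",
                               unit = "kcal/mol")$strength, 5.0,
                 tolerance = 1e-9)
    # mixed units are rejected at construction
    bad <- ledgerEntries(led)
    bad$unit[1] <- "hartree"
    expect_error(energyLedger(bad), "one unit")
})

test_that("replica statistics match a brute-force reference", {
    set.seed(13)
    for (n in c(2, 5, 10)) {
        strengths <- 170 + rnorm(n, sd = 4)
        rows <- do.call(rbind, lapply(seq_len(n), function(r) data.frame(
            state = "3[02E]", replica = r,
            fragment = c("full", "without_I"),
            energy = c(-5000, -5000 + 10 + strengths[r]),
            unit = "kcal/mol")))
        rows <- rbind(rows, data.frame(state = "*", replica = 1L,
                                       fragment = "ion", energy = -10,
                                       unit = "kcal/mol"))
        be <- bindingEnergy(energyLedger(rows), "3[02E]", "I")
        # brute force: loops, no vectorised shortcuts
        mu <- 0
        for (s in strengths) mu <- mu + s / n
        ss <- 0
        for (s in strengths) ss <- ss + (s - mu)^2
        se <- sqrt(ss / (n - 1)) / sqrt(n)
        expect_equal(be$strength, mu, tolerance = 1e-12)
        expect_equal(be$se, se, tolerance = 1e-12)
    }
})

test_that("hydration replicas reproduce the closed-form standard error", {
    led <- simulateEnergyLedger(list(), hydrationStrength = 170,
                                noiseSD = 4.4, shellReplicas = 10, seed = 21)
    he <- hydrationEnergy(led)
    expect_identical(he$n, 10L)
    # the SE is exactly sample SD / sqrt(10) ...
    expect_equal(he$se, sd(he$perReplica$strength) / sqrt(10),
                 tolerance = 1e-12)
    # ... and with planted SD 4.4 its expectation is 4.4/sqrt(10) = 1.39;
    # the sample SD of 10 Gaussian draws has SD sigma/sqrt(2(n-1)) ~ 1.04,
    # so allow a 3-sigma band around 1.39 on the SE scale
    expect_equal(he$se, 4.4 / sqrt(10), tolerance = 0.75)
    expect_equal(he$strength, 170, tolerance = 5)
})

test_that("verdicts separate 3-proton binding from the 4-proton shift", {
    strengths <- data.frame(
        state = rep(c("3[EEE]", "4[E2E]"), each = 3),
        site = rep(c("I", "II", "III"), 2),
        strength = c(182, 185, 173,            # ~180 vs hydration 170
                     152, 155, 143))           # shifted by ~ -30
    v <- bindingVerdicts(strengths, hydrationStrength = 170, tolerance = 5)
    expect_true(v$states$bindable_from_water[v$states$state == "3[EEE]"])
    expect_false(v$states$bindable_from_water[v$states$state == "4[E2E]"])
    # release: similar-to-hydration (within tolerance) or weaker
    s <- data.frame(state = "3[EED]", site = c("I", "II", "III"),
                    strength = c(185, 190, 172))
    v <- bindingVerdicts(s, 170, tolerance = 5)
    expect_identical(v$sites$releasable, c(FALSE, FALSE, TRUE))
    expect_true(bindingVerdicts(data.frame(state = "x", site = "III",
                                           strength = 150), 170,
                                tolerance = 5)$sites$releasable)
})

test_that("ledgers round-trip through TSV and feed the full report", {
    led <- simulateEnergyLedger(
        list("3[EEE]" = c(I = 185, II = 190, III = 178),
             "4[022]" = c(I = 150, II = 152, III = 148)),
        hydrationStrength = 170, noiseSD = 2, replicas = 3, seed = 17)
    f <- withr::local_tempfile(fileext = ".tsv")
    writeEnergyLedger(led, f)
    back <- readEnergyLedger(f)
    expect_equal(ledgerEntries(back)$energy, ledgerEntries(led)$energy)
    rep <- bindingEnergyReport(back)
    expect_identical(nrow(rep@perSite), 6L)
    expect_true(rep@verdicts$bindable_from_water[
        rep@verdicts$state == "3[EEE]"])
    expect_false(rep@verdicts$bindable_from_water[
        rep@verdicts$state == "4[022]"])
})
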