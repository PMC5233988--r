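test_that("residue selection applies the oxygen-radius plus adjacency rule", {
    # ion 2.3 A above the O of residue 322; O of 321/323 are ~4.4 A away
    st <- toyChainStructure(320:324,
                            ions = matrix(toyChainO(322) + c(0, 2.3, 0), 1))
    sel <- selectClusterResidues(st)
    expect_identical(sel$resno, c(321L, 322L, 323L))  # hit + adjacency
    # tighter radius drops everything (with a warning)
    expect_warning(sel0 <- selectClusterResidues(st, hydrationRadius = 1),
                   "no residue")
    expect_identical(nrow(sel0), 0L)
    # a larger radius reaches the neighbours directly, same deterministic order
    sel2 <- selectClusterResidues(st, hydrationRadius = 4.6)
    expect_identical(sel2$resno, c(320L, 321L, 322L, 323L, 324L))
})

test_that("net charge is ion count minus deprotonated included acids", {
    resnos <- c(327, 779, 804, 808, 926, 954)
    resnames <- c("GLU", "GLU", "ASP", "ASP", "ASP", "GLU")
    ions <- rbind(toyChainO(327) + c(0, 2, 0), toyChainO(779) + c(0, 2, 0),
                  toyChainO(926) + c(0, 2, 0))
    st <- toyChainStructure(resnos, resnames, ions = ions)
    residues <- data.frame(chain = "A", resno = resnos, resname = resnames)
    cm0 <- carveCluster(st, residues, decodeSymbol("0[000]"))
    expect_identical(cm0@netCharge, -3L)            # +3 ions - 6 acids
    cm3 <- carveCluster(st, residues, decodeSymbol("3[EEE]"))
    expect_identical(cm3@netCharge, 0L)             # +3 ions - 3 acids
    # +1 per additional protonated acidic residue
    for (sym in c("1[E00]", "2[EE0]", "4[220]", "6[222]")) {
        cm <- carveCluster(st, residues, decodeSymbol(sym))
        expect_identical(cm@netCharge,
                         as.integer(3L - (6L - nProtons(decodeSymbol(sym)))))
    }
    # acidic residues outside the registry count as deprotonated
    stray <- toyChainStructure(c(resnos, 500), c(resnames, "ASP"),
                               ions = ions)
    cmS <- carveCluster(stray, rbind(residues,
                        data.frame(chain = "A", resno = 500,
                                   resname = "ASP")), decodeSymbol("3[EEE]"))
    expect_identical(cmS@netCharge, -1L)
})

test_that("severed peptide bonds are capped and alpha carbons frozen", {
    ion <- matrix(toyChainO(326) + c(0, 2, 0), 1)
    st <- toyChainStructure(320:330, ions = ion)
    res1 <- data.frame(chain = "A", resno = 325:327, resname = "ALA")
    cm <- carveCluster(st, res1, decodeSymbol("0[000]"))
    expect_identical(sum(cm@atoms$source == "cap"), 2L)  # one per terminus
    expect_identical(length(cm@frozen), 3L)
    expect_true(all(cm@atoms$atom[cm@frozen] == "CA"))
    # cap geometry: 1.09 A from the kept backbone atom
    caps <- cm@atoms[cm@atoms$source == "cap", ]
    n325 <- cm@atoms[cm@atoms$resno == 325 & cm@atoms$atom == "N", ]
    d <- sqrt(sum((as.numeric(caps[1, c("x", "y", "z")]) -
                   as.numeric(n325[, c("x", "y", "z")]))^2))
    expect_equal(d, 1.09, tolerance = 1e-9)
    # two interior fragments -> 2 caps each
    res2 <- data.frame(chain = "A", resno = c(322, 323, 326, 327),
                       resname = "ALA")
    cm2 <- carveCluster(st, res2, decodeSymbol("0[000]"))
    expect_identical(sum(cm2@atoms$source == "cap"), 4L)
    # true chain termini get no cap
    res3 <- data.frame(chain = "A", resno = 320:330, resname = "ALA")
    cm3 <- carveCluster(st, res3, decodeSymbol("0[000]"))
    expect_identical(sum(cm3@atoms$source == "cap"), 0L)
    # missing residues are carve errors naming the residue
    expect_error(carveCluster(st, data.frame(chain = "A", resno = 999,
                                             resname = "ALA"),
                              decodeSymbol("0[000]")), "999")
})

test_that("carving is idempotent on an already-carved model", {
    ion <- matrix(toyChainO(326) + c(0, 2, 0), 1)
    wat <- matrix(toyChainO(326) + c(0, 4, 0), 1)
    st <- toyChainStructure(320:330, ions = ion, waters = wat)
    res <- data.frame(chain = "A", resno = 325:327, resname = "ALA")
    cm <- carveCluster(st, res, decodeSymbol("0[000]"))
    # rebuild a structure from the carved atoms and carve again
    part <- data.frame(
        role = c(residue = "protein_atom", ion = "ion",
                 water = "water_oxygen", cap = "protein_atom")[
                     cm@atoms$source],
        chain = cm@atoms$chain, resno = cm@atoms$resno,
        resname = cm@atoms$resname, atom = cm@atoms$atom)
    st2 <- ionTrajectory(as.matrix(cm@atoms[, c("x", "y", "z")]), part)
    cm2 <- carveCluster(st2, res, decodeSymbol("0[000]"))
    expect_identical(nrow(cm2@atoms), nrow(cm@atoms))
    expect_identical(sum(cm2@atoms$source == "cap"), 0L)  # none added anew
    expect_identical(cm2@netCharge, cm@netCharge)
})

test_that("water shells keep whole molecules within the radius", {
    ion <- matrix(c(0, 0, 0), 1)
    wat <- rbind(c(3, 0, 0), c(5, 0, 0), c(0, 8, 0),    # inside 9 A
                 c(12, 0, 0), c(0, 0, 20))              # outside
    st <- toyChainStructure(320, ions = ion, waters = wat)
    ws <- extractWaterShell(st, radius = 9)
    expect_identical(length(unique(ws@waters$resno)), 3L)
    expect_identical(length(unique(extractWaterShell(st,
                     radius = 0.1)@waters$resno)), 0L)
    # bulk water at ~1/32 waters per cubic Angstrom: a 9 A shell holds on
    # the order of a hundred waters
    set.seed(4)
    n <- 2000  # 40^3 A^3 box at bulk density
    bulk <- toyChainStructure(320, ions = matrix(c(0, 0, 0), 1),
                              waters = matrix(runif(3 * n, -20, 20), ncol = 3))
    nShell <- length(unique(extractWaterShell(bulk, radius = 9)@waters$resno))
    expect_gt(nShell, 60)
    expect_lt(nShell, 160)
})

test_that("deck emission is complete and byte-stable", {
    ion <- matrix(toyChainO(326) + c(0, 2, 0), 1)
    st <- toyChainStructure(324:328, ions = ion)
    res <- data.frame(chain = "A", resno = 325:327, resname = "ALA")
    cm <- carveCluster(st, res, decodeSymbol("0[000]"))
    d <- withr::local_tempdir()
    d1 <- file.path(d, "run1"); d2 <- file.path(d, "run2")
    dir.create(d1); dir.create(d2)
    writeQMDeck(cm, file.path(d1, "model.xyz"), file.path(d1, "model.deck"))
    xyz <- readLines(file.path(d1, "model.xyz"))
    expect_identical(as.integer(xyz[1]), nrow(cm@atoms))
    expect_identical(length(xyz) - 2L, nrow(cm@atoms))
    deck <- readLines(file.path(d1, "model.deck"))
    expect_identical(grep("^charge 1$", deck), 3L)  # 1 ion, no acids included
    expect_identical(sub("^frozen ", "", grep("^frozen", deck, value = TRUE)),
                     paste(cm@frozen, collapse = " "))
    writeQMDeck(cm, file.path(d2, "model.xyz"), file.path(d2, "model.deck"))
    expect_identical(readLines(file.path(d2, "model.xyz")), xyz)
    expect_identical(readLines(file.path(d2, "model.deck")), deck)
    # a water shell deck carries the cation charge
    ws <- extractWaterShell(toyChainStructure(320,
              ions = matrix(c(0, 0, 0), 1),
              waters = matrix(c(3, 0, 0), 1)))
    writeQMDeck(ws, file.path(d, "w.xyz"), file.path(d, "w.deck"))
    expect_true(any(readLines(file.path(d, "w.deck")) == "charge 1"))
})
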