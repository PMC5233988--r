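# Independent brute-force references and toy-structure builders used across
# the suite.  These deliberately avoid the package's vectorised code paths.

# double-loop RMSF: for each ion, mean position then mean squared deviation
bruteRMSF <- function(traj, frames) {
    ions <- which(particles(traj)$role == "ion")
    out <- numeric(length(ions))
    for (j in seq_along(ions)) {
        i <- ions[j]
        mu <- c(0, 0, 0)
        for (f in frames) mu <- mu + traj@coords[i, , f]
        mu <- mu / length(frames)
        acc <- 0
        for (f in frames) acc <- acc + sum((traj@coords[i, , f] - mu)^2)
        out[j] <- sqrt(acc / length(frames))
    }
    list(perIon = out, mean = mean(out))
}

# double-loop unique-water count within cutoff of any ion
bruteNwater <- function(traj, frames, cutoff = 5) {
    ions <- which(particles(traj)$role == "ion")
    wats <- which(particles(traj)$role == "water_oxygen")
    counts <- integer(length(frames))
    for (k in seq_along(frames)) {
        f <- frames[k]
        n <- 0L
        for (w in wats) {
            near <- FALSE
            for (i in ions) {
                d <- sqrt(sum((traj@coords[w, , f] - traj@coords[i, , f])^2))
                if (d <= cutoff) near <- TRUE
            }
            if (near) n <- n + 1L
        }
        counts[k] <- n
    }
    list(perFrame = counts, mean = mean(counts))
}

# small random trajectory (<= 10 frames, <= 20 particles) for oracle checks
randomTinyTrajectory <- function(nIons = 3, nWaters = 10, nFrames = 8) {
    coords <- array(runif((nIons + nWaters) * 3 * nFrames, -6, 6),
                    c(nIons + nWaters, 3, nFrames))
    part <- data.frame(
        role = c(rep("ion", nIons), rep("water_oxygen", nWaters)),
        chain = c(rep("A", nIons), rep("W", nWaters)),
        resno = seq_len(nIons + nWaters),
        resname = c(rep("SOD", nIons), rep("HOH", nWaters)),
        atom = c(rep("NA", nIons), rep("OW", nWaters)),
        stringsAsFactors = FALSE)
    ionTrajectory(coords, part)
}

# a trajectory with explicit per-frame coordinates for a single particle set
trajectoryFromFrames <- function(frames, part) {
    coords <- array(0, c(nrow(part), 3, length(frames)))
    for (f in seq_along(frames)) coords[, , f] <- frames[[f]]
    ionTrajectory(coords, part)
}

# toy peptide chain: residues `resnos` on one chain with N/CA/C/O backbone
# atoms, plus optional ions and water oxygens at given positions
toyChainStructure <- function(resnos, resnames = NULL, ions = NULL,
                              waters = NULL) {
    if (is.null(resnames)) resnames <- rep("ALA", length(resnos))
    rows <- list(); coords <- list()
    for (k in seq_along(resnos)) {
        rn <- resnos[k]
        base <- c(rn * 3.8, 0, 0)
        for (a in c("N", "CA", "C", "O")) {
            off <- switch(a, N = c(-1.2, 0.5, 0), CA = c(0, 0, 0),
                          C = c(1.2, 0.4, 0), O = c(1.4, 1.6, 0))
            rows[[length(rows) + 1]] <- data.frame(
                role = "protein_atom", chain = "A", resno = rn,
                resname = resnames[k], atom = a)
            coords[[length(coords) + 1]] <- base + off
        }
    }
    if (!is.null(ions)) for (i in seq_len(nrow(ions))) {
        rows[[length(rows) + 1]] <- data.frame(
            role = "ion", chain = "A", resno = 900 + i, resname = "SOD",
            atom = "NA")
        coords[[length(coords) + 1]] <- as.numeric(ions[i, ])
    }
    if (!is.null(waters)) for (i in seq_len(nrow(waters))) {
        rows[[length(rows) + 1]] <- data.frame(
            role = "water_oxygen", chain = "W", resno = i, resname = "HOH",
            atom = "OW")
        coords[[length(coords) + 1]] <- as.numeric(waters[i, ])
    }
    ionTrajectory(do.call(rbind, coords), do.call(rbind, rows))
}

# oxygen position of the toy chain's residue rn (used to place ions)
toyChainO <- function(rn) c(rn * 3.8 + 1.4, 1.6, 0)

# single-site registry around the toy chain's Glu327/Asp (for carving tests)
toyRegistry <- function() {
    bindingSiteRegistry(list(
        I = list(glu = list(chain = "A", resno = 327, resname = "GLU"),
                 asp = list(chain = "A", resno = 333, resname = "ASP"))))
}
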