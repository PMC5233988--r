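atomElement <- function(atom, role = NULL) {
    el <- toupper(substr(sub("^[0-9]*", "", atom), 1, 1))
    isIon <- atom %in% c("NA", "SOD")
    if (!is.null(role)) isIon <- isIon | role == "ion"
    ifelse(isIon, "Na", el)
}

frameAtoms <- function(traj, frame) {
    p <- traj@particles
    data.frame(p, x = traj@coords[, 1, frame], y = traj@coords[, 2, frame],
               z = traj@coords[, 3, frame], idx = seq_len(nrow(p)),
               stringsAsFactors = FALSE)
}

#' Select residues for the binding-pocket quantum-cluster model
#'
#' Returns the residues contributing any oxygen atom within the sodium
#' hydration radius (default 2.5 Angstrom) of any bound ion, plus residues
#' sequence-adjacent to them (residue number +/- 1 on the same chain).
#' Applied to the full pump structure this rule targets the published
#' 19-residue pocket model; the radius is exposed so users can calibrate
#' against their own structures.
#'
#' @param structure an [IonTrajectory-class] (a single-frame snapshot or a
#'   trajectory; `frame` selects the snapshot, default the last frame).
#' @param hydrationRadius selection radius in Angstrom (default 2.5).
#' @param frame frame index of the snapshot to use.
#' @return data.frame of selected residues (`chain`, `resno`, `resname`),
#'   ordered by chain then residue number; zero rows (with a warning) when
#'   nothing qualifies.
#' @export
selectClusterResidues <- function(structure, hydrationRadius = 2.5,
                                  frame = nFrames(structure)) {
    stopifnot(hydrationRadius > 0)
    at <- frameAtoms(structure, frame)
    ions <- at[at$role == "ion", ]
    if (!nrow(ions)) stop("structure contains no ion particles")
    prot <- at[at$role == "protein_atom", ]
    oxy <- prot[substr(prot$atom, 1, 1) == "O", ]
    hit <- character(0)
    if (nrow(oxy)) {
        d <- pairDistances(as.matrix(oxy[, c("x", "y", "z")]),
                           as.matrix(ions[, c("x", "y", "z")]),
                           structure@box)
        hit <- unique(paste(oxy$chain, oxy$resno)[apply(d, 1, min) <=
                                                  hydrationRadius])
    }
    if (!length(hit)) {
        warning("no residue has an oxygen atom within ", hydrationRadius,
                " A of an ion")
        return(data.frame(chain = character(), resno = integer(),
                          resname = character()))
    }
    present <- unique(prot[, c("chain", "resno", "resname")])
    key <- paste(present$chain, present$resno)
    keep <- key %in% hit
    for (h in hit) {  # sequence-adjacent residues (+/- 1, same chain)
        parts <- strsplit(h, " ")[[1]]
        adj <- paste(parts[1], as.integer(parts[2]) + c(-1L, 1L))
        keep <- keep | key %in% adj
    }
    sel <- present[keep, , drop = FALSE]
    sel <- sel[order(sel$chain, sel$resno), , drop = FALSE]
    sel$resno <- as.integer(sel$resno)
    rownames(sel) <- NULL
    sel
}

#' Carve a capped quantum-cluster model of the binding pocket
#'
#' Extracts the listed residues (whole residues: backbone plus side chain),
#' the bound ions, and every water molecule whose oxygen lies within
#' `waterCutoff` of any ion.  Every severed peptide bond is capped with a
#' hydrogen placed along the severed-bond vector at `capLength` from the
#' kept backbone atom; alpha carbons of all included residues are frozen.
#' The net formal charge is `+1 x ions - deprotonated included Glu/Asp side
#' chains + otherCharges`, with protonation read from `protonation`
#' (acidic residues absent from the registry count as deprotonated).
#'
#' @param structure an [IonTrajectory-class] snapshot source.
#' @param residues data.frame (`chain`, `resno`, ...) as returned by
#'   [selectClusterResidues()].
#' @param protonation a [ProtonationState-class].
#' @param registry the [BindingSiteRegistry-class] behind `protonation`.
#' @param waterCutoff water inclusion cutoff in Angstrom (default 5).
#' @param frame snapshot frame (default last).
#' @param otherCharges additional formal charges in e (default 0).
#' @param capLength cap bond length in Angstrom (default 1.09, a standard
#'   C-H/N-H geometry).
#' @param multiplicity spin multiplicity (default 1, closed shell).
#' @return a [ClusterModel-class].
#' @export
carveCluster <- function(structure, residues, protonation,
                         registry = nkaRegistry(), waterCutoff = 5,
                         frame = nFrames(structure), otherCharges = 0L,
                         capLength = 1.09, multiplicity = 1L) {
    stopifnot(waterCutoff > 0)
    at <- frameAtoms(structure, frame)
    ions <- at[at$role == "ion", ]
    # residue atoms, in the requested (chain, resno) order
    resAtoms <- list()
    for (i in seq_len(nrow(residues))) {
        sel <- at[at$chain == residues$chain[i] &
                  at$resno == residues$resno[i] &
                  at$role %in% c("protein_atom", "other") &
                  !(at$resname %in% pdbNameSets()$water), , drop = FALSE]
        if (!nrow(sel))
            stop("carve error: no atoms found for residue ",
                 residues$chain[i], ":", residues$resno[i])
        resAtoms[[i]] <- sel
    }
    resAtoms <- do.call(rbind, resAtoms)
    # waters with oxygen within cutoff of any ion, kept as whole molecules
    watO <- at[at$role == "water_oxygen", ]
    watAtoms <- at[0, ]
    if (nrow(watO) && nrow(ions)) {
        d <- pairDistances(as.matrix(watO[, c("x", "y", "z")]),
                           as.matrix(ions[, c("x", "y", "z")]),
                           structure@box)
        near <- watO[apply(d, 1, min) <= waterCutoff, ]
        keyNear <- unique(paste(near$chain, near$resno))
        isWat <- at$resname %in% pdbNameSets()$water
        watAtoms <- at[isWat & paste(at$chain, at$resno) %in% keyNear, ,
                       drop = FALSE]
    }
    mkAtoms <- function(df, source) {
        if (!nrow(df)) return(NULL)
        data.frame(element = atomElement(df$atom, df$role),
                   x = df$x, y = df$y, z = df$z, source = source,
                   chain = df$chain, resno = df$resno, resname = df$resname,
                   atom = df$atom, stringsAsFactors = FALSE)
    }
    atoms <- rbind(mkAtoms(resAtoms, "residue"), mkAtoms(ions, "ion"),
                   mkAtoms(watAtoms, "water"))
    # cap severed peptide bonds: fragments are runs of consecutive residue
    # numbers per chain; a bond is severed when the neighbouring residue
    # exists in the source structure but is not part of the cluster
    caps <- list()
    prot <- at[at$role == "protein_atom", ]
    structKey <- unique(paste(prot$chain, prot$resno))
    inCluster <- paste(residues$chain, residues$resno)
    backboneAtom <- function(chain, resno, name) {
        row <- at[at$chain == chain & at$resno == resno & at$atom == name, ]
        if (!nrow(row)) return(NULL)
        as.numeric(row[1, c("x", "y", "z")])
    }
    addCap <- function(chain, resno, resname, keepName, neighResno, neighName) {
        anchor <- backboneAtom(chain, resno, keepName)
        neigh <- backboneAtom(chain, neighResno, neighName)
        if (is.null(anchor) || is.null(neigh))
            stop("carve error: missing backbone atoms to cap residue ",
                 chain, ":", resno)
        u <- (neigh - anchor) / sqrt(sum((neigh - anchor)^2))
        pos <- anchor + capLength * u
        data.frame(element = "H", x = pos[1], y = pos[2], z = pos[3],
                   source = "cap", chain = chain, resno = resno,
                   resname = resname, atom = "HC", stringsAsFactors = FALSE)
    }
    for (i in seq_len(nrow(residues))) {
        ch <- residues$chain[i]; rn <- residues$resno[i]
        rname <- residues$resname[i]
        prevIn <- paste(ch, rn - 1L) %in% inCluster
        nextIn <- paste(ch, rn + 1L) %in% inCluster
        hasCap <- paste(ch, rn, "HC") %in%
            paste(at$chain, at$resno, at$atom)
        if (hasCap) next  # already-carved input: bonds were capped before
        if (!prevIn && paste(ch, rn - 1L) %in% structKey)
            caps[[length(caps) + 1L]] <- addCap(ch, rn, rname, "N",
                                                rn - 1L, "C")
        if (!nextIn && paste(ch, rn + 1L) %in% structKey)
            caps[[length(caps) + 1L]] <- addCap(ch, rn, rname, "C",
                                                rn + 1L, "N")
    }
    if (length(caps)) atoms <- rbind(atoms, do.call(rbind, caps))
    rownames(atoms) <- NULL
    frozen <- which(atoms$source == "residue" & atoms$atom == "CA")
    # formal charge bookkeeping
    acidic <- unique(atoms[atoms$source == "residue" &
                           atoms$resname %in% c("GLU", "ASP"),
                           c("chain", "resno", "resname")])
    flags <- protonationFlags(protonation)
    reg <- registryResidues(registry)
    deprot <- 0L
    for (i in seq_len(nrow(acidic))) {
        hit <- reg$label[reg$chain == acidic$chain[i] &
                         reg$resno == acidic$resno[i]]
        protonated <- length(hit) == 1L && isTRUE(flags[[hit]])
        if (!protonated) deprot <- deprot + 1L
    }
    netCharge <- as.integer(sum(atoms$source == "ion") - deprot +
                            otherCharges)
    new("ClusterModel", atoms = atoms,
        residues = residues[, intersect(c("chain", "resno", "resname"),
                                        names(residues)), drop = FALSE],
        frozen = as.integer(frozen), netCharge = netCharge,
        multiplicity = as.integer(multiplicity))
}

setMethod("show", "ClusterModel", function(object) {
    cat(sprintf(
        "ClusterModel: %d atoms (%d residue, %d ion, %d water, %d cap)\n",
        nrow(object@atoms), sum(object@atoms$source == "residue"),
        sum(object@atoms$source == "ion"),
        sum(object@atoms$source == "water"),
        sum(object@atoms$source == "cap")))
    cat(sprintf("  %d residues, %d frozen alpha carbons, charge %+d e, 2S+1 = %d\n",
                nrow(object@residues), length(object@frozen),
                object@netCharge, object@multiplicity))
    invisible(NULL)
})

#' Extract a single-ion water shell
#'
#' Keeps every water molecule whose oxygen lies within `radius` of the
#' chosen ion (default 9 Angstrom, sized to match the pocket cluster's
#' ~340 atoms with on the order of a hundred waters).
#'
#' @param structure an [IonTrajectory-class] snapshot source containing the
#'   ion and solvent.
#' @param ion particle index of the central ion; default the first ion.
#' @param radius shell radius in Angstrom (default 9).
#' @param frame snapshot frame (default last).
#' @return a [WaterShellModel-class].
#' @export
extractWaterShell <- function(structure, ion = ionIndices(structure)[1],
                              radius = 9, frame = nFrames(structure)) {
    stopifnot(radius > 0, length(ion) == 1L, !is.na(ion))
    at <- frameAtoms(structure, frame)
    ionRow <- at[ion, ]
    watO <- at[at$role == "water_oxygen", ]
    keyNear <- character(0)
    if (nrow(watO)) {
        d <- pairDistances(as.matrix(watO[, c("x", "y", "z")]),
                           matrix(as.numeric(ionRow[, c("x", "y", "z")]),
                                  ncol = 3), structure@box)
        keyNear <- unique(paste(watO$chain, watO$resno)[d[, 1] <= radius])
    }
    isWat <- at$resname %in% pdbNameSets()$water
    shell <- at[isWat & paste(at$chain, at$resno) %in% keyNear, ,
                drop = FALSE]
    waters <- data.frame(element = atomElement(shell$atom),
                         x = shell$x, y = shell$y, z = shell$z,
                         resno = shell$resno, atom = shell$atom,
                         stringsAsFactors = FALSE)
    rownames(waters) <- NULL
    new("WaterShellModel",
        ionPosition = as.numeric(ionRow[, c("x", "y", "z")]),
        ionElement = atomElement(ionRow$atom, ionRow$role),
        waters = waters, radius = radius)
}

setMethod("show", "WaterShellModel", function(object) {
    cat(sprintf("WaterShellModel: %s ion + %d waters within %g A\n",
                object@ionElement, length(unique(object@waters$resno)),
                object@radius))
    invisible(NULL)
})

#' Emit engine-agnostic quantum-chemistry input files
#'
#' Writes an XYZ coordinates file and a plain-text deck with charge, spin
#' multiplicity, frozen-atom indices and method keywords.  Output is
#' byte-stable: identical models and settings give identical files.
#'
#' @param model a [ClusterModel-class] or [WaterShellModel-class].
#' @param xyzFile,deckFile output paths.
#' @param settings named list of method keywords written verbatim into the
#'   deck (default B3LYP / 6-31G** with empirical dispersion, the level
#'   used for pocket-model optimisations).
#' @param title comment line for the XYZ file.
#' @return invisibly, `c(xyz = xyzFile, deck = deckFile)`.
#' @export
writeQMDeck <- function(model, xyzFile, deckFile,
                        settings = list(method = "B3LYP",
                                        basis = "6-31G**",
                                        dispersion = "GD3"),
                        title = "cluster model") {
    if (is(model, "ClusterModel")) {
        atoms <- model@atoms[, c("element", "x", "y", "z")]
        charge <- model@netCharge
        mult <- model@multiplicity
        frozen <- model@frozen
    } else if (is(model, "WaterShellModel")) {
        atoms <- rbind(
            data.frame(element = model@ionElement,
                       x = model@ionPosition[1], y = model@ionPosition[2],
                       z = model@ionPosition[3]),
            model@waters[, c("element", "x", "y", "z")])
        charge <- 1L   # single monovalent cation in neutral water
        mult <- 1L
        frozen <- integer(0)
    } else stop("model must be a ClusterModel or WaterShellModel")
    if (is.na(charge)) stop("net charge is unset")
    if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
        stop("model coordinates must be finite")
    xyz <- c(sprintf("%d", nrow(atoms)), title,
             sprintf("%-2s %14.6f %14.6f %14.6f", atoms$element,
                     atoms$x, atoms$y, atoms$z))
    writeLines(xyz, xyzFile)
    deck <- c("# quantum-cluster input deck",
              sprintf("natoms %d", nrow(atoms)),
              sprintf("charge %d", charge),
              sprintf("multiplicity %d", mult),
              sprintf("frozen %s",
                      if (length(frozen)) paste(frozen, collapse = " ")
                      else "none"),
              vapply(names(settings), function(k)
                  sprintf("%s %s", k, settings[[k]]), character(1)),
              sprintf("coordinates %s", basename(xyzFile)))
    writeLines(deck, deckFile)
    invisible(c(xyz = xyzFile, deck = deckFile))
}
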