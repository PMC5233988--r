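#' Particle naming conventions for PDB input
#'
#' Residue/atom name sets used to classify particles when reading PDB files.
#' Waters are recognised by residue name, ions by residue or atom name.
#'
#' @param water residue names identifying water molecules.
#' @param ion residue or atom names identifying bound sodium ions.
#' @return a named list consumed by [readMultiModelPDB()].
#' @export
pdbNameSets <- function(water = c("HOH", "TIP3", "SOL", "WAT"),
                        ion = c("NA", "SOD")) {
    list(water = water, ion = ion)
}

classifyRole <- function(resname, atom, nameSets) {
    role <- rep("protein_atom", length(resname))
    isWater <- resname %in% nameSets$water
    role[isWater] <- "other"                       # water hydrogens etc.
    role[isWater & substr(atom, 1, 1) == "O"] <- "water_oxygen"
    role[resname %in% nameSets$ion | atom %in% nameSets$ion] <- "ion"
    role
}

#' Read a (multi-model) PDB file as an IonTrajectory
#'
#' Each `MODEL`/`ENDMDL` block becomes one frame; a file without `MODEL`
#' records yields a single-frame trajectory (a static snapshot).  All models
#' must contain the same particles in the same order.  Frame times are taken
#' from `REMARK TIME=<ps>` lines when present, otherwise spaced by
#' `samplingInterval`.
#'
#' @param file path to the PDB file.
#' @param nameSets particle-classification name sets from [pdbNameSets()].
#' @param samplingInterval frame spacing in ps used when the file carries no
#'   time remarks (default 50 ps).
#' @return an [IonTrajectory-class].
#' @export
readMultiModelPDB <- function(file, nameSets = pdbNameSets(),
                              samplingInterval = 50) {
    lines <- readLines(file)
    isAtom <- startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")
    modelStarts <- which(startsWith(lines, "MODEL"))
    box <- numeric(0)
    cryst <- which(startsWith(lines, "CRYST1"))
    if (length(cryst)) {
        l <- lines[cryst[1]]
        box <- as.numeric(c(substr(l, 7, 15), substr(l, 16, 24),
                            substr(l, 25, 33)))
        if (anyNA(box) || all(box == 1)) box <- numeric(0)  # placeholder cell
    }
    frameOf <- if (length(modelStarts)) {
        findInterval(seq_along(lines), modelStarts)
    } else rep(1L, length(lines))
    atomLines <- lines[isAtom]
    atomFrame <- frameOf[isAtom]
    if (any(atomFrame == 0L))
        stop("ATOM records found before the first MODEL record in ", file)
    nFr <- max(atomFrame)
    perFrame <- tabulate(atomFrame, nFr)
    if (length(unique(perFrame)) != 1L)
        stop("models differ in atom count in ", file)
    nAt <- perFrame[1]
    first <- atomLines[atomFrame == 1L]
    part <- data.frame(
        role = character(nAt),
        chain = trimws(substr(first, 22, 22)),
        resno = as.integer(substr(first, 23, 26)),
        resname = trimws(substr(first, 18, 21)),
        atom = trimws(substr(first, 13, 16)),
        stringsAsFactors = FALSE)
    part$chain[part$chain == ""] <- "A"
    part$role <- classifyRole(part$resname, part$atom, nameSets)
    xyz <- cbind(as.numeric(substr(atomLines, 31, 38)),
                 as.numeric(substr(atomLines, 39, 46)),
                 as.numeric(substr(atomLines, 47, 54)))
    if (anyNA(xyz)) stop("unparsable coordinates in ", file)
    coords <- array(NA_real_, c(nAt, 3L, nFr))
    for (f in seq_len(nFr)) coords[, , f] <- xyz[atomFrame == f, , drop = FALSE]
    tl <- grep("^REMARK +TIME= *", lines, value = TRUE)
    times <- if (length(tl) == nFr)
        as.numeric(sub("^REMARK +TIME= *", "", tl))
    else (seq_len(nFr) - 1L) * samplingInterval
    new("IonTrajectory", coords = coords, particles = part,
        times = times, box = box)
}

#' Write an IonTrajectory as a multi-model PDB file
#'
#' Emits one `MODEL`/`ENDMDL` block per frame with a `REMARK TIME=` line
#' carrying the frame time in ps, so [readMultiModelPDB()] round-trips the
#' trajectory (coordinates at the format's 3-decimal precision).
#'
#' @param traj an [IonTrajectory-class].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeMultiModelPDB <- function(traj, file) {
    p <- traj@particles
    element <- ifelse(p$role == "ion", "NA",
                      toupper(substr(sub("^[0-9]*", "", p$atom), 1, 1)))
    name4 <- ifelse(nchar(p$atom) < 4, sprintf(" %-3s", p$atom),
                    substr(p$atom, 1, 4))
    rec <- ifelse(p$role == "protein_atom", "ATOM  ", "HETATM")
    con <- file(file, "w")
    on.exit(close(con))
    if (length(traj@box) == 3L)
        writeLines(sprintf(
            "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
            traj@box[1], traj@box[2], traj@box[3], 90, 90, 90), con)
    for (f in seq_len(nFrames(traj))) {
        writeLines(sprintf("MODEL     %4d", f), con)
        writeLines(sprintf("REMARK TIME= %.3f", traj@times[f]), con)
        writeLines(sprintf(
            "%s%5d %s %-4s%1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            rec, seq_len(nrow(p)) %% 100000L, name4, substr(p$resname, 1, 4),
            p$chain, p$resno, traj@coords[, 1, f], traj@coords[, 2, f],
            traj@coords[, 3, f], element), con)
        writeLines("ENDMDL", con)
    }
    writeLines("END", con)
    invisible(file)
}
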