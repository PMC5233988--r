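#' Define a water pathway corridor
#'
#' @param name pathway name: "extracellular", "N-terminal" or "C-terminal".
#' @param mouthPoint,sitePoint corridor endpoints (3-vectors, Angstrom);
#'   in real use these come from tunnel-finding output (e.g. CAVER), which
#'   is outside this package's scope.
#' @param corridorRadius corridor/zone radius in Angstrom (default 5).
#' @param associatedSite binding site gated by this pathway; defaults to the
#'   canonical association (extracellular - I, N-terminal - II,
#'   C-terminal - III).
#' @return a [PathwayDefinition-class].
#' @export
pathwayDefinition <- function(name, mouthPoint, sitePoint,
                              corridorRadius = 5,
                              associatedSite = sitePathwayMap()[
                                  match(name, names(sitePathwayMap()))]) {
    if (is.na(associatedSite))
        stop("associatedSite must be given for non-canonical pathway names")
    new("PathwayDefinition", name = name,
        mouthPoint = as.numeric(mouthPoint),
        sitePoint = as.numeric(sitePoint),
        corridorRadius = corridorRadius,
        associatedSite = unname(associatedSite))
}

#' Canonical pathway/site association
#'
#' The extracellular pathway runs near site I; the intracellular N- and
#' C-terminal pathways run near sites II and III.
#'
#' @return named character vector mapping pathway name to site label.
#' @export
sitePathwayMap <- function() {
    c("extracellular" = "I", "N-terminal" = "II", "C-terminal" = "III")
}

# zone label per frame for one particle: M (mouth sphere), S (site sphere),
# C (corridor cylinder between the endpoints), O (outside)
pathwayZones <- function(xyz, pathway) {
    r <- pathway@corridorRadius
    dm <- sqrt(colSums((t(xyz) - pathway@mouthPoint)^2))
    ds <- sqrt(colSums((t(xyz) - pathway@sitePoint)^2))
    axis <- pathway@sitePoint - pathway@mouthPoint
    L <- sqrt(sum(axis^2))
    u <- axis / L
    rel <- sweep(xyz, 2, pathway@mouthPoint)
    tproj <- as.numeric(rel %*% u)
    perp <- sqrt(pmax(0, rowSums(rel^2) - tproj^2))
    z <- rep("O", nrow(xyz))
    z[tproj >= 0 & tproj <= L & perp <= r] <- "C"
    inM <- dm <= r
    inS <- ds <= r
    z[inM] <- "M"
    z[inS] <- "S"
    both <- inM & inS
    z[both] <- ifelse(dm[both] < ds[both], "M", "S")  # nearer zone wins
    z
}

#' Count water transits through a pathway
#'
#' A water scores one inward transit when it passes from the mouth zone
#' (sphere of the corridor radius about the mouth point) to the site zone
#' (sphere about the site point) while staying inside the corridor between
#' the two zone visits; leaving the corridor resets the attempt.  Outward
#' transits are the symmetric event, and repeated crossings by the same
#' water count separately.  This zone-sequence rule is this package's
#' declared operational definition of "water movement through a pathway";
#' it is order-based and parameter-light, not a reproduction of any
#' particular published counting script.
#'
#' @param traj an [IonTrajectory-class].
#' @param pathway a [PathwayDefinition-class].
#' @return data.frame of transit records: `water` (particle index),
#'   `pathway`, `entry_frame`, `completion_frame`, `direction`
#'   ("inward"/"outward"); zero rows when nothing crosses.
#' @export
setMethod("countTransits", c("IonTrajectory", "PathwayDefinition"),
    function(traj, pathway) {
    waters <- waterOxygenIndices(traj)
    rec <- list()
    for (w in waters) {
        xyz <- t(traj@coords[w, , , drop = TRUE])
        if (ncol(xyz) != 3L) xyz <- matrix(xyz, ncol = 3L)  # single frame
        z <- pathwayZones(xyz, pathway)
        pending <- NA_character_; entry <- NA_integer_
        for (f in seq_along(z)) {
            if (z[f] == "M") {
                if (identical(pending, "S"))
                    rec[[length(rec) + 1L]] <- data.frame(
                        water = w, pathway = pathway@name,
                        entry_frame = entry, completion_frame = f,
                        direction = "outward")
                pending <- "M"; entry <- f
            } else if (z[f] == "S") {
                if (identical(pending, "M"))
                    rec[[length(rec) + 1L]] <- data.frame(
                        water = w, pathway = pathway@name,
                        entry_frame = entry, completion_frame = f,
                        direction = "inward")
                pending <- "S"; entry <- f
            } else if (z[f] == "O") {
                pending <- NA_character_; entry <- NA_integer_
            }  # "C": attempt stays alive
        }
    }
    if (!length(rec))
        return(data.frame(water = integer(), pathway = character(),
                          entry_frame = integer(),
                          completion_frame = integer(),
                          direction = character()))
    do.call(rbind, rec)
})

#' Summarise per-replica transit counts for one pathway
#'
#' @param counts numeric vector of inward transit counts, one per replica
#'   (e.g. `nrow(subset(countTransits(...), direction == "inward"))`).
#' @param baseline gate-call criterion: the pathway is called "open" when
#'   the mean inward flux exceeds `baseline` transits per replica
#'   (default 1).
#' @return a [FluxSummary-class]; the standard error is `NA` with a single
#'   replica.
#' @export
fluxSummary <- function(counts, baseline = 1) {
    if (!length(counts)) stop("at least one replica count is required")
    if (any(counts < 0)) stop("transit counts must be non-negative")
    m <- mean(counts)
    se <- if (length(counts) >= 2L) stats::sd(counts) / sqrt(length(counts))
          else NA_real_
    new("FluxSummary", counts = as.numeric(counts), mean = m, se = se,
        gateCall = if (m > baseline) "open" else "closed",
        baseline = baseline)
}

setMethod("show", "FluxSummary", function(object) {
    cat(sprintf("FluxSummary: mean %.2f %s %s transits/replica (n = %d) -> gate %s\n",
                object@mean, "±",
                ifelse(is.na(object@se), "NA", sprintf("%.2f", object@se)),
                length(object@counts), object@gateCall))
    invisible(NULL)
})

#' Test the glutamate water-gate association
#'
#' Given per-state flux summaries for the proton-transfer contrast (a
#' reference state with all three site glutamates protonated versus the
#' states obtained by moving one proton from a site's Glu to its Asp,
#' e.g. 3[EEE] vs 3[DEE], 3[EDE], 3[EED]), tabulates, for each pathway,
#' the mean flux with the site's Glu protonated vs deprotonated and calls
#' the direction of change.  Additional states (e.g. 4-proton states) are
#' screened: a state whose site Glu is deprotonated yet whose pathway flux
#' stays at or below the baseline is flagged as an exception to the
#' water-gate pattern.
#'
#' @param fluxes named list: state symbol -> named numeric vector of mean
#'   inward flux per pathway (names from [sitePathwayMap()]), or
#'   [FluxSummary-class] objects in place of numbers.
#' @param reference symbol of the all-Glu-protonated reference state
#'   (default "3[EEE]").
#' @param registry a [BindingSiteRegistry-class].
#' @param baseline open/closed flux baseline (default 1).
#' @return list with `table` (pathway, site, state, glu_protonated,
#'   mean_flux), `direction` (pathway, association: "opens" /
#'   "no association"), and `exceptions` (states breaking the pattern).
#' @export
gateAssociationTest <- function(fluxes, reference = "3[EEE]",
                                registry = nkaRegistry(), baseline = 1) {
    getFlux <- function(sym, pw) {
        v <- fluxes[[sym]][[pw]]
        if (is(v, "FluxSummary")) v@mean else as.numeric(v)
    }
    if (!reference %in% names(fluxes))
        stop("reference state ", reference, " missing from fluxes")
    refState <- decodeSymbol(reference, registry)
    df <- registryResidues(registry)
    map <- sitePathwayMap()
    states <- lapply(names(fluxes), decodeSymbol, registry = registry)
    names(states) <- names(fluxes)
    tab <- list(); dir <- list(); exc <- list()
    for (site in siteLabels(registry)) {
        pw <- names(map)[map == site]
        if (!length(pw)) next  # site without a canonical pathway
        glu <- df$label[df$site == site & df$role == "glu"]
        asp <- df$label[df$site == site & df$role == "asp"]
        if (!protonationFlags(refState)[[glu]])
            stop("reference state must have the site-", site,
                 " glutamate protonated")
        # the E->D variant: reference with this site's proton moved Glu->Asp
        want <- protonationFlags(refState)
        want[[glu]] <- FALSE; want[[asp]] <- TRUE
        variant <- Filter(function(s) identical(protonationFlags(states[[s]]),
                                                want), names(states))
        if (!length(variant))
            stop("fluxes do not contain the Glu<->Asp contrast state for ",
                 "site ", site, " (expected ",
                 stateSymbol(encodeState(want, registry)), ")")
        fRef <- getFlux(reference, pw)
        fVar <- getFlux(variant[1], pw)
        tab[[length(tab) + 1L]] <- data.frame(
            pathway = pw, site = site,
            state = c(reference, variant[1]),
            glu_protonated = c(TRUE, FALSE),
            mean_flux = c(fRef, fVar))
        dir[[length(dir) + 1L]] <- data.frame(
            pathway = pw, site = site, glu = glu,
            association = if (fVar > fRef && fVar > baseline)
                sprintf("%s deprotonation opens %s pathway", glu, pw)
            else "no association")
        # extra states with this Glu deprotonated but a closed pathway
        for (s in setdiff(names(states), c(reference, variant[1]))) {
            if (!protonationFlags(states[[s]])[[glu]] &&
                !is.null(fluxes[[s]][[pw]]) &&
                getFlux(s, pw) <= baseline)
                exc[[length(exc) + 1L]] <- data.frame(
                    state = s, pathway = pw, site = site,
                    mean_flux = getFlux(s, pw),
                    note = sprintf(
                        "%s deprotonated but %s pathway closed", glu, pw))
        }
    }
    list(table = do.call(rbind, tab), direction = do.call(rbind, dir),
         exceptions = if (length(exc)) do.call(rbind, exc) else
             data.frame(state = character(), pathway = character(),
                        site = character(), mean_flux = numeric(),
                        note = character()))
}
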