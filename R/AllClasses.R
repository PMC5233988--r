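#' @import methods
NULL

#' BindingSiteRegistry: the titratable residues of the ion-binding pocket
#'
#' Holds the ordered map from binding-site labels (I, II, III) to their
#' glutamate/aspartate pair.  The default registry for the sodium pump is
#' built by [nkaRegistry()]: site I = (Glu779, Asp808), site II =
#' (Glu327, Asp804), site III = (Glu954, Asp926), numbered after the pig
#' kidney crystal structure.  Degenerate registries with fewer sites are
#' permitted so the symbol codec stays total.
#'
#' @slot residues data.frame with one row per titratable residue and columns
#'   `site` (site label), `role` ("glu" or "asp"), `chain`, `resno`,
#'   `resname` (3-letter code, GLU or ASP) and `label` (e.g. "Glu779").
#' @export
setClass("BindingSiteRegistry",
    representation(residues = "data.frame"))

setValidity("BindingSiteRegistry", function(object) {
    df <- object@residues
    need <- c("site", "role", "chain", "resno", "resname", "label")
    if (!all(need %in% names(df)))
        return(paste("residues must have columns:", paste(need, collapse = ", ")))
    if (nrow(df) == 0L) return(TRUE)  # degenerate zero-site registry
    if (!all(df$resname %in% c("GLU", "ASP")))
        return("titratable residues must be GLU or ASP")
    if (any(df$resno < 1L)) return("residue numbers must be >= 1")
    if (anyDuplicated(df$label)) return("all registry residues must be distinct")
    for (s in unique(df$site)) {
        rows <- df[df$site == s, ]
        if (nrow(rows) != 2L || !identical(sort(rows$role), c("asp", "glu")) ||
            rows$resname[rows$role == "glu"] != "GLU" ||
            rows$resname[rows$role == "asp"] != "ASP")
            return(sprintf("site %s must have exactly one Glu and one Asp", s))
    }
    TRUE
})

#' ProtonationState: proton placement over the pocket's acidic residues
#'
#' A protonation state assigns a proton (or not) to each titratable residue
#' of a [BindingSiteRegistry-class].  The state is summarised by a symbol in
#' the grammar `n[ijk]`: `n` is the total proton count and each site code is
#' one of `0` (neither residue protonated), `E` (Glu only), `D` (Asp only)
#' or `2` (both).
#'
#' @slot symbol character(1), e.g. `"3[EEE]"`.
#' @slot flags named logical vector over the registry residues, in registry
#'   order (site I Glu, site I Asp, site II Glu, ...); `TRUE` = protonated.
#' @slot nProtons integer(1), number of `TRUE` flags.
#' @export
setClass("ProtonationState",
    representation(symbol = "character", flags = "logical", nProtons = "integer"))

setValidity("ProtonationState", function(object) {
    if (length(object@symbol) != 1L) return("symbol must be a single string")
    if (is.null(names(object@flags)) || anyNA(object@flags))
        return("flags must be a named logical vector without NA")
    if (object@nProtons != sum(object@flags))
        return("nProtons must equal the number of protonated residues")
    lead <- sub("\\[.*$", "", object@symbol)
    if (!identical(lead, as.character(object@nProtons)))
        return("symbol leading digit must equal the proton count")
    TRUE
})

#' IonTrajectory: labeled particles over time
#'
#' Time-ordered frames of labeled particles (bound ions, water oxygens,
#' protein atoms).  Coordinates are stored as an `nParticles x 3 x nFrames`
#' array in Angstrom.  A single-frame object doubles as a static structure
#' (snapshot) for cluster carving; fluctuation metrics require at least two
#' frames and exactly three bound ions.
#'
#' @slot coords numeric array `[particle, xyz, frame]`, Angstrom.
#' @slot particles data.frame with columns `role` (one of "ion",
#'   "water_oxygen", "protein_atom", "other"), `chain`, `resno`, `resname`,
#'   `atom` (atom name).
#' @slot times numeric vector of frame times in ps, strictly increasing.
#' @slot box numeric(0) for a non-periodic system or numeric(3) of orthogonal
#'   box lengths in Angstrom (minimum-image convention is applied to
#'   distances when present).
#' @export
setClass("IonTrajectory",
    representation(coords = "array", particles = "data.frame",
                   times = "numeric", box = "numeric"))

setValidity("IonTrajectory", function(object) {
    d <- dim(object@coords)
    if (length(d) != 3L || d[2] != 3L)
        return("coords must be an nParticles x 3 x nFrames array")
    if (d[1] != nrow(object@particles))
        return("coords and particles disagree on particle count")
    if (d[3] != length(object@times))
        return("coords and times disagree on frame count")
    if (length(object@times) >= 2L && any(diff(object@times) <= 0))
        return("frame times must be strictly increasing")
    if (!all(is.finite(object@coords)))
        return("all coordinates must be finite")
    if (!length(object@box) %in% c(0L, 3L))
        return("box must be absent (length 0) or 3 lengths in Angstrom")
    if (length(object@box) == 3L && any(object@box <= 0))
        return("box lengths must be positive")
    ok <- c("ion", "water_oxygen", "protein_atom", "other")
    if (!all(object@particles$role %in% ok))
        return(paste("particle roles must be in:", paste(ok, collapse = ", ")))
    TRUE
})

#' StabilityReport: per-state stability verdict over replicas
#'
#' @slot symbol protonation-state symbol the report refers to.
#' @slot metrics data.frame with one row per replica: `replica`,
#'   `mean_nwater`, `mean_rmsf`, `unbound` (any ion unbound in that replica).
#' @slot verdict one of "stable", "unstable", "excluded_unbinding".
#' @slot thresholds named list with `nwater` and `rmsf` (strict upper bounds).
#' @slot failures data.frame naming failing replicas and criteria.
#' @export
setClass("StabilityReport",
    representation(symbol = "character", metrics = "data.frame",
                   verdict = "character", thresholds = "list",
                   failures = "data.frame"))

setValidity("StabilityReport", function(object) {
    if (!object@verdict %in% c("stable", "unstable", "excluded_unbinding"))
        return("verdict must be stable, unstable or excluded_unbinding")
    if (nrow(object@metrics) < 1L) return("at least one replica is required")
    TRUE
})

#' PathwayDefinition: a water corridor between a pathway mouth and a site
#'
#' The pump has three water pathways: the extracellular pathway near site I
#' and the intracellular N- and C-terminal pathways near sites II and III.
#' A pathway is modelled as a straight corridor (cylinder of radius
#' `corridorRadius`) between a mouth point and a site point, with spherical
#' entry zones of the same radius about each endpoint.
#'
#' @slot name one of "extracellular", "N-terminal", "C-terminal".
#' @slot mouthPoint,sitePoint numeric(3) endpoints in Angstrom.
#' @slot corridorRadius corridor and zone radius in Angstrom (default 5).
#' @slot associatedSite the binding site ("I", "II" or "III") whose
#'   glutamate gates this pathway.
#' @export
setClass("PathwayDefinition",
    representation(name = "character", mouthPoint = "numeric",
                   sitePoint = "numeric", corridorRadius = "numeric",
                   associatedSite = "character"))

setValidity("PathwayDefinition", function(object) {
    if (length(object@mouthPoint) != 3L || length(object@sitePoint) != 3L)
        return("mouthPoint and sitePoint must be 3-vectors")
    if (all(object@mouthPoint == object@sitePoint))
        return("mouthPoint and sitePoint must differ")
    if (object@corridorRadius <= 0) return("corridorRadius must be positive")
    if (!object@associatedSite %in% c("I", "II", "III"))
        return("associatedSite must be I, II or III")
    TRUE
})

#' FluxSummary: replica statistics of water transit counts for one pathway
#'
#' @slot counts per-replica inward transit counts.
#' @slot mean mean inward transit count.
#' @slot se standard error of the mean (sample SD / sqrt(replicas)); `NA`
#'   when only one replica is available.
#' @slot gateCall "open" if the mean flux exceeds the baseline criterion,
#'   else "closed".
#' @slot baseline the open/closed baseline used (transits per replica).
#' @export
setClass("FluxSummary",
    representation(counts = "numeric", mean = "numeric", se = "numeric",
                   gateCall = "character", baseline = "numeric"))

setValidity("FluxSummary", function(object) {
    if (any(object@counts < 0)) return("transit counts must be non-negative")
    if (!object@gateCall %in% c("open", "closed"))
        return("gateCall must be open or closed")
    TRUE
})

#' ClusterModel: a carved, capped quantum-cluster model of the pocket
#'
#' @slot atoms data.frame with columns `element`, `x`, `y`, `z` (Angstrom),
#'   `source` (one of "residue", "ion", "water", "cap"), `chain`, `resno`,
#'   `resname`, `atom`.
#' @slot residues data.frame of included residues (`chain`, `resno`,
#'   `resname`).
#' @slot frozen integer indices (rows of `atoms`) of the frozen alpha
#'   carbons, one per included residue.
#' @slot netCharge integer formal charge in e: +1 per ion minus one per
#'   deprotonated included Glu/Asp side chain, plus other formal charges.
#' @slot multiplicity spin multiplicity (default 1, closed shell).
#' @export
setClass("ClusterModel",
    representation(atoms = "data.frame", residues = "data.frame",
                   frozen = "integer", netCharge = "integer",
                   multiplicity = "integer"))

setValidity("ClusterModel", function(object) {
    if (length(object@frozen) &&
        (min(object@frozen) < 1L || max(object@frozen) > nrow(object@atoms)))
        return("frozen indices must address rows of atoms")
    if (!all(object@atoms$source %in% c("residue", "ion", "water", "cap")))
        return("atom source tags must be residue, ion, water or cap")
    TRUE
})

#' WaterShellModel: a single ion and its surrounding water shell
#'
#' @slot ionPosition numeric(3), Angstrom.
#' @slot ionElement element symbol of the central ion (default "Na").
#' @slot waters data.frame of shell-water atoms (`element`, `x`, `y`, `z`,
#'   `resno` identifying the molecule, `atom`).
#' @slot radius shell radius in Angstrom (default 9).
#' @export
setClass("WaterShellModel",
    representation(ionPosition = "numeric", ionElement = "character",
                   waters = "data.frame", radius = "numeric"))

setValidity("WaterShellModel", function(object) {
    if (length(object@ionPosition) != 3L) return("ionPosition must be a 3-vector")
    if (object@radius <= 0) return("radius must be positive")
    TRUE
})

#' EnergyLedger: fragment energies from external quantum-chemistry runs
#'
#' A tidy table of counterpoise-corrected fragment energies keyed by
#' protonation-state symbol, replica and fragment name.  Recognised
#' fragments: `full` (pocket cluster with all three ions), `without_I`,
#' `without_II`, `without_III` (cluster minus that site's ion), `ion` (lone
#' ion in vacuum), `shell` (single ion plus water shell) and `shell_water`
#' (the shell without the ion).
#'
#' @slot entries data.frame with columns `state`, `replica`, `fragment`,
#'   `energy`, `unit` ("hartree" or "kcal/mol"; one unit per ledger).
#' @export
setClass("EnergyLedger", representation(entries = "data.frame"))

setValidity("EnergyLedger", function(object) {
    df <- object@entries
    need <- c("state", "replica", "fragment", "energy", "unit")
    if (!all(need %in% names(df)))
        return(paste("entries must have columns:", paste(need, collapse = ", ")))
    if (nrow(df) && length(unique(df$unit)) != 1L)
        return("all ledger energies must share one unit")
    if (nrow(df) && !all(df$unit %in% c("hartree", "kcal/mol")))
        return("unit must be 'hartree' or 'kcal/mol'")
    known <- c("full", "without_I", "without_II", "without_III",
               "ion", "shell", "shell_water")
    if (nrow(df) && !all(df$fragment %in% known))
        return(paste("unknown fragment; expected one of:",
                     paste(known, collapse = ", ")))
    TRUE
})

#' BindingEnergyReport: per-site binding energies, hydration reference and
#' verdicts
#'
#' Binding energies are stored signed (negative = stabilising) as
#' `dE = E_full - E_without_site - E_ion`; the "strength" reported alongside
#' is `-dE`, matching the convention of reporting binding energies as
#' positive magnitudes.
#'
#' @slot perSite data.frame: `state`, `site`, `dE`, `strength`, `se`
#'   (standard error over replicas, NA for a single replica), `n` replicas.
#' @slot hydration named list: `dE`, `strength`, `se`, `n` for the
#'   single-ion water-shell reference (elements NA when not computed).
#' @slot verdicts data.frame: `state`, `mean_strength`,
#'   `bindable_from_water`, and per-site `releasable` columns.
#' @slot unit energy unit of all reported values.
#' @export
setClass("BindingEnergyReport",
    representation(perSite = "data.frame", hydration = "list",
                   verdicts = "data.frame", unit = "character"))
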