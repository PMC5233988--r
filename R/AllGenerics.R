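#' @rdname ProtonationState-class
#' @param object,x an object.
#' @export
setGeneric("stateSymbol", function(x) standardGeneric("stateSymbol"))

#' @rdname ProtonationState-class
#' @export
setGeneric("protonationFlags", function(x) standardGeneric("protonationFlags"))

#' @rdname ProtonationState-class
#' @export
setGeneric("nProtons", function(x) standardGeneric("nProtons"))

#' @rdname BindingSiteRegistry-class
#' @param x a [BindingSiteRegistry-class].
#' @export
setGeneric("registryResidues", function(x) standardGeneric("registryResidues"))

#' @rdname BindingSiteRegistry-class
#' @export
setGeneric("siteLabels", function(x) standardGeneric("siteLabels"))

#' @rdname IonTrajectory-class
#' @param x an [IonTrajectory-class].
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname IonTrajectory-class
#' @export
setGeneric("nParticles", function(x) standardGeneric("nParticles"))

#' @rdname IonTrajectory-class
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' @rdname IonTrajectory-class
#' @export
setGeneric("particles", function(x) standardGeneric("particles"))

#' Per-ion root mean square fluctuation
#'
#' @param traj an [IonTrajectory-class].
#' @param ... passed to methods.
#' @export
setGeneric("ionRMSF", function(traj, ...) standardGeneric("ionRMSF"))

#' Hydration number of the bound ions
#'
#' @param traj an [IonTrajectory-class].
#' @param ... passed to methods.
#' @export
setGeneric("hydrationCount", function(traj, ...) standardGeneric("hydrationCount"))

#' Detect ion unbinding excursions
#'
#' @param traj an [IonTrajectory-class].
#' @param ... passed to methods.
#' @export
setGeneric("detectUnbinding", function(traj, ...) standardGeneric("detectUnbinding"))

#' Count water transit events through a pathway corridor
#'
#' @param traj an [IonTrajectory-class].
#' @param pathway a [PathwayDefinition-class].
#' @param ... passed to methods.
#' @export
setGeneric("countTransits",
    function(traj, pathway, ...) standardGeneric("countTransits"))

#' @rdname StabilityReport-class
#' @param x a report object.
#' @export
setGeneric("verdict", function(x) standardGeneric("verdict"))

#' @rdname EnergyLedger-class
#' @param x an [EnergyLedger-class].
#' @export
setGeneric("ledgerEntries", function(x) standardGeneric("ledgerEntries"))
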