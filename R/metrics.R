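#' Per-ion root mean square fluctuation over a time window
#'
#' For each bound ion the RMSF is the square root of the time-averaged
#' squared deviation of the ion's position from its window-average position:
#' `RMSF_i = sqrt( mean_t |r_i(t) - <r_i>|^2 )`.  No superposition or
#' alignment is applied: each ion fluctuates about its own mean.  The
#' per-ion values are averaged to give the pocket-level RMSF used for
#' stability classification.
#'
#' @param traj an [IonTrajectory-class] containing the bound ions.
#' @param window averaging window from [metricWindow()]; `NULL` (default)
#'   uses [defaultWindow()] (last 10 ns, or final 20% of frames).
#' @return list with `perIon` (named numeric, Angstrom) and `mean`.
#' @examples
#' traj <- simulateTrajectory(plantedStateSpec("3[EEE]", sigma = 0.2,
#'                            lambda = 0, nFrames = 200, seed = 1))[[1]]
#' ionRMSF(traj)$mean   # close to 0.2 * sqrt(3)
#' @export
setMethod("ionRMSF", "IonTrajectory", function(traj, window = NULL) {
    ions <- ionIndices(traj)
    if (!length(ions)) stop("trajectory contains no ion particles")
    idx <- windowFrames(traj, window)
    if (length(idx) < 2L)
        stop("insufficient data: the window must contain at least 2 frames")
    perIon <- vapply(ions, function(i) {
        r <- t(traj@coords[i, , idx])            # frames x 3
        mu <- colMeans(r)
        sqrt(mean(rowSums(sweep(r, 2, mu)^2)))
    }, numeric(1))
    names(perIon) <- paste0("ion", seq_along(ions))
    list(perIon = perIon, mean = mean(perIon))
})

#' Hydration number: waters within a cutoff of the bound ions
#'
#' Counts, per frame, the water molecules whose oxygen lies within `cutoff`
#' of any bound ion.  Each water counts once per frame even when it is
#' within the cutoff of several ions (unique-water rule).  Distances use the
#' minimum-image convention when the trajectory carries a box.
#'
#' @param traj an [IonTrajectory-class].
#' @param cutoff distance cutoff in Angstrom (default 5, chosen to cover all
#'   three binding sites and the water-channel entrances).
#' @param window averaging window; `NULL` for the default window.
#' @return list with `perFrame` (integer counts) and `mean` (N_water).
#' @export
setMethod("hydrationCount", "IonTrajectory",
    function(traj, cutoff = 5, window = NULL) {
    stopifnot(cutoff > 0)
    ions <- ionIndices(traj)
    if (!length(ions)) stop("trajectory contains no ion particles")
    wat <- waterOxygenIndices(traj)
    idx <- windowFrames(traj, window)
    if (!length(wat)) {
        warning("trajectory contains no water particles; N_water = 0")
        return(list(perFrame = integer(length(idx)), mean = 0))
    }
    perFrame <- vapply(idx, function(f) {
        d <- pairDistances(matrix(traj@coords[wat, , f], ncol = 3),
                           matrix(traj@coords[ions, , f], ncol = 3),
                           traj@box)
        sum(apply(d, 1L, min) <= cutoff)
    }, integer(1))
    list(perFrame = perFrame, mean = mean(perFrame))
})

#' Flag ions that have left their binding site
#'
#' An ion is flagged unbound when its distance from its reference point
#' exceeds `threshold` in the final frame of the window.  The default
#' reference is each ion's first-frame position; an excursion that returns
#' inside the threshold by the final frame is not flagged.
#'
#' @param traj an [IonTrajectory-class].
#' @param siteCenters optional `nIons x 3` matrix of reference points; by
#'   default each ion's first-frame position.
#' @param threshold escape distance in Angstrom (default 5).
#' @param window window whose final frame is tested; `NULL` for default.
#' @return named logical vector, one element per ion.
#' @export
setMethod("detectUnbinding", "IonTrajectory",
    function(traj, siteCenters = NULL, threshold = 5, window = NULL) {
    ions <- ionIndices(traj)
    if (!length(ions)) stop("trajectory contains no ion particles")
    if (is.null(siteCenters))
        siteCenters <- traj@coords[ions, , 1, drop = FALSE][, , 1]
    siteCenters <- matrix(siteCenters, ncol = 3)
    if (nrow(siteCenters) != length(ions))
        stop("one reference point per ion is required")
    lastF <- max(windowFrames(traj, window))
    final <- matrix(traj@coords[ions, , lastF], ncol = 3)
    d <- sqrt(rowSums((final - siteCenters)^2))
    setNames(d > threshold, paste0("ion", seq_along(ions)))
})

#' Compute all stability metrics for one replica trajectory
#'
#' Convenience wrapper producing the one-row metric record consumed by
#' [classifyStability()]: mean N_water, mean ion RMSF and the unbound flag.
#'
#' @param traj an [IonTrajectory-class].
#' @param replica replica identifier recorded in the output.
#' @param cutoff hydration cutoff in Angstrom (default 5).
#' @param escapeThreshold unbinding threshold in Angstrom (default 5).
#' @param window averaging window; `NULL` for default.
#' @return one-row data.frame: `replica`, `mean_nwater`, `mean_rmsf`,
#'   `unbound`.
#' @export
replicaMetrics <- function(traj, replica = 1L, cutoff = 5,
                           escapeThreshold = 5, window = NULL) {
    rmsf <- ionRMSF(traj, window)
    nw <- hydrationCount(traj, cutoff, window)
    ub <- detectUnbinding(traj, threshold = escapeThreshold, window = window)
    data.frame(replica = replica, mean_nwater = nw$mean,
               mean_rmsf = rmsf$mean, unbound = any(ub))
}

#' Classify a protonation state as stable or unstable
#'
#' A state is stable when every replica satisfies `N_water < nwater` AND
#' `RMSF < rmsf` (strict inequalities) and no ion unbinds in any replica.
#' States with any unbinding event are reported as `excluded_unbinding`,
#' mirroring the exclusion of runs where an ion left its site.
#'
#' @param metrics data.frame of replica metrics, one row per replica, with
#'   columns `replica`, `mean_nwater`, `mean_rmsf`, `unbound` (as produced
#'   by [replicaMetrics()]).
#' @param symbol protonation-state symbol the metrics belong to.
#' @param thresholds named list: `nwater` (default 8 waters) and `rmsf`
#'   (default 0.5 Angstrom), both strict upper bounds.
#' @return a [StabilityReport-class].
#' @examples
#' m <- data.frame(replica = 1:3, mean_nwater = c(7.0, 6.5, 7.9),
#'                 mean_rmsf = c(0.40, 0.45, 0.49), unbound = FALSE)
#' verdict(classifyStability(m, "3[EEE]"))   # "stable"
#' @export
classifyStability <- function(metrics, symbol = "?",
                              thresholds = list(nwater = 8, rmsf = 0.5)) {
    if (!is.data.frame(metrics) || nrow(metrics) < 1L)
        stop("at least one replica of metrics is required")
    stopifnot(thresholds$nwater > 0, thresholds$rmsf > 0)
    failN <- metrics$mean_nwater >= thresholds$nwater
    failR <- metrics$mean_rmsf >= thresholds$rmsf
    failures <- rbind(
        if (any(failN)) data.frame(replica = metrics$replica[failN],
                                   criterion = "nwater"),
        if (any(failR)) data.frame(replica = metrics$replica[failR],
                                   criterion = "rmsf"),
        if (any(metrics$unbound))
            data.frame(replica = metrics$replica[metrics$unbound],
                       criterion = "unbound"))
    if (is.null(failures))
        failures <- data.frame(replica = integer(), criterion = character())
    verdict <- if (any(metrics$unbound)) "excluded_unbinding"
               else if (any(failN | failR)) "unstable" else "stable"
    new("StabilityReport", symbol = symbol, metrics = metrics,
        verdict = verdict, thresholds = thresholds, failures = failures)
}

#' @rdname StabilityReport-class
#' @export
setMethod("verdict", "StabilityReport", function(x) x@verdict)

setMethod("show", "StabilityReport", function(object) {
    cat(sprintf("StabilityReport %s: %s (%d replica(s))\n", object@symbol,
                object@verdict, nrow(object@metrics)))
    cat(sprintf("  thresholds: N_water < %g, RMSF < %g A\n",
                object@thresholds$nwater, object@thresholds$rmsf))
    if (nrow(object@failures))
        cat("  failing:", paste(sprintf("replica %s (%s)",
            object@failures$replica, object@failures$criterion),
            collapse = "; "), "\n")
    invisible(NULL)
})
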