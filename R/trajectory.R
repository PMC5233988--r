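#' Construct an IonTrajectory
#'
#' @param coords numeric array `nParticles x 3 x nFrames` (Angstrom), or an
#'   `nParticles x 3` matrix for a single frame.
#' @param particles data.frame with columns `role`, `chain`, `resno`,
#'   `resname`, `atom` (see [IonTrajectory-class]).
#' @param times frame times in ps; default `0, 50, 100, ...` matching a
#'   50 ps sampling interval.
#' @param box numeric(3) orthogonal box lengths in Angstrom, or numeric(0)
#'   for a non-periodic system.
#' @return an [IonTrajectory-class].
#' @export
ionTrajectory <- function(coords, particles,
                          times = (seq_len(dim(coords)[3]) - 1) * 50,
                          box = numeric(0)) {
    if (length(dim(coords)) == 2L)
        coords <- array(coords, c(dim(coords), 1L))
    new("IonTrajectory", coords = coords, particles = particles,
        times = times, box = box)
}

#' @rdname IonTrajectory-class
#' @export
setMethod("nFrames", "IonTrajectory", function(x) dim(x@coords)[3])

#' @rdname IonTrajectory-class
#' @export
setMethod("nParticles", "IonTrajectory", function(x) dim(x@coords)[1])

#' @rdname IonTrajectory-class
#' @export
setMethod("frameTimes", "IonTrajectory", function(x) x@times)

#' @rdname IonTrajectory-class
#' @export
setMethod("particles", "IonTrajectory", function(x) x@particles)

setMethod("show", "IonTrajectory", function(object) {
    roles <- table(object@particles$role)
    cat("IonTrajectory:", nParticles(object), "particles x",
        nFrames(object), "frames (",
        paste(names(roles), roles, sep = "=", collapse = ", "), ")\n")
    cat("  time span:", min(object@times), "-", max(object@times), "ps;",
        if (length(object@box)) paste("box", paste(round(object@box, 1),
                                                   collapse = " x "), "A")
        else "no box", "\n")
    invisible(NULL)
})

ionIndices <- function(traj) which(traj@particles$role == "ion")
waterOxygenIndices <- function(traj) which(traj@particles$role == "water_oxygen")

# squared distance between particle sets at one frame, minimum-image when a
# box is present (orthogonal cells only)
pairDistances <- function(a, b, box = numeric(0)) {
    # a: n x 3, b: m x 3 -> n x m distance matrix
    n <- nrow(a); m <- nrow(b)
    d2 <- matrix(0, n, m)
    for (k in 1:3) {
        diff <- outer(a[, k], b[, k], "-")
        if (length(box) == 3L)
            diff <- diff - box[k] * round(diff / box[k])
        d2 <- d2 + diff^2
    }
    sqrt(d2)
}

#' Time window for trajectory averaging
#'
#' @param start,end window bounds in ps, `start < end`.
#' @return list with `start` and `end`, used by the metric functions.
#' @export
metricWindow <- function(start, end) {
    stopifnot(is.numeric(start), is.numeric(end), start < end)
    list(start = start, end = end)
}

#' Default averaging window: the last 10 ns of the trajectory
#'
#' Production analyses average over the final 10 ns of a 50 ns run.  For
#' shorter trajectories the window falls back to the final 20% of frames
#' (never fewer than two).
#'
#' @param traj an [IonTrajectory-class].
#' @param lastNs window length in ns (default 10).
#' @return a window as from [metricWindow()].
#' @export
defaultWindow <- function(traj, lastNs = 10) {
    t <- frameTimes(traj)
    span <- t[length(t)] - t[1]
    start <- if (span >= lastNs * 1000) t[length(t)] - lastNs * 1000
             else t[max(1L, length(t) - max(2L, ceiling(0.2 * length(t))) + 1L)]
    metricWindow(start, t[length(t)])
}

windowFrames <- function(traj, window) {
    if (is.null(window)) window <- defaultWindow(traj)
    idx <- which(traj@times >= window$start & traj@times <= window$end)
    if (!length(idx))
        stop("the averaging window contains no sampled frames")
    idx
}
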