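HARTREE_TO_KCAL <- 627.509

#' Convert energies between hartree and kcal/mol
#'
#' @param x numeric energies.
#' @param from,to "hartree" or "kcal/mol".
#' @return converted energies (1 hartree = 627.509 kcal/mol).
#' @export
convertEnergy <- function(x, from, to) {
    units <- c("hartree", "kcal/mol")
    if (!from %in% units || !to %in% units)
        stop("units must be 'hartree' or 'kcal/mol'")
    if (from == to) return(x)
    if (from == "hartree") x * HARTREE_TO_KCAL else x / HARTREE_TO_KCAL
}

#' Construct an energy ledger
#'
#' @param entries data.frame with columns `state`, `replica`, `fragment`,
#'   `energy`, `unit` (see [EnergyLedger-class]).  Rows with `state = "*"`
#'   are shared across states (the lone-ion reference and the water-shell
#'   fragments).
#' @return an [EnergyLedger-class].
#' @export
energyLedger <- function(entries) {
    entries$replica <- as.integer(entries$replica)
    new("EnergyLedger", entries = entries)
}

#' @rdname EnergyLedger-class
#' @export
setMethod("ledgerEntries", "EnergyLedger", function(x) x@entries)

setMethod("show", "EnergyLedger", function(object) {
    df <- object@entries
    cat(sprintf("EnergyLedger: %d entries, %d state(s), unit %s\n",
                nrow(df), length(setdiff(unique(df$state), "*")),
                if (nrow(df)) df$unit[1] else "unset"))
    invisible(NULL)
})

#' Read/write an energy ledger as TSV
#'
#' @param ledger an [EnergyLedger-class].
#' @param file path of the TSV file (columns state, replica, fragment,
#'   energy, unit).
#' @return `readEnergyLedger` returns an [EnergyLedger-class];
#'   `writeEnergyLedger` returns `file` invisibly.
#' @export
writeEnergyLedger <- function(ledger, file) {
    utils::write.table(ledgerEntries(ledger), file, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(file)
}

#' @rdname writeEnergyLedger
#' @export
readEnergyLedger <- function(file) {
    energyLedger(utils::read.table(file, sep = "\t", header = TRUE,
                                   stringsAsFactors = FALSE,
                                   check.names = FALSE))
}

# fragment lookup: exact (state, replica) first, then shared "*" rows
getFragment <- function(ledger, state, replica, fragment) {
    df <- ledgerEntries(ledger)
    hit <- df[df$state == state & df$replica == replica &
              df$fragment == fragment, ]
    if (!nrow(hit))
        hit <- df[df$state == "*" & df$fragment == fragment, ]
    if (!nrow(hit))
        stop("ledger error: missing fragment '", fragment, "' for state ",
             state, ", replica ", replica)
    hit$energy[1]
}

meanSE <- function(x) {
    list(mean = mean(x),
         se = if (length(x) >= 2L) stats::sd(x) / sqrt(length(x))
              else NA_real_,
         n = length(x))
}

#' Per-site sodium binding energy from a fragment-energy ledger
#'
#' Computes, per replica, `dE_bind = E_full - E_without_site - E_ion` where
#' `E_full` is the pocket cluster with all three ions, `E_without_site` the
#' cluster with that site's ion deleted, and `E_ion` the lone ion in vacuum
#' (all counterpoise-corrected by the upstream quantum-chemistry engine).
#' A negative `dE` is stabilising; the reported `strength = -dE` follows
#' the convention of quoting binding energies as positive magnitudes.
#'
#' @param ledger an [EnergyLedger-class].
#' @param state protonation-state symbol.
#' @param site binding site: "I", "II" or "III".
#' @param unit report unit; default the ledger's own unit.  Hartree ledgers
#'   are converted with 627.509 kcal/mol per hartree.
#' @return list: `perReplica` (data.frame replica, dE, strength), `dE`,
#'   `strength` (means), `se` (SE of strength over replicas, NA for one
#'   replica), `n`, `unit`.
#' @export
bindingEnergy <- function(ledger, state, site = c("I", "II", "III"),
                          unit = NULL) {
    site <- match.arg(site)
    df <- ledgerEntries(ledger)
    if (!nrow(df)) stop("ledger error: empty ledger")
    ledgerUnit <- df$unit[1]
    if (is.null(unit)) unit <- ledgerUnit
    reps <- sort(unique(df$replica[df$state == state &
                                   df$fragment == "full"]))
    if (!length(reps))
        stop("ledger error: no 'full' fragment for state ", state)
    frag <- paste0("without_", site)
    dE <- vapply(reps, function(r)
        getFragment(ledger, state, r, "full") -
        getFragment(ledger, state, r, frag) -
        getFragment(ledger, state, r, "ion"), numeric(1))
    dE <- convertEnergy(dE, ledgerUnit, unit)
    s <- meanSE(-dE)
    list(perReplica = data.frame(replica = reps, dE = dE, strength = -dE),
         dE = mean(dE), strength = s$mean, se = s$se, n = s$n, unit = unit)
}

#' Hydration energy of a single ion in a water shell
#'
#' `dE_hyd = E_shell - E_water - E_ion` per shell replica, where `E_shell`
#' is the ion-plus-shell fragment and `E_water` the shell without the ion.
#' Replicate shells (snapshots) are averaged with a standard error.
#'
#' @param ledger an [EnergyLedger-class] carrying `shell`, `shell_water`
#'   and `ion` fragments (conventionally under state `"*"`).
#' @param unit report unit; default the ledger's unit.
#' @return list: `perReplica`, `dE`, `strength`, `se`, `n`, `unit`.
#' @export
hydrationEnergy <- function(ledger, unit = NULL) {
    df <- ledgerEntries(ledger)
    if (!nrow(df)) stop("ledger error: empty ledger")
    ledgerUnit <- df$unit[1]
    if (is.null(unit)) unit <- ledgerUnit
    shell <- df[df$fragment == "shell", ]
    if (!nrow(shell)) stop("ledger error: no 'shell' fragments")
    dE <- vapply(seq_len(nrow(shell)), function(i) {
        st <- shell$state[i]; r <- shell$replica[i]
        shell$energy[i] - getFragment(ledger, st, r, "shell_water") -
            getFragment(ledger, st, r, "ion")
    }, numeric(1))
    dE <- convertEnergy(dE, ledgerUnit, unit)
    s <- meanSE(-dE)
    list(perReplica = data.frame(replica = shell$replica, dE = dE,
                                 strength = -dE),
         dE = mean(dE), strength = s$mean, se = s$se, n = s$n, unit = unit)
}

#' Binding/release verdicts against the hydration reference
#'
#' A state is `bindable_from_water` when the mean binding strength over its
#' three sites is at least the single-ion hydration strength: the pocket
#' then competes successfully with bulk water for a sodium ion (the ~180 vs
#' ~170 kcal/mol contrast for 3-proton states; a ~+30 kcal/mol destabilising
#' shift makes 4-proton states fail it).  A site is `releasable` when its
#' strength is below the hydration strength or within `tolerance` of it
#' ("similar to" the hydration energy).
#'
#' @param strengths data.frame with columns `state`, `site`, `strength`.
#' @param hydrationStrength the water-shell reference strength (same unit).
#' @param tolerance release similarity tolerance (default 5 kcal/mol).
#' @return list: `states` (state, mean_strength, bindable_from_water),
#'   `sites` (state, site, strength, releasable).
#' @export
bindingVerdicts <- function(strengths, hydrationStrength, tolerance = 5) {
    stopifnot(tolerance >= 0)
    states <- unique(strengths$state)
    st <- data.frame(
        state = states,
        mean_strength = vapply(states, function(s)
            mean(strengths$strength[strengths$state == s]), numeric(1)),
        row.names = NULL)
    st$bindable_from_water <- st$mean_strength >= hydrationStrength
    sites <- strengths[, c("state", "site", "strength")]
    sites$releasable <- sites$strength < hydrationStrength |
        abs(sites$strength - hydrationStrength) <= tolerance
    list(states = st, sites = sites)
}

#' Full binding-energy report for a ledger
#'
#' Runs [bindingEnergy()] for every state and site in the ledger,
#' [hydrationEnergy()] when shell fragments are present, and
#' [bindingVerdicts()] against the hydration reference.
#'
#' @param ledger an [EnergyLedger-class].
#' @param unit report unit (default "kcal/mol").
#' @param tolerance release tolerance passed to [bindingVerdicts()].
#' @return a [BindingEnergyReport-class].
#' @export
bindingEnergyReport <- function(ledger, unit = "kcal/mol", tolerance = 5) {
    df <- ledgerEntries(ledger)
    states <- setdiff(unique(df$state[df$fragment == "full"]), "*")
    rows <- list()
    for (s in states) for (site in c("I", "II", "III")) {
        if (!any(df$state == s & df$fragment == paste0("without_", site)))
            next
        be <- bindingEnergy(ledger, s, site, unit)
        rows[[length(rows) + 1L]] <- data.frame(
            state = s, site = site, dE = be$dE, strength = be$strength,
            se = be$se, n = be$n)
    }
    perSite <- if (length(rows)) do.call(rbind, rows) else
        data.frame(state = character(), site = character(), dE = numeric(),
                   strength = numeric(), se = numeric(), n = integer())
    hyd <- if (any(df$fragment == "shell"))
        hydrationEnergy(ledger, unit)[c("dE", "strength", "se", "n")]
    else list(dE = NA_real_, strength = NA_real_, se = NA_real_, n = 0L)
    verd <- if (nrow(perSite) && !is.na(hyd$strength)) {
        v <- bindingVerdicts(perSite, hyd$strength, tolerance)
        rel <- stats::reshape(v$sites[, c("state", "site", "releasable")],
                              idvar = "state", timevar = "site",
                              direction = "wide")
        names(rel) <- sub("^releasable\\.", "releasable_", names(rel))
        merge(v$states, rel, by = "state", sort = FALSE)
    } else data.frame(state = character(), mean_strength = numeric(),
                      bindable_from_water = logical())
    new("BindingEnergyReport", perSite = perSite, hydration = hyd,
        verdicts = verd, unit = unit)
}

setMethod("show", "BindingEnergyReport", function(object) {
    cat("BindingEnergyReport (", object@unit, ")\n", sep = "")
    if (!is.na(object@hydration$strength))
        cat(sprintf("  hydration reference: %.2f %s %s (n = %d)\n",
                    object@hydration$strength, "±",
                    ifelse(is.na(object@hydration$se), "NA",
                           sprintf("%.2f", object@hydration$se)),
                    object@hydration$n))
    for (i in seq_len(nrow(object@verdicts)))
        cat(sprintf("  %-8s mean strength %.2f -> %s\n",
                    object@verdicts$state[i],
                    object@verdicts$mean_strength[i],
                    if (object@verdicts$bindable_from_water[i])
                        "bindable from water" else "not bindable"))
    invisible(NULL)
})
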