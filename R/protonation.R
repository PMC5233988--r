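SITE_CODES <- c("0", "E", "D", "2")  # lexicographic order used for sorting

# (gluProtonated, aspProtonated) -> site code
siteCode <- function(glu, asp) {
    ifelse(glu & asp, "2", ifelse(glu, "E", ifelse(asp, "D", "0")))
}

# site code -> c(glu, asp)
codeFlags <- function(code) {
    switch(code,
        "0" = c(FALSE, FALSE), "E" = c(TRUE, FALSE),
        "D" = c(FALSE, TRUE),  "2" = c(TRUE, TRUE),
        stop("invalid site code '", code, "'"))
}

#' Encode per-residue proton flags as a protonation-state symbol
#'
#' Maps a named logical vector of proton placements over the registry's
#' residues to a [ProtonationState-class] with its `n[ijk]` symbol.  Site
#' codes follow the registry's site order; within a site the glutamate is
#' read first: `0` = neither protonated, `E` = Glu only, `D` = Asp only,
#' `2` = both.
#'
#' @param flags named logical vector; names must be exactly the registry
#'   residue labels (e.g. `"Glu779"`), in any order.
#' @param registry a [BindingSiteRegistry-class]; default [nkaRegistry()].
#' @return a [ProtonationState-class].
#' @examples
#' fl <- setNames(rep(FALSE, 6), registryResidues(nkaRegistry())$label)
#' fl[c("Glu779", "Glu954", "Asp926")] <- TRUE
#' stateSymbol(encodeState(fl))   # "3[E02]"
#' @export
encodeState <- function(flags, registry = nkaRegistry()) {
    df <- registryResidues(registry)
    if (!setequal(names(flags), df$label) || length(flags) != nrow(df))
        stop("flags must cover exactly the registry residues: ",
             paste(df$label, collapse = ", "))
    flags <- flags[df$label]  # registry order
    codes <- vapply(unique(df$site), function(s) {
        rows <- df[df$site == s, ]
        siteCode(flags[[rows$label[rows$role == "glu"]]],
                 flags[[rows$label[rows$role == "asp"]]])
    }, character(1))
    n <- sum(flags)
    new("ProtonationState",
        symbol = sprintf("%d[%s]", n, paste(codes, collapse = "")),
        flags = flags, nProtons = as.integer(n))
}

#' Decode a protonation-state symbol
#'
#' Parses a symbol in the grammar `n[ijk]` into per-residue proton flags.
#' The leading digit is validated against the proton count implied by the
#' site codes; a mismatch is an error (the consistency check is part of the
#' codec's contract, catching hand-edited tables).
#'
#' @param symbol character(1), e.g. `"4[022]"`.
#' @param registry a [BindingSiteRegistry-class]; the bracket must contain
#'   one code per registry site.
#' @return a [ProtonationState-class].
#' @examples
#' st <- decodeSymbol("4[022]")
#' names(which(protonationFlags(st)))  # Glu327, Asp804, Glu954, Asp926
#' @export
decodeSymbol <- function(symbol, registry = nkaRegistry()) {
    stopifnot(is.character(symbol), length(symbol) == 1L)
    m <- regmatches(symbol, regexec("^([0-9]+)\\[([0ED2]*)\\]$", symbol))[[1]]
    if (length(m) != 3L)
        stop("malformed protonation symbol '", symbol,
             "'; expected n[ijk] with codes in {0, E, D, 2}")
    df <- registryResidues(registry)
    sites <- unique(df$site)
    codes <- strsplit(m[3], "")[[1]]
    if (length(codes) != length(sites))
        stop("symbol '", symbol, "' has ", length(codes),
             " site codes but the registry has ", length(sites), " sites")
    flags <- logical(nrow(df))
    names(flags) <- df$label
    for (i in seq_along(sites)) {
        rows <- df[df$site == sites[i], ]
        gf <- codeFlags(codes[i])
        flags[rows$label[rows$role == "glu"]] <- gf[1]
        flags[rows$label[rows$role == "asp"]] <- gf[2]
    }
    n <- as.integer(m[2])
    if (n != sum(flags))
        stop("inconsistent symbol '", symbol, "': leading digit ", n,
             " but site codes imply ", sum(flags), " protons")
    new("ProtonationState", symbol = symbol, flags = flags, nProtons = n)
}

#' Enumerate all protonation states of a registry
#'
#' Generates every combination of proton placements over the registry's
#' titratable residues: `4^sites = 2^residues` states (64 for the default
#' three-site pocket).  Order is deterministic: by total proton count `n`,
#' then lexicographically by site codes with `0 < E < D < 2`.
#'
#' @param registry a [BindingSiteRegistry-class].
#' @return list of [ProtonationState-class], length `2^nResidues`.
#' @examples
#' states <- enumerateStates()
#' length(states)                       # 64
#' table(vapply(states, nProtons, 1L))  # 1 6 15 20 15 6 1
#' @export
enumerateStates <- function(registry = nkaRegistry()) {
    df <- registryResidues(registry)
    sites <- unique(df$site)
    if (!length(sites))
        return(list(new("ProtonationState", symbol = "0[]",
                        flags = setNames(logical(0), character(0)),
                        nProtons = 0L)))
    grid <- do.call(expand.grid,
                    c(rep(list(SITE_CODES), length(sites)),
                      stringsAsFactors = FALSE))
    symbols <- apply(grid, 1L, function(codes) {
        n <- sum(vapply(codes, function(cd) sum(codeFlags(cd)), numeric(1)))
        sprintf("%d[%s]", n, paste(codes, collapse = ""))
    })
    states <- lapply(symbols, decodeSymbol, registry = registry)
    rank <- vapply(states, function(st) {
        codes <- strsplit(sub("^[0-9]+\\[(.*)\\]$", "\\1", st@symbol), "")[[1]]
        idx <- match(codes, SITE_CODES) - 1L
        sum(idx * 4L^(rev(seq_along(idx)) - 1L))  # base-4 rank, 0<E<D<2
    }, numeric(1))
    states[order(vapply(states, nProtons, integer(1)), rank)]
}

#' @rdname ProtonationState-class
#' @export
setMethod("stateSymbol", "ProtonationState", function(x) x@symbol)

#' @rdname ProtonationState-class
#' @export
setMethod("protonationFlags", "ProtonationState", function(x) x@flags)

#' @rdname ProtonationState-class
#' @export
setMethod("nProtons", "ProtonationState", function(x) x@nProtons)

setMethod("show", "ProtonationState", function(object) {
    on <- names(which(object@flags))
    cat("ProtonationState", object@symbol, "—", object@nProtons,
        "proton(s)", if (length(on)) paste("on", paste(on, collapse = ", "))
        else "", "\n")
    invisible(NULL)
})

#' Read/write a protonation-state table
#'
#' The table layout mirrors the published presentation of the selected
#' states: one row per state, a `symbol` column and one `+`/`-` column per
#' registry residue (labelled `Glu779`, `Asp808`, ...).
#'
#' @param states list of [ProtonationState-class].
#' @param file path of the TSV file.
#' @param registry a [BindingSiteRegistry-class] used to validate columns.
#' @return `writeStateTable` returns `file` invisibly; `readStateTable`
#'   returns a list of [ProtonationState-class], each checked for
#'   symbol/flag consistency.
#' @export
writeStateTable <- function(states, file, registry = nkaRegistry()) {
    df <- registryResidues(registry)
    tab <- data.frame(symbol = vapply(states, stateSymbol, character(1)),
                      stringsAsFactors = FALSE)
    for (lab in df$label)
        tab[[lab]] <- vapply(states, function(st)
            if (protonationFlags(st)[[lab]]) "+" else "-", character(1))
    utils::write.table(tab, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}

#' @rdname writeStateTable
#' @export
readStateTable <- function(file, registry = nkaRegistry()) {
    tab <- utils::read.table(file, sep = "\t", header = TRUE,
                             check.names = FALSE, stringsAsFactors = FALSE)
    labels <- registryResidues(registry)$label
    if (!all(labels %in% names(tab)))
        stop("state table is missing residue columns: ",
             paste(setdiff(labels, names(tab)), collapse = ", "))
    lapply(seq_len(nrow(tab)), function(i) {
        flags <- setNames(unlist(tab[i, labels]) == "+", labels)
        st <- encodeState(flags, registry)
        if (stateSymbol(st) != tab$symbol[i])
            stop("row ", i, ": flags encode ", stateSymbol(st),
                 " but table says ", tab$symbol[i])
        st
    })
}
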