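#' Default pipeline configuration
#'
#' All tunables of the analysis in one structure: the residue registry,
#' distance cutoffs (hydration-count cutoff 5 A, ion escape threshold 5 A,
#' cluster-selection hydration radius 2.5 A, water-shell radius 9 A),
#' stability thresholds (N_water < 8, RMSF < 0.5 A), the averaging window,
#' pathway definitions, input locations and the seed.  The configuration
#' round-trips losslessly through JSON via [writePipelineConfig()] /
#' [readPipelineConfig()].
#'
#' @param inputDir directory of multi-model PDB trajectories named
#'   `state-<token>_rep<k>.pdb` (see [symbolToken()]); NULL to skip the
#'   metric stages.
#' @param ledgerFile TSV fragment-energy ledger; NULL to skip energies.
#' @param outputDir where report tables are written.
#' @param seed integer recorded in the run log and used for any stochastic
#'   stage.
#' @return a named list ("pipeline config").
#' @export
defaultPipelineConfig <- function(inputDir = NULL, ledgerFile = NULL,
                                  outputDir = tempfile("nakgate-run-"),
                                  seed = 1L) {
    list(registry = "nka",
         cutoffs = list(hydration = 5, escape = 5, hydration_radius = 2.5,
                        shell = 9),
         thresholds = list(nwater = 8, rmsf = 0.5),
         window = NULL,
         pathways = NULL,
         fluxBaseline = 1,
         energyTolerance = 5,
         inputDir = inputDir, ledgerFile = ledgerFile,
         outputDir = outputDir, seed = as.integer(seed))
}

validatePipelineConfig <- function(config) {
    cu <- config$cutoffs; th <- config$thresholds
    if (any(unlist(cu) <= 0) || any(unlist(th) <= 0))
        stop("config error: all cutoffs and thresholds must be positive")
    config
}

#' @rdname defaultPipelineConfig
#' @param config a pipeline config list.
#' @param file JSON path.
#' @export
writePipelineConfig <- function(config, file) {
    jsonlite::write_json(config, file, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    invisible(file)
}

#' @rdname defaultPipelineConfig
#' @export
readPipelineConfig <- function(file) {
    config <- jsonlite::read_json(file, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
    if (!is.null(config$seed)) config$seed <- as.integer(config$seed)
    validatePipelineConfig(config)
}

configRegistry <- function(config) {
    if (identical(config$registry, "nka") || is.null(config$registry))
        return(nkaRegistry())
    sites <- lapply(config$registry, function(s)
        list(glu = s$glu, asp = s$asp))
    bindingSiteRegistry(sites)
}

configPathways <- function(config) {
    if (is.null(config$pathways)) return(NULL)
    lapply(config$pathways, function(p)
        pathwayDefinition(p$name, unlist(p$mouthPoint),
                          unlist(p$sitePoint),
                          corridorRadius = p$corridorRadius %||% 5))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# short stable checksum for provenance lines (no external digest dep);
# hashes the scientific parameters only, not input/output locations, so
# identical analyses in different directories yield identical report bytes
configHash <- function(config) {
    params <- config[setdiff(names(config),
                             c("inputDir", "ledgerFile", "outputDir"))]
    s <- jsonlite::toJSON(params, auto_unbox = TRUE, digits = NA,
                          null = "null")
    v <- utf8ToInt(as.character(s))
    sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 2^31)
}

writeReportTSV <- function(df, file, stage, config) {
    con <- file(file, "w")
    on.exit(close(con))
    writeLines(sprintf("# NaKGate %s seed=%d config=%s", stage,
                       config$seed, configHash(config)), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}

#' Read a report table written by the pipeline
#' @param file TSV path (one `#` provenance header line).
#' @return data.frame.
#' @export
readReportTSV <- function(file) {
    utils::read.table(file, sep = "\t", header = TRUE, comment.char = "#",
                      check.names = FALSE, stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Orchestrates enumeration, per-replica stability metrics, stability
#' classification, water-pathway flux analysis and binding-energy verdicts,
#' writing one TSV per report plus a line-oriented run log.  Stages whose
#' inputs are absent are skipped with an explicit log line, and downstream
#' stages degrade gracefully (an empty input directory yields an
#' enumeration-only report).
#'
#' @param config pipeline config from [defaultPipelineConfig()] or
#'   [readPipelineConfig()].
#' @param trajectories optional in-memory input: a named list (by state
#'   symbol) of lists of [IonTrajectory-class] replicas, bypassing
#'   `config$inputDir`.
#' @param ledger optional in-memory [EnergyLedger-class], bypassing
#'   `config$ledgerFile`.
#' @return invisibly, a named list of the report tables (`states`,
#'   `metrics`, `stability`, `scatter`, `flux`, `energy`, `verdicts`) with
#'   NULL for skipped stages, plus `files` and `log`.
#' @export
runPipeline <- function(config = defaultPipelineConfig(),
                        trajectories = NULL, ledger = NULL) {
    config <- validatePipelineConfig(config)
    registry <- configRegistry(config)
    dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
    logLines <- c(sprintf("[config] hash=%s seed=%d", configHash(config),
                          config$seed),
                  sprintf("[config] output=%s", config$outputDir))
    logIt <- function(...) logLines <<- c(logLines, sprintf(...))
    out <- list()
    # --- enumeration -------------------------------------------------------
    states <- enumerateStates(registry)
    stateFile <- file.path(config$outputDir, "states.tsv")
    writeStateTable(states, stateFile, registry)
    logIt("[enumerate] %d states -> %s", length(states), stateFile)
    out$states <- states
    # --- gather trajectories ----------------------------------------------
    if (is.null(trajectories) && !is.null(config$inputDir) &&
        dir.exists(config$inputDir)) {
        files <- list.files(config$inputDir,
                            pattern = "^state-.*_rep[0-9]+\\.pdb$",
                            full.names = TRUE)
        if (length(files)) {
            tokens <- sub("^state-(.*)_rep[0-9]+\\.pdb$", "\\1",
                          basename(files))
            trajectories <- list()
            for (i in seq_along(files)) {
                sym <- tokenSymbol(tokens[i])
                trajectories[[sym]] <- c(trajectories[[sym]],
                                         list(readMultiModelPDB(files[i])))
            }
            logIt("[input] %d trajectory file(s), %d state(s)",
                  length(files), length(trajectories))
        }
    }
    window <- if (!is.null(config$window))
        metricWindow(config$window$start, config$window$end) else NULL
    # --- metrics + classification -----------------------------------------
    if (!is.null(trajectories) && length(trajectories)) {
        metrics <- list(); reports <- list()
        for (sym in names(trajectories)) {
            reps <- trajectories[[sym]]
            m <- do.call(rbind, lapply(seq_along(reps), function(k)
                replicaMetrics(reps[[k]], replica = k,
                               cutoff = config$cutoffs$hydration,
                               escapeThreshold = config$cutoffs$escape,
                               window = window)))
            metrics[[sym]] <- data.frame(state = sym, m)
            reports[[sym]] <- classifyStability(m, sym, config$thresholds)
        }
        metricTab <- do.call(rbind, metrics)
        rownames(metricTab) <- NULL
        metricFile <- file.path(config$outputDir, "metrics.tsv")
        writeReportTSV(metricTab, metricFile, "metrics", config)
        logIt("[metrics] %d state(s) x replicas -> %s", length(metrics),
              metricFile)
        out$metrics <- metricTab
        out$reports <- reports
        verdicts <- vapply(reports, verdict, character(1))
        stableSyms <- names(verdicts)[verdicts == "stable"]
        enumOrder <- vapply(states, stateSymbol, character(1))
        stableSyms <- enumOrder[enumOrder %in% stableSyms]
        stabFile <- file.path(config$outputDir, "stability.tsv")
        writeStateTable(lapply(stableSyms, decodeSymbol,
                               registry = registry), stabFile, registry)
        logIt("[classify] %d stable / %d unstable / %d excluded -> %s",
              sum(verdicts == "stable"), sum(verdicts == "unstable"),
              sum(verdicts == "excluded_unbinding"), stabFile)
        out$stability <- stableSyms
        out$verdictTable <- data.frame(state = names(verdicts),
                                       verdict = unname(verdicts))
        scatter <- metricTab
        scatter$n_protons <- vapply(scatter$state, function(s)
            nProtons(decodeSymbol(s, registry)), integer(1))
        scatterFile <- file.path(config$outputDir, "scatter.tsv")
        writeReportTSV(scatter, scatterFile, "scatter", config)
        out$scatter <- scatter
        # --- pathway flux --------------------------------------------------
        pws <- configPathways(config)
        if (!is.null(pws)) {
            fluxRows <- list()
            for (sym in names(trajectories)) {
                for (pw in pws) {
                    counts <- vapply(trajectories[[sym]], function(tr) {
                        tr_ <- countTransits(tr, pw)
                        sum(tr_$direction == "inward")
                    }, numeric(1))
                    fs <- fluxSummary(counts,
                                      baseline = config$fluxBaseline %||% 1)
                    fluxRows[[length(fluxRows) + 1L]] <- data.frame(
                        state = sym, pathway = pw@name,
                        site = pw@associatedSite, mean_flux = fs@mean,
                        se = fs@se, gate = fs@gateCall)
                }
            }
            fluxTab <- do.call(rbind, fluxRows)
            fluxFile <- file.path(config$outputDir, "flux.tsv")
            writeReportTSV(fluxTab, fluxFile, "pathways", config)
            logIt("[pathways] %d pathway(s) x %d state(s) -> %s",
                  length(pws), length(trajectories), fluxFile)
            out$flux <- fluxTab
        } else logIt("[pathways] skipped: no pathway definitions in config")
    } else {
        logIt("[metrics] skipped: no trajectories available")
        logIt("[classify] skipped: no trajectories available")
        logIt("[pathways] skipped: no trajectories available")
    }
    # --- binding energies --------------------------------------------------
    if (is.null(ledger) && !is.null(config$ledgerFile) &&
        file.exists(config$ledgerFile))
        ledger <- readEnergyLedger(config$ledgerFile)
    if (!is.null(ledger)) {
        rep <- bindingEnergyReport(ledger,
                                   tolerance = config$energyTolerance %||% 5)
        energyFile <- file.path(config$outputDir, "energies.tsv")
        writeReportTSV(rep@perSite, energyFile, "energies", config)
        verdictFile <- file.path(config$outputDir, "energy_verdicts.tsv")
        writeReportTSV(rep@verdicts, verdictFile, "energies", config)
        logIt("[energies] %d state(s) -> %s", nrow(rep@verdicts),
              energyFile)
        out$energy <- rep
    } else logIt("[energies] skipped: no energy ledger available")
    logFile <- file.path(config$outputDir, "run.log")
    writeLines(c(logLines, sprintf("[done] %s",
        format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))), logFile)
    out$log <- logLines
    out$files <- list.files(config$outputDir, full.names = TRUE)
    invisible(out)
}

#' Render a deterministic text summary of pipeline tables
#'
#' @param result the list returned by [runPipeline()].
#' @return character vector of summary lines (also printed).
#' @export
renderReport <- function(result) {
    lines <- character(0)
    add <- function(...) lines <<- c(lines, sprintf(...))
    if (is.null(result) || !length(result)) {
        add("no results")
        cat(lines, sep = "\n")
        return(invisible(lines))
    }
    if (!is.null(result$states))
        add("protonation states enumerated: %d", length(result$states))
    if (!is.null(result$stability)) {
        add("stable states (%d): %s", length(result$stability),
            paste(result$stability, collapse = ", "))
    }
    if (!is.null(result$verdictTable)) {
        v <- result$verdictTable$verdict
        add("verdicts: %d stable, %d unstable, %d excluded (ion unbinding)",
            sum(v == "stable"), sum(v == "unstable"),
            sum(v == "excluded_unbinding"))
    }
    if (!is.null(result$flux)) {
        f <- result$flux
        for (i in seq_len(nrow(f)))
            add("flux %-8s %-14s mean %.2f ± %s -> gate %s", f$state[i],
                f$pathway[i], f$mean_flux[i],
                ifelse(is.na(f$se[i]), "NA", sprintf("%.2f", f$se[i])),
                f$gate[i])
    }
    if (!is.null(result$energy)) {
        ps <- result$energy@perSite
        for (i in seq_len(nrow(ps)))
            add("energy %-8s site %-3s strength %.2f ± %s %s", ps$state[i],
                ps$site[i], ps$strength[i],
                ifelse(is.na(ps$se[i]), "NA", sprintf("%.2f", ps$se[i])),
                result$energy@unit)
        v <- result$energy@verdicts
        for (i in seq_len(nrow(v)))
            add("verdict %-8s %s", v$state[i],
                if (v$bindable_from_water[i]) "bindable from water"
                else "not bindable from water")
    }
    if (!length(lines)) add("no results")
    cat(lines, sep = "\n")
    invisible(lines)
}
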