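#' Read a delimited matrix file as a typed object
#'
#' Reads whitespace- or comma-delimited numeric text. BOLD files are
#' returned as [BoldMatrix-class] (rows = regions, columns = volumes);
#' structural files are checked for symmetry within \code{1e-6} (relative
#' to the largest weight), exactly symmetrized, and returned as
#' [SCMatrix-class]. Ragged rows and non-finite entries are rejected with
#' the offending line reported.
#'
#' @param path file path.
#' @param kind \code{"bold"} or \code{"sc"}.
#' @param tr repetition time for BOLD files (seconds, default 2).
#' @return a [BoldMatrix-class] or [SCMatrix-class].
#' @export
loadMatrix <- function(path, kind = c("bold", "sc"), tr = 2) {
    kind <- match.arg(kind)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("empty file: ", path)
    rows <- lapply(lines, function(l)
        strsplit(trimws(l), "[,[:space:]]+")[[1]])
    lens <- lengths(rows)
    if (length(unique(lens)) != 1)
        stop("ragged matrix file '", path, "': line ",
             which(lens != lens[1])[1], " has ",
             lens[which(lens != lens[1])[1]], " fields, expected ", lens[1])
    m <- do.call(rbind, lapply(rows, as.numeric))
    if (any(!is.finite(m))) {
        bad <- which(!is.finite(rowSums(m)))[1]
        stop("non-finite entries in '", path, "' (first on line ", bad, ")")
    }
    if (kind == "bold") return(boldMatrix(m, tr))
    if (nrow(m) != ncol(m)) stop("SC matrix must be square")
    asym <- max(abs(m - t(m)))
    if (asym > 1e-6 * max(abs(m), 1e-12))
        stop("SC matrix asymmetric beyond tolerance (max |C - t(C)| = ",
             format(asym), ")")
    m <- (m + t(m)) / 2
    diag(m) <- 0
    scMatrix(m)
}

#' Write a matrix (or typed container) as delimited text
#'
#' @param x matrix, [BoldMatrix-class] or [SCMatrix-class].
#' @param path output file path.
#' @param sep field separator (default a single space).
#' @return \code{path}, invisibly.
#' @export
writeMatrixFile <- function(x, path, sep = " ") {
    m <- if (is(x, "BoldMatrix")) x@values
         else if (is(x, "SCMatrix")) x@weights
         else as.matrix(x)
    utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                       path, sep = sep, row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Default pipeline configuration
#'
#' All defaults are the analysis constants used throughout: narrowband
#' 0.04-0.07 Hz, wide band 0.04-0.25 Hz, TR 2 s, FCD windows of 30 TRs
#' shifted by 1 TR (2 s), noise beta 0.02, learning rate eta 0.1, hub
#' strength threshold 4.5, per-pair significance 0.01, g grid 0-3 in steps
#' of 0.1 with 10 trials per candidate.
#'
#' @param ... named overrides of any field.
#' @return nested list of configuration values.
#' @export
defaultRunConfig <- function(...) {
    cfg <- list(
        band = c(0.04, 0.07),
        wideBand = c(0.04, 0.25),
        tr = 2,
        window = 30L,
        step = 1L,
        settle = 10L,
        gGrid = seq(0, 3, by = 0.1),
        gTrials = 10L,
        eta = 0.1,
        beta = 0.02,
        dt = 0.1,
        transient = 60,
        duration = 660,
        maxIter = 100L,
        tol = 0.01,
        hubThreshold = 4.5,
        alpha = 0.01,
        nSurrogates = 100L,
        seed = 1L
    )
    over <- list(...)
    cfg[names(over)] <- over
    cfg
}

# Run one stage, capturing failures as records instead of aborting the run.
runStage <- function(name, expr) {
    tryCatch(list(ok = TRUE, value = expr),
             error = function(e) {
                 warning("stage '", name, "' failed: ", conditionMessage(e))
                 list(ok = FALSE, error = conditionMessage(e))
             })
}

#' Run the full analysis pipeline on one or more groups
#'
#' Sequences the whole analysis for each group of subjects: per-subject
#' phase-dynamics summaries (integration, segregation, fluctuations, mean
#' FCD) with descriptive group means and standard errors; homogeneous
#' global-coupling fit on the pooled empirical FCD distribution;
#' heterogeneous local fits (bare a and effective a_eff); the
#' a_eff-versus-strength residual analysis; linear stability of the fitted
#' model; and the structural graph summary. Group comparisons are
#' descriptive only (means with standard errors) — no inferential
#' statistics are computed.
#'
#' @param groups named list; each element is a list of [BoldMatrix-class]
#'   objects (the group's subjects) or of file paths readable by
#'   [loadMatrix()].
#' @param sc an [SCMatrix-class] (model-scaled) or a file path.
#' @param config configuration list from [defaultRunConfig()].
#' @return list with one result bundle per group (dynamics, globalFit,
#'   localFit, effectiveFit, residuals, stability, each wrapped in a
#'   \code{list(ok, value/error)} stage record), a shared \code{graph}
#'   block, and a \code{manifest} echoing the configuration and seeds.
#' @export
runFullPipeline <- function(groups, sc, config = defaultRunConfig()) {
    if (is.character(sc)) sc <- loadMatrix(sc, "sc")
    cfg <- config
    groupResults <- list()
    for (gi in seq_along(groups)) {
        gname <- names(groups)[gi]
        if (is.null(gname) || !nzchar(gname)) gname <- paste0("group", gi)
        subjects <- lapply(groups[[gi]], function(b)
            if (is.character(b)) loadMatrix(b, "bold", tr = cfg$tr) else b)
        gseed <- subSeed(cfg$seed, gi)

        dyn <- runStage("dynamics", {
            per <- lapply(seq_along(subjects), function(s)
                dynamicsSummary(subjects[[s]], cfg$band[1], cfg$band[2],
                                cfg$settle, cfg$window, cfg$step,
                                cfg$nSurrogates, cfg$alpha,
                                seed = subSeed(gseed, s)))
            tab <- do.call(rbind, lapply(per, as.data.frame))
            list(perSubject = tab,
                 mean = colMeans(tab),
                 se = apply(tab, 2, stats::sd) / sqrt(nrow(tab)))
        })

        empValues <- runStage("empiricalFCD", {
            unlist(lapply(subjects, function(b) {
                series <- phaseInteractions(
                    instantaneousPhases(
                        bandpassFilter(b, cfg$band[1], cfg$band[2])),
                    cfg$settle)
                upperTriValues(fcd(series, cfg$window, cfg$step)@similarity)
            }))
        })

        omega <- runStage("frequencies",
            estimateIntrinsicFrequencies(subjects, cfg$band))

        gfit <- runStage("globalFit", {
            stopifnot(empValues$ok, omega$ok)
            template <- hopfModelSpec(a = 0, omega = omega$value$omega,
                                      g = 0, C = sc, beta = cfg$beta,
                                      dt = cfg$dt)
            fitGlobalCoupling(empValues$value, template, cfg$gGrid,
                              cfg$gTrials, cfg$duration, cfg$tr,
                              seed = subSeed(gseed, 101L),
                              low = cfg$band[1], high = cfg$band[2],
                              settle = cfg$settle, window = cfg$window,
                              step = cfg$step, transient = cfg$transient)
        })

        pEmp <- runStage("powerProportions", {
            p <- rowMeans(vapply(subjects, function(b)
                powerProportion(b, narrowBand = cfg$band,
                                wideBand = cfg$wideBand),
                numeric(nRegions(sc))))
            p
        })

        lfit <- runStage("localFit", {
            stopifnot(gfit$ok, pEmp$ok, omega$ok)
            spec <- hopfModelSpec(a = 0, omega = omega$value$omega,
                                  g = gfit$value@gOpt, C = sc,
                                  beta = cfg$beta, dt = cfg$dt)
            fitLocalBifurcation(pEmp$value, spec, cfg$eta, cfg$maxIter,
                                cfg$tol, seed = subSeed(gseed, 202L),
                                duration = cfg$duration, tr = cfg$tr,
                                transient = cfg$transient,
                                narrowBand = cfg$band,
                                wideBand = cfg$wideBand)
        })

        efit <- runStage("effectiveFit", {
            stopifnot(gfit$ok, pEmp$ok, omega$ok)
            gOpt <- gfit$value@gOpt
            spec <- hopfModelSpec(a = -gOpt * nodeStrengths(sc),
                                  omega = omega$value$omega, g = gOpt,
                                  C = sc, beta = cfg$beta, dt = cfg$dt,
                                  effectiveMode = TRUE)
            fitEffectiveParameters(pEmp$value, spec, cfg$eta, cfg$maxIter,
                                   cfg$tol, seed = subSeed(gseed, 303L),
                                   duration = cfg$duration, tr = cfg$tr,
                                   transient = cfg$transient,
                                   narrowBand = cfg$band,
                                   wideBand = cfg$wideBand)
        })

        resid <- runStage("residuals", {
            stopifnot(efit$ok)
            strengthResidualAnalysis(efit$value@aHat, nodeStrengths(sc))
        })

        stab <- runStage("stability", {
            stopifnot(gfit$ok, lfit$ok, omega$ok)
            spec <- hopfModelSpec(a = lfit$value@aHat,
                                  omega = omega$value$omega,
                                  g = gfit$value@gOpt, C = sc,
                                  beta = cfg$beta, dt = cfg$dt)
            res <- eigendecomposeSorted(buildJacobian(spec))
            list(result = res,
                 hubSummary = hubStabilitySummary(res, nodeStrengths(sc)))
        })

        groupResults[[gname]] <- list(
            dynamics = dyn, globalFit = gfit, localFit = lfit,
            effectiveFit = efit, residuals = resid, stability = stab)
    }

    graph <- runStage("graph", graphSummary(sc, cfg$hubThreshold))

    list(
        groups = groupResults,
        graph = graph,
        manifest = list(
            config = cfg,
            nGroups = length(groups),
            packageVersion = as.character(
                utils::packageVersion("hopfbrain")),
            rVersion = R.version.string
        )
    )
}

#' Write a pipeline result bundle as a JSON report
#'
#' Serializes the scalar outputs of [runFullPipeline()] (group summary
#' statistics, fitted parameters, stability depths, graph descriptors) and
#' the run manifest to JSON. Matrices are reduced to the quantities a
#' report needs; full objects stay in R.
#'
#' @param bundle result of [runFullPipeline()].
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeRunReport <- function(bundle, path) {
    pick <- function(st, f) if (isTRUE(st$ok)) f(st$value) else
        list(error = st$error)
    rep <- list(
        groups = lapply(bundle$groups, function(gr) list(
            dynamics = pick(gr$dynamics, function(v)
                list(mean = as.list(v$mean), se = as.list(v$se))),
            gOpt = pick(gr$globalFit, function(v) v@gOpt),
            ksCurve = pick(gr$globalFit, function(v)
                list(g = v@gGrid, ksMean = v@ksMean, ksSE = v@ksSE)),
            aHat = pick(gr$localFit, function(v) v@aHat),
            aEffHat = pick(gr$effectiveFit, function(v) v@aHat),
            medianAbsResidual = pick(gr$residuals,
                function(v) v$medianAbsResidual),
            stabilityDepth = pick(gr$stability,
                function(v) v$hubSummary$minReal),
            hubCorrelations = pick(gr$stability,
                function(v) v$hubSummary$correlations)
        )),
        graph = pick(bundle$graph, function(v) list(
            strengths = v$strengths, hubIndices = v$hubIndices,
            hubMeanWeight = v$hubMeanWeight,
            nonhubMeanWeight = v$nonhubMeanWeight,
            kDensityCutoff = attr(v$kDensityCurve, "cutoff"))),
        manifest = bundle$manifest
    )
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    invisible(path)
}
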