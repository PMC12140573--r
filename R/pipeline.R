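#' Run the full analysis pipeline from one configuration
#'
#' Orchestrates the stages synth -> (signals -> tfr -> surrogate) -> ec ->
#' netstats -> classify -> behavior from a single configuration (an R list or
#' a path to a JSON file), writing every artifact as CSV/TSV under `outDir`
#' together with a JSON manifest recording stage, seed and MD5 checksum per
#' file.  A second run with the same configuration reproduces identical
#' checksums.  No stage mutates its inputs; all randomness flows from the
#' per-stage seeds derived from `config$seed`.
#'
#' Recognised configuration entries (all optional): `seed` (default 1),
#' `stages` (subset of `c("synth", "tfr", "surrogate", "ec", "netstats",
#' "classify", "behavior")`), `table` (path to an existing portrait CSV,
#' replacing the synth stage), `synth` (arguments for [synthConfig()]),
#' `ec = list(nBoot, includeBehavior)`, `classify = list(nResamples)`,
#' `behavior = list(nFolds)`, `netstats = list(nShuffles)`.
#'
#' @param config list or JSON file path.
#' @param outDir output directory (created if missing); default
#'   `config$outDir` or a temporary directory.
#' @return the manifest as a `data.frame` (also written to
#'   `manifest.json`), invisibly the output directory in attribute `outDir`.
#' @export
runPipeline <- function(config = list(), outDir = NULL) {
    if (is.character(config)) config <- jsonlite::fromJSON(config)
    seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
    stages <- if (is.null(config$stages))
        c("synth", "ec", "netstats", "classify", "behavior")
    else config$stages
    known <- c("synth", "tfr", "surrogate", "ec", "netstats", "classify",
               "behavior")
    if (length(bad <- setdiff(stages, known)))
        stop("unknown stage(s): ", paste(bad, collapse = ", "))
    if (is.null(outDir))
        outDir <- if (!is.null(config$outDir)) config$outDir else tempfile("run")
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    manifest <- list()
    addArtifact <- function(stage, file) {
        manifest[[length(manifest) + 1L]] <<-
            data.frame(stage = stage, file = basename(file),
                       seed = deriveSeed(seed, stage),
                       md5 = unname(tools::md5sum(file)))
    }

    ## --- input table: synth stage or user-provided CSV -------------------
    pe <- NULL
    signals <- NULL
    if (!is.null(config$table)) {
        pe <- readPortraits(config$table)
    } else if (any(c("synth", "tfr", "surrogate") %in% stages)) {
        sc <- do.call(synthConfig,
                      c(config$synth, list(seed = deriveSeed(seed, "synth"))))
        if (any(c("tfr", "surrogate") %in% stages)) {
            signals <- generateSignals(sc)
            pe <- signals@portraits
        } else pe <- generatePortraits(sc)
        if ("synth" %in% stages) {
            f <- file.path(outDir, "portraits.csv")
            writePortraits(pe, f)
            addArtifact("synth", f)
            g <- file.path(outDir, "ground_truth_ec.csv")
            writeEC(groundTruthEC(sc, names(sc$trials_per_category)[1L]), g)
            addArtifact("synth", g)
        }
    }
    if (is.null(pe))
        stop("missing upstream artifact for stage '", stages[1L],
             "': provide config$table or enable the synth stage")

    if ("tfr" %in% stages) {
        peTfr <- portraitsFromSignals(signals)
        f <- file.path(outDir, "portraits_tfr.csv")
        writePortraits(peTfr, f)
        addArtifact("tfr", f)
        pe <- peTfr
    }
    if ("surrogate" %in% stages) {
        peSur <- surrogatePortraits(signals,
                                    seed = deriveSeed(seed, "surrogate"))
        f <- file.path(outDir, "portraits_surrogate.csv")
        writePortraits(peSur, f)
        addArtifact("surrogate", f)
    }

    ec <- NULL
    if (any(c("ec", "netstats") %in% stages)) {
        nBoot <- if (is.null(config$ec$nBoot)) 50L else config$ec$nBoot
        incB <- isTRUE(config$ec$includeBehavior)
        ec <- fitEC(pe, includeBehavior = incB, nBoot = nBoot,
                    seed = deriveSeed(seed, "ec"))
        f <- file.path(outDir, "ec_pooled.csv")
        writeEC(ec, f)
        addArtifact("ec", f)
        e <- file.path(outDir, "ec_pooled_edges.tsv")
        ecEdgeList(ec, e)
        addArtifact("ec", e)
        fc <- computeFC(pe, nBoot = nBoot, seed = deriveSeed(seed, "ec"))
        f2 <- file.path(outDir, "fc_pooled.csv")
        utils::write.csv(fc, f2, row.names = TRUE)
        addArtifact("ec", f2)
    }
    if ("netstats" %in% stages) {
        nSh <- if (is.null(config$netstats$nShuffles)) 1000L
               else config$netstats$nShuffles
        H <- homophily(ec)
        rows <- lapply(names(H), function(ax) {
            nn <- homophilyNull(ec, ax, nSh,
                                seed = deriveSeed(seed, paste("netstats", ax)))
            data.frame(category = "pooled", axis = ax, observed = H[[ax]],
                       null_mean = mean(nn$values), p = nn$p)
        })
        f <- file.path(outDir, "homophily.csv")
        utils::write.csv(do.call(rbind, rows), f, row.names = FALSE)
        addArtifact("netstats", f)
    }
    if ("classify" %in% stages) {
        nRes <- if (is.null(config$classify$nResamples)) 100L
                else config$classify$nResamples
        f <- file.path(outDir, "discrimination.csv")
        discriminationTable(pe, nResamples = nRes,
                            seed = deriveSeed(seed, "classify"), file = f)
        addArtifact("classify", f)
    }
    if ("behavior" %in% stages) {
        nF <- if (is.null(config$behavior$nFolds)) 20L else config$behavior$nFolds
        f <- file.path(outDir, "behavior.csv")
        behaviorTable(pe, nFolds = nF, seed = deriveSeed(seed, "behavior"),
                      file = f)
        addArtifact("behavior", f)
    }

    mf <- do.call(rbind, manifest)
    jsonlite::write_json(mf, file.path(outDir, "manifest.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    attr(mf, "outDir") <- outDir
    invisible(mf)
}
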