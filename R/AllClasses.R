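#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

## Frozen element ordering: region-major, then epoch, then band.
.REGIONS <- c("IC1", "IC2", "IC3", "IC4")
.EPOCHS  <- c("Pre", "During", "Post")
.BANDS   <- c("theta", "alpha", "beta", "gamma")
.CATEGORIES <- c("NR-Hit", "NR-Miss", "RS-Hit", "RS-Miss", "Ct-Miss", "AR-Miss")

#' Oscillatory element index
#'
#' The 48 oscillatory elements of a portrait are the combinations of
#' 4 cortical regions (independent components IC1--IC4), 3 movement epochs
#' (Pre / During / Post movement) and 4 frequency bands (theta, alpha, beta,
#' gamma).  The column order is frozen as region-major, then epoch, then band
#' (IC1_Pre_theta, IC1_Pre_alpha, ..., IC4_Post_gamma) and is used in every
#' table, matrix and CSV header produced by the package.
#'
#' @return A `data.frame` with columns `name`, `region`, `epoch`, `band` and
#'   `column` (1-based position in the frozen order), one row per element.
#' @examples
#' head(elementInfo())
#' @export
elementInfo <- function() {
    grid <- expand.grid(band = .BANDS, epoch = .EPOCHS, region = .REGIONS,
                        stringsAsFactors = FALSE)
    grid <- grid[, c("region", "epoch", "band")]
    data.frame(name = paste(grid$region, grid$epoch, grid$band, sep = "_"),
               grid, column = seq_len(nrow(grid)), stringsAsFactors = FALSE)
}

#' @rdname elementInfo
#' @export
elementNames <- function() elementInfo()$name

#' Trial categories
#'
#' The six trial categories of the visuomotor rotation task: NR (no rotation),
#' RS (rotation countered by a re-aiming strategy), Ct (unexpected rotation
#' onset) and AR (first trial after rotation removal), split into Hit/Miss by
#' target success where both outcomes occur.
#'
#' @return Character vector of the six category labels.
#' @export
trialCategories <- function() .CATEGORIES

#' PortraitExperiment: single-trial oscillatory portraits
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding one trial
#' per column and the 48 oscillatory elements as rows (assay `"elements"`).
#' `rowData` carries the (region, epoch, band) labels of each element;
#' `colData` carries per-trial metadata: `subject`, `category`,
#' `movement_error` (signed perpendicular deviation at peak velocity,
#' arbitrary units) and `movement_duration` (seconds).
#'
#' @slot .. inherited from `SummarizedExperiment`.
#' @seealso [PortraitExperiment()] for the constructor,
#'   [generatePortraits()] for synthetic tables,
#'   [readPortraits()]/[writePortraits()] for the CSV interface.
#' @aliases PortraitExperiment-class
#' @export
setClass("PortraitExperiment", contains = "SummarizedExperiment")

setValidity("PortraitExperiment", function(object) {
    msg <- NULL
    if (!"elements" %in% assayNames(object))
        msg <- c(msg, "assay 'elements' is required")
    if (nrow(object) != 48L)
        msg <- c(msg, "exactly 48 element rows are required")
    else if (!identical(rownames(object), elementNames()))
        msg <- c(msg, "rownames must follow the frozen element order (see elementNames())")
    need <- c("subject", "category", "movement_error", "movement_duration")
    miss <- setdiff(need, colnames(colData(object)))
    if (length(miss))
        msg <- c(msg, paste0("missing colData column(s): ",
                             paste(miss, collapse = ", ")))
    if (!length(msg)) {
        if (anyNA(assay(object, "elements")))
            msg <- c(msg, "element values must not contain NA")
        bad <- setdiff(unique(object$category), .CATEGORIES)
        if (length(bad))
            msg <- c(msg, paste0("unknown trial category: ",
                                 paste(bad, collapse = ", ")))
        if (any(object$movement_duration <= 0))
            msg <- c(msg, "movement_duration must be positive")
    }
    if (is.null(msg)) TRUE else msg
})

#' ECMatrix: weighted directed connectivity between oscillatory elements
#'
#' Square weighted adjacency matrix over element nodes (plus optional
#' `error`/`duration` behaviour nodes).  Entry `(t, s)` is the
#' bootstrap-averaged regression coefficient of source `s` in the
#' random-intercept model predicting target `t`; the diagonal is structurally
#' zero.  Coefficients are on the z-scored predictor/target scale, so weights
#' are comparable across nodes.
#'
#' @slot weights numeric matrix, target rows x source columns, zero diagonal.
#' @slot nodes character vector of node identifiers (row/column names).
#' @slot performance named numeric, per-target cross-validated Pearson r
#'   between held-out predictions and observed values (may be empty).
#' @slot nBoot integer, number of bootstrap resamples averaged.
#' @slot provenance character, trial category or `"pooled"`.
#' @seealso [fitEC()], [computeFC()], [groundTruthEC()], [homophily()]
#' @aliases ECMatrix-class
#' @export
setClass("ECMatrix",
         representation(weights = "matrix", nodes = "character",
                        performance = "numeric", nBoot = "integer",
                        provenance = "character"))

setValidity("ECMatrix", function(object) {
    w <- object@weights
    if (nrow(w) != ncol(w)) return("weights must be square")
    if (length(object@nodes) != nrow(w)) return("nodes must match weights dimension")
    if (any(!is.finite(w))) return("weights must be finite")
    if (any(diag(w) != 0)) return("diagonal must be zero")
    TRUE
})

#' MixedModelFit: Gaussian random-intercept linear model fit
#'
#' Result of [fitLMM()]: the model
#' \deqn{y_{ij} = \beta_0 + \beta_1 X_{ij} + u_j + e_{ij},\quad
#'       e_{ij} \sim N(0, \sigma_e^2),\ u_j \sim N(0, \tau^2)}
#' with a common intercept and slopes and one random intercept per subject,
#' estimated by (restricted) maximum likelihood profiled over the variance
#' ratio.
#'
#' @slot beta0 numeric(1), common intercept.
#' @slot beta named numeric, common slopes.
#' @slot u named numeric, per-subject intercept BLUPs (0 for unseen subjects).
#' @slot sigma2 numeric(1), residual variance.
#' @slot tau2 numeric(1), subject-intercept variance.
#' @slot se named numeric, standard errors of `c(beta0, beta)`.
#' @slot nObs integer, number of training observations.
#' @slot REML logical, restricted likelihood used.
#' @slot ridge numeric(1), ridge penalty actually applied (0 if none).
#' @seealso [fitLMM()], [predictLMM()]
#' @aliases MixedModelFit-class
#' @export
setClass("MixedModelFit",
         representation(beta0 = "numeric", beta = "numeric", u = "numeric",
                        sigma2 = "numeric", tau2 = "numeric", se = "numeric",
                        nObs = "integer", REML = "logical", ridge = "numeric"))

#' TFMap: single-trial time-frequency power map for one region
#'
#' @slot power numeric matrix, time x frequency; raw wavelet power
#'   (nonnegative) or log-normalized power.
#' @slot times numeric, seconds relative to movement onset.
#' @slot freqs numeric, Hz.
#' @slot onset,offset numeric(1), movement markers in seconds.
#' @slot region character(1).
#' @slot trialId character(1).
#' @slot logNormalized logical(1).
#' @slot edge logical, per-time-sample flag marking samples within 3 temporal
#'   standard deviations of either segment end at the lowest frequency.
#' @seealso [morletTransform()], [normalizePower()], [extractPortrait()]
#' @aliases TFMap-class
#' @export
setClass("TFMap",
         representation(power = "matrix", times = "numeric", freqs = "numeric",
                        onset = "numeric", offset = "numeric",
                        region = "character", trialId = "character",
                        logNormalized = "logical", edge = "logical"))

setValidity("TFMap", function(object) {
    if (nrow(object@power) != length(object@times))
        return("power rows must match times")
    if (ncol(object@power) != length(object@freqs))
        return("power columns must match freqs")
    if (!object@logNormalized && any(object@power < 0))
        return("raw power must be nonnegative")
    TRUE
})

#' SignalSet: per-trial, per-region raw time courses
#'
#' Container for trial-epoched multichannel signals, as produced by
#' [generateSignals()] or assembled from recordings.  Each trial spans
#' `[-1.5, duration + 1.5]` seconds around movement onset.
#'
#' @slot signals list, one element per trial: a numeric matrix
#'   (time x region) with attributes handled through `times`.
#' @slot times list of numeric vectors, seconds relative to movement onset.
#' @slot fs numeric(1), sampling rate in Hz.
#' @slot portraits the generating [PortraitExperiment] (trial metadata and,
#'   for synthetic data, the element values used to synthesise the signals).
#' @aliases SignalSet-class
#' @export
setClass("SignalSet",
         representation(signals = "list", times = "list", fs = "numeric",
                        portraits = "PortraitExperiment"))

setValidity("SignalSet", function(object) {
    if (length(object@signals) != length(object@times))
        return("signals and times must have equal length")
    if (length(object@signals) != ncol(object@portraits))
        return("one signal matrix per portrait trial is required")
    TRUE
})
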