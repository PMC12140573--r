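#' Predict single-trial behaviour from oscillatory portraits
#'
#' Per fold, a random-intercept linear model of the behavioural target on the
#' 48 (z-scored) portrait elements is fitted on a random 75% of trials
#' (stratified by subject) and evaluated on the held-out 25% by Pearson r and
#' mean squared error.
#'
#' @param pe a [PortraitExperiment-class].
#' @param target `"error"` (signed movement-direction error) or `"duration"`.
#' @param category a category label to restrict to, or `"pooled"` (default).
#' @param features `"portrait"` or a vector of element names.
#' @param nFolds number of random splits (default 20).
#' @param trainFrac training fraction (default 0.75).
#' @param seed integer seed.
#' @return list with `target`, `category`, `featureSet`, `r` and `mse`
#'   (per-fold vectors), `nFolds`, `shuffled`, `seed`.
#' @seealso [shuffledBehaviorControl()]
#' @export
predictBehavior <- function(pe, target = c("error", "duration"),
                            category = "pooled", features = "portrait",
                            nFolds = 20, trainFrac = 0.75, seed = 1) {
    behaviorCV(pe, match.arg(target), category, features, nFolds, trainFrac,
               seed, shuffle = FALSE)
}

#' Shuffled-target control for behaviour prediction
#'
#' Identical protocol to [predictBehavior()] except the target is permuted
#' within the training split only; the held-out r distribution then
#' calibrates chance.
#'
#' @inheritParams predictBehavior
#' @return as [predictBehavior()], with `shuffled = TRUE`.
#' @export
shuffledBehaviorControl <- function(pe, target = c("error", "duration"),
                                    category = "pooled",
                                    features = "portrait", nFolds = 20,
                                    trainFrac = 0.75, seed = 1) {
    behaviorCV(pe, match.arg(target), category, features, nFolds, trainFrac,
               seed, shuffle = TRUE)
}

behaviorCV <- function(pe, target, category, features, nFolds, trainFrac,
                       seed, shuffle) {
    if (!identical(category, "pooled")) {
        keep <- pe$category == category
        if (!any(keep)) stop("category absent: ", category)
        pe <- pe[, keep]
    }
    y <- switch(target, error = pe$movement_error,
                duration = pe$movement_duration)
    if (stats::sd(y) < 1e-12) stop("constant target: nothing to predict")
    X <- featureMatrix(pe, features)
    subj <- pe$subject
    withSeed(seed, {
        res <- vapply(seq_len(nFolds), function(b) {
            tr <- stratifiedTrainIndices(subj, trainFrac)
            te <- setdiff(seq_along(y), tr)
            ytr <- y[tr]
            if (shuffle) ytr <- sample(ytr)
            st <- scaleStats(X[tr, , drop = FALSE])
            fit <- fitLMM(applyScale(X[tr, , drop = FALSE], st), ytr, subj[tr])
            pred <- predictLMM(fit, applyScale(X[te, , drop = FALSE], st),
                               subj[te])
            c(safeCor(pred, y[te]), mean((pred - y[te])^2))
        }, numeric(2))
    })
    list(target = target, category = category,
         featureSet = if (identical(features, "portrait")) "portrait"
                      else paste(features, collapse = "+"),
         r = res[1L, ], mse = res[2L, ], nFolds = as.integer(nFolds),
         shuffled = shuffle, seed = as.integer(seed))
}

#' Bhattacharyya coefficient between two discrete distributions
#'
#' \deqn{BC(P, Q) = \sum_x \sqrt{P(x) Q(x)}}: symmetric, in [0, 1], equal to
#' 1 iff P = Q and 0 for disjoint supports.
#'
#' @param P,Q nonnegative vectors over the same support bins, each summing to
#'   1 (tolerance 1e-8).
#' @return numeric(1).
#' @examples
#' bhattacharyya(c(0.5, 0.5), c(0.9, 0.1))  # sqrt(.45) + sqrt(.05)
#' @export
bhattacharyya <- function(P, Q) {
    if (length(P) != length(Q)) stop("P and Q must share support bins")
    if (any(P < 0) || any(Q < 0)) stop("negative probability mass")
    if (abs(sum(P) - 1) > 1e-8 || abs(sum(Q) - 1) > 1e-8)
        stop("P and Q must each sum to 1")
    sum(sqrt(P * Q))
}

#' Distribution overlap of one element between trial groups
#'
#' Histograms the element's values in a trial category and in a reference
#' trial set on shared equal-width bins spanning their pooled range, and
#' returns the Bhattacharyya coefficient of the two normalized histograms.
#'
#' @param pe a [PortraitExperiment-class].
#' @param element element name (see [elementNames()]).
#' @param categoryA category label defining the first sample.
#' @param reference the reference sample: another category label, or a
#'   logical/integer trial subset.  Default: all Hit trials (the successful
#'   movements commonly used as the reference range).
#' @param nBins number of histogram bins (default 20, reported in the
#'   attributes).
#' @return numeric(1) Bhattacharyya coefficient, with attributes `nBins`,
#'   `nA`, `nRef`.
#' @export
elementOverlap <- function(pe, element, categoryA, reference = NULL,
                           nBins = 20) {
    x <- elementMatrix(pe)[, element]
    a <- x[pe$category == categoryA]
    ref <- if (is.null(reference)) x[grepl("-Hit$", pe$category)]
           else if (is.character(reference)) x[pe$category == reference]
           else x[reference]
    if (length(a) < 30L || length(ref) < 30L)
        stop("both samples need at least 30 trials")
    br <- seq(min(a, ref), max(a, ref), length.out = nBins + 1L)
    br[1L] <- br[1L] - 1e-9
    br[nBins + 1L] <- br[nBins + 1L] + 1e-9
    hA <- tabulate(findInterval(a, br, rightmost.closed = TRUE), nBins)
    hR <- tabulate(findInterval(ref, br, rightmost.closed = TRUE), nBins)
    bc <- bhattacharyya(hA / sum(hA), hR / sum(hR))
    attributes(bc) <- list(nBins = nBins, nA = length(a), nRef = length(ref))
    bc
}

#' Tidy behaviour-prediction report
#'
#' One row per (category, target, fold) with r, MSE and the shuffled flag;
#' includes the pooled model and optional shuffled controls.
#'
#' @inheritParams predictBehavior
#' @param withControl logical, add shuffled-target controls.
#' @param file optional CSV output path.
#' @return `data.frame`.
#' @export
behaviorTable <- function(pe, nFolds = 20, seed = 1, withControl = TRUE,
                          file = NULL) {
    cats <- c("pooled", intersect(.CATEGORIES, unique(pe$category)))
    rows <- list()
    for (cc in cats) for (tg in c("error", "duration")) {
        runs <- list(predictBehavior(pe, tg, cc, nFolds = nFolds,
                                     seed = deriveSeed(seed, paste(cc, tg))))
        if (withControl)
            runs <- c(runs, list(shuffledBehaviorControl(
                pe, tg, cc, nFolds = nFolds,
                seed = deriveSeed(seed, paste(cc, tg, "shuf")))))
        for (res in runs)
            rows[[length(rows) + 1L]] <-
                data.frame(category = cc, target = tg,
                           fold = seq_len(res$nFolds), r = res$r,
                           mse = res$mse, shuffled = res$shuffled)
    }
    out <- do.call(rbind, rows)
    if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
    out
}
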