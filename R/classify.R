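#' Area under the ROC curve
#'
#' Computed from the parametric TP-vs-FP curve over all score thresholds
#' (trapezoidal integration with tied scores grouped), which equals the
#' pair-counting definition \eqn{P(s_+ > s_-) + \frac12 P(s_+ = s_-)}
#' exactly.  The integration is carried out on integer counts and divided by
#' \eqn{n_+ n_-} once, so no floating-point accumulation error enters.
#'
#' @param scores numeric classifier scores (larger = more positive).
#' @param labels logical or 0/1 vector; both classes must be present.
#' @return numeric(1) in [0, 1].
#' @examples
#' rocAUC(c(0.9, 0.4, 0.4, 0.1), c(1, 1, 0, 0))  # 0.875
#' @export
rocAUC <- function(scores, labels) {
    labels <- as.logical(labels)
    nP <- sum(labels)
    nN <- sum(!labels)
    if (nP == 0L || nN == 0L) stop("both classes must be present")
    ord <- order(scores, decreasing = TRUE)
    s <- scores[ord]
    l <- labels[ord]
    last <- c(s[-length(s)] != s[-1L], TRUE)   # last index of each tie group
    tp <- c(0, cumsum(l)[last])
    fp <- c(0, cumsum(!l)[last])
    area2 <- sum(diff(fp) * (tp[-1L] + tp[-length(tp)]))  # 2 * area in counts
    area2 / (2 * nP * nN)
}

## shared engine for pairwise discrimination with optional label shuffling
discriminate <- function(pe, catA, catB, features, nResamples, trainFrac,
                         seed, shuffle) {
    idx <- which(pe$category %in% c(catA, catB))
    if (sum(pe$category == catA) < 10L || sum(pe$category == catB) < 10L)
        stop("both categories need at least 10 trials")
    X <- featureMatrix(pe, features)[idx, , drop = FALSE]
    y <- as.numeric(pe$category[idx] == catB)
    subj <- pe$subject[idx]
    strat <- paste(pe$category[idx], subj)   # preserve class and subject mix
    withSeed(seed, {
        auc <- vapply(seq_len(nResamples), function(b) {
            tr <- stratifiedTrainIndices(strat, trainFrac)
            te <- setdiff(seq_along(y), tr)
            ytr <- y[tr]
            if (shuffle) ytr <- sample(ytr)          # training labels only
            st <- scaleStats(X[tr, , drop = FALSE])
            fit <- fitLMM(applyScale(X[tr, , drop = FALSE], st), ytr, subj[tr])
            sc <- predictLMM(fit, applyScale(X[te, , drop = FALSE], st),
                             subj[te])
            rocAUC(sc, y[te])
        }, numeric(1))
    })
    list(categoryPair = c(catA, catB),
         featureSet = if (identical(features, "portrait")) "portrait"
                      else paste(features, collapse = "+"),
         auc = auc, nResamples = as.integer(nResamples),
         seed = as.integer(seed), shuffled = shuffle)
}

#' Pairwise trial-category discrimination
#'
#' For each of `nResamples` stratified train/test splits (75/25, preserving
#' category proportions and subject mix), a random-intercept linear model is
#' fitted with the 0/1 category as target and the feature set as (z-scored)
#' predictors; held-out trials are scored by the continuous model output and
#' an ROC AUC is recorded.  Deterministic given the seed.
#'
#' @param pe a [PortraitExperiment-class].
#' @param catA,catB the two category labels (each needs >= 10 trials).
#' @param features `"portrait"` (all 48 elements) or a vector of element
#'   names for single-element classifiers.
#' @param nResamples number of resampled splits (default 100).
#' @param trainFrac training fraction (default 0.75).
#' @param seed integer seed.
#' @return list with `categoryPair`, `featureSet`, `auc` (per-resample AUC
#'   vector), `nResamples`, `seed`, `shuffled`.
#' @seealso [shuffledControl()] for the label-shuffle null.
#' @export
pairwiseDiscriminate <- function(pe, catA, catB, features = "portrait",
                                 nResamples = 100, trainFrac = 0.75,
                                 seed = 1) {
    discriminate(pe, catA, catB, features, nResamples, trainFrac, seed,
                 shuffle = FALSE)
}

#' Label-shuffle control for pairwise discrimination
#'
#' Identical protocol to [pairwiseDiscriminate()], except category labels are
#' permuted within each training set (preserving class counts); test labels
#' stay intact, so the mean AUC calibrates the chance level.
#'
#' @inheritParams pairwiseDiscriminate
#' @return as [pairwiseDiscriminate()], with `shuffled = TRUE`.
#' @export
shuffledControl <- function(pe, catA, catB, features = "portrait",
                            nResamples = 100, trainFrac = 0.75, seed = 1) {
    discriminate(pe, catA, catB, features, nResamples, trainFrac, seed,
                 shuffle = TRUE)
}

#' Summarise pairwise discrimination over all category pairs
#'
#' Runs [pairwiseDiscriminate()] (and optionally its shuffled control) for
#' every unordered pair of categories present.
#'
#' @inheritParams pairwiseDiscriminate
#' @param withControl logical, also run the shuffled control per pair.
#' @param file optional CSV output path.
#' @return `data.frame`: pair, feature_set, mean_auc, sd_auc, shuffled_mean.
#' @export
discriminationTable <- function(pe, features = "portrait", nResamples = 100,
                                seed = 1, withControl = TRUE, file = NULL) {
    cats <- intersect(.CATEGORIES, unique(pe$category))
    rows <- list()
    for (i in seq_along(cats)) for (j in seq_along(cats)) {
        if (j <= i) next
        sd2 <- deriveSeed(seed, paste(cats[i], cats[j]))
        res <- pairwiseDiscriminate(pe, cats[i], cats[j], features,
                                    nResamples, seed = sd2)
        ctl <- if (withControl)
            mean(shuffledControl(pe, cats[i], cats[j], features, nResamples,
                                 seed = sd2)$auc) else NA_real_
        rows[[length(rows) + 1L]] <-
            data.frame(pair = paste(cats[i], cats[j], sep = " vs "),
                       feature_set = res$featureSet,
                       mean_auc = mean(res$auc), sd_auc = stats::sd(res$auc),
                       shuffled_mean = ctl)
    }
    out <- do.call(rbind, rows)
    if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
    out
}
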