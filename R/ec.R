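## Effective and functional connectivity between oscillatory elements.
##
## EC estimation follows the element-wise cross-prediction design: for every
## target node, a random-intercept model is fitted on the remaining nodes over
## 50 bootstrap resamples of 75% of the trials (subsampling without
## replacement, stratified by subject so random intercepts stay identifiable),
## coefficients are averaged over resamples, and per-target performance is the
## Pearson correlation between held-out 25% predictions and observed values,
## averaged over resamples.  Predictors and targets are z-scored with training
## statistics, so weights are comparable across nodes and the estimated EC is
## invariant to a common rescaling of element columns.

## trials x nodes data matrix for connectivity analyses.
nodeMatrix <- function(pe, includeBehavior = FALSE) {
    D <- elementMatrix(pe)
    if (includeBehavior) {
        if (!all(c("movement_error", "movement_duration") %in%
                 colnames(colData(pe))))
            stop("behaviour columns (movement_error/movement_duration) are missing")
        D <- cbind(D, error = pe$movement_error,
                   duration = pe$movement_duration)
    }
    D
}

#' Bootstrap-averaged functional connectivity (Pearson correlations)
#'
#' Pairwise Pearson correlation matrix over the 48 elements, computed on each
#' of `nBoot` random 75% subsamples (without replacement, stratified by
#' subject) and averaged.
#'
#' @param pe a [PortraitExperiment-class].
#' @param nBoot number of resamples (default 50); `nBoot = 0` skips
#'   resampling and returns the plain correlation matrix over all trials
#'   (deterministic, invariant to trial order).
#' @param frac subsample fraction (default 0.75).
#' @param seed integer seed; results are reproducible bit-for-bit.
#' @return 48 x 48 symmetric numeric matrix with unit diagonal.
#' @export
computeFC <- function(pe, nBoot = 50, frac = 0.75, seed = 1) {
    D <- nodeMatrix(pe)
    sds <- apply(D, 2L, stats::sd)
    if (any(sds < 1e-12))
        stop("constant element column: ",
             paste(colnames(D)[sds < 1e-12], collapse = ", "))
    if (nBoot == 0L) {
        fc <- stats::cor(D)
        diag(fc) <- 1
        return(fc)
    }
    if (floor(frac * nrow(D)) < 3L) stop("need at least 3 trials per resample")
    subj <- pe$subject
    withSeed(seed, {
        acc <- matrix(0, ncol(D), ncol(D))
        for (b in seq_len(nBoot)) {
            tr <- stratifiedTrainIndices(subj, frac)
            acc <- acc + stats::cor(D[tr, , drop = FALSE])
        }
    })
    fc <- acc / nBoot
    fc <- (fc + t(fc)) / 2
    diag(fc) <- 1
    dimnames(fc) <- list(colnames(D), colnames(D))
    fc
}

## Fit all per-target models for one training set; returns the coefficient
## matrix (target x source, zero diagonal), intercepts, per-target BLUPs and
## the scaling statistics, so predictions can be made on any test set.
ecFitOnce <- function(Dtr, subjTr, REML = TRUE) {
    m <- ncol(Dtr)
    st <- scaleStats(Dtr)
    Ztr <- applyScale(Dtr, st)
    A <- cbind(1, Ztr)
    G <- crossprod(A)
    S <- rowsum(A, as.character(subjTr))
    nj <- S[, 1L]
    n <- nrow(Ztr)
    W <- matrix(0, m, m, dimnames = list(colnames(Dtr), colnames(Dtr)))
    b0 <- numeric(m)
    U <- matrix(0, m, nrow(S), dimnames = list(colnames(Dtr), rownames(S)))
    for (t in seq_len(m)) {
        iW <- c(1L, 1L + setdiff(seq_len(m), t))
        iy <- 1L + t
        core <- lmmCore(list(G = G[iW, iW], gy = G[iW, iy], yy = G[iy, iy],
                             S = S[, iW, drop = FALSE], sy = S[, iy],
                             nj = nj, n = n, groups = rownames(S)),
                        REML = REML)
        W[t, -t] <- core$beta[-1L]
        b0[t] <- core$beta[1L]
        U[t, ] <- core$u
    }
    list(W = W, b0 = b0, U = U, scale = st)
}

## Held-out per-target Pearson r for a fitted ecFitOnce model.
ecEvaluate <- function(fit, Dte, subjTe) {
    Zte <- applyScale(Dte, fit$scale)
    m <- ncol(Zte)
    subjTe <- as.character(subjTe)
    known <- match(subjTe, colnames(fit$U))
    r <- numeric(m)
    for (t in seq_len(m)) {
        pred <- fit$b0[t] + Zte[, -t, drop = FALSE] %*% fit$W[t, -t] +
            ifelse(is.na(known), 0, fit$U[t, ][known])
        r[t] <- safeCor(as.numeric(pred), Zte[, t])
    }
    r
}

#' Estimate the effective-connectivity matrix
#'
#' Element-wise cross-prediction with random-intercept models: each node is
#' predicted from all remaining nodes, over bootstrap resamples (75% of
#' trials, without replacement, stratified by subject); coefficients are
#' averaged and per-target performance is the mean held-out Pearson r.
#' With `includeBehavior = TRUE`, `error` and `duration` join the node set as
#' both targets and predictors.
#'
#' @inheritParams computeFC
#' @param includeBehavior logical, add the two behaviour nodes.
#' @param REML logical, passed to the mixed-model engine.
#' @param provenance character label stored in the result (category name or
#'   `"pooled"`).
#' @return An [ECMatrix-class]; signed coefficients are stored, `|w|` is used
#'   wherever a nonnegative weight is required downstream.
#' @export
fitEC <- function(pe, includeBehavior = FALSE, nBoot = 50, frac = 0.75,
                  seed = 1, REML = TRUE, provenance = "pooled") {
    D <- nodeMatrix(pe, includeBehavior)
    subj <- pe$subject
    if (length(unique(subj)) < 2L && nBoot > 0L)
        message("single subject: the model degenerates to ordinary least squares")
    m <- ncol(D)
    withSeed(seed, {
        Wsum <- matrix(0, m, m, dimnames = list(colnames(D), colnames(D)))
        rsum <- numeric(m)
        for (b in seq_len(nBoot)) {
            tr <- stratifiedTrainIndices(subj, frac)
            te <- setdiff(seq_len(nrow(D)), tr)
            fit <- ecFitOnce(D[tr, , drop = FALSE], subj[tr], REML)
            Wsum <- Wsum + fit$W
            rsum <- rsum + ecEvaluate(fit, D[te, , drop = FALSE], subj[te])
        }
    })
    perf <- rsum / nBoot
    names(perf) <- colnames(D)
    new("ECMatrix", weights = Wsum / nBoot, nodes = colnames(D),
        performance = perf, nBoot = as.integer(nBoot),
        provenance = provenance)
}

#' Cross-training generalisation between trial categories
#'
#' Fits the per-target EC models on training trials (75%) of category A and
#' evaluates prediction of held-out (25%) trials of every category B; the
#' entry (A, B) is the Pearson correlation between actual and predicted
#' element values averaged over the 48 targets, then over resamples.  The
#' diagonal reproduces the within-category cross-validated performance.
#'
#' @param pe a [PortraitExperiment-class] containing >= 2 categories.
#' @param nResamples resamples over which entries are averaged (default 10).
#' @param frac training fraction within each category.
#' @param seed integer seed.
#' @param REML logical.
#' @return category x category numeric matrix of mean Pearson r (rows =
#'   training category).
#' @export
crossTrain <- function(pe, nResamples = 10, frac = 0.75, seed = 1,
                       REML = TRUE) {
    cats <- intersect(.CATEGORIES, unique(pe$category))
    if (length(cats) < 2L) stop("need at least 2 categories")
    D <- nodeMatrix(pe)
    subj <- pe$subject
    byCat <- lapply(cats, function(cc) which(pe$category == cc))
    names(byCat) <- cats
    if (any(vapply(byCat, length, 1L) < 8L))
        stop("category absent or too small for a 75/25 split")
    M <- matrix(0, length(cats), length(cats), dimnames = list(cats, cats))
    withSeed(seed, {
        for (b in seq_len(nResamples)) {
            splits <- lapply(cats, function(cc) {
                idx <- byCat[[cc]]
                tr <- idx[stratifiedTrainIndices(subj[idx], frac)]
                list(train = tr, test = setdiff(idx, tr))
            })
            names(splits) <- cats
            for (a in cats) {
                fit <- ecFitOnce(D[splits[[a]]$train, , drop = FALSE],
                                 subj[splits[[a]]$train], REML)
                for (cc in cats) {
                    te <- splits[[cc]]$test
                    M[a, cc] <- M[a, cc] +
                        mean(ecEvaluate(fit, D[te, , drop = FALSE], subj[te]))
                }
            }
        }
    })
    M / nResamples
}

#' Similarity between two connectivity matrices
#'
#' Pearson correlation of the flattened off-diagonal weights.  Node sets and
#' ordering must agree.
#'
#' @param ecA,ecB [ECMatrix-class] objects over the same nodes.
#' @return numeric(1), Pearson r.
#' @export
ecSimilarity <- function(ecA, ecB) {
    if (!identical(ecA@nodes, ecB@nodes))
        stop("node sets differ between the two matrices")
    off <- !diag(length(ecA@nodes))
    stats::cor(ecA@weights[off], ecB@weights[off])
}

#' @describeIn fitEC weight matrix accessor (target rows x source columns).
#' @param ec an `ECMatrix`.
#' @export
ecWeights <- function(ec) ec@weights

#' @describeIn fitEC node identifier accessor.
#' @export
ecNodes <- function(ec) ec@nodes

#' @describeIn fitEC per-target cross-validated Pearson r accessor.
#' @export
ecPerformance <- function(ec) ec@performance

setMethod("show", "ECMatrix", function(object) {
    cat(sprintf("ECMatrix (%s): %d nodes, %d bootstrap resamples\n",
                object@provenance, length(object@nodes), object@nBoot))
    if (length(object@performance))
        cat(sprintf("  cross-validated r: median %.3f (range %.3f-%.3f)\n",
                    stats::median(object@performance),
                    min(object@performance), max(object@performance)))
})

#' Export a connectivity matrix
#'
#' `writeEC` writes the labelled weight matrix as CSV (orientation: target
#' rows, source columns).  `ecEdgeList` flattens it to an edge table
#' (source, target, weight, abs_weight, provenance), optionally written as
#' TSV.
#'
#' @param ec an [ECMatrix-class].
#' @param file output path (for `ecEdgeList`, optional).
#' @return `writeEC`: `file`, invisibly.  `ecEdgeList`: a `data.frame`.
#' @export
writeEC <- function(ec, file) {
    utils::write.csv(ec@weights, file, row.names = TRUE)
    invisible(file)
}

#' @rdname writeEC
#' @export
ecEdgeList <- function(ec, file = NULL) {
    w <- ec@weights
    idx <- which(!diag(nrow(w)) > 0)
    df <- data.frame(source = rep(colnames(w), each = nrow(w))[idx],
                     target = rep(rownames(w), ncol(w))[idx],
                     weight = w[idx], abs_weight = abs(w[idx]),
                     provenance = ec@provenance)
    if (!is.null(file))
        utils::write.table(df, file, sep = "\t", row.names = FALSE,
                           quote = FALSE)
    df
}
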