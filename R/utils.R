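## Internal helpers shared across modules.

## Evaluate `expr` under a temporary RNG state seeded with `seed`,
## restoring the caller's RNG afterwards.
withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (is.null(old)) {
                if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                    rm(".Random.seed", envir = globalenv())
            } else assign(".Random.seed", old, envir = globalenv())
        })
        set.seed(as.integer(seed))
    }
    expr
}

## Derive a stream-specific 31-bit sub-seed from a master seed.
deriveSeed <- function(seed, stream) {
    s <- (as.double(seed) %% 2147483647) + 0
    for (k in utf8ToInt(paste0("s", stream)))
        s <- (s * 69069 + k) %% 2147483647
    as.integer(s)
}

## 75/25-style split stratified by a grouping factor: every group contributes
## floor(frac * n_g) (at least 1) training indices.  Returns train indices.
stratifiedTrainIndices <- function(group, frac) {
    group <- as.character(group)
    idx <- split(seq_along(group), group)
    unlist(lapply(idx, function(i) {
        k <- max(1L, floor(frac * length(i)))
        if (length(i) == 1L) i else sample(i, k)
    }), use.names = FALSE)
}

## Column-wise z-scoring with training statistics; constant columns get
## scale 1 so they pass through (their coefficient is then 0/ridge-handled).
scaleStats <- function(X) {
    ctr <- colMeans(X)
    sds <- apply(X, 2L, stats::sd)
    sds[!is.finite(sds) | sds < 1e-12] <- 1
    list(center = ctr, scale = sds)
}

applyScale <- function(X, st) {
    sweep(sweep(X, 2L, st$center, "-"), 2L, st$scale, "/")
}

## Pearson correlation that tolerates zero-variance inputs (returns 0).
safeCor <- function(a, b) {
    if (stats::sd(a) < 1e-300 || stats::sd(b) < 1e-300) return(0)
    stats::cor(a, b)
}
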