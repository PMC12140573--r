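## Graph-level characterization of effective-connectivity networks.
## All weighted statistics act on |w| (ratios of weight sums are ill-behaved
## under sign cancellation); directed ordered pairs are counted once and the
## structurally-zero diagonal is excluded throughout.

## node label table for the element nodes of an ECMatrix
nodeLabels <- function(ec) {
    info <- elementInfo()
    keep <- ec@nodes %in% info$name
    info[match(ec@nodes[keep], info$name), c("name", "region", "epoch", "band")]
}

## |weights| over element nodes only, diagonal dropped downstream
elementWeights <- function(ec) {
    keep <- ec@nodes %in% elementInfo()$name
    abs(ec@weights[keep, keep, drop = FALSE])
}

#' Strong-link mask by pooled percentile threshold
#'
#' The threshold is the given percentile of the absolute off-diagonal weights
#' pooled over all matrices in `pool`; the mask marks entries strictly above
#' it (so an all-equal network has no strong links).
#'
#' @param ec an [ECMatrix-class].
#' @param percentile percentile in (0, 100), default 97.
#' @param pool list of `ECMatrix` whose weights define the pooled threshold
#'   (defaults to `list(ec)`).
#' @return logical matrix of the same shape as the weights, `FALSE` diagonal.
#' @export
strongLinks <- function(ec, percentile = 97, pool = list(ec)) {
    if (percentile <= 0 || percentile >= 100)
        stop("percentile must be inside (0, 100)")
    if (!length(pool)) stop("pool must be nonempty")
    pooled <- unlist(lapply(pool, function(e) {
        w <- abs(e@weights)
        w[!diag(nrow(w))]
    }))
    thr <- stats::quantile(pooled, percentile / 100, names = FALSE)
    mask <- abs(ec@weights) > thr
    diag(mask) <- FALSE
    dimnames(mask) <- dimnames(ec@weights)
    mask
}

homophilyFromLabels <- function(W, labels) {
    off <- !diag(nrow(W))
    tot <- sum(W[off])
    if (tot <= 0) stop("total weight is zero: homophily undefined")
    same <- outer(labels, labels, "==") & off
    sum(W[same]) / tot
}

#' Weighted homophily triplet of an EC network
#'
#' Fraction of the total absolute edge weight carried by node pairs sharing a
#' label, for each of the three label axes:
#' \deqn{H_\mathrm{spatial} = \sum W_{s-s} / \sum W_\mathrm{tot}} (same
#' region), and analogously `H_spectral` (same band) and `H_temporal` (same
#' epoch).  Behaviour nodes are excluded.  Each ratio lies in [0, 1] and is
#' invariant to weight rescaling.
#'
#' @param ec an [ECMatrix-class] whose element nodes carry
#'   (region, epoch, band) labels through their names.
#' @return named numeric: `spatial`, `spectral`, `temporal`.
#' @examples
#' cfg <- synthConfig(n_subjects = 2,
#'                    trials_per_category = c("NR-Hit" = 30))
#' homophily(groundTruthEC(cfg, "NR-Hit"))
#' @export
homophily <- function(ec) {
    W <- elementWeights(ec)
    lab <- nodeLabels(ec)
    c(spatial = homophilyFromLabels(W, lab$region),
      spectral = homophilyFromLabels(W, lab$band),
      temporal = homophilyFromLabels(W, lab$epoch))
}

#' Label-permutation null distribution for homophily
#'
#' Permutes one label axis across nodes (keeping the other two axes attached
#' and the weighted wiring fixed), recomputing the homophily ratio each time.
#' The empirical p-value is `(1 + #(null >= observed)) / (1 + n_shuffles)`.
#'
#' @param ec an [ECMatrix-class].
#' @param axis one of `"spatial"`, `"spectral"`, `"temporal"`.
#' @param nShuffles number of permutations (>= 100).
#' @param seed integer seed; the distribution is reproducible from it.
#' @return list with `statistic` (axis name), `observed`, `values`
#'   (length `nShuffles`), `p`, `nShuffles`, `seed`.
#' @export
homophilyNull <- function(ec, axis = c("spatial", "spectral", "temporal"),
                          nShuffles = 1000, seed = 1) {
    axis <- match.arg(axis)
    if (nShuffles < 100) stop("nShuffles must be at least 100")
    W <- elementWeights(ec)
    lab <- nodeLabels(ec)
    labels <- switch(axis, spatial = lab$region, spectral = lab$band,
                     temporal = lab$epoch)
    obs <- homophilyFromLabels(W, labels)
    withSeed(seed, {
        vals <- vapply(seq_len(nShuffles), function(i)
            homophilyFromLabels(W, sample(labels)), numeric(1))
    })
    list(statistic = axis, observed = obs, values = vals,
         p = (1 + sum(vals >= obs)) / (1 + nShuffles),
         nShuffles = as.integer(nShuffles), seed = as.integer(seed))
}

#' Percentage change in homophily relative to a reference network
#'
#' \deqn{\Delta H = 100 (H_\mathrm{cat} - H_\mathrm{pooled}) /
#'   H_\mathrm{pooled}} per axis.
#'
#' @param H_category,H_pooled homophily triplets as returned by
#'   [homophily()]; all pooled entries must be positive.
#' @return named numeric triplet, in percent.
#' @export
deltaHomophily <- function(H_category, H_pooled) {
    if (any(H_pooled <= 0)) stop("pooled homophily entries must be positive")
    100 * (H_category[names(H_pooled)] - H_pooled) / H_pooled
}

#' In/out strength and strong-link degree of one node
#'
#' Out-strength is the total absolute weight of edges whose *source* is the
#' node (\eqn{\sum_t |w(t, \mathrm{node})|}); in-strength sums edges the node
#' receives (\eqn{\sum_s |w(\mathrm{node}, s)|}).  Counts are the number of
#' incoming/outgoing links in the strong-link mask.
#'
#' @param ec an [ECMatrix-class].
#' @param node node identifier (element name, `"error"` or `"duration"`).
#' @param mask optional logical strong-link mask (defaults to
#'   `strongLinks(ec)`).
#' @return named numeric: `in_strength`, `out_strength`, `in_count`,
#'   `out_count`.
#' @export
nodeStrengths <- function(ec, node, mask = NULL) {
    i <- match(node, ec@nodes)
    if (is.na(i)) stop("unknown node: ", node)
    if (is.null(mask)) mask <- strongLinks(ec)
    W <- abs(ec@weights)
    c(in_strength = sum(W[i, -i]), out_strength = sum(W[-i, i]),
      in_count = sum(mask[i, -i]), out_count = sum(mask[-i, i]))
}

#' Tidy homophily report over categories
#'
#' Convenience wrapper producing one row per (category, axis): observed
#' homophily, permutation-null mean and p-value, and percent change relative
#' to the pooled network.
#'
#' @param ecByCategory named list of per-category [ECMatrix-class] objects.
#' @param ecPooled the pooled-trials `ECMatrix`.
#' @param nShuffles permutations per axis.
#' @param seed integer seed.
#' @param file optional CSV output path.
#' @return `data.frame` with columns category, axis, observed, null_mean, p,
#'   delta_pct.
#' @export
homophilyTable <- function(ecByCategory, ecPooled, nShuffles = 1000, seed = 1,
                           file = NULL) {
    Hp <- homophily(ecPooled)
    rows <- list()
    for (cc in names(ecByCategory)) {
        Hc <- homophily(ecByCategory[[cc]])
        dH <- deltaHomophily(Hc, Hp)
        for (ax in names(Hc)) {
            nn <- homophilyNull(ecByCategory[[cc]], ax, nShuffles,
                                seed = deriveSeed(seed, paste(cc, ax)))
            rows[[length(rows) + 1L]] <-
                data.frame(category = cc, axis = ax, observed = Hc[[ax]],
                           null_mean = mean(nn$values), p = nn$p,
                           delta_pct = dH[[ax]])
        }
    }
    out <- do.call(rbind, rows)
    if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
    out
}
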