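# Shared fixtures and independent oracles, all built in code.

# Minimal PortraitExperiment with user-supplied element matrix (trials x 48).
makePE <- function(E, subject = rep("S01", nrow(E)),
                   category = rep("NR-Hit", nrow(E)),
                   error = rep(0, nrow(E)), duration = rep(1, nrow(E))) {
    colnames(E) <- elementNames()
    PortraitExperiment(E, subject = subject, category = category,
                       movement_error = error, movement_duration = duration)
}

# Exhaustive pair-counting AUC: the independent oracle for rocAUC.
aucByPairs <- function(scores, labels) {
    pos <- scores[as.logical(labels)]
    neg <- scores[!as.logical(labels)]
    tot <- 0
    for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
    tot / (length(pos) * length(neg))
}

# Uniform complete directed graph on the 48 element nodes (weight 1 off-diag).
uniformEC <- function() {
    w <- matrix(1, 48, 48, dimnames = list(elementNames(), elementNames()))
    diag(w) <- 0
    new("ECMatrix", weights = w, nodes = elementNames(),
        performance = numeric(0), nBoot = 0L, provenance = "uniform")
}

# ECMatrix from an arbitrary weight matrix over element nodes.
ecFromWeights <- function(w, nodes = elementNames()) {
    diag(w) <- 0
    dimnames(w) <- list(nodes, nodes)
    new("ECMatrix", weights = w, nodes = nodes, performance = numeric(0),
        nBoot = 0L, provenance = "test")
}

# Direct (loop-based) time-domain convolution of a signal with the sampled
# truncated Morlet kernel, 'same' alignment; oracle for FFT convolution.
directMorletPower <- function(x, f, ratio, fs) {
    sigma_t <- ratio / (2 * pi * f)
    half <- floor(3 * sigma_t * fs)
    tt <- (-half:half) / fs
    w <- exp(-tt^2 / (2 * sigma_t^2)) * exp(2i * pi * f * tt)
    w <- w / sqrt(sum(Mod(w)^2))
    n <- length(x)
    out <- complex(n)
    m <- (-half):half
    for (t in seq_len(n)) {
        keep <- t - m >= 1 & t - m <= n
        out[t] <- sum(w[keep] * x[t - m[keep]])
    }
    Mod(out)^2
}
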