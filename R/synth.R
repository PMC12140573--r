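#' Configuration for the synthetic portrait generator
#'
#' Defines the generating model for synthetic single-trial portraits.  Trial
#' `i` of category `c` and subject `s` is drawn as
#' \deqn{x_i = \mu_c + u_s + A_c z_i + \gamma_c\,\mathrm{err}_i + \eta_i}
#' with \eqn{A_c = B + \delta R_c} (a per-category perturbation of a common
#' low-rank backbone, \eqn{R_c} having seeded orthonormal columns so that
#' category manifolds differ by rotation rather than scale),
#' \eqn{z_i \sim N(0, I_k)} latent coordinates, \eqn{u_s \sim N(0, \tau^2)}
#' per-element subject intercepts, \eqn{\mathrm{err}_i \sim N(0,
#' \mathrm{error\_sd}^2)} an exogenous movement-error drive, and
#' \eqn{\eta_i \sim N(0, \sigma^2 I)} residual noise.  Movement duration is a
#' noisy linear readout \eqn{d_i = d_0 + v^\top x_i + \varepsilon_i}.
#'
#' The default backbone couples the 12 elements of each region through one
#' region factor (loading `block_loading`) plus one global factor
#' (`global_loading`), with N(0, `loading_jitter_sd`^2) jitter guaranteeing
#' full column rank; category means are `category_separation` times seeded
#' unit vectors, spreading a small shift over all 48 elements so per-element
#' marginals overlap heavily while the joint portrait remains discriminable.
#'
#' @param n_subjects number of subjects (default 24).
#' @param trials_per_category named integer vector, total trials per category
#'   (allocated round-robin across subjects).  Defaults to 600 per category.
#' @param k number of latent factors (default 5).
#' @param B optional 48 x k backbone loading matrix; built from the seed when
#'   `NULL`.
#' @param block_loading,global_loading,loading_jitter_sd parameters of the
#'   default backbone construction (see Details).
#' @param delta nonnegative scale of the per-category manifold perturbation.
#' @param category_separation nonnegative scale of the per-category mean
#'   shift (distributed over all 48 elements).
#' @param subject_intercept_sd tau, sd of per-subject per-element intercepts.
#' @param residual_sd sigma, sd of element residual noise (positive).
#' @param error_sd sd of the movement-error drive (positive).
#' @param error_loadings gamma: a 48-vector (recycled for every category) or
#'   a named list of per-category 48-vectors.  `NULL` gives the default drive
#'   into During (0.15) and Post (0.3) elements.
#' @param duration_readout v, 48-vector; `NULL` loads 0.05 on each During
#'   element.
#' @param duration_baseline baseline movement duration in seconds.
#' @param duration_noise_sd sd of duration noise (positive).
#' @param duration_min lower clip for generated durations, seconds.
#' @param hit_threshold positive threshold on |error| separating Hit from
#'   Miss when `couple_labels` is on.
#' @param couple_labels logical: draw |error| below (Hit) / above (Miss) the
#'   threshold consistently with the category label (default `TRUE`).
#' @param broadband_sd sd of the 1/f broadband noise added by
#'   [generateSignals()] (0 disables it).
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return A validated config object (list with class `"SynthConfig"`).
#' @seealso [generatePortraits()], [groundTruthEC()], [generateSignals()]
#' @examples
#' cfg <- synthConfig(n_subjects = 4,
#'                    trials_per_category = c("NR-Hit" = 40, "NR-Miss" = 40))
#' pe <- generatePortraits(cfg)
#' pe
#' @export
synthConfig <- function(n_subjects = 24,
                        trials_per_category = stats::setNames(rep(600L, 6), .CATEGORIES),
                        k = 5, B = NULL,
                        block_loading = 0.4, global_loading = 0.2,
                        loading_jitter_sd = 0.1,
                        delta = 1, category_separation = 1,
                        subject_intercept_sd = 0.5, residual_sd = 1,
                        error_sd = 1, error_loadings = NULL,
                        duration_readout = NULL, duration_baseline = 1,
                        duration_noise_sd = 0.15, duration_min = 0.4,
                        hit_threshold = 1, couple_labels = TRUE,
                        broadband_sd = 0.1, seed = 1) {
    trials_per_category <- unlist(trials_per_category)   # accept JSON lists
    cfg <- list(n_subjects = as.integer(n_subjects),
                trials_per_category = trials_per_category, k = as.integer(k),
                B = B, block_loading = block_loading,
                global_loading = global_loading,
                loading_jitter_sd = loading_jitter_sd, delta = delta,
                category_separation = category_separation,
                subject_intercept_sd = subject_intercept_sd,
                residual_sd = residual_sd, error_sd = error_sd,
                error_loadings = error_loadings,
                duration_readout = duration_readout,
                duration_baseline = duration_baseline,
                duration_noise_sd = duration_noise_sd,
                duration_min = duration_min, hit_threshold = hit_threshold,
                couple_labels = isTRUE(couple_labels),
                broadband_sd = broadband_sd, seed = as.integer(seed))
    class(cfg) <- "SynthConfig"
    validateSynthConfig(cfg)
    cfg
}

validateSynthConfig <- function(cfg) {
    tp <- cfg$trials_per_category
    if (is.null(names(tp)) || any(!names(tp) %in% .CATEGORIES))
        stop("trials_per_category must be named with categories among: ",
             paste(.CATEGORIES, collapse = ", "))
    if (any(tp < 1)) stop("trials_per_category must be positive")
    if (cfg$delta < 0) stop("delta must be nonnegative")
    if (cfg$category_separation < 0) stop("category_separation must be nonnegative")
    if (cfg$subject_intercept_sd < 0) stop("subject_intercept_sd must be nonnegative")
    if (cfg$residual_sd <= 0) stop("residual_sd must be positive")
    if (cfg$error_sd <= 0) stop("error_sd must be positive")
    if (cfg$duration_noise_sd <= 0) stop("duration_noise_sd must be positive")
    if (cfg$hit_threshold <= 0) stop("hit_threshold must be positive")
    if (cfg$n_subjects < 1) stop("n_subjects must be positive")
    if (!is.null(cfg$B)) {
        if (!is.matrix(cfg$B) || nrow(cfg$B) != 48L || ncol(cfg$B) != cfg$k)
            stop("B must be a 48 x k matrix")
        if (qr(cfg$B)$rank < cfg$k) stop("B must have full column rank")
    }
    invisible(cfg)
}

## Deterministic structural draw (depends on the seed only, never on trial
## counts): backbone B, per-category rotations R_c and means mu_c, error
## loadings gamma_c, duration readout v, per-subject intercepts u_s.
synthStructure <- function(cfg) {
    info <- elementInfo()
    withSeed(deriveSeed(cfg$seed, "structure"), {
        B <- cfg$B
        if (is.null(B)) {
            B <- matrix(0, 48L, cfg$k)
            for (r in seq_len(min(4L, cfg$k)))
                B[info$region == .REGIONS[r], r] <- cfg$block_loading
            if (cfg$k >= 5L) B[, 5L] <- cfg$global_loading
            B <- B + matrix(stats::rnorm(48L * cfg$k, sd = cfg$loading_jitter_sd),
                            48L, cfg$k)
        }
        cats <- names(cfg$trials_per_category)
        R <- mu <- list()
        for (cc in .CATEGORIES) {       # draw for all six: stable across subsets
            Rc <- qr.Q(qr(matrix(stats::rnorm(48L * cfg$k), 48L, cfg$k)))
            m <- stats::rnorm(48L)
            if (cc %in% cats) {
                R[[cc]] <- Rc
                mu[[cc]] <- cfg$category_separation * m / sqrt(sum(m^2))
            }
        }
        gam <- cfg$error_loadings
        if (is.null(gam)) {
            gam <- numeric(48L)
            gam[info$epoch == "During"] <- 0.15
            gam[info$epoch == "Post"] <- 0.3
        }
        if (!is.list(gam)) {
            if (length(gam) != 48L) stop("error_loadings must have length 48")
            gam <- stats::setNames(rep(list(gam), length(cats)), cats)
        } else if (any(!cats %in% names(gam)))
            stop("error_loadings list must cover every category")
        v <- cfg$duration_readout
        if (is.null(v)) {
            v <- numeric(48L)
            v[info$epoch == "During"] <- 0.05
        }
        if (length(v) != 48L) stop("duration_readout must have length 48")
        subjects <- sprintf("S%02d", seq_len(cfg$n_subjects))
        U <- matrix(stats::rnorm(48L * cfg$n_subjects,
                                 sd = cfg$subject_intercept_sd),
                    48L, cfg$n_subjects, dimnames = list(info$name, subjects))
        A <- lapply(R, function(Rc) B + cfg$delta * Rc)
        list(B = B, R = R, A = A, mu = mu, gamma = gam, v = v,
             subjects = subjects, U = U)
    })
}

## Inverse-CDF draw of |err| consistent with the Hit/Miss label.
drawCoupledError <- function(n, hit, sd, threshold) {
    pin <- 2 * stats::pnorm(threshold / sd) - 1   # P(|e| < threshold)
    u <- stats::runif(n)
    g <- ifelse(hit, u * pin, pin + u * (1 - pin))
    mag <- sd * stats::qnorm((1 + g) / 2)
    mag * sign(stats::runif(n) - 0.5)
}

#' Generate a synthetic portrait table with known ground truth
#'
#' Draws single-trial oscillatory portraits from the latent-factor model
#' described in [synthConfig()].  The returned object carries the generating
#' structures (latent coordinates, subject intercepts, error drive, loading
#' matrices) in its metadata under `"groundTruth"`, so downstream estimates
#' can be validated against the truth.  Identical seeds give bit-identical
#' tables.
#'
#' @param config a [synthConfig()] object.
#' @return A [PortraitExperiment-class]; `metadata(x)$groundTruth` holds the
#'   generating record (`z`, `u`, `err`, `A`, `mu`, `gamma`, `v`, `config`).
#' @export
generatePortraits <- function(config) {
    validateSynthConfig(config)
    str <- synthStructure(config)
    cats <- names(config$trials_per_category)
    nTot <- sum(config$trials_per_category)
    category <- rep(cats, config$trials_per_category)
    ## round-robin subject allocation within each category
    subject <- unlist(lapply(config$trials_per_category, function(nc)
        str$subjects[(seq_len(nc) - 1L) %% config$n_subjects + 1L]),
        use.names = FALSE)
    withSeed(deriveSeed(config$seed, "trials"), {
        hit <- grepl("-Hit$", category)
        err <- if (config$couple_labels)
            drawCoupledError(nTot, hit, config$error_sd, config$hit_threshold)
        else stats::rnorm(nTot, sd = config$error_sd)
        z <- matrix(stats::rnorm(nTot * config$k), nTot, config$k)
        eta <- matrix(stats::rnorm(48L * nTot, sd = config$residual_sd),
                      48L, nTot)
        X <- matrix(0, 48L, nTot, dimnames = list(elementNames(), NULL))
        for (cc in cats) {
            idx <- which(category == cc)
            X[, idx] <- str$mu[[cc]] + str$A[[cc]] %*% t(z[idx, , drop = FALSE]) +
                outer(str$gamma[[cc]], err[idx]) + eta[, idx]
        }
        X <- X + str$U[, subject]
        duration <- pmax(config$duration_min,
                         config$duration_baseline + as.numeric(crossprod(X, str$v)) +
                             stats::rnorm(nTot, sd = config$duration_noise_sd))
    })
    gt <- list(z = z, u = str$U, err = err, A = str$A, mu = str$mu,
               gamma = str$gamma, v = str$v, B = str$B, config = config)
    PortraitExperiment(X, subject = subject, category = category,
                       movement_error = err, movement_duration = duration,
                       metadata = list(groundTruth = gt))
}

#' Closed-form ground-truth effective connectivity of the generator
#'
#' For category `c` the model covariance of the 48 elements is
#' \eqn{\Sigma_c = A_c A_c^\top + \mathrm{error\_sd}^2\,\gamma_c \gamma_c^\top
#' + \sigma^2 I} (plus \eqn{\tau^2 I} when `includeSubjectVariance = TRUE`).
#' The population regression coefficient of element `t` on the other 47 is
#' \eqn{-\Omega_{ts}/\Omega_{tt}} with \eqn{\Omega = \Sigma_c^{-1}}; the
#' diagonal is zero.  The default excludes the subject-intercept variance,
#' matching what the random-intercept estimator (which absorbs per-subject
#' offsets) converges to.
#'
#' @param config a [synthConfig()].
#' @param category one of the configured category labels.
#' @param standardized logical: return coefficients on the z-scored scale
#'   (multiplied by `sd_source / sd_target` from the model marginals), the
#'   scale on which [fitEC()] reports weights.
#' @param includeSubjectVariance logical, add `tau^2 I` to the covariance.
#' @return An [ECMatrix-class] with `nBoot = 0` and the category as
#'   provenance.
#' @export
groundTruthEC <- function(config, category, standardized = FALSE,
                          includeSubjectVariance = FALSE) {
    validateSynthConfig(config)
    if (!category %in% names(config$trials_per_category))
        stop("unknown category: ", category)
    str <- synthStructure(config)
    A <- str$A[[category]]
    g <- str$gamma[[category]]
    Sigma <- tcrossprod(A) + config$error_sd^2 * tcrossprod(g) +
        diag(config$residual_sd^2, 48L)
    if (includeSubjectVariance)
        Sigma <- Sigma + diag(config$subject_intercept_sd^2, 48L)
    R <- tryCatch(chol(Sigma), error = function(e)
        stop("model covariance is singular for category ", category))
    Omega <- chol2inv(R)
    W <- -Omega / diag(Omega)          # row t scaled by Omega_tt
    diag(W) <- 0
    if (standardized) {
        sds <- sqrt(diag(Sigma))
        W <- W * outer(1 / sds, sds)   # w_ts * sd_s / sd_t
    }
    dimnames(W) <- list(elementNames(), elementNames())
    new("ECMatrix", weights = W, nodes = elementNames(),
        performance = numeric(0), nBoot = 0L, provenance = category)
}

## Band-limited unit-variance Gaussian noise via Fourier masking.
bandNoise <- function(n, fs, lo, hi) {
    x <- stats::rnorm(n)
    X <- stats::fft(x)
    f <- (seq_len(n) - 1) * fs / n
    f <- pmin(f, fs - f)               # two-sided frequency axis
    X[f < lo | f > hi] <- 0
    y <- Re(stats::fft(X, inverse = TRUE)) / n
    s <- stats::sd(y)
    if (s < 1e-12) stop("band [", lo, ",", hi, "] Hz contains no Fourier bin")
    y / s
}

## 1/f-shaped broadband noise with the requested sd.
pinkNoise <- function(n, fs, sd) {
    if (sd <= 0) return(numeric(n))
    x <- stats::rnorm(n)
    X <- stats::fft(x)
    f <- (seq_len(n) - 1) * fs / n
    f <- pmin(f, fs - f)
    X <- X / sqrt(pmax(f, 1))
    X[1] <- 0
    y <- Re(stats::fft(X, inverse = TRUE)) / n
    y / stats::sd(y) * sd
}

## Smooth 0->1 cosine step of the given width centred at `at`.
cosineStep <- function(t, at, width = 0.05) {
    s <- (t - (at - width / 2)) / width
    s <- pmin(pmax(s, 0), 1)
    0.5 * (1 - cos(pi * s))
}

#' Generate raw per-trial, per-region time series from a portrait model
#'
#' Synthesises trial-epoched signals whose band/epoch log-power reproduces a
#' generated portrait table: for each region the signal is a sum over
#' frequency bands of band-limited Gaussian noise scaled by
#' `exp(element / 2)` within each epoch (50-ms cosine ramps at the epoch
#' boundaries), plus 1/f broadband noise.  Each trial spans
#' `[-1.5, duration + 1.5]` s around movement onset.  This emulates the
#' burst-like, non-sinusoidal character of cortical oscillations without
#' modelling burst statistics.
#'
#' @param config a [synthConfig()].
#' @param fs sampling rate in Hz (default 256); must exceed twice the top
#'   band edge.
#' @param bands named list of band edges in Hz (defaults to
#'   `bandEpochSpec()$bands`).
#' @return A [SignalSet-class] whose `portraits` slot is the generating
#'   [PortraitExperiment-class], so time-frequency extraction can be
#'   validated against the generating element values.
#' @export
generateSignals <- function(config, fs = 256, bands = bandEpochSpec()$bands) {
    top <- max(unlist(bands))
    if (fs <= 2 * top)
        stop("fs must exceed twice the top band edge (", 2 * top, " Hz)")
    pe <- generatePortraits(config)
    if (any(pe$movement_duration <= 0)) stop("durations must be positive")
    E <- assay(pe, "elements")
    info <- elementInfo()
    signals <- times <- vector("list", ncol(pe))
    withSeed(deriveSeed(config$seed, "signals"), {
        for (i in seq_len(ncol(pe))) {
            d <- pe$movement_duration[i]
            tt <- seq(-1.5, d + 1.5, by = 1 / fs)
            n <- length(tt)
            sDur <- cosineStep(tt, 0)       # Pre -> During blend
            sPost <- cosineStep(tt, d)      # During -> Post blend
            x <- matrix(0, n, 4L, dimnames = list(NULL, .REGIONS))
            for (r in .REGIONS) {
                sig <- pinkNoise(n, fs, config$broadband_sd)
                for (b in names(bands)) {
                    el <- E[info$region == r & info$band == b, i]
                    names(el) <- info$epoch[info$region == r & info$band == b]
                    amp <- exp(el / 2)
                    env <- amp["Pre"] + (amp["During"] - amp["Pre"]) * sDur +
                        (amp["Post"] - amp["During"]) * sPost
                    sig <- sig + env * bandNoise(n, fs, bands[[b]][1], bands[[b]][2])
                }
                x[, r] <- sig
            }
            signals[[i]] <- x
            times[[i]] <- tt
        }
    })
    new("SignalSet", signals = signals, times = times, fs = fs, portraits = pe)
}

setMethod("show", "SignalSet", function(object) {
    cat("SignalSet:", length(object@signals), "trials x",
        ncol(object@signals[[1]]), "regions at", object@fs, "Hz\n")
})

#' Frozen behaviour-coupling scenario configurations
#'
#' Two ready-made generator configurations used to probe the directionality
#' of behaviour--element coupling in the estimated network:
#'
#' * `errorDriverConfig()`: movement error *drives* the elements (a strong
#'   exogenous drive, `gamma = 0.5`, into every During and Post element; no
#'   duration readout).  The expected signature is error-node out-strength
#'   exceeding its in-strength.
#' * `durationReadoutConfig()`: movement duration is a noisy *readout* of the
#'   elements (`v = 0.1` on every During element) under strong shared factor
#'   structure (`block_loading = 0.8`, `residual_sd = 0.5`) and readout noise
#'   comparable to the readout signal (`duration_noise_sd = 0.75`).  Because
#'   duration taps the factor component that the elements already share, it
#'   adds almost no unique information to any single element, so its
#'   in-strength exceeds its out-strength.
#'
#' @param trials_per_category trials per category (default 150 each).
#' @param n_subjects number of subjects (default 8).
#' @param seed integer seed.
#' @return a [synthConfig()] object.
#' @export
errorDriverConfig <- function(trials_per_category =
                                  stats::setNames(rep(150L, 6), .CATEGORIES),
                              n_subjects = 8, seed = 1) {
    info <- elementInfo()
    gam <- numeric(48L)
    gam[info$epoch %in% c("During", "Post")] <- 0.5
    synthConfig(n_subjects = n_subjects,
                trials_per_category = trials_per_category,
                error_loadings = gam, duration_readout = rep(0, 48L),
                seed = seed)
}

#' @rdname errorDriverConfig
#' @export
durationReadoutConfig <- function(trials_per_category =
                                      stats::setNames(rep(150L, 6), .CATEGORIES),
                                  n_subjects = 8, seed = 1) {
    info <- elementInfo()
    v <- numeric(48L)
    v[info$epoch == "During"] <- 0.1
    synthConfig(n_subjects = n_subjects,
                trials_per_category = trials_per_category,
                block_loading = 0.8, residual_sd = 0.5,
                error_loadings = rep(0, 48L), duration_readout = v,
                duration_noise_sd = 0.75, seed = seed)
}

#' @describeIn errorDriverConfig configuration whose only structure is a
#'   cross-epoch coupling: one factor per region loads jointly on the
#'   (Pre, theta) and (During, beta) elements, so those element pairs
#'   covary across trials.  Used to demonstrate that IAAFT surrogates, which
#'   preserve each trial's spectrum but destroy within-trial timing, abolish
#'   the coupling.
#' @export
crossEpochCouplingConfig <- function(trials_per_category = c("NR-Hit" = 120L),
                                     n_subjects = 2, seed = 1) {
    info <- elementInfo()
    B <- matrix(0, 48L, 4L)
    for (r in seq_len(4L)) {
        B[info$region == .REGIONS[r] & info$epoch == "Pre" &
          info$band == "theta", r] <- 0.9
        B[info$region == .REGIONS[r] & info$epoch == "During" &
          info$band == "beta", r] <- 0.9
    }
    synthConfig(n_subjects = n_subjects,
                trials_per_category = trials_per_category, k = 4, B = B,
                delta = 0, category_separation = 0,
                subject_intercept_sd = 0.1, residual_sd = 0.5,
                error_loadings = rep(0, 48L), duration_readout = rep(0, 48L),
                broadband_sd = 0.05, seed = seed)
}

## Element index pairs (Pre,theta) -> (During,beta) per region, the coupled
## pairs of crossEpochCouplingConfig.
crossEpochPairs <- function() {
    info <- elementInfo()
    cbind(pre_theta = which(info$epoch == "Pre" & info$band == "theta"),
          during_beta = which(info$epoch == "During" & info$band == "beta"))
}
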