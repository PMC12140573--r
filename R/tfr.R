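#' Wavelet and band/epoch specifications
#'
#' `waveletConfig()` parameterises the complex Morlet decomposition by the
#' ratio \eqn{f_0/\sigma_f} (default 7), a frequency grid (default 2--60 Hz in
#' 0.5-Hz steps, extended beyond 50 Hz so the gamma band is fully covered) and
#' the sampling rate.  `bandEpochSpec()` freezes the frequency bands
#' (theta 4--8, alpha 9--12, beta 13--35, gamma 36--60 Hz; shared integer
#' edges belong to the lower band, and band membership is inclusive of both
#' edges) and the movement epochs (Pre = [-1.5, 0) s from movement onset,
#' During = [onset, offset], Post = (offset, offset + 1.5] s).
#'
#' @param ratio positive ratio \eqn{f_0/\sigma_f} of centre frequency to
#'   spectral bandwidth of the wavelet.
#' @param freqs strictly increasing frequency grid in Hz.
#' @param fs sampling rate in Hz; must exceed twice the top frequency.
#' @return `waveletConfig`: a list with class `"WaveletConfig"`;
#'   `bandEpochSpec`: a list with `bands` (named list of c(lo, hi) in Hz),
#'   `pre` and `post` epoch paddings in seconds.
#' @export
waveletConfig <- function(ratio = 7, freqs = seq(2, 60, by = 0.5), fs = 256) {
    if (ratio <= 0) stop("ratio must be positive")
    if (any(diff(freqs) <= 0)) stop("freqs must be strictly increasing")
    if (max(freqs) >= fs / 2) stop("max(freqs) must be below fs/2")
    structure(list(ratio = ratio, freqs = freqs, fs = fs),
              class = "WaveletConfig")
}

#' @rdname waveletConfig
#' @export
bandEpochSpec <- function() {
    list(bands = list(theta = c(4, 8), alpha = c(9, 12),
                      beta = c(13, 35), gamma = c(36, 60)),
         pre = 1.5, post = 1.5)
}

## Sampled, truncated (+-3 sigma_t) unit-energy complex Morlet wavelet.
morletKernel <- function(f, ratio, fs) {
    sigma_t <- ratio / (2 * pi * f)
    half <- floor(3 * sigma_t * fs)
    t <- (-half:half) / fs
    w <- exp(-t^2 / (2 * sigma_t^2)) * exp(2i * pi * f * t)
    w / sqrt(sum(Mod(w)^2))
}

## Cache of wavelet spectra keyed by (fs, ratio, nfft, frequency grid).
.waveletCache <- new.env(parent = emptyenv())

waveletSpectra <- function(config, nfft) {
    key <- paste(config$fs, config$ratio, nfft,
                 length(config$freqs), config$freqs[1],
                 config$freqs[length(config$freqs)], sep = "|")
    if (!is.null(.waveletCache[[key]])) return(.waveletCache[[key]])
    half <- floor(3 * (config$ratio / (2 * pi * config$freqs[1])) * config$fs)
    out <- matrix(0i, nfft, length(config$freqs))
    for (j in seq_along(config$freqs)) {
        w <- morletKernel(config$freqs[j], config$ratio, config$fs)
        k <- (length(w) - 1L) / 2L
        buf <- complex(nfft)
        ## centre the kernel at index 1 (circular), so FFT convolution
        ## returns the 'same'-aligned filtered signal
        buf[1:(k + 1L)] <- w[(k + 1L):length(w)]
        buf[(nfft - k + 1L):nfft] <- w[1:k]
        out[, j] <- stats::fft(buf)
    }
    res <- list(spectra = out, maxHalf = half)
    .waveletCache[[key]] <- res
    res
}

#' Morlet time-frequency decomposition
#'
#' Convolves a single-trial signal with complex Morlet wavelets
#' (\eqn{\sigma_f = f / \mathrm{ratio}}, truncated at three temporal standard
#' deviations, unit energy) by zero-padded FFT convolution and returns raw
#' power \eqn{|w \ast x|^2}.  Samples within \eqn{3\sigma_t} of either
#' segment end at the lowest frequency are flagged as edge-affected.
#'
#' @param signal numeric vector, one trial's time course for one region.
#' @param config a [waveletConfig()].
#' @param times time axis in seconds relative to movement onset; defaults to
#'   consecutive samples starting at `onset - 1.5` s.
#' @param onset,offset movement markers in seconds.
#' @param region,trialId identifiers stored in the result.
#' @param nfft optional FFT length (padded up automatically); passing a
#'   common value across trials lets wavelet spectra be reused.
#' @return A [TFMap-class] with raw (nonnegative) power, time x frequency.
#' @examples
#' cfg <- waveletConfig(freqs = seq(4, 30, 2))
#' x <- sin(2 * pi * 10 * seq(0, 4, by = 1/256))
#' tf <- morletTransform(x, cfg, onset = 0, offset = 1)
#' @export
morletTransform <- function(signal, config = waveletConfig(), times = NULL,
                            onset = 0, offset = NA_real_, region = "",
                            trialId = "", nfft = NULL) {
    n <- length(signal)
    minLen <- 2L * floor(3 * (config$ratio / (2 * pi * config$freqs[1])) *
                             config$fs) + 1L
    if (n < minLen)
        stop("signal too short for the lowest frequency: need at least ",
             minLen, " samples, got ", n)
    if (anyNA(signal)) stop("signal must not contain missing values")
    if (is.null(times))
        times <- onset - 1.5 + (seq_len(n) - 1L) / config$fs
    want <- stats::nextn(n + minLen, 2)
    if (is.null(nfft)) nfft <- want
    if (nfft < want) stop("nfft too small for this signal length")
    ws <- waveletSpectra(config, nfft)
    X <- stats::fft(c(signal, numeric(nfft - n)))
    P <- matrix(0, n, length(config$freqs))
    for (j in seq_along(config$freqs)) {
        y <- stats::fft(X * ws$spectra[, j], inverse = TRUE)[seq_len(n)] / nfft
        P[, j] <- Mod(y)^2
    }
    edge <- seq_len(n) <= ws$maxHalf | seq_len(n) > n - ws$maxHalf
    new("TFMap", power = P, times = as.numeric(times), freqs = config$freqs,
        onset = onset, offset = as.numeric(offset), region = region,
        trialId = trialId, logNormalized = FALSE, edge = edge)
}

setMethod("show", "TFMap", function(object) {
    cat(sprintf("TFMap %s/%s: %d samples x %d freqs (%.1f-%.1f Hz), %s\n",
                object@trialId, object@region, nrow(object@power),
                length(object@freqs), min(object@freqs), max(object@freqs),
                if (object@logNormalized) "log-normalized" else "raw power"))
})

#' Log-transform and normalize power across trials
#'
#' Applies the task-free normalization used when no baseline interval exists:
#' for all trials of one subject and region,
#' `out(t, f) = log power(t, f) - meanlog(f)`, where `meanlog(f)` is the mean
#' of log power over all trials and all time points at frequency `f`.  The
#' result is invariant to a global multiplicative rescaling of the raw maps.
#'
#' @param tfmaps list of raw-power [TFMap-class]s from one subject and region,
#'   sharing a frequency grid.
#' @return list of log-normalized `TFMap`s.
#' @export
normalizePower <- function(tfmaps) {
    if (!length(tfmaps)) stop("no maps supplied")
    fr <- tfmaps[[1]]@freqs
    for (m in tfmaps) {
        if (!identical(m@freqs, fr)) stop("maps must share the frequency grid")
        if (m@logNormalized) stop("maps are already normalized")
        if (any(m@power <= 0))
            stop("nonpositive power encountered: degenerate input")
    }
    sums <- Reduce(`+`, lapply(tfmaps, function(m) colSums(log(m@power))))
    ntot <- sum(vapply(tfmaps, function(m) nrow(m@power), numeric(1)))
    meanlog <- sums / ntot
    lapply(tfmaps, function(m) {
        m@power <- sweep(log(m@power), 2L, meanlog, "-")
        m@logNormalized <- TRUE
        m
    })
}

## Index sets for one epoch/band cell (inclusive band edges; epoch
## conventions Pre = [-1.5, 0), During = [0, offset], Post = (offset, offset+1.5]).
epochIndices <- function(times, onset, offset, epoch, pad = 1.5) {
    switch(epoch,
           Pre = which(times >= onset - pad & times < onset),
           During = which(times >= onset & times <= offset),
           Post = which(times > offset & times <= offset + pad),
           stop("unknown epoch: ", epoch))
}

#' Reduce a normalized map to the 12 portrait elements of one region
#'
#' Each element is the mean of normalized log power over the epoch's time
#' samples and the band's frequency bins (band edges inclusive).
#'
#' @param tfmap a log-normalized [TFMap-class] with onset/offset markers.
#' @param spec a [bandEpochSpec()].
#' @return named numeric of length 12 (`{region}_{epoch}_{band}`), in the
#'   frozen element order.
#' @export
extractPortrait <- function(tfmap, spec = bandEpochSpec()) {
    if (!tfmap@logNormalized) stop("map must be log-normalized first")
    if (is.na(tfmap@offset) || tfmap@offset < tfmap@onset)
        stop("movement offset precedes onset")
    out <- numeric(0)
    for (ep in .EPOCHS) {
        ti <- epochIndices(tfmap@times, tfmap@onset, tfmap@offset, ep, spec$pre)
        if (!length(ti)) stop("epoch ", ep, " contains no samples")
        for (b in .BANDS) {
            fb <- which(tfmap@freqs >= spec$bands[[b]][1] &
                        tfmap@freqs <= spec$bands[[b]][2])
            if (!length(fb)) stop("band ", b, " not covered by frequency grid")
            out[paste(tfmap@region, ep, b, sep = "_")] <-
                mean(tfmap@power[ti, fb])
        }
    }
    ## reorder epoch-major -> frozen (epoch, band) order within region
    nm <- paste(tfmap@region, rep(.EPOCHS, each = 4L), rep(.BANDS, 3L), sep = "_")
    out[nm]
}

#' Extract portrait tables from raw signals
#'
#' Runs the full time-frequency stage: Morlet decomposition of every trial
#' and region, log-power normalization per subject and region (mean log power
#' per frequency over all of that subject's trials and time points), and
#' band/epoch averaging into the 48-element portrait.  Implemented as a
#' two-pass stream over trials, algebraically identical to
#' `normalizePower()` + `extractPortrait()` but without holding all maps in
#' memory.
#'
#' @param signals a [SignalSet-class] (e.g. from [generateSignals()]).
#' @param config a [waveletConfig()]; its `fs` is overridden by the signal
#'   sampling rate.
#' @param spec a [bandEpochSpec()].
#' @return A [PortraitExperiment-class] with the trial metadata of
#'   `signals@portraits` and elements re-derived from the raw signals.
#' @export
portraitsFromSignals <- function(signals, config = NULL,
                                 spec = bandEpochSpec()) {
    pe <- signals@portraits
    if (is.null(config))
        config <- waveletConfig(fs = signals@fs)
    else if (config$fs != signals@fs)
        config <- waveletConfig(config$ratio, config$freqs, signals@fs)
    nT <- length(signals@signals)
    nF <- length(config$freqs)
    minLen <- 2L * floor(3 * (config$ratio / (2 * pi * config$freqs[1])) *
                             config$fs) + 1L
    nfft <- stats::nextn(max(vapply(signals@signals, nrow, numeric(1))) + minLen, 2)
    subj <- pe$subject
    info <- elementInfo()
    bandBins <- lapply(spec$bands, function(b)
        which(config$freqs >= b[1] & config$freqs <= b[2]))
    if (any(!lengths(bandBins))) stop("frequency grid does not cover all bands")

    ## pass 1: per (subject, region) sums of log power over trials and times;
    ## per (trial, region) raw epoch x band means of log power
    keys <- unique(subj)
    sumlog <- array(0, c(length(keys), 4L, nF),
                    dimnames = list(keys, .REGIONS, NULL))
    counts <- matrix(0, length(keys), 4L, dimnames = list(keys, .REGIONS))
    rawMean <- array(NA_real_, c(nT, 4L, 3L, 4L),
                     dimnames = list(NULL, .REGIONS, .EPOCHS, .BANDS))
    for (i in seq_len(nT)) {
        x <- signals@signals[[i]]
        tt <- signals@times[[i]]
        d <- pe$movement_duration[i]
        epi <- lapply(.EPOCHS, function(ep) epochIndices(tt, 0, d, ep, spec$pre))
        names(epi) <- .EPOCHS
        if (any(!lengths(epi))) stop("trial ", i, " has an empty epoch")
        for (r in seq_len(4L)) {
            tf <- morletTransform(x[, r], config, times = tt, onset = 0,
                                  offset = d, region = .REGIONS[r],
                                  trialId = as.character(i), nfft = nfft)
            if (any(tf@power <= 0))
                stop("nonpositive power in trial ", i, ": degenerate signal")
            L <- log(tf@power)
            sumlog[subj[i], r, ] <- sumlog[subj[i], r, ] + colSums(L)
            counts[subj[i], r] <- counts[subj[i], r] + nrow(L)
            for (ep in .EPOCHS) for (b in .BANDS)
                rawMean[i, r, ep, b] <- mean(L[epi[[ep]], bandBins[[b]]])
        }
    }
    ## pass 2: element = raw mean log power - band average of meanlog(f)
    E <- matrix(0, 48L, nT, dimnames = list(elementNames(), colnames(pe)))
    for (i in seq_len(nT)) for (j in seq_len(48L)) {
        r <- info$region[j]
        E[j, i] <- rawMean[i, r, info$epoch[j], info$band[j]] -
            mean(sumlog[subj[i], r, bandBins[[info$band[j]]]] /
                     counts[subj[i], r])
    }
    PortraitExperiment(E, subject = subj, category = pe$category,
                       movement_error = pe$movement_error,
                       movement_duration = pe$movement_duration,
                       metadata = list(source = "tfr",
                                       wavelet = unclass(config)))
}
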