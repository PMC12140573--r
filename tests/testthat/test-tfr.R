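test_that("Morlet transform basics: ridge, scaling, zero input, length guard", {
    cfg <- waveletConfig(freqs = seq(4, 30, 0.5), fs = 256)
    tt <- seq(0, 5, by = 1 / 256)
    x <- sin(2 * pi * 10 * tt)
    tf <- morletTransform(x, cfg, onset = 0, offset = 2)
    mid <- !tf@edge
    p10 <- mean(tf@power[mid, tf@freqs == 10])
    p20 <- mean(tf@power[mid, tf@freqs == 20])
    expect_gt(p10 / p20, 100)
    # quadratic amplitude scaling
    tf2 <- morletTransform(2 * x, cfg, onset = 0, offset = 2)
    expect_equal(tf2@power, 4 * tf@power, tolerance = 1e-10)
    # zero signal -> zero power
    tf0 <- morletTransform(numeric(length(tt)), cfg, onset = 0, offset = 2)
    expect_true(all(tf0@power == 0))
    # too-short signal names the minimum length
    cfg2 <- waveletConfig(freqs = c(2, 10), fs = 256)
    expect_error(morletTransform(rnorm(100), cfg2), "at least")
})

test_that("FFT convolution equals direct time-domain convolution", {
    cfg <- waveletConfig(freqs = c(6, 11, 19), fs = 128)
    set.seed(8)
    x <- rnorm(400)
    tf <- morletTransform(x, cfg)
    for (j in seq_along(cfg$freqs)) {
        direct <- directMorletPower(x, cfg$freqs[j], cfg$ratio, cfg$fs)
        expect_lt(max(abs(tf@power[, j] - direct)), 1e-10)
    }
})

test_that("raw wavelet power grows linearly with white-noise variance", {
    cfg <- waveletConfig(freqs = seq(5, 40, 5), fs = 128)
    set.seed(9)
    sds <- c(1, 2, 3, 4, 5)
    tot <- vapply(sds, function(s)
        sum(morletTransform(rnorm(3000, sd = s), cfg)@power), numeric(1))
    fit <- lm(tot ~ I(sds^2))
    expect_gt(summary(fit)$r.squared, 0.99)
})

test_that("log-power normalization matches its definition", {
    cfg <- waveletConfig(freqs = seq(5, 20, 5), fs = 64)
    set.seed(10)
    maps <- lapply(1:4, function(i)
        morletTransform(rnorm(300) + 2, cfg, onset = 0, offset = 1,
                        trialId = as.character(i)))
    norm <- normalizePower(maps)
    # mean over trials and time is zero at every frequency
    tot <- Reduce(`+`, lapply(norm, function(m) colSums(m@power)))
    expect_lt(max(abs(tot / (4 * nrow(norm[[1]]@power)))), 1e-12)
    # identical raw maps: both trials normalize identically, zero column means
    same <- normalizePower(list(maps[[1]], maps[[1]]))
    expect_identical(same[[1]]@power, same[[2]]@power)
    expect_lt(max(abs(colMeans(same[[1]]@power))), 1e-12)
    # invariance to a global multiplicative constant
    scaled <- lapply(maps, function(m) { m@power <- 7 * m@power; m })
    norm2 <- normalizePower(scaled)
    expect_equal(norm2[[1]]@power, norm[[1]]@power, tolerance = 1e-10)
    # one trial scaled by e shifts by ~ +1 minus the 1/n adjustment
    up <- maps
    up[[1]]@power <- exp(1) * up[[1]]@power
    norm3 <- normalizePower(up)
    shift <- norm3[[1]]@power - norm[[1]]@power
    expect_equal(mean(shift), 1 - 1 / 4, tolerance = 1e-10)
    # degenerate input rejected
    bad <- maps
    bad[[2]]@power[5, 2] <- 0
    expect_error(normalizePower(bad), "degenerate")
})

test_that("portrait extraction averages exactly over band/epoch index sets", {
    freqs <- seq(2, 60, 0.5)
    times <- seq(-1.5, 2.5, by = 1 / 64)
    mk <- function(P) new("TFMap", power = P, times = times, freqs = freqs,
                          onset = 0, offset = 1, region = "IC2",
                          trialId = "t", logNormalized = TRUE,
                          edge = rep(FALSE, length(times)))
    # constant map: every element equals the constant
    el <- extractPortrait(mk(matrix(3.5, length(times), length(freqs))))
    expect_true(all(el == 3.5))
    expect_identical(names(el),
                     grep("^IC2_", elementNames(), value = TRUE))
    # indicator of (Pre, theta): that element 1, all others 0
    P <- matrix(0, length(times), length(freqs))
    P[times >= -1.5 & times < 0, freqs >= 4 & freqs <= 8] <- 1
    el2 <- extractPortrait(mk(P))
    expect_equal(unname(el2["IC2_Pre_theta"]), 1)
    expect_true(all(el2[setdiff(names(el2), "IC2_Pre_theta")] == 0))
    # brute-force oracle for a random map
    set.seed(11)
    P3 <- matrix(rnorm(length(times) * length(freqs)), length(times))
    el3 <- extractPortrait(mk(P3))
    ti <- which(times > 1 & times <= 2.5)
    fb <- which(freqs >= 13 & freqs <= 35)
    expect_equal(unname(el3["IC2_Post_beta"]),
                 mean(P3[ti, fb]), tolerance = 1e-12)
    # marker errors
    bad <- mk(P3)
    bad@offset <- -1
    expect_error(extractPortrait(bad), "offset precedes onset")
})

test_that("streaming portrait extraction equals the naive composition", {
    cfg <- synthConfig(n_subjects = 2, trials_per_category = c("NR-Hit" = 6),
                       seed = 15)
    sig <- generateSignals(cfg)
    wc <- waveletConfig(freqs = seq(3, 45, 1.5), fs = sig@fs)
    pe <- portraitsFromSignals(sig, config = wc)
    # naive path: full maps per subject and region, then normalize + extract
    spec <- bandEpochSpec()
    naive <- matrix(NA_real_, 6, 48, dimnames = list(NULL, elementNames()))
    for (s in unique(sig@portraits$subject)) {
        idx <- which(sig@portraits$subject == s)
        for (r in c("IC1", "IC2", "IC3", "IC4")) {
            maps <- lapply(idx, function(i)
                morletTransform(sig@signals[[i]][, r], wc,
                                times = sig@times[[i]], onset = 0,
                                offset = sig@portraits$movement_duration[i],
                                region = r, trialId = as.character(i)))
            nm <- normalizePower(maps)
            for (jj in seq_along(idx))
                naive[idx[jj], names(extractPortrait(nm[[jj]], spec))] <-
                    extractPortrait(nm[[jj]], spec)
        }
    }
    expect_equal(elementMatrix(pe), naive, tolerance = 1e-10,
                 ignore_attr = TRUE)
})

test_that("portrait extraction is invariant to padding outside the segment", {
    cfg <- waveletConfig(freqs = seq(4, 40, 2), fs = 128)
    set.seed(12)
    tt <- seq(-1.5, 2.5, by = 1 / 128)
    x <- rnorm(length(tt)) + 1
    tf <- normalizePower(list(morletTransform(x, cfg, times = tt, onset = 0,
                                              offset = 1, region = "IC1")))[[1]]
    elA <- extractPortrait(tf)
    # pad the map with extra samples outside [-1.5, offset + 1.5]
    extraT <- c(seq(-2.5, -1.51, by = 1 / 128), tt, seq(2.51, 3.5, by = 1 / 128))
    npadL <- sum(extraT < -1.5)
    npadR <- sum(extraT > 2.5)
    P <- rbind(matrix(5, npadL, length(cfg$freqs)), tf@power,
               matrix(-5, npadR, length(cfg$freqs)))
    tf2 <- new("TFMap", power = P, times = extraT, freqs = cfg$freqs,
               onset = 0, offset = 1, region = "IC1", trialId = "t",
               logNormalized = TRUE, edge = rep(FALSE, length(extraT)))
    expect_equal(extractPortrait(tf2), elA, tolerance = 1e-12)
})

test_that("wavelet configuration is validated", {
    expect_error(waveletConfig(ratio = 0), "positive")
    expect_error(waveletConfig(freqs = c(10, 10, 12)), "increasing")
    expect_error(waveletConfig(freqs = c(10, 200), fs = 256), "fs/2")
})
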