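test_that("generator is deterministic and validates its inputs", {
    cfg <- synthConfig(n_subjects = 3,
                       trials_per_category = c("NR-Hit" = 40, "RS-Miss" = 40),
                       seed = 7)
    a <- generatePortraits(cfg)
    b <- generatePortraits(cfg)
    expect_identical(assay(a, "elements"), assay(b, "elements"))
    expect_identical(a$movement_duration, b$movement_duration)

    expect_error(synthConfig(trials_per_category = c(Foo = 10)), "categories")
    expect_error(synthConfig(residual_sd = 0), "positive")
    expect_error(synthConfig(delta = -1), "nonnegative")
    expect_error(synthConfig(B = matrix(0, 48, 5)), "full column rank")
})

test_that("trial metadata respects the generating contracts", {
    cfg <- synthConfig(n_subjects = 4,
                       trials_per_category = c("NR-Hit" = 120, "Ct-Miss" = 120),
                       seed = 3)
    pe <- generatePortraits(cfg)
    expect_equal(dim(pe), c(48L, 240L))
    expect_true(all(pe$movement_duration > 0))
    # Hit/Miss membership consistent with |err| vs the threshold
    hit <- pe$category == "NR-Hit"
    expect_true(all(abs(pe$movement_error[hit]) < cfg$hit_threshold))
    expect_true(all(abs(pe$movement_error[!hit]) >= cfg$hit_threshold))
    # decoupled labels: magnitudes unconstrained
    cfg2 <- synthConfig(n_subjects = 4,
                        trials_per_category = c("NR-Hit" = 400),
                        couple_labels = FALSE, seed = 3)
    pe2 <- generatePortraits(cfg2)
    expect_gt(max(abs(pe2$movement_error)), cfg2$hit_threshold)
})

test_that("sample covariance approaches the closed-form model covariance", {
    cfg <- synthConfig(n_subjects = 1, trials_per_category = c("NR-Hit" = 50000),
                       subject_intercept_sd = 0, couple_labels = FALSE,
                       category_separation = 0, seed = 11)
    pe <- generatePortraits(cfg)
    gt <- metadata(pe)$groundTruth
    A <- gt$A[["NR-Hit"]]
    g <- gt$gamma[["NR-Hit"]]
    SigmaModel <- tcrossprod(A) + cfg$error_sd^2 * tcrossprod(g) +
        diag(cfg$residual_sd^2, 48)
    SigmaHat <- cov(elementMatrix(pe))
    relFrob <- norm(SigmaHat - SigmaModel, "F") / norm(SigmaModel, "F")
    expect_lt(relFrob, 0.05)
})

test_that("ground-truth EC matches brute-force least squares (k = 1 loading)", {
    B <- matrix(0, 48, 1)
    B[1:2, 1] <- 0.8
    cfg <- synthConfig(n_subjects = 1, trials_per_category = c("NR-Hit" = 300000),
                       k = 1, B = B, delta = 0, category_separation = 0,
                       subject_intercept_sd = 0, couple_labels = FALSE,
                       error_loadings = rep(0, 48),
                       duration_readout = rep(0, 48), seed = 13)
    gt <- groundTruthEC(cfg, "NR-Hit")
    W <- ecWeights(gt)
    # only elements 1 and 2 are coupled
    offdiag <- W
    diag(offdiag) <- NA
    expect_gt(abs(W[1, 2]), 0.2)
    expect_equal(W[1, 2], W[2, 1])
    expect_lt(max(abs(offdiag[-(1:2), ]), na.rm = TRUE), 1e-12)
    # empirical oracle: plain least squares of element 1 on the other 47
    pe <- generatePortraits(cfg)
    E <- elementMatrix(pe)
    b <- qr.coef(qr(cbind(1, E[, -1])), E[, 1])[-1]
    expect_lt(max(abs(b - W[1, -1])), 1e-2)
})

test_that("ground-truth EC degenerate and scale-invariance cases", {
    # near-zero loadings: independent elements, EC vanishes
    B0 <- matrix(1e-8, 48, 1)
    cfg0 <- synthConfig(k = 1, B = B0, delta = 0,
                        error_loadings = rep(0, 48), seed = 2)
    expect_lt(max(abs(ecWeights(groundTruthEC(cfg0, "NR-Hit")))), 1e-8)
    # common rescaling of the covariance leaves regression coefficients fixed
    set.seed(2)
    B <- matrix(rnorm(48 * 2, sd = 0.4), 48, 2)
    cfg1 <- synthConfig(k = 2, B = B, delta = 0, residual_sd = 1,
                        error_loadings = rep(0.2, 48), seed = 2)
    cfg2 <- synthConfig(k = 2, B = sqrt(2) * B, delta = 0,
                        residual_sd = sqrt(2),
                        error_loadings = rep(0.2, 48) * sqrt(2), seed = 2)
    expect_equal(ecWeights(groundTruthEC(cfg1, "NR-Hit")),
                 ecWeights(groundTruthEC(cfg2, "NR-Hit")), tolerance = 1e-10)
    expect_error(groundTruthEC(cfg1, "nope"), "unknown category")
})

test_that("generated signals are reproducible and encode element amplitudes", {
    cfg <- synthConfig(n_subjects = 1, trials_per_category = c("NR-Hit" = 30),
                       broadband_sd = 0.02, seed = 5)
    s1 <- generateSignals(cfg)
    s2 <- generateSignals(cfg)
    expect_identical(s1@signals, s2@signals)
    expect_error(generateSignals(cfg, fs = 100), "twice the top band edge")
    # in-band variance of the Pre segment tracks exp(element): bandpass the
    # theta band by FFT masking and compare log variance with the element
    el <- assay(s1@portraits, "elements")["IC1_Pre_theta", ]
    logvar <- vapply(seq_along(s1@signals), function(i) {
        tt <- s1@times[[i]]
        x <- s1@signals[[i]][tt < -0.1, "IC1"]   # clear of the onset ramp
        n <- length(x)
        f <- (seq_len(n) - 1) * s1@fs / n
        f <- pmin(f, s1@fs - f)
        X <- fft(x)
        X[f < 4 | f > 8] <- 0
        log(var(Re(fft(X, inverse = TRUE)) / n))
    }, numeric(1))
    expect_gt(cor(logvar, el), 0.8)
})

test_that("CSV round trip preserves the table", {
    cfg <- synthConfig(n_subjects = 2, trials_per_category = c("AR-Miss" = 25),
                       seed = 9)
    pe <- generatePortraits(cfg)
    f <- tempfile(fileext = ".csv")
    writePortraits(pe, f)
    pe2 <- readPortraits(f)
    expect_equal(elementMatrix(pe2), elementMatrix(pe),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_identical(pe2$category, pe$category)
    header <- strsplit(readLines(f, 1), ",")[[1]]
    expect_identical(gsub('"', "", header),
                     c("subject", "category", "movement_error",
                       "movement_duration", elementNames()))
})
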