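test_that("Bhattacharyya coefficient follows its definition", {
    expect_equal(bhattacharyya(c(0.5, 0.5), c(0.5, 0.5)), 1)
    expect_equal(bhattacharyya(c(1, 0), c(0, 1)), 0)
    expect_equal(bhattacharyya(c(0.5, 0.5), c(0.9, 0.1)),
                 sqrt(0.45) + sqrt(0.05), tolerance = 1e-12)
    expect_error(bhattacharyya(c(0.5, 0.6), c(0.5, 0.5)), "sum to 1")
    expect_error(bhattacharyya(c(-0.1, 1.1), c(0.5, 0.5)), "negative")
    expect_error(bhattacharyya(c(1), c(0.5, 0.5)), "support")
    # property: symmetry and bounds on random histograms
    set.seed(60)
    for (i in 1:200) {
        p <- rexp(15); p <- p / sum(p)
        q <- rexp(15); q <- q / sum(q)
        bc <- bhattacharyya(p, q)
        expect_true(bc >= 0 && bc <= 1 + 1e-12)
        expect_equal(bc, bhattacharyya(q, p), tolerance = 1e-14)
    }
})

test_that("element overlap matches the Gaussian closed form", {
    set.seed(61)
    n <- 2000
    E <- matrix(rnorm(n * 48), n, 48)
    E[1:(n / 2), 1] <- rnorm(n / 2, mean = 5)   # 5-sd shift in element 1
    pe <- makePE(E, category = rep(c("NR-Miss", "NR-Hit"), each = n / 2))
    bc <- elementOverlap(pe, elementNames()[1], "NR-Miss", "NR-Hit")
    expect_lt(as.numeric(bc), 0.05)             # exp(-25/8) ~ 0.044
    # identical generators: overlap near 1
    bc2 <- elementOverlap(pe, elementNames()[2], "NR-Miss", "NR-Hit")
    expect_gt(as.numeric(bc2), 0.97)
    expect_error(elementOverlap(pe[, 1:40], elementNames()[1], "NR-Miss",
                                "NR-Hit"), "at least 30")
})

test_that("noiseless linear readouts are predicted perfectly", {
    set.seed(62)
    E <- matrix(rnorm(400 * 48), 400, 48)
    v <- rnorm(48, sd = 0.2)
    dur <- 2 + as.numeric(E %*% v)
    pe <- makePE(E, subject = rep(c("S1", "S2"), 200), duration = dur - min(dur) + 0.5)
    res <- predictBehavior(pe, "duration", nFolds = 5, seed = 1)
    expect_gt(mean(res$r), 0.999)
    expect_lt(mean(res$mse), 1e-6 * var(dur))
})

test_that("held-out correlation matches the attainable closed form", {
    cfg <- synthConfig(n_subjects = 4, trials_per_category = c("NR-Hit" = 2500),
                       couple_labels = FALSE, duration_baseline = 1.5, seed = 63)
    pe <- generatePortraits(cfg)
    gt <- metadata(pe)$groundTruth
    A <- gt$A[["NR-Hit"]]
    g <- gt$gamma[["NR-Hit"]]
    Sigma <- tcrossprod(A) + cfg$error_sd^2 * tcrossprod(g) +
        diag(cfg$residual_sd^2 + cfg$subject_intercept_sd^2, 48)
    V <- as.numeric(t(gt$v) %*% Sigma %*% gt$v)
    rTheory <- sqrt(V / (V + cfg$duration_noise_sd^2))
    res <- predictBehavior(pe, "duration", nFolds = 10, seed = 2)
    expect_lt(abs(mean(res$r) - rTheory), 0.05)
})

test_that("shuffled-target control destroys predictability", {
    cfg <- synthConfig(n_subjects = 4, trials_per_category = c("RS-Miss" = 800),
                       seed = 64)
    pe <- generatePortraits(cfg)
    res <- predictBehavior(pe, "error", nFolds = 15, seed = 3)
    ctl <- shuffledBehaviorControl(pe, "error", nFolds = 15, seed = 3)
    expect_gt(mean(res$r), 0.3)              # gamma drive makes error readable
    se <- sd(ctl$r) / sqrt(length(ctl$r))
    expect_lt(abs(mean(ctl$r)), 3 * se + 0.02)
    # shuffled MSE exceeds unshuffled, fold-paired
    expect_gt(mean(ctl$mse - res$mse), 0)
    ctl2 <- shuffledBehaviorControl(pe, "error", nFolds = 15, seed = 3)
    expect_identical(ctl$r, ctl2$r)
    expect_error(predictBehavior(pe, "error", category = "NR-Hit"),
                 "category absent")
})

test_that("target independent of elements gives null correlation", {
    set.seed(65)
    E <- matrix(rnorm(600 * 48), 600, 48)
    pe <- makePE(E, subject = rep(c("S1", "S2"), 300),
                 error = rnorm(600), duration = runif(600, 0.5, 1.5))
    res <- predictBehavior(pe, "error", nFolds = 15, seed = 4)
    se <- sd(res$r) / sqrt(length(res$r))
    expect_lt(abs(mean(res$r)), 2 * se + 0.03)
})

test_that("portrait beats single elements when the readout is distributed", {
    info <- elementInfo()
    v <- numeric(48)
    v[info$epoch == "During"] <- 0.08      # spread over 16 elements
    cfg <- synthConfig(n_subjects = 3, trials_per_category = c("NR-Hit" = 900),
                       duration_readout = v, error_loadings = rep(0, 48),
                       seed = 66)
    pe <- generatePortraits(cfg)
    rPort <- mean(predictBehavior(pe, "duration", nFolds = 8, seed = 5)$r)
    rBest <- max(vapply(elementNames()[info$epoch == "During"], function(el)
        mean(predictBehavior(pe, "duration", features = el, nFolds = 8,
                             seed = 5)$r), numeric(1)))
    expect_gt(rPort, rBest)
})
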