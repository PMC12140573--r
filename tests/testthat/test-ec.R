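test_that("functional connectivity behaves on independent and duplicated data", {
    set.seed(20)
    E <- matrix(rnorm(10000 * 48), 10000, 48)
    pe <- makePE(E, subject = rep(c("S1", "S2"), 5000))
    fc <- computeFC(pe, nBoot = 10, seed = 1)
    off <- fc[!diag(48) > 0]
    expect_lt(max(abs(off)), 0.05)                 # independence null
    expect_true(all(diag(fc) == 1))
    expect_equal(fc, t(fc))
    # duplicated column pair -> correlation exactly 1
    E2 <- E
    E2[, 2] <- E2[, 1]
    fc2 <- computeFC(makePE(E2, subject = rep("S1", 10000)), nBoot = 5, seed = 1)
    expect_equal(unname(fc2[1, 2]), 1)
    # constant column is rejected by name
    E3 <- E
    E3[, 5] <- 2
    expect_error(computeFC(makePE(E3)), elementNames()[5])
})

test_that("exact correlation path is invariant to trial order", {
    set.seed(21)
    E <- matrix(rnorm(500 * 48), 500, 48)
    subj <- rep(c("S1", "S2"), 250)
    pe <- makePE(E, subject = subj)
    perm <- sample(500)
    peP <- makePE(E[perm, ], subject = subj[perm])
    expect_equal(computeFC(pe, nBoot = 0), computeFC(peP, nBoot = 0),
                 tolerance = 1e-12)
})

test_that("estimated EC recovers the generating precision structure", {
    cfg <- synthConfig(n_subjects = 4, trials_per_category = c("NR-Hit" = 1500),
                       seed = 22)
    pe <- generatePortraits(cfg)
    ec <- fitEC(pe, nBoot = 10, seed = 5)
    gt <- groundTruthEC(cfg, "NR-Hit", standardized = TRUE)
    off <- !diag(48) > 0
    r1500 <- cor(ecWeights(ec)[off], ecWeights(gt)[off])
    expect_gt(r1500, 0.6)
    # recovery improves with trial count
    cfgS <- synthConfig(n_subjects = 4, trials_per_category = c("NR-Hit" = 300),
                        seed = 22)
    ecS <- fitEC(generatePortraits(cfgS), nBoot = 10, seed = 5)
    gtS <- groundTruthEC(cfgS, "NR-Hit", standardized = TRUE)
    expect_gt(r1500, cor(ecWeights(ecS)[off], ecWeights(gtS)[off]))
    # reproducibility is bit-for-bit
    ec2 <- fitEC(pe, nBoot = 10, seed = 5)
    expect_identical(ecWeights(ec), ecWeights(ec2))
})

test_that("independent elements yield null cross-validated performance", {
    set.seed(23)
    E <- matrix(rnorm(800 * 48), 800, 48)
    pe <- makePE(E, subject = rep(c("S1", "S2"), 400))
    ec <- fitEC(pe, nBoot = 5, seed = 2)
    expect_lt(abs(mean(ecPerformance(ec))), 0.05)
})

test_that("EC weights are invariant to common rescaling of the elements", {
    cfg <- synthConfig(n_subjects = 3, trials_per_category = c("RS-Hit" = 400),
                       seed = 24)
    pe <- generatePortraits(cfg)
    peS <- makePE(elementMatrix(pe) * 3.7, subject = pe$subject,
                  category = pe$category, error = pe$movement_error,
                  duration = pe$movement_duration)
    ecA <- fitEC(pe, nBoot = 3, seed = 9)
    ecB <- fitEC(peS, nBoot = 3, seed = 9)
    expect_equal(ecWeights(ecA), ecWeights(ecB), tolerance = 1e-6)
})

test_that("behaviour nodes join the network when requested", {
    cfg <- synthConfig(n_subjects = 3, trials_per_category = c("NR-Hit" = 300),
                       seed = 25)
    pe <- generatePortraits(cfg)
    ec <- fitEC(pe, includeBehavior = TRUE, nBoot = 3, seed = 4)
    expect_identical(ecNodes(ec), c(elementNames(), "error", "duration"))
    expect_equal(dim(ecWeights(ec)), c(50L, 50L))
    expect_true(all(diag(ecWeights(ec)) == 0))
})

test_that("cross-training needs valid categories and reduces to CV on the diagonal", {
    cfg <- synthConfig(n_subjects = 3,
                       trials_per_category = c("NR-Hit" = 200, "RS-Hit" = 200),
                       seed = 26)
    pe <- generatePortraits(cfg)
    M <- crossTrain(pe, nResamples = 3, seed = 8)
    expect_identical(dimnames(M), list(c("NR-Hit", "RS-Hit"),
                                       c("NR-Hit", "RS-Hit")))
    expect_true(all(M > 0))                  # structured data are predictable
    expect_true(all(diag(M) > c(M[1, 2], M[2, 1])))
    peOne <- pe[, pe$category == "NR-Hit"]
    expect_error(crossTrain(peOne), "at least 2 categories")
})

test_that("EC similarity is the off-diagonal correlation", {
    set.seed(27)
    w <- matrix(rnorm(48 * 48), 48)
    ecA <- ecFromWeights(w)
    expect_equal(ecSimilarity(ecA, ecA), 1)
    ecNeg <- ecFromWeights(-w)
    expect_equal(ecSimilarity(ecA, ecNeg), -1)
    # independent matrices: near-zero similarity at 2256 paired entries
    rs <- replicate(20, ecSimilarity(ecFromWeights(matrix(rnorm(2304), 48)),
                                     ecFromWeights(matrix(rnorm(2304), 48))))
    expect_lt(median(abs(rs)), 0.06)
    ecSub <- new("ECMatrix", weights = w[1:10, 1:10] - diag(diag(w[1:10, 1:10])),
                 nodes = elementNames()[1:10], performance = numeric(0),
                 nBoot = 0L, provenance = "test")
    expect_error(ecSimilarity(ecA, ecSub), "node sets differ")
})

test_that("edge-list export matches the weight matrix", {
    set.seed(28)
    w <- matrix(rnorm(2304), 48)
    ec <- ecFromWeights(w)
    el <- ecEdgeList(ec)
    expect_equal(nrow(el), 48 * 47)
    i <- which(el$source == elementNames()[3] & el$target == elementNames()[7])
    expect_equal(el$weight[i], ecWeights(ec)[7, 3])
    expect_equal(el$abs_weight, abs(el$weight))
})
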