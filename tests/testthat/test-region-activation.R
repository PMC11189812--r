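# z-scoring, linear SVM, forward-model transform, ranking, AP binning

test_that("standardization gives exact column moments and keeps constants", {
    m <- matrix(c(1, 2, 3), nrow = 1,
                dimnames = list("IC", c("a1", "a2", "a3")))
    tab <- CellCountTable(m, group = c("saline", "R-ket", "S-ket"))
    z <- standardizeCounts(tab)
    expect_equal(as.numeric(zscores(z)), c(-1, 0, 1))
    expect_equal(z@centers[["IC"]], 2)
    expect_equal(z@scales[["IC"]], 1)

    sim <- simCellCounts(countSimConfig(seed = 9))
    z2 <- standardizeCounts(sim$table)
    zz <- zscores(z2)
    # brute-force moments, loops only
    for (j in seq_len(ncol(zz))) {
        mu <- sum(zz[, j]) / nrow(zz)
        s2 <- sum((zz[, j] - mu)^2) / (nrow(zz) - 1)
        expect_lt(abs(mu), 1e-10)
        expect_lt(abs(sqrt(s2) - 1), 1e-10)
    }
})

test_that("zero-variance regions are rejected by name", {
    m <- matrix(c(5, 5, 5, 1, 2, 4), nrow = 2, byrow = TRUE,
                dimnames = list(c("ACC", "IC"), c("a1", "a2", "a3")))
    tab <- CellCountTable(m, group = c("saline", "R-ket", "S-ket"))
    expect_error(standardizeCounts(tab), "ACC")
})

test_that("scaling one region's counts leaves z, W and A unchanged", {
    sim <- simCellCounts(countSimConfig(effectSize = 2, seed = 15))
    tab <- sim$table
    m2 <- counts(tab); m2["IC", ] <- m2["IC", ] * 2
    tab2 <- CellCountTable(m2, group = as.character(groups(tab)),
                           groupLevels = levels(groups(tab)))
    z1 <- standardizeCounts(tab);  z2 <- standardizeCounts(tab2)
    expect_equal(z2@scales[["IC"]], 2 * z1@scales[["IC"]], tolerance = 1e-12)
    expect_equal(zscores(z1), zscores(z2), tolerance = 1e-8)
    m1 <- fitLinearSVM(z1, positive = "R-ket", negative = "saline")
    mm2 <- fitLinearSVM(z2, positive = "R-ket", negative = "saline")
    expect_equal(weights(m1), weights(mm2), tolerance = 1e-8)
    expect_equal(activation(haufeActivation(m1, z1)),
                 activation(haufeActivation(mm2, z2)), tolerance = 1e-8)
})

test_that("hard-margin fit on symmetric 1-D data is exact", {
    x <- matrix(c(-1, 1), ncol = 1)
    m <- fitLinearSVM(x, c("neg", "pos"), positive = "pos", C = 1e6)
    expect_equal(unname(weights(m)), 1, tolerance = 1e-9)
    expect_equal(m@intercept, 0, tolerance = 1e-9)
    expect_equal(m@margin, 2, tolerance = 1e-8)
    expect_equal(m@trainAccuracy, 1)
    expect_equal(sign(decisionValues(m, x)), c(-1, 1))
})

test_that("label exchange negates weights and intercept exactly", {
    withr::with_seed(31, {
        for (r in 1:10) {
            pr <- separatedProblem(10, 5)
            m1 <- fitLinearSVM(pr$x, pr$y, positive = "b", negative = "a")
            m2 <- fitLinearSVM(pr$x, pr$y, positive = "a", negative = "b")
            expect_identical(unname(weights(m1)), -unname(weights(m2)))
            expect_identical(m1@intercept, -m2@intercept)
            # |A| ranking is label-invariant
            A1 <- activation(haufeActivation(m1, pr$x))
            A2 <- activation(haufeActivation(m2, pr$x))
            expect_equal(A1, -A2, tolerance = 1e-12)
        }
    })
})

test_that("dual objective matches the libsvm reference", {
    withr::with_seed(47, {
        for (r in 1:15) {
            pr <- separatedProblem(10, 5, sep = stats::runif(1, 0.5, 2.5))
            Cc <- sample(c(0.1, 1, 10), 1)
            m <- fitLinearSVM(pr$x, pr$y, positive = "b", negative = "a",
                              C = Cc)
            sv <- e1071::svm(pr$x, factor(pr$y, levels = c("b", "a")),
                             kernel = "linear", cost = Cc, scale = FALSE,
                             tolerance = 1e-8)
            av <- rep(0, nrow(pr$x)); av[sv$index] <- sv$coefs
            K <- tcrossprod(pr$x)
            ref <- 0.5 * sum(av * (K %*% av)) - sum(abs(av))
            expect_lt(abs(m@dualObjective - ref), 1e-6)
        }
    })
})

test_that("degenerate SVM inputs are refused", {
    x <- matrix(rnorm(20), 10, 2)
    expect_error(fitLinearSVM(x, rep("a", 10)), "two classes")
    x[1] <- NA
    expect_error(fitLinearSVM(x, rep(c("a", "b"), 5)), "finite")
})

test_that("whitened data collapses the pattern onto the weights", {
    withr::with_seed(53, {
        for (r in 1:10) {
            x <- whiten(matrix(rnorm(20 * 4), 20, 4))
            w <- rnorm(4)
            model <- new("ClassifierModel", weights = w, intercept = 0,
                         positive = "b", negative = "a", cost = 1,
                         alpha = numeric(20), rowIndex = seq_len(20),
                         trainAccuracy = 1, margin = 1, dualObjective = 0,
                         iterations = 0L, converged = TRUE)
            A <- activation(haufeActivation(model, x))
            expect_equal(unname(A), w / sum(w * w), tolerance = 1e-8)
            cosang <- sum(A * w) / sqrt(sum(A^2) * sum(w^2))
            expect_gte(cosang, 1 - 1e-8)
        }
    })
})

test_that("diagonal covariance leaves a unit weight vector untouched", {
    withr::with_seed(59, {
        x <- whiten(matrix(rnorm(30 * 3), 30, 3))
        x <- sweep(x, 2, c(2, 0.5, 3), `*`)    # exact diagonal covariance
        w <- c(1, 0, 0)
        model <- new("ClassifierModel", weights = w, intercept = 0,
                     positive = "b", negative = "a", cost = 1,
                     alpha = numeric(30), rowIndex = seq_len(30),
                     trainAccuracy = 1, margin = 1, dualObjective = 0,
                     iterations = 0L, converged = TRUE)
        A <- activation(haufeActivation(model, x))
        expect_equal(unname(A), c(1, 0, 0), tolerance = 1e-10)
    })
})

test_that("activation equals the brute-force covariance transform", {
    withr::with_seed(61, {
        worst <- 0
        for (r in 1:30) {
            p <- sample(2:8, 1)
            n <- 2 * sample(5:10, 1)
            pr <- separatedProblem(n, p)
            m <- fitLinearSVM(pr$x, pr$y, positive = "b", negative = "a")
            A <- activation(haufeActivation(m, pr$x))
            ref <- bruteActivation(pr$x, weights(m))
            worst <- max(worst, max(abs(unname(A) - ref)))
        }
        expect_lt(worst, 1e-10)
    })
})

test_that("degenerate latent variance raises a degeneracy error", {
    x <- matrix(rnorm(20), 10, 2)
    model <- new("ClassifierModel", weights = c(1e-9, 0), intercept = 0,
                 positive = "b", negative = "a", cost = 1,
                 alpha = numeric(10), rowIndex = 1:10, trainAccuracy = 1,
                 margin = 1, dualObjective = 0, iterations = 0L,
                 converged = TRUE)
    expect_error(haufeActivation(model, x), "degenerate")
})

test_that("regions rank by |A| with stable ties and a nominated top", {
    pat <- new("ActivationPattern",
               A = c(ACC = 0.1, IC = -0.9, PL = 0.5),
               sigmaX = diag(3), sigmaS = 1,
               weights = c(ACC = 0.1, IC = -0.9, PL = 0.5),
               positive = "R-ket", negative = "saline")
    # identity sigmaX with A == W keeps the class validity satisfied
    rk <- rankRegions(pat)
    expect_identical(rk$region, c("IC", "PL", "ACC"))
    expect_true(rk$nominated[1] && !any(rk$nominated[-1]))
    patTie <- new("ActivationPattern",
                  A = c(ACC = 0.5, IC = -0.5, PL = 0.5),
                  sigmaX = diag(3), sigmaS = 1,
                  weights = c(ACC = 0.5, IC = -0.5, PL = 0.5),
                  positive = "R-ket", negative = "saline")
    expect_identical(rankRegions(patTie)$region, c("ACC", "IC", "PL"))
})

test_that("a strongly planted region dominates both discriminations", {
    # large effect on few regions so the win probability is near 1
    nm <- c("IC", "ACC", "PL", "CLA", "STR", "TH", "HIP", "AMY")
    cfg <- countSimConfig(nPerGroup = 8, nRegions = 8, regionNames = nm,
                          effectRegions = "IC", effectSize = 3, seed = 101)
    sim <- simCellCounts(cfg)
    res <- classifyAndMap(sim$table)
    expect_identical(unname(res$nominated), c("IC", "IC"))
    expect_identical(names(res$comparisons),
                     c("R-ket_vs_saline", "R-ket_vs_S-ket"))
    expect_identical(nrow(res$joint), 8L)
    # single comparison -> list of length one
    res1 <- classifyAndMap(sim$table,
                           comparisons = list(c("R-ket", "saline")))
    expect_length(res1$comparisons, 1L)
})

test_that("planted-region recovery is far above the null rate", {
    hits <- 0; nullHits <- 0
    for (r in 1:40) {
        sim <- simCellCounts(countSimConfig(effectSize = 2, seed = 300 + r))
        res <- classifyAndMap(sim$table,
                              comparisons = list(c("R-ket", "saline")))
        hits <- hits + (res$nominated[[1]] == "IC")
        sim0 <- simCellCounts(countSimConfig(effectSize = 0, seed = 700 + r))
        res0 <- classifyAndMap(sim0$table,
                               comparisons = list(c("R-ket", "saline")))
        nullHits <- nullHits + (res0$nominated[[1]] == "IC")
    }
    expect_gt(hits / 40, 0.30)        # chance is 1/22
    expect_lt(nullHits / 40, 0.20)
})

test_that("AP binning places cells by half-open bins and conserves totals", {
    cells <- CellCoordinateSet(data.frame(
        animal_id = "a1", group = "R-ket",
        ap_mm = c(2.4, 1.5, 0.0), ml_mm = 3, dv_mm = -3))
    d <- binAPDistribution(cells)
    expect_identical(which(apCounts(d)[, "R-ket"] == 1L), c(1L, 3L, 8L))
    # edges: the anterior edge is included, the aIC lower edge is not
    edge <- CellCoordinateSet(data.frame(
        animal_id = "a1", group = "g",
        ap_mm = c(2.50, 1.45, -1.00), ml_mm = 3, dv_mm = -3))
    de <- binAPDistribution(edge)
    expect_identical(unname(apCounts(de)[c(1, 4, 10), "g"]), rep(1L, 3))
    expect_identical(d@subdivision,
                     rep(c("aIC", "mIC", "pIC"), c(3, 3, 4)))
    # empty input -> all-zero histogram
    d0 <- binAPDistribution(CellCoordinateSet(data.frame(
        animal_id = character(0), group = character(0), ap_mm = numeric(0),
        ml_mm = numeric(0), dv_mm = numeric(0))))
    expect_true(all(apCounts(d0) == 0))
    # point mass inside the aIC
    pm <- CellCoordinateSet(data.frame(animal_id = "a", group = "g",
                                       ap_mm = rep(2, 5), ml_mm = 3,
                                       dv_mm = -3))
    dp <- binAPDistribution(pm)
    expect_identical(sum(apCounts(dp) > 0), 1L)
    expect_identical(apSubdivisionCounts(dp)$g[1], 5L)
    # out-of-range cells land in the overflow bucket, totals conserved
    ov <- CellCoordinateSet(data.frame(animal_id = "a", group = "g",
                                       ap_mm = c(2.8, 1.0, -1.2), ml_mm = 3,
                                       dv_mm = -3))
    dov <- binAPDistribution(ov)
    expect_identical(unname(dov@overflow[["g"]]), 2)
    expect_identical(sum(apCounts(dov)) + sum(dov@overflow), 3)
})
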