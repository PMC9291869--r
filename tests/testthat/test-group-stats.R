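test_that("rank-sum test matches enumeration on canonical cases", {
    # identical multisets: exchangeable, p = 1
    expect_equal(rankSumTest(c(1, 2, 3), c(1, 2, 3))$p, 1.0)
    # complete separation of 3 vs 3: U maximal, p = 2/20
    ts <- rankSumTest(c(4, 5, 6), c(1, 2, 3))
    expect_equal(ts$U, 9)
    expect_equal(ts$p, 0.1)
    expect_error(rankSumTest(numeric(0), 1:3), "non-empty")
})

test_that("the exact branch equals exhaustive enumeration for small samples", {
    set.seed(301)
    for (case in 1:60) {
        m <- sample(1:5, 1); n <- sample(1:(10 - m), 1)
        a <- runif(m); b <- runif(n)     # continuous, no ties
        expect_equal(rankSumTest(a, b)$p, oracleRankSumP(a, b),
                     tolerance = 1e-12,
                     info = sprintf("case %d (m=%d n=%d)", case, m, n))
    }
})

test_that("bonferroni scales and caps p-values", {
    expect_equal(bonferroni(0.01, 6), 0.06)
    expect_equal(bonferroni(0.5, 6), 1.0)
    expect_error(bonferroni(c(0.1, 0.2), 1), "family size")
    set.seed(2)
    p <- runif(50)
    expect_equal(bonferroni(p, 80), pmin(1, 80 * p))
})

test_that("differential expression flags degenerate and untestable designs", {
    set.seed(4)
    m <- matrix(rnorm(2 * 20), 2, 20,
                dimnames = list(c("OXTR", "OXT"), paste0("s", 1:20)))
    z <- makeZExpr(t(scale(t(m))), paste0("s", 1:20))
    # identical groups built by duplicating samples into both labels
    dup <- cbind(exprValues(z), exprValues(z))
    colnames(dup) <- paste0("s", 1:40)
    zdup <- makeZExpr(dup, paste0("s", 1:40))
    cls <- makeClassification(paste0("s", 1:40),
                              rep(c("affected", "unaffected"), each = 20))
    de <- differentialExpression(zdup, cls, c("OXTR", "OXT"))
    sub <- de[de$compartment == "subcortex", ]
    expect_equal(sub$p_raw, c(1, 1), tolerance = 1e-12)
    expect_equal(sub$n_affected + sub$n_unaffected, c(40L, 40L))
    expect_equal(sub$m_tests, c(2L, 2L))
    # cortex has no samples here: untestable, not fabricated
    expect_true(all(de$untestable[de$compartment == "cortex"]))
    expect_true(all(is.na(de$p_raw[de$compartment == "cortex"])))
})

test_that("Pearson matrices match a covariance/sd oracle and calibrate under the null", {
    set.seed(11)
    m <- matrix(rnorm(6 * 200), 6, 200,
                dimnames = list(paste0("g", 1:6), NULL))
    z <- makeZExpr(m)
    pm <- pearsonMatrix(z, colnames(z), paste0("g", 1:6))
    # entrywise oracle from first principles
    for (i in 1:6) for (j in 1:6) {
        xi <- m[i, ]; xj <- m[j, ]
        o <- sum((xi - mean(xi)) * (xj - mean(xj))) /
            sqrt(sum((xi - mean(xi))^2) * sum((xj - mean(xj))^2))
        expect_lt(abs(pm$R[i, j] - o), 1e-10)
    }
    expect_equal(diag(pm$R), rep(1, 6), ignore_attr = TRUE)

    # exact duplicate genes correlate at 1
    m2 <- rbind(a = m[1, ], b = m[1, ], c = m[2, ])
    pm2 <- pearsonMatrix(makeZExpr(m2), sprintf("s%03d", 1:200),
                         c("a", "b", "c"))
    expect_equal(pm2$R["a", "b"], 1)

    # independent genes at n = 1000: |r| below the 99.9% bound
    set.seed(12)
    big <- matrix(rnorm(6 * 1000), 6, 1000,
                  dimnames = list(paste0("g", 1:6), NULL))
    pmb <- pearsonMatrix(makeZExpr(big), sprintf("s%03d", 1:1000),
                         paste0("g", 1:6))
    expect_true(all(abs(pmb$R[lower.tri(pmb$R)]) < 0.11))

    expect_error(pearsonMatrix(z, colnames(z)[1:3], paste0("g", 1:6)),
                 "at least 4")
})

test_that("the Steiger matrix test matches its closed form", {
    set.seed(3)
    A <- cor(matrix(rnorm(600), 100, 6))
    st <- steigerMatrixTest(A, 100, A, 80)
    expect_equal(st$chi2, 0)
    expect_equal(st$p, 1)
    expect_equal(st$df, 15L)   # k = 6 -> k(k-1)/2

    # k = 2 worked example, step-by-step oracle
    R1 <- matrix(c(1, 0.5, 0.5, 1), 2)
    R2 <- diag(2)
    st2 <- steigerMatrixTest(R1, 53, R2, 53)
    oracle <- (atanh(0.5) - atanh(0))^2 / (1 / 50 + 1 / 50)
    expect_equal(st2$chi2, oracle, tolerance = 1e-12)
    expect_equal(st2$chi2, 7.5434, tolerance = 1e-4)
    expect_equal(st2$df, 1L)
    expect_equal(st2$p, pchisq(oracle, 1, lower.tail = FALSE))

    # symmetry in the two groups
    B <- cor(matrix(rnorm(500), 100, 5)); C <- cor(matrix(rnorm(500), 100, 5))
    expect_equal(steigerMatrixTest(B, 60, C, 90)$chi2,
                 steigerMatrixTest(C, 90, B, 60)$chi2)
    # doubling both n rescales chi2 by the variance-sum ratio
    s1 <- steigerMatrixTest(B, 60, C, 90)
    s2 <- steigerMatrixTest(B, 120, C, 180)
    expect_equal(s2$chi2 / s1$chi2,
                 (1 / 57 + 1 / 87) / (1 / 117 + 1 / 177))

    Rdeg <- matrix(c(1, 1, 1, 1), 2)
    expect_error(steigerMatrixTest(Rdeg, 50, R2, 50), "diverges")
})

test_that("the two-sample Fisher r-to-z contrast matches its closed form", {
    expect_equal(fisherZCompare(0.3, 40, 0.3, 250)$z, 0)
    expect_equal(fisherZCompare(0.3, 40, 0.3, 250)$p, 1)

    fz <- fisherZCompare(0.5, 103, 0.2, 103)
    oracle_z <- (atanh(0.5) - atanh(0.2)) / sqrt(1 / 100 + 1 / 100)
    expect_equal(fz$z, oracle_z, tolerance = 1e-12)
    expect_equal(fz$z, 2.4505, tolerance = 1e-4)
    expect_equal(fz$p, 0.01426, tolerance = 1e-3)

    # antisymmetry
    sw <- fisherZCompare(0.2, 103, 0.5, 103)
    expect_equal(sw$z, -fz$z)
    expect_equal(sw$p, fz$p)

    # n2 -> infinity limit: reduces to the one-sample comparison
    lim <- fisherZCompare(0.45, 50, 0.1, 1e9)
    one <- (atanh(0.45) - atanh(0.1)) / sqrt(1 / 47)
    expect_equal(lim$z, one, tolerance = 1e-6)

    expect_error(fisherZCompare(1, 50, 0.2, 50), "< 1")
    expect_error(fisherZCompare(0.5, 3, 0.2, 50), "exceed 3")
})

test_that("co-expression contrast on identical groups finds nothing", {
    set.seed(6)
    genes <- c("OXT", "OXTR", "CD38", "AVPR1A")
    m <- matrix(rnorm(4 * 30), 4, 30, dimnames = list(genes, NULL))
    m["OXTR", ] <- m["OXT", ] * 0.9 + rnorm(30, 0, 0.2)  # a real correlation
    dup <- cbind(m, m)
    colnames(dup) <- paste0("s", 1:60)
    z <- makeZExpr(dup, paste0("s", 1:60))
    cls <- makeClassification(paste0("s", 1:60),
                              rep(c("affected", "unaffected"), each = 30))
    cc <- coexpressionContrast(z, cls, genes, focusGene = "OXTR")
    expect_equal(cc@steiger$chi2, 0)
    expect_equal(cc@steiger$p, 1)
    # pairs may be retained (the correlation is real in both groups) but
    # no contrast is significant: identical r gives z = 0
    if (nrow(cc@fisher)) {
        expect_equal(cc@fisher$z_stat, rep(0, nrow(cc@fisher)))
        expect_false(any(cc@fisher$significant))
    }
})

test_that("pair retention honors the either/both filter rules", {
    set.seed(61)
    genes <- c("OXTR", "AVPR1A", "AVPR2")
    n1 <- 150; n2 <- 600
    f <- rnorm(n1)
    aff <- rbind(OXTR = f + rnorm(n1, 0, 1),
                 AVPR1A = f + rnorm(n1, 0, 1),
                 AVPR2 = rnorm(n1))
    una <- matrix(rnorm(3 * n2), 3, 3 * n2 / 3,
                  dimnames = list(genes, NULL))
    m <- cbind(aff, una)
    ids <- paste0("s", seq_len(n1 + n2))
    z <- makeZExpr(m, ids)
    cls <- makeClassification(ids, rep(c("affected", "unaffected"),
                                       c(n1, n2)))
    ccE <- coexpressionContrast(z, cls, genes, focusGene = "OXTR",
                                filterRule = "either")
    # OXTR-AVPR1A correlates only in the affected group: retained under
    # "either", dropped under "both"
    expect_true("AVPR1A" %in% ccE@fisher$gene_b)
    ccB <- coexpressionContrast(z, cls, genes, focusGene = "OXTR",
                                filterRule = "both")
    expect_false("AVPR1A" %in% ccB@fisher$gene_b)
    # empty retained set is a valid outcome
    expect_equal(nrow(ccB@fisher), 0L)
})
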