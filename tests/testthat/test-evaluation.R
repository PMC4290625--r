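test_that("AUC agrees with brute-force pair counting", {
    expect_equal(aucScore(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0)), 0.75)
    expect_equal(aucScore(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
    expect_equal(aucScore(rep(0.5, 6), c(1, 0, 1, 0, 0, 1)), 0.5)
    expect_error(aucScore(1:3, c(1, 1, 1)), "both classes")

    set.seed(101)
    for (i in 1:40) {
        n <- sample(4:50, 1)
        scores <- sample(seq(0, 1, 0.05), n, TRUE)  # coarse grid -> ties
        labels <- c(0, 1, sample(0:1, n - 2, TRUE))
        expect_equal(aucScore(scores, labels),
                     oracleAuc(scores, labels), tolerance = 1e-12)
    }
})

test_that("AUC invariances hold", {
    set.seed(111)
    scores <- runif(30)
    labels <- c(0, 1, sample(0:1, 28, TRUE))
    a <- aucScore(scores, labels)
    expect_equal(aucScore(qlogis(scores), labels), a)     # monotone map
    expect_equal(aucScore(scores^3, labels), a)
    expect_equal(a + aucScore(-scores, labels), 1)        # no ties
})

test_that("the sign test matches full outcome enumeration", {
    cmp <- signTest(rep(0.8, 26), rep(0.7, 26))
    expect_equal(cmp@pValue, 0.5^26)
    expect_equal(cmp@winsA, 26L)

    for (n in c(3, 7, 12)) {
        for (w in 0:n) {
            if (w == 0) next   # winsA = 0 has p = 1, enumeration too
            a <- c(rep(1, w), rep(0, n - w))
            p <- signTest(a, 1 - a)@pValue
            expect_equal(p, oracleSignTail(n, w), tolerance = 1e-12)
        }
    }

    # ties are dropped before the binomial
    cmp2 <- signTest(c(0.8, 0.7, 0.5), c(0.6, 0.7, 0.6))
    expect_equal(cmp2@ties, 1L)
    expect_equal(cmp2@winsA + cmp2@winsB, 2L)
    expect_error(signTest(c(0.5, 0.5), c(0.5, 0.5)), "ties")
    expect_error(signTest(1:3 / 10, 1:2 / 10), "equal length")
})

test_that("comparison tables align methods and round half-up", {
    res <- list(m1 = data.frame(allele = c("a1", "a2", "a3"),
                                auc = c(0.7765, 0.701, 0.65)),
                m2 = data.frame(allele = c("a1", "a2", "a3"),
                                auc = c(0.70, 0.72, 0.66)))
    tab <- comparisonTable(res)
    expect_equal(nrow(tab), 4L)
    expect_equal(tab$allele[4], "average")
    expect_equal(tab$m1[1], 0.777)   # 0.7765 rounds half-up
    md <- attr(tab, "markdown")
    expect_match(md, "\\*\\*0.777\\*\\*")

    single <- comparisonTable(res["m1"])
    expect_equal(ncol(single), 2L)
    expect_false(grepl("\\*\\*", attr(single, "markdown")))

    bad <- res
    bad$m2$allele <- c("a1", "a2", "zz")
    expect_error(comparisonTable(bad), "different allele sets")
})

test_that("cross-validation pools out-of-fold predictions per allele", {
    set.seed(121)
    cfg <- milConfig("fl+kp")
    ps <- c(randomPeptideSet(30, allele = "AL1"),
            randomPeptideSet(30, allele = "AL2"))
    cv1 <- crossValidate(ps, cfg, k = 3, seed = 5)
    cv2 <- crossValidate(ps, cfg, k = 3, seed = 5)
    expect_identical(cv1$auc, cv2$auc)           # deterministic rerun
    expect_setequal(cv1$allele, c("AL1", "AL2"))
    expect_equal(attr(cv1, "averageAUC"), mean(cv1$auc))
    pred <- attr(cv1, "predictions")
    expect_equal(nrow(pred), 60L)
    expect_false(anyNA(pred$y_pred))

    # an allele whose training split collapses to one class is skipped
    oneclass <- PeptideSet("BAD", randomPeptides(6, c(11, 14)),
                           ic50 = rep(10, 6))
    both <- c(ps, oneclass)
    expect_warning(cv3 <- crossValidate(both, cfg, k = 3, seed = 5),
                   "skipped")
    expect_false("BAD" %in% cv3$allele)
})

test_that("cross-validation never trains on a held-out peptide", {
    # a sentinel peptide appears once; its out-of-fold prediction must
    # come from a meta-space that excludes its own instances
    set.seed(131)
    ps <- randomPeptideSet(20, allele = "S")
    ps <- assignFolds(ps, k = 4, seed = 2)
    rec <- peptideRecords(ps)
    cfg <- milConfig("fl+kp")
    for (f in 0:1) {
        tr <- ps[rec$fold != f]
        ms <- buildMetaSpace(makeBags(tr, cfg))
        held <- makeInstances(rec$sequence[rec$fold == f][1],
                              cfg@lengths)$instance
        overlap <- held %in% unlist(bagInstances(makeBags(tr, cfg)))
        expect_true(all(held[!overlap] %in%
                        setdiff(held, metaInstances(ms))))
    }
})
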