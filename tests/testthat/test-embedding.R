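test_that("meta-space deduplicates and orders deterministically", {
    ps <- PeptideSet("X", c("AAAAAAAAACDE", "CDEAAAAAAAAA"), c(10, 20))
    bags <- makeBags(ps, milConfig("mhcmir9"))
    ms <- buildMetaSpace(bags)
    expect_false(anyDuplicated(metaInstances(ms)) > 0)
    expect_identical(metaInstances(buildMetaSpace(bags)),
                     metaInstances(ms))

    # shared instance counted once
    shared <- list(c("AAAAAAAAA", "CCCCCCCCC", "DDDDDDDDD"),
                   c("AAAAAAAAA", "EEEEEEEEE", "FFFFFFFFF", "GGGGGGGGG"))
    expect_equal(length(buildMetaSpace(shared)), 6L)

    # ordered by length then lexicographically
    mixed <- buildMetaSpace(list(c(strrep("C", 11), "BAAAAAAAA",
                                   "AAAAAAAAA", strrep("A", 11))))
    expect_identical(metaInstances(mixed),
                     c("AAAAAAAAA", "BAAAAAAAA", strrep("A", 11),
                       strrep("C", 11)))
    expect_error(buildMetaSpace(list(character(0))), "empty")
})

test_that("embedding matches the brute-force double loop", {
    set.seed(21)
    for (preset in c("fl", "fl+kp", "mhcmir9")) {
        cfg <- milConfig(preset)
        ps <- randomPeptideSet(6, c(11, 16))
        bags <- makeBags(ps, cfg)
        ms <- buildMetaSpace(bags)
        F <- embedBags(bags, ms, cfg)
        expect_equal(dim(F), c(6L, length(ms)))
        expect_true(all(F > 0 & F <= 1))
        Fo <- oracleEmbed(bagInstances(bags), metaInstances(ms),
                          cfg@scheme@kp9, cfg@scheme@kp11, cfg@matrix)
        expect_equal(unname(F), unname(Fo), tolerance = 1e-12)
    }
})

test_that("test bags never alter the meta-space and keep its width", {
    set.seed(31)
    cfg <- milConfig("fl+kp")
    train <- randomPeptideSet(8)
    test <- randomPeptideSet(5)
    bags <- makeBags(train, cfg)
    ms <- buildMetaSpace(bags)
    before <- metaInstances(ms)
    Ftest <- embedBags(makeBags(test, cfg), ms, cfg)
    expect_identical(metaInstances(ms), before)
    expect_equal(ncol(Ftest), length(before))
    expect_equal(ncol(Ftest), ncol(embedBags(bags, ms, cfg)))
})

test_that("bag order does not change the meta-space or predictions", {
    set.seed(41)
    cfg <- milConfig("fl")
    ps <- randomPeptideSet(12)
    perm <- sample(length(ps))
    ms1 <- buildMetaSpace(makeBags(ps, cfg))
    ms2 <- buildMetaSpace(makeBags(ps[perm], cfg))
    expect_identical(metaInstances(ms1), metaInstances(ms2))

    probe <- randomPeptideSet(4)
    p1 <- milPredict(milFit(ps, cfg), probe)$y_pred
    p2 <- milPredict(milFit(ps[perm], cfg), probe)$y_pred
    expect_equal(p1, p2, tolerance = 1e-8)
})

test_that("bags emptied by the filter embed as all-sentinel", {
    cfg <- milConfig("fl+fpl")
    ps <- PeptideSet("X", c(strrep("G", 12), "ILMVFWYAILMV"), c(10, 20))
    bags <- makeBags(ps, cfg)
    ms <- buildMetaSpace(bags)
    expect_message(F <- embedBags(bags, ms, cfg), "all-sentinel")
    expect_true(all(F[1, ] == cfg@sentinel))

    strict <- milConfig("fl+fpl", emptyBagPolicy = "error")
    expect_error(embedBags(makeBags(ps, strict), ms, strict),
                 "no instances")
})
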