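test_that("instance enumeration follows the sliding-window bound", {
    p15 <- paste(rep(AA20[1:15], 1), collapse = "")
    inst <- makeInstances(p15, c(9, 11))
    expect_equal(sum(inst$length == 9), 7L)    # 15 - 8
    expect_equal(sum(inst$length == 11), 5L)   # 15 - 10
    expect_equal(inst$instance[1], substr(p15, 1, 9))
    # lengths ordered 9 before 11, offsets increasing within a length
    expect_true(!is.unsorted(inst$length))
    expect_true(all(tapply(inst$offset, inst$length,
                           function(o) !is.unsorted(o))))

    nine <- makeInstances(strrep("A", 9), c(9, 11))
    expect_equal(nrow(nine), 1L)
    expect_equal(nine$instance, strrep("A", 9))
    expect_error(makeInstances(strrep("A", 8), c(9, 11)), "too short")

    # conservation property for random lengths
    for (L in sample(11:20, 4)) {
        n <- nrow(makeInstances(strrep("G", L), c(9, 11)))
        expect_equal(n, (L - 8) + (L - 10))
    }
})

test_that("first-position limitation checks the core P1 residue", {
    inst <- makeInstances(strrep("G", 11), c(9, 11))
    expect_equal(nrow(firstPositionFilter(inst)), 0L)

    keep9 <- data.frame(instance = "LAAAAAAAA", offset = 1L, length = 9L)
    expect_equal(nrow(firstPositionFilter(keep9)), 1L)

    # 11-long instances are judged at position 2 (the embedded core's P1)
    both <- data.frame(instance = c("ALAAAAAAAAA", "AAAAAAAAALA"),
                       offset = c(1L, 1L), length = c(11L, 11L))
    kept <- firstPositionFilter(both)
    expect_equal(kept$instance, "ALAAAAAAAAA")
})

test_that("core key positions induce the printed 11-mer sets", {
    expect_identical(coreTo11Positions(c(1, 4, 6, 7, 9)),
                     c(1L, 2L, 5L, 7L, 8L, 10L, 11L))
    expect_identical(coreTo11Positions(c(1, 2, 4, 6, 7, 9)),
                     c(1L, 2L, 3L, 5L, 7L, 8L, 10L, 11L))
    expect_identical(coreTo11Positions(integer(0)), c(1L, 11L))
    expect_error(coreTo11Positions(10), "1..9")

    kp <- keyPositionScheme("kp")
    expect_identical(kp@kp9, c(1L, 4L, 6L, 7L, 9L))
    expect_identical(kp@kp11, c(1L, 2L, 5L, 7L, 8L, 10L, 11L))
    kp2 <- keyPositionScheme("kp+2")
    expect_identical(kp2@kp9, c(1L, 2L, 4L, 6L, 7L, 9L))
    expect_identical(kp2@kp11, c(1L, 2L, 3L, 5L, 7L, 8L, 10L, 11L))
    custom <- keyPositionScheme(kp9 = c(2, 3, 5, 8))
    expect_identical(custom@kp11, coreTo11Positions(c(2, 3, 5, 8)))
})

test_that("raw scores and distances follow the sign-scaling rule", {
    cfg <- milConfig("fl+kp")
    a9 <- strrep("A", 9)
    expect_equal(rawScore(a9, a9, cfg), 20)          # 5 positions x 4
    expect_equal(instanceDistance(a9, a9, cfg), 0.05)

    all9 <- milConfig("fl")
    expect_equal(rawScore(strrep("W", 9), strrep("P", 9), all9), -36)
    expect_equal(instanceDistance(strrep("W", 9), strrep("P", 9), all9), 1)

    expect_identical(rawScore(a9, strrep("A", 11), cfg), Inf)
    expect_equal(instanceDistance(a9, strrep("A", 11), cfg), 1)
    expect_error(rawScore("AAAAAAAAJ", a9, cfg), "alphabet")
})

test_that("distance is symmetric, in (0,1], and matches the scalar oracle", {
    set.seed(11)
    for (preset in c("fl", "fl+kp", "fl+kp+3")) {
        cfg <- milConfig(preset)
        for (i in 1:25) {
            n <- sample(c(9, 11), 1)
            x <- paste(sample(AA20, n, TRUE), collapse = "")
            y <- paste(sample(AA20, n, TRUE), collapse = "")
            d1 <- instanceDistance(x, y, cfg)
            expect_identical(d1, instanceDistance(y, x, cfg))
            expect_gt(d1, 0); expect_lte(d1, 1)
            expect_equal(d1, oracleDis(x, y, cfg@scheme@kp9,
                                       cfg@scheme@kp11, cfg@matrix))
            if (rawScore(x, y, cfg) <= 0) expect_identical(d1, 1)
        }
    }
})

test_that("the bag feature is the minimum over same-length instances", {
    cfg <- milConfig("fl")
    set.seed(5)
    bag <- c(replicate(4, paste(sample(AA20, 9, TRUE), collapse = "")),
             replicate(3, paste(sample(AA20, 11, TRUE), collapse = "")))
    xk <- bag[1]
    f <- bagFeature(xk, bag, cfg)
    same <- bag[nchar(bag) == 9]
    expect_true(all(f <= vapply(same, instanceDistance, numeric(1),
                                x = xk, config = cfg)))
    expect_lte(f, instanceDistance(xk, xk, cfg))  # min includes self

    # no same-length instance -> sentinel
    expect_identical(bagFeature(strrep("A", 9), bag[5:7], cfg), 1)
    expect_identical(bagFeature(xk, bag[2], cfg),
                     instanceDistance(xk, bag[2], cfg))
    expect_error(bagFeature(xk, character(0), cfg), "empty")
})

test_that("bags preserve instance counts and apply the filter", {
    ps <- PeptideSet("X", c("ILMVFWYAILMV", strrep("G", 12)),
                     c(100, 2000))
    bags <- makeBags(ps, milConfig("fl"))
    expect_equal(bagSizes(bags), c(4L + 2L, 4L + 2L))
    expect_equal(bagTargets(bags), transformAffinity(c(100, 2000)))

    fpl <- makeBags(ps, milConfig("fl+fpl"))
    expect_equal(bagSizes(fpl)[2], 0L)   # all-glycine peptide is emptied
    expect_gt(bagSizes(fpl)[1], 0L)
})
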