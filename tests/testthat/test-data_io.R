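test_that("peptide tables round-trip and invalid rows are handled", {
    tab <- tempfile(fileext = ".tsv")
    writeLines(c("allele\tsequence\tic50",
                 "HLA-X\tALMNPQRSTVWGYKL\t12.5",
                 "HLA-X\tGYKLMNPQRSTVALM\t3500",
                 "HLA-Y\tSVLLVVALFAVFLGS\t748.1"), tab)
    ps <- readPeptideTable(tab)
    expect_s4_class(ps, "PeptideSet")
    expect_equal(length(ps), 3L)
    expect_equal(peptides(ps)[3], "SVLLVVALFAVFLGS")
    expect_equal(ic50(ps), c(12.5, 3500, 748.1))

    # comma dialect is auto-detected
    tab2 <- tempfile(fileext = ".csv")
    writeLines(c("allele,sequence,ic50,fold", "HLA-X,ALMNPQRSTVW,50,0"),
               tab2)
    ps2 <- readPeptideTable(tab2)
    expect_equal(folds(ps2), 0L)

    # non-positive affinity names the row
    writeLines(c("allele\tsequence\tic50", "HLA-X\tALMNPQRSTVW\t0"), tab)
    expect_error(readPeptideTable(tab), "row")

    # J is not in the 24-letter BLOSUM62 alphabet -> row rejected
    writeLines(c("allele\tsequence\tic50",
                 "HLA-X\tALMNPQRSTVW\t50",
                 "HLA-X\tAJMNPQRSTVW\t60"), tab)
    expect_warning(ps3 <- readPeptideTable(tab), "rejected")
    expect_equal(length(ps3), 1L)
    expect_equal(attr(peptideRecords(ps3), "rejected")$row, 2L)

    writeLines(c("allele\tsequence", "HLA-X\tALMNPQRSTVW"), tab)
    expect_error(readPeptideTable(tab), "missing column")
})

test_that("the packaged BLOSUM62 agrees with an independent reference", {
    b62 <- blosum62()
    expect_equal(b62["A", "A"], 4L, ignore_attr = TRUE)
    expect_equal(b62["W", "P"], -4L, ignore_attr = TRUE)
    expect_true(isSymmetric(unname(b62)))
    expect_false("J" %in% matrixAlphabet(b62))

    data(BLOSUM62, package = "Biostrings", envir = environment())
    ref <- BLOSUM62[matrixAlphabet(b62), matrixAlphabet(b62)]
    expect_true(all(b62 == ref))
})

test_that("malformed matrix files are refused", {
    f <- tempfile()
    writeLines(c("   A  R", "A  4 -1", "R -2  5"), f)   # asymmetric
    expect_error(readSubstitutionMatrix(f), "symmetric")
    writeLines(c("   A  R", "A  4 -1", "R -1"), f)      # ragged
    expect_error(readSubstitutionMatrix(f), "ragged")
    writeLines(c("   A  R", "A  4 -1", "R -1  x"), f)   # non-integer
    expect_error(readSubstitutionMatrix(f), "non-integer")
})

test_that("affinity transform matches its closed form and inverts", {
    expect_identical(transformAffinity(50000), 0)
    expect_identical(transformAffinity(1), 1)
    expect_equal(transformAffinity(1000), 1 - log(1000) / log(50000),
                 tolerance = 1e-15)
    expect_equal(inverseTransform(0.5), sqrt(50000), tolerance = 1e-12)
    expect_identical(inverseTransform(0), 50000)
    expect_identical(inverseTransform(1), 1)

    # clamping outside the calibrated range
    expect_identical(transformAffinity(0.5), 1)
    expect_identical(transformAffinity(1e6), 0)
    expect_error(transformAffinity(-1), "positive")
    expect_error(inverseTransform(1.2), "0, 1")

    # monotone decreasing on the interior
    v <- sort(exp(runif(50, log(1), log(50000))))
    expect_true(all(diff(transformAffinity(v)) <= 0))
})

test_that("binder labelling is strict at the threshold", {
    expect_identical(binderLabel(c(999.9, 1000, 748.1)), c(1L, 0L, 1L))
    expect_identical(binderLabel(500, threshold = 500), 0L)
    expect_error(binderLabel(0), "positive")
})

test_that("fold assignment is stratified, balanced and deterministic", {
    set.seed(42)
    ps <- randomPeptideSet(40)
    f1 <- assignFolds(ps, k = 5, seed = 7)
    f2 <- assignFolds(ps, k = 5, seed = 7)
    expect_identical(folds(f1), folds(f2))
    expect_false(identical(folds(f1), folds(assignFolds(ps, 5, 8))))

    # sizes differ by at most one within each binder stratum
    rec <- peptideRecords(f1)
    for (l in unique(binderLabels(f1))) {
        tabs <- table(rec$fold[binderLabels(f1) == l])
        expect_lte(max(tabs) - min(tabs), 1L)
    }

    ten <- randomPeptideSet(10)
    expect_true(all(table(folds(assignFolds(ten, 5, 1))) == 2L))
    expect_error(assignFolds(randomPeptideSet(3), k = 5), "fewer than")

    # the caller's RNG stream is untouched
    set.seed(1); before <- runif(1)
    set.seed(1); invisible(assignFolds(ps, 5, 3)); after <- runif(1)
    expect_identical(before, after)
})
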