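# Independent brute-force oracles and small fixture builders.  The
# oracles re-derive every quantity from first principles (scalar loops,
# pair counting, outcome enumeration) and share no code path with the
# package implementation they check.

AA20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M",
          "F","P","S","T","W","Y","V")

randomPeptides <- function(n, lenRange = c(9, 20)) {
    vapply(seq_len(n), function(i) {
        L <- sample(seq(lenRange[1], lenRange[2]), 1)
        paste(sample(AA20, L, replace = TRUE), collapse = "")
    }, character(1))
}

randomPeptideSet <- function(n, lenRange = c(11, 18), allele = "TEST") {
    PeptideSet(allele, randomPeptides(n, lenRange),
               ic50 = exp(runif(n, log(1), log(50000))))
}

# scalar sign-scaled key-position distance, written independently:
# explicit character loop over the scheme's positions
oracleDis <- function(x, y, kp9, kp11, mat, sentinel = 1) {
    if (nchar(x) != nchar(y)) return(sentinel)
    pos <- if (nchar(x) == 9) kp9 else kp11
    d <- 0
    for (p in pos)
        d <- d + mat[substr(x, p, p), substr(y, p, p)]
    if (d > 0) 1 / d else 1
}

# brute-force bag embedding: double loop over (meta-space x bag
# instances), min over same-length instances only, sentinel otherwise
oracleEmbed <- function(bagList, msInstances, kp9, kp11, mat,
                        sentinel = 1) {
    t(vapply(bagList, function(bag) {
        vapply(msInstances, function(xk) {
            same <- bag[nchar(bag) == nchar(xk)]
            if (!length(same)) return(sentinel)
            best <- Inf
            for (b in same)
                best <- min(best, oracleDis(xk, b, kp9, kp11, mat,
                                            sentinel))
            best
        }, numeric(1), USE.NAMES = FALSE)
    }, numeric(length(msInstances))))
}

# brute-force AUC by counting concordant / tied binder-nonbinder pairs
oracleAuc <- function(scores, labels) {
    pos <- scores[labels == 1]
    neg <- scores[labels == 0]
    tot <- 0
    for (p in pos)
        for (q in neg)
            tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
}

# exact sign-test tail by enumerating all 2^n win/loss outcomes
oracleSignTail <- function(n, wins) {
    hits <- 0
    for (code in 0:(2^n - 1)) {
        w <- sum(bitwAnd(code, 2^(0:(n - 1))) > 0)
        if (w >= wins) hits <- hits + 1
    }
    hits / 2^n
}

# enumerate the instances of one peptide the slow way
oracleInstances <- function(seq, lengths) {
    out <- character(0)
    for (n in sort(lengths)) {
        L <- nchar(seq)
        if (L < n) next
        for (s in 1:(L - n + 1))
            out <- c(out, substr(seq, s, s + n - 1))
    }
    out
}
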