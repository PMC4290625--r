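#' @include AllClasses.R peptides.R
NULL

#' Configuration of the synthetic peptide generator
#'
#' Describes a motif-planted binding model on random peptides.  Each
#' peptide is drawn uniformly over the 20 standard residues with a length
#' uniform in \code{lengthRange}.  Its latent binding strength is the
#' best 9-mer window under a per-position residue weight table (the
#' planted binding-core motif), plus a contribution from the two residues
#' flanking that best window (the peptide flanking region), plus Gaussian
#' noise and an offset, clipped into [0, 1]:
#' \deqn{y = clip(baseline + max_w mean_{p in motif} W[res_w(p), p]
#'       + flankWeight * mean(F[flanks]) + N(0, noiseSd))}
#' IC50 is then 50000^(1 - y), so binders (IC50 < 1000 nM) are peptides
#' with y above about 0.362.
#'
#' Default weight tables are drawn once from the config seed: at each
#' motif position 4 favourable residues score +1 and 4 unfavourable score
#' -1 (0 otherwise), and similarly 5/5 for the flank table.  With the
#' default settings roughly 40\% of peptides are binders.
#'
#' @param nPeptides number of peptides.
#' @param lengthRange integer range of peptide lengths (default 11..20;
#'   the minimum must be >= 11 when \code{flankWeight > 0}, otherwise no
#'   flanks exist).
#' @param motifPositions core positions carrying the motif (default the
#'   canonical anchors 1, 4, 6, 7, 9).
#' @param motifWeights 20 x 9 residue-by-position weight matrix
#'   (rownames = residues); \code{NULL} draws the default table from the
#'   seed.
#' @param flankWeights length-20 named residue weight vector for the
#'   flanking residues; \code{NULL} draws the default from the seed.
#' @param motifScale scalar multiplier applied to the motif weight table
#'   (sets the relative strength of core versus flank signal).
#' @param flankWeight scalar multiplier of the flank contribution
#'   (0 = core-only signal).
#' @param noiseSd standard deviation of the additive Gaussian noise.
#' @param baseline offset added to the latent score; the default -0.04
#'   centres the default weight tables on a binder fraction near 40/60.
#' @param allele allele identifier stamped on the records.
#' @param seed integer seed; identical configs give identical datasets.
#' @return A list of class \code{"syntheticConfig"}.
#' @export
syntheticConfig <- function(nPeptides = 500L, lengthRange = c(11L, 20L),
                            motifPositions = c(1L, 4L, 6L, 7L, 9L),
                            motifWeights = NULL, flankWeights = NULL,
                            motifScale = 1, flankWeight = 0,
                            noiseSd = 0.05, baseline = -0.04,
                            allele = "SYNTH", seed = 1L) {
    lengthRange <- as.integer(lengthRange)
    if (length(lengthRange) != 2L || lengthRange[1L] > lengthRange[2L])
        stop("lengthRange must be c(min, max)")
    if (lengthRange[1L] < 9L)
        stop("peptides must be at least 9 residues long")
    if (flankWeight > 0 && lengthRange[1L] < 11L)
        stop("lengthRange minimum must be >= 11 when flankWeight > 0 (no flanks exist)")
    motifPositions <- sort(as.integer(motifPositions))
    if (any(motifPositions < 1L | motifPositions > 9L))
        stop("motifPositions must be a subset of 1..9")
    if (!is.null(motifWeights) &&
        (!is.matrix(motifWeights) || ncol(motifWeights) != 9L ||
         !all(.AA_STANDARD %in% rownames(motifWeights))))
        stop("motifWeights must be a residue x 9 matrix over the 20 standard residues")
    structure(list(nPeptides = as.integer(nPeptides),
                   lengthRange = lengthRange,
                   motifPositions = motifPositions,
                   motifWeights = motifWeights,
                   flankWeights = flankWeights,
                   motifScale = motifScale,
                   flankWeight = flankWeight, noiseSd = noiseSd,
                   baseline = baseline, allele = allele,
                   seed = as.integer(seed)),
              class = "syntheticConfig")
}

# default +1/-1/0 weight tables, drawn from the current RNG stream
.defaultMotifWeights <- function() {
    W <- matrix(0, 20L, 9L, dimnames = list(.AA_STANDARD, NULL))
    for (p in 1:9) {
        pick <- sample(20L, 8L)
        W[pick[1:4], p] <- 1
        W[pick[5:8], p] <- -1
    }
    W
}

.defaultFlankWeights <- function() {
    f <- stats::setNames(numeric(20L), .AA_STANDARD)
    pick <- sample(20L, 10L)
    f[pick[1:5]] <- 1
    f[pick[6:10]] <- -1
    f
}

# fixed core-motif table for the ablation suite: each anchor position
# favours two distinct high self-score residues (so planted identity is
# visible to a substitution-matrix distance) and penalises two others
.anchoredMotifWeights <- function() {
    W <- matrix(0, 20L, 9L, dimnames = list(.AA_STANDARD, NULL))
    fav <- list("1" = c("W", "F"), "4" = c("C", "Y"), "6" = c("H", "W"),
                "7" = c("P", "F"), "9" = c("Y", "C"))
    unf <- list("1" = c("A", "S"), "4" = c("T", "V"), "6" = c("I", "L"),
                "7" = c("G", "E"), "9" = c("K", "R"))
    for (p in names(fav)) W[fav[[p]], as.integer(p)] <- 1.6
    for (p in names(unf)) W[unf[[p]], as.integer(p)] <- -0.8
    W
}

# flank table with the favourable residues on high self-score letters
# (W, C, H, P, Y), so that planted flank identity is visible to a
# substitution-matrix distance; used by the ablation suite
.anchoredFlankWeights <- function() {
    f <- stats::setNames(numeric(20L), .AA_STANDARD)
    f[c("W", "C", "H", "P", "Y")] <- 1
    f[c("A", "S", "T", "V", "I")] <- -1
    f
}

#' Generate a motif-planted synthetic peptide dataset
#'
#' Draws random peptides and assigns affinities under the latent binding
#' model of \code{\link{syntheticConfig}}.  The generated IC50 values lie
#' in [1, 50000] nM, so \code{\link{transformAffinity}} recovers the
#' latent (clipped) score exactly.
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @return A \linkS4class{PeptideSet}; the config is kept in attribute
#'   \code{"config"}.
#' @examples
#' ps <- syntheticDataset(syntheticConfig(nPeptides = 50, seed = 3))
#' mean(binderLabels(ps))
#' @export
syntheticDataset <- function(config) {
    stopifnot(inherits(config, "syntheticConfig"))
    .withSeed(config$seed, {
        W <- config$motifWeights
        if (is.null(W)) W <- .defaultMotifWeights()
        W <- W * config$motifScale
        Fw <- config$flankWeights
        if (is.null(Fw)) Fw <- .defaultFlankWeights()
        n <- config$nPeptides
        lenSeq <- seq(config$lengthRange[1L], config$lengthRange[2L])
        lens <- if (length(lenSeq) == 1L) rep(lenSeq, n) else
            sample(lenSeq, n, replace = TRUE)
        seqs <- character(n)
        y <- numeric(n)
        mp <- config$motifPositions
        for (i in seq_len(n)) {
            res <- sample(.AA_STANDARD, lens[i], replace = TRUE)
            seqs[i] <- paste(res, collapse = "")
            starts <- seq_len(lens[i] - 8L)
            codes <- match(res, rownames(W))
            # each window scores its core motif plus its own flanking
            # residues; the peptide binds through its best total window
            win <- vapply(starts, function(s) {
                core <- mean(W[cbind(codes[s + mp - 1L], mp)])
                flanks <- c(if (s > 1L) res[s - 1L],
                            if (s + 9L <= lens[i]) res[s + 9L])
                fl <- if (length(flanks)) mean(Fw[flanks]) else 0
                core + config$flankWeight * fl
            }, numeric(1L))
            y[i] <- config$baseline + max(win) +
                stats::rnorm(1L, 0, config$noiseSd)
        }
        y <- pmin(1, pmax(0, y))
        ps <- PeptideSet(config$allele, seqs, ic50 = 50000^(1 - y))
        attr(ps@records, "config") <- config
        attr(ps@records, "latent") <- y
        ps
    })
}

#' Fixture bundle for method-ablation experiments
#'
#' Three datasets, each split train 400 / test 100: (A) core-only signal
#' at the canonical anchor positions 1, 4, 6, 7, 9 (no flank term);
#' (B) core plus flank signal, where the residues adjacent to the best
#' core contribute; (C) pure noise, with zero weight tables and a
#' baseline chosen so both binder classes occur.  Dataset A separates
#' key-position schemes, dataset B separates flexible-length from
#' 9-mer-only bags, and dataset C checks null behaviour.
#'
#' The suite uses peptide lengths 11-14: short peptides keep the number
#' of candidate cores per bag small, so the planted signal stays tied to
#' window alignment (position identity) rather than to overall residue
#' composition, which any position subset could recover.
#'
#' @param seed integer seed.
#' @return List of three elements \code{A}, \code{B}, \code{C}, each a
#'   list with \code{train} and \code{test} \linkS4class{PeptideSet}s.
#' @export
ablationSuite <- function(seed = 1L) {
    seed <- as.integer(seed)
    mk <- function(cfg) {
        ps <- syntheticDataset(cfg)
        list(train = ps[seq_len(400L)], test = ps[401:500])
    }
    zeroW <- matrix(0, 20L, 9L, dimnames = list(.AA_STANDARD, NULL))
    list(A = mk(syntheticConfig(nPeptides = 500L, lengthRange = c(11L, 14L),
                                motifWeights = .anchoredMotifWeights(),
                                flankWeight = 0, noiseSd = 0.08,
                                baseline = 0.08, allele = "SYNTH-A",
                                seed = seed)),
         B = mk(syntheticConfig(nPeptides = 500L, lengthRange = c(11L, 14L),
                                motifScale = 0.25,
                                flankWeights = .anchoredFlankWeights(),
                                flankWeight = 1.0, noiseSd = 0.05,
                                baseline = -0.4, allele = "SYNTH-B",
                                seed = seed + 1L)),
         C = mk(syntheticConfig(nPeptides = 500L, lengthRange = c(11L, 14L),
                                motifWeights = zeroW,
                                flankWeights = stats::setNames(
                                    numeric(20L), .AA_STANDARD),
                                flankWeight = 0, noiseSd = 0.15,
                                baseline = 0.35, allele = "SYNTH-C",
                                seed = seed + 2L)))
}
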