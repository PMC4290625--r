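#' @include AllClasses.R bags.R
NULL

#' Build the meta-space from training bags
#'
#' The meta-space is the deduplicated union of all instance strings across
#' the training bags, ordered deterministically (instance length
#' ascending, then lexicographic in the C locale).  It defines the
#' feature space: every bag is embedded as its vector of minimum
#' distances to each meta-space instance.  Build it from training bags
#' only; test bags are embedded against it unchanged.
#'
#' @param bags an \linkS4class{InstanceBags} (or a list of character
#'   vectors of instances).
#' @return A \linkS4class{MetaSpace}.
#' @export
buildMetaSpace <- function(bags) {
    inst <- if (is(bags, "InstanceBags")) bags@instances else bags
    all <- unique(unlist(inst, use.names = FALSE))
    if (is.null(all) || !length(all))
        stop("cannot build a meta-space from empty bags")
    len <- nchar(all)
    o <- order(len, all, method = "radix")
    new("MetaSpace", instances = all[o], lengths = len[o])
}

#' @describeIn buildMetaSpace number of meta-space instances.
#' @param x a \code{MetaSpace}.
#' @export
setMethod("length", "MetaSpace", function(x) length(x@instances))

#' Meta-space instance strings
#'
#' @param x a \linkS4class{MetaSpace}.
#' @return Character vector in feature order.
#' @export
metaInstances <- function(x) {
    stopifnot(is(x, "MetaSpace"))
    x@instances
}

setMethod("show", "MetaSpace", function(object) {
    tab <- table(object@lengths)
    cat(sprintf("MetaSpace with %d unique instances (%s)\n",
                length(object@instances),
                paste(sprintf("%s of length %s", tab, names(tab)),
                      collapse = ", ")))
})

# integer position-encoding of equal-length instance strings against an
# alphabet; rows = instances, cols = positions
.encodeInstances <- function(strs, len, alphabet) {
    codes <- match(unlist(strsplit(strs, ""), use.names = FALSE), alphabet)
    if (anyNA(codes))
        stop("residue outside the matrix alphabet")
    matrix(codes, nrow = length(strs), ncol = len, byrow = TRUE)
}

# raw key-position score matrix between two sets of equal-length
# instances: S[i, j] = sum over scheme positions of mat[q_i(t), r_j(t)].
# Vectorized as a sum of outer submatrix lookups, one per position.
.rawScoreBlock <- function(qEnc, rEnc, positions, mat) {
    S <- matrix(0, nrow(qEnc), nrow(rEnc))
    for (t in positions)
        S <- S + mat[qEnc[, t], rEnc[, t], drop = FALSE]
    S
}

# sign-scaled distance matrix in (0, 1]
.distanceBlock <- function(qEnc, rEnc, positions, mat) {
    S <- .rawScoreBlock(qEnc, rEnc, positions, mat)
    D <- 1 / S
    D[S <= 0] <- 1
    D
}

#' Embed bags into the meta-space
#'
#' Maps each bag to its feature vector: the k-th feature is the minimum
#' sign-scaled key-position distance between meta-space instance k and
#' the bag's instances of the same length (see \code{\link{bagFeature}}).
#' Meta-space coordinates with no same-length instance in the bag take
#' the cross-length sentinel.  A bag emptied by the first-position filter
#' is embedded as an all-sentinel vector (or raises an error, per
#' \code{config@emptyBagPolicy}); the meta-space is never modified.
#'
#' @param bags an \linkS4class{InstanceBags}.
#' @param metaspace the training \linkS4class{MetaSpace}.
#' @param config a \linkS4class{MilConfig}.
#' @return Numeric matrix, one row per bag, one column per meta-space
#'   instance, values in (0, 1].
#' @export
embedBags <- function(bags, metaspace, config) {
    stopifnot(is(bags, "InstanceBags"), is(metaspace, "MetaSpace"),
              is(config, "MilConfig"))
    nB <- length(bags@instances)
    nF <- length(metaspace@instances)
    empty <- which(lengths(bags@instances) == 0L)
    if (length(empty)) {
        if (config@emptyBagPolicy == "error")
            stop("bag(s) with no instances after filtering: ",
                 paste(empty, collapse = ", "))
        message(sprintf(
            "%d bag(s) left empty by the instance filter; embedded as all-sentinel",
            length(empty)))
    }
    F <- matrix(config@sentinel, nB, nF)
    alpha <- matrixAlphabet(config@matrix)
    for (len in unique(metaspace@lengths)) {
        msIdx <- which(metaspace@lengths == len)
        pos <- .schemePositions(config@scheme, len)
        # pool the distinct bag instances of this length across all bags
        perBag <- lapply(bags@instances, function(v) v[nchar(v) == len])
        pool <- unique(unlist(perBag, use.names = FALSE))
        if (is.null(pool) || !length(pool)) next
        qEnc <- .encodeInstances(metaspace@instances[msIdx], len, alpha)
        rEnc <- .encodeInstances(pool, len, alpha)
        D <- .distanceBlock(qEnc, rEnc, pos, config@matrix)
        for (b in seq_len(nB)) {
            ids <- match(perBag[[b]], pool)
            if (!length(ids)) next
            v <- D[, ids[1L]]
            for (j in ids[-1L]) v <- pmin(v, D[, j])
            F[b, msIdx] <- v
        }
    }
    F
}

#' Embed one bag of instances
#'
#' Convenience scalar form of \code{\link{embedBags}} for a single
#' instance vector.
#'
#' @param instances character vector of instances (one bag).
#' @param metaspace the training \linkS4class{MetaSpace}.
#' @param config a \linkS4class{MilConfig}.
#' @return Numeric feature vector of length \code{length(metaspace)}.
#' @export
embedBag <- function(instances, metaspace, config) {
    ps <- PeptideSet("·", strrep("A", 11L), 1000)  # placeholder peptide
    bags <- new("InstanceBags", instances = list(as.character(instances)),
                offsets = list(seq_along(instances)),
                targets = 0.5, peptides = ps)
    drop(embedBags(bags, metaspace, config))
}
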