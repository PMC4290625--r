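#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a PeptideSet
#'
#' @param allele allele identifier(s), recycled to the number of peptides.
#' @param sequence peptide sequences in one-letter amino-acid code.
#' @param ic50 measured binding affinities in nM (positive).
#' @param fold optional 0-based integer fold indices.
#' @return A \linkS4class{PeptideSet}.
#' @examples
#' PeptideSet("HLA-DRB1_0101", c("ALMNPQRSTVW", "GYKLMNPQRST"), c(12, 3500))
#' @export
PeptideSet <- function(allele, sequence, ic50, fold = NA_integer_) {
    df <- data.frame(allele = as.character(allele),
                     sequence = toupper(as.character(sequence)),
                     ic50 = as.numeric(ic50),
                     fold = as.integer(fold),
                     stringsAsFactors = FALSE)
    new("PeptideSet", records = df)
}

#' @rdname accessors
#' @export
setMethod("alleles", "PeptideSet", function(x, ...) x@records$allele)

#' @rdname accessors
#' @export
setMethod("peptides", "PeptideSet", function(x, ...) x@records$sequence)

#' @rdname accessors
#' @export
setMethod("ic50", "PeptideSet", function(x, ...) x@records$ic50)

#' @rdname accessors
#' @export
setMethod("folds", "PeptideSet", function(x, ...) x@records$fold)

#' @rdname accessors
#' @param threshold binder threshold in nM; IC50 strictly below it is a
#'   binder.
#' @export
setMethod("binderLabels", "PeptideSet", function(x, threshold = 1000, ...)
    binderLabel(x@records$ic50, threshold))

#' @describeIn PeptideSet number of peptide records.
#' @param x a \code{PeptideSet}.
#' @export
setMethod("length", "PeptideSet", function(x) nrow(x@records))

#' @describeIn PeptideSet subset records.
#' @param i index vector.
#' @param j,drop ignored.
#' @param ... ignored.
#' @export
setMethod("[", "PeptideSet", function(x, i, j, ..., drop = FALSE) {
    df <- x@records[i, , drop = FALSE]
    rownames(df) <- NULL
    new("PeptideSet", records = df)
})

#' @describeIn PeptideSet concatenate peptide sets.
#' @export
setMethod("c", "PeptideSet", function(x, ...) {
    sets <- list(x, ...)
    df <- do.call(rbind, lapply(sets, peptideRecords))
    rownames(df) <- NULL
    new("PeptideSet", records = df)
})

#' Records of a PeptideSet as a data.frame
#'
#' @param x a \linkS4class{PeptideSet}.
#' @return data.frame with columns allele, sequence, ic50, fold.
#' @export
peptideRecords <- function(x) {
    stopifnot(is(x, "PeptideSet"))
    x@records
}

setMethod("show", "PeptideSet", function(object) {
    df <- object@records
    cat(sprintf("PeptideSet with %d peptides, %d allele(s)\n",
                nrow(df), length(unique(df$allele))))
    if (nrow(df)) {
        cat(sprintf("  lengths %d..%d, IC50 %.4g..%.4g nM, %d binders (<1000 nM)\n",
                    min(nchar(df$sequence)), max(nchar(df$sequence)),
                    min(df$ic50), max(df$ic50), sum(df$ic50 < 1000)))
        if (any(!is.na(df$fold)))
            cat(sprintf("  folds: %s\n",
                        paste(sort(unique(df$fold[!is.na(df$fold)])),
                              collapse = " ")))
    }
})

#' Read a peptide binding-affinity table
#'
#' Reads a tab- or comma-delimited table with a header row and columns
#' \code{allele}, \code{sequence}, \code{ic50} and optionally \code{fold}.
#' Rows whose sequence contains a residue absent from the substitution
#' matrix alphabet are dropped with a per-row warning; a non-positive IC50
#' is an error naming the row.
#'
#' @param path path to the table.
#' @param matrix substitution matrix defining the accepted residue
#'   alphabet (default \code{\link{blosum62}()}).
#' @param sep field separator; \code{NULL} (default) auto-detects tab
#'   versus comma from the header line.
#' @return A \linkS4class{PeptideSet}.  Rejected rows (if any) are
#'   reported in attribute \code{"rejected"} of the returned object's
#'   records.
#' @export
readPeptideTable <- function(path, matrix = blosum62(), sep = NULL) {
    if (!file.exists(path))
        stop("peptide table not found: ", path)
    if (is.null(sep)) {
        header <- readLines(path, n = 1L)
        sep <- if (grepl("\t", header)) "\t" else ","
    }
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, quote = "\"",
                            comment.char = "")
    need <- c("allele", "sequence", "ic50")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("peptide table is missing column(s): ",
             paste(miss, collapse = ", "))
    if (!"fold" %in% names(df)) df$fold <- NA_integer_
    df <- df[, c("allele", "sequence", "ic50", "fold")]
    df$sequence <- toupper(trimws(df$sequence))
    df$ic50 <- as.numeric(df$ic50)
    bad <- which(!is.finite(df$ic50) | df$ic50 <= 0)
    if (length(bad))
        stop(sprintf("non-positive or missing ic50 in row(s): %s",
                     paste(bad, collapse = ", ")))
    alpha <- matrixAlphabet(matrix)
    chars <- strsplit(df$sequence, "")
    ok <- vapply(chars, function(ch) all(ch %in% alpha), logical(1L))
    rejected <- NULL
    if (any(!ok)) {
        rejected <- data.frame(row = which(!ok),
                               sequence = df$sequence[!ok],
                               stringsAsFactors = FALSE)
        for (r in seq_len(nrow(rejected)))
            warning(sprintf(
                "row %d rejected: sequence '%s' contains residue(s) outside the matrix alphabet",
                rejected$row[r], rejected$sequence[r]), call. = FALSE)
        df <- df[ok, , drop = FALSE]
        rownames(df) <- NULL
    }
    ps <- new("PeptideSet", records = df)
    if (!is.null(rejected)) attr(ps@records, "rejected") <- rejected
    ps
}

#' Write a peptide table
#'
#' Writes the standard tab-delimited peptide table (columns allele,
#' sequence, ic50 and, when present, fold).
#'
#' @param x a \linkS4class{PeptideSet}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePeptideTable <- function(x, path) {
    df <- peptideRecords(x)
    if (all(is.na(df$fold))) df$fold <- NULL
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Affinity transform between IC50 and the regression target
#'
#' The regression target is \code{y = 1 - log(ic50) / log(50000)}, clamped
#' into [0, 1] (the log base cancels in the ratio).  IC50 = 50000 nM maps
#' to 0, IC50 = 1 nM maps to 1; affinities outside [1, 50000] nM are
#' clamped.  \code{inverseTransform} maps a target back to the nM scale,
#' \code{ic50 = 50000^(1 - y)}.
#'
#' @param ic50 binding affinities in nM (positive).
#' @return \code{transformAffinity}: transformed targets in [0, 1].
#' @examples
#' transformAffinity(c(1, 1000, 50000))
#' inverseTransform(0.5)    # sqrt(50000)
#' @export
transformAffinity <- function(ic50) {
    if (any(!is.finite(ic50)) || any(ic50 <= 0))
        stop("ic50 must be positive and finite")
    pmin(1, pmax(0, 1 - log(ic50) / log(50000)))
}

#' @rdname transformAffinity
#' @param y transformed affinities in [0, 1].
#' @return \code{inverseTransform}: affinities in nM, in [1, 50000].
#' @export
inverseTransform <- function(y) {
    if (any(!is.finite(y)) || any(y < 0) || any(y > 1))
        stop("transformed affinities must lie in [0, 1]")
    50000^(1 - y)
}

#' Binary binder label from IC50
#'
#' A peptide is a binder when its IC50 is strictly below the threshold
#' (1000 nM by default).
#'
#' @param ic50 affinities in nM (positive).
#' @param threshold binder threshold in nM.
#' @return Integer vector of 0/1 labels.
#' @examples
#' binderLabel(c(999.9, 1000, 748.1))   # 1 0 1
#' @export
binderLabel <- function(ic50, threshold = 1000) {
    if (any(!is.finite(ic50)) || any(ic50 <= 0))
        stop("ic50 must be positive and finite")
    as.integer(ic50 < threshold)
}

#' Assign stratified cross-validation folds
#'
#' Assigns each record a fold in 0..k-1, stratified by binder label within
#' each allele so every fold sees a similar class balance; within each
#' stratum the fold sizes differ by at most one.  Deterministic given the
#' seed; the caller's RNG state is left untouched.
#'
#' @param x a \linkS4class{PeptideSet}.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @param threshold binder threshold in nM used for stratification.
#' @return \code{x} with the fold column filled in.
#' @export
assignFolds <- function(x, k = 5L, seed = 1L, threshold = 1000) {
    stopifnot(is(x, "PeptideSet"))
    k <- as.integer(k)
    if (k < 2L) stop("k must be at least 2")
    df <- x@records
    if (nrow(df) == 0L) stop("no records to assign folds to")
    small <- table(df$allele)
    if (any(small < k))
        stop(sprintf("allele(s) with fewer than k=%d records: %s", k,
                     paste(names(small)[small < k], collapse = ", ")))
    lab <- binderLabel(df$ic50, threshold)
    fold <- integer(nrow(df))
    rng <- .withSeed(seed, {
        for (al in unique(df$allele)) {
            # continue the fold cycle across the two strata so that the
            # per-allele totals stay balanced as well
            cursor <- 0L
            for (l in c(0L, 1L)) {
                idx <- which(df$allele == al & lab == l)
                if (!length(idx)) next
                idx <- sample(idx)
                fold[idx] <- (cursor + seq_along(idx) - 1L) %% k
                cursor <- (cursor + length(idx)) %% k
            }
        }
        fold
    })
    df$fold <- rng
    new("PeptideSet", records = df)
}

# Evaluate expr under a private RNG stream, restoring the caller's state.
.withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}
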