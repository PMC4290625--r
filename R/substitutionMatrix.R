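#' @include AllClasses.R
NULL

#' Read a substitution matrix in NCBI format
#'
#' Parses the plain-text scoring-matrix format distributed with BLAST:
#' \code{#} comment lines, a header row of residue codes, then one row of
#' integer scores per residue, optionally prefixed with the row residue.
#' The parsed matrix must be square and symmetric.
#'
#' @param path path to the matrix file.
#' @return A symmetric integer matrix with residue codes as dimnames.
#' @examples
#' b62 <- readSubstitutionMatrix(system.file("extdata", "BLOSUM62",
#'                                           package = "PepMIL"))
#' b62["A", "A"]   # 4
#' b62["W", "P"]   # -4
#' @export
readSubstitutionMatrix <- function(path) {
    if (!file.exists(path))
        stop("substitution matrix file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^\\s*#", lines)]
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) < 2L)
        stop("matrix file has no score rows: ", path)
    toks <- strsplit(trimws(lines), "\\s+")
    alphabet <- toks[[1L]]
    n <- length(alphabet)
    if (anyDuplicated(alphabet))
        stop("duplicated residue codes in matrix header")
    if (length(toks) != n + 1L)
        stop(sprintf("expected %d score rows, found %d", n,
                     length(toks) - 1L))
    scores <- matrix(NA_integer_, n, n, dimnames = list(alphabet, alphabet))
    for (i in seq_len(n)) {
        row <- toks[[i + 1L]]
        # row residue label is optional in the wild; require it to match
        # the header order when present
        if (suppressWarnings(is.na(as.integer(row[1L])))) {
            if (row[1L] != alphabet[i])
                stop(sprintf("row %d labelled '%s', expected '%s'",
                             i, row[1L], alphabet[i]))
            row <- row[-1L]
        }
        if (length(row) != n)
            stop(sprintf("ragged row for residue '%s': %d scores, expected %d",
                         alphabet[i], length(row), n))
        vals <- suppressWarnings(as.integer(row))
        if (anyNA(vals))
            stop(sprintf("non-integer score in row for residue '%s'",
                         alphabet[i]))
        scores[i, ] <- vals
    }
    bad <- which(scores != t(scores), arr.ind = TRUE)
    if (nrow(bad))
        stop(sprintf("matrix is not symmetric: score(%s,%s) != score(%s,%s)",
                     alphabet[bad[1L, 1L]], alphabet[bad[1L, 2L]],
                     alphabet[bad[1L, 2L]], alphabet[bad[1L, 1L]]))
    scores
}

.pkg_cache <- new.env(parent = emptyenv())

#' The packaged BLOSUM62 matrix
#'
#' Loads (and caches) the BLOSUM62 matrix shipped with the package, in the
#' canonical 24-letter NCBI alphabet (the 20 standard residues plus B, Z,
#' X and *).
#'
#' @return A symmetric integer matrix.
#' @examples
#' blosum62()["L", "L"]
#' @export
blosum62 <- function() {
    if (is.null(.pkg_cache$blosum62)) {
        path <- system.file("extdata", "BLOSUM62", package = "PepMIL")
        .pkg_cache$blosum62 <- readSubstitutionMatrix(path)
    }
    .pkg_cache$blosum62
}

#' Alphabet of a substitution matrix
#'
#' @param matrix a parsed substitution matrix.
#' @return Character vector of residue codes.
#' @export
matrixAlphabet <- function(matrix) rownames(matrix)
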