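#' @include AllClasses.R peptides.R substitutionMatrix.R
NULL

#' Map core key positions to 11-mer positions
#'
#' An 11-long instance is a 9-long binding core plus the residues
#' immediately left and right of it, so core position p sits at p + 1 in
#' the 11-mer and the two flanks sit at positions 1 and 11.  The induced
#' 11-mer position set is \{1\} U \{p + 1 : p in kp9\} U \{11\}.
#'
#' @param kp9 integer subset of 1..9.
#' @return Sorted integer subset of 1..11.
#' @examples
#' coreTo11Positions(c(1, 4, 6, 7, 9))      # 1 2 5 7 8 10 11
#' coreTo11Positions(c(1, 2, 4, 6, 7, 9))   # 1 2 3 5 7 8 10 11
#' @export
coreTo11Positions <- function(kp9) {
    kp9 <- as.integer(kp9)
    if (any(kp9 < 1L | kp9 > 9L))
        stop("core key positions must lie in 1..9")
    sort(unique(c(1L, kp9 + 1L, 11L)))
}

#' Key-position scheme presets
#'
#' Builds a \linkS4class{KeyPositionScheme}.  Presets: \code{"all"} uses
#' every position of either instance length; \code{"kp"} uses the five
#' canonical core anchor positions 1, 4, 6, 7, 9 (11-mer set induced via
#' \code{\link{coreTo11Positions}}); \code{"kp+n"} (n in 2, 3, 5, 8) adds
#' one core position to \code{"kp"}.  Alternatively pass a custom
#' \code{kp9}; its 11-mer set is induced unless \code{kp11} is given.
#'
#' @param name preset name, ignored when \code{kp9} is supplied.
#' @param kp9 custom core position set (subset of 1..9).
#' @param kp11 custom 11-mer position set; default induced from
#'   \code{kp9}.
#' @return A \linkS4class{KeyPositionScheme}.
#' @examples
#' keyPositionScheme("kp")
#' keyPositionScheme(kp9 = c(2, 3, 5, 8))
#' @export
keyPositionScheme <- function(name = c("all", "kp", "kp+2", "kp+3", "kp+5",
                                       "kp+8"),
                              kp9 = NULL, kp11 = NULL) {
    if (!is.null(kp9)) {
        kp9 <- sort(unique(as.integer(kp9)))
        if (is.null(kp11)) kp11 <- coreTo11Positions(kp9)
        nm <- if (is.character(name) && length(name) == 1L &&
                  !name %in% c("all", "kp", "kp+2", "kp+3", "kp+5", "kp+8"))
            name else "custom"
        return(new("KeyPositionScheme", name = nm, kp9 = kp9,
                   kp11 = sort(unique(as.integer(kp11)))))
    }
    name <- match.arg(name)
    canon <- c(1L, 4L, 6L, 7L, 9L)
    kp9 <- switch(name,
                  "all" = 1:9,
                  "kp" = canon,
                  sort(c(canon, as.integer(sub("^kp\\+", "", name)))))
    kp11 <- if (name == "all") 1:11 else coreTo11Positions(kp9)
    new("KeyPositionScheme", name = name, kp9 = as.integer(kp9),
        kp11 = kp11)
}

setMethod("show", "KeyPositionScheme", function(object) {
    cat(sprintf("KeyPositionScheme '%s'\n  kp9:  {%s}\n  kp11: {%s}\n",
                object@name, paste(object@kp9, collapse = ","),
                paste(object@kp11, collapse = ",")))
})

#' Method presets
#'
#' @return Character vector of the recognised method preset names.
#' @export
milPresets <- function()
    c("mhcmir9", "mhcmir11", "fl", "fl+fpl", "fl+kp",
      "fl+kp+2", "fl+kp+3", "fl+kp+5", "fl+kp+8")

#' Configure a MIL method variant
#'
#' Resolves a method preset into a full \linkS4class{MilConfig}.  The
#' presets are the ablation family around the flexible-length key-position
#' model: \code{"mhcmir9"} / \code{"mhcmir11"} fill bags with one fixed
#' instance length and score all positions; \code{"fl"} uses both 9- and
#' 11-long instances; \code{"fl+fpl"} additionally restricts candidate
#' cores to those starting with an aliphatic or aromatic residue
#' (I, L, M, V, F, W, Y); \code{"fl+kp"} scores only the key positions;
#' \code{"fl+kp+n"} adds core position n to the key set.  Any component
#' can be overridden.
#'
#' @param preset preset name, see \code{\link{milPresets}}.
#' @param matrix substitution matrix (default \code{\link{blosum62}()}).
#' @param lengths override the instance lengths (subset of c(9, 11)).
#' @param scheme override the \linkS4class{KeyPositionScheme}.
#' @param fpl override the first-position limitation flag.
#' @param fplAllowed residues allowed at the core first position.
#' @param fplCorePos where the core first residue sits in an 11-long
#'   instance: 2 (default; position 1 is the left flank) or 1.
#' @param sentinel distance used across instance lengths, in (0, 1].
#' @param cost,gamma,epsilon SVR hyperparameters; \code{gamma = NA} means
#'   1/#features at fit time (the libsvm default).
#' @param emptyBagPolicy \code{"sentinel"} (embed an all-sentinel vector,
#'   with a message) or \code{"error"} for bags emptied by the filter.
#' @return A \linkS4class{MilConfig}.
#' @examples
#' milConfig("fl+kp")
#' milConfig("fl", scheme = keyPositionScheme(kp9 = c(2, 3, 5, 8)))
#' @export
milConfig <- function(preset = "fl+kp", matrix = blosum62(),
                      lengths = NULL, scheme = NULL, fpl = NULL,
                      fplAllowed = c("I", "L", "M", "V", "F", "W", "Y"),
                      fplCorePos = 2L, sentinel = 1.0, cost = 1.0,
                      gamma = NA_real_, epsilon = 0.1,
                      emptyBagPolicy = "sentinel") {
    if (!preset %in% milPresets())
        stop("unknown preset '", preset, "'; available: ",
             paste(milPresets(), collapse = ", "))
    def <- switch(preset,
        "mhcmir9"  = list(lengths = 9L, scheme = "all", fpl = FALSE),
        "mhcmir11" = list(lengths = 11L, scheme = "all", fpl = FALSE),
        "fl"       = list(lengths = c(9L, 11L), scheme = "all", fpl = FALSE),
        "fl+fpl"   = list(lengths = c(9L, 11L), scheme = "all", fpl = TRUE),
        "fl+kp"    = list(lengths = c(9L, 11L), scheme = "kp", fpl = FALSE),
        list(lengths = c(9L, 11L),
             scheme = sub("^fl\\+", "", preset), fpl = FALSE))
    if (is.null(lengths)) lengths <- def$lengths
    if (is.null(scheme)) scheme <- keyPositionScheme(def$scheme)
    if (is.null(fpl)) fpl <- def$fpl
    new("MilConfig", preset = preset, matrix = matrix,
        lengths = sort(as.integer(lengths)), scheme = scheme,
        sentinel = sentinel, fpl = fpl,
        fplAllowed = toupper(fplAllowed), fplCorePos = as.integer(fplCorePos),
        cost = cost, gamma = gamma, epsilon = epsilon,
        emptyBagPolicy = emptyBagPolicy)
}

setMethod("show", "MilConfig", function(object) {
    cat(sprintf("MilConfig preset '%s'\n", object@preset))
    cat(sprintf("  instance lengths: %s | scheme '%s' kp9={%s} kp11={%s}\n",
                paste(object@lengths, collapse = ","), object@scheme@name,
                paste(object@scheme@kp9, collapse = ","),
                paste(object@scheme@kp11, collapse = ",")))
    cat(sprintf("  fpl: %s | sentinel: %g | SVR: C=%g gamma=%s eps=%g\n",
                if (object@fpl) paste0("yes (", paste(object@fplAllowed,
                    collapse = ""), " at core P1)") else "no",
                object@sentinel, object@cost,
                if (is.na(object@gamma)) "1/#features" else
                    format(object@gamma), object@epsilon))
})

#' Enumerate the candidate-core instances of a peptide
#'
#' All contiguous substrings of the requested lengths, ordered by length
#' (9 before 11) and then by offset: a peptide of length L contributes
#' L - n + 1 instances of length n.
#'
#' @param sequence a single peptide sequence.
#' @param lengths instance lengths, subset of c(9, 11).
#' @return data.frame with columns \code{instance}, \code{offset}
#'   (1-based start in the peptide) and \code{length}.
#' @examples
#' nrow(makeInstances(strrep("A", 15)))   # 7 nine-mers + 5 eleven-mers
#' @export
makeInstances <- function(sequence, lengths = c(9L, 11L)) {
    stopifnot(length(sequence) == 1L)
    lengths <- sort(as.integer(lengths))
    if (!all(lengths %in% c(9L, 11L)) || !length(lengths))
        stop("instance lengths must be a non-empty subset of c(9, 11)")
    L <- nchar(sequence)
    if (L < min(lengths))
        stop(sprintf("peptide of length %d is too short to form any instance (min %d)",
                     L, min(lengths)))
    out <- lapply(lengths, function(n) {
        if (L < n) return(NULL)
        off <- seq_len(L - n + 1L)
        data.frame(instance = substring(sequence, off, off + n - 1L),
                   offset = off, length = n, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' First-position limitation filter
#'
#' Keeps only instances whose binding-core first residue is aliphatic or
#' aromatic: position 1 of a 9-long instance, position \code{corePos}
#' (default 2, since position 1 is the left flank) of an 11-long instance.
#' May return zero rows.
#'
#' @param instances data.frame from \code{\link{makeInstances}}.
#' @param allowed residues allowed at the core first position.
#' @param corePos position checked within 11-long instances.
#' @return The filtered data.frame.
#' @export
firstPositionFilter <- function(instances,
                                allowed = c("I","L","M","V","F","W","Y"),
                                corePos = 2L) {
    if (!nrow(instances)) return(instances)
    pos <- ifelse(instances$length == 11L, as.integer(corePos), 1L)
    keep <- substring(instances$instance, pos, pos) %in% allowed
    out <- instances[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Build instance bags from peptides
#'
#' Turns each peptide of a \linkS4class{PeptideSet} into a bag of
#' candidate-core instances under a \linkS4class{MilConfig} (instance
#' lengths, optional first-position filter) and attaches the transformed
#' affinity target.
#'
#' @param x a \linkS4class{PeptideSet}; every sequence must reach the
#'   configured minimum instance length.
#' @param config a \linkS4class{MilConfig}.
#' @return An \linkS4class{InstanceBags}.
#' @export
makeBags <- function(x, config) {
    stopifnot(is(x, "PeptideSet"), is(config, "MilConfig"))
    seqs <- peptides(x)
    alpha <- matrixAlphabet(config@matrix)
    bad <- vapply(strsplit(seqs, ""), function(ch) !all(ch %in% alpha),
                  logical(1L))
    if (any(bad))
        stop("sequence(s) with residues outside the matrix alphabet: ",
             paste(which(bad), collapse = ", "))
    inst <- vector("list", length(seqs))
    offs <- vector("list", length(seqs))
    for (i in seq_along(seqs)) {
        tab <- makeInstances(seqs[i], config@lengths)
        if (config@fpl)
            tab <- firstPositionFilter(tab, config@fplAllowed,
                                       config@fplCorePos)
        inst[[i]] <- tab$instance
        offs[[i]] <- tab$offset
    }
    new("InstanceBags", instances = inst, offsets = offs,
        targets = transformAffinity(ic50(x)), peptides = x)
}

#' @rdname accessors
#' @export
setMethod("bagSizes", "InstanceBags", function(x, ...)
    lengths(x@instances))

#' @describeIn InstanceBags number of bags.
#' @param x an \code{InstanceBags}.
#' @export
setMethod("length", "InstanceBags", function(x) length(x@instances))

#' Instances of each bag
#'
#' @param x an \linkS4class{InstanceBags}.
#' @return List of character vectors, one per bag.
#' @export
bagInstances <- function(x) {
    stopifnot(is(x, "InstanceBags"))
    x@instances
}

#' Transformed affinity targets of the bags
#'
#' @param x an \linkS4class{InstanceBags}.
#' @return Numeric vector in [0, 1].
#' @export
bagTargets <- function(x) {
    stopifnot(is(x, "InstanceBags"))
    x@targets
}

setMethod("show", "InstanceBags", function(object) {
    sz <- lengths(object@instances)
    cat(sprintf("InstanceBags with %d bags (%d empty), %d instances total\n",
                length(sz), sum(sz == 0L), sum(sz)))
    if (length(sz))
        cat(sprintf("  bag sizes %d..%d, targets %.3f..%.3f\n",
                    min(sz), max(sz), min(object@targets),
                    max(object@targets)))
})

# positions the scheme uses for one instance length
.schemePositions <- function(scheme, len) {
    pos <- if (len == 9L) scheme@kp9 else scheme@kp11
    if (!length(pos))
        stop(sprintf("scheme '%s' defines no positions for length %d",
                     scheme@name, len))
    pos
}

#' Raw key-position score between two instances
#'
#' For two instances of equal length, the sum of substitution-matrix
#' scores at the scheme's position set for that length.  Instances of
#' different lengths never match and score \code{Inf} (the cross-length
#' marker); \code{\link{instanceDistance}} maps it to the configured
#' sentinel.
#'
#' @param x,y instance strings of length 9 or 11.
#' @param config a \linkS4class{MilConfig}.
#' @return A single numeric score, or \code{Inf} for a cross-length pair.
#' @examples
#' cfg <- milConfig("fl+kp")
#' rawScore(strrep("A", 9), strrep("A", 9), cfg)   # 5 * 4 = 20
#' @export
rawScore <- function(x, y, config) {
    nx <- nchar(x); ny <- nchar(y)
    if (nx != ny) return(Inf)
    pos <- .schemePositions(config@scheme, nx)
    a <- substring(x, pos, pos)
    b <- substring(y, pos, pos)
    alpha <- matrixAlphabet(config@matrix)
    if (any(!a %in% alpha) || any(!b %in% alpha))
        stop("residue outside the matrix alphabet")
    sum(config@matrix[cbind(a, b)])
}

#' Scaled distance between two instances
#'
#' The raw key-position score d is scaled into (0, 1] by its sign:
#' 1/d when d > 0, 1 when d <= 0.  A cross-length pair takes the
#' configured sentinel (1 by default, the maximum of the range), so
#' instances of different lengths never look similar.  Symmetric.
#'
#' @inheritParams rawScore
#' @return A distance in (0, 1].
#' @examples
#' cfg <- milConfig("fl+kp")
#' instanceDistance(strrep("A", 9), strrep("A", 9), cfg)   # 1/20
#' @export
instanceDistance <- function(x, y, config) {
    d <- rawScore(x, y, config)
    if (is.infinite(d)) return(config@sentinel)
    if (d > 0) 1 / d else 1
}

#' Minimum distance from a meta-space instance to a bag
#'
#' The bag-level feature: the minimum \code{\link{instanceDistance}}
#' between \code{x} and the bag's instances of the same length.  When the
#' bag holds no instance of that length the feature is the cross-length
#' sentinel.
#'
#' @param x an instance string.
#' @param bag character vector of bag instances (non-empty).
#' @param config a \linkS4class{MilConfig}.
#' @return A feature value in (0, 1].
#' @export
bagFeature <- function(x, bag, config) {
    if (!length(bag)) stop("bag is empty")
    same <- bag[nchar(bag) == nchar(x)]
    if (!length(same)) return(config@sentinel)
    min(vapply(same, instanceDistance, numeric(1L), x = x,
               config = config, USE.NAMES = FALSE))
}
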