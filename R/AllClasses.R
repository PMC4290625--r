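#' @import methods
NULL

.AA_STANDARD <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M",
                  "F","P","S","T","W","Y","V")

#' Key-position scheme for instance distances
#'
#' Holds the position subsets used when scoring a pair of equal-length
#' instances: \code{kp9} for 9-long instances and \code{kp11} for 11-long
#' instances.  The named presets are \code{"all"} (every position),
#' \code{"kp"} (the five canonical binding-core anchor positions
#' 1, 4, 6, 7, 9 and the induced 11-mer set 1, 2, 5, 7, 8, 10, 11) and
#' \code{"kp+n"} for n in 2, 3, 5, 8 (one extra core position, with its
#' induced 11-mer position).
#'
#' @slot name preset identifier.
#' @slot kp9 integer subset of 1..9 used for 9-long instances.
#' @slot kp11 integer subset of 1..11 used for 11-long instances.
#' @exportClass KeyPositionScheme
setClass("KeyPositionScheme",
         representation(name = "character", kp9 = "integer", kp11 = "integer"))

setValidity("KeyPositionScheme", function(object) {
    msg <- character()
    if (length(object@kp9) == 0 && length(object@kp11) == 0)
        msg <- c(msg, "at least one of kp9, kp11 must be non-empty")
    if (any(object@kp9 < 1L | object@kp9 > 9L))
        msg <- c(msg, "kp9 must be a subset of 1..9")
    if (any(object@kp11 < 1L | object@kp11 > 11L))
        msg <- c(msg, "kp11 must be a subset of 1..11")
    if (anyDuplicated(object@kp9) || anyDuplicated(object@kp11))
        msg <- c(msg, "position sets must not contain duplicates")
    if (is.unsorted(object@kp9) || is.unsorted(object@kp11))
        msg <- c(msg, "position sets must be sorted increasingly")
    if (length(msg)) msg else TRUE
})

#' Configuration of a MIL method variant
#'
#' Bundles everything that defines one method preset: the substitution
#' matrix, the instance lengths used to fill bags, the key-position scheme
#' of the distance, the first-position limitation filter, the cross-length
#' sentinel, and the SVR hyperparameters.
#'
#' @slot preset preset name (e.g. \code{"fl+kp"}).
#' @slot matrix symmetric integer substitution matrix with residue dimnames.
#' @slot lengths instance lengths used to fill bags; subset of c(9, 11).
#' @slot scheme a \linkS4class{KeyPositionScheme}.
#' @slot sentinel distance assigned across instance lengths, in (0, 1].
#' @slot fpl logical; apply the first-position limitation filter.
#' @slot fplAllowed residues allowed at the core first position under fpl.
#' @slot fplCorePos position of the core first residue within an 11-long
#'   instance (2 by default: the flank occupies position 1).
#' @slot cost SVR cost parameter C.
#' @slot gamma RBF kernel width; \code{NA} means 1/#features at fit time.
#' @slot epsilon SVR epsilon-tube width.
#' @slot emptyBagPolicy \code{"sentinel"} or \code{"error"} for bags left
#'   empty by the filter.
#' @exportClass MilConfig
setClass("MilConfig",
         representation(preset = "character", matrix = "matrix",
                        lengths = "integer", scheme = "KeyPositionScheme",
                        sentinel = "numeric", fpl = "logical",
                        fplAllowed = "character", fplCorePos = "integer",
                        cost = "numeric", gamma = "numeric",
                        epsilon = "numeric", emptyBagPolicy = "character"))

setValidity("MilConfig", function(object) {
    msg <- character()
    m <- object@matrix
    if (is.null(dimnames(m)) || !identical(rownames(m), colnames(m)))
        msg <- c(msg, "matrix must have identical row and column names")
    else if (!isSymmetric(unname(m)))
        msg <- c(msg, "substitution matrix must be symmetric")
    if (!all(object@lengths %in% c(9L, 11L)) || length(object@lengths) == 0)
        msg <- c(msg, "lengths must be a non-empty subset of c(9, 11)")
    if (object@sentinel <= 0 || object@sentinel > 1)
        msg <- c(msg, "sentinel must lie in (0, 1]")
    if (!object@fplCorePos %in% c(1L, 2L))
        msg <- c(msg, "fplCorePos must be 1 or 2")
    if (!object@emptyBagPolicy %in% c("sentinel", "error"))
        msg <- c(msg, "emptyBagPolicy must be 'sentinel' or 'error'")
    if (object@cost <= 0 || object@epsilon < 0)
        msg <- c(msg, "cost must be > 0 and epsilon >= 0")
    if (length(msg)) msg else TRUE
})

#' Set of peptide binding-affinity records
#'
#' One record per measured peptide: the restricting MHC-II allele, the
#' peptide sequence in one-letter code, the measured IC50 in nM, and an
#' optional 0-based cross-validation fold index.
#'
#' @slot records data.frame with columns \code{allele}, \code{sequence},
#'   \code{ic50} and \code{fold} (\code{NA} when unassigned).
#' @exportClass PeptideSet
setClass("PeptideSet", representation(records = "data.frame"))

setValidity("PeptideSet", function(object) {
    df <- object@records
    need <- c("allele", "sequence", "ic50", "fold")
    if (!all(need %in% names(df)))
        return(sprintf("records must have columns %s",
                       paste(need, collapse = ", ")))
    msg <- character()
    if (nrow(df)) {
        if (any(!nzchar(df$sequence)))
            msg <- c(msg, "sequences must be non-empty")
        if (any(!is.finite(df$ic50)) || any(df$ic50 <= 0))
            msg <- c(msg, "ic50 must be positive and finite")
        if (any(grepl("[^A-Z*]", df$sequence)))
            msg <- c(msg, "sequences must use one-letter residue codes")
        f <- df$fold[!is.na(df$fold)]
        if (length(f) && any(f < 0))
            msg <- c(msg, "fold indices are 0-based and non-negative")
    }
    if (length(msg)) msg else TRUE
})

#' Bags of candidate binding-core instances
#'
#' The multiple-instance view of a \linkS4class{PeptideSet}: each peptide
#' becomes a bag holding its contiguous substrings of the configured
#' lengths (its candidate binding cores), paired with the transformed
#' affinity target.  A bag can be empty after the first-position filter.
#'
#' @slot instances list of character vectors, one per peptide.
#' @slot offsets list of integer vectors; 1-based start of each instance
#'   within its source peptide.
#' @slot targets numeric vector of transformed affinities in [0, 1].
#' @slot peptides the source \linkS4class{PeptideSet}.
#' @exportClass InstanceBags
setClass("InstanceBags",
         representation(instances = "list", offsets = "list",
                        targets = "numeric", peptides = "PeptideSet"))

setValidity("InstanceBags", function(object) {
    n <- length(object@instances)
    if (length(object@offsets) != n || length(object@targets) != n ||
        nrow(object@peptides@records) != n)
        return("instances, offsets, targets and peptides must be parallel")
    if (length(object@targets) && (any(object@targets < 0) ||
                                   any(object@targets > 1)))
        return("targets must lie in [0, 1]")
    TRUE
})

#' Meta-space of training instances
#'
#' The ordered, deduplicated catalogue of all instances seen in the
#' training bags.  Bags are embedded as their vector of minimum distances
#' to every catalogue member, so the meta-space fixes the feature space:
#' its order (instance length ascending, then lexicographic) is the
#' feature order.
#'
#' @slot instances character vector of unique instance strings.
#' @slot lengths integer vector, \code{nchar} of each instance.
#' @exportClass MetaSpace
setClass("MetaSpace",
         representation(instances = "character", lengths = "integer"))

setValidity("MetaSpace", function(object) {
    if (length(object@instances) == 0)
        return("meta-space must be non-empty")
    if (anyDuplicated(object@instances))
        return("meta-space instances must be unique")
    if (!identical(object@lengths, nchar(object@instances)))
        return("lengths must equal nchar(instances)")
    o <- order(object@lengths, object@instances, method = "radix")
    if (!identical(o, seq_along(o)))
        return("instances must be ordered by length, then lexicographically")
    TRUE
})

#' Fitted MIL regression model for one allele
#'
#' Couples the training meta-space, the method configuration and the
#' fitted epsilon-SVR.  Predictions are a pure function of
#' (model, peptide sequence).
#'
#' @slot config the \linkS4class{MilConfig} used for training.
#' @slot metaspace the training \linkS4class{MetaSpace}.
#' @slot svr fitted \code{e1071::svm} regressor.
#' @slot allele allele identifier the model was trained for.
#' @slot nFeatures feature-space dimension (= meta-space size).
#' @slot provenance list with seed and package version.
#' @exportClass MilModel
setClass("MilModel",
         representation(config = "MilConfig", metaspace = "MetaSpace",
                        svr = "ANY", allele = "character",
                        nFeatures = "integer", provenance = "list"))

#' Paired comparison of two methods by per-allele wins
#'
#' Result of the exact one-tailed binomial sign test: per-allele AUC wins
#' of method A over method B, ties dropped, and the exact tail probability
#' P(X >= winsA) for X ~ Binomial(winsA + winsB, 1/2).
#'
#' @slot methodA,methodB method names.
#' @slot winsA,winsB,ties allele counts.
#' @slot pValue exact one-tailed binomial probability.
#' @slot alleles data.frame with per-allele AUCs and the win direction.
#' @exportClass MethodComparison
setClass("MethodComparison",
         representation(methodA = "character", methodB = "character",
                        winsA = "integer", winsB = "integer",
                        ties = "integer", pValue = "numeric",
                        alleles = "data.frame"))

setValidity("MethodComparison", function(object) {
    n <- nrow(object@alleles)
    if (object@winsA + object@winsB + object@ties != n)
        return("winsA + winsB + ties must equal the number of alleles")
    if (object@pValue <= 0 || object@pValue > 1)
        return("pValue must lie in (0, 1]")
    TRUE
})
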