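#' @include AllClasses.R
NULL

#' Accessors for PepMIL objects
#'
#' \code{alleles} returns the allele identifier(s); \code{peptides} the
#' peptide sequences; \code{ic50} the measured affinities in nM;
#' \code{folds} the 0-based cross-validation fold indices (\code{NA} when
#' unassigned); \code{binderLabels} the binary binder labels at a
#' threshold; \code{bagSizes} the number of instances per bag;
#' \code{metaSpace} the training instance catalogue of a model.
#'
#' @param x a \linkS4class{PeptideSet}, \linkS4class{InstanceBags},
#'   \linkS4class{MetaSpace} or \linkS4class{MilModel}.
#' @param ... passed to methods.
#' @return A vector (accessors on record fields) or the extracted object.
#' @name accessors
#' @examples
#' ps <- PeptideSet(allele = "X", sequence = c("ALMNPQRST", "GGGGGGGGGGG"),
#'                  ic50 = c(50, 5000))
#' alleles(ps)
#' binderLabels(ps)
NULL

#' @rdname accessors
#' @export
setGeneric("alleles", function(x, ...) standardGeneric("alleles"))

#' @rdname accessors
#' @export
setGeneric("peptides", function(x, ...) standardGeneric("peptides"))

#' @rdname accessors
#' @export
setGeneric("ic50", function(x, ...) standardGeneric("ic50"))

#' @rdname accessors
#' @export
setGeneric("folds", function(x, ...) standardGeneric("folds"))

#' @rdname accessors
#' @export
setGeneric("binderLabels", function(x, ...) standardGeneric("binderLabels"))

#' @rdname accessors
#' @export
setGeneric("bagSizes", function(x, ...) standardGeneric("bagSizes"))

#' @rdname accessors
#' @export
setGeneric("metaSpace", function(x, ...) standardGeneric("metaSpace"))
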