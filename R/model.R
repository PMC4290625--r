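#' @include AllClasses.R embedding.R
NULL

#' Fit the MIL regression model for one allele
#'
#' Builds the meta-space from the training bags, embeds every bag as its
#' minimum-distance feature vector, and fits an epsilon-SVR with RBF
#' kernel on the transformed affinities.  Hyperparameters follow the
#' libsvm defaults: C = 1, gamma = 1/#features, epsilon = 0.1 (all
#' overridable through the \linkS4class{MilConfig}).  Deterministic given
#' identical inputs.
#'
#' @param x a \linkS4class{PeptideSet} or \linkS4class{InstanceBags}.
#' @param config a \linkS4class{MilConfig}.
#' @param allele allele label stored in the model (default: the single
#'   allele of \code{x}).
#' @return A \linkS4class{MilModel}.
#' @examples
#' ps <- syntheticDataset(syntheticConfig(nPeptides = 30, seed = 7))
#' fit <- milFit(ps, milConfig("fl+kp"))
#' fit
#' @export
milFit <- function(x, config, allele = NULL) {
    stopifnot(is(config, "MilConfig"))
    bags <- if (is(x, "InstanceBags")) x else makeBags(x, config)
    if (length(bags@instances) < 2L)
        stop("need at least 2 training bags")
    if (is.null(allele)) {
        al <- unique(alleles(bags@peptides))
        allele <- if (length(al) == 1L) al else paste(al, collapse = "+")
    }
    ms <- buildMetaSpace(bags)
    F <- embedBags(bags, ms, config)
    gamma <- if (is.na(config@gamma)) 1 / ncol(F) else config@gamma
    svr <- e1071::svm(x = F, y = bags@targets, scale = FALSE,
                      type = "eps-regression", kernel = "radial",
                      cost = config@cost, gamma = gamma,
                      epsilon = config@epsilon, fitted = FALSE)
    new("MilModel", config = config, metaspace = ms, svr = svr,
        allele = allele, nFeatures = ncol(F),
        provenance = list(package = "PepMIL",
                          version = as.character(utils::packageVersion("PepMIL")),
                          nTrain = length(bags@instances)))
}

#' @rdname accessors
#' @export
setMethod("metaSpace", "MilModel", function(x, ...) x@metaspace)

#' @rdname accessors
#' @export
setMethod("alleles", "MilModel", function(x, ...) x@allele)

setMethod("show", "MilModel", function(object) {
    cat(sprintf("MilModel for allele '%s' (preset '%s')\n", object@allele,
                object@config@preset))
    cat(sprintf("  %d training bags, %d meta-space features, %d support vectors\n",
                object@provenance$nTrain, object@nFeatures,
                object@svr$tot.nSV))
})

#' Predict binding affinity for peptides
#'
#' Embeds each peptide's bag against the model's training meta-space and
#' applies the fitted regressor.  The regressor output is clamped into
#' [0, 1] and mapped back to the nM scale, ic50 = 50000^(1 - y).
#' Predictions are a pure function of (model, sequence).
#'
#' @param model a \linkS4class{MilModel}.
#' @param x a \linkS4class{PeptideSet} or a character vector of peptide
#'   sequences.
#' @return data.frame with columns \code{allele}, \code{sequence},
#'   \code{y_pred} (clamped regressor output) and \code{ic50_pred_nM}.
#' @export
milPredict <- function(model, x) {
    stopifnot(is(model, "MilModel"))
    if (is.character(x))
        x <- PeptideSet(model@allele, x, ic50 = 25000)  # affinity unused
    bags <- makeBags(x, model@config)
    F <- embedBags(bags, model@metaspace, model@config)
    # libsvm leaves no support vectors when all targets fit inside the
    # epsilon tube; the decision function is then the constant -rho
    y <- if (model@svr$tot.nSV == 0L) rep(-model@svr$rho, nrow(F))
         else unname(stats::predict(model@svr, F))
    y <- pmin(1, pmax(0, y))
    data.frame(allele = alleles(x), sequence = peptides(x),
               y_pred = y, ic50_pred_nM = inverseTransform(y),
               stringsAsFactors = FALSE)
}

#' Save and load a fitted model
#'
#' The archive is a single serialized object holding the configuration,
#' the meta-space strings and the fitted regressor payload; reloading it
#' reproduces predictions exactly on the same platform.
#'
#' @param model a \linkS4class{MilModel} (or a named list of them, as
#'   written by \code{\link{runTrain}}).
#' @param path archive path.
#' @return \code{saveModel}: \code{path}, invisibly; \code{loadModel}:
#'   the restored object.
#' @export
saveModel <- function(model, path) {
    saveRDS(model, path, version = 2)
    invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
    if (!file.exists(path)) stop("model archive not found: ", path)
    readRDS(path)
}

#' Write a prediction table
#'
#' @param predictions data.frame from \code{\link{milPredict}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePredictions <- function(predictions, path) {
    df <- predictions
    df$y_pred <- sprintf("%.6f", df$y_pred)
    df$ic50_pred_nM <- sprintf("%.4f", as.numeric(df$ic50_pred_nM))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
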