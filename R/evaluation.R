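#' @include AllClasses.R model.R
NULL

#' Area under the ROC curve
#'
#' Mann-Whitney formulation via midranks: the probability that a random
#' binder outranks a random non-binder, with tied scores contributing
#' 1/2 per tied binder/non-binder pair.  Both classes must be present.
#'
#' @param scores numeric prediction scores (higher = more binder-like).
#' @param labels binary labels (1 = binder).
#' @return AUC in [0, 1].
#' @examples
#' aucScore(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))   # 0.75
#' @export
aucScore <- function(scores, labels) {
    if (length(scores) != length(labels))
        stop("scores and labels must have equal length")
    labels <- as.integer(labels)
    n1 <- sum(labels == 1L)
    n0 <- sum(labels == 0L)
    if (n1 == 0L || n0 == 0L)
        stop("both classes must be present to compute AUC")
    r <- rank(scores)   # midranks handle ties as 1/2 per discordant pair
    (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-allele cross-validation of a MIL method
#'
#' For each allele, and each fold in turn: the model is trained on the
#' remaining folds (the meta-space is rebuilt from those training bags
#' only, so held-out instances never enter the feature space), the
#' held-out fold is predicted, and the allele's AUC is computed over the
#' pooled out-of-fold predictions against the binder labels.  Alleles
#' whose training split misses a class in some fold are reported and
#' skipped.
#'
#' @param x a \linkS4class{PeptideSet}; when its fold column is
#'   unassigned, stratified folds are generated with
#'   \code{\link{assignFolds}}.
#' @param config a \linkS4class{MilConfig}.
#' @param k number of folds (used only when folds are generated).
#' @param seed seed for generated folds.
#' @param threshold binder threshold in nM.
#' @return data.frame with one row per allele (\code{allele}, \code{auc},
#'   \code{n}, \code{n_binder}), plus attributes \code{"averageAUC"}
#'   (unweighted mean across alleles), \code{"predictions"} (pooled
#'   out-of-fold predictions) and \code{"skipped"} (alleles skipped, with
#'   reasons).
#' @export
crossValidate <- function(x, config, k = 5L, seed = 1L, threshold = 1000) {
    stopifnot(is(x, "PeptideSet"), is(config, "MilConfig"))
    if (all(is.na(folds(x))))
        x <- assignFolds(x, k = k, seed = seed, threshold = threshold)
    df <- peptideRecords(x)
    if (anyNA(df$fold))
        stop("some records have no fold assignment")
    out <- list(); preds <- list(); skipped <- list()
    for (al in unique(df$allele)) {
        sub <- x[df$allele == al]
        rec <- peptideRecords(sub)
        lab <- binderLabel(rec$ic50, threshold)
        fids <- sort(unique(rec$fold))
        ok <- TRUE
        for (f in fids) {
            trLab <- lab[rec$fold != f]
            if (length(unique(trLab)) < 2L) {
                skipped[[al]] <- sprintf(
                    "training split of fold %d has a single class", f)
                warning(sprintf("allele %s skipped: %s", al, skipped[[al]]),
                        call. = FALSE)
                ok <- FALSE
                break
            }
        }
        if (!ok) next
        yPred <- rep(NA_real_, nrow(rec))
        for (f in fids) {
            tr <- sub[rec$fold != f]
            te <- sub[rec$fold == f]
            fit <- milFit(tr, config, allele = al)
            yPred[rec$fold == f] <- milPredict(fit, te)$y_pred
        }
        out[[al]] <- data.frame(allele = al,
                                auc = aucScore(yPred, lab),
                                n = nrow(rec), n_binder = sum(lab),
                                stringsAsFactors = FALSE)
        preds[[al]] <- data.frame(allele = al, sequence = rec$sequence,
                                  ic50 = rec$ic50, label = lab,
                                  fold = rec$fold, y_pred = yPred,
                                  stringsAsFactors = FALSE)
    }
    if (!length(out))
        stop("no allele could be cross-validated")
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    attr(res, "averageAUC") <- mean(res$auc)
    attr(res, "predictions") <- do.call(rbind, c(preds,
                                                 make.row.names = FALSE))
    attr(res, "skipped") <- skipped
    res
}

#' Train/test evaluation of a MIL method
#'
#' Fits on the training set, predicts the test set, and scores the AUC of
#' the predicted affinities against the test binder labels.
#'
#' @param train,test \linkS4class{PeptideSet}s (single allele each).
#' @param config a \linkS4class{MilConfig}.
#' @param threshold binder threshold in nM.
#' @return List with elements \code{auc} and \code{predictions}.
#' @export
evaluateSplit <- function(train, test, config, threshold = 1000) {
    fit <- milFit(train, config)
    pr <- milPredict(fit, test)
    lab <- binderLabels(test, threshold)
    list(auc = aucScore(pr$y_pred, lab),
         predictions = cbind(pr, label = lab))
}

#' Exact one-tailed binomial sign test on per-allele AUC wins
#'
#' Counts, over allele-aligned AUC vectors, how often method A strictly
#' beats method B; ties are dropped; the p-value is the exact binomial
#' tail P(X >= winsA) for X ~ Binomial(winsA + winsB, 1/2), i.e. the
#' classic one-tailed sign test with the alternative "method A is
#' better".  Wins are compared at full floating precision.
#'
#' @param aucA,aucB equal-length numeric vectors of per-allele AUCs,
#'   aligned on the same alleles.
#' @param methodA,methodB names used in the report.
#' @param alleleNames optional allele identifiers.
#' @return A \linkS4class{MethodComparison}.
#' @examples
#' signTest(rep(0.8, 26), rep(0.7, 26))@pValue   # 0.5^26
#' @export
signTest <- function(aucA, aucB, methodA = "A", methodB = "B",
                     alleleNames = NULL) {
    if (length(aucA) != length(aucB))
        stop("AUC vectors must be allele-aligned and of equal length")
    if (is.null(alleleNames))
        alleleNames <- paste0("allele", seq_along(aucA))
    winsA <- sum(aucA > aucB)
    winsB <- sum(aucB > aucA)
    ties <- sum(aucA == aucB)
    nEff <- winsA + winsB
    if (nEff == 0L)
        stop("all alleles are ties; the sign test is undefined")
    p <- stats::pbinom(winsA - 1L, nEff, 0.5, lower.tail = FALSE)
    new("MethodComparison", methodA = methodA, methodB = methodB,
        winsA = as.integer(winsA), winsB = as.integer(winsB),
        ties = as.integer(ties), pValue = p,
        alleles = data.frame(allele = alleleNames, aucA = aucA,
                             aucB = aucB,
                             winner = ifelse(aucA > aucB, methodA,
                                             ifelse(aucB > aucA, methodB,
                                                    "tie")),
                             stringsAsFactors = FALSE))
}

setMethod("show", "MethodComparison", function(object) {
    cat(sprintf("Sign test: %s vs %s over %d alleles\n", object@methodA,
                object@methodB, nrow(object@alleles)))
    cat(sprintf("  wins %d / %d (ties %d), one-tailed exact binomial p = %.4g\n",
                object@winsA, object@winsB, object@ties, object@pValue))
})

# half-up rounding to 3 decimals (round() would round half to even)
.round3 <- function(x) floor(x * 1000 + 0.5) / 1000

#' Per-allele AUC comparison table
#'
#' Assembles allele-aligned AUC results of one or more methods into a
#' table with an unweighted average row, plus a Markdown rendering in
#' which the best method per allele is bold.  Values are printed to 3
#' decimals, rounded half-up.
#'
#' @param results named list; each element either a data.frame with
#'   columns \code{allele} and \code{auc} (as from
#'   \code{\link{crossValidate}}) or a named numeric vector of AUCs.
#' @return data.frame with one column per method and a final
#'   \code{"average"} row; the Markdown table is in attribute
#'   \code{"markdown"}.
#' @export
comparisonTable <- function(results) {
    if (is.null(names(results)) || any(!nzchar(names(results))))
        stop("results must be a named list of methods")
    aucs <- lapply(results, function(r) {
        if (is.data.frame(r)) stats::setNames(r$auc, r$allele)
        else r
    })
    al <- names(aucs[[1L]])
    for (a in aucs)
        if (!identical(sort(names(a)), sort(al)))
            stop("methods cover different allele sets")
    mat <- do.call(cbind, lapply(aucs, function(a) unname(a[al])))
    mat <- rbind(mat, colMeans(mat))
    tab <- data.frame(allele = c(al, "average"), .round3(mat),
                      check.names = FALSE, stringsAsFactors = FALSE)
    lines <- c(paste0("| allele | ", paste(names(aucs), collapse = " | "),
                      " |"),
               paste0("|", paste(rep("---", length(aucs) + 1L),
                                 collapse = "|"), "|"))
    for (i in seq_len(nrow(tab))) {
        vals <- sprintf("%.3f", unlist(tab[i, -1L]))
        best <- unlist(tab[i, -1L]) == max(unlist(tab[i, -1L]))
        if (length(aucs) > 1L)
            vals[best] <- paste0("**", vals[best], "**")
        lines <- c(lines, paste0("| ", tab$allele[i], " | ",
                                 paste(vals, collapse = " | "), " |"))
    }
    attr(tab, "markdown") <- paste(lines, collapse = "\n")
    tab
}
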