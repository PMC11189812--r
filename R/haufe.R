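# Forward-model (activation-pattern) transform of linear classifier weights.

#' Transform classifier weights into a forward-model activation pattern
#'
#' The weight vector W of a linear backward model (here a linear SVM) is not
#' interpretable feature by feature; the corresponding forward model is
#' obtained by the covariance transform
#' \deqn{A = \Sigma_x W \Sigma_{\hat s}^{-1}, \qquad
#'       \Sigma_{\hat s} = W' \Sigma_x W,}
#' where \eqn{\Sigma_x} is the covariance of the observed data the classifier
#' was fitted on and \eqn{\Sigma_{\hat s}} the covariance of the latent
#' decision variable (a positive scalar for a single binary classification,
#' K = 1, so the matrix inverse degenerates to scalar division). The intercept
#' never enters the transform.
#'
#' \eqn{\Sigma_x} is estimated from exactly the animals used for the fit
#' (both classes pooled, grand-mean centering, unbiased n - 1 denominator).
#'
#' @param model a \linkS4class{ClassifierModel}.
#' @param data the data the model was fitted on: a
#'   \linkS4class{ZScoreMatrix} (rows are selected via the model's stored row
#'   index) or the samples x features matrix itself.
#' @return an \linkS4class{ActivationPattern} carrying A, Sigma_x and Sigma_s.
#' @examples
#' sim <- simCellCounts(countSimConfig(effectSize = 2, seed = 3))
#' z <- standardizeCounts(sim$table)
#' m <- fitLinearSVM(z, positive = "R-ket", negative = "saline")
#' haufeActivation(m, z)
#' @export
haufeActivation <- function(model, data) {
    stopIfNot(is(model, "ClassifierModel"), "model must be a ClassifierModel")
    x <- if (is(data, "ZScoreMatrix")) {
        zscores(data)[model@rowIndex, , drop = FALSE]
    } else {
        as.matrix(data)
    }
    stopIfNot(ncol(x) == length(model@weights),
              "data has %d features but the model has %d weights",
              ncol(x), length(model@weights))
    stopIfNot(nrow(x) >= 2L, "need >= 2 samples to estimate a covariance")
    sigmaX <- stats::cov(x)
    w <- model@weights
    sigmaS <- as.numeric(t(w) %*% sigmaX %*% w)
    if (!is.finite(sigmaS) || sigmaS <= 1e-14)
        stop("degenerate latent variance: W' Sigma_x W <= 0 ",
             "(rank-deficient data or zero weights)", call. = FALSE)
    A <- as.numeric(sigmaX %*% w) / sigmaS
    names(A) <- names(w)
    new("ActivationPattern", A = A, sigmaX = sigmaX, sigmaS = sigmaS,
        weights = w, positive = model@positive, negative = model@negative)
}

#' Rank brain regions by activation-pattern magnitude
#'
#' Orders regions by decreasing |A|; ties keep the declared region order
#' (stable sort), and the top region is flagged as the nominated
#' discriminator.
#'
#' @param pattern an \linkS4class{ActivationPattern}.
#' @return data.frame with columns \code{rank}, \code{region},
#'   \code{activation}, \code{absActivation}, \code{nominated}.
#' @export
rankRegions <- function(pattern) {
    stopIfNot(is(pattern, "ActivationPattern"),
              "pattern must be an ActivationPattern")
    A <- activation(pattern)
    stopIfNot(all(is.finite(A)), "non-finite activation pattern")
    o <- order(-abs(A))              # base order() is stable on ties
    data.frame(rank = seq_along(A),
               region = names(A)[o],
               activation = as.numeric(A[o]),
               absActivation = abs(as.numeric(A[o])),
               nominated = seq_along(A) == 1L,
               row.names = NULL)
}

#' Classify group pairs and map their activation patterns
#'
#' Full count-side analysis: standardize the whole cohort once, then for each
#' requested group pair fit the linear SVM on that pair's animals, transform
#' the weights into the forward-model activation pattern, and rank regions by
#' |A|. A joint table juxtaposes |A| across comparisons (the
#' activation-pattern scatter as a table) so regions contributing to several
#' discriminations can be read off.
#'
#' @param table a \linkS4class{CellCountTable} containing all named groups.
#' @param comparisons list of length-2 character vectors
#'   \code{c(positive, negative)}.
#' @param C SVM regularization constant.
#' @return list with elements \code{comparisons} (named list of lists with
#'   \code{model}, \code{pattern}, \code{ranking}), \code{joint} (data.frame
#'   region x per-comparison |A|), and \code{nominated} (named character:
#'   top region per comparison).
#' @examples
#' sim <- simCellCounts(countSimConfig(effectSize = 2, seed = 11))
#' res <- classifyAndMap(sim$table)
#' res$nominated
#' @export
classifyAndMap <- function(table,
                           comparisons = list(c("R-ket", "saline"),
                                              c("R-ket", "S-ket")),
                           C = 1) {
    z <- standardizeCounts(table)
    out <- vector("list", length(comparisons))
    names(out) <- vapply(comparisons, paste, "", collapse = "_vs_")
    for (i in seq_along(comparisons)) {
        cmp <- comparisons[[i]]
        stopIfNot(length(cmp) == 2L, "each comparison is a pair of groups")
        model <- fitLinearSVM(z, positive = cmp[1], negative = cmp[2], C = C)
        pattern <- haufeActivation(model, z)
        out[[i]] <- list(model = model, pattern = pattern,
                         ranking = rankRegions(pattern))
    }
    joint <- data.frame(region = regionNames(z), row.names = NULL)
    for (nm in names(out))
        joint[[paste0("absA_", nm)]] <- abs(activation(out[[nm]]$pattern))
    nominated <- vapply(out, function(o) o$ranking$region[1], "")
    list(comparisons = out, joint = joint, nominated = nominated)
}
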