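# Deterministic soft-margin linear SVM, solved in the dual with an SMO
# (maximal-violating-pair) scheme. Written in-package so that the fit is
# exactly reproducible, exactly antisymmetric under label exchange, and
# checkable against an independent dual-QP reference.

# core dual solver: y in {-1, +1}, x is n x p
smoLinearSVM <- function(x, y, C, tol = 1e-10, maxIter = 100000L) {
    n <- nrow(x)
    K <- tcrossprod(x)                    # kernel matrix
    alpha <- numeric(n)
    grad <- rep(-1, n)                    # grad of 0.5 a'Qa - 1'a at a = 0
    it <- 0L
    converged <- FALSE
    repeat {
        yg <- -y * grad
        up <- (y > 0 & alpha < C - 1e-15) | (y < 0 & alpha > 1e-15)
        lo <- (y > 0 & alpha > 1e-15) | (y < 0 & alpha < C - 1e-15)
        if (!any(up) || !any(lo)) { converged <- TRUE; break }
        iUp <- which(up)[which.max(yg[up])]
        iLo <- which(lo)[which.min(yg[lo])]
        m <- yg[iUp]; M <- yg[iLo]
        if (m - M < tol) { converged <- TRUE; break }
        if (it >= maxIter) break
        a2 <- K[iUp, iUp] + K[iLo, iLo] - 2 * K[iUp, iLo]
        if (a2 <= 0) a2 <- 1e-12
        delta <- (m - M) / a2
        # constraint-preserving step: alpha_iUp += y_iUp d, alpha_iLo -= y_iLo d
        dmax <- if (y[iUp] > 0) C - alpha[iUp] else alpha[iUp]
        dmax <- min(dmax, if (y[iLo] > 0) alpha[iLo] else C - alpha[iLo])
        delta <- min(delta, dmax)
        alpha[iUp] <- alpha[iUp] + y[iUp] * delta
        alpha[iLo] <- alpha[iLo] - y[iLo] * delta
        # d(alpha)_iUp = y_iUp delta, d(alpha)_iLo = -y_iLo delta, y_i^2 = 1
        grad <- grad + delta * y * (K[, iUp] - K[, iLo])
        it <- it + 1L
    }
    w <- as.numeric(crossprod(x, alpha * y))
    free <- alpha > 1e-8 * C & alpha < C * (1 - 1e-8)
    b <- if (any(free)) {
        mean(y[free] - x[free, , drop = FALSE] %*% w)
    } else {
        yg <- -y * grad
        up <- (y > 0 & alpha < C - 1e-15) | (y < 0 & alpha > 1e-15)
        lo <- (y > 0 & alpha > 1e-15) | (y < 0 & alpha < C - 1e-15)
        -(max(yg[up], -Inf) + min(yg[lo], Inf)) / 2
    }
    obj <- 0.5 * sum(alpha * y * (K %*% (alpha * y))) - sum(alpha)
    list(alpha = alpha, w = w, b = as.numeric(b), iterations = it,
         converged = converged, dualObjective = obj)
}

#' Fit a two-class soft-margin linear SVM
#'
#' Solves the standard dual problem
#' \deqn{\min_\alpha \tfrac12 \alpha' Q \alpha - 1'\alpha,\quad
#'       y'\alpha = 0,\ 0 \le \alpha_i \le C,}
#' with a deterministic maximal-violating-pair SMO (no random initialization),
#' and returns weights W, intercept and diagnostics. Inputs are expected to be
#' z-scored already; no further feature scaling is applied.
#'
#' For a \linkS4class{ZScoreMatrix} the animals of the two named groups are
#' selected (positive class mapped to +1) and the fit runs on those rows.
#'
#' @param x numeric matrix (samples x features) or a
#'   \linkS4class{ZScoreMatrix}.
#' @param y for the matrix method: labels, two levels; coerced so that
#'   \code{positive} maps to +1.
#' @param positive,negative class labels. For the matrix method they default
#'   to the second and first factor level of \code{y}.
#' @param C soft-margin regularization constant (> 0).
#' @param tol KKT-gap convergence tolerance of the dual solver.
#' @param maxIter cap on pairwise updates.
#' @param ... passed through.
#' @return a \linkS4class{ClassifierModel}.
#' @examples
#' x <- matrix(c(-1, 1), ncol = 1)
#' fitLinearSVM(x, c("a", "b"), positive = "b", C = 1e6)
#' @export
setGeneric("fitLinearSVM",
           function(x, ...) standardGeneric("fitLinearSVM"))

#' @rdname fitLinearSVM
#' @export
setMethod("fitLinearSVM", "matrix",
    function(x, y, positive = NULL, negative = NULL, C = 1,
             tol = 1e-10, maxIter = 100000L, ...) {
        stopIfNot(is.numeric(C) && C > 0, "C must be > 0")
        stopIfNot(all(is.finite(x)), "non-finite feature values")
        y <- as.character(y)
        lev <- unique(y)
        stopIfNot(length(lev) == 2L,
                  "exactly two classes required, got %d", length(lev))
        if (is.null(negative)) negative <- lev[lev != ifelse(is.null(positive),
                                                             lev[2], positive)][1]
        if (is.null(positive)) positive <- lev[lev != negative][1]
        stopIfNot(all(sort(c(positive, negative)) == sort(lev)),
                  "positive/negative must name the two classes present")
        yy <- ifelse(y == positive, 1, -1)
        stopIfNot(sum(yy > 0) >= 2L && sum(yy < 0) >= 2L || nrow(x) <= 3L,
                  "each class needs at least 2 samples")
        fit <- smoLinearSVM(x, yy, C = C, tol = tol, maxIter = maxIter)
        pred <- sign(as.numeric(x %*% fit$w) + fit$b)
        wn <- sqrt(sum(fit$w^2))
        w <- fit$w
        names(w) <- colnames(x)
        new("ClassifierModel", weights = w, intercept = fit$b,
            positive = positive, negative = negative, cost = C,
            alpha = fit$alpha, rowIndex = seq_len(nrow(x)),
            trainAccuracy = mean(pred == yy),
            margin = if (wn > 0) 2 / wn else Inf,
            dualObjective = fit$dualObjective,
            iterations = fit$iterations, converged = fit$converged)
    })

#' @rdname fitLinearSVM
#' @export
setMethod("fitLinearSVM", "ZScoreMatrix",
    function(x, positive, negative, C = 1, tol = 1e-10,
             maxIter = 100000L, ...) {
        g <- as.character(groups(x))
        stopIfNot(all(c(positive, negative) %in% g),
                  "groups %s/%s not both present", positive, negative)
        idx <- which(g %in% c(positive, negative))
        stopIfNot(sum(g == positive) >= 2L && sum(g == negative) >= 2L,
                  "each class needs at least 2 animals")
        model <- fitLinearSVM(zscores(x)[idx, , drop = FALSE], g[idx],
                              positive = positive, negative = negative,
                              C = C, tol = tol, maxIter = maxIter)
        model@rowIndex <- as.integer(idx)
        model
    })

#' Decision values of a fitted linear SVM
#'
#' @param object a \linkS4class{ClassifierModel}.
#' @param newdata samples x features matrix.
#' @return numeric decision values \code{newdata \%*\% W + b}; positive means
#'   the positive class.
#' @export
decisionValues <- function(object, newdata) {
    as.numeric(newdata %*% object@weights) + object@intercept
}
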