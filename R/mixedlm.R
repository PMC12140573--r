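## Random-intercept Gaussian linear mixed model, estimated by (restricted)
## maximum likelihood profiled over the variance ratio lambda = tau^2/sigma^2.
##
## All computations run on sufficient statistics: with W = [1, X] and a
## subject indicator Z, V* = I + lambda Z Z' has the closed-form inverse
## V*^-1 = I - Z diag(c) Z', c_j = lambda / (1 + lambda n_j), so the GLS
## normal equations need only W'W, W'y, y'y and per-subject column sums.
## This makes fitting O(p^3) per likelihood evaluation, independent of n,
## which is what allows effective-connectivity estimation (48 targets x 50
## bootstrap resamples) to share one crossproduct per resample.

## Build sufficient statistics from raw data.
lmmStats <- function(X, y, subject) {
    W <- cbind(`(Intercept)` = 1, X)
    g <- as.character(subject)
    S <- rowsum(W, g)                      # J x (p+1) column sums per subject
    sy <- rowsum(y, g)[, 1L]
    list(G = crossprod(W), gy = crossprod(W, y)[, 1L], yy = sum(y * y),
         S = S, sy = sy, nj = rowsum(rep(1, length(y)), g)[, 1L],
         n = length(y), groups = rownames(S))
}

## Core profiled solver on sufficient statistics.
## Returns the fit at the optimal lambda (lambda fixed to 0 when J < 2).
lmmCore <- function(st, REML = TRUE, ridge = 0) {
    p1 <- nrow(st$G)
    n <- st$n
    J <- length(st$nj)
    pen <- diag(c(0, rep(ridge, p1 - 1L)), p1)

    eval_at <- function(lambda) {
        cj <- lambda / (1 + lambda * st$nj)
        M <- st$G - crossprod(st$S, st$S * cj)
        m <- st$gy - colSums(st$S * (cj * st$sy))
        q <- st$yy - sum(cj * st$sy^2)
        R <- tryCatch(chol(M + pen), error = function(e) NULL)
        if (is.null(R) ||
            min(diag(R))^2 < .Machine$double.eps * max(diag(M)) * p1)
            return(NULL)                # singular / numerically rank-deficient
        beta <- backsolve(R, backsolve(R, m, transpose = TRUE))
        rss <- max(q - 2 * sum(beta * m) + sum(beta * (M %*% beta)), 1e-300)
        ldV <- sum(log1p(lambda * st$nj))
        crit <- if (REML)
            max(n - p1, 1L) * log(rss) + ldV + 2 * sum(log(diag(R)))
        else n * log(rss) + ldV
        list(crit = crit, beta = beta, rss = rss, M = M, cj = cj, R = R)
    }

    sol0 <- eval_at(0)
    if (is.null(sol0)) {                    # singular even at lambda = 0
        ridge <- if (ridge > 0) ridge * 100 else 1e-6
        warning("singular design: applying ridge penalty ", ridge)
        return(lmmCore(st, REML = REML, ridge = ridge))
    }
    lambda <- 0
    sol <- sol0
    if (J >= 2L) {
        f <- function(loglam) {
            s <- eval_at(exp(loglam))
            if (is.null(s)) Inf else s$crit
        }
        opt <- stats::optimize(f, interval = c(-15, 12), tol = 1e-6)
        if (is.finite(opt$objective) && opt$objective < sol0$crit) {
            lambda <- exp(opt$minimum)
            sol <- eval_at(lambda)
        }
    }
    sigma2 <- sol$rss / if (REML) max(n - p1, 1L) else n
    ## BLUPs from per-subject mean residuals
    resSum <- st$sy - as.numeric(st$S %*% sol$beta)
    u <- (lambda * st$nj / (1 + lambda * st$nj)) * (resSum / st$nj)
    names(u) <- st$groups
    Minv <- chol2inv(sol$R)
    se <- sqrt(pmax(diag(Minv), 0) * sigma2)
    list(beta = sol$beta, u = u, sigma2 = sigma2, tau2 = lambda * sigma2,
         lambda = lambda, se = se, ridge = ridge)
}

#' Fit a Gaussian random-intercept linear mixed model
#'
#' Fits \eqn{y_{ij} = \beta_0 + \beta_1 X_{ij} + u_j + e_{ij}} with
#' \eqn{e_{ij} \sim N(0,\sigma_e^2)} and one random intercept
#' \eqn{u_j \sim N(0,\tau^2)} per subject, by REML (default) or ML, profiling
#' the likelihood over the variance ratio.  The fit is deterministic given the
#' data.  With a single subject the model degenerates to ordinary least
#' squares (\eqn{\hat\tau^2 = 0}); a singular design triggers a small ridge
#' penalty (1e-6) with a warning.
#'
#' @param X numeric matrix of predictors (trials x p), or `NULL` for an
#'   intercept-only model.  Columns should be named.
#' @param y numeric response vector.
#' @param subject subject identifier per observation.
#' @param REML logical, use restricted maximum likelihood (default `TRUE`).
#' @return A [MixedModelFit-class] object.
#' @examples
#' X <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
#' y <- 1 + X %*% c(2, -1, 0.5) + rnorm(100, sd = 0.1)
#' fit <- fitLMM(X, as.numeric(y), subject = rep(c("s1", "s2"), 50))
#' coef(fit)
#' @export
fitLMM <- function(X, y, subject, REML = TRUE) {
    y <- as.numeric(y)
    if (is.null(X)) X <- matrix(numeric(0), length(y), 0L)
    X <- as.matrix(X)
    if (is.null(colnames(X)) && ncol(X) > 0L)
        colnames(X) <- paste0("x", seq_len(ncol(X)))
    if (length(y) < 2L) stop("at least 2 observations are required")
    if (nrow(X) != length(y) || length(subject) != length(y))
        stop("X, y and subject must agree in length")
    if (anyNA(X) || anyNA(y)) stop("missing values are not supported")
    st <- lmmStats(X, y, subject)
    core <- lmmCore(st, REML = REML)
    beta <- core$beta[-1L]
    names(beta) <- colnames(X)
    se <- core$se
    names(se) <- c("(Intercept)", colnames(X))
    new("MixedModelFit", beta0 = core$beta[1L], beta = beta, u = core$u,
        sigma2 = core$sigma2, tau2 = core$tau2, se = se,
        nObs = length(y), REML = REML, ridge = core$ridge)
}

#' Predict from a random-intercept model fit
#'
#' \eqn{\hat y = \beta_0 + \beta_1 X + u_j} for subjects seen in training;
#' unseen subjects use \eqn{u = 0} (the population-level prediction).
#'
#' @param fit a [MixedModelFit-class].
#' @param X predictor matrix with the training predictors, in training order.
#' @param subject subject identifier per row of `X`.
#' @return numeric vector of predictions.
#' @export
predictLMM <- function(fit, X, subject) {
    p <- length(fit@beta)
    if (p == 0L) {
        eta <- rep(fit@beta0, length(subject))
    } else {
        X <- as.matrix(X)
        if (ncol(X) != p)
            stop("predictor mismatch: expected ", p, " columns")
        if (!is.null(colnames(X)) &&
            !identical(colnames(X), names(fit@beta)))
            stop("predictor mismatch: column names differ from training order")
        eta <- fit@beta0 + as.numeric(X %*% fit@beta)
    }
    u <- fit@u[as.character(subject)]
    u[is.na(u)] <- 0
    as.numeric(eta + u)
}

#' @describeIn fitLMM fixed-effect coefficients (intercept first).
#' @param object,... a `MixedModelFit` (S4 method dispatch).
#' @export
setMethod("coef", "MixedModelFit", function(object, ...) {
    c("(Intercept)" = object@beta0, object@beta)
})

#' @describeIn fitLMM `predict` method delegating to [predictLMM()]
#'   (arguments `X`, `subject`).
#' @param newdata predictor matrix.
#' @param subject subject ids for prediction rows.
#' @export
setMethod("predict", "MixedModelFit", function(object, newdata, subject, ...) {
    predictLMM(object, newdata, subject)
})

setMethod("show", "MixedModelFit", function(object) {
    cat(sprintf("MixedModelFit: %d obs, %d predictors, %d subjects (%s)\n",
                object@nObs, length(object@beta), length(object@u),
                if (object@REML) "REML" else "ML"))
    cat(sprintf("  sigma_e^2 = %.4g, tau^2 = %.4g\n",
                object@sigma2, object@tau2))
})

#' Serialize / restore a model fit as JSON
#'
#' @param fit a [MixedModelFit-class].
#' @param file optional path; if `NULL` the JSON string is returned.
#' @return `lmmToJSON` returns the path (invisibly) or the JSON string;
#'   `lmmFromJSON` returns a `MixedModelFit`.
#' @export
lmmToJSON <- function(fit, file = NULL) {
    obj <- list(beta0 = fit@beta0, beta = as.list(fit@beta),
                u = as.list(fit@u), sigma2 = fit@sigma2, tau2 = fit@tau2,
                se = as.list(fit@se), nObs = fit@nObs, REML = fit@REML,
                ridge = fit@ridge)
    js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
    if (is.null(file)) return(as.character(js))
    writeLines(js, file)
    invisible(file)
}

#' @rdname lmmToJSON
#' @export
lmmFromJSON <- function(file) {
    o <- jsonlite::fromJSON(file)
    new("MixedModelFit", beta0 = o$beta0, beta = unlist(o$beta),
        u = if (length(o$u)) unlist(o$u) else stats::setNames(numeric(0), character(0)),
        sigma2 = o$sigma2, tau2 = o$tau2, se = unlist(o$se),
        nObs = as.integer(o$nObs), REML = o$REML, ridge = o$ridge)
}
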