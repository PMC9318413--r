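#' Per-patient segment indicator from leave-one-out group means
#'
#' Indicator of carrying the segment aberration: 1 iff the sum of squared
#' differences (over the filtration grid) between the patient's curve and
#' the leave-one-out test-group mean is strictly smaller than the distance
#' to the leave-one-out control-group mean; ties give 0.
#'
#' @param patientCurve,looTestMean,looCtrlMean
#'   \linkS4class{PersistenceCurve}s on one grid; the means are computed
#'   with the patient removed from whichever group contains them.
#' @return 0 or 1.
#' @export
segmentIndicator <- function(patientCurve, looTestMean, looCtrlMean) {
    ssT <- curveDistance(patientCurve, looTestMean, "ss")
    ssC <- curveDistance(patientCurve, looCtrlMean, "ss")
    as.integer(ssT < ssC)
}

#' Segment indicators for every patient of a cohort
#'
#' Vectorised builder over a patients x grid curve matrix: for each patient
#' the group means are recomputed with that patient removed from its own
#' group, then the [segmentIndicator()] rule is applied.
#'
#' @param curves patients x grid matrix (see [segmentCurves()]).
#' @param isTest logical test-group membership per row.
#' @return integer 0/1 vector, one entry per patient (named by rownames).
#' @export
segmentIndicators <- function(curves, isTest) {
    curves <- as.matrix(curves)
    isTest <- as.logical(isTest)
    n <- nrow(curves)
    sumT <- colSums(curves[isTest, , drop = FALSE])
    sumC <- colSums(curves[!isTest, , drop = FALSE])
    nT <- sum(isTest); nC <- n - nT
    out <- integer(n)
    for (i in seq_len(n)) {
        if (isTest[i]) {
            mt <- (sumT - curves[i, ]) / (nT - 1L)
            mc <- sumC / nC
        } else {
            mt <- sumT / nT
            mc <- (sumC - curves[i, ]) / (nC - 1L)
        }
        ssT <- sum((curves[i, ] - mt)^2)
        ssC <- sum((curves[i, ] - mc)^2)
        out[i] <- as.integer(ssT < ssC)
    }
    names(out) <- rownames(curves)
    out
}

#' Center-of-mass arm indicator
#'
#' Flags a patient whose mean log2 ratio over an arm falls outside a
#' one-sided Student-t confidence bound for the control-group arm mean:
#' gains use xbar > mu + t_alpha * sigma / sqrt(n), losses use
#' xbar < mu - t_alpha * sigma / sqrt(n) (t with n - 1 degrees of freedom).
#'
#' @param xbar patient's mean probe value on the arm (may be a vector).
#' @param mu,sigma control-group mean and standard deviation of the arm
#'   means.
#' @param n number of control patients behind \code{mu} and \code{sigma}.
#' @param direction "gain" or "loss".
#' @param alpha one-sided tail probability (default 0.05).
#' @return integer 0/1, same length as \code{xbar}.
#' @export
centerOfMassIndicator <- function(xbar, mu, sigma, n,
                                  direction = c("gain", "loss"),
                                  alpha = 0.05) {
    direction <- match.arg(direction)
    if (n < 2L) stop("need n >= 2 control patients")
    if (sigma < 0) stop("sigma must be nonnegative")
    t <- stats::qt(1 - alpha, df = n - 1L)
    half <- t * sigma / sqrt(n)
    as.integer(if (direction == "gain") xbar > mu + half
               else xbar < mu - half)
}

.glmAIC <- function(y, X, covs) {
    dat <- data.frame(y = y, X, check.names = FALSE)
    form <- if (length(covs))
        stats::as.formula(paste("y ~", paste(sprintf("`%s`", covs),
                                             collapse = " + ")))
    else y ~ 1
    fit <- suppressWarnings(stats::glm(form, family = stats::binomial(),
                                       data = dat))
    fit
}

#' Forward-selection logistic regression under AIC
#'
#' Starts from the intercept-only model and greedily adds the single
#' indicator covariate that most lowers AIC (= 2k - 2 ln Lhat, with k
#' counting all estimated coefficients including the intercept), stopping
#' when no addition lowers it. Small cohorts of binary indicators often
#' separate perfectly; such fits are kept (IRLS stops at its iteration cap,
#' so coefficients are large but finite) and flagged via the
#' \code{separated} slot.
#'
#' @param X data.frame or matrix of 0/1 indicator covariates (columns
#'   named).
#' @param y binary response (0/1, logical, or two-level factor).
#' @return A \linkS4class{LogisticModel}.
#' @export
fitForwardAIC <- function(X, y) {
    X <- as.data.frame(X, check.names = FALSE)
    if (!ncol(X)) stop("need at least one candidate covariate")
    if (is.factor(y)) y <- as.integer(y) - 1L
    y <- as.numeric(y)
    if (length(unique(y)) < 2L)
        stop("response must contain both classes")
    selected <- character(0)
    current <- .glmAIC(y, X, selected)
    repeat {
        rest <- setdiff(colnames(X), selected)
        if (!length(rest)) break
        trials <- lapply(rest, function(v) .glmAIC(y, X, c(selected, v)))
        aics <- vapply(trials, stats::AIC, numeric(1))
        best <- which.min(aics)
        if (aics[best] < stats::AIC(current) - 1e-8) {
            selected <- c(selected, rest[best])
            current <- trials[[best]]
        } else break
    }
    mu <- stats::fitted(current)
    separated <- length(selected) > 0 &&
        all(abs(mu - y) < 1e-6)
    new("LogisticModel", fit = current, covariates = selected,
        aic = stats::AIC(current),
        logLik = as.numeric(stats::logLik(current)),
        separated = separated)
}

#' Confusion matrix of a logistic classifier
#'
#' Predicted positive iff the fitted probability is >= \code{threshold}
#' (note the closed inequality: probability exactly 0.5 classifies
#' positive).
#'
#' @param model a \linkS4class{LogisticModel}.
#' @param X covariate data for prediction (must contain the model's
#'   covariates).
#' @param y true binary labels.
#' @param threshold classification threshold (default 0.5).
#' @return A \linkS4class{ClassificationSummary}.
#' @export
predictConfusion <- function(model, X, y, threshold = 0.5) {
    X <- as.data.frame(X, check.names = FALSE)
    missing <- setdiff(model@covariates, colnames(X))
    if (length(missing))
        stop("covariate column(s) missing from X: ",
             paste(missing, collapse = ", "))
    if (is.factor(y)) y <- as.integer(y) - 1L
    y <- as.numeric(y)
    p <- stats::predict(model@fit, newdata = X, type = "response")
    pos <- p >= threshold
    ClassificationSummary(tp = sum(pos & y == 1), fp = sum(pos & y == 0),
                          tn = sum(!pos & y == 0), fn = sum(!pos & y == 1))
}

#' Leave-one-out cross-validated mean squared error
#'
#' For each patient the whole forward-AIC selection is refit on the
#' remaining n - 1 patients and the held-out probability is scored as
#' (probability - y_i)^2; the mean over scored folds is returned. Folds
#' whose training response collapses to a single class are skipped with a
#' warning and counted in the \code{skipped} attribute.
#'
#' @param X indicator covariates (data.frame or matrix).
#' @param y binary response.
#' @return scalar MSE in [0, 1] with attribute \code{skipped}.
#' @export
loocvMSE <- function(X, y) {
    X <- as.data.frame(X, check.names = FALSE)
    if (is.factor(y)) y <- as.integer(y) - 1L
    y <- as.numeric(y)
    n <- length(y)
    if (n < 3L) stop("need at least 3 patients for LOOCV")
    errs <- rep(NA_real_, n)
    for (i in seq_len(n)) {
        yi <- y[-i]
        if (length(unique(yi)) < 2L) next
        m <- fitForwardAIC(X[-i, , drop = FALSE], yi)
        p <- stats::predict(m@fit, newdata = X[i, , drop = FALSE],
                            type = "response")
        errs[i] <- (p - y[i])^2
    }
    skipped <- sum(is.na(errs))
    if (skipped)
        warning(skipped, " fold(s) skipped (single-class training set)")
    structure(mean(errs, na.rm = TRUE), skipped = skipped)
}

#' Build the indicator matrix for a phenotype
#'
#' One column per selected segment (leave-one-out curve-similarity
#' indicators, [segmentIndicators()]) and, optionally, one per candidate
#' arm (center-of-mass indicators, [centerOfMassIndicator()], with the
#' control-group mean/sd of the patient arm means and direction chosen by
#' the sign of the test-group shift).
#'
#' @param pset a \linkS4class{CNProfileSet}.
#' @param phenotype test subtype.
#' @param segments data.frame of selected segments (rows of
#'   [runTAaCGH()] output, e.g. the set K from
#'   [maximalNonintersecting()]).
#' @param arms optional character vector of arm names (e.g. "17q") entering
#'   center-of-mass indicators.
#' @param exclude subtypes excluded from the control group.
#' @param kind,k,dim,s,nGrid curve parameters (as in [runTAaCGH()]).
#' @param alphaCM one-sided level of the center-of-mass t-interval.
#' @return list with \code{X} (data.frame of 0/1 indicators, one row per
#'   patient) and \code{y} (0/1 response: 1 = phenotype).
#' @export
indicatorMatrix <- function(pset, phenotype, segments,
                            arms = character(0), exclude = character(0),
                            kind = "lifespan", k = 2L, dim = 0L, s = 2L,
                            nGrid = 100L, alphaCM = 0.05) {
    groups <- splitTestControl(pset, phenotype, exclude)
    keep <- c(groups$test, groups$control)
    vals <- assay(pset)[, keep, drop = FALSE]
    isTest <- keep %in% groups$test
    X <- data.frame(row.names = keep, check.names = FALSE)
    for (i in seq_len(nrow(segments))) {
        sv <- vals[segments$FirstProbe[i]:segments$LastProbe[i], ,
                   drop = FALSE]
        curves <- .segmentCurveMatrix(sv, kind, k, dim, s, nGrid)
        X[[segments$Name[i]]] <- segmentIndicators(curves, isTest)
    }
    if (length(arms)) {
        rd <- probeData(pset)
        armKey <- paste0(rd$Chrom, rd$Arm)
        for (a in arms) {
            idx <- which(armKey == a)
            if (!length(idx)) stop("arm not found in probe panel: ", a)
            xbar <- colMeans(vals[idx, , drop = FALSE])
            mu <- mean(xbar[!isTest]); sg <- stats::sd(xbar[!isTest])
            dir <- if (mean(xbar[isTest]) >= mu) "gain" else "loss"
            X[[paste0(a, "CM")]] <- centerOfMassIndicator(
                xbar, mu, sg, n = sum(!isTest), direction = dir,
                alpha = alphaCM)
        }
    }
    list(X = X, y = as.numeric(isTest))
}

#' End-to-end subtype classifier
#'
#' Runs the association scan, keeps the maximal non-intersecting significant
#' segments K, builds the indicator matrix, fits the forward-AIC logistic
#' model and evaluates it (confusion matrix at threshold 0.5 and
#' leave-one-out cross-validated MSE).
#'
#' @inheritParams indicatorMatrix
#' @param nPerm,alpha,seed association-scan parameters (see [runTAaCGH()]).
#' @return list report: selected segments, model coefficients, AIC,
#'   confusion counts, accuracy, sensitivity, specificity, LOOCV MSE.
#' @export
classifySubtype <- function(pset, phenotype, exclude = character(0),
                            arms = character(0), kind = "lifespan", k = 2L,
                            dim = 0L, nPerm = 1000L, alpha = 0.05,
                            alphaCM = 0.05, nGrid = 100L, seed = 1L) {
    scan <- runTAaCGH(pset, phenotype, exclude = exclude, kind = kind,
                      k = k, dim = dim, nGrid = nGrid, nPerm = nPerm,
                      alpha = alpha, seed = seed)
    K <- maximalNonintersecting(scan)
    if (!nrow(K) && !length(arms))
        return(list(phenotype = phenotype, segments = character(0),
                    model = NULL,
                    note = "no significant segments; no model fitted"))
    ind <- indicatorMatrix(pset, phenotype, K, arms = arms,
                           exclude = exclude, kind = kind, k = k,
                           dim = dim, nGrid = nGrid, alphaCM = alphaCM)
    model <- fitForwardAIC(ind$X, ind$y)
    conf <- predictConfusion(model, ind$X, ind$y)
    mse <- suppressWarnings(loocvMSE(ind$X, ind$y))
    list(phenotype = phenotype, segments = K$Name,
         covariates = model@covariates,
         coefficients = as.list(stats::coef(model@fit)),
         aic = model@aic, separated = model@separated,
         confusion = list(tp = conf@tp, fp = conf@fp, tn = conf@tn,
                          fn = conf@fn),
         accuracy = accuracy(conf), sensitivity = sensitivity(conf),
         specificity = specificity(conf), loocvMSE = as.numeric(mse))
}
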