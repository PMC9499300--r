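#' Fit a logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit with Newton/IRLS updates, converging
#' when the largest coefficient change falls below `tol` (default 1e-8) or
#' after `max_iter` iterations.  When coefficients diverge beyond
#' `separation_limit` in absolute value — the signature of (quasi-)complete
#' separation — the model is refit with a small ridge penalty
#' (`lambda = 1e-4` on all non-intercept terms) and flagged.
#' Constant (zero-variance) predictor columns are dropped with a warning.
#'
#' @param formula Model formula; the response must be 0/1, logical, or a
#'   two-level factor.
#' @param data A data frame of predictors and response.
#' @param tol Convergence tolerance on `max |delta beta|`.
#' @param max_iter Maximum IRLS iterations (default 100).
#' @param separation_limit Absolute coefficient magnitude taken as evidence
#'   of separation (default 15).
#' @param lambda Ridge penalty used in the separation fallback.
#' @return An object of class `logit_fit` with coefficients, standard
#'   errors, log-likelihood trace, and `separation` flag.  Supports
#'   [tidy()], [glance()], [predict()].
#' @export
fit_logistic <- function(formula, data, tol = 1e-8, max_iter = 100,
                         separation_limit = 15, lambda = 1e-4) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) abort("response must be binary (0/1)")
  if (length(unique(y)) < 2) abort("response has a single class; cannot fit")
  X <- model.matrix(attr(mf, "terms"), mf)

  constant <- apply(X, 2, function(col) diff(range(col)) == 0)
  constant["(Intercept)"] <- FALSE
  if (any(constant)) {
    warn(paste0(
      "dropping constant predictor column(s): ",
      paste(colnames(X)[constant], collapse = ", ")
    ))
    X <- X[, !constant, drop = FALSE]
  }

  fit <- irls_logistic(X, y, tol, max_iter, penalty = 0)
  separation <- max(abs(fit$beta)) > separation_limit
  if (separation || fit$singular) {
    # singular Hessians (collinear designs) also need the ridge to proceed
    pen <- rep(lambda, ncol(X))
    pen[colnames(X) == "(Intercept)"] <- 0
    fit <- irls_logistic(X, y, tol, max_iter, penalty = pen)
  }

  se <- tryCatch(sqrt(diag(solve(fit$hessian))), error = function(e) rep(NA_real_, ncol(X)))
  structure(
    list(
      coefficients = setNames(fit$beta, colnames(X)),
      std_error = setNames(se, colnames(X)),
      loglik = fit$loglik,
      loglik_trace = fit$trace,
      iterations = fit$iterations,
      converged = fit$converged,
      separation = separation,
      nobs = length(y),
      terms = attr(mf, "terms"),
      xlevels = stats::.getXlevels(attr(mf, "terms"), mf)
    ),
    class = "logit_fit"
  )
}

irls_logistic <- function(X, y, tol, max_iter, penalty = 0) {
  p <- ncol(X)
  beta <- rep(0, p)
  if (length(penalty) == 1) penalty <- rep(penalty, p)
  P <- diag(penalty, nrow = p)
  trace <- numeric()
  converged <- FALSE
  singular <- FALSE
  iter <- 0
  log1pexp <- function(eta) ifelse(eta > 30, eta, log1p(exp(pmin(eta, 30))))
  loglik <- function(b) {
    eta <- drop(X %*% b)
    sum(y * eta - log1pexp(eta)) - 0.5 * sum(penalty * b^2)
  }
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X, X * w) + P
    score <- crossprod(X, y - mu) - penalty * beta
    delta <- tryCatch(drop(solve(H, score)), error = function(e) NULL)
    if (is.null(delta)) {
      singular <- TRUE
      break
    }
    beta <- beta + delta
    trace <- c(trace, loglik(beta))
    if (max(abs(delta)) < tol) {
      converged <- TRUE
      break
    }
  }
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  list(
    beta = beta, loglik = loglik(beta), trace = trace,
    iterations = iter, converged = converged, singular = singular,
    hessian = crossprod(X, X * w) + P
  )
}

#' @export
print.logit_fit <- function(x, ...) {
  cat("<logit_fit>", x$nobs, "observations,",
      x$iterations, "IRLS iterations",
      if (x$separation) "(separation: ridge fallback)" else "", "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.logit_fit <- function(object, ...) object$coefficients

#' @export
predict.logit_fit <- function(object, newdata,
                              type = c("response", "link"), ...) {
  type <- match.arg(type)
  tt <- stats::delete.response(object$terms)
  mf <- stats::model.frame(tt, newdata, xlev = object$xlevels)
  X <- model.matrix(tt, mf)
  X <- X[, names(object$coefficients), drop = FALSE]
  eta <- drop(X %*% object$coefficients)
  if (type == "response") plogis(eta) else eta
}

#' @export
tidy.logit_fit <- function(x, ...) {
  est <- x$coefficients
  se <- x$std_error
  z <- est / se
  tibble::tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(z),
    p.value = unname(2 * stats::pnorm(-abs(z)))
  )
}

#' @export
glance.logit_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik,
    nobs = x$nobs,
    iterations = x$iterations,
    converged = x$converged,
    separation = x$separation
  )
}

#' Area under the ROC curve by pair counting
#'
#' `AUC = (concordant pairs + 0.5 * tied pairs) / (n_pos * n_neg)`,
#' equivalently the Wilcoxon rank-sum statistic of the positive-class
#' scores; invariant to any strictly increasing score transform.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary labels (0/1 or logical).
#' @return The AUC in `[0, 1]`.
#' @export
evaluate_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) abort("labels must be binary")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) abort("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' @inheritParams evaluate_auc
#' @return A tibble of `threshold`, `tpr`, `fpr` stepping through the
#'   distinct score values from most to least extreme.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.numeric(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  thresholds <- c(Inf, unique(s))
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  tibble::tibble(
    threshold = thresholds,
    tpr = vapply(thresholds, function(t) sum(y == 1 & s >= t) / n1, numeric(1)),
    fpr = vapply(thresholds, function(t) sum(y == 0 & s >= t) / n0, numeric(1))
  )
}

#' Build the metastasis model frame
#'
#' Assembles, per patient, the logistic-model design: `log10(PSA + 1)`,
#' ISUP grade as an ordinal integer, a 0/1 indicator per model gene
#' (carrier of any supplied variant in that gene), and the binary
#' metastasis outcome.
#'
#' @param clinical Clinical tibble from [read_clinical()].
#' @param variants Variant tibble whose carriers define gene status (for
#'   the published model specification these are the VUS-containing
#'   variants of the PI3K-Akt gene set).
#' @param genes Character vector of model genes.
#' @return A tibble with columns `sample_id`, `log10_psa`, `isup`, one
#'   column per gene, and `metastasis` (0/1).
#' @export
build_model_frame <- function(clinical, variants, genes) {
  out <- tibble::tibble(
    sample_id = clinical$sample_id,
    log10_psa = log10(clinical$psa + 1),
    isup = as.integer(clinical$isup)
  )
  for (g in genes) {
    carriers <- unique(unlist(variants$carriers[variants$gene == g]))
    out[[g]] <- as.integer(out$sample_id %in% carriers)
  }
  out$metastasis <- as.integer(clinical$metastasis == "M1")
  out
}

#' Train on one cohort, evaluate on another, against a covariate-only control
#'
#' Fits the full model (clinical covariates plus gene indicators) and the
#' control model (clinical covariates only) on the training cohort, scores
#' both cohorts, and reports train and test AUC for each.
#'
#' @param train,test Model frames from [build_model_frame()] (identical
#'   columns).
#' @param features Character vector of full-model predictor columns.
#' @param control_features Character vector of control-model predictors
#'   (default `c("log10_psa", "isup")`).
#' @param outcome Name of the binary outcome column.
#' @return An object of class `model_eval` holding both fits, their AUCs
#'   and ROC points.
#' @export
cross_cohort_evaluate <- function(train, test, features,
                                  control_features = c("log10_psa", "isup"),
                                  outcome = "metastasis") {
  missing_tr <- setdiff(c(features, control_features, outcome), names(train))
  missing_te <- setdiff(c(features, control_features, outcome), names(test))
  if (length(missing_tr) > 0 || length(missing_te) > 0) {
    abort(paste0(
      "feature column(s) missing: ",
      paste(unique(c(missing_tr, missing_te)), collapse = ", ")
    ))
  }
  fit_one <- function(feats) {
    f <- stats::reformulate(feats, response = outcome)
    fit <- fit_logistic(f, train)
    s_train <- predict(fit, train)
    s_test <- predict(fit, test)
    list(
      fit = fit,
      auc_train = evaluate_auc(s_train, train[[outcome]]),
      auc_test = evaluate_auc(s_test, test[[outcome]]),
      roc_test = roc_points(s_test, test[[outcome]])
    )
  }
  structure(
    list(full = fit_one(features), control = fit_one(control_features)),
    class = "model_eval"
  )
}

#' @export
print.model_eval <- function(x, ...) {
  cat("<model_eval>\n")
  cat(sprintf("  full model:    AUC train %.3f, test %.3f\n",
              x$full$auc_train, x$full$auc_test))
  cat(sprintf("  control model: AUC train %.3f, test %.3f\n",
              x$control$auc_train, x$control$auc_test))
  invisible(x)
}

#' @export
glance.model_eval <- function(x, ...) {
  tibble::tibble(
    model = c("full", "control"),
    auc_train = c(x$full$auc_train, x$control$auc_train),
    auc_test = c(x$full$auc_test, x$control$auc_test),
    separation = c(x$full$fit$separation, x$control$fit$separation)
  )
}

#' @export
tidy.model_eval <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy(x$full$fit), model = "full"),
    dplyr::mutate(tidy(x$control$fit), model = "control")
  )
}
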