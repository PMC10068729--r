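#' Feature set of the screening logistic model
#'
#' The 15 model features: the 8 digital cognitive scores (5-WT total and
#' weighted totals, TMT A/B/B-A times, NCT good/wrong/total answers), age,
#' a female-sex indicator, the ordinal education level, and the four
#' comorbidity indicators.
#'
#' @return A character vector of cohort column names (with `sex` encoded
#'   downstream as a female indicator).
#' @export
logistic_features <- function() {
  c("fwt_total", "fwt_weighted", "tmt_a_s", "tmt_b_s", "tmt_delta_s",
    "nct_good", "nct_wrong", "nct_total", "age", "sex", "education_level",
    "hypertension", "diabetes", "cardiovascular", "depression")
}

# Numeric design matrix (without intercept) from a cohort data frame.
logistic_design <- function(data, features = logistic_features()) {
  missing_cols <- setdiff(features, names(data))
  if (length(missing_cols)) {
    abort(paste0("Missing feature column(s): ",
                 paste(missing_cols, collapse = ", "), "."),
          class = "cogsieve_validation_error")
  }
  cols <- lapply(features, function(f) {
    v <- data[[f]]
    if (f == "sex") as.numeric(v == "female") else as.numeric(v)
  })
  x <- do.call(cbind, cols)
  colnames(x) <- sub("^sex$", "sex_female", features)
  x
}

#' Ridge-penalized logistic regression by iteratively reweighted least squares
#'
#' Maximizes the Bernoulli log-likelihood minus `penalty / 2 * sum(beta^2)`
#' with the penalty applied to the slopes on internally standardized features
#' (never to the intercept); coefficients are reported back on the original
#' scale. The small default ridge guarantees a finite optimum under complete
#' separation and under exactly collinear features (the screening feature set
#' contains the identities NCT total = good + wrong and TMT B-A = B - A).
#' The fit is deterministic: Newton/IRLS with step-halving from a zero start.
#'
#' @param x Numeric feature matrix or data frame (rows = subjects). A cohort
#'   data frame is accepted and encoded via the packaged feature set.
#' @param y Logical/0-1 outcome with both classes present.
#' @param penalty Ridge weight on standardized slopes (default `1e-4`; `0`
#'   gives the unpenalized MLE when it exists).
#' @param max_iter,tol Convergence controls; non-convergence is an error
#'   carrying the iteration diagnostics.
#' @return An object of class `cogsieve_logit` with elements `coefficients`
#'   (original scale, intercept first), `penalty`, `converged`, `iterations`,
#'   `deviance`.
#' @export
#' @examples
#' fit <- fit_logistic(matrix(rnorm(60), 30), rbinom(30, 1, 0.5), penalty = 0)
#' coef(fit)
fit_logistic <- function(x, y, penalty = 1e-4, max_iter = 100L, tol = 1e-10) {
  if (is.data.frame(x) && all(logistic_features() %in% names(x))) {
    x <- logistic_design(x)
  } else if (is.data.frame(x)) {
    x <- as.matrix(x)
  }
  if (is.null(x)) x <- matrix(numeric(0), nrow = length(y), ncol = 0)
  y <- as.numeric(as.logical(y))
  if (any(is.na(x)) || any(is.na(y))) {
    abort("Features and labels must be complete (no missing values).",
          class = "cogsieve_validation_error")
  }
  if (length(unique(y)) < 2) {
    abort("Outcome labels must contain both classes.",
          class = "cogsieve_validation_error")
  }
  if (penalty < 0) abort("`penalty` must be nonnegative.")
  n <- length(y)
  p <- ncol(x)
  center <- if (p) colMeans(x) else numeric(0)
  scale_ <- if (p) apply(x, 2, sd) else numeric(0)
  scale_[!is.finite(scale_) | scale_ == 0] <- 1
  xs <- if (p) cbind(1, sweep(sweep(x, 2, center), 2, scale_, "/")) else
    matrix(1, n, 1)
  pen <- c(0, rep(penalty, p)) # intercept unpenalized
  beta <- numeric(p + 1)
  objective <- function(b) {
    eta <- drop(xs %*% b)
    # log(1 + exp(eta)) computed stably for large |eta|
    log1pe <- pmax(eta, 0) + log1p(exp(-abs(eta)))
    -sum(y * eta - log1pe) + sum(pen * b^2) / 2
  }
  obj <- objective(beta)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- drop(xs %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    g <- drop(crossprod(xs, y - mu)) - pen * beta
    h <- crossprod(xs, xs * w)
    diag(h) <- diag(h) + pen
    step <- tryCatch(solve(h, g), error = function(e) {
      abort(paste0("Logistic fit failed: singular information matrix ",
                   "(iteration ", iter, "). Use a positive ridge penalty ",
                   "for collinear features."),
            class = "cogsieve_fit_error")
    })
    # step-halving keeps the penalized deviance monotone
    lambda_step <- 1
    repeat {
      cand <- beta + lambda_step * step
      cand_obj <- objective(cand)
      if (cand_obj <= obj + 1e-12 || lambda_step < 1e-8) break
      lambda_step <- lambda_step / 2
    }
    moved <- max(abs(cand - beta))
    beta <- cand
    obj <- cand_obj
    if (moved < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    abort(sprintf(
      "Logistic fit did not converge in %d iterations (last step %.3e, penalized deviance %.6f).",
      max_iter, moved, 2 * obj), class = "cogsieve_fit_error")
  }
  slopes <- if (p) beta[-1] / scale_ else numeric(0)
  intercept <- beta[1] - sum(slopes * center)
  coefs <- c("(Intercept)" = unname(intercept),
             setNames(slopes, colnames(x)))
  structure(list(coefficients = coefs, penalty = penalty,
                 converged = converged, iterations = iter,
                 deviance = 2 * (obj - sum(pen * beta^2) / 2),
                 center = center, scale = scale_, n = n),
            class = "cogsieve_logit")
}

#' @export
coef.cogsieve_logit <- function(object, ...) object$coefficients

#' Predict screening probabilities from a fitted logistic model
#'
#' @param object A `cogsieve_logit` fit.
#' @param newdata Feature matrix or cohort data frame.
#' @param ... Unused.
#' @return Fitted probabilities in \[0, 1\].
#' @export
predict.cogsieve_logit <- function(object, newdata, ...) {
  if (is.data.frame(newdata) && all(logistic_features() %in% names(newdata))) {
    newdata <- logistic_design(newdata)
  } else if (is.data.frame(newdata)) {
    newdata <- as.matrix(newdata)
  }
  cf <- object$coefficients
  drop(plogis(cf[1] + newdata %*% cf[-1]))
}

#' @export
print.cogsieve_logit <- function(x, ...) {
  cat("Ridge-penalized logistic screening model\n")
  cat(sprintf("  n = %d, penalty = %g, converged in %d iterations\n",
              x$n, x$penalty, x$iterations))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
tidy.cogsieve_logit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @export
glance.cogsieve_logit <- function(x, ...) {
  tibble::tibble(n = x$n, deviance = x$deviance, penalty = x$penalty,
                 iterations = x$iterations, converged = x$converged)
}
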