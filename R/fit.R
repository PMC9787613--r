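# OLS on the log scale, fit statistics, backward stepwise AIC selection and
# variance-inflation screening.

#' Ordinary least squares fit of a leaf-mass design
#'
#' Fits `ln(leaf_mass)` on a design built by [build_design()] (or builds it
#' from a tree table and a spec). Standard errors use the unbiased residual
#' variance `RSS / (n - k)`; that same quantity is the model's `sigma2` used
#' by the Baskerville back-transformation correction unless
#' `sigma2_method = "ml"` selects `RSS / n`.
#'
#' Reported statistics: `adj_r2 = 1 - (RSS/(n-k)) / (TSS/(n-1))` with TSS
#' about the response mean, `rmse = sqrt(RSS/(n-k))`, Gaussian maximum
#' log-likelihood, and `aic = -2 logLik + 2 (k + 1)` (the residual variance
#' counts as a parameter, matching `stats::AIC` on `lm`). Absolute AIC
#' depends on this convention; only AIC differences between specs on the same
#' data are convention-free.
#'
#' @param data a `"leaf_design"` from [build_design()], or a tree table
#'   (traits attached) when `spec` is supplied.
#' @param spec a [model_spec()]; ignored when `data` is already a design.
#' @param sigma2_method `"unbiased"` (`RSS/(n-k)`, default) or `"ml"`
#'   (`RSS/n`) for the stored residual variance.
#' @return object of class `"leaf_model"`: coefficients, standard errors,
#'   `sigma2`, `n`, `k`, `rss`, `tss`, `fit_stats`
#'   (`adj_r2`, `rmse`, `aic`, `log_likelihood`), the spec, residuals and
#'   fitted log values, and the training ranges of the raw predictors.
#' @export
fit_ols <- function(data, spec = NULL, sigma2_method = c("unbiased", "ml")) {
  sigma2_method <- match.arg(sigma2_method)
  design <- if (inherits(data, "leaf_design")) data else {
    stopifnot(inherits(spec, "leaf_spec"))
    build_design(data, spec, response = TRUE)
  }
  X <- design$X
  y <- design$y
  if (is.null(y)) stop("design has no response; build with response = TRUE",
                       call. = FALSE)
  # crown classes absent from the data leave all-zero indicator columns;
  # their cell means are undefined, so they are not estimated (prediction for
  # such a class is then an explicit error, not an extrapolated average)
  zero_cols <- colSums(X != 0) == 0
  if (any(zero_cols)) X <- X[, !zero_cols, drop = FALSE]
  n <- nrow(X)
  k <- ncol(X)
  if (n <= k) stop(sprintf("n (%d) must exceed number of parameters (%d)",
                           n, k), call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < k) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):k]]
    stop("design is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm.fit(X, y)
  coefs <- fit$coefficients
  res <- fit$residuals
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  s2_unbiased <- rss / (n - k)
  XtX_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(s2_unbiased * diag(XtX_inv))
  names(se) <- colnames(X)
  loglik <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  fit_stats <- list(
    adj_r2 = 1 - s2_unbiased / (tss / (n - 1)),
    rmse = sqrt(s2_unbiased),
    aic = -2 * loglik + 2 * (k + 1),
    log_likelihood = loglik
  )
  ranges <- NULL
  if (!inherits(data, "leaf_design")) {
    fields <- unique(.term_field[design$spec$terms])
    ranges <- lapply(data[fields], range)
  }
  structure(list(
    spec = design$spec,
    coefficients = coefs,
    standard_errors = se,
    sigma2 = if (sigma2_method == "unbiased") s2_unbiased else rss / n,
    sigma2_method = sigma2_method,
    n = n, k = k, rss = rss, tss = tss,
    fit_stats = fit_stats,
    residuals = res,
    fitted_log = as.numeric(X %*% coefs),
    training_ranges = ranges,
    source = "fitted"
  ), class = "leaf_model")
}

#' @export
print.leaf_model <- function(x, ...) {
  cat(sprintf("<leaf_model %s | %s> n = %d, k = %d\n", x$spec$eq_id, x$source,
              x$n, x$k))
  tab <- data.frame(estimate = round(x$coefficients, 4),
                    se = round(x$standard_errors, 4))
  print(tab)
  fs <- x$fit_stats
  if (!is.null(fs))
    cat(sprintf("adj R2 = %.4f, RMSE(log) = %.4f, AIC = %.2f\n",
                fs$adj_r2, fs$rmse, fs$aic))
  invisible(x)
}

#' Fit statistics of a fitted model
#'
#' @param m a `"leaf_model"` from [fit_ols()].
#' @return list with `adj_r2`, `rmse`, `aic`, `log_likelihood`.
#' @export
model_stats <- function(m) {
  stopifnot(inherits(m, "leaf_model"))
  m$fit_stats
}

#' Backward stepwise term selection by AIC
#'
#' Starting from a full specification, repeatedly drops the single continuous
#' term whose removal most decreases AIC, until no removal decreases it. The
#' intercept block (crown-class cell means or the global constant) is
#' structural and never a removal candidate. Ties are broken by dropping the
#' term listed later in spec order, deterministically.
#'
#' @param data tree table with traits attached.
#' @param full_spec the starting [model_spec()].
#' @param sigma2_method passed to [fit_ols()].
#' @return list: `spec` (selected specification), `model` (its fit), `trace`
#'   (data.frame of every candidate evaluation: step, terms, aic, dropped).
#' @export
backward_stepwise <- function(data, full_spec,
                              sigma2_method = c("unbiased", "ml")) {
  sigma2_method <- match.arg(sigma2_method)
  stopifnot(inherits(full_spec, "leaf_spec"))
  spec_with_terms <- function(terms) {
    model_spec("custom", terms = terms,
               intercept_mode = full_spec$intercept_mode,
               mat_offset = full_spec$mat_offset)
  }
  current_terms <- full_spec$terms
  current_fit <- fit_ols(data, full_spec, sigma2_method)
  current_aic <- current_fit$fit_stats$aic
  trace <- list(data.frame(step = 0L, terms = paste(current_terms, collapse = "+"),
                           aic = current_aic, dropped = "", stringsAsFactors = FALSE))
  step <- 0L
  while (length(current_terms) > 1) {
    step <- step + 1L
    cand_aic <- rep(NA_real_, length(current_terms))
    for (i in seq_along(current_terms)) {
      cand_terms <- current_terms[-i]
      f <- fit_ols(data, spec_with_terms(cand_terms), sigma2_method)
      cand_aic[i] <- f$fit_stats$aic
      trace[[length(trace) + 1L]] <- data.frame(
        step = step, terms = paste(cand_terms, collapse = "+"),
        aic = cand_aic[i], dropped = current_terms[i], stringsAsFactors = FALSE)
    }
    if (min(cand_aic) >= current_aic) break
    # tie-break: later term in spec order, i.e. the largest index among minima
    best <- max(which(cand_aic == min(cand_aic)))
    current_terms <- current_terms[-best]
    current_aic <- min(cand_aic)
  }
  selected <- if (identical(current_terms, full_spec$terms)) full_spec else
    spec_with_terms(current_terms)
  list(spec = selected,
       model = fit_ols(data, selected, sigma2_method),
       trace = do.call(rbind, trace))
}

#' Variance-inflation screening
#'
#' Computes variance inflation factors for the continuous terms of a
#' specification, plus a generalized VIF for the crown-class intercept block.
#' A cell-means design makes the textbook VIF ill-posed, so the design is
#' re-expressed with a global constant and four crown-class dummies
#' (reference level = first crown class); each continuous term's VIF is then
#' `1 / (1 - R2_aux)` from regressing its column on all other columns, and
#' the crown-class block gets the determinant-based generalized VIF, reported
#' on the squared-comparable scale `(GVIF^(1/(2 df)))^2`. Perfectly collinear
#' columns yield `Inf`, not an error. This is a screening device (flag values
#' over ~5), not a reproduction target.
#'
#' @param data tree table with traits attached.
#' @param spec a [model_spec()].
#' @return named numeric vector: one VIF per continuous term and, in
#'   crown-class mode, a `crown_class` entry.
#' @export
vif_screen <- function(data, spec) {
  stopifnot(inherits(spec, "leaf_spec"))
  design <- build_design(data, spec, response = FALSE)
  X <- design$X
  cont <- spec$terms
  if (spec$intercept_mode == "crown_class") {
    cc_cols <- paste0("cc_", crown_classes)
    dummies <- X[, cc_cols[-1], drop = FALSE]  # reference = first level
    M <- cbind(dummies, X[, cont, drop = FALSE])
  } else {
    M <- X[, cont, drop = FALSE]
  }
  aux_r2 <- function(j) {
    yj <- M[, j]
    others <- cbind(1, M[, -j, drop = FALSE])
    f <- stats::lm.fit(others, yj)
    tssj <- sum((yj - mean(yj))^2)
    if (tssj == 0) return(1)
    1 - sum(f$residuals^2) / tssj
  }
  out <- numeric(0)
  for (term in cont) {
    r2 <- aux_r2(which(colnames(M) == term))
    out[term] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  if (spec$intercept_mode == "crown_class" && ncol(M) > length(cont)) {
    R <- suppressWarnings(stats::cor(M))
    g <- seq_len(ncol(M) - length(cont))
    detR <- det(R)
    if (!is.finite(detR) || detR <= 1e-14) {
      out["crown_class"] <- Inf
    } else {
      gvif <- det(R[g, g, drop = FALSE]) *
        det(R[-g, -g, drop = FALSE]) / detR
      df <- length(g)
      out["crown_class"] <- (gvif^(1 / (2 * df)))^2
    }
  }
  out
}
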