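# Error metrics and the three cross-validation schemes.

#' Prediction error metrics
#'
#' Computes the four comparison metrics on observed/predicted leaf-mass pairs
#' (both in kg, both strictly positive):
#' \itemize{
#'   \item MPE, mean percentage error `100/n * sum((p - a)/a)` — signed,
#'     positive = overestimation;
#'   \item MAE, mean absolute error `1/n * sum(|p - a|)` in kg;
#'   \item MAPE, mean absolute percentage error `100/n * sum(|p - a|/a)`;
#'   \item MAAPE, mean arctangent absolute percentage error
#'     `1/n * sum(atan(|p - a|/a))`.
#' }
#' MAAPE is reported in radians, bounded in `[0, pi/2)`. The formula is often
#' printed with a `x100` factor, but reported values in the 0.38-0.52 range
#' are only consistent with plain radians; set `times_100 = TRUE` to apply
#' the factor anyway.
#'
#' @param actual observed leaf mass (kg), all > 0.
#' @param predicted predicted leaf mass (kg), all > 0.
#' @param times_100 multiply MAAPE by 100 (default `FALSE`).
#' @return list of class `"leaf_metrics"`: `mpe`, `mae`, `mape`, `maape`, `n`.
#' @export
#' @examples
#' compute_metrics(c(1, 2), c(2, 2))  # MPE 50, MAE 0.5, MAPE 50, MAAPE 0.3927
compute_metrics <- function(actual, predicted, times_100 = FALSE) {
  if (length(actual) == 0) stop("empty prediction set", call. = FALSE)
  if (length(actual) != length(predicted))
    stop("actual and predicted differ in length", call. = FALSE)
  if (any(!is.finite(actual)) || any(actual <= 0))
    stop("observed masses must be positive and finite", call. = FALSE)
  if (any(!is.finite(predicted)) || any(predicted <= 0))
    stop("predicted masses must be positive and finite", call. = FALSE)
  rel <- (predicted - actual) / actual
  structure(list(
    mpe = mean(rel) * 100,
    mae = mean(abs(predicted - actual)),
    mape = mean(abs(rel)) * 100,
    maape = mean(atan(abs(rel))) * (if (times_100) 100 else 1),
    n = length(actual)
  ), class = "leaf_metrics")
}

#' @export
print.leaf_metrics <- function(x, ...) {
  cat(sprintf("n = %d | MPE %.2f%% | MAE %.3f kg | MAPE %.2f%% | MAAPE %.4f\n",
              x$n, x$mpe, x$mae, x$mape, x$maape))
  invisible(x)
}

# shared engine: fit on data[-unit], predict unit, for a unit labelling
cv_engine <- function(data, spec, unit, scheme, correct = TRUE,
                      sigma2_method = "unbiased", seed = NULL) {
  stopifnot(is.data.frame(data), inherits(spec, "leaf_spec"),
            length(unit) == nrow(data))
  if (!"leaf_mass" %in% names(data))
    stop("cross-validation needs observed leaf_mass", call. = FALSE)
  units <- unique(unit)
  if (length(units) < 2) stop("need at least 2 held-out units", call. = FALSE)
  pairs <- vector("list", length(units))
  per_unit <- vector("list", length(units))
  for (i in seq_along(units)) {
    u <- units[i]
    test_idx <- which(unit == u)
    train <- data[-test_idx, , drop = FALSE]
    test <- data[test_idx, , drop = FALSE]
    if (spec$intercept_mode == "crown_class") {
      missing_cc <- setdiff(unique(test$cc), unique(train$cc))
      if (length(missing_cc))
        stop(sprintf("training set for unit '%s' lacks crown class(es) %s present in its test set; stratify folds or use larger folds",
                     u, paste(missing_cc, collapse = ", ")), call. = FALSE)
    }
    m <- fit_ols(train, spec, sigma2_method)
    p <- predict_leaf_mass(m, test, correct = correct,
                           warn_extrapolation = FALSE)
    pairs[[i]] <- data.frame(unit = u, species = test$species,
                             actual = test$leaf_mass, predicted = as.numeric(p),
                             stringsAsFactors = FALSE)
    mt <- compute_metrics(test$leaf_mass, p)
    per_unit[[i]] <- data.frame(unit = u, n = mt$n,
                                mean_error = mean(p - test$leaf_mass),
                                mpe = mt$mpe, mae = mt$mae, mape = mt$mape,
                                maape = mt$maape, stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, pairs)
  structure(list(
    scheme = scheme,
    per_unit = do.call(rbind, per_unit),
    pooled = compute_metrics(pairs$actual, pairs$predicted),
    pairs = pairs,
    seed = seed
  ), class = "leaf_cv")
}

#' @export
print.leaf_cv <- function(x, ...) {
  cat(sprintf("<leaf_cv %s> %d units, %d held-out pairs\npooled: ",
              x$scheme, nrow(x$per_unit), nrow(x$pairs)))
  print(x$pooled)
  invisible(x)
}

#' k-fold cross-validation
#'
#' Randomly partitions the records into `k` near-equal folds (a seeded
#' uniform permutation cut into contiguous blocks; optionally stratified by
#' crown class), fits the model on each training set and predicts the
#' held-out fold with the Baskerville correction using that training fit's
#' residual variance. Per-fold and pooled (union of all held-out pairs,
#' tree-weighted) metrics are returned; output is reproducible for a given
#' seed.
#'
#' @param data tree table with traits attached and observed `leaf_mass`.
#' @param spec a [model_spec()].
#' @param k number of folds (>= 2; `k = n` gives leave-one-out).
#' @param seed integer seed for the fold assignment.
#' @param stratify stratify the permutation by crown class so each fold gets
#'   a share of every class (default `FALSE`).
#' @param correct apply Baskerville correction to held-out predictions.
#' @param sigma2_method passed to [fit_ols()].
#' @return object of class `"leaf_cv"`: `scheme`, `per_unit` metrics,
#'   `pooled` metrics, all held-out `pairs`, and `seed`.
#' @export
kfold_cv <- function(data, spec, k = 10, seed = 1, stratify = FALSE,
                     correct = TRUE, sigma2_method = "unbiased") {
  n <- nrow(data)
  stopifnot(k >= 2, k <= n)
  fold <- integer(n)
  withr::with_seed(seed, {
    if (stratify) {
      for (lev in unique(data$cc)) {
        idx <- which(data$cc == lev)
        fold[idx[sample.int(length(idx))]] <-
          rep_len(seq_len(k), length(idx))
      }
    } else {
      perm <- sample.int(n)
      sizes <- rep(n %/% k, k) + c(rep(1, n %% k), rep(0, k - n %% k))
      fold[perm] <- rep(seq_len(k), times = sizes)
    }
  })
  cv_engine(data, spec, unit = paste0("fold", fold), scheme = "kfold",
            correct = correct, sigma2_method = sigma2_method, seed = seed)
}

#' Leave-one-species-out cross-validation
#'
#' For each species in turn, refits the model on all other species' records
#' and predicts the held-out species from its published trait values. This
#' measures transferability: how the model performs for a species that
#' contributed no calibration data. Fully deterministic. Per-species rows
#' report `n`, signed mean error (kg, predicted minus observed), MPE and
#' MAPE (plus MAE and MAAPE); pooled metrics use the union of held-out pairs.
#'
#' @inheritParams kfold_cv
#' @return a `"leaf_cv"` object (`scheme = "loso"`).
#' @export
loso_cv <- function(data, spec, correct = TRUE, sigma2_method = "unbiased") {
  if (length(unique(data$species)) < 2)
    stop("leave-one-species-out needs at least 2 species", call. = FALSE)
  cv_engine(data, spec, unit = data$species, scheme = "loso",
            correct = correct, sigma2_method = sigma2_method)
}

#' Leave-one-group-out cross-validation
#'
#' Same contract as [loso_cv()] but holding out any grouping column (e.g.
#' `study_id` to leave one source study out at a time).
#'
#' @inheritParams kfold_cv
#' @param group_field name of the column in `data` defining the groups.
#' @return a `"leaf_cv"` object (`scheme = "logo"`).
#' @export
logo_cv <- function(data, spec, group_field = "study_id", correct = TRUE,
                    sigma2_method = "unbiased") {
  if (!group_field %in% names(data))
    stop(sprintf("group field '%s' not present", group_field), call. = FALSE)
  g <- data[[group_field]]
  if (anyNA(g) || any(!nzchar(as.character(g))))
    stop("missing group labels", call. = FALSE)
  cv_engine(data, spec, unit = as.character(g), scheme = "logo",
            correct = correct, sigma2_method = sigma2_method)
}

#' Per-tree percentage-error distribution
#'
#' Returns the individual-tree percentage errors `100 (p - a) / a` together
#' with summary location and shape statistics. With right-skewed errors (a
#' few large overestimates among many near-zero errors) the mean exceeds the
#' median; both are reported, neither asserted.
#'
#' @inheritParams compute_metrics
#' @return list: `errors_pct` (per tree), `median`, `mean`, `skewness`
#'   (moment coefficient `m3 / m2^1.5`).
#' @export
error_distribution <- function(actual, predicted) {
  if (length(actual) == 0) stop("empty prediction set", call. = FALSE)
  e <- 100 * (predicted - actual) / actual
  m <- mean(e)
  m2 <- mean((e - m)^2)
  skew <- if (m2 > 0) mean((e - m)^3) / m2^1.5 else 0
  list(errors_pct = e, median = stats::median(e), mean = m, skewness = skew)
}
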