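# Dominance-analysis (LMG) decomposition of model R2 into nonnegative
# per-predictor contributions, averaged over predictor orderings.

# columns for each importance group, against a global-constant baseline:
# the crown-class group contributes its 4 degrees of freedom beyond the
# constant (treatment coding), each continuous term its own column
importance_columns <- function(data, spec) {
  design <- build_design(data, spec, response = TRUE)
  groups <- list()
  if (spec$intercept_mode == "crown_class") {
    cc_cols <- paste0("cc_", crown_classes)
    groups$CC <- design$X[, cc_cols[-1], drop = FALSE]
  }
  for (term in spec$terms)
    groups[[term]] <- design$X[, term, drop = FALSE]
  list(groups = groups, y = design$y)
}

# plain R2 of y on constant + the given column blocks
r2_of_subset <- function(cols, y, tss) {
  X <- do.call(cbind, c(list(rep(1, length(y))), cols))
  f <- stats::lm.fit(X, y)
  1 - sum(f$residuals^2) / tss
}

#' Sequential R-squared increments for one predictor ordering
#'
#' Adds predictor groups one at a time, in the given order, on top of a
#' global-constant baseline, and reports each group's gain in plain
#' (unadjusted) R-squared. The increments telescope: they sum to the full
#' model's R-squared regardless of order.
#'
#' @param data tree table with traits attached and observed `leaf_mass`.
#' @param spec a [model_spec()].
#' @param ordering character vector: a permutation of the group names (the
#'   spec's terms plus `"CC"` in crown-class mode).
#' @return named numeric vector of R-squared increments, in entry order.
#' @export
sequential_r2 <- function(data, spec, ordering) {
  ic <- importance_columns(data, spec)
  if (!setequal(ordering, names(ic$groups)) ||
      length(ordering) != length(ic$groups))
    stop("ordering must be a permutation of: ",
         paste(names(ic$groups), collapse = ", "), call. = FALSE)
  y <- ic$y
  tss <- sum((y - mean(y))^2)
  r2_prev <- 0
  out <- numeric(length(ordering))
  for (i in seq_along(ordering)) {
    r2 <- r2_of_subset(ic$groups[ordering[seq_len(i)]], y, tss)
    out[i] <- r2 - r2_prev
    r2_prev <- r2
  }
  names(out) <- ordering
  out
}

#' Dominance-analysis relative importance
#'
#' Decomposes the model-explained variance into nonnegative contributions
#' from each predictor group by averaging each group's sequential R-squared
#' increment over orderings of the groups (the LMG / dominance-analysis
#' statistic), then normalizing the contributions to percentages of the full
#' model's R-squared.
#'
#' The crown-class intercept block participates as one group (`"CC"`, its 4
#' indicator degrees of freedom beyond a global constant); the baseline for
#' all subsets is the constant-only model. With `<= exact_threshold` groups
#' the exact subset-average identity is used (enumerate all subsets, weight
#' increments by how many orderings realize them); beyond that, orderings are
#' sampled uniformly with a mandatory seed.
#'
#' @param data tree table with traits attached and observed `leaf_mass`.
#' @param spec a [model_spec()].
#' @param groups optional named list partitioning the group names into
#'   super-groups (e.g. `list(size = c("lnDBH", "lnLCR"), ...)`); default is
#'   one group per term plus `"CC"`.
#' @param exact_threshold maximum number of groups for exact enumeration
#'   (default 10, i.e. 1024 subsets).
#' @param n_samples number of sampled orderings in sampled mode.
#' @param seed seed for sampled mode.
#' @return object of class `"leaf_importance"`: data.frame `shares` (`group`,
#'   `contribution` — raw R-squared units — and `share_pct`), `r2_full`,
#'   `method` (`"exact"` or `"sampled"`), and `n_orderings`/`n_samples`.
#' @export
dominance_importance <- function(data, spec, groups = NULL,
                                 exact_threshold = 10, n_samples = 10000,
                                 seed = NULL) {
  ic <- importance_columns(data, spec)
  base_names <- names(ic$groups)
  if (is.null(groups)) {
    groups <- as.list(base_names)
    names(groups) <- base_names
  }
  if (is.null(names(groups)))
    names(groups) <- vapply(groups, paste, character(1), collapse = "+")
  flat <- unlist(groups, use.names = FALSE)
  if (!setequal(flat, base_names) || length(flat) != length(base_names))
    stop("groups must partition: ", paste(base_names, collapse = ", "),
         call. = FALSE)
  cols <- lapply(groups, function(g)
    do.call(cbind, ic$groups[g]))
  y <- ic$y
  tss <- sum((y - mean(y))^2)
  g <- length(cols)
  gnames <- names(cols)

  if (g <= exact_threshold) {
    # exact LMG via the subset-average identity
    n_sub <- 2^g
    r2_cache <- numeric(n_sub)          # index = bitmask + 1
    for (mask in 0:(n_sub - 1)) {
      members <- which(bitwAnd(mask, 2^(seq_len(g) - 1)) > 0)
      r2_cache[mask + 1] <- if (length(members) == 0) 0 else
        r2_of_subset(cols[members], y, tss)
    }
    lfact <- lgamma(seq_len(g + 1))      # lfact[i+1] = log(i!)
    w <- function(s) exp(lfact[s + 1] + lfact[g - s] - lfact[g + 1])
    contrib <- numeric(g)
    for (j in seq_len(g)) {
      bit_j <- 2^(j - 1)
      acc <- 0
      for (mask in 0:(n_sub - 1)) {
        if (bitwAnd(mask, bit_j) > 0) next
        s <- sum(bitwAnd(mask, 2^(seq_len(g) - 1)) > 0)
        acc <- acc + w(s) * (r2_cache[bitwOr(mask, bit_j) + 1] -
                               r2_cache[mask + 1])
      }
      contrib[j] <- acc
    }
    method <- "exact"
    n_ord <- factorial(g)
  } else {
    if (is.null(seed))
      stop("sampled mode (groups > exact_threshold) requires a seed",
           call. = FALSE)
    contrib <- numeric(g)
    withr::with_seed(seed, {
      for (r in seq_len(n_samples)) {
        ord <- sample.int(g)
        r2_prev <- 0
        for (i in seq_along(ord)) {
          r2 <- r2_of_subset(cols[ord[seq_len(i)]], y, tss)
          contrib[ord[i]] <- contrib[ord[i]] + (r2 - r2_prev)
          r2_prev <- r2
        }
      }
    })
    contrib <- contrib / n_samples
    method <- "sampled"
    n_ord <- n_samples
  }
  r2_full <- r2_of_subset(cols, y, tss)
  shares <- data.frame(group = gnames, contribution = contrib,
                       share_pct = 100 * contrib / r2_full,
                       stringsAsFactors = FALSE)
  structure(list(shares = shares, r2_full = r2_full, method = method,
                 n_orderings = n_ord),
            class = "leaf_importance")
}

#' @export
print.leaf_importance <- function(x, ...) {
  cat(sprintf("<leaf_importance %s> model R2 = %.4f\n", x$method, x$r2_full))
  tab <- x$shares[order(-x$shares$share_pct), ]
  tab$share_pct <- round(tab$share_pct, 2)
  print(tab, row.names = FALSE)
  invisible(x)
}
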