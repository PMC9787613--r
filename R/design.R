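# Model specifications, crown-class coding and log-scale design matrices.

#' @rdname encode_crown_class
#' @format NULL
#' @export
crown_classes <- c("open_grown", "dominant", "codominant", "intermediate",
                   "overtopped")

# all continuous log-scale terms the model family knows about, in the
# canonical equation order
.all_terms <- c("lnDBH", "lnLL", "lnLCR", "lnSG", "lnSGp", "lnST",
                "lnMAT30", "lnMAP")
# which tree/trait column feeds each term
.term_field <- c(lnDBH = "dbh", lnLL = "ll", lnLCR = "lcr", lnSG = "sg_obs",
                 lnSGp = "sg_pub", lnST = "st", lnMAT30 = "mat", lnMAP = "map")

.eq_terms <- list(
  eq1 = c("lnDBH", "lnLL", "lnLCR", "lnSG", "lnST", "lnMAT30", "lnMAP"),
  eq2 = c("lnDBH", "lnLL", "lnLCR", "lnSGp", "lnST", "lnMAT30", "lnMAP"),
  eq3 = "lnDBH",
  eq4 = c("lnDBH", "lnLCR"),
  eq5 = c("lnDBH", "lnLCR", "lnMAT30", "lnMAP"),
  eq6 = c("lnDBH", "lnLL", "lnLCR", "lnST", "lnMAT30", "lnMAP")
)

#' Model specification for the trans-species leaf mass family
#'
#' Describes which log-scale terms enter the model and how the intercept is
#' coded. The six named equations range from diameter-only (`eq3`, single
#' global intercept) to the full eight-predictor models `eq1` (observed wood
#' specific gravity) and `eq2` (published specific gravity — the recommended
#' general-purpose model). All equations except `eq3` use the tree's crown
#' class as a variable intercept (five cell means, no global constant).
#'
#' @param eq_id one of `"eq1"`..`"eq6"`, or `"custom"` with explicit `terms`.
#' @param terms character vector of terms from
#'   `lnDBH, lnLL, lnLCR, lnSG, lnSGp, lnST, lnMAT30, lnMAP` (custom specs
#'   only; named equations fix their own terms).
#' @param intercept_mode `"crown_class"` (five cell-mean intercepts) or
#'   `"single"`; fixed by `eq_id` for named equations.
#' @param mat_offset constant (degC) added to mean annual temperature before
#'   the log transform, so that sites below 0 degC stay loggable. Default 30;
#'   recorded in fitted models so predictions reuse the training offset.
#' @return object of class `"leaf_spec"`.
#' @export
#' @examples
#' model_spec("eq2")
#' model_spec("custom", terms = c("lnDBH", "lnLCR"))
model_spec <- function(eq_id = "eq2", terms = NULL, intercept_mode = NULL,
                       mat_offset = 30) {
  eq_id <- match.arg(eq_id, c(names(.eq_terms), "custom"))
  if (eq_id != "custom") {
    if (!is.null(terms))
      stop("terms are fixed for named equations; use eq_id = 'custom'",
           call. = FALSE)
    terms <- .eq_terms[[eq_id]]
    intercept_mode <- if (eq_id == "eq3") "single" else "crown_class"
  } else {
    if (is.null(terms) || !length(terms))
      stop("custom spec needs at least one term", call. = FALSE)
    bad <- setdiff(terms, .all_terms)
    if (length(bad)) stop("unknown term(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    if (anyDuplicated(terms)) stop("duplicated terms", call. = FALSE)
    if (is.null(intercept_mode)) intercept_mode <- "crown_class"
    intercept_mode <- match.arg(intercept_mode, c("crown_class", "single"))
  }
  if (all(c("lnSG", "lnSGp") %in% terms))
    stop("a model uses observed SG or published SG, never both", call. = FALSE)
  stopifnot(is.numeric(mat_offset), length(mat_offset) == 1)
  structure(list(eq_id = eq_id, terms = terms,
                 intercept_mode = intercept_mode, mat_offset = mat_offset),
            class = "leaf_spec")
}

#' @export
print.leaf_spec <- function(x, ...) {
  cat(sprintf("<leaf_spec %s> ln(M_l) ~ %s | intercept: %s | MAT offset: +%g\n",
              x$eq_id, paste(x$terms, collapse = " + "), x$intercept_mode,
              x$mat_offset))
  invisible(x)
}

# accept labels (case-insensitive, 'suppressed' alias for overtopped) or
# integer codes 1-5 (1 = overtopped ... 5 = open grown); returns canonical
# labels, NA where unrecognized
parse_crown_class <- function(x, cc_codes = "auto") {
  x <- trimws(as.character(x))
  key <- gsub("[ -]+", "_", tolower(x))
  key[key == "suppressed"] <- "overtopped"
  out <- ifelse(key %in% crown_classes, key, NA_character_)
  if (!identical(cc_codes, FALSE)) {
    code_levels <- rev(crown_classes)  # 1 = overtopped ... 5 = open_grown
    code <- suppressWarnings(as.integer(x))
    usable <- !is.na(code) & code >= 1 & code <= 5
    out[is.na(out) & usable] <- code_levels[code[is.na(out) & usable]]
  }
  out
}

#' Crown-class indicator coding
#'
#' Encodes crown-class labels as five 0/1 indicator columns in the fixed
#' level order `open_grown, dominant, codominant, intermediate, overtopped`
#' (cell means: each row has exactly one 1 and there is no global constant).
#' `"suppressed"` is accepted as an alias for `"overtopped"`.
#'
#' @param cc character vector of crown-class labels (or 1-5 integer codes,
#'   1 = overtopped ... 5 = open grown).
#' @return numeric matrix with `length(cc)` rows and five columns named
#'   `cc_open_grown` ... `cc_overtopped`.
#' @export
#' @examples
#' encode_crown_class(c("open_grown", "suppressed"))
encode_crown_class <- function(cc) {
  lab <- parse_crown_class(cc)
  if (anyNA(lab))
    stop("unknown crown class: ",
         paste(unique(cc[is.na(lab)]), collapse = ", "), call. = FALSE)
  m <- outer(lab, crown_classes, "==") * 1
  colnames(m) <- paste0("cc_", crown_classes)
  rownames(m) <- NULL
  m
}

#' Build the log-scale design matrix for a model specification
#'
#' Constructs the response `ln(leaf_mass)` and design matrix for a tree table
#' (with traits attached, see [attach_traits()]). Each term `lnX` is the
#' natural log of its source field; `lnMAT30` is `ln(mat + mat_offset)`.
#' Column order is deterministic: the intercept block first (five crown-class
#' indicators, or a single constant), then terms in spec order. Rows are kept
#' in input order.
#'
#' @param data tree table with any trait columns the spec needs (`ll`, `st`,
#'   `sg_pub` from [attach_traits()]; `sg_obs` for `eq1`).
#' @param spec a [model_spec()].
#' @param response if `TRUE` (fitting context) `leaf_mass` is required and
#'   returned as the log response; set `FALSE` for prediction tables.
#' @return list of class `"leaf_design"`: `X` (matrix), `y` (log response or
#'   `NULL`), `spec`, `cc` (canonical labels, or `NULL` in single-intercept
#'   mode).
#' @export
build_design <- function(data, spec, response = TRUE) {
  stopifnot(inherits(spec, "leaf_spec"), is.data.frame(data))
  n <- nrow(data)
  cols <- list()
  need_pos <- function(v, what, rows_shift = 0) {
    bad <- which(!is.finite(v) | v <= 0)
    if (length(bad))
      stop(sprintf("%s must be positive and finite; offending row(s): %s",
                   what, paste(utils::head(bad, 10), collapse = ", ")),
           call. = FALSE)
  }
  for (term in spec$terms) {
    f <- .term_field[[term]]
    if (!f %in% names(data) || all(is.na(data[[f]])))
      stop(sprintf("field '%s' required by term %s is missing", f, term),
           call. = FALSE)
    v <- data[[f]]
    if (anyNA(v))
      stop(sprintf("field '%s' has missing values in row(s): %s", f,
                   paste(utils::head(which(is.na(v)), 10), collapse = ", ")),
           call. = FALSE)
    if (term == "lnMAT30") {
      v <- v + spec$mat_offset
      need_pos(v, sprintf("mat + %g", spec$mat_offset))
    } else {
      need_pos(v, f)
    }
    cols[[term]] <- log(v)
  }
  if (spec$intercept_mode == "crown_class") {
    icpt <- encode_crown_class(data$cc)
    cc_lab <- parse_crown_class(data$cc)
  } else {
    icpt <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
    cc_lab <- NULL
  }
  X <- cbind(icpt, do.call(cbind, cols))
  colnames(X) <- c(colnames(icpt), names(cols))
  y <- NULL
  if (response) {
    if (!"leaf_mass" %in% names(data) || anyNA(data$leaf_mass))
      stop("leaf_mass is required (and must be complete) to build a fitting design",
           call. = FALSE)
    need_pos(data$leaf_mass, "leaf_mass")
    y <- log(data$leaf_mass)
  }
  structure(list(X = X, y = y, spec = spec, cc = cc_lab),
            class = "leaf_design")
}
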