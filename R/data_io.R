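# Reading, validating and writing flat tree-record tables.

# canonical internal column names and the default external CSV header
.canonical_cols <- c(tree_id = "tree_id", species = "species", dbh = "dbh_cm",
                     lcr = "lcr", cc = "crown_class", sg_obs = "sg_obs",
                     leaf_mass = "leaf_mass_kg", mat = "mat_c", map = "map_mm",
                     study_id = "study_id")
.required_cols <- c("species", "dbh", "lcr", "cc")
.numeric_cols <- c("dbh", "lcr", "sg_obs", "leaf_mass", "mat", "map")

#' Read and validate a tree-record table
#'
#' Reads a delimited text file (CSV with header by default) of individual
#' tree records, validates each row against the record invariants and
#' returns the valid rows in input order with canonical column names.
#' Rows violating an invariant (e.g. `lcr > 1`, `dbh <= 0`, unknown crown
#' class) are rejected, with row-indexed diagnostics attached as the
#' `"rejected"` attribute. The as-read text tokens of the numeric fields are
#' kept in the `"raw"` attribute so that [filter_min_sigfigs()] can assess
#' recording precision, which binary numerics cannot preserve.
#'
#' Record invariants: `dbh > 0`; `0 < lcr <= 1`; `map > 0`; `mat > -30`
#' (so `mat + 30 > 0` for the log transform); `leaf_mass > 0` and
#' `sg_obs > 0` where present. `leaf_mass` may be absent entirely
#' (prediction-only tables).
#'
#' @param source path to a delimited text file (or a connection).
#' @param column_map named character vector remapping canonical names
#'   (`tree_id, species, dbh, lcr, cc, sg_obs, leaf_mass, mat, map,
#'   study_id`) to the file's column names; defaults to
#'   `dbh_cm, crown_class, leaf_mass_kg, mat_c, map_mm` etc.
#' @param cc_codes if `TRUE`, the crown-class column holds integer codes
#'   1-5 (1 = overtopped ... 5 = open grown) instead of labels. `"auto"`
#'   (default) accepts either.
#' @param sep field separator, default `","`.
#' @return data.frame of valid tree records (canonical columns), attributes
#'   `"raw"` (character data of kept rows) and `"rejected"`
#'   (data.frame `row`, `field`, `message`).
#' @export
read_tree_table <- function(source, column_map = NULL, cc_codes = "auto",
                            sep = ",") {
  raw <- utils::read.csv(source, colClasses = "character", sep = sep,
                         strip.white = TRUE, check.names = FALSE)
  cmap <- .canonical_cols
  if (!is.null(column_map)) {
    stopifnot(is.character(column_map), !is.null(names(column_map)))
    bad <- setdiff(names(column_map), names(cmap))
    if (length(bad)) stop("unknown canonical fields in column_map: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    cmap[names(column_map)] <- column_map
  }
  present <- names(cmap)[cmap %in% names(raw)]
  missing_req <- setdiff(.required_cols, present)
  if (length(missing_req)) {
    stop("missing required column(s): ",
         paste(cmap[missing_req], collapse = ", "), call. = FALSE)
  }
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (f in present) out[[f]] <- raw[[cmap[[f]]]]

  problems <- list()
  note <- function(row, field, msg) {
    problems[[length(problems) + 1L]] <<- data.frame(
      row = row, field = field, message = msg, stringsAsFactors = FALSE)
  }
  n <- nrow(out)
  num <- list()
  for (f in intersect(.numeric_cols, present)) {
    txt <- out[[f]]
    v <- suppressWarnings(as.numeric(txt))
    bad <- which(!is.na(txt) & nzchar(txt) & is.na(v))
    for (r in bad) note(r, f, sprintf("unparseable numeric '%s'", txt[r]))
    v[!nzchar(txt) | is.na(txt)] <- NA_real_
    num[[f]] <- v
  }
  cc_parsed <- parse_crown_class(out$cc, cc_codes = cc_codes)
  for (r in which(is.na(cc_parsed) & nzchar(out$cc)))
    note(r, "cc", sprintf("unknown crown-class label '%s'", out$cc[r]))
  for (r in which(!nzchar(out$cc) | is.na(out$cc)))
    note(r, "cc", "missing crown class")

  check <- function(f, ok_fun, msg) {
    if (!f %in% names(num)) return()
    v <- num[[f]]
    bad <- which(!is.na(v) & !ok_fun(v))
    for (r in bad) note(r, f, msg)
  }
  check("dbh", function(v) v > 0, "dbh must be > 0")
  check("lcr", function(v) v > 0 & v <= 1, "lcr must be in (0, 1]")
  check("map", function(v) v > 0, "map must be > 0")
  check("mat", function(v) v > -30, "mat must exceed -30 (mat + 30 > 0)")
  check("leaf_mass", function(v) v > 0, "leaf_mass must be > 0 when present")
  check("sg_obs", function(v) v > 0, "sg_obs must be > 0 when present")
  # required numerics may not be missing
  for (f in intersect(c("dbh", "lcr"), names(num)))
    for (r in which(is.na(num[[f]]))) note(r, f, paste(f, "is missing"))

  rejected <- if (length(problems)) do.call(rbind, problems) else
    data.frame(row = integer(), field = character(), message = character())
  keep <- setdiff(seq_len(n), unique(rejected$row))

  res <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
                    species = out$species[keep])
  res$tree_id <- if ("tree_id" %in% present) out$tree_id[keep] else
    as.character(keep)
  for (f in names(num)) res[[f]] <- num[[f]][keep]
  res$cc <- cc_parsed[keep]
  if ("study_id" %in% present) res$study_id <- out$study_id[keep]
  ord <- intersect(names(.canonical_cols), names(res))
  res <- res[, ord, drop = FALSE]

  attr(res, "raw") <- out[keep, , drop = FALSE]
  attr(res, "rejected") <- rejected
  res
}

#' Write a tree-record table
#'
#' Inverse of [read_tree_table()]: writes canonical tree records back to CSV
#' using the default external column names (remappable). Crown class is
#' written as its label.
#'
#' @param trees data.frame of tree records.
#' @param path output file path.
#' @param column_map as in [read_tree_table()].
#' @return `path`, invisibly.
#' @export
write_tree_table <- function(trees, path, column_map = NULL) {
  cmap <- .canonical_cols
  if (!is.null(column_map)) cmap[names(column_map)] <- column_map
  out <- trees[, intersect(names(.canonical_cols), names(trees)), drop = FALSE]
  names(out) <- cmap[names(out)]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# significant digits of a numeric text token: digits from the first nonzero
# digit of the mantissa to its last digit ("20" -> 2, "0.1" -> 1, "0.010" -> 2)
count_sigfigs <- function(token) {
  token <- trimws(token)
  vapply(token, function(t) {
    if (!nzchar(t) || is.na(suppressWarnings(as.numeric(t)))) return(NA_integer_)
    mant <- sub("[eE][+-]?[0-9]+$", "", t)
    digits <- gsub("[^0-9]", "", mant)
    digits <- sub("^0+", "", digits)
    if (!nzchar(digits)) return(1L)  # literal zero
    nchar(digits)
  }, integer(1), USE.NAMES = FALSE)
}

#' Filter tree records by recording precision
#'
#' Keeps only records whose required numeric fields were all recorded with at
#' least `min_sigfigs` significant figures, mirroring the data-selection rule
#' that trees lacking two significant figures in any numeric variable are
#' excluded. Precision is judged on the as-read text token (kept by
#' [read_tree_table()]): trailing zeros count, leading zeros do not, so
#' `"20"` has two significant figures and `"0.1"` one. If `trees` carries no
#' raw text (constructed from binary numerics), the filter is a no-op with a
#' warning, because recording precision is a property of text only.
#'
#' @param trees data.frame from [read_tree_table()].
#' @param min_sigfigs minimum significant figures required (>= 1).
#' @param fields numeric fields to screen; defaults to all numeric fields
#'   present in the table.
#' @return list with elements `kept` and `dropped` (both tree tables; raw
#'   attributes subset accordingly).
#' @export
filter_min_sigfigs <- function(trees, min_sigfigs = 2, fields = NULL) {
  stopifnot(min_sigfigs >= 1)
  raw <- attr(trees, "raw")
  if (is.null(raw)) {
    warning("no as-read text available; significant-figure filter is a no-op")
    return(list(kept = trees, dropped = trees[0, , drop = FALSE]))
  }
  if (is.null(fields)) fields <- intersect(.numeric_cols, names(trees))
  ok <- rep(TRUE, nrow(trees))
  for (f in fields) {
    if (!f %in% names(raw)) next
    tok <- raw[[f]]
    sf <- count_sigfigs(tok)
    # absent optional values don't disqualify a record
    ok <- ok & (is.na(sf) | sf >= min_sigfigs)
  }
  subset_tree_table <- function(idx) {
    res <- trees[idx, , drop = FALSE]
    row.names(res) <- NULL
    attr(res, "raw") <- raw[idx, , drop = FALSE]
    res
  }
  list(kept = subset_tree_table(which(ok)),
       dropped = subset_tree_table(which(!ok)))
}
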