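# Packaged species-trait reference table and the trait join.

#' Packaged species functional-trait table
#'
#' Returns the packaged reference table of species-level published trait
#' values for 61 North American tree species (25 softwoods, 36 hardwoods):
#' leaf longevity (months), shade tolerance score and published wood specific
#' gravity. Species carry both a scientific name and an FIA-style numeric
#' code; [attach_traits()] matches on either.
#'
#' Per-species sample sizes are deliberately not part of this table: the
#' printed per-species summaries and the per-species cross-validation table
#' in the source material disagree on N for several species (e.g. *Acer
#' rubrum* 196 vs 201), and the overall tree count is quoted both as 3628
#' and 3901 in different places. Trait values themselves are unaffected.
#'
#' @return A data.frame with columns `species`, `species_code`, `wood_type`,
#'   `ll` (leaf longevity, months), `st` (shade tolerance), `sg_pub`
#'   (published specific gravity).
#' @export
#' @examples
#' tt <- trait_table()
#' tt[tt$species == "Pinus taeda", ]
trait_table <- function() {
  if (is.null(.transleaf_env$traits)) {
    path <- system.file("extdata", "species_traits.csv", package = "transleaf",
                        mustWork = TRUE)
    raw <- utils::read.csv(path, comment.char = "#", strip.white = TRUE)
    traits <- data.frame(
      species = raw$species,
      species_code = as.integer(raw$species_code),
      wood_type = raw$wood_type,
      ll = as.numeric(raw$leaf_longevity_months),
      st = as.numeric(raw$shade_tolerance),
      sg_pub = as.numeric(raw$sg_published),
      stringsAsFactors = FALSE
    )
    stopifnot(!anyDuplicated(traits$species), !anyDuplicated(traits$species_code),
              all(traits$ll > 0), all(traits$st > 0), all(traits$sg_pub > 0))
    .transleaf_env$traits <- traits
  }
  .transleaf_env$traits
}

# normalized join key: case/space/underscore-insensitive
normalize_species_key <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[ _]+", " ", x)
}

#' Attach species trait values to tree records
#'
#' Joins species-level published trait values (leaf longevity `ll`, shade
#' tolerance `st`, published specific gravity `sg_pub`) onto a tree table by
#' species. Matching is case-insensitive on the scientific name and also
#' accepts the numeric species code. A pure join: row count and order are
#' preserved and existing columns are untouched (any previous `ll`, `st`,
#' `sg_pub` columns are replaced, so the operation is idempotent).
#'
#' @param trees data.frame of tree records with a `species` column (see
#'   [read_tree_table()]).
#' @param traits trait table as returned by [trait_table()] (the default),
#'   or any data.frame with the same columns.
#' @return `trees` with columns `ll`, `st`, `sg_pub` appended.
#' @export
attach_traits <- function(trees, traits = trait_table()) {
  stopifnot(is.data.frame(trees), "species" %in% names(trees))
  key <- normalize_species_key(trees$species)
  idx <- match(key, normalize_species_key(traits$species))
  by_code <- match(key, as.character(traits$species_code))
  idx[is.na(idx)] <- by_code[is.na(idx)]
  if (anyNA(idx)) {
    missing <- sort(unique(trees$species[is.na(idx)]))
    stop("species not found in trait table: ", paste(missing, collapse = ", "),
         ". Supply ll, st and sg_pub for these species to use them.",
         call. = FALSE)
  }
  trees$ll <- traits$ll[idx]
  trees$st <- traits$st[idx]
  trees$sg_pub <- traits$sg_pub[idx]
  trees
}
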