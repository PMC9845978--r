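#' Colour and pattern vocabularies
#'
#' The fixed vocabularies used to score larval coloration: eleven basic
#' colour categories and five repeated pattern elements (band, stripe,
#' spot, stipple, blotch).
#'
#' @return Character vector of valid trait names.
#' @export
colour_vocabulary <- function() {
  c("brown", "green", "white", "red", "orange", "yellow",
    "black", "grey", "pink", "blue", "purple")
}

#' @rdname colour_vocabulary
#' @export
pattern_vocabulary <- function() {
  c("stripe", "band", "spot", "stipple", "blotch")
}

diet_levels   <- function() c("monophagous", "oligophagous", "polyphagous")
tissue_levels <- function() c("reproductive", "interior", "leaves", "other")
growth_levels <- function() c("forb", "graminoid", "woody")

#' Canonical name of a two-colour composite trait
#'
#' Pair traits are named by joining the two component colours with "/" in
#' lexicographic order, so the column identity is stable across observers
#' and bootstrap replicates ("black/yellow", never "yellow/black").
#'
#' @param a,b Single colour names.
#' @return Canonical pair name.
#' @export
pair_name <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "/")
}

#' Expand a species' salient colours into single and pairwise colour traits
#'
#' Each species is scored for up to three salient colours. For analysis,
#' the colour set is expanded into one binary trait per single colour plus
#' one per unordered two-colour combination, because colour combinations
#' can signal differently from their components (e.g. yellow with green is
#' cryptic, yellow with black aposematic). Three-colour combinations are
#' never generated. A set of k colours yields k + k(k-1)/2 traits, at most
#' six: a species scored yellow, black and white carries yellow, black,
#' white, black/yellow, black/white and white/yellow.
#'
#' @param colours Character vector (treated as a set) of at most three
#'   colour names from [colour_vocabulary()].
#' @return Character vector of trait names: singles then canonical pairs,
#'   each group sorted.
#' @export
expand_composites <- function(colours) {
  colours <- unique(as.character(colours))
  bad <- setdiff(colours, colour_vocabulary())
  if (length(bad) > 0L) {
    stop("unknown colour name(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (length(colours) > 3L) {
    stop("at most 3 salient colours per species, got ", length(colours),
         call. = FALSE)
  }
  singles <- sort(colours)
  if (length(singles) < 2L) return(singles)
  idx <- utils::combn(singles, 2L)
  c(singles, sort(pair_name(idx[1L, ], idx[2L, ])))
}

#' All colour trait names (singles plus canonical pairs)
#' @return Character vector of the 11 single colours and 55 pairs.
#' @export
all_colour_traits <- function() {
  voc <- sort(colour_vocabulary())
  idx <- utils::combn(voc, 2L)
  c(voc, pair_name(idx[1L, ], idx[2L, ]))
}

trait_class_of <- function(trait_names) {
  voc <- colour_vocabulary()
  cls <- ifelse(grepl("/", trait_names, fixed = TRUE), "colour_pair",
         ifelse(trait_names %in% voc, "colour_single",
         ifelse(trait_names %in% pattern_vocabulary(), "pattern", "ecology")))
  names(cls) <- trait_names
  cls
}

#' Construct a trait_matrix object
#'
#' @param values Binary integer matrix, species in rows (rownames), traits
#'   in columns (colnames). NA allowed only in ecology columns (species
#'   with missing ecology records).
#' @param trait_class Named character vector mapping each column to one of
#'   "colour_single", "colour_pair", "pattern", "ecology". Derived from
#'   column names when omitted.
#' @return An object of class `trait_matrix`.
#' @export
trait_matrix <- function(values, trait_class = NULL) {
  values <- as.matrix(values)
  if (ncol(values) == 0L) {
    vals <- matrix(integer(0), nrow(values), 0L,
                   dimnames = list(rownames(values), character(0)))
    return(structure(list(values = vals,
                          trait_class = stats::setNames(character(0),
                                                        character(0))),
                     class = "trait_matrix"))
  }
  if (is.null(trait_class)) trait_class <- trait_class_of(colnames(values))
  stopifnot(identical(sort(names(trait_class)), sort(colnames(values))))
  vals <- values[, names(trait_class), drop = FALSE]
  storage.mode(vals) <- "integer"
  ok <- vals %in% c(0L, 1L, NA_integer_)
  if (!all(ok)) stop("trait values must be 0/1", call. = FALSE)
  structure(list(values = vals, trait_class = trait_class),
            class = "trait_matrix")
}

#' @export
print.trait_matrix <- function(x, ...) {
  tab <- table(factor(x$trait_class,
                      c("colour_single", "colour_pair", "pattern", "ecology")))
  cat(sprintf("trait_matrix: %d species x %d traits\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  colour: %d single + %d pair; pattern: %d; ecology: %d\n",
              tab[["colour_single"]], tab[["colour_pair"]],
              tab[["pattern"]], tab[["ecology"]]))
  excl <- attr(x, "excluded_traits")
  if (!is.null(excl) && length(excl)) {
    cat("  excluded as rare:", paste(excl, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Species identifiers of a trait matrix
#' @param x A `trait_matrix`.
#' @export
species_ids <- function(x) rownames(x$values)

#' Drop rarely observed trait columns
#'
#' Rare colour traits generate spurious correlations and inflate the number
#' of tests, so colour traits observed in fewer than `min_occurrences`
#' species (strictly fewer: a column sum equal to the threshold survives)
#' are removed before modelling. By default only colour traits are in
#' scope; pattern and ecology columns are kept regardless unless
#' `scope = "all"`.
#'
#' @param x A `trait_matrix`.
#' @param min_occurrences Minimum number of species (column sum) a trait in
#'   scope needs to be retained. Default 5.
#' @param scope `"colour"` (default) to filter colour singles and pairs
#'   only, or `"all"` to filter every column.
#' @return The filtered `trait_matrix`, with the removed trait names in
#'   attribute `"excluded_traits"` (also reported by `excluded_traits()`).
#' @export
filter_rare_traits <- function(x, min_occurrences = 5L,
                               scope = c("colour", "all")) {
  scope <- match.arg(scope)
  stopifnot(inherits(x, "trait_matrix"), min_occurrences >= 1L)
  in_scope <- if (scope == "colour") {
    x$trait_class %in% c("colour_single", "colour_pair")
  } else rep(TRUE, ncol(x$values))
  sums <- colSums(x$values, na.rm = TRUE)
  drop <- in_scope & sums < min_occurrences
  out <- trait_matrix(x$values[, !drop, drop = FALSE],
                      x$trait_class[!drop])
  attr(out, "excluded_traits") <- colnames(x$values)[drop]
  attr(out, "missing_ecology") <- attr(x, "missing_ecology")
  out
}

#' @rdname filter_rare_traits
#' @export
excluded_traits <- function(x) attr(x, "excluded_traits") %||% character(0)

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- score tables ----------------------------------------------------------

#' Read per-observer colour/pattern scores from CSV
#'
#' One row per (species, observer): columns `species`, `observer`,
#' `colour1..colour3` (blank allowed), the five pattern columns
#' `stripe,band,spot,stipple,blotch` as 0/1.
#'
#' @param path CSV file path.
#' @return A data frame validated against the vocabularies.
#' @export
read_scores <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_scores(df)
}

validate_scores <- function(df) {
  need <- c("species", "observer", paste0("colour", 1:3), pattern_vocabulary())
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("scores table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  key <- paste(df$species, df$observer, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (species, observer) rows in scores table", call. = FALSE)
  }
  for (cc in paste0("colour", 1:3)) {
    v <- df[[cc]]
    v[is.na(v)] <- ""
    bad <- setdiff(unique(v), c("", colour_vocabulary()))
    if (length(bad)) stop("unknown colour name(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    df[[cc]] <- v
  }
  for (pp in pattern_vocabulary()) {
    if (!all(df[[pp]] %in% c(0L, 1L))) {
      stop("pattern column '", pp, "' must be 0/1", call. = FALSE)
    }
  }
  df
}

#' Read species ecology records from CSV
#'
#' Columns `species`, `diet_breadth` (monophagous/oligophagous/polyphagous),
#' `tissue` (reproductive/interior/leaves/other) and `growth_forms`
#' (semicolon-separated non-empty subset of forb;graminoid;woody — a species
#' feeding on several growth forms lists each).
#'
#' @param path CSV file path.
#' @return A validated data frame.
#' @export
read_ecology <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_ecology(df)
}

validate_ecology <- function(df) {
  need <- c("species", "diet_breadth", "tissue", "growth_forms")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("ecology table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$species)) {
    stop("duplicate species in ecology table", call. = FALSE)
  }
  if (!all(df$diet_breadth %in% diet_levels())) {
    stop("diet_breadth must be one of: ",
         paste(diet_levels(), collapse = ", "), call. = FALSE)
  }
  if (!all(df$tissue %in% tissue_levels())) {
    stop("tissue must be one of: ",
         paste(tissue_levels(), collapse = ", "), call. = FALSE)
  }
  gf <- strsplit(df$growth_forms, ";", fixed = TRUE)
  if (any(lengths(gf) == 0L) ||
      !all(unlist(gf) %in% growth_levels())) {
    stop("growth_forms must be a non-empty ';'-separated subset of: ",
         paste(growth_levels(), collapse = ", "), call. = FALSE)
  }
  df
}

ecology_colnames <- function() {
  c(paste0("diet_", diet_levels()),
    paste0("tissue_", tissue_levels()),
    growth_levels())
}

# one-hot expansion (multi-hot for growth forms); rows = species order given
ecology_block <- function(species, ecology) {
  cols <- ecology_colnames()
  m <- matrix(NA_integer_, length(species), length(cols),
              dimnames = list(species, cols))
  if (is.null(ecology) || nrow(ecology) == 0L) return(m)
  idx <- match(species, ecology$species)
  has <- !is.na(idx)
  for (lv in diet_levels()) {
    m[has, paste0("diet_", lv)] <-
      as.integer(ecology$diet_breadth[idx[has]] == lv)
  }
  for (lv in tissue_levels()) {
    m[has, paste0("tissue_", lv)] <-
      as.integer(ecology$tissue[idx[has]] == lv)
  }
  gf <- strsplit(ecology$growth_forms[idx[has]], ";", fixed = TRUE)
  for (lv in growth_levels()) {
    m[has, lv] <- vapply(gf, function(g) as.integer(lv %in% g), integer(1))
  }
  m
}

# species x 11 colour membership from colour1..3 columns (vectorized)
colour_membership <- function(scores) {
  voc <- sort(colour_vocabulary())
  m <- matrix(0L, nrow(scores), length(voc),
              dimnames = list(scores$species, voc))
  for (cc in paste0("colour", 1:3)) {
    v <- scores[[cc]]
    hit <- v != ""
    m[cbind(which(hit), match(v[hit], voc))] <- 1L
  }
  m
}

# colour single + pair columns for a fixed universe of colour trait names
colour_block <- function(scores, colour_traits = all_colour_traits()) {
  mem <- colour_membership(scores)
  out <- matrix(0L, nrow(scores), length(colour_traits),
                dimnames = list(scores$species, colour_traits))
  is_pair <- grepl("/", colour_traits, fixed = TRUE)
  singles <- colour_traits[!is_pair]
  out[, singles] <- mem[, singles, drop = FALSE]
  if (any(is_pair)) {
    parts <- strsplit(colour_traits[is_pair], "/", fixed = TRUE)
    a <- vapply(parts, `[`, "", 1L)
    b <- vapply(parts, `[`, "", 2L)
    out[, colour_traits[is_pair]] <-
      mem[, a, drop = FALSE] * mem[, b, drop = FALSE]
  }
  out
}

#' Build the binary species-by-trait matrix from scores and ecology
#'
#' Assembles one binary column per single colour, retained two-colour
#' composite, pattern element, and ecology level (diet breadth, tissue type
#' and growth form are one-hot expanded; growth form is a non-exclusive set,
#' so a species feeding on forbs and woody plants gets a 1 in both columns).
#' The rarity filter is then applied to colour traits. Species present in
#' the scores but absent from the ecology table get NA ecology columns and
#' are recorded in attribute `"missing_ecology"`; they are excluded from
#' ecology models only, not globally.
#'
#' @param scores A scores data frame (see [read_scores()]) restricted to a
#'   single observer per species.
#' @param ecology An ecology data frame (see [read_ecology()]) or NULL for
#'   a colour/pattern-only matrix.
#' @param min_occurrences Rarity threshold passed to [filter_rare_traits()];
#'   use 0 with `trait_universe` set to skip re-filtering.
#' @param trait_universe Optional character vector freezing the colour
#'   trait columns (used by the observer bootstrap so every replicate has
#'   identical columns). Default: all colour traits observed in `scores`.
#' @param filter_scope Scope passed to [filter_rare_traits()].
#' @return A `trait_matrix`.
#' @export
build_trait_matrix <- function(scores, ecology = NULL, min_occurrences = 5L,
                               trait_universe = NULL,
                               filter_scope = "colour") {
  if (nrow(scores) == 0L) {
    return(trait_matrix(matrix(integer(0), 0L, 0L,
                               dimnames = list(NULL, character(0))),
                        stats::setNames(character(0), character(0))))
  }
  if (anyDuplicated(scores$species)) {
    stop("duplicate species in scores: pass one observer's row per species",
         call. = FALSE)
  }
  scores <- validate_scores(scores)
  if (is.null(trait_universe)) {
    sets <- Map(function(a, b, c) setdiff(unique(c(a, b, c)), ""),
                scores$colour1, scores$colour2, scores$colour3)
    colour_traits <- sort(unique(unlist(lapply(sets, expand_composites))))
    is_pair <- grepl("/", colour_traits, fixed = TRUE)
    colour_traits <- c(colour_traits[!is_pair], colour_traits[is_pair])
  } else {
    colour_traits <- trait_universe
  }
  cb <- colour_block(scores, colour_traits)
  pb <- as.matrix(scores[, pattern_vocabulary()])
  storage.mode(pb) <- "integer"
  rownames(pb) <- scores$species
  blocks <- cbind(cb, pb)
  missing_eco <- character(0)
  if (!is.null(ecology)) {
    ecology <- validate_ecology(ecology)
    eb <- ecology_block(scores$species, ecology)
    missing_eco <- scores$species[!scores$species %in% ecology$species]
    blocks <- cbind(blocks, eb)
  }
  tm <- trait_matrix(blocks)
  attr(tm, "missing_ecology") <- missing_eco
  if (min_occurrences >= 1L && is.null(trait_universe)) {
    tm <- filter_rare_traits(tm, min_occurrences, scope = filter_scope)
  }
  tm
}

#' Write a trait matrix to CSV plus a JSON metadata sidecar
#'
#' @param x A `trait_matrix`.
#' @param path CSV path for the 0/1 species-by-trait table; the sidecar
#'   `<path>.json` records trait classes, rarity exclusions and species
#'   with missing ecology.
#' @export
write_trait_matrix <- function(x, path) {
  df <- data.frame(species = rownames(x$values), x$values,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(trait_class = as.list(x$trait_class),
               excluded_traits = excluded_traits(x),
               missing_ecology = attr(x, "missing_ecology") %||% character(0))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
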