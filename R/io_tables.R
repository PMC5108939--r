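#' Names of the seven linear measurements in a trait table
#'
#' Column order used throughout: beak length (exposed culmen), beak width and
#' depth at the nares, tail length, tarsus length, whole body length and wing
#' chord, all in millimetres.
#' @return Character vector of length 7.
#' @export
trait_measurement_names <- function() {
  c("beak_length", "beak_width", "beak_depth", "tail_length",
    "tarsus_length", "body_length", "wing_length")
}

#' Read a rooted phylogeny from a Newick file
#'
#' Thin validating wrapper around [ape::read.tree()]. The returned tree keeps
#' ape's tip ordering (the order tips are encountered in the Newick string).
#' Trees must carry a branch length on every edge; a missing length is an
#' error rather than a silent default.
#'
#' @param path Path to a Newick file.
#' @return An [ape::phylo] object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  # name the offending token for the two commonest syntax faults
  n_open <- lengths(regmatches(txt, gregexpr("\\(", txt)))
  n_close <- lengths(regmatches(txt, gregexpr("\\)", txt)))
  if (n_open != n_close) {
    stop("Newick parse error in ", path, ": unbalanced parentheses (",
         n_open, " '(' vs ", n_close, " ')')")
  }
  if (!grepl(";", txt, fixed = TRUE)) {
    stop("Newick parse error in ", path, ": missing terminating ';'")
  }
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree)) stop("Newick parse error in ", path)
  validate_phylogeny(tree)
  tree
}

#' Validate the phylogeny contract
#'
#' Checks the invariants every analysis operation assumes: at least two tips,
#' unique tip labels, a branch length on every edge, and no negative lengths.
#'
#' @param tree An [ape::phylo] object.
#' @return `tree`, invisibly; errors otherwise.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (length(tree$tip.label) < 2) stop("phylogeny must have >= 2 tips")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup)) stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  if (is.null(tree$edge.length)) {
    stop("phylogeny has no branch lengths; lengths are required")
  }
  if (anyNA(tree$edge.length)) stop("phylogeny has missing branch lengths")
  if (any(tree$edge.length < 0)) stop("phylogeny has negative branch lengths")
  invisible(tree)
}

#' Read occurrence records (species, latitude, longitude)
#'
#' Expects a comma-separated UTF-8 file with header `species,lat,lon`.
#' Coordinates are decimal degrees (WGS84 assumed, never reprojected).
#' Out-of-range coordinates are reported with their line number.
#'
#' @param path CSV path.
#' @return data.frame with columns `species`, `lat`, `lon`.
#' @export
read_occurrences <- function(path) {
  if (!file.exists(path)) stop("occurrence file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "lat", "lon")
  if (!all(need %in% names(df))) {
    stop("occurrence CSV must have header species,lat,lon; found: ",
         paste(names(df), collapse = ","))
  }
  df <- df[need]
  validate_occurrences(df)
  df
}

#' @rdname read_occurrences
#' @param records data.frame of occurrence records to validate or write.
#' @export
validate_occurrences <- function(records) {
  if (nrow(records) == 0) return(invisible(records))
  bad <- which(is.na(records$species) | !nzchar(records$species))
  if (length(bad)) stop("empty species label at data row(s) ",
                        paste(bad, collapse = ", "))
  bad <- which(!is.finite(records$lat) | records$lat < -90 | records$lat > 90)
  if (length(bad)) {
    stop("latitude out of [-90, 90] at data row(s) ",
         paste(bad, collapse = ", "), " (line ",
         paste(bad + 1L, collapse = ", "), " of file)")
  }
  bad <- which(!is.finite(records$lon) | records$lon < -180 | records$lon > 180)
  if (length(bad)) {
    stop("longitude out of [-180, 180] at data row(s) ",
         paste(bad, collapse = ", "), " (line ",
         paste(bad + 1L, collapse = ", "), " of file)")
  }
  invisible(records)
}

#' @rdname read_occurrences
#' @export
write_occurrences <- function(records, path) {
  validate_occurrences(records)
  write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a specimen-level morphometric table
#'
#' Expects header `specimen_id,species,` followed by the seven measurement
#' columns of [trait_measurement_names()], in millimetres. Every measurement
#' must be strictly positive (the downstream log-transform must be defined)
#' and no cell may be missing.
#'
#' @param path CSV path.
#' @return data.frame with columns `specimen_id`, `species` and the seven
#'   measurements.
#' @export
read_traits <- function(path) {
  if (!file.exists(path)) stop("trait file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "species", trait_measurement_names())
  if (!all(need %in% names(df))) {
    stop("trait CSV missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  df <- df[need]
  validate_traits(df)
  df
}

#' @rdname read_traits
#' @param traits data.frame to validate or write.
#' @export
validate_traits <- function(traits) {
  for (tr in trait_measurement_names()) {
    v <- traits[[tr]]
    bad <- which(is.na(v) | !is.finite(v) | v <= 0)
    if (length(bad)) {
      stop("non-positive or missing ", tr, " for specimen(s) ",
           paste(traits$specimen_id[bad], collapse = ", "))
    }
  }
  invisible(traits)
}

#' @rdname read_traits
#' @export
write_traits <- function(traits, path) {
  validate_traits(traits)
  write.csv(traits, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read vocal-element annotations
#'
#' Expects header `recording_id,species,onset_s,offset_s`; onset/offset are
#' seconds from the start of the recording and every element must have
#' `offset_s > onset_s`. Elements used for within-recording statistical
#' comparison must additionally not overlap in time; that is checked by
#' [compare_chorus()], not here, so that annotation files covering several
#' overlapping singers can still be read.
#'
#' @param path CSV path.
#' @return data.frame with columns `recording_id`, `species`, `onset_s`,
#'   `offset_s`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("recording_id", "species", "onset_s", "offset_s")
  if (!all(need %in% names(df))) {
    stop("annotation CSV missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  df <- df[need]
  validate_annotations(df)
  df
}

#' @rdname read_annotations
#' @param annotations data.frame to validate or write.
#' @export
validate_annotations <- function(annotations) {
  bad <- which(!(annotations$offset_s > annotations$onset_s))
  if (length(bad)) {
    stop("element offset <= onset at data row(s) ",
         paste(bad, collapse = ", "))
  }
  invisible(annotations)
}

#' @rdname read_annotations
#' @export
write_annotations <- function(annotations, path) {
  validate_annotations(annotations)
  write.csv(annotations, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
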