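#' Grid occurrence records into a site x species presence-absence matrix
#'
#' Records are binned on a regular latitude/longitude grid of square cells
#' `cell_size_deg` degrees on a side. Cells are half-open intervals
#' `[a, a + cell)`, so a record exactly on a boundary falls in the
#' higher-index cell. Only cells holding at least one record become sites;
#' repeated records of a species in a cell collapse to a single presence
#' (abundance is ignored).
#'
#' @param records Occurrence data.frame (`species`, `lat`, `lon`), see
#'   [read_occurrences()].
#' @param cell_size_deg Cell side in decimal degrees (default 0.2).
#' @param origin Optional `c(lat, lon)` of the grid origin. Default: the
#'   region's minimum latitude and longitude, each floored to a multiple of
#'   the cell size.
#' @return Binary integer matrix, sites (grid cells) in rows, species in
#'   columns (alphabetical). Row names are `"<lat index>_<lon index>"` cell
#'   indices; the origin used is attached as attribute `origin`.
#' @export
grid_occurrences <- function(records, cell_size_deg = 0.2, origin = NULL) {
  stopifnot(cell_size_deg > 0)
  if (nrow(records) == 0) stop("no occurrence records to grid")
  validate_occurrences(records)
  if (is.null(origin)) {
    origin <- c(floor(min(records$lat) / cell_size_deg) * cell_size_deg,
                floor(min(records$lon) / cell_size_deg) * cell_size_deg)
  }
  # tolerance so coordinates on a cell boundary land in the higher-index
  # cell despite floating-point division error
  eps <- 1e-9
  ilat <- floor((records$lat - origin[1]) / cell_size_deg + eps)
  ilon <- floor((records$lon - origin[2]) / cell_size_deg + eps)
  site <- paste0(ilat, "_", ilon)
  species <- sort(unique(records$species))
  sites <- sort(unique(site))
  m <- matrix(0L, nrow = length(sites), ncol = length(species),
              dimnames = list(sites, species))
  m[cbind(match(site, sites), match(records$species, species))] <- 1L
  attr(m, "origin") <- origin
  attr(m, "cell_size_deg") <- cell_size_deg
  m
}

#' Validate a community (presence-absence) matrix
#'
#' @param m Matrix with 0/1 entries, sites in rows, species in columns.
#' @return `m` (as integer matrix), invisibly; errors otherwise.
#' @export
validate_community_matrix <- function(m) {
  if (!is.matrix(m)) stop("community matrix must be a matrix")
  if (!all(m %in% c(0L, 1L))) stop("community matrix entries must be 0 or 1")
  if (is.null(colnames(m))) stop("community matrix must have species column names")
  invisible(matrix(as.integer(m), nrow(m), dimnames = dimnames(m)))
}

#' Pairwise DO co-occurrence index
#'
#' For each unordered species pair, `DO = (P_ij - P_i P_j) / (P_i P_j)` where
#' `P_i`, `P_j` are the proportions of sites occupied by each species and
#' `P_ij` the proportion occupied by both. `DO` is about 0 when species are
#' distributed independently, -1 when they are mutually exclusive, and grows
#' with positive association; it is robust to abundance differences because
#' only presence enters. Pairs in which either species occupies no site have
#' an undefined index and are flagged rather than given a number.
#'
#' @param m Binary site x species matrix, e.g. from [grid_occurrences()].
#' @return data.frame with one row per unordered pair: `species_i`,
#'   `species_j`, `p_i`, `p_j`, `p_ij`, `do` (NA when undefined), `defined`,
#'   `reason` (why undefined, `""` otherwise).
#' @export
do_index <- function(m) {
  m <- validate_community_matrix(m)
  if (nrow(m) < 1) stop("community matrix needs >= 1 site")
  if (ncol(m) < 2) stop("need >= 2 species for pairwise co-occurrence")
  n_sites <- nrow(m)
  p <- colMeans(m)
  pij <- crossprod(m) / n_sites
  pairs <- combn(colnames(m), 2)
  out <- data.frame(
    species_i = pairs[1, ], species_j = pairs[2, ],
    p_i = p[pairs[1, ]], p_j = p[pairs[2, ]],
    p_ij = pij[cbind(pairs[1, ], pairs[2, ])],
    stringsAsFactors = FALSE, row.names = NULL
  )
  denom <- out$p_i * out$p_j
  out$do <- ifelse(denom > 0, (out$p_ij - denom) / denom, NA_real_)
  out$defined <- denom > 0
  out$reason <- ifelse(out$defined, "",
                       "species absent from all sites; P_i * P_j = 0")
  out
}
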