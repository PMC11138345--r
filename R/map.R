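#' Construct a linkage map
#'
#' A linkage map is a data frame with one row per marker and columns
#' `chromosome` (integer id), `marker` (unique label) and `position`
#' (map position in centiMorgans). Positions must be strictly increasing
#' within each chromosome.
#'
#' @param chromosome integer vector of chromosome ids, one per marker.
#' @param position numeric vector of map positions in cM, non-negative and
#'   strictly increasing within each chromosome.
#' @param marker optional character vector of marker labels; generated when
#'   missing.
#' @return A `data.frame` of class `linkage_map`.
#' @examples
#' linkage_map(chromosome = c(1, 1, 2), position = c(0, 12.5, 3))
#' @export
linkage_map <- function(chromosome, position, marker = NULL) {
  chromosome <- as.integer(chromosome)
  position <- as.numeric(position)
  if (length(chromosome) != length(position)) {
    stop("chromosome and position must have equal length")
  }
  if (any(position < 0)) stop("map positions must be non-negative")
  if (is.null(marker)) {
    marker <- sprintf("c%d_m%d", chromosome,
                      stats::ave(position, chromosome, FUN = seq_along))
  }
  if (anyDuplicated(marker)) stop("marker labels must be unique")
  for (ch in unique(chromosome)) {
    p <- position[chromosome == ch]
    if (length(p) > 1L && any(diff(p) <= 0)) {
      stop(sprintf("positions on chromosome %d are not strictly increasing", ch))
    }
  }
  out <- data.frame(chromosome = chromosome, marker = as.character(marker),
                    position = position, stringsAsFactors = FALSE)
  class(out) <- c("linkage_map", "data.frame")
  out
}

#' Simulate marker positions for a genome
#'
#' Marker positions are sorted uniform draws along each chromosome of the
#' given map length.
#'
#' @param n_chromosomes number of chromosomes (default 10).
#' @param markers_per_chromosome loci per chromosome (default 500).
#' @param length_cM chromosome map length in centiMorgans (default 1000).
#' @param seed integer seed.
#' @return A [linkage_map()].
#' @export
sim_linkage_map <- function(n_chromosomes = 10, markers_per_chromosome = 500,
                            length_cM = 1000, seed = 1L) {
  stopifnot(n_chromosomes >= 1, markers_per_chromosome >= 1, length_cM > 0)
  set.seed(seed)
  chromosome <- rep(seq_len(n_chromosomes), each = markers_per_chromosome)
  position <- unlist(lapply(seq_len(n_chromosomes), function(ch) {
    sort(stats::runif(markers_per_chromosome, 0, length_cM))
  }), use.names = FALSE)
  linkage_map(chromosome, position)
}

#' Kosambi map function
#'
#' Converts map distance to recombination fraction, r = tanh(2d)/2 with d in
#' Morgans (here supplied in centiMorgans).
#'
#' @param d map distance in centiMorgans, `d >= 0`.
#' @return Recombination fraction in `[0, 0.5)`.
#' @examples
#' kosambi_r(10) # 0.5 * tanh(0.2)
#' @export
kosambi_r <- function(d) {
  if (any(d < 0)) stop("map distance must be non-negative")
  0.5 * tanh(2 * d / 100)
}

#' Inverse Kosambi map function
#'
#' @param r recombination fraction in `[0, 0.5)`.
#' @return Map distance in centiMorgans.
#' @export
kosambi_d <- function(r) {
  if (any(r < 0 | r >= 0.5)) stop("recombination fraction must lie in [0, 0.5)")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Adjacent-marker recombination fractions for meiosis
#'
#' Returns a vector of per-marker source-switch probabilities: the Kosambi
#' recombination fraction to the previous marker within a chromosome, and 0.5
#' at the first marker of each chromosome (independent segregation across
#' chromosomes).
#'
#' @param map a [linkage_map()].
#' @return Numeric vector of length `nrow(map)`.
#' @export
recomb_fractions <- function(map) {
  stopifnot(inherits(map, "linkage_map"))
  rec <- numeric(nrow(map))
  for (ch in unique(map$chromosome)) {
    idx <- which(map$chromosome == ch)
    rec[idx[1L]] <- 0.5
    if (length(idx) > 1L) {
      rec[idx[-1L]] <- kosambi_r(diff(map$position[idx]))
    }
  }
  rec
}

#' Read / write a linkage map as CSV
#'
#' The CSV has header columns `chromosome`, `marker_id`, `position_cM`.
#'
#' @param map a [linkage_map()].
#' @param path file path.
#' @return `read_linkage_map` returns a [linkage_map()];
#'   `write_linkage_map` returns `path` invisibly.
#' @export
write_linkage_map <- function(map, path) {
  stopifnot(inherits(map, "linkage_map"))
  utils::write.csv(data.frame(chromosome = map$chromosome,
                              marker_id = map$marker,
                              position_cM = map$position),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_linkage_map
#' @export
read_linkage_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("chromosome", "marker_id", "position_cM")
  if (!all(need %in% names(df))) {
    stop("linkage-map CSV must have columns chromosome, marker_id, position_cM")
  }
  linkage_map(df$chromosome, df$position_cM, df$marker_id)
}
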