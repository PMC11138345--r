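#' Trait architecture: QTL positions and additive effects
#'
#' @param qtl_indices unique marker indices of the QTLs.
#' @param effects additive effect per QTL, or `NULL` while unset.
#' @param n_markers total marker count the indices refer to (optional bound
#'   check).
#' @return An object of class `trait_arch`.
#' @export
trait_arch <- function(qtl_indices, effects = NULL, n_markers = NULL) {
  qtl_indices <- as.integer(qtl_indices)
  if (anyDuplicated(qtl_indices)) stop("qtl_indices must be unique")
  if (any(qtl_indices < 1)) stop("qtl_indices must be positive")
  if (!is.null(n_markers) && any(qtl_indices > n_markers)) {
    stop("qtl_indices exceed the marker range")
  }
  if (!is.null(effects)) {
    effects <- as.numeric(effects)
    if (length(effects) != length(qtl_indices)) {
      stop("effects must match qtl_indices in length")
    }
    if (any(!is.finite(effects))) stop("effects must be finite")
  }
  structure(list(qtl_indices = qtl_indices, effects = effects),
            class = "trait_arch")
}

#' @export
print.trait_arch <- function(x, ...) {
  cat(sprintf("trait architecture: %d QTLs%s\n", length(x$qtl_indices),
              if (is.null(x$effects)) " (effects unset)" else ""))
  invisible(x)
}

#' Assign QTL positions uniformly within chromosomes
#'
#' Selects `per_chromosome` markers per chromosome uniformly without
#' replacement as QTLs.
#'
#' @param map a [linkage_map()].
#' @param per_chromosome QTLs per chromosome (default 2).
#' @param seed integer seed.
#' @return A [trait_arch()] with effects unset.
#' @export
assign_qtls <- function(map, per_chromosome = 2, seed = 1L) {
  stopifnot(inherits(map, "linkage_map"))
  set.seed(seed)
  idx <- unlist(lapply(unique(map$chromosome), function(ch) {
    cand <- which(map$chromosome == ch)
    if (per_chromosome > length(cand)) {
      stop(sprintf("chromosome %d has fewer than %d markers", ch,
                   per_chromosome))
    }
    sort(sample(cand, per_chromosome))
  }), use.names = FALSE)
  trait_arch(idx, n_markers = nrow(map))
}

#' Sample additive QTL effects
#'
#' Effects are i.i.d. normal with mean 0 and variance `1 / n_QTL`, so the
#' total genetic variance contributed is insensitive to the QTL count.
#'
#' @param arch a [trait_arch()] with QTL indices set.
#' @param seed integer seed.
#' @return The architecture with `effects` filled in.
#' @export
sample_qtl_effects <- function(arch, seed = 1L) {
  stopifnot(inherits(arch, "trait_arch"))
  set.seed(seed)
  m <- length(arch$qtl_indices)
  trait_arch(arch$qtl_indices, stats::rnorm(m, 0, sqrt(1 / m)))
}

#' Read / write a trait architecture as JSON
#'
#' @param arch a [trait_arch()].
#' @param path file path.
#' @return `read_trait_arch` returns a [trait_arch()]; the writer returns
#'   `path` invisibly.
#' @export
write_trait_arch <- function(arch, path) {
  jsonlite::write_json(list(qtl = arch$qtl_indices, effects = arch$effects),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trait_arch
#' @export
read_trait_arch <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  trait_arch(x$qtl, x$effects)
}
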