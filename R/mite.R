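## MITE-style tiling: partition a coding region into contiguous tiles.

#' Partition a coding sequence into contiguous tiles
#'
#' Equal-as-possible ceiling partition of `n_codons` codons into
#' `ceiling(n_codons / max_tile_codons)` contiguous, non-overlapping tiles
#' covering `1..n_codons` exactly. When the division is not exact, earlier
#' tiles take the extra codon (longer tiles first), so the layout is
#' deterministic. With the default tile capacity of 42 codons this yields
#' the 15 + 7 tile layout used for a 593-residue full-length construct and
#' a 289-residue catalytic-domain construct.
#'
#' @param n_codons Number of codons to cover (>= 1).
#' @param max_tile_codons Maximum codons per tile (>= 1, default 42).
#' @return data.frame of class `tile_set` with columns `tile`,
#'   `start_codon`, `end_codon` (1-based inclusive).
#' @export
tile_sequence <- function(n_codons, max_tile_codons = 42L) {
  n_codons <- as.integer(n_codons)
  max_tile_codons <- as.integer(max_tile_codons)
  if (is.na(n_codons) || n_codons < 1L) stop("n_codons must be >= 1")
  if (is.na(max_tile_codons) || max_tile_codons < 1L) {
    stop("max_tile_codons must be >= 1")
  }
  k <- ceiling(n_codons / max_tile_codons)
  base <- n_codons %/% k
  extra <- n_codons %% k
  lens <- rep.int(base, k) + as.integer(seq_len(k) <= extra)
  ends <- cumsum(lens)
  tiles <- data.frame(
    tile = seq_len(k),
    start_codon = c(1L, head(ends, -1L) + 1L),
    end_codon = ends
  )
  class(tiles) <- c("tile_set", "data.frame")
  tiles
}

#' Assign variants to tiles
#'
#' Maps each variant to the unique tile whose inclusive codon interval
#' contains its (construct-local) position.
#'
#' @param positions Integer vector of 1-based codon positions, local to
#'   the tiled region (i.e. position 1 = first codon of tile 1).
#' @param tiles A [tile_sequence()] table.
#' @return Integer vector of 1-based tile indices.
#' @export
assign_tiles <- function(positions, tiles) {
  positions <- as.integer(positions)
  lo <- min(tiles$start_codon)
  hi <- max(tiles$end_codon)
  if (any(positions < lo | positions > hi)) {
    stop("position outside tile coverage (", lo, "..", hi, ")")
  }
  findInterval(positions, tiles$start_codon)
}

#' Write / read a tile table (BED-like TSV, 1-based inclusive)
#'
#' @param tiles A [tile_sequence()] table.
#' @param path File path.
#' @return `write_tile_table`: the path, invisibly.
#' @export
write_tile_table <- function(tiles, path) {
  utils::write.table(tiles, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tile_table
#' @export
read_tile_table <- function(path) {
  tiles <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(tiles) <- c("tile_set", "data.frame")
  tiles
}
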