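#' Genome layout for an allotetraploid panel
#'
#' A `genome_layout` records the chromosome complement of the A and D
#' subgenomes and, optionally, a homoeolog map pairing coordinate intervals
#' on A chromosomes with their counterparts on D chromosomes. Allotetraploid
#' cotton carries 13 A- and 13 D-subgenome chromosomes; the default
#' desk-scale layout uses two of each at 2 Mb.
#'
#' @param chromosomes Tibble/data frame with columns `chrom` (unique names),
#'   `length` (bp, > 0) and `subgenome` (`"A"` or `"D"`).
#' @param homoeolog_map Optional tibble with columns `a_chrom`, `a_start`,
#'   `a_end`, `d_chrom`, `d_start`, `d_end` (0-based half-open intervals)
#'   pairing homoeologous segments. `NULL` for none.
#'
#' @return An object of class `genome_layout`: a list with elements
#'   `chromosomes` and `homoeolog_map`, both tibbles.
#' @export
#' @examples
#' genome_layout(tibble::tibble(
#'   chrom = c("A01", "D01"), length = 1e6, subgenome = c("A", "D")
#' ))
genome_layout <- function(chromosomes, homoeolog_map = NULL) {
  chromosomes <- tibble::as_tibble(chromosomes)
  stopifnot(all(c("chrom", "length", "subgenome") %in% names(chromosomes)))
  if (anyDuplicated(chromosomes$chrom) > 0) {
    stop("chromosome names must be unique", call. = FALSE)
  }
  if (any(chromosomes$length <= 0)) {
    stop("chromosome lengths must be positive", call. = FALSE)
  }
  if (!all(chromosomes$subgenome %in% c("A", "D"))) {
    stop("subgenome tags must be 'A' or 'D'", call. = FALSE)
  }
  if (!is.null(homoeolog_map)) {
    homoeolog_map <- tibble::as_tibble(homoeolog_map)
    need <- c("a_chrom", "a_start", "a_end", "d_chrom", "d_start", "d_end")
    stopifnot(all(need %in% names(homoeolog_map)))
    len <- stats::setNames(chromosomes$length, chromosomes$chrom)
    ok <- homoeolog_map$a_chrom %in% chromosomes$chrom &
      homoeolog_map$d_chrom %in% chromosomes$chrom &
      homoeolog_map$a_start >= 0 & homoeolog_map$d_start >= 0 &
      homoeolog_map$a_start < homoeolog_map$a_end &
      homoeolog_map$d_start < homoeolog_map$d_end &
      homoeolog_map$a_end <= len[homoeolog_map$a_chrom] &
      homoeolog_map$d_end <= len[homoeolog_map$d_chrom]
    if (!all(ok)) stop("homoeolog intervals must lie within their chromosomes",
                       call. = FALSE)
  }
  structure(list(chromosomes = chromosomes, homoeolog_map = homoeolog_map),
            class = "genome_layout")
}

#' Default desk-scale genome layout
#'
#' Two A-subgenome and two D-subgenome chromosomes of `chrom_length` bp
#' each, with A01/D01 and A02/D02 paired end-to-end in the homoeolog map
#' (collinear homoeologs, the dominant pattern between the cotton
#' subgenomes).
#'
#' @param chrom_length Chromosome length in bp (default 2 Mb).
#' @return A [genome_layout()].
#' @export
default_layout <- function(chrom_length = 2e6) {
  chroms <- tibble::tibble(
    chrom = c("A01", "A02", "D01", "D02"),
    length = chrom_length,
    subgenome = c("A", "A", "D", "D")
  )
  map <- tibble::tibble(
    a_chrom = c("A01", "A02"), a_start = 0, a_end = chrom_length,
    d_chrom = c("D01", "D02"), d_start = 0, d_end = chrom_length
  )
  genome_layout(chroms, map)
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("<genome_layout> ", nrow(x$chromosomes), " chromosomes, ",
      sum(x$chromosomes$length) / 1e6, " Mb total",
      if (!is.null(x$homoeolog_map))
        paste0("; ", nrow(x$homoeolog_map), " homoeologous segment pairs"),
      "\n", sep = "")
  invisible(x)
}

#' Subgenome of a chromosome
#'
#' @param layout A [genome_layout()].
#' @param chrom Character vector of chromosome names.
#' @return Character vector of subgenome tags (`"A"`/`"D"`).
#' @export
subgenome_of <- function(layout, chrom) {
  m <- match(chrom, layout$chromosomes$chrom)
  if (anyNA(m)) stop("unknown chromosome: ",
                     paste(unique(chrom[is.na(m)]), collapse = ", "),
                     call. = FALSE)
  layout$chromosomes$subgenome[m]
}

#' Tile a genome layout into fixed-size intervals
#'
#' Produces the non-overlapping window (or block) tiling used by the
#' windowed statistics: 0-based half-open intervals of `size` bp per
#' chromosome, the last one truncated at the chromosome end.
#'
#' @param layout A [genome_layout()].
#' @param size Interval size in bp (100 kb windows, 1 Mb blocks).
#' @return Tibble with columns `chrom`, `start`, `end`, `label`.
#' @export
tile_genome <- function(layout, size) {
  stopifnot(size > 0)
  purrr::pmap_dfr(layout$chromosomes[, c("chrom", "length")],
    function(chrom, length) {
      start <- seq(0, length - 1, by = size)
      tibble::tibble(
        chrom = chrom, start = start, end = pmin(start + size, length)
      )
    }) |>
    dplyr::mutate(label = paste0(.data$chrom, ":", .data$start, "-", .data$end))
}
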