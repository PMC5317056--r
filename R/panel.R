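#' Accession panel
#'
#' The accession panel drives every population split in the pipeline: each
#' accession carries a species (`hirsutum`, `barbadense` or `outgroup`) and
#' a group (`race`, `cultivar`, `landrace` or `outgroup`).
#'
#' @param id Character vector of unique accession ids.
#' @param species Character vector, one of `"hirsutum"`, `"barbadense"`,
#'   `"outgroup"`.
#' @param group Character vector, one of `"race"`, `"cultivar"`,
#'   `"landrace"`, `"outgroup"`.
#' @param origin Free-text origin labels (optional).
#' @return A tibble with columns `id`, `species`, `group`, `origin`.
#' @export
#' @examples
#' accession_panel(c("a1", "a2"), c("hirsutum", "barbadense"),
#'                 c("race", "cultivar"))
accession_panel <- function(id, species, group, origin = NA_character_) {
  id <- as.character(id)
  if (anyDuplicated(id) > 0) stop("accession ids must be unique", call. = FALSE)
  if (!all(species %in% c("hirsutum", "barbadense", "outgroup"))) {
    stop("species must be hirsutum, barbadense or outgroup", call. = FALSE)
  }
  if (!all(group %in% c("race", "cultivar", "landrace", "outgroup"))) {
    stop("group must be race, cultivar, landrace or outgroup", call. = FALSE)
  }
  tibble::tibble(id = id, species = as.character(species),
                 group = as.character(group),
                 origin = as.character(origin))
}

#' Read an accession panel from a TSV file
#'
#' Expects columns `id`, `species`, `group` and optionally `origin`.
#'
#' @param path Path to a tab-separated panel file.
#' @return A validated panel tibble (see [accession_panel()]).
#' @export
read_panel <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = "c"))
  if (!all(c("id", "species", "group") %in% names(d))) {
    stop("panel file needs columns id, species, group", call. = FALSE)
  }
  accession_panel(d$id, d$species, d$group,
                  if ("origin" %in% names(d)) d$origin else NA_character_)
}

#' Write an accession panel to TSV
#'
#' @param panel Panel tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  readr::write_tsv(panel, path)
  invisible(path)
}

#' Accession ids belonging to a species or group
#'
#' @param panel Panel tibble.
#' @param species,group Optional filters; either or both may be given.
#' @return Character vector of ids.
#' @export
panel_ids <- function(panel, species = NULL, group = NULL) {
  keep <- rep(TRUE, nrow(panel))
  if (!is.null(species)) keep <- keep & panel$species %in% species
  if (!is.null(group)) keep <- keep & panel$group %in% group
  panel$id[keep]
}
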