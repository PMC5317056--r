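# Simple-matching distance between accession rows of a call matrix:
# 1 - (identical genotype states) / (jointly called sites), pairwise
# complete. Pairs with no jointly called site get NA.
simple_matching <- function(calls) {
  obs <- !is.na(calls)
  joint <- obs %*% t(obs)
  match_count <- matrix(0, nrow(calls), nrow(calls))
  for (s in 0:2) {
    m <- (calls == s) & obs
    mode(m) <- "numeric"
    match_count <- match_count + m %*% t(m)
  }
  d <- 1 - match_count / joint
  d[joint == 0] <- NA
  diag(d) <- 0
  dimnames(d) <- list(rownames(calls), rownames(calls))
  d
}

#' Per-block simple-matching distance matrices
#'
#' Within each genomic block the genetic distance between two accessions
#' is one minus the simple matching coefficient: the fraction of jointly
#' called sites with identical genotype states.
#'
#' @param x A `cotton_geno`.
#' @param blocks Block tibble (`chrom`, `start`, `end`, `label`), e.g.
#'   `tile_genome(layout, 1e6)`.
#' @return Tibble: block columns plus `n_snps`, `n_missing_pairs` and a
#'   `dist` list-column of accession-by-accession matrices (`NULL` for
#'   blocks without SNPs).
#' @export
block_distances <- function(x, blocks) {
  res <- purrr::map(seq_len(nrow(blocks)), function(i) {
    idx <- which(sites_in_intervals(x, blocks[i, , drop = FALSE]))
    if (length(idx) == 0) return(list(d = NULL, nm = NA_integer_))
    d <- simple_matching(x$calls[, idx, drop = FALSE])
    list(d = d, nm = sum(is.na(d[upper.tri(d)])))
  })
  dplyr::mutate(tibble::as_tibble(blocks),
                n_snps = purrr::map_int(seq_len(nrow(blocks)), function(i) {
                  sum(sites_in_intervals(x, blocks[i, , drop = FALSE]))
                }),
                n_missing_pairs = purrr::map_int(res, "nm"),
                dist = purrr::map(res, "d"))
}

#' Clade placements of accessions in a block tree
#'
#' Roots the tree on the outgroup, finds each species' *core clade* and
#' labels accessions of the other species found inside it. The core
#' clade maximises the net species content (species members minus alien
#' tips; ties resolved towards more species members, then fewer tips)
#' among rooted clades that contain at least `core_fraction` of the
#' species, no outgroup tip, and more than `purity` species tips. The
#' net-content criterion keeps the clade from either ballooning across
#' the other species or opportunistically trimming introgressed
#' accessions that nest basally inside it. When both cores are defined,
#' an accession left outside its own species' core (for instance one
#' attaching as immediate sister to the other species' clade) is
#' assigned to whichever core it is closer to in mean patristic
#' distance.
#'
#' @param tree A `phylo` tree whose tips are accession ids.
#' @param panel Accession panel covering the tips.
#' @param outgroup_ids Outgroup accession ids (>= 1 present in the tree).
#' @param core_fraction Minimum fraction of a species' accessions inside
#'   its core clade (default 0.8).
#' @param purity Minimum fraction of core-clade tips belonging to the
#'   species (default 0.5).
#' @return Tibble `accession`, `species`, `placed_in` (species label) for
#'   each misplaced accession; zero rows when species separate cleanly;
#'   `NULL` with a warning-free `unresolvable` marker when a core clade
#'   cannot be found (returned as attribute-free tibble with
#'   `unresolvable = TRUE`).
#' @export
clade_membership <- function(tree, panel, outgroup_ids,
                             core_fraction = 0.8, purity = 0.5) {
  og <- intersect(outgroup_ids, tree$tip.label)
  if (length(og) == 0) stop("no outgroup taxon in tree", call. = FALSE)
  rooted <- ape::root(tree, outgroup = og, resolve.root = TRUE)
  tips <- rooted$tip.label
  species <- panel$species[match(tips, panel$id)]
  clades <- ape::prop.part(rooted)  # tip-index sets per internal node
  cores <- list()
  unresolvable <- FALSE
  for (sp in c("hirsutum", "barbadense")) {
    sp_tips <- which(species == sp)
    if (length(sp_tips) == 0) next
    need <- core_fraction * length(sp_tips)
    og_tips <- which(species == "outgroup")
    best <- NULL; best_score <- -Inf; best_sp <- -1L; best_size <- Inf
    for (cl in clades) {
      n_sp <- length(intersect(cl, sp_tips))
      score <- 2L * n_sp - length(cl)         # species members minus aliens
      if (n_sp >= need &&
          n_sp > purity * length(cl) &&
          length(intersect(cl, og_tips)) == 0 &&
          (score > best_score ||
             (score == best_score && n_sp > best_sp) ||
             (score == best_score && n_sp == best_sp &&
                length(cl) < best_size))) {
        best <- cl; best_score <- score; best_sp <- n_sp
        best_size <- length(cl)
      }
    }
    if (is.null(best)) { unresolvable <- TRUE; next }
    cores[[sp]] <- best
  }
  out <- list()
  for (sp in names(cores)) {
    alien <- setdiff(cores[[sp]],
                     c(which(species == sp), which(species == "outgroup")))
    if (length(alien) > 0) {
      out[[sp]] <- tibble::tibble(accession = tips[alien],
                                  species = species[alien],
                                  placed_in = sp)
    }
  }
  # Rescue for accessions attaching at a core clade's boundary: an
  # accession outside its own species' core is assigned to whichever
  # core it is closer to in mean patristic distance.
  if (all(c("hirsutum", "barbadense") %in% names(cores))) {
    coph <- ape::cophenetic.phylo(rooted)
    flagged <- unlist(lapply(out, function(d) d$accession))
    for (sp in c("hirsutum", "barbadense")) {
      other <- setdiff(c("hirsutum", "barbadense"), sp)
      loose <- setdiff(which(species == sp),
                       c(cores[[sp]], match(flagged, tips)))
      for (t in loose) {
        d_own <- mean(coph[t, tips[setdiff(cores[[sp]], t)]])
        d_other <- mean(coph[t, tips[setdiff(cores[[other]], t)]])
        if (isTRUE(d_other < d_own)) {
          out[[paste0("rescue_", tips[t])]] <- tibble::tibble(
            accession = tips[t], species = sp, placed_in = other)
        }
      }
    }
  }
  res <- if (length(out) > 0) dplyr::bind_rows(out) else
    tibble::tibble(accession = character(), species = character(),
                   placed_in = character())
  attr(res, "unresolvable") <- unresolvable
  res
}

#' Scan blocks for misplaced accessions
#'
#' Builds the per-block NJ tree from simple-matching distances and runs
#' [clade_membership()] on each block with at least `min_snps` SNPs and
#' complete distances.
#'
#' @param x A `cotton_geno`.
#' @param blocks Block tibble.
#' @param outgroup_ids Outgroup accession ids.
#' @param min_snps Minimum SNPs per usable block (default 10).
#' @param core_fraction Passed to [clade_membership()].
#' @return Tibble of placements with block columns (`block`, `chrom`,
#'   `start`, `end`, `accession`, `species`, `placed_in`).
#' @export
block_placements <- function(x, blocks, outgroup_ids, min_snps = 10,
                             core_fraction = 0.8, purity = 0.5) {
  bd <- block_distances(x, blocks)
  purrr::map_dfr(seq_len(nrow(bd)), function(i) {
    d <- bd$dist[[i]]
    if (is.null(d) || bd$n_snps[i] < min_snps || anyNA(d)) return(NULL)
    tree <- nj_tree(d)
    pl <- clade_membership(tree, x$panel, outgroup_ids, core_fraction, purity)
    if (nrow(pl) == 0) return(NULL)
    dplyr::mutate(pl, block = bd$label[i], chrom = bd$chrom[i],
                  start = bd$start[i], end = bd$end[i], .before = 1)
  })
}

#' Call introgression events from per-block placements
#'
#' One event per (block, direction) supported by at least
#' `min_accessions` misplaced accessions. A hirsutum accession placed in
#' the barbadense clade carries barbadense-like sequence, i.e. gene flow
#' from barbadense into hirsutum (`Gb_to_Gh`), and vice versa.
#'
#' @param placements Tibble from [block_placements()].
#' @param layout Optional [genome_layout()]; adds the block's subgenome.
#' @param min_accessions Minimum supporting accessions (default 2).
#' @return Tibble of events: block columns, `direction`, `subgenome` (if
#'   layout given), `n_accessions`, `accessions` (list-column).
#' @export
call_introgression_events <- function(placements, layout = NULL,
                                      min_accessions = 2) {
  if (is.null(placements) || nrow(placements) == 0) {
    return(tibble::tibble(block = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          direction = character(), n_accessions = integer(),
                          accessions = list()))
  }
  ev <- placements |>
    dplyr::mutate(direction = dplyr::case_when(
      .data$species == "barbadense" & .data$placed_in == "hirsutum" ~ "Gh_to_Gb",
      .data$species == "hirsutum" & .data$placed_in == "barbadense" ~ "Gb_to_Gh",
      TRUE ~ NA_character_
    )) |>
    dplyr::filter(!is.na(.data$direction)) |>
    dplyr::group_by(.data$block, .data$chrom, .data$start, .data$end,
                    .data$direction) |>
    dplyr::summarise(n_accessions = dplyr::n(),
                     accessions = list(.data$accession), .groups = "drop") |>
    dplyr::filter(.data$n_accessions >= min_accessions)
  if (!is.null(layout) && nrow(ev) > 0) {
    ev <- dplyr::mutate(ev, subgenome = subgenome_of(layout, .data$chrom),
                        .after = "direction")
  }
  ev
}

#' Exact/chi-square test for a count imbalance against balance
#'
#' Tests observed counts in two classes (introgression directions, or A
#' versus D subgenome) against the balanced expectation in a 2x2 table
#' `[[n1, n2], [E, E]]` with `E = round((n1 + n2) / 2)`. The default
#' Pearson chi-square (no continuity correction) is the computation that
#' reproduces published analyses of this design; `method = "fisher"`
#' gives the two-sided exact test by hypergeometric point-probability
#' summation.
#'
#' @param n1,n2 Nonnegative integer counts (not both zero).
#' @param method `"chisq"` (default) or `"fisher"`.
#' @return One-row tibble: `n1`, `n2`, `expected`, `method`, `p_value`.
#' @export
#' @examples
#' direction_bias_test(265, 119)
direction_bias_test <- function(n1, n2, method = c("chisq", "fisher")) {
  method <- match.arg(method)
  if (n1 < 0 || n2 < 0 || (n1 + n2) == 0) {
    stop("counts must be nonnegative and not both zero", call. = FALSE)
  }
  e <- round((n1 + n2) / 2)
  tab <- rbind(c(n1, n2), c(e, e))
  p <- if (method == "chisq") {
    suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  } else {
    stats::fisher.test(tab)$p.value
  }
  tibble::tibble(n1 = n1, n2 = n2, expected = e, method = method,
                 p_value = p)
}

#' f3 three-population statistic from per-site allele frequencies
#'
#' `f3(C; A, B)` is the normalised mean over sites of `(c-a)(c-b)`. With
#' `n_target` allele counts supplied, the finite-sample heterozygosity
#' correction `h/n` is subtracted from the numerator and the
#' normalisation uses the unbiased target heterozygosity
#' `2c(1-c)n/(n-1)`; without counts, the plain product and `2c(1-c)` are
#' used. A significantly negative f3 indicates that the target C is
#' admixed between A-like and B-like sources. Standard error and Z score
#' come from a delete-one block jackknife over contiguous site blocks.
#'
#' @param freq_target,freq_src1,freq_src2 Per-site alternate-allele
#'   frequencies (equal length).
#' @param n_target Per-site called allele counts of the target, or
#'   `NULL` to skip the finite-sample correction.
#' @param block Integer block index per site (contiguous blocks; default
#'   splits sites into `n_blocks` equal runs).
#' @param n_blocks Number of jackknife blocks when `block` is `NULL`
#'   (default 20).
#' @return One-row tibble of class `f3_result`: `f3`, `se`, `z`,
#'   `n_sites_used`, `n_blocks`.
#' @export
f3_statistic <- function(freq_target, freq_src1, freq_src2,
                         n_target = NULL, block = NULL, n_blocks = 20) {
  c_ <- freq_target; a <- freq_src1; b <- freq_src2
  stopifnot(length(a) == length(c_), length(b) == length(c_))
  if (is.null(block)) {
    block <- ceiling(seq_along(c_) / (length(c_) / n_blocks))
  }
  if (!is.null(n_target)) {
    h <- ifelse(n_target >= 2,
                2 * c_ * (1 - c_) * n_target / (n_target - 1), NA_real_)
    num <- (c_ - a) * (c_ - b) - h / n_target
    den <- h
  } else {
    num <- (c_ - a) * (c_ - b)
    den <- 2 * c_ * (1 - c_)
  }
  use <- !is.na(num) & !is.na(den) & den > 0
  if (!any(use)) stop("target monomorphic at all usable sites", call. = FALSE)
  num <- num[use]; den <- den[use]; block <- block[use]
  blocks <- unique(block)
  f3_hat <- sum(num) / sum(den)
  nb <- length(blocks)
  se <- if (nb >= 2) {
    theta <- vapply(blocks, function(bl) {
      keep <- block != bl
      sum(num[keep]) / sum(den[keep])
    }, numeric(1))
    sqrt((nb - 1) / nb * sum((theta - mean(theta))^2))
  } else NA_real_
  res <- tibble::tibble(f3 = f3_hat, se = se,
                        z = if (!is.na(se) && se > 0) f3_hat / se else NA_real_,
                        n_sites_used = sum(use), n_blocks = nb)
  class(res) <- c("f3_result", class(res))
  res
}

#' f3 test on a genotype matrix
#'
#' Convenience wrapper computing per-site frequencies for three
#' populations of the panel and running [f3_statistic()] with 1-Mb
#' jackknife blocks (matching the analysis block size).
#'
#' @param x A `cotton_geno`.
#' @param target_ids,src1_ids,src2_ids Accession id sets.
#' @param block_size Jackknife block size in bp (default 1 Mb).
#' @return See [f3_statistic()].
#' @export
f3_test <- function(x, target_ids, src1_ids, src2_ids, block_size = 1e6) {
  ft <- site_frequencies(x, target_ids)
  fa <- site_frequencies(x, src1_ids)
  fb <- site_frequencies(x, src2_ids)
  block <- as.integer(factor(paste0(x$sites$chrom, "_",
                                    x$sites$pos %/% block_size)))
  f3_statistic(ft$freq, fa$freq, fb$freq, n_target = ft$n_called,
               block = block)
}
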