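#' Per-window race/cultivar diversity ratio
#'
#' Joins the two windowed diversity tracks and computes the selection
#' signal `pi_race / pi_cultivar`. Windows with diversity below
#' `min_diversity` in BOTH groups are masked (excluded from the ratio).
#' Windows where the cultivar diversity is exactly zero while the race
#' diversity qualifies get an infinite ratio, which sorts above any
#' finite signal.
#'
#' @param stats_race,stats_cultivar Window tibbles from [window_pi()] on
#'   the same tiling.
#' @param min_diversity Masking threshold (default 0.001 per bp).
#' @return Tibble: window columns plus `pi_race`, `pi_cultivar`, `ratio`,
#'   `masked`.
#' @export
sweep_ratio_profile <- function(stats_race, stats_cultivar,
                                min_diversity = 0.001) {
  if (!identical(stats_race[, c("chrom", "start", "end")],
                 stats_cultivar[, c("chrom", "start", "end")])) {
    stop("window tilings differ between the two tracks", call. = FALSE)
  }
  pr <- stats_race$pi; pc <- stats_cultivar$pi
  masked <- (pr < min_diversity & pc < min_diversity) |
    stats_race$undefined | stats_cultivar$undefined
  ratio <- rep(NA_real_, length(pr))
  live <- !masked
  ratio[live] <- ifelse(pc[live] > 0, pr[live] / pc[live], Inf)
  tibble::tibble(chrom = stats_race$chrom, start = stats_race$start,
                 end = stats_race$end, pi_race = pr, pi_cultivar = pc,
                 ratio = ratio, masked = masked)
}

#' Call selective-sweep regions from a ratio track
#'
#' Windows with `ratio > threshold` are merged into regions when directly
#' adjacent on the same chromosome; a masked or sub-threshold window
#' breaks a region. Masked windows never join a region.
#'
#' @param ratio_track Output of [sweep_ratio_profile()].
#' @param threshold Ratio threshold (strict `>`; default 25).
#' @return Tibble of sweep regions: `sweep_id`, `chrom`, `start`, `end`,
#'   `n_windows`, `max_ratio`, `mean_ratio` (means/maxima over member
#'   windows; infinite member ratios propagate to `max_ratio`).
#' @export
call_sweeps <- function(ratio_track, threshold = 25) {
  hot <- !ratio_track$masked & !is.na(ratio_track$ratio) &
    ratio_track$ratio > threshold
  if (!any(hot)) {
    return(tibble::tibble(sweep_id = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          n_windows = integer(), max_ratio = numeric(),
                          mean_ratio = numeric()))
  }
  d <- dplyr::mutate(ratio_track, hot = hot,
                     new_run = hot & !dplyr::lag(hot, default = FALSE) |
                       hot & .data$chrom != dplyr::lag(.data$chrom,
                                                       default = ""))
  d$run <- cumsum(d$new_run)
  d <- d[d$hot, , drop = FALSE]
  out <- d |>
    dplyr::group_by(.data$run) |>
    dplyr::summarise(chrom = .data$chrom[1], start = min(.data$start),
                     end = max(.data$end), n_windows = dplyr::n(),
                     max_ratio = max(.data$ratio),
                     mean_ratio = mean(.data$ratio), .groups = "drop") |>
    dplyr::arrange(.data$chrom, .data$start)
  dplyr::mutate(out, sweep_id = sprintf("sweep%03d", dplyr::row_number()),
                .before = 1) |>
    dplyr::select(-"run")
}

#' Permutation estimate of the sweep-scan false-positive rate
#'
#' Race/cultivar labels are shuffled among the combined accession set
#' (group sizes preserved), the ratio track is recomputed, and the
#' fraction of unmasked windows exceeding the threshold is recorded for
#' each permutation.
#'
#' @param x A `cotton_geno`.
#' @param race_ids,cultivar_ids The two groups' accession ids (>= 3
#'   each).
#' @param windows Window tibble.
#' @param threshold Ratio threshold (default 25).
#' @param n_perm Number of permutations (>= 100 recommended).
#' @param seed Integer seed.
#' @param min_diversity Masking threshold passed to
#'   [sweep_ratio_profile()].
#' @return A list: `fpr` (mean exceedance fraction), `per_perm` (tibble
#'   with per-permutation exceedance fractions).
#' @export
permutation_fpr <- function(x, race_ids, cultivar_ids, windows,
                            threshold = 25, n_perm = 200, seed = 1L,
                            min_diversity = 0.001) {
  if (length(race_ids) < 3 || length(cultivar_ids) < 3) {
    stop("groups too small to permute (< 3 accessions)", call. = FALSE)
  }
  pool <- c(race_ids, cultivar_ids)
  n_r <- length(race_ids)
  wi <- site_window_index(x, windows)     # fixed across permutations
  wlen <- windows$end - windows$start
  n_w <- nrow(windows)
  pool_rows <- match(pool, x$panel$id)
  win_pi <- function(rows) {
    calls <- x$calls[rows, , drop = FALSE]
    nc <- 2 * colSums(!is.na(calls))
    p <- ifelse(nc > 0, colSums(calls, na.rm = TRUE) / nc, NA_real_)
    het <- ifelse(nc >= 2, 2 * p * (1 - p) * nc / (nc - 1), NA_real_)
    use <- !is.na(wi) & !is.na(het)
    s <- rep(0, n_w)
    if (any(use)) {
      agg <- rowsum(het[use], wi[use], reorder = TRUE)
      s[as.integer(rownames(agg))] <- agg[, 1]
    }
    s / wlen
  }
  with_seed(seed, {
    frac <- vapply(seq_len(n_perm), function(p) {
      perm <- sample(pool_rows)
      pr <- win_pi(perm[seq_len(n_r)])
      pc <- win_pi(perm[-seq_len(n_r)])
      live <- !(pr < min_diversity & pc < min_diversity)
      ratio <- ifelse(pc > 0, pr / pc, Inf)
      if (!any(live)) return(0)
      mean(ratio[live] > threshold)
    }, numeric(1))
    list(fpr = mean(frac),
         per_perm = tibble::tibble(perm = seq_len(n_perm),
                                   exceedance = frac))
  })
}

# Map an interval through the homoeolog map onto the partner subgenome.
# Proportional coordinate transfer within each overlapping segment pair.
map_homoeolog <- function(layout, chrom, start, end) {
  hm <- layout$homoeolog_map
  if (is.null(hm)) stop("layout has no homoeolog map", call. = FALSE)
  sg <- subgenome_of(layout, chrom)
  if (sg == "A") {
    rows <- hm[hm$a_chrom == chrom & hm$a_start < end & hm$a_end > start, ]
    src <- rows[, c("a_start", "a_end")]; dst <- rows[, c("d_start", "d_end")]
    dchrom <- rows$d_chrom
  } else {
    rows <- hm[hm$d_chrom == chrom & hm$d_start < end & hm$d_end > start, ]
    src <- rows[, c("d_start", "d_end")]; dst <- rows[, c("a_start", "a_end")]
    dchrom <- rows$a_chrom
  }
  if (nrow(rows) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric()))
  }
  purrr::map_dfr(seq_len(nrow(rows)), function(i) {
    s <- max(start, src[[1]][i]); e <- min(end, src[[2]][i])
    scale <- (dst[[2]][i] - dst[[1]][i]) / (src[[2]][i] - src[[1]][i])
    tibble::tibble(chrom = dchrom[i],
                   start = dst[[1]][i] + (s - src[[1]][i]) * scale,
                   end = dst[[1]][i] + (e - src[[1]][i]) * scale)
  })
}

#' Pair selective sweeps across homoeologous subgenome regions
#'
#' A sweep is paired when its interval, mapped through the homoeolog map
#' onto the partner subgenome, covers at least one window whose ratio
#' exceeds `partner_threshold`. Pairing is symmetric in the A/D
#' direction.
#'
#' @param sweeps Sweep tibble from [call_sweeps()].
#' @param ratio_track Full ratio track (both subgenomes).
#' @param layout A [genome_layout()] with a homoeolog map covering the
#'   sweep chromosomes.
#' @param partner_threshold Ratio required on the partner interval
#'   (default 15, admitting modest partner signals).
#' @return Tibble of pairs: `sweep_id`, `partner_chrom`,
#'   `partner_start`, `partner_end`, `partner_max_ratio`.
#' @export
homoeolog_pairs <- function(sweeps, ratio_track, layout,
                            partner_threshold = 15) {
  out <- purrr::map_dfr(seq_len(nrow(sweeps)), function(i) {
    sw <- sweeps[i, ]
    tgt <- map_homoeolog(layout, sw$chrom, sw$start, sw$end)
    if (nrow(tgt) == 0) return(NULL)
    hits <- purrr::map_dfr(seq_len(nrow(tgt)), function(k) {
      w <- ratio_track[ratio_track$chrom == tgt$chrom[k] &
                         ratio_track$start < tgt$end[k] &
                         ratio_track$end > tgt$start[k] &
                         !ratio_track$masked &
                         !is.na(ratio_track$ratio), , drop = FALSE]
      w[w$ratio > partner_threshold, , drop = FALSE]
    })
    if (nrow(hits) == 0) return(NULL)
    tibble::tibble(sweep_id = sw$sweep_id,
                   partner_chrom = hits$chrom[1],
                   partner_start = min(hits$start),
                   partner_end = max(hits$end),
                   partner_max_ratio = max(hits$ratio))
  })
  if (nrow(out) == 0) {
    out <- tibble::tibble(sweep_id = character(), partner_chrom = character(),
                          partner_start = numeric(), partner_end = numeric(),
                          partner_max_ratio = numeric())
  }
  out
}

#' Overlap sweeps with QTL intervals
#'
#' Strict half-open interval intersection (an abutting QTL does not
#' overlap), with an optional symmetric flank.
#'
#' @param sweeps Sweep tibble (`sweep_id`, `chrom`, `start`, `end`).
#' @param qtl Interval tibble (`chrom`, `start`, `end`, `label`).
#' @param flank Flank in bp added to each sweep side (default 0).
#' @return A list: `overlaps` (tibble `sweep_id`, `qtl`), and `summary`
#'   (one-row tibble `n_sweeps_with_qtl`, `n_qtl_near_sweeps`).
#' @export
qtl_overlap <- function(sweeps, qtl, flank = 0) {
  hits <- purrr::map_dfr(seq_len(nrow(sweeps)), function(i) {
    sw <- sweeps[i, ]
    q <- qtl[qtl$chrom == sw$chrom & qtl$start < sw$end + flank &
               qtl$end > sw$start - flank, , drop = FALSE]
    if (nrow(q) == 0) return(NULL)
    tibble::tibble(sweep_id = sw$sweep_id, qtl = q$label)
  })
  if (nrow(hits) == 0) {
    hits <- tibble::tibble(sweep_id = character(), qtl = character())
  }
  list(overlaps = hits,
       summary = tibble::tibble(
         n_sweeps_with_qtl = dplyr::n_distinct(hits$sweep_id),
         n_qtl_near_sweeps = dplyr::n_distinct(hits$qtl)))
}
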