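#' Pipeline run configuration
#'
#' Bundles every stage parameter of the end-to-end scans. All randomness
#' flows from `seed` via fixed offsets per stage (simulation, sweep
#' planting, introgression planting, spacing filter, permutations), so a
#' rerun with the same config is bit-identical.
#'
#' @param sim A [sim_config()] (its own seed is overridden by `seed`).
#' @param out_dir Output directory (created if missing).
#' @param seed Master integer seed.
#' @param window_size Diversity window size in bp (default 100 kb).
#' @param block_size Introgression block size in bp (default 1 Mb).
#' @param maf,miss,min_gap,min_carriers Variant-filter parameters.
#' @param threshold Sweep ratio threshold (default 25).
#' @param n_perm Permutations for the false-positive estimate.
#' @param min_event_accessions Event support threshold (default 2).
#' @param sweep_windows,introgression_events Optional plantings (see
#'   [plant_sweeps()], [plant_introgressions()]).
#' @param qtl Optional QTL interval tibble.
#' @return List of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), out_dir = tempfile("cottonpop_"),
                       seed = 1L, window_size = 1e5, block_size = 1e6,
                       maf = 0.05, miss = 0.10, min_gap = 10,
                       min_carriers = 2, threshold = 25, n_perm = 200,
                       min_event_accessions = 2, sweep_windows = NULL,
                       introgression_events = NULL, qtl = NULL) {
  sim$seed <- as.integer(seed)
  structure(list(sim = sim, out_dir = out_dir, seed = as.integer(seed),
                 window_size = window_size, block_size = block_size,
                 maf = maf, miss = miss, min_gap = min_gap,
                 min_carriers = min_carriers, threshold = threshold,
                 n_perm = n_perm,
                 min_event_accessions = min_event_accessions,
                 sweep_windows = sweep_windows,
                 introgression_events = introgression_events, qtl = qtl),
            class = "run_config")
}

run_stage <- function(stage, expr) {
  tryCatch(force(expr), error = function(e) {
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

manifest_of <- function(out_dir, seed) {
  files <- sort(list.files(out_dir, full.names = TRUE))
  tibble::tibble(file = basename(files),
                 md5 = unname(tools::md5sum(files)),
                 seed = seed)
}

# simulate + filter cascade shared by both scans
prepare_matrix <- function(config) {
  geno <- run_stage("simulate", {
    g <- simulate_genotypes(config$sim)
    if (!is.null(config$sweep_windows)) {
      g <- plant_sweeps(g, config$sweep_windows, seed = config$seed + 101L)
    }
    if (!is.null(config$introgression_events)) {
      g <- plant_introgressions(g, config$introgression_events,
                                seed = config$seed + 202L)
    }
    g
  })
  run_stage("filter", {
    geno |>
      nonsingleton_filter(min_accessions = config$min_carriers) |>
      maf_missing_filter(maf = config$maf, miss = config$miss) |>
      spacing_filter(min_gap = config$min_gap, seed = config$seed + 303L)
  })
}

#' Run the domestication sweep scan end to end
#'
#' Simulate (with optional planted sweeps), filter, compute windowed
#' race/cultivar diversity, call sweeps, estimate the permutation false
#' positive rate, and write a BED of sweep regions, a window-stats TSV
#' and a JSON manifest with md5 checksums.
#'
#' @param config A [run_config()].
#' @return The manifest tibble, invisibly; files under
#'   `config$out_dir`.
#' @export
run_domestication_scan <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  filtered <- prepare_matrix(config)
  res <- run_stage("stats", {
    windows <- tile_genome(config$sim$layout, config$window_size)
    race <- panel_ids(filtered$panel, species = "hirsutum", group = "race")
    cult <- panel_ids(filtered$panel, species = "hirsutum", group = "cultivar")
    pr <- window_pi(filtered, race, windows)
    pc <- window_pi(filtered, cult, windows)
    list(track = sweep_ratio_profile(pr, pc), race = race, cult = cult,
         windows = windows)
  })
  sweeps <- run_stage("sweep", call_sweeps(res$track, config$threshold))
  fpr <- run_stage("permutation",
                   permutation_fpr(filtered, res$race, res$cult,
                                   res$windows, threshold = config$threshold,
                                   n_perm = config$n_perm,
                                   seed = config$seed + 404L))
  run_stage("write", {
    readr::write_tsv(res$track, file.path(config$out_dir, "ratio_track.tsv"))
    write_bed(tibble::tibble(chrom = sweeps$chrom, start = sweeps$start,
                             end = sweeps$end, label = sweeps$sweep_id),
              file.path(config$out_dir, "sweeps.bed"))
    readr::write_tsv(sweeps, file.path(config$out_dir, "sweeps.tsv"))
    if (!is.null(config$qtl)) {
      ov <- qtl_overlap(sweeps, config$qtl)
      readr::write_tsv(ov$overlaps,
                       file.path(config$out_dir, "qtl_overlap.tsv"))
    }
    jsonlite::write_json(list(fpr = fpr$fpr, threshold = config$threshold,
                              n_perm = config$n_perm, seed = config$seed),
                         file.path(config$out_dir, "sweep_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  })
  manifest <- manifest_of(config$out_dir, config$seed)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"))
  invisible(manifest)
}

#' Run the introgression scan end to end
#'
#' Simulate (with optional planted introgression blocks), filter, build
#' per-block NJ trees, call events, run the direction and subgenome bias
#' tests, and compute the f3 statistic for the
#' (barbadense; hirsutum-race, outgroup) configuration. Writes an event
#' TSV, per-block newick trees, a JSON test report and a manifest.
#'
#' @param config A [run_config()]; the panel must contain outgroup
#'   accessions.
#' @return The manifest tibble, invisibly.
#' @export
run_introgression_scan <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  filtered <- prepare_matrix(config)
  outg <- panel_ids(filtered$panel, species = "outgroup")
  if (length(outg) == 0) stop("[stage blocks] no outgroup in panel",
                              call. = FALSE)
  blocks <- tile_genome(config$sim$layout, config$block_size)
  placements <- run_stage("trees",
                          block_placements(filtered, blocks, outg))
  events <- run_stage("events",
                      call_introgression_events(
                        placements, layout = config$sim$layout,
                        min_accessions = config$min_event_accessions))
  report <- run_stage("tests", {
    n_gh <- sum(events$direction == "Gh_to_Gb")
    n_gb <- sum(events$direction == "Gb_to_Gh")
    dir_p <- if (n_gh + n_gb > 0) direction_bias_test(n_gh, n_gb)$p_value
             else NA_real_
    n_a <- sum(events$subgenome == "A")
    n_d <- sum(events$subgenome == "D")
    sub_p <- if (n_a + n_d > 0) direction_bias_test(n_a, n_d)$p_value
             else NA_real_
    f3 <- tryCatch(
      f3_test(filtered,
              target_ids = panel_ids(filtered$panel, species = "barbadense"),
              src1_ids = panel_ids(filtered$panel, species = "hirsutum",
                                   group = "race"),
              src2_ids = outg, block_size = config$block_size),
      error = function(e) NULL)
    list(n_gh_to_gb = n_gh, n_gb_to_gh = n_gb, direction_p = dir_p,
         n_subgenome_a = n_a, n_subgenome_d = n_d, subgenome_p = sub_p,
         f3 = if (is.null(f3)) NULL else
           list(f3 = f3$f3, se = f3$se, z = f3$z))
  })
  run_stage("write", {
    ev_out <- events
    if (nrow(ev_out) > 0) {
      ev_out$accessions <- purrr::map_chr(ev_out$accessions, paste,
                                          collapse = ",")
    }
    readr::write_tsv(ev_out, file.path(config$out_dir, "events.tsv"))
    bd <- block_distances(filtered, blocks)
    trees <- purrr::compact(purrr::map(seq_len(nrow(bd)), function(i) {
      d <- bd$dist[[i]]
      if (is.null(d) || anyNA(d) || nrow(d) < 3) return(NULL)
      ape::write.tree(nj_tree(d))
    }))
    writeLines(unlist(trees), file.path(config$out_dir, "block_trees.nwk"))
    jsonlite::write_json(report,
                         file.path(config$out_dir, "introgression_report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  })
  manifest <- manifest_of(config$out_dir, config$seed)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"))
  invisible(manifest)
}
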