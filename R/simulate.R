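#' Simulation configuration for a two-species allotetraploid panel
#'
#' Defines the study conditions the synthetic genotypes emulate: two
#' diverged tetraploid species (G. hirsutum and G. barbadense analogues)
#' sharing A and D subgenome chromosomes, a race/cultivar split inside
#' hirsutum with a strong domestication bottleneck on the cultivars, a
#' fraction of sites at alternate fixation between the species, missing
#' genotypes, and a small distant outgroup for tree rooting.
#'
#' Drift is parameterised Balding-Nichols style: the expected
#' heterozygosity after drifting with coefficient `F` is `(1 - F)` times
#' the parental heterozygosity, so the default race/cultivar pair
#' (`f_race = 0.25`, `f_cultivar = 0.75`) yields an expected
#' cultivar-to-race diversity ratio of (1-0.75)/(1-0.25) = 1/3, the
#' magnitude of the domestication bottleneck seen in upland cotton
#' resequencing panels (~34%).
#'
#' @param layout A [genome_layout()] (default: [default_layout()]).
#' @param n_race,n_cultivar,n_barbadense,n_outgroup Accession counts per
#'   group.
#' @param snp_density Expected SNPs per kb (default 15, calibrated so the
#'   realized race-group diversity is about 0.002 per bp, the scale seen
#'   in upland cotton races, comfortably above the 0.001 masking floor of
#'   the sweep scan).
#' @param f_species Species-split drift coefficient in (0,1).
#' @param f_race,f_cultivar,f_barbadense Group-level drift coefficients
#'   applied on top of the species frequencies.
#' @param f_outgroup Drift of the outgroup from the ancestral frequencies.
#' @param fixed_diff_fraction Share of sites forced to alternate fixation
#'   between the two species.
#' @param missing_rate Per-genotype missing probability.
#' @param seed Integer seed; same seed, same data, bit for bit.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(layout = default_layout(),
                       n_race = 16, n_cultivar = 24, n_barbadense = 24,
                       n_outgroup = 3,
                       snp_density = 15,
                       f_species = 0.1,
                       f_race = 0.25, f_cultivar = 0.75, f_barbadense = 0.5,
                       f_outgroup = 0.8,
                       fixed_diff_fraction = 0.3,
                       missing_rate = 0.05,
                       seed = 1L) {
  rates <- c(fixed_diff_fraction = fixed_diff_fraction,
             missing_rate = missing_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]", call. = FALSE)
  fs <- c(f_species, f_race, f_cultivar, f_barbadense, f_outgroup)
  if (any(fs <= 0 | fs >= 1)) stop("drift coefficients must lie in (0, 1)",
                                   call. = FALSE)
  structure(list(layout = layout, n_race = n_race, n_cultivar = n_cultivar,
                 n_barbadense = n_barbadense, n_outgroup = n_outgroup,
                 snp_density = snp_density, f_species = f_species,
                 f_race = f_race, f_cultivar = f_cultivar,
                 f_barbadense = f_barbadense, f_outgroup = f_outgroup,
                 fixed_diff_fraction = fixed_diff_fraction,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_config")
}

# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Balding-Nichols drift: child frequency ~ Beta(p(1-F)/F, (1-p)(1-F)/F).
# Frequencies of exactly 0 or 1 stay fixed.
bn_drift <- function(p, f) {
  q <- p
  mid <- p > 0 & p < 1
  k <- (1 - f) / f
  q[mid] <- stats::rbeta(sum(mid), p[mid] * k, (1 - p[mid]) * k)
  q
}

#' Simulate a genotype matrix under the hierarchical drift model
#'
#' Ancestral allele frequencies are drawn uniformly on (0.05, 0.95); the
#' two species drift from the ancestor with `f_species`
#' (Balding-Nichols beta sampling); a `fixed_diff_fraction` of sites is
#' instead set to alternate fixation (1,0) or (0,1) between the species;
#' the groups (hirsutum races, hirsutum cultivars, barbadense cultivars)
#' drift further from their species frequency; the outgroup drifts heavily
#' from the ancestor. Genotypes are Binomial(2, group frequency) and
#' missing entries are masked at `missing_rate`.
#'
#' @param config A [sim_config()].
#' @return A [geno_matrix()] with a `truth` attribute: a list with the
#'   per-site group frequencies (`freqs`), the per-site class
#'   (`site_class`, `"drift"` or `"fixed_diff"`), and the config.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  counts <- c(config$n_race, config$n_cultivar, config$n_barbadense,
              config$n_outgroup)
  if (any(counts[1:3] < 2) || counts[4] < 1) {
    stop("need >= 2 accessions in race/cultivar/barbadense and >= 1 outgroup",
         call. = FALSE)
  }
  with_seed(config$seed, {
    chroms <- config$layout$chromosomes
    sites <- purrr::pmap_dfr(chroms[, c("chrom", "length")],
      function(chrom, length) {
        n <- max(1L, round(length / 1000 * config$snp_density))
        pos <- sort(sample.int(length, n))
        tibble::tibble(chrom = chrom, pos = pos)
      })
    bases <- c("A", "C", "G", "T")
    n_site <- nrow(sites)
    ref <- sample(bases, n_site, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
    sites <- dplyr::mutate(sites, ref = ref, alt = unname(alt),
                           vtype = "snp", indel_length = 0L)

    p_anc <- stats::runif(n_site, 0.05, 0.95)
    site_class <- rep("drift", n_site)
    n_fix <- round(config$fixed_diff_fraction * n_site)
    fix_idx <- if (n_fix > 0) sample.int(n_site, n_fix) else integer(0)
    site_class[fix_idx] <- "fixed_diff"

    p_hir <- bn_drift(p_anc, config$f_species)
    p_bar <- bn_drift(p_anc, config$f_species)
    if (n_fix > 0) {
      hir_alt <- stats::runif(n_fix) < 0.5
      p_hir[fix_idx] <- as.numeric(hir_alt)
      p_bar[fix_idx] <- as.numeric(!hir_alt)
    }
    freqs <- list(
      race = bn_drift(p_hir, config$f_race),
      cultivar = bn_drift(p_hir, config$f_cultivar),
      barbadense = bn_drift(p_bar, config$f_barbadense),
      outgroup = bn_drift(p_anc, config$f_outgroup)
    )

    panel <- accession_panel(
      id = c(sprintf("race%02d", seq_len(config$n_race)),
             sprintf("cult%02d", seq_len(config$n_cultivar)),
             sprintf("barb%02d", seq_len(config$n_barbadense)),
             sprintf("outg%02d", seq_len(config$n_outgroup))),
      species = rep(c("hirsutum", "hirsutum", "barbadense", "outgroup"),
                    counts),
      group = rep(c("race", "cultivar", "cultivar", "outgroup"), counts),
      origin = rep(c("synthetic race", "synthetic cultivar",
                     "synthetic barbadense", "synthetic outgroup"), counts)
    )
    group_of <- rep(c("race", "cultivar", "barbadense", "outgroup"), counts)
    calls <- matrix(NA_integer_, nrow = nrow(panel), ncol = n_site,
                    dimnames = list(panel$id, NULL))
    for (g in names(freqs)) {
      rows <- which(group_of == g)
      calls[rows, ] <- stats::rbinom(length(rows) * n_site, 2,
                                     rep(freqs[[g]], each = length(rows)))
    }
    if (config$missing_rate > 0) {
      calls[stats::runif(length(calls)) < config$missing_rate] <- NA_integer_
    }
    out <- geno_matrix(calls, sites, panel)
    attr(out, "truth") <- list(freqs = freqs, site_class = site_class,
                               config = config)
    out
  })
}

#' Plant selective sweeps into a genotype matrix
#'
#' Inside each window, cultivar-group genotypes (hirsutum cultivars) are
#' redrawn from frequencies pushed towards fixation by `suppression`,
#' emulating the near-loss of diversity at a domestication sweep; race
#' genotypes are untouched. `suppression = 1` fixes the window's major
#' allele in the cultivars (window pi = 0); the default 0.97 targets a
#' realized race/cultivar diversity ratio around 50 under the default
#' drift settings.
#'
#' @param x A `cotton_geno` (typically from [simulate_genotypes()]).
#' @param sweep_windows Tibble with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param suppression Fraction in `[0, 1]` of the distance to fixation.
#' @param seed Integer seed for the redraw.
#' @return The modified `cotton_geno`; a `planted_sweeps` attribute
#'   records the windows.
#' @export
plant_sweeps <- function(x, sweep_windows, suppression = 0.97, seed = 1L) {
  stopifnot(suppression >= 0, suppression <= 1)
  if (is.null(sweep_windows) || nrow(sweep_windows) == 0) return(x)
  cult <- x$panel$id[x$panel$species == "hirsutum" &
                       x$panel$group == "cultivar"]
  rows <- match(cult, x$panel$id)
  with_seed(seed, {
    for (i in seq_len(nrow(sweep_windows))) {
      idx <- which(sites_in_intervals(x, sweep_windows[i, , drop = FALSE]))
      if (length(idx) == 0) stop("sweep window contains no sites", call. = FALSE)
      sub <- x$calls[rows, idx, drop = FALSE]
      called <- colSums(!is.na(sub))
      p <- ifelse(called > 0, colSums(sub, na.rm = TRUE) / (2 * called), 0.5)
      target <- as.numeric(p >= 0.5)
      p_new <- (1 - suppression) * p + suppression * target
      redraw <- matrix(stats::rbinom(length(rows) * length(idx), 2,
                                     rep(p_new, each = length(rows))),
                       nrow = length(rows))
      redraw[is.na(sub)] <- NA_integer_
      x$calls[rows, idx] <- redraw
    }
    attr(x, "planted_sweeps") <- sweep_windows
    x
  })
}

#' Plant interspecific introgression blocks
#'
#' For each event, the recipient accessions' genotypes inside the block
#' are replaced by draws from the donor species' realized allele
#' frequencies (computed from the non-recipient accessions of the donor
#' species), emulating a donor-like haplotype tract.
#'
#' @param x A `cotton_geno`.
#' @param events Tibble with columns `chrom`, `start`, `end` (0-based
#'   half-open), `donor_species` (`"hirsutum"`/`"barbadense"`), and
#'   `recipients` (list-column of accession id vectors).
#' @param seed Integer seed.
#' @return The modified `cotton_geno`; a `planted_introgressions`
#'   attribute records the events with their direction.
#' @export
plant_introgressions <- function(x, events, seed = 1L) {
  if (is.null(events) || nrow(events) == 0) return(x)
  with_seed(seed, {
    for (i in seq_len(nrow(events))) {
      ev <- events[i, ]
      rec <- ev$recipients[[1]]
      if (length(rec) < 1) stop("event needs >= 1 recipient", call. = FALSE)
      if (!all(rec %in% x$panel$id)) stop("recipient not in panel", call. = FALSE)
      if (!ev$chrom %in% x$sites$chrom) {
        stop("event block on unknown chromosome ", ev$chrom, call. = FALSE)
      }
      idx <- which(sites_in_intervals(x, ev[, c("chrom", "start", "end")]))
      if (length(idx) == 0) next
      donor_ids <- setdiff(x$panel$id[x$panel$species == ev$donor_species], rec)
      if (length(donor_ids) == 0) stop("donor species empty", call. = FALSE)
      don <- x$calls[match(donor_ids, x$panel$id), idx, drop = FALSE]
      called <- colSums(!is.na(don))
      p <- ifelse(called > 0, colSums(don, na.rm = TRUE) / (2 * called), 0.5)
      rows <- match(rec, x$panel$id)
      sub <- x$calls[rows, idx, drop = FALSE]
      redraw <- matrix(stats::rbinom(length(rows) * length(idx), 2,
                                     rep(p, each = length(rows))),
                       nrow = length(rows))
      redraw[is.na(sub)] <- NA_integer_
      x$calls[rows, idx] <- redraw
    }
    rec_species <- purrr::map_chr(events$recipients, function(r) {
      sp <- unique(x$panel$species[match(r, x$panel$id)])
      if (length(sp) != 1) "mixed" else sp
    })
    attr(x, "planted_introgressions") <- dplyr::mutate(
      events,
      direction = dplyr::case_when(
        events$donor_species == "hirsutum" & rec_species == "barbadense" ~ "Gh_to_Gb",
        events$donor_species == "barbadense" & rec_species == "hirsutum" ~ "Gb_to_Gh",
        TRUE ~ "other"
      )
    )
    x
  })
}
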