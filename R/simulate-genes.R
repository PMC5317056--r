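# Standard genetic code, DNA alphabet.
GENETIC_CODE_DNA <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

translate_codon <- function(codon) unname(GENETIC_CODE_DNA[codon])

revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         vapply(s, function(x) paste(rev(strsplit(x, "")[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}

#' Simulate gene models with planted coding variants
#'
#' Places `n_genes` non-overlapping single-exon genes with valid open
#' reading frames (ATG start, no internal stop, terminal stop) on random
#' chromosomes and strands of the layout, generates a random reference
#' sequence, and plants coding SNPs and indels whose functional effect
#' (synonymous, nonsynonymous, stop gained, frameshift, in-frame indel) is
#' recorded as truth at construction time from the planted codon itself.
#'
#' @param layout A [genome_layout()].
#' @param n_genes Number of genes (>= 1).
#' @param n_variants Number of coding variants to plant.
#' @param cds_codons Number of codons per CDS including start and stop
#'   (default 101, i.e. a 303-bp CDS).
#' @param seed Integer seed.
#' @return A list with `models` (gene-model tibble as from [read_gff()]),
#'   `genome` (named character vector of chromosome sequences), and
#'   `variants` (tibble of planted sites with a `truth` effect column,
#'   usable as the `sites` of a genotype matrix).
#' @export
simulate_gene_models <- function(layout, n_genes, n_variants = 100,
                                 cds_codons = 101, seed = 1L) {
  stopifnot(n_genes >= 1, cds_codons >= 5)
  chroms <- layout$chromosomes
  cds_len <- 3L * cds_codons
  if (sum(floor(chroms$length / (cds_len + 200))) < n_genes) {
    stop("genome too small for n_genes", call. = FALSE)
  }
  bases <- c("A", "C", "G", "T")
  stops <- c("TAA", "TAG", "TGA")
  codons <- names(GENETIC_CODE_DNA)
  sense <- setdiff(codons, stops)

  with_seed(seed, {
    genome <- stats::setNames(vapply(chroms$length, function(L) {
      paste(sample(bases, L, replace = TRUE), collapse = "")
    }, character(1)), chroms$chrom)

    # lay genes down left to right with random gaps, round-robin chromosomes
    slots <- purrr::pmap_dfr(chroms[, c("chrom", "length")],
      function(chrom, length) {
        n_fit <- floor(length / (cds_len + 1000))
        if (n_fit == 0) return(NULL)
        start <- (seq_len(n_fit) - 1L) * (cds_len + 1000L) +
          sample.int(500, n_fit, replace = TRUE)
        tibble::tibble(chrom = chrom, start = start)
      })
    slots <- slots[sample.int(nrow(slots), n_genes), , drop = FALSE]
    slots <- dplyr::arrange(slots, .data$chrom, .data$start)

    models <- vector("list", n_genes)
    for (i in seq_len(n_genes)) {
      body <- paste(sample(sense, cds_codons - 2L, replace = TRUE),
                    collapse = "")
      orf <- paste0("ATG", body, sample(stops, 1))
      strand <- sample(c("+", "-"), 1)
      g_start <- slots$start[i] + 1L  # 1-based
      g_end <- g_start + cds_len - 1L
      chrom <- slots$chrom[i]
      genomic <- if (strand == "+") orf else revcomp(orf)
      substr(genome[[chrom]], g_start, g_end) <- genomic
      models[[i]] <- tibble::tibble(
        gene_id = sprintf("gene%03d", i), chrom = chrom, strand = strand,
        length_ok = TRUE,
        cds = list(tibble::tibble(start = g_start, end = g_end, phase = 0L))
      )
    }
    models <- dplyr::bind_rows(models)

    variants <- vector("list", n_variants)
    for (v in seq_len(n_variants)) {
      gi <- sample.int(n_genes, 1)
      m <- models[gi, ]
      seg <- m$cds[[1]]
      kind <- sample(c("snp", "indel"), 1, prob = c(0.7, 0.3))
      if (kind == "snp") {
        # pick a codon (not start/stop) and position within it
        codon_i <- sample(2:(cds_codons - 1L), 1)
        within <- sample.int(3L, 1)
        t_off <- (codon_i - 1L) * 3L + within      # 1-based offset in ORF
        orf <- if (m$strand == "+")
          substr(genome[[m$chrom]], seg$start, seg$end)
        else revcomp(substr(genome[[m$chrom]], seg$start, seg$end))
        codon <- substr(orf, (codon_i - 1L) * 3L + 1L, codon_i * 3L)
        ref_t <- substr(codon, within, within)
        alt_t <- sample(setdiff(bases, ref_t), 1)
        new_codon <- codon
        substr(new_codon, within, within) <- alt_t
        aa0 <- translate_codon(codon); aa1 <- translate_codon(new_codon)
        truth <- if (aa1 == "*") "stop_gained"
                 else if (aa0 == aa1) "synonymous" else "nonsynonymous"
        # genomic position and alleles
        if (m$strand == "+") {
          pos <- seg$start + t_off - 1L
          ref <- ref_t; alt <- alt_t
        } else {
          pos <- seg$end - t_off + 1L
          ref <- chartr("ACGT", "TGCA", ref_t)
          alt <- chartr("ACGT", "TGCA", alt_t)
        }
        variants[[v]] <- tibble::tibble(
          chrom = m$chrom, pos = pos, ref = ref, alt = alt, vtype = "snp",
          indel_length = 0L, gene_id = m$gene_id, truth = truth
        )
      } else {
        ilen <- sample.int(4L, 1)
        pos <- sample((seg$start + 3L):(seg$end - 6L - ilen), 1)
        del <- stats::runif(1) < 0.5
        anchor <- substr(genome[[m$chrom]], pos, pos)
        if (del) {
          ref <- substr(genome[[m$chrom]], pos, pos + ilen)
          alt <- anchor
          delta <- -ilen
        } else {
          ref <- anchor
          alt <- paste0(anchor, paste(sample(bases, ilen, replace = TRUE),
                                      collapse = ""))
          delta <- ilen
        }
        variants[[v]] <- tibble::tibble(
          chrom = m$chrom, pos = pos, ref = ref, alt = alt, vtype = "indel",
          indel_length = delta, gene_id = m$gene_id,
          truth = if (ilen %% 3L == 0L) "inframe_indel" else "frameshift"
        )
      }
    }
    variants <- dplyr::bind_rows(variants) |>
      dplyr::distinct(.data$chrom, .data$pos, .keep_all = TRUE) |>
      dplyr::arrange(.data$chrom, .data$pos)
    list(models = models, genome = genome, variants = variants)
  })
}

#' Write gene models as GFF3
#'
#' @param models Gene-model tibble (as from [read_gff()] or
#'   [simulate_gene_models()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff <- function(models, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    seg <- m$cds[[1]]
    lo <- min(seg$start); hi <- max(seg$end)
    lines <- c(lines,
      paste(m$chrom, "cottonpop", "gene", lo, hi, ".", m$strand, ".",
            paste0("ID=", m$gene_id, ".g"), sep = "\t"),
      paste(m$chrom, "cottonpop", "mRNA", lo, hi, ".", m$strand, ".",
            paste0("ID=", m$gene_id, ";Parent=", m$gene_id, ".g"), sep = "\t"),
      paste(m$chrom, "cottonpop", "CDS", seg$start, seg$end, ".", m$strand,
            seg$phase, paste0("Parent=", m$gene_id), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Simulate a tissue FPKM expression matrix with planted specific genes
#'
#' Baseline FPKM is log-normal per gene with log-normal tissue noise; a
#' `specific_fraction` of genes get one tissue inflated `inflation`-fold,
#' recorded as truth.
#'
#' @param n_genes Number of genes.
#' @param n_tissues Number of tissues (>= 3; the cotton panel uses 14).
#' @param specific_fraction Fraction of genes made tissue-specific.
#' @param inflation Fold inflation of the specific tissue (default 20).
#' @param seed Integer seed.
#' @return A list with `expr` (long tibble: `gene`, `tissue`, `fpkm`) and
#'   `truth` (tibble of planted gene/tissue pairs).
#' @export
simulate_expression <- function(n_genes, n_tissues = 14,
                                specific_fraction = 0.1, inflation = 20,
                                seed = 1L) {
  stopifnot(n_tissues >= 3, specific_fraction >= 0, specific_fraction <= 1)
  with_seed(seed, {
    genes <- sprintf("gene%04d", seq_len(n_genes))
    tissues <- sprintf("tissue%02d", seq_len(n_tissues))
    base <- exp(stats::rnorm(n_genes, 2, 1))
    fpkm <- matrix(base, n_genes, n_tissues) *
      exp(stats::rnorm(n_genes * n_tissues, 0, 0.3))
    n_spec <- round(specific_fraction * n_genes)
    truth <- tibble::tibble(gene = character(), tissue = character())
    if (n_spec > 0) {
      gi <- sample.int(n_genes, n_spec)
      ti <- sample.int(n_tissues, n_spec, replace = TRUE)
      fpkm[cbind(gi, ti)] <- fpkm[cbind(gi, ti)] * inflation
      truth <- tibble::tibble(gene = genes[gi], tissue = tissues[ti])
    }
    dimnames(fpkm) <- list(genes, tissues)
    expr <- tibble::as_tibble(fpkm, rownames = "gene") |>
      tidyr::pivot_longer(-"gene", names_to = "tissue", values_to = "fpkm")
    list(expr = expr, truth = truth)
  })
}
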