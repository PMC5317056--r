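#' Read a VCF into a genotype matrix
#'
#' Loads biallelic SNP and indel records from a VCF (4.x) with GT fields.
#' Multiallelic records are dropped by default (the analysis operates on
#' biallelic variation) or split into one record per alternate allele.
#'
#' @param path Path to a VCF file (plain text or bgzip, as supported by
#'   vcfR).
#' @param panel Accession panel; VCF sample names must be a subset of the
#'   panel ids (the panel is subset and reordered to the VCF samples).
#' @param multiallelic `"drop"` (default) or `"split"`.
#' @return A [geno_matrix()].
#' @export
read_vcf <- function(path, panel, multiallelic = c("drop", "split")) {
  multiallelic <- match.arg(multiallelic)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  if (!all(samples %in% panel$id)) {
    stop("VCF samples not in panel: ",
         paste(setdiff(samples, panel$id), collapse = ", "), call. = FALSE)
  }
  panel <- panel[match(samples, panel$id), , drop = FALSE]

  alt_list <- strsplit(ifelse(is.na(fix$ALT), "", fix$ALT), ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  keep <- which(n_alt == 1L)
  rows <- keep
  alt_idx <- rep(1L, length(keep))
  if (multiallelic == "split") {
    multi <- which(n_alt > 1L)
    rows <- c(rows, rep(multi, n_alt[multi]))
    alt_idx <- c(alt_idx, unlist(lapply(n_alt[multi], seq_len), use.names = FALSE))
  }
  if (length(rows) == 0L) {
    sites <- tibble::tibble(chrom = character(), pos = integer(),
                            ref = character(), alt = character(),
                            vtype = character(), indel_length = integer())
    return(geno_matrix(matrix(integer(), nrow = nrow(panel), ncol = 0,
                              dimnames = list(panel$id, NULL)), sites, panel))
  }

  ref <- fix$REF[rows]
  alt <- purrr::map2_chr(alt_list[rows], alt_idx, ~ .x[.y])
  sites <- tibble::tibble(
    chrom = fix$CHROM[rows],
    pos = as.integer(fix$POS[rows]),
    ref = ref, alt = alt,
    vtype = ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "snp", "indel"),
    indel_length = nchar(alt) - nchar(ref)
  )

  # count occurrences of the chosen alt allele per genotype string
  gt <- gsub("|", "/", gt, fixed = TRUE)
  calls <- matrix(NA_integer_, nrow = length(samples), ncol = length(rows),
                  dimnames = list(samples, NULL))
  for (j in seq_along(rows)) {
    g <- gt[rows[j], ]
    a <- strsplit(g, "/", fixed = TRUE)
    target <- as.character(alt_idx[j])
    calls[, j] <- vapply(a, function(al) {
      if (length(al) == 0L || anyNA(al) || any(al == ".")) return(NA_integer_)
      sum(al == target)
    }, integer(1))
  }
  calls[is.na(gt[rows, , drop = FALSE]) |> t()] <- NA_integer_
  geno_matrix(calls, sites, panel)
}

#' Write a genotype matrix as VCF 4.2
#'
#' Deterministic plain-text output: sites in (chrom, pos) order, samples in
#' panel order, genotypes written unphased (`0/0`, `0/1`, `1/1`, `./.`).
#'
#' @param x A `cotton_geno`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  gt_code <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$panel$id), collapse = "\t")
  )
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(header, con)
  if (n_sites(x) > 0) {
    gt <- matrix(gt_code[x$calls + 1L], nrow = nrow(x$calls))
    gt[is.na(x$calls)] <- "./."
    lines <- paste(x$sites$chrom, x$sites$pos, ".", x$sites$ref, x$sites$alt,
                   ".", "PASS", ".", "GT",
                   apply(gt, 2, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Builds one gene model per mRNA from gene/mRNA/CDS features, honouring
#' CDS phase. Models whose total CDS length is not divisible by three are
#' kept but flagged (`length_ok = FALSE`).
#'
#' @param path Path to a GFF3 file.
#' @return Tibble of gene models: `gene_id`, `chrom`, `strand`,
#'   `length_ok`, and a `cds` list-column of tibbles (`start`, `end`,
#'   `phase`; 1-based closed, ordered 5' to 3' on the transcript).
#' @export
read_gff <- function(path) {
  g <- ape::read.gff(path)
  cds <- g[g$type == "CDS", , drop = FALSE]
  if (nrow(cds) == 0) {
    return(tibble::tibble(gene_id = character(), chrom = character(),
                          strand = character(), length_ok = logical(),
                          cds = list()))
  }
  parent <- stringr::str_match(cds$attributes, "Parent=([^;]+)")[, 2]
  if (anyNA(parent)) stop("CDS feature without Parent attribute", call. = FALSE)
  if (any(cds$start > cds$end)) stop("malformed CDS coordinates", call. = FALSE)
  tibble::tibble(
    gene_id = parent, chrom = as.character(cds$seqid),
    strand = as.character(cds$strand),
    start = cds$start, end = cds$end,
    phase = as.integer(as.character(cds$phase))
  ) |>
    dplyr::group_by(.data$gene_id, .data$chrom, .data$strand) |>
    dplyr::group_modify(~ {
      seg <- dplyr::arrange(.x, .data$start)
      if (any(seg$end[-nrow(seg)] >= seg$start[-1])) {
        stop("overlapping CDS segments in one model", call. = FALSE)
      }
      # 5'->3' on the transcript: ascending for +, descending for -
      if (.y$strand == "-") seg <- seg[rev(seq_len(nrow(seg))), , drop = FALSE]
      seg$phase[is.na(seg$phase)] <- 0L
      total <- sum(seg$end - seg$start + 1L) - seg$phase[1]
      tibble::tibble(length_ok = total %% 3L == 0L, cds = list(seg))
    }) |>
    dplyr::ungroup()
}

#' Read genomic intervals from BED or 1-based TSV
#'
#' Internal coordinates are 0-based half-open everywhere in the package;
#' BED input is taken as-is and 1-based closed TSV (`chrom start end
#' [label]`) is shifted by one at the start. Overlapping intervals are
#' preserved, never merged.
#'
#' @param path Path to the interval file.
#' @param format `"bed"` (0-based half-open) or `"tsv1"` (1-based closed).
#' @return Tibble with `chrom`, `start`, `end`, `label` (0-based
#'   half-open).
#' @export
read_intervals <- function(path, format = c("bed", "tsv1")) {
  format <- match.arg(format)
  d <- utils::read.table(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE)
  names(d)[1:3] <- c("chrom", "start", "end")
  label <- if (ncol(d) >= 4) as.character(d[[4]]) else
    paste0(d$chrom, ":", d$start, "-", d$end)
  out <- tibble::tibble(
    chrom = as.character(d$chrom),
    start = if (format == "bed") as.numeric(d$start) else as.numeric(d$start) - 1,
    end = as.numeric(d$end),
    label = label
  )
  if (any(out$start >= out$end)) stop("interval start must precede end",
                                      call. = FALSE)
  out
}

#' Write intervals as BED
#'
#' @param intervals Tibble with `chrom`, `start`, `end` and optionally
#'   `label` (0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  lines <- paste(intervals$chrom,
                 format(intervals$start, scientific = FALSE, trim = TRUE),
                 format(intervals$end, scientific = FALSE, trim = TRUE),
                 sep = "\t")
  if ("label" %in% names(intervals)) {
    lines <- paste(lines, intervals$label, sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}
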