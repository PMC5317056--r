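#' Annotate coding effects of SNPs and indels
#'
#' SNPs falling in a CDS are classified by codon substitution on the
#' coding strand as `synonymous`, `nonsynonymous` or `stop_gained`;
#' coding indels are `frameshift` when their length is not divisible by
#' three and `inframe_indel` otherwise; everything else is `noncoding`.
#' Genes carrying premature stops or frameshifts form the
#' "large-effect mutation" set.
#'
#' @param sites Tibble of variant sites (`chrom`, `pos`, `ref`, `alt`,
#'   `vtype`, `indel_length`), or a `cotton_geno` (its `sites` are used).
#' @param models Gene-model tibble (see [read_gff()]).
#' @param genome Named character vector of chromosome sequences (as
#'   returned by [simulate_gene_models()]); needed to reconstruct codons.
#' @return Tibble `chrom`, `pos`, `gene_id` (`NA` when noncoding) and
#'   `effect`.
#' @export
annotate_coding_effects <- function(sites, models, genome) {
  if (inherits(sites, "cotton_geno")) sites <- sites$sites
  n <- nrow(sites)
  effect <- rep("noncoding", n)
  gene_id <- rep(NA_character_, n)

  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    seg <- m$cds[[1]]
    lo <- min(seg$start); hi <- max(seg$end)
    # affected reference span: single base for SNPs and insertions,
    # the deleted bases for deletions
    span_end <- sites$pos + pmax(nchar(sites$ref) - 1L, 0L)
    in_cds <- sites$chrom == m$chrom & span_end >= lo & sites$pos <= hi
    idx <- which(in_cds)
    if (length(idx) == 0) next
    # orient the CDS 5'->3' and index transcript offsets
    orf <- cds_sequence(m, genome)
    for (j in idx) {
      gene_id[j] <- m$gene_id
      if (sites$vtype[j] == "indel") {
        effect[j] <- if (sites$indel_length[j] %% 3L != 0L) "frameshift"
                     else "inframe_indel"
        next
      }
      t_off <- transcript_offset(m, sites$pos[j])
      if (is.na(t_off) || t_off < 1L) {
        effect[j] <- "noncoding"; gene_id[j] <- NA_character_; next
      }
      codon_i <- (t_off - 1L) %/% 3L
      codon <- substr(orf, codon_i * 3L + 1L, codon_i * 3L + 3L)
      within <- t_off - codon_i * 3L
      ref_t <- if (m$strand == "+") sites$ref[j] else
        chartr("ACGT", "TGCA", sites$ref[j])
      alt_t <- if (m$strand == "+") sites$alt[j] else
        chartr("ACGT", "TGCA", sites$alt[j])
      if (substr(codon, within, within) != ref_t) {
        stop("reference allele inconsistent with genome at ", sites$chrom[j],
             ":", sites$pos[j], call. = FALSE)
      }
      new_codon <- codon
      substr(new_codon, within, within) <- alt_t
      aa0 <- translate_codon(codon)
      aa1 <- translate_codon(new_codon)
      effect[j] <- if (aa1 == "*" && aa0 != "*") "stop_gained"
                   else if (aa0 == aa1) "synonymous" else "nonsynonymous"
    }
  }
  tibble::tibble(chrom = sites$chrom, pos = sites$pos,
                 gene_id = gene_id, effect = effect)
}

# CDS sequence 5'->3' on the coding strand, honouring phase of the first
# segment (phase bases are trimmed).
cds_sequence <- function(m, genome) {
  seg <- m$cds[[1]]
  pieces <- substring(genome[[m$chrom]], seg$start, seg$end)
  if (m$strand == "-") pieces <- revcomp(pieces)
  s <- paste(pieces, collapse = "")
  if (seg$phase[1] > 0) s <- substr(s, seg$phase[1] + 1L, nchar(s))
  s
}

# 1-based offset of genomic position `pos` on the transcript (coding
# strand), or NA if outside the CDS segments.
transcript_offset <- function(m, pos) {
  seg <- m$cds[[1]]
  off <- 0L
  for (k in seq_len(nrow(seg))) {
    if (pos >= seg$start[k] && pos <= seg$end[k]) {
      within <- if (m$strand == "+") pos - seg$start[k] + 1L
                else seg$end[k] - pos + 1L
      return(off + within - m$cds[[1]]$phase[1])
    }
    off <- off + (seg$end[k] - seg$start[k] + 1L)
  }
  NA_integer_
}
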