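## snp_discovery: count-rule SNP calling and dataset summaries.

#' Call candidate SNPs from a pileup under read-count rules
#'
#' A pileup column yields a candidate if and only if exactly two of the four
#' nucleotides each have at least `min_allele_reads` supporting reads and the
#' total nucleotide depth at the column is at least `min_depth`. `N` and gap
#' (`-`) observations never count as alleles and never count toward depth;
#' columns where three or more nucleotides reach `min_allele_reads` are
#' rejected as multiallelic rather than reduced to their top two alleles
#' (downstream genotyping assays are biallelic). Indels are never called: gap
#' observations are ignored entirely.
#'
#' For each candidate the descriptor variables are filled in: `depth`
#' (nucleotide observations at the site), `msaf` (minor allele reads / depth),
#' `individuals` and `geosites` (number of distinct labelled individuals and
#' geographic sites contributing at least one read covering the site; reads
#' without a label contribute to depth only). A major/minor tie at
#' `msaf = 0.5` is broken lexicographically: the alphabetically first base is
#' the major allele.
#'
#' @param pileup pileup data.table (see [read_pileup()]); may span several
#'   contigs.
#' @param min_depth minimum nucleotide depth at the site (default 4).
#' @param min_allele_reads minimum reads supporting each allele (default 2).
#' @return data.table of candidates with the descriptor columns of
#'   [snp_table_columns()] (0-based `pos`; assay-design descriptors `NA`).
#' @export
call_snps <- function(pileup, min_depth = 4L, min_allele_reads = 2L) {
  if (2L * min_allele_reads > min_depth) {
    stop("configuration error: 2 * min_allele_reads exceeds min_depth")
  }
  empty <- data.table(
    contig_id = character(), pos = integer(), major_allele = character(),
    minor_allele = character(), major_count = integer(), minor_count = integer(),
    depth = integer(), msaf = numeric(), individuals = integer(),
    geosites = integer(), target_region = NA_character_,
    q_score = NA_integer_, snp_score = NA_real_, ie_code = NA_character_,
    ie_species_match = NA_integer_, rank = NA_integer_
  )[0]
  if (nrow(pileup) == 0) return(empty)
  nuc <- pileup[base %chin% CALL_BASES]
  if (nrow(nuc) == 0) return(empty)
  cnt <- nuc[, .(n = .N), by = .(contig_id, pos, base)]
  site <- cnt[, .(depth = sum(n), npass = sum(n >= min_allele_reads)),
              by = .(contig_id, pos)]
  keep <- site[npass == 2L & depth >= min_depth, .(contig_id, pos, depth)]
  if (nrow(keep) == 0) return(empty)
  sel <- cnt[n >= min_allele_reads][keep, on = .(contig_id, pos), nomatch = NULL]
  setorder(sel, contig_id, pos, -n, base)  # count tie: alphabetical = major
  cand <- sel[, .(major_allele = base[1], minor_allele = base[2],
                  major_count = n[1], minor_count = n[2], depth = depth[1]),
              by = .(contig_id, pos)]
  cand[, msaf := minor_count / depth]
  ids <- nuc[keep[, .(contig_id, pos)], on = .(contig_id, pos), nomatch = NULL][
    , .(individuals = uniqueN(individual_id, na.rm = TRUE),
        geosites = uniqueN(geosite_id, na.rm = TRUE)),
    by = .(contig_id, pos)]
  cand <- ids[cand, on = .(contig_id, pos)]
  setcolorder(cand, c("contig_id", "pos", "major_allele", "minor_allele",
                      "major_count", "minor_count", "depth", "msaf",
                      "individuals", "geosites"))
  cand[, `:=`(target_region = NA_character_, q_score = NA_integer_,
              snp_score = NA_real_, ie_code = NA_character_,
              ie_species_match = NA_integer_, rank = NA_integer_)]
  setorder(cand, contig_id, pos)
  cand[]
}

#' Summarize a SNP discovery run
#'
#' `snps_per_100bp` is the candidate count per 100 bp of SNP-containing
#' contig sequence (denominator: cumulative length of contigs that carry at
#' least one candidate); `snps_per_mbp` is the candidate count per megabase
#' of raw sequence generated by the platform.
#'
#' @param contig_lengths named integer vector: length of every assembled
#'   contig (names = contig ids).
#' @param candidates candidate table from [call_snps()].
#' @param total_sequenced_mbp raw sequence output of the platform, in Mbp
#'   (optional; `NA` leaves `snps_per_mbp` unset).
#' @return list of class `discovery_summary`: `n_contigs`, `n_snp_contigs`,
#'   `n_candidates`, `mean_contig_length`, `mean_depth_at_snp`,
#'   `snps_per_100bp`, `snps_per_mbp`, `snps_per_contig_histogram`.
#' @export
summarize_discovery <- function(contig_lengths, candidates,
                                total_sequenced_mbp = NA_real_) {
  stopifnot(!is.null(names(contig_lengths)))
  unknown <- setdiff(unique(candidates$contig_id), names(contig_lengths))
  if (length(unknown)) {
    stop("candidates reference unknown contig(s): ",
         paste(head(unknown, 5), collapse = ", "))
  }
  n_cand <- nrow(candidates)
  per_contig <- if (n_cand) table(table(candidates$contig_id)) else table(integer())
  snp_contigs <- unique(candidates$contig_id)
  snp_len <- sum(contig_lengths[snp_contigs])
  if (n_cand > 0 && snp_len <= 0) stop("zero-length density denominator")
  dens100 <- if (n_cand) 100 * n_cand / snp_len else 0
  dens_mbp <- if (is.na(total_sequenced_mbp)) NA_real_ else {
    if (n_cand > 0 && total_sequenced_mbp <= 0) stop("zero-length density denominator")
    if (n_cand) n_cand / total_sequenced_mbp else 0
  }
  structure(list(
    n_contigs = length(contig_lengths),
    n_snp_contigs = length(snp_contigs),
    n_candidates = n_cand,
    mean_contig_length = mean(contig_lengths),
    mean_depth_at_snp = if (n_cand && "depth" %in% names(candidates)) {
      mean(candidates$depth)
    } else NA_real_,
    snps_per_100bp = dens100,
    snps_per_mbp = dens_mbp,
    snps_per_contig_histogram = per_contig
  ), class = "discovery_summary")
}

#' @export
print.discovery_summary <- function(x, ...) {
  cat("<discovery_summary>\n",
      " contigs: ", x$n_contigs, " (", x$n_snp_contigs, " with SNPs)\n",
      " candidates: ", x$n_candidates,
      "  mean depth at SNP: ", round(x$mean_depth_at_snp, 1), "\n",
      " SNPs / 100 bp: ", signif(x$snps_per_100bp, 3),
      "  SNPs / Mbp: ", signif(x$snps_per_mbp, 3), "\n", sep = "")
  invisible(x)
}

#' Per-locus validation outcomes from a genotype matrix
#'
#' For each locus: `snp_assay_conversion` is 1 when the assay produced
#' interpretable clusters (`cluster_ok`) and at least one called sample,
#' else 0. For converted loci, `snp_genotype` is 0 (monomorphic: all called
#' samples homozygous for the same allele) or 1 (polymorphic), `maf` is the
#' minor allele frequency among called genotypes and `ho` the observed
#' heterozygote fraction; for failed loci these are `NA`.
#'
#' @param gm `genotype_matrix`, QC already applied (see [apply_qc()]).
#' @return data.table: `locus_id`, `snp_assay_conversion`, `snp_genotype`,
#'   `maf`, `ho`, `n_called`.
#' @export
compute_locus_stats <- function(gm) {
  calls <- gm$calls
  res <- lapply(seq_len(nrow(calls)), function(i) {
    g <- calls[i, ]
    g <- g[!is.na(g)]
    n <- length(g)
    conv <- as.integer(gm$cluster_ok[i] && n > 0)
    if (!conv) {
      return(data.table(locus_id = rownames(calls)[i], snp_assay_conversion = 0L,
                        snp_genotype = NA_integer_, maf = NA_real_,
                        ho = NA_real_, n_called = n))
    }
    nb <- sum(g == "AB") + 2L * sum(g == "BB")
    p <- nb / (2L * n)
    maf <- min(p, 1 - p)
    ho <- mean(g == "AB")
    data.table(locus_id = rownames(calls)[i], snp_assay_conversion = 1L,
               snp_genotype = as.integer(maf > 0 || ho > 0),
               maf = maf, ho = ho, n_called = n)
  })
  rbindlist(res)
}
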