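## io_core: domain containers, readers/writers, coordinate helpers.

PILEUP_BASES <- c("A", "C", "G", "T", "N", "-")
CALL_BASES   <- c("A", "C", "G", "T")

#' Convert between internal 0-based and reported 1-based coordinates
#'
#' Internal positions are 0-based, half-open; all human-readable outputs use
#' 1-based, fully-closed positions. The two functions are mutual inverses.
#'
#' @param pos integer vector of positions.
#' @return integer vector.
#' @export
to_one_based <- function(pos) as.integer(pos) + 1L

#' @rdname to_one_based
#' @export
to_zero_based <- function(pos) as.integer(pos) - 1L

snp_log <- function(...) message("[snpanel] ", ...)

#' Read contig or reference sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that uppercases the
#' sequences and keeps only the first whitespace-delimited token of each
#' header as the sequence id.
#'
#' @param path FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write named sequences to FASTA
#' @param seqs named character vector (nucleotide or peptide; auto-detected
#'   unless `type` is given).
#' @param path output file.
#' @param type `"auto"`, `"dna"` or `"protein"`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, type = c("auto", "dna", "protein")) {
  type <- match.arg(type)
  if (type == "auto") {
    type <- if (grepl("[^ACGTNacgtn-]", paste(seqs, collapse = ""))) "protein" else "dna"
  }
  x <- if (type == "dna") Biostrings::DNAStringSet(seqs) else
    Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read sequencing reads from FASTQ
#'
#' @param path FASTQ file.
#' @return data.table with columns `read_id`, `sequence`, `quality`,
#'   `individual_id`, `geosite_id` (ids `NA` until demultiplexed).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.table(
    read_id       = sub("\\s.*$", "", names(x)),
    sequence      = toupper(as.character(x)),
    quality       = as.character(S4Vectors::mcols(x)$qualities),
    individual_id = NA_character_,
    geosite_id    = NA_character_
  )
}

#' Write reads to FASTQ
#' @param reads data.table as returned by [read_fastq()]; missing qualities
#'   are written as constant `"I"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- reads$quality
  if (is.null(qual)) qual <- rep(NA_character_, nrow(reads))
  fix <- is.na(qual) | nchar(qual) != nchar(reads$sequence)
  qual[fix] <- vapply(nchar(reads$sequence[fix]),
                      function(n) strrep("I", n), character(1))
  dna <- Biostrings::DNAStringSet(reads$sequence)
  names(dna) <- reads$read_id
  Biostrings::writeXStringSet(dna, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual))
  invisible(path)
}

#' Read a pileup of per-read base observations
#'
#' The pileup dialect is a 6-column TSV with header:
#' `contig_id, pos0, read_id, base, individual_id, geosite_id`. Positions are
#' 0-based; `base` is one of `A,C,G,T,N,-`; empty `individual_id`/`geosite_id`
#' mean the read carries no sample label (such reads count toward depth but
#' not toward the Individuals/Geosites descriptors).
#'
#' @param path pileup TSV.
#' @return data.table sorted by (`contig_id`, `pos`) with columns `contig_id`,
#'   `pos` (0-based integer), `read_id`, `base`, `individual_id`, `geosite_id`.
#' @export
read_pileup <- function(path) {
  p <- fread(path, sep = "\t", header = TRUE, colClasses = "character",
             na.strings = NULL, showProgress = FALSE)
  if (nrow(p) == 0) {
    return(data.table(contig_id = character(), pos = integer(),
                      read_id = character(), base = character(),
                      individual_id = character(), geosite_id = character()))
  }
  need <- c("contig_id", "pos0", "read_id", "base", "individual_id", "geosite_id")
  if (!all(need %in% names(p))) {
    stop("pileup file lacks required columns: ",
         paste(setdiff(need, names(p)), collapse = ", "))
  }
  bad <- which(!p$base %in% PILEUP_BASES)
  if (length(bad)) {
    stop("unknown base symbol(s) in pileup at data line(s) ",
         paste(head(bad, 10), collapse = ", "),
         " (values: ", paste(unique(p$base[head(bad, 10)]), collapse = ","), ")")
  }
  posn <- suppressWarnings(as.integer(p$pos0))
  bad <- which(is.na(posn) | posn < 0)
  if (length(bad)) {
    stop("malformed position(s) in pileup at data line(s) ",
         paste(head(bad, 10), collapse = ", "))
  }
  out <- data.table(
    contig_id = p$contig_id, pos = posn, read_id = p$read_id, base = p$base,
    individual_id = fifelse(p$individual_id == "", NA_character_, p$individual_id),
    geosite_id = fifelse(p$geosite_id == "", NA_character_, p$geosite_id)
  )
  dup <- duplicated(out, by = c("contig_id", "pos", "read_id"))
  if (any(dup)) {
    stop("duplicate (contig, position, read) observation(s) at data line(s) ",
         paste(head(which(dup), 10), collapse = ", "))
  }
  setorder(out, contig_id, pos)
  out[]
}

#' Write a pileup table
#' @param pileup data.table as returned by [read_pileup()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_pileup <- function(pileup, path) {
  out <- data.table(
    contig_id = pileup$contig_id, pos0 = pileup$pos, read_id = pileup$read_id,
    base = pileup$base,
    individual_id = fifelse(is.na(pileup$individual_id), "", pileup$individual_id),
    geosite_id = fifelse(is.na(pileup$geosite_id), "", pileup$geosite_id)
  )
  fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

## Canonical SNP descriptor schema, in file column order. `position` is
## written 1-based; internally candidates carry 0-based `pos`.
SNP_TABLE_COLS <- c(
  "contig_id", "position", "major_allele", "minor_allele", "major_count",
  "minor_count", "depth", "msaf", "individuals", "geosites", "target_region",
  "q_score", "snp_score", "ie_code", "ie_species_match", "rank"
)

#' Write candidate SNPs with their descriptor variables to TSV
#'
#' One row per candidate, 16 columns ([snp_table_columns()]), positions
#' 1-based. Descriptors not yet computed are written as `NA`; the intron-exon
#' code is written as `1`, `0` or `no`.
#'
#' @param candidates data.table of candidates (internal 0-based `pos`).
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_snp_table <- function(candidates, path) {
  out <- data.table(
    contig_id = character(), position = integer(), major_allele = character(),
    minor_allele = character(), major_count = integer(), minor_count = integer(),
    depth = integer(), msaf = numeric(), individuals = integer(),
    geosites = integer(), target_region = character(), q_score = integer(),
    snp_score = numeric(), ie_code = character(), ie_species_match = integer(),
    rank = integer()
  )
  if (nrow(candidates)) {
    out <- copy(candidates)
    out[, position := to_one_based(pos)]
    for (col in setdiff(SNP_TABLE_COLS, names(out))) out[, (col) := NA]
    out <- out[, SNP_TABLE_COLS, with = FALSE]
  }
  fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_snp_table
#' @export
snp_table_columns <- function() SNP_TABLE_COLS

#' Read a SNP descriptor table written by [write_snp_table()]
#' @param path TSV file.
#' @return data.table with internal 0-based `pos` restored.
#' @export
read_snp_table <- function(path) {
  x <- fread(path, sep = "\t", header = TRUE, na.strings = "NA",
             colClasses = list(character = c("ie_code", "major_allele",
                                             "minor_allele", "target_region")),
             showProgress = FALSE)
  x[, pos := to_zero_based(position)]
  x[, position := NULL]
  ## canonical column types survive even all-NA columns
  int_cols <- intersect(c("major_count", "minor_count", "depth", "individuals",
                          "geosites", "q_score", "ie_species_match", "rank"),
                        names(x))
  for (cc in int_cols) x[, (cc) := as.integer(get(cc))]
  num_cols <- intersect(c("msaf", "snp_score"), names(x))
  for (cc in num_cols) x[, (cc) := as.numeric(get(cc))]
  setcolorder(x, c("contig_id", "pos"))
  x[]
}

#' Construct a genotype matrix object
#'
#' @param calls character matrix of genotype calls in `AA`/`AB`/`BB`/`NA`,
#'   rows = loci, columns = samples; dimnames required.
#' @param cluster_ok named logical vector per locus: did the assay produce
#'   interpretable clusters? Defaults to `TRUE` for every locus.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, cluster_ok = NULL) {
  stopifnot(is.matrix(calls), !is.null(rownames(calls)), !is.null(colnames(calls)))
  ok <- !is.na(calls) & !calls %in% c("AA", "AB", "BB")
  if (any(ok)) stop("genotype calls must be AA, AB, BB or NA")
  if (is.null(cluster_ok)) {
    cluster_ok <- setNames(rep(TRUE, nrow(calls)), rownames(calls))
  }
  stopifnot(length(cluster_ok) == nrow(calls))
  if (is.null(names(cluster_ok))) names(cluster_ok) <- rownames(calls)
  structure(list(calls = calls, cluster_ok = cluster_ok),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$calls), " loci x ", ncol(x$calls),
      " samples; ", sum(!x$cluster_ok), " loci flagged poor-clustering\n",
      sep = "")
  invisible(x)
}

#' Per-sample call rate of a genotype matrix
#' @param gm `genotype_matrix`.
#' @return named numeric vector in \[0, 1\].
#' @export
call_rates <- function(gm) colMeans(!is.na(gm$calls))

#' Read a genotype call matrix from CSV
#'
#' Rows are loci (first column `locus_id`), remaining columns one per sample,
#' values in `AA`/`AB`/`BB`/`NA`. An optional column `cluster_ok`
#' (`TRUE`/`FALSE`) flags loci with interpretable clustering.
#'
#' @param path CSV file.
#' @return `genotype_matrix`.
#' @export
read_genotype_csv <- function(path) {
  x <- fread(path, sep = ",", header = TRUE, na.strings = "NA",
             colClasses = "character", showProgress = FALSE)
  stopifnot("locus_id" %in% names(x))
  cl <- NULL
  if ("cluster_ok" %in% names(x)) {
    cl <- setNames(as.logical(x$cluster_ok), x$locus_id)
    x[, cluster_ok := NULL]
  }
  m <- as.matrix(x[, -"locus_id"])
  rownames(m) <- x$locus_id
  genotype_matrix(m, cl)
}

#' Write a genotype matrix to CSV
#' @param gm `genotype_matrix`.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_genotype_csv <- function(gm, path) {
  dt <- data.table(locus_id = rownames(gm$calls))
  dt <- cbind(dt, as.data.table(gm$calls))
  dt[, cluster_ok := gm$cluster_ok]
  fwrite(dt, path, sep = ",", quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a key-value configuration file (YAML)
#' @param path YAML file.
#' @return named list.
#' @export
read_config <- function(path) yaml::read_yaml(path)
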