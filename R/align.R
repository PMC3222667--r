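## align: built-in nucleotide local aligner (k-mer seed + per-diagonal
## best-segment extension). Stands behind the comparative-annotation module
## in place of an external BLAST; an adapter for external tabular hits is in
## annotation.R.

#' Reverse complement of nucleotide strings
#' @param x character vector of sequences (ACGTN).
#' @return character vector.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## positions (1-based) of every k-mer of `seq`
seq_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1), k:n)
}

#' Build a reusable seed index over a subject set
#'
#' Indexes every k-mer of every subject on both strands; [find_hsps()] joins
#' query k-mers against it, so building the index once and passing it to many
#' queries makes the per-query cost independent of the subject set size.
#'
#' @param subjects named character vector of subject sequences.
#' @param k seed length (default 12).
#' @param both_strands index the reverse complement too (default TRUE).
#' @return keyed data.table of class `subject_index` (attributes carry the
#'   strand-oriented sequences).
#' @export
subject_index <- function(subjects, k = 12L, both_strands = TRUE) {
  if (is.null(names(subjects)) && length(subjects)) {
    names(subjects) <- paste0("subject", seq_along(subjects))
  }
  fw <- toupper(unlist(as.list(subjects)))
  strands <- if (both_strands) c("+", "-") else "+"
  seqs <- list(`+` = fw, `-` = if (both_strands) setNames(revcomp(fw), names(fw)))
  rows <- list()
  for (st in strands) {
    for (sid in names(fw)) {
      km <- seq_kmers(seqs[[st]][[sid]], k)
      if (!length(km)) next
      rows[[paste(st, sid)]] <- data.table(kmer = km, subject_id = sid,
                                           strand = st, spos = seq_along(km))
    }
  }
  idx <- if (length(rows)) rbindlist(rows) else {
    data.table(kmer = character(), subject_id = character(),
               strand = character(), spos = integer())
  }
  setkey(idx, kmer)
  setattr(idx, "k", as.integer(k))
  setattr(idx, "seqs", seqs)
  setattr(idx, "ints", lapply(seqs, function(s) lapply(as.list(s), utf8ToInt)))
  setattr(idx, "class", c("subject_index", class(idx)))
  idx
}

## best-scoring segment on one seeded diagonal (Kadane over match/mismatch
## scores); returns NULL below min_score
diag_best <- function(qv, sv, d, match, mismatch, min_score, nn) {
  qlen <- length(qv); slen <- length(sv)
  q0 <- max(1L, 1L - d); q1 <- min(qlen, slen - d)
  if (q1 < q0) return(NULL)
  qi <- q0:q1
  m <- qv[qi] == sv[qi + d] & qv[qi] != nn
  sc <- ifelse(m, match, mismatch)
  cs <- cumsum(sc)
  pc <- c(0, cs)                    # pc[t] = sum of sc[1..t-1]
  pm <- cummin(pc)
  gain <- cs - pm[seq_along(cs)]
  jj <- which.max(gain)
  best <- gain[jj]
  if (best < min_score) return(NULL)
  ii <- max(which(pc[seq_len(jj)] == pm[jj]))  # latest minimal prefix: tight span
  while (ii < jj && !m[ii]) ii <- ii + 1L      # trim terminal mismatches
  jj2 <- jj
  while (jj2 > ii && !m[jj2]) jj2 <- jj2 - 1L
  qs <- qi[ii]; qe <- qi[jj2]
  list(qstart = qs - 1L, qend = qe,            # 0-based half-open
       sstart = qs + d - 1L, send = qe + d,
       score = best, n_ident = sum(m[ii:jj2]), length = jj2 - ii + 1L)
}

#' Find local similarity segments (HSPs) of a query in a subject set
#'
#' Seed-and-extend local search: exact k-mer seeds define diagonals, and each
#' seeded (subject, strand, diagonal) triple contributes its maximum-scoring
#' ungapped segment. Substitution-only alignment is intentional: the SNP
#' calling rules exclude indel variants, and the exons of a genomic subject
#' fall on distinct diagonals — one HSP per exon is exactly the structure
#' intron-exon boundary prediction needs (a gapped aligner can bridge an
#' intron with one long gap and blur that structure).
#'
#' Coordinates are 0-based half-open on the forward query; `strand = "-"`
#' means the reverse complement of the subject matched, with subject
#' coordinates reported on the subject's forward strand.
#'
#' @param query nucleotide string.
#' @param subjects named character vector of subject sequences (ignored when
#'   `index` is given).
#' @param index prebuilt [subject_index()] for repeated queries.
#' @param k seed length (default 12).
#' @param match,mismatch per-base scores (defaults +2 / -3).
#' @param min_score minimum segment score to report (default 40, i.e. at
#'   least 20 identical bases; calibrated so shuffled-sequence false hits are
#'   rarer than 1e-3 per comparison at typical contig lengths).
#' @param both_strands also search the reverse complement (default TRUE).
#' @return data.table of HSPs: `subject_id`, `strand`, `qstart`, `qend`,
#'   `sstart`, `send`, `score`, `n_ident`, `length`, sorted by descending
#'   score (ties: `subject_id`, `sstart`); zero rows when nothing passes.
#' @export
find_hsps <- function(query, subjects = NULL, index = NULL, k = 12L,
                      match = 2L, mismatch = -3L, min_score = 40L,
                      both_strands = TRUE) {
  empty <- data.table(subject_id = character(), strand = character(),
                      qstart = integer(), qend = integer(), sstart = integer(),
                      send = integer(), score = numeric(), n_ident = integer(),
                      length = integer())
  if (is.null(index)) {
    if (is.null(subjects) || length(subjects) == 0) return(empty)
    index <- subject_index(subjects, k = k, both_strands = both_strands)
  }
  k <- attr(index, "k")
  query <- toupper(query)
  qk <- data.table(kmer = seq_kmers(query, k), qpos = seq_len(max(0L, nchar(query) - k + 1L)))
  if (nrow(qk) == 0 || nrow(index) == 0) return(empty)
  seeds <- index[qk, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(seeds) == 0) return(empty)
  if (!both_strands) seeds <- seeds[strand == "+"]
  if (nrow(seeds) == 0) return(empty)
  seeds[, diag_id := spos - qpos]
  groups <- unique(seeds[, .(subject_id, strand, diag_id)])
  ints <- attr(index, "ints")
  qv <- utf8ToInt(query)
  nn <- utf8ToInt("N")
  out <- vector("list", nrow(groups))
  for (i in seq_len(nrow(groups))) {
    sid <- groups$subject_id[i]; st <- groups$strand[i]
    sv <- ints[[st]][[sid]]
    h <- diag_best(qv, sv, groups$diag_id[i], match, mismatch, min_score, nn)
    if (is.null(h)) next
    if (st == "-") {                 # map back to subject forward strand
      slen <- length(sv)
      h[c("sstart", "send")] <- list(slen - h$send, slen - h$sstart)
    }
    out[[i]] <- c(list(subject_id = sid, strand = st), h)
  }
  out <- rbindlist(out[!vapply(out, is.null, logical(1))])
  if (nrow(out) == 0) return(empty)
  ## drop HSPs whose query span is nested inside a higher-scoring one
  setorder(out, -score, subject_id, sstart)
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))[-1]) {
    keep[i] <- !any(keep[seq_len(i - 1)] &
                      out$qstart[seq_len(i - 1)] <= out$qstart[i] &
                      out$qend[seq_len(i - 1)] >= out$qend[i] &
                      out$subject_id[seq_len(i - 1)] == out$subject_id[i] &
                      out$score[seq_len(i - 1)] >= out$score[i])
  }
  out <- out[keep]
  setcolorder(out, names(empty))
  out[]
}

#' Best local hit of a query against a subject set
#'
#' Highest-scoring HSP passing `min_score`; ties broken deterministically by
#' (`subject_id`, `sstart`).
#'
#' @inheritParams find_hsps
#' @return one-row data.table (the best hit) or `NULL` when no segment
#'   passes the cutoff or the subject set is empty.
#' @export
local_align <- function(query, subjects = NULL, index = NULL, k = 12L,
                        match = 2L, mismatch = -3L, min_score = 40L,
                        both_strands = TRUE) {
  hits <- find_hsps(query, subjects, index = index, k = k, match = match,
                    mismatch = mismatch, min_score = min_score,
                    both_strands = both_strands)
  if (nrow(hits) == 0) return(NULL)
  hits[1]
}
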