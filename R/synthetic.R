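## synthetic: seeded data generator emulating a two-platform transcriptome
## SNP discovery study, with planted truth for every downstream stage.

SIM_BASES <- c("A", "C", "G", "T")
SENSE_CODONS <- {
  all64 <- as.vector(outer(outer(SIM_BASES, SIM_BASES, paste0), SIM_BASES, paste0))
  setdiff(all64, c("TAA", "TAG", "TGA"))
}

rand_seq <- function(n) {
  if (n <= 0) return("")
  paste(sample(SIM_BASES, n, replace = TRUE), collapse = "")
}

#' Built-in platform profiles
#'
#' Two named profiles parameterized from the magnitudes typical of the two
#' sequencing platforms compared in transcriptome SNP discovery studies:
#' `longread` (pyrosequencing-like: mean read length 206 bp, substitution
#' error 0.3%, mean contig depth 45x, contig lengths log-normal around a
#' 331 bp mean) and `shortread` (short-read sequencing-by-synthesis:
#' 74 bp reads, 1% error, mean depth 600x, contigs around 190 bp). All
#' fields can be overridden through [sim_config()].
#'
#' @return named list of profile parameter lists.
#' @export
sim_profiles <- function() {
  list(
    longread = list(read_length_mean = 206, read_length_sd = 40,
                    error_rate = 0.003, mean_depth = 45,
                    contig_meanlog = log(280), contig_sdlog = 0.6),
    shortread = list(read_length_mean = 74, read_length_sd = 0,
                     error_rate = 0.01, mean_depth = 600,
                     contig_meanlog = log(180), contig_sdlog = 0.35)
  )
}

#' Simulation configuration
#'
#' @param seed integer seed (mandatory; the whole dataset is a deterministic
#'   function of the configuration).
#' @param n_contigs number of contigs (default 200).
#' @param n_individuals discovery-panel size (default 8, spread over the
#'   geosites round-robin: 2+2+2+2 over four sites).
#' @param geosites geographic site labels (default AEGS, TYRS, NTHS, ATIB).
#' @param profile `"longread"` or `"shortread"` (see [sim_profiles()]).
#' @param snp_rate per-site SNP planting probability (default 0.01).
#' @param maf_beta Beta prior (shape1, shape2) for the planted alternate
#'   allele frequency (default c(1, 3)).
#' @param fst optional between-geosite divergence (Balding-Nichols F;
#'   default 0 = panmixia).
#' @param mito_fraction fraction of contigs drawn from a synthetic
#'   mitochondrial genome (default 0.02).
#' @param intron_bp_rate per-bp rate of intron insertion points in the
#'   companion reference genome (default 1/300).
#' @param intron_len_range intron length range, bp (default 200-800).
#' @param divergence per-base substitution rate between contigs and the
#'   reference transcriptome (default 0 = identical homologs).
#' @param reads_per_individual optional exact read count per individual
#'   (overrides depth-driven read totals).
#' @param barcode attach a two-tag barcode scheme (tag table is always
#'   generated; this switches tagged-read FASTQ output on in [sim_write()]).
#' @param ... profile field overrides (e.g. `error_rate = 0`).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed, n_contigs = 200L, n_individuals = 8L,
                       geosites = c("AEGS", "TYRS", "NTHS", "ATIB"),
                       profile = "longread", snp_rate = 0.01,
                       maf_beta = c(1, 3), fst = 0, mito_fraction = 0.02,
                       intron_bp_rate = 1 / 300,
                       intron_len_range = c(200L, 800L), divergence = 0,
                       reads_per_individual = NULL, barcode = FALSE, ...) {
  if (missing(seed)) stop("seed is mandatory")
  prof <- sim_profiles()[[match.arg(profile, names(sim_profiles()))]]
  over <- list(...)
  for (k in names(over)) {
    if (!k %in% names(prof)) stop("unknown profile override: ", k)
    prof[[k]] <- over[[k]]
  }
  stopifnot(snp_rate >= 0, snp_rate <= 1, mito_fraction >= 0, mito_fraction <= 1,
            prof$error_rate >= 0, prof$error_rate <= 1, fst >= 0, fst < 1,
            divergence >= 0, divergence <= 1)
  if (is.null(reads_per_individual) && prof$mean_depth <= 0) {
    stop("profile mean depth must be positive")
  }
  structure(c(list(seed = as.integer(seed), n_contigs = as.integer(n_contigs),
                   n_individuals = as.integer(n_individuals),
                   geosites = geosites, profile = profile, snp_rate = snp_rate,
                   maf_beta = maf_beta, fst = fst,
                   mito_fraction = mito_fraction,
                   intron_bp_rate = intron_bp_rate,
                   intron_len_range = as.integer(intron_len_range),
                   divergence = divergence,
                   reads_per_individual = reads_per_individual,
                   barcode = isTRUE(barcode)),
              prof), class = "sim_config")
}

## barcode tags: random 10-mers, pairwise Hamming >= 3
make_tags <- function(n, len = 10L, min_dist = 3L) {
  tags <- character(0)
  while (length(tags) < n) {
    cand <- rand_seq(len)
    if (all(vapply(tags, function(t) hamming_dist(t, cand) >= min_dist,
                   logical(1)))) {
      tags <- c(tags, cand)
    }
  }
  tags
}

mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  if (length(hit)) {
    for (i in hit) ch[i] <- sample(setdiff(SIM_BASES, ch[i]), 1)
  }
  paste(ch, collapse = "")
}

#' Simulate a transcriptome SNP discovery dataset with planted truth
#'
#' Generates contigs (with a known coding frame; a configured fraction drawn
#' from a synthetic mitochondrial genome), plants biallelic SNPs with
#' Hardy-Weinberg genotypes in the discovery panel, samples reads per
#' individual under the platform profile (length, error rate, depth) into a
#' pileup, and derives a companion "model species" reference set: a genome
#' with introns inserted at the configured rate, the homolog transcriptome,
#' an exon map, and the proteome of the true reading frames. Everything is a
#' deterministic function of the configuration (including its seed).
#'
#' @param config [sim_config()].
#' @return list of class `sim_dataset`: `contigs` (data.table: `contig_id`,
#'   `sequence`, `length`, `is_mito`, `frame`, `strand`), `pileup`,
#'   `reads` (per-read metadata), `individuals`, `tag_table`, `refset`
#'   ([reference_set()]), `mito_reference`, and `truth` (list: `snps` with
#'   planted alleles, population and realized panel allele frequencies,
#'   pre-error sampled allele counts and the expected intron-exon code;
#'   `genotypes` long table of planted copies; `introns`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  geos <- rep(cfg$geosites, length.out = cfg$n_individuals)
  individuals <- data.table(
    individual_id = paste0(geos, "_", ave(seq_along(geos), geos, FUN = seq_along)),
    geosite_id = geos
  )
  n_ind <- cfg$n_individuals
  tag_table <- data.table(
    tag = make_tags(2L * n_ind),
    individual_id = rep(individuals$individual_id, each = 2L),
    geosite_id = rep(individuals$geosite_id, each = 2L)
  )

  mito_genome <- rand_seq(16000L)
  n <- cfg$n_contigs
  lens <- pmax(100L, as.integer(round(rlnorm(n, cfg$contig_meanlog,
                                             cfg$contig_sdlog))))
  is_mito <- seq_len(n) %in% sample(n, round(cfg$mito_fraction * n))
  contig_ids <- sprintf("ctg%04d", seq_len(n))

  seqs <- character(n); frames <- integer(n); strands <- character(n)
  peptides <- setNames(character(n), contig_ids)
  for (i in seq_len(n)) {
    if (is_mito[i]) {
      len <- min(lens[i], nchar(mito_genome) - 1L)
      st <- sample.int(nchar(mito_genome) - len, 1)
      seqs[i] <- substr(mito_genome, st, st + len - 1L)
      lens[i] <- len; frames[i] <- NA_integer_; strands[i] <- NA_character_
      next
    }
    off <- sample(0:2, 1)
    ncod <- (lens[i] - off) %/% 3L
    tail_n <- lens[i] - off - 3L * ncod
    core <- paste(sample(SENSE_CODONS, ncod, replace = TRUE), collapse = "")
    fw <- paste0(rand_seq(off), core, rand_seq(tail_n))
    strands[i] <- sample(c("+", "-"), 1)
    frames[i] <- off
    seqs[i] <- if (strands[i] == "+") fw else revcomp(fw)
    peptides[i] <- as.character(Biostrings::translate(Biostrings::DNAString(core)))
  }
  contigs <- data.table(contig_id = contig_ids, sequence = seqs, length = lens,
                        is_mito = is_mito, frame = frames, strand = strands)

  ## ---- plant SNPs (nuclear contigs only; the mitochondrial genome is
  ## haploid and excluded from panels downstream) ----
  snp_list <- vector("list", n)
  geno_list <- vector("list", n)
  for (i in which(!is_mito)) {
    k <- rbinom(1, lens[i], cfg$snp_rate)
    if (k == 0) next
    pos <- sort(sample.int(lens[i], k)) - 1L
    ref <- substring(seqs[i], pos + 1L, pos + 1L)
    alt <- vapply(ref, function(b) sample(setdiff(SIM_BASES, b), 1), character(1))
    p_alt <- rbeta(k, cfg$maf_beta[1], cfg$maf_beta[2])
    if (cfg$fst > 0) {
      fs <- cfg$fst
      pg <- matrix(rbeta(k * length(unique(geos)),
                         rep(p_alt, each = length(unique(geos))) * (1 - fs) / fs,
                         rep(1 - p_alt, each = length(unique(geos))) * (1 - fs) / fs),
                   nrow = length(unique(geos)))
      rownames(pg) <- unique(geos)
      p_ind <- pg[match(individuals$geosite_id, rownames(pg)), , drop = FALSE]
    } else {
      p_ind <- matrix(rep(p_alt, each = n_ind), nrow = n_ind)
    }
    copies <- matrix(rbinom(n_ind * k, 2L, as.vector(p_ind)), nrow = n_ind)
    f_panel <- colSums(copies) / (2 * n_ind)
    snp_list[[i]] <- data.table(contig_id = contig_ids[i], pos = pos,
                                ref = unname(ref), alt = unname(alt),
                                p_alt = p_alt, panel_freq_alt = f_panel,
                                panel_maf = pmin(f_panel, 1 - f_panel))
    geno_list[[i]] <- data.table(contig_id = contig_ids[i],
                                 pos = rep(pos, each = n_ind),
                                 individual_id = rep(individuals$individual_id, k),
                                 copies = as.vector(copies))
  }
  snps <- rbindlist(snp_list)
  genotypes <- rbindlist(geno_list)

  ## ---- sample reads into a pileup ----
  if (!is.null(cfg$reads_per_individual)) {
    rpi <- as.integer(cfg$reads_per_individual)
    ind_idx_all <- rep(seq_len(n_ind), each = rpi)
    ctg_all <- sample.int(n, length(ind_idx_all), replace = TRUE, prob = lens)
  } else {
    nr_ctg <- pmax(1L, as.integer(round(cfg$mean_depth * lens /
                                          cfg$read_length_mean)))
    ctg_all <- rep(seq_len(n), nr_ctg)
    ind_idx_all <- sample.int(n_ind, length(ctg_all), replace = TRUE)
  }
  others <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
                  G = c("A", "C", "T"), T = c("A", "C", "G"))
  pile_list <- vector("list", n)
  reads_list <- vector("list", n)
  sampled_counts <- if (nrow(snps)) {
    snps[, .(contig_id, pos, sampled_ref = 0L, sampled_alt = 0L)]
  } else NULL
  for (i in seq_len(n)) {
    ridx <- which(ctg_all == i)
    if (!length(ridx)) next
    nr <- length(ridx)
    len <- lens[i]
    rl <- as.integer(pmin(len, pmax(30, round(rnorm(nr, cfg$read_length_mean,
                                                    cfg$read_length_sd)))))
    start <- as.integer(floor(runif(nr, 0, len - rl + 1)))
    rid <- paste0(contig_ids[i], "_r", seq_len(nr))
    iidx <- ind_idx_all[ridx]
    reads_list[[i]] <- data.table(read_id = rid, contig_id = contig_ids[i],
                                  individual_id = individuals$individual_id[iidx],
                                  start = start, length = rl)
    pos <- sequence(rl) - 1L + rep(start, rl)
    obs <- data.table(
      contig_id = contig_ids[i], pos = pos,
      read_id = rep(rid, rl),
      base = strsplit(seqs[i], "")[[1]][pos + 1L],
      individual_id = rep(individuals$individual_id[iidx], rl),
      geosite_id = rep(individuals$geosite_id[iidx], rl)
    )
    if (!is_mito[i] && !is.null(snp_list[[i]])) {
      sdt <- snp_list[[i]]
      sp <- match(obs$pos, sdt$pos)
      hit <- which(!is.na(sp))
      if (length(hit)) {
        cp <- geno_list[[i]]$copies[
          match(paste(sdt$pos[sp[hit]], obs$individual_id[hit]),
                paste(geno_list[[i]]$pos, geno_list[[i]]$individual_id))]
        is_alt <- runif(length(hit)) < cp / 2
        obs$base[hit[is_alt]] <- sdt$alt[sp[hit][is_alt]]
        tab_alt <- tabulate(sp[hit][is_alt], nbins = nrow(sdt))
        tab_all <- tabulate(sp[hit], nbins = nrow(sdt))
        j <- which(sampled_counts$contig_id == contig_ids[i])
        sampled_counts$sampled_alt[j] <- tab_alt
        sampled_counts$sampled_ref[j] <- tab_all - tab_alt
      }
    }
    if (cfg$error_rate > 0) {
      ei <- which(runif(nrow(obs)) < cfg$error_rate)
      if (length(ei)) {
        obs$base[ei] <- others[cbind(match(obs$base[ei], SIM_BASES),
                                     sample.int(3L, length(ei), replace = TRUE))]
      }
    }
    pile_list[[i]] <- obs
  }
  pileup <- rbindlist(pile_list)
  setorder(pileup, contig_id, pos)
  reads <- rbindlist(reads_list)
  if (!is.null(sampled_counts) && nrow(snps)) {
    snps <- sampled_counts[snps, on = c("contig_id", "pos")]
  }

  ## ---- companion reference set: intron-inserted genome, homolog
  ## transcriptome, exon map, proteome ----
  gen_list <- vector("list", n); tx_list <- vector("list", n)
  map_list <- vector("list", n); intr_list <- vector("list", n)
  for (i in which(!is_mito)) {
    len <- lens[i]
    k <- rpois(1, cfg$intron_bp_rate * len)
    cuts <- if (k > 0) sort(unique(sample.int(len - 1L, min(k, len - 1L)))) else integer(0)
    bounds <- c(0L, cuts, len)
    exon_seqs <- substring(seqs[i], head(bounds, -1) + 1L, tail(bounds, -1))
    intron_lens <- if (length(cuts)) {
      as.integer(round(runif(length(cuts), cfg$intron_len_range[1],
                             cfg$intron_len_range[2])))
    } else integer(0)
    introns <- vapply(intron_lens, rand_seq, character(1))
    ## boundary barriers: force the first/last intron bases to mismatch the
    ## exon-adjacent contig bases they would be compared against during
    ## ungapped extension, so planted intron positions are exactly
    ## recoverable by alignment (real splice boundaries are fuzzy by a few
    ## chance-matching bases; exact truth requires decodable boundaries)
    qch <- strsplit(seqs[i], "")[[1]]
    for (e in seq_along(introns)) {
      cut <- cuts[e]; L <- intron_lens[e]
      B <- min(20L, L %/% 2L)
      ich <- strsplit(introns[e], "")[[1]]
      for (m in 0:(B - 1L)) {
        qr <- cut + m + 1L                 # 1-based query index cut+m
        if (qr <= len && ich[m + 1L] == qch[qr]) {
          ich[m + 1L] <- sample(setdiff(SIM_BASES, qch[qr]), 1)
        }
        ql <- cut - m                      # 1-based query index cut-1-m
        if (ql >= 1L && ich[L - m] == qch[ql]) {
          ich[L - m] <- sample(setdiff(SIM_BASES, qch[ql]), 1)
        }
      }
      introns[e] <- paste(ich, collapse = "")
    }
    flank5 <- rand_seq(100L); flank3 <- rand_seq(100L)
    pieces <- character(0)
    g_off <- nchar(flank5)
    g_starts <- integer(length(exon_seqs)); g_ends <- integer(length(exon_seqs))
    for (e in seq_along(exon_seqs)) {
      g_starts[e] <- g_off
      g_off <- g_off + nchar(exon_seqs[e])
      g_ends[e] <- g_off
      pieces <- c(pieces, exon_seqs[e])
      if (e <= length(introns)) {
        pieces <- c(pieces, introns[e])
        g_off <- g_off + nchar(introns[e])
      }
    }
    gid <- paste0("g_", contig_ids[i])
    tid <- paste0("t_", contig_ids[i])
    gen_list[[i]] <- setNames(paste0(flank5, paste(pieces, collapse = ""), flank3), gid)
    tx_list[[i]] <- setNames(mutate_seq(seqs[i], cfg$divergence), tid)
    map_list[[i]] <- data.table(transcript_id = tid, genome_id = gid,
                                t_start = head(bounds, -1), t_end = tail(bounds, -1),
                                g_start = g_starts, g_end = g_ends, strand = "+")
    intr_list[[i]] <- if (length(cuts)) {
      data.table(contig_id = contig_ids[i], cut = cuts,
                 intron_length = intron_lens)
    } else NULL
  }
  refset <- reference_set(
    species_id = "simspecies",
    genome = unlist(gen_list[!vapply(gen_list, is.null, logical(1))]),
    transcriptome = unlist(tx_list[!vapply(tx_list, is.null, logical(1))]),
    exon_map = rbindlist(map_list),
    proteome = setNames(unname(peptides[!is_mito]),
                        paste0("t_", contig_ids[!is_mito]))
  )
  introns_truth <- rbindlist(intr_list[!vapply(intr_list, is.null, logical(1))])
  if (nrow(snps)) {
    snps[, target_present := pos >= 60L & pos <= contigs$length[match(contig_id, contigs$contig_id)] - 61L]
    if (nrow(introns_truth)) {
      snps[, ie_truth := {
        ct <- introns_truth[contig_id == .BY$contig_id, cut]
        vapply(pos, function(p) {
          if (any(ct >= p - 59L & ct <= p + 60L)) "0" else "1"
        }, character(1))
      }, by = contig_id]
    } else {
      snps[, ie_truth := "1"]
    }
    snps[target_present == FALSE, ie_truth := NA_character_]
  }

  structure(list(contigs = contigs, pileup = pileup, reads = reads,
                 individuals = individuals, tag_table = tag_table,
                 refset = refset, mito_reference = c(mito = mito_genome),
                 truth = list(snps = snps, genotypes = genotypes,
                              introns = introns_truth),
                 config = cfg),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("<sim_dataset> ", nrow(x$contigs), " contigs (",
      sum(x$contigs$is_mito), " mitochondrial), ", nrow(x$reads), " reads, ",
      nrow(x$truth$snps), " planted SNPs; profile ", x$config$profile,
      ", seed ", x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Write a simulated dataset to plain-text files
#'
#' @param sim [simulate_dataset()] output.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
sim_write <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(setNames(sim$contigs$sequence, sim$contigs$contig_id),
              file.path(dir, "contigs.fasta"))
  write_pileup(sim$pileup, file.path(dir, "pileup.tsv"))
  fwrite(sim$tag_table, file.path(dir, "tags.tsv"), sep = "\t")
  write_fasta(sim$refset$genome, file.path(dir, "ref_genome.fasta"))
  write_fasta(sim$refset$transcriptome, file.path(dir, "ref_transcripts.fasta"))
  write_fasta(sim$refset$proteome, file.path(dir, "ref_proteome.fasta"))
  fwrite(sim$refset$exon_map, file.path(dir, "ref_exon_map.tsv"), sep = "\t")
  write_fasta(sim$mito_reference, file.path(dir, "mito_reference.fasta"))
  if (nrow(sim$truth$snps)) {
    out <- copy(sim$truth$snps)
    out[, position := to_one_based(pos)][, pos := NULL]
    fwrite(out, file.path(dir, "truth_snps.tsv"), sep = "\t")
  }
  invisible(dir)
}

#' Simulate barcode-tagged reads for demultiplexing
#'
#' Each read is a 5' tag (drawn from the individual's two tags) followed by a
#' random insert; a configured fraction of reads get two substitutions inside
#' the tag, making them unassignable under exact matching.
#'
#' @param tag_table tag table (see [read_tag_table()]).
#' @param n_reads number of reads.
#' @param insert_length insert length after the tag (default 60).
#' @param corrupt_fraction fraction of reads with a corrupted tag (default 0).
#' @param seed integer seed.
#' @return list: `reads` (data.table: `read_id`, `sequence`, `quality`,
#'   `individual_id`, `geosite_id` all `NA`), `truth` (`read_id`,
#'   `individual_id`, `corrupted`).
#' @export
simulate_tagged_reads <- function(tag_table, n_reads, insert_length = 60L,
                                  corrupt_fraction = 0, seed) {
  stopifnot(!missing(seed))
  set.seed(as.integer(seed))
  tt <- as.data.table(tag_table)
  tag_len <- nchar(tt$tag[1])
  pick <- sample.int(nrow(tt), n_reads, replace = TRUE)
  tags <- tt$tag[pick]
  n_corrupt <- round(corrupt_fraction * n_reads)
  corrupted <- rep(FALSE, n_reads)
  if (n_corrupt > 0) {
    ci <- sample.int(n_reads, n_corrupt)
    corrupted[ci] <- TRUE
    for (i in ci) {
      ch <- strsplit(tags[i], "")[[1]]
      at <- sample.int(tag_len, 2L)
      for (j in at) ch[j] <- sample(setdiff(SIM_BASES, ch[j]), 1)
      tags[i] <- paste(ch, collapse = "")
    }
  }
  inserts <- vapply(seq_len(n_reads), function(i) rand_seq(insert_length),
                    character(1))
  reads <- data.table(
    read_id = sprintf("sr%06d", seq_len(n_reads)),
    sequence = paste0(tags, inserts),
    quality = strrep("I", tag_len + insert_length),
    individual_id = NA_character_, geosite_id = NA_character_
  )
  list(reads = reads,
       truth = data.table(read_id = reads$read_id,
                          individual_id = tt$individual_id[pick],
                          corrupted = corrupted))
}

#' Compare called candidates against planted truth
#'
#' Sensitivity is assessed over planted SNPs that were *discoverable* under
#' the count rules: both alleles drawn at least twice among the (pre-error)
#' sampled read bases. `msaf_bias` is the mean of (MSAF - realized panel
#' minor allele frequency) over true-positive calls: MSAF estimates the
#' allele frequency of the sequenced discovery panel, so its deviation from
#' the planted panel frequency isolates sequencing sampling noise.
#'
#' @param candidates candidate table from [call_snps()].
#' @param truth `truth` element of a [simulate_dataset()] result.
#' @return list: `sensitivity` (`NA` when nothing was discoverable),
#'   `n_eligible`, `n_true_positive`, `false_positives`, `msaf_bias`,
#'   `abs_dev` (per-true-positive |MSAF - panel MAF|).
#' @export
truth_compare <- function(candidates, truth) {
  snps <- truth$snps
  cand <- as.data.table(candidates)
  if (is.null(snps) || nrow(snps) == 0) {
    return(list(sensitivity = NA_real_, n_eligible = 0L, n_true_positive = 0L,
                false_positives = nrow(cand), msaf_bias = NA_real_,
                abs_dev = numeric(0)))
  }
  eligible <- snps[sampled_ref >= 2L & sampled_alt >= 2L]
  hit <- cand[snps, on = c("contig_id", "pos"), nomatch = NULL]
  hit_eligible <- cand[eligible, on = c("contig_id", "pos"), nomatch = NULL]
  fp <- nrow(cand) - nrow(hit)
  sens <- if (nrow(eligible)) nrow(hit_eligible) / nrow(eligible) else NA_real_
  dev <- hit$msaf - hit$panel_maf
  list(sensitivity = sens, n_eligible = nrow(eligible),
       n_true_positive = nrow(hit_eligible), false_positives = fp,
       msaf_bias = if (length(dev)) mean(dev) else NA_real_,
       abs_dev = abs(dev))
}
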