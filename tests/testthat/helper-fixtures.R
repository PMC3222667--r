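## fixture builders and independent oracles shared across test files

library(data.table)

BASES4 <- c("A", "C", "G", "T")

rnd_seq <- function(n) paste(sample(BASES4, n, replace = TRUE), collapse = "")

## one pileup column at a given position from a vector of observed bases
make_column <- function(bases, contig = "c1", position = 10L,
                        individuals = NULL, geosites = NULL) {
  n <- length(bases)
  data.table(
    contig_id = contig, pos = as.integer(position),
    read_id = paste0(contig, "_p", position, "_r", seq_len(n)),
    base = bases,
    individual_id = individuals %||% paste0("ind", seq_len(n)),
    geosite_id = geosites %||% rep("SITE1", n)
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

## independent count-rule oracle for a single column of observed bases
oracle_call_column <- function(bases, min_depth = 4L, min_allele = 2L) {
  nuc <- bases[bases %in% BASES4]
  tab <- table(factor(nuc, levels = BASES4))
  tab <- tab[tab > 0]
  pass <- tab[tab >= min_allele]
  if (length(pass) != 2L || sum(tab) < min_depth) return(NULL)
  ord <- order(-pass, names(pass))   # count desc, base asc on ties
  list(major = names(pass)[ord[1]], minor = names(pass)[ord[2]],
       major_count = as.integer(pass[ord[1]]),
       minor_count = as.integer(pass[ord[2]]),
       depth = as.integer(sum(tab)),
       msaf = as.integer(pass[ord[2]]) / sum(tab))
}

## all multisets of `symbols` of size d (rows of a character matrix)
all_multisets <- function(symbols, d) {
  if (d == 0) return(matrix(character(0), nrow = 1, ncol = 0))
  g <- do.call(expand.grid, c(rep(list(symbols), d),
                              stringsAsFactors = FALSE))
  m <- t(apply(as.matrix(g), 1, sort))
  unique(m)
}

## genotype matrix from per-locus call vectors
make_gm <- function(..., cluster_ok = NULL) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows) %||% paste0("locus", seq_along(rows))
  colnames(m) <- paste0("s", seq_len(ncol(m)))
  genotype_matrix(m, cluster_ok)
}

## brute-force AUC by concordant-pair counting (ties count 1/2)
oracle_auc <- function(scores, labels) {
  xs <- scores[labels == 1]; ys <- scores[labels == 0]
  tot <- 0
  for (x in xs) for (y in ys) tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(xs) * length(ys))
}
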