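## demux: assign barcode-tagged reads to individuals/geosites.

hamming_dist <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

#' Read and validate a barcode tag table
#'
#' TSV with header `tag, individual_id, geosite_id`. All tags must have equal
#' length, be unique, and be pairwise at least `min_hamming` substitutions
#' apart (the multiplexing protocol relies on tags being unambiguously
#' recognizable).
#'
#' @param path TSV file.
#' @param min_hamming minimum pairwise Hamming distance between tags.
#' @return data.table with columns `tag`, `individual_id`, `geosite_id`.
#' @export
read_tag_table <- function(path, min_hamming = 2L) {
  x <- fread(path, sep = "\t", header = TRUE, colClasses = "character",
             showProgress = FALSE)
  validate_tag_table(x, min_hamming)
}

#' @rdname read_tag_table
#' @param tags data.table/data.frame with columns `tag`, `individual_id`,
#'   `geosite_id`.
#' @export
validate_tag_table <- function(tags, min_hamming = 2L) {
  tags <- as.data.table(tags)
  need <- c("tag", "individual_id", "geosite_id")
  if (!all(need %in% names(tags))) {
    stop("tag table needs columns: ", paste(need, collapse = ", "))
  }
  if (nrow(tags) == 0) stop("empty tag table")
  tags[, tag := toupper(tag)]
  if (length(unique(nchar(tags$tag))) != 1) stop("tags must all have the same length")
  if (anyDuplicated(tags$tag)) stop("duplicate tags in tag table")
  if (grepl("[^ACGT]", paste(tags$tag, collapse = ""))) {
    stop("tags must be over the ACGT alphabet")
  }
  n <- nrow(tags)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (hamming_dist(tags$tag[i], tags$tag[j]) < min_hamming) {
          stop("tags ", tags$tag[i], " and ", tags$tag[j],
               " are closer than the minimum Hamming distance ", min_hamming)
        }
      }
    }
  }
  tags[]
}

#' Demultiplex barcode-tagged reads
#'
#' Assigns each read to an individual/geosite by its 5' barcode tag and clips
#' the tag from the assigned read. Only the 5' tag is required; a 3' tag, when
#' recognizably present at the read end (a table tag or its reverse
#' complement), is clipped but not checked. In the default `exact` mode a read
#' is assigned only when its 5' prefix equals a table tag verbatim; mode
#' `mismatch` tolerates up to `max_mismatch` substitutions provided the best
#' tag is unique.
#'
#' @param reads data.table with at least `read_id` and `sequence` (see
#'   [read_fastq()]).
#' @param tags tag table (see [read_tag_table()]).
#' @param mode `"exact"` (default) or `"mismatch"`.
#' @param max_mismatch maximum substitutions tolerated in `mismatch` mode.
#' @return list with `assigned` (ids set, tag clipped), `unassigned`
#'   (untouched reads), and `summary` (counts per individual plus
#'   `n_unassigned`); the two sets partition the input.
#' @export
demultiplex <- function(reads, tags, mode = c("exact", "mismatch"),
                        max_mismatch = 1L) {
  mode <- match.arg(mode)
  tags <- validate_tag_table(tags, min_hamming = 1L)
  reads <- as.data.table(reads)
  tag_len <- nchar(tags$tag[1])
  if (nrow(reads) == 0) {
    return(list(assigned = reads, unassigned = reads,
                summary = data.table(bin = character(), n = integer())))
  }
  if (min(nchar(reads$sequence)) < tag_len) {
    stop("tag length exceeds the shortest read length")
  }
  prefix <- toupper(substr(reads$sequence, 1L, tag_len))
  hit <- match(prefix, tags$tag)
  if (mode == "mismatch") {
    todo <- which(is.na(hit))
    if (length(todo)) {
      tag_mat <- do.call(rbind, strsplit(tags$tag, ""))
      for (i in todo) {
        pv <- strsplit(prefix[i], "")[[1]]
        d <- rowSums(tag_mat != matrix(pv, nrow(tag_mat), tag_len, byrow = TRUE))
        ok <- which(d <= max_mismatch)
        if (length(ok) >= 1 && sum(d == min(d)) == 1 && min(d) <= max_mismatch) {
          hit[i] <- which.min(d)
        }
      }
    }
  }
  assigned <- reads[!is.na(hit)]
  unassigned <- reads[is.na(hit)]
  idx <- hit[!is.na(hit)]
  if (nrow(assigned)) {
    assigned[, individual_id := tags$individual_id[idx]]
    assigned[, geosite_id := tags$geosite_id[idx]]
    assigned[, sequence := substr(sequence, tag_len + 1L, nchar(sequence))]
    if ("quality" %in% names(assigned)) {
      assigned[, quality := substr(quality, tag_len + 1L, nchar(quality))]
    }
    ## clip a recognizable 3' tag (tag or reverse complement), unchecked
    tail_seq <- substr(assigned$sequence,
                       pmax(1L, nchar(assigned$sequence) - tag_len + 1L),
                       nchar(assigned$sequence))
    tag_rc <- revcomp(tags$tag)
    clip <- tail_seq %in% c(tags$tag, tag_rc) &
      nchar(assigned$sequence) > tag_len
    if (any(clip)) {
      assigned[clip, sequence := substr(sequence, 1L, nchar(sequence) - tag_len)]
      if ("quality" %in% names(assigned)) {
        assigned[clip, quality := substr(quality, 1L, nchar(quality))]
        assigned[clip, quality := substr(quality, 1L, nchar(sequence))]
      }
    }
  }
  summ <- assigned[, .(n = .N), by = .(bin = individual_id)]
  summ <- rbind(summ, data.table(bin = "n_unassigned", n = nrow(unassigned)))
  list(assigned = assigned[], unassigned = unassigned[], summary = summ[])
}
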