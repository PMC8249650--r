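#' Genome record
#'
#' Lightweight container for a named nucleotide sequence with a topology
#' flag. Bacterial chromosomes are circular; plasmids may be circular or
#' linear.
#'
#' @param id Sequence identifier.
#' @param sequence Nucleotide string over `A`, `C`, `G`, `T`, `N`.
#' @param circular Is the replicon circular?
#' @return An object of class `genome_record` with elements `id`,
#'   `sequence`, `circular` and `length`.
#' @export
genome_record <- function(id, sequence, circular = TRUE) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  check_flag(circular, "circular")
  if (nchar(sequence) == 0L)
    stop("sequence must be non-empty", call. = FALSE)
  if (grepl("[^ACGTN]", sequence))
    stop("sequence contains characters outside {A,C,G,T,N}", call. = FALSE)
  structure(list(id = id, sequence = sequence, circular = circular,
                 length = nchar(sequence)),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %s bp, %s\n", x$id,
              format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Read a FASTA file
#'
#' @param path Path to a FASTA file.
#' @param circular Topology flag applied to every record.
#' @return A single [genome_record()] if the file holds one sequence,
#'   otherwise a named list of records.
#' @export
read_fasta <- function(path, circular = TRUE) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("no sequences in ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(seqs))
  recs <- lapply(seq_along(seqs), function(i)
    genome_record(ids[i], as.character(seqs[[i]]), circular = circular))
  names(recs) <- ids
  if (length(recs) == 1L) recs[[1L]] else recs
}

#' Write genome records to FASTA
#'
#' @param records A [genome_record()] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "genome_record")) records <- list(records)
  set <- Biostrings::DNAStringSet(vapply(records, `[[`, "", "sequence"))
  names(set) <- vapply(records, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read gene features from GFF3
#'
#' Coordinates are kept 1-based inclusive (the GFF3 convention, used
#' throughout the package).
#'
#' @param path Path to a GFF3 file.
#' @param feature_types Feature types to retain; `NULL` keeps everything.
#' @return A data frame with columns `id`, `seqid`, `start`, `end`,
#'   `strand`, `kind`.
#' @export
read_gff3 <- function(path, feature_types = c("gene", "CDS")) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e)
                   stop("malformed GFF3 in ", path, ": ",
                        conditionMessage(e), call. = FALSE))
  df <- data.frame(
    id     = as.character(gr$ID %||% paste0("feature_", seq_along(gr))),
    seqid  = as.character(GenomicRanges::seqnames(gr)),
    start  = GenomicRanges::start(gr),
    end    = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    kind   = as.character(gr$type),
    stringsAsFactors = FALSE
  )
  na_id <- is.na(df$id)
  if (any(na_id)) df$id[na_id] <- paste0("feature_", which(na_id))
  if (!is.null(feature_types)) df <- df[df$kind %in% feature_types, ]
  rownames(df) <- NULL
  validate_annotation(df)
  df
}

#' Write gene features to GFF3
#'
#' @param features Annotation data frame as returned by [read_gff3()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  validate_annotation(features)
  gr <- GenomicRanges::GRanges(
    seqnames = features$seqid,
    ranges   = IRanges::IRanges(features$start, features$end),
    strand   = features$strand
  )
  gr$type   <- features$kind
  gr$ID     <- features$id
  gr$source <- "strainprofiler"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

validate_annotation <- function(features) {
  need <- c("id", "seqid", "start", "end", "strand")
  miss <- setdiff(need, names(features))
  if (length(miss))
    stop("annotation lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(features$end < features$start)
  if (length(bad))
    stop("annotation feature(s) with end < start: ",
         paste(features$id[bad], collapse = ", "), call. = FALSE)
  if (any(features$start < 1L))
    stop("annotation coordinates are 1-based; start < 1 found",
         call. = FALSE)
  if (!all(features$strand %in% c("+", "-")))
    stop("annotation strand must be '+' or '-'", call. = FALSE)
  invisible(features)
}

#' Read a depth track TSV
#'
#' Expected format: `seqid<TAB>pos<TAB>depth[<TAB>strand]`, no header,
#' positions 1-based. Positions outside `1..seq_length` (when given) are
#' rejected.
#'
#' @param path Path to the TSV.
#' @param seq_length Optional sequence length used to validate positions.
#' @return A depth-track data frame with columns `seqid`, `pos`, `depth`
#'   and, when present in the file, `strand`.
#' @export
read_depth_tsv <- function(path, seq_length = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (!ncol(df) %in% c(3L, 4L))
    stop("depth TSV must have 3 or 4 columns, found ", ncol(df),
         call. = FALSE)
  names(df) <- c("seqid", "pos", "depth", if (ncol(df) == 4L) "strand")
  bad <- which(!is.finite(df$pos) | df$pos < 1 | df$pos != floor(df$pos))
  if (length(bad))
    stop("depth TSV line ", bad[1L],
         ": positions must be 1-based integers", call. = FALSE)
  bad <- which(!is.finite(df$depth) | df$depth < 0)
  if (length(bad))
    stop("depth TSV line ", bad[1L], ": depth must be >= 0", call. = FALSE)
  if (!is.null(seq_length)) {
    bad <- which(df$pos > seq_length)
    if (length(bad))
      stop("depth TSV line ", bad[1L], ": position ", df$pos[bad[1L]],
           " outside sequence of length ", seq_length, call. = FALSE)
  }
  if ("strand" %in% names(df) && !all(df$strand %in% c("+", "-", "both")))
    stop("depth TSV strand column must be '+', '-' or 'both'",
         call. = FALSE)
  df$pos <- as.integer(df$pos)
  df
}

#' Write a depth track TSV
#'
#' @param track Depth-track data frame (`seqid`, `pos`, `depth`
#'   and optionally `strand`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_depth_tsv <- function(track, path) {
  cols <- c("seqid", "pos", "depth",
            if ("strand" %in% names(track)) "strand")
  utils::write.table(track[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a numeric matrix TSV
#'
#' Matrices (expression, counts, abundances) are stored as TSV with a
#' header row of sample names and row names in the first column.
#'
#' @param path File path.
#' @return `read_matrix_tsv`: a numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          row.names = 1L, check.names = FALSE)
  as.matrix(df)
}

#' @rdname read_matrix_tsv
#' @param mat Numeric matrix with row and column names.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(feature = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a FASTQ file into read records
#'
#' @param path Path to an (uncompressed or gzipped) FASTQ file.
#' @return Data frame with columns `id`, `bases`, `quals` (Phred+33
#'   encoded quality string).
#' @export
read_fastq <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq",
                                       with.qualities = TRUE)
  data.frame(
    id    = unname(sub("\\s.*$", "", names(seqs))),
    bases = unname(as.character(seqs)),
    quals = unname(as.character(S4Vectors::mcols(seqs)$qualities)),
    stringsAsFactors = FALSE
  )
}

#' Write read records to FASTQ
#'
#' @param reads Data frame with `id`, `bases`, `quals`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  set <- Biostrings::DNAStringSet(reads$bases)
  names(set) <- reads$id
  Biostrings::writeXStringSet(set, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$quals))
  invisible(path)
}

#' Quality-filter sequencing reads
#'
#' Applies the standard raw-read filters in order: (1) discard reads with
#' more than `max_n` ambiguous `N` bases; (2) trim consecutive 3' bases
#' whose quality is below `quality_floor`; (3) discard reads shorter than
#' `min_len` after trimming. Adapter clipping is assumed to have happened
#' upstream.
#'
#' @param reads Data frame with columns `id`, `bases`, `quals`
#'   (Phred+33). `quals` may be omitted, in which case no trimming occurs.
#' @param max_n Maximum tolerated number of `N` bases (default 2).
#' @param min_len Minimum read length after trimming (default 16 nt).
#' @param quality_floor Phred score below which 3' bases are trimmed
#'   (default 20).
#' @param quality_offset ASCII offset of the quality encoding (33).
#' @return A list with `reads` (the surviving, possibly trimmed records)
#'   and `summary`, a named integer vector with counts per rule
#'   (`input`, `removed_n`, `removed_short`, `output`).
#' @export
filter_reads <- function(reads, max_n = 2L, min_len = 16L,
                         quality_floor = 20L, quality_offset = 33L) {
  check_number(max_n, "max_n", lower = 0)
  check_number(min_len, "min_len", lower = 1)
  n_input <- nrow(reads)
  if (n_input == 0L)
    return(list(reads = reads,
                summary = c(input = 0L, removed_n = 0L,
                            removed_short = 0L, output = 0L)))
  if (any(nchar(reads$bases) != nchar(reads$quals %||% reads$bases)))
    stop("bases and quality strings differ in length", call. = FALSE)

  n_count <- nchar(reads$bases) - nchar(gsub("N", "", reads$bases, fixed = TRUE))
  keep_n <- n_count <= max_n
  removed_n <- sum(!keep_n)
  out <- reads[keep_n, , drop = FALSE]

  if ("quals" %in% names(out) && nrow(out) > 0L) {
    keep_len <- vapply(out$quals, function(q) {
      qs <- utf8ToInt(q) - quality_offset
      ok <- which(qs >= quality_floor)
      if (length(ok)) ok[length(ok)] else 0L
    }, integer(1L), USE.NAMES = FALSE)
    out$bases <- substr(out$bases, 1L, keep_len)
    out$quals <- substr(out$quals, 1L, keep_len)
  }
  keep_short <- nchar(out$bases) >= min_len
  removed_short <- sum(!keep_short)
  out <- out[keep_short, , drop = FALSE]
  rownames(out) <- NULL

  list(reads = out,
       summary = c(input = n_input, removed_n = removed_n,
                   removed_short = removed_short, output = nrow(out)))
}

#' Read an alignment summary TSV
#'
#' One row per reported hit with a header row:
#' `read_id<TAB>n_hits<TAB>seqid<TAB>start<TAB>strand`. `n_hits` is the
#' total number of places the read aligned; uniquely aligned reads have
#' `n_hits == 1`.
#'
#' @param path Path to the TSV.
#' @return Data frame with those columns.
#' @export
read_alignment_summary <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("read_id", "n_hits", "seqid", "start", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("alignment summary lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (any(df$n_hits < 1L))
    stop("n_hits must be >= 1", call. = FALSE)
  df
}
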