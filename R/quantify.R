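## Strain-specific quantification from unique alignments: mapped
## fractions, RPKM/TPM, and taxonomic roll-ups of relative abundances.

#' Extract uniquely aligned reads and mapping statistics
#'
#' Keeps alignment records with exactly one reported hit
#' (`n_hits == 1`); multi-mapping reads are excluded so conserved regions
#' shared between related strains do not inflate strain-specific signal.
#'
#' @param alignments Alignment-summary data frame
#'   (see [read_alignment_summary()]): one row per hit with columns
#'   `read_id`, `n_hits`, `seqid`, `start`, `strand`.
#' @return List with `alignments` (the unique-read rows), and `stats`:
#'   `total_reads`, `n_unique`, `unique_fraction` (0 with `empty = TRUE`
#'   when the input has no reads), and `per_seqid`, a data frame of
#'   unique-read counts and fractions per target sequence.
#' @export
extract_unique <- function(alignments) {
  total <- length(unique(alignments$read_id))
  uni <- alignments[alignments$n_hits == 1L, , drop = FALSE]
  rownames(uni) <- NULL
  n_unique <- nrow(uni)
  empty <- total == 0L
  per_seqid <- if (n_unique) {
    tab <- table(uni$seqid)
    data.frame(seqid = names(tab), n_unique = as.integer(tab),
               fraction = as.integer(tab) / total,
               stringsAsFactors = FALSE)
  } else {
    data.frame(seqid = character(0), n_unique = integer(0),
               fraction = numeric(0))
  }
  list(alignments = uni,
       stats = list(total_reads = total, n_unique = n_unique,
                    unique_fraction = if (empty) 0 else n_unique / total,
                    empty = empty, per_seqid = per_seqid))
}

#' Reads Per Kilobase per Million mapped reads
#'
#' `RPKM_i = counts_i / ((lengths_i / 1e3) * (total_mapped / 1e6))`.
#'
#' @param counts Per-feature read counts (non-negative).
#' @param lengths Per-feature lengths in bp (positive).
#' @param total_mapped Library size: total mapped reads (positive).
#' @return Numeric vector of RPKM values.
#' @export
rpkm <- function(counts, lengths, total_mapped) {
  if (any(lengths <= 0)) stop("feature lengths must be > 0", call. = FALSE)
  check_number(total_mapped, "total_mapped", lower = 0, strict_lower = TRUE)
  counts / ((lengths / 1e3) * (total_mapped / 1e6))
}

#' Transcripts Per Million
#'
#' Length-normalized rates rescaled so each library sums to one million:
#' `rate_i = counts_i / lengths_i; TPM_i = 1e6 * rate_i / sum(rate)`.
#'
#' @param counts Per-feature read counts with at least one nonzero entry.
#' @param lengths Per-feature lengths in bp (positive).
#' @return Numeric vector of TPM values summing to 1e6.
#' @export
tpm <- function(counts, lengths) {
  if (any(lengths <= 0)) stop("feature lengths must be > 0", call. = FALSE)
  if (all(counts == 0)) stop("all counts are zero", call. = FALSE)
  rate <- counts / lengths
  1e6 * rate / sum(rate)
}

#' Roll contig/feature abundances up a taxonomy
#'
#' Sums per-sample relative abundances of features grouped by their
#' lineage label at the requested rank; per-sample totals are conserved
#' exactly.
#'
#' @param abundance Numeric matrix, features x samples (relative
#'   fractions or any additive value).
#' @param taxmap Data frame mapping `feature` to one column per rank
#'   (e.g. `species`, `genus`, ..., `kingdom`). Every feature in
#'   `abundance` must be present exactly once.
#' @param level Rank column of `taxmap` to aggregate at.
#' @return Numeric matrix, taxa x samples.
#' @export
aggregate_taxa <- function(abundance, taxmap, level) {
  if (!level %in% names(taxmap))
    stop("taxonomy has no rank column `", level, "`", call. = FALSE)
  if (anyDuplicated(taxmap$feature))
    stop("taxonomy maps some features to more than one lineage",
         call. = FALSE)
  miss <- setdiff(rownames(abundance), taxmap$feature)
  if (length(miss))
    stop("features missing from the taxonomy: ",
         paste(miss, collapse = ", "), call. = FALSE)
  labels <- taxmap[[level]][match(rownames(abundance), taxmap$feature)]
  rowsum(abundance, labels)
}
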