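## Candidate sRNA discovery from strand-specific RNA-seq coverage: region
## classification, per-stage peak calling, cross-stage merging by genomic
## location, stage-overlap (Venn) statistics, and per-sample expression.

#' Peak-calling configuration
#'
#' @param min_depth Minimum depth a position must reach to seed a peak
#'   (default 10).
#' @param min_fold Minimum fold enrichment over the local background
#'   median (default 5; must be > 1).
#' @param background_window Flank size in bp over which the local
#'   background median is taken, excluding the run itself (default 2000).
#' @param min_len,max_len Candidate length bounds in nt (defaults 50 and
#'   600, spanning the typical bacterial sRNA range).
#' @param merge_rule Cross-stage merge criterion: `"any_overlap"`
#'   (default) or `"reciprocal_50"`.
#' @return A list of class `peak_call_config`.
#' @export
peak_call_config <- function(min_depth = 10, min_fold = 5,
                             background_window = 2000L, min_len = 50L,
                             max_len = 600L,
                             merge_rule = c("any_overlap", "reciprocal_50")) {
  merge_rule <- match.arg(merge_rule)
  check_number(min_depth, "min_depth", lower = 0)
  if (min_fold <= 1) stop("`min_fold` must be > 1", call. = FALSE)
  check_number(background_window, "background_window", lower = 1)
  if (min_len > max_len) stop("min_len must be <= max_len", call. = FALSE)
  structure(list(min_depth = min_depth, min_fold = min_fold,
                 background_window = as.integer(background_window),
                 min_len = as.integer(min_len),
                 max_len = as.integer(max_len), merge_rule = merge_rule),
            class = "peak_call_config")
}

#' Classify a transcribed interval relative to the gene annotation
#'
#' `"intragenic"` if the interval overlaps a gene on the same strand
#' (same-strand signal dominates when genes on both strands are touched),
#' `"antisense"` if it overlaps genes only on the opposite strand, and
#' `"intergenic"` if it overlaps no gene.
#'
#' @param start,end 1-based inclusive interval coordinates.
#' @param strand Interval strand, `"+"` or `"-"`.
#' @param annotation Annotation data frame ([read_gff3()] layout).
#' @return One of `"intragenic"`, `"antisense"`, `"intergenic"`.
#' @export
classify_region <- function(start, end, strand, annotation) {
  if (end < start) stop("end < start", call. = FALSE)
  ov <- annotation$start <= end & annotation$end >= start
  if (any(ov & annotation$strand == strand)) return("intragenic")
  if (any(ov)) return("antisense")
  "intergenic"
}

#' Call candidate sRNA peaks from one stage's stranded coverage
#'
#' On each strand, maximal runs of positions exceeding a per-position
#' threshold are found: inside a same-strand gene the threshold is
#' `max(min_depth, min_fold x the gene's own body level)` — so an
#' intragenic peak must rise above its host gene's expression and an
#' expressed gene body does not call as a peak — and elsewhere it is
#' `min_depth`. Runs are split at same-strand gene boundaries so
#' intergenic/antisense signal is not fused with gene bodies; segments
#' outside genes must additionally exceed `min_fold` times the local
#' background median over `background_window` bp of flank (run
#' excluded). Surviving segments are filtered to `[min_len, max_len]`
#' and classified.
#'
#' @param track Stranded depth-track data frame (`seqid`, `pos`, `depth`,
#'   `strand`); an unstranded track is an error since the antisense
#'   category requires strand-resolved coverage.
#' @param annotation Annotation data frame.
#' @param genome_length Sequence length in bp.
#' @param config A [peak_call_config()].
#' @return Data frame of candidates: `seqid`, `start`, `end`, `strand`,
#'   `category`, `mean_depth`, ordered by coordinate.
#' @export
detect_peaks <- function(track, annotation, genome_length,
                         config = peak_call_config()) {
  if (!"strand" %in% names(track))
    stop("strand-resolved coverage required: the track has no strand ",
         "column", call. = FALSE)
  L <- as.integer(genome_length)
  out <- list()
  for (std in c("+", "-")) {
    vec <- numeric(L)
    rows <- track$strand == std
    vec[track$pos[rows]] <- track$depth[rows]
    ann_same <- annotation[annotation$strand == std, , drop = FALSE]
    segs <- call_peaks_one_strand(vec, ann_same, config)
    if (nrow(segs)) {
      segs$strand <- std
      out[[std]] <- segs
    }
  }
  if (!length(out))
    return(data.frame(seqid = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      category = character(0), mean_depth = numeric(0)))
  res <- do.call(rbind, out)
  res$seqid <- track$seqid[1L]
  res$category <- vapply(seq_len(nrow(res)), function(i)
    classify_region(res$start[i], res$end[i], res$strand[i], annotation),
    "")
  ## intragenic calls must rise above their own gene body, not just the
  ## genome background
  keep <- rep.int(TRUE, nrow(res))
  for (i in which(res$category == "intragenic")) {
    std <- res$strand[i]
    vec <- numeric(L)
    rows <- track$strand == std
    vec[track$pos[rows]] <- track$depth[rows]
    host <- host_gene(res$start[i], res$end[i],
                      annotation[annotation$strand == std, , drop = FALSE])
    if (is.null(host)) next
    gene_pos <- setdiff(host$start:host$end, res$start[i]:res$end[i])
    gene_bg <- if (length(gene_pos)) stats::median(vec[gene_pos]) else 0
    if (gene_bg > 0 && res$mean_depth[i] < config$min_fold * gene_bg)
      keep[i] <- FALSE
  }
  res <- res[keep, , drop = FALSE]
  res <- res[order(res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res[, c("seqid", "start", "end", "strand", "category", "mean_depth")]
}

## gene-aware thresholding -> runs -> gene-boundary splitting ->
## local-background refinement, for a single strand's depth vector
call_peaks_one_strand <- function(vec, ann_same, config) {
  L <- length(vec)
  ## per-position seeding threshold: inside a same-strand gene a peak must
  ## clear min_fold times the gene's own body level (robust low quantile,
  ## so a broad peak cannot mask itself), elsewhere min_depth
  thr_vec <- rep.int(config$min_depth, L)
  for (i in seq_len(nrow(ann_same))) {
    idx <- ann_same$start[i]:ann_same$end[i]
    body <- stats::quantile(vec[idx], 0.1, names = FALSE)
    thr_vec[idx] <- pmax(thr_vec[idx], config$min_fold * body)
  }
  r <- rle(vec >= thr_vec)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  run_s <- starts[r$values]
  run_e <- ends[r$values]
  cuts <- sort(unique(c(ann_same$start, ann_same$end + 1L)))
  in_gene <- logical(L)
  for (i in seq_len(nrow(ann_same)))
    in_gene[ann_same$start[i]:ann_same$end[i]] <- TRUE
  segs <- list()
  for (j in seq_along(run_s)) {
    ## split the run at same-strand gene boundaries so intergenic or
    ## antisense signal is never fused with gene-body signal
    cc <- cuts[cuts > run_s[j] & cuts <= run_e[j]]
    seg_s <- c(run_s[j], cc)
    seg_e <- c(cc - 1L, run_e[j])
    for (m in seq_along(seg_s)) {
      s <- seg_s[m]; e <- seg_e[m]
      if (!in_gene[s]) {
        ## outside genes: require min_fold over the local background
        ## median in the flanking window, run excluded
        w <- config$background_window
        flank <- c(seq.int(max(1L, s - w), s - 1L),
                   seq.int(e + 1L, min(L, e + w)))
        bg <- if (length(flank)) stats::median(vec[flank]) else 0
        thr <- max(config$min_depth, config$min_fold * bg)
        inside <- vec[s:e] >= thr
        if (!any(inside)) next
        rr <- rle(inside)
        ee2 <- cumsum(rr$lengths); ss2 <- ee2 - rr$lengths + 1L
        sub_s <- s + ss2[rr$values] - 1L
        sub_e <- s + ee2[rr$values] - 1L
      } else {
        sub_s <- s; sub_e <- e
      }
      for (k in seq_along(sub_s)) {
        len <- sub_e[k] - sub_s[k] + 1L
        if (len < config$min_len || len > config$max_len) next
        segs[[length(segs) + 1L]] <-
          data.frame(start = sub_s[k], end = sub_e[k],
                     mean_depth = mean(vec[sub_s[k]:sub_e[k]]))
      }
    }
  }
  if (!length(segs))
    return(data.frame(start = integer(0), end = integer(0),
                      mean_depth = numeric(0)))
  do.call(rbind, segs)
}

host_gene <- function(start, end, ann_same) {
  ov <- pmin(ann_same$end, end) - pmax(ann_same$start, start) + 1L
  ov[ov < 0L] <- 0L
  if (!length(ov) || max(ov) == 0L) return(NULL)
  ann_same[which.max(ov), , drop = FALSE]
}

#' Merge per-stage sRNA candidates by genomic location
#'
#' Candidates on the same strand satisfying the merge rule are unified
#' into one candidate spanning their union; `stage_support` records which
#' stages contributed. Output ordering (by seqid, start, strand) and ids
#' are deterministic and invariant to stage order.
#'
#' @param per_stage Named list (stage label -> candidate data frame as
#'   returned by [detect_peaks()]).
#' @param merge_rule `"any_overlap"` (default) or `"reciprocal_50"`
#'   (both intervals must overlap by at least half their length).
#' @param annotation Optional annotation; when given, each merged
#'   candidate's category is re-derived from its final coordinates.
#' @return Data frame of merged candidates: `id`, `seqid`, `start`,
#'   `end`, `strand`, `category` (if derivable), `stage_support` (list
#'   column of stage labels), `n_stages`.
#' @export
merge_stages <- function(per_stage, merge_rule = c("any_overlap",
                                                   "reciprocal_50"),
                         annotation = NULL) {
  merge_rule <- match.arg(merge_rule)
  stages <- names(per_stage)
  if (is.null(stages) || any(!nzchar(stages)))
    stop("per_stage must be a named list of candidate tables",
         call. = FALSE)
  all <- do.call(rbind, lapply(stages, function(st) {
    df <- per_stage[[st]]
    if (is.null(df) || nrow(df) == 0L) return(NULL)
    df$stage <- st
    df
  }))
  empty <- data.frame(id = character(0), seqid = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), category = character(0),
                      n_stages = integer(0))
  if (is.null(all) || nrow(all) == 0L) {
    empty$stage_support <- list()
    return(empty)
  }
  groups <- split(seq_len(nrow(all)),
                  paste(all$seqid, all$strand, sep = "\r"))
  merged <- list()
  for (g in groups) {
    ir <- IRanges::IRanges(all$start[g], all$end[g])
    comp <- if (merge_rule == "any_overlap") {
      red <- IRanges::reduce(ir)
      S4Vectors::subjectHits(IRanges::findOverlaps(ir, red))
    } else {
      reciprocal_components(ir, 0.5)
    }
    for (cid in unique(comp)) {
      rows <- g[comp == cid]
      cats <- all$category[rows]
      merged[[length(merged) + 1L]] <- data.frame(
        seqid = all$seqid[rows[1L]],
        start = min(all$start[rows]), end = max(all$end[rows]),
        strand = all$strand[rows[1L]],
        category = names(sort(table(cats), decreasing = TRUE))[1L],
        stage_support = I(list(sort(unique(all$stage[rows])))),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, merged)
  res <- res[order(res$seqid, res$start, res$strand), , drop = FALSE]
  if (!is.null(annotation))
    res$category <- vapply(seq_len(nrow(res)), function(i)
      classify_region(res$start[i], res$end[i], res$strand[i], annotation),
      "")
  res$n_stages <- lengths(res$stage_support)
  res$id <- sprintf("srna_%04d", seq_len(nrow(res)))
  rownames(res) <- NULL
  res[, c("id", "seqid", "start", "end", "strand", "category",
          "stage_support", "n_stages")]
}

## connected components under reciprocal-overlap >= frac of both widths
reciprocal_components <- function(ir, frac) {
  n <- length(ir)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  hits <- IRanges::findOverlaps(ir, ir)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  keep <- qh < sh
  qh <- qh[keep]; sh <- sh[keep]
  if (length(qh)) {
    ov <- pmin(IRanges::end(ir)[qh], IRanges::end(ir)[sh]) -
      pmax(IRanges::start(ir)[qh], IRanges::start(ir)[sh]) + 1L
    good <- ov >= frac * IRanges::width(ir)[qh] &
      ov >= frac * IRanges::width(ir)[sh]
    for (i in which(good)) {
      a <- find(qh[i]); b <- find(sh[i])
      if (a != b) parent[a] <- b
    }
  }
  vapply(seq_len(n), find, integer(1L))
}

#' Stage-overlap (Venn) statistics for merged sRNA candidates
#'
#' Exact candidate counts for every non-empty subset of stages, plus the
#' headline summaries: how many candidates were detected in all stages
#' and in at least two.
#'
#' @param merged Output of [merge_stages()].
#' @param stages Stage universe; defaults to the union of observed
#'   supports.
#' @return List with `by_combination` (named counts, names like
#'   `"lag&log"`), `by_support_size`, `n_total`, `n_all_stages`,
#'   `n_at_least_2`.
#' @export
stage_overlap_counts <- function(merged, stages = NULL) {
  supports <- merged$stage_support
  stages <- stages %||% sort(unique(unlist(supports)))
  k <- length(stages)
  combos <- unlist(lapply(seq_len(max(k, 0L)), function(m)
    utils::combn(stages, m, paste, collapse = "&", simplify = FALSE)),
    use.names = FALSE)
  keys <- vapply(supports, function(s) paste(sort(s), collapse = "&"), "")
  by_comb <- stats::setNames(integer(length(combos)), combos)
  tab <- table(keys)
  by_comb[names(tab)] <- as.integer(tab)
  sizes <- lengths(supports)
  by_size <- stats::setNames(integer(k), as.character(seq_len(max(k, 0L))))
  st <- table(factor(sizes, levels = seq_len(max(k, 0L))))
  by_size[names(st)] <- as.integer(st)
  list(by_combination = by_comb, by_support_size = by_size,
       n_total = nrow(merged),
       n_all_stages = sum(sizes == k),
       n_at_least_2 = sum(sizes >= 2L))
}

#' Per-candidate, per-sample sRNA expression (RPKM)
#'
#' Counts uniquely aligned reads whose start lies within each candidate
#' interval on the candidate's strand, then normalizes by interval length
#' and library size via [rpkm()].
#'
#' @param candidates Candidate data frame (needs `seqid`, `start`, `end`,
#'   `strand`; rownames or `id` used for output rows).
#' @param alignments Named list of per-sample alignment data frames
#'   (`seqid`, `start`, `strand`; already unique-filtered).
#' @param library_sizes Optional named vector of per-sample total mapped
#'   reads; defaults to `nrow` of each alignment table.
#' @return Numeric matrix, candidates x samples, of RPKM values.
#' @export
srna_expression <- function(candidates, alignments, library_sizes = NULL) {
  samples <- names(alignments)
  if (is.null(samples)) stop("alignments must be a named list", call. = FALSE)
  lens <- candidates$end - candidates$start + 1L
  out <- matrix(0, nrow(candidates), length(samples),
                dimnames = list(candidates$id %||% rownames(candidates),
                                samples))
  for (s in samples) {
    aln <- alignments[[s]]
    total <- if (!is.null(library_sizes)) library_sizes[[s]] else nrow(aln)
    counts <- vapply(seq_len(nrow(candidates)), function(i) {
      sum(aln$seqid == candidates$seqid[i] &
            aln$strand == candidates$strand[i] &
            aln$start >= candidates$start[i] &
            aln$start <= candidates$end[i])
    }, integer(1L))
    out[, s] <- rpkm(counts, lens, total)
  }
  out
}

#' Write sRNA candidates as BED6
#'
#' @param candidates Merged candidate data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(candidates, path) {
  bed <- data.frame(chrom = candidates$seqid,
                    start = candidates$start - 1L,  # BED is 0-based half-open
                    end = candidates$end,
                    name = candidates$id %||%
                      sprintf("srna_%04d", seq_len(nrow(candidates))),
                    score = candidates$n_stages %||% 0L,
                    strand = candidates$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
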