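## Independent brute-force oracles, deliberately implemented differently
## from the package code paths they check.

## Two-sided rank-sum p by enumeration over index subsets (bitmask-free,
## but independent of wilcoxon_rank_sum's combn-over-rank-sums path).
oracle_wilcoxon_p <- function(x, y) {
  na <- length(x)
  n <- na + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(na)])
  subsets <- utils::combn(n, na, simplify = FALSE)
  sums <- vapply(subsets, function(i) sum(r[i]), numeric(1))
  p_le <- mean(sums <= w_obs + 1e-9)
  p_ge <- mean(sums >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

## Hypergeometric upper tail by counting draws explicitly.
oracle_hypergeom_p <- function(N, K, n, k) {
  draws <- utils::combn(N, n, simplify = FALSE)
  in_path <- seq_len(K)
  overlaps <- vapply(draws, function(d) sum(d %in% in_path), numeric(1))
  mean(overlaps >= k)
}

## Venn counting by direct set bookkeeping over (interval, stage) pairs:
## two intervals belong together iff they overlap on the same strand.
oracle_merge_counts <- function(stage_lists) {
  all <- do.call(rbind, lapply(names(stage_lists), function(st) {
    df <- stage_lists[[st]]
    if (is.null(df) || !nrow(df)) return(NULL)
    cbind(df, stage = st)
  }))
  n <- nrow(all)
  group <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (group[i] != group[j] &&
          all$strand[i] == all$strand[j] &&
          all$start[i] <= all$end[j] && all$end[i] >= all$start[j]) {
        group[group == group[j]] <- group[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  supports <- tapply(all$stage, group, function(s) sort(unique(s)))
  sizes <- lengths(supports)
  list(total = length(supports),
       all_four = sum(sizes == length(stage_lists)),
       at_least_2 = sum(sizes >= 2))
}

## small fixture builders ---------------------------------------------

make_track <- function(depth, seqid = "chr", strand = NULL) {
  df <- data.frame(seqid = seqid, pos = seq_along(depth), depth = depth,
                   stringsAsFactors = FALSE)
  if (!is.null(strand)) df$strand <- strand
  df
}

make_stranded_track <- function(plus, minus, seqid = "chr") {
  L <- length(plus)
  data.frame(seqid = seqid, pos = rep(seq_len(L), 2L),
             depth = c(plus, minus), strand = rep(c("+", "-"), each = L),
             stringsAsFactors = FALSE)
}

make_genes <- function(starts, ends, strands, seqid = "chr") {
  data.frame(id = sprintf("g%02d", seq_along(starts)), seqid = seqid,
             start = starts, end = ends, strand = strands, kind = "gene",
             stringsAsFactors = FALSE)
}
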