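## Simulators for every input the pipeline consumes, each returning the
## generated data together with a ground-truth record. Same seed =>
## bit-identical output.

#' Simulate a circular genome with replication-associated GC skew
#'
#' Generates a random sequence whose leading strand (the ori -> ter arc in
#' the forward direction) carries an excess of G over C and the
#' complementary arc the mirrored excess, so the per-window skew
#' `(G - C) / (G + C)` switches sign at the origin and terminus, as on real
#' bacterial chromosomes. Third-codon-position structure is not emulated.
#'
#' @param length Genome length in bp.
#' @param ori,ter 1-based positions of the replication origin and terminus
#'   (`ori != ter`).
#' @param skew_strength Target per-window GC skew magnitude, in `[0, 1]`.
#'   Must not exceed `min(gc_content, 1 - gc_content)` for the base
#'   probabilities to stay feasible. `0` gives a driftless random walk with
#'   no reliable skew extrema.
#' @param gc_content Overall G+C fraction, in (0, 1).
#' @param seed Optional integer seed; the same seed reproduces the same
#'   sequence exactly.
#' @return List with `genome` (a [genome_record()]) and `truth`
#'   (list with `ori`, `ter`, `skew_strength`, `gc_content`).
#' @export
simulate_genome <- function(length, ori, ter, skew_strength = 0.3,
                            gc_content = 0.46, seed = NULL) {
  check_number(length, "length", lower = 2)
  check_number(ori, "ori", lower = 1, upper = length)
  check_number(ter, "ter", lower = 1, upper = length)
  if (ori == ter) stop("ori and ter must differ", call. = FALSE)
  check_number(skew_strength, "skew_strength", lower = 0, upper = 1)
  check_number(gc_content, "gc_content", lower = 0, upper = 1,
               strict_lower = TRUE)
  if (gc_content >= 1)
    stop("`gc_content` must be in (0, 1)", call. = FALSE)
  if (skew_strength > min(gc_content, 1 - gc_content))
    stop("infeasible skew/gc combination: skew_strength must be <= ",
         "min(gc_content, 1 - gc_content)", call. = FALSE)

  L <- as.integer(length)
  pos <- seq_len(L)
  on_leading <- if (ori < ter) pos >= ori & pos < ter else pos >= ori | pos < ter
  half_gc <- gc_content / 2
  p_lead <- c(A = (1 - gc_content) / 2, C = half_gc * (1 - skew_strength),
              G = half_gc * (1 + skew_strength), T = (1 - gc_content) / 2)
  p_lag <- p_lead[c("A", "G", "C", "T")]
  names(p_lag) <- c("A", "C", "G", "T")

  bases <- character(L)
  seq <- with_seed(seed, {
    n_lead <- sum(on_leading)
    bases[on_leading] <- sample(names(p_lead), n_lead, replace = TRUE,
                                prob = p_lead)
    bases[!on_leading] <- sample(names(p_lag), L - n_lead, replace = TRUE,
                                 prob = p_lag)
    paste0(bases, collapse = "")
  })
  list(genome = genome_record("sim_chr", seq, circular = TRUE),
       truth = list(ori = as.integer(ori), ter = as.integer(ter),
                    skew_strength = skew_strength, gc_content = gc_content))
}

#' Simulate metagenomic coverage under a replication gradient
#'
#' Expected depth is log2-linear along each replichore: at the origin it is
#' `log2(ptr)` (in log2 units) above the trough level, declining linearly
#' with position along the arc to the trough at the terminus, so that
#' `expected(ori) / expected(ter) == ptr` exactly. The trough level is
#' scaled so the genome-wide mean of the expectation equals `mean_depth`.
#' Noise is drawn per `bin_size`-bp chunk (keeping generation O(bins));
#' set `bin_size = 1` for per-base noise.
#'
#' @param genome_length Genome length in bp.
#' @param ori,ter Origin and terminus positions (1-based).
#' @param ptr True peak-to-trough ratio, `>= 1`.
#' @param mean_depth Genome-wide mean depth, `> 0`.
#' @param noise `"poisson"` (default), `"nbinom"`, or `"none"` for the
#'   noiseless expectation curve.
#' @param dispersion Negative-binomial size parameter (only for
#'   `noise = "nbinom"`).
#' @param bin_size Chunk size in bp at which noise is drawn (default 100).
#' @param seqid Sequence name for the emitted track.
#' @param seed Optional integer seed.
#' @return List with `track` (depth-track data frame over every position)
#'   and `truth` (list with `ptr`, `ori`, `ter`, `mean_depth`).
#' @export
simulate_replication_coverage <- function(genome_length, ori, ter, ptr,
                                          mean_depth = 50,
                                          noise = c("poisson", "nbinom", "none"),
                                          dispersion = NULL, bin_size = 100L,
                                          seqid = "sim_chr", seed = NULL) {
  noise <- match.arg(noise)
  check_number(genome_length, "genome_length", lower = 2)
  if (ptr < 1) stop("`ptr` must be >= 1", call. = FALSE)
  check_number(mean_depth, "mean_depth", lower = 0, strict_lower = TRUE)
  check_number(bin_size, "bin_size", lower = 1)
  L <- as.integer(genome_length)

  lambda <- expected_replication_depth(L, ori, ter, ptr, mean_depth)

  starts <- seq.int(1L, L, by = bin_size)
  ends <- pmin(starts + bin_size - 1L, L)
  lens <- ends - starts + 1L
  mids <- floor((starts + ends) / 2)
  lam_chunk <- lambda[mids] * lens

  depth_chunk <- with_seed(seed, switch(
    noise,
    poisson = stats::rpois(base::length(lam_chunk), lam_chunk) / lens,
    nbinom = {
      if (is.null(dispersion))
        stop("`dispersion` required for nbinom noise", call. = FALSE)
      stats::rnbinom(base::length(lam_chunk), mu = lam_chunk,
                     size = dispersion) / lens
    },
    none = lambda[mids]
  ))

  track <- data.frame(seqid = seqid, pos = seq_len(L),
                      depth = rep.int(depth_chunk, lens),
                      stringsAsFactors = FALSE)
  list(track = track,
       truth = list(ptr = ptr, ori = as.integer(ori), ter = as.integer(ter),
                    mean_depth = mean_depth))
}

#' Noiseless replication-gradient expectation curve
#'
#' @inheritParams simulate_replication_coverage
#' @return Numeric vector of expected depth at every position `1..genome_length`.
#' @export
expected_replication_depth <- function(genome_length, ori, ter, ptr,
                                       mean_depth = 50) {
  L <- as.integer(genome_length)
  a <- log2(ptr)
  pos <- seq_len(L)
  ## fractional progress along whichever replichore the position sits on
  arc_fwd <- (ter - ori) %% L          # ori -> ter going forward
  if (arc_fwd == 0L) stop("ori and ter must differ", call. = FALSE)
  arc_rev <- L - arc_fwd               # ori -> ter going backward
  off <- (pos - ori) %% L              # forward offset from ori
  frac <- ifelse(off <= arc_fwd, off / arc_fwd, (L - off) / arc_rev)
  shape <- 2^(a * (1 - frac))          # ptr at ori, 1 at ter
  trough <- if (a == 0) mean_depth else mean_depth * a * log(2) / (2^a - 1)
  trough * shape
}

#' Simulate a compact gene annotation
#'
#' Lays non-overlapping genes with random strands and intergenic gaps along
#' a sequence; used as input for the stranded RNA-seq simulator.
#'
#' @param genome_length Sequence length in bp.
#' @param n_genes Number of genes to place (fewer are returned if the
#'   sequence fills up).
#' @param gene_length_range Min/max gene length in bp.
#' @param gap_range Min/max intergenic gap in bp.
#' @param seqid Sequence name.
#' @param seed Optional integer seed.
#' @return Annotation data frame (`id`, `seqid`, `start`, `end`, `strand`,
#'   `kind`).
#' @export
simulate_annotation <- function(genome_length, n_genes,
                                gene_length_range = c(600L, 1500L),
                                gap_range = c(150L, 500L),
                                seqid = "sim_chr", seed = NULL) {
  check_number(n_genes, "n_genes", lower = 1)
  with_seed(seed, {
    starts <- integer(0); ends <- integer(0)
    cursor <- sample(gap_range[1]:gap_range[2], 1L)
    for (i in seq_len(n_genes)) {
      len <- sample(gene_length_range[1]:gene_length_range[2], 1L)
      if (cursor + len - 1L > genome_length) break
      starts <- c(starts, cursor)
      ends <- c(ends, cursor + len - 1L)
      cursor <- cursor + len + sample(gap_range[1]:gap_range[2], 1L)
    }
    n <- base::length(starts)
    data.frame(id = sprintf("gene_%04d", seq_len(n)), seqid = seqid,
               start = starts, end = ends,
               strand = sample(c("+", "-"), n, replace = TRUE),
               kind = "gene", stringsAsFactors = FALSE)
  })
}

#' Sample valid planted sRNA peaks for a given annotation
#'
#' Draws non-overlapping peak intervals consistent with their declared
#' region category: intergenic peaks inside annotation gaps, intragenic
#' peaks inside a gene on its coding strand, antisense peaks inside a gene
#' on the opposite strand.
#'
#' @param annotation Annotation data frame ([read_gff3()] layout).
#' @param genome_length Sequence length in bp.
#' @param n Number of peaks.
#' @param categories Categories to cycle through.
#' @param length_range Min/max peak length in nt.
#' @param fold Fold enrichment over the background depth (recycled).
#' @param stages Stage labels available.
#' @param stage_sets Optional list of stage subsets per peak; default all
#'   stages for every peak.
#' @param seed Optional integer seed.
#' @return Data frame of planted peaks (`start`, `end`, `strand`,
#'   `category`, `fold`, `stages` as a list column).
#' @export
sample_srna_peaks <- function(annotation, genome_length, n,
                              categories = c("intergenic", "intragenic",
                                             "antisense"),
                              length_range = c(100L, 500L), fold = 10,
                              stages = c("lag", "log", "stationary", "death"),
                              stage_sets = NULL, seed = NULL) {
  check_number(n, "n", lower = 1)
  fold <- rep_len(fold, n)
  cat_cycle <- rep_len(categories, n)
  ann <- annotation[order(annotation$start), , drop = FALSE]
  gaps <- annotation_gaps(ann, genome_length)
  with_seed(seed, {
    out <- vector("list", n)
    taken_start <- integer(0); taken_end <- integer(0)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (attempt in seq_len(200L)) {
        len <- sample(length_range[1]:length_range[2], 1L)
        cat_i <- cat_cycle[i]
        if (cat_i == "intergenic") {
          ok <- gaps[gaps$end - gaps$start + 1L >= len + 20L, , drop = FALSE]
          if (nrow(ok) == 0L) next
          g <- ok[sample.int(nrow(ok), 1L), ]
          s <- sample(g$start:(g$end - len + 1L), 1L)
          strand <- sample(c("+", "-"), 1L)
        } else {
          ok <- ann[ann$end - ann$start + 1L >= len + 40L, , drop = FALSE]
          if (nrow(ok) == 0L) next
          g <- ok[sample.int(nrow(ok), 1L), ]
          s <- sample((g$start + 20L):(g$end - len - 19L), 1L)
          strand <- if (cat_i == "intragenic") g$strand else
            setdiff(c("+", "-"), g$strand)
        }
        e <- s + len - 1L
        ## keep planted peaks well separated so truth intervals are unambiguous
        if (any(pmax(taken_start - 60L, 1L) <= e & taken_end + 60L >= s)) next
        out[[i]] <- data.frame(start = s, end = e, strand = strand,
                               category = cat_i, fold = fold[i],
                               stringsAsFactors = FALSE)
        taken_start <- c(taken_start, s); taken_end <- c(taken_end, e)
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place peak ", i,
             "; annotation too crowded for the requested peaks",
             call. = FALSE)
    }
    peaks <- do.call(rbind, out)
    peaks$stages <- if (is.null(stage_sets)) {
      replicate(n, stages, simplify = FALSE)
    } else {
      rep_len(stage_sets, n)
    }
    peaks
  })
}

annotation_gaps <- function(ann, genome_length) {
  ann <- ann[order(ann$start), , drop = FALSE]
  bounds <- c(0L, ann$end, genome_length + 1L)
  starts <- c(1L, ann$end + 1L)
  ends <- c(ann$start - 1L, genome_length)
  keep <- ends >= starts
  data.frame(start = starts[keep], end = ends[keep])
}

#' Simulate stranded RNA-seq coverage with planted sRNA peaks
#'
#' Background expression covers every annotated gene on its coding strand
#' at `background_depth`; each planted peak adds
#' `fold * background_depth` over its interval on its strand, only in the
#' growth stages listed in its `stages` entry. Poisson noise is applied
#' per position.
#'
#' @param annotation Annotation data frame.
#' @param genome_length Sequence length in bp.
#' @param peaks Planted-peak data frame as from [sample_srna_peaks()];
#'   may have zero rows. Declared categories are validated against the
#'   annotation.
#' @param background_depth Mean depth over gene bodies (default 5).
#' @param stages Stage labels to simulate.
#' @param noise `"poisson"` or `"none"`.
#' @param seqid Sequence name.
#' @param seed Optional integer seed.
#' @return List with `tracks` (named list, one stranded depth-track data
#'   frame per stage) and `truth` (the validated peak table).
#' @export
simulate_rnaseq_coverage <- function(annotation, genome_length, peaks,
                                     background_depth = 5,
                                     stages = c("lag", "log", "stationary",
                                                "death"),
                                     noise = c("poisson", "none"),
                                     seqid = "sim_chr", seed = NULL) {
  noise <- match.arg(noise)
  check_number(background_depth, "background_depth",
               lower = 0, strict_lower = TRUE)
  L <- as.integer(genome_length)
  if (nrow(peaks)) {
    if (any(peaks$start < 1L | peaks$end > L))
      stop("planted peak outside the genome", call. = FALSE)
    if (any(peaks$fold <= 1))
      stop("fold_over_background must be > 1", call. = FALSE)
    declared <- peaks$category
    actual <- vapply(seq_len(nrow(peaks)), function(i)
      classify_region(peaks$start[i], peaks$end[i], peaks$strand[i],
                      annotation), "")
    bad <- which(declared != actual)
    if (length(bad))
      stop("planted peak category mismatch with annotation at row(s) ",
           paste(bad, collapse = ", "), " (declared ",
           paste(declared[bad], collapse = ","), ", actual ",
           paste(actual[bad], collapse = ","), ")", call. = FALSE)
  }

  base_plus <- numeric(L); base_minus <- numeric(L)
  for (i in seq_len(nrow(annotation))) {
    idx <- annotation$start[i]:annotation$end[i]
    if (annotation$strand[i] == "+") base_plus[idx] <- background_depth
    else base_minus[idx] <- background_depth
  }

  tracks <- with_seed(seed, {
    lapply(stats::setNames(stages, stages), function(st) {
      lp <- base_plus; lm <- base_minus
      for (i in seq_len(nrow(peaks))) {
        if (!st %in% peaks$stages[[i]]) next
        idx <- peaks$start[i]:peaks$end[i]
        add <- peaks$fold[i] * background_depth
        if (peaks$strand[i] == "+") lp[idx] <- lp[idx] + add
        else lm[idx] <- lm[idx] + add
      }
      dp <- if (noise == "poisson") stats::rpois(L, lp) else lp
      dm <- if (noise == "poisson") stats::rpois(L, lm) else lm
      data.frame(seqid = seqid, pos = rep.int(seq_len(L), 2L),
                 depth = c(dp, dm),
                 strand = rep(c("+", "-"), each = L),
                 stringsAsFactors = FALSE)
    })
  })
  list(tracks = tracks, truth = peaks)
}

#' Simulate an expression matrix with planted co-expression modules
#'
#' Genes in module `m` follow the module's sample profile plus Gaussian
#' noise of standard deviation `noise_sd`; remaining genes are independent
#' standard-normal noise.
#'
#' @param n_genes Total number of genes (`>= sum(module_sizes)`).
#' @param n_samples Number of samples (`>= 2`).
#' @param module_sizes Integer vector of planted module sizes (may be
#'   empty, giving a pure-noise matrix).
#' @param module_effects Optional list of per-module sample profiles
#'   (each length `n_samples`); defaults to independent standardized
#'   Gaussian profiles.
#' @param noise_sd Within-module noise standard deviation, `>= 0`.
#' @param seed Optional integer seed.
#' @return List with `matrix` (genes x samples), `labels` (named integer
#'   vector; 0 = background), and `effects` (the module profiles used).
#' @export
simulate_expression_matrix <- function(n_genes, n_samples, module_sizes,
                                       module_effects = NULL, noise_sd = 0.5,
                                       seed = NULL) {
  check_number(n_genes, "n_genes", lower = 1)
  check_number(n_samples, "n_samples", lower = 2)
  check_number(noise_sd, "noise_sd", lower = 0)
  module_sizes <- as.integer(module_sizes)
  if (sum(module_sizes) > n_genes)
    stop("sum(module_sizes) must be <= n_genes", call. = FALSE)
  m <- length(module_sizes)
  with_seed(seed, {
    effects <- module_effects %||% lapply(seq_len(m), function(i) {
      p <- stats::rnorm(n_samples)
      as.numeric(scale(p))
    })
    if (m > 0 && length(effects) != m)
      stop("module_effects must have one profile per module", call. = FALSE)
    labels <- rep.int(0L, n_genes)
    mat <- matrix(stats::rnorm(n_genes * n_samples), n_genes, n_samples)
    row <- 1L
    for (i in seq_len(m)) {
      rows <- row:(row + module_sizes[i] - 1L)
      mat[rows, ] <- matrix(rep(effects[[i]], each = length(rows)),
                            nrow = length(rows)) +
        stats::rnorm(length(rows) * n_samples, sd = noise_sd)
      labels[rows] <- i
      row <- row + module_sizes[i]
    }
    rownames(mat) <- sprintf("gene_%05d", seq_len(n_genes))
    colnames(mat) <- sprintf("sample_%02d", seq_len(n_samples))
    names(labels) <- rownames(mat)
    list(matrix = mat, labels = labels, effects = effects)
  })
}
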