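test_that("region classification follows the strand rules", {
  ann <- make_genes(c(1000, 5000), c(2000, 6000), c("+", "-"))
  expect_equal(classify_region(1200, 1400, "+", ann), "intragenic")
  expect_equal(classify_region(1200, 1400, "-", ann), "antisense")
  expect_equal(classify_region(3000, 3300, "+", ann), "intergenic")
  expect_equal(classify_region(5100, 5300, "-", ann), "intragenic")
  expect_equal(classify_region(5100, 5300, "+", ann), "antisense")
  # same-strand overlap dominates when genes on both strands are touched
  ann2 <- make_genes(c(100, 150), c(300, 400), c("+", "-"))
  expect_equal(classify_region(140, 320, "+", ann2), "intragenic")
})

test_that("a planted intergenic plateau yields exactly one clean candidate", {
  L <- 10000
  plus <- rep(5, L)
  ann <- make_genes(c(1, 8000), c(3000, 10000), c("+", "+"))
  plus[1:3000] <- 5; plus[8000:10000] <- 5
  plus[4000:4299] <- 50                       # 300-nt plateau, fold 10
  track <- make_stranded_track(plus, rep(0, L))
  calls <- detect_peaks(track, ann, L,
                        peak_call_config(min_fold = 5))
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$start, 4000L)
  expect_equal(calls$end, 4299L)
  expect_equal(calls$category, "intergenic")
  expect_equal(calls$strand, "+")
})

test_that("peak caller applies length bounds and depth floors", {
  L <- 5000
  plus <- rep(0, L)
  plus[1000:1029] <- 50                       # 30 nt < min_len
  track <- make_stranded_track(plus, rep(0, L))
  ann <- make_genes(1, 100, "+")
  expect_equal(nrow(detect_peaks(track, ann, L)), 0L)

  # zero coverage everywhere -> empty list
  empty <- detect_peaks(make_stranded_track(rep(0, L), rep(0, L)), ann, L)
  expect_equal(nrow(empty), 0L)

  # unstranded track is a contract error
  expect_error(detect_peaks(make_track(rep(0, L)), ann, L),
               "strand")
})

test_that("intragenic peaks must rise above their own gene body", {
  L <- 8000
  ann <- make_genes(1000, 4000, "+")
  plus <- rep(0, L); plus[1000:4000] <- 20    # well-expressed gene
  track <- make_stranded_track(plus, rep(0, L))
  # the gene body alone is not a peak
  expect_equal(nrow(detect_peaks(track, ann, L)), 0L)
  # a 300-nt burst at 10x the gene body is
  plus2 <- plus; plus2[2000:2299] <- 200
  calls <- detect_peaks(make_stranded_track(plus2, rep(0, L)), ann, L)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$category, "intragenic")
  expect_lte(calls$start, 2010L); expect_gte(calls$end, 2290L)
})

test_that("antisense peaks are called on the opposite strand of a gene", {
  L <- 6000
  ann <- make_genes(2000, 4000, "+")
  minus <- rep(0, L); minus[2500:2799] <- 40
  calls <- detect_peaks(make_stranded_track(rep(0, L), minus), ann, L)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$category, "antisense")
  expect_equal(calls$strand, "-")
})

test_that("cross-stage merging matches brute-force set enumeration", {
  cand <- function(start, end, strand = "+")
    data.frame(seqid = "chr", start = start, end = end, strand = strand,
               category = "intergenic", mean_depth = 50,
               stringsAsFactors = FALSE)
  s1 <- cand(100, 300)                        # in all four stages
  stage_lists <- list(
    A = rbind(s1, cand(1000, 1200)),          # s2 unique to A
    B = s1,
    C = rbind(s1, cand(5000, 5400)),          # s3 unique to C
    D = s1)
  merged <- merge_stages(stage_lists)
  oracle <- oracle_merge_counts(stage_lists)
  counts <- stage_overlap_counts(merged, stages = names(stage_lists))
  expect_equal(counts$n_total, oracle$total)          # 3
  expect_equal(counts$n_all_stages, oracle$all_four)  # 1
  expect_equal(counts$n_at_least_2, oracle$at_least_2)# 1
  expect_equal(counts$n_total, 3L)
  expect_equal(counts$by_combination[["A&B&C&D"]], 1L)
  expect_equal(sum(counts$by_combination), counts$n_total)

  # identical interval in all four stages collapses to one candidate
  all4 <- merge_stages(list(A = s1, B = s1, C = s1, D = s1))
  expect_equal(nrow(all4), 1L)
  expect_equal(all4$n_stages, 4L)

  # disjoint intervals stay separate with support 1
  dis <- merge_stages(list(A = cand(1, 100), B = cand(500, 600)))
  expect_equal(dis$n_stages, c(1L, 1L))

  # stage-order invariance
  perm <- merge_stages(stage_lists[c("D", "B", "A", "C")])
  expect_equal(perm[, c("start", "end", "strand", "stage_support")],
               merged[, c("start", "end", "strand", "stage_support")])

  # empty input
  none <- merge_stages(list(A = cand(1, 10)[0, ]))
  expect_equal(nrow(none), 0L)
  expect_equal(stage_overlap_counts(none, stages = "A")$n_total, 0L)
})

test_that("reciprocal-50 merging is stricter than any-overlap", {
  a <- data.frame(seqid = "chr", start = 1L, end = 1000L, strand = "+",
                  category = "intergenic", mean_depth = 10)
  b <- data.frame(seqid = "chr", start = 950L, end = 2000L, strand = "+",
                  category = "intergenic", mean_depth = 10)
  loose <- merge_stages(list(A = a, B = b), merge_rule = "any_overlap")
  strict <- merge_stages(list(A = a, B = b), merge_rule = "reciprocal_50")
  expect_equal(nrow(loose), 1L)
  expect_equal(nrow(strict), 2L)
})

test_that("candidate categories match classify_region on final coordinates", {
  ann <- simulate_annotation(40000, 25, seed = 31)
  peaks <- sample_srna_peaks(ann, 40000, 9, fold = 12, seed = 31)
  sim <- simulate_rnaseq_coverage(ann, 40000, peaks, seed = 31)
  calls <- lapply(sim$tracks, detect_peaks, annotation = ann,
                  genome_length = 40000)
  merged <- merge_stages(calls, annotation = ann)
  for (i in seq_len(nrow(merged)))
    expect_equal(merged$category[i],
                 classify_region(merged$start[i], merged$end[i],
                                 merged$strand[i], ann))
})

test_that("sRNA expression reproduces the RPKM identities", {
  cand <- data.frame(id = "s1", seqid = "chr", start = 1001L, end = 2000L,
                     strand = "+", stringsAsFactors = FALSE)
  aln <- data.frame(seqid = "chr",
                    start = c(seq(1100, 1900, length.out = 10), 5000),
                    strand = "+")
  mats <- srna_expression(cand, list(lib = aln), library_sizes = c(lib = 1e6))
  expect_equal(unname(mats["s1", "lib"]), 10)
  # doubling library size halves RPKM
  half <- srna_expression(cand, list(lib = aln),
                          library_sizes = c(lib = 2e6))
  expect_equal(unname(half["s1", "lib"]), 5)
  # zero reads -> 0
  none <- srna_expression(cand, list(lib = aln[aln$start > 4000, ]),
                          library_sizes = c(lib = 1e6))
  expect_equal(unname(none["s1", "lib"]), 0)
})

test_that("BED6 export is 0-based half-open", {
  cand <- data.frame(id = "s1", seqid = "chr", start = 11L, end = 60L,
                     strand = "-", n_stages = 3L)
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed6(cand, path)
  bed <- utils::read.table(path, sep = "\t")
  expect_equal(bed$V2, 10L)
  expect_equal(bed$V3, 60L)
  expect_equal(bed$V6, "-")
})
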