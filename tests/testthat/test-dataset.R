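# Window extraction, BCA filtering, redundancy removal, sampling, splits.

test_that("extract_window slices, strand-flips and validates", {
  ref <- c(chrT = paste(rep(c("A", "C", "G", "T"), 30), collapse = ""))
  # exact-fit: site at 0-based position 20 of a 41-nt reference
  ref41 <- c(mini = paste0(strrep("C", 20), "A", strrep("G", 20)))
  rec <- extract_window(ref41, list(chromosome = "mini", position = 20,
                                    strand = "+", label = "positive"), 20)
  expect_identical(rec$window, normalize_sequence(ref41[["mini"]]))
  expect_identical(rec$label, 1L)
  expect_match(rec$record_id, "^mini:20:\\+:1$")

  expect_error(extract_window(ref41, list(chromosome = "mini", position = 5,
                                          strand = "+"), 20),
               "out of bounds")
  expect_error(extract_window(ref41, list(chromosome = "nope", position = 20,
                                          strand = "+"), 20),
               "not in reference")
  # center must be A after strand handling
  expect_error(extract_window(ref41, list(chromosome = "mini", position = 19,
                                          strand = "+"), 5), "not A")

  # minus strand: window equals reverse complement of the forward slice,
  # cross-checked against the Biostrings oracle on random references
  m6amnet:::with_seed(42, {
    for (rep_i in 1:5) {
      fwd <- paste(sample(c("A", "C", "G", "T"), 61, TRUE), collapse = "")
      pos <- 30L
      substr(fwd, pos + 1L, pos + 1L) <- "T"  # minus-strand A
      refr <- c(chr = fwd)
      rec <- extract_window(refr, list(chromosome = "chr", position = pos,
                                       strand = "-"), 10)
      oracle <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(substr(fwd, pos + 1L - 10L, pos + 1L + 10L))))
      expect_identical(rec$window, chartr("T", "U", oracle))
    }
  })
})

test_that("has_bca_center implements B in {C,G,U} upstream of CA", {
  mk <- function(ctx) paste0(strrep("G", 18), ctx, strrep("G", 20))
  expect_true(has_bca_center(mk("GCA")))
  expect_false(has_bca_center(mk("ACA")))  # B = A not allowed
  expect_false(has_bca_center(mk("GGA")))  # -1 must be C
  # oracle over all 16 two-letter upstream contexts
  for (b2 in c("A", "C", "G", "U")) {
    for (b1 in c("A", "C", "G", "U")) {
      expect_identical(has_bca_center(mk(paste0(b2, b1, "A"))),
                       b1 == "C" && b2 != "A")
    }
  }
  # vectorized over a record data.frame
  ds <- small_synthetic(30, seed = 8)
  expect_true(all(has_bca_center(ds$records)))
  expect_error(has_bca_center("ACA"), "odd length")
})

test_that("redundancy_filter clusters greedily at the identity threshold", {
  w <- random_windows(1, 41, seed = 10)
  expect_identical(redundancy_filter(c(w, w)), w)  # identical -> one kept

  # 9 of 41 mismatches: identity 32/41 ~ 0.78 < 0.8 -> both retained
  w2 <- w
  for (i in 1:9) {
    old <- substr(w2, i, i)
    substr(w2, i, i) <- setdiff(c("A", "C", "G", "U"), old)[1]
  }
  expect_equal(sum(m6amnet:::seqs_to_int_matrix(c(w, w2))[1, ] ==
                   m6amnet:::seqs_to_int_matrix(c(w, w2))[2, ]), 32)
  expect_length(redundancy_filter(c(w, w2), 0.8), 2)
  # one fewer mismatch crosses the threshold (33/41 > 0.8)
  w3 <- w2
  substr(w3, 9, 9) <- substr(w, 9, 9)
  expect_length(redundancy_filter(c(w, w3), 0.8), 1)

  # random windows are pairwise dissimilar -> all retained
  wins <- random_windows(40, 41, seed = 11)
  expect_length(redundancy_filter(wins, 0.8), 40)

  # property: no retained pair reaches the threshold (brute force)
  pool <- c(wins, vapply(sample(wins, 60, replace = TRUE), function(s) {
    i <- sample(41, 3)
    for (j in i) substr(s, j, j) <- sample(c("A", "C", "G", "U"), 1)
    s
  }, character(1), USE.NAMES = FALSE))
  kept <- redundancy_filter(pool, 0.85)
  M <- m6amnet:::seqs_to_int_matrix(kept)
  for (i in seq_len(nrow(M) - 1)) {
    ident <- rowMeans(M[-seq_len(i), , drop = FALSE] ==
                      matrix(M[i, ], nrow(M) - i, 41, byrow = TRUE))
    expect_true(all(ident < 0.85))
  }
  # first-seen representative is retained
  expect_identical(kept[1], pool[1])
})

test_that("cd-hit-est backend validates inputs and reports a missing binary", {
  wins <- random_windows(3, 41, seed = 12)
  expect_error(redundancy_filter(wins, 0.7, backend = "cd-hit-est"),
               "0.8")
  if (Sys.which("cd-hit-est") == "") {
    expect_error(redundancy_filter(wins, 0.8, backend = "cd-hit-est"),
                 "internal")
  } else {
    expect_length(redundancy_filter(c(wins, wins[1]), 0.9,
                                    backend = "cd-hit-est"), 3)
  }
})

test_that("sample_negatives is uniform, seeded and bounded", {
  ds <- small_synthetic(50, seed = 13)
  neg <- ds$records[ds$records$label == 0L, ]
  s1 <- sample_negatives(neg, 20, seed = 5)
  s2 <- sample_negatives(neg, 20, seed = 5)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 20)
  s3 <- sample_negatives(neg, 20, seed = 6)
  expect_false(identical(s1$record_id, s3$record_id))
  expect_equal(nrow(sample_negatives(neg, 0, seed = 1)), 0)
  expect_error(sample_negatives(neg, nrow(neg) + 1, seed = 1),
               "candidates available")
})

test_that("train_test_split is a stratified disjoint cover", {
  ds <- small_synthetic(500, seed = 14)  # 1000 records, balanced
  plan <- train_test_split(ds, 0.8, seed = 2)
  parts <- split_dataset(ds, plan)
  expect_equal(nrow(parts$train$records), 800)
  expect_equal(nrow(parts$test$records), 200)
  expect_equal(as.vector(table(parts$train$records$label)), c(400, 400))
  expect_equal(as.vector(table(parts$test$records$label)), c(100, 100))
  expect_length(intersect(parts$train$records$record_id,
                          parts$test$records$record_id), 0)
  expect_setequal(c(parts$train$records$record_id,
                    parts$test$records$record_id), ds$records$record_id)
  # determinism
  expect_identical(train_test_split(ds, 0.8, seed = 2)$assignment,
                   plan$assignment)

  # two records, one per class, fraction 0.5 -> 1 train / 1 test
  ds2 <- m6amnet:::new_m6am_dataset(ds$records[c(1, 600), ], ds$flank)
  p2 <- train_test_split(ds2, 0.5, seed = 1)
  expect_equal(sort(as.vector(table(p2$assignment$partition))), c(1, 1))

  expect_error(train_test_split(ds, 1.2, seed = 1), "in \\(0, 1\\)")
  ds1 <- m6amnet:::new_m6am_dataset(
    ds$records[ds$records$label == 1L, ], ds$flank)
  expect_error(train_test_split(ds1, 0.8, seed = 1), "both classes")
})

test_that("chromosome hold-out groups follow the min-count rule", {
  counts <- data.frame(chromosome = c("chr1", "chr2", "chr3", "chr4"),
                       positive = c(50, 30, 15, 5),
                       negative = c(50, 30, 15, 5))
  ds <- counts_dataset(counts)
  plans <- chromosome_holdout_groups(ds, min_count = 50,
                                     count_mode = "total")
  # totals: 100, 60, 30, 10 -> chr1, chr2 separate; chr3+chr4 pooled
  expect_length(plans, 3)
  test_chroms <- lapply(plans, function(p) {
    ids <- p$assignment$record_id[p$assignment$partition == "test"]
    unique(ds$records$chromosome[match(ids, ds$records$record_id)])
  })
  expect_identical(test_chroms[[1]], "chr1")
  expect_identical(test_chroms[[2]], "chr2")
  expect_setequal(test_chroms[[3]], c("chr3", "chr4"))
  # a chromosome never appears on both sides of a plan
  for (p in plans) {
    ch <- split(ds$records$chromosome[match(p$assignment$record_id,
                                            ds$records$record_id)],
                p$assignment$partition)
    expect_length(intersect(ch$train, ch$test), 0)
    expect_equal(sort(p$assignment$record_id), sort(ds$records$record_id))
  }
  # all chromosomes large -> no pooled group
  plans2 <- chromosome_holdout_groups(ds, min_count = 10,
                                      count_mode = "total")
  expect_length(plans2, 4)

  # benchmark-shaped counts, per-class mode: the five small chromosomes
  # (13, 18, 20, 21, 22) pool into one final group
  dsb <- counts_dataset(benchmark_chrom_counts())
  plansb <- chromosome_holdout_groups(dsb, min_count = 50,
                                      count_mode = "per_class")
  expect_length(plansb, 19)  # 18 singles + 1 pooled
  pooled <- plansb[[19]]
  pooled_chroms <- unique(dsb$records$chromosome[
    match(pooled$assignment$record_id[pooled$assignment$partition == "test"],
          dsb$records$record_id)])
  expect_setequal(pooled_chroms, c("chr13", "chr18", "chr20", "chr21",
                                   "chr22"))
})

test_that("build_benchmark_dataset runs the full pipeline deterministically", {
  # synthetic genome: plant BCA sites at known positions
  m6amnet:::with_seed(77, {
    chr <- paste(sample(c("A", "C", "G", "T"), 4000, TRUE), collapse = "")
  })
  pos_sites <- seq(100, 1900, by = 120)
  neg_sites <- seq(2000, 3900, by = 90)
  for (p in c(pos_sites, neg_sites)) {
    substr(chr, p - 1, p + 1) <- "GCA"  # 1-based context ending at center
  }
  ref <- c(chr1 = chr)
  sites <- data.frame(
    chromosome = "chr1", position = c(pos_sites, neg_sites),  # 0-based
    strand = "+",
    label = rep(c("positive", "candidate"),
                c(length(pos_sites), length(neg_sites))))
  ds <- build_benchmark_dataset(ref, sites, flank = 20, seed = 3,
                                verbose = FALSE)
  expect_s3_class(ds, "m6am_dataset")
  expect_equal(sum(ds$records$label == 1L), sum(ds$records$label == 0L))
  expect_true(all(has_bca_center(ds$records)))
  expect_true(all(nchar(ds$records$window) == 41))
  ds2 <- build_benchmark_dataset(ref, sites, flank = 20, seed = 3,
                                 verbose = FALSE)
  expect_identical(ds$records, ds2$records)
})

test_that("dataset FASTA+TSV round-trips", {
  ds <- small_synthetic(20, seed = 15)
  prefix <- file.path(withr::local_tempdir(), "bench")
  write_benchmark_dataset(ds, prefix)
  back <- read_benchmark_dataset(prefix)
  ord <- match(ds$records$record_id, back$records$record_id)
  expect_identical(back$records$window[ord], ds$records$window)
  expect_identical(back$records$label[ord], ds$records$label)
  expect_equal(back$flank, ds$flank)
})

test_that("site lists parse from TSV and BED6", {
  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "sites.tsv")
  write.table(data.frame(chromosome = "chr1", position = 10, strand = "+",
                         label = "positive"),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  s <- read_sites(tsv)
  expect_identical(s$label, "positive")
  bed <- file.path(dir, "sites.bed")
  writeLines("chr2\t99\t100\tnegative\t0\t-", bed)
  b <- read_sites(bed)
  expect_identical(b$chromosome, "chr2")
  expect_equal(b$position, 99)
  expect_identical(b$strand, "-")
  expect_identical(b$label, "negative")
  expect_error(read_sites(file.path(dir, "missing.tsv")), "not found")
})
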