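sim_pool <- function(n_samples = 3, depth = 6, seed = 13, genome_len = 120000,
                     error_rate = 0, read_through = FALSE) {
  g <- synth_genome(1, genome_len, 0.5, 0, seed = seed)
  set <- generate_barcode_set(20, c(4, 8), seed = 2)
  sheet <- build_sample_sheet(paste0("s", seq_len(n_samples)), set, 1)
  ad <- build_adapters(set$barcode[1])
  cfg <- sim_config(mean_depth = depth, error_rate = error_rate,
                    window = size_window(400, 700), seed = seed + 1,
                    read_through = read_through)
  list(lib = simulate_library(g, sheet, ad, cfg), sheet = sheet, set = set,
       adapters = ad)
}

test_that("error-free pools demultiplex perfectly and conserve reads", {
  p <- sim_pool()
  dm <- demultiplex(p$lib$r1, p$lib$r2, p$sheet, tol = 1)
  expect_equal(dm$n_assigned, dm$n_input)
  expect_equal(dm$n_input, nrow(p$lib$r1))
  # every read lands with its true sample
  truth <- p$lib$r1$sample_id
  expect_equal(dm$assignments$sample_id, truth)
  # conservation: assigned + unassigned = input
  expect_equal(sum(dm$stats$n_reads), dm$n_input)
  # barcode trimmed: R1 now starts with the AvaII remnant
  expect_equal(remnant_check(dm$assignments$r1_seq, "AvaII", "R1"), 1.0)
  expect_equal(remnant_check(dm$assignments$r2_seq, "MspI", "R2"), 1.0)
})

test_that("single barcode substitutions are rescued at tol 1, ties rejected", {
  p <- sim_pool(n_samples = 2, depth = 2)
  r1 <- p$lib$r1
  bc <- p$sheet$barcode[p$sheet$sample_id == r1$sample_id[1]]
  # corrupt one barcode base of the first read
  s <- r1$seq[1]
  pos <- 2
  old_base <- substr(s, pos, pos)
  new_base <- setdiff(c("A", "C", "G", "T"), old_base)[1]
  substr(s, pos, pos) <- new_base
  r1$seq[1] <- s
  dm0 <- demultiplex(r1[1, ], p$lib$r2[1, ], p$sheet, tol = 0)
  dm1 <- demultiplex(r1[1, ], p$lib$r2[1, ], p$sheet, tol = 1)
  expect_true(is.na(dm0$assignments$sample_id[1]))
  expect_equal(dm1$assignments$sample_id[1], r1$sample_id[1])

  # a read equidistant from two barcodes is unassigned
  sheet <- tibble::tibble(sample_id = c("a", "b"),
                          barcode = c("AAAAT", "AAAAC"), pool_index = 1L)
  read <- tibble::tibble(id = "x", seq = paste0("AAAAG", "GACC", strrep("T", 60)),
                         qual = strrep("F", 69))
  dm <- demultiplex(read, NULL, sheet, tol = 1)
  expect_true(is.na(dm$assignments$sample_id[1]))
})

test_that("raising the mismatch tolerance never loses assignments", {
  p <- sim_pool(depth = 4, error_rate = 0.01)
  n_assigned <- vapply(0:2, function(tol) {
    demultiplex(p$lib$r1, p$lib$r2, p$sheet, tol = tol)$n_assigned
  }, numeric(1))
  expect_true(all(diff(n_assigned) >= 0))
})

test_that("remnant_check counts matching windows exactly", {
  reads <- c("GACCTTTT", "GTCCAAAA", "TTTTTTTT")
  expect_equal(remnant_check(reads, "AvaII", "R1"), 2 / 3)
  expect_equal(remnant_check(character(0), "AvaII", "R1"), NA_real_)
  scrambled <- c("AAAATTTT", "CCCCAAAA")
  expect_equal(remnant_check(scrambled, "AvaII", "R1"), 0)
  expect_equal(remnant_check(rep("CGGAT", 95), "MspI", "R2"), 1)
  expect_equal(remnant_check(c(rep("CGGAT", 95), rep("TTTTT", 5)), "MspI", "R2"),
               0.95)
})

test_that("adapter_fraction flags read-through by 3' overlap", {
  adapter <- "GTGACTGGAGTTCAGACGTG"
  clean <- vapply(1:30, function(i) random_dna(80), character(1))
  set.seed(2)
  with_adapter <- paste0(substr(clean, 1, 50), substr(adapter, 1, 30))
  expect_equal(adapter_fraction(with_adapter, adapter, min_overlap = 10), 1)
  expect_lte(adapter_fraction(clean, adapter, min_overlap = 10), 0.05)
  mix <- c(with_adapter[1:20], clean[1:30])
  expect_equal(adapter_fraction(mix, adapter, min_overlap = 10), 0.4)
  expect_error(adapter_fraction(clean, adapter, min_overlap = 3), ">= 5")

  # round trip: simulated read-through pools are flagged, long inserts not
  g <- synth_genome(1, 200000, 0.5, 0, seed = 4)
  set <- generate_barcode_set(20, c(4, 8), seed = 2)
  sheet <- build_sample_sheet("s1", set, 1)
  ad <- build_adapters(set$barcode[1])
  short_cfg <- sim_config(mean_depth = 3, window = size_window(60, 120),
                          seed = 5, read_through = TRUE)
  long_cfg <- sim_config(mean_depth = 3, window = size_window(400, 700),
                         seed = 5, read_through = TRUE)
  rc_p2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(ad$p2_top)))
  short_lib <- simulate_library(g, sheet, ad, short_cfg)
  long_lib <- simulate_library(g, sheet, ad, long_cfg)
  expect_equal(adapter_fraction(short_lib$r1$seq, rc_p2), 1)
  expect_equal(adapter_fraction(long_lib$r1$seq, rc_p2), 0)
})

test_that("quality_filter discards reads with any low-quality window", {
  q40 <- strrep(rawToChar(as.raw(40 + 33)), 60)
  q2 <- strrep(rawToChar(as.raw(2 + 33)), 60)
  # 15-base Q9 patch amid Q40: window mean 9 < 10 -> discarded
  q9 <- rawToChar(as.raw(9 + 33))
  patched <- paste0(strrep(rawToChar(as.raw(40 + 33)), 20), strrep(q9, 15),
                    strrep(rawToChar(as.raw(40 + 33)), 25))
  reads <- tibble::tibble(
    seq = vapply(1:3, function(i) random_dna(60), character(1)),
    qual = c(q40, q2, patched)
  )
  kept <- quality_filter(reads)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$qual, q40)
  expect_equal(attr(kept, "n_discarded"), 2)

  # a 14-base Q9 patch dilutes below threshold in every 15-window: kept
  patched14 <- paste0(strrep(rawToChar(as.raw(40 + 33)), 20), strrep(q9, 14),
                      strrep(rawToChar(as.raw(40 + 33)), 26))
  reads14 <- tibble::tibble(seq = random_dna(60), qual = patched14)
  expect_equal(nrow(quality_filter(reads14)), 1)
})

test_that("pool balance CV matches hand computation and is scale invariant", {
  expect_equal(pool_balance(c(10, 10, 10, 10))$cv, 0)
  expect_equal(pool_balance(c(2, 4))$cv, 0.4714)  # sd = sqrt(2), mean = 3
  set.seed(6)
  x <- rpois(10, 1000)
  expect_equal(pool_balance(x)$cv, pool_balance(17 * x)$cv)
  expect_error(pool_balance(5), "at least 2")
})

test_that("gc_fraction counts unambiguous bases", {
  expect_equal(gc_fraction("GCGC"), 1)
  expect_equal(gc_fraction("ATAT"), 0)
  expect_equal(gc_fraction("ACGT"), 0.5)
  expect_equal(gc_fraction(c("AC", "GT")), 0.5)
  expect_equal(gc_fraction("ACGN"), 2 / 3)
})

test_that("qc_report summarises a simulated pool per sample", {
  p <- sim_pool(n_samples = 2, depth = 4)
  dm <- demultiplex(p$lib$r1, p$lib$r2, p$sheet, tol = 1)
  rc_p2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(p$adapters$p2_top)))
  qc <- qc_report(dm, adapter_r1 = rc_p2)
  expect_equal(nrow(qc), 2)
  expect_equal(qc$remnant_r1, c(1, 1))
  expect_equal(qc$remnant_r2, c(1, 1))
  expect_equal(qc$adapter_r1, c(0, 0))
  expect_equal(qc$n_quality_discarded, c(0, 0))
  expect_true(all(qc$gc > 0.3 & qc$gc < 0.7))
  expect_equal(sum(qc$n_reads), nrow(p$lib$r1))
})

test_that("demultiplexed reads write to per-sample FASTQ files", {
  p <- sim_pool(n_samples = 2, depth = 2)
  dm <- demultiplex(p$lib$r1, p$lib$r2, p$sheet, tol = 1)
  dir <- withr::local_tempdir()
  write_demultiplexed(dm, dir)
  f <- file.path(dir, "s1_R1.fastq.gz")
  expect_true(file.exists(f))
  reads <- read_fastq(f)
  expect_equal(nrow(reads), sum(dm$assignments$sample_id == "s1", na.rm = TRUE))
  expect_true(all(startsWith(reads$seq, "G")))  # barcode trimmed, remnant leads
})
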