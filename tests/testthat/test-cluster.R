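mutate_at_pos <- function(seq, pos, base) {
  substr(seq, pos, pos) <- base
  seq
}

test_that("truncate_reads yields exact-length prefixes and counts drops", {
  set.seed(1)
  reads <- c(random_dna(150), random_dna(140), random_dna(100))
  out <- truncate_reads(reads, 140)
  expect_equal(nchar(out), c(140, 140))
  expect_equal(out[1], substr(reads[1], 1, 140))
  expect_equal(out[2], reads[2])
  expect_equal(attr(out, "n_dropped"), 1)
})

test_that("build_stacks merges stacks by the m/M rules", {
  set.seed(2)
  x <- random_dna(140)
  p <- cluster_params(m = 10, M = 3)

  # 12 identical reads -> one tag, depth 12, no variant columns
  t1 <- build_stacks(rep(x, 12), p)
  expect_equal(nrow(t1), 1)
  expect_equal(t1$depth, 12)
  expect_equal(t1$consensus, x)
  expect_length(t1$variant_cols[[1]], 0)

  # 9 identical reads: below m, no neighbours -> no tag, reads accounted
  t2 <- build_stacks(rep(x, 9), p)
  expect_equal(nrow(t2), 0)
  expect_equal(attr(t2, "n_unmerged"), 9)

  # 12 X + 11 X-with-one-substitution -> one tag, depth 23, 1 variant column
  y <- mutate_at_pos(x, 70, setdiff(c("A", "C", "G", "T"),
                                    substr(x, 70, 70))[1])
  t3 <- build_stacks(c(rep(x, 12), rep(y, 11)), p)
  expect_equal(nrow(t3), 1)
  expect_equal(t3$depth, 23)
  expect_equal(t3$variant_cols[[1]], 70)
  expect_equal(sort(t3$alleles[[1]]$depth), c(11, 12))
  # consensus takes the deeper allele's base
  expect_equal(substr(t3$consensus, 70, 70), substr(x, 70, 70))

  # two stacks farther apart than M stay separate tags
  z <- x
  for (pos in c(10, 40, 80, 120)) {
    z <- mutate_at_pos(z, pos, setdiff(c("A", "C", "G", "T"),
                                       substr(z, pos, pos))[1])
  }
  t4 <- build_stacks(c(rep(x, 12), rep(z, 12)), p)
  expect_equal(nrow(t4), 2)
})

test_that("read conservation holds through stacking", {
  set.seed(3)
  base <- random_dna(140)
  variants <- vapply(1:5, function(i) {
    mutate_at_pos(base, i * 10, "A")
  }, character(1))
  reads <- c(rep(base, 15), rep(variants[1], 3), rep(variants[2], 12),
             rep(random_dna(140), 4))
  tags <- build_stacks(reads, cluster_params(m = 10, M = 3))
  total <- sum(tags$depth) + attr(tags, "n_unmerged") + attr(tags, "n_repetitive")
  expect_equal(total, length(reads))
})

test_that("abnormally deep stacks are excluded as repetitive", {
  set.seed(4)
  normal <- vapply(1:12, function(i) random_dna(140), character(1))
  deep <- random_dna(140)
  reads <- c(rep(normal, each = 20), rep(deep, 2000))
  tags <- build_stacks(reads, cluster_params(m = 10, M = 3))
  expect_false(deep %in% tags$consensus)
  expect_equal(attr(tags, "n_repetitive"), 2000)
  expect_equal(nrow(tags), 12)
})

test_that("catalog merging follows the n threshold", {
  set.seed(5)
  x <- random_dna(140)
  p <- cluster_params(m = 2, M = 3, n = 5)
  tag_of <- function(seq, sample) build_stacks(rep(seq, 5), p, sample = sample)

  # identical consensuses -> one locus
  tags_same <- dplyr::bind_rows(tag_of(x, "a"), tag_of(x, "b"))
  expect_equal(nrow(build_catalog(tags_same, p)), 1)

  # 1 mismatch -> one locus with 1 variant column
  y <- mutate_at_pos(x, 33, setdiff(c("A", "C", "G", "T"),
                                    substr(x, 33, 33))[1])
  tags_1 <- dplyr::bind_rows(tag_of(x, "a"), tag_of(y, "b"))
  cat1 <- build_catalog(tags_1, p)
  expect_equal(nrow(cat1), 1)
  expect_equal(cat1$variant_columns[[1]], 33)

  # 6 mismatches with n = 5 -> two loci
  z <- x
  for (pos in c(5, 25, 45, 65, 85, 105)) {
    z <- mutate_at_pos(z, pos, setdiff(c("A", "C", "G", "T"),
                                       substr(z, pos, pos))[1])
  }
  tags_6 <- dplyr::bind_rows(tag_of(x, "a"), tag_of(z, "b"))
  expect_equal(nrow(build_catalog(tags_6, p)), 2)
})

test_that("genotyping calls bases at variant columns with missing as N", {
  set.seed(6)
  x <- random_dna(140)
  p <- cluster_params(m = 2, M = 3, n = 5)
  y <- mutate_at_pos(x, 50, setdiff(c("A", "C", "G", "T"),
                                    substr(x, 50, 50))[1])
  w <- random_dna(140)  # a locus only sample a has
  tags <- dplyr::bind_rows(
    build_stacks(c(rep(x, 5), rep(w, 5)), p, sample = "a"),
    build_stacks(rep(y, 5), p, sample = "b"),
    build_stacks(rep(x, 5), p, sample = "c")
  )
  catalog <- build_catalog(tags, p)
  snps <- match_and_genotype(tags, catalog, p)
  sites <- attr(snps, "sites")
  expect_equal(nrow(sites), 1)
  col <- sites$site[1]
  expect_equal(snps[[col]][snps$sample == "a"], substr(x, 50, 50))
  expect_equal(snps[[col]][snps$sample == "b"], substr(y, 50, 50))
  expect_equal(snps[[col]][snps$sample == "c"], substr(x, 50, 50))

  # heterozygous-style tags produce an IUPAC code
  het_tags <- dplyr::bind_rows(
    build_stacks(c(rep(x, 6), rep(y, 6)), p, sample = "a"),
    build_stacks(rep(y, 5), p, sample = "b"),
    build_stacks(rep(x, 5), p, sample = "c")
  )
  het_cat <- build_catalog(het_tags, p)
  het_snps <- match_and_genotype(het_tags, het_cat, p)
  hc <- attr(het_snps, "sites")$site[1]
  amb <- het_snps[[hc]][het_snps$sample == "a"]
  expect_true(amb %in% c("M", "R", "W", "S", "Y", "K"))
})

test_that("phylip export round-trips and enforces preconditions", {
  m <- tibble::tibble(
    sample = c("alpha", "beta", "gamma"),
    s1 = c("A", "C", "A"), s2 = c("G", "G", "T"), s3 = c("T", "T", "C"),
    s4 = c("A", "A", "A"), s5 = c("C", "G", "C")
  )
  f <- withr::local_tempfile(fileext = ".phy")
  export_phylip(m, f)
  lines <- readLines(f)
  expect_equal(lines[1], "3 5")
  expect_equal(substr(lines[2], 1, 10), "alpha     ")
  back <- read_phylip(f)
  expect_equal(back$sample, m$sample)
  expect_equal(unname(as.matrix(back[, -1])),
               unname(as.matrix(m[, -1])))

  expect_error(export_phylip(m[0, ], f), "empty")
  dup <- m
  dup$sample <- c("a", "a", "b")
  expect_error(export_phylip(dup, f), "Duplicate")
  expect_warning(export_phylip(m[1:2, ], f), "3 samples")
})

test_that("fixed-within / variable-among filtering keeps diagnostic sites", {
  m <- tibble::tibble(
    sample = c("sp1_a", "sp1_b", "sp2_a", "sp2_b"),
    s1 = c("A", "A", "G", "G"),  # fixed within, differs among -> keep
    s2 = c("A", "C", "G", "G"),  # varies within sp1 -> drop
    s3 = c("T", "T", "T", "T"),  # invariant -> drop
    s4 = c("A", "A", "N", "G")   # missing -> drop at max_missing 0
  )
  groups <- c(sp1_a = "sp1", sp1_b = "sp1", sp2_a = "sp2", sp2_b = "sp2")
  out <- filter_fixed_among(m, groups)
  expect_equal(setdiff(names(out), "sample"), "s1")
  out2 <- filter_fixed_among(m, groups, max_missing = 0.25)
  expect_setequal(setdiff(names(out2), "sample"), c("s1", "s4"))
})

test_that("error-free round trip recovers one tag per manifest fragment and planted SNPs", {
  g <- synth_genome(1, 250000, 0.5, 0, seed = 31)
  set <- generate_barcode_set(20, c(4, 8), seed = 2)
  sheet <- build_sample_sheet(c("sA", "sB", "sC"), set, 1)
  ad <- build_adapters(set$barcode[1])
  cfg <- sim_config(mean_depth = 15, window = size_window(400, 700), seed = 32)

  # plant fixed differences inside in-window fragments, away from the ends
  frags <- double_digest(g, "AvaII", "MspI")
  ab <- frags[frags$end_class == "AB" & frags$length >= 400 & frags$length <= 700, ]
  # plant 60 bp in from the A (read1) end so the SNP lies inside the 140-bp tag
  a_left <- ab$left_enzyme == "AvaII"
  plant_pos <- ifelse(a_left[1:2], ab$start[1:2] + 60, ab$end[1:2] - 1 - 60)
  plant_contig <- ab$contig[1:2]
  seq_chr <- as.character(g$sequences)[[1]]
  ref_base <- vapply(plant_pos, function(p) substr(seq_chr, p + 1, p + 1),
                     character(1))
  alt <- vapply(ref_base, function(b) setdiff(c("A", "C", "G", "T"), b)[1],
                character(1), USE.NAMES = FALSE)
  variants <- tibble::tibble(
    sample = rep(c("sB", "sC"), each = 2),
    contig = rep(plant_contig, 2),
    pos = rep(plant_pos, 2),
    base = rep(alt, 2)
  )

  lib <- simulate_library(g, sheet, ad, cfg, variants = variants)
  dm <- demultiplex(lib$r1, lib$r2, sheet, tol = 1)
  expect_equal(dm$n_assigned, dm$n_input)

  p <- cluster_params(m = 10, M = 3, n = 5)
  tags <- dplyr::bind_rows(lapply(sheet$sample_id, function(s) {
    rows <- dm$assignments[dm$assignments$sample_id == s, ]
    build_stacks(truncate_reads(rows$r1_seq, 140), p, sample = s)
  }))

  # per-sample tag count = manifest in-window AB fragment count
  for (s in sheet$sample_id) {
    expect_equal(sum(tags$sample == s), sum(lib$manifest$sample_id == s),
                 info = s)
  }

  catalog <- build_catalog(tags, p)
  snps <- match_and_genotype(tags, catalog, p)
  site_cols <- setdiff(names(snps), "sample")
  # exactly the two planted sites are recovered as variant columns
  expect_length(site_cols, 2)
  for (sc in site_cols) {
    calls <- setNames(snps[[sc]], snps$sample)
    expect_equal(unname(calls["sB"]), unname(calls["sC"]))
    expect_false(calls[["sA"]] == calls[["sB"]])
  }
})
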