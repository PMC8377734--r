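test_that("transcriptome generation is byte-deterministic under a fixed seed", {
  cfg <- tiny_cfg(n_transcripts = 1L, length_range = c(100L, 100L),
                  read_length = 60L, seed = 7L)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  c1 <- tempfile(); c2 <- tempfile()
  write_transcriptome(generate_transcriptome(cfg), f1, c1)
  write_transcriptome(generate_transcriptome(cfg), f2, c2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_identical(readLines(c1), readLines(c2))
})

test_that("generated sequences hit the configured GC content", {
  # binomial SE at n = 1e5 is ~0.0016, so 0.01 is a > 6 sigma band
  cfg <- tiny_cfg(n_transcripts = 1L, length_range = c(100000L, 100000L),
                  gc_content = 0.5, seed = 3L)
  s <- as.character(generate_transcriptome(cfg)$seq[[1]])
  gc <- mean(strsplit(s, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.5), 0.01)
})

test_that("record counts and CDS structure honour the configuration", {
  cfg <- tiny_cfg(n_transcripts = 20L)
  tx <- generate_transcriptome(cfg)
  fa <- tempfile(fileext = ".fa"); cd <- tempfile()
  write_transcriptome(tx, fa, cd)
  expect_equal(sum(startsWith(readLines(fa), ">")), 20L)
  cds <- read.table(cd, header = TRUE, sep = "\t")
  expect_equal(nrow(cds), 20L)
  seqs <- unname(as.character(tx$seq))
  for (i in seq_len(20L)) {
    cs <- tx$cds$cds_start[i]; ce <- tx$cds$cds_end[i]
    expect_gte(cs, 1L)
    expect_lte(ce, nchar(seqs[i]))
    expect_equal((ce - cs + 1L) %% 3L, 0L)
    expect_equal(substr(seqs[i], cs, cs + 2L), "ATG")
    expect_true(substr(seqs[i], ce - 2L, ce) %in% c("TAA", "TAG", "TGA"))
    # no internal stop codon: planted ORFs are open
    starts <- seq.int(cs, ce - 3L, by = 3L)
    expect_false(any(substring(seqs[i], starts, starts + 2L)[-1] %in%
                       c("TAA", "TAG", "TGA")))
  }
})

test_that("EMS mutagenesis plants exactly the requested transitions", {
  cfg <- tiny_cfg(n_transcripts = 20L, length_range = c(1000L, 1000L))
  tx <- generate_transcriptome(cfg)

  none <- apply_ems_mutations(tx, 0L, seed = 5L)
  expect_identical(as.character(none$transcriptome$seq), as.character(tx$seq))
  expect_equal(nrow(none$truth), 0L)

  mut <- apply_ems_mutations(tx, 5L, seed = 5L, k = 22L)
  expect_equal(nrow(mut$truth), 5L)
  expect_true(all(mut$truth$ref_base %in% c("G", "C")))
  expect_identical(mut$truth$alt_base,
                   ifelse(mut$truth$ref_base == "G", "A", "T"))

  # direct character-comparison oracle: total Hamming distance equals n_snps
  a <- strsplit(as.character(tx$seq), "")
  b <- strsplit(as.character(mut$transcriptome$seq), "")
  expect_equal(sum(mapply(function(x, y) sum(x != y), a, b)), 5L)

  # spacing >= k within each transcript, and inside the k-mer-covered region
  by_tx <- split(mut$truth$position, mut$truth$transcript_id)
  expect_true(all(vapply(by_tx, function(p)
    length(p) < 2 || min(diff(sort(p))) >= 22, logical(1))))
  lens <- setNames(nchar(as.character(tx$seq)), names(tx$seq))
  expect_true(all(mut$truth$position <=
                    lens[mut$truth$transcript_id] - 22L + 1L))
})

test_that("EMS mutagenesis fails loudly when placement is infeasible", {
  tx <- transcriptome(c(T1 = strrep("AT", 30)))  # no G or C anywhere
  expect_error(apply_ems_mutations(tx, 2L, seed = 1L), "eligible")
})

test_that("error-free reads from a single k-length transcript are exact", {
  s <- "ACGTTTAGGCATCAGATTACGG"  # 22 nt
  tx <- transcriptome(c(T1 = s))
  cfg <- tiny_cfg(length_range = c(22L, 22L), read_length = 22L,
                  reads_per_replicate = 500L,
                  n_replicates_per_genotype = 1L, error_rate = 0)
  rs <- simulate_reads(tx, cfg, "wt", seed = 2L)
  reads <- rs$reads[[1]]
  expect_length(reads, 500L)
  expect_true(all(reads %in% c(s, rc_oracle(s))))
  expect_true(any(reads == rc_oracle(s)))  # unstranded mode uses both strands
  fwd <- simulate_reads(tx, cfg, "wt", seed = 2L, unstranded = FALSE)
  expect_true(all(fwd$reads[[1]] == s))
})

test_that("FASTQ output conserves the configured read count and layout", {
  cfg <- tiny_cfg(reads_per_replicate = 1234L, n_replicates_per_genotype = 2L)
  tx <- generate_transcriptome(cfg)
  out <- tempfile(); dir.create(out)
  rs <- simulate_reads(tx, cfg, "wt", seed = 4L, outdir = out)
  expect_equal(nrow(rs$manifest), 2L)
  lines <- readLines(gzfile(rs$manifest$fastq[1]))
  expect_equal(length(lines), 4L * 1234L)
  expect_true(all(startsWith(lines[seq(1, length(lines), 4)], "@wt_rep1_")))
  expect_true(all(lines[seq(3, length(lines), 4)] == "+"))
  expect_true(all(nchar(lines[seq(2, length(lines), 4)]) == cfg$read_length))
})

test_that("injected substitution rate matches the configured error rate", {
  # forward-only reads from a read-length transcript: every base comparable
  set.seed(99)
  s <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
             collapse = "")
  tx <- transcriptome(c(T1 = s))
  cfg <- tiny_cfg(length_range = c(100L, 100L), read_length = 100L,
                  reads_per_replicate = 10000L,
                  n_replicates_per_genotype = 1L, error_rate = 0.01)
  rs <- simulate_reads(tx, cfg, "wt", seed = 21L, unstranded = FALSE)
  ref <- strsplit(s, "")[[1]]
  mism <- vapply(strsplit(rs$reads[[1]], ""), function(x) sum(x != ref),
                 numeric(1))
  rate <- sum(mism) / 1e6  # binomial SE at 1e6 draws is ~1e-4
  expect_lt(abs(rate - 0.01), 5e-4)
})

test_that("fold-change tables plant the configured sets exactly", {
  ft <- generate_fc_tables(n_genes = 2000L,
                           up_spec = c(a = 50L, b = 120L, ab = 15L),
                           down_spec = c(a = 80L, b = 60L, ab = 10L),
                           seed = 8L)
  expect_identical(sort(threshold_genes(ft$table_a, 1.5, "up")), ft$truth$up_a)
  expect_identical(sort(threshold_genes(ft$table_b, 1.5, "up")), ft$truth$up_b)
  expect_identical(sort(threshold_genes(ft$table_a, 1.5, "down")),
                   ft$truth$down_a)
  expect_identical(sort(threshold_genes(ft$table_b, 1.5, "down")),
                   ft$truth$down_b)
  # disjoint planting is honoured
  ft0 <- generate_fc_tables(n_genes = 500L,
                            up_spec = c(a = 20L, b = 30L, ab = 0L),
                            down_spec = c(a = 5L, b = 5L, ab = 0L), seed = 1L)
  ov <- venn_overlap(threshold_genes(ft0$table_a, 1.5, "up"),
                     threshold_genes(ft0$table_b, 1.5, "up"),
                     ft0$table_a$gene_id)
  expect_equal(ov$n_intersection, 0L)
  expect_error(generate_fc_tables(up_spec = c(a = 10L, b = 5L, ab = 8L)),
               "intersection")
  expect_error(generate_fc_tables(n_genes = 100L,
                                  up_spec = c(a = 90L, b = 90L, ab = 10L),
                                  down_spec = c(a = 10L, b = 10L, ab = 0L)),
               "distinct genes")
})

test_that("vitamer tables have planted structure and truncate at zero", {
  means <- expand.grid(condition = c("0nM", "30nM"), genotype = "WT",
                       vitamer = c("thiamin", "ThMP", "ThDP"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  means$mean <- c(10, 25, 16, 16, 70, 70)
  means$sd <- 0
  tab <- generate_vitamer_table(means, n_replicates = 3L, seed = 2L)
  expect_equal(nrow(tab), 18L)  # 2 conditions x 3 vitamers x 3 replicates
  expect_identical(tab$value,
                   rep(means$mean, each = 3L))  # dispersion 0 => exact means
  fc <- fold_change(tab, "thiamin", "WT", "30nM", "0nM")
  expect_equal(fc$estimate, 2.5)
  expect_true(all(generate_vitamer_table(
    within(means, sd <- mean * 5), seed = 3L)$value >= 0))
  expect_error(generate_vitamer_table(within(means, mean[1] <- -1)),
               "non-negative")
})
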