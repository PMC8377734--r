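# build a count matrix by hand around one site of a real database, so the
# policy logic can be probed without simulating reads
fabricate_site <- function(wt_ref = c(40L, 38L), wt_alt = c(0L, 0L),
                           mut_ref = c(0L, 0L), mut_alt = c(35L, 42L),
                           second_alt_mut = NULL) {
  cfg <- tiny_cfg(n_transcripts = 2L, seed = 71L)
  tx <- generate_transcriptome(cfg)
  db <- build_variant_db(tx, k = 22L)
  rec <- db$records
  ref_rows <- which(rec$is_reference)
  site_ref <- ref_rows[10]
  tid <- rec$transcript_id[site_ref]
  pos <- rec$position[site_ref]
  alt_rows <- which(!rec$is_reference & rec$transcript_id == tid &
                      rec$position == pos)
  n <- nrow(rec)
  sids <- c("wt_rep1", "wt_rep2", "mut_rep1", "mut_rep2")
  counts <- setNames(lapply(seq_along(sids), function(j) integer(n)), sids)
  g <- function(wt, mut) c(wt, mut)
  refv <- g(wt_ref, mut_ref)
  altv <- g(wt_alt, mut_alt)
  for (j in seq_along(sids)) {
    counts[[j]][site_ref] <- refv[j]
    counts[[j]][alt_rows[1]] <- altv[j]
    if (!is.null(second_alt_mut) && j > 2)
      counts[[j]][alt_rows[2]] <- second_alt_mut[j - 2]
  }
  manifest <- data.frame(sample_id = sids,
                         genotype = c("wild-type", "wild-type",
                                      "mutant", "mutant"),
                         stringsAsFactors = FALSE)
  mat <- assemble_matrix(counts, manifest, db)
  list(db = db, mat = mat, tid = tid, pos = pos,
       alt1 = rec$obs_base[alt_rows[1]], alt2 = rec$obs_base[alt_rows[2]])
}

test_that("error-free synthetic run recovers exactly the planted SNPs", {
  cfg <- tiny_cfg(n_transcripts = 8L, length_range = c(500L, 600L),
                  n_ems_snps = 4L, reads_per_replicate = 8000L,
                  n_replicates_per_genotype = 3L, error_rate = 0, seed = 81L)
  res <- run_snp_pipeline(cfg)
  expect_equal(res$evaluation$recall, 1)
  expect_equal(res$evaluation$false_positives, 0L)
  expect_true(all(res$calls$filter == "PASS"))
  key <- function(d) paste(d$transcript_id, d$position, d$ref_base, d$alt_base)
  expect_setequal(key(res$calls), key(res$truth))

  # homozygous expectation: alt fraction 1 in mutants, 0 in wild type
  frac_cols <- grep("^alt_frac_", names(res$calls), value = TRUE)
  mut_cols <- grep("mut", frac_cols, value = TRUE)
  wt_cols <- grep("wt", frac_cols, value = TRUE)
  expect_true(all(res$calls[, mut_cols] == 1))
  expect_true(all(res$calls[, wt_cols] == 0))
})

test_that("a qualifying shift passes and zero mutant support never calls", {
  f <- fabricate_site()
  calls <- call_snps(f$mat, f$db)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$filter, "PASS")
  expect_equal(calls$transcript_id, f$tid)
  expect_equal(calls$position, f$pos)

  none <- fabricate_site(mut_ref = c(40L, 41L), mut_alt = c(0L, 0L))
  expect_equal(nrow(call_snps(none$mat, none$db)), 0L)
})

test_that("positions without wild-type coverage are never PASS", {
  f <- fabricate_site(wt_ref = c(0L, 0L), wt_alt = c(0L, 0L))
  expect_equal(nrow(call_snps(f$mat, f$db)), 0L)
  flagged <- call_snps(f$mat, f$db, emit_filtered = TRUE)
  expect_equal(nrow(flagged), 1L)
  expect_match(flagged$filter, "NO_WT_COVERAGE")
})

test_that("wild-type alt contamination and weak mutant support are filtered", {
  wt_contam <- fabricate_site(wt_ref = c(40L, 38L), wt_alt = c(10L, 9L))
  got <- call_snps(wt_contam$mat, wt_contam$db, emit_filtered = TRUE)
  expect_match(got$filter, "WT_ALT_FRACTION")

  weak <- fabricate_site(mut_ref = c(30L, 30L), mut_alt = c(10L, 12L))
  got <- call_snps(weak$mat, weak$db, emit_filtered = TRUE)
  expect_match(got$filter, "MUT_SUPPORT")
  expect_equal(nrow(call_snps(weak$mat, weak$db)), 0L)
})

test_that("two qualifying alt alleles at one site are flagged MULTIALLELIC", {
  f <- fabricate_site(mut_ref = c(0L, 0L), mut_alt = c(35L, 42L),
                      second_alt_mut = c(33L, 40L))
  # both alts have fraction ~0.5 of (ref+alt); use a permissive policy so both qualify
  pol <- calling_policy(min_alt_fraction_mut = 0.4)
  calls <- call_snps(f$mat, f$db, pol)
  expect_equal(nrow(calls), 2L)
  expect_true(all(calls$filter == "MULTIALLELIC"))
  expect_setequal(calls$alt_base, c(f$alt1, f$alt2))
})

test_that("tightening any single policy threshold never adds PASS calls", {
  cfg <- tiny_cfg(n_transcripts = 6L, n_ems_snps = 3L,
                  reads_per_replicate = 4000L,
                  n_replicates_per_genotype = 3L, error_rate = 0.02,
                  seed = 83L)
  res <- run_snp_pipeline(cfg)
  base_pol <- calling_policy()
  n_pass <- function(pol)
    sum(call_snps(res$matrix, res$db, pol)$filter == "PASS")
  base_n <- n_pass(base_pol)
  tighter <- list(calling_policy(min_ref_count_wt = 20L),
                  calling_policy(max_alt_fraction_wt = 0),
                  calling_policy(min_alt_count_mut = 25L),
                  calling_policy(min_alt_fraction_mut = 0.999),
                  calling_policy(require_all_mut_replicates = TRUE))
  for (pol in tighter) expect_lte(n_pass(pol), base_n)
})

test_that("calls are invariant to sample-column permutation", {
  cfg <- tiny_cfg(n_transcripts = 4L, n_ems_snps = 2L,
                  reads_per_replicate = 3000L,
                  n_replicates_per_genotype = 2L, seed = 85L)
  tx <- generate_transcriptome(cfg)
  mut <- apply_ems_mutations(tx, 2L, seed = 86L)
  db <- build_variant_db(tx)
  wt <- simulate_reads(tx, cfg, "wt", seed = 87L)
  mu <- simulate_reads(mut$transcriptome, cfg, "mut", seed = 88L)
  manifest <- rbind(wt$manifest, mu$manifest)
  manifest$genotype <- rep(c("wild-type", "mutant"), each = 2L)
  counts <- lapply(c(wt$reads, mu$reads), function(r) count_reads(db, r))
  a <- call_snps(assemble_matrix(counts, manifest, db), db)
  perm <- c(3, 1, 4, 2)
  b <- call_snps(assemble_matrix(counts[perm], manifest[perm, ], db), db)
  cols <- c("transcript_id", "position", "ref_base", "alt_base", "filter")
  expect_equal(a[, cols], b[, cols])
})

test_that("mismatched matrix/database checksums are refused", {
  f <- fabricate_site()
  other_db <- build_variant_db(generate_transcriptome(tiny_cfg(seed = 5L)))
  expect_error(call_snps(f$mat, other_db), "checksum")
})

test_that("genotype handling is strict and report shape follows Fig-2A style", {
  f <- fabricate_site()
  bad <- f$mat
  bad$samples$genotype <- c("wild-type", "wild-type", "odd", "mutant")
  expect_error(call_snps(bad, f$db), "unrecognized genotype")
  onegeno <- f$mat
  onegeno$samples$genotype <- rep("wild-type", 4L)
  expect_error(call_snps(onegeno, f$db), "at least one")

  calls <- call_snps(f$mat, f$db)
  p <- tempfile(fileext = ".tsv")
  report_calls(calls, p)
  tab <- read.table(p, header = TRUE, sep = "\t")
  # per-sample ref and alt count columns: 4 samples -> 8 count fields
  expect_equal(sum(grepl("^(ref|alt)_(wt|mut)_rep", names(tab))), 8L)
  # pass-through contract: reported counts equal the matrix counts
  rec <- f$db$records
  ref_key <- rec$key[rec$is_reference & rec$transcript_id == f$tid &
                       rec$position == f$pos]
  expect_equal(unname(unlist(tab[1, paste0("ref_", f$mat$samples$sample_id)])),
               unname(f$mat$counts[ref_key, ]))
  # empty call set -> header-only file
  p2 <- tempfile(fileext = ".tsv")
  report_calls(calls[0, ], p2)
  expect_equal(length(readLines(p2)), 1L)

  v <- tempfile(fileext = ".vcf")
  write_calls_vcf(calls, v)
  lines <- readLines(v)
  expect_equal(sum(!startsWith(lines, "#")), nrow(calls))
  chrom <- strsplit(grep("^#CHROM", lines, value = TRUE), "\t")[[1]]
  expect_identical(chrom[10:13], f$mat$samples$sample_id)
})
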