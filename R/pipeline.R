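#' Run the full simulate -> database -> count -> call pipeline
#'
#' Convenience driver for end-to-end experiments on synthetic data: generates
#' a wild-type transcriptome, plants EMS transitions, builds the k-mer
#' variant database from the wild-type reference, simulates replicated reads
#' for both genotypes (wild type from the reference, mutant from the
#' mutagenized copy), counts, and calls SNPs.
#'
#' All randomness derives from `cfg$seed`; runs with the same configuration
#' are reproducible (and byte-identical on disk when `outdir` is given).
#'
#' @param cfg A [sim_config()].
#' @param policy A [calling_policy()].
#' @param k k-mer length for the database.
#' @param outdir Optional directory; when given, the FASTA/CDS sidecar,
#'   per-replicate FASTQ files, database, count matrix and call table are
#'   written there.
#' @param unstranded Passed to [simulate_reads()].
#' @return List with `tx` (wild-type transcriptome), `tx_mut`, `truth`
#'   (planted SNPs), `db`, `matrix`, `calls`, `evaluation` (from
#'   [evaluate_calls()]) and `manifest`.
#' @export
run_snp_pipeline <- function(cfg = sim_config(), policy = calling_policy(),
                             k = 22L, outdir = NULL, unstranded = TRUE) {
  tx <- generate_transcriptome(cfg)
  mut <- apply_ems_mutations(tx, cfg$n_ems_snps, seed = cfg$seed + 1L, k = k,
                             margin = max(0L, cfg$read_length - k))
  db <- build_variant_db(tx, k = k, canonical = TRUE)

  wt_rs <- simulate_reads(tx, cfg, "wt", seed = cfg$seed + 100L,
                          outdir = outdir, unstranded = unstranded)
  mut_rs <- simulate_reads(mut$transcriptome, cfg, "mut",
                           seed = cfg$seed + 200L, outdir = outdir,
                           unstranded = unstranded)
  manifest <- rbind(wt_rs$manifest, mut_rs$manifest)
  manifest$genotype <- ifelse(manifest$genotype == "wt", "wild-type", "mutant")

  all_reads <- c(wt_rs$reads, mut_rs$reads)
  counts <- lapply(all_reads, function(r) count_reads(db, r))
  mat <- assemble_matrix(counts, manifest, db)
  calls <- call_snps(mat, db, policy)

  if (!is.null(outdir)) {
    write_transcriptome(tx, file.path(outdir, "reference.fa"),
                        file.path(outdir, "reference.cds.tsv"))
    write_db(db, file.path(outdir, "variants.db.tsv"))
    write_count_matrix(mat, file.path(outdir, "kmer_counts.tsv"))
    report_calls(calls, file.path(outdir, "snp_calls.tsv"))
    write.table(mut$truth, file.path(outdir, "planted_truth.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  list(tx = tx, tx_mut = mut$transcriptome, truth = mut$truth, db = db,
       matrix = mat, calls = calls,
       evaluation = evaluate_calls(calls, mut$truth), manifest = manifest)
}
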