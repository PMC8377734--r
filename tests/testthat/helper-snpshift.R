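# small, fast study design used by most unit tests
tiny_cfg <- function(...) {
  args <- list(n_transcripts = 5L, length_range = c(300L, 400L),
               gc_content = 0.4, n_ems_snps = 3L, read_length = 60L,
               reads_per_replicate = 3000L, n_replicates_per_genotype = 2L,
               error_rate = 0, seed = 11L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# independent reverse complement (Biostrings, not the package's own helper)
rc_oracle <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

# independent per-window count oracle: tabulate every valid length-k window
# of the reads (canonicalized lexicographically), then look keys up
oracle_counts <- function(reads, keys, k, canonical = TRUE) {
  windows <- unlist(lapply(reads, function(r) {
    if (nchar(r) < k) return(character(0))
    st <- seq_len(nchar(r) - k + 1L)
    substring(r, st, st + k - 1L)
  }))
  windows <- windows[!grepl("[^ACGT]", windows)]
  if (canonical) windows <- pmin(windows, rc_oracle(windows))
  tab <- table(windows)
  out <- as.integer(tab[keys])
  out[is.na(out)] <- 0L
  out
}

# enumerate all k-mer variant records of a transcriptome the slow way
oracle_all_records <- function(seqs, k) {
  do.call(rbind, lapply(names(seqs), function(id) {
    s <- seqs[[id]]
    L <- nchar(s)
    if (L < k) return(NULL)
    rows <- list()
    for (p in seq_len(L - k + 1L)) {
      w <- substr(s, p, p + k - 1L)
      if (grepl("[^ACGT]", w)) next
      for (b in c("A", "C", "G", "T")) {
        km <- w
        substr(km, 1L, 1L) <- b
        rows[[length(rows) + 1L]] <-
          data.frame(transcript_id = id, position = p, kmer = km,
                     is_reference = b == substr(w, 1L, 1L),
                     stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  }))
}
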