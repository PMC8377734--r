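#' Simulation configuration
#'
#' Bundles all parameters of the synthetic study design: a small reference
#' transcriptome, an EMS-mutagenized copy carrying sparse G>A / C>T
#' transitions, and replicated error-bearing single-end read sets for a
#' wild-type and a mutant line. Defaults emulate a scaled-down two-genotype
#' RNA-seq experiment with three biological replicates per genotype.
#'
#' @param n_transcripts Number of transcripts to simulate.
#' @param length_range Integer vector of length 2: min and max transcript
#'   length in nt. The minimum must be at least `read_length`.
#' @param gc_content Target GC fraction in (0, 1).
#' @param n_ems_snps Number of EMS transitions to plant across the
#'   transcriptome.
#' @param read_length Read length in nt.
#' @param reads_per_replicate Number of single-end reads per replicate.
#' @param n_replicates_per_genotype Replicates for each of wild type and
#'   mutant.
#' @param error_rate Per-base substitution probability in `[0, 0.05]`.
#' @param seed Integer seed; a fixed seed gives byte-identical outputs.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_transcripts = 20L,
                       length_range = c(1000L, 1200L),
                       gc_content = 0.4,
                       n_ems_snps = 5L,
                       read_length = 75L,
                       reads_per_replicate = 50000L,
                       n_replicates_per_genotype = 3L,
                       error_rate = 0.005,
                       seed = 1L) {
  stopifnot(length(length_range) == 2L, length_range[1] <= length_range[2])
  if (n_transcripts < 1L) stop("n_transcripts must be >= 1")
  if (gc_content <= 0 || gc_content >= 1) stop("gc_content must be in (0, 1)")
  if (error_rate < 0 || error_rate > 0.05)
    stop("error_rate must be in [0, 0.05]")
  if (length_range[1] < read_length)
    stop("minimum transcript length (", length_range[1],
         ") must be >= read_length (", read_length, ")")
  if (length_range[1] < 6L)
    stop("transcripts shorter than 6 nt cannot hold a CDS")
  structure(list(n_transcripts = as.integer(n_transcripts),
                 length_range = as.integer(length_range),
                 gc_content = gc_content,
                 n_ems_snps = as.integer(n_ems_snps),
                 read_length = as.integer(read_length),
                 reads_per_replicate = as.integer(reads_per_replicate),
                 n_replicates_per_genotype = as.integer(n_replicates_per_genotype),
                 error_rate = error_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# draw one random sequence at the configured GC (P(G)=P(C)=gc/2)
random_sequence <- function(len, gc) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")
# GC-neutral recodings so ORFs stay open without biasing base composition
STOP_RECODE <- c(TAA = "TAT", TAG = "TAC", TGA = "TGT")

# stamp a valid ORF (ATG ... stop, no internal stops) onto a raw sequence
place_cds <- function(seq) {
  L <- nchar(seq)
  if (L < 6L) stop("transcript of length ", L, " cannot hold a CDS")
  utr5 <- sample.int(min(300L, L - 6L) + 1L, 1L) - 1L
  utr3 <- sample.int(min(200L, L - utr5 - 6L) + 1L, 1L) - 1L
  cds_len <- ((L - utr5 - utr3) %/% 3L) * 3L
  stopifnot(cds_len >= 6L)
  cds_start <- utr5 + 1L
  cds_end <- utr5 + cds_len
  substr(seq, cds_start, cds_start + 2L) <- "ATG"
  substr(seq, cds_end - 2L, cds_end) <- sample(STOP_CODONS, 1L)
  if (cds_len > 6L) {
    starts <- seq.int(cds_start + 3L, cds_end - 5L, by = 3L)
    codons <- substring(seq, starts, starts + 2L)
    bad <- which(codons %in% STOP_CODONS)
    for (i in bad)
      substr(seq, starts[i], starts[i] + 2L) <- STOP_RECODE[[codons[i]]]
  }
  list(seq = seq, cds_start = cds_start, cds_end = cds_end)
}

#' Generate a synthetic transcriptome
#'
#' Produces random cDNA sequences at the configured GC content, each carrying
#' a coding sequence that starts with ATG, ends with a stop codon, has length
#' a multiple of 3, contains no internal stop codon, and leaves 5' and 3'
#' UTRs of length >= 0.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `transcriptome`: a list with `seq` (a named
#'   [Biostrings::DNAStringSet]) and `cds` (a data frame with columns
#'   `transcript_id`, `cds_start`, `cds_end`; 1-based inclusive).
#' @export
generate_transcriptome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  lens <- sample(seq.int(cfg$length_range[1], cfg$length_range[2]),
                 cfg$n_transcripts, replace = TRUE)
  ids <- sprintf("TX%04d", seq_len(cfg$n_transcripts))
  seqs <- character(cfg$n_transcripts)
  cds <- data.frame(transcript_id = ids, cds_start = 0L, cds_end = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_len(cfg$n_transcripts)) {
    placed <- place_cds(random_sequence(lens[i], cfg$gc_content))
    seqs[i] <- placed$seq
    cds$cds_start[i] <- placed$cds_start
    cds$cds_end[i] <- placed$cds_end
  }
  new_transcriptome(setNames(seqs, ids), cds)
}

#' Construct a transcriptome from sequences and CDS coordinates
#'
#' @param seqs Named character vector (or [Biostrings::DNAStringSet]) of cDNA
#'   sequences.
#' @param cds Data frame with columns `transcript_id`, `cds_start`, `cds_end`
#'   (1-based inclusive), one row per transcript; may be `NULL` for purely
#'   non-coding use (k-mer database and counting do not need it).
#' @return An object of class `transcriptome`.
#' @export
transcriptome <- function(seqs, cds = NULL) {
  if (is.character(seqs) && is.null(names(seqs)))
    stop("sequences must be named")
  if (is.null(cds))
    cds <- data.frame(transcript_id = names(seqs), cds_start = NA_integer_,
                      cds_end = NA_integer_, stringsAsFactors = FALSE)
  stopifnot(all(c("transcript_id", "cds_start", "cds_end") %in% names(cds)),
            all(names(seqs) %in% cds$transcript_id))
  new_transcriptome(seqs, cds)
}

new_transcriptome <- function(seqs, cds) {
  structure(list(seq = Biostrings::DNAStringSet(seqs), cds = cds),
            class = "transcriptome")
}

#' @export
print.transcriptome <- function(x, ...) {
  cat("transcriptome:", length(x$seq), "transcripts,",
      sum(Biostrings::width(x$seq)), "nt total\n")
  invisible(x)
}

#' Write / read a transcriptome (FASTA + CDS sidecar)
#'
#' @param tx A `transcriptome`.
#' @param fasta_path Output FASTA path.
#' @param cds_path Output TSV path (`transcript_id`, `cds_start`, `cds_end`;
#'   1-based inclusive).
#' @return `write_transcriptome` returns `fasta_path` invisibly;
#'   `read_transcriptome` returns a `transcriptome`.
#' @export
write_transcriptome <- function(tx, fasta_path, cds_path) {
  stopifnot(inherits(tx, "transcriptome"))
  Biostrings::writeXStringSet(tx$seq, fasta_path)
  write.table(tx$cds, cds_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fasta_path)
}

#' @rdname write_transcriptome
#' @export
read_transcriptome <- function(fasta_path, cds_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  cds <- read.table(cds_path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  stopifnot(all(c("transcript_id", "cds_start", "cds_end") %in% names(cds)))
  new_transcriptome(seqs, cds[match(names(seqs), cds$transcript_id), ,
                              drop = FALSE])
}

#' Plant EMS transition mutations in a transcriptome
#'
#' EMS chemistry induces predominantly G:C -> A:T transitions; accordingly
#' every planted SNP is G>A or C>T on the transcript strand. Positions are
#' restricted to `1 .. L - k + 1` of each transcript (a SNP in the final
#' `k - 1` bases starts no k-mer and is invisible to the count-shift method)
#' and no two SNPs on one transcript are closer than `k` bases, so each SNP
#' is unambiguous in a k-mer variant database.
#'
#' A positive `margin` further narrows the eligible interval to
#' `[1 + margin, L - k + 1 - margin]`: with fixed-length single-end reads, a
#' k-mer window starting within one read length of a transcript end is
#' covered by few read start positions, so planting SNPs inside the
#' well-covered core keeps the planted truth detectable at the depths the
#' study design provides (the pipeline driver uses
#' `margin = read_length - k`).
#'
#' @param tx A `transcriptome` (the wild-type reference).
#' @param n_snps Number of mutations to plant.
#' @param seed Integer seed.
#' @param k Minimum spacing / k-mer length context (default 22).
#' @param margin Extra nt excluded at both ends of the eligible interval
#'   (default 0).
#' @return A list with `transcriptome` (the mutated copy) and `truth`, a data
#'   frame of planted SNPs (`transcript_id`, `position`, `ref_base`,
#'   `alt_base`).
#' @export
apply_ems_mutations <- function(tx, n_snps, seed = 1L, k = 22L,
                                margin = 0L) {
  stopifnot(inherits(tx, "transcriptome"), n_snps >= 0L)
  seqs <- as.character(tx$seq)
  truth <- data.frame(transcript_id = character(0), position = integer(0),
                      ref_base = character(0), alt_base = character(0),
                      stringsAsFactors = FALSE)
  if (n_snps == 0L)
    return(list(transcriptome = new_transcriptome(seqs, tx$cds), truth = truth))

  set.seed(seed)
  elig <- do.call(rbind, lapply(seq_along(seqs), function(i) {
    L <- nchar(seqs[i])
    if (L < k) return(NULL)
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    pos <- which(ch %in% c("G", "C"))
    pos <- pos[pos >= 1L + margin & pos <= L - k + 1L - margin]
    if (!length(pos)) return(NULL)
    data.frame(tx = i, position = pos, ref = ch[pos], stringsAsFactors = FALSE)
  }))
  if (is.null(elig) || nrow(elig) < n_snps)
    stop("cannot place ", n_snps, " EMS SNPs: only ",
         if (is.null(elig)) 0L else nrow(elig), " eligible G/C positions")

  elig <- elig[sample.int(nrow(elig)), , drop = FALSE]
  chosen <- integer(0)
  taken <- vector("list", length(seqs))
  for (r in seq_len(nrow(elig))) {
    i <- elig$tx[r]
    p <- elig$position[r]
    if (length(taken[[i]]) && any(abs(taken[[i]] - p) < k)) next
    taken[[i]] <- c(taken[[i]], p)
    chosen <- c(chosen, r)
    if (length(chosen) == n_snps) break
  }
  if (length(chosen) < n_snps)
    stop("cannot place ", n_snps, " EMS SNPs at spacing >= ", k,
         ": placed only ", length(chosen))

  sel <- elig[chosen, , drop = FALSE]
  sel$alt <- ifelse(sel$ref == "G", "A", "T")
  for (r in seq_len(nrow(sel)))
    substr(seqs[sel$tx[r]], sel$position[r], sel$position[r]) <- sel$alt[r]

  truth <- data.frame(transcript_id = names(tx$seq)[sel$tx],
                      position = sel$position,
                      ref_base = sel$ref, alt_base = sel$alt,
                      stringsAsFactors = FALSE)
  truth <- truth[order(truth$transcript_id, truth$position), , drop = FALSE]
  rownames(truth) <- NULL
  list(transcriptome = new_transcriptome(seqs, tx$cds), truth = truth)
}

# one replicate's worth of reads: abundance-weighted start positions,
# optional random strand, uniform substitution errors
simulate_replicate <- function(seqs, weights, n_reads, read_length,
                               error_rate, unstranded = TRUE) {
  lens <- nchar(seqs)
  if (read_length > min(lens))
    stop("read_length (", read_length, ") exceeds shortest transcript (",
         min(lens), ")")
  tidx <- sample.int(length(seqs), n_reads, replace = TRUE, prob = weights)
  span <- lens[tidx] - read_length + 1L
  start <- 1L + as.integer(floor(runif(n_reads) * span))
  reads <- substring(seqs[tidx], start, start + read_length - 1L)
  if (unstranded) {
    flip <- runif(n_reads) < 0.5
    if (any(flip)) reads[flip] <- revcomp(reads[flip])
  }
  if (error_rate > 0) {
    total <- n_reads * read_length
    n_err <- rbinom(1L, total, error_rate)
    if (n_err > 0L) {
      at <- sample.int(total, n_err)
      ridx <- (at - 1L) %/% read_length + 1L
      off <- (at - 1L) %% read_length + 1L
      bases <- c("A", "C", "G", "T")
      cur <- match(substring(reads[ridx], off, off), bases)
      newb <- bases[((cur - 1L + sample.int(3L, n_err, replace = TRUE)) %% 4L) + 1L]
      reads <- cpp_inject_errors(reads, ridx, off, newb)
    }
  }
  reads
}

# fixed "I" qualities: the count-shift method never consults quality values
write_fastq <- function(reads, path, id_prefix) {
  qual <- strrep("I", nchar(reads))
  lines <- as.vector(rbind(paste0("@", id_prefix, "_", seq_along(reads)),
                           reads, "+", qual))
  con <- gzfile(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Simulate replicated single-end read sets
#'
#' Draws fixed-length single-end reads from the transcriptome with
#' per-transcript abundance weights (default log-uniform over one order of
#' magnitude), flips each base to a uniformly chosen different base with
#' probability `error_rate`, and (in unstranded mode) emits each read from a
#' random strand. Quality strings are constant. When `outdir` is given, one
#' gzip FASTQ (Phred+33) is written per replicate; reads are always returned
#' in memory as well.
#'
#' @param tx A `transcriptome` to draw reads from.
#' @param cfg A [sim_config()] (read length, depth, replicates, error rate).
#' @param genotype Label used in sample ids (e.g. `"wt"` or `"mut"`).
#' @param seed Integer seed for this genotype's replicates.
#' @param outdir Optional directory for FASTQ output.
#' @param unstranded Emit reads from both strands (default) or forward only.
#' @param weights Optional abundance weights (length = n transcripts).
#' @return A list with `reads` (named list of character vectors, one per
#'   replicate), `manifest` (data frame `sample_id`, `genotype`, `fastq`) and
#'   `weights`.
#' @export
simulate_reads <- function(tx, cfg, genotype, seed = cfg$seed, outdir = NULL,
                           unstranded = TRUE, weights = NULL) {
  stopifnot(inherits(tx, "transcriptome"), inherits(cfg, "sim_config"))
  seqs <- as.character(tx$seq)
  if (!length(seqs)) stop("transcript set is empty")
  set.seed(seed)
  if (is.null(weights)) weights <- 10^runif(length(seqs))
  reads <- vector("list", cfg$n_replicates_per_genotype)
  manifest <- data.frame(sample_id = character(0), genotype = character(0),
                         fastq = character(0), stringsAsFactors = FALSE)
  for (rep_i in seq_len(cfg$n_replicates_per_genotype)) {
    set.seed(seed + rep_i)
    sid <- paste0(genotype, "_rep", rep_i)
    reads[[rep_i]] <- simulate_replicate(seqs, weights,
                                         cfg$reads_per_replicate,
                                         cfg$read_length, cfg$error_rate,
                                         unstranded = unstranded)
    fq <- NA_character_
    if (!is.null(outdir)) {
      if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
      fq <- file.path(outdir, paste0(sid, ".fastq.gz"))
      write_fastq(reads[[rep_i]], fq, sid)
    }
    manifest <- rbind(manifest,
                      data.frame(sample_id = sid, genotype = genotype,
                                 fastq = fq, stringsAsFactors = FALSE))
  }
  names(reads) <- manifest$sample_id
  list(reads = reads, manifest = manifest, weights = weights)
}

#' Generate paired fold-change tables with a planted overlap
#'
#' Builds two per-gene log2 fold-change tables (two contrasts over a shared
#' gene universe) such that the genes exceeding the fold threshold in each
#' direction are exactly the planted sets: up-regulated sets of sizes
#' `up_spec["a"]` and `up_spec["b"]` sharing `up_spec["ab"]` genes, and
#' likewise for down-regulation. All non-members receive |log2 FC| strictly
#' below the threshold, so thresholding recovers the planted configuration
#' exactly.
#'
#' @param n_genes Universe size.
#' @param up_spec,down_spec Named integer vectors `c(a=, b=, ab=)`: set sizes
#'   in table A, table B and their intersection.
#' @param fold Fold-change threshold the planted sets are built around.
#' @param seed Integer seed.
#' @return A list with `table_a`, `table_b` (data frames `gene_id`,
#'   `log2fc`) and `truth` (gene-id sets `up_a`, `up_b`, `down_a`, `down_b`).
#' @export
generate_fc_tables <- function(n_genes = 20000L,
                               up_spec = c(a = 344L, b = 1200L, ab = 153L),
                               down_spec = c(a = 552L, b = 800L, ab = 73L),
                               fold = 1.5, seed = 1L) {
  check_spec <- function(s, what) {
    if (!all(c("a", "b", "ab") %in% names(s)))
      stop(what, " must have names a, b, ab")
    if (s[["ab"]] > min(s[["a"]], s[["b"]]))
      stop(what, ": intersection ", s[["ab"]], " exceeds min(|A|,|B|) = ",
           min(s[["a"]], s[["b"]]))
    if (max(s[["a"]], s[["b"]]) > n_genes)
      stop(what, ": set size exceeds universe (", n_genes, ")")
  }
  check_spec(up_spec, "up_spec")
  check_spec(down_spec, "down_spec")
  need <- sum(up_spec[c("a", "b")]) - up_spec[["ab"]] +
    sum(down_spec[c("a", "b")]) - down_spec[["ab"]]
  if (need > n_genes)
    stop("planted sets need ", need, " distinct genes but universe has ",
         n_genes)

  set.seed(seed)
  genes <- sprintf("G%05d", seq_len(n_genes))
  pool <- sample(genes)
  take <- function(n) {
    out <- pool[seq_len(n)]
    pool <<- pool[-seq_len(n)]
    out
  }
  up_both <- take(up_spec[["ab"]])
  up_a_only <- take(up_spec[["a"]] - up_spec[["ab"]])
  up_b_only <- take(up_spec[["b"]] - up_spec[["ab"]])
  dn_both <- take(down_spec[["ab"]])
  dn_a_only <- take(down_spec[["a"]] - down_spec[["ab"]])
  dn_b_only <- take(down_spec[["b"]] - down_spec[["ab"]])

  truth <- list(up_a = sort(c(up_both, up_a_only)),
                up_b = sort(c(up_both, up_b_only)),
                down_a = sort(c(dn_both, dn_a_only)),
                down_b = sort(c(dn_both, dn_b_only)))

  thr <- log2(fold)
  fill <- function(up_set, down_set) {
    v <- runif(n_genes, -(thr - 0.02), thr - 0.02)
    names(v) <- genes
    v[up_set] <- runif(length(up_set), thr + 0.1, 3)
    v[down_set] <- -runif(length(down_set), thr + 0.1, 3)
    data.frame(gene_id = genes, log2fc = unname(v), stringsAsFactors = FALSE)
  }
  list(table_a = fill(truth$up_a, truth$down_a),
       table_b = fill(truth$up_b, truth$down_b),
       truth = truth)
}

#' Default planted vitamer means
#'
#' Per-condition, per-genotype means (arbitrary concentration units per g
#' fresh weight) and standard deviations for the three thiamin vitamers. The
#' defaults embed a 2.6-fold (wild type) and 2.3-fold (mutant) ThDP increase
#' on 30 nM thiamin supplementation, with free thiamin accounting for 14%
#' (wild type) and 11% (mutant) of the total pool in the supplemented
#' condition.
#'
#' @param cv Coefficient of variation applied to every mean (default 0.1).
#' @return Data frame with columns `condition`, `genotype`, `vitamer`,
#'   `mean`, `sd`.
#' @export
default_vitamer_means <- function(cv = 0.1) {
  grid <- expand.grid(condition = c("0nM", "30nM"),
                      genotype = c("WT", "th3"),
                      vitamer = c("thiamin", "ThMP", "ThDP"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  means <- c(
    "0nM.WT.thiamin" = 8,    "0nM.th3.thiamin" = 7,
    "0nM.WT.ThMP"    = 30,   "0nM.th3.ThMP"    = 28,
    "0nM.WT.ThDP"    = 100,  "0nM.th3.ThDP"    = 100,
    "30nM.WT.thiamin" = 50.1, "30nM.th3.thiamin" = 33.4,
    "30nM.WT.ThMP"    = 48,   "30nM.th3.ThMP"    = 40,
    "30nM.WT.ThDP"    = 260,  "30nM.th3.ThDP"    = 230)
  grid$mean <- means[paste(grid$condition, grid$genotype, grid$vitamer,
                           sep = ".")]
  grid$sd <- cv * grid$mean
  grid
}

#' Generate a replicated vitamer measurement table
#'
#' Draws `n_replicates` Gaussian measurements around each planted mean,
#' truncated at zero (concentrations cannot be negative).
#'
#' @param means Data frame as returned by [default_vitamer_means()] (columns
#'   `condition`, `genotype`, `vitamer`, `mean`, `sd`).
#' @param n_replicates Replicates per cell (default 3).
#' @param seed Integer seed.
#' @return Data frame with columns `condition`, `genotype`, `vitamer`,
#'   `replicate`, `value`.
#' @export
generate_vitamer_table <- function(means = default_vitamer_means(),
                                   n_replicates = 3L, seed = 1L) {
  stopifnot(all(c("condition", "genotype", "vitamer", "mean", "sd") %in%
                  names(means)))
  if (any(means$mean < 0)) stop("planted means must be non-negative")
  if (any(means$sd < 0)) stop("planted sds must be non-negative")
  set.seed(seed)
  n <- nrow(means)
  out <- means[rep(seq_len(n), each = n_replicates),
               c("condition", "genotype", "vitamer")]
  out$replicate <- rep(seq_len(n_replicates), times = n)
  mu <- rep(means$mean, each = n_replicates)
  sdv <- rep(means$sd, each = n_replicates)
  out$value <- pmax(0, rnorm(n * n_replicates, mu, sdv))
  rownames(out) <- NULL
  out
}
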