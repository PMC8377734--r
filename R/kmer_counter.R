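#' Count database k-mers in a read set
#'
#' Streams every length-k window of every read against the database's
#' retained k-mer keys (closed-set exact counting: memory is proportional to
#' the database, not to the read set). In canonical mode each window and its
#' reverse complement are one key and increment one counter, counted once per
#' window. Windows containing non-ACGT characters are skipped.
#'
#' @param db A `variant_kmer_db`.
#' @param fastq_path Path to a (optionally gzipped) FASTQ file, Phred+33.
#' @return Integer vector of counts, one per row of `db$records`, with the
#'   number of windows scanned attached as attribute `windows`.
#' @export
count_sample <- function(db, fastq_path) {
  stopifnot(inherits(db, "variant_kmer_db"))
  if (!file.exists(fastq_path)) stop("FASTQ not found: ", fastq_path)
  reads <- tryCatch(
    as.character(Biostrings::readDNAStringSet(fastq_path, format = "fastq")),
    error = function(e) stop("failed to parse FASTQ ", fastq_path, ": ",
                             conditionMessage(e)))
  count_reads(db, reads, verbose = TRUE)
}

#' @rdname count_sample
#' @param reads Character vector of read sequences (in-memory variant).
#' @param verbose Log a line with the number of windows scanned.
#' @export
count_reads <- function(db, reads, verbose = FALSE) {
  stopifnot(inherits(db, "variant_kmer_db"))
  res <- cpp_count_kmers(reads, db$records$key, db$k, db$canonical)
  if (verbose)
    message(sprintf("counted %s reads: %.0f windows scanned, %.0f valid",
                    length(reads), res$windows_scanned, res$windows_valid))
  structure(res$counts, windows = res$windows_scanned,
            db_checksum = db$checksum)
}

#' Assemble per-sample counts into a count matrix
#'
#' @param counts Named list of per-sample count vectors (names are sample
#'   ids; each as returned by [count_sample()], all against the same
#'   database).
#' @param manifest Data frame with columns `sample_id` and `genotype`
#'   (`"wild-type"`/`"wt"` or `"mutant"`/`"mut"`); column order of the matrix
#'   follows the manifest, regardless of the order of `counts`.
#' @param db The `variant_kmer_db` the samples were counted against.
#' @return An object of class `kmer_count_matrix`: list with `counts`
#'   (integer matrix, rows = retained DB k-mers keyed by `db$records$key`,
#'   columns = samples), `samples` (the manifest) and `db_checksum`.
#' @export
assemble_matrix <- function(counts, manifest, db) {
  stopifnot(inherits(db, "variant_kmer_db"),
            all(c("sample_id", "genotype") %in% names(manifest)))
  missing <- setdiff(manifest$sample_id, names(counts))
  if (length(missing))
    stop("counts missing for samples: ", paste(missing, collapse = ", "))
  sums <- lapply(counts[manifest$sample_id], attr, "db_checksum")
  bad_sum <- !vapply(sums, function(s) is.null(s) || identical(s, db$checksum),
                     logical(1))
  if (any(bad_sum))
    stop("samples counted against a different database: ",
         paste(manifest$sample_id[bad_sum], collapse = ", "))
  n_kmer <- nrow(db$records)
  bad_len <- vapply(counts[manifest$sample_id], length, integer(1)) != n_kmer
  if (any(bad_len))
    stop("count vectors do not match the database (expected ", n_kmer,
         " k-mers): ", paste(manifest$sample_id[bad_len], collapse = ", "))
  m <- vapply(manifest$sample_id, function(s) as.integer(counts[[s]]),
              integer(n_kmer))
  if (is.null(dim(m))) m <- matrix(m, nrow = n_kmer)
  dimnames(m) <- list(db$records$key, manifest$sample_id)
  structure(list(counts = m, samples = manifest, db_checksum = db$checksum),
            class = "kmer_count_matrix")
}

#' @export
print.kmer_count_matrix <- function(x, ...) {
  cat("kmer_count_matrix:", nrow(x$counts), "k-mers x", ncol(x$counts),
      "samples (", paste(x$samples$genotype, collapse = ", "), ")\n")
  invisible(x)
}

#' Write / read a k-mer count matrix
#'
#' TSV with comment-header lines for the database checksum and the sample
#' manifest; gzip when the path ends in `.gz`.
#'
#' @param mat A `kmer_count_matrix`.
#' @param path Output path.
#' @return `write_count_matrix` returns `path` invisibly;
#'   `read_count_matrix` a `kmer_count_matrix`.
#' @export
write_count_matrix <- function(mat, path) {
  stopifnot(inherits(mat, "kmer_count_matrix"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(c(paste0("#db_checksum=", mat$db_checksum),
               paste0("#genotypes=", paste(mat$samples$genotype,
                                           collapse = ","))), con)
  df <- data.frame(kmer = rownames(mat$counts), mat$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  writeLines(paste(colnames(df), collapse = "\t"), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  get <- function(key) sub(paste0("^#", key, "="), "",
                           hdr[startsWith(hdr, paste0("#", key, "="))][1])
  cols <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  df <- read.table(text = body[-1], sep = "\t", col.names = cols,
                   stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$kmer
  manifest <- data.frame(sample_id = colnames(m),
                         genotype = strsplit(get("genotypes"), ",")[[1]],
                         stringsAsFactors = FALSE)
  structure(list(counts = m, samples = manifest,
                 db_checksum = get("db_checksum")),
            class = "kmer_count_matrix")
}
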