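# md5 of the FASTA representation; ties a DB / count matrix to its source
tx_checksum <- function(tx) {
  tf <- tempfile(fileext = ".fa")
  on.exit(unlink(tf))
  Biostrings::writeXStringSet(tx$seq, tf)
  unname(tools::md5sum(tf))
}

#' Build a k-mer SNP variant database from a transcriptome
#'
#' For each transcript of length L, reference k-mers are taken at positions
#' `1 .. L - k + 1`; each reference k-mer is accompanied by the three possible
#' single-base substitutions of its FIRST position, so a SNP at any covered
#' position shifts counts from the reference k-mer starting there to exactly
#' one variant k-mer. Windows containing non-ACGT characters are skipped.
#' k-mers whose key occurs in more than one record — the same sequence at two
#' positions, a variant colliding with a reference, or (in canonical mode)
#' reverse-complement collisions — are moved to a masked set with reason
#' codes, so every retained k-mer identifies a unique
#' (transcript, position, observed base).
#'
#' The last `k - 1` positions of each transcript start no k-mer and are
#' therefore a blind spot of the method; `uncovered` reports that interval
#' per transcript.
#'
#' @param tx A `transcriptome`.
#' @param k k-mer length (default 22; must be >= 8).
#' @param canonical Treat a k-mer and its reverse complement as one key
#'   (default TRUE; correct for unstranded or unknown-strand libraries).
#' @return An object of class `variant_kmer_db`: list with `k`, `canonical`,
#'   `records` (retained records: `kmer`, `key`, `transcript_id`, `position`,
#'   `ref_base`, `obs_base`, `is_reference`), `masked` (dropped records with
#'   a `reason` column), `uncovered` (per-transcript 3' blind interval) and
#'   `checksum` (md5 of the source FASTA representation).
#' @export
build_variant_db <- function(tx, k = 22L, canonical = TRUE) {
  stopifnot(inherits(tx, "transcriptome"))
  k <- as.integer(k)
  if (k < 8L) stop("k must be >= 8")
  if (k > 32L) stop("k must be <= 32")
  seqs <- as.character(tx$seq)
  if (!length(seqs)) stop("transcript set is empty")
  if (all(nchar(seqs) < k))
    stop("k = ", k, " is larger than every transcript")

  per_tx <- lapply(seq_along(seqs), function(i) {
    L <- nchar(seqs[i])
    if (L < k) return(NULL)
    st <- seq_len(L - k + 1L)
    km <- substring(seqs[i], st, st + k - 1L)
    ok <- !grepl("[^ACGT]", km)
    if (!any(ok)) return(NULL)
    data.frame(transcript_id = names(seqs)[i], position = st[ok],
               kmer = km[ok], stringsAsFactors = FALSE)
  })
  ref <- do.call(rbind, per_tx)
  if (is.null(ref) || !nrow(ref))
    stop("no valid k-mer windows found (all windows contain non-ACGT?)")
  ref$ref_base <- substr(ref$kmer, 1L, 1L)
  ref$obs_base <- ref$ref_base
  ref$is_reference <- TRUE

  # three first-position substitution variants per reference k-mer
  suffix <- substring(ref$kmer, 2L)
  vars <- do.call(rbind, lapply(c("A", "C", "G", "T"), function(b) {
    keep <- ref$ref_base != b
    if (!any(keep)) return(NULL)
    data.frame(transcript_id = ref$transcript_id[keep],
               position = ref$position[keep],
               kmer = paste0(b, suffix[keep]),
               ref_base = ref$ref_base[keep],
               obs_base = b,
               is_reference = FALSE,
               stringsAsFactors = FALSE)
  }))
  rec <- rbind(ref, vars)
  rec$key <- if (canonical) canonical_key(rec$kmer) else rec$kmer
  rec <- rec[order(rec$transcript_id, rec$position, rec$obs_base), ,
             drop = FALSE]
  rownames(rec) <- NULL

  dup_keys <- unique(rec$key[duplicated(rec$key)])
  masked_idx <- rec$key %in% dup_keys
  masked <- rec[masked_idx, , drop = FALSE]
  retained <- rec[!masked_idx, , drop = FALSE]

  if (nrow(masked)) {
    reasons <- vapply(split(seq_len(nrow(masked)), masked$key), function(ii) {
      g <- masked[ii, , drop = FALSE]
      r <- character(0)
      if (any(duplicated(g$kmer))) r <- c(r, "multi_position")
      if (any(g$is_reference) && any(!g$is_reference))
        r <- c(r, "ref_variant_collision")
      if (canonical && length(unique(g$kmer)) > 1L)
        r <- c(r, "strand_collision")
      if (!length(r)) r <- "ambiguous"
      paste(r, collapse = ";")
    }, character(1))
    masked$reason <- reasons[masked$key]
  } else {
    masked$reason <- character(0)
  }
  rownames(masked) <- NULL
  rownames(retained) <- NULL

  lens <- nchar(seqs)
  uncovered <- data.frame(transcript_id = names(seqs),
                          blind_start = pmax(lens - k + 2L, 1L),
                          blind_end = lens, stringsAsFactors = FALSE)

  structure(list(k = k, canonical = canonical, records = retained,
                 masked = masked, uncovered = uncovered,
                 checksum = tx_checksum(tx)),
            class = "variant_kmer_db")
}

#' @export
print.variant_kmer_db <- function(x, ...) {
  cat("variant_kmer_db: k =", x$k, "| canonical =", x$canonical, "|",
      nrow(x$records), "retained records (",
      sum(x$records$is_reference), "reference /",
      sum(!x$records$is_reference), "variant ) |",
      nrow(x$masked), "masked\n")
  invisible(x)
}

#' Query a database by k-mer
#'
#' Looks a k-mer up under the database's key convention: in canonical mode a
#' k-mer and its reverse complement return the same record.
#'
#' @param db A `variant_kmer_db`.
#' @param kmer Character vector of k-mers.
#' @return The matching retained records (zero rows when absent).
#' @export
lookup_kmer <- function(db, kmer) {
  stopifnot(inherits(db, "variant_kmer_db"))
  if (any(nchar(kmer) != db$k)) stop("query length must equal k = ", db$k)
  key <- if (db$canonical) canonical_key(kmer) else kmer
  db$records[db$records$key %in% key, , drop = FALSE]
}

#' Write / read a variant k-mer database
#'
#' Serializes to TSV (gzip when the path ends in `.gz`) with header comment
#' lines carrying `k`, the canonical mode and the source checksum; masked
#' records go to a sibling `<path>.masked` file. Round-trips are lossless.
#'
#' @param db A `variant_kmer_db`.
#' @param path Output path (main records).
#' @param masked_path Path for masked records (default `<path>.masked`).
#' @param expected_checksum Optional md5 to compare against the header on
#'   read; a mismatch raises a warning.
#' @param expected_k Optional k to enforce on read; mismatch is an error.
#' @return `write_db` returns `path` invisibly; `read_db` a
#'   `variant_kmer_db`.
#' @export
write_db <- function(db, path, masked_path = paste0(path, ".masked")) {
  stopifnot(inherits(db, "variant_kmer_db"))
  open_out <- function(p) if (grepl("\\.gz$", p)) gzfile(p, "wb") else file(p, "wb")
  hdr <- c(paste0("#k=", db$k),
           paste0("#canonical=", db$canonical),
           paste0("#checksum=", db$checksum))
  emit <- function(df, p, extra_cols) {
    con <- open_out(p)
    on.exit(close(con))
    writeLines(hdr, con)
    cols <- c("kmer", "transcript_id", "position", "ref_base", "obs_base",
              "is_reference", extra_cols)
    writeLines(paste(cols, collapse = "\t"), con)
    if (nrow(df))
      write.table(df[, cols, drop = FALSE], con, sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = FALSE)
  }
  emit(db$records, path, character(0))
  emit(db$masked, masked_path, "reason")
  invisible(path)
}

#' @rdname write_db
#' @export
read_db <- function(path, masked_path = paste0(path, ".masked"),
                    expected_checksum = NULL, expected_k = NULL) {
  parse_one <- function(p, has_reason) {
    lines <- readLines(if (grepl("\\.gz$", p)) gzfile(p) else p)
    hdr <- lines[startsWith(lines, "#")]
    body <- lines[!startsWith(lines, "#")]
    get <- function(key) sub(paste0("^#", key, "="), "",
                             hdr[startsWith(hdr, paste0("#", key, "="))][1])
    cols <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
    df <- if (length(body) > 1L)
      read.table(text = body[-1], sep = "\t", col.names = cols,
                 stringsAsFactors = FALSE)
    else {
      empty <- data.frame(kmer = character(0), transcript_id = character(0),
                          position = integer(0), ref_base = character(0),
                          obs_base = character(0), is_reference = logical(0),
                          stringsAsFactors = FALSE)
      if (has_reason) empty$reason <- character(0)
      empty
    }
    list(k = as.integer(get("k")), canonical = as.logical(get("canonical")),
         checksum = get("checksum"), df = df)
  }
  main <- parse_one(path, FALSE)
  msk <- parse_one(masked_path, TRUE)
  if (!is.null(expected_k) && main$k != expected_k)
    stop("database k = ", main$k, " does not match expected k = ", expected_k)
  if (!is.null(expected_checksum) && main$checksum != expected_checksum)
    warning("database checksum (", main$checksum,
            ") differs from supplied FASTA checksum (", expected_checksum, ")")
  rec <- main$df
  msk_df <- msk$df
  rec$key <- if (main$canonical) canonical_key(rec$kmer) else rec$kmer
  if (nrow(msk_df))
    msk_df$key <- if (main$canonical) canonical_key(msk_df$kmer) else msk_df$kmer
  else msk_df$key <- character(0)
  structure(list(k = main$k, canonical = main$canonical, records = rec,
                 masked = msk_df, uncovered = NULL, checksum = main$checksum),
            class = "variant_kmer_db")
}
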