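#' Calling policy for count-shift SNP detection
#'
#' The count-shift criterion — the mutant carries a variant k-mer that the
#' wild type does not — is qualitative; these thresholds make it operational
#' for error-bearing reads. Defaults encode the homozygous-mutant
#' expectation: essentially all mutant-read k-mers at the site carry the
#' variant, while wild-type replicates show the variant at no more than
#' sequencing-error level.
#'
#' @param min_ref_count_wt Coverage floor: minimum reference-k-mer count
#'   required in every wild-type replicate.
#' @param max_alt_fraction_wt Maximum tolerated alt fraction
#'   (alt / (ref + alt)) in any wild-type replicate.
#' @param min_alt_count_mut Minimum alt-k-mer count per mutant replicate.
#' @param min_alt_fraction_mut Minimum alt fraction per mutant replicate.
#' @param require_all_mut_replicates If `TRUE` (default) every mutant
#'   replicate must pass the mutant-side thresholds; if `FALSE`, a strict
#'   majority suffices.
#' @return An object of class `calling_policy`.
#' @export
calling_policy <- function(min_ref_count_wt = 5L,
                           max_alt_fraction_wt = 0.05,
                           min_alt_count_mut = 3L,
                           min_alt_fraction_mut = 0.8,
                           require_all_mut_replicates = TRUE) {
  stopifnot(min_ref_count_wt >= 0, min_alt_count_mut >= 0,
            max_alt_fraction_wt >= 0, max_alt_fraction_wt <= 1,
            min_alt_fraction_mut >= 0, min_alt_fraction_mut <= 1)
  structure(list(min_ref_count_wt = min_ref_count_wt,
                 max_alt_fraction_wt = max_alt_fraction_wt,
                 min_alt_count_mut = min_alt_count_mut,
                 min_alt_fraction_mut = min_alt_fraction_mut,
                 require_all_mut_replicates = require_all_mut_replicates),
            class = "calling_policy")
}

normalize_genotype <- function(g) {
  g <- tolower(g)
  out <- ifelse(g %in% c("wild-type", "wildtype", "wt"), "wt",
                ifelse(g %in% c("mutant", "mut"), "mut", NA_character_))
  if (anyNA(out))
    stop("unrecognized genotype label(s): ",
         paste(unique(g[is.na(out)]), collapse = ", "),
         " (use wild-type/wt or mutant/mut)")
  out
}

#' Call mutant-specific SNPs from a k-mer count matrix
#'
#' For every retained (transcript, position) the four allele counts per
#' sample are gathered from the reference k-mer and its three first-position
#' variants. An alt allele is called when (a) every wild-type replicate has
#' reference coverage of at least `min_ref_count_wt` and an alt fraction no
#' greater than `max_alt_fraction_wt`, and (b) the mutant replicates (all, or
#' a strict majority, per the policy) reach `min_alt_count_mut` and
#' `min_alt_fraction_mut`. Positions without wild-type coverage can never
#' PASS (`NO_WT_COVERAGE`): a shift cannot be established without a baseline.
#' If two alt alleles at one position both qualify, both are emitted flagged
#' `MULTIALLELIC` — unexpected under EMS, so made visible rather than
#' silently resolved.
#'
#' @param mat A `kmer_count_matrix`.
#' @param db The `variant_kmer_db` the matrix was counted against (checksums
#'   must match).
#' @param policy A [calling_policy()].
#' @param emit_filtered Also return near-misses (alt alleles reaching
#'   `min_alt_count_mut` in at least one mutant replicate) with named filter
#'   status instead of only PASS/MULTIALLELIC rows.
#' @return Data frame of calls sorted by (transcript, position):
#'   `transcript_id`, `position`, `ref_base`, `alt_base`, `filter`, one
#'   `ref_<sample>` and `alt_<sample>` count column per sample, and
#'   `alt_frac_<sample>` columns (NA where ref + alt = 0).
#' @export
call_snps <- function(mat, db, policy = calling_policy(),
                      emit_filtered = FALSE) {
  stopifnot(inherits(mat, "kmer_count_matrix"),
            inherits(db, "variant_kmer_db"),
            inherits(policy, "calling_policy"))
  if (!identical(mat$db_checksum, db$checksum))
    stop("count matrix checksum (", mat$db_checksum,
         ") does not match database checksum (", db$checksum, ")")
  geno <- normalize_genotype(mat$samples$genotype)
  if (!any(geno == "wt") || !any(geno == "mut"))
    stop("need at least one wild-type and one mutant sample; got: ",
         paste(mat$samples$genotype, collapse = ", "))

  counts <- mat$counts[match(db$records$key, rownames(mat$counts)), ,
                       drop = FALSE]
  rec <- db$records
  ref_i <- which(rec$is_reference)
  alt_i <- which(!rec$is_reference)
  site <- function(i) paste(rec$transcript_id[i], rec$position[i], sep = "\r")
  ref_at <- match(site(alt_i), site(ref_i))
  keep <- !is.na(ref_at)                      # alt needs its ref k-mer retained
  alt_i <- alt_i[keep]
  ref_row <- ref_i[ref_at[keep]]

  rc <- counts[ref_row, , drop = FALSE]
  ac <- counts[alt_i, , drop = FALSE]
  wt <- geno == "wt"
  mut <- geno == "mut"
  n_mut <- sum(mut)

  tot_wt <- rc[, wt, drop = FALSE] + ac[, wt, drop = FALSE]
  frac_wt <- ac[, wt, drop = FALSE] / tot_wt          # NaN where 0/0
  no_wt_cov <- rowSums(tot_wt == 0) > 0
  wt_cov_ok <- rowSums(rc[, wt, drop = FALSE] >= policy$min_ref_count_wt) ==
    sum(wt)
  wt_frac_ok <- !no_wt_cov &
    rowSums(frac_wt <= policy$max_alt_fraction_wt, na.rm = TRUE) == sum(wt)

  tot_mut <- rc[, mut, drop = FALSE] + ac[, mut, drop = FALSE]
  frac_mut <- ac[, mut, drop = FALSE] / tot_mut
  rep_ok <- (ac[, mut, drop = FALSE] >= policy$min_alt_count_mut) &
    !is.na(frac_mut) & (frac_mut >= policy$min_alt_fraction_mut)
  n_rep_ok <- rowSums(rep_ok)
  mut_ok <- if (policy$require_all_mut_replicates) n_rep_ok == n_mut
            else n_rep_ok > n_mut / 2

  pass <- wt_cov_ok & wt_frac_ok & !no_wt_cov & mut_ok

  filter <- character(length(alt_i))
  add <- function(f, cond) ifelse(cond, ifelse(filter == "", f,
                                               paste(filter, f, sep = ";")),
                                  filter)
  filter <- add("NO_WT_COVERAGE", no_wt_cov)
  filter <- add("LOW_WT_COVERAGE", !no_wt_cov & !wt_cov_ok)
  filter <- add("WT_ALT_FRACTION", !no_wt_cov & !wt_frac_ok)
  filter <- add("MUT_SUPPORT", !mut_ok)
  filter[pass] <- "PASS"

  # multiallelic: >= 2 qualifying alts at one site are flagged, never PASS
  site_key <- paste(rec$transcript_id[alt_i], rec$position[alt_i], sep = "\r")
  multi <- site_key %in% names(which(table(site_key[pass]) >= 2)) & pass
  filter[multi] <- "MULTIALLELIC"

  near_miss <- rowSums(ac[, mut, drop = FALSE] >= policy$min_alt_count_mut) > 0
  keep_row <- filter %in% c("PASS", "MULTIALLELIC") |
    (emit_filtered & near_miss)

  out <- data.frame(transcript_id = rec$transcript_id[alt_i],
                    position = rec$position[alt_i],
                    ref_base = rec$ref_base[alt_i],
                    alt_base = rec$obs_base[alt_i],
                    filter = filter, stringsAsFactors = FALSE)
  sid <- mat$samples$sample_id
  for (j in seq_along(sid)) {
    out[[paste0("ref_", sid[j])]] <- rc[, j]
    out[[paste0("alt_", sid[j])]] <- ac[, j]
  }
  frac_all <- ac / (rc + ac)
  for (j in seq_along(sid))
    out[[paste0("alt_frac_", sid[j])]] <- round(frac_all[, j], 4)

  out <- out[keep_row, , drop = FALSE]
  out <- out[order(out$transcript_id, out$position, out$alt_base), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Report SNP calls as a TSV table
#'
#' One row per call with the transcript, cDNA position, ref/alt base and the
#' per-sample reference-k-mer and variant-k-mer counts (the count-shift
#' evidence table). An empty call set yields a header-only file.
#'
#' @param calls Data frame from [call_snps()].
#' @param path Output TSV path.
#' @return The calls, invisibly.
#' @export
report_calls <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message(nrow(calls), " call(s) written to ", path)
  invisible(calls)
}

#' Write calls in a minimal VCF-style format
#'
#' CHROM is the transcript id and POS the 1-based cDNA position; per-sample
#' allele-depth style counts go in an `AD` field (ref,alt). Intended for
#' interoperability, not as a fully compliant VCF.
#'
#' @param calls Data frame from [call_snps()].
#' @param path Output path.
#' @param sample_ids Sample ids (order of the genotype columns); defaults to
#'   those recoverable from the call columns.
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(calls, path, sample_ids = NULL) {
  if (is.null(sample_ids))
    sample_ids <- setdiff(
      sub("^ref_", "", grep("^ref_", names(calls), value = TRUE)), "base")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=snpshift",
               "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"k-mer counts for ref,alt\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", sample_ids), collapse = "\t")), con)
  if (nrow(calls)) {
    ad <- vapply(seq_len(nrow(calls)), function(i) {
      paste(vapply(sample_ids, function(s)
        paste0(calls[[paste0("ref_", s)]][i], ",",
               calls[[paste0("alt_", s)]][i]), character(1)),
        collapse = "\t")
    }, character(1))
    writeLines(paste(calls$transcript_id, calls$position, ".",
                     calls$ref_base, calls$alt_base, ".", calls$filter, ".",
                     "AD", ad, sep = "\t"), con)
  }
  invisible(path)
}

#' Compare calls with a planted truth set
#'
#' @param calls Data frame from [call_snps()].
#' @param truth Planted-SNP data frame (`transcript_id`, `position`,
#'   `ref_base`, `alt_base`), as from [apply_ems_mutations()].
#' @return List with `n_truth`, `n_pass`, `n_recovered`, `recall`,
#'   `false_positives`.
#' @export
evaluate_calls <- function(calls, truth) {
  key <- function(d) paste(d$transcript_id, d$position, d$ref_base,
                           d$alt_base)
  pass <- calls[calls$filter == "PASS", , drop = FALSE]
  hit <- key(pass) %in% key(truth)
  list(n_truth = nrow(truth),
       n_pass = nrow(pass),
       n_recovered = sum(hit),
       recall = if (nrow(truth)) sum(hit) / nrow(truth) else NA_real_,
       false_positives = sum(!hit))
}
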