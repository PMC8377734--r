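# three-letter amino-acid codes for HGVS-like protein shorthand
AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", `*` = "Ter")

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[codon]
  if (anyNA(aa)) stop("cannot translate codon(s): ",
                      paste(codon[is.na(aa)], collapse = ", "))
  unname(aa)
}

#' Annotate the coding effect of SNP calls
#'
#' Classifies each call against the transcript's CDS interval (1-based
#' inclusive cDNA coordinates). Positions before `cds_start` are 5'UTR, after
#' `cds_end` 3'UTR. For CDS positions the residue number is
#' `codon_index = ceiling((position - cds_start + 1) / 3)` with
#' `codon_position` 1-3 within the codon; ref and alt codons are translated
#' under the standard genetic code and the effect classed as synonymous,
#' missense, nonsense (gain of stop), stop_loss, or start_loss (any change to
#' the initiator ATG, which encodes the only Met codon).
#'
#' @param calls Data frame with at least `transcript_id`, `position`,
#'   `ref_base`, `alt_base` (e.g. from [call_snps()]).
#' @param tx The reference `transcriptome` (sequence + CDS sidecar).
#' @return Data frame with one row per call: region, codon fields (NA outside
#'   the CDS), amino acids and `effect_class`.
#' @export
annotate_effects <- function(calls, tx) {
  stopifnot(inherits(tx, "transcriptome"))
  need <- c("transcript_id", "position", "ref_base", "alt_base")
  stopifnot(all(need %in% names(calls)))
  n <- nrow(calls)
  out <- data.frame(transcript_id = calls$transcript_id,
                    position = calls$position,
                    ref_base = calls$ref_base,
                    alt_base = calls$alt_base,
                    region = rep(NA_character_, n),
                    codon_index = rep(NA_integer_, n),
                    codon_position = rep(NA_integer_, n),
                    ref_codon = rep(NA_character_, n),
                    alt_codon = rep(NA_character_, n),
                    ref_aa = rep(NA_character_, n),
                    alt_aa = rep(NA_character_, n),
                    effect_class = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  if (!n) return(out)
  seqs <- as.character(tx$seq)
  cds <- tx$cds
  for (i in seq_len(n)) {
    tid <- calls$transcript_id[i]
    j <- match(tid, cds$transcript_id)
    if (is.na(j)) stop("unknown transcript: ", tid)
    s <- seqs[[tid]]
    pos <- calls$position[i]
    if (pos < 1L || pos > nchar(s))
      stop("position ", pos, " outside transcript ", tid,
           " (length ", nchar(s), ")")
    cs <- cds$cds_start[j]
    ce <- cds$cds_end[j]
    if ((ce - cs + 1L) %% 3L != 0L)
      stop("CDS length of ", tid, " is not a multiple of 3")
    ref_here <- substr(s, pos, pos)
    if (ref_here != calls$ref_base[i])
      warning("reference base at ", tid, ":", pos, " is ", ref_here,
              " but call says ", calls$ref_base[i])
    if (pos < cs) {
      out$region[i] <- "5'UTR"; out$effect_class[i] <- "utr"
    } else if (pos > ce) {
      out$region[i] <- "3'UTR"; out$effect_class[i] <- "utr"
    } else {
      off <- pos - cs + 1L
      ci <- (off - 1L) %/% 3L + 1L
      cp <- (off - 1L) %% 3L + 1L
      codon_start <- cs + (ci - 1L) * 3L
      ref_codon <- substr(s, codon_start, codon_start + 2L)
      alt_codon <- ref_codon
      substr(alt_codon, cp, cp) <- calls$alt_base[i]
      ref_aa <- translate_codon(ref_codon)
      alt_aa <- translate_codon(alt_codon)
      cls <- if (ci == 1L && alt_codon != "ATG") "start_loss"
      else if (ref_aa == alt_aa) "synonymous"
      else if (alt_aa == "*") "nonsense"
      else if (ref_aa == "*") "stop_loss"
      else "missense"
      out$region[i] <- "CDS"
      out$codon_index[i] <- ci
      out$codon_position[i] <- cp
      out$ref_codon[i] <- ref_codon
      out$alt_codon[i] <- alt_codon
      out$ref_aa[i] <- ref_aa
      out$alt_aa[i] <- alt_aa
      out$effect_class[i] <- cls
    }
  }
  out
}

#' Summarize effect annotations with HGVS-like shorthand
#'
#' Adds `hgvs_c` (cDNA-numbered, e.g. `c.1278G>A` — positions count from the
#' first base of the full-length cDNA, matching the pipeline's coordinate
#' convention) and `hgvs_p` (e.g. `p.Glu323Lys`, `p.Glu323=` for synonymous,
#' `Ter` for stops), sorts by (transcript, position), and optionally writes a
#' TSV (header-only when empty).
#'
#' @param annotations Data frame from [annotate_effects()].
#' @param path Optional output TSV path.
#' @return The augmented, sorted data frame (invisibly when `path` is given).
#' @export
summarize_effects <- function(annotations, path = NULL) {
  a <- annotations
  a$hgvs_c <- if (nrow(a)) paste0("c.", a$position, a$ref_base, ">",
                                  a$alt_base) else character(0)
  in_cds <- !is.na(a$region) & a$region == "CDS"
  a$hgvs_p <- rep(NA_character_, nrow(a))
  if (any(in_cds)) {
    ref3 <- AA3[a$ref_aa[in_cds]]
    alt3 <- AA3[a$alt_aa[in_cds]]
    syn <- a$effect_class[in_cds] == "synonymous"
    p <- paste0("p.", ref3, a$codon_index[in_cds], alt3)
    p[syn] <- paste0("p.", ref3[syn], a$codon_index[in_cds][syn], "=")
    a$hgvs_p[in_cds] <- p
  }
  a <- a[order(a$transcript_id, a$position, a$alt_base), , drop = FALSE]
  rownames(a) <- NULL
  if (!is.null(path)) {
    write.table(a, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(a))
  }
  a
}
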