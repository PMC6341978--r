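#' GC fraction of a nucleotide sequence
#'
#' Fraction of unambiguous bases (A, C, G, T; case-insensitive) that are G or
#' C. Ambiguous bases are excluded from both numerator and denominator.
#'
#' @param sequence A single nucleotide string.
#' @return GC fraction in \[0, 1\].
#' @export
compute_gc <- function(sequence) {
  if (!nzchar(sequence)) stop("empty sequence")
  b <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  n_gc <- sum(b == "G" | b == "C")
  n_at <- sum(b == "A" | b == "T")
  if (n_gc + n_at == 0L) stop("GC undefined: no unambiguous bases")
  n_gc / (n_gc + n_at)
}

#' Find open reading frames on both strands
#'
#' Scans all three frames of the forward and reverse strand for ORFs
#' (ATG ... stop, standard code) of at least `min_codons` codons including
#' the stop. Coordinates are 0-based half-open on the forward strand,
#' regardless of the ORF's strand. Within a frame, nested ATGs inside an
#' already-reported ORF are not reported again (the first ATG wins).
#'
#' @param sequence Nucleotide string.
#' @param min_codons Minimum ORF length in codons (start through stop).
#' @return data.frame with columns start, end, frame (0-2), strand (+/-).
#' @export
find_orfs <- function(sequence, min_codons = 100L) {
  stopifnot(min_codons >= 1L)
  seq_fwd <- toupper(sequence)
  n <- nchar(seq_fwd)
  res <- list(orfs_one_strand(seq_fwd, "+", n),
              orfs_one_strand(revcomp(seq_fwd), "-", n))
  out <- do.call(rbind, res)
  out <- out[(out$end - out$start) / 3L >= min_codons, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$start, out$end), , drop = FALSE]
}

orfs_one_strand <- function(s, strand, n_fwd) {
  stops <- c("TAA", "TAG", "TGA")
  out <- list()
  n <- nchar(s)
  codmat <- function(offset) {
    starts <- seq(offset + 1L, n - 2L, by = 3L)
    if (starts[length(starts)] + 2L > n) starts <- starts[-length(starts)]
    substring(s, starts, starts + 2L)
  }
  for (frame in 0:2) {
    if (n - frame < 3L) next
    cods <- codmat(frame)
    in_orf <- FALSE
    orf_start <- NA_integer_
    for (k in seq_along(cods)) {
      if (!in_orf && cods[k] == "ATG") {
        in_orf <- TRUE
        orf_start <- frame + (k - 1L) * 3L     # 0-based on this strand
      } else if (in_orf && cods[k] %in% stops) {
        orf_end <- frame + k * 3L              # half-open
        out[[length(out) + 1L]] <-
          data.frame(start = orf_start, end = orf_end, frame = frame,
                     strand = strand, stringsAsFactors = FALSE)
        in_orf <- FALSE
      }
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(),
                      frame = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  if (strand == "-") {
    # map minus-strand coordinates back onto the forward strand
    new_start <- n_fwd - res$end
    res$end <- n_fwd - res$start
    res$start <- new_start
  }
  res
}

#' Remove low-expression transcripts by summed FPKM
#'
#' A transcript is discarded when its FPKM summed across all samples falls
#' strictly below `threshold`; a sum exactly equal to the threshold is kept.
#'
#' @param fpkm Numeric matrix (transcripts x samples) with rownames.
#' @param threshold Minimum summed FPKM (default 0.5).
#' @return Character vector of retained transcript ids.
#' @export
filter_low_expression <- function(fpkm, threshold = 0.5) {
  stopifnot(threshold >= 0, nrow(fpkm) > 0)
  keep <- rowSums(fpkm) >= threshold
  rownames(fpkm)[keep]
}

#' Reciprocal best hits between two hit tables
#'
#' A query q is a reciprocal best hit iff its best-scoring subject s (ties
#' broken by lexicographically smallest subject id) itself has q as its
#' best-scoring query in the reverse table (same tie-break). Reciprocity is
#' checked against the tie-broken best subject only.
#'
#' @param forward data.frame with columns query, subject, score.
#' @param reverse data.frame with columns query, subject, score, where the
#'   roles are swapped (queries are the forward table's subjects).
#' @return Character vector of forward-query ids with an RBH.
#' @export
reciprocal_best_hits <- function(forward, reverse) {
  best <- function(tab) {
    if (!nrow(tab)) return(character(0))
    o <- order(tab$query, -tab$score, tab$subject)
    tab <- tab[o, , drop = FALSE]
    keep <- !duplicated(tab$query)
    stats::setNames(tab$subject[keep], tab$query[keep])
  }
  fb <- best(forward)
  rb <- best(reverse)
  qs <- names(fb)
  qs[!is.na(rb[fb]) & rb[fb] == qs]
}

#' Classify transcripts into host, symbiont, or discarded
#'
#' Applies the partition rules in precedence order: (1) ortholog evidence to
#' the coral reference makes a transcript host; (2) ortholog evidence to the
#' symbiont reference makes it symbiont; (3) a reciprocal best hit against
#' the cnidarian database makes it host; (4) with no homology evidence, a GC
#' fraction at or below `gc_cutoff` makes it host via the GC rule; (5)
#' anything else is discarded. Transcripts with ortholog evidence to both
#' references are discarded as conflicting. Transcripts flagged by the
#' prefilters (low expression, no ORF) are discarded with the corresponding
#' evidence code before any homology rule applies.
#'
#' @param info data.frame with columns id and gc (GC fraction); optional
#'   logical columns low_expression and no_orf carry the prefilter flags.
#' @param evidence Homology-evidence data.frame with columns query_id,
#'   database (coral_reference / symbiont_reference / cnidarian_db) and
#'   reciprocal (logical, used for cnidarian_db rows).
#' @param gc_cutoff Inclusive GC boundary for the GC rule (default 0.47).
#' @return data.frame with one row per transcript: transcript_id, label
#'   (host / symbiont / discarded) and evidence code.
#' @export
classify_transcripts <- function(info, evidence, gc_cutoff = 0.47) {
  ids <- info$id
  unknown <- setdiff(unique(evidence$query_id), ids)
  if (length(unknown))
    stop("evidence refers to unknown transcript id(s): ",
         paste(utils::head(unknown, 3), collapse = ", "))
  coral <- unique(evidence$query_id[evidence$database == "coral_reference"])
  symb <- unique(evidence$query_id[evidence$database == "symbiont_reference"])
  rbh <- unique(evidence$query_id[evidence$database == "cnidarian_db" &
                                    isTRUE_vec(evidence$reciprocal)])
  low <- if ("low_expression" %in% names(info)) info$low_expression
         else rep(FALSE, length(ids))
  noorf <- if ("no_orf" %in% names(info)) info$no_orf
           else rep(FALSE, length(ids))
  in_coral <- ids %in% coral
  in_symb <- ids %in% symb
  in_rbh <- ids %in% rbh
  label <- rep("discarded", length(ids))
  evid <- rep("gc_fail", length(ids))
  gc_ok <- info$gc <= gc_cutoff
  sel <- !low & !noorf & !(in_coral & in_symb)
  set <- function(cond, lab, ev) {
    i <- sel & cond
    label[i] <<- lab; evid[i] <<- ev; sel[i] <<- FALSE
  }
  set(in_coral, "host", "ortholog_coral")
  set(in_symb, "symbiont", "ortholog_symbiont")
  set(in_rbh, "host", "rbh_cnidarian")
  set(gc_ok, "host", "gc_rule")
  label[low] <- "discarded"; evid[low] <- "low_expression"
  label[!low & noorf] <- "discarded"; evid[!low & noorf] <- "no_orf"
  data.frame(transcript_id = ids, label = label, evidence = evid,
             stringsAsFactors = FALSE)
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Read a BLAST tabular (outfmt 6) file as a hit table
#'
#' Standard 12-column output: qseqid sseqid pident length mismatch gapopen
#' qstart qend sstart send evalue bitscore.
#'
#' @param path File path.
#' @return data.frame with the 12 standard columns, plus aliases `query`,
#'   `subject`, `score` (bitscore) used by [reciprocal_best_hits()].
#' @export
read_blast6 <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(tab) != 12L) stop("expected 12 tab-separated columns")
  names(tab) <- cols
  tab$query <- tab$qseqid
  tab$subject <- tab$sseqid
  tab$score <- tab$bitscore
  tab
}
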