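#' Generate a synthetic host/symbiont meta-transcriptome
#'
#' Builds a pool of host and symbiont transcripts whose per-transcript GC
#' fractions follow truncated normal distributions around the configured
#' means (defaults 0.40 for host, 0.55 for symbiont, sd 0.04). Every
#' transcript is a single full-length open reading frame (ATG ... TAA) of at
#' least 100 codons (>= 300 bases), with no internal in-frame stop codon, so
#' the ORF prefilter of the partition stage is satisfied by construction.
#' The realised GC of each transcript matches its drawn target exactly up to
#' integer base-count quantization.
#'
#' A homology-evidence table is also emitted: a configurable fraction of
#' transcripts (`cfg$evidence_fraction`) receive an ortholog hit to their
#' true reference (`coral_reference` for host, `symbiont_reference` for
#' symbiont transcripts).
#'
#' @param cfg A [simulation_config()].
#' @return A list with elements
#'   \describe{
#'     \item{sequences}{named character vector of transcript sequences}
#'     \item{info}{data.frame: id, origin, length, gc_target, gc}
#'     \item{evidence}{homology-evidence data.frame
#'       (query_id, database, subject_id, score, e_value, reciprocal)}
#'     \item{truth}{list with `transcript_origin`, a named character vector}
#'   }
#' @export
gen_meta_transcriptome <- function(cfg) {
  validate_sim_config(cfg)
  with_seed(stream_seed(cfg, "transcriptome"), {
    n <- cfg$n_host + cfg$n_symbiont
    origin <- rep(c("host", "symbiont"), c(cfg$n_host, cfg$n_symbiont))
    ids <- sprintf("tx%05d", seq_len(n))
    gc_target <- c(
      rnorm_trunc(cfg$n_host, cfg$gc_host_mean, cfg$gc_sd),
      rnorm_trunc(cfg$n_symbiont, cfg$gc_symbiont_mean, cfg$gc_sd))
    ncodons <- sample(98:398, n, replace = TRUE)
    seqs <- vapply(seq_len(n),
                   function(i) orf_sequence(ncodons[i], gc_target[i]),
                   character(1))
    names(seqs) <- ids
    info <- data.frame(id = ids, origin = origin,
                       length = nchar(seqs), gc_target = gc_target,
                       gc = vapply(seqs, compute_gc, numeric(1),
                                   USE.NAMES = FALSE),
                       stringsAsFactors = FALSE)
    has_ev <- stats::runif(n) < cfg$evidence_fraction
    evidence <- data.frame(
      query_id = ids[has_ev],
      database = ifelse(origin[has_ev] == "host",
                        "coral_reference", "symbiont_reference"),
      subject_id = sprintf("ref_%05d", which(has_ev)),
      score = round(stats::runif(sum(has_ev), 100, 800), 1),
      e_value = 10^-stats::runif(sum(has_ev), 10, 60),
      reciprocal = FALSE,
      stringsAsFactors = FALSE)
    list(sequences = seqs, info = info, evidence = evidence,
         truth = list(transcript_origin = stats::setNames(origin, ids)))
  })
}

# One transcript: ATG + `ncodons` interior codons + TAA, with exactly
# round(gc * length) G+C bases and no internal in-frame stop codon.
# Stops are removed by composition-preserving base swaps (A <-> T).
orf_sequence <- function(ncodons, gc) {
  L <- 3L * ncodons
  total <- L + 6L
  gc_int <- round(gc * total) - 1L        # ATG contributes one G
  gc_int <- max(0L, min(L, gc_int))
  base <- character(L)
  gc_pos <- sample.int(L, gc_int)
  base[gc_pos] <- sample(c("G", "C"), gc_int, replace = TRUE)
  at_pos <- setdiff(seq_len(L), gc_pos)
  base[at_pos] <- sample(c("A", "T"), length(at_pos), replace = TRUE)
  starts <- seq(1L, L, by = 3L)
  for (iter in 1:100) {
    cod <- paste0(base[starts], base[starts + 1L], base[starts + 2L])
    bad <- which(cod %in% c("TAA", "TAG", "TGA"))
    if (!length(bad)) break
    for (b in bad) {
      s <- starts[b]
      # position of the swappable A within the codon
      a_off <- if (base[s + 2L] == "A") 2L else 1L
      a_pos <- s + a_off
      t_pos <- which(base == "T")
      t_pos <- setdiff(t_pos, s:(s + 2L))
      if (length(t_pos)) {
        j <- t_pos[sample.int(length(t_pos), 1L)]
        base[j] <- "A"
        base[a_pos] <- "T"
      } else {
        # no T available anywhere: swap the codon's leading T with an A
        a_other <- setdiff(which(base == "A"), s:(s + 2L))
        j <- a_other[sample.int(length(a_other), 1L)]
        base[j] <- "T"
        base[s] <- "A"
      }
    }
  }
  paste0("ATG", paste(base, collapse = ""), "TAA")
}

#' Write transcripts to a FASTA file
#'
#' @param sequences Named character vector of nucleotide sequences.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}
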