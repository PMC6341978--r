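#' Search an assembly for ITS2-like marker transcripts
#'
#' Seeded ungapped local alignment: shared k-mers (default k = 11) between
#' the query and each transcript, on both strands, are extended along the
#' diagonal with an X-drop rule under +1/-1 match/mismatch scoring. The
#' best score per transcript/query/strand is converted to a Karlin-Altschul
#' style e-value, E = K m n exp(-lambda S), with ungapped parameters for
#' +1/-1 scoring on uniform base composition (lambda = ln 3, K ~= 0.33);
#' only hits with e-value below `e_cutoff` are reported.
#'
#' @param assembly Named character vector of transcript sequences.
#' @param queries Named character vector of marker query sequences.
#' @param e_cutoff Maximum e-value (default 1e-3).
#' @param k Seed length (default 11).
#' @param xdrop Score drop at which the extension stops (default 10).
#' @return data.frame: transcript_id, query_id, strand, score, e_value.
#' @export
search_markers <- function(assembly, queries, e_cutoff = 1e-3, k = 11L,
                           xdrop = 10) {
  if (!length(queries)) stop("queries must be non-empty")
  if (!length(assembly))
    return(data.frame(transcript_id = character(), query_id = character(),
                      strand = character(), score = numeric(),
                      e_value = numeric(), stringsAsFactors = FALSE))
  lambda <- log(3)
  K <- 0.333
  rows <- list()
  for (qi in seq_along(queries)) {
    qname <- names(queries)[qi]
    for (strand in c("+", "-")) {
      q <- if (strand == "+") queries[[qi]] else revcomp(queries[[qi]])
      qk <- kmer_index(q, k)
      for (ti in seq_along(assembly)) {
        s <- best_seeded_score(assembly[[ti]], q, qk, k, xdrop)
        if (s <= 0) next
        e <- K * nchar(q) * nchar(assembly[[ti]]) * exp(-lambda * s)
        if (e < e_cutoff)
          rows[[length(rows) + 1L]] <-
            data.frame(transcript_id = names(assembly)[ti],
                       query_id = qname, strand = strand,
                       score = s, e_value = e, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(transcript_id = character(), query_id = character(),
                      strand = character(), score = numeric(),
                      e_value = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  # keep the best strand per transcript/query
  o <- order(out$transcript_id, out$query_id, -out$score)
  out <- out[o, , drop = FALSE]
  out[!duplicated(out[, c("transcript_id", "query_id")]), , drop = FALSE]
}

kmer_index <- function(q, k) {
  n <- nchar(q)
  if (n < k) return(list())
  starts <- seq_len(n - k + 1L)
  kms <- substring(q, starts, starts + k - 1L)
  split(starts, kms)
}

best_seeded_score <- function(target, query, qk, k, xdrop) {
  n <- nchar(target)
  if (n < k) return(0)
  starts <- seq_len(n - k + 1L)
  tkm <- substring(target, starts, starts + k - 1L)
  hits <- which(tkm %in% names(qk))
  if (!length(hits)) return(0)
  tb <- strsplit(target, "")[[1]]
  qb <- strsplit(query, "")[[1]]
  best <- 0
  seen_diag <- integer(0)
  for (tpos in hits) {
    for (qpos in qk[[tkm[tpos]]]) {
      diag <- tpos - qpos
      if (diag %in% seen_diag) next
      seen_diag <- c(seen_diag, diag)
      best <- max(best, extend_diagonal(tb, qb, tpos, qpos, k, xdrop))
    }
  }
  best
}

extend_diagonal <- function(tb, qb, tpos, qpos, k, xdrop) {
  score <- k
  # extend right
  i <- tpos + k; j <- qpos + k
  cur <- score; mx <- score
  while (i <= length(tb) && j <= length(qb)) {
    cur <- cur + if (tb[i] == qb[j]) 1 else -1
    if (cur > mx) mx <- cur
    if (mx - cur > xdrop) break
    i <- i + 1L; j <- j + 1L
  }
  score <- mx
  # extend left
  i <- tpos - 1L; j <- qpos - 1L
  cur <- score; mx <- score
  while (i >= 1L && j >= 1L) {
    cur <- cur + if (tb[i] == qb[j]) 1 else -1
    if (cur > mx) mx <- cur
    if (mx - cur > xdrop) break
    i <- i - 1L; j <- j - 1L
  }
  mx
}

#' Filter a BLAST tabular file to marker hits
#'
#' The alternative input path for marker discovery: reads an outfmt-6 table
#' and applies the same e-value cutoff as [search_markers()].
#'
#' @param path BLAST outfmt-6 file.
#' @param e_cutoff Maximum e-value (default 1e-3).
#' @return data.frame with transcript_id (qseqid), query_id (sseqid),
#'   score, e_value.
#' @export
search_markers_blast6 <- function(path, e_cutoff = 1e-3) {
  tab <- read_blast6(path)
  tab <- tab[tab$evalue < e_cutoff, , drop = FALSE]
  data.frame(transcript_id = tab$qseqid, query_id = tab$sseqid,
             score = tab$bitscore, e_value = tab$evalue,
             stringsAsFactors = FALSE)
}

#' Assign a marker transcript to its nearest type
#'
#' Global-alignment percent identity against every panel member; the best
#' label is returned, with all tied labels reported on an exact tie.
#'
#' @param sequence Marker transcript sequence.
#' @param panel Named character vector of type sequences.
#' @return List with `labels` (character, usually length 1) and `identity`.
#' @export
assign_type <- function(sequence, panel) {
  if (!length(panel)) stop("empty type panel")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(panel),
    Biostrings::DNAString(sequence), type = "global")
  ident <- Biostrings::pid(aln, type = "PID1") / 100
  best <- max(ident)
  list(labels = names(panel)[ident >= best - 1e-9], identity = best)
}

#' Align read pairs against the joint reference set
#'
#' Each mate is aligned semi-globally (read global, reference local)
#' against every reference in both orientations with +1/-1 scoring and
#' heavy gap penalties; a mate maps when its best score implies an edit
#' distance of at most `max_edit_frac` of its length. The pair-combined
#' score per reference is the sum of its mapped mates' scores (one-mate
#' alignments allowed).
#'
#' @param r1,r2 Character vectors of mate sequences (same length).
#' @param refs Named character vector of reference sequences.
#' @param max_edit_frac Maximum edit fraction for a mate to count as mapped
#'   (default 0.1).
#' @return List: `alignments` (data.frame pair_id, ref_id, score, n_mates,
#'   mismatch — only pairs with at least one mapped mate appear, one row
#'   per reference they map to) and `n_pairs`.
#' @export
map_read_pairs <- function(r1, r2, refs, max_edit_frac = 0.1) {
  stopifnot(length(r1) == length(r2))
  n <- length(r1)
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 1, mismatch = -1, baseOnly = FALSE)
  pa <- function(p, subj) Biostrings::pairwiseAlignment(
    p, subj, type = "global-local", substitutionMatrix = submat,
    gapOpening = 4, gapExtension = 2, scoreOnly = TRUE)
  # first orientation for all mates; the opposite orientation is only
  # evaluated for mates that fail to map in the first - once a mate maps,
  # its reverse complement cannot align better under substitution-only
  # errors, so the maximum over orientations is preserved
  score_vs <- function(reads, ref, first_rc = FALSE) {
    subj <- Biostrings::DNAString(ref)
    p1 <- Biostrings::DNAStringSet(reads)
    if (first_rc) p1 <- Biostrings::reverseComplement(p1)
    s <- pa(p1, subj)
    thr <- nchar(reads) * (1 - 2 * max_edit_frac)
    retry <- which(s < thr)
    if (length(retry)) {
      p2 <- Biostrings::DNAStringSet(reads[retry])
      if (!first_rc) p2 <- Biostrings::reverseComplement(p2)
      s[retry] <- pmax(s[retry], pa(p2, subj))
    }
    s
  }
  rows <- list()
  for (ref_id in names(refs)) {
    s1 <- score_vs(r1, refs[[ref_id]])
    s2 <- score_vs(r2, refs[[ref_id]], first_rc = TRUE)
    len1 <- nchar(r1); len2 <- nchar(r2)
    ok1 <- s1 >= len1 * (1 - 2 * max_edit_frac)
    ok2 <- s2 >= len2 * (1 - 2 * max_edit_frac)
    any_ok <- ok1 | ok2
    if (!any(any_ok)) next
    score <- ifelse(ok1, s1, 0) + ifelse(ok2, s2, 0)
    mm <- ifelse(ok1, (len1 - s1) / 2, 0) + ifelse(ok2, (len2 - s2) / 2, 0)
    rows[[ref_id]] <- data.frame(
      pair_id = which(any_ok), ref_id = ref_id,
      score = score[any_ok], n_mates = (ok1 + ok2)[any_ok],
      mismatch = mm[any_ok], stringsAsFactors = FALSE)
  }
  alignments <- if (length(rows)) do.call(rbind, rows)
    else data.frame(pair_id = integer(), ref_id = character(),
                    score = numeric(), n_mates = integer(),
                    mismatch = numeric(), stringsAsFactors = FALSE)
  rownames(alignments) <- NULL
  list(alignments = alignments, n_pairs = n)
}

#' Count uniquely mapped read pairs per reference
#'
#' A read pair contributes one count to a reference iff its pair-combined
#' alignment score to that reference strictly exceeds its best score to
#' every other reference; a pair tied between references contributes
#' nothing. Each pair is counted once, whether both mates or only one mate
#' aligned.
#'
#' @param alignments data.frame with columns pair_id, ref_id, score (as
#'   produced by [map_read_pairs()]).
#' @param references Character vector of all reference ids (the joint
#'   target set; zero counts are reported for references with no reads).
#' @return Named integer vector of unique-pair counts per reference.
#' @export
count_unique_mappings <- function(alignments, references) {
  counts <- stats::setNames(integer(length(references)), references)
  if (!nrow(alignments)) return(counts)
  if (!all(c("pair_id", "ref_id", "score") %in% names(alignments)))
    stop("malformed alignment record: need pair_id, ref_id, score")
  best <- stats::aggregate(score ~ pair_id, alignments, max)
  m <- merge(alignments, best, by = "pair_id",
             suffixes = c("", "_best"))
  at_best <- m[m$score == m$score_best, , drop = FALSE]
  n_best <- table(at_best$pair_id)
  unique_pairs <- as.integer(names(n_best)[n_best == 1])
  u <- at_best[at_best$pair_id %in% unique_pairs, , drop = FALSE]
  tab <- table(u$ref_id)
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' Per-sample clade composition from unique read counts
#'
#' Proportions are clade totals over the grand total of uniquely mapped
#' pairs. The dominant clade carries the maximum proportion; a sample is a
#' mixed outlier when at least two clades each reach `mixed_threshold`.
#' With zero total the proportions are undefined and the sample is flagged
#' as having no ITS2 signal.
#'
#' @param unique_counts Named counts per reference
#'   (from [count_unique_mappings()]).
#' @param clade_of Named clade label per reference id.
#' @param sample_id Sample label (default "sample").
#' @param mixed_threshold Secondary-clade proportion that flags a mixed
#'   sample (default 0.25).
#' @return List of class `clade_composition`: sample_id, unique_counts,
#'   proportions (per clade), dominant_clade, mixed_outlier, no_signal.
#' @export
composition <- function(unique_counts, clade_of, sample_id = "sample",
                        mixed_threshold = 0.25) {
  missing_clade <- setdiff(names(unique_counts), names(clade_of))
  if (length(missing_clade))
    stop("reference(s) without clade assignment: ",
         paste(missing_clade, collapse = ", "))
  clades <- sort(unique(clade_of[names(unique_counts)]))
  by_clade <- vapply(clades, function(cl)
    sum(unique_counts[clade_of[names(unique_counts)] == cl]), numeric(1))
  total <- sum(by_clade)
  if (total == 0) {
    return(structure(list(sample_id = sample_id,
                          unique_counts = unique_counts,
                          proportions = stats::setNames(
                            rep(NA_real_, length(clades)), clades),
                          dominant_clade = NA_character_,
                          mixed_outlier = FALSE, no_signal = TRUE),
                     class = "clade_composition"))
  }
  prop <- by_clade / total
  structure(list(sample_id = sample_id, unique_counts = unique_counts,
                 proportions = prop,
                 dominant_clade = names(prop)[which.max(prop)],
                 mixed_outlier = sum(prop >= mixed_threshold) >= 2L,
                 no_signal = FALSE),
            class = "clade_composition")
}

#' @export
print.clade_composition <- function(x, ...) {
  if (x$no_signal) {
    cat(sprintf("%s: no ITS2 signal\n", x$sample_id))
  } else {
    cat(sprintf("%s: %s, dominant %s%s\n", x$sample_id,
                paste(sprintf("%s=%.2f", names(x$proportions),
                              x$proportions), collapse = " "),
                x$dominant_clade,
                if (x$mixed_outlier) " [mixed outlier]" else ""))
  }
  invisible(x)
}

#' Mismatch profile of mapped reads
#'
#' Fraction of mapped units (read pairs by default) carrying at least one
#' mismatch against their reference, and the histogram of mismatch counts.
#'
#' @param mismatch Numeric vector of per-unit mismatch counts (e.g. the
#'   `mismatch` column of [map_read_pairs()] alignments restricted to one
#'   reference).
#' @return List with mismatch_fraction and histogram (table of counts).
#' @export
mismatch_profile <- function(mismatch) {
  if (!length(mismatch))
    return(list(mismatch_fraction = NA_real_, histogram = table(integer())))
  if (anyNA(mismatch)) stop("missing mismatch counts")
  list(mismatch_fraction = mean(mismatch >= 1),
       histogram = table(mismatch))
}
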