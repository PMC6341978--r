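#' Synthetic ITS2 reference pair and type panel
#'
#' Builds a synthetic clade-C reference, a clade-D reference derived from it
#' by random substitutions at the given divergence, and a panel of type
#' sequences per clade (each a light variant of its clade reference). The
#' C31 and D1a panel entries are identical to the respective references.
#' These sequences are synthetic stand-ins for the marker panel; they mimic
#' only its lengths and divergence structure.
#'
#' @param seed Seed for the panel stream.
#' @param length Reference length in bases (default 400).
#' @param divergence Fraction of substituted sites between clades
#'   (default 0.15).
#' @param within_divergence Substitution fraction between types within a
#'   clade (default 0.02).
#' @return List with refC, refD (character), panel (named character vector,
#'   names like "C31", "D1a"), clade_of (named clade per panel entry).
#' @export
make_its2_references <- function(seed = 2203L, length = 400L,
                                 divergence = 0.15,
                                 within_divergence = 0.02) {
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    refC <- paste(sample(bases, length, replace = TRUE), collapse = "")
    mutate <- function(s, frac) {
      b <- strsplit(s, "")[[1]]
      idx <- sample.int(length(b), round(frac * length(b)))
      b[idx] <- vapply(b[idx],
                       function(x) sample(setdiff(bases, x), 1L), "")
      paste(b, collapse = "")
    }
    refD <- mutate(refC, divergence)
    c_types <- c("C31", "C1", "C3", "C15", "C17", "C21")
    d_types <- c("D1a", "D8", "D12", "D13", "D15")
    panel <- c(
      stats::setNames(c(refC, vapply(c_types[-1], function(t)
        mutate(refC, within_divergence), "")), c_types),
      stats::setNames(c(refD, vapply(d_types[-1], function(t)
        mutate(refD, within_divergence), "")), d_types))
    clade_of <- stats::setNames(substr(names(panel), 1L, 1L), names(panel))
    list(refC = refC, refD = refD, panel = panel, clade_of = clade_of)
  })
}

#' Generate paired ITS2 reads at known clade mixtures
#'
#' For each sample, `cfg$n_its2_reads` read pairs are drawn: each pair
#' originates from the clade-D reference with the sample's mixture
#' probability, otherwise from clade C. A fragment is placed uniformly on
#' the source, the two mates are its ends (reverse-complemented second
#' mate), and uniform substitution errors are applied at `cfg$error_rate`.
#'
#' @param cfg A [simulation_config()]; `cfg$clade_mixtures` gives the
#'   per-sample clade-D proportion (recycled; default pattern
#'   0, 0.12, 0.33, 0.67, 0.91, 1).
#' @param refC,refD Reference sequences, each at least `2 * read_length`
#'   long.
#' @return List with `samples` (list per sample: r1, r2 character vectors,
#'   origin "C"/"D", true_mixture) and `truth$true_mixtures`.
#' @export
gen_its2_reads <- function(cfg, refC, refD) {
  validate_sim_config(cfg)
  rl <- cfg$read_length
  if (nchar(refC) < 2 * rl || nchar(refD) < 2 * rl)
    stop("reference shorter than the fragment length")
  mixtures <- rep_len(cfg$clade_mixtures %||%
                        c(0, 0.12, 0.33, 0.67, 0.91, 1),
                      cfg$n_samples)
  with_seed(stream_seed(cfg, "its2"), {
    samples <- lapply(seq_len(cfg$n_samples), function(s) {
      m <- mixtures[s]
      n <- cfg$n_its2_reads
      origin <- ifelse(stats::runif(n) < m, "D", "C")
      src <- ifelse(origin == "D", refD, refC)
      src_len <- nchar(src)
      frag <- pmin(src_len,
                   sample(seq(2L * rl, 2L * rl + 100L), n, replace = TRUE))
      start <- vapply(src_len - frag + 1L,
                      function(mx) sample.int(mx, 1L), integer(1))
      fragment <- substr(src, start, start + frag - 1L)
      r1 <- substr(fragment, 1L, rl)
      r2 <- revcomp(substr(fragment, frag - rl + 1L, frag))
      list(r1 = add_substitutions(r1, cfg$error_rate),
           r2 = add_substitutions(r2, cfg$error_rate),
           origin = origin, true_mixture = m)
    })
    names(samples) <- sprintf("s%02d", seq_len(cfg$n_samples))
    list(samples = samples, truth = list(true_mixtures = mixtures))
  })
}

# Uniform substitution errors on a character vector of equal-length reads.
add_substitutions <- function(reads, rate) {
  if (rate <= 0) return(reads)
  bases <- c("A", "C", "G", "T")
  mat <- do.call(rbind, strsplit(reads, ""))
  hit <- which(matrix(stats::runif(length(mat)) < rate, nrow(mat)))
  if (length(hit)) {
    mat[hit] <- vapply(mat[hit],
                       function(x) sample(setdiff(bases, x), 1L), "")
  }
  apply(mat, 1L, paste, collapse = "")
}

#' Write paired reads as two FASTQ files (Phred+33)
#'
#' @param r1,r2 Character vectors of mate sequences.
#' @param prefix Output prefix; files are `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq`.
#' @param qual_char Constant quality character (default "I", Q40).
#' @return Character vector of the two paths, invisibly.
#' @export
write_fastq_pairs <- function(r1, r2, prefix, qual_char = "I") {
  paths <- paste0(prefix, c("_1.fastq", "_2.fastq"))
  for (i in 1:2) {
    reads <- list(r1, r2)[[i]]
    qual <- strrep(qual_char, nchar(reads))
    lines <- as.vector(rbind(sprintf("@pair%06d/%d", seq_along(reads), i),
                             reads, "+", qual))
    writeLines(lines, paths[i])
  }
  invisible(paths)
}

#' Read a FASTQ file as a named character vector
#'
#' @param path FASTQ file.
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- readLines(path)
  ids <- sub("^@", "", x[seq(1, length(x), by = 4)])
  stats::setNames(x[seq(2, length(x), by = 4)], sub("\\s.*$", "", ids))
}
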