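#' Parse a pfam2go flat mapping file
#'
#' Lines have the form
#' `Pfam:PF00001 7tm_1 > GO:G protein-coupled receptor activity ; GO:0004930`.
#' Comment lines starting with `!` are skipped; malformed lines produce a
#' warning and are skipped, never an error. A domain may map to several GO
#' terms (one line each).
#'
#' @param path File path, or a character vector of lines via `lines`.
#' @param lines Optional character vector (overrides `path`).
#' @return data.frame with columns pfam, pfam_name, go_name, go_id.
#' @export
parse_pfam2go <- function(path = NULL, lines = NULL) {
  if (is.null(lines)) lines <- readLines(path)
  lines <- lines[!startsWith(lines, "!")]
  lines <- lines[nzchar(trimws(lines))]
  pat <- "^Pfam:(PF\\d+)\\s+(\\S+)\\s+>\\s+GO:(.*?)\\s+;\\s+(GO:\\d+)\\s*$"
  ok <- grepl(pat, lines)
  if (any(!ok))
    warning(sum(!ok), " malformed pfam2go line(s) skipped")
  m <- regmatches(lines[ok], regexec(pat, lines[ok]))
  data.frame(pfam = vapply(m, `[`, "", 2),
             pfam_name = vapply(m, `[`, "", 3),
             go_name = vapply(m, `[`, "", 4),
             go_id = vapply(m, `[`, "", 5),
             stringsAsFactors = FALSE)
}

#' Transfer GO terms to genes via Pfam domain assignments
#'
#' @param gene_domains data.frame with columns gene, pfam.
#' @param pfam2go Parsed mapping from [parse_pfam2go()].
#' @return data.frame with columns gene, go_id, go_name (unique pairs).
#' @export
annotate_genes_go <- function(gene_domains, pfam2go) {
  m <- merge(gene_domains, pfam2go, by = "pfam")
  unique(m[, c("gene", "go_id", "go_name")])
}

#' Hypergeometric overrepresentation test for GO terms
#'
#' For every term, counts the overlap between the test set and the term's
#' annotated genes within the universe, and computes the upper-tail
#' hypergeometric probability P(X >= count) (count included) together with
#' the odds ratio of the implied 2x2 table. Zero-cell convention: a zero
#' denominator cell yields an infinite odds ratio; 0/0 yields NaN.
#'
#' @param test_set Character vector of gene ids (must be within universe).
#' @param annotations data.frame with columns gene, go_id (and optionally
#'   go_name).
#' @param universe Character vector of background gene ids.
#' @return data.frame: go_id, go_name, count, size, expected, odds_ratio, p;
#'   ordered by p.
#' @export
hypergeom_enrich <- function(test_set, annotations, universe) {
  if (!length(universe)) stop("empty universe")
  if (!all(test_set %in% universe))
    stop("test set must be a subset of the universe")
  annotations <- annotations[annotations$gene %in% universe, , drop = FALSE]
  N <- length(unique(universe))
  n <- length(unique(test_set))
  terms <- split(annotations$gene, annotations$go_id)
  name_of <- if ("go_name" %in% names(annotations))
    tapply(annotations$go_name, annotations$go_id, `[`, 1)
  else NULL
  rows <- lapply(names(terms), function(tid) {
    genes <- unique(terms[[tid]])
    K <- length(genes)
    x <- length(intersect(genes, test_set))
    p <- stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
    num <- x / (n - x)
    den <- (K - x) / (N - K - n + x)
    oratio <- if (is.nan(num / den)) NaN
              else if (den == 0) Inf else num / den
    data.frame(go_id = tid,
               go_name = if (!is.null(name_of)) name_of[[tid]] else NA,
               count = x, size = K, expected = n * K / N,
               odds_ratio = oratio, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p, -out$count), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply the reporting filters to enrichment results
#'
#' Keeps terms with p below `alpha` and a count of at least
#' `ceiling(min_fraction * test_size)` genes.
#'
#' @param stats Result of [hypergeom_enrich()].
#' @param test_size Size of the test set.
#' @param alpha p-value threshold (default 0.05, strict).
#' @param min_fraction Minimum represented fraction of the test set
#'   (default 0.02).
#' @return Filtered data.frame.
#' @export
filter_terms <- function(stats, test_size, alpha = 0.05,
                         min_fraction = 0.02) {
  min_count <- ceiling(min_fraction * test_size)
  stats[stats$p < alpha & stats$count >= min_count, , drop = FALSE]
}
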