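#' Sample metadata of the Montipora capitata study
#'
#' The 27 tissue samples from 18 colonies at two Hawai'i Island sites
#' (Wai'opae, Kiholo), with dominant Symbiodinium clade from ITS2 read
#' abundance and Growth Anomaly (GA) disease status. Five samples carried a
#' mixed clade composition; their estimated clade proportions are included.
#' Colony ids pair the affected/unaffected samples taken from the same
#' diseased colony.
#'
#' @return data.frame: sample_id, colony_id, site, clade (dominant),
#'   prop_C, prop_D, ga_status.
#' @export
montipora_samples <- function() {
  txt <- "sample_id colony_id site clade prop_C prop_D ga_status
KH1 K_h1 kiholo D 0 1 healthy
KH2 K_h2 kiholo D 0 1 healthy
KH8 K_h8 kiholo D 0 1 healthy
KU2 K_2 kiholo C 1 0 ga_unaffected
KU3 K_3 kiholo D 0 1 ga_unaffected
KU5 K_5 kiholo D 0 1 ga_unaffected
KA2 K_2 kiholo C 1 0 ga_affected
KA3 K_3 kiholo D 0 1 ga_affected
KA5 K_5 kiholo D 0 1 ga_affected
WH1 W_h1 waiopae C 1 0 healthy
WH2 W_h2 waiopae D 0 1 healthy
WH3 W_h3 waiopae C 1 0 healthy
WH5 W_h5 waiopae D 0 1 healthy
WH8 W_h8 waiopae D 0.33 0.67 healthy
WH12 W_h12 waiopae D 0 1 healthy
WU1 W_1 waiopae C 1 0 ga_unaffected
WU2 W_2 waiopae C 1 0 ga_unaffected
WU3 W_3 waiopae D 0 1 ga_unaffected
WU5 W_5 waiopae C 1 0 ga_unaffected
WU8 W_8 waiopae C 1 0 ga_unaffected
WU12 W_12 waiopae D 0.09 0.91 ga_unaffected
WA1 W_1 waiopae C 0.88 0.12 ga_affected
WA2 W_2 waiopae C 1 0 ga_affected
WA3 W_3 waiopae D 0.13 0.87 ga_affected
WA5 W_5 waiopae C 1 0 ga_affected
WA8 W_8 waiopae C 1 0 ga_affected
WA12 W_12 waiopae D 0.38 0.62 ga_affected"
  utils::read.table(text = txt, header = TRUE, stringsAsFactors = FALSE)
}

#' Colony-level clade contingency tables
#'
#' Collapses sample metadata to one record per colony (for diseased
#' colonies the unaffected tissue's dominant clade represents the colony)
#' and builds the 2x2 tables of site by clade and disease status by clade
#' used for the chi-square association tests.
#'
#' @param metadata Sample metadata in the format of [montipora_samples()].
#' @return List with `site_by_clade` and `ga_by_clade` 2x2 matrices
#'   (rows: site / health status, columns: clade C, D).
#' @export
colony_clade_tables <- function(metadata = montipora_samples()) {
  md <- metadata
  md$diseased <- md$ga_status != "healthy"
  # one row per colony; prefer the unaffected tissue for diseased colonies
  pref <- order(md$colony_id,
                match(md$ga_status, c("healthy", "ga_unaffected",
                                      "ga_affected")))
  md <- md[pref, , drop = FALSE]
  col <- md[!duplicated(md$colony_id), , drop = FALSE]
  site_by_clade <- rbind(
    waiopae = table(factor(col$clade[col$site == "waiopae"],
                           levels = c("C", "D"))),
    kiholo = table(factor(col$clade[col$site == "kiholo"],
                          levels = c("C", "D"))))
  ga_by_clade <- rbind(
    healthy = table(factor(col$clade[!col$diseased], levels = c("C", "D"))),
    diseased = table(factor(col$clade[col$diseased], levels = c("C", "D"))))
  list(site_by_clade = site_by_clade, ga_by_clade = ga_by_clade)
}

#' Build the analysis dataset specifications
#'
#' Derives the sample subsets used across the expression analyses:
#' \describe{
#'   \item{all}{every sample}
#'   \item{default}{all samples minus mixed-clade outliers (secondary clade
#'     proportion at or above `mixed_threshold`) and the explicit
#'     `clustering_outliers` list}
#'   \item{waiopae}{default restricted to the Wai'opae site}
#'   \item{hu}{default restricted to healthy and GA-unaffected tissue}
#' }
#' Clustering-based exclusions are config input, never computed silently.
#'
#' @param metadata Sample metadata (needs sample_id, site, ga_status, and
#'   prop_C/prop_D or a `compositions` list).
#' @param compositions Optional named list of `clade_composition` objects
#'   overriding the proportions in `metadata`.
#' @param clustering_outliers Character vector of sample ids excluded after
#'   expression clustering review (default "WA8" for the study metadata).
#' @param mixed_threshold Secondary-clade outlier threshold (default 0.25).
#' @return Named list of dataset specs; each has `name`, `samples`,
#'   `excluded` (with reasons).
#' @export
build_datasets <- function(metadata = montipora_samples(),
                           compositions = NULL,
                           clustering_outliers = "WA8",
                           mixed_threshold = 0.25) {
  unknown <- setdiff(clustering_outliers, metadata$sample_id)
  if (length(unknown))
    stop("unknown sample(s) in exclusion list: ",
         paste(unknown, collapse = ", "))
  if (!is.null(compositions)) {
    secondary <- vapply(metadata$sample_id, function(s) {
      cc <- compositions[[s]]
      if (is.null(cc) || cc$no_signal) return(0)
      sort(cc$proportions, decreasing = TRUE)[2] %||% 0
    }, numeric(1))
    secondary[is.na(secondary)] <- 0
  } else {
    secondary <- pmin(metadata$prop_C, metadata$prop_D)
  }
  mixed <- metadata$sample_id[secondary >= mixed_threshold]
  excl_default <- data.frame(
    sample_id = c(mixed, setdiff(clustering_outliers, mixed)),
    reason = c(rep("mixed_clade", length(mixed)),
               rep("clustering_outlier",
                   length(setdiff(clustering_outliers, mixed)))),
    stringsAsFactors = FALSE)
  default_ids <- setdiff(metadata$sample_id, excl_default$sample_id)
  spec <- function(name, ids, excluded) {
    list(name = name, samples = ids, excluded = excluded)
  }
  list(
    all = spec("all", metadata$sample_id,
               excl_default[0, , drop = FALSE]),
    default = spec("default", default_ids, excl_default),
    waiopae = spec("waiopae",
                   intersect(default_ids,
                             metadata$sample_id[metadata$site == "waiopae"]),
                   excl_default),
    hu = spec("hu",
              intersect(default_ids,
                        metadata$sample_id[metadata$ga_status !=
                                             "ga_affected"]),
              excl_default))
}

#' Percentage of host transcripts called differentially expressed
#'
#' `100 * n_deg / n_host`, rounded to one decimal as reported.
#'
#' @param n_deg Number of DEGs.
#' @param n_host Number of host transcripts.
#' @return Percentage rounded to one decimal.
#' @export
deg_percentage <- function(n_deg, n_host) {
  round(100 * n_deg / n_host, 1)
}
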