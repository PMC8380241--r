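#' @useDynLib mnflow, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rbinom rmultinom sd median quantile
#'   shapiro.test bartlett.test optim uniroot qchisq pchisq pnorm qnorm qf
#'   ave integrate aggregate complete.cases setNames
#' @importFrom utils read.csv write.csv modifyList head tail
"_PACKAGE"

#' The nine-class CBMN phenotype taxonomy
#'
#' Scoring classes of the cytokinesis-block micronucleus assay: mono-, bi-,
#' tri- and tetranucleated cells, each with or without micronuclei (MN), plus
#' a catch-all class for other/unscorable events (debris, doublets,
#' out-of-focus, mitotic and dead cells). The integer encoding 0-8 in this
#' order is stable and used throughout the package (e.g. in network label
#' encodings and CSV manifests).
#'
#' @format Character vector of length 9.
#' @export
PHENOTYPE_CLASSES <- c(
  "mononucleate", "mononucleate_mn",
  "binucleate",   "binucleate_mn",
  "trinucleate",  "trinucleate_mn",
  "tetranucleate", "tetranucleate_mn",
  "other"
)

#' The four classes central to CBMN scoring
#' @format Character vector of length 4.
#' @export
CORE_CLASSES <- c("mononucleate", "mononucleate_mn",
                  "binucleate", "binucleate_mn")

.UNSCORABLE_KINDS <- c("debris", "doublet", "out_of_focus", "mitotic", "dead")

#' Validate phenotype labels
#'
#' @param labels character vector of candidate class labels.
#' @param taxonomy allowed labels (default the nine-class taxonomy).
#' @return `labels`, invisibly, as a factor over `taxonomy`.
#' @keywords internal
assert_phenotype <- function(labels, taxonomy = PHENOTYPE_CLASSES) {
  bad <- which(!(labels %in% taxonomy))
  if (length(bad) > 0L) {
    stop("unknown phenotype label(s) at position(s) ",
         paste(head(bad, 5L), collapse = ", "), ": '",
         paste(unique(labels[bad])[seq_len(min(3, length(unique(labels[bad]))))],
               collapse = "', '"), "'", call. = FALSE)
  }
  invisible(factor(labels, levels = taxonomy))
}

#' Phenotype implied by nucleus and micronucleus counts
#'
#' @param n_nuclei integer 1-4.
#' @param has_mn logical, any micronucleus present.
#' @return a label from [PHENOTYPE_CLASSES].
#' @export
phenotype_from_counts <- function(n_nuclei, has_mn) {
  stopifnot(n_nuclei >= 1, n_nuclei <= 4)
  base <- c("mononucleate", "binucleate", "trinucleate", "tetranucleate")[n_nuclei]
  ifelse(has_mn, paste0(base, "_mn"), base)
}

#' Merge tri- and tetranucleated classes into a single polynucleated class
#'
#' Collapses `trinucleate`, `trinucleate_mn`, `tetranucleate` and
#' `tetranucleate_mn` into one `polynucleated` label, producing the reduced
#' six-class taxonomy used to probe whether class reduction helps with the
#' rare multinucleated phenotypes. All other labels pass through unchanged;
#' the mapping is idempotent.
#'
#' @param labels character vector of nine-class (or already merged) labels.
#' @return character vector over the reduced taxonomy.
#' @export
merge_polynucleated <- function(labels) {
  merged_tax <- c(PHENOTYPE_CLASSES[1:4], "polynucleated", "other")
  assert_phenotype(labels, taxonomy = c(PHENOTYPE_CLASSES, "polynucleated"))
  poly <- c("trinucleate", "trinucleate_mn", "tetranucleate", "tetranucleate_mn")
  out <- ifelse(labels %in% poly, "polynucleated", labels)
  attr(out, "taxonomy") <- merged_tax
  out
}
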