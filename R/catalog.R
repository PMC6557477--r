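#' Load the catalog of dysregulated target RNAs
#'
#' The package ships a transcribed catalog of the 62 sperm RNAs
#' dysregulated across the strain-by-exposure conditions, one row per
#' gene: the expression pattern it belongs to (DEHP-resistance,
#' DEHP-susceptibility or generational), the tissue annotation, the
#' microarray expression triple across germ-cell stages (spermatogonia,
#' spermatocytes, spermatids), the printed increasing-in-spermatogenesis
#' label, the verbatim hormonal-regulation annotation and the hormone
#' class mapped from it (androgen, glucocorticoid, ppar, t3, estrogen or
#' none). Descriptive regulator annotations map to the hormone they
#' regulate (e.g. "Androgen regulator", "Testosterone hydroxylation" to
#' androgen); annotations naming no specific hormone map to none.
#'
#' @param path Path to a catalog TSV; defaults to the shipped fixture.
#' @return Data.frame of 62 target annotations.
#' @export
read_target_catalog <- function(path = system.file("extdata",
                                                   "dysregulated_targets.tsv",
                                                   package = "strainMotif")) {
  cat <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = "NA", check.names = FALSE)
  need <- c("gene", "pattern", "tissue", "spermatogonia", "spermatocytes",
            "spermatids", "trend_label", "hormone_annotation",
            "hormone_class")
  if (!all(need %in% names(cat))) {
    stop("catalog needs columns: ", paste(need, collapse = ", "))
  }
  cat
}

#' Classify the spermatogenesis expression trend of a gene
#'
#' A gene's expression is "increasing in spermatogenesis" when its
#' stage-wise expression increases strictly from spermatogonia through
#' spermatocytes to spermatids. NA if any stage value is missing. The
#' strict inequality is deliberate: stage profiles with a minute
#' spermatocyte-to-spermatid dip are labelled "no".
#'
#' @param spermatogonia,spermatocytes,spermatids Numeric vectors of
#'   stage-wise expression (log2 microarray scale).
#' @return Character vector of \code{"yes"}, \code{"no"} or \code{NA}.
#' @export
#' @examples
#' classify_spermatogenesis_trend(3.89, 4.44, 4.53)  # "yes"
#' classify_spermatogenesis_trend(4.12, 4.57, 4.53)  # "no"
classify_spermatogenesis_trend <- function(spermatogonia, spermatocytes,
                                           spermatids) {
  n <- length(spermatogonia)
  stopifnot(length(spermatocytes) == n, length(spermatids) == n)
  out <- ifelse(spermatogonia < spermatocytes & spermatocytes < spermatids,
                "yes", "no")
  out[is.na(spermatogonia) | is.na(spermatocytes) | is.na(spermatids)] <-
    NA_character_
  out
}

#' Summarise the target catalog
#'
#' Computes the headline tallies of the catalog: total size, number of
#' hormonally regulated targets (hormone class other than none),
#' per-class counts, the androgen-regulated count, and the percentage of
#' classifiable targets with strictly increasing spermatogenesis
#' expression (denominator = rows with complete stage data).
#'
#' @param catalog Data.frame from \code{\link{read_target_catalog}}.
#' @return List \code{(n_total, n_hormonal, n_androgen, class_counts,
#'   percent_increasing, n_yes, n_no, n_na)}.
#' @export
catalog_summaries <- function(catalog) {
  if (anyDuplicated(catalog$gene)) {
    stop("duplicate gene symbols in catalog: ",
         paste(unique(catalog$gene[duplicated(catalog$gene)]),
               collapse = ", "))
  }
  cls <- c(table(factor(catalog$hormone_class,
                        levels = c("androgen", "glucocorticoid", "ppar", "t3",
                                   "estrogen", "none"))))
  trend <- classify_spermatogenesis_trend(catalog$spermatogonia,
                                          catalog$spermatocytes,
                                          catalog$spermatids)
  n_yes <- sum(trend == "yes", na.rm = TRUE)
  n_no <- sum(trend == "no", na.rm = TRUE)
  list(
    n_total = nrow(catalog),
    n_hormonal = nrow(catalog) - unname(cls[["none"]]),
    n_androgen = unname(cls[["androgen"]]),
    class_counts = cls,
    percent_increasing = round(100 * n_yes / (n_yes + n_no)),
    n_yes = n_yes, n_no = n_no, n_na = sum(is.na(trend))
  )
}
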