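## Feature refinement: interclass coefficient-of-variation selection and
## chi-square filter-type selection.

#' Class-conditional feature means
#'
#' Mean of every feature within each stage class.
#'
#' @param se feature-table `SummarizedExperiment` with a `label` column in
#'   `colData`; every stage must be represented.
#' @return numeric matrix, rows = EFS/EF/AA, cols = features.
#' @export
classMeans <- function(se) {
  labs <- se$label
  missing <- setdiff(stageLevels(), unique(labs))
  if (length(missing))
    stop("class(es) with zero rows: ", paste(missing, collapse = ", "))
  feat <- SummarizedExperiment::assay(se, "features")
  out <- vapply(stageLevels(),
                function(s) rowMeans(feat[, labs == s, drop = FALSE]),
                numeric(nrow(feat)))
  t(out)
}

#' Coefficient-of-variation feature selection
#'
#' The interclass refinement rule: for each feature, take the three
#' class-conditional means and compute their coefficient of variation,
#' `CV% = 100 * sd(class means) / mean(class means)` (sample standard
#' deviation over the three means). Features whose CV strictly exceeds the
#' threshold show enough variation between the stages to carry predictive
#' power and are retained.
#'
#' @param se feature-table `SummarizedExperiment`.
#' @param thresholdPct retention threshold in percent (default 8).
#' @return a [SelectionResult-class] with method "CV". A feature whose
#'   grand mean of class means is 0 has an undefined CV; it is assigned
#'   `Inf` and retained, with a warning.
#' @export
#' @examples
#' # three classes with means 90 / 100 / 110 give CV = 10% (retained at 8%)
cvSelect <- function(se, thresholdPct = 8) {
  cm <- classMeans(se)
  grand <- colMeans(cm)
  cv <- 100 * apply(cm, 2, sd) / grand
  undef <- grand == 0
  if (any(undef)) {
    warning("grand mean of class means is 0 for: ",
            paste(colnames(cm)[undef], collapse = ", "),
            "; CV undefined, assigned Inf and retained")
    cv[undef] <- Inf
  }
  retained <- colnames(cm)[cv > thresholdPct]
  new("SelectionResult", method = "CV", retained = retained,
      scores = cv, pValues = setNames(rep(NA_real_, length(cv)), names(cv)),
      thresholdOrK = thresholdPct)
}

#' Chi-square filter-type feature selection (FTF)
#'
#' Ranks every feature by a chi-square test of independence between the
#' discretized feature and the stage label: each feature is cut into
#' `nBins` equal-frequency bins (degenerate bins merged), the chi-square
#' statistic of the bin-by-class contingency table is computed, and
#' features are ranked by ascending p-value (ties broken by descending
#' statistic, then canonical name order). The top `k` become the refined
#' panel. Constant features score 0 and rank last.
#'
#' @param se feature-table `SummarizedExperiment`.
#' @param k number of features to retain (default 15).
#' @param nBins equal-frequency bins for discretization (default 10).
#' @return a [SelectionResult-class] with method "FTF".
#' @export
ftfSelect <- function(se, k = 15L, nBins = 10L) {
  feat <- SummarizedExperiment::assay(se, "features")
  labs <- se$label
  if (length(unique(labs)) < 2L) stop("need at least two classes")
  k <- as.integer(k)
  if (k < 1L || k > nrow(feat)) stop("k must be in 1..", nrow(feat))
  stat <- pval <- setNames(numeric(nrow(feat)), rownames(feat))
  for (f in rownames(feat)) {
    x <- feat[f, ]
    br <- unique(quantile(x, probs = seq(0, 1, length.out = nBins + 1),
                          names = FALSE))
    if (length(br) < 3L) { # constant (or near-constant) feature
      stat[f] <- 0; pval[f] <- 1
      next
    }
    bins <- cut(x, breaks = br, include.lowest = TRUE)
    tab <- table(bins, labs)
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    ct <- suppressWarnings(chisq.test(tab))
    stat[f] <- unname(ct$statistic)
    pval[f] <- if (is.na(ct$p.value)) 1 else ct$p.value
  }
  ord <- order(pval, -stat, match(names(stat), featurePanelNames()))
  retained <- names(stat)[ord][seq_len(k)]
  new("SelectionResult", method = "FTF", retained = retained,
      scores = stat, pValues = pval, thresholdOrK = as.numeric(k))
}

#' Serialize a SelectionResult
#'
#' `writeSelectionJSON` stores method, threshold/k, the retained list and
#' all per-feature scores; `writeSelectionCSV` stores a two-column
#' (feature, score) table.
#'
#' @param sel a [SelectionResult-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSelectionJSON <- function(sel, path) {
  jsonlite::write_json(
    list(method = sel@method, threshold_or_k = sel@thresholdOrK,
         retained = sel@retained, scores = as.list(sel@scores),
         p_values = if (sel@method == "FTF") as.list(sel@pValues) else NULL),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeSelectionJSON
#' @export
writeSelectionCSV <- function(sel, path) {
  write.csv(data.frame(feature = names(sel@scores),
                       score = unname(sel@scores),
                       retained = names(sel@scores) %in% sel@retained),
            path, row.names = FALSE)
  invisible(path)
}
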