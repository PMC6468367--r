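#' Decoy-set confusion counts
#'
#' The four integers of Guener-Henry decoy-set validation: D molecules in
#' the database of which A are known actives; a screen retrieves Ht hits
#' of which Ha are active.
#'
#' @param D,A,Ht,Ha nonnegative integers with `A <= D`, `Ht <= D`,
#'   `Ha <= min(Ht, A)`.
#' @return object of class `decoy_counts`.
#' @export
decoy_counts <- function(D, A, Ht, Ha) {
  v <- c(D = D, A = A, Ht = Ht, Ha = Ha)
  if (any(v < 0) || any(v != round(v)))
    stop("decoy counts must be nonnegative integers")
  if (A > D) stop("A (actives) cannot exceed D (database size)")
  if (Ht > D) stop("Ht (hits) cannot exceed D (database size)")
  if (Ha > min(Ht, A)) stop("Ha cannot exceed min(Ht, A)")
  structure(as.list(stats::setNames(as.integer(v), names(v))),
            class = "decoy_counts")
}

# truncate (not round) x to k decimals; display convention for yield,
# ratio and EF
.trunc_dec <- function(x, k) trunc(x * 10^k) / 10^k

#' Guener-Henry decoy-set statistics
#'
#' From the confusion counts computes the percent yield of actives
#' `100 * Ha / Ht`, percent ratio of actives `100 * Ha / A`, enrichment
#' factor `EF = (Ha * D) / (Ht * A)`, false negatives `A - Ha`, false
#' positives `Ht - Ha`, and the goodness-of-fit score in both published
#' numerator variants:
#' \deqn{GF_{eq} = \frac{Ha\,(3A + Ht)}{4\,Ht\,A}
#'       \left(1 - \frac{Ht - Ha}{D - A}\right)}
#' \deqn{GF_{alt} = \frac{Ha\,(3Ha + Ht)}{4\,Ht\,A}
#'       \left(1 - \frac{Ht - Ha}{D - A}\right)}
#' The two variants circulate in the literature because the defining
#' equation is frequently typeset ambiguously; on the canonical worked
#' example (D=720, A=24, Ht=26, Ha=23) they give 0.90 and 0.87
#' respectively. Both are always computed and reported so the discrepancy
#' is visible rather than silently resolved.
#'
#' Raw full-precision values are returned together with display values
#' following the conventional reporting style: yield floored to an
#' integer, ratio truncated to 1 decimal, EF truncated to 2 decimals, GF
#' rounded to 2 decimals.
#'
#' @param counts a [decoy_counts()] (or anything coercible via
#'   `decoy_counts(D, A, Ht, Ha)`).
#' @param auc optional ROC AUC to carry in the report.
#' @return object of class `validation_report` with elements `counts`,
#'   `raw` (yield_pct, ratio_pct, EF, GF_eq, GF_alt, FN, FP, auc) and
#'   `display`.
#' @export
gh_metrics <- function(counts, auc = NULL) {
  stopifnot(inherits(counts, "decoy_counts"))
  D <- counts$D; A <- counts$A; Ht <- counts$Ht; Ha <- counts$Ha
  if (Ht == 0L) stop("undefined metrics: Ht = 0 (no hits retrieved; ",
                     "yield and EF denominators vanish)")
  if (A == 0L) stop("undefined metrics: A = 0 (no actives; ratio and EF ",
                    "denominators vanish)")
  if (D == A) stop("undefined metrics: D = A (no decoys; GF penalty ",
                   "denominator D - A vanishes)")
  yield <- 100 * Ha / Ht
  ratio <- 100 * Ha / A
  ef <- (Ha * D) / (Ht * A)
  penalty <- 1 - (Ht - Ha) / (D - A)
  gf_eq <- (Ha * (3 * A + Ht) / (4 * Ht * A)) * penalty
  gf_alt <- (Ha * (3 * Ha + Ht) / (4 * Ht * A)) * penalty
  raw <- list(yield_pct = yield, ratio_pct = ratio, EF = ef,
              GF_eq = gf_eq, GF_alt = gf_alt,
              FN = A - Ha, FP = Ht - Ha,
              auc = if (is.null(auc)) NA_real_ else auc)
  display <- list(yield_pct = floor(yield),
                  ratio_pct = .trunc_dec(ratio, 1),
                  EF = .trunc_dec(ef, 2),
                  GF_eq = round(gf_eq, 2), GF_alt = round(gf_alt, 2),
                  FN = A - Ha, FP = Ht - Ha)
  structure(list(counts = counts, raw = raw, display = display),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  c_ <- x$counts; d <- x$display
  cat("Guener-Henry decoy-set validation\n")
  cat(sprintf("  Database (D) %d | actives (A) %d | hits (Ht) %d | active hits (Ha) %d\n",
              c_$D, c_$A, c_$Ht, c_$Ha))
  cat(sprintf("  %% yield of actives      %d\n", d$yield_pct))
  cat(sprintf("  %% ratio of actives      %.1f\n", d$ratio_pct))
  cat(sprintf("  Enrichment factor (EF)  %.2f\n", d$EF))
  cat(sprintf("  False negatives (A-Ha)  %d\n", d$FN))
  cat(sprintf("  False positives (Ht-Ha) %d\n", d$FP))
  cat(sprintf("  Goodness of fit: %.2f [(3Ha+Ht) numerator] vs %.2f [(3A+Ht) numerator]\n",
              d$GF_alt, d$GF_eq))
  cat("  (both GF numerator conventions are reported; see ?gh_metrics)\n")
  if (!is.na(x$raw$auc)) cat(sprintf("  ROC AUC                 %.3f\n", x$raw$auc))
  invisible(x)
}

#' ROC curve and AUC over screening scores
#'
#' Standard threshold sweep over the unique score values, descending;
#' each threshold yields one (false-positive rate, true-positive rate)
#' point. The area under the curve is computed by the trapezoid rule,
#' which equals the Mann-Whitney pair statistic with ties counted one
#' half.
#'
#' @param scores numeric scores, larger = more active-like.
#' @param labels logical (or 0/1) activity labels, same length.
#' @return list with `points` (data frame: threshold, fpr, tpr) and
#'   `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0L || nn == 0L)
    stop("ROC requires at least one active and one inactive")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  # cumulative counts at the end of each tie group == the threshold sweep
  last <- c(which(diff(s) != 0), length(s))
  tpr <- cumsum(l)[last] / np
  fpr <- cumsum(!l)[last] / nn
  pts <- data.frame(threshold = c(Inf, s[last]), fpr = c(0, fpr),
                    tpr = c(0, tpr))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

#' Validate a pharmacophore model against a labelled library
#'
#' Screens the library, derives the decoy-set confusion counts (D =
#' library size, A = labelled actives, Ht = matched molecules, Ha =
#' labelled actives among them) and returns the Guener-Henry report with
#' the ROC AUC over fit scores attached.
#'
#' @param model a `pharmacophore_model`.
#' @param lib a `screening_library` with complete activity labels.
#' @return a `validation_report` (see [gh_metrics()]); the screened
#'   library is attached as attribute `"screen"`.
#' @export
validate_model <- function(model, lib) {
  stopifnot(inherits(lib, "screening_library"))
  labels <- vapply(lib$records, function(r) r$label, TRUE)
  if (anyNA(labels)) stop("validation requires activity labels on every record")
  sc <- screen_library(model, lib)
  tab <- as.data.frame(sc$library)
  counts <- decoy_counts(D = nrow(tab), A = sum(tab$label),
                         Ht = sum(tab$matched),
                         Ha = sum(tab$matched & tab$label))
  auc <- roc_curve(tab$score, tab$label)$auc
  rep <- gh_metrics(counts, auc = auc)
  attr(rep, "screen") <- sc
  rep
}
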