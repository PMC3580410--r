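#' Rescale module scores from one platform to a reference profile
#'
#' Affine (mean/sd) matching: each target score is standardized by the
#' target cohort's mean and standard deviation and re-expressed on the
#' reference cohort's scale, so module expression levels become directly
#' comparable across array platforms before pooling. A quantile mode maps
#' target scores to the reference empirical quantiles instead, for
#' sensitivity analysis.
#'
#' @param target_scores per-sample scores to rescale (nonconstant).
#' @param reference_scores per-sample scores defining the reference profile
#'   (nonconstant).
#' @param method \code{"affine"} (default) or \code{"quantile"}.
#' @return rescaled target scores; under \code{"affine"} their mean and sd
#'   equal the reference mean and sd.
#' @export
rescale_to_reference <- function(target_scores, reference_scores,
                                 method = c("affine", "quantile")) {
  method <- match.arg(method)
  if (stats::sd(target_scores) == 0 || stats::sd(reference_scores) == 0)
    stop("constant score vector: rescaling undefined")
  if (method == "affine") {
    (target_scores - mean(target_scores)) / stats::sd(target_scores) *
      stats::sd(reference_scores) + mean(reference_scores)
  } else {
    p <- (rank(target_scores, ties.method = "average") - 0.5) / length(target_scores)
    stats::quantile(reference_scores, probs = p, names = FALSE, type = 7)
  }
}

#' Merge rescaled cohorts into one pooled survival series
#'
#' Concatenates per-sample (score, time, event) triples from several
#' cohorts, keeping a source label per sample. Cohorts should be rescaled
#' to a common reference first, and time units must be consistent across
#' cohorts (caller-asserted). Cohorts tagged with an endpoint other than
#' overall survival (e.g. disease-free survival) are excluded unless
#' \code{keep_endpoints} includes their tag. Duplicate sample ids across
#' sources are disambiguated by suffixing the source name.
#'
#' @param datasets named list; each element a list with \code{scores}
#'   (named per-sample numeric), \code{time}, \code{event}, and optional
#'   \code{endpoint} tag (default "os").
#' @param keep_endpoints endpoint tags admitted to the pool (default "os").
#' @return data frame with columns sample, score, time, event, source,
#'   endpoint.
#' @export
merge_cohorts <- function(datasets, keep_endpoints = "os") {
  if (length(datasets) == 0L) stop("no datasets to merge")
  if (is.null(names(datasets)) || any(!nzchar(names(datasets))))
    names(datasets) <- paste0("dataset", seq_along(datasets))
  parts <- lapply(names(datasets), function(nm) {
    d <- datasets[[nm]]
    endpoint <- if (is.null(d$endpoint)) "os" else d$endpoint
    if (!endpoint %in% keep_endpoints) return(NULL)
    ids <- names(d$scores)
    if (is.null(ids)) ids <- paste0(nm, "_", seq_along(d$scores))
    data.frame(sample = ids, score = as.numeric(d$scores),
               time = as.numeric(d$time), event = as.integer(d$event),
               source = nm, endpoint = endpoint, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  if (is.null(out) || nrow(out) == 0L)
    stop("no datasets remain after endpoint filtering")
  dup <- duplicated(out$sample) | duplicated(out$sample, fromLast = TRUE)
  out$sample[dup] <- paste(out$sample[dup], out$source[dup], sep = ".")
  rownames(out) <- NULL
  out
}
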