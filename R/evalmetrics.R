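# Target-difficulty binning and quality-estimation (QE) assessment metrics.
#
# QE asks how well a confidence score predicts model accuracy. Models are
# labeled "good" when their true lDDT reaches the threshold (default 0.6) and
# the confidence score is assessed as a classifier via ROC and
# precision-recall curves, including the partial areas used for benchmarking
# (FPR 0-0.2, TPR 0.8-1.0).

#' Target difficulty parameters
#' @param hard_below lDDT below which a target is "hard".
#' @param easy_at_or_above lDDT at or above which a target is "easy".
#' @export
difficulty_params <- function(hard_below = 0.5, easy_at_or_above = 0.75) {
  stopifnot(hard_below > 0, hard_below < easy_at_or_above,
            easy_at_or_above < 1)
  structure(list(hard_below = hard_below,
                 easy_at_or_above = easy_at_or_above),
            class = "difficulty_params")
}

#' Target difficulty from model-1 lDDT scores
#'
#' "hard" if the mean lDDT of the first-ranked server models is smaller than
#' \code{hard_below}, "easy" if it is \code{easy_at_or_above} or higher,
#' otherwise "medium".
#'
#' @param model1_lddts numeric vector of per-server model-1 lDDT scores.
#' @param params \code{\link{difficulty_params}}.
#' @return \code{"hard"}, \code{"medium"} or \code{"easy"}.
#' @export
difficulty <- function(model1_lddts, params = difficulty_params()) {
  if (!length(model1_lddts)) stop("empty lDDT list")
  m <- mean(model1_lddts)
  if (m < params$hard_below) "hard"
  else if (m >= params$easy_at_or_above) "easy"
  else "medium"
}

qe_labels <- function(samples, lddt_threshold) {
  pos <- samples$true_lddt >= lddt_threshold
  if (all(pos) || !any(pos))
    stop("undefined ROC: only one class present at lDDT threshold ",
         lddt_threshold)
  pos
}

# threshold sweep over distinct predicted values descending, ties grouped
sweep_counts <- function(predicted, pos) {
  ord <- order(-predicted)
  p <- predicted[ord]; y <- pos[ord]
  grp_end <- which(c(p[-1] != p[-length(p)], TRUE))
  tp <- cumsum(y)[grp_end]
  fp <- cumsum(!y)[grp_end]
  list(tp = tp, fp = fp, n_pos = sum(pos), n_neg = sum(!pos))
}

#' ROC curve points
#'
#' One (FPR, TPR) point per distinct predicted value (ties grouped), with
#' (0,0) prepended and (1,1) appended. Positives are samples with true lDDT
#' at or above the threshold.
#'
#' @param samples data.frame with columns \code{predicted} and
#'   \code{true_lddt}.
#' @param lddt_threshold positive-class threshold on true lDDT (default 0.6).
#' @return data.frame with columns \code{fpr}, \code{tpr}.
#' @export
roc_points <- function(samples, lddt_threshold = 0.6) {
  pos <- qe_labels(samples, lddt_threshold)
  sw <- sweep_counts(samples$predicted, pos)
  data.frame(fpr = c(0, sw$fp / sw$n_neg, 1),
             tpr = c(0, sw$tp / sw$n_pos, 1))
}

#' Precision-recall curve points
#'
#' One (recall, precision) point per distinct predicted value, ties grouped,
#' descending score; a leading point at recall 0 carries the first group's
#' precision.
#'
#' @inheritParams roc_points
#' @return data.frame with columns \code{recall}, \code{precision}.
#' @export
pr_points <- function(samples, lddt_threshold = 0.6) {
  pos <- qe_labels(samples, lddt_threshold)
  sw <- sweep_counts(samples$predicted, pos)
  rec <- sw$tp / sw$n_pos
  prec <- sw$tp / (sw$tp + sw$fp)
  data.frame(recall = c(0, rec), precision = c(prec[1], prec))
}

#' Trapezoidal area under a curve segment
#'
#' Area of the piecewise-linear curve through \code{points} restricted to
#' \code{[x_lo, x_hi]}, with linear interpolation at the bounds.
#'
#' @param points data.frame whose first two columns are x and y, sorted
#'   non-decreasing in x.
#' @param x_lo,x_hi integration bounds.
#' @param normalize divide by \code{x_hi - x_lo}.
#' @export
auc <- function(points, x_lo = 0, x_hi = 1, normalize = FALSE) {
  if (x_hi <= x_lo) stop("x_hi must exceed x_lo")
  x <- points[[1]]; y <- points[[2]]
  if (is.unsorted(x)) stop("points must be sorted in x")
  n <- length(x)
  # flat extension beyond the covered range
  if (x[1] > x_lo) { x <- c(x_lo, x); y <- c(y[1], y); n <- n + 1L }
  if (x[n] < x_hi) { x <- c(x, x_hi); y <- c(y, y[n]); n <- n + 1L }
  a <- 0
  for (k in seq_len(n - 1L)) {
    x1 <- x[k]; x2 <- x[k + 1L]
    if (x2 <= x_lo || x1 >= x_hi || x2 == x1) next
    c1 <- max(x1, x_lo); c2 <- min(x2, x_hi)
    y1 <- y[k] + (y[k + 1L] - y[k]) * (c1 - x1) / (x2 - x1)
    y2 <- y[k] + (y[k + 1L] - y[k]) * (c2 - x1) / (x2 - x1)
    a <- a + (c2 - c1) * (y1 + y2) / 2
  }
  if (normalize) a / (x_hi - x_lo) else a
}

qe_metrics_one <- function(samples, lddt_threshold) {
  res <- c(roc_auc = NA_real_, partial_roc_auc = NA_real_,
           pr_auc = NA_real_, partial_pr_auc = NA_real_)
  ok <- TRUE
  roc <- try(roc_points(samples, lddt_threshold), silent = TRUE)
  if (inherits(roc, "try-error")) ok <- FALSE
  if (ok) {
    pr <- pr_points(samples, lddt_threshold)
    res["roc_auc"] <- auc(roc)
    res["partial_roc_auc"] <- auc(roc, 0, 0.2, normalize = TRUE)
    res["pr_auc"] <- auc(pr)
    res["partial_pr_auc"] <- auc(pr, 0.8, 1.0, normalize = TRUE)
  }
  c(as.list(res), list(defined = ok, n = nrow(samples),
                       n_pos = sum(samples$true_lddt >= lddt_threshold)))
}

#' Quality-estimation metrics report
#'
#' ROC AUC, partial ROC AUC (FPR 0-0.2, normalized), PR AUC and partial PR
#' AUC (recall 0.8-1.0, normalized) per group. Groups containing a single
#' class are reported with \code{defined = FALSE} rather than dropped.
#'
#' @param samples data.frame with columns \code{predicted},
#'   \code{true_lddt} and, depending on grouping, \code{server} or
#'   \code{target_id}.
#' @param group_by \code{"pooled"}, \code{"server"} or \code{"target"}.
#' @param lddt_threshold positive-class threshold (default 0.6).
#' @return data.frame with one row per group.
#' @export
qe_report <- function(samples, group_by = c("pooled", "server", "target"),
                      lddt_threshold = 0.6) {
  group_by <- match.arg(group_by)
  if (!nrow(samples)) stop("empty sample table")
  key <- switch(group_by,
                pooled = rep("all", nrow(samples)),
                server = samples$server,
                target = samples$target_id)
  if (is.null(key)) stop("samples lack the ", group_by, " column")
  groups <- split(seq_len(nrow(samples)), key)
  rows <- lapply(names(groups), function(g) {
    m <- qe_metrics_one(samples[groups[[g]], , drop = FALSE], lddt_threshold)
    cbind(data.frame(group = g, stringsAsFactors = FALSE),
          as.data.frame(m))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
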