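# Instance-segmentation metrics: SEG and average precision at an IoU
# threshold. Boundary (0) pixels belong to no cell; the background is never a
# cell.

#' Intersection over union of two pixel sets
#'
#' @param a,b Logical matrices (same shape) or integer index vectors over the
#'   same grid.
#' @return `|a & b| / |a | b|`. Two empty sets are an error (undefined).
#' @export
iou <- function(a, b) {
  if (is.matrix(a)) a <- which(a > 0)
  if (is.matrix(b)) b <- which(b > 0)
  if (length(a) == 0L && length(b) == 0L) {
    stop("IoU of two empty sets is undefined")
  }
  length(intersect(a, b)) / length(union(a, b))
}

# Sparse overlap table between two label images: data.frame(g, p, o) for all
# co-occurring positive label pairs, plus per-label areas.
.overlap_table <- function(gt, pred) {
  ng <- max(gt, 0L); np <- max(pred, 0L)
  both <- gt > 0L & pred > 0L
  if (any(both)) {
    key <- (as.numeric(gt[both]) - 1) * np + as.numeric(pred[both])
    tab <- tabulate(key, nbins = ng * np)
    nz <- which(tab > 0)
    pairs <- data.frame(g = (nz - 1) %/% np + 1, p = (nz - 1) %% np + 1,
                        o = tab[nz])
  } else {
    pairs <- data.frame(g = integer(), p = integer(), o = integer())
  }
  list(pairs = pairs,
       area_g = tabulate(gt[gt > 0L], nbins = ng),
       area_p = tabulate(pred[pred > 0L], nbins = np))
}

#' SEG score of a predicted segmentation
#'
#' For each ground-truth cell R, its match is the predicted cell S covering
#' more than half of R (`|R & S| > 0.5 |R|`; at most one such S can exist).
#' Matched cells contribute `iou(R, S)`, unmatched cells contribute 0; the
#' score is the mean over all ground-truth cells.
#'
#' @param gt,pred Integer label images of the same shape; `gt` must contain
#'   at least one cell.
#' @return SEG in \[0, 1\].
#' @export
seg_score <- function(gt, pred) {
  .stopifnot_matrix(gt); .stopifnot_matrix(pred)
  if (!all(dim(gt) == dim(pred))) stop("shapes differ")
  ot <- .overlap_table(gt, pred)
  gcells <- which(ot$area_g > 0)
  if (length(gcells) == 0L) stop("ground truth has no cells")
  contrib <- vapply(gcells, function(g) {
    rows <- ot$pairs[ot$pairs$g == g, , drop = FALSE]
    hit <- rows[rows$o > 0.5 * ot$area_g[g], , drop = FALSE]
    if (nrow(hit) == 0L) return(0)
    hit$o[1] / (ot$area_g[g] + ot$area_p[hit$p[1]] - hit$o[1])
  }, numeric(1))
  mean(contrib)
}

#' Average precision with one-to-one IoU matching
#'
#' Candidate (gt, pred) pairs with IoU at or above `iou_thr` are matched
#' greedily in descending IoU (ties broken by gt label, then pred label).
#' TP = matched pairs; FP = surplus predicted cells (over-segmentation);
#' FN = missed ground-truth cells (under-segmentation);
#' AP = TP / (TP + FP + FN). At `iou_thr >= 0.5` greedy matching is provably
#' optimal because each cell can exceed 0.5 IoU with at most one partner.
#'
#' @param gt,pred Integer label images of the same shape.
#' @param iou_thr IoU threshold (default 0.7).
#' @return A `match_report`: list with `seg`, `tp`, `fp`, `fn`, `ap` and a
#'   `per_cell` data.frame (gt_label, pred_label or NA, iou). When both
#'   images are empty of cells, AP is defined as 1 with tp = fp = fn = 0 and
#'   the report is flagged `empty = TRUE`.
#' @export
average_precision <- function(gt, pred, iou_thr = 0.7) {
  .stopifnot_matrix(gt); .stopifnot_matrix(pred)
  if (!all(dim(gt) == dim(pred))) stop("shapes differ")
  ot <- .overlap_table(gt, pred)
  gcells <- which(ot$area_g > 0)
  pcells <- which(ot$area_p > 0)
  if (length(gcells) == 0L && length(pcells) == 0L) {
    rep0 <- structure(list(seg = NA_real_, tp = 0L, fp = 0L, fn = 0L, ap = 1,
                           per_cell = data.frame(gt_label = integer(),
                                                 pred_label = integer(),
                                                 iou = numeric()),
                           empty = TRUE),
                      class = "match_report")
    return(rep0)
  }
  pr <- ot$pairs
  pr$iou <- if (nrow(pr)) {
    pr$o / (ot$area_g[pr$g] + ot$area_p[pr$p] - pr$o)
  } else numeric()
  cand <- pr[pr$iou >= iou_thr, , drop = FALSE]
  cand <- cand[order(-cand$iou, cand$g, cand$p), , drop = FALSE]
  used_g <- logical(max(gt, 1L)); used_p <- logical(max(pred, 1L))
  match_g <- integer(); match_p <- integer(); match_iou <- numeric()
  for (i in seq_len(nrow(cand))) {
    g <- cand$g[i]; p <- cand$p[i]
    if (!used_g[g] && !used_p[p]) {
      used_g[g] <- TRUE; used_p[p] <- TRUE
      match_g <- c(match_g, g); match_p <- c(match_p, p)
      match_iou <- c(match_iou, cand$iou[i])
    }
  }
  tp <- length(match_g)
  fp <- length(pcells) - tp
  fn <- length(gcells) - tp
  per_cell <- data.frame(gt_label = gcells,
                         pred_label = NA_integer_,
                         iou = 0)
  if (tp) {
    mi <- match(match_g, gcells)
    per_cell$pred_label[mi] <- match_p
    per_cell$iou[mi] <- match_iou
  }
  sg <- if (length(gcells)) seg_score(gt, pred) else NA_real_
  structure(list(seg = sg, tp = tp, fp = as.integer(fp), fn = as.integer(fn),
                 ap = tp / (tp + fp + fn), per_cell = per_cell,
                 empty = FALSE),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("<match_report: SEG %.4f | AP %.4f (TP %d, FP %d, FN %d)>\n",
              x$seg, x$ap, x$tp, x$fp, x$fn))
  invisible(x)
}
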