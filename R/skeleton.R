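# Morphological thinning (Zhang-Suen) and connected-component labelling.

# Shift a matrix by (dr, dc) with zero fill; used for neighbourhood lookups.
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
  rok <- rs >= 1L & rs <= nr; cok <- cs >= 1L & cs <= nc
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

#' Label 8-connected foreground components
#'
#' Two-pass run-based labelling with union-find. Exposed because component
#' bookkeeping is occasionally useful when inspecting binarized angiograms.
#'
#' @param mask logical matrix.
#' @return Integer matrix of the same shape; background is 0, components are
#'   numbered 1..k in scan order.
#' @export
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  mask <- mask != 0
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  prev_runs <- NULL  # matrix: c1, c2, label
  for (i in seq_len(nr)) {
    row <- mask[i, ]
    if (!any(row)) { prev_runs <- NULL; next }
    d <- diff(c(FALSE, row, FALSE))
    starts <- which(d == 1L); ends <- which(d == -1L) - 1L
    cur <- matrix(0L, length(starts), 3L)
    for (k in seq_along(starts)) {
      c1 <- starts[k]; c2 <- ends[k]
      lk <- 0L
      if (!is.null(prev_runs)) {
        # 8-connectivity: previous-row runs overlapping [c1-1, c2+1]
        ov <- which(prev_runs[, 1L] <= c2 + 1L & prev_runs[, 2L] >= c1 - 1L)
        for (o in ov) {
          lo <- find(prev_runs[o, 3L])
          if (lk == 0L) lk <- lo
          else if (lo != lk) parent[max(lo, lk)] <- min(lo, lk)
          if (lo != 0L && lo < lk) lk <- lo
        }
      }
      if (lk == 0L) {
        parent[length(parent) + 1L] <- length(parent) + 1L
        lk <- length(parent)
      }
      lab[i, c1:c2] <- lk
      cur[k, ] <- c(c1, c2, lk)
    }
    prev_runs <- cur
  }
  if (length(parent)) {
    roots <- vapply(seq_along(parent), find, integer(1))
    relab <- integer(length(parent))
    relab[unique(roots)] <- seq_along(unique(roots))
    pos <- lab > 0L
    lab[pos] <- relab[roots[lab[pos]]]
  }
  lab
}

#' Skeletonize a binary mask
#'
#' Iterative Zhang-Suen thinning (two parallel sub-iterations per pass,
#' 8-connected) down to 1-pixel-wide centrelines, used to turn a binarized
#' angiogram into the vessel skeleton whose pixel count yields vessel length
#' density. Idempotent, and guarded so that no foreground component is thinned
#' away entirely.
#'
#' @param mask logical matrix (foreground = vessel).
#' @return Logical matrix of the same shape; skeleton is a subset of `mask`.
#' @export
skeletonize_mask <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- (mask != 0) * 1L
  if (!any(m == 1L)) return(mask != 0)
  lab <- label_components(m == 1L)
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p2 <- shift_mat(m, -1L, 0L); p3 <- shift_mat(m, -1L, 1L)
      p4 <- shift_mat(m, 0L, 1L);  p5 <- shift_mat(m, 1L, 1L)
      p6 <- shift_mat(m, 1L, 0L);  p7 <- shift_mat(m, 1L, -1L)
      p8 <- shift_mat(m, 0L, -1L); p9 <- shift_mat(m, -1L, -1L)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0L & p3 == 1L) + (p3 == 0L & p4 == 1L) +
        (p4 == 0L & p5 == 1L) + (p5 == 0L & p6 == 1L) +
        (p6 == 0L & p7 == 1L) + (p7 == 0L & p8 == 1L) +
        (p8 == 0L & p9 == 1L) + (p9 == 0L & p2 == 1L)
      if (step == 1L) {
        cond <- p2 * p4 * p6 == 0L & p4 * p6 * p8 == 0L
      } else {
        cond <- p2 * p4 * p8 == 0L & p2 * p6 * p8 == 0L
      }
      flag <- m == 1L & b >= 2L & b <= 6L & a == 1L & cond
      if (any(flag)) {
        # never delete the last remaining pixels of a component
        rem <- tabulate(lab[m == 1L], nbins = max(lab))
        fl <- tabulate(lab[flag], nbins = max(lab))
        dying <- which(fl > 0L & fl == rem)
        for (dl in dying) {
          idx <- which(flag & lab == dl)
          flag[idx[1L]] <- FALSE
        }
      }
      if (any(flag)) {
        m[flag] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1L
}
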