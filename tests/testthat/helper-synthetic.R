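# Shared fixtures and oracles, built in code at test time.

# Greedy centroid matching of detections against ground truth.
match_score <- function(rois, truth, tol = 2) {
  if (nrow(rois) == 0)
    return(c(recall = 0, precision = NA_real_))
  used <- rep(FALSE, nrow(rois))
  tp <- 0L
  for (i in seq_len(nrow(truth))) {
    d <- sqrt((rois$centroid_x_um - truth$x[i])^2 +
                (rois$centroid_y_um - truth$y[i])^2)
    j <- which.min(ifelse(used, Inf, d))
    if (length(j) && d[j] <= tol) {
      tp <- tp + 1L
      used[j] <- TRUE
    }
  }
  c(recall = tp / nrow(truth), precision = tp / nrow(rois))
}

# Small acquisition used by most unit tests (fast to render).
small_acq <- function(field_px = 256, n_z = 30, ...)
  acquisition_config(field_px = field_px, n_z = n_z, ...)

# Binary disc mask (pixel centers within radius r of (cx, cy), 1-based px).
disc_mask <- function(nr, nc, cy, cx, r) {
  yy <- matrix(seq_len(nr), nr, nc)
  xx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ((yy - cy)^2 + (xx - cx)^2 <= r^2) * 1L
}

# Brute-force grey-scale opening with a disc structuring element: the
# independent oracle for rolling-ball background estimation on toy images.
brute_opening <- function(m, radius) {
  offs <- which(disc_mask(2 * radius + 1, 2 * radius + 1,
                          radius + 1, radius + 1, radius) > 0,
                arr.ind = TRUE) - (radius + 1)
  nr <- nrow(m); nc <- ncol(m)
  pad <- function(v) v
  stage <- function(src, fun, init) {
    out <- matrix(init, nr, nc)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      rs <- i + offs[, 1]; cs <- j + offs[, 2]
      ok <- rs >= 1 & rs <= nr & cs >= 1 & cs <= nc
      out[i, j] <- fun(src[cbind(rs[ok], cs[ok])])
    }
    out
  }
  er <- stage(m, min, Inf)
  stage(er, max, -Inf)
}
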