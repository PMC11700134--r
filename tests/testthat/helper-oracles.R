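# Brute-force oracles, deliberately written as plain loops independent of
# the package's vectorized implementations.

oracle_footprint_pixels <- function(lon, lat, dem, radius_m = 12.5) {
  m_per_deg <- pi / 180 * 6371008.8
  hits <- integer(0)
  nr <- nrow(dem$values)
  for (cc in seq_len(ncol(dem$values))) {
    for (rr in seq_len(nr)) {
      xc <- dem$xmin + (cc - 0.5) * dem$dx
      yc <- dem$ymax - (rr - 0.5) * dem$dy
      east <- (xc - lon) * m_per_deg * cos(lat * pi / 180)
      north <- (yc - lat) * m_per_deg
      if (east^2 + north^2 <= radius_m^2)
        hits <- c(hits, (cc - 1L) * nr + rr)
    }
  }
  sort(hits)
}

oracle_resample_nearest <- function(src, target) {
  out <- matrix(NA_real_, nrow(target$values), ncol(target$values))
  for (r in seq_len(nrow(out))) {
    for (c in seq_len(ncol(out))) {
      x <- target$xmin + (c - 0.5) * target$dx
      y <- target$ymax - (r - 0.5) * target$dy
      sc <- floor((x - src$xmin) / src$dx) + 1
      sr <- floor((src$ymax - y) / src$dy) + 1
      if (sr >= 1 && sr <= nrow(src$values) && sc >= 1 && sc <= ncol(src$values))
        out[r, c] <- src$values[sr, sc]
    }
  }
  out
}

oracle_water_persistence <- function(stack, threshold_db) {
  nr <- nrow(stack[[1]]$values); nc <- ncol(stack[[1]]$values)
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      votes <- 0; valid <- 0
      for (layer in stack) {
        v <- layer$values[r, c]
        if (!is.na(v)) {
          valid <- valid + 1
          if (v <= threshold_db) votes <- votes + 1
        }
      }
      if (valid > 0) out[r, c] <- votes / valid
    }
  }
  out
}

oracle_aggregate_chm <- function(als_values, f, min_coverage) {
  nr <- nrow(als_values) / f; nc <- ncol(als_values) / f
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      block <- als_values[((r - 1) * f + 1):(r * f), ((c - 1) * f + 1):(c * f)]
      nv <- sum(!is.na(block))
      if (nv / f^2 >= min_coverage) out[r, c] <- mean(block, na.rm = TRUE)
    }
  }
  out
}

# textbook linear-interpolation percentile: h = (n-1)p + 1 on the sorted
# sample
oracle_quantile <- function(v, p) {
  s <- sort(v)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

oracle_binned_outliers <- function(x, y, width = 2, sigma = 3, min_n = 3) {
  # returns indices removed by either marginal pass (x tested in y-bins,
  # y tested in x-bins)
  removed <- logical(length(x))
  one_pass <- function(bin_var, test_var) {
    bad <- logical(length(bin_var))
    for (i in seq_along(bin_var)) {
      b <- floor(bin_var[i] / width)
      members <- which(floor(bin_var / width) == b)
      if (length(members) < min_n) next
      m <- mean(test_var[members])
      s <- sd(test_var[members])
      if (abs(test_var[i] - m) > sigma * s) bad[i] <- TRUE
    }
    bad
  }
  which(one_pass(y, x) | one_pass(x, y))
}

# 4-connected component count of a logical matrix, by flood fill
count_patches <- function(mask) {
  seen <- matrix(FALSE, nrow(mask), ncol(mask))
  n_comp <- 0
  for (r0 in seq_len(nrow(mask))) {
    for (c0 in seq_len(ncol(mask))) {
      if (!mask[r0, c0] || seen[r0, c0]) next
      n_comp <- n_comp + 1
      queue <- list(c(r0, c0)); seen[r0, c0] <- TRUE
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
          q <- p + d
          if (q[1] >= 1 && q[1] <= nrow(mask) && q[2] >= 1 &&
              q[2] <= ncol(mask) && mask[q[1], q[2]] && !seen[q[1], q[2]]) {
            seen[q[1], q[2]] <- TRUE
            queue <- c(queue, list(q))
          }
        }
      }
    }
  }
  n_comp
}
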