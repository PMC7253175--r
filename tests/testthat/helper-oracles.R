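# Independent oracles used to cross-check the implementation.

# exhaustive multi-level Otsu: enumerate every strictly increasing tuple of
# class start bins and maximise between-class variance directly
brute_otsu <- function(h, n_classes = 4L) {
  n <- length(h$counts)
  w <- h$counts / sum(h$counts)
  cw <- c(0, cumsum(w))
  cm <- c(0, cumsum(w * h$values))
  seg <- function(i, j) {
    W <- cw[j + 1] - cw[i]
    if (W <= 0) return(-Inf)
    (cm[j + 1] - cm[i])^2 / W
  }
  tuples <- utils::combn(2:n, n_classes - 1L)
  best <- -Inf; best_t <- NULL
  for (k in seq_len(ncol(tuples))) {
    s <- c(1L, tuples[, k], n + 1L)
    score <- 0
    for (c in seq_len(n_classes)) {
      sc <- seg(s[c], s[c + 1] - 1L)
      if (!is.finite(sc)) { score <- -Inf; break }
      score <- score + sc
    }
    if (score > best) { best <- score; best_t <- tuples[, k] }
  }
  list(thresholds = as.numeric(h$breaks[best_t]),
       between_class_variance = best - cm[n + 1]^2)
}

# reference 2D hole fill: breadth-first flood of the background from the
# border, everything unreached becomes part of the mask
fill_ref <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  reached <- matrix(FALSE, nr, nc)
  q <- list()
  for (y in 1:nr) for (x in c(1, nc)) if (!m[y, x]) q[[length(q) + 1]] <- c(y, x)
  for (x in 1:nc) for (y in c(1, nr)) if (!m[y, x]) q[[length(q) + 1]] <- c(y, x)
  while (length(q)) {
    v <- q[[length(q)]]; q[[length(q)]] <- NULL
    y <- v[1]; x <- v[2]
    if (y < 1 || y > nr || x < 1 || x > nc || reached[y, x] || m[y, x]) next
    reached[y, x] <- TRUE
    q <- c(q, list(c(y - 1, x), c(y + 1, x), c(y, x - 1), c(y, x + 1)))
  }
  m | !reached
}

# digitised sphere of radius r voxels, centred in a cube with `pad` margin
digitised_sphere <- function(r, pad = 3) {
  n <- 2 * r + 2 * pad + 1
  c0 <- (n + 1) / 2
  arr <- array(FALSE, dim = c(n, n, n))
  for (z in 1:n)
    arr[, , z] <- outer(1:n, 1:n, function(y, x)
      (x - c0)^2 + (y - c0)^2 + (z - c0)^2) <= r^2
  arr
}

# wrap an integer 0..3 array as a tier label volume
as_tier_labels <- function(arr, voxel_size = 9) {
  structure(array(as.integer(arr), dim = dim(arr)),
            levels = c("excluded", "low", "mid", "high"),
            voxel_size = voxel_size, class = "tier_labels")
}

# tier fractions by direct voxel counting inside a given envelope
count_fractions <- function(lab, env, slices) {
  lab <- unclass(lab)[, , slices, drop = FALSE]
  env <- env[, , slices, drop = FALSE]
  counts <- vapply(0:3, function(t) sum(lab[env] == t), 0)
  counts / sum(env)
}

# synthetic slice profiles for the group-statistics tests: one sample's
# per-slice tier percentages as a slice_profile-shaped data.frame
synthetic_profile <- function(values, tier = "high", sample_id = "s1") {
  ns <- length(values)
  lv <- c("excluded", "low", "mid", "high")
  df <- do.call(rbind, lapply(seq_len(ns), function(i) {
    pct <- c(0, 0, 0, 0)
    names(pct) <- lv
    pct[tier] <- values[i]
    data.frame(slice = i, distance_um = (i - 1) * 9,
               cross_section_um2 = 1000 * 81, tier = factor(lv, levels = lv),
               area_um2 = 81 * pct * 10, percent = pct)
  }))
  df$sample_id <- sample_id
  class(df) <- c("slice_profile", "data.frame")
  df
}

# roi_summary-shaped object from given tier percentages
synthetic_summary <- function(low, mid, high, sample_id = NA_character_) {
  fr <- c(low = low, mid = mid, high = high) / 100
  structure(list(table = NULL,
                 fractions = c(fr, bone = unname(sum(fr))),
                 roi_volume_um3 = 1e9, voxel_size = 9, sample_id = sample_id),
            class = "roi_summary")
}
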