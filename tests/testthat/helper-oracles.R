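# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: shoelace on raw vertices, ray-casting
# Monte-Carlo integration, full-permutation enumeration, and the
# variance form of the related-samples statistic.

# Shoelace (surveyor's) area of a polygon given as an n x 2 matrix.
oracle_shoelace <- function(verts) {
  n <- nrow(verts)
  j <- c(2:n, 1)
  abs(sum(verts[, 1] * verts[j, 2] - verts[j, 1] * verts[, 2])) / 2
}

# Even-odd ray-casting point-in-polygon test (vectorized over points).
oracle_in_polygon <- function(px, py, verts) {
  n <- nrow(verts)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- verts[i, 1]; yi <- verts[i, 2]
    xj <- verts[j, 1]; yj <- verts[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Monte-Carlo centroid by rejection sampling in the bounding box.
# Returns the estimate and the standard error of each coordinate.
oracle_mc_centroid <- function(verts, n = 20000, seed = 1) {
  set.seed(seed)
  xr <- range(verts[, 1]); yr <- range(verts[, 2])
  px <- runif(n, xr[1], xr[2])
  py <- runif(n, yr[1], yr[2])
  keep <- oracle_in_polygon(px, py, verts)
  list(centroid = c(x = mean(px[keep]), y = mean(py[keep])),
       se = c(x = sd(px[keep]), y = sd(py[keep])) / sqrt(sum(keep)),
       n_inside = sum(keep))
}

# Maximal polygon area over ALL axis orderings (full permutations,
# including rotations/reflections) of values on n evenly spaced axes.
oracle_max_area <- function(v) {
  n <- length(v)
  perm_all <- function(x) {
    if (length(x) <= 1) return(matrix(x, nrow = 1))
    do.call(rbind, lapply(seq_along(x), function(i) {
      cbind(x[i], perm_all(x[-i]), deparse.level = 0)
    }))
  }
  p <- perm_all(seq_len(n))
  s <- apply(p, 1, function(idx) sum(v[idx] * v[c(idx[-1], idx[1])]))
  0.5 * sinpi(2 / n) * max(s)
}

# Variance form of the related-samples (Cochran) statistic, algebraically
# distinct from the product-sum form the package implements.
oracle_cochran_variance_form <- function(m) {
  k <- ncol(m)
  cj <- colSums(m)
  ri <- rowSums(m)
  denom <- k * sum(ri) - sum(ri^2)
  if (denom == 0) return(NA_real_)
  k * (k - 1) * sum((cj - mean(cj))^2) / denom
}

# Trials tibble for an arbitrary binary response-by-condition matrix.
trials_from_matrix <- function(m, speaker_id = "s", session = 1L) {
  forms <- paste0("form_", seq_len(nrow(m)))
  tibble::tibble(
    speaker_id = speaker_id, session = session,
    response_form = rep(forms, each = 4),
    condition = rep(vox_operants, times = nrow(m)),
    emitted = as.integer(t(m)))
}

table2_matrix <- function() {
  matrix(c(0, 0, 1, 0,
           1, 0, 1, 0,
           1, 0, 1, 1,
           1, 1, 1, 0,
           1, 0, 0, 0,
           1, 1, 1, 0),
         nrow = 6, byrow = TRUE, dimnames = list(NULL, vox_operants))
}

random_axis_values <- function(max = 20) {
  axis_values(tact = runif(1, 0, max), mand = runif(1, 0, max),
              echoic = runif(1, 0, max), sequelic = runif(1, 0, max))
}
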