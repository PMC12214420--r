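# Independent brute-force oracles and tiny fixture builders. These
# deliberately avoid the package's own code paths (loops, textbook
# formulas) so agreement is evidence, not tautology.

# Pearson correlation by explicit term sums.
oracle_pearson <- function(x, y) {
  T_len <- length(x)
  xb <- sum(x) / T_len
  yb <- sum(y) / T_len
  num <- sum((x - xb) * (y - yb))
  den <- sqrt(sum((x - xb)^2)) * sqrt(sum((y - yb)^2))
  num / den
}

# AR-Dice by unordered pair enumeration: 2 * N11 / (pairs_x + pairs_y),
# with each symmetric AR entry counted (matching zero-diagonal AR sums).
oracle_dice <- function(lx, ly) {
  n <- length(lx)
  n11 <- px <- py <- 0
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    sx <- lx[i] == lx[j]
    sy <- ly[i] == ly[j]
    px <- px + sx
    py <- py + sy
    n11 <- n11 + (sx && sy)
  }
  if (px + py == 0) return(NaN)
  2 * n11 / (px + py)
}

# NMI from an explicitly assembled contingency table.
oracle_nmi <- function(lx, ly) {
  n <- length(lx)
  ux <- unique(lx); uy <- unique(ly)
  joint <- matrix(0, length(ux), length(uy))
  for (t in seq_len(n))
    joint[match(lx[t], ux), match(ly[t], uy)] <-
      joint[match(lx[t], ux), match(ly[t], uy)] + 1
  p <- joint / n
  px <- rowSums(p); py <- colSums(p)
  hx <- -sum(ifelse(px > 0, px * log(px), 0))
  hy <- -sum(ifelse(py > 0, py * log(py), 0))
  if (hx + hy == 0) return(1)
  mi <- 0
  for (a in seq_along(ux)) for (b in seq_along(uy))
    if (p[a, b] > 0) mi <- mi + p[a, b] * log(p[a, b] / (px[a] * py[b]))
  2 * mi / (hx + hy)
}

# AIRH in the fully expanded form: (2/n) sum_k 1/(C_k - 1) sum_{pairs} Corr.
# Assumes no singleton clusters (n is then the full voxel count).
oracle_airh <- function(values, labels) {
  n <- length(labels)
  total <- 0
  for (k in unique(labels)) {
    mem <- which(labels == k)
    ck <- length(mem)
    s <- 0
    for (a in seq_len(ck - 1)) for (b in seq.int(a + 1, ck))
      s <- s + oracle_pearson(values[mem[a], ], values[mem[b], ])
    total <- total + s / (ck - 1)
  }
  2 * total / n
}

# Random label vector guaranteed to occupy 1..K.
random_labels <- function(n, K) {
  stopifnot(n >= K)
  labels <- c(seq_len(K), sample.int(K, n - K, replace = TRUE))
  sample(labels)
}

# Small fully-filled box mask.
box_mask <- function(dims = c(4, 4, 4)) {
  voxel_mask(array(TRUE, dim = dims))
}

# timeseries_matrix from an explicit n x T matrix on a box mask.
ts_from_matrix <- function(values, mask = NULL) {
  n <- nrow(values)
  if (is.null(mask)) mask <- voxel_mask(array(TRUE, dim = c(n, 1, 1)))
  specparc:::new_timeseries(values, mask)
}

# Block-diagonal sparse similarity: two internally connected blocks with
# no cross edges.
two_block_similarity <- function(n1 = 30, n2 = 20, seed = 1) {
  set.seed(seed)
  n <- n1 + n2
  W <- matrix(0, n, n)
  block <- function(idx) {
    m <- length(idx)
    B <- matrix(runif(m * m, 0.4, 1), m, m)
    B <- (B + t(B)) / 2
    W[idx, idx] <<- B
  }
  block(seq_len(n1))
  block(seq.int(n1 + 1, n))
  diag(W) <- 0
  W
}
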