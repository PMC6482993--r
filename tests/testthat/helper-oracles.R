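# Independent brute-force oracles and small fixture builders used across
# the suite. The oracles evaluate the defining objectives directly and
# never share code with the implementations they check.

# exhaustive Otsu: evaluate sigma_B^2(t) from its definition for every t
otsu_brute <- function(counts) {
  g <- 0:255
  p <- counts / sum(counts)
  best_t <- NA_integer_; best_obj <- -Inf
  for (t in 0:254) {
    w0 <- sum(p[g <= t]); w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    mu0 <- sum(p[g <= t] * g[g <= t]) / w0
    mu1 <- sum(p[g > t] * g[g > t]) / w1
    obj <- w0 * w1 * (mu0 - mu1)^2
    if (obj > best_obj) { best_obj <- obj; best_t <- t }
  }
  list(t = best_t, objective = best_obj)
}

# exhaustive Huang fuzzy-entropy minimizer, straight from the definition
huang_brute <- function(counts) {
  g <- 0:255
  occ <- g[counts > 0]
  C <- max(occ) - min(occ)
  S <- function(u) ifelse(u <= 0 | u >= 1, 0, -u * log(u) - (1 - u) * log(1 - u))
  best_t <- NA_integer_; best_e <- Inf
  for (t in 0:254) {
    in0 <- g <= t
    c0 <- sum(counts[in0]); c1 <- sum(counts[!in0])
    if (c0 == 0 || c1 == 0) next
    m0 <- sum(counts[in0] * g[in0]) / c0
    m1 <- sum(counts[!in0] * g[!in0]) / c1
    m <- ifelse(in0, m0, m1)
    u <- 1 / (1 + abs(g - m) / C)
    e <- sum(counts * S(u))
    if (e < best_e) { best_e <- e; best_t <- t }
  }
  list(t = best_t, objective = best_e)
}

# literal BH step-up: q(i) = min_{j >= i} min(1, p(j) m / j) on sorted p
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m))
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}

# seeded random occupied-bin histogram as a 256-count vector
random_histogram <- function(seed) {
  set.seed(seed)
  counts <- integer(256)
  k <- sample(2:40, 1)
  bins <- sample(0:255, k)
  counts[bins + 1] <- sample(1:500, k, replace = TRUE)
  counts
}

as_hist <- function(counts) {
  structure(list(counts = counts,
                 bin_map = list(offset = 0, scale = 1),
                 n = sum(counts)), class = "oir_histogram")
}

# Bresenham rasterization of a segment from (r0, c0) at `deg` degrees for
# chain length `len` pixels along the major axis
draw_segment <- function(nrow, ncol, r0, c0, deg, len) {
  th <- deg * pi / 180
  m <- matrix(FALSE, nrow, ncol)
  if (abs(cos(th)) >= abs(sin(th))) {
    slope <- tan(th)
    for (i in 0:len) m[round(r0 + i * slope), c0 + i] <- TRUE
  } else {
    slope <- cos(th) / sin(th)
    for (i in 0:len) m[r0 + i, round(c0 + i * slope)] <- TRUE
  }
  m
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
iou_coef <- function(a, b) sum(a & b) / sum(a | b)

# digital ball mask inside a cubic array
digital_ball <- function(dim3, center, radius) {
  i <- array(rep(seq_len(dim3[1]), times = dim3[2] * dim3[3]), dim = dim3)
  j <- array(rep(rep(seq_len(dim3[2]), each = dim3[1]), times = dim3[3]), dim = dim3)
  k <- array(rep(seq_len(dim3[3]), each = dim3[1] * dim3[2]), dim = dim3)
  (i - center[1])^2 + (j - center[2])^2 + (k - center[3])^2 <= radius^2
}
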