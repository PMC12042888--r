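# Raster fixtures ------------------------------------------------------------

rasterDisk <- function(radius = 20, pad = 3) {
  n <- 2 * (radius + pad) + 1
  ctr <- radius + pad + 1
  g <- expand.grid(r = 1:n, c = 1:n)
  matrix((g$r - ctr)^2 + (g$c - ctr)^2 <= radius^2, n, n)
}

rasterLine <- function(len = 256) {
  m <- matrix(FALSE, 3, len + 2)
  m[2, 1 + seq_len(len)] <- TRUE
  m
}

sierpinskiRaster <- function(depth = 6) {
  n <- 2^depth
  outer(0:(n - 1), 0:(n - 1), function(x, y) bitwAnd(x, y) == 0)
}

# 8x8 checkerboard of full/empty 2x2 blocks: at box size 2 exactly half the
# tiles have mass 4 and half mass 0, so Lambda(2) = <M^2>/<M>^2 = 8/4 = 2.
checkerboard8 <- function() {
  cb <- matrix(FALSE, 8, 8)
  for (bi in 0:3) for (bj in 0:3)
    if ((bi + bj) %% 2 == 0) cb[bi * 2 + 1:2, bj * 2 + 1:2] <- TRUE
  cb
}

rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

upscaleMask <- function(m, s) {
  m[rep(seq_len(nrow(m)), each = s), rep(seq_len(ncol(m)), each = s)]
}

# Independent oracles ---------------------------------------------------------

# Brute-force box counter: explicit loop over box windows, any() per window.
bruteBoxCount <- function(m, s) {
  n <- 0L
  for (r0 in seq(1, nrow(m), by = s))
    for (c0 in seq(1, ncol(m), by = s))
      if (any(m[r0:min(nrow(m), r0 + s - 1), c0:min(ncol(m), c0 + s - 1)]))
        n <- n + 1L
  n
}

# Exact optimal-transport cost between two empirical distributions: the
# north-west-corner rule on sorted atoms (optimal for 1-D convex cost), run in
# integer mass units m and n so there is no floating-point mass bookkeeping.
transportOracle <- function(a, b) {
  a <- sort(a); b <- sort(b)
  n <- length(a); m <- length(b)
  wa <- rep(m, n); wb <- rep(n, m)   # masses scaled by n*m
  i <- 1L; j <- 1L; cost <- 0
  while (i <= n && j <= m) {
    mv <- min(wa[i], wb[j])
    cost <- cost + mv * abs(a[i] - b[j])
    wa[i] <- wa[i] - mv
    wb[j] <- wb[j] - mv
    if (wa[i] == 0L) i <- i + 1L
    if (j <= m && wb[j] == 0L) j <- j + 1L
  }
  cost / (n * m)
}

# One-way ANOVA F from explicit sums of squares.
bruteAnovaF <- function(groups) {
  allv <- unlist(groups)
  gm <- mean(allv)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 1.0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1.0))
  dfb <- length(groups) - 1
  dfw <- length(allv) - length(groups)
  (ssb / dfb) / (ssw / dfw)
}

# Feature-table fixtures ------------------------------------------------------

randomFeatureTable <- function(n = 30, K = 4, groups = c("A", "B"), seed = 1,
                               shift = 0) {
  set.seed(seed)
  g <- rep(groups, length.out = n)
  x <- matrix(rnorm(n * K), n, K,
              dimnames = list(NULL, paste0("f", seq_len(K))))
  if (length(groups) > 1)
    x[g == groups[2], 1] <- x[g == groups[2], 1] + shift
  FeatureTable(x, data.frame(cell_id = paste0("c", seq_len(n)), group = g,
                             stringsAsFactors = FALSE))
}

# Uniform marginals on [0, 1] for copula-mode populations.
uniformMarginals <- function(K, names = paste0("f", seq_len(K))) {
  setNames(rep(list(function(p) p), K), names)
}
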