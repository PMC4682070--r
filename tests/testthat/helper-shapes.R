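# Shared fixtures: shapes and small populations built in code.

rotate2 <- function(v, a) {
  cbind(cos(a) * v[, 1] - sin(a) * v[, 2],
        sin(a) * v[, 1] + cos(a) * v[, 2])
}

circle_poly <- function(r = 1, n = 96, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

ellipse_poly <- function(a = 2, b = 1, n = 96, angle = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  rotate2(cbind(a * cos(th), b * sin(th)), angle)
}

square_poly <- function(side = 1) {
  s <- side
  rbind(c(0, 0), c(s, 0), c(s, s), c(0, s))
}

# random star-convex polygon (independent of the package generator)
random_star_poly <- function(seed, n = 80, irregularity = 0.25) {
  set.seed(seed)
  hs <- 2:7
  a <- rnorm(length(hs), 0, irregularity / hs)
  b <- rnorm(length(hs), 0, irregularity / hs)
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r <- 1
  for (i in seq_along(hs)) r <- r + a[i] * cos(hs[i] * th) + b[i] * sin(hs[i] * th)
  r <- pmax(r, 0.2)
  cbind(r * cos(th), r * sin(th))
}

# brute-force equal-arc-length resampling oracle (cumulative interpolation)
brute_resample <- function(v, n) {
  vc <- rbind(v, v[1, ])
  seg <- sqrt(rowSums(diff(vc)^2))
  cs <- c(0, cumsum(seg))
  per <- cs[length(cs)]
  t(sapply((0:(n - 1)) * per / n, function(s) {
    k <- max(which(cs <= s + 1e-15))
    if (k >= length(cs)) k <- length(cs) - 1
    f <- (s - cs[k]) / seg[k]
    vc[k, ] + f * (vc[k + 1, ] - vc[k, ])
  }))
}

# brute-force validity indices (independent of cluster_validity)
brute_validity <- function(scores, centroids, labels) {
  n <- nrow(scores)
  K <- nrow(centroids)
  scatter <- 0
  for (i in 1:n)
    scatter <- scatter + sum((scores[i, ] - centroids[labels[i], ])^2)
  mincd2 <- Inf
  for (j in 1:(K - 1)) for (k in (j + 1):K)
    mincd2 <- min(mincd2, sum((centroids[j, ] - centroids[k, ])^2))
  diam <- 0
  for (k in 1:K) {
    pk <- scores[labels == k, , drop = FALSE]
    if (nrow(pk) > 1)
      for (i in 1:(nrow(pk) - 1)) for (j in (i + 1):nrow(pk))
        diam <- max(diam, sqrt(sum((pk[i, ] - pk[j, ])^2)))
  }
  list(xie_beni = scatter / (n * mincd2),
       separation = if (diam > 0) sqrt(mincd2) / diam else 1e12)
}

# agreement between two labelings under the best label permutation
best_permutation_agreement <- function(truth, labels) {
  k1 <- sort(unique(truth)); k2 <- sort(unique(labels))
  tab <- table(factor(truth, k1), factor(labels, k2))
  if (length(k2) > 6) {
    # greedy matching for larger K
    agree <- 0
    tb <- as.matrix(tab)
    while (any(tb > -1) && nrow(tb) && ncol(tb)) {
      m <- which(tb == max(tb), arr.ind = TRUE)[1, ]
      agree <- agree + tb[m[1], m[2]]
      tb <- tb[-m[1], -m[2], drop = FALSE]
      if (!nrow(tb) || !ncol(tb)) break
    }
    return(agree / length(truth))
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- 0
  for (p in perms(seq_along(k2))) {
    idx <- cbind(rep(seq_along(k1), length.out = min(length(k1), length(k2))),
                 p[seq_len(min(length(k1), length(k2)))])
    best <- max(best, sum(tab[idx]))
  }
  best / length(truth)
}

# small standard synthetic study used by several context/heritability tests
make_standard_records <- function(n = 400, seed = 1, colony_cv = 0,
                                  n_colonies = 8) {
  set.seed(seed)
  colony <- sort(rep_len(seq_len(n_colonies), n))
  cfac <- exp(rnorm(n_colonies, 0, colony_cv))
  phase <- sample(c("G0G1", "S", "G2M"), n, TRUE, c(0.6, 0.25, 0.15))
  dna <- ifelse(phase == "G0G1", 1, ifelse(phase == "G2M", 2, runif(n, 1, 2)))
  size <- cfac[colony] * dna^(1 / 3) * exp(rnorm(n, 0, 0.05))
  rho <- rpois(n, 1.2)
  ctr <- cbind(rep(seq(100, 1500, length.out = n_colonies)), 500)
  data.frame(sample_id = "S1", cell_id = 1:n,
             R_N = 12 * size, R_C = 30 * size,
             nucleus_mode = sample(1:4, n, TRUE),
             cell_mode = sample(1:4, n, TRUE),
             dna_content_raw = dna, dna_content_norm = dna, phase = phase,
             rho_D = rho, density_category = density_category(rho),
             x = ctr[colony, 1] + rnorm(n, 0, 25),
             y = ctr[colony, 2] + rnorm(n, 0, 25),
             colony_id = colony, stringsAsFactors = FALSE)
}
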