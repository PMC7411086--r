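# Independent oracles and fixture builders shared across the suite.
# Everything here is deliberately written with different primitives than the
# package code paths it checks.

# Kruskal-Wallis H by the direct rank formula (no stats::kruskal.test).
kw_h_oracle <- function(values, groups) {
  groups <- factor(groups)
  n <- length(values)
  r <- rank(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(x) length(x) * mean(x)^2)) -
    3 * (n + 1)
  ties <- table(r)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Exact permutation distribution of H for a two-group design by exhaustive
# enumeration of group-1 index sets.
kw_exact_perm_p <- function(values, groups) {
  groups <- factor(groups)
  idx1 <- utils::combn(length(values), sum(groups == levels(groups)[1]))
  h_obs <- kw_h_oracle(values, groups)
  h_all <- apply(idx1, 2, function(ii) {
    g <- rep(levels(groups)[2], length(values))
    g[ii] <- levels(groups)[1]
    kw_h_oracle(values, g)
  })
  mean(h_all >= h_obs - 1e-12)
}

# Brute-force CAP leave-one-out nearest-centroid allocation for Euclidean
# features: PCA by prcomp on the training rows (not Gower double-centering),
# held-out row projected through the rotation, canonical axes from an
# explicit solve(W) %*% B eigen-decomposition.
cap_loo_oracle <- function(features, groups, m) {
  features <- as.matrix(features)
  groups <- as.character(groups)
  n <- nrow(features)
  alloc <- character(n)
  for (i in seq_len(n)) {
    tr <- features[-i, , drop = FALSE]
    gtr <- groups[-i]
    pc <- stats::prcomp(tr, center = TRUE, scale. = FALSE)
    mi <- min(m, sum(pc$sdev > 1e-9))
    s_tr <- pc$x[, seq_len(mi), drop = FALSE]
    s_te <- ((features[i, ] - pc$center) %*%
               pc$rotation[, seq_len(mi), drop = FALSE])[1, ]
    lev <- unique(gtr)
    cent <- t(vapply(lev, function(g) colMeans(s_tr[gtr == g, , drop = FALSE]),
                     numeric(mi)))
    w <- matrix(0, mi, mi)
    for (g in lev) {
      xc <- sweep(s_tr[gtr == g, , drop = FALSE], 2, cent[match(g, lev), ])
      w <- w + t(xc) %*% xc
    }
    w <- w / (nrow(s_tr) - length(lev))
    grand <- colMeans(s_tr)
    b <- matrix(0, mi, mi)
    for (g in lev) {
      dv <- cent[match(g, lev), ] - grand
      b <- b + sum(gtr == g) * (dv %o% dv)
    }
    ev <- eigen(solve(w) %*% b)
    n_can <- min(mi, length(lev) - 1)
    a <- Re(ev$vectors[, seq_len(n_can), drop = FALSE])
    z_cent <- cent %*% a
    z_te <- rbind(s_te) %*% a
    d2 <- rowSums(sweep(z_cent, 2, z_te[1, ])^2)
    alloc[i] <- lev[which.min(d2)]
  }
  alloc
}

# Random but always-feasible OJIP target parameters.
random_transient_params <- function() {
  f0 <- stats::runif(1, 300, 800)
  vj <- stats::runif(1, 0.35, 0.6)
  list(f0 = f0,
       fm = f0 * stats::runif(1, 2.5, 6),
       vj = vj,
       vi = stats::runif(1, vj + 0.15, 0.88))
}

# Uniform random 7-pigment mixture at comparable magnitudes.
random_pigment_mixture <- function(library) {
  stats::setNames(stats::runif(length(library$pigments), 0.5, 1.5),
                  library$pigments)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / abs(expected)), tol)
}
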