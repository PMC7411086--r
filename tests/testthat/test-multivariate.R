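test_that("identical groups give H = 0 and one shared letter", {
  kw <- kruskal_wallis_letters(rep(5, 9), rep(letters[1:3], each = 3))
  expect_equal(kw$h, 0)
  expect_true(all(kw$letters == "a"))
})

test_that("H matches the direct rank-formula oracle on separated groups", {
  v <- c(1.2, 1.5, 1.9, 8.1, 8.7, 9.3)
  g <- rep(c("lo", "hi"), each = 3)
  kw <- kruskal_wallis_letters(v, g)
  expect_equal(kw$h, kw_h_oracle(v, g), tolerance = 1e-12)
  expect_equal(kw$h, 3.857142857, tolerance = 1e-8)  # 12/42*(3*1.5^2*2)
})

test_that("letter displays are equivariant to group relabelling", {
  set.seed(44)
  v <- c(rnorm(4, 0), rnorm(4, 0.2), rnorm(4, 8))
  g <- rep(c("a1", "a2", "b"), each = 4)
  kw1 <- kruskal_wallis_letters(v, g, alpha = 0.5)
  g2 <- c(a1 = "x", a2 = "y", b = "z")[g]
  kw2 <- kruskal_wallis_letters(v, g2, alpha = 0.5)
  same1 <- outer(kw1$letters[g], kw1$letters[g], function(a, b) {
    mapply(function(x, y) any(strsplit(x, "")[[1]] %in% strsplit(y, "")[[1]]),
           a, b)
  })
  same2 <- outer(kw2$letters[g2], kw2$letters[g2], function(a, b) {
    mapply(function(x, y) any(strsplit(x, "")[[1]] %in% strsplit(y, "")[[1]]),
           a, b)
  })
  expect_equal(unname(same1), unname(same2))
})

test_that("spearman_dose reports rho, squared and signed conventions", {
  d <- c(0, 0.3, 0.6, 20, 40, 80)
  up <- spearman_dose(seq_along(d), d)
  expect_equal(up$rho, 1)
  expect_equal(up$signed_rho_sq, 1)
  dn <- spearman_dose(rev(seq_along(d)), d)
  expect_equal(dn$rho, -1)
  expect_equal(dn$signed_rho_sq, -1)
  const <- spearman_dose(rep(2, 6), d)
  expect_true(const$constant)
  expect_true(is.na(const$rho))
})

test_that("tied data match a brute-force rank-correlation oracle", {
  v <- c(3, 3, 5, 7, 7, 10)
  d <- c(0, 0.3, 0.6, 20, 40, 80)
  sp <- spearman_dose(v, d)
  expect_equal(sp$rho, cor(rank(v), rank(d)), tolerance = 1e-12)
})

test_that("well-separated clusters classify perfectly by LOO", {
  set.seed(3)
  x <- rbind(matrix(rnorm(15, 0, 0.1), 5), matrix(rnorm(15, 10, 0.1), 5),
             matrix(rnorm(15, -10, 0.1), 5))
  g <- rep(c("a", "b", "c"), each = 5)
  res <- cap(x, g, n_perm = 99, seed = 2)
  expect_equal(res$accuracy_pct, 100)
  expect_equal(unname(rowSums(res$confusion)), rep(5, 3))
  expect_lt(res$p_permutation, 0.05)
})

test_that("CAP allocations equal the brute-force LOO oracle on small data", {
  set.seed(21)
  for (k in 1:8) {
    x <- matrix(rnorm(8 * 4, sd = 1), 8, 4)
    x[5:8, 1] <- x[5:8, 1] + runif(1, 0, 3)  # varying separation
    g <- rep(c("a", "b"), each = 4)
    got <- phaeotox:::cap_loo(as.matrix(dist(x))^2, factor(g), m = 2)
    oracle <- cap_loo_oracle(x, g, m = 2)
    expect_equal(got, oracle)
  }
})

test_that("PCoA of Euclidean distances reproduces PCA scores", {
  set.seed(33)
  x <- matrix(rnorm(12 * 5), 12, 5)
  dec <- phaeotox:::pcoa_decompose(as.matrix(dist(x))^2)
  pc <- prcomp(x, center = TRUE)
  k <- min(ncol(dec$scores), sum(pc$sdev > 1e-9))
  for (j in seq_len(k)) {
    # axes match up to sign
    expect_equal(min(sum((dec$scores[, j] - pc$x[, j])^2),
                     sum((dec$scores[, j] + pc$x[, j])^2)), 0,
                 tolerance = 1e-12)
  }
})

test_that("supplementary projection reproduces held-in coordinates", {
  set.seed(34)
  x <- matrix(rnorm(10 * 3), 10, 3)
  d2 <- as.matrix(dist(x))^2
  dec <- phaeotox:::pcoa_decompose(d2[-1, -1])
  q <- phaeotox:::pcoa_project(dec, d2[-1, 1])
  # the projected point must sit at its true Euclidean distances (in the
  # PCoA coordinate system) up to the dropped dimension
  d_rec <- sqrt(colSums((t(dec$scores) - q)^2))
  expect_equal(d_rec, unname(sqrt(d2[-1, 1])), tolerance = 1e-6)
})

test_that("LOO accuracy is invariant to uniform feature scaling", {
  set.seed(35)
  x <- matrix(rnorm(18 * 6), 18, 6)
  x[10:18, ] <- x[10:18, ] + 1.5
  g <- rep(c("a", "b"), c(9, 9))
  r1 <- cap(x, g, m_rule = 3, n_perm = 9, seed = 1)
  r2 <- cap(x * 42, g, m_rule = 3, n_perm = 9, seed = 1)
  expect_equal(r1$accuracy_pct, r2$accuracy_pct)
  expect_equal(r1$confusion, r2$confusion)
})

test_that("confusion-matrix bookkeeping holds for every run", {
  set.seed(36)
  for (k in 1:5) {
    g <- rep(letters[1:3], each = 4)
    x <- matrix(rnorm(12 * 5), 12, 5) + as.numeric(factor(g)) * runif(1, 0, 2)
    res <- cap(x, g, n_perm = 9, seed = k)
    expect_equal(unname(rowSums(res$confusion)), as.vector(table(g)))
    expect_equal(res$accuracy_pct,
                 100 * sum(diag(res$confusion)) / length(g))
    expect_true(res$m <= length(g) - 3)
  }
})
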