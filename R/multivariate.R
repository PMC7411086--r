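#' Kruskal-Wallis test with Dunn post hoc and compact letter display
#'
#' Kruskal-Wallis rank test (tie-corrected, via [stats::kruskal.test()]).
#' When the omnibus test is significant at `alpha`, pairwise Dunn z-tests
#' with Holm adjustment feed a compact letter display: groups not sharing a
#' letter differ significantly. When the omnibus test is not significant all
#' groups share one letter.
#'
#' @param values Numeric response.
#' @param groups Group labels (coerced to factor).
#' @param alpha Significance level.
#' @return List: `h`, `df`, `p_value`, `letters` (named by group),
#'   `pairwise` (Dunn table or NULL).
#' @export
kruskal_wallis_letters <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (any(table(groups) < 2)) stop("each group needs >= 2 observations")
  kw <- stats::kruskal.test(values, groups)
  lev <- levels(groups)
  if (is.nan(kw$statistic)) {  # all values identical -> no variance in ranks
    kw$statistic <- 0; kw$p.value <- 1
  }
  if (kw$p.value >= alpha || !is.finite(kw$p.value)) {
    return(list(h = unname(kw$statistic), df = unname(kw$parameter),
                p_value = kw$p.value,
                letters = stats::setNames(rep("a", length(lev)), lev),
                pairwise = NULL))
  }
  pw <- dunn_pairwise(values, groups)
  differ <- pw$p_adjusted < alpha
  letters <- compact_letters(lev, pw$group_1[differ], pw$group_2[differ])
  list(h = unname(kw$statistic), df = unname(kw$parameter),
       p_value = kw$p.value, letters = letters, pairwise = pw)
}

# Dunn (1964) pairwise rank z-tests with tie correction, Holm-adjusted.
dunn_pairwise <- function(values, groups) {
  groups <- factor(groups)
  n <- length(values)
  r <- rank(values)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  rb <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  lev <- levels(groups)
  combs <- utils::combn(lev, 2)
  z <- apply(combs, 2, function(gp) {
    se <- sqrt((n * (n + 1) / 12 - tie_corr) *
                 (1 / ns[[gp[1]]] + 1 / ns[[gp[2]]]))
    (rb[[gp[1]]] - rb[[gp[2]]]) / se
  })
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(group_1 = combs[1, ], group_2 = combs[2, ], z = z,
             p_value = p, p_adjusted = stats::p.adjust(p, "holm"),
             row.names = NULL)
}

# Compact letter display: letters = maximal cliques of the "not significantly
# different" graph, enumerated exhaustively (group counts here are small).
compact_letters <- function(levels, differ_1, differ_2) {
  g <- length(levels)
  differ <- matrix(FALSE, g, g, dimnames = list(levels, levels))
  for (k in seq_along(differ_1)) {
    differ[differ_1[k], differ_2[k]] <- TRUE
    differ[differ_2[k], differ_1[k]] <- TRUE
  }
  compatible <- function(members) {
    if (length(members) < 2) return(TRUE)
    !any(differ[members, members])
  }
  cliques <- list()
  for (mask in seq_len(2^g - 1)) {
    members <- levels[bitwAnd(mask, 2^(seq_len(g) - 1)) > 0]
    if (!compatible(members)) next
    # maximal: no further group can join
    if (any(vapply(setdiff(levels, members),
                   function(x) compatible(c(members, x)), logical(1)))) next
    cliques[[length(cliques) + 1]] <- members
  }
  # order cliques by their first group to get a stable display
  ord <- order(vapply(cliques, function(m) min(match(m, levels)), numeric(1)))
  cliques <- cliques[ord]
  out <- stats::setNames(rep("", g), levels)
  for (i in seq_along(cliques)) {
    out[cliques[[i]]] <- paste0(out[cliques[[i]]], letters[i])
  }
  out
}

#' Spearman rank correlation of an endpoint against dose
#'
#' Tie-handling rank correlation via [stats::cor.test()] with both rho and
#' the signed squared coefficient reported (dose-response studies often print
#' a signed "r^2"; both conventions can be read from the result).
#'
#' @param values Endpoint values.
#' @param doses Matched doses.
#' @return List: `rho`, `rho_sq`, `signed_rho_sq`, `p_value`, `constant`
#'   (flag: TRUE when an input had no variance so the correlation is
#'   undefined).
#' @export
spearman_dose <- function(values, doses) {
  if (length(values) < 3) stop("need >= 3 paired observations")
  if (stats::sd(values) == 0 || stats::sd(doses) == 0) {
    return(list(rho = NA_real_, rho_sq = NA_real_,
                signed_rho_sq = NA_real_, p_value = NA_real_,
                constant = TRUE))
  }
  ct <- suppressWarnings(stats::cor.test(values, doses, method = "spearman",
                                         exact = FALSE))
  rho <- unname(ct$estimate)
  list(rho = rho, rho_sq = rho^2, signed_rho_sq = sign(rho) * rho^2,
       p_value = ct$p.value, constant = FALSE)
}

# --- CAP -------------------------------------------------------------------

# Gower-centered PCoA. Returns axis scores (columns scaled by sqrt(eigval)),
# orthonormal eigenvectors, positive eigenvalues, and the info needed to
# project supplementary points.
pcoa_decompose <- function(d2, tol = 1e-9) {
  n <- nrow(d2)
  j <- diag(n) - matrix(1 / n, n, n)
  g <- -0.5 * j %*% d2 %*% j
  e <- eigen((g + t(g)) / 2, symmetric = TRUE)
  keep <- e$values > tol * max(abs(e$values))
  list(values = e$values[keep],
       vectors = e$vectors[, keep, drop = FALSE],
       scores = sweep(e$vectors[, keep, drop = FALSE], 2,
                      sqrt(e$values[keep]), "*"),
       diag_g = diag(g),
       n_dropped_negative = sum(e$values < -tol * max(abs(e$values))))
}

# Project a supplementary point onto existing PCoA axes from its squared
# distances to the training points (Gower's add-a-point formula).
pcoa_project <- function(dec, d2_new) {
  as.numeric(0.5 * (t(dec$scores) %*% (dec$diag_g - d2_new)) / dec$values)
}

# Canonical discriminant analysis of scores (rows) against group labels.
# Solves W^-1 B through the symmetric W^-1/2 B W^-1/2 form; a ridge is added
# (and flagged) when the pooled within-group covariance is singular.
cda_fit <- function(scores, groups, ridge = 1e-8) {
  groups <- factor(groups)
  m <- ncol(scores)
  centroids <- apply(scores, 2, tapply, groups, mean)
  if (nlevels(groups) == 1) stop("need >= 2 groups")
  centroids <- matrix(centroids, nrow = nlevels(groups),
                      dimnames = list(levels(groups), NULL))
  w <- matrix(0, m, m); b <- matrix(0, m, m)
  grand <- colMeans(scores)
  for (lv in levels(groups)) {
    x <- scores[groups == lv, , drop = FALSE]
    cc <- centroids[lv, ]
    xc <- sweep(x, 2, cc)
    w <- w + crossprod(xc)
    b <- b + nrow(x) * tcrossprod(cc - grand)
  }
  w <- w / (nrow(scores) - nlevels(groups))
  ridged <- FALSE
  ew <- eigen((w + t(w)) / 2, symmetric = TRUE)
  if (min(ew$values) < ridge * max(ew$values)) {
    w <- w + diag(ridge * max(max(ew$values), 1), m)
    ew <- eigen((w + t(w)) / 2, symmetric = TRUE)
    ridged <- TRUE
  }
  w_inv_sqrt <- ew$vectors %*% diag(1 / sqrt(ew$values), m) %*% t(ew$vectors)
  eb <- eigen(w_inv_sqrt %*% b %*% w_inv_sqrt, symmetric = TRUE)
  n_axes <- min(m, nlevels(groups) - 1)
  a <- w_inv_sqrt %*% eb$vectors[, seq_len(n_axes), drop = FALSE]
  list(coef = a, centroids_canonical = centroids %*% a,
       groups = levels(groups), ridged = ridged)
}

cda_allocate <- function(fit, score) {
  z <- as.numeric(score %*% fit$coef)
  d2 <- rowSums(sweep(fit$centroids_canonical, 2, z)^2)
  fit$groups[which.min(d2)]
}

# LOO allocation of every sample for a fixed number of PCoA axes m.
# True leave-one-out: the PCoA axes and the canonical discriminant are
# recomputed without the held-out sample, which is then projected onto them.
cap_loo <- function(d2, groups, m) {
  n <- nrow(d2)
  alloc <- character(n)
  for (i in seq_len(n)) {
    dec <- pcoa_decompose(d2[-i, -i, drop = FALSE])
    mi <- min(m, ncol(dec$scores))
    train <- dec$scores[, seq_len(mi), drop = FALSE]
    fit <- cda_fit(train, groups[-i])
    q <- pcoa_project(dec, d2[-i, i])[seq_len(mi)]
    alloc[i] <- cda_allocate(fit, q)
  }
  alloc
}

#' Canonical analysis of principal coordinates with LOO classification
#'
#' CAP in the Anderson & Willis construction: (1) principal-coordinate
#' analysis of the chosen distance (Euclidean by default); (2) canonical
#' discriminant analysis of the first m PCoA axes against the group factor;
#' (3) leave-one-out allocation success, with the held-out sample projected
#' onto axes recomputed without it and allocated to the nearest group
#' centroid in canonical space; (4) m chosen to maximize LOO success
#' (smallest m on ties) unless fixed by the caller; (5) permutation test of
#' the canonical trace statistic tr(Q'm H Qm) under group-label permutation.
#'
#' @param features Numeric matrix or data.frame, rows = samples.
#' @param groups Group labels, length `nrow(features)`.
#' @param distance Distance metric passed to [stats::dist()].
#' @param m_rule `"max_loo"` or a fixed integer number of PCoA axes.
#' @param n_perm Number of label permutations for the trace test.
#' @param seed RNG seed for the permutations (recorded in the result).
#' @return List of class `cap_result`: `eigenvalues`, `m`, `m_rule`,
#'   `scores` (canonical axis scores of all samples), `confusion`
#'   (groups x allocated), `accuracy_pct`, `loo_by_m`, `trace_stat`,
#'   `p_permutation`, `n_perm`, `seed`.
#' @export
cap <- function(features, groups, distance = "euclidean",
                m_rule = "max_loo", n_perm = 999, seed = 1L) {
  x <- as.matrix(features)
  groups <- factor(groups)
  n <- nrow(x)
  if (n < nlevels(groups) + 1) stop("need n >= number of groups + 1")
  if (any(table(groups) < 2)) stop("each group needs >= 2 samples")
  d2 <- as.matrix(stats::dist(x, method = distance))^2
  dec <- pcoa_decompose(d2)
  if (dec$n_dropped_negative > 0) {
    warning(dec$n_dropped_negative,
            " negative-eigenvalue PCoA axes excluded")
  }
  m_max <- min(ncol(dec$scores), n - nlevels(groups))
  if (m_max < 1) stop("not enough positive PCoA axes")
  if (identical(m_rule, "max_loo")) {
    cand <- seq_len(m_max)
    acc <- vapply(cand, function(m) {
      mean(cap_loo(d2, groups, m) == as.character(groups))
    }, numeric(1))
    m <- cand[which.max(acc)]  # which.max takes the smallest on ties
    loo_by_m <- stats::setNames(acc * 100, cand)
    alloc <- cap_loo(d2, groups, m)
  } else {
    m <- min(as.integer(m_rule), m_max)
    alloc <- cap_loo(d2, groups, m)
    loo_by_m <- stats::setNames(mean(alloc == as.character(groups)) * 100, m)
  }
  confusion <- table(observed = groups,
                     allocated = factor(alloc, levels = levels(groups)))
  accuracy <- 100 * sum(diag(confusion)) / n

  # canonical scores on the full data for plotting
  full_fit <- cda_fit(dec$scores[, seq_len(m), drop = FALSE], groups)
  scores <- dec$scores[, seq_len(m), drop = FALSE] %*% full_fit$coef

  # trace statistic tr(Q'm H Qm) on orthonormal axes, permutation p
  q <- dec$vectors[, seq_len(m), drop = FALSE]
  h <- group_hat_matrix(groups)
  stat <- sum(diag(t(q) %*% h %*% q))
  set.seed(seed)
  perm <- replicate(n_perm, {
    idx <- sample.int(n)
    qp <- q[idx, , drop = FALSE]
    sum(diag(t(qp) %*% h %*% qp))
  })
  p_perm <- (1 + sum(perm >= stat)) / (n_perm + 1)

  structure(list(
    eigenvalues = dec$values, m = m, m_rule = m_rule,
    scores = scores, confusion = confusion, accuracy_pct = accuracy,
    loo_by_m = loo_by_m, trace_stat = stat, p_permutation = p_perm,
    n_perm = n_perm, seed = seed, ridged = full_fit$ridged
  ), class = "cap_result")
}

group_hat_matrix <- function(groups) {
  groups <- factor(groups)
  xg <- stats::model.matrix(~ groups - 1)
  xg %*% solve(crossprod(xg)) %*% t(xg)
}

#' @export
print.cap_result <- function(x, ...) {
  cat("CAP:", x$m, "PCoA axes; LOO correct classification",
      sprintf("%.1f%%", x$accuracy_pct), "\n")
  cat("trace statistic", sprintf("%.3f", x$trace_stat),
      sprintf("(permutation p = %.4g, %d permutations)\n",
              x$p_permutation, x$n_perm))
  print(x$confusion)
  invisible(x)
}
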