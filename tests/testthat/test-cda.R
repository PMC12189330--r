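# small labeled table with a controllable group-mean shift on column 1
planted_table <- function(n_per = 50, delta = 0, p = 3, seed = 1) {
  set.seed(seed)
  g <- rep(c("G1", "G2"), each = n_per)
  X <- matrix(stats::rnorm(2 * n_per * p), ncol = p,
              dimnames = list(NULL, paste0("v", seq_len(p))))
  X[g == "G2", 1] <- X[g == "G2", 1] + delta
  list(features = as.data.frame(X), group = factor(g))
}

test_that("VIF screen flags exact dependence and spares independent noise", {
  set.seed(10)
  z <- stats::rnorm(200)
  dup <- data.frame(a = z, b = 2 * z, c = stats::rnorm(200))
  out <- collinearity_screen(dup)
  expect_equal(out$removed$column, "b")      # rightmost of the tied infinite pair
  expect_equal(out$removed$vif, Inf)
  noise <- as.data.frame(matrix(stats::rnorm(5000), ncol = 5))
  out2 <- collinearity_screen(noise)
  expect_equal(nrow(out2$removed), 0L)
  expect_true(all(out2$vif < 1.2))
  expect_error(collinearity_screen(noise[, 1, drop = FALSE]), "at least 2")
})

test_that("screen on an invariant-honoring feature table drops the redundant trio", {
  set.seed(11)
  C <- stats::rexp(300, 500)
  # founder columns: strongly collinear with each other, only moderately with C
  f1 <- 0.3 * C + stats::rexp(300, 800)
  tab <- data.frame(loop_contribution = 2 * C,
                    founder_to_meanF = f1,
                    founder_to_meanCoancestry = 0.5 * f1 + stats::rnorm(300, 0, 2e-5),
                    coancestry_C = C,
                    alpha = 1 - 1 / (1 - C))
  out <- collinearity_screen(tab)
  expect_true(all(c("coancestry_C", "alpha") %in% out$removed$column))
  expect_true("loop_contribution" %in% names(out$vif))  # the earlier scale survives
  expect_true(any(c("founder_to_meanF", "founder_to_meanCoancestry") %in%
                    out$removed$column))
})

test_that("forward stepwise selection finds a planted discriminating column", {
  pt <- planted_table(n_per = 100, delta = 2, p = 4, seed = 12)
  sel <- stepwise_variable_selection(pt$features, pt$group)
  expect_equal(sel$selected[1], "v1")
  # a perfectly collinear copy of the selected column adds nothing
  pt$features$v1copy <- pt$features$v1
  sel2 <- stepwise_variable_selection(pt$features, pt$group)
  expect_false(all(c("v1", "v1copy") %in% sel2$selected))
  # pure noise: empty (or rarely a single spurious pick) with a warning path
  nt <- planted_table(n_per = 100, delta = 0, p = 3, seed = 13)
  sel3 <- suppressWarnings(stepwise_variable_selection(nt$features, nt$group))
  expect_lte(length(sel3$selected), 1L)
})

test_that("one-variable two-group CDA reduces to the F-ratio closed form", {
  pt <- planted_table(n_per = 40, delta = 1.5, p = 1, seed = 14)
  fit <- fit_canonical_discriminant(pt$features, pt$group)
  x <- pt$features$v1; g <- pt$group
  ssb <- sum(tapply(x, g, length) * (tapply(x, g, mean) - mean(x))^2)
  ssw <- sum((x - ave(x, g))^2)
  expect_length(fit$lambda, 1L)
  expect_equal(fit$lambda, ssb / ssw, tolerance = 1e-10)
  # canonical correlation arithmetic at a published eigenvalue: below the
  # 0.30 emphasis threshold
  expect_equal(round(sqrt(0.0157 / 1.0157), 4), 0.1243)
  expect_lt(sqrt(0.0157 / 1.0157), 0.30)
})

test_that("label permutation collapses the leading eigenvalue", {
  pt <- planted_table(n_per = 60, delta = 3, p = 2, seed = 15)
  fit <- fit_canonical_discriminant(pt$features, pt$group)
  set.seed(16)
  perm <- fit_canonical_discriminant(pt$features, sample(pt$group))
  expect_lt(perm$lambda[1], fit$lambda[1] / 10)
})

test_that("model invariants hold: Wilks and Pillai identities, loadings, centroids", {
  set.seed(17)
  g <- factor(rep(c("a", "b", "c"), each = 40))
  X <- as.data.frame(matrix(stats::rnorm(360), ncol = 3))
  X[[1]] <- X[[1]] + 0.8 * (g == "b")
  fit <- fit_canonical_discriminant(X, g)
  expect_equal(length(fit$lambda), 2L)   # min(p, g - 1)
  expect_true(all(diff(fit$lambda) <= 1e-12))
  expect_equal(sum(fit$percent_discrimination), 100)
  tst <- discriminant_significance_tests(fit)
  expect_equal(tst$wilks$lambda * prod(1 + fit$lambda), 1, tolerance = 1e-12)
  expect_equal(tst$pillai$V, sum(fit$lambda / (1 + fit$lambda)), tolerance = 1e-12)
  expect_true(all(abs(fit$loadings) <= 1 + 1e-8))
  # scores have unit pooled within-group variance
  sw <- sum((fit$scores[, 1] - ave(fit$scores[, 1], g))^2) / (nrow(X) - 3)
  expect_equal(sw, 1, tolerance = 1e-10)
})

test_that("significance tests reconstruct the published statistics from eigenvalues", {
  l1 <- 0.0157
  lam <- c(l1, l1 * 19.04 / 79.72, l1 * 1.25 / 79.72)
  L <- prod(1 / (1 + lam))
  V <- sum(lam / (1 + lam))
  expect_equal(round(L, 4), 0.9806)
  expect_equal(round(V, 4), 0.0194)
  # null case: a single zero eigenvalue
  pt <- planted_table(n_per = 30, delta = 0, p = 1, seed = 18)
  fit <- fit_canonical_discriminant(pt$features, pt$group)
  fit$lambda <- 0
  tst <- discriminant_significance_tests(fit)
  expect_equal(tst$wilks$lambda, 1)
  expect_equal(tst$pillai$V, 0)
  expect_equal(tst$wilks$p_value, 1)
})

test_that("Pillai's F approximation reproduces the published degrees of freedom", {
  # p = 3 variables, g = 4 groups, n = 912 rows: DF1 = 9, DF2 = 2724
  p <- 3; g <- 4; n <- 912
  s <- min(p, g - 1)
  m_ <- (abs(p - g + 1) - 1) / 2
  nn <- (n - g - p - 1) / 2
  expect_equal(s * (2 * m_ + s + 1), 9)
  expect_equal(s * (2 * nn + s + 1), 2724)
})

test_that("LOOCV separates planted groups and degrades under shuffling", {
  pt <- planted_table(n_per = 50, delta = 10, p = 2, seed = 19)
  rep <- loocv_classification(pt$features, pt$group)
  expect_gte(rep$hit_ratio, 0.98)
  expect_gt(rep$press_q, 6.63)
  expect_equal(sum(rep$confusion), 100)
  expect_equal(unname(rowSums(rep$confusion)), c(50, 50))
  # hand-evaluated Press's Q: N = 100, K = 2, all correct
  expect_equal((100 - 100 * 2)^2 / (100 * (2 - 1)), 100)
  set.seed(20)
  shuf <- loocv_classification(pt$features, sample(pt$group))
  expect_lt(shuf$hit_ratio, 0.65)
  # LOOCV never beats resubstitution on average over repeats
  diffs <- vapply(1:5, function(k) {
    q <- planted_table(n_per = 25, delta = 1, p = 3, seed = 20 + k)
    r <- loocv_classification(q$features, q$group)
    r$resubstitution_hit_ratio - r$hit_ratio
  }, numeric(1))
  expect_gte(mean(diffs), 0)
})

test_that("hit ratios are invariant to affine rescaling of the features", {
  pt <- planted_table(n_per = 40, delta = 1.2, p = 3, seed = 26)
  r1 <- loocv_classification(pt$features, pt$group)
  scaled <- sweep(sweep(pt$features, 2, c(100, 0.01, 7), "*"), 2, c(1, -5, 0.3), "+")
  r2 <- loocv_classification(scaled, pt$group)
  expect_equal(r1$hit_ratio, r2$hit_ratio)
  expect_equal(unclass(r1$confusion), unclass(r2$confusion))
})

test_that("Mahalanobis centroid distances obey the metric closed forms", {
  pt <- planted_table(n_per = 60, delta = 2, p = 1, seed = 21)
  fit <- fit_canonical_discriminant(pt$features, pt$group)
  D <- mahalanobis_centroid_distances(fit)
  expect_equal(diag(D), c(G1 = 0, G2 = 0))
  expect_equal(D, t(D))
  # univariate case: distance = centroid gap / pooled sd
  gap <- abs(diff(tapply(pt$features$v1, pt$group, mean)))
  s <- sqrt(fit$Sw[1, 1])
  expect_equal(D["G1", "G2"], unname(gap / s), tolerance = 1e-10)
  # duplicated group: off-diagonal zero
  X2 <- rbind(pt$features, pt$features)
  g2 <- factor(c(as.character(pt$group), sub("G", "H", pt$group)))
  D2 <- mahalanobis_centroid_distances(fit_canonical_discriminant(X2, g2))
  expect_equal(D2["G1", "H1"], 0)
})

test_that("UPGMA dendrogram matches a brute-force agglomeration oracle", {
  D <- matrix(c(0, 1, 10, 1, 0, 10, 10, 10, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  dd <- distance_dendrogram(D)
  expect_equal(dd$hclust$merge[1, ], c(-1, -2))   # A and B merge first
  expect_setequal(dd$phylo$tip.label, c("A", "B", "C"))
  expect_match(dd$newick, "^\\(")
  zero <- matrix(0, 3, 3, dimnames = dimnames(D))
  expect_equal(max(distance_dendrogram(zero)$hclust$height), 0)
  expect_error(distance_dendrogram(D[1, 1, drop = FALSE]), "at least 2")

  set.seed(23)
  P <- matrix(stats::rnorm(16), 8, 2)
  R <- as.matrix(stats::dist(P))
  dimnames(R) <- list(letters[1:8], letters[1:8])
  hc <- distance_dendrogram(R)$hclust
  expect_equal(hc$height, naive_upgma(R), tolerance = 1e-12)
})

test_that("feature assembly satisfies the scale and alpha identities", {
  cfg <- sim_config(seed = 99)
  ped <- generate_structured_pedigree(cfg)
  ref <- subset_population(ped, "reference", both_parents_known = TRUE)
  ft <- assemble_ancestor_features(ped, ref$member_ids)
  expect_gt(nrow(ft), 0)
  expect_equal(ft$loop_contribution, 2 * ft$coancestry_C, tolerance = 1e-12)
  expect_equal(ft$alpha, 1 - 1 / (1 - ft$coancestry_C), tolerance = 1e-12)
  expect_true(all(rowSums(abs(as.matrix(ft[, c("loop_contribution",
    "founder_to_meanF", "founder_to_meanCoancestry", "coancestry_C")]))) > 0))
  expect_true(all(ft$id %in% c(ped$sire, ped$dam)))
  # ancestors without origin labels are excluded with a warning
  ped2 <- ped
  ped2$municipality[1] <- NA
  ped2$province[1] <- NA
  if (ped$id[1] %in% ft$id)
    expect_warning(assemble_ancestor_features(ped2, ref$member_ids), "origin label")
})
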