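#' Assemble the per-ancestor feature table for discriminant analysis
#'
#' One row per identified ancestor (an animal appearing as sire or dam of at
#' least one pedigree record) carrying the five genetic variables used to
#' discriminate birth origins:
#' \describe{
#'   \item{loop_contribution}{the ancestor's marginal NCA contribution to the
#'     reference population's mean inbreeding coefficient through closed
#'     inbreeding loops, relationship scale (zero for ancestors that close
#'     no loop);}
#'   \item{founder_to_meanF}{founder contribution to the mean inbreeding
#'     coefficient (zero for non-founders);}
#'   \item{founder_to_meanCoancestry}{founder contribution to the mean
#'     coancestry;}
#'   \item{coancestry_C}{the same loop contribution on the coancestry
#'     (probability-of-IBD) scale, so loop_contribution = 2 * coancestry_C
#'     holds for every row;}
#'   \item{alpha}{the per-record non-random mating coefficient implied by the
#'     Caballero-Toro identity with the record's own inbreeding term zeroed:
#'     alpha = 1 - 1/(1 - C).}
#' }
#' plus the ancestor's birth municipality and province. Ancestors with all
#' contributions zero are dropped; ancestors without an origin label are
#' excluded with a warning.
#'
#' @param ped pedigree.
#' @param reference_ids member ids of the reference population.
#' @return data frame of features; attribute `excluded_no_label` lists
#'   ancestors dropped for missing origin labels.
#' @export
assemble_ancestor_features <- function(ped, reference_ids) {
  stopifnot(inherits(ped, "pedigree"))
  b <- mendelian_sampling_variances(ped)
  m_f <- msv_decomposition_group(ped, reference_ids, "mean_coancestry", b = b)
  u_f <- nca_contributions(ped, m_f)
  m_F <- msv_decomposition_group(ped, reference_ids, "mean_F", b = b)
  u_F <- nca_contributions(ped, m_F)
  v_F <- founder_contributions(ped, u_F)
  v_f <- founder_contributions(ped, u_f)

  is_parent <- ped$id %in% c(ped$sire, ped$dam)
  anc <- ped$id[is_parent]
  take <- function(w, ids) {
    out <- stats::setNames(numeric(length(ids)), ids)
    hit <- intersect(names(w), ids)
    out[hit] <- w[hit]
    out
  }
  C <- take(u_F$weights, anc)
  feats <- data.frame(
    id = anc,
    loop_contribution = 2 * C,
    founder_to_meanF = take(v_F$v, anc),
    founder_to_meanCoancestry = take(v_f$v, anc),
    coancestry_C = C,
    alpha = 1 - 1 / (1 - C),
    municipality = ped$municipality[match(anc, ped$id)],
    province = ped$province[match(anc, ped$id)],
    stringsAsFactors = FALSE
  )
  num <- c("loop_contribution", "founder_to_meanF", "founder_to_meanCoancestry",
           "coancestry_C", "alpha")
  feats <- feats[rowSums(abs(as.matrix(feats[num]))) > 0, , drop = FALSE]
  no_label <- feats$id[is.na(feats$municipality) & is.na(feats$province)]
  if (length(no_label)) {
    warning(length(no_label), " ancestor(s) without origin label excluded")
    feats <- feats[!feats$id %in% no_label, , drop = FALSE]
  }
  rownames(feats) <- NULL
  attr(feats, "excluded_no_label") <- no_label
  feats
}

# VIF of every column of a numeric matrix; exact linear dependence -> Inf
.vif <- function(X) {
  p <- ncol(X)
  vapply(seq_len(p), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    tss <- sum((X[, j] - mean(X[, j]))^2)
    if (tss == 0) return(Inf)
    r2 <- 1 - sum(fit$residuals^2) / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Multicollinearity screen by variance inflation factors
#'
#' Iteratively removes the column with the largest VIF while any VIF exceeds
#' the threshold. VIF_j = 1/(1 - R^2_j) from regressing column j on the
#' remaining columns; exact linear dependence is reported as infinite VIF.
#' Ties at the maximum (e.g. a pair of exactly proportional columns) are
#' broken by dropping the rightmost tied column, so earlier columns take
#' precedence deterministically.
#'
#' @param features data frame; all numeric columns are screened, non-numeric
#'   columns pass through untouched.
#' @param threshold conservative VIF cut-off (default 5).
#' @return list with `features` (reduced), `removed` (data frame of dropped
#'   columns and their VIF at removal), `vif` and `tolerance` (= 1/VIF) of the
#'   surviving columns.
#' @export
collinearity_screen <- function(features, threshold = 5) {
  num <- names(features)[vapply(features, is.numeric, logical(1))]
  if (length(num) < 2) stop("need at least 2 numeric columns to screen")
  X <- as.matrix(features[num])
  removed <- data.frame(column = character(0), vif = numeric(0))
  repeat {
    v <- .vif(X)
    if (!any(v > threshold)) break
    if (ncol(X) <= 2)
      stop("collinearity screen would leave fewer than 2 columns")
    worst <- max(which(v == max(v)))
    removed <- rbind(removed, data.frame(column = colnames(X)[worst], vif = v[worst]))
    X <- X[, -worst, drop = FALSE]
  }
  v <- .vif(X)
  keep <- c(setdiff(names(features), num), colnames(X))
  list(features = features[, names(features)[names(features) %in% keep], drop = FALSE],
       removed = removed,
       vif = stats::setNames(v, colnames(X)),
       tolerance = stats::setNames(1 / v, colnames(X)))
}

#' Forward stepwise variable selection by regularized multinomial regression
#'
#' Greedy forward selection for the discriminant predictors: at each step the
#' candidate column giving the largest BIC improvement of a ridge-penalized
#' multinomial logistic regression of the group label (priors implicitly
#' weighted by group size) is added; selection stops when no candidate
#' improves the criterion.
#'
#' @param features data frame with numeric candidate columns.
#' @param group factor (or coercible) of group labels, one per row.
#' @param decay ridge (weight-decay) penalty passed to [nnet::multinom()].
#' @return list with `selected` (character, possibly empty with a warning) and
#'   `trace` (data frame of steps and BIC values).
#' @export
stepwise_variable_selection <- function(features, group, decay = 1e-4) {
  group <- factor(group)
  num <- names(features)[vapply(features, is.numeric, logical(1))]
  X <- as.data.frame(scale(as.matrix(features[num])))
  X <- X[, vapply(X, function(z) all(is.finite(z)), logical(1)), drop = FALSE]
  n <- nrow(X)
  bic <- function(cols) {
    dat <- cbind(X[cols], .grp = group)
    fml <- if (length(cols)) stats::reformulate(cols, ".grp") else .grp ~ 1
    fit <- nnet::multinom(fml, data = dat, decay = decay, trace = FALSE, maxit = 500)
    fit$deviance + log(n) * (length(cols) + 1) * (nlevels(group) - 1)
  }
  selected <- character(0)
  best <- bic(selected)
  trace <- data.frame(step = 0L, added = NA_character_, bic = best)
  repeat {
    cand <- setdiff(colnames(X), selected)
    if (!length(cand)) break
    vals <- vapply(cand, function(cl) bic(c(selected, cl)), numeric(1))
    if (min(vals) >= best) break
    add <- cand[which.min(vals)]
    selected <- c(selected, add)
    best <- min(vals)
    trace <- rbind(trace, data.frame(step = nrow(trace), added = add, bic = best))
  }
  if (!length(selected)) warning("no variable improves the selection criterion")
  list(selected = selected, trace = trace)
}

#' Fit a canonical discriminant analysis
#'
#' Eigen-solution of within-scatter^-1 between-scatter, giving
#' min(p, g - 1) canonical functions. Raw coefficients are scaled so that
#' canonical scores have unit pooled within-group variance; standardized
#' coefficients multiply by the pooled within-group standard deviations;
#' structure loadings are the pooled within-group correlations between each
#' variable and each canonical score. A singular within-scatter is ridge
#' inflated (epsilon = 1e-8 trace/p) with a warning; drop exactly dependent
#' columns (see [collinearity_screen()]) before fitting.
#'
#' @param features data frame (numeric columns are used) or numeric matrix.
#' @param group factor of group labels.
#' @param min_obs_ratio warn when the observation-to-variable ratio falls
#'   below this value (default 4, the conventional 4:1 floor).
#' @return an object of class `cda`.
#' @export
fit_canonical_discriminant <- function(features, group, min_obs_ratio = 4) {
  group <- droplevels(factor(group))
  num <- if (is.data.frame(features))
    as.matrix(features[vapply(features, is.numeric, logical(1))])
  else as.matrix(features)
  X <- num
  n <- nrow(X); p <- ncol(X); g <- nlevels(group)
  if (g < 2) stop("need at least 2 groups")
  if (min(table(group)) < 2) stop("every group needs at least 2 rows")
  if (p < 1) stop("need at least 1 numeric variable")
  if (n / p < min_obs_ratio)
    warning(sprintf("observation-to-variable ratio %.1f:1 below %g:1", n / p, min_obs_ratio))

  gm <- rowsum(X, group) / as.vector(table(group))
  xbar <- colMeans(X)
  R <- X - gm[group, , drop = FALSE]
  W <- crossprod(R)
  ns <- as.vector(table(group))
  D <- sweep(gm, 2, xbar)
  B <- crossprod(D * sqrt(ns))

  ridge_used <- FALSE
  Rc <- tryCatch(chol(W), error = function(e) NULL)
  if (is.null(Rc) || rcond(W) < 1e-12) {
    eps <- 1e-8 * sum(diag(W)) / p
    W <- W + diag(eps, p)
    Rc <- chol(W)
    ridge_used <- TRUE
    warning("singular within-group scatter; ridge inflated by ", format(eps))
  }
  Ri <- backsolve(Rc, diag(p))
  K <- t(Ri) %*% B %*% Ri
  ev <- eigen((K + t(K)) / 2, symmetric = TRUE)
  q <- min(p, g - 1)
  lambda <- pmax(ev$values[seq_len(q)], 0)
  A <- Ri %*% ev$vectors[, seq_len(q), drop = FALSE]
  # unit pooled within-group variance of scores: a' (W/(n-g)) a = 1
  A <- A * sqrt(n - g)
  # deterministic sign: largest-|coefficient| entry positive
  for (k in seq_len(q)) {
    jmx <- which.max(abs(A[, k]))
    if (A[jmx, k] < 0) A[, k] <- -A[, k]
  }
  Sw <- W / (n - g)
  scores <- sweep(X, 2, xbar) %*% A
  centroids <- rowsum(scores, group) / ns
  dimnames(A) <- list(colnames(X), paste0("F", seq_len(q)))
  colnames(scores) <- colnames(A)
  loadings <- (Sw %*% A) / sqrt(diag(Sw))
  dimnames(loadings) <- dimnames(A)

  structure(list(
    lambda = lambda,
    percent_discrimination = if (sum(lambda) > 0) 100 * lambda / sum(lambda) else rep(NA_real_, q),
    canonical_correlation = sqrt(lambda / (1 + lambda)),
    coef_raw = A,
    coef_std = A * sqrt(diag(Sw)),
    loadings = loadings,
    centroids = centroids,
    Sw = Sw, W = W, B = B,
    grand_mean = xbar,
    group_means = gm,
    group_sizes = stats::setNames(ns, levels(group)),
    scores = scores,
    group = group,
    n = n, p = p, g = g,
    ridge_used = ridge_used
  ), class = "cda")
}

#' @export
print.cda <- function(x, ...) {
  cat(sprintf("canonical discriminant analysis: %d rows, %d variables, %d groups\n",
              x$n, x$p, x$g))
  tab <- data.frame(eigenvalue = x$lambda,
                    percent = x$percent_discrimination,
                    canonical_correlation = x$canonical_correlation)
  rownames(tab) <- colnames(x$coef_raw)
  print(round(tab, 4))
  invisible(x)
}

#' Significance tests for a canonical discriminant model
#'
#' Wilks' Lambda = prod 1/(1 + lambda_i) with Rao's F approximation;
#' Bartlett's residual chi-square for each function,
#' chi2_k = -(n - 1 - (p + g)/2) log Lambda_k with df (p - k)(g - 1 - k);
#' Pillai's trace V = sum lambda_i/(1 + lambda_i) with its F approximation;
#' and per-variable one-way (univariate) Wilks/F tests of equality of group
#' means.
#'
#' @param model a `cda` fit.
#' @param features,group optionally re-supply the data for the univariate
#'   tests (defaults to what the model stored).
#' @return list with components `wilks`, `bartlett`, `pillai`, `univariate`.
#' @export
discriminant_significance_tests <- function(model, features = NULL, group = NULL) {
  stopifnot(inherits(model, "cda"))
  n <- model$n; p <- model$p; g <- model$g
  if (n <= g + p) stop("insufficient residual degrees of freedom (n <= g + p)")
  lambda <- model$lambda

  L <- prod(1 / (1 + lambda))
  t_ <- n - 1 - (p + g) / 2
  df1 <- p * (g - 1)
  s2 <- if (p^2 + (g - 1)^2 - 5 > 0) sqrt((p^2 * (g - 1)^2 - 4) / (p^2 + (g - 1)^2 - 5)) else 1
  df2 <- t_ * s2 - (df1 - 2) / 2
  Ls <- L^(1 / s2)
  Fw <- if (L < 1) (1 - Ls) / Ls * df2 / df1 else 0
  wilks <- list(lambda = L, F = Fw, df1 = df1, df2 = df2,
                p_value = stats::pf(Fw, df1, df2, lower.tail = FALSE))

  bart <- do.call(rbind, lapply(seq_along(lambda), function(k) {
    Lk <- prod(1 / (1 + lambda[seq.int(k, length(lambda))]))
    chi2 <- -(n - 1 - (p + g) / 2) * log(Lk)
    df <- (p - (k - 1)) * (g - k)
    data.frame(fn = k, residual_lambda = Lk, chi2 = chi2, df = df,
               p_value = if (df > 0) stats::pchisq(chi2, df, lower.tail = FALSE) else NA_real_)
  }))

  V <- sum(lambda / (1 + lambda))
  s <- min(p, g - 1)
  m_ <- (abs(p - g + 1) - 1) / 2
  nn <- (n - g - p - 1) / 2
  pf1 <- s * (2 * m_ + s + 1)
  pf2 <- s * (2 * nn + s + 1)
  Fp <- if (V < s) ((2 * nn + s + 1) * V) / ((2 * m_ + s + 1) * (s - V)) else Inf
  pillai <- list(V = V, F = Fp, df1 = pf1, df2 = pf2,
                 p_value = stats::pf(Fp, pf1, pf2, lower.tail = FALSE))

  univariate <- NULL
  X <- if (!is.null(features)) {
    as.matrix(features[vapply(features, is.numeric, logical(1))])
  } else NULL
  grp <- if (!is.null(group)) factor(group) else model$group
  if (is.null(X) && !is.null(model$scores)) {
    # reconstruct from stored scatter: per-variable Wilks = diag(W)/diag(W+B)
    dW <- diag(model$W); dT <- diag(model$W + model$B)
    lam_u <- dW / dT
    Fu <- (1 - lam_u) / lam_u * (n - g) / (g - 1)
    univariate <- data.frame(variable = rownames(model$coef_raw),
                             wilks = lam_u, F = Fu, df1 = g - 1, df2 = n - g,
                             p_value = stats::pf(Fu, g - 1, n - g, lower.tail = FALSE))
    rownames(univariate) <- NULL
  }
  list(wilks = wilks, bartlett = bart, pillai = pillai, univariate = univariate)
}

# pooled within-group covariance and group means with one row removed,
# ridge fallback mirroring the main fit
.lda_train <- function(X, group, drop = NULL) {
  if (!is.null(drop)) {
    X <- X[-drop, , drop = FALSE]
    group <- droplevels(group[-drop])
  }
  ns <- table(group)
  gm <- rowsum(X, group) / as.vector(ns)
  R <- X - gm[group, , drop = FALSE]
  S <- crossprod(R) / (nrow(X) - nlevels(group))
  p <- ncol(X)
  Si <- tryCatch({
    if (rcond(S) < 1e-12) stop("singular")
    solve(S)
  }, error = function(e) solve(S + diag(1e-8 * sum(diag(S)) / p, p)))
  list(means = gm, Si = Si, ns = ns, levels = levels(group))
}

#' Leave-one-out cross-validated classification
#'
#' For every row, the classification functions (group centroids and pooled
#' within-group covariance) are refit without it, and the row is assigned to
#' the group minimizing the Mahalanobis distance to the centroid penalized by
#' -2 log(prior). Reports the confusion matrix, per-group and overall hit
#' ratios, the resubstitution hit ratio, Press's Q = (N - nK)^2 / (N (K - 1))
#' against the 6.63 critical value, and the proportional- and maximum-chance
#' criteria with the 1.25x rule.
#'
#' @param features data frame or matrix of predictors.
#' @param group factor of group labels.
#' @param priors "proportional" (group-size weighted) or "uniform".
#' @return list of class `classification_report`.
#' @export
loocv_classification <- function(features, group, priors = c("proportional", "uniform")) {
  priors <- match.arg(priors)
  group <- droplevels(factor(group))
  X <- if (is.data.frame(features))
    as.matrix(features[vapply(features, is.numeric, logical(1))])
  else as.matrix(features)
  n <- nrow(X); K <- nlevels(group)
  if (any(table(group) == 1))
    warning("group(s) of size 1 can never be correctly assigned under LOOCV: ",
            paste(names(which(table(group) == 1)), collapse = ", "))

  classify <- function(x, fit) {
    pr <- if (priors == "proportional") as.vector(fit$ns) / sum(fit$ns)
          else rep(1 / length(fit$ns), length(fit$ns))
    d2 <- vapply(seq_along(fit$levels), function(k) {
      dv <- x - fit$means[k, ]
      as.numeric(dv %*% fit$Si %*% dv)
    }, numeric(1))
    fit$levels[which.min(d2 - 2 * log(pr))]
  }

  full <- .lda_train(X, group)
  resub <- vapply(seq_len(n), function(i) classify(X[i, ], full), character(1))
  pred <- vapply(seq_len(n), function(i) classify(X[i, ], .lda_train(X, group, drop = i)),
                 character(1))
  pred <- factor(pred, levels = levels(group))
  confusion <- table(prior = group, posterior = pred)
  correct <- sum(diag(confusion))
  hit <- correct / n
  per_group <- diag(confusion) / rowSums(confusion)
  Q <- (n - correct * K)^2 / (n * (K - 1))
  shares <- as.vector(table(group)) / n
  c_pro <- sum(shares^2)
  c_max <- max(shares)
  structure(list(
    confusion = confusion,
    hit_ratio = hit,
    per_group_hit = per_group,
    resubstitution_hit_ratio = mean(resub == as.character(group)),
    press_q = Q,
    press_q_critical = 6.63,
    press_q_significant = Q > 6.63,
    chance = list(proportional = c_pro, maximum = c_max,
                  beats_proportional_25 = hit >= 1.25 * c_pro,
                  beats_maximum_25 = hit >= 1.25 * c_max),
    priors = priors, n = n, K = K
  ), class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("LOOCV hit ratio %.3f (resubstitution %.3f); Press's Q %.2f (crit %.2f)\n",
              x$hit_ratio, x$resubstitution_hit_ratio, x$press_q, x$press_q_critical))
  print(x$confusion)
  invisible(x)
}

#' Mahalanobis distances between group centroids
#'
#' Pairwise distances d_gh = sqrt((m_g - m_h)' S^-1 (m_g - m_h)) under the
#' pooled within-group covariance metric of a fitted model; zero diagonal,
#' symmetric.
#'
#' @param model a `cda` fit.
#' @return symmetric labeled matrix of distances.
#' @export
mahalanobis_centroid_distances <- function(model) {
  stopifnot(inherits(model, "cda"))
  gm <- model$group_means
  p <- ncol(gm)
  Si <- tryCatch({
    if (rcond(model$Sw) < 1e-12) stop("singular")
    solve(model$Sw)
  }, error = function(e) solve(model$Sw + diag(1e-8 * sum(diag(model$Sw)) / p, p)))
  g <- nrow(gm)
  D <- matrix(0, g, g, dimnames = list(rownames(gm), rownames(gm)))
  for (i in seq_len(g)) for (j in seq_len(g)) if (i < j) {
    dv <- gm[i, ] - gm[j, ]
    D[i, j] <- D[j, i] <- sqrt(max(0, as.numeric(dv %*% Si %*% dv)))
  }
  D
}

#' Hierarchical dendrogram from a distance matrix
#'
#' Agglomerates group centroids (UPGMA by default) and returns the tree both
#' as an `hclust` object and as a Newick string with branch lengths.
#'
#' @param distances symmetric distance matrix with labels.
#' @param linkage "average" (UPGMA), "single" or "complete".
#' @return list with `hclust`, `phylo` (an [ape] tree) and `newick`.
#' @export
distance_dendrogram <- function(distances, linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  if (nrow(distances) < 2) stop("need at least 2 groups for a dendrogram")
  hc <- stats::hclust(stats::as.dist(distances), method = linkage)
  tr <- ape::as.phylo(hc)
  list(hclust = hc, phylo = tr, newick = ape::write.tree(tr))
}
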