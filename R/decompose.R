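#' @name contribution
#' @title Per-ancestor contribution vectors
#' @description The decomposition functions return `contribution` objects: a
#' target statistic (an individual's F, a group's mean F, or a group's mean
#' coancestry), a scale ("coancestry" or "relationship", the latter exactly
#' twice the former), a named vector of nonnegative per-ancestor weights, and
#' the total they conserve. `nca_contribution` objects additionally carry the
#' set of nodal common ancestors (NCAs) — the ancestors at which the paternal
#' and maternal gene lineages first coalesce, closing an inbreeding loop.
NULL

.new_contribution <- function(kind, target, ids, scale, weights, total) {
  weights <- weights[weights != 0]
  structure(list(target = target, ids = ids, scale = scale,
                 weights = weights, total = total),
            class = c(kind, "contribution"))
}

#' @export
print.contribution <- function(x, ...) {
  cat(sprintf("%s decomposition of %s (%s scale): total %.8g over %d ancestors\n",
              if (inherits(x, "nca_contribution")) "NCA" else "MSV",
              x$target, x$scale, x$total, length(x$weights)))
  w <- sort(x$weights, decreasing = TRUE)
  print(utils::head(w, 10L))
  invisible(x)
}

# ancestor closure (positions), including the starting positions themselves
.anc_set <- function(si, di, start) {
  seen <- logical(length(si))
  stack <- start
  while (length(stack)) {
    h <- stack[[1L]]; stack <- stack[-1L]
    if (h > 0L && !seen[h]) {
      seen[h] <- TRUE
      stack <- c(stack, si[h], di[h])
    }
  }
  which(seen)
}

#' MSV decomposition of an individual's inbreeding coefficient
#'
#' Splits F of a focal animal into the Mendelian-sampling-variance
#' contributions of its ancestors: m_k = b_k c_k(sire) c_k(dam) on the
#' relationship scale (halved on the coancestry scale on which F itself
#' lives), where c_k(.) are genetic contributions. The weights are
#' nonnegative and sum exactly to the target statistic.
#'
#' @param ped pedigree.
#' @param id focal animal (both parents known for a non-empty result).
#' @param scale "coancestry" (sums to F) or "relationship" (sums to 2F).
#' @param b Mendelian sampling variances (computed if missing).
#' @return a `contribution` object.
#' @export
msv_decomposition_individual <- function(ped, id,
                                         scale = c("coancestry", "relationship"),
                                         b = mendelian_sampling_variances(ped)) {
  stopifnot(inherits(ped, "pedigree"))
  scale <- match.arg(scale)
  j <- .ped_pos(ped, id)
  s <- ped$sire_i[j]; d <- ped$dam_i[j]
  n <- nrow(ped)
  if (s == 0L || d == 0L)
    return(.new_contribution("msv_contribution", "individual_F", id, scale,
                             stats::setNames(numeric(0), character(0)), 0))
  cs <- .contrib_trace(ped$sire_i, ped$dam_i, s, n)
  cd <- .contrib_trace(ped$sire_i, ped$dam_i, d, n)
  m <- unname(b) * cs * cd
  if (scale == "coancestry") m <- m / 2
  .new_contribution("msv_contribution", "individual_F", id, scale,
                    stats::setNames(m, ped$id), sum(m))
}

#' MSV decomposition of a group statistic
#'
#' Decomposes a group's mean inbreeding or mean coancestry into per-ancestor
#' MSV contributions. Mean F is the average of the member decompositions,
#' implemented with one paired sire/dam tracing pass per distinct mating
#' (members sharing parents share a decomposition). Mean coancestry uses the
#' group-mean genetic contribution vector c-bar: m_k = b_k c-bar_k^2 on the
#' relationship scale, which conserves (1/n^2) x' A x exactly (self terms
#' included).
#'
#' @param ped pedigree.
#' @param ids group member ids.
#' @param target "mean_F" or "mean_coancestry".
#' @param scale "coancestry" or "relationship" (exactly twice the former).
#' @param b Mendelian sampling variances.
#' @return a `contribution` object.
#' @export
msv_decomposition_group <- function(ped, ids,
                                    target = c("mean_F", "mean_coancestry"),
                                    scale = c("coancestry", "relationship"),
                                    b = mendelian_sampling_variances(ped)) {
  stopifnot(inherits(ped, "pedigree"))
  target <- match.arg(target)
  scale <- match.arg(scale)
  if (!length(ids)) stop("empty group")
  pos <- .ped_pos(ped, ids)
  n <- nrow(ped)
  si <- ped$sire_i; di <- ped$dam_i
  bb <- unname(b)
  ng <- length(ids)

  if (target == "mean_F") {
    keep <- si[pos] > 0L & di[pos] > 0L
    m <- numeric(n)
    if (any(keep)) {
      mat <- paste(si[pos][keep], di[pos][keep])
      for (key in unique(mat)) {
        cnt <- sum(mat == key)
        sd_ <- as.integer(strsplit(key, " ", fixed = TRUE)[[1L]])
        cs <- .contrib_trace(si, di, sd_[1L], n)
        cd <- .contrib_trace(si, di, sd_[2L], n)
        m <- m + cnt * bb * cs * cd
      }
    }
    m <- m / ng            # relationship scale: sums to 2 * mean F
    tname <- "group_mean_F"
  } else {
    x <- numeric(n)
    for (p in pos) x[p] <- x[p] + 1
    cbar <- .contrib_trace(si, di, NA, n, w0 = x / ng)
    m <- bb * cbar^2       # relationship scale: sums to (1/n^2) x'Ax
    tname <- "group_mean_coancestry"
  }
  if (scale == "coancestry") m <- m / 2
  .new_contribution("msv_contribution", tname, ids, scale,
                    stats::setNames(m, ped$id), sum(m))
}

#' Nodal common ancestors of an individual
#'
#' The intersection of the sire-side and dam-side ancestor sets (each side
#' including the parent itself). These are the ancestors able to close an
#' inbreeding loop for the focal animal; for a non-inbred animal the set may
#' be empty. An NCA that is itself descended from another NCA captures the
#' older ancestor's genes, leaving the older one only a marginal (possibly
#' zero) contribution.
#'
#' @param ped pedigree.
#' @param id focal animal.
#' @return character vector of NCA ids (possibly empty).
#' @export
find_nodal_common_ancestors <- function(ped, id) {
  stopifnot(inherits(ped, "pedigree"))
  j <- .ped_pos(ped, id)
  s <- ped$sire_i[j]; d <- ped$dam_i[j]
  if (s == 0L || d == 0L) return(character(0))
  common <- intersect(.anc_set(ped$sire_i, ped$dam_i, s),
                      .anc_set(ped$sire_i, ped$dam_i, d))
  ped$id[sort(common)]
}

# first-coalescence pair elimination: W is a symmetric matrix of ordered
# lineage-pair weights; eliminating animals from youngest to oldest, a
# diagonal weight w at h is attributed as w * (1 + F_h) (the pair of lineages
# meets first at h) and off-diagonal pairs (i, h) are propagated to h's
# recorded parents with coefficient 1/2 (lineages through an unknown parent
# are lost). This is the upward-exploration tabular method; its attribution
# rule is exactly Wright's marginal path counting.
.pair_eliminate <- function(si, di, F, W) {
  n <- length(si)
  u <- numeric(n)
  for (h in seq.int(n, 1L)) {
    r <- W[h, ]
    if (all(r == 0)) next
    u[h] <- r[h] * (1 + F[h])
    r[h] <- 0
    W[h, ] <- 0
    W[, h] <- 0
    s <- si[h]; d <- di[h]
    if (s > 0L) {
      W[s, ] <- W[s, ] + 0.5 * r
      W[, s] <- W[, s] + 0.5 * r
    }
    if (d > 0L) {
      W[d, ] <- W[d, ] + 0.5 * r
      W[, d] <- W[, d] + 0.5 * r
    }
  }
  u
}

# build the seed matrix for a target and run the elimination; returns the
# per-ancestor attribution on the coancestry scale of the target
.nca_engine <- function(ped, target, ids, memory_cap_mb = 2048) {
  n <- nrow(ped)
  if (8 * n^2 / 2^20 > memory_cap_mb)
    stop("pair table would need ", round(8 * n^2 / 2^20, 2), " MB, above the ",
         "memory cap; use the MSV decomposition route for pedigrees this large")
  si <- ped$sire_i; di <- ped$dam_i
  F <- unname(compute_inbreeding(ped))
  W <- matrix(0, n, n)
  pos <- .ped_pos(ped, ids)
  ng <- length(ids)
  if (target == "individual_F" || target == "group_mean_F") {
    keep <- pos[si[pos] > 0L & di[pos] > 0L]
    for (p in keep) {
      s <- si[p]; d <- di[p]
      W[s, d] <- W[s, d] + 0.25 / ng
      W[d, s] <- W[d, s] + 0.25 / ng
    }
  } else if (target == "group_mean_coancestry") {
    for (p in pos) W[pos, p] <- W[pos, p] + 1 / (2 * ng^2)
  } else stop("unknown target: ", target)
  u <- .pair_eliminate(si, di, F, W)
  stats::setNames(u, ped$id)
}

#' Marginal contributions of nodal common ancestors
#'
#' Converts an MSV decomposition into the marginal contributions u of nodal
#' common ancestors: each non-NCA ancestor's weight is captured by the
#' nearest descendant NCA(s) on its paths to the target, so u is zero outside
#' the NCA set and conserves the same total as m. The conversion attributes
#' weight at the first coalescence of the paternal and maternal gene
#' lineages (see [upward_exploration()]); Wright's path counting
#' ([wright_path_counting()]) is the independent arbiter of this rule.
#'
#' @param ped pedigree.
#' @param m a `contribution` from [msv_decomposition_individual()] or
#'   [msv_decomposition_group()]; supplies the target, scale and the total
#'   that u must conserve.
#' @param tol consistency tolerance between sum(u) and m's total.
#' @return an `nca_contribution` object with elements `ncas` (for individual
#'   targets, the full common-ancestor set) and nonzero marginal `weights`.
#' @export
nca_contributions <- function(ped, m, tol = 1e-8) {
  stopifnot(inherits(ped, "pedigree"), inherits(m, "contribution"))
  u <- .nca_engine(ped, m$target, m$ids)
  if (m$scale == "relationship") u <- 2 * u
  total <- sum(u)
  if (abs(total - m$total) > tol)
    stop(sprintf("NCA conversion does not conserve the MSV total (%.3g vs %.3g): inconsistent m/pedigree", total, m$total))
  out <- .new_contribution("nca_contribution", m$target, m$ids, m$scale,
                           u, total)
  out$ncas <- if (m$target == "individual_F")
    find_nodal_common_ancestors(ped, m$ids) else names(out$weights)
  out
}

#' Founder contributions
#'
#' Pushes the marginal NCA contributions up to the founders: v = T' u with
#' t_jk the expected proportion of genes of ancestor j descending from
#' founder k (each animal's founder profile is half its sire's plus half its
#' dam's). The half-genome behind an unknown parent of a non-founder is
#' attributed to a flagged phantom founder ("<id>/sire" or "<id>/dam") so
#' that sum(v) = sum(u) exactly.
#'
#' @param ped pedigree.
#' @param u an `nca_contribution` (or any `contribution`) object.
#' @return list with `v` (named weights over founders and phantoms),
#'   `phantom` (logical, flags phantom and stub founders), `scale`, `total`.
#' @export
founder_contributions <- function(ped, u) {
  stopifnot(inherits(ped, "pedigree"), inherits(u, "contribution"))
  n <- nrow(ped)
  si <- ped$sire_i; di <- ped$dam_i
  founder <- attr(ped, "founder")
  w <- numeric(n)
  w[.ped_pos(ped, names(u$weights))] <- u$weights
  ph <- character(0); phw <- numeric(0)
  for (h in seq.int(n, 1L)) {
    v <- w[h]
    if (v == 0 || founder[h]) next
    if (si[h] > 0L) w[si[h]] <- w[si[h]] + 0.5 * v
    else { ph <- c(ph, paste0(ped$id[h], "/sire")); phw <- c(phw, 0.5 * v) }
    if (di[h] > 0L) w[di[h]] <- w[di[h]] + 0.5 * v
    else { ph <- c(ph, paste0(ped$id[h], "/dam")); phw <- c(phw, 0.5 * v) }
    w[h] <- 0
  }
  keep <- which(w != 0)
  v <- c(stats::setNames(w[keep], ped$id[keep]), stats::setNames(phw, ph))
  phantom <- c(ped$stub[keep], rep(TRUE, length(ph)))
  list(v = v, phantom = stats::setNames(phantom, names(v)),
       scale = u$scale, total = sum(v))
}

#' Wright's path counting
#'
#' Small-pedigree oracle for the NCA contributions: F of the focal animal is
#' the sum over all non-self-intersecting ancestral loops of
#' (1/2)^(n1 + n2 + 1) (1 + F_A), where n1 and n2 are the generation counts
#' from sire and dam up to the common ancestor A at the apex, and the two
#' branches share no animal besides A. Terms are accumulated per apex,
#' giving the marginal NCA contributions directly. Path enumeration is
#' exponential; a cap guards against explosion.
#'
#' @param ped pedigree.
#' @param id focal animal.
#' @param max_paths cap on the number of enumerated upward paths per side.
#' @return an `nca_contribution` on the coancestry (F) scale.
#' @export
wright_path_counting <- function(ped, id, max_paths = 1e6) {
  stopifnot(inherits(ped, "pedigree"))
  j <- .ped_pos(ped, id)
  s <- ped$sire_i[j]; d <- ped$dam_i[j]
  F <- unname(compute_inbreeding(ped))
  si <- ped$sire_i; di <- ped$dam_i
  if (s == 0L || d == 0L) {
    out <- .new_contribution("nca_contribution", "individual_F", id,
                             "coancestry", stats::setNames(numeric(0), character(0)), 0)
    out$ncas <- character(0)
    return(out)
  }
  count <- 0L
  paths_up <- function(x) {
    count <<- count + 1L
    if (count > max_paths)
      stop("path enumeration exceeded max_paths = ", max_paths,
           "; use the MSV decomposition route instead")
    res <- list(x)
    for (p in c(si[x], di[x])) if (p > 0L)
      res <- c(res, lapply(paths_up(p), function(pp) c(x, pp)))
    res
  }
  P1 <- paths_up(s)
  P2 <- paths_up(d)
  end1 <- vapply(P1, function(p) p[length(p)], integer(1))
  end2 <- vapply(P2, function(p) p[length(p)], integer(1))
  n <- nrow(ped)
  u <- numeric(n)
  for (k in intersect(unique(end1), unique(end2))) {
    for (p1 in P1[end1 == k]) for (p2 in P2[end2 == k]) {
      # branches must be disjoint except at the apex k
      if (length(intersect(p1[-length(p1)], p2[-length(p2)])) == 0L) {
        u[k] <- u[k] + 0.5^(length(p1) + length(p2) - 1) * (1 + F[k])
      }
    }
  }
  out <- .new_contribution("nca_contribution", "individual_F", id,
                           "coancestry", stats::setNames(u, ped$id), sum(u))
  out$ncas <- find_nodal_common_ancestors(ped, id)
  out
}

#' Upward-exploration tabular method
#'
#' Independent second backend for the decomposition: starting from a table of
#' labeled gene-lineage pair frequencies at the target (the group members or
#' the focal animal's parents), pairs are propagated recursively to older
#' generations — each animal's weight splitting half-and-half to its recorded
#' parents — and a pair coinciding at an animal h contributes its frequency
#' times (1 + F_h) to h's marginal contribution. Totals agree with the MSV
#' route to numerical precision; the per-ancestor weights are the marginal
#' NCA contributions (Wright's attribution). Memory is quadratic in pedigree
#' size, hence the cap.
#'
#' @param ped pedigree.
#' @param ids group member ids (a single id decomposes that animal's F).
#' @param target "mean_F" or "mean_coancestry".
#' @param scale "coancestry" or "relationship".
#' @param memory_cap_mb refuse to allocate a pair table beyond this size.
#' @return an `nca_contribution` object.
#' @export
upward_exploration <- function(ped, ids, target = c("mean_F", "mean_coancestry"),
                               scale = c("coancestry", "relationship"),
                               memory_cap_mb = 2048) {
  stopifnot(inherits(ped, "pedigree"))
  target <- match.arg(target)
  scale <- match.arg(scale)
  if (!length(ids)) stop("empty group")
  tname <- if (target == "mean_F") {
    if (length(ids) == 1L) "individual_F" else "group_mean_F"
  } else "group_mean_coancestry"
  u <- .nca_engine(ped, tname, ids, memory_cap_mb = memory_cap_mb)
  if (scale == "relationship") u <- 2 * u
  out <- .new_contribution("nca_contribution", tname, ids, scale, u, sum(u))
  out$ncas <- names(out$weights)
  out
}
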