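#' Inbreeding coefficients from a pedigree
#'
#' F of each animal is the coancestry of its parents, computed in a single
#' pass in pedigree order from the factorization A = U^-1 B (U^-1)' of the
#' numerator relationship matrix: for an animal with both parents recorded,
#' F = 1/2 * sum_k b_k c_k(sire) c_k(dam), where b_k is ancestor k's Mendelian
#' sampling variance and c_k(.) its genetic contribution to the parent.
#' Animals with an unknown parent have F = 0.
#'
#' @param ped pedigree.
#' @return numeric vector of F in [0, 1], named by animal id.
#' @export
compute_inbreeding <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  si <- ped$sire_i; di <- ped$dam_i
  F <- numeric(n)
  b <- numeric(n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (s > 0L && d > 0L) {
      cs <- .contrib_trace(si, di, s, n)
      cd <- .contrib_trace(si, di, d, n)
      F[i] <- 0.5 * sum(b * cs * cd)
      b[i] <- 0.5 - 0.25 * (F[s] + F[d])
    } else if (s > 0L) {
      b[i] <- 0.75 - 0.25 * F[s]
    } else if (d > 0L) {
      b[i] <- 0.75 - 0.25 * F[d]
    } else {
      b[i] <- 1
    }
  }
  stats::setNames(F, ped$id)
}

# genetic contributions of all ancestors to animal at position `start`:
# the start-th row of U^-1 (start itself gets 1); one descending sweep
.contrib_trace <- function(si, di, start, n, w0 = NULL) {
  w <- numeric(n)
  if (is.null(w0)) w[start] <- 1 else w <- w0
  top <- if (is.null(w0)) start else n
  for (h in seq.int(top, 1L)) {
    v <- w[h]
    if (v != 0) {
      if (si[h] > 0L) w[si[h]] <- w[si[h]] + 0.5 * v
      if (di[h] > 0L) w[di[h]] <- w[di[h]] + 0.5 * v
    }
  }
  w
}

#' Genetic contributions of ancestors to a focal animal
#'
#' Expected proportion of the focal animal's genes transmitted by each
#' ancestor: the focal animal's row of U^-1 (1 at the animal itself, and each
#' ancestor's value is half the sum over its offspring on descending paths).
#'
#' @param ped pedigree.
#' @param id focal animal, or a named numeric vector of weights over ids to
#'   obtain the weighted mean contribution vector for a group.
#' @return numeric vector over all animals, named by id.
#' @export
genetic_contributions <- function(ped, id) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  if (is.numeric(id) && !is.null(names(id))) {
    w0 <- numeric(n)
    w0[.ped_pos(ped, names(id))] <- id
    w <- .contrib_trace(ped$sire_i, ped$dam_i, NA, n, w0 = w0)
  } else {
    w <- .contrib_trace(ped$sire_i, ped$dam_i, .ped_pos(ped, id), n)
  }
  stats::setNames(w, ped$id)
}

#' Mendelian sampling variances
#'
#' The diagonal of B in A = U^-1 B (U^-1)': b = 1 for founders,
#' b = 1/2 - 1/4 (F_sire + F_dam) when both parents are recorded, and
#' b = 3/4 - 1/4 F_known when one parent is recorded (the unknown-parent
#' convention that keeps the factorization exact).
#'
#' @param ped pedigree.
#' @param F inbreeding coefficients (computed if missing).
#' @return numeric vector b in (0, 1], named by animal id.
#' @export
mendelian_sampling_variances <- function(ped, F = compute_inbreeding(ped)) {
  stopifnot(inherits(ped, "pedigree"))
  si <- ped$sire_i; di <- ped$dam_i
  F <- unname(F)
  b <- ifelse(si > 0L & di > 0L, 0.5 - 0.25 * (F[pmax(si, 1L)] + F[pmax(di, 1L)]),
       ifelse(si > 0L, 0.75 - 0.25 * F[pmax(si, 1L)],
       ifelse(di > 0L, 0.75 - 0.25 * F[pmax(di, 1L)], 1)))
  stats::setNames(b, ped$id)
}

#' Relationship matrix times a vector without forming A
#'
#' Computes A x through the factorization A = U^-1 B (U^-1)': one upward
#' sweep (solve with U'), a diagonal scaling by the Mendelian sampling
#' variances, and one downward sweep (solve with U). U has 1 on the diagonal
#' and -1/2 linking each animal to each recorded parent, so each sweep is a
#' single pedigree tracing pass.
#'
#' @param ped pedigree.
#' @param x numeric vector, one entry per animal (pedigree order), or a named
#'   vector over a subset of ids (zero elsewhere).
#' @param b Mendelian sampling variances (computed if missing).
#' @return numeric vector A x, named by animal id.
#' @export
relationship_times_vector <- function(ped, x, b = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  if (!is.null(names(x)) && length(x) != n) {
    xv <- numeric(n)
    xv[.ped_pos(ped, names(x))] <- x
    x <- xv
  }
  if (length(x) != n) stop("x must have one entry per animal (", n, ")")
  if (is.null(b)) b <- mendelian_sampling_variances(ped)
  si <- ped$sire_i; di <- ped$dam_i
  # z = (U')^-1 x: descending sweep pushes weight to parents
  z <- as.numeric(x)
  for (h in seq.int(n, 1L)) {
    v <- z[h]
    if (v != 0) {
      if (si[h] > 0L) z[si[h]] <- z[si[h]] + 0.5 * v
      if (di[h] > 0L) z[di[h]] <- z[di[h]] + 0.5 * v
    }
  }
  z <- z * unname(b)
  # w = U^-1 z: ascending sweep pulls from parents
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (s > 0L) z[i] <- z[i] + 0.5 * z[s]
    if (d > 0L) z[i] <- z[i] + 0.5 * z[d]
  }
  stats::setNames(z, ped$id)
}

#' Dense numerator relationship matrix (tabular method)
#'
#' Builds A row by row with the recursive tabular method: A[i, j] =
#' 1/2 (A[sire_i, j] + A[dam_i, j]) for j < i and A[i, i] = 1 + F_i with
#' F_i = 1/2 A[sire_i, dam_i]. Quadratic in memory; intended for small and
#' moderate pedigrees and as an independent cross-check of the indirect
#' method.
#'
#' @param ped pedigree.
#' @return dense symmetric matrix with dimnames = animal ids.
#' @export
relationship_matrix <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  si <- ped$sire_i; di <- ped$dam_i
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (s > 0L) row <- row + 0.5 * A[s, j]
      if (d > 0L) row <- row + 0.5 * A[d, j]
      A[i, j] <- row
      A[j, i] <- row
    }
    Fi <- if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
    A[i, i] <- 1 + Fi
  }
  A
}

#' Mean coancestry of a group
#'
#' For a group G of size n with indicator x, the relationship-scale mean is
#' (1/n^2) x' A x (self terms included) and the coancestry-scale mean is half
#' of it. Computed with a single indirect pass per group.
#'
#' @param ped pedigree.
#' @param ids group member ids (repeats allowed; weights accumulate).
#' @return list with `relationship` and `coancestry` scale values and `n`.
#' @export
group_mean_coancestry <- function(ped, ids) {
  stopifnot(inherits(ped, "pedigree"))
  if (!length(ids)) stop("empty group")
  pos <- .ped_pos(ped, ids)
  x <- numeric(nrow(ped))
  for (p in pos) x[p] <- x[p] + 1
  ax <- relationship_times_vector(ped, x)
  rel <- sum(x * ax) / length(ids)^2
  list(relationship = rel, coancestry = rel / 2, n = length(ids))
}

#' Individual rate of coancestry
#'
#' Coancestry standardized by the pair's equivalent complete generations:
#' Delta C = 1 - (1 - C)^(2 / (t_b + t_a)).
#'
#' @param C coancestry of the pair, in [0, 1).
#' @param t_b,t_a equivalent complete generations of the two animals.
#' @return Delta C.
#' @export
rate_of_coancestry <- function(C, t_b, t_a) {
  stopifnot(C >= 0, C < 1, t_b >= 0, t_a >= 0)
  tt <- t_b + t_a
  if (tt == 0) {
    if (C > 0) stop("rate of coancestry undefined: C > 0 with zero generations")
    return(0)
  }
  1 - (1 - C)^(2 / tt)
}

#' Mean pairwise rate of coancestry for a group
#'
#' Convenience average of the pairwise [rate_of_coancestry()] over all
#' unordered pairs of distinct group members. Quadratic in the group size;
#' meant for cohort-level summaries on moderate groups.
#'
#' @param ped pedigree.
#' @param ids group member ids (at least 2).
#' @return mean Delta C over pairs.
#' @export
mean_rate_of_coancestry <- function(ped, ids) {
  stopifnot(inherits(ped, "pedigree"), length(ids) >= 2)
  pos <- .ped_pos(ped, ids)
  t <- equivalent_complete_generations(ped, ids)
  A <- NULL
  n <- length(ids)
  # one indirect pass per member gives its coancestry with the others
  acc <- 0; np <- 0L
  for (i in seq_len(n - 1L)) {
    x <- numeric(nrow(ped)); x[pos[i]] <- 1
    ax <- relationship_times_vector(ped, x)
    for (j in seq.int(i + 1L, n)) {
      C <- ax[pos[j]] / 2
      acc <- acc + rate_of_coancestry(unname(C), t[i], t[j])
      np <- np + 1L
    }
  }
  acc / np
}

#' Non-random mating coefficient
#'
#' The departure from random mating alpha in (1 - Fbar) = (1 - fbar)(1 -
#' alpha): alpha = 1 - (1 - Fbar) / (1 - fbar). Negative values indicate
#' avoidance of matings between relatives.
#'
#' @param F_bar mean inbreeding.
#' @param f_bar mean coancestry (< 1).
#' @return alpha.
#' @export
nonrandom_mating_alpha <- function(F_bar, f_bar) {
  if (any(f_bar >= 1)) stop("alpha undefined at f_bar = 1")
  1 - (1 - F_bar) / (1 - f_bar)
}
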