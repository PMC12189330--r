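# Independent oracles, written from first principles and kept free of the
# package's computational routes.

# naive recursive kinship f(i, j) with memoization; founders unrelated.
# Positions refer to a topologically ordered pedigree.
naive_kinship <- function(ped) {
  n <- nrow(ped)
  si <- ped$sire_i; di <- ped$dam_i
  memo <- new.env(parent = emptyenv())
  f <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    key <- paste(i, j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    val <- if (i == j) 0.5 * (1 + f(si[i], di[i]))
           else 0.5 * (f(i, si[j]) + f(i, di[j]))  # j is the younger (larger index)
    memo[[key]] <- val
    val
  }
  list(f = f,
       A = function() {
         A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
         for (i in seq_len(n)) for (j in i:n) A[i, j] <- A[j, i] <- 2 * f(i, j)
         A
       })
}

# random valid pedigree: founders plus animals whose parents are drawn from
# strictly earlier animals of the right sex (or left unknown)
random_pedigree <- function(n, n_founders = max(4L, n %/% 5L),
                            unknown_rate = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  id <- sprintf("A%03d", seq_len(n))
  sex <- rep(c("male", "female"), length.out = n)
  sire <- dam <- rep(NA_character_, n)
  for (i in seq.int(n_founders + 1L, n)) {
    males <- which(sex[seq_len(i - 1L)] == "male")
    females <- which(sex[seq_len(i - 1L)] == "female")
    if (length(males) && stats::runif(1) > unknown_rate)
      sire[i] <- id[males[sample.int(length(males), 1L)]]
    if (length(females) && stats::runif(1) > unknown_rate)
      dam[i] <- id[females[sample.int(length(females), 1L)]]
  }
  as_pedigree(data.frame(id = id, sire = sire, dam = dam, sex = sex,
                         stringsAsFactors = FALSE))
}

# brute-force UPGMA on a distance matrix, independent of hclust
naive_upgma <- function(D) {
  labs <- rownames(D)
  k <- nrow(D)
  sizes <- rep(1, k)
  active <- seq_len(k)
  heights <- numeric(0)
  D0 <- D
  while (length(active) > 1) {
    best <- c(NA, NA); bd <- Inf
    for (a in seq_along(active)) for (b in seq_along(active)) if (a < b) {
      dd <- D0[active[a], active[b]]
      if (dd < bd) { bd <- dd; best <- c(a, b) }
    }
    i <- active[best[1]]; j <- active[best[2]]
    heights <- c(heights, bd)
    # merged cluster distances: size-weighted average
    newd <- (sizes[i] * D0[i, ] + sizes[j] * D0[j, ]) / (sizes[i] + sizes[j])
    D0[i, ] <- newd; D0[, i] <- newd
    sizes[i] <- sizes[i] + sizes[j]
    active <- setdiff(active, j)
  }
  heights
}

fixtures <- reference_fixtures()
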