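test_that("MSV decomposition of individual F matches the fixture closed forms", {
  m <- msv_decomposition_individual(fixtures[["FIX-FS"]], "X")
  expect_equal(m$weights, c(A = 0.125, B = 0.125))
  expect_equal(m$total, 0.25)
  m <- msv_decomposition_individual(fixtures[["FIX-HS"]], "X")
  expect_equal(m$weights, c(A = 0.125))
  m <- msv_decomposition_individual(fixtures[["FIX-CHAIN"]], "X")
  expect_equal(m$weights[order(names(m$weights))],
               c(A = 0.03125, B = 0.03125, M = 0.0625))
  expect_equal(m$total, 0.125)
  # relationship scale is exactly twice the coancestry scale
  m2 <- msv_decomposition_individual(fixtures[["FIX-CHAIN"]], "X", "relationship")
  expect_equal(m2$weights, 2 * m$weights[names(m2$weights)])
  # non-inbred focal animal: empty vector, zero total
  m0 <- msv_decomposition_individual(fixtures[["FIX-FS"]], "S")
  expect_length(m0$weights, 0)
  expect_equal(m0$total, 0)
})

test_that("group decompositions conserve their target statistic", {
  ped <- fixtures[["FIX-FS"]]
  # singleton group reduces to the individual decomposition
  g1 <- msv_decomposition_group(ped, "X", "mean_F")
  expect_equal(g1$weights, msv_decomposition_individual(ped, "X")$weights)
  # pair {S, D}: relationship-scale total is the dense-oracle mean incl. self terms
  g2 <- msv_decomposition_group(ped, c("S", "D"), "mean_coancestry", "relationship")
  expect_equal(g2$total, 0.75)
  expect_equal(g2$weights[c("A", "B")], c(A = 0.25, B = 0.25))

  syn <- random_pedigree(300, unknown_rate = 0.2, seed = 41)
  set.seed(42)
  grp <- syn$id[sample.int(nrow(syn), 20)]
  gc <- msv_decomposition_group(syn, grp, "mean_coancestry")
  expect_equal(gc$total, group_mean_coancestry(syn, grp)$coancestry,
               tolerance = 1e-10)
  gF <- msv_decomposition_group(syn, grp, "mean_F")
  expect_equal(gF$total, mean(compute_inbreeding(syn)[grp]), tolerance = 1e-10)
  expect_true(all(gc$weights >= 0) && all(gF$weights >= 0))
})

test_that("nodal common ancestors are the two-sided ancestor intersection", {
  expect_setequal(find_nodal_common_ancestors(fixtures[["FIX-HS"]], "X"), "A")
  expect_setequal(find_nodal_common_ancestors(fixtures[["FIX-FS"]], "X"), c("A", "B"))
  expect_setequal(find_nodal_common_ancestors(fixtures[["FIX-CHAIN"]], "X"),
                  c("A", "B", "M"))
  expect_length(find_nodal_common_ancestors(fixtures[["FIX-FS"]], "S"), 0)
})

test_that("NCA conversion concentrates weight in the nearest descendant NCA", {
  ped <- fixtures[["FIX-CHAIN"]]
  u <- nca_contributions(ped, msv_decomposition_individual(ped, "X"))
  expect_equal(u$weights, c(M = 0.125))          # A and B fully captured by M
  expect_equal(u$total, 0.125)
  u2 <- nca_contributions(fixtures[["FIX-FS"]],
                          msv_decomposition_individual(fixtures[["FIX-FS"]], "X"))
  expect_equal(u2$weights[order(names(u2$weights))], c(A = 0.125, B = 0.125))
  # inbred common ancestor: Wright's (1/2)^(n1+n2+1) (1 + F_A)
  ia <- as_pedigree(data.frame(
    id = c("G1", "G2", "P1", "P2", "A", "B", "C", "S", "D", "X"),
    sire = c("0", "0", "G1", "G1", "P1", "0", "0", "A", "A", "S"),
    dam = c("0", "0", "G2", "G2", "P2", "0", "0", "B", "C", "D")))
  u3 <- nca_contributions(ia, msv_decomposition_individual(ia, "X"))
  expect_equal(u3$weights, c(A = 0.15625))
})

test_that("Wright path counting agrees with the MSV+NCA route everywhere it runs", {
  w <- wright_path_counting(fixtures[["FIX-HS"]], "X")
  expect_equal(w$weights, c(A = 0.125))
  w <- wright_path_counting(fixtures[["FIX-FS"]], "X")
  expect_equal(w$weights[order(names(w$weights))], c(A = 0.125, B = 0.125))

  for (seed in 1:10) {
    ped <- random_pedigree(50, unknown_rate = 0.1, seed = 600 + seed)
    F <- compute_inbreeding(ped)
    for (id in ped$id[F > 0]) {
      wpc <- wright_path_counting(ped, id)
      expect_equal(wpc$total, F[[id]], tolerance = 1e-12)
      u <- nca_contributions(ped, msv_decomposition_individual(ped, id))
      expect_equal(u$weights[order(names(u$weights))],
                   wpc$weights[order(names(wpc$weights))], tolerance = 1e-10)
    }
  }
})

test_that("path enumeration refuses to explode", {
  # ~2^k paths per side on a dense diamond ladder
  n <- 40
  id <- sprintf("N%02d", 1:n)
  sire <- c(NA, NA, id[seq_len(n - 2)])
  dam <- c(NA, NA, id[pmax(seq_len(n - 2) - 1, 1)])
  ped <- as_pedigree(data.frame(id = id, sire = sire, dam = dam))
  expect_error(wright_path_counting(ped, id[n], max_paths = 100), "max_paths")
})

test_that("founder contributions conserve and flow through gene proportions", {
  ped <- fixtures[["FIX-CHAIN"]]
  u <- nca_contributions(ped, msv_decomposition_individual(ped, "X"))
  v <- founder_contributions(ped, u)
  expect_equal(v$v[order(names(v$v))], c(A = 0.0625, B = 0.0625))
  expect_equal(v$total, u$total)
  v2 <- founder_contributions(fixtures[["FIX-FS"]],
                              nca_contributions(fixtures[["FIX-FS"]],
                                msv_decomposition_individual(fixtures[["FIX-FS"]], "X")))
  expect_equal(v2$v[order(names(v2$v))], c(A = 0.125, B = 0.125))
})

test_that("unknown parents route conserved weight to flagged phantom founders", {
  ped <- as_pedigree(data.frame(
    id = c("A", "B", "H", "S", "D", "X"),
    sire = c("0", "0", "A", "H", "H", "S"),
    dam = c("0", "0", "0", "B", "B", "D")))  # H has an unknown dam
  m <- msv_decomposition_individual(ped, "X")
  u <- nca_contributions(ped, m)
  v <- founder_contributions(ped, u)
  expect_equal(v$total, u$total, tolerance = 1e-12)
  expect_true("H/dam" %in% names(v$v))
  expect_true(all(v$phantom[grepl("/", names(v$v))]))
})

test_that("upward exploration is an equivalent independent backend", {
  ped <- fixtures[["FIX-FS"]]
  ue <- upward_exploration(ped, "X", "mean_F")
  expect_equal(ue$weights[order(names(ue$weights))], c(A = 0.125, B = 0.125))
  expect_equal(ue$total, msv_decomposition_group(ped, "X", "mean_F")$total)
  # founder singleton: only the self term
  uf <- upward_exploration(ped, "A", "mean_coancestry")
  expect_equal(uf$weights, c(A = 0.5))

  syn <- random_pedigree(200, unknown_rate = 0.15, seed = 77)
  set.seed(78)
  grp <- syn$id[sample.int(nrow(syn), 30)]
  for (tg in c("mean_F", "mean_coancestry")) {
    ue <- upward_exploration(syn, grp, tg)
    ms <- msv_decomposition_group(syn, grp, tg)
    expect_equal(ue$total, ms$total, tolerance = 1e-10)
  }
  expect_error(upward_exploration(syn, grp, memory_cap_mb = 0.01), "memory")
})

test_that("relationship-scale totals are exactly twice coancestry-scale totals", {
  syn <- random_pedigree(150, seed = 55)
  set.seed(56)
  grp <- syn$id[sample.int(nrow(syn), 15)]
  for (tg in c("mean_F", "mean_coancestry")) {
    a <- msv_decomposition_group(syn, grp, tg, "coancestry")
    b <- msv_decomposition_group(syn, grp, tg, "relationship")
    expect_equal(b$total, 2 * a$total, tolerance = 1e-12)
  }
})
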