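test_that("downscaling aggregates settler counts, not fractions", {
  # one site per population: matrix unchanged
  C <- structure(matrix(c(0.1, 0, 0.2, 0.3), 2, 2,
                        dimnames = list(c("S1", "S2"), c("S1", "S2"))),
                 released = c(S1 = 10, S2 = 10),
                 class = c("connectivity_matrix", "matrix"))
  P <- downscale_to_populations(C, c(S1 = "A", S2 = "B"))
  expect_equal(unname(mval(P)), unname(mval(C)))
  expect_equal(rownames(P), c("A", "B"))

  # two equal-release sites merged: count-level arithmetic
  C3 <- structure(matrix(c(0.2, 0.1, 0.0,
                           0.0, 0.3, 0.1,
                           0.1, 0.0, 0.4), 3, 3, byrow = TRUE,
                        dimnames = list(c("S1", "S2", "S3"),
                                        c("S1", "S2", "S3"))),
                 released = c(S1 = 100, S2 = 100, S3 = 200),
                 class = c("connectivity_matrix", "matrix"))
  P3 <- downscale_to_populations(C3, c(S1 = "A", S2 = "A", S3 = "B"))
  # settlers S1->(S1,S2): 20 + 10; S2->(S1,S2): 0 + 30 => A->A = 60/200
  expect_equal(P3["A", "A"], 60 / 200)
  expect_equal(P3["A", "B"], (0 + 10) / 200)
  expect_equal(P3["B", "A"], (20 + 0) / 200)
  expect_equal(P3["B", "B"], 80 / 200)
  # total settled count conserved
  tot_site <- sum(mval(C3) * c(100, 100, 200))
  tot_pop <- sum(mval(P3) * c(200, 200))
  expect_equal(tot_pop, tot_site)

  expect_error(downscale_to_populations(C3, c(S1 = "A", S2 = "A")),
               "unmapped site id: S3")
})

test_that("migration matrices are column-stochastic with degenerate columns flagged", {
  P <- matrix(c(2, 3, 5, 1, 1, 2, 0, 0, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  M <- to_migration_matrix(P)
  expect_equal(unname(mval(M)[, 1]), c(0.2, 0.3, 0.5))
  expect_equal(colSums(mval(M))[1:2], c(a = 1, b = 1))
  expect_equal(attr(M, "degenerate_columns"), "c")
  expect_equal(unname(mval(M)[, 3]), c(0, 0, 0))

  # already column-stochastic input unchanged
  M2 <- to_migration_matrix(mval(M)[, 1:2] %*% diag(2) / 1)
  expect_equal(unname(mval(M2)), unname(mval(M)[, 1:2]))
  expect_error(to_migration_matrix(-P), "negative")
})

test_that("generational projection is a stochastic matrix power", {
  M <- to_migration_matrix(matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2,
                                  dimnames = list(c("a", "b"), c("a", "b"))))
  expect_equal(mval(project_generations(M, 1)), mval(M))
  M2 <- project_generations(M, 2)
  expect_equal(unname(mval(M2)),
               matrix(c(0.83, 0.17, 0.34, 0.66), 2, 2))
  expect_equal(attr(M2, "generations"), 2L)

  I3 <- to_migration_matrix(diag(3))
  expect_equal(unname(mval(project_generations(I3, 7))), diag(3))

  M10 <- project_generations(M, 10)
  expect_equal(unname(colSums(mval(M10))), c(1, 1), tolerance = 1e-12)
  expect_error(project_generations(M, 0), "integer >= 1")

  # flux routed into a degenerate (no-immigrant) population must not leak
  # out of the chain: live columns of M^g stay exactly stochastic
  Pd <- matrix(c(0.5, 0.5, 0, 0.2, 0.3, 0.5, 0, 0, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  Md <- to_migration_matrix(Pd)
  Md10 <- project_generations(Md, 10)
  expect_equal(unname(colSums(mval(Md10))), c(1, 1, 0), tolerance = 1e-12)
  expect_equal(attr(Md10, "degenerate_columns"), "c")
})

test_that("Nei's D_A distance follows the Bhattacharyya form on columns", {
  cols <- cbind(c(0.5, 0.5, 0), c(0, 0.5, 0.5), c(0.5, 0.5, 0))
  dimnames(cols) <- list(letters[1:3], c("p", "q", "r"))
  M <- structure(cols, degenerate_columns = character(0), generations = 1L,
                 class = c("migration_matrix", "matrix"))
  D <- nei_da_distance(M)
  expect_equal(D["p", "q"], 0.5)       # 1 - (0 + 0.5 + 0)
  expect_equal(D["p", "r"], 0)         # identical columns
  expect_equal(unname(diag(mval(D))), rep(0, 3))
  expect_equal(mval(D), t(mval(D)))

  # disjoint support -> distance 1
  dj <- cbind(c(1, 0), c(0, 1))
  dimnames(dj) <- list(c("x", "y"), c("p", "q"))
  Mdj <- structure(dj, degenerate_columns = character(0), generations = 1L,
                   class = c("migration_matrix", "matrix"))
  expect_equal(nei_da_distance(Mdj)["p", "q"], 1)

  # property: bounded in [0, 1], symmetric, zero diagonal for random
  # column-stochastic matrices
  set.seed(41)
  for (i in 1:20) {
    raw <- matrix(rexp(25), 5, 5, dimnames = list(letters[1:5], letters[1:5]))
    Mr <- to_migration_matrix(raw)
    Dr <- mval(nei_da_distance(Mr))
    expect_true(all(Dr >= -1e-12 & Dr <= 1 + 1e-12))
    expect_equal(Dr, t(Dr))
    expect_equal(unname(diag(Dr)), rep(0, 5))
  }

  # homogenisation: mixing two columns toward each other shrinks D_A
  a <- c(0.7, 0.2, 0.1); b <- c(0.1, 0.1, 0.8)
  mix <- function(lam) {
    m <- cbind((1 - lam) * a + lam * (a + b) / 2,
               (1 - lam) * b + lam * (a + b) / 2, c(1, 0, 0))
    dimnames(m) <- list(1:3, c("p", "q", "r"))
    structure(m, degenerate_columns = character(0), generations = 1L,
              class = c("migration_matrix", "matrix"))
  }
  d_vals <- vapply(c(0, 0.3, 0.6, 0.9),
                   function(l) nei_da_distance(mix(l))["p", "q"], numeric(1))
  expect_true(all(diff(d_vals) <= 1e-12))

  # degenerate columns: distance 1 to everything, 0 to themselves
  dg <- cbind(c(0.5, 0.5), c(0, 0))
  dimnames(dg) <- list(c("x", "y"), c("p", "q"))
  Mdg <- structure(dg, degenerate_columns = "q", generations = 1L,
                   class = c("migration_matrix", "matrix"))
  Ddg <- nei_da_distance(Mdg)
  expect_equal(Ddg["p", "q"], 1)
  expect_equal(Ddg["q", "q"], 0)
})

test_that("Mantel test matches an independent permutation oracle", {
  set.seed(10)
  mk_dist <- function(n) {
    m <- matrix(0, n, n)
    m[upper.tri(m)] <- runif(n * (n - 1) / 2)
    m + t(m)
  }
  A <- mk_dist(6); B <- mk_dist(6)
  res <- mantel_test(A, B, n_perm = 999, seed = 5)
  # r equals the Pearson correlation of strict upper triangles
  expect_equal(res$r, cor(A[upper.tri(A)], B[upper.tri(B)]))

  # independent oracle: brute-force simultaneous row/column permutations
  set.seed(123)
  r_obs <- cor(A[upper.tri(A)], B[upper.tri(B)])
  n_perm <- 2000
  r_perm <- replicate(n_perm, {
    p <- sample(6)
    Bp <- B[p, p]
    cor(A[upper.tri(A)], Bp[upper.tri(Bp)])
  })
  p_hand <- (1 + sum(r_perm >= r_obs)) / (1 + n_perm)
  expect_lt(abs(res$p - p_hand), 0.06)

  # self-correlation: r = 1 and the minimal attainable p
  self <- mantel_test(A, A, n_perm = 999, seed = 2)
  expect_equal(self$r, 1)
  expect_lte(self$p, 5 / 1000)  # ties possible only under degenerate perms

  # affine invariance: B = 2A + 3 has r = 1
  aff <- mantel_test(A, 2 * A + 3, n_perm = 99, seed = 3)
  expect_equal(aff$r, 1)

  expect_error(mantel_test(A[1:2, 1:2], B[1:2, 1:2], 99), "dimension")
})

test_that("the genetics comparison pipeline produces DOR matrices and Mantel tests", {
  set.seed(9)
  ids <- sprintf("S%02d", 1:8)
  pops <- rep(c("P1", "P2", "P3", "P4"), each = 2)
  raw <- matrix(rexp(64), 8, 8, dimnames = list(ids, ids))
  C <- structure(raw / 10, released = stats::setNames(rep(100, 8), ids),
                 class = c("connectivity_matrix", "matrix"))
  map <- stats::setNames(pops, ids)

  M <- to_migration_matrix(downscale_to_populations(C, map))
  D1 <- nei_da_distance(M)
  fst <- mval(D1)  # genetic distances exactly equal to DOR
  cmp <- compare_to_genetics(C, map, fst, generations_list = c(1, 10),
                             n_perm = 199, seed = 4)
  expect_equal(cmp$per_generation[["1"]]$mantel$r, 1)
  for (pg in cmp$per_generation) {
    expect_equal(pg$dor, t(pg$dor))
    expect_equal(unname(diag(pg$dor)), rep(0, 4))
  }
  expect_error(compare_to_genetics(C, map, fst[1:2, 1:2], 1),
               "fewer than 3 shared")
})

test_that("F_ST matrices load with symmetry checks and negative clamping", {
  m <- matrix(c(0, 0.01, -0.002, 0.01, 0, 0.004, -0.002, 0.004, 0), 3, 3,
              dimnames = list(c("P1", "P2", "P3"), c("P1", "P2", "P3")))
  path <- tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(m), path)
  expect_warning(fst <- read_fst_matrix(path), "clamped")
  expect_equal(fst["P1", "P3"], 0)
  expect_equal(fst["P1", "P2"], 0.01)
  expect_equal(fst, t(fst))

  bad <- m; bad[1, 2] <- 0.5
  utils::write.csv(as.data.frame(bad), path)
  expect_error(read_fst_matrix(path), "symmetric")
})
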