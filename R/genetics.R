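# From connectivity to genetics: population-level migration matrices,
# generational projection, derived oceanographic resistance (Nei's D_A)
# and Mantel comparison with pairwise F_ST.

#' Downscale a site connectivity matrix to populations
#'
#' Aggregation happens at the settler-count level: fractions are converted
#' back to counts with each source's release number, summed over the site
#' groups, and re-fractionalised by the group releases — so the total
#' number of settlers is conserved exactly (naive averaging of fractions
#' would not conserve it when releases differ).
#'
#' @param C site-level `connectivity_matrix` (square, sites as rows and
#'   columns).
#' @param site_to_population named character vector mapping every site id
#'   to its population id.
#' @param released per-site release counts (default: the matrix's
#'   `released` attribute).
#' @return Population-level `connectivity_matrix`.
#' @export
downscale_to_populations <- function(C, site_to_population, released = NULL) {
  if (is.null(released)) released <- attr(C, "released")
  ids <- rownames(C)
  if (any(!ids %in% names(site_to_population)))
    stop("data error: unmapped site id: ",
         setdiff(ids, names(site_to_population))[1])
  pops <- unique(site_to_population[ids])
  grp <- factor(site_to_population[ids], levels = pops)
  counts <- unclass(C) * as.numeric(released[ids])
  agg <- rowsum(counts, grp)                 # sum over source groups
  agg <- t(rowsum(t(agg), grp))              # sum over sink groups
  rel_pop <- as.numeric(rowsum(as.numeric(released[ids]), grp))
  out <- agg
  nz <- rel_pop > 0
  out[nz, ] <- out[nz, , drop = FALSE] / rel_pop[nz]
  dimnames(out) <- list(pops, pops)
  structure(out, kind = attr(C, "kind"),
            released = stats::setNames(rel_pop, pops),
            class = c("connectivity_matrix", "matrix"))
}

#' Column-standardised migration matrix
#'
#' Divides every column of a population exchange matrix by its sum, so
#' column `j` is the distribution of source contributions to the
#' settlement at receiving population `j`; the diagonal is
#' self-recruitment. All-zero columns (populations receiving no settlers)
#' are left zero and flagged degenerate.
#'
#' @param P non-negative population matrix (rows sources, columns sinks).
#' @return A `migration_matrix` (column-stochastic; attribute
#'   `degenerate_columns`, `generations = 1`).
#' @export
to_migration_matrix <- function(P) {
  m <- unclass(P)
  if (any(m < 0)) stop("invalid argument: negative entries")
  cs <- colSums(m)
  nz <- cs > 0
  m[, nz] <- sweep(m[, nz, drop = FALSE], 2, cs[nz], `/`)
  structure(m, degenerate_columns = colnames(m)[!nz], generations = 1L,
            class = c("migration_matrix", "matrix"))
}

#' Project a migration matrix over generations
#'
#' Plain matrix power `M^g`, simulating `g` generations of exchange.
#' Column-stochasticity is preserved automatically — no renormalisation is
#' applied. Degenerate (all-zero) columns would leak any mass routed into
#' their population out of the chain, so for the power they are treated as
#' pure self-recruitment (a unit diagonal entry): settlers arriving at a
#' population that received no modelled immigrants simply stay there. The
#' degeneracy flags are carried through unchanged.
#'
#' @param M a `migration_matrix`.
#' @param g integer >= 1.
#' @return The projected `migration_matrix` (attribute `generations = g`).
#' @export
project_generations <- function(M, g) {
  if (g < 1 || g != round(g)) stop("invalid argument: g must be an integer >= 1")
  base <- unclass(M)
  deg <- which(colnames(base) %in% attr(M, "degenerate_columns"))
  for (k in deg) { base[, k] <- 0; base[k, k] <- 1 }
  out <- base
  for (i in seq_len(g - 1)) out <- out %*% base
  out[, deg] <- unclass(M)[, deg]   # flagged columns stay as supplied
  structure(out, degenerate_columns = attr(M, "degenerate_columns"),
            generations = as.integer(g),
            class = c("migration_matrix", "matrix"))
}

#' Derived oceanographic resistance (Nei's D_A)
#'
#' Pairwise distance between the source-composition profiles of receiving
#' populations: `D(i, j) = 1 - sum_k sqrt(M[k, i] * M[k, j])` — one minus
#' the Bhattacharyya coefficient of columns `i` and `j` of the
#' column-standardised migration matrix. Distances lie in [0, 1] with a
#' zero diagonal. Degenerate (all-zero) columns are assigned distance 1 to
#' every other population.
#'
#' A row-based variant (profiles of where a source's settlers go) is
#' available with `margin = "rows"`; note that rows of a
#' column-standardised matrix need not sum to 1, so the [0, 1] bounds are
#' only guaranteed for the column margin.
#'
#' @param M a `migration_matrix`.
#' @param margin `"columns"` (default) or `"rows"`.
#' @return A `dor_matrix`: symmetric, zero-diagonal distance matrix with
#'   attribute `generations`.
#' @export
nei_da_distance <- function(M, margin = c("columns", "rows")) {
  margin <- match.arg(margin)
  m <- unclass(M)
  if (margin == "rows") m <- t(m)
  s <- sqrt(m)
  D <- 1 - crossprod(s)
  D[D < 0] <- 0
  D <- (D + t(D)) / 2
  diag(D) <- 0
  deg <- colnames(m) %in% attr(M, "degenerate_columns")
  if (any(deg)) {
    D[deg, ] <- 1; D[, deg] <- 1
    diag(D) <- 0
  }
  structure(D, generations = attr(M, "generations"),
            class = c("dor_matrix", "matrix"))
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the vectorised strict upper triangles, with a
#' one-tailed permutation p-value (`p = (1 + #(r_perm >= r_obs)) /
#' (1 + n_perm)`) from simultaneous row/column permutations of the second
#' matrix. The permutation machinery is `vegan::mantel`; the seed fixes
#' the permutation stream.
#'
#' @param A,B symmetric zero-diagonal distance matrices, same dimension
#'   (>= 3).
#' @param n_perm number of permutations (default 5000).
#' @param seed integer seed.
#' @return List: `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(A, B, n_perm = 5000, seed = 1L) {
  A <- unclass(A); B <- unclass(B)
  if (!identical(dim(A), dim(B)) || nrow(A) < 3)
    stop("invalid argument: matrices must match and have dimension >= 3")
  res <- with_seed(seed, suppressMessages(
    vegan::mantel(stats::as.dist(A), stats::as.dist(B),
                  method = "pearson", permutations = n_perm)))
  list(r = unname(res$statistic), p = unname(res$signif), n_perm = n_perm)
}

#' Compare modelled connectivity to genetic differentiation
#'
#' Full genetics pipeline: downscale the decadal connectivity matrix to
#' populations, column-standardise into a migration matrix, project over
#' each requested generation count, compute the DOR distance matrices, and
#' Mantel-test each against the pairwise F_ST matrix restricted to the
#' shared population set.
#'
#' @param C_decadal site-level decadal `connectivity_matrix`.
#' @param site_to_population named site-to-population map.
#' @param fst symmetric F_ST matrix with population-id dimnames (a subset
#'   of the model populations; at least 3 shared).
#' @param generations_list generation counts to project (default `c(1, 10)`).
#' @param n_perm,seed Mantel settings.
#' @param released per-site releases (see [downscale_to_populations()]).
#' @return List of class `genetics_comparison`: `migration`, and per
#'   generation count `dor` (shared-subset DOR), `mantel` (r, p).
#' @export
compare_to_genetics <- function(C_decadal, site_to_population, fst,
                                generations_list = c(1, 10),
                                n_perm = 5000, seed = 1L, released = NULL) {
  P <- downscale_to_populations(C_decadal, site_to_population, released)
  M <- to_migration_matrix(P)
  shared <- intersect(rownames(fst), rownames(M))
  if (length(shared) < 3)
    stop("invalid argument: fewer than 3 shared populations")
  out <- list(migration = M, shared = shared, per_generation = list())
  for (g in generations_list) {
    Mg <- project_generations(M, g)
    D <- nei_da_distance(Mg)
    Dsub <- unclass(D)[shared, shared]
    mt <- mantel_test(Dsub, unclass(fst)[shared, shared],
                      n_perm = n_perm, seed = seed + g)
    out$per_generation[[as.character(g)]] <-
      list(generations = g, dor = Dsub, mantel = mt)
  }
  class(out) <- "genetics_comparison"
  out
}

#' @export
print.genetics_comparison <- function(x, ...) {
  cat("genetics_comparison over", length(x$shared), "shared populations\n")
  for (pg in x$per_generation)
    cat(sprintf("  %2d generation(s): Mantel r = %+.4f, p = %.4f\n",
                pg$generations, pg$mantel$r, pg$mantel$p))
  invisible(x)
}
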