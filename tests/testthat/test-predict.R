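random_adjacency <- function(nl, nd, seed, p = 0.3) {
  set.seed(seed)
  m <- matrix(rbinom(nl * nd, 1L, p), nl, nd,
              dimnames = list(sprintf("L%02d", 1:nl),
                              sprintf("d%02d", 1:nd)))
  m[rowSums(m) == 0, 1] <- 1L  # no empty profiles by default
  m
}

test_that("interaction-profile kernel matches its closed form", {
  # identical profiles
  adj <- rbind(L1 = c(1L, 0L), L2 = c(1L, 0L))
  colnames(adj) <- c("d1", "d2")
  expect_equal(unname(gaussian_profile_kernel(adj, "lncrna")),
               matrix(1, 2, 2))
  # orthogonal unit profiles: mean squared norm 1, distance^2 = 2
  k <- gaussian_profile_kernel(diag(1L, 2), "lncrna")
  expect_equal(k[1, 2], exp(-2), tolerance = 1e-12)
  expect_error(gaussian_profile_kernel(matrix(0L, 2, 2), "lncrna"),
               "all-zero")
})

test_that("kernel equals a double-loop recomputation on random adjacencies", {
  for (s in 1:4) {
    adj <- random_adjacency(8, 6, s)
    for (axis in c("lncrna", "disease")) {
      k <- gaussian_profile_kernel(adj, axis, gamma_prime = 1.3)
      prof <- if (axis == "lncrna") adj else t(adj)
      gam <- 1.3 / mean(rowSums(prof^2))
      ref <- outer(seq_len(nrow(prof)), seq_len(nrow(prof)),
                   Vectorize(function(i, j)
                     exp(-gam * sum((prof[i, ] - prof[j, ])^2))))
      expect_equal(unname(k), ref, tolerance = 1e-12)
      expect_identical(k, t(k))
      expect_true(all(diag(k) == 1) && all(k > 0) && all(k <= 1))
    }
  }
})

test_that("similarity integration averages, falls back and records provenance", {
  a <- matrix(c(0.4, 0.2, 0.2, 0.4), 2, 2)
  b <- matrix(c(0.2, 0.0, 0.0, 0.2), 2, 2)
  expect_equal(unname(integrate_similarity(a, a)), a,
               ignore_attr = TRUE)
  expect_equal(integrate_similarity(a, b)[1, 1], 0.3)
  a_na <- a; a_na[1, 2] <- a_na[2, 1] <- NA
  out <- integrate_similarity(a_na, b)
  expect_equal(out[1, 2], b[1, 2])
  expect_identical(attr(out, "provenance")[1, 2], "kernel")
  kf <- integrate_similarity(a_na, b, mode = "kernel_fill")
  expect_equal(kf[1, 1], 0.4)  # primary kept where defined and nonzero
  expect_equal(kf[1, 2], 0.0)  # kernel elsewhere
  expect_error(integrate_similarity(a, matrix(0, 3, 3)), "shape")
})

test_that("identity similarities reproduce the known associations exactly", {
  adj <- random_adjacency(5, 4, 3)
  cfg <- predictor_config()
  f <- lrlslda_scores(diag(5), diag(4), adj, cfg)
  expect_equal(unname(f), unname(adj * 1), tolerance = 1e-10)
})

test_that("single-space solutions minimize the regularized least-squares objective", {
  # independent oracle: numerical minimization of
  # J(F) = ||F - Y||^2 + eta tr(F' L F) for a full-rank similarity
  adj <- random_adjacency(5, 4, 7)
  s_l <- gaussian_profile_kernel(adj, "lncrna")
  eta <- 0.8
  f_pkg <- lrlslda_scores(s_l, diag(4), adj,
                          predictor_config(eta_l = eta, w = 1))
  l <- lncfunsim:::normalized_laplacian(s_l)
  obj <- function(v) {
    f <- matrix(v, 5, 4)
    sum((f - adj)^2) + eta * sum(diag(t(f) %*% l %*% f))
  }
  fit <- optim(as.vector(adj * 0.5), obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  expect_equal(unname(f_pkg), matrix(fit$par, 5, 4), tolerance = 1e-4)
  # and w = 0 gives the transposed-space analogue
  s_d <- gaussian_profile_kernel(adj, "disease")
  f_d <- lrlslda_scores(diag(5), s_d, adj,
                        predictor_config(eta_d = eta, w = 0))
  l_d <- lncfunsim:::normalized_laplacian(s_d)
  obj_d <- function(v) {
    f <- matrix(v, 4, 5)
    sum((f - t(adj))^2) + eta * sum(diag(t(f) %*% l_d %*% f))
  }
  fit_d <- optim(as.vector(t(adj) * 0.5), obj_d, method = "BFGS",
                 control = list(maxit = 2000, reltol = 1e-14))
  expect_equal(unname(f_d), t(matrix(fit_d$par, 4, 5)), tolerance = 1e-4)
})

test_that("scores are equivariant under joint relabeling", {
  adj <- random_adjacency(6, 5, 11)
  s_l <- gaussian_profile_kernel(adj, "lncrna")
  s_d <- gaussian_profile_kernel(adj, "disease")
  f <- lrlslda_scores(s_l, s_d, adj)
  set.seed(2)
  pl <- sample(6); pd <- sample(5)
  f_perm <- lrlslda_scores(s_l[pl, pl], s_d[pd, pd],
                           adj[pl, pd])
  expect_equal(unname(f_perm), unname(f[pl, pd]), tolerance = 1e-9)
})

test_that("scores vary continuously with the regularization strength", {
  adj <- random_adjacency(6, 5, 13)
  s_l <- gaussian_profile_kernel(adj, "lncrna")
  s_d <- gaussian_profile_kernel(adj, "disease")
  f1 <- lrlslda_scores(s_l, s_d, adj, predictor_config(eta_l = 1, eta_d = 1))
  f2 <- lrlslda_scores(s_l, s_d, adj,
                       predictor_config(eta_l = 1 + 1e-6, eta_d = 1 + 1e-6))
  expect_lt(max(abs(f1 - f2)), 1e-4)
  expect_error(lrlslda_scores(matrix(c(0, 1, 0, 0), 2), diag(5),
                              random_adjacency(2, 5, 1)), "symmetric")
})

test_that("the full scoring pipeline ranks planted partners above noise", {
  # held-out within-module associations outscore random cross-module
  # pairs (median-rank comparison over seeds)
  wins <- 0L
  fracs <- numeric(20)
  for (s in 1:20) {
    dag <- generate_dag(n_terms = 40L, seed = s)
    ss <- semantic_similarity_matrix(dag, compute_ic(dag))
    assoc <- generate_associations(dag, n_lncrnas = 12L, n_modules = 3L,
                                   diseases_per_module = 3L, seed = s)
    adj <- association_matrix(assoc)
    lmod <- attr(assoc, "lncrna_module")
    dmod <- attr(assoc, "disease_module")
    known <- which(adj == 1L, arr.ind = TRUE)
    in_module <- lmod[rownames(adj)[known[, 1]]] ==
      dmod[colnames(adj)[known[, 2]]]
    within <- known[in_module, , drop = FALSE]
    set.seed(s)
    f <- within[sample.int(nrow(within), 1L), ]
    y <- adj; y[f[1], f[2]] <- 0L
    sc <- score_associations(y, ss)
    held <- sc[f[1], f[2]]
    cross_pairs <- outer(lmod[rownames(adj)], dmod[colnames(adj)],
                         "!=") & adj == 0L
    if (held > median(sc[cross_pairs])) wins <- wins + 1L
    fracs[s] <- mean(sc[cross_pairs] < held)
  }
  expect_gte(wins, 15L)
  # the planted partner outranks at least 80% of non-module candidates
  # (median over seeds)
  expect_gte(median(fracs), 0.8)
})
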