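#' Predictor configuration
#'
#' Bundles the tunable parameters of the kernel + Laplacian-regularized
#' least-squares scorer.  `gamma_l_prime`/`gamma_d_prime` are the
#' Gaussian interaction-profile kernel bandwidth numerators (the
#' effective bandwidth divides by the mean squared profile norm, so 1
#' is scale-free); `eta_l`/`eta_d` the Laplacian regularization
#' strengths; `w` the weight of the lncRNA-space solution in the final
#' combination.  Neutral defaults of 1, 1 and 0.5 are used throughout.
#'
#' @param gamma_l_prime,gamma_d_prime positive kernel bandwidth
#'   numerators.
#' @param eta_l,eta_d positive regularization strengths.
#' @param w weight in \[0, 1\] of the lncRNA-space scores.
#' @return A list of class `predictor_config`.
#' @export
predictor_config <- function(gamma_l_prime = 1, gamma_d_prime = 1,
                             eta_l = 1, eta_d = 1, w = 0.5) {
  stopifnot(gamma_l_prime > 0, gamma_d_prime > 0,
            eta_l > 0, eta_d > 0, w >= 0, w <= 1)
  structure(list(gamma_l_prime = gamma_l_prime,
                 gamma_d_prime = gamma_d_prime,
                 eta_l = eta_l, eta_d = eta_d, w = w),
            class = "predictor_config")
}

#' Gaussian interaction-profile kernel
#'
#' Similarity between entities computed from their binary association
#' profiles: K(u, v) = exp(-gamma ||y_u - y_v||^2), where gamma =
#' `gamma_prime` divided by the mean squared profile norm over entities
#' with at least one association.  Entities with all-zero profiles are
#' excluded from the bandwidth normalization but still get rows
#' (K(u, u) = 1).
#'
#' @param adjacency binary lncRNA x disease matrix.
#' @param axis "lncrna" (rows) or "disease" (columns).
#' @param gamma_prime positive bandwidth numerator.
#' @return Symmetric matrix in (0, 1\] with unit diagonal.
#' @export
gaussian_profile_kernel <- function(adjacency,
                                    axis = c("lncrna", "disease"),
                                    gamma_prime = 1) {
  axis <- match.arg(axis)
  stopifnot(gamma_prime > 0)
  prof <- if (axis == "lncrna") adjacency else t(adjacency)
  norms2 <- rowSums(prof^2)
  nz <- norms2 > 0
  if (!any(nz)) stop("all-zero adjacency: kernel bandwidth undefined")
  gam <- gamma_prime / mean(norms2[nz])
  # ||u - v||^2 = |u|^2 + |v|^2 - 2 u.v
  cross <- tcrossprod(prof)
  d2 <- outer(norms2, norms2, "+") - 2 * cross
  d2[d2 < 0] <- 0  # numerical guard
  k <- exp(-gam * d2)
  diag(k) <- 1
  k
}

#' Average two similarity sources entrywise
#'
#' "average" mode takes the entrywise mean; where the primary source is
#' undefined (NA) or zero in `kernel_fill` mode, the kernel entry is
#' used alone.  In "average" mode NA primary entries (e.g. diseases
#' absent from the ontology) also fall back to the kernel value, so the
#' result is always fully defined.  The per-entry provenance is
#' recorded in the `provenance` attribute ("average", "primary",
#' "kernel").
#'
#' @param primary primary similarity matrix (may contain NA).
#' @param kernel fallback/kernel similarity matrix, same dimnames.
#' @param mode "average" or "kernel_fill".
#' @return Matrix of the shared shape with `provenance` attribute.
#' @export
integrate_similarity <- function(primary, kernel,
                                 mode = c("average", "kernel_fill")) {
  mode <- match.arg(mode)
  if (!all(dim(primary) == dim(kernel)))
    stop("shape mismatch between similarity sources")
  prov <- matrix("average", nrow(primary), ncol(primary))
  if (mode == "average") {
    out <- (primary + kernel) / 2
    miss <- is.na(primary)
    out[miss] <- kernel[miss]
    prov[miss] <- "kernel"
  } else {
    use_primary <- !is.na(primary) & primary != 0
    out <- kernel
    out[use_primary] <- primary[use_primary]
    prov[] <- "kernel"; prov[use_primary] <- "primary"
  }
  dimnames(out) <- dimnames(kernel)
  attr(out, "provenance") <- prov
  out
}

# normalized graph Laplacian; zero-degree rows become identity rows
normalized_laplacian <- function(s) {
  d <- rowSums(s)
  dis <- ifelse(d > 0, 1 / sqrt(d), 0)
  diag(nrow(s)) - (dis * s) %*% diag(dis, nrow(s))
}

# single-space LapRLS closed form: F = S (S + eta L S)^+ Y
laprls_space <- function(s, y, eta) {
  l <- normalized_laplacian(s)
  a <- s + eta * l %*% s
  s %*% MASS::ginv(a) %*% y
}

#' Laplacian-regularized least-squares association scores
#'
#' Solves the regularized least-squares problem in the lncRNA space
#' (F_l = S_l (S_l + eta L_l S_l)^+ Y, with L the normalized Laplacian
#' of the similarity graph and ^+ the Moore-Penrose pseudo-inverse) and
#' the transposed problem in the disease space, then combines
#' F = w F_l + (1 - w) F_d.  With a full-rank similarity this is the
#' minimizer of ||F - Y||_F^2 + eta tr(F' L F).  Deterministic given
#' its inputs.
#'
#' @param sim_lnc symmetric lncRNA similarity (rows of `adjacency`).
#' @param sim_dis symmetric disease similarity (columns of
#'   `adjacency`).
#' @param adjacency binary lncRNA x disease association matrix Y.
#' @param config a [predictor_config()].
#' @return Score matrix, same shape and dimnames as `adjacency`.
#' @export
lrlslda_scores <- function(sim_lnc, sim_dis, adjacency,
                           config = predictor_config()) {
  if (!isSymmetric(unname(sim_lnc), tol = 1e-8) ||
      !isSymmetric(unname(sim_dis), tol = 1e-8))
    stop("similarity matrices must be symmetric")
  if (nrow(sim_lnc) != nrow(adjacency) || nrow(sim_dis) != ncol(adjacency))
    stop("similarity/adjacency shape mismatch")
  f_l <- laprls_space(sim_lnc, adjacency, config$eta_l)
  f_d <- t(laprls_space(sim_dis, t(adjacency), config$eta_d))
  f <- config$w * f_l + (1 - config$w) * f_d
  dimnames(f) <- dimnames(adjacency)
  f
}

#' Full similarity-to-scores pipeline for one association matrix
#'
#' Builds both Gaussian interaction-profile kernels from the adjacency,
#' integrates them with the semantic/functional similarities by
#' entrywise averaging (an optional precomputed lncRNA expression
#' similarity enters an equal-weight average), and runs the
#' least-squares scorer.  This is the unit the cross-validation
#' routines re-run per fold so held-out associations never leak into
#' the kernels or the functional similarity.
#'
#' @param adjacency binary lncRNA x disease matrix (current training
#'   associations).
#' @param ss disease semantic similarity matrix covering the adjacency
#'   columns (entries for diseases absent from the ontology may be NA).
#' @param fs lncRNA functional similarity covering the adjacency rows,
#'   or NULL to recompute from `adjacency` and `ss`.
#' @param expression optional lncRNA expression-similarity matrix.
#' @param config a [predictor_config()].
#' @return Score matrix shaped like `adjacency`.
#' @export
score_associations <- function(adjacency, ss, fs = NULL,
                               expression = NULL,
                               config = predictor_config()) {
  ln <- rownames(adjacency); di <- colnames(adjacency)
  if (is.null(fs)) {
    tab <- adjacency_to_table(adjacency)
    fs <- functional_similarity_matrix(ss, tab)
  }
  k_l <- gaussian_profile_kernel(adjacency, "lncrna", config$gamma_l_prime)
  k_d <- gaussian_profile_kernel(adjacency, "disease", config$gamma_d_prime)
  fs_full <- matrix(NA_real_, length(ln), length(ln),
                    dimnames = list(ln, ln))
  common <- intersect(ln, rownames(fs))
  fs_full[common, common] <- fs[common, common]
  sim_l <- integrate_similarity(fs_full, k_l, "average")
  if (!is.null(expression)) {
    sim_l <- (fs_full + k_l + expression[ln, ln]) / 3
    miss <- is.na(sim_l)
    sim_l[miss] <- ((k_l + expression[ln, ln]) / 2)[miss]
  }
  ss_full <- matrix(NA_real_, length(di), length(di),
                    dimnames = list(di, di))
  commond <- intersect(di, rownames(ss))
  ss_full[commond, commond] <- ss[commond, commond]
  sim_d <- integrate_similarity(ss_full, k_d, "average")
  lrlslda_scores(sim_l, sim_d, adjacency, config)
}

# adjacency matrix back to an association table
adjacency_to_table <- function(adjacency) {
  idx <- which(adjacency == 1L, arr.ind = TRUE)
  data.frame(lncrna = rownames(adjacency)[idx[, 1]],
             disease = colnames(adjacency)[idx[, 2]],
             stringsAsFactors = FALSE)
}

#' Export a score matrix, or a per-disease ranked candidate list
#'
#' @param scores score matrix from [lrlslda_scores()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  write.table(as.data.frame(scores), path, sep = "\t", quote = FALSE,
              row.names = TRUE, col.names = NA)
  invisible(path)
}
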