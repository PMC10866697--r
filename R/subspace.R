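#' Standardized trial-averaged population trajectory (PETH matrix)
#'
#' Averages each selected unit's smoothed instantaneous rate over all
#' words of an epoch into a single peri-event trajectory, then standardizes
#' each unit's trace to zero mean and unit variance, yielding the T x N
#' matrix whose rows sample the population state every 5 ms. The
#' trajectory analyses use a 50 ms kernel (wider than the 25 ms used for
#' time-resolved decoding).
#'
#' @param session A `session_bundle`.
#' @param units Unit ids to include (typically the feature-selective ones).
#' @param epoch `"planning"` (`[-0.5, 0)`) or `"production"` (`[0, 0.5)`),
#'   or a numeric window.
#' @param bin,kernel_sd Rate-estimation parameters (5 ms / 50 ms).
#' @param exclude_overlap,min_rate_hz Word/unit filters, as in
#'   [assemble_counts()].
#' @return Object of class `peth_matrix`: standardized matrix `M`
#'   (time x units), the time grid, epoch tag and the ids of any units
#'   dropped for zero variance.
#' @export
build_peth <- function(session, units = NULL, epoch = "planning",
                       bin = 0.005, kernel_sd = 0.05,
                       exclude_overlap = TRUE, min_rate_hz = 0.1) {
  cm <- assemble_counts(session, window = if (is.character(epoch)) epoch else epoch,
                        exclude_overlap = exclude_overlap,
                        min_rate_hz = min_rate_hz)
  if (!is.null(units)) {
    keep <- cm$unit_ids %in% units
    cm$unit_ids <- cm$unit_ids[keep]
    cm$counts <- cm$counts[keep, , drop = FALSE]
  }
  assert_that(length(cm$unit_ids) > 0, "no units to include")

  arr <- rate_tensor(session, cm, window = cm$window_s, bin = bin,
                     kernel_sd = kernel_sd)
  avg <- apply(arr, c(3, 2), mean)           # time x units
  colnames(avg) <- cm$unit_ids

  mu <- colMeans(avg)
  sdev <- apply(avg, 2, sd)
  flat <- sdev == 0 | !is.finite(sdev)
  if (any(flat)) {
    warn(paste0("dropping zero-variance unit(s): ",
                paste(colnames(avg)[flat], collapse = ", ")))
  }
  M <- sweep(sweep(avg[, !flat, drop = FALSE], 2, mu[!flat]), 2,
             sdev[!flat], `/`)

  structure(
    list(M = M, time = attr(arr, "time"),
         epoch = if (is.character(epoch)) epoch else "custom",
         bin = bin, kernel_sd = kernel_sd,
         dropped = colnames(avg)[flat]),
    class = "peth_matrix"
  )
}

#' @export
print.peth_matrix <- function(x, ...) {
  cat("<peth_matrix>", x$epoch, ":", nrow(x$M), "time bins x", ncol(x$M),
      "units\n")
  invisible(x)
}

# Unbiased covariance (T - 1 denominator) of a standardized PETH.
peth_covariance <- function(peth) {
  M <- if (inherits(peth, "peth_matrix")) peth$M else as.matrix(peth)
  stats::cov(M)
}

#' Principal-component subspace of a population trajectory
#'
#' SVD-based PCA of the (already standardized) T x N trajectory. The
#' columns of the returned N x k basis are orthonormal; the sign of each
#' component is fixed so its largest-magnitude loading is positive.
#'
#' @param peth A `peth_matrix` or numeric T x N matrix.
#' @param k Subspace dimension (default 5).
#' @return Object of class `subspace_basis`: `basis` (N x k), per-component
#'   `var_explained` fractions, singular values.
#' @export
pca_subspace <- function(peth, k = 5) {
  M <- if (inherits(peth, "peth_matrix")) peth$M else as.matrix(peth)
  M <- sweep(M, 2, colMeans(M))
  sv <- svd(M)
  r <- sum(sv$d > max(dim(M)) * .Machine$double.eps * sv$d[1])
  if (k > r) {
    abort(sprintf("k = %d exceeds the trajectory rank (%d)", k, r),
          class = "phonopop_rank_exceeded")
  }
  V <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(V[, j]))
    if (V[i_max, j] < 0) V[, j] <- -V[, j]
  }
  rownames(V) <- colnames(M)
  structure(
    list(basis = V, k = k,
         var_explained = (sv$d^2 / sum(sv$d^2))[seq_len(k)],
         singular_values = sv$d),
    class = "subspace_basis"
  )
}

#' @export
print.subspace_basis <- function(x, ...) {
  cat("<subspace_basis>", nrow(x$basis), "x", x$k, "| variance captured",
      sprintf("%.1f%%", 100 * sum(x$var_explained)), "\n")
  invisible(x)
}

#' Alignment index between a subspace and another epoch's covariance
#'
#' `A = Tr(D' C D) / sum(top-k eigenvalues of C)`: the fraction of the
#' target epoch's variance recovered when its data are projected into the
#' k-dimensional subspace `D`, relative to the most that any k-dimensional
#' subspace could recover. Equals 1 when `D` spans the top-k eigenvectors
#' of `C`; 0 when `D` is orthogonal to the support of a rank-k `C`.
#'
#' @param basis A `subspace_basis` or N x k orthonormal matrix.
#' @param cov_b Covariance matrix of the other epoch's trajectory.
#' @param denominator `"top_k"` (default; the index attains 1) or `"all"`
#'   (normalizes by total variance).
#' @return Alignment index in `[0, 1]`, or flagged `NA` for a zero
#'   covariance.
#' @export
alignment_index <- function(basis, cov_b, denominator = c("top_k", "all")) {
  denominator <- match.arg(denominator)
  D <- if (inherits(basis, "subspace_basis")) basis$basis else as.matrix(basis)
  cov_b <- as.matrix(cov_b)
  assert_that(nrow(D) == nrow(cov_b) && nrow(cov_b) == ncol(cov_b),
              "dimension mismatch between basis and covariance")
  k <- ncol(D)
  ev <- eigen(cov_b, symmetric = TRUE, only.values = TRUE)$values
  denom <- if (denominator == "top_k") sum(ev[seq_len(k)]) else sum(ev)
  if (denom <= .Machine$double.eps) {
    out <- NA_real_
    attr(out, "reason") <- "zero_covariance"
    return(out)
  }
  sum(diag(t(D) %*% cov_b %*% D)) / denom
}

#' Monte-Carlo null of the alignment index
#'
#' Generates random k-dimensional subspaces with the same covariance
#' structure as the observed data -- `V = orth(U sqrt(S) v / ||U sqrt(S) v||)`
#' with `U, S` the eigenvectors/values of the pooled covariance and `v`
#' white noise -- and recomputes the alignment index against `target_cov`
#' for each. The default 1,000 repetitions give the distribution of
#' alignment attributable to chance alone.
#'
#' @param cov_pooled Covariance of the observed data across all epochs
#'   being compared.
#' @param k Subspace dimension.
#' @param target_cov Covariance the alignment is evaluated against
#'   (defaults to `cov_pooled`).
#' @param n_reps Number of random subspaces (default 1000).
#' @param seed Seed.
#' @param observed Optional observed index, located within the null.
#' @param denominator Passed to [alignment_index()].
#' @return Object of class `alignment_null`: `null` (numeric vector),
#'   `observed`, `percentile` of the observed value.
#' @export
random_subspace_null <- function(cov_pooled, k, target_cov = cov_pooled,
                                 n_reps = 1000, seed = 1, observed = NULL,
                                 denominator = "top_k") {
  cov_pooled <- as.matrix(cov_pooled)
  n <- nrow(cov_pooled)
  eg <- eigen(cov_pooled, symmetric = TRUE)
  S_half <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), n)

  null <- with_seed(seed, {
    vapply(seq_len(n_reps), function(r) {
      v <- matrix(rnorm(n * k), n, k)
      M <- S_half %*% v
      M <- M / norm(M, "2")
      V <- qr.Q(qr(M))[, seq_len(k), drop = FALSE]
      alignment_index(V, target_cov, denominator = denominator)
    }, numeric(1))
  })
  pct <- if (!is.null(observed)) mean(null < observed) else NA_real_
  structure(
    list(null = null, n_reps = n_reps, k = k, observed = observed,
         percentile = pct),
    class = "alignment_null"
  )
}

#' @export
print.alignment_null <- function(x, ...) {
  cat("<alignment_null>", x$n_reps, "reps; null mean",
      sprintf("%.3f", mean(x$null)))
  if (!is.null(x$observed)) {
    cat(sprintf("; observed %.3f (percentile %.1f%%)",
                x$observed, 100 * x$percentile))
  }
  cat("\n")
  invisible(x)
}

#' Grassmannian chordal distance between subspaces
#'
#' `d(A, B) = ||A A' - B B'||_F / sqrt(2)` for orthonormal bases `A`, `B`
#' of equal dimension. Depends only on the subspaces (invariant to
#' within-subspace rotation of either basis). Normalizing by
#' `||A||_F = sqrt(k)` scales the distance to `[0, 1]`, with 0 for
#' identical subspaces and 1 for mutually orthogonal ones.
#'
#' @param A,B `subspace_basis` objects or orthonormal N x k matrices.
#' @param normalize Return the normalized distance (default `FALSE`).
#' @return Non-negative distance.
#' @export
chordal_distance <- function(A, B, normalize = FALSE) {
  A <- if (inherits(A, "subspace_basis")) A$basis else as.matrix(A)
  B <- if (inherits(B, "subspace_basis")) B$basis else as.matrix(B)
  assert_that(identical(dim(A), dim(B)),
              "bases must share ambient dimension and k",
              class = "phonopop_dim_mismatch")
  d <- norm(tcrossprod(A) - tcrossprod(B), "F") / sqrt(2)
  if (normalize) d / sqrt(ncol(A)) else d
}

#' Planning vs production subspace comparison
#'
#' End-to-end wrapper: builds the two epochs' standardized PETHs over the
#' selective units, extracts k-dimensional PCA subspaces, computes both
#' cross-projection alignment indices, the covariance-matched Monte-Carlo
#' null (from the pooled covariance of the concatenated epochs), and the
#' normalized chordal distance.
#'
#' @param session A `session_bundle`.
#' @param units Selective unit ids (NULL = all passing filters).
#' @param k Subspace dimension.
#' @param n_reps Null repetitions.
#' @param seed Seed for the null.
#' @return List of class `subspace_comparison`.
#' @export
compare_subspaces <- function(session, units = NULL, k = 5, n_reps = 1000,
                              seed = 1) {
  peth_a <- build_peth(session, units, "planning")
  peth_b <- build_peth(session, units, "production")
  shared <- intersect(colnames(peth_a$M), colnames(peth_b$M))
  peth_a$M <- peth_a$M[, shared, drop = FALSE]
  peth_b$M <- peth_b$M[, shared, drop = FALSE]

  basis_a <- pca_subspace(peth_a, k)
  basis_b <- pca_subspace(peth_b, k)
  cov_a <- peth_covariance(peth_a)
  cov_b <- peth_covariance(peth_b)

  a_in_b <- alignment_index(basis_a, cov_b)
  b_in_a <- alignment_index(basis_b, cov_a)
  pooled <- stats::cov(rbind(peth_a$M, peth_b$M))
  null <- random_subspace_null(pooled, k, target_cov = cov_b,
                               n_reps = n_reps, seed = seed,
                               observed = a_in_b)
  structure(
    list(
      alignment_planning_in_production = a_in_b,
      alignment_production_in_planning = b_in_a,
      null = null,
      chordal = chordal_distance(basis_a, basis_b),
      chordal_normalized = chordal_distance(basis_a, basis_b, normalize = TRUE),
      var_explained = list(planning = basis_a$var_explained,
                           production = basis_b$var_explained),
      k = k, units = shared
    ),
    class = "subspace_comparison"
  )
}

#' @export
print.subspace_comparison <- function(x, ...) {
  cat("<subspace_comparison> k =", x$k, "over", length(x$units), "units\n")
  cat(sprintf("  alignment planning->production: %.3f (null mean %.3f)\n",
              x$alignment_planning_in_production, mean(x$null$null)))
  cat(sprintf("  alignment production->planning: %.3f\n",
              x$alignment_production_in_planning))
  cat(sprintf("  chordal distance: %.3f (normalized %.3f)\n",
              x$chordal, x$chordal_normalized))
  invisible(x)
}
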