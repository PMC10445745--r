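#' z-transform expression trajectories
#'
#' Standardizes each gene's trajectory across timepoints using the
#' population standard deviation (divisor n), so `(1,2,3)` maps to
#' `(-1.2247, 0, 1.2247)`. Zero-variance trajectories cannot be
#' standardized; they are set to all-zero and flagged.
#'
#' @param mat genes x timepoints matrix (typically log2 normalized,
#'   replicate-averaged expression).
#' @return List with `z` (standardized matrix) and `flat` (character vector
#'   of zero-variance genes).
#' @export
z_transform <- function(mat) {
  if (ncol(mat) < 2) stop("need >= 2 timepoints")
  mu <- rowMeans(mat)
  sd_pop <- sqrt(rowMeans((mat - mu)^2))
  flat <- rownames(mat)[sd_pop == 0]
  z <- (mat - mu) / ifelse(sd_pop == 0, 1, sd_pop)
  z[sd_pop == 0, ] <- 0
  list(z = z, flat = flat)
}

# Per-component Gaussian log density with ridge-stabilized covariance.
log_dmvnorm <- function(x, mu, sigma) {
  ch <- chol(sigma)
  d <- ncol(x)
  xc <- sweep(x, 2, mu)
  q <- colSums(backsolve(ch, t(xc), transpose = TRUE)^2)
  -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(ch))) + q)
}

# One EM fit of a full-covariance Gaussian mixture (covariances carry a
# ridge of 1e-6 on the diagonal, so z-scored trajectories, which are
# rank-deficient by construction, remain fittable). Initialization is a
# seeded k-means hard assignment. Returns NULL on degenerate fits.
fit_gmm_once <- function(x, k, seed, ridge = 1e-6, max_iter = 300L,
                         tol = 1e-8) {
  n <- nrow(x)
  d <- ncol(x)
  set.seed(seed)
  assign <- tryCatch(
    stats::kmeans(x, centers = k, nstart = 5, iter.max = 50)$cluster,
    error = function(e) sample(rep_len(seq_len(k), n)))
  if (length(unique(assign)) < k) {
    assign <- sample(rep_len(seq_len(k), n))
  }
  z <- matrix(0, n, k)
  z[cbind(seq_len(n), assign)] <- 1
  loglik <- -Inf
  means <- matrix(0, k, d)
  for (iter in seq_len(max_iter)) {
    w <- colSums(z)
    if (any(w < 1e-8)) return(NULL)
    pi_k <- w / n
    logd <- matrix(0, n, k)
    for (j in seq_len(k)) {
      mu <- colSums(z[, j] * x) / w[j]
      xc <- sweep(x, 2, mu)
      sigma <- crossprod(xc * sqrt(z[, j])) / w[j] + diag(ridge, d)
      means[j, ] <- mu
      dens <- tryCatch(log_dmvnorm(x, mu, sigma),
                       error = function(e) NULL)
      if (is.null(dens)) return(NULL)
      logd[, j] <- log(pi_k[j]) + dens
    }
    m <- apply(logd, 1, max)
    lse <- m + log(rowSums(exp(logd - m)))
    new_loglik <- sum(lse)
    z <- exp(logd - lse)
    if (is.finite(loglik) && abs(new_loglik - loglik) <
        tol * (abs(loglik) + 1)) {
      loglik <- new_loglik
      break
    }
    loglik <- new_loglik
  }
  if (!is.finite(loglik)) return(NULL)
  npar <- k - 1 + k * d + k * d * (d + 1) / 2
  labels <- apply(z, 1, which.max)
  list(loglik = loglik, bic = -2 * loglik + npar * log(n),
       labels = labels, means = means)
}

#' Select the number of clusters and fit trajectory GMMs
#'
#' For each candidate k, fits `n_init` full-covariance Gaussian mixtures
#' from distinct random initializations and computes the Bayesian
#' Information Criterion (as -2 logL + npar log n, so smaller is better).
#' The selected k minimizes the mean BIC across initializations; the
#' per-initialization label vectors at that k are retained for consensus
#' clustering.
#'
#' @param z genes x timepoints matrix of standardized trajectories.
#' @param k_range integer vector of candidate cluster numbers (default 2:10).
#' @param n_init random initializations per k.
#' @param seed master seed; per-fit seeds are derived from it.
#' @return List with `k_selected`, `mean_bic` (named by k), and `labels`
#'   (matrix of per-initialization label vectors, initializations x genes).
#' @export
select_k_and_cluster <- function(z, k_range = 2:10, n_init = 20L,
                                 seed = 1L) {
  if (length(k_range) < 2) stop("k_range must contain >= 2 values")
  if (nrow(z) <= max(k_range)) stop("need more genes than max(k_range)")
  all_fits <- list()
  mean_bic <- numeric(length(k_range))
  names(mean_bic) <- as.character(k_range)
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    fits <- lapply(seq_len(n_init), function(i) {
      fit_gmm_once(z, k, seed = (seed %% 100000L) * 1000L + k * 50L + i)
    })
    fits <- Filter(Negate(is.null), fits)
    if (length(fits) == 0) {
      mean_bic[ki] <- Inf
    } else {
      mean_bic[ki] <- mean(vapply(fits, `[[`, 1.0, "bic"))
    }
    all_fits[[as.character(k)]] <- fits
  }
  k_selected <- k_range[which.min(mean_bic)]
  fits <- all_fits[[as.character(k_selected)]]
  labels <- do.call(rbind, lapply(fits, `[[`, "labels"))
  colnames(labels) <- rownames(z)
  list(k_selected = k_selected, mean_bic = mean_bic, labels = labels)
}

#' Consensus cluster labels from repeated fits
#'
#' Builds the co-association matrix (fraction of fits in which two genes
#' share a cluster) and partitions it into k groups by average-linkage
#' hierarchical clustering of 1 - co-association. The result is invariant
#' to per-fit label permutations.
#'
#' @param labels matrix of label vectors (fits x genes).
#' @param k number of consensus clusters (default: max label observed).
#' @return Integer vector of consensus labels named by gene.
#' @export
consensus_labels <- function(labels, k = max(labels)) {
  if (nrow(labels) < 2) stop("need >= 2 label vectors")
  n <- ncol(labels)
  co <- matrix(0, n, n)
  for (i in seq_len(nrow(labels))) {
    same <- outer(labels[i, ], labels[i, ], "==")
    co <- co + same
  }
  co <- co / nrow(labels)
  hc <- stats::hclust(stats::as.dist(1 - co), method = "average")
  out <- stats::cutree(hc, k = k)
  names(out) <- colnames(labels)
  out
}

#' Assign a trajectory pattern to each cluster
#'
#' Rule-based classification of cluster mean z-trajectories into the three
#' patterns observed across the time course: `up_after_d3` (steep
#' upregulation after day 3), `transient` (rise until around day 3 then
#' sharp repression) and `gradual_down`.
#'
#' @param means clusters x timepoints matrix of mean z-trajectories.
#' @param days numeric vector of days corresponding to the columns.
#' @param delta z-score margin for the upregulation rule (default 0.5).
#' @return Character vector of patterns, one per cluster (named by row).
#' @export
assign_patterns <- function(means, days = as.numeric(sub("^d", "", colnames(means))),
                            delta = 0.5) {
  if (!any(days > 3) || !any(days <= 3)) {
    stop("timepoints must include day 3 and a later day")
  }
  apply(means, 1, function(v) {
    pre <- mean(v[days <= 3])
    post <- mean(v[days > 3])
    amax <- which.max(v)
    if (post - pre > delta && amax == length(v)) {
      "up_after_d3"
    } else if (amax > 1 && days[amax] <= 3 && v[length(v)] < mean(v)) {
      "transient"
    } else {
      "gradual_down"
    }
  })
}

#' Cluster EF gene trajectories end to end
#'
#' Convenience wrapper: z-transform, model selection, consensus labels and
#' pattern assignment.
#'
#' @param expr_day_means genes x days matrix of replicate-mean normalized
#'   expression (GFP+ branch at days 4-5).
#' @param k_range,n_init,seed passed to [select_k_and_cluster()].
#' @param delta passed to [assign_patterns()].
#' @return List with `k_selected`, `labels` (consensus), `patterns`
#'   (cluster -> pattern), `gene_patterns`, `cluster_means`, `flat`.
#' @export
cluster_trajectories <- function(expr_day_means, k_range = 2:10,
                                 n_init = 20L, seed = 1L, delta = 0.5) {
  zt <- z_transform(log2(expr_day_means + 1))
  z <- zt$z[!(rownames(zt$z) %in% zt$flat), , drop = FALSE]
  sel <- select_k_and_cluster(z, k_range = k_range, n_init = n_init,
                              seed = seed)
  labels <- consensus_labels(sel$labels, k = sel$k_selected)
  cmeans <- do.call(rbind, lapply(sort(unique(labels)), function(cl) {
    colMeans(z[names(labels)[labels == cl], , drop = FALSE])
  }))
  rownames(cmeans) <- sort(unique(labels))
  days <- as.numeric(sub("^d", "", colnames(expr_day_means)))
  patterns <- assign_patterns(cmeans, days = days, delta = delta)
  list(k_selected = sel$k_selected, labels = labels, patterns = patterns,
       gene_patterns = stats::setNames(patterns[as.character(labels)],
                                       names(labels)),
       cluster_means = cmeans, flat = zt$flat)
}
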