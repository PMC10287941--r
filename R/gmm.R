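## Diagonal-covariance Gaussian mixture fit by EM, with the cluster-number
## scan minimising BIC = theta * ln(n) - 2 * ln(Lhat) as used for gene
## grouping in H3K27me3 PC space. The penalty is theta * ln(n), not the
## textbook free-parameter count; `bic_mode = "standard"` offers the latter
## for comparison.

# one EM fit; diagonal covariances, k-means initialisation
.gmm_em <- function(x, k, tol = 1e-3, max_iter = 200L, var_floor = 1e-6,
                    init_seed = NULL) {
  n <- nrow(x); d <- ncol(x)
  if (!is.null(init_seed)) set.seed(init_seed)
  if (k == 1L) {
    mu <- matrix(colMeans(x), 1)
    sg <- matrix(pmax(apply(x, 2, function(v) mean((v - mean(v))^2)), var_floor), 1)
    pi_k <- 1
  } else {
    km <- suppressWarnings(stats::kmeans(x, centers = k, nstart = 1, iter.max = 50))
    mu <- km$centers
    pi_k <- as.numeric(table(factor(km$cluster, levels = seq_len(k)))) / n
    pi_k <- pmax(pi_k, 1e-10); pi_k <- pi_k / sum(pi_k)
    sg <- t(vapply(seq_len(k), function(j) {
      mem <- km$cluster == j
      if (sum(mem) > 1)
        pmax(apply(x[mem, , drop = FALSE], 2,
                   function(v) mean((v - mean(v))^2)), var_floor)
      else pmax(apply(x, 2, stats::var), var_floor)
    }, numeric(d)))
  }
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    # E step in log space
    logdens <- vapply(seq_len(k), function(j) {
      -0.5 * (d * log(2 * pi) + sum(log(sg[j, ])) +
              rowSums(sweep(sweep(x, 2, mu[j, ]), 2, sqrt(sg[j, ]), "/")^2))
    }, numeric(n))
    logdens <- matrix(logdens, n, k)
    lw <- sweep(logdens, 2, log(pi_k), `+`)
    mx <- apply(lw, 1, max)
    ll <- sum(mx + log(rowSums(exp(lw - mx))))
    resp <- exp(lw - mx - log(rowSums(exp(lw - mx))))
    if (is.finite(ll_old) && ll - ll_old < tol) break
    ll_old <- ll
    # M step
    nk <- colSums(resp)
    if (any(nk < 1e-8)) return(NULL)          # empty component: caller refits
    pi_k <- nk / n
    mu <- sweep(t(resp) %*% x, 1, nk, "/")
    for (j in seq_len(k))
      sg[j, ] <- pmax(colSums(resp[, j] * sweep(x, 2, mu[j, ])^2) / nk[j],
                      var_floor)
  }
  list(loglik = ll, pi = pi_k, mu = mu, sigma2 = sg, posterior = resp, k = k)
}

.gmm_fit <- function(x, k, seed, tol = 1e-3, tries = 5L) {
  for (t in seq_len(tries)) {
    fit <- tryCatch(.gmm_em(x, k, tol = tol, init_seed = seed + (t - 1L) * 1000L),
                    error = function(e) NULL)
    if (!is.null(fit)) return(fit)
  }
  NULL
}

#' BIC scan for the Gaussian-mixture cluster number
#'
#' For each candidate cluster number theta in `1..theta_max`, fits a
#' diagonal-covariance GMM by EM (stopping when the log-likelihood gain
#' drops below `tol`) and scores it with `BIC = penalty * ln(n) - 2 *
#' ln(Lhat)`, choosing the theta that minimises it.
#' Because EM is sensitive to initialisation, the scan is repeated
#' (default 10 times) with seeds derived deterministically from `seed`; the
#' chosen theta* is the most frequent per-repeat argmin (ties toward the
#' smaller theta).
#'
#' @param features n x m numeric matrix (genes x selected PC scores).
#' @param theta_max largest candidate cluster number (<= n).
#' @param repeats scan repetitions (default 10).
#' @param seed base seed (default 42).
#' @param tol EM log-likelihood stopping tolerance (default 1e-3).
#' @param bic_mode `"standard"` (default; penalty = free parameter count
#'   times ln n, as computed by the mixture-model libraries this procedure
#'   descends from) or `"published"` (penalty theta * ln n as the criterion
#'   is often quoted; degenerate for model selection in multivariate
#'   feature spaces - the likelihood gain of an extra component always
#'   exceeds ln n, so the scan returns theta_max; kept for comparison).
#' @return list with `theta_star`, `per_repeat` (argmin per repeat), `bic`
#'   (repeats x theta matrix), `loglik` (same shape); class `"bic_scan"`.
#' @export
scan_cluster_number <- function(features, theta_max = 100, repeats = 10,
                                seed = 42, tol = 1e-3,
                                bic_mode = c("standard", "published")) {
  bic_mode <- match.arg(bic_mode)
  features <- as.matrix(features)
  n <- nrow(features); d <- ncol(features)
  if (theta_max > n) .stop2("theta_max exceeds number of genes")
  thetas <- seq_len(theta_max)
  bic <- loglik <- matrix(NA_real_, repeats, theta_max,
                          dimnames = list(NULL, thetas))
  for (rep_i in seq_len(repeats)) {
    for (k in thetas) {
      fit <- .gmm_fit(features, k, seed = seed + 7919L * (rep_i - 1L) + k,
                      tol = tol)
      if (is.null(fit)) {
        warning("EM failed for theta=", k, " (repeat ", rep_i, "); skipped",
                call. = FALSE)
        next
      }
      loglik[rep_i, k] <- fit$loglik
      pen <- if (bic_mode == "published") k
             else (k - 1) + 2 * k * d          # weights + means + variances
      bic[rep_i, k] <- pen * log(n) - 2 * fit$loglik
    }
  }
  per_repeat <- apply(bic, 1, function(row) {
    if (all(is.na(row))) NA_integer_ else which.min(row)
  })
  tabulated <- table(factor(per_repeat, levels = thetas))
  theta_star <- as.integer(names(tabulated)[which.max(tabulated)]) # ties -> smaller
  structure(list(theta_star = theta_star, per_repeat = per_repeat,
                 bic = bic, loglik = loglik, repeats = repeats,
                 bic_mode = bic_mode, seed = seed),
            class = "bic_scan")
}

#' Fit the final Gaussian mixture and assign genes to clusters
#'
#' Fits a diagonal-covariance GMM with `theta_star` components by EM
#' (tolerance `tol` on the log-likelihood gain) and assigns each gene to
#' the cluster with the highest posterior probability. EM is restarted from
#' `n_init` deterministic initialisations (seeds derived from `seed`) and
#' the fit with the best log-likelihood is kept; an empty component
#' triggers a refit with a shifted seed.
#'
#' @param features n x m numeric matrix.
#' @param theta_star number of mixture components (>= 1).
#' @param seed RNG seed for initialisation (default 42).
#' @param tol EM stopping tolerance.
#' @param n_init number of EM restarts (default 10).
#' @return list with `pi`, `mu` (k x m), `sigma2` (k x m), `posterior`
#'   (n x k), `assignment` (argmax posterior), `loglik`; class
#'   `"gene_cluster_model"`.
#' @export
assign_gene_clusters <- function(features, theta_star, seed = 42, tol = 1e-3,
                                 n_init = 10L) {
  if (theta_star < 1) .stop2("theta_star must be >= 1")
  features <- as.matrix(features)
  fit <- NULL
  for (init in seq_len(n_init)) {
    cand <- .gmm_fit(features, theta_star, seed = seed + (init - 1L) * 101L,
                     tol = tol)
    if (!is.null(cand) && (is.null(fit) || cand$loglik > fit$loglik))
      fit <- cand
  }
  if (is.null(fit)) .stop2("EM failed to produce a non-degenerate fit")
  assignment <- apply(fit$posterior, 1, which.max)
  structure(list(pi = fit$pi, mu = fit$mu, sigma2 = fit$sigma2,
                 posterior = fit$posterior, assignment = assignment,
                 loglik = fit$loglik, theta = as.integer(theta_star)),
            class = "gene_cluster_model")
}
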