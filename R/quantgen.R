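#' Additive and dominance genomic relationship matrices
#'
#' Standard centered parameterization: the additive GRM is built from
#' dosages centered at `2p` and scaled by `sum(2 p (1-p))`; the dominance GRM
#' from heterozygosity indicators centered at `2 p (1-p)` and scaled by
#' `sum((2 p (1-p))^2)`. Missing dosages are mean-imputed per site;
#' monomorphic sites are dropped.
#'
#' @param X dosage matrix, samples x markers, values `{0, 1, 2, NA}` (or a
#'   [GenoPanel-class], transposed internally).
#' @param p optional vector of reference allele frequencies (one per marker);
#'   by default frequencies are estimated from `X` itself.
#' @return list with `GA`, `GD` (n x n symmetric matrices), `p` (allele
#'   frequencies of the retained markers), `keep` (retained marker indices),
#'   `cA`, `cD` (the two scaling constants).
#' @export
buildGRMs <- function(X, p = NULL) {
  X <- .as_sample_matrix(X)
  if (is.null(p)) p <- colMeans(X, na.rm = TRUE) / 2
  keep <- which(!is.na(p) & p > 0 & p < 1)
  if (!length(keep)) stop("all markers are monomorphic; no GRM can be built")
  X <- X[, keep, drop = FALSE]
  p <- p[keep]
  W <- sweep(X, 2, 2 * p)
  W[is.na(W)] <- 0
  H <- (X == 1) * 1
  H[is.na(H)] <- 2 * p[col(H)][is.na(H)] * (1 - p[col(H)][is.na(H)])
  H <- sweep(H, 2, 2 * p * (1 - p))
  cA <- sum(2 * p * (1 - p))
  cD <- sum((2 * p * (1 - p))^2)
  list(
    GA = tcrossprod(W) / cA, GD = tcrossprod(H) / cD,
    p = p, keep = keep, cA = cA, cD = cD
  )
}

.as_sample_matrix <- function(X) {
  if (is(X, "GenoPanel")) X <- t(dosage(X))
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  X
}

#' GBLUP variance components by REML
#'
#' Fits `y = X b + u_A + u_D + e` with `u_A ~ N(0, GA sigma2_A)`,
#' `u_D ~ N(0, GD sigma2_D)` by average-information REML with an EM fallback
#' when an AI step leaves the parameter space or decreases the restricted
#' likelihood. Components are clamped at a small positive floor; convergence
#' is declared when the log-likelihood changes by less than `tol`.
#'
#' @param y numeric phenotype vector (n >= 30), centered internally.
#' @param GA additive GRM.
#' @param GD optional dominance GRM (`NULL` fits the additive-only model).
#' @param covariates optional n x q matrix of fixed covariates (an intercept
#'   is always included).
#' @param maxit,tol iteration cap and log-likelihood convergence tolerance.
#' @return list with `varcomp` (sigma2_A, sigma2_D, sigma2_E), `h2_A`, `h2_D`,
#'   `beta`, `u_A`, `u_D`, `Py`, `loglik`, `converged`, `iterations`.
#' @export
fitGBLUP <- function(y, GA, GD = NULL, covariates = NULL,
                     maxit = 200L, tol = 1e-6) {
  n <- length(y)
  X <- cbind(intercept = rep(1, n), covariates)
  K <- list(A = GA)
  if (!is.null(GD)) K$D <- GD
  r <- length(K) + 1L # + residual
  vy <- var(y)
  sigma <- rep(vy / r, r)
  floor_v <- 1e-8 * vy

  mkP <- function(sigma) {
    V <- diag(sigma[r], n)
    for (i in seq_along(K)) V <- V + sigma[i] * K[[i]]
    ch <- tryCatch(chol(V), error = function(e) chol(V + diag(1e-8 * vy, n)))
    Vi <- chol2inv(ch)
    XtVi <- crossprod(X, Vi)
    XtViX <- XtVi %*% X
    P <- Vi - t(XtVi) %*% solve(XtViX, XtVi)
    ll <- -0.5 * (2 * sum(log(diag(ch))) +
      determinant(XtViX, logarithm = TRUE)$modulus +
      drop(crossprod(y, P %*% y)))
    list(P = P, ll = drop(ll), XtViX = XtViX, Vi = Vi)
  }

  st <- mkP(sigma)
  converged <- FALSE
  it <- 0L
  Klist <- c(K, list(E = NULL)) # NULL marks the identity
  for (it in seq_len(maxit)) {
    Py <- st$P %*% y
    KPy <- lapply(Klist, function(Ki) if (is.null(Ki)) Py else Ki %*% Py)
    score <- vapply(seq_len(r), function(i) {
      trPK <- if (is.null(Klist[[i]])) sum(diag(st$P)) else sum(st$P * t(Klist[[i]]))
      -0.5 * (trPK - drop(crossprod(Py, KPy[[i]])))
    }, numeric(1))
    AI <- matrix(0, r, r)
    PKPy <- lapply(KPy, function(v) st$P %*% v)
    for (i in seq_len(r)) {
      for (j in i:r) {
        AI[i, j] <- AI[j, i] <- 0.5 * drop(crossprod(KPy[[i]], PKPy[[j]]))
      }
    }
    step <- tryCatch(solve(AI, score), error = function(e) NULL)
    new_sigma <- if (is.null(step)) NULL else sigma + step
    ok <- !is.null(new_sigma) && all(new_sigma > 0)
    if (ok) {
      st_new <- mkP(new_sigma)
      ok <- is.finite(st_new$ll) && st_new$ll >= st$ll - 1e-4
    }
    if (!ok) { # EM fallback, always increases the likelihood
      new_sigma <- vapply(seq_len(r), function(i) {
        trPK <- if (is.null(Klist[[i]])) sum(diag(st$P)) else sum(st$P * t(Klist[[i]]))
        sigma[i] + (sigma[i]^2 / n) * (drop(crossprod(Py, KPy[[i]])) - trPK)
      }, numeric(1))
      new_sigma <- pmax(new_sigma, floor_v)
      st_new <- mkP(new_sigma)
    }
    done <- abs(st_new$ll - st$ll) < tol
    sigma <- new_sigma
    st <- st_new
    if (done) {
      converged <- TRUE
      break
    }
  }

  Py <- st$P %*% y
  beta <- solve(st$XtViX, crossprod(X, st$Vi %*% y))
  uA <- drop(sigma[1] * (GA %*% Py))
  uD <- if (!is.null(GD)) drop(sigma[2] * (GD %*% Py)) else NULL
  sA <- sigma[1]
  sD <- if (!is.null(GD)) sigma[2] else 0
  sE <- sigma[r]
  tot <- sA + sD + sE
  list(
    varcomp = c(sigma2_A = sA, sigma2_D = sD, sigma2_E = sE),
    h2_A = sA / tot, h2_D = sD / tot,
    beta = drop(beta), u_A = uA, u_D = uD, Py = drop(Py),
    loglik = st$ll, converged = converged, iterations = it
  )
}

#' Backsolve SNP effects from a GBLUP fit
#'
#' Converts genomic breeding values to per-SNP additive (`a`) and dominance
#' (`d`) effects via the standard BLUP backsolution
#' `a = (sigma2_A / cA) W' Py`, `d = (sigma2_D / cD) H' Py`, and scores each
#' SNP's explained variance as `2pq a^2 + (2pq)^2 d^2`. Filter flags follow
#' the effect-size protocol: nonzero additive effect (`|a| > eps`), explained
#' variance strictly greater than the genome-wide mean, and degree of
#' dominance `|k = d/a| < 2`.
#'
#' @param fit result of [fitGBLUP()].
#' @param X the dosage matrix the fit was built from (samples x markers).
#' @param grms the [buildGRMs()] result (supplies scalings and frequencies).
#' @param eps threshold operationalizing "nonzero" additive effect.
#' @return data.frame with `marker`, `maf`, `a`, `d`, `k`, `var_explained`
#'   and logical `pass_a`, `pass_var`, `pass_k`, `pass` columns.
#' @export
backsolveEffects <- function(fit, X, grms, eps = 1e-12) {
  X <- .as_sample_matrix(X)[, grms$keep, drop = FALSE]
  p <- grms$p
  W <- sweep(X, 2, 2 * p)
  W[is.na(W)] <- 0
  H <- (X == 1) * 1
  H[is.na(H)] <- 2 * p[col(H)][is.na(H)] * (1 - p[col(H)][is.na(H)])
  H <- sweep(H, 2, 2 * p * (1 - p))
  a <- drop(crossprod(W, fit$Py)) * fit$varcomp["sigma2_A"] / grms$cA
  d <- if (is.null(fit$u_D)) {
    rep(0, length(a))
  } else {
    drop(crossprod(H, fit$Py)) * fit$varcomp["sigma2_D"] / grms$cD
  }
  v2pq <- 2 * p * (1 - p)
  var_explained <- v2pq * a^2 + v2pq^2 * d^2
  k <- ifelse(abs(a) > eps, d / a, NA_real_)
  out <- data.frame(
    marker = grms$keep, maf = pmin(p, 1 - p), a = a, d = d, k = k,
    var_explained = var_explained,
    pass_a = abs(a) > eps,
    pass_var = var_explained > mean(var_explained),
    row.names = NULL
  )
  out$pass_k <- !is.na(out$k) & abs(out$k) < 2
  out$pass <- out$pass_a & out$pass_var & out$pass_k
  out
}

#' Frequency-matched null SNP sets
#'
#' Draws `n_sets` sets of SNPs from a pool so that every set reproduces the
#' target set's minor-allele-frequency histogram exactly, using `n_bins`
#' equal-width bins on (0, 0.5]. Sampling is without replacement within a
#' set and deterministic under the seed.
#'
#' @param target_maf MAF of the target (e.g. deleterious) SNPs.
#' @param pool_maf MAF of the candidate pool (e.g. nondeleterious SNPs).
#' @param n_sets number of null sets.
#' @param n_bins number of MAF bins.
#' @param seed integer seed.
#' @return list of integer vectors, each indexing `pool_maf`.
#' @export
frequencyMatchedNull <- function(target_maf, pool_maf, n_sets = 10L,
                                 n_bins = 10L, seed = 1L) {
  bin_of <- function(maf) pmax(1L, pmin(n_bins, ceiling(maf / 0.5 * n_bins)))
  tb <- bin_of(target_maf)
  pb <- bin_of(pool_maf)
  need <- table(factor(tb, levels = seq_len(n_bins)))
  have <- table(factor(pb, levels = seq_len(n_bins)))
  short <- which(need > have)
  if (length(short)) {
    stop(
      "pool shortfall in MAF bin(s) ",
      paste(sprintf("(%.2f,%.2f]", (short - 1) * 0.5 / n_bins, short * 0.5 / n_bins),
        collapse = ", "
      )
    )
  }
  set.seed(seed)
  lapply(seq_len(n_sets), function(s) {
    idx <- integer(0)
    for (b in which(need > 0)) {
      cand <- which(pb == b)
      idx <- c(idx, cand[sample.int(length(cand), need[b])])
    }
    sort(idx)
  })
}

#' LD pruning of a marker panel
#'
#' Greedy sliding-window pruning in the style of PLINK's `indep-pairwise`:
#' within each window of `window` SNPs (advanced by `step`), every surviving
#' pair with squared correlation at or above `r2_threshold` loses its
#' later-positioned member. The surviving set contains no within-window pair
#' at `r^2 >=` threshold.
#'
#' @param X dosage matrix, samples x markers, markers in genome order.
#' @param r2_threshold squared-correlation threshold.
#' @param window window size in SNPs; `step` the window increment.
#' @return integer vector of surviving marker indices.
#' @export
ldPrune <- function(X, r2_threshold = 0.1, window = 50L, step = 5L) {
  X <- .as_sample_matrix(X)
  m <- ncol(X)
  alive <- rep(TRUE, m)
  starts <- unique(c(seq(1L, max(1L, m - 1L), by = step)))
  for (s in starts) {
    idx <- s:min(m, s + window - 1L)
    idx <- idx[alive[idx]]
    if (length(idx) < 2) next
    r2 <- suppressWarnings(cor(X[, idx, drop = FALSE], use = "pairwise.complete.obs"))^2
    for (i in seq_along(idx)) {
      if (!alive[idx[i]]) next
      for (j in seq_along(idx)) {
        if (j <= i || !alive[idx[j]]) next
        if (!is.na(r2[i, j]) && r2[i, j] >= r2_threshold) alive[idx[j]] <- FALSE
      }
    }
  }
  which(alive)
}

#' BayesS-style Bayesian SNP model with frequency-coupled effect variance
#'
#' Gibbs sampler over the mixture model
#' `beta_j ~ pi0 delta_0 + (1 - pi0) N(0, sigma_b^2 (2 p_j q_j)^S)`,
#' with `S` updated by random-walk Metropolis within Gibbs, scaled
#' inverse-chi-square conditionals for the variance components and a
#' Beta(1,1) prior on the mixture weight. Fixed effects are an intercept and
#' the first `n_pcs` principal components of the (centered) dosage matrix.
#' `S > 0` means effect size rises with minor allele frequency; `S < 0` is
#' the signature of (purifying or stabilizing) selection on the trait.
#'
#' @param y phenotype vector.
#' @param X dosage matrix (samples x markers), ideally LD-pruned
#'   ([ldPrune()]).
#' @param n_pcs number of leading principal components used as covariates.
#' @param chain_length,burn_in,thin chain control. Desk-scale defaults; the
#'   full-scale protocol (410000 / 10000) is available by argument.
#' @param seed integer seed (R RNG; the sampler is deterministic given it).
#' @param s_prior_sd standard deviation of the N(0, .) prior on `S`.
#' @param mh_step random-walk step for the `S` update.
#' @param start_pi1 starting value for the nonzero-effect probability.
#' @param pi_prior Beta(a, b) prior on the nonzero-effect probability;
#'   the default favors sparse architectures, which keeps the S update
#'   informed by genuinely supported effects at panel-scale n.
#' @return list with posterior draws (`S`, `pi`, `h2`, `sigma_b2`,
#'   `sigma_e2`), `pip` (per-SNP inclusion probabilities), `beta_mean`,
#'   `accept_rate`, and posterior summaries `S_mean`, `S_ci` (95% credible
#'   interval), `h2_mean`, `pi_mean`.
#' @export
fitBayesS <- function(y, X, n_pcs = 3L, chain_length = 20000L,
                      burn_in = 2000L, thin = 10L, seed = 1L,
                      s_prior_sd = 1, mh_step = 0.3, start_pi1 = 0.05,
                      pi_prior = c(1, 49)) {
  if (chain_length <= burn_in) stop("chain_length must exceed burn_in")
  X <- .as_sample_matrix(X)
  p <- colMeans(X, na.rm = TRUE) / 2
  keep <- which(!is.na(p) & p > 0 & p < 1)
  X <- X[, keep, drop = FALSE]
  p <- p[keep]
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (any(miss)) X[miss, j] <- 2 * p[j]
  }
  Xc <- sweep(X, 2, 2 * p)
  Q <- cbind(intercept = rep(1, nrow(Xc)))
  if (n_pcs > 0) {
    pcs <- svd(Xc, nu = n_pcs, nv = 0)$u[, seq_len(n_pcs), drop = FALSE]
    colnames(pcs) <- paste0("PC", seq_len(n_pcs))
    Q <- cbind(Q, pcs)
  }
  set.seed(seed)
  res <- .bayess_gibbs(
    Xc, y, Q, 2 * p * (1 - p), as.integer(chain_length),
    as.integer(burn_in), as.integer(thin), s_prior_sd, mh_step,
    start_pi1, 0, 4, pi_prior[1], pi_prior[2]
  )
  res$markers <- keep
  res$S_mean <- mean(res$S)
  res$S_ci <- unname(quantile(res$S, c(0.025, 0.975)))
  res$h2_mean <- mean(res$h2)
  res$pi_mean <- mean(res$pi)
  res
}
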