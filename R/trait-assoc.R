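#' Phylogenetic logistic regression of gene retention on a trait
#'
#' Fits logit P(y = 1) = b0 + b1 x with phylogenetic dependence between
#' species governed by a signal parameter alpha: the working correlation
#' between tips i and j is exp(-alpha d_ij), with d_ij the patristic
#' distance, so large alpha means independence. Two estimators are offered:
#' `logistic_IG10`, a generalized estimating-equation fit with this working
#' correlation (the binary mean-reversion construction of Ives & Garland),
#' and `logistic_MPLE`, the same estimating equations augmented with a
#' Firth-type penalty 0.5 log det of the working information, which keeps
#' coefficients finite under separation. On a star phylogeny (or as alpha
#' hits its upper bound) MPLE reduces to ordinary Firth-penalized logistic
#' regression. alpha is profiled on a log grid over [1e-4, 1e4] (1/MY) and
#' refined; boundary hits are flagged. Two-sided p-values for b1 come from a
#' Wald test and optionally from a seeded parametric bootstrap under the
#' fitted null.
#'
#' @param st A [status_tree()] or `phylo` covering all species.
#' @param y Named 0/1 retention vector (1 = gene retained).
#' @param x Named numeric predictor (e.g. percent fast-glycolytic fiber).
#' @param method `"logistic_MPLE"` (default) or `"logistic_IG10"`.
#' @param nboot Parametric bootstrap replicates for the b1 p-value
#'   (0 = Wald only; 499 recommended for reporting).
#' @param seed Seed for the bootstrap.
#' @return A `phylo_glm_fit`: coefficients, alpha, standard errors, Wald and
#'   bootstrap p-values, convergence and boundary flags.
#' @export
fit_phylo_logistic <- function(st, y, x,
                               method = c("logistic_MPLE", "logistic_IG10"),
                               nboot = 0L, seed = 1L) {
  method <- match.arg(method)
  phy <- if (inherits(st, "status_tree")) st$phylo else st
  if (is.null(names(y)) || is.null(names(x))) {
    stop("y and x must be named by species")
  }
  miss <- setdiff(phy$tip.label, names(y))
  extra <- setdiff(names(y), phy$tip.label)
  if (length(miss) || length(extra)) {
    stop("species mismatch between tree and data: ",
         paste(c(miss, extra), collapse = ", "))
  }
  sp <- phy$tip.label
  y <- as.numeric(y[sp]); x <- as.numeric(x[sp])
  if (length(y) < 10L) stop("need at least 10 species")
  if (length(unique(y)) < 2L) stop("retention vector is constant")
  D <- ape::cophenetic.phylo(phy)[sp, sp]
  X <- cbind(1, x)

  prof <- .profile_alpha(X, y, D, penalized = method == "logistic_MPLE")
  fit <- prof$fit

  p_boot <- NA_real_
  if (nboot > 0L) {
    null_prof <- .profile_alpha(X[, 1, drop = FALSE], y, D,
                                penalized = method == "logistic_MPLE")
    b0 <- null_prof$fit$beta[1]
    alpha0 <- null_prof$alpha
    set.seed(seed)
    Cn <- exp(-alpha0 * D)
    ref <- replicate(nboot, {
      ystar <- .sim_correlated_binary(rep(b0, length(y)), Cn)
      if (length(unique(ystar)) < 2L) return(NA_real_)
      f <- tryCatch(.profile_alpha(X, ystar, D,
                                   penalized = method == "logistic_MPLE"),
                    error = function(e) NULL)
      if (is.null(f)) NA_real_ else f$fit$beta[2]
    })
    ref <- ref[!is.na(ref)]
    p_boot <- (1 + sum(abs(ref) >= abs(fit$beta[2]))) / (length(ref) + 1)
  }

  se <- sqrt(diag(fit$vcov))
  z <- fit$beta / se
  structure(list(method = method,
                 coefficients = setNames(fit$beta, c("(Intercept)", "slope")),
                 alpha = prof$alpha,
                 se = setNames(se, c("(Intercept)", "slope")),
                 p_wald = setNames(2 * stats::pnorm(-abs(z)),
                                   c("(Intercept)", "slope")),
                 p_boot = p_boot,
                 converged = fit$converged,
                 alpha_boundary = prof$boundary,
                 n = length(y)),
            class = "phylo_glm_fit")
}

#' @export
print.phylo_glm_fit <- function(x, ...) {
  cat(sprintf("<phylo_glm_fit> %s (n = %d)\n", x$method, x$n))
  cat(sprintf("  b0 = %.4f (se %.4f), b1 = %.4f (se %.4f)\n",
              x$coefficients[1], x$se[1], x$coefficients[2], x$se[2]))
  cat(sprintf("  alpha = %.4g%s; p(slope): Wald %.4g%s\n", x$alpha,
              if (x$alpha_boundary) " [boundary]" else "",
              x$p_wald[2],
              if (!is.na(x$p_boot)) sprintf(", bootstrap %.4g", x$p_boot) else ""))
  invisible(x)
}

# profile the Gaussian working quasi-likelihood over alpha (log grid + refine)
.profile_alpha <- function(X, y, D, penalized) {
  crit <- function(la) {
    C <- exp(-exp(la) * D)
    f <- tryCatch(.gee_logistic(X, y, C, penalized), error = function(e) NULL)
    if (is.null(f)) return(list(val = -Inf, fit = NULL))
    mu <- f$mu
    v <- mu * (1 - mu)
    V <- (sqrt(v) %o% sqrt(v)) * C
    diag(V) <- v + 1e-9
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(list(val = -Inf, fit = NULL))
    r <- y - mu
    q <- -sum(log(diag(ch))) - 0.5 * sum(backsolve(ch, r, transpose = TRUE)^2)
    list(val = q, fit = f)
  }
  grid <- seq(log(1e-4), log(1e4), length.out = 13)
  vals <- lapply(grid, crit)
  vv <- vapply(vals, `[[`, numeric(1), "val")
  best <- which.max(vv)
  lo <- grid[max(best - 1L, 1L)]; hi <- grid[min(best + 1L, length(grid))]
  safe_val <- function(la) {
    v <- crit(la)$val
    if (!is.finite(v)) -1e12 else v
  }
  op <- stats::optimize(safe_val, c(lo, hi), maximum = TRUE, tol = 1e-3)
  cand <- if (op$objective > vv[best]) op$maximum else grid[best]
  res <- crit(cand)
  boundary <- abs(cand - log(1e-4)) < 1e-6 || abs(cand - log(1e4)) < 0.34
  list(alpha = exp(cand), fit = res$fit, boundary = boundary)
}

# GEE / penalized-GEE logistic fit for fixed working correlation C
.gee_logistic <- function(X, y, C, penalized, max_iter = 50L, btol = 12) {
  beta <- rep(0, ncol(X))
  beta[1] <- stats::qlogis(min(max(mean(y), 0.05), 0.95))
  Cinv <- solve(C + diag(1e-9, nrow(C)))
  info <- function(beta) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    a <- mu * (1 - mu)
    sa <- sqrt(pmax(a, 1e-10))
    # V^{ -1} = A^{-1/2} Cinv A^{-1/2}
    Vinv <- Cinv / (sa %o% sa)
    Dm <- X * a
    list(mu = mu, a = a, Vinv = Vinv, Dm = Dm,
         I = crossprod(Dm, Vinv %*% Dm))
  }
  pen_grad <- function(beta) {
    # numeric gradient of 0.5 log det I(beta)
    h <- 1e-5
    vapply(seq_along(beta), function(k) {
      bp <- beta; bp[k] <- bp[k] + h
      bm <- beta; bm[k] <- bm[k] - h
      (determinant(info(bp)$I)$modulus - determinant(info(bm)$I)$modulus) /
        (4 * h)
    }, numeric(1))
  }
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    ii <- info(beta)
    U <- drop(crossprod(ii$Dm, ii$Vinv %*% (y - ii$mu)))
    if (penalized) U <- U + pen_grad(beta)
    step <- tryCatch(solve(ii$I + diag(1e-8, ncol(X)), U),
                     error = function(e) NULL)
    if (is.null(step)) break
    if (max(abs(step)) > 2) step <- step * 2 / max(abs(step))
    beta_new <- beta + step
    beta_new <- pmin(pmax(beta_new, -btol), btol)
    if (max(abs(beta_new - beta)) < 1e-8) {
      beta <- beta_new; converged <- TRUE; break
    }
    beta <- beta_new
  }
  ii <- info(beta)
  list(beta = beta, mu = ii$mu,
       vcov = solve(ii$I + diag(1e-10, ncol(X))),
       converged = converged)
}

# correlated binary draws with marginal logit means eta via Gaussian copula
.sim_correlated_binary <- function(eta, C) {
  n <- length(eta)
  ch <- chol(C + diag(1e-8, n))
  z <- drop(crossprod(ch, stats::rnorm(n)))
  u <- stats::pnorm(z / sqrt(diag(crossprod(ch))))
  as.numeric(u < stats::plogis(eta))
}

#' Brownian-motion ancestral states for continuous traits
#'
#' Maximum-likelihood (equivalently GLS) estimates of internal-node states
#' under Brownian motion: the estimates minimize the sum over branches of
#' squared state changes weighted by inverse branch length, which is a
#' sparse linear system in the internal states. Multiple components (e.g.
#' white/pink/red fiber percentages) are estimated independently and then
#' renormalized to sum to 100.
#'
#' @param st A [status_tree()] or `phylo` with positive branch lengths.
#' @param x Named vector of tip values, or a matrix/data.frame with species
#'   rows and component columns.
#' @param renormalize_to Row-sum target after renormalization (default 100
#'   for compositional input; NA = no renormalization; always NA for
#'   single-component input).
#' @return data.frame: one row per internal node with component estimates
#'   and estimator variances (`var_<component>`).
#' @export
ancestral_continuous <- function(st, x, renormalize_to = 100) {
  phy <- if (inherits(st, "status_tree")) st$phylo else st
  node_names <- if (inherits(st, "status_tree")) st$node_names else {
    nl <- if (!is.null(phy$node.label) && all(phy$node.label != "")) {
      phy$node.label
    } else paste0("node", length(phy$tip.label) + seq_len(phy$Nnode))
    c(phy$tip.label, nl)
  }
  if (is.vector(x)) x <- matrix(x, ncol = 1,
                                dimnames = list(names(x), "trait"))
  x <- as.matrix(x)
  if (ncol(x) == 1L) renormalize_to <- NA
  if (!setequal(rownames(x), phy$tip.label)) {
    stop("tip values must be named by the tree's species")
  }
  x <- x[phy$tip.label, , drop = FALSE]
  el <- phy$edge.length
  if (any(el <= 0)) {
    warning("non-positive branch lengths perturbed by 1e-8")
    el[el <= 0] <- 1e-8
  }
  n_tip <- length(phy$tip.label)
  n_node <- n_tip + phy$Nnode
  w <- 1 / el
  # weighted graph Laplacian over all nodes
  L <- matrix(0, n_node, n_node)
  for (e in seq_len(nrow(phy$edge))) {
    i <- phy$edge[e, 1]; j <- phy$edge[e, 2]
    L[i, i] <- L[i, i] + w[e]; L[j, j] <- L[j, j] + w[e]
    L[i, j] <- L[i, j] - w[e]; L[j, i] <- L[j, i] - w[e]
  }
  int <- seq(n_tip + 1L, n_node)
  Lii <- L[int, int, drop = FALSE]
  Lit <- L[int, seq_len(n_tip), drop = FALSE]
  Lii_inv <- solve(Lii)
  est <- -Lii_inv %*% Lit %*% x
  # BM rate per component from phylogenetically independent contrasts (REML)
  sig2 <- apply(x, 2, function(v) mean(ape::pic(v, phy)^2))
  vars <- outer(diag(Lii_inv), sig2)
  colnames(vars) <- paste0("var_", colnames(x))
  if (!is.na(renormalize_to)) {
    est <- est * renormalize_to / rowSums(est)
  }
  out <- data.frame(node = node_names[int], est, vars,
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}
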