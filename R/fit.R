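#' Maximum-likelihood fit of the MG94xHKY branch model
#'
#' Estimates kappa, one omega per branch category, and branch lengths
#' (expected substitutions per codon) by bounded numerical maximization of
#' the pruning likelihood. Kappa/omega are optimized jointly by quasi-Newton
#' on the log scale (start chosen from a 3-point grid: omega 0.1/0.5/1.5,
#' kappa 1/2/5); branch lengths by per-branch Brent passes with cached
#' outside partials, alternating until the log-likelihood improves by less
#' than `tol`. The fit is deterministic for fixed inputs.
#'
#' @param st A [status_tree()] (or `phylo`).
#' @param aln A [codon_alignment()].
#' @param categories Character vector, one omega-category name per tree edge
#'   (default: a single shared category `"all"`).
#' @param pi_mode Codon frequency model: `"f3x4"` (default), `"f1x4"`,
#'   `"equal"`.
#' @param fixed_omega Named numeric vector of categories whose omega is held
#'   fixed (e.g. `c(fg = 1)`).
#' @param optimize_blen Optimize branch lengths (TRUE) or hold them at
#'   `init_blen`.
#' @param init_blen Optional starting branch lengths per edge.
#' @param tol Convergence tolerance on the log-likelihood.
#' @param max_passes Maximum alternation passes.
#' @param use_grid Use the 3-point starting grid (disable for speed when a
#'   good start is supplied).
#' @return List with `params` (kappa, omega, pi, branch_lengths,
#'   categories), `loglik`, `iterations`, `converged`.
#' @export
fit_codon_model <- function(st, aln, categories = NULL,
                            pi_mode = c("f3x4", "f1x4", "equal"),
                            fixed_omega = NULL, optimize_blen = TRUE,
                            init_blen = NULL, tol = 1e-6, max_passes = 8L,
                            use_grid = TRUE) {
  phy <- if (inherits(st, "status_tree")) st$phylo else st
  pi_mode <- match.arg(pi_mode)
  n_edge <- nrow(phy$edge)
  if (is.null(categories)) categories <- rep("all", n_edge)
  stopifnot(length(categories) == n_edge)
  pi <- codon_frequencies(pi_mode, aln$sequences)
  eng <- .likelihood_engine(phy, aln)

  cats <- unique(categories)
  free_cats <- setdiff(cats, names(fixed_omega))
  omega0 <- setNames(rep(0.5, length(cats)), cats)
  if (!is.null(fixed_omega)) omega0[names(fixed_omega)] <- fixed_omega

  if (is.null(init_blen)) {
    pd <- .mean_pairwise_pdist(aln)
    tree_d <- mean(ape::cophenetic.phylo(phy)[lower.tri(diag(length(phy$tip.label)))])
    rate <- max(pd / max(tree_d, 1e-8), 1e-4)
    init_blen <- pmin(pmax(phy$edge.length * rate, 1e-4), 3)
  }
  params <- list(kappa = 2, omega = omega0, pi = pi,
                 branch_lengths = init_blen, categories = categories)

  obj_ko <- function(x, params) {
    params$kappa <- exp(x[1])
    params$omega[free_cats] <- exp(x[-1])
    -eng$loglik(params)
  }

  # starting grid on (kappa, omega) with initial branch lengths
  if (use_grid && length(free_cats) > 0) {
    grid <- expand.grid(k = c(1, 2, 5), w = c(0.1, 0.5, 1.5))
    vals <- apply(grid, 1, function(g) {
      p <- params; p$kappa <- g[["k"]]; p$omega[free_cats] <- g[["w"]]
      eng$loglik(p)
    })
    best <- which.max(vals)
    params$kappa <- grid$k[best]
    params$omega[free_cats] <- grid$w[best]
  }

  ll <- eng$loglik(params)
  passes <- 0L
  converged <- FALSE
  while (passes < max_passes) {
    passes <- passes + 1L
    ll_old <- ll
    if (length(free_cats) > 0) {
      x0 <- log(c(params$kappa, params$omega[free_cats]))
      opt <- tryCatch(
        stats::optim(x0, obj_ko, params = params, method = "L-BFGS-B",
                     lower = log(c(0.05, rep(1e-4, length(free_cats)))),
                     upper = log(c(100, rep(20, length(free_cats)))),
                     control = list(factr = 1e7, maxit = 50)),
        error = function(e) NULL)
      if (!is.null(opt)) {
        params$kappa <- exp(opt$par[1])
        params$omega[free_cats] <- exp(opt$par[-1])
        ll <- -opt$value
      }
    }
    if (optimize_blen) {
      decs <- lapply(unique(params$categories), function(cc) {
        .decompose_q(build_rate_matrix(params$kappa, params$omega[[cc]], pi),
                     pi)
      })
      names(decs) <- unique(params$categories)
      # one-shot pass: optimize every branch against the current cache
      # (Jacobi update), accept jointly if the likelihood improves,
      # otherwise fall back to branch-by-branch accepted updates
      cache <- eng$branch_cache(params)
      prop <- params
      for (e in seq_len(n_edge)) {
        op <- stats::optimize(function(t)
          eng$branch_loglik(cache, e, t, decs[[params$categories[e]]]),
          interval = c(1e-7, 5), maximum = TRUE, tol = 1e-6)
        prop$branch_lengths[e] <- op$maximum
      }
      ll_prop <- eng$loglik(prop)
      if (ll_prop >= ll) {
        params <- prop
        ll <- ll_prop
      } else {
        for (e in seq_len(n_edge)) {
          cache <- eng$branch_cache(params)
          op <- stats::optimize(function(t)
            eng$branch_loglik(cache, e, t, decs[[params$categories[e]]]),
            interval = c(1e-7, 5), maximum = TRUE, tol = 1e-6)
          if (op$objective >= ll) {
            params$branch_lengths[e] <- op$maximum
            ll <- op$objective
          }
        }
      }
    }
    if (ll - ll_old < tol) { converged <- TRUE; break }
  }
  list(params = params, loglik = ll, iterations = passes,
       converged = converged)
}

.mean_pairwise_pdist <- function(aln) {
  st <- aln$states
  n <- nrow(st)
  if (n < 2L) return(0.1)
  tot <- 0; cnt <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      ok <- !is.na(st[i, ]) & !is.na(st[j, ])
      if (any(ok)) { tot <- tot + mean(st[i, ok] != st[j, ok]); cnt <- cnt + 1 }
    }
  }
  if (cnt == 0) 0.1 else tot / cnt
}

#' Likelihood-ratio test for relaxed selection on foreground branches
#'
#' Null: one omega shared by all branches. Alternative: a separate omega on
#' the foreground branches. The statistic 2 (lnL1 - lnL0) is referred to a
#' chi-squared distribution with 1 df (optionally the 50:50 boundary
#' mixture). An auxiliary test of foreground omega fixed at 1 versus free is
#' also reported.
#'
#' @param st A [status_tree()] or `phylo`.
#' @param aln A [codon_alignment()].
#' @param foreground Edge indices, or child-node branch names, of the
#'   foreground branches (non-empty proper subset).
#' @param pi_mode Codon frequency model.
#' @param boundary_mix Use the 50:50 chi2_0/chi2_1 mixture p-value
#'   (default FALSE).
#' @param aux Also run the auxiliary foreground-omega-fixed-at-1 fit
#'   (default TRUE; disable to save one fit when only the relaxation test
#'   is needed).
#' @return An `lrt_result`: log-likelihoods, statistic, df, p-value, fits,
#'   and the auxiliary omega=1 test.
#' @export
lrt_relaxation <- function(st, aln, foreground,
                           pi_mode = c("f3x4", "f1x4", "equal"),
                           boundary_mix = FALSE, aux = TRUE) {
  phy <- if (inherits(st, "status_tree")) st$phylo else st
  pi_mode <- match.arg(pi_mode)
  n_edge <- nrow(phy$edge)
  fg <- .resolve_edges(st, foreground)
  if (length(fg) == 0L) stop("foreground must be non-empty")
  if (length(fg) >= n_edge) stop("foreground must be a proper subset of branches")
  cats_alt <- ifelse(seq_len(n_edge) %in% fg, "foreground", "background")

  fit0 <- fit_codon_model(st, aln, categories = rep("all", n_edge),
                          pi_mode = pi_mode)
  fit1 <- fit_codon_model(st, aln, categories = cats_alt, pi_mode = pi_mode,
                          init_blen = fit0$params$branch_lengths,
                          use_grid = FALSE)
  stat <- 2 * (fit1$loglik - fit0$loglik)
  if (stat < 0 && stat > -1e-6) stat <- 0
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  if (boundary_mix) p <- 0.5 * p

  # auxiliary: foreground omega fixed at 1 vs free
  aux_res <- NULL
  if (aux) {
    fit_w1 <- fit_codon_model(st, aln, categories = cats_alt,
                              pi_mode = pi_mode,
                              fixed_omega = c(foreground = 1),
                              init_blen = fit1$params$branch_lengths,
                              use_grid = FALSE)
    stat1 <- 2 * (fit1$loglik - fit_w1$loglik)
    if (stat1 < 0 && stat1 > -1e-6) stat1 <- 0
    aux_res <- list(loglik = fit_w1$loglik, statistic = stat1,
                    p_value = stats::pchisq(stat1, 1, lower.tail = FALSE))
  }
  structure(list(
    loglik_null = fit0$loglik, loglik_alt = fit1$loglik,
    statistic = stat, df = 1L,
    p_value = p,
    omega_shared = unname(fit0$params$omega["all"]),
    omega_foreground = unname(fit1$params$omega["foreground"]),
    omega_background = unname(fit1$params$omega["background"]),
    aux_omega1 = aux_res,
    fits = list(null = fit0, alt = fit1)
  ), class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("<lrt_result> 2*dlnL = %.4f (df = %d), p = %.4g\n",
              x$statistic, x$df, x$p_value))
  cat(sprintf("  omega: shared %.3f | foreground %.3f vs background %.3f\n",
              x$omega_shared, x$omega_foreground, x$omega_background))
  invisible(x)
}

.resolve_edges <- function(st, branches) {
  phy <- if (inherits(st, "status_tree")) st$phylo else st
  if (is.numeric(branches)) return(as.integer(branches))
  if (!inherits(st, "status_tree")) stop("branch names require a status_tree")
  nodes <- match(branches, st$node_names)
  if (anyNA(nodes)) stop("unknown branch: ",
                         paste(branches[is.na(nodes)], collapse = ", "))
  match(nodes, phy$edge[, 2])
}

#' Branch-category omega estimates feeding the dating step
#'
#' Pools all functional branches into one omega category, all fully
#' pseudogenic branches into another, and gives each mixed branch its own
#' omega. Also derives per-branch synonymous rates and the 2ds synonymous
#' rate ratio r (pseudogenic vs functional dS per MY; 1 when no fully
#' pseudogenic branch exists).
#'
#' @param st A labeled [status_tree()] (see [label_branches()]).
#' @param aln A [codon_alignment()].
#' @param pi_mode Codon frequency model.
#' @return List: `omega_f`, `omega_m` (named by mixed branch), `r_hat`,
#'   `table` (per-branch category, omega, t, dS, dS per MY), `fit`.
#' @export
branch_omegas_for_dating <- function(st, aln,
                                     pi_mode = c("f3x4", "f1x4", "equal")) {
  stopifnot(inherits(st, "status_tree"))
  pi_mode <- match.arg(pi_mode)
  bt <- branch_table(st)
  if (!any(bt$label == "functional")) stop("no functional branches to pool")
  categories <- bt$label
  mixed_idx <- which(bt$label == "mixed")
  categories[mixed_idx] <- paste0("mixed:", bt$branch[mixed_idx])
  fit <- fit_codon_model(st, aln, categories = categories, pi_mode = pi_mode)

  pi <- fit$params$pi
  rho_s <- vapply(unique(categories), function(cc) {
    .syn_fraction(build_rate_matrix(fit$params$kappa, fit$params$omega[[cc]],
                                    pi), pi)
  }, numeric(1))
  tab <- data.frame(
    branch = bt$branch, label = bt$label, category = categories,
    T_my = bt$T, child_age = bt$child_age,
    omega = unname(fit$params$omega[categories]),
    t = fit$params$branch_lengths,
    dS = fit$params$branch_lengths * rho_s[categories],
    stringsAsFactors = FALSE)
  tab$dS_per_my <- ifelse(tab$T_my > 0, tab$dS / tab$T_my, NA)

  f <- tab$label == "functional" & tab$T_my > 0
  p <- tab$label == "pseudogenic" & tab$T_my > 0
  r_hat <- if (any(p)) mean(tab$dS_per_my[p]) / mean(tab$dS_per_my[f]) else 1
  omega_m <- setNames(tab$omega[mixed_idx], tab$branch[mixed_idx])
  list(omega_f = unname(fit$params$omega["functional"]),
       omega_m = omega_m, r_hat = r_hat, table = tab, fit = fit)
}
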