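#' Mixed-branch observation for inactivation dating
#'
#' Bundles the quantities needed to date a gene inactivation on a mixed
#' branch: the branch duration `T` (MY), the pooled functional dN/dS
#' `omega_f`, the mixed-branch dN/dS `omega_m`, the synonymous-rate ratio
#' `r` (pseudogenic vs functional portion; 1 under the 1ds model), and the
#' age of the branch's child node. `omega_m` outside [omega_f, 1] is clamped
#' into the interval and flagged.
#'
#' @param T Branch duration in MY (> 0).
#' @param omega_f Functional dN/dS (0 <= omega_f < 1).
#' @param omega_m Mixed-branch dN/dS.
#' @param r Synonymous-rate ratio s_p / s_f (> 0).
#' @param child_age Age of the child node in MY.
#' @return A `mixed_branch_obs` list with a `clamped` flag.
#' @export
mixed_branch_obs <- function(T, omega_f, omega_m, r = 1, child_age = 0) {
  stopifnot(T > 0, r > 0)
  if (omega_f >= 1) {
    stop("omega_f >= 1: functional class not under purifying selection; ",
         "dating undefined")
  }
  if (omega_f < 0) stop("omega_f must be non-negative")
  clamped <- FALSE
  if (omega_m > 1) { omega_m <- 1; clamped <- TRUE }
  if (omega_m < omega_f) { omega_m <- omega_f; clamped <- TRUE }
  structure(list(T = T, omega_f = omega_f, omega_m = omega_m, r = r,
                 child_age = child_age, clamped = clamped),
            class = "mixed_branch_obs")
}

#' Duration of the pseudogenic portion of a mixed branch
#'
#' Under the mixture premise the pseudogenic portion evolves neutrally
#' (omega = 1) while the functional portion evolves at omega_f, with
#' synonymous substitutions accruing at portion-specific rates s_f and
#' s_p = r s_f. Solving
#' omega_m (s_f t_f + s_p t_p) = omega_f s_f t_f + s_p t_p with
#' t_f = T - t_p gives
#' t_p = T (omega_m - omega_f) / (r (1 - omega_m) + (omega_m - omega_f)).
#' With r = 1 (the 1ds model) this reduces to
#' t_p = T (omega_m - omega_f) / (1 - omega_f).
#'
#' @param obs A [mixed_branch_obs()].
#' @return Named vector with `t_p_1ds` and `t_p_2ds` (equal when r = 1),
#'   each in [0, T].
#' @export
pseudogenic_time <- function(obs) {
  stopifnot(inherits(obs, "mixed_branch_obs"))
  tp <- function(r) {
    num <- obs$omega_m - obs$omega_f
    den <- r * (1 - obs$omega_m) + num
    if (den <= 0) return(obs$T)  # omega_m = 1: fully neutral branch
    min(max(obs$T * num / den, 0), obs$T)
  }
  c(t_p_1ds = tp(1), t_p_2ds = tp(obs$r))
}

#' Inactivation age from a pseudogenic duration
#'
#' The pseudogenic portion is the most recent part of the mixed branch, so
#' the inactivation point sits `t_p` MY above the child node.
#'
#' @param obs A [mixed_branch_obs()].
#' @param t_p Pseudogenic duration(s), in [0, T].
#' @return Inactivation age(s) in MYA: `child_age + t_p`.
#' @export
inactivation_age <- function(obs, t_p) {
  stopifnot(all(t_p >= -1e-12 & t_p <= obs$T + 1e-9))
  obs$child_age + t_p
}

#' Date all loss events on a labeled tree
#'
#' Applies the 1ds and 2ds mixed-branch decompositions to every mixed branch
#' using the branch-category omega estimates (see
#' [branch_omegas_for_dating()]). The reported range is the min/max over the
#' two models. Mixed branches lacking an omega estimate are reported
#' `undatable`.
#'
#' @param st A labeled [status_tree()].
#' @param omegas Output of [branch_omegas_for_dating()], or a list with
#'   `omega_f`, `omega_m` (named by mixed branch) and optionally `r_hat`.
#' @param r Override for the synonymous-rate ratio (default: `omegas$r_hat`,
#'   falling back to 1).
#' @return data.frame: one row per mixed branch with `t_p` per model,
#'   inactivation age per model (MYA), the age range, clamp flags and
#'   status.
#' @export
date_all <- function(st, omegas, r = NULL) {
  stopifnot(inherits(st, "status_tree"))
  bt <- branch_table(st)
  mixed <- bt[bt$label == "mixed", , drop = FALSE]
  if (is.null(r)) r <- if (!is.null(omegas$r_hat)) omegas$r_hat else 1
  rows <- lapply(seq_len(nrow(mixed)), function(i) {
    br <- mixed$branch[i]
    om <- omegas$omega_m[br]
    base <- data.frame(branch = br, T_my = mixed$T[i],
                       child_age = mixed$child_age[i],
                       omega_f = omegas$omega_f, omega_m = NA_real_,
                       r = r, t_p_1ds = NA_real_, t_p_2ds = NA_real_,
                       age_1ds = NA_real_, age_2ds = NA_real_,
                       age_min = NA_real_, age_max = NA_real_,
                       clamped = NA, status = "undatable",
                       stringsAsFactors = FALSE)
    if (is.na(om)) return(base)
    obs <- mixed_branch_obs(mixed$T[i], omegas$omega_f, unname(om), r = r,
                            child_age = mixed$child_age[i])
    tp <- pseudogenic_time(obs)
    ages <- inactivation_age(obs, tp)
    base$omega_m <- obs$omega_m
    base$t_p_1ds <- tp[["t_p_1ds"]]; base$t_p_2ds <- tp[["t_p_2ds"]]
    base$age_1ds <- ages[[1]]; base$age_2ds <- ages[[2]]
    base$age_min <- min(ages); base$age_max <- max(ages)
    base$clamped <- obs$clamped
    base$status <- "dated"
    base
  })
  if (length(rows) == 0L) {
    return(data.frame(branch = character(0), T_my = numeric(0),
                      child_age = numeric(0), omega_f = numeric(0),
                      omega_m = numeric(0), r = numeric(0),
                      t_p_1ds = numeric(0), t_p_2ds = numeric(0),
                      age_1ds = numeric(0), age_2ds = numeric(0),
                      age_min = numeric(0), age_max = numeric(0),
                      clamped = logical(0), status = character(0)))
  }
  do.call(rbind, rows)
}

#' Site-bootstrap confidence intervals for inactivation ages
#'
#' Resamples codon columns with replacement, refits the branch-category
#' omegas on each replicate and re-dates every mixed branch. Reported
#' quantiles are over the replicate 1ds ages.
#'
#' @param st A labeled [status_tree()].
#' @param aln A [codon_alignment()].
#' @param n_boot Number of bootstrap replicates.
#' @param seed RNG seed.
#' @param pi_mode Codon frequency model.
#' @param probs Quantile probabilities to report.
#' @return data.frame: branch, point estimate, and one column per quantile.
#' @export
bootstrap_dating <- function(st, aln, n_boot = 100L, seed = 1L,
                             pi_mode = c("f3x4", "f1x4", "equal"),
                             probs = c(0.025, 0.5, 0.975)) {
  pi_mode <- match.arg(pi_mode)
  om0 <- branch_omegas_for_dating(st, aln, pi_mode = pi_mode)
  d0 <- date_all(st, om0)
  set.seed(seed)
  ages <- replicate(n_boot, {
    idx <- sample.int(aln$n_sites, replace = TRUE)
    starts <- 3L * (idx - 1L) + 1L
    seqs <- vapply(aln$taxa, function(tx) {
      paste0(substring(aln$sequences[[tx]], starts, starts + 2L),
             collapse = "")
    }, character(1))
    bal <- codon_alignment(seqs, pseudogenic = aln$taxa)
    om <- tryCatch(branch_omegas_for_dating(st, bal, pi_mode = pi_mode),
                   error = function(e) NULL)
    if (is.null(om)) return(rep(NA_real_, nrow(d0)))
    date_all(st, om)$age_1ds
  })
  ages <- matrix(ages, nrow = nrow(d0))
  q <- t(apply(ages, 1, stats::quantile, probs = probs, na.rm = TRUE))
  out <- data.frame(branch = d0$branch, age_1ds = d0$age_1ds, q,
                    check.names = FALSE)
  rownames(out) <- NULL
  out
}
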