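# Branch-site Model A fitting ------------------------------------------------
#
# The positive-selection test for a designated foreground branch: sites fall
# into four classes (0: purifying omega0 everywhere; 1: neutral everywhere;
# 2a/2b: purifying/neutral on background branches but omega2 >= 1 on the
# foreground). The null model fixes omega2 = 1; twice the log-likelihood
# difference is referred to chi-square df = 1.
#
# Numerical strategy: branch lengths are rescaled once under a single-ratio
# (M0) fit and then fixed, kappa is taken from M0, and the class proportions
# are profiled out by EM (the Model A mixture factorizes into independent
# binary factors), leaving a 1-2 parameter outer optimization over the omegas.

em_weights <- function(f_hk, counts, q0 = 0.8, r0 = 0.9, max_iter = 200L, tol = 1e-9) {
  mx <- apply(f_hk, 1L, max)
  F <- exp(f_hk - mx) # npat x 4, scaled
  n <- sum(counts)
  q <- q0
  r <- r0
  lnl_old <- -Inf
  for (it in seq_len(max_iter)) {
    w <- c(r * q, r * (1 - q), (1 - r) * q, (1 - r) * (1 - q))
    L <- as.numeric(F %*% w)
    L[L <= 0] <- 1e-300
    lnl <- sum(counts * (log(L) + mx))
    resp <- F * rep(w, each = nrow(F)) / L
    q <- sum(counts * (resp[, 1L] + resp[, 3L])) / n
    r <- sum(counts * (resp[, 1L] + resp[, 2L])) / n
    q <- min(max(q, 1e-8), 1 - 1e-8)
    r <- min(max(r, 1e-8), 1 - 1e-8)
    if (lnl - lnl_old < tol && it > 3L) break
    lnl_old <- lnl
  }
  p0 <- r * q
  p1 <- r * (1 - q)
  list(lnl = lnl, q = q, r = r, weights = model_a_weights(p0, p1), p0 = p0, p1 = p1)
}

# Profile log-likelihood over (omega0, omega2): class likelihoods via pruning,
# proportions via EM. `scale_weights` fixes the mixture-scaling weights so the
# class likelihood matrix is weight-independent within one round.
bs_profile_lnl <- function(omega0, omega2, kappa, states, eng, freqs, code, counts,
                           scale_weights, start = list(q = 0.8, r = 0.9)) {
  pi <- as.numeric(freqs[as_code(code)$sense_codons])
  Qs <- bs_scaled_generators(kappa, omega0, omega2, freqs, code, scale_weights)
  f_hk <- cpp_bs_class_loglik(states, eng$edge, eng$elen, eng$fg, Qs, pi)
  em <- em_weights(f_hk, counts, q0 = start$q, r0 = start$r)
  em$f_hk <- f_hk
  em
}

#' Single-ratio (M0) codon model fit
#'
#' Fits the GY94 model with one omega shared by all sites and branches,
#' optimizing kappa, omega and a proportional rescaling of the input tree's
#' branch lengths. Used to fix branch lengths (and kappa) before the
#' branch-site fits, mirroring the usual two-step workflow.
#'
#' @param aln Named character vector of in-frame aligned CDSs.
#' @param tree `ape::phylo` with (relative) branch lengths.
#' @param code A [genetic_code()].
#' @param freqs Codon frequencies; default F3x4 from the alignment.
#' @return List with `kappa`, `omega`, `tree_scale`, `lnL`, and `tree` (the
#'   rescaled tree).
#' @export
fit_m0 <- function(aln, tree, code = genetic_code(), freqs = NULL) {
  code <- as_code(code)
  pat <- codon_patterns(aln, code)
  eng <- tree_engine_data(tree)
  states <- match_tree_alignment(pat, eng)
  if (is.null(freqs)) freqs <- f3x4_frequencies(aln, code)
  pi <- as.numeric(freqs[code$sense_codons])
  obj <- function(par) {
    kappa <- exp(par[1L])
    omega <- exp(par[2L])
    s <- exp(par[3L])
    Q <- gy94_matrix(kappa, omega, freqs, code, scale = "unit")
    lnl <- sum(pat$counts * cpp_site_loglik(
      states, eng$edge, eng$elen * s, eng$fg, list(Q), pi, 0L, 0L
    ))
    -lnl
  }
  fit <- stats::optim(
    c(log(2), log(0.2), 0), obj,
    method = "L-BFGS-B",
    lower = c(log(0.1), log(1e-4), log(1e-3)),
    upper = c(log(50), log(10), log(1e3)),
    control = list(factr = 1e9, maxit = 60L)
  )
  tree_scaled <- tree
  tree_scaled$edge.length <- tree$edge.length * exp(fit$par[3L])
  list(
    kappa = exp(fit$par[1L]), omega = exp(fit$par[2L]),
    tree_scale = exp(fit$par[3L]), lnL = -fit$value, tree = tree_scaled
  )
}

OMEGA2_MAX <- 999

fit_bs_model <- function(null, kappa, states, eng, freqs, code, counts,
                         omega0_start = 0.2, omega2_starts = c(1.5, 5, 50, OMEGA2_MAX / 2),
                         warm = NULL, scale_rounds = 2L) {
  scale_weights <- model_a_weights(0.7, 0.2)
  start_qr <- list(q = 0.8, r = 0.9)
  run_round <- function(sw, o0_init, o2_init, qr) {
    if (null) {
      opt <- stats::optimize(function(x) {
        -bs_profile_lnl(stats::plogis(x), 1, kappa, states, eng, freqs, code, counts, sw, qr)$lnl
      }, interval = c(stats::qlogis(1e-4), stats::qlogis(0.999)), tol = 1e-4)
      o0 <- stats::plogis(opt$minimum)
      em <- bs_profile_lnl(o0, 1, kappa, states, eng, freqs, code, counts, sw, qr)
      list(omega0 = o0, omega2 = 1, em = em)
    } else {
      obj <- function(par) {
        o0 <- stats::plogis(par[1L])
        o2 <- 1 + exp(par[2L])
        -bs_profile_lnl(o0, o2, kappa, states, eng, freqs, code, counts, sw, qr)$lnl
      }
      p0 <- c(stats::qlogis(min(max(o0_init, 1e-4), 0.999)), log(max(o2_init - 1, 1e-6)))
      fit <- stats::optim(p0, obj,
        method = "L-BFGS-B",
        lower = c(stats::qlogis(1e-4), log(1e-6)),
        upper = c(stats::qlogis(0.999), log(OMEGA2_MAX - 1)),
        control = list(factr = 1e9, maxit = 40L)
      )
      o0 <- stats::plogis(fit$par[1L])
      o2 <- 1 + exp(fit$par[2L])
      em <- bs_profile_lnl(o0, o2, kappa, states, eng, freqs, code, counts, sw, qr)
      list(omega0 = o0, omega2 = o2, em = em)
    }
  }
  # choose the most promising omega2 start by a single profile evaluation
  if (!null) {
    cand <- vapply(omega2_starts, function(o2) {
      bs_profile_lnl(omega0_start, o2, kappa, states, eng, freqs, code, counts,
        scale_weights, start_qr
      )$lnl
    }, numeric(1))
    best_o2 <- omega2_starts[which.max(cand)]
    starts <- list(c(omega0_start, best_o2))
    if (!is.null(warm)) starts <- c(starts, list(c(warm$omega0, max(1 + 1e-5, warm$omega2))))
  } else {
    starts <- list(c(omega0_start, 1))
  }
  best <- NULL
  for (st in starts) {
    res <- NULL
    sw <- scale_weights
    qr <- start_qr
    o0 <- st[1L]
    o2 <- st[2L]
    for (round in seq_len(scale_rounds)) {
      res <- run_round(sw, o0, o2, qr)
      sw <- res$em$weights
      qr <- list(q = res$em$q, r = res$em$r)
      o0 <- res$omega0
      o2 <- res$omega2
    }
    if (is.null(best) || res$em$lnl > best$em$lnl) best <- res
  }
  best
}

#' Branch-site positive-selection test (Model A)
#'
#' Fits the branch-site Model A alternative and its null (foreground omega2
#' fixed at 1) to a codon alignment with one or more designated foreground
#' branches, and computes the likelihood ratio statistic 2*deltaL. Branch
#' lengths are proportionally rescaled under a preliminary M0 fit and then
#' held fixed, as is kappa; site-class proportions are profiled out by EM and
#' the alternative fit is warm-started from the null optimum in addition to a
#' deterministic grid of omega2 starts (the likelihood surface is multimodal
#' in omega2). omega2 is capped at 999.
#'
#' @param aln Named character vector of in-frame aligned CDSs (taxa matching
#'   the tree's tip labels). Gapped/ambiguous codons are treated as missing.
#' @param tree `ape::phylo` with branch lengths in expected substitutions per
#'   codon (relative lengths suffice; the scale is re-fit).
#' @param foreground Foreground specification: integer edge indices into
#'   `tree$edge`, or a character vector of taxa whose stem branch (MRCA
#'   branch) is the foreground.
#' @param code A [genetic_code()].
#' @param freqs Codon equilibrium frequencies; default F3x4.
#' @param scale_rounds Rounds of alternation between optimization and
#'   refreshing the mixture-scaling weights.
#' @return Object of class `branch_site_fit`; see [tidy.branch_site_fit()],
#'   [glance.branch_site_fit()], [lrt()] and [beb()].
#' @export
fit_branch_site <- function(aln, tree, foreground, code = genetic_code(),
                            freqs = NULL, scale_rounds = 2L) {
  code <- as_code(code)
  if (is.character(foreground)) foreground <- foreground_stem(tree, foreground)
  if (length(foreground) < 1L) stop("at least one foreground branch is required", call. = FALSE)
  m0 <- fit_m0(aln, tree, code, freqs)
  tree <- m0$tree
  pat <- codon_patterns(aln, code)
  eng <- tree_engine_data(tree, foreground)
  states <- match_tree_alignment(pat, eng)
  if (is.null(freqs)) freqs <- f3x4_frequencies(aln, code)

  null_fit <- fit_bs_model(TRUE, m0$kappa, states, eng, freqs, code, pat$counts,
    omega0_start = min(m0$omega, 0.9), scale_rounds = scale_rounds
  )
  alt_fit <- fit_bs_model(FALSE, m0$kappa, states, eng, freqs, code, pat$counts,
    omega0_start = null_fit$omega0,
    warm = list(omega0 = null_fit$omega0, omega2 = 1),
    scale_rounds = scale_rounds
  )
  two_dl <- max(0, 2 * (alt_fit$em$lnl - null_fit$em$lnl))
  fit <- structure(
    list(
      kappa = m0$kappa,
      m0 = m0[c("kappa", "omega", "tree_scale", "lnL")],
      tree = tree,
      foreground = foreground,
      null = list(
        lnL = null_fit$em$lnl, omega0 = null_fit$omega0, omega2 = 1,
        proportions = null_fit$em$weights, p0 = null_fit$em$p0, p1 = null_fit$em$p1
      ),
      alt = list(
        lnL = alt_fit$em$lnl, omega0 = alt_fit$omega0, omega2 = alt_fit$omega2,
        proportions = alt_fit$em$weights, p0 = alt_fit$em$p0, p1 = alt_fit$em$p1
      ),
      twoDeltaL = two_dl,
      nsites = pat$nsites,
      engine = list(
        states = states, eng = eng, freqs = freqs, code = code,
        counts = pat$counts, site2pat = pat$site2pat, aln = aln
      )
    ),
    class = "branch_site_fit"
  )
  fit$p_value <- lrt(fit)
  fit
}

#' @export
print.branch_site_fit <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<branch_site_fit> %d sites, kappa = %.3f\n",
      "  null: lnL = %.4f (omega0 = %.4f)\n",
      "  alt:  lnL = %.4f (omega0 = %.4f, omega2 = %.4f)\n",
      "  2*deltaL = %.4f, p = %.4g\n"
    ),
    x$nsites, x$kappa, x$null$lnL, x$null$omega0,
    x$alt$lnL, x$alt$omega0, x$alt$omega2, x$twoDeltaL, x$p_value
  ))
  invisible(x)
}

#' Likelihood ratio test for a branch-site fit
#'
#' p-value of 2*deltaL under its reference distribution: chi-square with one
#' degree of freedom (default; conservative for this boundary test) or the
#' 50:50 mixture of a point mass at zero and chi-square df 1.
#'
#' @param fit A [fit_branch_site()] object, or a numeric 2*deltaL value.
#' @param reference `"chisq1"` (default) or `"mixture"`.
#' @return p-value.
#' @export
lrt <- function(fit, reference = c("chisq1", "mixture")) {
  reference <- match.arg(reference)
  stat <- if (inherits(fit, "branch_site_fit")) fit$twoDeltaL else fit
  if (is.null(stat) || is.na(stat)) stop("missing 2*deltaL; fit both models first", call. = FALSE)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  if (reference == "mixture") p <- if (stat == 0) 1 else p / 2
  p
}

#' Bayes empirical Bayes site identification
#'
#' Posterior probability per codon site of belonging to the positively
#' selected classes (2a + 2b), averaging over a uniform grid of
#' (p0, p1, omega0, omega2) weighted by the whole-alignment likelihood, with
#' the remaining parameters (kappa, branch lengths, scaling) fixed at their
#' estimates. Sites with posterior > 0.95 are starred `*`, > 0.99 `**`.
#'
#' @param fit A [fit_branch_site()] object.
#' @param grid_size Grid points per parameter dimension (default 10).
#' @return Tibble: `site`, `ref_aa` (amino acid in the first sequence),
#'   `pp` (posterior of positive selection), `stars`.
#' @export
beb <- function(fit, grid_size = 10L) {
  stopifnot(inherits(fit, "branch_site_fit"))
  en <- fit$engine
  code <- en$code
  pi <- as.numeric(en$freqs[code$sense_codons])
  g <- (seq_len(grid_size) - 0.5) / grid_size
  omega0_grid <- g
  omega2_grid <- 1 + 10 * g
  # proportion grid: p0 and p1' = p1/(1-p0), both uniform on (0,1)
  props <- expand.grid(p0g = g, p1g = g)
  W <- t(apply(props, 1L, function(x) model_a_weights(x[1L], (1 - x[1L]) * x[2L])))
  scale_weights <- fit$alt$proportions
  counts <- en$counts
  npat <- length(counts)
  num <- numeric(npat) # posterior-weighted P(class 2a/2b | site)
  log_marg <- c() # log alignment likelihood per grid point (for normalization)
  resp_list <- list()
  k <- 0L
  for (o0 in omega0_grid) {
    for (o2 in omega2_grid) {
      Qs <- bs_scaled_generators(fit$kappa, o0, o2, en$freqs, code, scale_weights)
      f_hk <- cpp_bs_class_loglik(en$states, en$eng$edge, en$eng$elen, en$eng$fg, Qs, pi)
      mx <- apply(f_hk, 1L, max)
      F <- exp(f_hk - mx)
      L <- F %*% t(W) # npat x nprop
      L[L <= 0] <- 1e-300
      tot <- as.numeric(counts %*% log(L)) + sum(counts * mx)
      sel <- (F[, 3L] %o% W[, 3L] + F[, 4L] %o% W[, 4L]) / L
      k <- k + 1L
      log_marg <- c(log_marg, tot)
      resp_list[[k]] <- sel
    }
  }
  log_marg_all <- unlist(log_marg)
  wts <- exp(log_marg_all - max(log_marg_all))
  wts <- wts / sum(wts)
  idx <- 0L
  nprop <- nrow(W)
  for (k2 in seq_along(resp_list)) {
    w_here <- wts[(idx + 1L):(idx + nprop)]
    num <- num + as.numeric(resp_list[[k2]] %*% w_here)
    idx <- idx + nprop
  }
  pp_site <- num[en$site2pat]
  ref <- en$aln[[1L]]
  ref_aa <- {
    cod <- split_codons(ref, partial = FALSE)
    aa <- code$aa[cod]
    aa[is.na(aa)] <- "X"
    unname(aa)
  }
  tibble::tibble(
    site = seq_along(pp_site),
    ref_aa = ref_aa,
    pp = pp_site,
    stars = dplyr::case_when(pp_site > 0.99 ~ "**", pp_site > 0.95 ~ "*", TRUE ~ "")
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a branch-site fit into a parameter table
#'
#' @param x A [fit_branch_site()] object.
#' @param ... Unused.
#' @return Tibble with one row per (model, term).
#' @export
tidy.branch_site_fit <- function(x, ...) {
  one <- function(model, m) {
    tibble::tibble(
      model = model,
      term = c("kappa", "omega0", "omega2", "p0", "p1", "p2a", "p2b"),
      estimate = c(x$kappa, m$omega0, m$omega2, m$proportions)
    )
  }
  dplyr::bind_rows(one("null", x$null), one("alternative", x$alt))
}

#' One-row summary of a branch-site fit
#'
#' @param x A [fit_branch_site()] object.
#' @param ... Unused.
#' @return One-row tibble: `lnL_null`, `lnL_alt`, `twoDeltaL`, `p_value`,
#'   `omega2`, `n_sites`.
#' @export
glance.branch_site_fit <- function(x, ...) {
  tibble::tibble(
    lnL_null = x$null$lnL, lnL_alt = x$alt$lnL,
    twoDeltaL = x$twoDeltaL, p_value = x$p_value,
    omega2 = x$alt$omega2, n_sites = x$nsites
  )
}
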