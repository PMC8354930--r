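# MAP inversion of the neural coupling parameters under Gaussian shrinkage
# priors, with a Laplace approximation to the log model evidence. The
# haemodynamic constants are fixed (see default_hemo_params), which keeps
# the inverse problem identifiable at desk scale.

#' Prior specification for DCM inversion
#'
#' Zero-mean Gaussian shrinkage priors on the free parameters: intrinsic
#' off-diagonal couplings (sd `sd_a`), small deviations of the
#' self-connections around the -0.5 1/s baseline (sd `sd_a_self`),
#' modulatory weights (sd `sd_b`) and the driving-input weight (sd `sd_c`).
#'
#' @param sd_a,sd_a_self,sd_b,sd_c Prior standard deviations.
#' @return A `dcm_priors` list.
#' @export
dcm_priors <- function(sd_a = 0.5, sd_a_self = 0.05, sd_b = 1, sd_c = 1) {
  structure(list(sd_a = sd_a, sd_a_self = sd_a_self, sd_b = sd_b,
                 sd_c = sd_c, a_self_baseline = -0.5), class = "dcm_priors")
}

# Free-parameter layout for a model. Each row of the template maps one
# theta entry to a slot of A (off-diagonal or self-deviation), B or C.
param_template <- function(model, priors, free_a = TRUE, free_self = TRUE,
                           free_c = TRUE) {
  kind <- character(0); idx <- integer(0); sd <- numeric(0)
  if (free_a) {
    off <- which(!diag(TRUE, 3))
    kind <- c(kind, rep("a_off", 6)); idx <- c(idx, off)
    sd <- c(sd, rep(priors$sd_a, 6))
  }
  if (free_self) {
    kind <- c(kind, rep("a_self", 3)); idx <- c(idx, 1:3)
    sd <- c(sd, rep(priors$sd_a_self, 3))
  }
  nb <- sum(model$b_support)
  if (nb > 0) {
    kind <- c(kind, rep("b", nb)); idx <- c(idx, which(model$b_support))
    sd <- c(sd, rep(priors$sd_b, nb))
  }
  if (free_c) {
    kind <- c(kind, "c"); idx <- c(idx, 1L)
    sd <- c(sd, priors$sd_c)
  }
  list(kind = kind, idx = idx, prior_sd = sd, n = length(kind))
}

slot_of <- function(tmpl, kind, idx) which(tmpl$kind == kind & tmpl$idx == idx)

unpack_params <- function(theta, model, priors, tmpl) {
  A <- matrix(0, 3, 3)
  diag(A) <- priors$a_self_baseline
  B <- matrix(0, 3, 3)
  C <- c(0, 0, 0)
  for (k in seq_len(tmpl$n)) {
    switch(tmpl$kind[k],
      a_off = { A[tmpl$idx[k]] <- theta[k] },
      a_self = { A[tmpl$idx[k], tmpl$idx[k]] <- A[tmpl$idx[k], tmpl$idx[k]] + theta[k] },
      b = { B[tmpl$idx[k]] <- theta[k] },
      c = { C[tmpl$idx[k]] <- theta[k] }
    )
  }
  dimnames(A) <- dimnames(B) <- list(dcm_nodes(), dcm_nodes())
  list(A = A, B = B, C = C)
}

# Forward prediction for a parameter vector; NULL if the implied system is
# unstable at rest or the integration blows up.
dcm_predict <- function(theta, model, u, priors, hemo, tmpl) {
  p <- unpack_params(theta, model, priors, tmpl)
  if (max(Re(eigen(p$A, only.values = TRUE)$values)) >= -1e-6) return(NULL)
  keep <- as.integer(round(u$tr / u$dt))
  o <- dcm_integrate_cpp(p$A, p$B, p$C, u$u_task, u$u_drive, u$dt, keep,
                         as.numeric(hemo), FALSE)
  if (o$blowup) NULL else o$bold
}

# Negative log joint: Gaussian likelihood with per-node noise variance
# concentrated out, plus the Gaussian prior. Used to compare optima and as
# the height term of the Laplace evidence.
dcm_neg_log_joint <- function(theta, y, model, u, priors, hemo, tmpl,
                              rss_floor = 1e-12) {
  prior_term <- if (tmpl$n > 0) {
    0.5 * sum((theta / tmpl$prior_sd)^2) +
      0.5 * sum(log(2 * pi * tmpl$prior_sd^2))
  } else 0
  pred <- dcm_predict(theta, model, u, priors, hemo, tmpl)
  if (is.null(pred)) return(1e10 + prior_term)
  n <- nrow(y)
  rss <- colSums((y - pred)^2) + rss_floor
  -(-sum((n / 2) * (log(2 * pi * rss / n) + 1))) + prior_term
}

# BOLD impulse response of the haemodynamic subsystem (response to a unit
# neural delta), integrated by RK4 on the fine grid and sampled at TR.
# Used only to initialise the inversion by deconvolution.
hemo_impulse_kernel <- function(tr, dt, hemo = default_hemo_params(),
                                duration = 32) {
  kappa <- hemo[["kappa"]]; gam <- hemo[["gamma"]]; tau <- hemo[["tau"]]
  alpha <- hemo[["alpha"]]; rho <- hemo[["rho"]]; V0 <- hemo[["V0"]]
  k1 <- 7 * rho; k2 <- 2; k3 <- 2 * rho - 0.2
  n_steps <- round(duration / dt)
  state <- c(0, 1, 1, 1)  # s, f, v, q
  dstate <- function(st, z) {
    fv <- st[3]^(1 / alpha)
    Ef <- 1 - (1 - rho)^(1 / st[2])
    c(z - kappa * st[1] - gam * (st[2] - 1),
      st[1],
      (st[2] - fv) / tau,
      (st[2] * Ef / rho - fv * st[4] / st[3]) / tau)
  }
  out <- numeric(n_steps)
  for (step in seq_len(n_steps)) {
    z <- if (step == 1) 1 / dt else 0
    k1v <- dstate(state, z)
    k2v <- dstate(state + 0.5 * dt * k1v, z)
    k3v <- dstate(state + 0.5 * dt * k2v, z)
    k4v <- dstate(state + dt * k3v, z)
    state <- state + dt / 6 * (k1v + 2 * k2v + 2 * k3v + k4v)
    out[step] <- V0 * (k1 * (1 - state[4]) + k2 * (1 - state[4] / state[3]) +
                       k3 * (1 - state[3]))
  }
  out[round(seq(1, n_steps, by = tr / dt))]
}

# Average the fine-grid inputs within each TR.
tr_grid_inputs <- function(u) {
  per <- round(u$tr / u$dt)
  list(task = colMeans(matrix(u$u_task, per)),
       drive = colMeans(matrix(u$u_drive, per)))
}

# Initialise the coupling parameters by Wiener deconvolution of each node's
# BOLD to an approximate neural signal, followed by ridge regression of the
# finite-difference neural derivative on the bilinear terms (the neural ODE
# is linear in A, B, C given the neural states). Only used as a starting
# point.
dcm_init_regression <- function(y, model, u, priors, hemo, tmpl) {
  n <- nrow(y)
  theta <- rep(0, tmpl$n)
  if (tmpl$n == 0) return(theta)
  kern <- hemo_impulse_kernel(u$tr, u$dt, hemo)
  K <- stats::fft(c(kern * u$tr, numeric(n - length(kern))))
  lam <- 0.05 * max(Mod(K)^2)
  Z <- apply(y, 2, function(col) {
    Re(stats::fft(stats::fft(col) * Conj(K) / (Mod(K)^2 + lam),
                  inverse = TRUE)) / n
  })
  ug <- tr_grid_inputs(u)
  mid <- 2:(n - 1)
  dZ <- (Z[mid + 1, ] - Z[mid - 1, ]) / (2 * u$tr)
  Zm <- Z[mid, ]; utm <- ug$task[mid]; udm <- ug$drive[mid]
  A_est <- matrix(0, 3, 3)
  for (i in 1:3) {
    G <- Zm
    bsel <- which(model$b_support[i, ])
    if (length(bsel) > 0) G <- cbind(G, Zm[, bsel, drop = FALSE] * utm)
    if (i == 1) G <- cbind(G, udm)
    co <- tryCatch(
      solve(crossprod(G) + diag(0.1, ncol(G)), crossprod(G, dZ[, i])),
      error = function(e) numeric(ncol(G))
    )
    A_est[i, ] <- co[1:3]
    for (k in seq_along(bsel)) {
      slot <- slot_of(tmpl, "b", (bsel[k] - 1) * 3 + i)
      if (length(slot)) theta[slot] <- max(-1.5, min(1.5, co[3 + k]))
    }
    if (i == 1) {
      slot <- slot_of(tmpl, "c", 1L)
      if (length(slot)) theta[slot] <- max(-2, min(2, co[length(co)]))
    }
  }
  for (lin in which(!diag(TRUE, 3))) {
    slot <- slot_of(tmpl, "a_off", lin)
    if (length(slot)) theta[slot] <- max(-0.8, min(0.8, A_est[lin]))
  }
  for (i in 1:3) {
    slot <- slot_of(tmpl, "a_self", i)
    if (length(slot)) {
      theta[slot] <- max(-0.2, min(0.2, A_est[i, i] - priors$a_self_baseline))
    }
  }
  # shrink the intrinsic part toward the prior mean until stable at rest
  a_slots <- which(tmpl$kind %in% c("a_off", "a_self"))
  for (shrink in c(1, 0.7, 0.5, 0.3, 0.1, 0)) {
    th <- theta
    th[a_slots] <- th[a_slots] * shrink
    A <- unpack_params(th, model, priors, tmpl)$A
    if (max(Re(eigen(A, only.values = TRUE)$values)) < -1e-3) {
      theta[a_slots] <- theta[a_slots] * shrink
      return(theta)
    }
  }
  theta[a_slots] <- 0
  theta
}

# Gauss-Newton Laplace curvature: finite-difference Jacobian of the
# predicted BOLD with respect to theta, weighted by the concentrated noise
# precisions, plus the prior precision.
dcm_gn_hessian <- function(theta, y, model, u, priors, hemo, tmpl,
                           eps = 1e-4) {
  base <- dcm_predict(theta, model, u, priors, hemo, tmpl)
  n <- nrow(y)
  s2 <- pmax(colSums((y - base)^2) / n, 1e-12)
  H <- diag(1 / tmpl$prior_sd^2, tmpl$n)
  Jarr <- array(0, c(n, 3, tmpl$n))
  for (k in seq_len(tmpl$n)) {
    th <- theta; th[k] <- th[k] + eps
    pk <- dcm_predict(th, model, u, priors, hemo, tmpl)
    if (!is.null(pk)) Jarr[, , k] <- (pk - base) / eps
  }
  for (i in 1:3) {
    Ji <- matrix(Jarr[, i, ], n, tmpl$n)
    H <- H + crossprod(Ji) / s2[i]
  }
  (H + t(H)) / 2
}

#' Invert a DCM on observed node timecourses
#'
#' Maximum-a-posteriori estimation of the free coupling parameters:
#' penalised least squares solved by Levenberg-Marquardt, with the per-node
#' noise variances re-estimated between passes (iteratively reweighted),
#' started from a deconvolution-plus-regression estimate and from the prior
#' mean (the better optimum under the concentrated log joint is kept). The
#' log model evidence is a Laplace approximation,
#' `log Z ~ log p(y, theta_hat) + (p/2) log(2 pi) - 0.5 log det H`, with
#' Gauss-Newton curvature `H`. A model with no free parameters returns the
#' prior as posterior and the likelihood at the prior mean as evidence.
#' Deterministic given the data.
#'
#' @param y `n_volumes x 3` matrix of node timecourses (pMTG, aIPS, PMv).
#' @param model A `dcm_model`.
#' @param u Inputs from [dcm_inputs_from_schedule()].
#' @param priors A `dcm_priors`.
#' @param hemo Haemodynamic constants.
#' @param outer Reweighting passes (default 3).
#' @param maxiter Levenberg-Marquardt iteration cap per pass (default 100).
#' @param use_zero_start Also optimise from the prior mean and keep the
#'   better optimum (default TRUE).
#' @param free_a,free_self,free_c Which parameter blocks are free (defaults
#'   all `TRUE`); with everything fixed and an empty modulatory support the
#'   inversion is degenerate and returns the prior.
#' @return A `dcm_fit`: list with `A`, `B`, `C` (posterior means in 1/s),
#'   `theta`, `log_evidence`, `converged`, `model_id`, `rss`.
#' @export
invert_dcm <- function(y, model, u, priors = dcm_priors(),
                       hemo = default_hemo_params(), outer = 3,
                       maxiter = 100, use_zero_start = TRUE,
                       free_a = TRUE, free_self = TRUE, free_c = TRUE) {
  y <- as.matrix(y)
  if (ncol(y) != 3) stop("`y` must have 3 node columns")
  if (nrow(y) != u$n_volumes) {
    stop("`y` has ", nrow(y), " volumes but the inputs describe ",
         u$n_volumes)
  }
  tmpl <- param_template(model, priors, free_a, free_self, free_c)
  n <- nrow(y)
  finish <- function(theta, converged) {
    par <- unpack_params(theta, model, priors, tmpl)
    pred <- dcm_predict(theta, model, u, priors, hemo, tmpl)
    rss <- colSums((y - pred)^2)
    nlj <- dcm_neg_log_joint(theta, y, model, u, priors, hemo, tmpl)
    log_evidence <- if (tmpl$n > 0) {
      H <- dcm_gn_hessian(theta, y, model, u, priors, hemo, tmpl)
      ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
      -nlj + (tmpl$n / 2) * log(2 * pi) - 0.5 * sum(log(pmax(ev, 1e-10)))
    } else {
      -nlj
    }
    structure(
      list(A = par$A, B = par$B, C = par$C, theta = theta,
           log_evidence = log_evidence, converged = converged,
           model_id = model$model_id, rss = rss, neg_log_joint = nlj),
      class = "dcm_fit"
    )
  }
  if (tmpl$n == 0) return(finish(numeric(0), TRUE))

  run_lm <- function(th0) {
    th <- th0
    s2 <- apply(y, 2, stats::var)
    conv <- FALSE
    for (it in seq_len(outer)) {
      resid <- function(t_) {
        pred <- dcm_predict(t_, model, u, priors, hemo, tmpl)
        if (is.null(pred)) return(rep(1e3, n * 3 + tmpl$n))
        c(as.vector(sweep(y - pred, 2, sqrt(s2), "/")), t_ / tmpl$prior_sd)
      }
      fit <- suppressWarnings(minpack.lm::nls.lm(
        th, fn = resid,
        control = minpack.lm::nls.lm.control(maxiter = maxiter,
                                             ptol = 1e-12, ftol = 1e-12)
      ))
      th <- fit$par
      conv <- fit$info %in% 1:4
      pred <- dcm_predict(th, model, u, priors, hemo, tmpl)
      if (is.null(pred)) break
      s2 <- pmax(colSums((y - pred)^2) / n, 1e-14)
    }
    list(theta = th, converged = conv)
  }

  starts <- list(dcm_init_regression(y, model, u, priors, hemo, tmpl))
  if (use_zero_start) starts <- c(starts, list(rep(0, tmpl$n)))
  best <- NULL; best_nlj <- Inf; best_conv <- FALSE
  for (st in starts) {
    res <- run_lm(st)
    nlj <- dcm_neg_log_joint(res$theta, y, model, u, priors, hemo, tmpl)
    if (nlj < best_nlj) {
      best <- res$theta; best_nlj <- nlj; best_conv <- res$converged
    }
  }
  finish(best, best_conv)
}

#' Random-effects Bayesian model selection
#'
#' Variational estimation of the Dirichlet posterior over model frequencies
#' in the population (uniform prior, one count per model), from a subjects
#' x models matrix of log evidences, with exceedance probabilities (the
#' probability that each model is the most frequent) estimated by Monte
#' Carlo sampling of the posterior Dirichlet.
#'
#' @param log_evidences Subjects x models matrix of (approximate) log model
#'   evidences.
#' @param alpha0 Dirichlet prior count per model (default 1).
#' @param n_samples Monte Carlo draws for the exceedance probabilities
#'   (default 1e6).
#' @param seed Seed for the sampling.
#' @param tol,max_iter Convergence controls for the variational updates.
#' @return A `bms_result`: list with `alpha` (posterior Dirichlet counts),
#'   `expected_r` (expected model frequencies), `exceedance`, and `g`
#'   (subjects x models posterior model assignments).
#' @export
rfx_bms <- function(log_evidences, alpha0 = 1, n_samples = 1e6, seed = 1,
                    tol = 1e-8, max_iter = 500) {
  lme <- as.matrix(log_evidences)
  if (any(!is.finite(lme))) stop("log evidences must be finite")
  n_sub <- nrow(lme); n_mod <- ncol(lme)
  if (n_mod < 2) stop("need at least 2 models")
  if (n_sub < 1) stop("need at least 1 subject")
  alpha <- rep(alpha0, n_mod)
  g <- matrix(1 / n_mod, n_sub, n_mod)
  for (it in seq_len(max_iter)) {
    w <- sweep(lme, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    w <- w - apply(w, 1, max)
    g <- exp(w) / rowSums(exp(w))
    alpha_new <- alpha0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) { alpha <- alpha_new; break }
    alpha <- alpha_new
  }
  xp <- local_seed(seed, {
    draws <- matrix(stats::rgamma(n_samples * n_mod,
                                  shape = rep(alpha, each = n_samples)),
                    n_samples, n_mod)
    tabulate(max.col(draws, ties.method = "first"), n_mod) / n_samples
  })
  names(alpha) <- names(xp) <- colnames(lme)
  structure(list(alpha = alpha, expected_r = alpha / sum(alpha),
                 exceedance = xp, g = g), class = "bms_result")
}

#' Group-level tests on DCM connection parameters
#'
#' Two-sided one-sample t-tests of each connection parameter against zero
#' across subjects, with Benjamini-Yekutieli FDR control over the parameter
#' family.
#'
#' @param posteriors Subjects x parameters matrix (e.g. the per-subject
#'   posterior means of the winning model's B entries), with column names.
#' @param q FDR level (default 0.05).
#' @return data.frame with `parameter`, `mean`, `t`, `df`, `p`,
#'   `significant`.
#' @export
group_test_parameters <- function(posteriors, q = 0.05) {
  posteriors <- as.matrix(posteriors)
  if (nrow(posteriors) < 2) stop("need at least 2 subjects")
  res <- do.call(rbind, lapply(seq_len(ncol(posteriors)), function(j) {
    ht <- stats::t.test(posteriors[, j], mu = 0)
    data.frame(parameter = colnames(posteriors)[j],
               mean = mean(posteriors[, j]),
               t = unname(ht$statistic), df = unname(ht$parameter),
               p = ht$p.value, stringsAsFactors = FALSE)
  }))
  res$significant <- fdr_correct_by(res$p, q)
  rownames(res) <- NULL
  res
}
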