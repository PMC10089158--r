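# Binomial logit mixed-model engine: random intercept per fire, log-area
# offset, Laplace-approximate marginal likelihood maximized over
# (beta, log sigma) by quasi-Newton with analytic gradients; inner Newton on
# the per-group random-effect modes.

# log(1 + exp(x)) without overflow
log1pexp <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

# inner Newton for the per-group modes u given (beta, sigma); vectorized over
# groups (u is one scalar per group). Returns modes and per-group summaries.
solve_modes <- function(Xb_off, y, gi, q, sigma2, u = rep(0, q),
                        tol = 1e-10, maxit = 50L) {
  if (sigma2 <= 0) {
    eta <- Xb_off
    p <- logistic(eta)
    return(list(u = rep(0, q), p = p, eta = eta,
                W = rowsum_vec(p * (1 - p), gi, q), converged = TRUE))
  }
  pen_ll <- function(u) {
    eta <- Xb_off + u[gi]
    sum(y * eta - log1pexp(eta)) - sum(u^2) / (2 * sigma2)
  }
  f_old <- pen_ll(u)
  for (it in seq_len(maxit)) {
    eta <- Xb_off + u[gi]
    p <- logistic(eta)
    s <- rowsum_vec(y - p, gi, q)
    g <- s - u / sigma2
    if (max(abs(g)) < tol) {
      return(list(u = u, p = p, eta = eta,
                  W = rowsum_vec(p * (1 - p), gi, q), converged = TRUE))
    }
    W <- rowsum_vec(p * (1 - p), gi, q)
    H <- W + 1 / sigma2
    step <- g / H
    # damped Newton: halve until the penalized log-likelihood does not drop
    for (h in 0:30) {
      u_new <- u + step / 2^h
      f_new <- pen_ll(u_new)
      if (f_new >= f_old - 1e-12) break
    }
    u <- u_new
    f_old <- f_new
  }
  eta <- Xb_off + u[gi]
  p <- logistic(eta)
  list(u = u, p = p, eta = eta, W = rowsum_vec(p * (1 - p), gi, q),
       converged = max(abs(rowsum_vec(y - p, gi, q) - u / sigma2)) < 1e-6)
}

rowsum_vec <- function(x, gi, q) {
  out <- numeric(q)
  r <- rowsum(x, gi)
  out[as.integer(rownames(r))] <- r[, 1]
  out
}

rowsum_mat <- function(M, gi, q) {
  out <- matrix(0, q, ncol(M))
  r <- rowsum(M, gi)
  out[as.integer(rownames(r)), ] <- r
  out
}

# Laplace log-likelihood and its analytic gradient in (beta, tau = log sigma).
# Modes are warm-started through `env` across calls.
laplace_obj <- function(par, X, y, off, gi, q, env) {
  p_dim <- ncol(X)
  beta <- par[seq_len(p_dim)]
  tau <- par[p_dim + 1L]
  sigma2 <- exp(2 * tau)
  Xb_off <- drop(X %*% beta) + off
  m <- solve_modes(Xb_off, y, gi, q, sigma2, u = env$u)
  env$u <- m$u
  D <- sigma2 * m$W + 1                      # sigma^2 * H per group
  ll <- sum(y * m$eta - log1pexp(m$eta)) - sum(m$u^2) / (2 * sigma2) -
    0.5 * sum(log(D))

  w <- m$p * (1 - m$p)
  wp <- w * (1 - 2 * m$p)                    # d w / d eta
  A <- rowsum_mat(X * w, gi, q)              # q x p: sum_i w_i x_ij
  B <- rowsum_mat(X * wp, gi, q)
  cc <- rowsum_vec(wp, gi, q)
  H <- m$W + 1 / sigma2
  # d ll / d beta_j = sum (y - p) x_j - 0.5/H * (B_gj - c_g A_gj / H_g)
  resid_term <- colSums(X * (y - m$p))
  logdet_term <- colSums((B - (cc / H) * A) / H)
  g_beta <- resid_term - 0.5 * logdet_term
  # d ll / d tau = u^2/sigma^2 - sigma^2 W / D - sigma^2 c u / D^2 (per group)
  g_tau <- sum(m$u^2 / sigma2 - sigma2 * m$W / D - sigma2 * cc * m$u / D^2)
  list(value = ll, gradient = c(g_beta, g_tau))
}

#' Fit the binomial recruitment mixed model
#'
#' Maximizes the Laplace-approximate marginal likelihood of a binomial logit
#' model with a random intercept per wildfire and a fixed log(plot area)
#' offset. The outer problem over (beta, log sigma) is solved by L-BFGS-B
#' with analytic gradients; the inner problem (the per-fire random-effect
#' modes) by damped Newton. The coefficient covariance is the inverse of the
#' observed information (numerically differentiated analytic gradient).
#'
#' @param design A `regen_design` from [build_design()], or a numeric design
#'   matrix (then `y`, `offset`, `groups` must be given).
#' @param y Binary response (when `design` is a matrix).
#' @param offset Per-row offset (log area m2).
#' @param groups Grouping factor (fire id).
#' @param start Optional named list with `beta` and `tau` start values.
#' @param grad_tol Convergence tolerance on the max absolute (projected)
#'   gradient (default 1e-6).
#' @param maxit Outer iteration cap (default 500).
#' @return Object of class `regen_glmm` with elements `coefficients`,
#'   `sigma`, `vcov` (fixed-effect block), `vcov_full` (incl. log sigma),
#'   `ranef` (conditional modes), `loglik`, `convergence`, `design_info`.
#' @export
fit_glmm <- function(design, y = NULL, offset = NULL, groups = NULL,
                     start = NULL, grad_tol = 1e-6, maxit = 500L) {
  design_info <- NULL
  if (inherits(design, "regen_design")) {
    design_info <- design[c("spec", "scaling", "xlevels")]
    X <- design$X; y <- design$y; offset <- design$offset; groups <- design$groups
  } else {
    X <- as.matrix(design)
  }
  stop_if_not(!is.null(y), "response `y` is required")
  stop_if_not(all(y %in% c(0, 1)), "response must be binary 0/1")
  if (is.null(offset)) offset <- rep(0, nrow(X))
  stop_if_not(!is.null(groups), "grouping factor `groups` is required")
  groups <- factor(groups)
  stop_if_not(nlevels(groups) >= 2L, "need at least 2 groups, found %d", nlevels(groups))
  qr_X <- qr(X)
  stop_if_not(qr_X$rank == ncol(X), "design matrix is rank deficient (rank %d < %d columns)",
              qr_X$rank, ncol(X))
  gi <- as.integer(groups)
  q <- nlevels(groups)
  p_dim <- ncol(X)

  if (is.null(start)) {
    glm0 <- suppressWarnings(
      stats::glm.fit(X, y, offset = offset, family = stats::binomial()))
    par0 <- c(glm0$coefficients, log(0.5))
  } else {
    par0 <- c(start$beta, start$tau)
  }
  stop_if_not(length(par0) == p_dim + 1L, "start values have wrong length")

  env <- new.env(parent = emptyenv())
  env$u <- rep(0, q)
  fn <- function(par) -laplace_obj(par, X, y, offset, gi, q, env)$value
  gr <- function(par) -laplace_obj(par, X, y, offset, gi, q, env)$gradient
  lower <- c(rep(-Inf, p_dim), -12)
  upper <- c(rep(Inf, p_dim), 5)
  opt <- stats::optim(par0, fn, gr, method = "L-BFGS-B", lower = lower,
                      upper = upper,
                      control = list(maxit = maxit, factr = 1e4))
  iterations <- unname(opt$counts["function"])
  # Newton polish: L-BFGS-B stops on relative progress, a few full Newton
  # steps with the observed-information Hessian tighten the gradient norm
  par_cur <- opt$par
  f_cur <- opt$value
  proj <- projected_grad(-gr(par_cur), par_cur, lower, upper)
  polish <- 0L
  while (max(abs(proj)) >= grad_tol && polish < 15L) {
    polish <- polish + 1L
    H <- num_hessian_from_grad(gr, par_cur)       # Hessian of -loglik
    free <- !(par_cur <= lower + 1e-10 | par_cur >= upper - 1e-10)
    step <- numeric(length(par_cur))
    st <- tryCatch(solve(H[free, free, drop = FALSE], proj[free]),
                   error = function(e) NULL)
    if (is.null(st)) break
    step[free] <- st
    accepted <- FALSE
    for (h in 0:20) {
      cand <- pmin(pmax(par_cur + step / 2^h, lower), upper)
      f_new <- fn(cand)
      if (is.finite(f_new) && f_new <= f_cur + 1e-10) {
        par_cur <- cand; f_cur <- f_new; accepted <- TRUE
        break
      }
    }
    if (!accepted) break
    proj <- projected_grad(-gr(par_cur), par_cur, lower, upper)
  }
  opt$par <- par_cur
  iterations <- iterations + polish
  if (max(abs(proj)) >= grad_tol) {
    stop(sprintf("fit_glmm did not converge: max |projected gradient| = %.3g (tol %.1g) after %d evaluations",
                 max(abs(proj)), grad_tol, iterations), call. = FALSE)
  }

  par_hat <- opt$par
  beta_hat <- stats::setNames(par_hat[seq_len(p_dim)], colnames(X))
  tau_hat <- unname(par_hat[p_dim + 1L])
  sigma_hat <- exp(tau_hat)
  final <- laplace_obj(par_hat, X, y, offset, gi, q, env)

  Hobs <- -num_hessian_from_grad(function(par)
    laplace_obj(par, X, y, offset, gi, q, env)$gradient, par_hat)
  Hobs <- (Hobs + t(Hobs)) / 2
  at_bound <- tau_hat <= lower[p_dim + 1L] + 1e-8
  vcov_full <- tryCatch(solve(Hobs), error = function(e) NULL)
  if (is.null(vcov_full) || at_bound ||
      any(!is.finite(vcov_full)) || any(diag(vcov_full)[seq_len(p_dim)] <= 0)) {
    # fall back to the beta block at fixed sigma (boundary or singular cases)
    Hb <- Hobs[seq_len(p_dim), seq_len(p_dim), drop = FALSE]
    vb <- solve(Hb)
    vcov_full <- matrix(NA_real_, p_dim + 1L, p_dim + 1L)
    vcov_full[seq_len(p_dim), seq_len(p_dim)] <- vb
  }
  dimnames(vcov_full) <- list(c(colnames(X), "log_sigma"),
                              c(colnames(X), "log_sigma"))
  vcov_beta <- vcov_full[seq_len(p_dim), seq_len(p_dim), drop = FALSE]

  structure(list(
    coefficients = beta_hat,
    sigma = sigma_hat,
    tau = tau_hat,
    vcov = vcov_beta,
    vcov_full = vcov_full,
    ranef = stats::setNames(env$u, levels(groups)),
    loglik = unname(final$value),
    convergence = list(iterations = iterations,
                       gradient_norm = max(abs(proj)),
                       sigma_at_boundary = at_bound),
    design_info = design_info,
    group_levels = levels(groups),
    n = length(y), n_groups = q,
    X_colnames = colnames(X)
  ), class = "regen_glmm")
}

projected_grad <- function(g, par, lower, upper) {
  at_lo <- par <= lower + 1e-10
  at_hi <- par >= upper - 1e-10
  g[at_lo & g < 0] <- 0
  g[at_hi & g > 0] <- 0
  g
}

# central-difference Hessian of a scalar function with analytic gradient
num_hessian_from_grad <- function(grad_fn, par, h = 1e-5) {
  p <- length(par)
  H <- matrix(0, p, p)
  for (j in seq_len(p)) {
    hj <- h * max(1, abs(par[j]))
    e <- numeric(p); e[j] <- hj
    H[, j] <- (grad_fn(par + e) - grad_fn(par - e)) / (2 * hj)
  }
  H
}

#' @export
print.regen_glmm <- function(x, ...) {
  cat("Binomial logit mixed model (Laplace), random intercept by fire\n")
  cat(sprintf("  n = %d plots in %d fires; logLik = %.3f\n",
              x$n, x$n_groups, x$loglik))
  cat(sprintf("  random-intercept sd (logit scale): %.4f\n", x$sigma))
  se <- sqrt(diag(x$vcov))
  tab <- data.frame(estimate = x$coefficients, std_error = se,
                    z = x$coefficients / se)
  print(round(tab, 4))
  invisible(x)
}

#' @export
coef.regen_glmm <- function(object, ...) object$coefficients

#' @export
vcov.regen_glmm <- function(object, ...) object$vcov

#' @export
logLik.regen_glmm <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients) + 1L,
            class = "logLik")
}

#' Marginal log-likelihood by adaptive Gauss-Hermite quadrature
#'
#' Evaluates the same marginal likelihood the Laplace engine approximates,
#' by adaptive Gauss-Hermite quadrature centered and scaled at each group's
#' conditional mode. With `nodes = 1` the value equals the Laplace
#' log-likelihood exactly, so this is the independent accuracy oracle for
#' the fitting engine.
#'
#' @param X Design matrix (including intercept).
#' @param y Binary response.
#' @param offset Per-row offset.
#' @param groups Grouping factor.
#' @param beta Fixed-effect coefficients.
#' @param sigma Random-intercept sd (>= 0).
#' @param nodes Number of quadrature nodes (>= 1).
#' @return The marginal log-likelihood (a single number).
#' @export
marginal_loglik_gh <- function(X, y, offset, groups, beta, sigma, nodes = 50L) {
  nodes <- check_count(nodes, "nodes")
  check_number(sigma, "sigma", lower = 0)
  X <- as.matrix(X)
  groups <- factor(groups)
  gi <- as.integer(groups)
  q <- nlevels(groups)
  Xb_off <- drop(X %*% beta) + offset
  if (sigma == 0) {
    return(sum(y * Xb_off - log1pexp(Xb_off)))
  }
  sigma2 <- sigma^2
  gh <- gauss_hermite(nodes)
  m <- solve_modes(Xb_off, y, gi, q, sigma2)
  H <- m$W + 1 / sigma2
  ll <- 0
  for (g in seq_len(q)) {
    rows <- which(gi == g)
    s <- 1 / sqrt(H[g])
    u_k <- m$u[g] + sqrt(2) * s * gh$x
    h_k <- vapply(u_k, function(u) {
      eta <- Xb_off[rows] + u
      sum(y[rows] * eta - log1pexp(eta)) - u^2 / (2 * sigma2)
    }, numeric(1))
    h_k <- h_k - 0.5 * log(2 * pi * sigma2)
    lt <- log(gh$w) + gh$x^2 + h_k + 0.5 * log(2) + log(s)
    mx <- max(lt)
    ll <- ll + mx + log(sum(exp(lt - mx)))
  }
  ll
}

# Gauss-Hermite nodes/weights by Golub-Welsch (symmetric tridiagonal Jacobi
# matrix; weights from first eigenvector components)
gauss_hermite <- function(n) {
  if (n == 1L) return(list(x = 0, w = sqrt(pi)))
  b <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1), 2:n)] <- b
  J[cbind(2:n, seq_len(n - 1))] <- b
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- sqrt(pi) * e$vectors[1, ]^2
  ord <- order(x)
  list(x = x[ord], w = w[ord])
}

#' Predict recruitment probability
#'
#' Population-level predictions set the random intercept to zero (new,
#' unobserved fires); conditional predictions add the fitted conditional mode
#' of each plot's fire. The linear predictor always includes the log(area)
#' offset, so predictions refer to a plot of the stated size.
#'
#' @param fitted A `regen_glmm` fitted with a `regen_design` (so term scaling
#'   and factor levels are stored).
#' @param newdata Data.frame of raw-scale covariates covering all model terms.
#' @param area_m2 Plot area in m2 (scalar or per-row), > 0.
#' @param level `"population"` (default) or `"conditional"` (requires a
#'   `fire_id` column with fitted fires).
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_probability <- function(fitted, newdata, area_m2 = 100,
                                level = c("population", "conditional")) {
  stopifnot(inherits(fitted, "regen_glmm"))
  level <- match.arg(level)
  stop_if_not(!is.null(fitted$design_info),
              "model was fitted on a bare matrix; predict via the design matrix instead")
  stop_if_not(all(area_m2 > 0), "`area_m2` must be positive")
  nd <- newdata
  nd$area_m2 <- area_m2
  nd$fire_id <- if ("fire_id" %in% names(newdata)) newdata$fire_id else "new_fire"
  nd[[fitted$design_info$spec$response]] <- NULL
  des <- build_design(nd, fitted$design_info$spec,
                      scaling = fitted$design_info$scaling)
  stop_if_not(identical(colnames(des$X), fitted$X_colnames),
              "newdata produced a different design than the fitted model")
  eta <- drop(des$X %*% fitted$coefficients) + des$offset
  if (level == "conditional") {
    idx <- match(as.character(nd$fire_id), names(fitted$ranef))
    stop_if_not(!anyNA(idx), "conditional prediction requires fitted fire ids")
    eta <- eta + fitted$ranef[idx]
  }
  logistic(eta)
}

#' Simulation-based quantile residuals
#'
#' For each plot, simulates `n_sims` unconditional replicates of the outcome
#' (random intercepts redrawn from the fitted Normal(0, sigma^2), outcomes
#' from the fitted Bernoulli probabilities) and returns the randomized
#' quantile of the observed outcome among the simulations. Under a correctly
#' specified model the residuals are approximately Uniform(0, 1).
#'
#' @param fitted A `regen_glmm`.
#' @param X Design matrix used for the fit.
#' @param y Observed binary response.
#' @param offset Offset used in the fit.
#' @param groups Grouping factor used in the fit.
#' @param n_sims Number of simulations (>= 20).
#' @param seed Integer seed.
#' @return Numeric vector of residuals in \[0, 1\].
#' @export
simulation_residuals <- function(fitted, X, y, offset, groups, n_sims = 250L,
                                 seed = DEFAULT_SEED) {
  stopifnot(inherits(fitted, "regen_glmm"))
  n_sims <- check_count(n_sims, "n_sims", min = 20L)
  X <- as.matrix(X)
  groups <- factor(groups)
  gi <- as.integer(groups)
  q <- nlevels(groups)
  eta_fix <- drop(X %*% fitted$coefficients) + offset
  n <- length(y)
  with_seed(seed, {
    below <- equal <- numeric(n)
    for (s in seq_len(n_sims)) {
      u <- stats::rnorm(q, 0, fitted$sigma)
      ysim <- stats::rbinom(n, 1L, logistic(eta_fix + u[gi]))
      below <- below + (ysim < y)
      equal <- equal + (ysim == y)
    }
    (below + stats::runif(n) * (equal + 1)) / (n_sims + 1)
  })
}

#' Serialize a fitted model to JSON
#'
#' Writes coefficients, covariance, random-intercept sd, conditional modes,
#' term scaling, factor levels and fit diagnostics so the model can be
#' reloaded for projection without refitting.
#'
#' @param fitted A `regen_glmm` fitted from a `regen_design`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_glmm_json <- function(fitted, path) {
  stopifnot(inherits(fitted, "regen_glmm"))
  spec <- fitted$design_info$spec
  doc <- list(
    coefficients = as.list(fitted$coefficients),
    sigma = fitted$sigma,
    vcov = unname(apply(fitted$vcov, 1, as.list)),
    vcov_names = colnames(fitted$vcov),
    ranef = as.list(fitted$ranef),
    loglik = fitted$loglik,
    convergence = fitted$convergence,
    n = fitted$n, n_groups = fitted$n_groups,
    spec = list(response = spec$response, fixed = spec$fixed,
                quadratic = spec$quadratic,
                interactions = spec$interactions,
                categorical = spec$categorical, climate = spec$climate),
    scaling = list(center = as.list(fitted$design_info$scaling$center),
                   scale = as.list(fitted$design_info$scaling$scale),
                   xlevels = fitted$design_info$scaling$xlevels)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Reload a fitted model from JSON
#'
#' @param path File written by [write_glmm_json()].
#' @return A `regen_glmm` usable with [predict_probability()] and
#'   [partial_dependence()].
#' @export
read_glmm_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- model_spec(fixed = doc$spec$fixed,
                     quadratic = as.character(unlist(doc$spec$quadratic)),
                     interactions = if (length(doc$spec$interactions))
                       lapply(seq_len(nrow(doc$spec$interactions)),
                              function(i) doc$spec$interactions[i, ]) else list(),
                     categorical = as.character(unlist(doc$spec$categorical)),
                     climate = as.character(unlist(doc$spec$climate)),
                     response = doc$spec$response)
  vcov <- do.call(rbind, lapply(doc$vcov, unlist))
  dimnames(vcov) <- list(doc$vcov_names, doc$vcov_names)
  structure(list(
    coefficients = unlist(doc$coefficients),
    sigma = doc$sigma, tau = log(max(doc$sigma, 1e-12)),
    vcov = vcov, vcov_full = NULL,
    ranef = unlist(doc$ranef),
    loglik = doc$loglik, convergence = doc$convergence,
    design_info = list(spec = spec,
                       scaling = list(center = unlist(doc$scaling$center),
                                      scale = unlist(doc$scaling$scale),
                                      xlevels = doc$scaling$xlevels),
                       xlevels = doc$scaling$xlevels),
    group_levels = names(doc$ranef),
    n = doc$n, n_groups = doc$n_groups,
    X_colnames = doc$vcov_names
  ), class = "regen_glmm")
}
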