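#' Independent uniform priors
#'
#' @param ... Named length-2 numeric vectors `c(lower, upper)`, one per
#'   parameter, in sampling order.
#' @return An object of class `prior_spec` with fields `names`, `lower`,
#'   `upper`.
#' @examples
#' uniform_priors(alpha_par = c(0, 500), delta = c(0, 1))
#' @export
uniform_priors <- function(...) {
  b <- list(...)
  if (length(b) == 0L || is.null(names(b)) || any(names(b) == "")) {
    rlang::abort("Provide named `c(lower, upper)` bounds.",
      class = "voltaxis_invalid_input"
    )
  }
  lower <- purrr::map_dbl(b, 1)
  upper <- purrr::map_dbl(b, 2)
  if (any(!is.finite(lower)) || any(!is.finite(upper)) ||
    any(lower >= upper)) {
    rlang::abort("Each prior needs finite `lower < upper`.",
      class = "voltaxis_invalid_input"
    )
  }
  structure(
    list(names = names(b), lower = lower, upper = upper),
    class = "prior_spec"
  )
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("<prior_spec> independent uniforms\n")
  for (i in seq_along(x$names)) {
    cat(sprintf("  %s ~ U(%g, %g)\n", x$names[i], x$lower[i], x$upper[i]))
  }
  invisible(x)
}

#' Gaussian observation log-likelihood
#'
#' Sum over all observations of the normal log-density of the residuals
#' between model output and data, under i.i.d. Gaussian observation error
#' with standard deviation `sigma`.
#'
#' @param model Numeric vector/matrix or data frame of model values.
#' @param data Same shape as `model`: the observations.
#' @param sigma Noise standard deviation, > 0.
#' @return The scalar log-likelihood.
#' @examples
#' gaussian_log_likelihood(rep(0, 5), rep(0, 5), sigma = 1) # -(5/2) log(2*pi)
#' @export
gaussian_log_likelihood <- function(model, data, sigma) {
  check_number(sigma, "sigma", positive = TRUE)
  m <- as.numeric(as.matrix(model))
  d <- as.numeric(as.matrix(data))
  if (length(m) != length(d)) {
    rlang::abort("`model` and `data` must be on identical grids.",
      class = "voltaxis_invalid_input"
    )
  }
  sum(dnorm(d, mean = m, sd = sigma, log = TRUE))
}

#' Adaptive-covariance Metropolis sampling
#'
#' Random-walk Metropolis with Haario-style adaptive covariance and
#' Bardenet-style global scaling, run as several independent chains. During
#' an initial non-adaptive phase the proposal is an axis-aligned Gaussian
#' scaled to the prior widths; afterwards the running posterior covariance
#' is learned online with decaying weight `(i - warmup)^(-0.6)` and the
#' global step scale is tuned towards an acceptance rate of 0.234. Priors
#' are independent uniforms, so the posterior is the likelihood restricted
#' to the prior box.
#'
#' @param log_lik Function `theta -> scalar` log-likelihood; `theta` is a
#'   named numeric vector in the order of `priors`. Must be finite somewhere
#'   in the prior box.
#' @param priors A [uniform_priors()] specification.
#' @param n_chains Number of independent chains (default 4).
#' @param max_iter Iterations per chain (default `2e4`).
#' @param seed Integer seed; the whole run is reproducible given it.
#' @param init Optional matrix (`n_chains` x d) of start points; default
#'   independent prior draws (re-drawn until the likelihood is finite).
#' @param warmup Iterations of the initial non-adaptive phase (default 200).
#' @param target_accept Target acceptance rate for scale adaptation.
#' @return An object of class `posterior_result`: `chains` (iteration x
#'   parameter x chain array, all iterations), `draws` (tibble of
#'   post-burn-in samples; burn-in is the first half of each chain),
#'   `r_hat` (split-R-hat per parameter, computed post burn-in), `means`,
#'   `ci` (2.5/97.5% quantiles), `accept_rate`, `seed`, `priors`.
#' @export
run_adaptive_mcmc <- function(log_lik, priors, n_chains = 4, max_iter = 2e4,
                              seed = NULL, init = NULL, warmup = 200,
                              target_accept = 0.234) {
  stopifnot(inherits(priors, "prior_spec"))
  d <- length(priors$names)
  n_chains <- as.integer(n_chains)
  max_iter <- as.integer(max_iter)
  if (!is.null(seed)) set.seed(seed)

  lp <- function(theta) {
    if (any(theta < priors$lower) || any(theta > priors$upper)) {
      return(-Inf)
    }
    ll <- log_lik(setNames(theta, priors$names))
    if (!is.finite(ll)) -Inf else ll
  }

  chains <- array(NA_real_,
    dim = c(max_iter, d, n_chains),
    dimnames = list(NULL, priors$names, NULL)
  )
  accept_rate <- numeric(n_chains)
  width <- priors$upper - priors$lower

  for (ch in seq_len(n_chains)) {
    # initial point: supplied, else prior draws until the likelihood is finite
    if (!is.null(init)) {
      x <- as.numeric(init[ch, ])
      f <- lp(x)
      if (!is.finite(f)) {
        rlang::abort("Supplied `init` has non-finite posterior.",
          class = "voltaxis_initialization_error"
        )
      }
    } else {
      f <- -Inf
      for (attempt in 1:200) {
        x <- priors$lower + runif(d) * width
        f <- lp(x)
        if (is.finite(f)) break
      }
      if (!is.finite(f)) {
        rlang::abort(
          "Could not find a prior draw with finite likelihood (200 attempts).",
          class = "voltaxis_initialization_error"
        )
      }
    }

    mu <- x
    Sigma <- diag((0.05 * width)^2, d)
    chol_S <- chol(Sigma)
    log_lambda <- 0
    base_scale <- 2.38^2 / d
    n_acc <- 0L

    for (i in seq_len(max_iter)) {
      prop <- x + sqrt(base_scale * exp(log_lambda)) *
        as.numeric(crossprod(chol_S, rnorm(d)))
      fp <- lp(prop)
      accepted <- is.finite(fp) && log(runif(1)) < fp - f
      if (accepted) {
        x <- prop
        f <- fp
        n_acc <- n_acc + 1L
      }
      chains[i, , ch] <- x

      if (i > warmup) {
        eta <- (i - warmup)^-0.6
        dx <- x - mu
        mu <- mu + eta * dx
        Sigma <- Sigma + eta * (tcrossprod(dx) - Sigma)
        log_lambda <- log_lambda + eta * ((accepted) - target_accept)
        chol_ok <- tryCatch(
          {
            chol_S <- chol(Sigma + diag(1e-12 * width^2, d))
            TRUE
          },
          error = function(e) FALSE
        )
        if (!chol_ok) chol_S <- chol(diag((0.05 * width)^2, d))
      }
    }
    accept_rate[ch] <- n_acc / max_iter
  }

  post <- posterior_from_chains(chains, priors)
  post$accept_rate <- accept_rate
  post$seed <- seed
  post
}

# Summaries from a full chains array: burn-in = first half of each chain.
posterior_from_chains <- function(chains, priors) {
  n <- dim(chains)[1]
  keep <- seq.int(floor(n / 2) + 1L, n)
  kept <- chains[keep, , , drop = FALSE]
  r_hat <- gelman_rubin(kept)
  flat <- apply(kept, 2, as.numeric)
  draws <- tibble::as_tibble(as.data.frame(flat))
  draws$.chain <- rep(seq_len(dim(kept)[3]), each = length(keep))
  ci <- apply(flat, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
  structure(
    list(
      chains = chains,
      draws = draws,
      r_hat = r_hat,
      means = colMeans(flat),
      ci = ci,
      priors = priors
    ),
    class = "posterior_result"
  )
}

#' @export
print.posterior_result <- function(x, ...) {
  cat(sprintf(
    "<posterior_result> %d chains x %d iterations (post-burn-in draws: %d)\n",
    dim(x$chains)[3], dim(x$chains)[1], nrow(x$draws)
  ))
  print(tidy(x))
  invisible(x)
}

#' @rdname run_adaptive_mcmc
#' @param x A `posterior_result`.
#' @param ... Unused.
#' @export
tidy.posterior_result <- function(x, ...) {
  tibble::tibble(
    term = x$priors$names,
    estimate = unname(x$means),
    conf.low = x$ci[1, ],
    conf.high = x$ci[2, ],
    r_hat = unname(x$r_hat)
  )
}

#' @rdname run_adaptive_mcmc
#' @export
glance.posterior_result <- function(x, ...) {
  tibble::tibble(
    n_chains = dim(x$chains)[3],
    n_iter = dim(x$chains)[1],
    max_r_hat = max(x$r_hat),
    converged = max(x$r_hat) <= 1.05,
    mean_accept = mean(x$accept_rate %||% NA_real_)
  )
}

#' Split Gelman-Rubin convergence diagnostic
#'
#' Classic (not rank-normalised) split-R-hat: each chain is halved, and the
#' between- to within-chain variance ratio is computed over the resulting
#' `2m` sequences. Values near 1 indicate mixing; the package adopts the
#' usual 1.05 reference threshold for four chains. Parameters with
#' (numerically) zero variance in every chain return exactly 1.
#'
#' @param chains Iteration x parameter x chain array, or a list of
#'   iteration x parameter matrices (equal lengths >= 10), or a matrix
#'   (iterations x chains) for a single parameter.
#' @return Named numeric of R-hat values per parameter.
#' @export
gelman_rubin <- function(chains) {
  if (is.list(chains) && !is.array(chains)) {
    stopifnot(length(chains) >= 2L)
    chains <- simplify2array(chains) # iter x param x chain
  }
  if (length(dim(chains)) == 2L) {
    dn <- dimnames(chains)
    chains <- array(chains, dim = c(nrow(chains), 1L, ncol(chains)))
    dimnames(chains) <- list(NULL, "param", NULL)
  }
  n_iter <- dim(chains)[1]
  n_par <- dim(chains)[2]
  n_ch <- dim(chains)[3]
  if (n_ch < 2L) {
    rlang::abort("R-hat needs at least 2 chains.",
      class = "voltaxis_invalid_input"
    )
  }
  if (n_iter < 10L) {
    rlang::abort("R-hat needs chains of length >= 10.",
      class = "voltaxis_invalid_input"
    )
  }
  half <- floor(n_iter / 2)
  out <- numeric(n_par)
  for (p in seq_len(n_par)) {
    segs <- list()
    for (ch in seq_len(n_ch)) {
      segs[[2 * ch - 1]] <- chains[1:half, p, ch]
      segs[[2 * ch]] <- chains[(n_iter - half + 1):n_iter, p, ch]
    }
    m <- length(segs)
    n <- half
    means <- vapply(segs, mean, 0)
    vars <- vapply(segs, var, 0)
    W <- mean(vars)
    B <- n * var(means)
    scale <- mean(vapply(segs, function(s) mean(s^2), 0))
    if (W <= 1e-300 || W < 1e-15 * max(scale, 1e-300)) {
      # degenerate (constant) chains: defined as perfectly mixed
      out[p] <- 1
    } else {
      out[p] <- sqrt(((n - 1) / n * W + B / n) / W)
    }
  }
  names(out) <- dimnames(chains)[[2]]
  out
}

#' Posterior predictive envelope
#'
#' Simulates the model at draws from the posterior and returns per-position
#' quantile envelopes (by default the middle 95%), together with the
#' trajectory at the posterior mean.
#'
#' @param posterior A `posterior_result` (or `electro_fit`).
#' @param simulator Function mapping a named parameter vector to a numeric
#'   vector of model output (constant length).
#' @param quantiles Length-2 probabilities for the envelope.
#' @param n_draws Number of posterior draws to simulate (>= 200 recommended;
#'   capped at the number of available draws).
#' @return A tibble with columns `position`, `lower`, `upper`, `mean_curve`.
#'   Draws on which the simulator fails are skipped with a message; more
#'   than 10% failures is an error.
#' @export
posterior_predictive_band <- function(posterior, simulator,
                                      quantiles = c(0.025, 0.975),
                                      n_draws = 200) {
  if (inherits(posterior, "electro_fit")) posterior <- posterior$posterior
  stopifnot(inherits(posterior, "posterior_result"))
  draws <- posterior$draws
  par_names <- posterior$priors$names
  n_avail <- nrow(draws)
  if (n_avail == 0L) {
    rlang::abort("Posterior has no draws.", class = "voltaxis_invalid_input")
  }
  n_draws <- min(n_draws, n_avail)
  idx <- if (n_avail == n_draws) {
    seq_len(n_avail)
  } else {
    round(seq(1, n_avail, length.out = n_draws))
  }
  sims <- vector("list", length(idx))
  failed <- 0L
  for (k in seq_along(idx)) {
    th <- setNames(as.numeric(draws[idx[k], par_names]), par_names)
    res <- tryCatch(as.numeric(simulator(th)), error = function(e) NULL)
    if (is.null(res)) {
      failed <- failed + 1L
    } else {
      sims[[k]] <- res
    }
  }
  if (failed > 0.1 * length(idx)) {
    rlang::abort(
      sprintf("Simulator failed on %d of %d draws.", failed, length(idx)),
      class = "voltaxis_simulator_failure"
    )
  }
  if (failed > 0) {
    rlang::inform(sprintf("Skipped %d failed simulator draws.", failed))
  }
  sims <- sims[!vapply(sims, is.null, TRUE)]
  mat <- do.call(rbind, sims)
  mean_curve <- as.numeric(
    simulator(setNames(posterior$means[par_names], par_names))
  )
  tibble::tibble(
    position = seq_len(ncol(mat)),
    lower = apply(mat, 2, quantile, probs = quantiles[1]),
    upper = apply(mat, 2, quantile, probs = quantiles[2]),
    mean_curve = mean_curve
  )
}
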