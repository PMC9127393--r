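#' Build the trial-level regressor design for the neurally-informed fit
#'
#' Joins the behavioural trials with the per-trial absolute component
#' amplitudes so that every regression coefficient (per-condition
#' intercepts and early/late slopes on drift rate, boundary and
#' non-decision time) is estimable. Rows align 1:1 with the trial
#' table.
#'
#' @param trials Filtered trial table (columns `subject`, `congruency`,
#'   `response_correct`, `rt_ms`).
#' @param amplitudes Data frame with `abs_early` and `abs_late` (and
#'   optionally `trial`), one row per trial row.
#' @param standardize If `TRUE`, centre and scale the amplitude columns
#'   to mean 0, SD 1 within each condition.
#' @return Data frame with `subject`, `congruency`, `rt_s`, `correct`,
#'   `abs_early`, `abs_late`; attribute `"standardized"` records the
#'   flag.
#' @export
build_design <- function(trials, amplitudes, standardize = FALSE) {
  if (nrow(amplitudes) != nrow(trials)) {
    missing_ids <- if (!is.null(amplitudes$trial)) {
      setdiff(trials$trial, amplitudes$trial)
    } else {
      seq_len(abs(nrow(trials) - nrow(amplitudes)))
    }
    stop("build_design: amplitudes (", nrow(amplitudes), " rows) do not ",
         "cover trials (", nrow(trials), " rows); missing trial ids: ",
         paste(utils::head(missing_ids, 10), collapse = ", "))
  }
  if (anyNA(amplitudes$abs_early) || anyNA(amplitudes$abs_late)) {
    bad <- which(is.na(amplitudes$abs_early) | is.na(amplitudes$abs_late))
    stop("build_design: missing amplitudes for trial rows ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  out <- data.frame(subject = trials$subject, congruency = trials$congruency,
                    rt_s = trials$rt_ms / 1000,
                    correct = as.logical(trials$response_correct),
                    abs_early = amplitudes$abs_early,
                    abs_late = amplitudes$abs_late)
  if (standardize) {
    for (cond in unique(out$congruency)) {
      m <- out$congruency == cond
      for (col in c("abs_early", "abs_late")) {
        mu <- mean(out[[col]][m])
        s <- sd(out[[col]][m])
        out[[col]][m] <- (out[[col]][m] - mu) / if (s > 0) s else 1
      }
    }
  }
  attr(out, "standardized") <- standardize
  out
}

#' Prior settings of the hierarchical fit
#'
#' Weakly informative defaults: diffuse normals on group drift
#' intercepts and all slopes, positive-truncated normals on group
#' boundary and non-decision-time means, and inverse-gamma priors on the
#' group variances. Any setting that passes the parameter-recovery suite
#' is conforming; these are exposed for sensitivity analysis.
#'
#' @param mu_alpha0,mu_beta0,mu_gamma0 `c(mean, sd)` of the group
#'   intercept priors (boundary and non-decision means truncated at 0).
#' @param sigma2_alpha0,sigma2_beta0,sigma2_gamma0 `c(shape, scale)` of
#'   the inverse-gamma priors on group variances.
#' @param slope_sd Named SDs of the zero-mean normal slope priors.
#' @return List of class `hddm_priors`.
#' @export
hddm_priors <- function(mu_alpha0 = c(0, 5), mu_beta0 = c(1.5, 1.5),
                        mu_gamma0 = c(0.3, 0.5),
                        sigma2_alpha0 = c(2, 0.5), sigma2_beta0 = c(2, 0.1),
                        sigma2_gamma0 = c(2, 0.01),
                        slope_sd = c(alpha = 2, beta = 1, gamma = 0.5)) {
  structure(list(mu = list(alpha0 = mu_alpha0, beta0 = mu_beta0,
                           gamma0 = mu_gamma0),
                 sigma2 = list(alpha0 = sigma2_alpha0, beta0 = sigma2_beta0,
                               gamma0 = sigma2_gamma0),
                 slope_sd = slope_sd),
            class = "hddm_priors")
}

#' Retained-draw bookkeeping of an MCMC run
#'
#' Retained draws per chain are `floor((n_samples - burn_in) / thin)`;
#' the canonical run of 5 chains x 11,000 samples with 1,000 burn-in and
#' thinning by 2 retains 25,000 draws in total.
#'
#' @param chains,n_samples,burn_in,thin Chain settings.
#' @return List with `retained_per_chain` and `retained_total`.
#' @export
mcmc_bookkeeping <- function(chains = 5, n_samples = 11000, burn_in = 1000,
                             thin = 2) {
  stopifnot(chains >= 1, n_samples > burn_in, burn_in >= 0, thin >= 1)
  per_chain <- floor((n_samples - burn_in) / thin)
  list(retained_per_chain = per_chain, retained_total = per_chain * chains)
}

# EZ-style moment initialisation of (drift, boundary, ndt) from
# accuracy, RT mean and RT variance of one subject x condition cell.
.ez_init <- function(rt, correct) {
  pc <- min(max(mean(correct), 0.55), 0.98)
  vrt <- max(var(rt), 1e-4)
  mrt <- mean(rt)
  L <- qlogis(pc)
  x <- L * (L * pc^2 - L * pc + pc - 0.5) / vrt
  v <- sign(pc - 0.5) * abs(x)^0.25
  a <- L / v
  mdt <- (a / (2 * v)) * (1 - exp(-v * a)) / (1 + exp(-v * a))
  tau <- mrt - mdt
  tau <- min(max(tau, 0.1 * min(rt)), 0.85 * min(rt))
  c(drift = v, boundary = min(max(a, 0.5), 4), ndt = tau)
}

#' Fit the hierarchical drift-diffusion model with EEG regressors
#'
#' Accuracy-coded hierarchical diffusion model: per trial the drift
#' rate, boundary separation and non-decision time are linear in the
#' trial's absolute early and late component amplitudes, with
#' per-condition coefficient sets. Subject-level intercepts are drawn
#' from group-level normal distributions (mean and variance estimated);
#' slopes are group-level. The starting point is fixed at the midpoint
#' and no inter-trial variability parameters are included.
#'
#' Sampling is adaptive Metropolis-within-Gibbs: joint random-walk
#' updates of each subject's intercept triple and of each slope pair,
#' with conjugate Gibbs draws for the group means and variances;
#' proposal scales adapt during burn-in. Proposals implying a
#' non-positive boundary or non-decision time on any observed trial have
#' zero likelihood and are rejected. The canonical run is 5 chains of
#' 11,000 samples, 1,000 burn-in, thinned by 2, leaving 25,000 retained
#' draws.
#'
#' @param design Output of [build_design()].
#' @param chains Number of Markov chains (>= 2 for diagnostics).
#' @param n_samples Samples per chain (including burn-in).
#' @param burn_in Discarded initial samples per chain.
#' @param thin Keep every `thin`-th post-burn-in sample.
#' @param seed Seed; chain `k` uses a sub-stream `seed + k`.
#' @param min_trials Minimum trials required per subject x condition.
#' @param priors An [hddm_priors()] object.
#' @param progress Print a line per chain.
#' @return An object of class `hddm_fit`: retained draws
#'   (`iterations x chains x parameters` with named parameters), a
#'   `group_param` indicator, chain metadata, and acceptance rates.
#' @export
fit_hddm <- function(design, chains = 5, n_samples = 11000, burn_in = 1000,
                     thin = 2, seed = 1, min_trials = 20,
                     priors = hddm_priors(), progress = FALSE) {
  stopifnot(is.data.frame(design), chains >= 1, n_samples > burn_in,
            thin >= 1)
  needed <- c("subject", "congruency", "rt_s", "correct", "abs_early",
              "abs_late")
  if (!all(needed %in% names(design))) {
    stop("fit_hddm: design must come from build_design() (missing: ",
         paste(setdiff(needed, names(design)), collapse = ", "), ")")
  }
  conditions <- sort(unique(as.character(design$congruency)))
  subjects <- sort(unique(design$subject))
  S <- length(subjects)
  cell_n <- table(design$subject, design$congruency)
  if (any(cell_n < min_trials)) {
    stop("fit_hddm: some subject x condition cells have fewer than ",
         min_trials, " trials")
  }
  # per-condition data blocks with internally centred regressors
  blocks <- lapply(conditions, function(cond) {
    m <- design$congruency == cond
    e <- design$abs_early[m]
    l <- design$abs_late[m]
    list(cond = cond, rt = design$rt_s[m], correct = design$correct[m],
         sidx = match(design$subject[m], subjects),
         me = mean(e), ml = mean(l), e = e - mean(e), l = l - mean(l),
         rows_by_subj = split(seq_len(sum(m)), match(design$subject[m],
                                                     subjects)))
  })
  names(blocks) <- conditions

  ll_rows <- function(bl, ridx, a0, b0, g0, sl) {
    .wfpt_loglik_cpp(bl$rt[ridx], bl$correct[ridx],
                     a0[bl$sidx[ridx]] + sl[1] * bl$e[ridx] + sl[2] * bl$l[ridx],
                     b0[bl$sidx[ridx]] + sl[3] * bl$e[ridx] + sl[4] * bl$l[ridx],
                     g0[bl$sidx[ridx]] + sl[5] * bl$e[ridx] + sl[6] * bl$l[ridx],
                     0.5)
  }
  ll_all <- function(bl, a0, b0, g0, sl) {
    .wfpt_loglik_cpp(bl$rt, bl$correct,
                     a0[bl$sidx] + sl[1] * bl$e + sl[2] * bl$l,
                     b0[bl$sidx] + sl[3] * bl$e + sl[4] * bl$l,
                     g0[bl$sidx] + sl[5] * bl$e + sl[6] * bl$l,
                     0.5)
  }

  param_names <- c(
    unlist(lapply(conditions, function(cn) {
      c(paste0(c("mu_alpha0_", "sigma2_alpha0_", "mu_beta0_", "sigma2_beta0_",
                 "mu_gamma0_", "sigma2_gamma0_"), cn),
        paste0(c("alpha1_", "alpha2_", "beta1_", "beta2_", "gamma1_",
                 "gamma2_"), cn))
    })),
    unlist(lapply(conditions, function(cn) {
      as.vector(t(outer(c("alpha0_", "beta0_", "gamma0_"),
                        paste0(subjects, "_", cn), paste0)))
    })))
  group_param <- !grepl("^(alpha0|beta0|gamma0)_", param_names)
  P <- length(param_names)
  n_ret <- mcmc_bookkeeping(chains, n_samples, burn_in, thin)$retained_per_chain

  run_chain <- function(chain_id) {
    set.seed(.substream_seed(seed, "chain", chain_id))
    # state per condition
    st <- lapply(blocks, function(bl) {
      a0 <- b0 <- g0 <- numeric(S)
      for (s in seq_len(S)) {
        ridx <- bl$rows_by_subj[[as.character(s)]]
        ez <- .ez_init(bl$rt[ridx], bl$correct[ridx])
        a0[s] <- ez[["drift"]] * exp(rnorm(1, 0, 0.1))
        b0[s] <- ez[["boundary"]] * exp(rnorm(1, 0, 0.1))
        g0[s] <- ez[["ndt"]] * runif(1, 0.8, 0.98)
      }
      sl <- rnorm(6, 0, 0.01)
      # repair any invalid starting cell
      for (s in seq_len(S)) {
        ridx <- bl$rows_by_subj[[as.character(s)]]
        tries <- 0
        while (!is.finite(ll_rows(bl, ridx, a0, b0, g0, sl)) && tries < 30) {
          g0[s] <- g0[s] * 0.8
          b0[s] <- max(b0[s], 0.5)
          tries <- tries + 1
        }
      }
      list(a0 = a0, b0 = b0, g0 = g0, sl = sl,
           mu = c(mean(a0), mean(b0), mean(g0)),
           sg2 = pmax(c(var(a0), var(b0), var(g0)), c(0.05, 0.02, 1e-4)))
    })
    ls_subj <- matrix(log(0.15), S, length(conditions))  # block log-scales
    ls_slope <- matrix(log(c(0.1, 0.05, 0.01)), 3, length(conditions),
                       byrow = FALSE)
    acc_subj <- n_subj <- matrix(0, S, length(conditions))
    acc_slope <- n_slope <- matrix(0, 3, length(conditions))
    # adaptive-Metropolis state for the joint 6-slope update: running
    # moments accumulated during burn-in, proposal covariance frozen after
    am <- lapply(seq_along(conditions), function(i) {
      list(n = 0, mean = numeric(6), m2 = matrix(0, 6, 6), ls = log(1),
           acc = 0, tries = 0, chol = NULL)
    })
    am_start <- min(200L, max(50L, burn_in %/% 4L))
    rel_subj <- c(1, 0.7, 0.15)  # relative proposal scale (drift, bound, ndt)
    draws <- matrix(NA_real_, n_ret, P, dimnames = list(NULL, param_names))
    keep <- 0
    prior_mu <- priors$mu
    prior_s2 <- priors$sigma2
    slope_sd <- priors$slope_sd[c("alpha", "alpha", "beta", "beta",
                                  "gamma", "gamma")]
    for (it in seq_len(n_samples)) {
      for (ci in seq_along(conditions)) {
        bl <- blocks[[ci]]
        stc <- st[[ci]]
        # --- subject intercept triples ---
        for (s in seq_len(S)) {
          ridx <- bl$rows_by_subj[[as.character(s)]]
          cur <- c(stc$a0[s], stc$b0[s], stc$g0[s])
          prop <- cur + rnorm(3, 0, exp(ls_subj[s, ci]) * rel_subj)
          a0p <- stc$a0; a0p[s] <- prop[1]
          b0p <- stc$b0; b0p[s] <- prop[2]
          g0p <- stc$g0; g0p[s] <- prop[3]
          lp_cur <- ll_rows(bl, ridx, stc$a0, stc$b0, stc$g0, stc$sl) +
            sum(dnorm(cur, stc$mu, sqrt(stc$sg2), log = TRUE))
          lp_prop <- ll_rows(bl, ridx, a0p, b0p, g0p, stc$sl) +
            sum(dnorm(prop, stc$mu, sqrt(stc$sg2), log = TRUE))
          n_subj[s, ci] <- n_subj[s, ci] + 1
          if (is.finite(lp_prop) && log(runif(1)) < lp_prop - lp_cur) {
            stc$a0 <- a0p; stc$b0 <- b0p; stc$g0 <- g0p
            acc_subj[s, ci] <- acc_subj[s, ci] + 1
          }
        }
        # --- slopes: pairwise random-walk early on, then joint
        #     adaptive-Metropolis updates with the learned covariance ---
        if (is.null(am[[ci]]$chol)) {
          for (tp in 1:3) {
            ix <- c(2 * tp - 1, 2 * tp)
            cur <- stc$sl[ix]
            prop_sl <- stc$sl
            prop_sl[ix] <- cur + rnorm(2, 0, exp(ls_slope[tp, ci]))
            lp_cur <- ll_all(bl, stc$a0, stc$b0, stc$g0, stc$sl) +
              sum(dnorm(stc$sl[ix], 0, slope_sd[ix], log = TRUE))
            lp_prop <- ll_all(bl, stc$a0, stc$b0, stc$g0, prop_sl) +
              sum(dnorm(prop_sl[ix], 0, slope_sd[ix], log = TRUE))
            n_slope[tp, ci] <- n_slope[tp, ci] + 1
            if (is.finite(lp_prop) && log(runif(1)) < lp_prop - lp_cur) {
              stc$sl <- prop_sl
              acc_slope[tp, ci] <- acc_slope[tp, ci] + 1
            }
          }
        } else {
          for (rep2 in 1:3) {
            step <- exp(am[[ci]]$ls) *
              as.vector(am[[ci]]$chol %*% rnorm(6))
            prop_sl <- stc$sl + step
            lp_cur <- ll_all(bl, stc$a0, stc$b0, stc$g0, stc$sl) +
              sum(dnorm(stc$sl, 0, slope_sd, log = TRUE))
            lp_prop <- ll_all(bl, stc$a0, stc$b0, stc$g0, prop_sl) +
              sum(dnorm(prop_sl, 0, slope_sd, log = TRUE))
            am[[ci]]$tries <- am[[ci]]$tries + 1
            if (is.finite(lp_prop) && log(runif(1)) < lp_prop - lp_cur) {
              stc$sl <- prop_sl
              am[[ci]]$acc <- am[[ci]]$acc + 1
            }
          }
        }
        # accumulate slope moments for the adaptive proposal
        if (it >= am_start && it <= burn_in) {
          a_ <- am[[ci]]
          a_$n <- a_$n + 1
          d_ <- stc$sl - a_$mean
          a_$mean <- a_$mean + d_ / a_$n
          a_$m2 <- a_$m2 + tcrossprod(d_, stc$sl - a_$mean)
          am[[ci]] <- a_
        }
        # --- conjugate group-level draws ---
        vals <- list(stc$a0, stc$b0, stc$g0)
        types <- c("alpha0", "beta0", "gamma0")
        for (tp in 1:3) {
          x <- vals[[tp]]
          pm <- prior_mu[[types[tp]]]
          prec <- S / stc$sg2[tp] + 1 / pm[2]^2
          mean_post <- (sum(x) / stc$sg2[tp] + pm[1] / pm[2]^2) / prec
          sd_post <- sqrt(1 / prec)
          if (tp == 1) {
            stc$mu[tp] <- rnorm(1, mean_post, sd_post)
          } else {  # boundary / ndt group means constrained positive
            u <- runif(1, pnorm(0, mean_post, sd_post), 1)
            stc$mu[tp] <- qnorm(pmin(u, 1 - 1e-12), mean_post, sd_post)
          }
          ps <- prior_s2[[types[tp]]]
          stc$sg2[tp] <- 1 / rgamma(1, shape = ps[1] + S / 2,
                                    rate = ps[2] + sum((x - stc$mu[tp])^2) / 2)
        }
        st[[ci]] <- stc
      }
      # --- adaptation during burn-in ---
      if (it <= burn_in && it %% 50 == 0) {
        batch <- it / 50
        delta <- min(0.25, 2 / sqrt(batch))
        ls_subj <- ls_subj + delta * (acc_subj / pmax(n_subj, 1) - 0.25)
        ls_slope <- ls_slope + delta * (acc_slope / pmax(n_slope, 1) - 0.25)
        acc_subj[] <- n_subj[] <- 0
        acc_slope[] <- n_slope[] <- 0
        for (ci in seq_along(conditions)) {
          a_ <- am[[ci]]
          if (a_$n >= 100) {  # switch to the joint covariance proposal
            cov_sl <- a_$m2 / (a_$n - 1) + diag(1e-10, 6)
            ch <- try(chol(cov_sl), silent = TRUE)
            if (!inherits(ch, "try-error")) {
              if (is.null(a_$chol)) a_$ls <- log(2.4 / sqrt(6))
              a_$chol <- t(ch)
            }
          }
          if (a_$tries >= 50) {
            a_$ls <- a_$ls + delta * (a_$acc / a_$tries - 0.25)
            a_$acc <- 0
            a_$tries <- 0
          }
          am[[ci]] <- a_
        }
      }
      # --- storage (de-centred intercepts) ---
      if (it > burn_in && (it - burn_in) %% thin == 0) {
        keep <- keep + 1
        row <- numeric(0)
        for (ci in seq_along(conditions)) {
          stc <- st[[ci]]
          bl <- blocks[[ci]]
          shift <- c(stc$sl[1] * bl$me + stc$sl[2] * bl$ml,
                     stc$sl[3] * bl$me + stc$sl[4] * bl$ml,
                     stc$sl[5] * bl$me + stc$sl[6] * bl$ml)
          row <- c(row, stc$mu[1] - shift[1], stc$sg2[1],
                   stc$mu[2] - shift[2], stc$sg2[2],
                   stc$mu[3] - shift[3], stc$sg2[3], stc$sl)
        }
        for (ci in seq_along(conditions)) {
          stc <- st[[ci]]
          bl <- blocks[[ci]]
          shift <- c(stc$sl[1] * bl$me + stc$sl[2] * bl$ml,
                     stc$sl[3] * bl$me + stc$sl[4] * bl$ml,
                     stc$sl[5] * bl$me + stc$sl[6] * bl$ml)
          row <- c(row, stc$a0 - shift[1], stc$b0 - shift[2],
                   stc$g0 - shift[3])
        }
        draws[keep, ] <- row
      }
    }
    list(draws = draws,
         acc = list(subject = acc_subj / pmax(n_subj, 1),
                    slope = acc_slope / pmax(n_slope, 1)))
  }

  chains_out <- vector("list", chains)
  for (k in seq_len(chains)) {
    if (progress) message("hddm chain ", k, "/", chains)
    chains_out[[k]] <- run_chain(k)
  }
  draws <- array(NA_real_, dim = c(n_ret, chains, P),
                 dimnames = list(NULL, paste0("chain", seq_len(chains)),
                                 param_names))
  for (k in seq_len(chains)) draws[, k, ] <- chains_out[[k]]$draws
  structure(list(draws = draws, param_names = param_names,
                 group_param = group_param, conditions = conditions,
                 subjects = subjects,
                 meta = list(chains = chains, n_samples = n_samples,
                             burn_in = burn_in, thin = thin,
                             retained_per_chain = n_ret,
                             retained_total = n_ret * chains, seed = seed),
                 acceptance = lapply(chains_out, `[[`, "acc")),
            class = "hddm_fit")
}

#' @export
print.hddm_fit <- function(x, ...) {
  m <- x$meta
  cat(sprintf("hddm_fit: %d chain(s) x %d samples (burn-in %d, thin %d) -> %d retained draws\n",
              m$chains, m$n_samples, m$burn_in, m$thin, m$retained_total),
      sprintf("  %d parameters (%d group-level), %d subject(s), conditions: %s\n",
              length(x$param_names), sum(x$group_param), length(x$subjects),
              paste(x$conditions, collapse = ", ")), sep = "")
  invisible(x)
}

#' Pooled posterior draws of one parameter
#'
#' @param fit An `hddm_fit`.
#' @param parameter Parameter name (see `fit$param_names`).
#' @return Numeric vector of retained draws pooled over chains.
#' @export
posterior_draws <- function(fit, parameter) {
  stopifnot(inherits(fit, "hddm_fit"))
  if (!parameter %in% fit$param_names) {
    stop("posterior_draws: unknown parameter '", parameter, "'")
  }
  as.vector(fit$draws[, , parameter])
}

#' Gelman-Rubin convergence diagnostics
#'
#' Split-chain potential scale reduction factor per parameter: each
#' chain is split in half, and the between- to within-sequence variance
#' ratio is folded into the usual R-hat statistic. The pass flag follows
#' the convergence criterion R-hat in \[0.98, 1.02\].
#'
#' @param x An `hddm_fit`, or a 3-d array `iterations x chains x
#'   parameters` (or a matrix `iterations x chains` for one parameter).
#' @param split Split each chain in half before computing R-hat.
#' @return Data frame of class `convergence_diagnostics` with columns
#'   `parameter`, `rhat`, `pass` (and `group` for fits).
#' @export
gelman_rubin <- function(x, split = TRUE) {
  group <- NULL
  if (inherits(x, "hddm_fit")) {
    group <- x$group_param
    x <- x$draws
  }
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1),
                               dimnames = list(NULL, NULL, "parameter"))
  if (dim(x)[2] < 2) stop("gelman_rubin: need at least 2 chains")
  rhat_one <- function(M) {
    if (split) {
      n2 <- floor(nrow(M) / 2)
      M <- cbind(M[seq_len(n2), , drop = FALSE],
                 M[n2 + seq_len(n2), , drop = FALSE])
    }
    n <- nrow(M)
    W <- mean(apply(M, 2, var))
    B <- n * var(colMeans(M))
    if (!is.finite(W) || W <= 0) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  }
  rhat <- vapply(seq_len(dim(x)[3]), function(p) rhat_one(x[, , p]),
                 numeric(1))
  out <- data.frame(parameter = dimnames(x)[[3]], rhat = rhat,
                    pass = rhat >= 0.98 & rhat <= 1.02)
  if (!is.null(group)) out$group <- group
  class(out) <- c("convergence_diagnostics", "data.frame")
  out
}

#' Directional posterior probability and log-odds of a coefficient
#'
#' The posterior probability that a coefficient satisfies a directional
#' hypothesis, expressed as log-odds via the logit. The proportion is
#' clipped to `[1/(M+1), M/(M+1)]` over `M` retained draws so the
#' log-odds stay finite. The decision threshold is
#' `ln(0.95/0.05) = 2.944`, the log-odds of a 5% false-positive rate.
#'
#' @param fit An `hddm_fit` (or numeric vector of draws).
#' @param coefficient Parameter name (ignored when `fit` is a vector).
#' @param direction `"greater"` (> 0) or `"less"` (< 0).
#' @return List of class `log_odds` with `probability`, `log_odds`,
#'   `threshold`, `exceeds_threshold`, `n_draws`.
#' @export
directional_log_odds <- function(fit, coefficient = NULL,
                                 direction = c("greater", "less")) {
  direction <- match.arg(direction)
  draws <- if (inherits(fit, "hddm_fit")) {
    posterior_draws(fit, coefficient)
  } else {
    as.numeric(fit)
  }
  M <- length(draws)
  p <- if (direction == "greater") mean(draws > 0) else mean(draws < 0)
  p_clip <- min(max(p, 1 / (M + 1)), M / (M + 1))
  lo <- qlogis(p_clip)
  thr <- qlogis(0.95)
  structure(list(probability = p, log_odds = lo, threshold = thr,
                 exceeds_threshold = lo > thr, n_draws = M,
                 coefficient = coefficient, direction = direction),
            class = "log_odds")
}

#' @export
print.log_odds <- function(x, ...) {
  cat(sprintf("P(%s %s 0) = %.3f, log-odds = %.3f (threshold %.3f: %s)\n",
              if (is.null(x$coefficient)) "coefficient" else x$coefficient,
              if (x$direction == "greater") ">" else "<",
              x$probability, x$log_odds, x$threshold,
              if (x$exceeds_threshold) "exceeds" else "does not exceed"))
  invisible(x)
}

#' Posterior predictive RT quantiles by condition and correctness
#'
#' Simulates choices and RTs from posterior draws (trial-level
#' parameters rebuilt from each draw's subject intercepts and slopes)
#' and compares RT quantiles of the simulated data with the observed
#' data in every condition x correctness cell.
#'
#' @param design The [build_design()] table the model was fitted to.
#' @param fit The `hddm_fit`.
#' @param n_draws Posterior draws to simulate from.
#' @param quantiles Probabilities of the RT quantiles.
#' @param seed Optional seed.
#' @param dt Simulator step (s).
#' @return Data frame with `congruency`, `correct`, `prob`,
#'   `observed_rt_s`, `predicted_rt_s`; empty observed cells are
#'   flagged `NA` with a warning.
#' @export
posterior_predictive <- function(design, fit, n_draws = 100,
                                 quantiles = c(0.1, 0.3, 0.5, 0.7, 0.9),
                                 seed = NULL, dt = 1e-3) {
  stopifnot(inherits(fit, "hddm_fit"))
  run <- function() {
    total <- dim(fit$draws)[1] * dim(fit$draws)[2]
    pick <- sample.int(total, min(n_draws, total))
    flat <- matrix(fit$draws, nrow = total,
                   dimnames = list(NULL, fit$param_names))
    sim_rt <- vector("list", length(pick))
    sim_up <- vector("list", length(pick))
    sim_cond <- vector("list", length(pick))
    sidx <- match(design$subject, fit$subjects)
    for (j in seq_along(pick)) {
      dr <- flat[pick[j], ]
      v <- a <- tau <- numeric(nrow(design))
      for (cond in fit$conditions) {
        m <- design$congruency == cond
        nm <- function(base) paste0(base, "_", fit$subjects, "_", cond)
        v[m] <- dr[nm("alpha0")][sidx[m]] +
          dr[paste0("alpha1_", cond)] * design$abs_early[m] +
          dr[paste0("alpha2_", cond)] * design$abs_late[m]
        a[m] <- dr[nm("beta0")][sidx[m]] +
          dr[paste0("beta1_", cond)] * design$abs_early[m] +
          dr[paste0("beta2_", cond)] * design$abs_late[m]
        tau[m] <- dr[nm("gamma0")][sidx[m]] +
          dr[paste0("gamma1_", cond)] * design$abs_early[m] +
          dr[paste0("gamma2_", cond)] * design$abs_late[m]
      }
      ok <- a > 0.05 & tau >= 0
      sim <- .ddm_sim_cpp(v[ok], pmax(a[ok], 0.05), pmax(tau[ok], 0),
                          0.5, dt, sum(ok))
      sim_rt[[j]] <- sim$rt
      sim_up[[j]] <- sim$upper
      sim_cond[[j]] <- design$congruency[ok]
    }
    pred <- data.frame(congruency = unlist(sim_cond),
                       correct = unlist(sim_up), rt = unlist(sim_rt))
    cells <- expand.grid(congruency = fit$conditions,
                         correct = c(TRUE, FALSE), prob = quantiles,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    cells$observed_rt_s <- NA_real_
    cells$predicted_rt_s <- NA_real_
    for (i in seq_len(nrow(cells))) {
      mo <- design$congruency == cells$congruency[i] &
        design$correct == cells$correct[i]
      mp <- pred$congruency == cells$congruency[i] &
        pred$correct == cells$correct[i]
      if (any(mo)) {
        cells$observed_rt_s[i] <- quantile(design$rt_s[mo], cells$prob[i],
                                           names = FALSE)
      }
      if (any(mp)) {
        cells$predicted_rt_s[i] <- quantile(pred$rt[mp], cells$prob[i],
                                            names = FALSE)
      }
    }
    if (anyNA(cells$observed_rt_s)) {
      warning("posterior_predictive: some condition x correctness cells ",
              "have no observed trials")
    }
    cells[order(cells$congruency, !cells$correct, cells$prob), ]
  }
  if (is.null(seed)) run() else {
    .local_seed(.substream_seed(seed, "predictive"), run())
  }
}
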