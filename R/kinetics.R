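## Weighted alternating Gauss-Newton fit of level = plateau*(1 - exp(-k_i tau_j))
## on a (contexts x reactions) level matrix M with weight matrix W.
## tau can be frozen (fixed_tau). Internal workhorse shared by the NNCGNN and
## CpN-class fitters.
fit_progress_curves <- function(M, W, plateau_mode = c("fixed_1", "fitted"),
                                fixed_tau = NULL, n_restarts = 3L,
                                seed = NULL, max_iter = 1000L,
                                rel_tol = 1e-10) {
  plateau_mode <- match.arg(plateau_mode)
  if (!is.null(seed)) set.seed(seed)
  nI <- nrow(M); nJ <- ncol(M)
  obs <- W > 0 & is.finite(M)
  W[!obs] <- 0

  sse_fun <- function(k, tau, P) {
    model <- P * (1 - exp(-outer(k, tau)))
    sum(W * (M - model)^2)
  }

  ## closed-form per-context initial estimate at given tau
  closed_form_k <- function(tau, P) {
    mm <- pmin(M / P, 0.9999)
    kk <- -log(1 - mm) / rep(tau, each = nI)
    kk[!obs] <- NA
    rowMeans(kk, na.rm = TRUE)
  }

  run_once <- function(jitter_sd) {
    P <- 1
    tau <- if (is.null(fixed_tau)) {
      ## reaction-level scale from its weighted mean level
      mbar <- colSums(W * M) / pmax(colSums(W), .Machine$double.eps)
      pmax(-log(1 - pmin(mbar / P, 0.999)), 1e-6)
    } else fixed_tau
    k <- pmax(closed_form_k(tau, P), 0)
    k[!is.finite(k)] <- 1
    if (jitter_sd > 0) {
      k <- k * exp(stats::rnorm(nI, 0, jitter_sd))
      if (is.null(fixed_tau)) tau <- tau * exp(stats::rnorm(nJ, 0, jitter_sd))
    }
    sse <- sse_fun(k, tau, P)
    for (it in seq_len(max_iter)) {
      ## k-block Gauss-Newton with backtracking
      E <- exp(-outer(k, tau))
      R <- M - P * (1 - E); R[!obs] <- 0
      D <- P * E * rep(tau, each = nI)          # d model / d k
      num <- rowSums(W * R * D)
      den <- rowSums(W * D^2)
      delta <- ifelse(den > 0, num / den, 0)
      step <- 1
      repeat {
        k_new <- pmax(k + step * delta, 0)
        s_new <- sse_fun(k_new, tau, P)
        if (s_new <= sse || step < 1e-8) break
        step <- step / 2
      }
      if (s_new <= sse) { k <- k_new; sse <- s_new }

      ## tau-block
      if (is.null(fixed_tau)) {
        E <- exp(-outer(k, tau))
        R <- M - P * (1 - E); R[!obs] <- 0
        D <- P * E * k                          # d model / d tau
        num <- colSums(W * R * D)
        den <- colSums(W * D^2)
        delta <- ifelse(den > 0, num / den, 0)
        step <- 1
        repeat {
          tau_new <- pmax(tau + step * delta, 0)
          s_new <- sse_fun(k, tau_new, P)
          if (s_new <= sse || step < 1e-8) break
          step <- step / 2
        }
        if (s_new <= sse) { tau <- tau_new; sse <- s_new }
      }

      ## plateau block: model is linear in P
      if (plateau_mode == "fitted") {
        A <- 1 - exp(-outer(k, tau)); A[!obs] <- 0
        P_new <- sum(W * M * A) / max(sum(W * A^2), .Machine$double.eps)
        P_new <- min(max(P_new, 1e-6), 1)
        s_new <- sse_fun(k, tau, P_new)
        if (s_new <= sse) { P <- P_new; sse <- s_new }
      }

      if (it > 1 && (sse_prev - sse) <= rel_tol * max(sse_prev, 1e-300)) break
      sse_prev <- sse
    }
    list(k = k, tau = tau, plateau = P, sse = sse)
  }

  fits <- lapply(seq_len(n_restarts), function(r)
    run_once(jitter_sd = if (r == 1L) 0 else 0.3))
  sses <- vapply(fits, `[[`, numeric(1), "sse")
  best <- fits[[which.min(sses)]]
  agree <- sum(sses - min(sses) <= 1e-6 * max(min(sses), 1e-12))
  best$n_restarts_agreeing <- agree
  best$converged <- agree >= min(3L, n_restarts)
  best
}

#' Fit NNCGNN methylation rate constants on a virtual time axis
#'
#' Fits per-context methylation levels observed across several independent
#' reactions (different enzyme concentrations / incubation times) to
#' monoexponential reaction progress curves
#' `level = plateau * (1 - exp(-k_context * tau_reaction))`, where each
#' reaction contributes one latent "virtual time" absorbing its enzyme
#' concentration and incubation time so the 256 rate constants are comparable
#' across reactions. The weighted least-squares objective (weights = total
#' read counts per context) is minimised by multi-start alternating
#' (serial) Gauss-Newton refinement of the k and tau blocks, initialised from
#' single-reaction closed-form estimates; the fit is flagged converged only
#' when the random restarts agree in SSE. The gauge is fixed by scaling the
#' geometric mean of the fitted rate constants to 1 (relative rates), with
#' virtual times rescaled inversely.
#'
#' @param levels_list list of per-reaction context-level tables as returned
#'   by [context_levels()] (columns context, n_meth, n_total, level).
#' @param plateau_mode `"fixed_1"` (default) or `"fitted"` (one global
#'   plateau for incomplete conversion).
#' @param min_count minimum total reads per context per reaction for the
#'   observation to enter the fit (default 10).
#' @param fix_tau optional numeric vector freezing the virtual times (e.g.
#'   `1` for the single-reaction closed form `k = -ln(1 - level)`).
#' @param n_restarts number of random restarts (default 3).
#' @param seed RNG seed for restart jitter.
#' @return an object of class `rate_table`: named `k` (relative rates,
#'   geometric mean 1 over fitted contexts; 0 / `Inf` sentinels for contexts
#'   stuck at 0 / plateau), `tau`, `plateau`, `residual_sse`, `converged`,
#'   `n_restarts_agreeing`, `excluded_contexts`, `flagged` (sentinel
#'   contexts).
#' @export
fit_virtual_time_rates <- function(levels_list,
                                   plateau_mode = c("fixed_1", "fitted"),
                                   min_count = 10L, fix_tau = NULL,
                                   n_restarts = 3L, seed = NULL) {
  plateau_mode <- match.arg(plateau_mode)
  if (is.data.frame(levels_list)) levels_list <- list(levels_list)
  nJ <- length(levels_list)
  ctx <- sort(unique(unlist(lapply(levels_list, `[[`, "context"))))
  M <- matrix(NA_real_, length(ctx), nJ, dimnames = list(ctx, NULL))
  W <- matrix(0, length(ctx), nJ, dimnames = list(ctx, NULL))
  for (j in seq_len(nJ)) {
    lv <- levels_list[[j]]
    i <- match(lv$context, ctx)
    M[i, j] <- lv$level
    W[i, j] <- lv$n_total
  }
  W[W < min_count] <- 0

  min_reactions <- if (nJ == 1L || !is.null(fix_tau)) 1L else 2L
  n_obs <- rowSums(W > 0)
  excluded <- ctx[n_obs < min_reactions]
  keep <- n_obs >= min_reactions
  M <- M[keep, , drop = FALSE]; W <- W[keep, , drop = FALSE]
  if (nrow(M) == 0L) stop("no context has enough observations to fit")

  ## degenerate contexts: never methylated -> k = 0; always at plateau -> Inf
  obs <- W > 0
  zero_ctx <- rownames(M)[rowSums(obs & M > 0) == 0]
  plateau_guess <- if (plateau_mode == "fixed_1") 1 else max(M[obs])
  sat_ctx <- rownames(M)[apply(obs & (M < plateau_guess - 1e-12), 1, sum) == 0]
  sat_ctx <- setdiff(sat_ctx, zero_ctx)
  fit_ctx <- setdiff(rownames(M), c(zero_ctx, sat_ctx))
  if (length(fit_ctx) == 0L) stop("all contexts degenerate (all 0 or all at plateau)")

  fit <- fit_progress_curves(M[fit_ctx, , drop = FALSE],
                             W[fit_ctx, , drop = FALSE],
                             plateau_mode = plateau_mode,
                             fixed_tau = fix_tau,
                             n_restarts = n_restarts, seed = seed)

  k <- stats::setNames(rep(NA_real_, nrow(M)), rownames(M))
  k[fit_ctx] <- fit$k
  k[zero_ctx] <- 0
  k[sat_ctx] <- Inf

  ## gauge: geometric mean of fitted (finite, positive) rates = 1
  g <- geomean(k[fit_ctx])
  tau <- fit$tau
  if (is.finite(g) && g > 0 && is.null(fix_tau)) {
    k[fit_ctx] <- k[fit_ctx] / g
    tau <- tau * g
  }
  structure(list(k = k,
                 tau = stats::setNames(tau, paste0("reaction_", seq_along(tau))),
                 plateau = fit$plateau,
                 residual_sse = fit$sse,
                 converged = fit$converged,
                 n_restarts_agreeing = fit$n_restarts_agreeing,
                 excluded_contexts = excluded,
                 flagged = list(zero = zero_ctx, saturated = sat_ctx)),
            class = "rate_table")
}

#' @export
print.rate_table <- function(x, ...) {
  kf <- x$k[is.finite(x$k) & x$k > 0]
  cat(sprintf("rate_table: %d contexts (%d fitted), %d reactions, plateau %.3f\n",
              length(x$k), length(kf), length(x$tau), x$plateau))
  cat(sprintf("  SSE %.4g, converged %s (%d restarts agree)\n",
              x$residual_sse, x$converged, x$n_restarts_agreeing))
  if (length(kf)) {
    cat(sprintf("  max rate: %s (%.3g)  min rate: %s (%.3g)  ratio %.1f\n",
                names(kf)[which.max(kf)], max(kf),
                names(kf)[which.min(kf)], min(kf), max(kf) / min(kf)))
  }
  invisible(x)
}

#' Fit CpN class rates relative to CpG
#'
#' Same monoexponential model at CpG/CpA/CpT/CpC class granularity. When a
#' `shared_tau` rate table is given (from the CpG fit), the virtual times are
#' frozen to it so the class rates are directly comparable; otherwise class
#' rates and virtual times are fitted jointly. Rates are reported relative to
#' CpG = 1.
#'
#' @param class_levels list of per-reaction data.frames with columns
#'   `class` (CpG/CpA/CpT/CpC), `n_meth`, `n_total`, `level`.
#' @param shared_tau optional `rate_table` whose `tau` is reused.
#' @param ... passed to the fitter (e.g. `n_restarts`, `seed`).
#' @return named numeric vector of relative class rates (CpG = 1), with the
#'   underlying fit in attribute `"fit"`.
#' @export
fit_cpn_class_rates <- function(class_levels, shared_tau = NULL, ...) {
  ll <- lapply(class_levels, function(d) {
    data.frame(context = d$class, n_meth = d$n_meth, n_total = d$n_total,
               level = d$level, stringsAsFactors = FALSE)
  })
  fix_tau <- if (!is.null(shared_tau)) unname(shared_tau$tau) else NULL
  fit <- fit_virtual_time_rates(ll, min_count = 1L, fix_tau = fix_tau, ...)
  if (!"CpG" %in% names(fit$k) || !is.finite(fit$k[["CpG"]]) ||
      fit$k[["CpG"]] <= 0)
    stop("CpG class rate unavailable; cannot normalise")
  rel <- fit$k / fit$k[["CpG"]]
  attr(rel, "fit") <- fit
  rel
}

#' Initial-rate linear regression
#'
#' Ordinary least-squares fit of signal (incorporated radioactivity) against
#' time over the initial linear phase of a reaction progress curve. Duplicate
#' time points are collapsed to their mean signal.
#'
#' @param time numeric, strictly increasing after collapsing duplicates.
#' @param signal numeric, same length.
#' @return list (class `initial_rate`): `slope`, `intercept`, `r_squared`,
#'   `slope_se`, `n_points`.
#' @export
initial_rate <- function(time, signal) {
  stopifnot(length(time) == length(signal))
  if (anyDuplicated(time)) {
    signal <- tapply(signal, time, mean)
    time <- as.numeric(names(signal))
    signal <- as.numeric(signal)
  }
  if (length(time) < 3L) stop("need >= 3 (distinct) time points")
  if (is.unsorted(time, strictly = TRUE)) {
    o <- order(time); time <- time[o]; signal <- signal[o]
  }
  fit <- stats::lm(signal ~ time)
  ## summary.lm warns on exact lines ("essentially perfect fit"); exact
  ## calibration data are legitimate input here
  sm <- suppressWarnings(summary(fit))
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 slope_se = sm$coefficients[2, 2],
                 n_points = length(time)),
            class = "initial_rate")
}

#' Central-site rate from a hemimethylated/fully-methylated substrate pair
#'
#' In a radioactive assay the hm substrate exposes the central CpG cytosine
#' for methylation while the fm substrate does not; all non-CpG background
#' activity is common to both. The difference of initial-rate slopes
#' therefore isolates the methylation rate of the central site. The standard
#' error is propagated in quadrature; a negative difference is allowed but
#' flagged.
#'
#' @param hm,fm `initial_rate` results for the hm and fm substrates.
#' @return list: `rate`, `se`, `negative_flag`.
#' @export
hm_fm_difference <- function(hm, fm) {
  stopifnot(inherits(hm, "initial_rate"), inherits(fm, "initial_rate"))
  rate <- hm$slope - fm$slope
  list(rate = rate,
       se = sqrt(hm$slope_se^2 + fm$slope_se^2),
       negative_flag = rate < 0)
}

#' Predict the average flanking-preference of a substrate sequence
#'
#' Looks up the NNCGNN relative rate of every CpG site in the sequence on
#' both strands (the lower-strand context is the reverse complement) and
#' returns the mean over all strand-sites. CpGs without a full -2..+3 context
#' are skipped and counted.
#'
#' @param sequence DNA string with at least one internal CpG.
#' @param rates a `rate_table` or named context -> rate vector.
#' @return list: `mean_rate`, `per_site` (data.frame pos, strand, context,
#'   rate), `n_skipped`.
#' @export
predict_substrate_preference <- function(sequence, rates) {
  k <- if (inherits(rates, "rate_table")) rates$k else rates
  n <- nchar(sequence)
  starts <- BiocGenerics::start(
    Biostrings::matchPattern("CG", Biostrings::DNAString(sequence)))
  usable <- starts[starts >= 3L & starts + 3L <= n]
  n_skipped <- length(starts) - length(usable)
  if (!length(usable)) stop("no CpG with a full -2..+3 context")
  ctx_up <- substring(sequence, usable - 2L, usable + 3L)
  ctx_lo <- revcomp(ctx_up)
  per_site <- data.frame(
    pos = rep(usable, 2L),
    strand = rep(c("+", "-"), each = length(usable)),
    context = c(ctx_up, ctx_lo),
    rate = unname(k[c(ctx_up, ctx_lo)]),
    stringsAsFactors = FALSE)
  if (anyNA(per_site$rate))
    stop("rate table missing context(s): ",
         paste(unique(per_site$context[is.na(per_site$rate)]), collapse = ", "))
  list(mean_rate = mean(per_site$rate), per_site = per_site,
       n_skipped = n_skipped)
}
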