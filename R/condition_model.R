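#' Prepare a modelling frame from the observation table
#'
#' Encodes the factors used by the candidate models: reproductive status
#' (\code{solitary} vs \code{with_young}), diet class 1 (\code{high} = high
#' consumption of both pine nuts and salmon, else \code{other}), diet class 2
#' (\code{low} = low consumption of both, else \code{other}) and the two
#' random-intercept factors year and bear.
#'
#' @param observations output of \code{\link{build_observations}}.
#' @return data.frame ready for \code{\link{fit_condition_gamm}}.
#' @export
condition_model_frame <- function(observations) {
  req <- c("bear_id", "year", "session", "th_htl", "status", "diet1", "diet2")
  miss <- setdiff(req, names(observations))
  if (length(miss))
    stop("observations are missing column(s): ", paste(miss, collapse = ", "))
  data.frame(
    th_htl = observations$th_htl,
    session = as.numeric(observations$session),
    status = factor(observations$status, levels = c("solitary", "with_young")),
    diet1 = factor(ifelse(observations$diet1, "high", "other"),
                   levels = c("high", "other")),
    diet2 = factor(ifelse(observations$diet2, "low", "other"),
                   levels = c("low", "other")),
    year_f = factor(observations$year),
    bear_f = factor(observations$bear_id)
  )
}

#' The candidate model set
#'
#' The thirteen candidate specifications compared by AICc: a thin-plate
#' smooth of session (optionally one smooth per level of reproductive status
#' or a diet class), fixed effects among reproductive status, diet class 1 or
#' 2 and their interaction, and crossed random intercepts for year and bear
#' in every model.
#'
#' @return list of specs, each with \code{name}, \code{smooth_by} (NULL or a
#'   factor name) and \code{fixed} (NULL or an R formula fragment).
#' @export
candidate_models <- function() {
  spec <- function(smooth_by, fixed) {
    nm <- paste0(
      if (is.null(smooth_by)) "s(session)" else sprintf("s(session,by=%s)", smooth_by),
      if (is.null(fixed)) "" else paste0(" + ", fixed),
      " + re(year) + re(id)")
    list(name = nm, smooth_by = smooth_by, fixed = fixed)
  }
  list(
    spec("diet1", "status * diet1"),
    spec("status", "status * diet2"),
    spec("status", "status * diet1"),
    spec("status", "status"),
    spec(NULL, "status * diet2"),
    spec(NULL, "status * diet1"),
    spec("diet2", "status * diet2"),
    spec(NULL, "status"),
    spec("diet1", "diet1"),
    spec(NULL, "diet1"),
    spec(NULL, NULL),
    spec(NULL, "diet2"),
    spec("diet2", "diet2")
  )
}

#' Fit one candidate body-condition GAMM
#'
#' Fits TH:HTL with a gamma family and log link: a thin-plate regression
#' spline of session (one centered smooth per level when \code{smooth_by} is
#' a factor, each with its own smoothing parameter), the requested fixed
#' terms, and crossed random intercepts for year and bear ID expressed as
#' ridge-penalized ("re") smooths. Smoothing and variance parameters are
#' selected by REML unless fixed via \code{sp}.
#'
#' @param observations output of \code{\link{build_observations}}, or a frame
#'   from \code{\link{condition_model_frame}}.
#' @param smooth_by NULL, \code{"status"}, \code{"diet1"} or \code{"diet2"}.
#' @param fixed NULL or a formula fragment such as \code{"status * diet1"}.
#' @param k basis dimension of each session smooth (default 5; capped at the
#'   number of distinct session values).
#' @param sp optional fixed smoothing parameters passed to \code{mgcv::gam}.
#' @param method smoothing-selection criterion (default \code{"REML"}).
#' @param aicc_mode effective-parameter accounting for AICc; see
#'   \code{\link{compute_aicc}}.
#' @return object of class \code{bear_gamm}.
#' @export
fit_condition_gamm <- function(observations, smooth_by = NULL, fixed = NULL,
                               k = 5, sp = NULL, method = "REML",
                               aicc_mode = c("edf", "params")) {
  aicc_mode <- match.arg(aicc_mode)
  if (k < 3) stop("basis dimension k must be at least 3")
  df <- if ("th_htl" %in% names(observations) && "year_f" %in% names(observations))
    observations else condition_model_frame(observations)
  if (any(!is.finite(df$th_htl)) || any(df$th_htl <= 0))
    stop("response TH:HTL must be strictly positive")
  k <- min(k, length(unique(df$session)))
  if (!is.null(smooth_by)) {
    if (!smooth_by %in% c("status", "diet1", "diet2"))
      stop("smooth_by must be one of status, diet1, diet2")
    counts <- table(df[[smooth_by]])
    if (any(counts == 0))
      stop("no observations for ", smooth_by, " level '",
           names(counts)[counts == 0][1], "' in a by-factor smooth")
  }
  smooth_term <- if (is.null(smooth_by))
    sprintf("s(session, k = %d, bs = 'tp')", k)
  else
    sprintf("s(session, k = %d, bs = 'tp', by = %s)", k, smooth_by)
  rhs <- paste(c(smooth_term, fixed,
                 "s(year_f, bs = 're')", "s(bear_f, bs = 're')"),
               collapse = " + ")
  form <- stats::as.formula(paste("th_htl ~", rhs))
  fit <- mgcv::gam(form, family = stats::Gamma(link = "log"), data = df,
                   method = method, sp = sp)
  out <- structure(list(gam = fit,
                        smooth_by = smooth_by, fixed = fixed, k = k,
                        name = candidate_name(smooth_by, fixed),
                        n = length(fit$y),
                        converged = isTRUE(fit$converged),
                        aicc_mode = aicc_mode,
                        data = df),
                   class = "bear_gamm")
  if (!out$converged)
    warning("GAMM did not converge: ", out$name)
  out$k_eff <- effective_parameters(fit, mode = aicc_mode)
  out$aicc <- compute_aicc(out)
  out
}

candidate_name <- function(smooth_by, fixed) {
  paste0(if (is.null(smooth_by)) "s(session)"
         else sprintf("s(session,by=%s)", smooth_by),
         if (is.null(fixed)) "" else paste0(" + ", fixed),
         " + re(year) + re(id)")
}

#' @export
print.bear_gamm <- function(x, ...) {
  cat("<bear_gamm>", x$name, "\n")
  cat(sprintf("  n = %d, k_eff = %.2f, AICc = %.2f, converged = %s\n",
              x$n, x$k_eff, x$aicc, x$converged))
  invisible(x)
}

is_re_smooth <- function(s) inherits(s, "random.effect")

effective_parameters <- function(gam_fit, mode = c("edf", "params")) {
  mode <- match.arg(mode)
  sm <- gam_fit$smooth
  if (mode == "params")
    return(length(coef(gam_fit)) + length(gam_fit$sp) + 1)
  re <- vapply(sm, is_re_smooth, logical(1))
  blocks <- lapply(sm, function(s) s$first.para:s$last.para)
  n_fixed <- length(coef(gam_fit)) - length(unlist(blocks))
  edf_smooth <- if (any(!re)) sum(gam_fit$edf[unlist(blocks[!re])]) else 0
  # fixed coefficients + smooth edf + one variance parameter per random
  # intercept factor + the gamma dispersion parameter
  n_fixed + edf_smooth + sum(re) + 1
}

#' Fit a single penalized session smooth in isolation
#'
#' Exposes the penalized-regression core used by the condition models on one
#' predictor, without random effects: a thin-plate regression spline of
#' \code{x} with optional fixed smoothing parameter and arbitrary family.
#' With a Gaussian family, identity link and fixed smoothing parameter the
#' coefficients equal the generalized-ridge closed form
#' \code{solve(X'X + lambda*S, X'y)}, which is useful for calibration checks.
#'
#' @param x,y predictor and response vectors.
#' @param k basis dimension (default 5).
#' @param sp optional fixed smoothing parameter.
#' @param family a \code{stats::family} (default \code{gaussian()}).
#' @return a fitted \code{mgcv::gam} object.
#' @export
fit_session_smooth <- function(x, y, k = 5, sp = NULL, family = stats::gaussian()) {
  if (k < 3) stop("basis dimension k must be at least 3")
  df <- data.frame(x = x, y = y)
  mgcv::gam(y ~ s(x, k = k, bs = "tp"), data = df, family = family,
            sp = sp, method = "REML")
}

#' Small-sample corrected AIC
#'
#' \code{aicc(ll, k, n) = -2*ll + 2*k + 2*k*(k + 1)/(n - k - 1)}.
#'
#' @param loglik log-likelihood.
#' @param k_eff effective number of parameters.
#' @param n number of observations; must exceed \code{k_eff + 1}.
#' @return AICc value.
#' @export
aicc <- function(loglik, k_eff, n) {
  if (n <= k_eff + 1)
    stop("AICc correction undefined: n must exceed k_eff + 1")
  -2 * loglik + 2 * k_eff + 2 * k_eff * (k_eff + 1) / (n - k_eff - 1)
}

#' AICc of a fitted body-condition GAMM
#'
#' Effective parameters count the strictly parametric coefficients, the
#' summed effective degrees of freedom of the session smooths, one variance
#' parameter per random-intercept factor, and the dispersion parameter
#' (\code{mode = "edf"}, the default), or simply every coefficient plus every
#' smoothing/variance parameter plus dispersion (\code{mode = "params"}).
#'
#' @param fit a \code{bear_gamm}.
#' @param mode \code{"edf"} or \code{"params"}.
#' @return AICc value.
#' @export
compute_aicc <- function(fit, mode = NULL) {
  stopifnot(inherits(fit, "bear_gamm"))
  mode <- if (is.null(mode)) fit$aicc_mode else match.arg(mode, c("edf", "params"))
  k_eff <- effective_parameters(fit$gam, mode = mode)
  aicc(as.numeric(logLik(fit$gam)), k_eff, fit$n)
}

#' Akaike weights
#'
#' \code{w_i = exp(-delta_i/2) / sum_j exp(-delta_j/2)} with
#' \code{delta_i = x_i - min(x)}; \code{x} may be AICc values or deltas.
#'
#' @param x numeric vector of AICc values (or AICc differences).
#' @return numeric vector of weights summing to 1.
#' @export
akaike_weights <- function(x) {
  d <- x - min(x)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Rank candidate fits by AICc
#'
#' @param fits list of \code{bear_gamm} objects.
#' @return data.frame \code{model, aicc, delta, weight}, sorted ascending by
#'   AICc, of class \code{selection_table}.
#' @export
rank_models <- function(fits) {
  stopifnot(length(fits) >= 1)
  a <- vapply(fits, function(f) f$aicc, numeric(1))
  nm <- vapply(fits, function(f) f$name, character(1))
  out <- data.frame(model = nm, aicc = a, delta = a - min(a),
                    weight = akaike_weights(a))
  out <- out[order(out$aicc), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("selection_table", "data.frame")
  out
}

#' Population-level prediction curves with confidence bands
#'
#' Predicts mean TH:HTL over a session grid for every combination of the
#' factor levels used by the model, with random intercepts set to zero
#' (population-level curves). Bands are the inverse-link transform of the
#' linear predictor plus/minus 1.96 standard errors.
#'
#' @param fit a \code{bear_gamm}.
#' @param sessions numeric grid (default 101 points over the observed range;
#'   values outside the observed range trigger an extrapolation warning).
#' @return data.frame with the group factors, \code{session, mean, lo95,
#'   hi95}.
#' @export
predict_curve <- function(fit, sessions = NULL) {
  stopifnot(inherits(fit, "bear_gamm"))
  df <- fit$data
  rng <- range(df$session)
  if (is.null(sessions)) sessions <- seq(rng[1], rng[2], length.out = 101)
  if (any(sessions < rng[1] | sessions > rng[2]))
    warning("prediction grid extends outside the observed session range")
  used <- intersect(c("status", "diet1", "diet2"),
                    all.vars(stats::formula(fit$gam)))
  grid <- expand.grid(c(list(session = sessions),
                        lapply(df[used], function(f) factor(levels(f), levels(f)))),
                      stringsAsFactors = FALSE)
  grid$year_f <- df$year_f[1]
  grid$bear_f <- df$bear_f[1]
  re_labels <- vapply(Filter(is_re_smooth, fit$gam$smooth),
                      function(s) s$label, character(1))
  pr <- predict(fit$gam, newdata = grid, type = "link", se.fit = TRUE,
                exclude = re_labels, newdata.guaranteed = TRUE)
  linkinv <- fit$gam$family$linkinv
  out <- grid[, c(used, "session"), drop = FALSE]
  out$mean <- linkinv(as.numeric(pr$fit))
  out$lo95 <- linkinv(as.numeric(pr$fit) - 1.96 * as.numeric(pr$se.fit))
  out$hi95 <- linkinv(as.numeric(pr$fit) + 1.96 * as.numeric(pr$se.fit))
  rownames(out) <- NULL
  out
}

#' Per-smooth effective degrees of freedom and approximate significance
#'
#' Returns the effective degrees of freedom and the Wald-type F statistic and
#' p-value for each session smooth (random-intercept terms are omitted). A
#' significant F indicates nonlinearity. The p-values are approximate, as is
#' usual for penalized smooths.
#'
#' @param fit a \code{bear_gamm}.
#' @return data.frame \code{term, edf, f, p}.
#' @export
smooth_summary <- function(fit) {
  stopifnot(inherits(fit, "bear_gamm"))
  s <- summary(fit$gam)
  tab <- s$s.table
  re <- vapply(fit$gam$smooth, is_re_smooth, logical(1))
  tab <- tab[!re, , drop = FALSE]
  data.frame(term = rownames(tab), edf = tab[, "edf"],
             f = tab[, "F"], p = tab[, "p-value"], row.names = NULL)
}

#' Parametric coefficient table of a fitted GAMM
#'
#' @param fit a \code{bear_gamm}.
#' @return data.frame \code{term, beta, se, t, p}.
#' @export
coef_summary <- function(fit) {
  stopifnot(inherits(fit, "bear_gamm"))
  tab <- summary(fit$gam)$p.table
  data.frame(term = rownames(tab), beta = tab[, "Estimate"],
             se = tab[, "Std. Error"], t = tab[, "t value"],
             p = tab[, "Pr(>|t|)"], row.names = NULL)
}
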