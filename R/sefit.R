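# Semi-experimental structure refinement: derive SE rotational constants from
# measured ground-state constants and computed vibrational contributions,
# then refine internal coordinates by weighted nonlinear least squares over
# isotopologues, optionally stabilized by predicate observations (the mixed
# regression model).

#' Semi-experimental rotational constant
#'
#' \eqn{B^{SE} = B^0 - \Delta B^{vib}} per inertial axis; the uncertainty of
#' the ground-state constant is propagated unchanged (the vibrational
#' contribution is treated as exact input).
#'
#' @param b0 Ground-state constant(s), MHz; numeric vector.
#' @param dvib Vibrational contribution(s) with the convention
#'   \eqn{\Delta B^{vib} = B^0 - B^e}, MHz; same length as `b0`.
#' @param sigma Optional uncertainties of `b0`, MHz.
#' @return Tibble with `B_se` and `sigma`.
#' @export
#' @examples
#' se_constant(3071.437, -29.267)$B_se  # 3100.704
se_constant <- function(b0, dvib, sigma = 0) {
  stopifnot(length(b0) == length(dvib), all(b0 > 0), all(sigma >= 0))
  tibble::tibble(B_se = b0 - dvib, sigma = rep_len(sigma, length(b0)))
}

#' Forward model: constants and moments for a set of isotopologues
#'
#' The geometry is isotope-independent: Cartesians are built once and only
#' the masses change per isotopologue.
#'
#' @param sd A [structure_def()].
#' @param isotopologues Named list of override vectors (see
#'   [isotopologue_masses()]); an empty vector is the parent.
#' @return Tibble with `iso`, `axis`, `B_MHz`, `I_amuA2`.
#' @export
predict_observables <- function(sd, isotopologues = list(parent = integer())) {
  geom <- build_cartesian(sd)
  rows <- purrr::imap(isotopologues, function(ov, nm) {
    rc <- rotational_constants(geom, isotopologue_masses(sd, ov))
    tibble::tibble(iso = nm, axis = c("a", "b", "c"),
                   B_MHz = c(rc$A, rc$B, rc$C),
                   I_amuA2 = c(rc$Ia, rc$Ib, rc$Ic))
  })
  dplyr::bind_rows(rows)
}

#' Specify a structure refinement
#'
#' @param sd Initial-guess [structure_def()].
#' @param free Character vector of free parameter ids (must exist in `sd`);
#'   all other parameters are held fixed.
#' @param observations Tibble with columns `iso`, `axis` (`"a"/"b"/"c"`),
#'   `B_se` (MHz) and optionally `sigma` (MHz) and `weight` (multiplicative,
#'   default 1); axes may be omitted per isotopologue to drop them from the
#'   fit.
#' @param isotopologues Named list of mass-number override vectors, names
#'   matching `observations$iso`.
#' @param predicates Optional tibble with `param`, `value`, `sigma`
#'   (Angstrom or degrees): theoretical parameter values entering the least
#'   squares as extra observations.
#' @param residual_space `"moments"` (amu A^2; default) or `"constants"`
#'   (MHz).
#' @param max_iter,ftol,xtol Optimizer controls: iteration cap, relative
#'   objective-decrease tolerance, step-norm tolerance.
#' @return A `fit_spec` object.
#' @export
fit_spec <- function(sd, free, observations, isotopologues,
                     predicates = NULL,
                     residual_space = c("moments", "constants"),
                     max_iter = 100, ftol = 1e-12, xtol = 1e-10) {
  residual_space <- match.arg(residual_space)
  stopifnot(all(free %in% sd$params$id))
  observations <- tibble::as_tibble(observations)
  if (!"weight" %in% names(observations)) observations$weight <- 1
  if (!"sigma" %in% names(observations)) observations$sigma <- 0
  stopifnot(all(observations$iso %in% names(isotopologues)))
  if (!is.null(predicates)) {
    predicates <- tibble::as_tibble(predicates)
    stopifnot(all(predicates$param %in% sd$params$id),
              all(predicates$sigma > 0))
    if (any(predicates$param %in% setdiff(sd$params$id, free))) {
      # predicates on fixed parameters are inert but allowed
    }
  }
  n_eff <- nrow(observations) + if (is.null(predicates)) 0 else nrow(predicates)
  if (n_eff < length(free)) {
    stop("under-determined fit: ", n_eff, " effective observations for ",
         length(free), " free parameters", call. = FALSE)
  }
  structure(
    list(structure = sd, free = free, observations = observations,
         isotopologues = isotopologues, predicates = predicates,
         residual_space = residual_space,
         max_iter = max_iter, ftol = ftol, xtol = xtol),
    class = "fit_spec"
  )
}

#' Down-weight one isotopologue
#'
#' Scales the statistical weight of every retained axis of the chosen
#' isotopologue down by `factor^2` (equivalently, its effective uncertainty
#' up by `factor`); `factor = Inf` removes it from the fit in the limit.
#'
#' @param fs A `fit_spec` (or the observations tibble alone).
#' @param iso Isotopologue id.
#' @param factor Positive scale factor.
#' @return The modified object.
#' @export
down_weight <- function(fs, iso, factor) {
  stopifnot(factor > 0)
  obs <- if (inherits(fs, "fit_spec")) fs$observations else fs
  if (!iso %in% obs$iso) stop("unknown isotopologue id: ", iso, call. = FALSE)
  obs$weight[obs$iso == iso] <- obs$weight[obs$iso == iso] / factor^2
  if (inherits(fs, "fit_spec")) {
    fs$observations <- obs
    fs
  } else {
    obs
  }
}

# whitened residual vector: c(sqrt(w) * (obs - calc), (pred - value)/sigma)
.sefit_residuals <- function(fs, par) {
  sd <- set_param_values(fs$structure, stats::setNames(par, fs$free))
  geom <- build_cartesian(sd)
  K <- rotational_constant_K()
  obs <- fs$observations
  calc <- lapply(fs$isotopologues, function(ov) {
    rc <- rotational_constants(geom, isotopologue_masses(sd, ov))
    list(B = c(a = rc$A, b = rc$B, c = rc$C),
         I = c(a = rc$Ia, b = rc$Ib, c = rc$Ic))
  })
  if (fs$residual_space == "moments") {
    y <- K / obs$B_se
    yhat <- vapply(seq_len(nrow(obs)),
                   function(i) calc[[obs$iso[i]]]$I[[obs$axis[i]]], 0)
    sig <- ifelse(obs$sigma > 0, K / obs$B_se^2 * obs$sigma, 1)
  } else {
    y <- obs$B_se
    yhat <- vapply(seq_len(nrow(obs)),
                   function(i) calc[[obs$iso[i]]]$B[[obs$axis[i]]], 0)
    sig <- ifelse(obs$sigma > 0, obs$sigma, 1)
  }
  w <- obs$weight / sig^2
  r <- sqrt(w) * (y - yhat)
  attr(r, "moment_resid") <- if (fs$residual_space == "moments") {
    list(resid = y - yhat, w = w)
  } else {
    I_obs <- K / obs$B_se
    I_hat <- vapply(seq_len(nrow(obs)),
                    function(i) calc[[obs$iso[i]]]$I[[obs$axis[i]]], 0)
    list(resid = I_obs - I_hat, w = obs$weight)
  }
  if (!is.null(fs$predicates)) {
    vals <- stats::setNames(sd$params$value, sd$params$id)
    rp <- (fs$predicates$value - vals[fs$predicates$param]) /
      fs$predicates$sigma
    r <- c(r, unname(rp))
  }
  r
}

# finite-difference Jacobian of the whitened residuals
.sefit_jacobian <- function(fs, par, r0) {
  kinds <- fs$structure$params$kind[match(fs$free, fs$structure$params$id)]
  floors <- ifelse(kinds == "bond", 1e-6, 1e-5)
  J <- matrix(0, length(r0), length(par))
  for (j in seq_along(par)) {
    h <- max(1e-6 * abs(par[j]), floors[j])
    pj <- par
    pj[j] <- pj[j] + h
    J[, j] <- (.sefit_residuals(fs, pj) - r0) / h
  }
  J
}

#' Refine structural parameters against SE rotational constants
#'
#' Minimizes the weighted sum of squared residuals between observed and
#' computed inertia moments (default) or rotational constants over all
#' isotopologues, plus predicate terms \eqn{((p - p_{pred})/\sigma_p)^2},
#' with a damped Gauss-Newton (Levenberg) iteration and finite-difference
#' Jacobian. Parameter uncertainties come from the covariance at the
#' optimum with predicates counted as observations in the degrees of
#' freedom (mixed-regression convention).
#'
#' @param fs A [fit_spec()].
#' @return A `sefit_result`: refined values, standard deviations,
#'   correlation matrix, weighted RMS of the inertia-moment residuals
#'   (amu A^2), convergence diagnostics.
#' @export
fit_structure <- function(fs) {
  stopifnot(inherits(fs, "fit_spec"))
  par <- fs$structure$params$value[match(fs$free, fs$structure$params$id)]
  names(par) <- fs$free
  r <- .sefit_residuals(fs, par)
  J <- .sefit_jacobian(fs, par, r)
  if (qr(J)$rank < length(par)) {
    stop("rank-deficient system: unidentifiable parameters ",
         "(strong correlation); fix parameters or add predicates",
         call. = FALSE)
  }
  obj <- sum(r^2)
  lambda <- 1e-4
  converged <- FALSE
  iter <- 0
  while (iter < fs$max_iter) {
    iter <- iter + 1
    p <- length(par)
    Aw <- rbind(J, diag(sqrt(lambda), p))
    bw <- c(-r, rep(0, p))
    delta <- tryCatch(qr.solve(Aw, bw), error = function(e) NULL)
    if (is.null(delta)) {
      lambda <- lambda * 10
      next
    }
    par_new <- par + delta
    r_new <- tryCatch(.sefit_residuals(fs, par_new), error = function(e) NULL)
    obj_new <- if (is.null(r_new)) Inf else sum(r_new^2)
    if (obj_new <= obj) {
      step_norm <- sqrt(sum(delta^2))
      rel_dec <- (obj - obj_new) / max(obj, .Machine$double.eps)
      par <- par_new
      r <- r_new
      J <- .sefit_jacobian(fs, par, r)
      obj <- obj_new
      lambda <- max(lambda / 3, 1e-12)
      if (rel_dec < fs$ftol || step_norm < fs$xtol) {
        converged <- TRUE
        break
      }
    } else {
      lambda <- lambda * 10
      if (lambda > 1e12) {
        converged <- TRUE  # no further progress possible
        break
      }
    }
  }
  if (!converged) {
    warning("maximum iterations reached without convergence")
  }
  n_obs <- nrow(fs$observations)
  n_pred <- if (is.null(fs$predicates)) 0 else nrow(fs$predicates)
  dof <- n_obs + n_pred - length(par)
  JtJ <- crossprod(J)
  cov <- tryCatch({
    s2 <- if (dof > 0) obj / dof else NA_real_
    s2 * solve(JtJ)
  }, error = function(e) matrix(NA_real_, length(par), length(par)))
  sds <- sqrt(pmax(diag(cov), 0))
  corr <- tryCatch(stats::cov2cor(cov), error = function(e) cov * NA)
  mr <- attr(.sefit_residuals(fs, par), "moment_resid")
  rms <- sqrt(sum(mr$w * mr$resid^2) / sum(mr$w))
  structure(
    list(
      values = par, sd = stats::setNames(sds, fs$free),
      correlation = `dimnames<-`(corr, list(fs$free, fs$free)),
      rms = rms, objective = obj, iterations = iter, converged = converged,
      n_obs = n_obs, n_predicates = n_pred, dof = dof,
      structure = set_param_values(fs$structure,
                                   stats::setNames(par, fs$free)),
      fit_spec = fs
    ),
    class = "sefit_result"
  )
}

#' @export
print.sefit_result <- function(x, ...) {
  cat("<sefit_result> ", length(x$values), " refined parameters, ",
      x$n_obs, " constants + ", x$n_predicates, " predicates\n", sep = "")
  cat(sprintf("  weighted RMS (moments): %.3g amu A^2;  converged: %s (%d it)\n",
              x$rms, x$converged, x$iterations))
  df <- data.frame(estimate = x$values, std.error = x$sd)
  print(df, digits = 7)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy sefit_result
#' @export
tidy.sefit_result <- function(x, ...) {
  tibble::tibble(term = names(x$values), estimate = unname(x$values),
                 std.error = unname(x$sd))
}

#' @method glance sefit_result
#' @export
glance.sefit_result <- function(x, ...) {
  tibble::tibble(rms = x$rms, objective = x$objective, n_obs = x$n_obs,
                 n_predicates = x$n_predicates, df.residual = x$dof,
                 converged = x$converged, iterations = x$iterations)
}

#' @method tidy lra_fit
#' @export
tidy.lra_fit <- function(x, ...) {
  tibble::tibble(
    term = c("A", "B"), estimate = c(x$A, x$B),
    std.error = c(x$se_A, x$se_B)
  )
}

#' @method glance lra_fit
#' @export
glance.lra_fit <- function(x, ...) {
  tibble::tibble(n = x$n, md = x$md, mad = x$mad, neg = x$neg, pos = x$pos,
                 fix_intercept = x$fix_intercept)
}
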