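#' Pairwise inequality measures between two groups, per draw
#'
#' For a declared disadvantaged group `d` and advantaged group `a`,
#' computes per posterior draw and period, on the rate scale:
#' rate ratio `RR = R_d / R_a`; rate difference `RD = R_d - R_a`;
#' proportion attributable risk `PAR = RD / R_d`; excess cases
#' `EC = RD * P_d`; and the cumulative forms
#' `cumEC = sum_t EC_t` and `cumPAR = sum_t EC_t / sum_t R_dt * P_dt`.
#' Excess cases use model-estimated rates times population (expected
#' cases), so every measure carries posterior uncertainty.
#'
#' The advantaged group is declared by the analyst, not picked by rate
#' ranking: rankings can flip between draws, and silent flips would
#' corrupt the credible intervals.
#'
#' @param fit An [fit_rw()] result.
#' @param group_d,group_a Labels of the disadvantaged and advantaged
#'   groups (must differ).
#' @param stratum Stratum to compare (default first).
#' @param per Reporting scale for RR-independent quantities `RD`
#'   (e.g. `1e5`); `EC` is always in cases.
#' @return An object of class `pairwise_ineq`: list of draw matrices
#'   `rr`, `rd`, `par`, `ec` (draws x periods) and draw vectors
#'   `cum_ec`, `cum_par`, plus labels. `summary()` turns it into a
#'   `rate_summary` data frame.
#' @export
pairwise_inequality <- function(fit, group_d, group_a, stratum = NULL,
                                per = 1) {
  stopifnot(inherits(fit, "rw_fit"))
  if (identical(group_d, group_a))
    stop("`group_d` and `group_a` must differ", call. = FALSE)
  stratum <- stratum %||% fit$series$strata[1]
  rd_ <- rate_draws(fit, group_d, stratum, per = 1)
  ra_ <- rate_draws(fit, group_a, stratum, per = 1)
  P_d <- fit$series$populations[, match(group_d, fit$series$groups),
                                match(stratum, fit$series$strata)]
  Pd <- matrix(P_d, nrow(rd_), length(P_d), byrow = TRUE)

  rr <- unclass(rd_) / unclass(ra_)
  rdiff <- unclass(rd_) - unclass(ra_)
  par <- rdiff / unclass(rd_)
  ec <- rdiff * Pd
  burden <- unclass(rd_) * Pd
  structure(
    list(rr = rr, rd = rdiff * per, par = par, ec = ec,
         cum_ec = rowSums(ec), cum_par = rowSums(ec) / rowSums(burden),
         time = fit$series$time, group_d = group_d, group_a = group_a,
         stratum = stratum, per = per),
    class = "pairwise_ineq"
  )
}

#' Age-standardized pairwise inequality, per draw
#'
#' Relative measures come from directly standardized rates
#' (`SRR = SR_d / SR_a`, `SRD = SR_d - SR_a`), but excess cases must
#' be accumulated within age strata before summing —
#' `EC_t = sum_i (R_dit - R_ait) * P_dit` — never from standardized
#' rates, because the standard-population weights do not reflect the
#' disadvantaged group's actual age structure. The attributable risk
#' is `PAR_t = EC_t / sum_i R_dit * P_dit`, and the cumulative forms
#' sum the stratum sums over periods.
#'
#' @inheritParams pairwise_inequality
#' @param std A [standard_population()].
#' @return An object of class `pairwise_ineq` (quantities `srr`,
#'   `srd`, `par`, `ec`, `cum_ec`, `cum_par`).
#' @export
standardized_pairwise <- function(fit, std, group_d, group_a, per = 1) {
  stopifnot(inherits(fit, "rw_fit"))
  if (identical(group_d, group_a))
    stop("`group_d` and `group_a` must differ", call. = FALSE)
  sr_d <- direct_standardize(fit, std, group_d, per = 1)
  sr_a <- direct_standardize(fit, std, group_a, per = 1)
  strata <- fit$series$strata
  gi_d <- match(group_d, fit$series$groups)
  gi_a <- match(group_a, fit$series$groups)
  ndraw <- nrow(sr_d)
  ec <- matrix(0, ndraw, length(fit$series$time))
  burden <- matrix(0, ndraw, length(fit$series$time))
  for (i in seq_along(strata)) {
    r_di <- unclass(rate_draws(fit, group_d, strata[i], per = 1))
    r_ai <- unclass(rate_draws(fit, group_a, strata[i], per = 1))
    P_di <- matrix(fit$series$populations[, gi_d, i], ndraw,
                   length(fit$series$time), byrow = TRUE)
    ec <- ec + (r_di - r_ai) * P_di
    burden <- burden + r_di * P_di
  }
  structure(
    list(rr = unclass(sr_d) / unclass(sr_a),
         rd = (unclass(sr_d) - unclass(sr_a)) * per,
         par = ec / burden, ec = ec,
         cum_ec = rowSums(ec), cum_par = rowSums(ec) / rowSums(burden),
         time = fit$series$time, group_d = group_d, group_a = group_a,
         stratum = "age-standardized", per = per),
    class = "pairwise_ineq"
  )
}

#' @export
print.pairwise_ineq <- function(x, ...) {
  cat("<pairwise_ineq> ", x$group_d, " (disadvantaged) vs ", x$group_a,
      " (advantaged), stratum: ", x$stratum, "\n", sep = "")
  print(summary(x)[, c("time", "quantity", "mean")])
  invisible(x)
}

#' @export
summary.pairwise_ineq <- function(object, level = 0.95, ...) {
  lab <- paste0(object$group_d, " vs ", object$group_a)
  one <- function(mat, q) {
    mat <- as.matrix(mat)
    tm <- if (ncol(mat) == length(object$time)) object$time else "cumulative"
    m <- new_rate_draws(mat, tm, object$per)
    summarize_draws(m, level = level, quantity = q, group = lab,
                    stratum = object$stratum)
  }
  out <- rbind(one(object$rr, "rate_ratio"),
               one(object$rd, "rate_difference"),
               one(object$par, "attributable_risk"),
               one(object$ec, "excess_cases"))
  cum <- rbind(one(matrix(object$cum_ec, ncol = 1), "cumulative_excess_cases"),
               one(matrix(object$cum_par, ncol = 1),
                   "cumulative_attributable_risk"))
  cum$time <- paste0(object$time[1], "-", object$time[length(object$time)])
  rbind(out, cum)
}

#' Convert a proportion attributable risk to the equivalent rate ratio
#'
#' `RR = (1/PAR) / (1/PAR - 1)`, the rate ratio whose implied
#' attributable risk equals the input; the inverse relation
#' `PAR = 1 - 1/RR` holds to machine precision.
#'
#' @param par Attributable risk in (0, 1) (vectorized).
#' @return Rate ratio(s) > 1.
#' @export
par_to_rr <- function(par) {
  if (any(!is.finite(par)) || any(par <= 0) || any(par >= 1))
    stop("`par` must lie strictly in (0, 1)", call. = FALSE)
  (1 / par) / (1 / par - 1)
}

#' Theil index of between-group inequality, per draw
#'
#' Measures the discrepancy between each group's share of the
#' expected disease burden and its share of the population. Per draw
#' and period, with expected burden `b_j = R_j * P_j`, burden shares
#' `w_j = b_j / sum(b)` and population shares `p_j = P_j / sum(P)`:
#' \deqn{T = \sum_j w_j \log(w_j / p_j).}
#' `T = 0` iff every burden share equals its population share, and
#' `T >= 0` whenever all shares are positive.
#'
#' @param fit An [fit_rw()] result with `k >= 2` groups.
#' @param stratum Stratum (default first).
#' @param groups Subset of groups (default all).
#' @return An object of class `theil_result`: `total` (draws x
#'   periods), `components` (draws x periods x groups), labels.
#' @export
theil_index <- function(fit, stratum = NULL, groups = NULL) {
  stopifnot(inherits(fit, "rw_fit"))
  groups <- groups %||% fit$series$groups
  if (length(groups) < 2L) stop("at least 2 groups required", call. = FALSE)
  stratum <- stratum %||% fit$series$strata[1]
  si <- match(stratum, fit$series$strata)
  n <- length(fit$series$time)
  r_list <- lapply(groups, function(g)
    unclass(rate_draws(fit, g, stratum, per = 1)))
  P <- sapply(groups, function(g)
    fit$series$populations[, match(g, fit$series$groups), si])  # n x k
  P <- matrix(P, n, length(groups))
  ndraw <- nrow(r_list[[1]])

  b <- array(NA_real_, c(ndraw, n, length(groups)))
  for (j in seq_along(groups))
    b[, , j] <- r_list[[j]] * matrix(P[, j], ndraw, n, byrow = TRUE)
  bsum <- apply(b, c(1, 2), sum)
  if (any(b <= 0)) stop("zero expected burden; Theil index undefined",
                        call. = FALSE)
  psh <- P / rowSums(P)  # n x k population shares
  comp <- array(NA_real_, c(ndraw, n, length(groups)),
                dimnames = list(NULL, fit$series$time, groups))
  for (j in seq_along(groups)) {
    w <- b[, , j] / bsum
    comp[, , j] <- w * log(w / matrix(psh[, j], ndraw, n, byrow = TRUE))
  }
  total <- apply(comp, c(1, 2), sum)
  structure(list(total = new_rate_draws(total, fit$series$time, 1),
                 components = comp, groups = groups, stratum = stratum,
                 time = fit$series$time),
            class = "theil_result")
}

#' @export
summary.theil_result <- function(object, level = 0.95, ...) {
  out <- summarize_draws(object$total, level = level, quantity = "theil",
                         group = paste(object$groups, collapse = "+"),
                         stratum = object$stratum)
  if (!is.null(object$between)) {
    btw <- summarize_draws(new_rate_draws(object$between, object$time, 1),
                           level = level, quantity = "theil_between",
                           group = "units", stratum = object$stratum)
    wth <- summarize_draws(new_rate_draws(object$within, object$time, 1),
                           level = level, quantity = "theil_within",
                           group = "units", stratum = object$stratum)
    out <- rbind(out, btw, wth)
  }
  out
}

#' @export
print.theil_result <- function(x, ...) {
  cat("<theil_result> groups:", paste(x$groups, collapse = ", "), "\n")
  print(summary(x)[, c("time", "quantity", "mean")])
  invisible(x)
}

#' Theil decomposition over nested units
#'
#' Splits the Theil index into a between-unit part (computed over unit
#' burden/population aggregates) and a population-share-weighted
#' within-unit part:
#' \deqn{T = T_{between} + \sum_u \Omega_u T_{within,u},}
#' with \eqn{\Omega_u} the unit's share of total burden. Additivity
#' holds per draw to numerical precision, which makes the index usable
#' across geographically nested populations.
#'
#' @param fit An [fit_rw()] result; groups are the leaves.
#' @param nesting Named character vector mapping each group (name) to
#'   its unit (value); every group must appear exactly once.
#' @param stratum Stratum (default first).
#' @return A `theil_result` whose `total` is the leaf-level index,
#'   with extra draw matrices `between` and `within` and the
#'   `nesting` map.
#' @export
theil_decomposition <- function(fit, nesting, stratum = NULL) {
  stopifnot(inherits(fit, "rw_fit"))
  groups <- fit$series$groups
  if (is.null(names(nesting)) || !setequal(names(nesting), groups))
    stop("`nesting` must be a named vector covering every group exactly once",
         call. = FALSE)
  res <- theil_index(fit, stratum = stratum, groups = groups)
  stratum <- res$stratum
  si <- match(stratum, fit$series$strata)
  n <- length(fit$series$time)
  ndraw <- nrow(res$total)
  units <- unique(unname(nesting[groups]))

  P <- sapply(groups, function(g)
    fit$series$populations[, match(g, groups), si])
  P <- matrix(P, n, length(groups))
  b <- array(NA_real_, c(ndraw, n, length(groups)))
  for (j in seq_along(groups))
    b[, , j] <- unclass(rate_draws(fit, groups[j], stratum, per = 1)) *
      matrix(P[, j], ndraw, n, byrow = TRUE)
  bsum <- apply(b, c(1, 2), sum)
  Ptot <- rowSums(P)

  between <- matrix(0, ndraw, n)
  within <- matrix(0, ndraw, n)
  for (u in units) {
    members <- groups[nesting[groups] == u]
    ju <- match(members, groups)
    Bu <- apply(b[, , ju, drop = FALSE], c(1, 2), sum)
    Pu <- if (length(ju) > 1L) rowSums(P[, ju, drop = FALSE]) else P[, ju]
    Wu <- Bu / bsum                              # unit burden share
    PuSh <- matrix(Pu / Ptot, ndraw, n, byrow = TRUE)
    between <- between + Wu * log(Wu / PuSh)
    tw <- matrix(0, ndraw, n)                    # within-unit Theil
    for (j in ju) {
      wj <- b[, , j] / Bu
      pj <- matrix(P[, j] / Pu, ndraw, n, byrow = TRUE)
      tw <- tw + wj * log(wj / pj)
    }
    within <- within + Wu * tw
  }
  res$between <- between
  res$within <- within
  res$nesting <- nesting
  res
}
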