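# Cosine-annealed loss-weight schedules for the joint objective
# L_total = lambda_d(k) * L_d + lambda_c(k) * L_contrast.

#' Contrastive-weight schedule
#'
#' `lambda_c(k) = lambda_c_init / 2 * (1 + cos(k * pi / K_total))`:
#' starts at `lambda_c_init`, decays to 0 at `k = K_total`.
#'
#' @param k current outer iteration (0 <= k <= K_total).
#' @param K_total total outer iterations.
#' @param lambda_c_init initial weight (default 1.0).
#' @export
lambda_c <- function(k, K_total, lambda_c_init = 1.0) {
  if (any(k < 0) || any(k > K_total)) {
    stopf("k must lie in [0, K_total]; got k=%s, K_total=%s",
          paste(k, collapse = ","), K_total)
  }
  lambda_c_init / 2 * (1 + cos(k * pi / K_total))
}

#' Distillation-weight schedule
#'
#' `lambda_d(k) = lambda_d_init + (lambda_d_final - lambda_d_init) / 2 *
#' (1 - cos(k * pi / K_total))`: rises from `lambda_d_init` at k = 0 to
#' `lambda_d_final` at k = K_total.
#'
#' @param k current outer iteration (0 <= k <= K_total).
#' @param K_total total outer iterations.
#' @param lambda_d_init initial weight (default 0.1).
#' @param lambda_d_final final weight (default 1.0).
#' @export
lambda_d <- function(k, K_total, lambda_d_init = 0.1, lambda_d_final = 1.0) {
  if (any(k < 0) || any(k > K_total)) {
    stopf("k must lie in [0, K_total]; got k=%s, K_total=%s",
          paste(k, collapse = ","), K_total)
  }
  lambda_d_init + (lambda_d_final - lambda_d_init) / 2 *
    (1 - cos(k * pi / K_total))
}

#' Schedule state at outer iteration k
#'
#' @param k current outer iteration.
#' @param K_total total outer iterations.
#' @param lambda_c_init,lambda_d_init,lambda_d_final schedule parameters.
#' @param fixed optional length-2 numeric `c(lambda_c, lambda_d)` overriding
#'   both schedules with constants (fixed-weight ablations).
#' @return a `schedule_state` list with current `lambda_c` and `lambda_d`.
#' @export
schedule_state <- function(k, K_total, lambda_c_init = 1.0,
                           lambda_d_init = 0.1, lambda_d_final = 1.0,
                           fixed = NULL) {
  st <- list(k = k, K_total = K_total, lambda_c_init = lambda_c_init,
             lambda_d_init = lambda_d_init, lambda_d_final = lambda_d_final)
  if (!is.null(fixed)) {
    st$lambda_c <- fixed[1]
    st$lambda_d <- fixed[2]
  } else {
    st$lambda_c <- lambda_c(k, K_total, lambda_c_init)
    st$lambda_d <- lambda_d(k, K_total, lambda_d_init, lambda_d_final)
  }
  structure(st, class = "schedule_state")
}

#' Weighted total loss
#'
#' `L_total = lambda_d * L_d + lambda_c * L_contrast`.
#'
#' @param L_d distillation loss value.
#' @param L_contrast contrastive loss value.
#' @param schedule a [schedule_state()] (or any list with `lambda_c`,
#'   `lambda_d`).
#' @export
total_loss <- function(L_d, L_contrast, schedule) {
  stopifnot(is.finite(L_d), is.finite(L_contrast))
  schedule$lambda_d * L_d + schedule$lambda_c * L_contrast
}

#' Count lambda_c / lambda_d crossings on a dense grid
#'
#' With the default initialization (lambda_c,init = 1.0, lambda_d,init = 0.1,
#' lambda_d,final = 1.0) the contrastive weight starts above the distillation
#' weight and ends below it with exactly one crossing.
#'
#' @param K_total total outer iterations.
#' @param lambda_c_init,lambda_d_init,lambda_d_final schedule parameters.
#' @param n grid resolution.
#' @export
schedule_crossings <- function(K_total, lambda_c_init = 1.0,
                               lambda_d_init = 0.1, lambda_d_final = 1.0,
                               n = 2000) {
  k <- seq(0, K_total, length.out = n)
  diff_sign <- sign(lambda_c(k, K_total, lambda_c_init) -
                      lambda_d(k, K_total, lambda_d_init, lambda_d_final))
  sum(diff(diff_sign[diff_sign != 0]) != 0)
}
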