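# Harrell's concordance index, implemented directly over permissible pairs.
# A pair (i, j) is permissible when patient i can be established as the
# earlier event: t_i < t_j with i an observed event, or t_i == t_j with i an
# event and j censored. The pair is concordant when the earlier event has
# the higher predicted risk; tied risks contribute 1/2. Pairs of tied event
# times with both events observed are not permissible.

#' Harrell's concordance index
#'
#' @param risk per-patient predicted risk (higher = worse prognosis).
#' @param time overall survival time.
#' @param event event indicator (1 = event, 0 = censored).
#' @return C in `[0, 1]`: 1 is perfect concordance, 0.5 chance level.
#' @export
#' @examples
#' # risk equal to the negative survival time is perfectly concordant
#' concordance_index(-(1:10), 1:10, rep(1, 10))
concordance_index <- function(risk, time, event) {
  n <- length(risk)
  stopifnot(length(time) == n, length(event) == n)
  if (anyNA(risk) || anyNA(time) || anyNA(event)) {
    abort("missing values in risk, time, or event",
          class = "netprog_concordance_error")
  }
  t_lt <- outer(time, time, "<")
  t_eq <- outer(time, time, "==")
  ev_i <- matrix(event == 1, n, n)          # event status of i, by row
  cens_j <- matrix(event == 0, n, n, byrow = TRUE)
  permissible <- (t_lt & ev_i) | (t_eq & ev_i & cens_j)
  diag(permissible) <- FALSE
  n_perm <- sum(permissible)
  if (n_perm == 0) {
    abort("no comparable pairs", class = "netprog_concordance_error")
  }
  r_gt <- outer(risk, risk, ">")
  r_eq <- outer(risk, risk, "==")
  score <- sum(r_gt[permissible]) + 0.5 * sum(r_eq[permissible])
  score / n_perm
}
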