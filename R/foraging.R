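# Pollinator foraging: Holling type II visitation, preference-driven
# movement between flower sexes, and the four pollen-load compartments
# (high / medium / low / none). A male-flower visit reloads a pollinator to
# the high-load class; each female-flower visit steps it down one class and
# deposits pollen (a "type n" visit for a class-n pollinator).

#' Total per-pollinator visitation rate
#'
#' Holling type II functional response in the total number of open flowers:
#' `alpha * x / (1 + alpha * beta * x)` with `x = open_male + open_female`.
#' Saturates at `1/beta` visits per day.
#'
#' @param open_male,open_female Numbers of currently open flowers.
#' @param pollinators A [pollinator_params()] object.
#' @return Visits per pollinator per day.
#' @examples
#' visitation_rate(500, 500, pollinator_params())
#' @export
visitation_rate <- function(open_male, open_female, pollinators) {
  stopifnot(inherits(pollinators, "pollinator_params"))
  if (any(!is.finite(open_male)) || any(!is.finite(open_female)) ||
      any(open_male < 0) || any(open_female < 0))
    stop("visitation_rate: open flower counts must be finite and >= 0",
         call. = FALSE)
  x <- open_male + open_female
  pollinators$search_rate * x / (1 + pollinators$search_rate *
                                   pollinators$handling_time * x)
}

#' Probability of staying on the current flower sex
#'
#' The probability that a pollinator's next visit is to the same flower sex
#' it currently occupies: the own-sex share of open flowers raised to the
#' preference exponent, `(open_same/open_total)^pref`. Exponent 1 means no
#' preference; exponents near 0 mean the pollinator almost never switches.
#' When no flowers are open the stay probability is defined as 1 (no
#' movement is possible; the visitation rate is simultaneously 0, so the
#' convention never affects the dynamics).
#'
#' @param open_same Open flowers of the currently occupied sex.
#' @param open_total Total open flowers (both sexes).
#' @param pref Preference exponent in `[0, 1]`.
#' @return Probability in `[0, 1]`.
#' @examples
#' stay_probability(500, 1000, preference_from_stay(0.957)) # 0.957
#' @export
stay_probability <- function(open_same, open_total, pref) {
  if (any(!is.finite(pref)) || any(pref < 0) || any(pref > 1))
    stop("stay_probability: pref must lie in [0, 1]", call. = FALSE)
  if (any(!is.finite(open_same)) || any(!is.finite(open_total)) ||
      any(open_same < 0) || any(open_same > open_total))
    stop("stay_probability: need 0 <= open_same <= open_total", call. = FALSE)
  n <- max(length(open_same), length(open_total), length(pref))
  os <- rep_len(open_same, n)
  ot <- rep_len(open_total, n)
  share <- ifelse(ot > 0, os / ot, 1)
  share^rep_len(pref, n)
}

#' Pollinator compartment state
#'
#' @param high_load,mid_load,low_load,no_load Nonnegative pollinator counts
#'   in the four pollen-load compartments.
#' @return A named numeric vector of class `pollinator_state` with
#'   components `high_load`, `mid_load`, `low_load`, `no_load`.
#' @export
pollinator_state <- function(high_load = 0, mid_load = 0, low_load = 0,
                             no_load = 0) {
  v <- c(high_load = high_load, mid_load = mid_load, low_load = low_load,
         no_load = no_load)
  if (any(!is.finite(v)) || any(v < 0))
    stop("pollinator_state: components must be finite and >= 0",
         call. = FALSE)
  structure(v, class = "pollinator_state")
}

# Shared movement terms for the compartment system at given open counts.
movement_terms <- function(open_male, open_female, pollinators) {
  tot <- open_male + open_female
  V <- visitation_rate(open_male, open_female, pollinators)
  if (tot > 0) {
    stay_m <- (open_male / tot)^pollinators$pref_male
    stay_f <- (open_female / tot)^pollinators$pref_female
  } else {
    stay_m <- 1
    stay_f <- 1
  }
  list(V = V, leave_male = 1 - stay_m, stay_female = stay_f,
       leave_female = 1 - stay_f)
}

#' Time derivative of the pollinator compartments
#'
#' Right-hand side of the compartment system. Each pollinator visits flowers
#' at the total visitation rate; a visit to a male flower (probability given
#' by the movement model) reloads it into the high-load class, and a visit to
#' a female flower steps it down one class. The four components always sum to
#' zero: the pollinator population is closed.
#'
#' @param state A [pollinator_state()] (or a 4-vector in the same order).
#' @param open_male,open_female Currently open flower counts.
#' @param pollinators A [pollinator_params()] object.
#' @return Named numeric 4-vector of derivatives (pollinators/day).
#' @export
state_derivative <- function(state, open_male, open_female, pollinators) {
  state <- as.numeric(state)
  if (length(state) != 4L || any(!is.finite(state)))
    stop("state_derivative: state must be 4 finite components",
         call. = FALSE)
  mt <- movement_terms(open_male, open_female, pollinators)
  p1 <- state[1]; p2 <- state[2]; p3 <- state[3]; pf <- state[4]
  r1 <- mt$V * mt$leave_male * p1          # high -> mid   (type-one visits)
  r2 <- mt$V * mt$stay_female * p2         # mid  -> low   (type-two visits)
  r3 <- mt$V * mt$stay_female * p3         # low  -> none  (type-three visits)
  to_male <- mt$V * mt$leave_female        # any female-located class -> high
  c(high_load = to_male * (p2 + p3 + pf) - r1,
    mid_load = r1 - to_male * p2 - r2,
    low_load = r2 - to_male * p3 - r3,
    no_load = r3 - to_male * pf)
}

#' Instantaneous pollen-depositing visit rates
#'
#' The three female-flower visit channels that deposit pollen, equal to the
#' downward compartment fluxes of [state_derivative()]: type one
#' (high-load pollinators arriving on a female flower), type two (mid-load
#' pollinators revisiting female flowers) and type three (low-load ditto).
#' Visits by empty pollinators deposit nothing and are not counted.
#'
#' @inheritParams state_derivative
#' @return Named numeric 3-vector `c(type1, type2, type3)` in visits/day.
#' @export
deposit_visit_rates <- function(state, open_male, open_female, pollinators) {
  state <- as.numeric(state)
  if (length(state) != 4L || any(!is.finite(state)))
    stop("deposit_visit_rates: state must be 4 finite components",
         call. = FALSE)
  mt <- movement_terms(open_male, open_female, pollinators)
  c(type1 = mt$V * mt$leave_male * state[1],
    type2 = mt$V * mt$stay_female * state[2],
    type3 = mt$V * mt$stay_female * state[3])
}
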