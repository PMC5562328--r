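#' Mode-weight series h(s) of the steady-state solution
#'
#' The steady-state spatial difference of a diffusing, decaying species
#' forced by a linear input gradient on a reflecting domain of length `L`
#' is proportional to
#' \deqn{h(s) = \sum_{m \ge 0} \frac{1}{(2m+1)^2\,[(2m+1)^2 s + (L/\pi)^2]},}
#' where `s = D/k` is the squared length scale of the species (um^2). Only
#' odd cosine modes contribute; `h` is strictly decreasing in `s` and
#' converges to 0 as `s` grows. At `s = 0` it equals `pi^4 / (8 L^2)`.
#'
#' `h_series()` evaluates the truncated sum over `n_terms` odd modes and
#' attaches an analytic bound on the discarded tail (attribute
#' `"tail_bound"`, one value per element of `s`). When the bound exceeds
#' `tail_tol` times the partial sum a warning of condition class
#' `"chemotaxmap_tail"` is raised; increase `n_terms` when full precision
#' near `s = 0` matters. `h_closed()` is the exact closed form obtained
#' from the partial-fraction identity
#' \eqn{\sum_{odd\,n} (n^2+a^2)^{-1} = (\pi/4a)\tanh(\pi a/2)} and serves
#' as an independent cross-check of the series.
#'
#' @param s Length-squared ratio D/k (um^2), `>= 0`. Vectorised.
#' @param L Growth-cone length (um), `> 0`.
#' @param n_terms Number of odd modes retained, `>= 1`.
#' @param tail_tol Relative tail-bound threshold above which a
#'   `"chemotaxmap_tail"` warning is raised.
#' @return `h_series`: the partial sums (same length as `s`) with attribute
#'   `"tail_bound"`. `h_closed`: the exact values.
#' @examples
#' h_series(0, L = 10, n_terms = 1e5)  # ~ pi^4 / 800
#' h_closed(c(0.05, 20), L = 10)
#' @export
h_series <- function(s, L, n_terms = 500, tail_tol = 1e-6) {
  if (!is.numeric(s) || length(s) < 1L || any(!is.finite(s)))
    stop("s must be finite numeric (D/k ratio)", call. = FALSE)
  if (any(s < 0)) stop("s = D/k must be >= 0", call. = FALSE)
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L) || L <= 0)
    stop("L must be a positive scalar", call. = FALSE)
  if (!is.numeric(n_terms) || length(n_terms) != 1L || !is.finite(n_terms) ||
      n_terms < 1)
    stop("n_terms must be >= 1", call. = FALSE)
  n_terms <- as.integer(n_terms)
  n <- 2 * (seq_len(n_terms) - 1) + 1          # odd modes 1, 3, 5, ...
  csq <- (L / pi)^2
  n2 <- n^2
  val <- vapply(s, function(si) sum(1 / (n2 * (n2 * si + csq))), numeric(1))
  # Tail over odd n >= n0: terms bounded by (1/csq)/n^2 and (for s>0) by 1/(s n^4);
  # sum_{odd n >= n0} n^-2 <= 1/(2(n0-2)) and sum n^-4 <= 1/(5 (n0-2)^3).
  n0 <- 2 * n_terms + 1
  b1 <- 1 / (csq * 2 * (n0 - 2))
  b2 <- ifelse(s > 0, 1 / (s * 5 * (n0 - 2)^3), Inf)
  bound <- pmin(b1, b2)
  rel <- bound / pmax(val, .Machine$double.xmin)
  if (any(rel > tail_tol))
    warning(warningCondition(
      sprintf("h_series tail bound %.2g relative exceeds tail_tol = %g; increase n_terms",
              max(rel), tail_tol),
      class = "chemotaxmap_tail"))
  structure(val, tail_bound = bound)
}

#' @rdname h_series
#' @export
h_closed <- function(s, L) {
  if (!is.numeric(s) || any(!is.finite(s)) || any(s < 0))
    stop("s must be finite numeric >= 0", call. = FALSE)
  if (!is.numeric(L) || length(L) != 1L || L <= 0)
    stop("L must be a positive scalar", call. = FALSE)
  # h(s) = (pi/L)^2 [ pi^2/8 - (pi^2 sqrt(s) / 4L) tanh(L / 2 sqrt(s)) ]
  rs <- sqrt(s)
  arg <- ifelse(rs > 0, L / (2 * rs), Inf)
  (pi / L)^2 * (pi^2 / 8 - (pi^2 * rs / (4 * L)) * tanh(arg))
}

#' Baseline activity of a species
#'
#' The uniform steady state under the baseline stimulus alone:
#' `Z* = (alpha * f_star + c) / k`.
#'
#' @param p A [species_params()] object.
#' @param f_star Baseline transduced signal f(R, G*), `>= 0`.
#' @return The baseline activity (uM). When it is exactly zero the result
#'   carries attribute `degenerate = TRUE` and a warning is raised: the
#'   relative response dZ/Z* is undefined downstream.
#' @examples
#' baseline_activity(species_params(D = 1, k = 1, c = 0.05, alpha = 5), 10)
#' @export
baseline_activity <- function(p, f_star) {
  assert_species(p)
  if (!is.numeric(f_star) || length(f_star) != 1L || !is.finite(f_star) ||
      f_star < 0)
    stop("f_star must be a finite scalar >= 0", call. = FALSE)
  z <- (p$alpha * f_star + p$c) / p$k
  if (z == 0) {
    warning("baseline activity is 0 (alpha * f_star + c = 0); relative responses are undefined",
            call. = FALSE)
    attr(z, "degenerate") <- TRUE
  }
  z
}

#' Steady-state spatial difference of one species across the cone
#'
#' The difference `dZ = Z(L/2) - Z(-L/2)` of the steady-state profile under
#' the linearised stimulus, `dZ = 8 g_eff L^3 h(D/k) / (pi^4 k)`. In
#' `"physical"` mode the input gradient amplitude carries the efficacy and
#' the result is multiplied by `alpha`; in `"reduced"` mode (default) it is
#' not. The sign of `dZ` equals the sign of `g_eff`.
#'
#' @param p A [species_params()] object.
#' @param g_eff Effective stimulus slope across the cone (per um).
#' @param L Growth-cone length (um).
#' @param mode `"reduced"` or `"physical"`; see [relative_polarity()].
#' @param n_terms Odd modes retained in the h-series.
#' @return The spatial difference (uM).
#' @examples
#' p <- species_params(D = 0, k = 1, c = 1)
#' spatial_difference(p, g_eff = 1, L = 10, n_terms = 1e5)  # ~ g*L/k = 10
#' @export
spatial_difference <- function(p, g_eff, L = 10, mode = "reduced",
                               n_terms = 500) {
  assert_species(p)
  mode <- match_mode(mode)
  if (!is.numeric(g_eff) || length(g_eff) != 1L || !is.finite(g_eff))
    stop("g_eff must be a finite scalar", call. = FALSE)
  h <- h_series(p$D / p$k, L, n_terms)
  amp <- if (mode == "physical") p$alpha * g_eff else g_eff
  as.numeric(8 * amp * L^3 * h / (pi^4 * p$k))
}
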