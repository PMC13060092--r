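# Four-state alternating-access kinetic model: exact steady-state oracle,
# the closed-form Vmax ratio as a function of the conformational energy
# gap perturbation (ddG_flip), and epistasis/specificity predictions on the
# conformational-balance manifold.
#
# Sign convention (stated nowhere upstream, so fixed here and documented
# prominently): positive ddG_flip destabilizes the inward-open state
# relative to the outward-open state. With transition-state fraction phi,
# the loaded outward->inward flip slows by exp(-phi x) and the empty
# inward->outward return flip accelerates by exp((1-phi) x), x = ddG/RT.

#' Four-state transport cycle
#'
#' States: outward-empty (Oe) -> outward-bound (Ob) -> inward-bound (Ib)
#' -> inward-empty (Ie) -> Oe. Each step carries a forward and a reverse
#' rate constant; substrate binding is folded into the pseudo-first-order
#' binding rates.
#'
#' @param forward,reverse numeric length-4 rate vectors for steps
#'   (Oe->Ob, Ob->Ib, Ib->Ie, Ie->Oe) and their reverses; all >= 0
#' @return a `four_state_model`
#' @export
four_state_model <- function(forward, reverse = rep(0, 4)) {
  stopifnot(length(forward) == 4L, length(reverse) == 4L,
            all(forward >= 0), all(reverse >= 0))
  structure(list(forward = forward, reverse = reverse),
            class = "four_state_model")
}

#' Steady-state cycle flux (exact linear algebra)
#'
#' Solves the master equation at steady state (state probabilities sum to
#' one) and returns the net flux around the cycle — the direct numerical
#' implementation of the model's stated assumptions, used as the oracle
#' for the closed-form Vmax expression.
#'
#' @param model a [four_state_model()]
#' @return list `flux` (net cycle flux), `p` (state probabilities)
#' @export
four_state_flux <- function(model) {
  f <- model$forward; r <- model$reverse
  Q <- matrix(0, 4, 4)
  step <- cbind(c(1, 2, 3, 4), c(2, 3, 4, 1))
  for (s in 1:4) {
    Q[step[s, 1], step[s, 2]] <- Q[step[s, 1], step[s, 2]] + f[s]
    Q[step[s, 2], step[s, 1]] <- Q[step[s, 2], step[s, 1]] + r[s]
  }
  diag(Q) <- -rowSums(Q)
  A <- rbind(t(Q)[1:3, ], rep(1, 4))
  p <- tryCatch(solve(A, c(0, 0, 0, 1)),
                error = function(e) stop("singular steady-state system ",
                                         "(disconnected cycle)"))
  list(flux = p[2] * f[2] - p[3] * r[2], p = p)
}

#' Closed-form Vmax ratio under a conformational-balance perturbation
#'
#' For a transporter whose conformational flips are rate-limiting, a
#' mutation that shifts the inward/outward free-energy gap by ddG changes
#' the maximal transport rate by
#' `V'/V0 = (1 + r) / (exp(phi x) + r exp((phi - 1) x))`, with x = ddG/RT
#' and r = k+/k- the baseline ratio of loaded-flip to return-flip rates — a
#' bell-shaped curve peaking at x = log(r (1 - phi) / phi) and vanishing as
#' ddG -> +/- Inf. Agrees with [four_state_flux()] in the
#' rate-limiting-flip limit.
#'
#' @param ddg energy-gap perturbation (energy units of `RT`); positive =
#'   inward-open destabilized
#' @param phi transition-state fraction, in (0, 1)
#' @param kratio baseline k+/k- (> 0)
#' @param RT thermal energy in the same units as `ddg` (default 0.593
#'   kcal/mol, 298 K)
#' @return Vmax ratio V'/V0 (vectorized over `ddg`)
#' @export
vmax_ratio <- function(ddg, phi, kratio, RT = 0.593) {
  if (phi <= 0 || phi >= 1) stop("phi must be in (0, 1)")
  if (kratio <= 0) stop("kratio must be > 0")
  x <- ddg / RT
  (1 + kratio) / (exp(phi * x) + kratio * exp((phi - 1) * x))
}

#' Optimal energy-gap perturbation and peak Vmax ratio
#'
#' The closed form peaks at ddG* = RT log(kratio (1 - phi) / phi); for a
#' symmetric cycle (kratio = 1, phi = 1/2) the optimum is at 0 — the WT is
#' already maximal. Note the peak *value* depends on phi for this closed
#' form; `peak_phi_profile()` reports that dependence numerically.
#'
#' @inheritParams vmax_ratio
#' @return list `ddg_opt`, `peak` (Vmax ratio at the optimum)
#' @export
optimal_ddg <- function(phi, kratio, RT = 0.593) {
  ddg_opt <- RT * log(kratio * (1 - phi) / phi)
  list(ddg_opt = ddg_opt, peak = vmax_ratio(ddg_opt, phi, kratio, RT))
}

#' @rdname optimal_ddg
#' @param phi_grid phi values to profile
#' @return for `peak_phi_profile`: data.frame (phi, ddg_opt, peak) showing
#'   how the peak location and height move with phi
#' @export
peak_phi_profile <- function(kratio, phi_grid = seq(0.2, 0.8, by = 0.1),
                             RT = 0.593) {
  rows <- lapply(phi_grid, function(ph) {
    o <- optimal_ddg(ph, kratio, RT)
    data.frame(phi = ph, ddg_opt = o$ddg_opt, peak = o$peak)
  })
  do.call(rbind, rows)
}

#' Double-mutant cycle on the conformational-balance curve
#'
#' Evaluates the Vmax ratio at ddG in \{0, A, B, A+B\} (mutational energy
#' perturbations combine additively on the latent energy scale) and
#' classifies the epistasis of the quartet: epsilon is the departure of
#' the double from the additive expectation V_A + V_B - 1, and sign
#' classes come from [classify_sign_epistasis()] on the four values.
#'
#' @param ddg_a,ddg_b single-mutation energy perturbations
#' @inheritParams vmax_ratio
#' @return list `v` (named WT/A/B/AB ratios), `epsilon`, `positive`,
#'   `negative`, `reciprocal_sign`
#' @export
predict_double_cycle <- function(ddg_a, ddg_b, phi, kratio, RT = 0.593) {
  v <- c(WT = 1,
         A = vmax_ratio(ddg_a, phi, kratio, RT),
         B = vmax_ratio(ddg_b, phi, kratio, RT),
         AB = vmax_ratio(ddg_a + ddg_b, phi, kratio, RT))
  eps <- v[["AB"]] - (v[["A"]] + v[["B"]] - 1)
  cls <- classify_sign_epistasis(v[["WT"]], v[["A"]], v[["B"]], v[["AB"]],
                                 k = 0)
  list(v = v, epsilon = eps,
       positive = eps > 0, negative = eps < 0,
       reciprocal_sign = cls$reciprocal)
}

#' Paired Vmax curves for two substrates
#'
#' Two substrates see the same conformational perturbation ddG but
#' different baseline flip-rate ratios, so their bell curves peak at
#' different ddG; wherever the optima differ there are perturbations that
#' raise one substrate's Vmax while lowering the other's. The returned
#' table carries both curves, their derivatives in ddG, and the
#' opposite-sign predicate.
#'
#' @param ddg vector of energy perturbations to trace
#' @param phi transition-state fraction
#' @param kratio1,kratio2 baseline k+/k- for the two substrates
#' @param RT thermal energy
#' @return list `curve` data.frame (ddg, v1, v2, dv1, dv2,
#'   opposite_sign), `any_opposite` (does any traced ddG move the two
#'   Vmax in opposite directions?)
#' @export
specificity_trajectory <- function(ddg, phi, kratio1, kratio2,
                                   RT = 0.593) {
  dlog <- function(x, r) (1 - phi) - exp(x) / (r + exp(x))
  x <- ddg / RT
  v1 <- vmax_ratio(ddg, phi, kratio1, RT)
  v2 <- vmax_ratio(ddg, phi, kratio2, RT)
  dv1 <- v1 * dlog(x, kratio1) / RT
  dv2 <- v2 * dlog(x, kratio2) / RT
  opp <- sign(dv1) * sign(dv2) < 0
  list(curve = data.frame(ddg = ddg, v1 = v1, v2 = v2, dv1 = dv1,
                          dv2 = dv2, opposite_sign = opp),
       any_opposite = any(opp))
}

#' Four-state model realizing a conformational-balance mutant
#'
#' Convenience constructor for the rate-limiting-flip regime used to
#' validate the closed form: fast, saturating substrate binding and
#' release (rate `fast`), loaded flip k+ exp(-phi x), return flip
#' k- exp((1-phi) x).
#'
#' @param ddg energy perturbation
#' @param phi transition-state fraction
#' @param kplus,kminus baseline flip rates
#' @param RT thermal energy
#' @param fast binding/release rate (>> flip rates)
#' @return a [four_state_model()]
#' @export
flip_limited_model <- function(ddg, phi, kplus, kminus, RT = 0.593,
                               fast = 1e10) {
  x <- ddg / RT
  four_state_model(
    forward = c(fast, kplus * exp(-phi * x), fast,
                kminus * exp((1 - phi) * x)))
}
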