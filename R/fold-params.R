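#' Energy parameters for RNA secondary-structure folding
#'
#' Returns the nearest-neighbour energy tables used by [rnaFold()].  The
#' model is a simplified Turner-style set: stacking free energies (37 degC,
#' kcal/mol) for all canonical pairs including G:U wobbles, tabulated
#' hairpin/bulge/internal loop initiation penalties with Jacobson-Stockmayer
#' log extrapolation of large hairpin loops, a linear internal-loop asymmetry
#' penalty, and an affine multibranch-loop model.  Exact mfold 3.x energies
#' are not reproduced; the table is deliberately editable so that users can
#' substitute their own parameter set.
#'
#' Pair order in the `stack` matrix is AU, UA, CG, GC, GU, UG; entry
#' `stack[p1, p2]` is the energy of pair `p2` (closer to the loop) stacked on
#' the closing pair `p1`.  Bulge and internal loops larger than `max_loop`
#' nucleotides are not considered (treated as prohibitively unstable).
#'
#' @return A named list of energy tables and scalar parameters.
#' @examples
#' p <- foldEnergyParams()
#' p$stack["CG", "GC"] # 5'CG3'/3'GC5' stack
#' @export
foldEnergyParams <- function() {
  pairs <- c("AU", "UA", "CG", "GC", "GU", "UG")
  st <- matrix(NA_real_, 6, 6, dimnames = list(pairs, pairs))
  # Watson-Crick on Watson-Crick (Turner-type 37 degC values)
  st["AU", "AU"] <- -0.93; st["AU", "UA"] <- -1.10
  st["AU", "CG"] <- -2.24; st["AU", "GC"] <- -2.08
  st["UA", "AU"] <- -1.33; st["UA", "UA"] <- -0.93
  st["UA", "CG"] <- -2.35; st["UA", "GC"] <- -2.11
  st["CG", "AU"] <- -2.11; st["CG", "UA"] <- -2.08
  st["CG", "CG"] <- -3.26; st["CG", "GC"] <- -2.36
  st["GC", "AU"] <- -2.35; st["GC", "UA"] <- -2.24
  st["GC", "CG"] <- -3.42; st["GC", "GC"] <- -3.26
  # simplified wobble set: G:U next to C-G/G-C pairs is moderately stable,
  # next to A-U/U-A weakly so; tandem wobbles are weak or destabilizing
  for (p in c("CG", "GC")) {
    for (q in c("GU", "UG")) { st[p, q] <- -1.5; st[q, p] <- -1.5 }
  }
  for (p in c("AU", "UA")) {
    for (q in c("GU", "UG")) { st[p, q] <- -0.6; st[q, p] <- -0.6 }
  }
  st["GU", "GU"] <- -0.5; st["UG", "UG"] <- -0.5
  st["GU", "UG"] <- +0.5; st["UG", "GU"] <- -0.5

  inf <- 1e9
  js <- 1.75 * 0.616 # 1.75 RT at 37 degC
  hp <- c(inf, inf, 5.4, 5.6, 5.7, 5.4, 6.0, 5.5, 6.4,
          6.4 + js * log(10:30 / 9))
  bu <- c(3.8, 2.8, 3.2, 3.6, 4.0, 4.4, 4.4 + js * log(7:30 / 6))
  il <- c(1.0, 1.4, 1.7, 1.8, 1.9, 2.0, 2.0 + js * log(7:30 / 6))
  list(stack = st,
       hairpin = hp, bulge = bu, internal = il,
       asym = 0.5, asym_max = 3.0,
       multi_a = 3.4, multi_b = 0.4, multi_c = 0.0,
       js_coef = js, max_loop = 30L)
}
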