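# Independent brute-force enumeration oracle: full loop over the
# heteroatom/oxygen grid with an exhaustive carbon sweep (every carbon
# count in range, no mass-band pruning) and a rounding neighbourhood of
# hydrogen candidates, in R arithmetic. Used only to prove the packaged
# enumerator exhaustive.
oracle_enumerate <- function(mass, rules = assignment_rules()) {
  tol <- mass * rules$tolerance_ppm * 1e-6
  em <- ELEMENT_MASSES
  grid <- expand.grid(n = rules$n_range[1]:rules$n_range[2],
                      s = rules$s_range[1]:rules$s_range[2],
                      p = rules$p_range[1]:rules$p_range[2],
                      o = rules$o_range[1]:rules$o_range[2])
  cs <- rules$c_range[1]:rules$c_range[2]
  hits <- list()
  for (g in seq_len(nrow(grid))) {
    base <- grid$n[g] * em[["n"]] + grid$s[g] * em[["s"]] +
      grid$p[g] * em[["p"]] + grid$o[g] * em[["o"]]
    if (base > mass + tol) next
    rem <- mass - base - cs * em[["c"]]
    for (dh in -1:1) {
      h <- round(rem / em[["h"]]) + dh
      total <- base + cs * em[["c"]] + h * em[["h"]]
      ok <- which(h >= rules$h_range[1] & h <= rules$h_range[2] &
                    abs(total - mass) <= tol)
      for (i in ok) {
        hits[[length(hits) + 1]] <- data.frame(
          c = cs[i], h = h[i], n = grid$n[g], o = grid$o[g],
          s = grid$s[g], p = grid$p[g])
      }
    }
  }
  if (length(hits) == 0) return(character(0))
  f <- do.call(rbind, hits)
  f <- f[conforms_to_rules(f, rules), , drop = FALSE]
  unique(format_formula(f))
}
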