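# Independent oracles used across the test files. Each re-derives the
# quantity it checks by a route separate from the package implementation.

# Fine-step forward-Euler integration of the pool-dilution ODE system
# dM/dt = p - c, dH/dt = -c H / M, APE = H / M.
euler_pool_dilution <- function(p, c, M0, APE0, dt, n_steps = 200000) {
  h <- dt / n_steps
  M <- M0
  H <- APE0 / 100 * M0
  for (i in seq_len(n_steps)) {
    dH <- -c * H / M
    M <- M + h * (p - c)
    H <- H + h * dH
  }
  list(Mt = M, APEt = 100 * H / M)
}

# Exhaustive permutation two-sided p value for the difference in mean ranks
# between two of several groups, permuting group labels over all
# observations (feasible for 3 groups of 3: 1680 assignments).
perm_rank_p <- function(values, groups, g1, g2) {
  groups <- as.character(groups)
  r <- rank(values)
  obs <- abs(mean(r[groups == g1]) - mean(r[groups == g2]))
  labs <- groups
  perms <- all_label_perms(labs)
  stat <- vapply(perms, function(lab) {
    abs(mean(r[lab == g1]) - mean(r[lab == g2]))
  }, numeric(1))
  mean(stat >= obs - 1e-12)
}

# all distinct assignments of a multiset of labels to positions
all_label_perms <- function(labs) {
  n <- length(labs)
  uniq <- unique(labs)
  out <- list()
  recurse <- function(remaining, acc) {
    if (!length(remaining)) {
      out[[length(out) + 1]] <<- acc
      return(invisible())
    }
    for (u in unique(remaining)) {
      i <- match(u, remaining)
      recurse(remaining[-i], c(acc, u))
    }
  }
  recurse(labs, character(0))
  out
}

# independent hand evaluation of the chamber unit-conversion chain,
# written as explicit sequential steps (the "spreadsheet" route)
hand_chamber_flux <- function(slope_ppm_min, height_m, temp_k, pressure_pa,
                              g_per_mol = 28.0134) {
  mol_per_m3 <- pressure_pa / (8.314 * temp_k)       # ideal gas molar density
  mole_frac_per_min <- slope_ppm_min * 1e-6
  mol_m2_min <- mole_frac_per_min * mol_per_m3 * height_m
  g_m2_day <- mol_m2_min * g_per_mol * 60 * 24
  g_m2_day * 1e6                                      # ug
}

# independent Fick / Millington-Quirk chain for the pore-gas flux
hand_pore_flux <- function(pore_ppm, surf_ppm, depth_m, theta_a, phi, temp_k) {
  d0 <- 1.43e-5 * (temp_k / 293)^1.75
  ds <- d0 * theta_a^(10 / 3) / phi^2
  grad_mol_m3 <- (pore_ppm - surf_ppm) * 1e-6 * 101325 / (8.314 * temp_k)
  flux_mol_m2_s <- ds * grad_mol_m3 / depth_m
  flux_mol_m2_s * 28.0134 * 1e6 * 86400
}

# axioms a compact letter display must satisfy, given the significance matrix
letters_satisfy_axioms <- function(letters, sig) {
  g <- names(letters)
  for (i in seq_along(g)) {
    for (j in seq_along(g)) {
      if (i >= j) next
      shared <- length(intersect(strsplit(letters[[i]], "")[[1]],
                                 strsplit(letters[[j]], "")[[1]])) > 0
      if (sig[g[i], g[j]] && shared) return(FALSE)
      if (!sig[g[i], g[j]] && !shared) return(FALSE)
    }
  }
  TRUE
}
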