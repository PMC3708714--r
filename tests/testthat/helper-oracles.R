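# Independent oracles used across tests: naive implementations kept
# deliberately separate from the package's optimized code paths.

# naive O(n*m) boxcar-kernel CDF with reflection at zero
naive_boxcar_cdf <- function(x, samples, h) {
  ramp <- function(u) pmin(1, pmax(0, (u + h) / (2 * h)))
  vapply(x, function(xi) mean(ramp(xi - samples) + ramp(xi + samples) - 1),
         numeric(1))
}

# Gaussian-chain (Maxwell) radial CDF with per-coordinate sd sigc
maxwell_cdf <- function(r, sigc) {
  z <- r / sigc
  pchisq(z^2, df = 3)
}

# render a point-sampled symmetric 2D Gaussian patch (the fitting model
# itself, used where a model-exact patch is wanted)
gauss_patch <- function(npx, A, x, y, sigma, B) {
  xg <- matrix(rep(0:(npx - 1), each = npx), npx, npx)
  yg <- matrix(rep(0:(npx - 1), times = npx), npx, npx)
  A * exp(-((xg - x)^2 + (yg - y)^2) / (2 * sigma^2)) + B
}

# brute-force Shea-Ackers partition sums from an independently coded
# microstate enumeration (no grouping, no log-domain tricks)
brute_force_lambda <- function(ci2_nM, G, coop, dG_oct, dG_tet, RT = 0.593) {
  c_M <- ci2_nM * 1e-9
  side <- function(prefix_idx) {
    # list of c(occ1, occ2, occ3, n_pair) for one operator triple
    out <- list()
    for (o1 in 0:1) for (o2 in 0:1) for (o3 in 0:1) {
      pairings <- list(c(0, 0))
      if (o1 && o2) pairings <- c(pairings, list(c(1, 0)))
      if (o2 && o3) pairings <- c(pairings, list(c(0, 1)))
      for (p in pairings)
        out[[length(out) + 1]] <- list(occ = c(o1, o2, o3), p12 = p[1], p23 = p[2])
    }
    out
  }
  Ls <- side(); Rs <- side()
  w_tot <- 0; w_loop <- 0; w_by_class <- c(repressed = 0, basal = 0,
                                           active_unlooped = 0, active_looped = 0)
  add <- function(occL, occR, npair, oct, tet, looped) {
    dG <- sum(occL * G[1:3]) + sum(occR * G[4:6]) + npair * coop +
      oct * dG_oct + tet * dG_tet
    i <- sum(occL) + sum(occR)
    w <- c_M^i * exp(-dG / RT)
    cls <- if (occR[3]) "repressed"
           else if (occR[1] && occR[2]) (if (looped) "active_looped" else "active_unlooped")
           else "basal"
    w_tot <<- w_tot + w
    if (looped) w_loop <<- w_loop + w
    w_by_class[cls] <<- w_by_class[cls] + w
  }
  for (l in Ls) for (r in Rs)
    add(l$occ, r$occ, l$p12 + l$p23 + r$p12 + r$p23, 0, 0, FALSE)
  # looped microstates: any pair x any pair, thirds optional, orientation x2,
  # obligate 3:3 tetramer on the 12:12 octamer
  for (lp in c("p12", "p23")) for (rp in c("p12", "p23"))
    for (l3 in 0:1) for (r3 in 0:1) for (orient in 1:2) {
      occL <- if (lp == "p12") c(1, 1, l3) else c(l3, 1, 1)
      occR <- if (rp == "p12") c(1, 1, r3) else c(r3, 1, 1)
      tet <- as.integer(lp == "p12" && rp == "p12" && l3 && r3)
      add(occL, occR, 2, 1, tet, TRUE)
    }
  list(p_loop = w_loop / w_tot, class_probs = w_by_class / w_tot)
}
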