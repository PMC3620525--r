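# Independent oracles used across tests. These deliberately share no code
# with the package implementation.

# Brute-force Benjamini-Hochberg step-up scan: sort, find the largest i with
# p(i) <= i*q/m, declare everything at or below that p significant.
bh_scan_oracle <- function(p, q) {
  m <- length(p)
  ps <- sort(p)
  ok <- which(ps <= seq_len(m) * q / m)
  if (length(ok) == 0) {
    list(k = 0L, significant = rep(FALSE, m))
  } else {
    k <- max(ok)
    list(k = k, significant = p <= ps[k])
  }
}

# Connected-component labelling by iterated minimum-label propagation: start
# with unique labels, repeatedly replace each voxel's label by the minimum
# over itself and its neighbours until a fixpoint, then renumber.
flood_fill_oracle <- function(mask, connectivity) {
  d <- dim(mask)
  idx <- which(mask != 0)
  if (length(idx) == 0) return(array(0L, dim = d))
  lab <- array(0L, dim = d)
  lab[idx] <- seq_along(idx)
  co <- arrayInd(idx, .dim = d)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nz <- rowSums(offs != 0)
  offs <- offs[switch(as.character(connectivity),
                      "6" = nz == 1, "18" = nz >= 1 & nz <= 2, "26" = nz >= 1), ,
               drop = FALSE]
  repeat {
    changed <- FALSE
    for (v in seq_along(idx)) {
      best <- lab[idx[v]]
      for (o in seq_len(nrow(offs))) {
        nb <- co[v, ] + offs[o, ]
        if (any(nb < 1) || any(nb > d)) next
        l <- lab[nb[1], nb[2], nb[3]]
        if (l > 0L && l < best) best <- l
      }
      if (best < lab[idx[v]]) {
        lab[idx[v]] <- best
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  # renumber labels to 1..n in first-appearance order
  u <- unique(lab[idx])
  lab[idx] <- match(lab[idx], u)
  lab
}

# equivalence of two labelings up to label permutation
same_partition <- function(a, b) {
  ia <- which(a > 0); ib <- which(b > 0)
  if (!identical(ia, ib)) return(FALSE)
  identical(
    split(ia, a[ia])[order(vapply(split(ia, a[ia]), min, numeric(1)))],
    split(ib, b[ib])[order(vapply(split(ib, b[ib]), min, numeric(1)))]
  )
}

# small, fast simulation configuration for unit tests
tiny_config <- function(seed = 1, n_patients = 40, ...) {
  sim_config(
    n_patients = n_patients,
    grid = voxel_grid(c(12, 12, 8)),
    tracts = list(
      tract_a = tract_spec("tract_a", center = c(3.5, 6, 4), radii = c(1.5, 2.5, 2),
                           falloff = 0.8),
      tract_b = tract_spec("tract_b", center = c(9.5, 6, 4), radii = c(1.5, 2.5, 2),
                           falloff = 0.8)
    ),
    seed = seed,
    ...
  )
}
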