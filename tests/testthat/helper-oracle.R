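# Exhaustive enumeration oracle: nested expand.grid over the bounds lattice,
# independent of the package's branch-and-bound search. Only usable at small
# bounds, which is the point.
oracle_enumerate <- function(neutral_mass, tolerance_ppm, bounds,
                             integer_dbe_only = TRUE, min_dbe = 0) {
  grid <- do.call(expand.grid, lapply(bounds, function(b) b[1]:b[2]))
  m <- element_masses()
  mass <- as.numeric(as.matrix(grid) %*% m[names(bounds)])
  tol <- tolerance_ppm * neutral_mass * 1e-6
  keep <- abs(mass - neutral_mass) <= tol & rowSums(grid) > 0
  grid <- grid[keep, , drop = FALSE]
  if (nrow(grid) == 0) return(character(0))
  getc <- function(e) if (e %in% names(grid)) grid[[e]] else 0
  d <- getc("C") - getc("H") / 2 + getc("N") / 2 + 1
  ok <- rep(TRUE, nrow(grid))
  if (integer_dbe_only) ok <- ok & abs(d - round(d)) < 1e-9
  ok <- ok & d >= min_dbe
  grid <- grid[ok, , drop = FALSE]
  if (nrow(grid) == 0) return(character(0))
  sort(vapply(seq_len(nrow(grid)), function(i) {
    v <- unlist(grid[i, ])
    format_formula(v[v > 0])
  }, character(1)))
}

# random valid neutral CHNO composition (integer DBE >= 0)
random_composition <- function(c_max = 40, n_max = 4, o_max = 15) {
  repeat {
    C <- sample(1:c_max, 1)
    N <- sample(0:n_max, 1)
    H <- sample(0:(2 * C + N + 2), 1)
    if ((H + N) %% 2 != 0) H <- H + 1
    O <- sample(0:o_max, 1)
    counts <- c(C = C, H = H, N = N, O = O)
    counts <- counts[counts > 0]
    d <- dbe(counts)
    if (d >= 0 && abs(d - round(d)) < 1e-9 && H <= 2 * C + N + 2) return(counts)
  }
}
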