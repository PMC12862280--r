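# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive (full enumeration, dense double sums, interval
# arithmetic) and share no code with the implementation they check.

# all permutations of 1..n as a matrix (n! rows)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# naive dense double-sum global Moran: I = (n/S0) sum_ij w_ij zx_i zy_j / sum zx^2
oracle_global_moran <- function(zx, zy, W) {
  n <- length(zx)
  s0 <- sum(W)
  (n / s0) * sum(W * outer(zx, zy)) / sum(zx^2)
}

# naive local Moran: I_i = zx_i * sum_j w_ij zy_j
oracle_local_moran <- function(zx, zy, W) {
  as.numeric(zx * (W %*% zy))
}

# exact conditional-permutation p for tract i on a small (n <= 7) system:
# enumerate every arrangement of the other tracts' zy values over i's
# neighbor slots; directed one-sided convention
oracle_exact_conditional_p <- function(zx, zy, nb, wts, i) {
  others <- zy[-i]
  m <- length(others)
  perms <- all_perms(m)
  k <- length(nb[[i]])
  obs <- zx[i] * sum(wts[[i]] * zy[nb[[i]]])
  stat <- apply(perms, 1L, function(p) zx[i] * sum(wts[[i]] * others[p[seq_len(k)]]))
  eps <- 1e-10 * max(1, abs(obs))  # count floating-point ties as extreme
  if (obs >= 0) mean(stat >= obs - eps) else mean(stat <= obs + eps)
}

# random grid-partition rectangles: split the unit square by random break
# points, keep a sample of cells; queen adjacency of kept cells is known
# in closed form (|di| <= 1 and |dj| <= 1), independent of any geometry code
random_grid_rectangles <- function(n_keep, nx = 6, ny = 6) {
  xs <- sort(c(0, runif(nx - 1L), 1))
  ys <- sort(c(0, runif(ny - 1L), 1))
  cells <- expand.grid(i = seq_len(ny), j = seq_len(nx))
  keep <- cells[sample.int(nrow(cells), n_keep), ]
  polys <- lapply(seq_len(n_keep), function(r) {
    i <- keep$i[r]; j <- keep$j[r]
    cbind(c(xs[j], xs[j + 1], xs[j + 1], xs[j], xs[j]),
          c(ys[i], ys[i], ys[i + 1], ys[i + 1], ys[i]))
  })
  adj <- matrix(FALSE, n_keep, n_keep)
  for (a in seq_len(n_keep)) for (b in seq_len(n_keep)) {
    if (a == b) next
    adj[a, b] <- abs(keep$i[a] - keep$i[b]) <= 1L &&
                 abs(keep$j[a] - keep$j[b]) <= 1L
  }
  list(geometry = tract_geometry(polys), adjacency = adj)
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "floodlisa", mustWork = TRUE)
}
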