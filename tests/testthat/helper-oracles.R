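# Independent brute-force oracles (direct double loops, no spatial index)
# against which the package implementations are checked on small inputs.

oracle_contacts <- function(pos, r_ext) {
  n <- nrow(pos)
  out <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt(sum((pos[i, ] - pos[j, ])^2))
      if (d < r_ext[i] + r_ext[j]) out <- rbind(out, c(i, j))
    }
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

oracle_gauss <- function(src, q, delta, tgt) {
  q <- rep_len(q, nrow(src))
  sapply(seq_len(nrow(tgt)), function(t) {
    s <- 0
    for (j in seq_len(nrow(src))) {
      s <- s + q[j] * exp(-sum((tgt[t, ] - src[j, ])^2) / delta)
    }
    s
  })
}

oracle_moran <- function(tab, radius = 15) {
  n <- nrow(tab)
  x <- as.numeric(tab$label == "stem")
  d <- as.matrix(dist(cbind(tab$x_um, tab$y_um)))
  w <- (d <= radius) * 1
  diag(w) <- 0
  deg <- rowSums(w)
  w[deg > 0, ] <- w[deg > 0, ] / deg[deg > 0]
  z <- x - mean(x)
  n * sum(w * outer(z, z)) / (sum(w) * sum(z^2))
}

oracle_entropy <- function(tab, bins = 64, range_max = NULL) {
  s <- tab[tab$label == "stem", ]
  if (is.null(range_max))
    range_max <- sqrt(diff(range(tab$x_um))^2 + diff(range(tab$y_um))^2)
  d <- as.numeric(dist(cbind(s$x_um, s$y_um)))
  idx <- pmin(floor(pmin(d, range_max) / range_max * bins) + 1, bins)
  p <- as.numeric(table(factor(idx, levels = 1:bins)))
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log(p))
}

oracle_centrality <- function(tab) {
  ctr <- c(mean(tab$x_um), mean(tab$y_um))
  d <- sqrt((tab$x_um - ctr[1])^2 + (tab$y_um - ctr[2])^2)
  stem <- tab$label == "stem"
  mean(d[stem]) / mean(d[!stem])
}

oracle_a_ss <- function(tab, r) {
  n <- nrow(tab)
  stem <- which(tab$label == "stem")
  ns <- length(stem)
  d <- as.matrix(dist(cbind(tab$x_um, tab$y_um)))
  total <- 0
  for (i in stem) {
    nb <- which(d[i, ] <= r)
    nb <- nb[nb != i]
    nt_i <- length(nb)
    ns_i <- sum(nb %in% stem)
    total <- total + if (nt_i == 0) 1 else ns_i / nt_i
  }
  (n - 1) / (ns * (ns - 1)) * total
}

# fourth-order Runge-Kutta integration of the deterministic relaxation ODE
oracle_relax_rk4 <- function(M0, P0, t_end, d0, d1, s1, n_steps = 4000) {
  h <- t_end / n_steps
  y <- c(M0, P0)
  f <- function(y) c(-d0 * y[1], s1 * y[1] - d1 * y[2])
  for (i in seq_len(n_steps)) {
    k1 <- f(y)
    k2 <- f(y + h / 2 * k1)
    k3 <- f(y + h / 2 * k2)
    k4 <- f(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y
}

# small rotated/translated copy of a table (for invariance checks)
transform_table <- function(tab, angle = 0, shift = c(0, 0)) {
  x <- tab$x_um * cos(angle) - tab$y_um * sin(angle) + shift[1]
  y <- tab$x_um * sin(angle) + tab$y_um * cos(angle) + shift[2]
  cell_table(x, y, tab$label,
             if ("radius_um" %in% names(tab)) tab$radius_um else NULL)
}
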