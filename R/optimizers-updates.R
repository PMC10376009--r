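# Canonical position-update equations of the ten population metaheuristics,
# each specialized to the unit box [0,1]^d. Every scheme receives the current
# positions P (N x d), their costs, the evaluator ev (which clips, binarizes,
# repairs, scores, and tracks the global best), the iteration counters t and
# T, a per-run scratch environment aux, and a parameter override list.
# Each returns list(P, costs) for the next iteration.

rep_row <- function(x, n) matrix(x, n, length(x), byrow = TRUE)

# Marine predators algorithm: three predation phases (Brownian, mixed,
# Levy), FADs/eddy effect, and per-agent memory saving. Constants: FADs
# probability 0.2 and phase constant P = 0.5.
up_mpa <- function(P, costs, ev, t, T, aux, par) {
  N <- nrow(P); d <- ncol(P)
  fads <- par$fads %||% 0.2
  Pc <- par$P %||% 0.5
  Elite <- rep_row(ev$best_position, N)
  CF <- (1 - t / T)^(2 * t / T)
  RB <- matrix(stats::rnorm(N * d), N, d)
  RL <- levy_steps(N, d)
  R <- matrix(stats::runif(N * d), N, d)
  Pn <- P
  if (t <= T / 3) {
    Pn <- P + Pc * R * (RB * (Elite - RB * P))
  } else if (t <= 2 * T / 3) {
    h <- seq_len(floor(N / 2)); r <- setdiff(seq_len(N), h)
    Pn[h, ] <- P[h, ] + Pc * R[h, ] * (RL[h, ] * (Elite[h, ] - RL[h, ] * P[h, ]))
    Pn[r, ] <- Elite[r, ] + Pc * CF * (RB[r, ] * (RB[r, ] * Elite[r, ] - P[r, ]))
  } else {
    Pn <- Elite + Pc * CF * (RL * (RL * Elite - P))
  }
  rr <- stats::runif(1)
  if (rr < fads) {
    U <- matrix(stats::runif(N * d) < fads, N, d)
    Pn <- Pn + CF * matrix(stats::runif(N * d), N, d) * U  # box is [0,1]
  } else {
    i1 <- sample.int(N); i2 <- sample.int(N)
    Pn <- Pn + (fads * (1 - rr) + rr) * (Pn[i1, , drop = FALSE] - Pn[i2, , drop = FALSE])
  }
  res <- ev$eval(Pn)
  worse <- res$costs > costs  # marine memory: revert agents that got worse
  res$P[worse, ] <- P[worse, ]
  res$costs[worse] <- costs[worse]
  list(P = res$P, costs = res$costs)
}

# Generalized normal distribution optimization: local exploitation samples
# around the (agent, best, mean) centroid with a generalized-normal step;
# global exploration takes fitness-directed pairwise jumps. Greedy accept.
up_gndo <- function(P, costs, ev, t, T, aux, par) {
  N <- nrow(P); d <- ncol(P)
  M <- colMeans(P)
  best <- ev$best_position
  V <- P
  for (i in seq_len(N)) {
    if (stats::runif(1) > 0.5) {
      mu <- (P[i, ] + best + M) / 3
      delta <- sqrt(((P[i, ] - mu)^2 + (best - mu)^2 + (M - mu)^2) / 3)
      l1 <- stats::runif(d); l2 <- stats::runif(d)
      a <- stats::runif(1); b <- stats::runif(1)
      eta <- if (a <= b) {
        sqrt(-log(l1)) * cos(2 * pi * l2)
      } else {
        sqrt(-log(l1)) * cos(2 * pi * l2 + pi)
      }
      V[i, ] <- mu + delta * eta
    } else {
      others <- setdiff(seq_len(N), i)
      p <- sample(others, 3L, replace = length(others) < 3L)
      v1 <- if (costs[i] < costs[p[1]]) P[i, ] - P[p[1], ] else P[p[1], ] - P[i, ]
      v2 <- if (costs[p[2]] < costs[p[3]]) P[p[2], ] - P[p[3], ] else P[p[3], ] - P[p[2], ]
      beta <- stats::runif(1)
      V[i, ] <- P[i, ] + beta * abs(stats::rnorm(1)) * v1 +
        (1 - beta) * abs(stats::rnorm(1)) * v2
    }
  }
  res <- ev$eval(V)
  worse <- res$costs > costs
  res$P[worse, ] <- P[worse, ]
  res$costs[worse] <- costs[worse]
  list(P = res$P, costs = res$costs)
}

# Slime mould algorithm: fitness-ranked oscillation weights, vibration
# parameter a = arctanh(1 - t/T), contraction parameter b = 1 - t/T, and a
# small random-restart probability z.
up_sma <- function(P, costs, ev, t, T, aux, par) {
  N <- nrow(P); d <- ncol(P)
  z <- par$z %||% 0.03
  eps <- 1e-12
  ord <- order(costs)
  bF <- costs[ord[1]]; wF <- costs[ord[N]]
  W <- matrix(1, N, d)
  half <- ceiling(N / 2)
  for (k in seq_len(N)) {
    i <- ord[k]
    lg <- log10((bF - costs[i]) / (bF - wF - eps) + 1)
    W[i, ] <- if (k <= half) 1 + stats::runif(d) * lg else 1 - stats::runif(d) * lg
  }
  a <- atanh(min(1 - t / T, 1 - eps))
  b <- 1 - t / T
  Xb <- ev$best_position
  DF <- ev$best_cost
  Pn <- P
  for (i in seq_len(N)) {
    if (stats::runif(1) < z) {
      Pn[i, ] <- stats::runif(d)
    } else {
      p <- tanh(abs(costs[i] - DF))
      vb <- stats::runif(d, -a, a)
      vc <- stats::runif(d, -b, b)
      A <- sample.int(N, 1L); B <- sample.int(N, 1L)
      r <- stats::runif(d)
      Pn[i, ] <- ifelse(r < p, Xb + vb * (W[i, ] * P[A, ] - P[B, ]), vc * P[i, ])
    }
  }
  res <- ev$eval(Pn)
  list(P = res$P, costs = res$costs)
}

# Equilibrium optimizer: equilibrium pool of the 4 best-ever agents plus
# their mean; exponential decay F with a1 = 2, generation-rate term with
# a2 = 1, generation probability 0.5.
up_eo <- function(P, costs, ev, t, T, aux, par) {
  N <- nrow(P); d <- ncol(P)
  a1 <- par$a1 %||% 2
  a2 <- par$a2 %||% 1
  GP <- par$gp %||% 0.5
  if (is.null(aux$pool)) {
    aux$pool <- matrix(NA_real_, 0, d)
    aux$pool_costs <- numeric(0)
  }
  allP <- rbind(aux$pool, P)
  allc <- c(aux$pool_costs, costs)
  keep <- order(allc)[seq_len(min(4L, length(allc)))]
  aux$pool <- allP[keep, , drop = FALSE]
  aux$pool_costs <- allc[keep]
  pool <- rbind(aux$pool, colMeans(aux$pool))
  tchar <- (1 - t / T)^(a2 * t / T)
  Pn <- P
  for (i in seq_len(N)) {
    Ceq <- pool[sample.int(nrow(pool), 1L), ]
    lambda <- stats::runif(d)
    r <- stats::runif(d)
    F <- a1 * sign(r - 0.5) * (exp(-lambda * tchar) - 1)
    r1 <- stats::runif(1); r2 <- stats::runif(1)
    GCP <- 0.5 * r1 * (r2 >= GP)
    G <- GCP * (Ceq - lambda * P[i, ]) * F
    Pn[i, ] <- Ceq + (P[i, ] - Ceq) * F + (G / lambda) * (1 - F)  # V = 1
  }
  res <- ev$eval(Pn)
  list(P = res$P, costs = res$costs)
}

# Manta-ray foraging: chain or cyclone foraging (cyclone around a random
# position early in the run, around the best later), then a somersault move
# around the best with somersault factor S = 2.
up_mrfo <- function(P, costs, ev, t, T, aux, par) {
  N <- nrow(P); d <- ncol(P)
  S <- par$somersault %||% 2
  Xb <- ev$best_position
  Pn <- P
  for (i in seq_len(N)) {
    prev <- if (i == 1L) Xb else Pn[i - 1L, ]
    r <- stats::runif(d)
    if (stats::runif(1) < 0.5) {
      r1 <- stats::runif(1)
      beta <- 2 * exp(r1 * (T - t + 1) / T) * sin(2 * pi * r1)
      if (t / T < stats::runif(1)) {
        Xr <- stats::runif(d)
        anchor <- Xr
      } else {
        anchor <- Xb
      }
      Pn[i, ] <- anchor + r * (prev - P[i, ]) + beta * (anchor - P[i, ])
    } else {
      alpha <- 2 * r * sqrt(abs(log(r)))
      Pn[i, ] <- P[i, ] + r * (prev - P[i, ]) + alpha * (Xb - P[i, ])
    }
  }
  res <- ev$eval(Pn)
  P1 <- res$P
  r2 <- matrix(stats::runif(N * d), N, d)
  r3 <- matrix(stats::runif(N * d), N, d)
  P2 <- P1 + S * (r2 * rep_row(ev$best_position, N) - r3 * P1)
  res2 <- ev$eval(P2)
  better <- res2$costs <= res$costs
  P1[better, ] <- res2$P[better, ]
  res$costs[better] <- res2$costs[better]
  list(P = P1, costs = res$costs)
}

# Atom search optimization: Lennard-Jones-style interaction among the K best
# atoms (K shrinking over time) plus a bond constraint toward the best atom;
# velocity integration. Depth weight alpha = 50, multiplier weight beta = 0.2.
up_aso <- function(P, costs, ev, t, T, aux, par) {
  N <- nrow(P); d <- ncol(P)
  alpha <- par$depth %||% 50
  beta <- par$multiplier %||% 0.2
  eps <- 1e-12
  if (is.null(aux$V)) aux$V <- matrix(0, N, d)
  spread <- max(costs) - min(costs) + eps
  Mass <- exp(-(costs - min(costs)) / spread)
  m <- Mass / sum(Mass)
  K <- max(2L, ceiling(N - (N - 2) * sqrt(t / T)))
  kbest <- order(costs)[seq_len(K)]
  G <- exp(-20 * t / T)
  lambda <- beta * G
  eta_c <- alpha * (1 - (t - 1) / T)^3 * G
  hmin <- 1.1 + 0.1 * sin(pi / 2 * t / T)
  hmax <- 1.24
  Xmean <- colMeans(P[kbest, , drop = FALSE])
  Xb <- ev$best_position
  Pn <- P
  for (i in seq_len(N)) {
    sigma <- sqrt(sum((P[i, ] - Xmean)^2)) + eps
    acc <- numeric(d)
    for (j in kbest) {
      if (j == i) next
      diff <- P[j, ] - P[i, ]
      rij <- sqrt(sum(diff^2))
      h <- min(max(rij / sigma, hmin), hmax)
      Fm <- -eta_c * (2 * h^(-13) - h^(-7))  # attraction for h above 2^(1/6)
      acc <- acc + stats::runif(1) * Fm * diff / (rij + eps)
    }
    acc <- acc / m[i] + lambda * (Xb - P[i, ]) / m[i]
    aux$V[i, ] <- stats::runif(d) * aux$V[i, ] + acc
    Pn[i, ] <- P[i, ] + aux$V[i, ]
  }
  res <- ev$eval(Pn)
  list(P = res$P, costs = res$costs)
}

# Harris hawks optimization: escape-energy schedule E = 2*E0*(1 - t/T)
# switches between exploration, soft/hard besiege, and Levy-flight rapid
# dives (dives accepted only if they improve the agent).
up_hho <- function(P, costs, ev, t, T, aux, par) {
  N <- nrow(P); d <- ncol(P)
  Xb <- ev$best_position
  Xm <- colMeans(P)
  Pn <- P
  for (i in seq_len(N)) {
    E0 <- stats::runif(1, -1, 1)
    E <- 2 * E0 * (1 - t / T)
    J <- 2 * (1 - stats::runif(1))
    if (abs(E) >= 1) {
      q <- stats::runif(1)
      k <- sample(setdiff(seq_len(N), i), 1L)
      Pn[i, ] <- if (q >= 0.5) {
        P[k, ] - stats::runif(1) * abs(P[k, ] - 2 * stats::runif(1) * P[i, ])
      } else {
        (Xb - Xm) - stats::runif(1) * stats::runif(d)  # lb + r*(ub-lb) on [0,1]
      }
    } else {
      r <- stats::runif(1)
      if (r >= 0.5 && abs(E) >= 0.5) {
        Pn[i, ] <- (Xb - P[i, ]) - E * abs(J * Xb - P[i, ])
      } else if (r >= 0.5) {
        Pn[i, ] <- Xb - E * abs(Xb - P[i, ])
      } else {
        base <- if (abs(E) >= 0.5) P[i, ] else Xm
        Y <- Xb - E * abs(J * Xb - base)
        ry <- ev$eval(matrix(Y, 1L))
        if (ry$costs[1] < costs[i]) {
          Pn[i, ] <- ry$P[1, ]
        } else {
          Z <- Y + stats::runif(d) * levy_steps(1L, d)[1, ]
          rz <- ev$eval(matrix(Z, 1L))
          Pn[i, ] <- if (rz$costs[1] < costs[i]) rz$P[1, ] else P[i, ]
        }
      }
    }
  }
  res <- ev$eval(Pn)
  list(P = res$P, costs = res$costs)
}

# Henry gas solubility optimization: two gas clusters with per-cluster Henry
# constants updated by an exponential temperature schedule; solubility-driven
# moves toward the cluster best and the global best; worst-agent
# re-initialization scaled by `constant` (default 1 = canonical fraction).
up_hgso <- function(P, costs, ev, t, T, aux, par) {
  N <- nrow(P); d <- ncol(P)
  n_types <- par$n_types %||% 2L
  const <- par$constant %||% 1
  l1 <- 5e-3; l2 <- 100; l3 <- 1e-2
  alpha <- 1; beta_c <- 1; Kh <- 1
  if (is.null(aux$cluster)) {
    aux$cluster <- rep(seq_len(n_types), length.out = N)
    aux$H <- l1 * stats::runif(n_types)
    aux$C <- l3 * stats::runif(n_types)
    aux$p <- l2 * stats::runif(N)
  }
  Temp <- exp(-t / T)
  aux$H <- aux$H * exp(-aux$C * (1 / Temp - 1 / 298.15))
  Xb <- ev$best_position
  Pn <- P
  for (j in seq_len(n_types)) {
    members <- which(aux$cluster == j)
    jb <- members[which.min(costs[members])]
    Xjb <- P[jb, ]
    for (i in members) {
      Sij <- Kh * aux$H[j] * aux$p[i]
      gamma <- beta_c * exp(-(ev$best_cost + 0.05) / (costs[i] + 0.05))
      Fd <- sample(c(-1, 1), 1L)
      r <- stats::runif(d)
      Pn[i, ] <- P[i, ] + Fd * r * gamma * (Xjb - P[i, ]) +
        Fd * r * alpha * (Sij * Xb - P[i, ])
    }
  }
  res <- ev$eval(Pn)
  Pn <- res$P; cn <- res$costs
  n_worst <- max(1L, round(N * (0.1 + stats::runif(1) * 0.1) * const))
  n_worst <- min(n_worst, N - 1L)
  worst <- order(cn, decreasing = TRUE)[seq_len(n_worst)]
  Pw <- matrix(stats::runif(n_worst * d), n_worst, d)
  rw <- ev$eval(Pw)
  Pn[worst, ] <- rw$P
  cn[worst] <- rw$costs
  list(P = Pn, costs = cn)
}

# Pathfinder algorithm: the pathfinder (global best) takes a perturbed step
# with a decaying oscillation term; followers combine attraction to a random
# peer and to the pathfinder with a decaying vibration term. Greedy accept.
up_pfa <- function(P, costs, ev, t, T, aux, par) {
  N <- nrow(P); d <- ncol(P)
  if (is.null(aux$prev_pf)) aux$prev_pf <- ev$best_position
  Xpf <- ev$best_position
  A <- stats::runif(d, -1, 1) * exp(-2 * t / T)
  cand <- Xpf + 2 * stats::runif(1) * (Xpf - aux$prev_pf) + A
  aux$prev_pf <- Xpf
  ev$eval(matrix(cand, 1L))  # pathfinder move kept only if it improves (via best tracking)
  Xpf_cur <- ev$best_position
  pf_idx <- which.min(costs)
  alpha <- stats::runif(1, 1, 2)
  beta <- stats::runif(1, 1, 2)
  Pn <- P
  for (i in setdiff(seq_len(N), pf_idx)) {
    j <- sample(setdiff(seq_len(N), i), 1L)
    Dij <- sqrt(sum((P[i, ] - P[j, ])^2))
    epsv <- (1 - t / T) * stats::runif(d, -1, 1) * Dij
    Pn[i, ] <- P[i, ] + alpha * stats::runif(1) * (P[j, ] - P[i, ]) +
      beta * stats::runif(1) * (Xpf_cur - P[i, ]) + epsv
  }
  Pn[pf_idx, ] <- Xpf_cur
  res <- ev$eval(Pn)
  worse <- res$costs > costs
  res$P[worse, ] <- P[worse, ]
  res$costs[worse] <- costs[worse]
  list(P = res$P, costs = res$costs)
}

# Poor-and-rich optimization: the fitter half (rich) is repelled from the
# best poor agent to widen the gap; the poor half moves toward a composite
# rich pattern. One-coordinate mutation with small probability; greedy accept.
up_pro <- function(P, costs, ev, t, T, aux, par) {
  N <- nrow(P); d <- ncol(P)
  pmut <- par$pmut %||% 0.1
  ord <- order(costs)
  n_rich <- floor(N / 2)
  rich <- ord[seq_len(n_rich)]
  poor <- ord[(n_rich + 1L):N]
  rich_best <- P[ord[1], ]
  rich_mean <- colMeans(P[rich, , drop = FALSE])
  rich_worst <- P[ord[n_rich], ]
  poor_best <- P[poor[1], ]
  pattern <- (rich_best + rich_mean + rich_worst) / 3
  Pn <- P
  for (i in rich) Pn[i, ] <- P[i, ] + stats::runif(1) * (P[i, ] - poor_best)
  for (i in poor) Pn[i, ] <- P[i, ] + stats::runif(1) * (pattern - P[i, ])
  for (i in seq_len(N)) {
    if (stats::runif(1) < pmut) Pn[i, sample.int(d, 1L)] <- stats::runif(1)
  }
  res <- ev$eval(Pn)
  worse <- res$costs > costs
  res$P[worse, ] <- P[worse, ]
  res$costs[worse] <- costs[worse]
  list(P = res$P, costs = res$costs)
}

.UPDATE_FNS <- list(
  mpa = up_mpa, gndo = up_gndo, sma = up_sma, eo = up_eo, mrfo = up_mrfo,
  aso = up_aso, hho = up_hho, hgso = up_hgso, pfa = up_pfa, pro = up_pro
)
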