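# Independent oracle implementations used to cross-check the package.
# Everything here is written as plain, direct code paths sharing nothing with
# the implementations under test.

# --- chains ----------------------------------------------------------------

make_chain <- function(xyz, q = NULL, h = NULL) {
  n <- nrow(xyz)
  structure(list(
    xyz = unname(as.matrix(xyz)),
    q = if (is.null(q)) rep(0, n) else q,
    h = if (is.null(h)) rep(1, n) else h,
    span = cbind(first = seq_len(n), last = seq_len(n)),
    rigid_group = rep(NA_integer_, n),
    frame = rep(list(diag(3)), n),
    local = rep(list(matrix(0, 1, 3)), n),
    pivots = if (n < 2L) data.frame(from = integer(0), frozen = logical(0),
                                    win_count = integer(0))
             else data.frame(from = seq_len(n - 1L), frozen = FALSE,
                             win_count = 0L),
    residues = rep("A", n), n_res = n, bond_length = 0.38),
    class = "coarse_chain")
}

make_random_chain <- function(n, seed) {
  set.seed(seed)
  make_chain(matrix(stats::rnorm(n * 3, sd = 1.5), n, 3),
             q = sample(c(-1, -0.5, 0, 0.5, 1), n, replace = TRUE),
             h = round(stats::runif(n, -4.5, 4.5), 2))
}

# --- brute-force pairwise forces ------------------------------------------

oracle_net_force <- function(chain, i, params) {
  F <- c(0, 0, 0)
  for (j in seq_len(nrow(chain$xyz))) {
    if (abs(i - j) <= 1L) next
    rv <- chain$xyz[i, ] - chain$xyz[j, ]
    d <- sqrt(sum(rv^2))
    u <- rv / d
    F <- F + params$ke * chain$q[i] * chain$q[j] / (params$eps_rel * d^2) * u
    if (chain$h[i] > 0)
      F <- F + params$beta * chain$q[j]^2 / d^5 * u
  }
  F
}

oracle_torque_census <- function(chain, params) {
  n <- nrow(chain$xyz)
  rows <- NULL
  for (k in which(!chain$pivots$frozen)) {
    nN <- k - 1L; nC <- n - k - 1L
    mob <- if (nN == 0L && nC == 0L) integer(0)
           else if (nC == 0L || (nN > 0L && nN < nC)) seq_len(nN)
           else (k + 2L):n
    if (length(mob) == 0L) {
      rows <- rbind(rows, c(k, 0, 0, 0, 0))
      next
    }
    u <- chain$xyz[k + 1L, ] - chain$xyz[k, ]
    u <- u / sqrt(sum(u^2))
    tv <- c(0, 0, 0); rs <- 0
    for (i in mob) {
      Fi <- oracle_net_force(chain, i, params)
      r <- chain$xyz[i, ] - chain$xyz[k, ]
      tv <- tv + c(r[2] * Fi[3] - r[3] * Fi[2],
                   r[3] * Fi[1] - r[1] * Fi[3],
                   r[1] * Fi[2] - r[2] * Fi[1])
      rs <- rs + sqrt(sum(r^2))
    }
    ta <- sum(u * tv)
    lever <- rs / length(mob)
    rows <- rbind(rows, c(k, abs(ta), abs(ta) / lever, lever, sign(ta)))
  }
  colnames(rows) <- c("pivot", "torque", "force", "lever", "sign")
  as.data.frame(rows)
}

# --- direct-scan secondary-structure oracle (4-letter alphabet) -------------

SS4_ALPHABET <- c("A", "H", "N", "D")

oracle_ss4 <- function(letters, pH = 7) {
  qtab <- c(A = 0, H = 1 / (1 + 10^(pH - 6)), N = 0,
            D = -1 / (1 + 10^(3.9 - pH)))
  htab <- c(A = 1.8, H = -3.2, N = -3.5, D = -3.5)
  q <- unname(qtab[letters]); h <- unname(htab[letters])
  philic <- h <= -3.3
  L <- length(letters)
  lab <- rep("C", L)

  helix_rule <- function(qv, hv) {
    n <- length(qv)
    a <- sum(qv)
    if (n %in% 1:2) {
      p <- prod(qv)
      return((a > 0 && a < 0.2 && p > 0) ||
             (a < -0.5 && p == 0) ||
             (qv[1] > 0.9 && sum(hv) < -0.3) ||
             (a > 1 && a < 0.5 && p < 0))
    }
    if (n %in% 3:4)
      return((a > 1 && qv[2] != qv[3]) ||
             (abs(a) < 0.5 && sum(hv) < -6))
    if (n %in% 5:6)
      return((a > 0.3 && a < 0.5) || (abs(a) > 1) ||
             all(qv > 0) || all(abs(qv) > 0.6))
    FALSE
  }

  ph_idx <- which(philic)
  if (length(ph_idx) >= 2L) {
    i <- ph_idx[1]
    repeat {
      rest <- ph_idx[ph_idx > i]
      if (length(rest) == 0L) break
      j <- rest[1]
      if (j - i <= 6L && j - i >= 2L) {
        iv <- (i + 1L):(j - 1L)
        if (helix_rule(q[iv], h[iv])) lab[i:j] <- "H"
      }
      i <- j
    }
  }

  i <- 1L
  while (i <= L - 4L) {
    w <- i:(i + 4L)
    if (all(lab[w] == "C") &&
        sum(abs(q[w])) - sum(h[w]) < 0.3 && sum(h[w]) > 0.1) {
      lab[w] <- "E"
      i <- i + 5L
    } else i <- i + 1L
  }
  lab
}

# integer (0-based) -> letters, base-4 encoding of a sequence
int_to_seq4 <- function(idx, len) {
  out <- character(len)
  for (p in seq_len(len)) {
    out[p] <- SS4_ALPHABET[idx %% 4L + 1L]
    idx <- idx %/% 4L
  }
  out
}

# --- quaternion-search RMSD oracle ------------------------------------------

quat_to_rotmat <- function(v) {
  v <- v / sqrt(sum(v^2))
  w <- v[1]; x <- v[2]; y <- v[3]; z <- v[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

oracle_rmsd_min <- function(A, B) {
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  obj <- function(v) {
    if (sum(v^2) < 1e-8) return(1e6)
    sqrt(mean(rowSums((Bc %*% t(quat_to_rotmat(v)) - Ac)^2)))
  }
  g <- seq(-1, 1, by = 0.5)
  grid <- as.matrix(expand.grid(g, g, g, g))
  grid <- grid[rowSums(grid^2) > 1e-8, ]
  vals <- apply(grid, 1, obj)
  best <- Inf
  for (s in order(vals)[1:12]) {
    r <- stats::optim(grid[s, ], obj,
                      control = list(reltol = 1e-14, maxit = 5000))
    r <- stats::optim(r$par, obj,
                      control = list(reltol = 1e-14, maxit = 5000))
    best <- min(best, r$value)
  }
  best
}
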