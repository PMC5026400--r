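## Independent brute-force reference implementations used to cross-check the
## package. Deliberately written as plain loops over the literal rules, with
## no shared code with the implementation.

## Literal pair-enumeration transition detector: pair (i-1, i) is a
## candidate when the pitch or roll change exceeds its threshold; confirmed
## when at least `confirm_adjacent` of the pairs within that distance on
## either side are also candidates; runs of consecutive confirmed pairs
## collapse to the midpoint between the first run pair's frame centres.
oracle_detect <- function(ext, cfg) {
  n <- nrow(ext)
  if (n < 2) return(numeric(0))
  is_cand <- function(j) {
    abs(ext$p[j + 1] - ext$p[j]) > cfg$theta_p ||
      abs(ext$r[j + 1] - ext$r[j]) > cfg$theta_r
  }
  cand <- sapply(seq_len(n - 1), is_cand)
  conf <- rep(FALSE, n - 1)
  for (j in seq_len(n - 1)) {
    if (!cand[j]) next
    n_ok <- 0
    for (d in seq_len(cfg$confirm_adjacent)) {
      if (j - d >= 1 && cand[j - d]) n_ok <- n_ok + 1
      if (j + d <= n - 1 && cand[j + d]) n_ok <- n_ok + 1
    }
    conf[j] <- n_ok >= cfg$confirm_adjacent
  }
  pts <- numeric(0)
  j <- 1
  while (j <= n - 1) {
    if (conf[j]) {
      c1 <- (ext$start_s[j] + ext$end_s[j]) / 2
      c2 <- (ext$start_s[j + 1] + ext$end_s[j + 1]) / 2
      pts <- c(pts, (c1 + c2) / 2)
      while (j <= n - 1 && conf[j]) j <- j + 1
    } else j <- j + 1
  }
  pts
}

## Brute-force bipartite event matcher: full overlap enumeration.
oracle_match <- function(det, ann, tol) {
  nd <- nrow(det); na <- nrow(ann)
  overlap <- matrix(FALSE, nd, na)
  for (i in seq_len(nd)) for (j in seq_len(na)) {
    overlap[i, j] <- det$start_s[i] <= ann$end_s[j] + tol &&
      det$end_s[i] >= ann$start_s[j] - tol
  }
  tp <- 0; fn <- 0
  for (j in seq_len(na)) {
    if (nd > 0 && any(overlap[, j])) tp <- tp + 1 else fn <- fn + 1
  }
  fp <- 0
  for (i in seq_len(nd)) if (na == 0 || !any(overlap[i, ])) fp <- fp + 1
  list(tp = tp, fp = fp, fn = fn)
}

## Unrolled recursive smoothing filter (scalar loop).
oracle_smooth <- function(s, alpha, init, literal = FALSE) {
  g <- numeric(length(s))
  prev <- init
  for (t in seq_along(s)) {
    g[t] <- if (literal) alpha * s[t] - (1 - alpha) * prev
            else alpha * s[t] + (1 - alpha) * prev
    prev <- g[t]
  }
  g
}

## Random feature-frame table shaped like a short trace's 2-s frames:
## a smooth orientation random walk with occasional jumps.
random_frames <- function(n_frames, step_s = 2, jump_prob = 0.1,
                          jump_scale = 40, walk_sd = 2) {
  jumps_p <- ifelse(stats::runif(n_frames) < jump_prob,
                    stats::rnorm(n_frames, 0, jump_scale), 0)
  jumps_r <- ifelse(stats::runif(n_frames) < jump_prob,
                    stats::rnorm(n_frames, 0, jump_scale), 0)
  p <- cumsum(stats::rnorm(n_frames, 0, walk_sd) + jumps_p)
  p <- pmin(pmax(p, -85), 85)
  r <- cumsum(stats::rnorm(n_frames, 0, walk_sd) + jumps_r)
  r <- pmin(pmax(r, -175), 175)
  a <- abs(stats::rnorm(n_frames, 0.02, 0.01))
  g <- invert_orientation(p, r)
  structure(
    data.frame(frame = seq_len(n_frames),
               start_s = (seq_len(n_frames) - 1) * step_s,
               end_s = seq_len(n_frames) * step_s,
               p = p, r = r, a = a,
               gx = g[, 1], gy = g[, 2], gz = g[, 3],
               m1 = 1, m2 = 1 + a^2),
    class = c("feature_frames", "data.frame"), frame_step_s = step_s)
}

## Noise-free trace holding a piecewise orientation profile: `pieces` is a
## data frame with columns dur_s, pitch, roll (constant orientation per
## piece, linearly interpolated over ramp_s seconds between pieces).
orientation_trace <- function(pieces, rate = 100, ramp_s = 0,
                              id = "synthetic") {
  p <- numeric(0); r <- numeric(0)
  for (i in seq_len(nrow(pieces))) {
    n_i <- round(pieces$dur_s[i] * rate)
    p <- c(p, rep(pieces$pitch[i], n_i))
    r <- c(r, rep(pieces$roll[i], n_i))
    if (ramp_s > 0 && i < nrow(pieces)) {
      n_r <- round(ramp_s * rate)
      p <- c(p, seq(pieces$pitch[i], pieces$pitch[i + 1], length.out = n_r))
      r <- c(r, seq(pieces$roll[i], pieces$roll[i + 1], length.out = n_r))
    }
  }
  g <- invert_orientation(p, r)
  signal_trace(g[, 1], g[, 2], g[, 3], rate_hz = rate, animal_id = id)
}

## Trace with a prescribed per-sample magnitude along +z.
magnitude_trace <- function(m, rate = 100) {
  signal_trace(rep(0, length(m)), rep(0, length(m)), m, rate_hz = rate)
}

## Random rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

## Confirmed-pair mask of the threshold rule (mirrors the confirmation
## semantics; used for the monotonicity property, which holds at pair
## level but not for run-collapsed event counts).
confirmed_pairs <- function(ext, th, ca = 1) {
  cand <- abs(diff(ext$p)) > th | abs(diff(ext$r)) > th
  np <- length(cand)
  vapply(seq_len(np), function(j) {
    if (!cand[j]) return(FALSE)
    nb <- setdiff(seq(max(1, j - ca), min(np, j + ca)), j)
    sum(cand[nb]) >= ca
  }, logical(1))
}
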