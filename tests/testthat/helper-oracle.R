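# Brute-force reference implementation of the flexible learning filter.
# Everything is written as explicit loops over grid cells, independent of the
# package's vectorized kernels, so it can serve as an oracle for exact
# agreement checks on tiny grids.

oracle_filter <- function(s, r, k_vals, a_vals, p_vals,
                          beta1 = NULL, beta2 = NULL) {
  mk <- length(k_vals); ma <- length(a_vals); mp <- length(p_vals)
  P <- array(1 / (mk * ma * mp), c(mk, ma, mp))
  n <- length(s)
  o_seq <- as.integer(s == r)
  out <- data.frame(alpha_mean = numeric(n), p_mean = numeric(n),
                    ps = numeric(n), o = o_seq, pe = numeric(n))
  sp_identity <- is.null(beta1)

  for (i in seq_len(n)) {
    if (i > 1) {
      # learning-rate transition: stay with prob k, else uniform over alpha
      Q <- array(0, c(mk, ma, mp))
      for (ki in 1:mk) for (ai in 1:ma) for (pi in 1:mp) {
        acc <- 0
        for (aj in 1:ma) {
          w <- (1 - k_vals[ki]) / ma + if (aj == ai) k_vals[ki] else 0
          acc <- acc + w * P[ki, aj, pi]
        }
        Q[ki, ai, pi] <- acc
      }
      P <- Q / sum(Q)
      # Beta-kernel propagation of p
      Q <- array(0, c(mk, ma, mp))
      for (ki in 1:mk) for (ai in 1:ma) {
        v <- 1 / a_vals[ai] - 2
        for (pi in 1:mp) {
          dens <- stats::dbeta(p_vals, p_vals[pi] * v + 1,
                               v - p_vals[pi] * v + 1)
          dens <- dens / sum(dens)
          for (pj in 1:mp) {
            Q[ki, ai, pj] <- Q[ki, ai, pj] + P[ki, ai, pi] * dens[pj]
          }
        }
      }
      P <- Q / sum(Q)
      # delta-rule drift driven by the previous outcome, linear re-binning
      o_prev <- o_seq[i - 1]
      Q <- array(0, c(mk, ma, mp))
      for (ki in 1:mk) for (ai in 1:ma) for (pi in 1:mp) {
        tgt <- p_vals[pi] + a_vals[ai] * (o_prev - p_vals[pi])
        if (tgt <= p_vals[1]) {
          Q[ki, ai, 1] <- Q[ki, ai, 1] + P[ki, ai, pi]
        } else if (tgt >= p_vals[mp]) {
          Q[ki, ai, mp] <- Q[ki, ai, mp] + P[ki, ai, pi]
        } else {
          j <- max(which(p_vals <= tgt))
          w <- (tgt - p_vals[j]) / (p_vals[j + 1] - p_vals[j])
          Q[ki, ai, j] <- Q[ki, ai, j] + (1 - w) * P[ki, ai, pi]
          Q[ki, ai, j + 1] <- Q[ki, ai, j + 1] + w * P[ki, ai, pi]
        }
      }
      P <- Q / sum(Q)
    }
    # posterior means before observing the trial
    am <- 0; pm <- 0
    for (ki in 1:mk) for (ai in 1:ma) for (pi in 1:mp) {
      am <- am + P[ki, ai, pi] * a_vals[ai]
      pm <- pm + P[ki, ai, pi] * p_vals[pi]
    }
    out$alpha_mean[i] <- am
    out$p_mean[i] <- pm
    out$ps[i] <- if (sp_identity) pm else stats::plogis(beta1 + beta2 * pm)
    out$pe[i] <- if (s[i] == 1) r[i] - pm else r[i] - (1 - pm)
    # observation update
    for (ki in 1:mk) for (ai in 1:ma) for (pi in 1:mp) {
      p <- p_vals[pi]
      sp <- if (sp_identity) p else stats::plogis(beta1 + beta2 * p)
      lik <- (1 - abs(o_seq[i] - p)) * (1 - abs(s[i] - sp))
      P[ki, ai, pi] <- P[ki, ai, pi] * lik
    }
    P <- P / sum(P)
  }
  out
}
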