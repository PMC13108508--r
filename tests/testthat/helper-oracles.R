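# Independent reference implementations used as oracles.  These are kept
# deliberately naive and separate from the package's code paths.

# Naive LZW over {0,1}: dictionary as a character vector searched linearly.
# Returns c(number of emitted codes, final dictionary size).
ref_lzw_stats <- function(bits) {
  dict <- c("0", "1")
  cur <- ""
  codes <- 0L
  for (b in as.character(bits)) {
    cand <- paste0(cur, b)
    if (cand %in% dict) {
      cur <- cand
    } else {
      codes <- codes + 1L
      dict <- c(dict, cand)
      cur <- b
    }
  }
  if (nzchar(cur)) codes <- codes + 1L
  c(codes = codes, dict = length(dict))
}

ref_lzw_rho0 <- function(bits) {
  st <- ref_lzw_stats(bits)
  st[["codes"]] * ceiling(log2(st[["dict"]])) / length(bits)
}

# Naive conditional entropy H(X_t | previous n) by enumerating contexts.
ref_entropy_rate <- function(bits, order) {
  n <- length(bits)
  if (order == 0) {
    p <- table(bits) / n
    return(-sum(p * log2(p)))
  }
  ctx <- vapply(seq_len(n - order), function(i)
    paste(bits[i:(i + order - 1)], collapse = ""), "")
  nxt <- bits[(order + 1):n]
  h <- 0
  for (cx in unique(ctx)) {
    sel <- ctx == cx
    pcx <- mean(sel)
    p <- table(nxt[sel]) / sum(sel)
    h <- h + pcx * (-sum(p * log2(p)))
  }
  h
}

# Fixed point of the autonomous (noise-free) column by damped iteration on
# the per-synapse steady states u_s* = (A_s / a_s) C_s phi(source).
ref_column_fixed_point <- function(params, ext = c(e1 = 0, e2 = 0),
                                   iter = 5000, damp = 0.05) {
  syn <- params$synapses
  sig <- sigmoid_parameters()
  u <- numeric(nrow(syn))
  pops <- c("P1", "SS", "SST", "P2", "PV")
  for (k in seq_len(iter)) {
    v <- vapply(pops, function(p) {
      idx <- syn$target == p
      s <- ifelse(syn$sign == "inhibitory", -1, 1)
      sum(s[idx] * u[idx])
    }, numeric(1))
    phi <- sigmoid_rate(v, sig)
    names(phi) <- pops
    drive <- ifelse(syn$source %in% pops, phi[syn$source], ext[syn$source])
    u_new <- (syn$A / syn$a) * syn$C * drive
    u <- (1 - damp) * u + damp * u_new
  }
  v <- vapply(pops, function(p) {
    idx <- syn$target == p
    s <- ifelse(syn$sign == "inhibitory", -1, 1)
    sum(s[idx] * u[idx])
  }, numeric(1))
  list(u = u, v = v)
}

# Build a synthetic lanmm_sweep object from given alpha/gamma profiles.
fake_sweep <- function(gains, p1_alpha, p2_gamma) {
  stopifnot(length(gains) == length(p1_alpha),
            length(gains) == length(p2_gamma))
  bands <- band_definitions()
  rows <- lapply(seq_along(gains), function(i) {
    psd1 <- c(delta = 0, theta = 0, alpha = p1_alpha[i], beta = 0, gamma = 0)
    psd2 <- c(delta = 0, theta = 0, alpha = 0, beta = 0, gamma = p2_gamma[i])
    data.frame(gain = gains[i],
               population = rep(c("P1", "P2"), each = 5),
               band = rep(bands$name, 2),
               mean_psd = c(psd1, psd2), diverged = FALSE,
               stringsAsFactors = FALSE)
  })
  structure(list(table = do.call(rbind, rows), gains = gains,
                 cfg = sweep_config(g_lo = min(gains), g_hi = max(gains),
                                    step = diff(gains[1:2])),
                 seed = 0),
            class = "lanmm_sweep")
}

# A minimal network-time-series stand-in for EEG-level tests.
fake_network_ts <- function(vP1, vP2, fs = 1000, discard = 0) {
  labels <- paste0("parcel_", seq_len(ncol(vP1)))
  colnames(vP1) <- colnames(vP2) <- labels
  structure(list(vP1 = vP1, vP2 = vP2, fs = fs,
                 duration = nrow(vP1) / fs, discard = discard, seed = 0,
                 psi = 0, labels = labels),
            class = "lanmm_network_ts")
}

# Zero-noise parameter variant (constant external drive).
quiet_params <- function(mean1 = 0, mean2 = 0) {
  p <- lanmm_parameters()
  p$inputs$mean <- c(mean1, mean2)
  p$inputs$sd <- c(0, 0)
  p
}
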