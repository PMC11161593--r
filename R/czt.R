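# Bluestein chirp-z evaluation of centered Fourier sums.
#
# The focal-field computation needs G[m] = sum_j f[j] exp(i * psi * jc * mc)
# with jc = j - (N-1)/2 and mc = m - (M-1)/2 (both grids centered), for an
# arbitrary frequency step psi = k * ds * dx. A plain FFT would force
# dx = 2*pi/(k*ds*N); Bluestein's identity jc*mc = (jc^2 + mc^2 -
# (jc-mc)^2)/2 turns the sum into a linear convolution of chirped sequences,
# evaluated with FFTs of length >= N + M - 1, for any psi.

next_pow2 <- function(n) 2^ceiling(log2(n))

# Chirp-z along the first dimension of a matrix (columns transformed
# independently). `f` is N x C complex; returns M x C.
czt_mat <- function(f, m_out, psi) {
  f <- as.matrix(f)
  n <- nrow(f)
  jc <- (0:(n - 1)) - (n - 1) / 2
  mc <- (0:(m_out - 1)) - (m_out - 1) / 2
  a <- exp(1i * psi * jc^2 / 2)          # input chirp
  b <- exp(1i * psi * mc^2 / 2)          # output chirp
  L <- next_pow2(n + m_out - 1L)
  # g_t = exp(-i psi (t - delta)^2 / 2) at t = m - j  (delta = (M-N)/2),
  # wrapped into [0, L) for circular convolution == linear convolution.
  delta <- (m_out - n) / 2
  g <- complex(length.out = L)
  idx_pos <- 0:(m_out - 1)
  g[idx_pos + 1L] <- exp(-1i * psi * (idx_pos - delta)^2 / 2)
  idx_neg <- 1:(n - 1)
  g[L - idx_neg + 1L] <- exp(-1i * psi * (-idx_neg - delta)^2 / 2)
  fg <- stats::fft(g)
  fa <- stats::mvfft(rbind(f * a, matrix(0i, L - n, ncol(f))))
  conv <- stats::mvfft(fa * fg, inverse = TRUE) / L
  sweep(conv[seq_len(m_out), , drop = FALSE], 1L, b, `*`)
}

# Two-dimensional centered chirp-z: G[mx,my] =
#   sum_{j,l} F[j,l] exp(i psi_x jc mxc) exp(i psi_y lc myc)
czt2d <- function(f, mx, my, psi_x, psi_y) {
  g <- czt_mat(f, mx, psi_x)
  t(czt_mat(t(g), my, psi_y))
}
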