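# Independent cross-check oracle: sequential two-pressure (IMPES)
# formulation of the two-phase system. Each step solves the incompressible
# pressure equation for the wetting pressure on the cells (air pressure
# following as p_n = p_w + pc), computes the wetting Darcy flux from the
# solved pressure field, and advances the saturation explicitly. This is a
# deliberately different route from the package's single-saturation-
# equation kernel: same physics, different unknowns and assembly.

impes_simulate <- function(K, eps_p, mu_w, mu_n, pec, lp, s0, L0, n_cells,
                           out_times, ds_max = 0.01) {
  dx <- L0 / n_cells
  clamp01 <- function(x) pmin(pmax(x, 0), 1)
  krw <- function(se) clamp01(se)^((2 + 3 * lp) / lp)
  krn <- function(se) {
    se <- clamp01(se)
    (1 - se)^2 * (1 - se^((2 + lp) / lp))
  }
  pcf <- function(se) pec * pmax(se, 1e-9)^(-1 / lp)
  mdpc <- function(se) (pec / lp) * pmax(se, 1e-9)^(-1 / lp - 1)

  S <- rep(s0, n_cells)
  t <- 0
  iout <- 1
  Sout <- matrix(NA_real_, length(out_times), n_cells)
  while (iout <= length(out_times)) {
    t_next <- out_times[iout]
    if (t >= t_next - 1e-9) {
      Sout[iout, ] <- S
      iout <- iout + 1
      next
    }
    n <- n_cells
    # faces 1..n+1; left ghost state is the reservoir (S = 1)
    SL <- c(1, S)
    SR <- c(S, S[n])
    Sf <- (SL + SR) / 2
    lw_f <- krw(Sf) / mu_w
    ln_f <- krn(Sf) / mu_n
    lt_f <- lw_f + ln_f
    h <- c(dx / 2, rep(dx, n - 1), dx / 2)
    pc_cell <- pcf(S)
    # pc jump across each face (outlet face: zero, sealed)
    dpc_face <- c(pc_cell[1] - pec, diff(pc_cell), 0)
    Tt <- K * lt_f / h
    Gc <- K * ln_f * dpc_face / h
    # total flux at face j: F = -Tt_j (p_R - p_L) - Gc_j, zero at outlet;
    # cell balance F_j - F_{j+1} = 0 with inlet Dirichlet p_w = 0
    A <- matrix(0, n, n)
    b <- numeric(n)
    for (i in seq_len(n)) {
      if (i == 1) {
        A[1, 1] <- A[1, 1] + Tt[1]
        b[1] <- b[1] - Gc[1]
      } else {
        A[i, i] <- A[i, i] + Tt[i]
        A[i, i - 1] <- A[i, i - 1] - Tt[i]
        b[i] <- b[i] - Gc[i]
      }
      if (i < n) {
        A[i, i] <- A[i, i] + Tt[i + 1]
        A[i, i + 1] <- A[i, i + 1] - Tt[i + 1]
        b[i] <- b[i] + Gc[i + 1]
      }
    }
    p <- solve(A, b)
    dp_face <- c(p[1] - 0, diff(p), 0)
    Fw <- -K * lw_f * dp_face / h
    Fw[n + 1] <- 0
    div <- (Fw[1:n] - Fw[2:(n + 1)]) / (eps_p * dx)
    Gmax <- max((lw_f * ln_f / pmax(lt_f, 1e-300)) * mdpc(Sf))
    dt_stab <- 0.4 * eps_p * dx^2 / (2 * K * max(Gmax, 1e-300))
    dt_ds <- ds_max / max(abs(div), 1e-300)
    dt <- min(dt_stab, dt_ds, t_next - t)
    S <- clamp01(S + dt * div)
    t <- t + dt
  }
  list(x = (seq_len(n_cells) - 0.5) * dx, times = out_times, S = Sout)
}

impes_front <- function(res, threshold, L0) {
  vapply(seq_along(res$times), function(i) {
    xs <- res$x
    Ss <- res$S[i, ]
    above <- Ss >= threshold
    if (!above[1]) return(0)
    j <- max(which(above))
    if (j == length(Ss)) return(L0)
    xs[j] + (Ss[j] - threshold) / (Ss[j] - Ss[j + 1]) * (xs[j + 1] - xs[j])
  }, numeric(1))
}
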