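# Independent fixed-step Euler oracles, written directly from the reaction
# scheme (binding, dissociation, stepwise ubiquitin transfer, degradation at
# four ubiquitins, APC/C input).  Deliberately separate from the package's
# solver path.  Scalar state variables keep the tight loop affordable in R.

eulerOneSubstrate <- function(ka, kd, kc, e, pA, S0 = 200,
                              mode = "linear", Aconst = 100,
                              horizon = 600, dt = 1e-3, outStep = 1) {
  nOut <- floor(horizon / outStep) + 1L
  every <- round(outStep / dt)
  out <- matrix(NA_real_, nOut, 11,
                dimnames = list(NULL, c("A", paste0("S", 0:4),
                                        paste0("AS", 0:4))))
  A <- if (mode == "constant") Aconst else 0
  s0 <- S0; s1 <- 0; s2 <- 0; s3 <- 0; s4 <- 0
  a0 <- 0; a1 <- 0; a2 <- 0; a3 <- 0; a4 <- 0
  out[1, ] <- c(A, s0, s1, s2, s3, s4, a0, a1, a2, a3, a4)
  row <- 2L
  pTerm <- if (mode == "linear") pA else 0
  nSteps <- round(horizon / dt)
  for (n in seq_len(nSteps)) {
    b0 <- ka * A * s0; b1 <- ka * A * s1; b2 <- ka * A * s2
    b3 <- ka * A * s3; b4 <- ka * A * s4
    d0 <- kd * a0; d1 <- kd * a1; d2 <- kd * a2; d3 <- kd * a3; d4 <- kd * a4
    c0 <- kc * a0; c1 <- kc * a1; c2 <- kc * a2; c3 <- kc * a3
    An <- A + dt * (pTerm - (b0 + b1 + b2 + b3 + b4) +
                    (d0 + d1 + d2 + d3 + d4) + e * a4)
    s0n <- s0 + dt * (-b0 + d0)
    s1n <- s1 + dt * (-b1 + d1)
    s2n <- s2 + dt * (-b2 + d2)
    s3n <- s3 + dt * (-b3 + d3)
    s4n <- s4 + dt * (-b4 + d4 - e * s4)
    a0n <- a0 + dt * (b0 - d0 - c0)
    a1n <- a1 + dt * (b1 - d1 - c1 + c0)
    a2n <- a2 + dt * (b2 - d2 - c2 + c1)
    a3n <- a3 + dt * (b3 - d3 - c3 + c2)
    a4n <- a4 + dt * (b4 - d4 + c3 - e * a4)
    A <- An; s0 <- s0n; s1 <- s1n; s2 <- s2n; s3 <- s3n; s4 <- s4n
    a0 <- a0n; a1 <- a1n; a2 <- a2n; a3 <- a3n; a4 <- a4n
    if (n %% every == 0L && row <= nOut) {
      out[row, ] <- c(A, s0, s1, s2, s3, s4, a0, a1, a2, a3, a4)
      row <- row + 1L
    }
  }
  list(times = seq(0, horizon, by = outStep), conc = out,
       total = rowSums(out[, 2:11]))
}

eulerTwoSubstrate <- function(ka, kdS, kcS, kdC, kcC, e, pA,
                              S0 = 200, C0 = 200, mode = "linear",
                              Aconst = 100, horizon = 600, dt = 1e-3,
                              outStep = 1) {
  nOut <- floor(horizon / outStep) + 1L
  every <- round(outStep / dt)
  nm <- c("A", paste0("S", 0:4), paste0("AS", 0:4),
          paste0("C", 0:4), paste0("AC", 0:4))
  out <- matrix(NA_real_, nOut, 21, dimnames = list(NULL, nm))
  A <- if (mode == "constant") Aconst else 0
  S <- c(S0, 0, 0, 0, 0); AS <- numeric(5)
  C <- c(C0, 0, 0, 0, 0); AC <- numeric(5)
  out[1, ] <- c(A, S, AS, C, AC)
  row <- 2L
  pTerm <- if (mode == "linear") pA else 0
  for (n in seq_len(round(horizon / dt))) {
    bS <- ka * A * S; dS <- kdS * AS
    bC <- ka * A * C; dC <- kdC * AC
    cS <- kcS * AS[1:4]; cC <- kcC * AC[1:4]
    An <- A + dt * (pTerm - sum(bS) - sum(bC) + sum(dS) + sum(dC) +
                    e * (AS[5] + AC[5]))
    Sn <- S + dt * (-bS + dS); Sn[5] <- Sn[5] - dt * e * S[5]
    ASn <- AS + dt * (bS - dS)
    ASn[1:4] <- ASn[1:4] - dt * cS
    ASn[2:5] <- ASn[2:5] + dt * cS
    ASn[5] <- ASn[5] - dt * e * AS[5]
    Cn <- C + dt * (-bC + dC); Cn[5] <- Cn[5] - dt * e * C[5]
    ACn <- AC + dt * (bC - dC)
    ACn[1:4] <- ACn[1:4] - dt * cC
    ACn[2:5] <- ACn[2:5] + dt * cC
    ACn[5] <- ACn[5] - dt * e * AC[5]
    A <- An; S <- Sn; AS <- ASn; C <- Cn; AC <- ACn
    if (n %% every == 0L && row <= nOut) {
      out[row, ] <- c(A, S, AS, C, AC)
      row <- row + 1L
    }
  }
  list(times = seq(0, horizon, by = outStep), conc = out,
       totalS = rowSums(out[, 2:11]), totalC = rowSums(out[, 12:21]))
}

# random valid one-substrate parameter sets for property-style tests
randomRateParams <- function(n, mode = "linear", e = 1000) {
  lapply(seq_len(n), function(i)
    RateParams(ka = 10^runif(1, -4, 0), kd = 10^runif(1, -2, 2),
               kc = 10^runif(1, -2, 2), e = e,
               pA = runif(1, 0.01, 0.2), Aconst = runif(1, 20, 200),
               S0 = runif(1, 50, 400), apcMode = mode))
}
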