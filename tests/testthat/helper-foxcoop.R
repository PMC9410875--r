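# Shared fixtures and independent oracles used across the suite.

P53_16MER <- "AAATATTTATTATCGA"
DBE2_16MER <- "CAAAATGTAAACAAGT"
FBE <- "RYAAAYA"

# Brute-force scanner oracle: tests every window on both strands with a
# from-scratch IUPAC table, independent of scan_motif internals.
brute_scan <- function(bases, pattern) {
  sets <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T")
  )
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  pc <- strsplit(pattern, "")[[1]]
  w <- length(pc)
  L <- nchar(bases)
  ok <- function(site) {
    sc <- strsplit(site, "")[[1]]
    if (any(sc == "N")) return(FALSE)
    all(mapply(function(s, p) s %in% sets[[p]], sc, pc))
  }
  out <- NULL
  for (s in 0:(L - w)) {
    win <- substr(bases, s + 1, s + w)
    rc <- paste(rev(comp[strsplit(win, "")[[1]]]), collapse = "")
    if (ok(win)) out <- rbind(out, data.frame(start = s, strand = "+"))
    if (ok(rc)) out <- rbind(out, data.frame(start = s, strand = "-"))
  }
  out
}

# Independent 4-microstate Boltzmann enumeration oracle for the two-site
# model: weights of {empty, site1 only, site2 only, both}.
boltzmann_fractions <- function(K1, K2, omega, p) {
  w <- c(1, K1 * p, K2 * p, omega * K1 * K2 * p^2)
  Z <- sum(w)
  c(f0 = w[1] / Z, f1 = (w[2] + w[3]) / Z, f2 = w[4] / Z)
}

# Random rigid-body motion of a nucleic structure (isometry checks).
apply_isometry <- function(struct, seed = 1) {
  withr::with_seed(seed, {
    angles <- runif(3, 0, 2 * pi)
    shift <- runif(3, -50, 50)
  })
  rx <- function(a) matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)), 3, byrow = TRUE)
  rz <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, byrow = TRUE)
  R <- rz(angles[1]) %*% rx(angles[2]) %*% rz(angles[3])
  xyz <- as.matrix(struct$atoms[, c("x", "y", "z")]) %*% t(R)
  out <- struct
  out$atoms$x <- xyz[, 1] + shift[1]
  out$atoms$y <- xyz[, 2] + shift[2]
  out$atoms$z <- xyz[, 3] + shift[3]
  out
}
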