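# Shared in-code fixtures: published score tables and small builders.

# Primary-screen best-pose docking characteristics of the twelve purchased
# compounds (binding score, crash penalty, polar score) against the
# reference target.
primary_screen_scores <- data.frame(
  compound_id = c("A01", "B01", "C01", "D01", "E01", "F01", "G01", "H01",
                  "I01", "J01", "K01", "L01"),
  bs    = c(7.56, 7.71, 8.09, 7.63, 8.36, 7.78, 7.81, 7.79, 7.76, 8.51,
            7.58, 7.66),
  crash = c(-1.12, -1.66, -1.66, -1.11, -1.27, -1.04, -1.77, -0.99, -1.72,
            -0.85, -1.4, -1.32),
  polar = c(6.96, 8.67, 6.9, 7.57, 6.05, 6.62, 4.94, 5.98, 8.99, 6.87,
            8.94, 6.92),
  stringsAsFactors = FALSE)

# Re-screen summary rows: best STAT1 binding score and the CBAV values
# against STAT2 / STAT3 for the similarity-screen candidates.
rescreen_cbav <- data.frame(
  compound_id = c("C01", "E01", "F01", "C01L_A03", "C01L_B03", "C01L_C03",
                  "C01L_D03", "C01L_E03", "C01L_F03"),
  bs_stat1   = c(6.73, 6.95, 6.38, 9.84, 8.31, 7.08, 7.30, 8.01, 8.23),
  cbav_stat2 = c(1.74, -1.65, -0.09, 3.60, 2.19, 0.70, 1.50, 2.94, 3.36),
  cbav_stat3 = c(2.08, -0.73, -0.19, 4.14, 1.19, 1.00, 1.78, 2.68, 0.22),
  stringsAsFactors = FALSE)

# Build a flags-dialect pose set for one compound x target from exclusive
# pocket-class counts (ranked by descending bs).
make_pose_set <- function(compound_id = "CMP", target_id = "STAT1",
                          n_both = 0, n_py0 = 0, n_pyx = 0, n_neither = 0,
                          bs_top = 8) {
  cls <- c(rep("BOTH", n_both), rep("PY0_ONLY", n_py0),
           rep("PYX_ONLY", n_pyx), rep("NEITHER", n_neither))
  n <- length(cls)
  data.frame(
    compound_id = compound_id, target_id = target_id, pose_rank = seq_len(n),
    bs = bs_top - 0.05 * (seq_len(n) - 1), crash = -1, polar_score = 6,
    occupies_py0 = as.integer(cls %in% c("BOTH", "PY0_ONLY")),
    occupies_pyx = as.integer(cls %in% c("BOTH", "PYX_ONLY")),
    stringsAsFactors = FALSE)
}

# A tiny deterministic PWM for oracle tests (width 4).
toy_pwm <- function() {
  counts <- matrix(c(8, 1, 1, 0,   # A
                     1, 8, 0, 1,   # C
                     1, 0, 8, 1,   # G
                     0, 1, 1, 8),  # T
                   nrow = 4, byrow = TRUE,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm_model(counts, matrix_id = "TOY")
}

# Independent (test-side) similarity score: explicit per-position lookup.
oracle_mss <- function(pwm, window) {
  b <- strsplit(window, "")[[1]]
  s <- 0
  for (j in seq_along(b)) {
    w <- pwm$weights[, j]
    s <- s + if (b[j] %in% names(w)) w[[b[j]]] else min(w)
  }
  (s - pwm$s_min) / (pwm$s_max - pwm$s_min)
}

# Independent brute-force scan over both strands.
oracle_scan_max <- function(seq, pwm) {
  rc <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s),
                                       "")[[1]]), collapse = "")
  n <- nchar(seq); w <- pwm$width
  best <- -Inf
  for (i in 1:(n - w + 1)) {
    win <- substr(seq, i, i + w - 1)
    best <- max(best, oracle_mss(pwm, win), oracle_mss(pwm, rc(win)))
  }
  best
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
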